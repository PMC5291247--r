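#' Spin-label sites and simulated electron ensembles
#'
#' A `label_site` names a labeling position: monofunctional nitroxide (R1,
#' one cysteine anchor) or bifunctional bis-nitroxide (Rx2, bridging two
#' cysteines, e.g. across a dimer 2-fold). The simulated ensemble represents
#' the unpaired-electron (N-O midpoint proxy) positions as a weighted point
#' cloud; no label atoms are added to the host body.
#'
#' @param kind "R1" or "Rx2".
#' @param chain chain id of the (first) anchor.
#' @param resnum residue number of the (first) anchor.
#' @param chain2,resnum2 second anchor (Rx2 only).
#' @param label free-text site name, e.g. "H3 Q125R1".
#' @return object of class `label_site`.
#' @export
label_site <- function(kind = c("R1", "Rx2"), chain, resnum,
                       chain2 = NULL, resnum2 = NULL, label = NULL) {
  kind <- match.arg(kind)
  if (kind == "Rx2" && (is.null(chain2) || is.null(resnum2)))
    stop("Rx2 sites need two anchors")
  if (kind == "R1" && !is.null(chain2))
    stop("R1 sites have exactly one anchor")
  if (is.null(label))
    label <- sprintf("%s%s%s", chain, resnum, kind)
  structure(list(kind = kind, chain = chain, resnum = resnum,
                 chain2 = chain2, resnum2 = resnum2, label = label),
            class = "label_site")
}

#' Accessible-volume sampling parameters
#'
#' Defaults follow a MTSSLwizard-style accessible-volume model: electron
#' positions on shells 4--12 A from the anchor C-beta, biased away from the
#' backbone, rejected within 3 A of any host heavy atom.
#'
#' @param r_min,r_max shell radii from C-beta, Angstrom.
#' @param clash_cutoff minimum allowed distance to host heavy atoms, Angstrom.
#' @param n_samples candidate positions drawn.
#' @param backbone_cos_min minimum cosine between the candidate direction and
#'   the CA->CB vector; -0.2 admits a wide cone away from the backbone.
#' @return parameter list.
#' @export
r1_params <- function(r_min = 4, r_max = 12, clash_cutoff = 3.0,
                      n_samples = 5000, backbone_cos_min = -0.2) {
  list(r_min = r_min, r_max = r_max, clash_cutoff = clash_cutoff,
       n_samples = n_samples, backbone_cos_min = backbone_cos_min)
}

#' Bifunctional (Rx2) sampling parameters
#'
#' @param b_min,b_max bridgeable C-beta--C-beta separation, Angstrom (tether
#'   geometry of the bis-nitroxide; a tunable, not a measured value).
#' @param t_min,t_max electron distance from each anchor C-beta, Angstrom.
#' @param asym_tol maximum |d1 - d2| between the electron-anchor distances,
#'   Angstrom (keeps the ensemble near the bisector plane).
#' @param clash_cutoff,n_samples as in [r1_params()].
#' @return parameter list.
#' @export
rx2_params <- function(b_min = 5, b_max = 14, t_min = 4, t_max = 10,
                       asym_tol = 1.5, clash_cutoff = 3.0, n_samples = 5000) {
  list(b_min = b_min, b_max = b_max, t_min = t_min, t_max = t_max,
       asym_tol = asym_tol, clash_cutoff = clash_cutoff,
       n_samples = n_samples)
}

new_spin_ensemble <- function(site, positions, weights = NULL) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1L) stop("empty spin ensemble")
  if (is.null(weights)) weights <- rep(1 / nrow(positions), nrow(positions))
  weights <- weights / sum(weights)
  structure(list(site = site, positions = positions, weights = weights),
            class = "spin_ensemble")
}

#' @export
print.spin_ensemble <- function(x, ...) {
  cat(sprintf("<spin_ensemble '%s'> %d conformers, centroid (%s) A\n",
              x$site$label, nrow(x$positions),
              paste(signif(colSums(x$positions * x$weights), 4),
                    collapse = ", ")))
  invisible(x)
}

# residue geometry helpers --------------------------------------------------

residue_anchor_frame <- function(body, chain, resnum) {
  res <- select_atoms(body, chain = chain, resnum = resnum)
  if (nrow(res) == 0L)
    stop(sprintf("site residue %s:%s absent from body '%s'", chain, resnum,
                 body$name))
  get1 <- function(nm) {
    r <- res[res$atom == nm, , drop = FALSE]
    if (nrow(r) == 0L) return(NULL)
    c(r$x[1], r$y[1], r$z[1])
  }
  ca <- get1("CA"); n <- get1("N"); cc <- get1("C"); cb <- get1("CB")
  if (is.null(ca) || is.null(n) || is.null(cc))
    stop("site residue lacks backbone atoms N/CA/C")
  if (is.null(cb)) cb <- pseudo_cbeta(n, ca, cc)
  list(ca = ca, cb = cb, n = n, c = cc)
}

# ideal tetrahedral C-beta from backbone geometry (for Gly sites)
pseudo_cbeta <- function(n, ca, cc) {
  b1 <- n - ca; b2 <- cc - ca
  b1 <- b1 / sqrt(sum(b1^2)); b2 <- b2 / sqrt(sum(b2^2))
  bis <- -(b1 + b2); bis <- bis / sqrt(sum(bis^2))
  perp <- pracma_cross(b1, b2); perp <- perp / sqrt(sum(perp^2))
  # 1.53 A bond, ~54.75 deg out of the N-CA-C plane
  ca + 1.53 * (cos(0.9557) * bis + sin(0.9557) * perp)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# uniform directions on the unit sphere, n x 3
runif_sphere <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# right-handed orthonormal frame attached to a residue: z along CA->CB,
# x from CA->N orthogonalized, y = z cross x. Sampling in this frame makes
# labeling covariant with rigid motions of the host body.
residue_local_frame <- function(fr) {
  z <- fr$cb - fr$ca; z <- z / sqrt(sum(z^2))
  x <- fr$n - fr$ca; x <- x - sum(x * z) * z
  x <- x / sqrt(sum(x^2))
  y <- pracma_cross(z, x)
  cbind(x, y, z)
}

# host atoms relevant for clash checks: all heavy atoms except the labeled
# residue's own side chain (the native side chain is replaced by the label)
clash_environment <- function(body, exclude) {
  a <- body$atoms
  excl <- rep(FALSE, nrow(a))
  for (e in exclude) {
    excl <- excl | (a$chain == e$chain & a$resnum == e$resnum &
                      !(a$atom %in% BACKBONE_ATOMS))
  }
  as.matrix(a[!excl, c("x", "y", "z")])
}

min_dist_to_set <- function(points, set) {
  # for each row of points, min distance to any row of set
  if (nrow(set) == 0L) return(rep(Inf, nrow(points)))
  d2 <- outer(rowSums(points^2), rep(1, nrow(set))) +
    outer(rep(1, nrow(points)), rowSums(set^2)) -
    2 * points %*% t(set)
  sqrt(pmax(apply(d2, 1L, min), 0))
}

#' Simulate a monofunctional (R1) spin-label ensemble
#'
#' Accessible-volume model: candidate electron positions are drawn on shells
#' `r_min..r_max` from the anchor C-beta (pseudo-C-beta constructed for Gly),
#' directions biased away from the backbone, and candidates clashing with
#' host heavy atoms (excluding the labeled residue's own side chain) are
#' rejected. Survivors are uniformly weighted. Uses R's RNG; seed outside
#' for determinism.
#'
#' @param body host `rigid_body`.
#' @param site `label_site` of kind R1.
#' @param params see [r1_params()].
#' @return `spin_ensemble`.
#' @export
attach_r1_ensemble <- function(body, site, params = r1_params()) {
  if (site$kind != "R1") stop("site is not R1")
  fr <- residue_anchor_frame(body, site$chain, site$resnum)
  M <- residue_local_frame(fr)
  dirs <- runif_sphere(params$n_samples)  # in the residue-local frame
  keep <- dirs[, 3] >= params$backbone_cos_min  # cone about the CA->CB axis
  dirs <- dirs[keep, , drop = FALSE]
  radii <- stats::runif(nrow(dirs), params$r_min, params$r_max)
  cand <- sweep((dirs * radii) %*% t(M), 2L, fr$cb, "+")
  env <- clash_environment(body, list(site))
  ok <- min_dist_to_set(cand, env) >= params$clash_cutoff
  if (!any(ok))
    stop(sprintf("unlabelable site %s: all candidates clash", site$label))
  new_spin_ensemble(site, cand[ok, , drop = FALSE])
}

#' Simulate a bifunctional (Rx2) spin-label ensemble
#'
#' The bis-nitroxide bridges two cysteine anchors; electron positions are
#' sampled near the perpendicular bisector plane of the two anchor C-beta
#' atoms at tether-consistent distances from both, then clash-filtered. The
#' resulting ensemble is compact (the label is conformationally restricted).
#'
#' @param body host `rigid_body`.
#' @param site `label_site` of kind Rx2.
#' @param params see [rx2_params()].
#' @return `spin_ensemble`.
#' @export
attach_rx2_label <- function(body, site, params = rx2_params()) {
  if (site$kind != "Rx2") stop("site is not Rx2")
  f1 <- residue_anchor_frame(body, site$chain, site$resnum)
  f2 <- residue_anchor_frame(body, site$chain2, site$resnum2)
  sep <- sqrt(sum((f1$cb - f2$cb)^2))
  if (sep < params$b_min || sep > params$b_max)
    stop(sprintf("unbridgeable site %s: C-beta separation %.1f A outside [%g, %g]",
                 site$label, sep, params$b_min, params$b_max))
  mid <- (f1$cb + f2$cb) / 2
  # sample around the midpoint in a frame built from the two anchors (z along
  # the inter-anchor axis, x from anchor-1 CA): covariant with rigid motion
  z <- (f2$cb - f1$cb) / sep
  x <- f1$ca - mid; x <- x - sum(x * z) * z; x <- x / sqrt(sum(x^2))
  M <- cbind(x, pracma_cross(z, x), z)
  span <- params$t_max
  local <- runif_sphere(params$n_samples) *
    stats::runif(params$n_samples, 0, span)
  cand <- sweep(local %*% t(M), 2L, mid, "+")
  d1 <- sqrt(rowSums(sweep(cand, 2L, f1$cb)^2))
  d2 <- sqrt(rowSums(sweep(cand, 2L, f2$cb)^2))
  ok <- abs(d1 - d2) <= params$asym_tol &
    d1 >= params$t_min & d1 <= params$t_max &
    d2 >= params$t_min & d2 <= params$t_max
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L)
    stop(sprintf("unbridgeable site %s: no tether-consistent positions", site$label))
  env <- clash_environment(body, list(site, list(chain = site$chain2,
                                                 resnum = site$resnum2)))
  keep <- min_dist_to_set(cand, env) >= params$clash_cutoff
  if (!any(keep))
    stop(sprintf("unlabelable site %s: all candidates clash", site$label))
  new_spin_ensemble(site, cand[keep, , drop = FALSE])
}

#' Transform a spin ensemble with a rigid motion
#' @param ensemble `spin_ensemble`.
#' @param tr `spindock_transform`.
#' @return transformed `spin_ensemble`.
#' @export
transform_ensemble <- function(ensemble, tr) {
  ensemble$positions <- apply_transform(tr, ensemble$positions)
  ensemble
}

#' Down-sample a spin ensemble (for fast docking energetics)
#' @param ensemble `spin_ensemble`.
#' @param n maximum conformers kept (evenly strided; weights renormalized).
#' @return `spin_ensemble`.
#' @export
thin_ensemble <- function(ensemble, n = 64L) {
  m <- nrow(ensemble$positions)
  if (m <= n) return(ensemble)
  idx <- unique(round(seq(1L, m, length.out = n)))
  new_spin_ensemble(ensemble$site, ensemble$positions[idx, , drop = FALSE],
                    ensemble$weights[idx])
}

#' Inter-ensemble distance statistics
#'
#' Computes all weighted pairwise distances between two electron ensembles
#' and returns the weighted mean, the histogram modal distance, and the
#' histogram itself.
#'
#' @param a,b `spin_ensemble` objects.
#' @param breaks histogram bin width in Angstrom.
#' @return list with `mean` (A), `modal` (A), `histogram` (data.frame with
#'   `mid`, `density`).
#' @export
ensemble_distance <- function(a, b, breaks = 0.5) {
  if (!inherits(a, "spin_ensemble") || !inherits(b, "spin_ensemble"))
    stop("need two spin_ensemble objects")
  pa <- a$positions; pb <- b$positions
  d2 <- outer(rowSums(pa^2), rep(1, nrow(pb))) +
    outer(rep(1, nrow(pa)), rowSums(pb^2)) - 2 * pa %*% t(pb)
  d <- sqrt(pmax(d2, 0))
  w <- outer(a$weights, b$weights)
  mean_d <- sum(w * d)
  edges <- seq(floor(min(d)), ceiling(max(d)) + breaks, by = breaks)
  bin <- findInterval(d, edges, rightmost.closed = TRUE)
  dens <- tapply(as.vector(w), factor(bin, levels = seq_len(length(edges) - 1L)),
                 sum, default = 0)
  mids <- edges[-length(edges)] + breaks / 2
  list(mean = mean_d, modal = mids[which.max(dens)],
       histogram = data.frame(mid = mids, density = as.numeric(dens)))
}

#' Weighted centroid of an ensemble
#' @param ensemble `spin_ensemble`.
#' @return numeric 3-vector.
#' @export
ensemble_centroid <- function(ensemble) {
  colSums(ensemble$positions * ensemble$weights)
}

#' Export an ensemble as tabular text (x, y, z, weight)
#' @param ensemble `spin_ensemble`.
#' @param path output file.
#' @export
write_ensemble_table <- function(ensemble, path) {
  df <- data.frame(x = ensemble$positions[, 1], y = ensemble$positions[, 2],
                   z = ensemble$positions[, 3], weight = ensemble$weights)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
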