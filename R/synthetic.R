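#' Synthetic two-body docking scenarios with known ground truth
#'
#' Builds two non-overlapping helical toy bodies (~200 atoms each: backbone
#' N/CA/C/O, C-beta, and NZ pseudo-atoms on designated lysines), a known
#' truth pose placing body B relative to body A, plus designated spin-label
#' anchor residues and lysine sites. Everything is a pure function of the
#' seed.
#'
#' @param seed integer seed.
#' @param n_res residues per body (split over two packed helices).
#' @return list with `bodyA`, `bodyB` (B in its own local frame),
#'   `truth_pose` (`spindock_transform`), `label_sites_a`, `label_sites_b`
#'   (residue numbers), `lysines_a`, `lysines_b` (residue numbers).
#' @export
make_toy_bodies <- function(seed = 1L, n_res = 36L) {
  set.seed(seed)
  bodyA <- globular_body("A", "A", n_res, lysines = c(4L, 8L, 14L, 20L, 26L, 32L))
  bodyB <- globular_body("B", "B", n_res, lysines = c(3L, 7L, 13L, 19L, 25L, 31L))
  # truth pose: random orientation; translation chosen among candidate
  # contact directions to maximize interface contact (a snug, interlocking
  # interface is what makes sparse restraints informative, as for real
  # docked complexes)
  rot <- sample_rotation()
  ctrA <- colMeans(body_coords(bodyA))
  ctrB <- colMeans(body_coords(bodyB))
  pa <- body_coords(bodyA)
  pb0 <- body_coords(bodyB) %*% t(rot$R)
  place <- function(u) {
    sep <- 5
    repeat {
      tv <- ctrA + u * sep - as.vector(rot$R %*% ctrB)
      pb <- sweep(pb0, 2L, tv, "+")
      d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * tcrossprod(pa, pb)
      if (min(d2) > 4.5^2)
        return(list(tv = tv, contacts = sum(d2 < 8^2)))
      sep <- sep + 1
    }
  }
  dirs <- runif_sphere(24L)
  placements <- lapply(seq_len(nrow(dirs)), function(i) place(dirs[i, ]))
  best <- which.max(vapply(placements, `[[`, 0, "contacts"))
  pose <- new_transform(rot$R, placements[[best]]$tv)
  lys_a <- c(4L, 8L, 14L, 20L, 26L, 32L)
  lys_b <- c(3L, 7L, 13L, 19L, 25L, 31L)
  list(bodyA = bodyA, bodyB = bodyB, truth_pose = pose,
       label_sites_a = setdiff(seq(2L, n_res - 1L, by = 3L), lys_a),
       label_sites_b = setdiff(seq(3L, n_res - 1L, by = 3L), lys_b),
       lysines_a = lys_a, lysines_b = lys_b)
}

# compact two-helix bundle: two antiparallel helices side by side, so the
# body is globular rather than rod-like (clashes then restrict the
# restraint-satisfying pose manifold, as for real proteins)
globular_body <- function(name, chain, n_res, lysines = integer()) {
  # unequal helix lengths avoid an adventitious internal 2-fold that would
  # create near-degenerate docking twins
  n1 <- ceiling(0.55 * n_res); n2 <- n_res - n1
  h1 <- helical_body(name, chain, n1, lysines = lysines[lysines <= n1])
  h2 <- helical_body(name, chain, n2,
                     lysines = lysines[lysines > n1] - n1)
  # flip the second helix and pack it alongside the first
  flip <- new_transform(rbind(c(1, 0, 0), c(0, -1, 0), c(0, 0, -1)),
                        c(9.5, 0, (n1 + 1) * 1.5))
  h2 <- transform_body(h2, flip)
  h2$atoms$resnum <- h2$atoms$resnum + n1
  rigid_body(rbind(h1$atoms, h2$atoms), name = name,
             source = sprintf("synthetic two-helix bundle (%d res)", n_res))
}

# ideal-ish alpha helix with CB and lysine NZ pseudo-atoms
helical_body <- function(name, chain, n_res, lysines = integer()) {
  radius <- 2.3; rise <- 1.5; twist <- 100 * pi / 180
  rows <- list()
  for (i in seq_len(n_res)) {
    th <- i * twist; z <- i * rise
    ca <- c(radius * cos(th), radius * sin(th), z)
    nn <- c(radius * cos(th - 0.35), radius * sin(th - 0.35), z - 0.8)
    cc <- c(radius * cos(th + 0.38), radius * sin(th + 0.38), z + 0.7)
    oo <- cc + c(1.0 * cos(th + 0.38), 1.0 * sin(th + 0.38), 0.6)
    out <- c(cos(th), sin(th), 0)
    cb <- ca + 1.53 * (0.9 * out + c(0, 0, 0.44))
    resname <- if (i %in% lysines) "LYS" else "ALA"
    add <- function(atom, p, el)
      data.frame(chain = chain, resnum = i, resname = resname, atom = atom,
                 element = el, x = p[1], y = p[2], z = p[3],
                 stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- rbind(
      add("N", nn, "N"), add("CA", ca, "C"), add("C", cc, "C"),
      add("O", oo, "O"), add("CB", cb, "C"),
      if (i %in% lysines) add("NZ", ca + 6.0 * out + c(0, 0, 0.7), "N"))
  }
  rigid_body(do.call(rbind, rows), name = name,
             source = sprintf("synthetic helix (%d res)", n_res))
}

# greedy selection of n cross-body site pairs, preferring short (interface-
# spanning) distances, with per-site usage caps and sequence-separation
# spread -- mirrors the fact that only interface-proximal labels and
# cross-links inform a docking experiment
pick_interface_pairs <- function(pa, resa, pb, resb, n, max_use = 2L,
                                 min_sep = 4L) {
  d <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * tcrossprod(pa, pb)
  d <- sqrt(pmax(d, 0))
  picks <- list(); use_a <- integer(nrow(pa)); use_b <- integer(nrow(pb))
  for (k in order(d)) {
    i <- (k - 1L) %% nrow(d) + 1L; j <- (k - 1L) %/% nrow(d) + 1L
    if (use_a[i] >= max_use || use_b[j] >= max_use) next
    dup <- any(vapply(picks, function(p)
      abs(resa[p$i] - resa[i]) < min_sep && abs(resb[p$j] - resb[j]) < min_sep,
      TRUE))
    if (dup) next
    picks[[length(picks) + 1L]] <- list(i = i, j = j, d = d[i, j])
    use_a[i] <- use_a[i] + 1L; use_b[j] <- use_b[j] + 1L
    if (length(picks) == n) break
  }
  if (length(picks) < n) stop("could not select enough restraint site pairs")
  picks
}

#' Simulate distance restraints from a known pose
#'
#' Emulates the sparse-restraint structure of a PELDOR + cross-linking
#' experiment: `n_peldor` ensemble-ensemble restraints between simulated R1
#' labels at interface-proximal residues and `n_xl` lysine NZ-NZ cross-link
#' restraints. Targets are the true model distances at `truth_pose` plus
#' Gaussian noise; flat-bottom half-widths default to the noise level (a
#' noiseless world gives harmonic pulls to the exact targets).
#'
#' @param scenario output of [make_toy_bodies()].
#' @param noise_sd restraint noise, Angstrom.
#' @param n_peldor,n_xl restraint counts (defaults 3 + 2).
#' @param halfwidth flat-bottom half-width, Angstrom; default
#'   `max(noise_sd, 0)`.
#' @param seed integer seed.
#' @return list with `restraints` (list of `distance_restraint`), `labels`
#'   (named `spin_ensemble` list), `true_distances`.
#' @export
simulate_restraints <- function(scenario, noise_sd = 0, n_peldor = 3L,
                                n_xl = 2L, halfwidth = NULL, seed = 1L,
                                params = docking_params()) {
  set.seed(seed)
  if (is.null(halfwidth)) halfwidth <- max(noise_sd, 0)
  A <- scenario$bodyA; B <- scenario$bodyB
  pose <- scenario$truth_pose
  Bt <- transform_body(B, pose)
  restraints <- list(); labels <- list()
  # compact, conformationally restricted labels (narrow cone, short tether):
  # emulates the restricted bifunctional-label strategy that keeps the
  # electron position sharply localized and the distances informative
  av_params <- r1_params(r_min = 3.5, r_max = 6.5, backbone_cos_min = 0.5,
                         n_samples = 2000)
  # PELDOR: R1 labels at candidate residues; pairs picked by proximity of
  # the simulated label centroids at the truth pose (interface-proximal
  # label pairs are the informative ones)
  ens_a <- lapply(scenario$label_sites_a, function(r)
    attach_r1_ensemble(A, label_site("R1", "A", r,
                                     label = sprintf("A%d_R1", r)), av_params))
  ens_b <- lapply(scenario$label_sites_b, function(r)
    attach_r1_ensemble(B, label_site("R1", "B", r,
                                     label = sprintf("B%d_R1", r)), av_params))
  cen_a <- do.call(rbind, lapply(ens_a, ensemble_centroid))
  cen_b <- do.call(rbind, lapply(ens_b, function(e)
    apply_transform(pose, matrix(ensemble_centroid(e), 1L))))
  pp <- pick_interface_pairs(cen_a, scenario$label_sites_a,
                             cen_b, scenario$label_sites_b, n_peldor)
  for (k in seq_along(pp)) {
    ea <- ens_a[[pp[[k]]$i]]; eb <- ens_b[[pp[[k]]$j]]
    la <- ea$site$label; lb <- eb$site$label
    labels[[la]] <- ea; labels[[lb]] <- eb
    restraints[[length(restraints) + 1L]] <- distance_restraint(
      site_a = list(body = "A", kind = "ensemble", ensemble = la),
      site_b = list(body = "B", kind = "ensemble", ensemble = lb),
      target = 1, lower = 0, upper = 2, source = "PELDOR",
      label = sprintf("E%d", k))
  }
  # cross-links: the shortest lysine NZ-NZ pairs across the interface
  nz_a <- select_atoms(A, atom = "NZ"); nz_b <- select_atoms(Bt, atom = "NZ")
  xp <- pick_interface_pairs(as.matrix(nz_a[, c("x", "y", "z")]),
                             nz_a$resnum,
                             as.matrix(nz_b[, c("x", "y", "z")]),
                             nz_b$resnum, n_xl, min_sep = 1L)
  for (k in seq_along(xp)) {
    restraints[[length(restraints) + 1L]] <- distance_restraint(
      site_a = list(body = "A", kind = "atom", chain = "A",
                    resnum = nz_a$resnum[xp[[k]]$i], atom = "NZ"),
      site_b = list(body = "B", kind = "atom", chain = "B",
                    resnum = nz_b$resnum[xp[[k]]$j], atom = "NZ"),
      target = 1, lower = 0, upper = 2, source = "XLMS",
      label = sprintf("X%d", k))
  }
  # measure true model distances at the truth pose with the same evaluation
  # parameters used during docking, then set targets/bounds
  e <- pose_energy(A, B, pose, restraints, labels, params)
  true_d <- e$distances
  for (i in seq_along(restraints)) {
    tgt <- max(0.5, true_d[i] + stats::rnorm(1, 0, noise_sd))
    r <- restraints[[i]]
    r$target <- tgt
    r$lower <- max(0, tgt - halfwidth)
    r$upper <- tgt + halfwidth
    restraints[[i]] <- r
  }
  list(restraints = restraints, labels = labels, true_distances = true_d)
}

#' Simulate a dipolar dataset with known distance distribution
#'
#' @param mu,sigma,mix Gaussian mixture components (nm) and mixture weights.
#' @param times microseconds (default 0 to 8 us, 400 points).
#' @param r_grid nm grid for the true distribution.
#' @param background `background_model`.
#' @param noise_sd trace noise.
#' @param seed integer seed.
#' @return list with `trace` (`dipolar_trace`) and `truth`
#'   (`distance_distribution`).
#' @export
simulate_dipolar_dataset <- function(mu = 5.49, sigma = 0.3, mix = NULL,
                                     times = seq(0, 8, length.out = 400L),
                                     r_grid = default_r_grid(),
                                     background = background_model(0.05, 0.3),
                                     noise_sd = 0.002, seed = 1L) {
  set.seed(seed)
  if (is.null(mix)) mix <- rep(1 / length(mu), length(mu))
  p <- Reduce(`+`, lapply(seq_along(mu), function(i)
    mix[i] * stats::dnorm(r_grid, mu[i], sigma[min(i, length(sigma))])))
  truth <- distance_distribution(r_grid, p)
  trace <- simulate_trace(truth, times, background, noise_sd)
  list(trace = trace, truth = truth)
}

#' Random tryptic-friendly protein sequences
#'
#' Proteins are concatenations of tryptic segments (4--9 non-K/R residues
#' closed by K or R); some segments carry one internal lysine so that
#' missed-cleavage peptides provide linkable sites.
#'
#' @param n_proteins number of sequences.
#' @param n_segments tryptic segments per protein.
#' @param seed integer seed.
#' @return named character vector.
#' @export
make_xl_sequences <- function(n_proteins = 4L, n_segments = 8L, seed = 1L) {
  set.seed(seed)
  alphabet <- setdiff(names(AA_MONO), c("K", "R"))
  seqs <- vapply(seq_len(n_proteins), function(i) {
    segs <- vapply(seq_len(n_segments), function(j) {
      len <- sample(4:9, 1L)
      core <- paste(sample(alphabet, len, replace = TRUE), collapse = "")
      if (stats::runif(1) < 0.5 && len >= 5) {
        # internal lysine (a linkable, missed-cleavage site)
        pos <- sample(2:(len - 1L), 1L)
        substr(core, pos, pos) <- "K"
      }
      paste0(core, sample(c("K", "R"), 1L))
    }, "")
    paste(segs, collapse = "")
  }, "")
  stats::setNames(seqs, paste0("prot", seq_len(n_proteins)))
}

# linkable internal lysines of a protein: K at position p such that some
# tryptic peptide (with missed cleavage) of length >= 5 contains p
# internally. With unique_only, the shortest such peptide must offer p as
# its only link site, so a planted link is unambiguously assignable from
# fragment ions (mirrors restricting restraints to links that are
# "resolved" in the structures)
linkable_lysines <- function(sequence, max_missed = 3L, min_length = 5L,
                             unique_only = FALSE) {
  peps <- digest(sequence, max_missed = max_missed)
  res <- strsplit(sequence, "")[[1]]
  ks <- which(res == "K")
  ok <- vapply(ks, function(p) {
    cover <- peps[peps$start <= p & peps$end >= p &
                    nchar(peps$sequence) >= min_length, , drop = FALSE]
    cover <- cover[p - cover$start + 1L < nchar(cover$sequence), ,
                   drop = FALSE]
    if (nrow(cover) == 0L) return(FALSE)
    if (!unique_only) return(TRUE)
    best <- cover[which.min(nchar(cover$sequence)), ]
    length(link_sites(best$sequence, best$start)) == 1L
  }, TRUE)
  ks[ok]
}

# shortest qualifying peptide covering a linked position
covering_peptide <- function(peptides, parent, pos, min_length = 5L) {
  cand <- peptides[peptides$parent == parent & peptides$start <= pos &
                     peptides$end >= pos &
                     nchar(peptides$sequence) >= min_length, , drop = FALSE]
  cand <- cand[pos - cand$start + 1L < nchar(cand$sequence), , drop = FALSE]
  if (nrow(cand) == 0L) stop("no qualifying peptide covers position ", pos)
  cand[which.min(nchar(cand$sequence)), ]
}

#' Simulate isotope-coded cross-linked MS/MS spectra
#'
#' For each planted lysine-lysine link, emits d0 and d4 spectra (repeated
#' `n_repeats` times each) at the correct neutral precursor masses with the
#' configured fraction of theoretical b/y fragment ions plus uniform random
#' noise peaks, and adds noise-only background spectra at random plausible
#' precursor masses (the false-positive bait for the decoy FDR).
#'
#' @param sequences named character vector of protein sequences.
#' @param n_links number of planted links (random linkable K pairs across
#'   distinct proteins).
#' @param linker `xl_linker`.
#' @param coverage fraction of theoretical fragment ions present.
#' @param n_noise_peaks random peaks added per spectrum.
#' @param n_background noise-only spectra.
#' @param n_repeats repeats per isotope form per link.
#' @param seed integer seed.
#' @return list with `spectra` (list, see [xl_search()]), `truth`
#'   (data.frame of planted residue pairs).
#' @export
simulate_xl_spectra <- function(sequences, n_links = 5L,
                                linker = linker_bs2g(), coverage = 0.7,
                                n_noise_peaks = 30L, n_background = 20L,
                                n_repeats = 2L, seed = 1L) {
  set.seed(seed)
  peptides <- digest_fasta(sequences, max_missed = 3L)
  sites <- lapply(sequences, linkable_lysines, unique_only = TRUE)
  pool <- do.call(rbind, lapply(names(sites), function(p)
    if (length(sites[[p]])) data.frame(parent = p, pos = sites[[p]])))
  if (is.null(pool) || nrow(pool) < 2L) stop("no linkable lysines in sequences")
  links <- list()
  tries <- 0L
  while (length(links) < n_links && tries < 50L * n_links) {
    tries <- tries + 1L
    ij <- sample(nrow(pool), 2L)
    a <- pool[ij[1], ]; b <- pool[ij[2], ]
    if (a$parent == b$parent) next
    key <- paste(a$parent, a$pos, b$parent, b$pos)
    if (key %in% names(links)) next
    links[[key]] <- list(a = a, b = b)
  }
  truth <- do.call(rbind, lapply(links, function(l)
    data.frame(alpha_parent = l$a$parent, alpha_pos = l$a$pos,
               beta_parent = l$b$parent, beta_pos = l$b$pos)))
  rownames(truth) <- NULL
  spectra <- list()
  for (l in links) {
    pa <- covering_peptide(peptides, l$a$parent, l$a$pos)
    pb <- covering_peptide(peptides, l$b$parent, l$b$pos)
    for (form in c("d0", "d4")) {
      bridge <- if (form == "d0") linker$bridge_mass_light
                else linker$bridge_mass_heavy
      mass <- pa$mass + pb$mass + bridge
      ions <- fragment_ions(pa$sequence, pb$sequence,
                            l$a$pos - pa$start + 1L, l$b$pos - pb$start + 1L,
                            bridge, max_charge = 2L)
      for (rep_i in seq_len(n_repeats)) {
        charge <- sample(3:6, 1L)
        keep <- stats::runif(nrow(ions)) < coverage
        mz <- ions$mz[keep]
        intensity <- stats::runif(sum(keep), 0.2, 1)
        if (n_noise_peaks > 0L) {
          mz <- c(mz, stats::runif(n_noise_peaks, 150, 1600))
          intensity <- c(intensity, stats::runif(n_noise_peaks, 0.02, 0.4))
        }
        spectra[[length(spectra) + 1L]] <- list(
          title = sprintf("planted_%s_%s_rep%d", form,
                          paste(l$a$parent, l$a$pos, l$b$parent, l$b$pos,
                                sep = "_"), rep_i),
          precursor_mass = mass, charge = charge,
          rt = stats::runif(1, 0, 100),
          peaks = data.frame(mz = mz, intensity = intensity))
      }
    }
  }
  # background: noise-only spectra at plausible cross-link precursor masses
  long_peps <- peptides[nchar(peptides$sequence) >= 5, ]
  for (i in seq_len(n_background)) {
    ij <- sample(nrow(long_peps), 2L, replace = TRUE)
    mass <- sum(long_peps$mass[ij]) + linker$bridge_mass_light +
      stats::rnorm(1, 0, 0.0005)
    spectra[[length(spectra) + 1L]] <- list(
      title = sprintf("background_%d", i),
      precursor_mass = mass, charge = sample(3:6, 1L),
      rt = stats::runif(1, 0, 100),
      peaks = data.frame(mz = stats::runif(3 * n_noise_peaks, 150, 1600),
                         intensity = stats::runif(3 * n_noise_peaks, 0.02, 1)))
  }
  list(spectra = spectra, truth = truth)
}
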