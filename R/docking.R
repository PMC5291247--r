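#' Flat-bottom distance restraint
#'
#' A restraint between two sites, each either a named atom on one body or a
#' spin-label ensemble attached to one body. The well is flat between
#' `lower` and `upper`; deviations outside it are penalized quadratically.
#'
#' @param site_a,site_b site descriptors: lists with `body` ("A"/"B") and
#'   either `kind = "atom"` plus `chain`, `resnum`, `atom`, or
#'   `kind = "ensemble"` plus `ensemble` (a label name resolved against the
#'   `labels` argument of the docking functions).
#' @param target target distance, Angstrom (may be `NA` for pure bound
#'   restraints such as cross-links).
#' @param lower,upper flat-bottom bounds, Angstrom.
#' @param weight positive restraint weight.
#' @param source "PELDOR" or "XLMS" (free text allowed).
#' @param label restraint label.
#' @return object of class `distance_restraint`.
#' @export
distance_restraint <- function(site_a, site_b, target = NA, lower, upper,
                               weight = 1, source = "generic", label = "") {
  if (!is.na(target) && (lower > target || target > upper))
    stop("need lower <= target <= upper")
  if (lower > upper) stop("lower bound exceeds upper bound")
  if (weight <= 0) stop("weight must be positive")
  structure(list(site_a = site_a, site_b = site_b, target = target,
                 lower = lower, upper = upper, weight = weight,
                 source = source, label = label),
            class = "distance_restraint")
}

#' Docking energy / acceptance parameters
#'
#' @param d_clash inter-body heavy-atom distance below which the soft
#'   repulsion turns on, Angstrom.
#' @param k_rep repulsion force constant, model units per A^2.
#' @param d_acc acceptance cutoff on the maximum restraint violation,
#'   Angstrom (3 A: the criterion used to call restraints satisfied).
#' @param clash_max acceptance cutoff on the clash energy, model units.
#' @param ensemble_max spin ensembles are thinned to at most this many
#'   conformers for energy evaluation (speed; the mean distance converges
#'   quickly).
#' @param clash_atoms atom names used in the clash and contact terms, or
#'   `NULL` for all heavy atoms.
#' @param k_attract weight of the weak contact attraction added to the
#'   minimization objective (a Gaussian bump per inter-body atom pair near
#'   `d_attract`); stands in for the attractive nonbonded energy of a full
#'   force field and pulls minimized solutions into snug interfaces. Set 0
#'   to disable. It is reported separately and never enters `e_total`.
#' @param d_attract centre of the attraction well, Angstrom.
#' @return parameter list.
#' @export
docking_params <- function(d_clash = 3.0, k_rep = 1.0, d_acc = 3.0,
                           clash_max = 10, ensemble_max = 48L,
                           clash_atoms = c("N", "CA", "C", "O", "CB"),
                           k_attract = 0, d_attract = 6.0) {
  list(d_clash = d_clash, k_rep = k_rep, d_acc = d_acc,
       clash_max = clash_max, ensemble_max = ensemble_max,
       clash_atoms = clash_atoms, k_attract = k_attract,
       d_attract = d_attract)
}

# Pre-resolve restraint sites against the two bodies (in their own frames)
# into point sets + weights; B-body sites get transformed per pose later.
resolve_sites <- function(bodyA, bodyB, restraints, labels = list(),
                          params = docking_params()) {
  resolve_one <- function(site) {
    if (site$kind == "atom") {
      body <- if (site$body == "A") bodyA else bodyB
      p <- atom_position(body, site$chain, site$resnum, site$atom)
      list(body = site$body, pts = matrix(p, 1L), w = 1)
    } else if (site$kind == "ensemble") {
      ens <- labels[[site$ensemble]]
      if (is.null(ens)) stop("unknown label ensemble: ", site$ensemble)
      ens <- thin_ensemble(ens, params$ensemble_max)
      list(body = site$body, pts = ens$positions, w = ens$weights)
    } else stop("unknown site kind: ", site$kind)
  }
  lapply(restraints, function(r)
    list(a = resolve_one(r$site_a), b = resolve_one(r$site_b),
         lower = r$lower, upper = r$upper, target = r$target,
         weight = r$weight, label = r$label, source = r$source))
}

cross_dist <- function(pa, pb) {
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * tcrossprod(pa, pb)
  sqrt(pmax(d2, 0))
}

site_mean_distance <- function(sa, sb, pose) {
  pa <- if (sa$body == "B") apply_transform(pose, sa$pts) else sa$pts
  pb <- if (sb$body == "B") apply_transform(pose, sb$pts) else sb$pts
  if (nrow(pa) == 1L && nrow(pb) == 1L)
    return(sqrt(sum((pa[1, ] - pb[1, ])^2)))
  sum(outer(sa$w, sb$w) * cross_dist(pa, pb))
}

clash_energy_points <- function(pa, pb, d_clash, k_rep) {
  # all-pairs soft quadratic repulsion below d_clash; sqrt only where needed
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * tcrossprod(pa, pb)
  close_ <- d2 < d_clash^2
  if (!any(close_)) return(0)
  sum(k_rep * (d_clash - sqrt(pmax(d2[close_], 0)))^2)
}

# Compiled-style energy closure: stacks every B-side coordinate block into
# one matrix transformed once per evaluation.
make_energy_fn <- function(bodyA, bodyB, restraints, labels, params) {
  resolved <- resolve_sites(bodyA, bodyB, restraints, labels, params)
  clashA <- clash_coords(bodyA, params)
  clashB <- clash_coords(bodyB, params)
  nR <- length(resolved)
  lower <- vapply(resolved, `[[`, 0, "lower")
  upper <- vapply(resolved, `[[`, 0, "upper")
  wgt <- vapply(resolved, `[[`, 0, "weight")
  target <- vapply(resolved, `[[`, 0, "target")
  # stack B-side points: per-restraint A/B blocks plus the clash block
  bstack <- list(); bindex <- list()
  push <- function(m) {
    bstack[[length(bstack) + 1L]] <<- m
    from <- if (length(bindex)) bindex[[length(bindex)]][2] else 0L
    bindex[[length(bindex) + 1L]] <<- c(from + 1L, from + nrow(m))
    length(bindex)
  }
  sides <- lapply(resolved, function(r) {
    get_side <- function(s)
      if (s$body == "B") list(fixed = NULL, idx = push(s$pts), w = s$w)
      else list(fixed = s$pts, idx = NA_integer_, w = s$w)
    list(a = get_side(r$a), b = get_side(r$b),
         wab = as.vector(outer(r$a$w, r$b$w)))
  })
  clash_idx <- push(clashB)
  Bmat <- do.call(rbind, bstack)
  # bounding spheres for a cheap clash early-exit
  ctrA <- colMeans(clashA); radA <- sqrt(max(rowSums(sweep(clashA, 2, ctrA)^2)))
  ctrB <- colMeans(clashB); radB <- sqrt(max(rowSums(sweep(clashB, 2, ctrB)^2)))
  clashA_r2 <- rowSums(clashA^2)
  block <- function(moved, i) {
    rng <- bindex[[i]]
    moved[rng[1]:rng[2], , drop = FALSE]
  }
  # with_grad: also return the gradient of the objective with respect to a
  # perturbation (dphi, dt) of the pose, where the rotation perturbs as
  # R -> exp(dphi^) R (left trivialization); callers map dphi to their own
  # rotation parameterization via the SO(3) left Jacobian
  function(R, tv, with_grad = FALSE) {
    moved <- Bmat %*% t(R)
    moved[, 1] <- moved[, 1] + tv[1]
    moved[, 2] <- moved[, 2] + tv[2]
    moved[, 3] <- moved[, 3] + tv[3]
    # gmoved accumulates dE/d(moved point)
    if (with_grad) gmoved <- matrix(0, nrow(moved), 3L)
    d <- numeric(nR)
    pair_cache <- vector("list", nR)
    for (i in seq_len(nR)) {
      s <- sides[[i]]
      pa <- if (is.null(s$a$fixed)) block(moved, s$a$idx) else s$a$fixed
      pb <- if (is.null(s$b$fixed)) block(moved, s$b$idx) else s$b$fixed
      if (nrow(pa) == 1L && nrow(pb) == 1L) {
        d[i] <- sqrt(sum((pa[1, ] - pb[1, ])^2))
      } else {
        dm <- cross_dist(pa, pb)
        d[i] <- sum(s$wab * dm)
        if (with_grad) pair_cache[[i]] <- dm
      }
    }
    viol <- pmax(0, d - upper, lower - d)
    e_noe <- sum(wgt * viol^2)
    ctrBm <- as.vector(R %*% ctrB) + tv
    e_clash <- 0; e_attract <- 0
    clash_pb <- NULL
    if (sqrt(sum((ctrA - ctrBm)^2)) <=
          radA + radB + params$d_attract + 6) {
      clash_pb <- block(moved, clash_idx)
      d2 <- outer(clashA_r2, rowSums(clash_pb^2), `+`) -
        2 * tcrossprod(clashA, clash_pb)
      close_ <- d2 < params$d_clash^2
      if (any(close_))
        e_clash <- sum(params$k_rep *
                         (params$d_clash - sqrt(pmax(d2[close_], 0)))^2)
      if (params$k_attract > 0) {
        near <- d2 < (params$d_attract + 6)^2
        if (any(near))
          e_attract <- -params$k_attract *
            sum(exp(-(sqrt(pmax(d2[near], 0)) - params$d_attract)^2 / 8))
      }
    }
    deviations <- ifelse(is.na(target),
                         ifelse(d > upper, d - upper,
                                ifelse(d < lower, d - lower, 0)),
                         d - target)
    out <- list(e_noe = e_noe, e_clash = e_clash, e_total = e_noe + e_clash,
                e_attract = e_attract,
                objective = e_noe + e_clash + e_attract,
                deviations = deviations, violations = viol, distances = d)
    if (!with_grad) return(out)
    # ---- gradient accumulation ----
    dE_dd <- 2 * wgt * viol * ifelse(d > upper, 1, ifelse(d < lower, -1, 0))
    for (i in seq_len(nR)) {
      if (dE_dd[i] == 0) next
      s <- sides[[i]]
      pa <- if (is.null(s$a$fixed)) block(moved, s$a$idx) else s$a$fixed
      pb <- if (is.null(s$b$fixed)) block(moved, s$b$idx) else s$b$fixed
      if (nrow(pa) == 1L && nrow(pb) == 1L) {
        u <- (pa[1, ] - pb[1, ]) / max(d[i], 1e-9)  # dd/dpa
        if (is.null(s$a$fixed))
          gmoved[bindex[[s$a$idx]][1], ] <-
            gmoved[bindex[[s$a$idx]][1], ] + dE_dd[i] * u
        if (is.null(s$b$fixed))
          gmoved[bindex[[s$b$idx]][1], ] <-
            gmoved[bindex[[s$b$idx]][1], ] - dE_dd[i] * u
      } else {
        dm <- pair_cache[[i]]
        W <- matrix(s$wab, nrow(pa), nrow(pb)) / pmax(dm, 1e-9)
        # d(sum w_ij d_ij)/dpa_i = sum_j w_ij (pa_i - pb_j)/d_ij
        if (is.null(s$a$fixed)) {
          ga <- pa * rowSums(W) - W %*% pb
          rng <- bindex[[s$a$idx]]
          gmoved[rng[1]:rng[2], ] <- gmoved[rng[1]:rng[2], ] + dE_dd[i] * ga
        }
        if (is.null(s$b$fixed)) {
          gb <- pb * colSums(W) - crossprod(W, pa)
          rng <- bindex[[s$b$idx]]
          gmoved[rng[1]:rng[2], ] <- gmoved[rng[1]:rng[2], ] + dE_dd[i] * gb
        }
      }
    }
    if (!is.null(clash_pb)) {
      d2 <- outer(clashA_r2, rowSums(clash_pb^2), `+`) -
        2 * tcrossprod(clashA, clash_pb)
      dm <- sqrt(pmax(d2, 1e-12))
      coef <- matrix(0, nrow(clashA), nrow(clash_pb))
      close_ <- dm < params$d_clash
      if (any(close_))
        coef[close_] <- -2 * params$k_rep * (params$d_clash - dm[close_])
      if (params$k_attract > 0) {
        near <- dm < params$d_attract + 6
        coef[near] <- coef[near] + params$k_attract *
          (dm[near] - params$d_attract) / 4 *
          exp(-(dm[near] - params$d_attract)^2 / 8)
      }
      if (any(coef != 0)) {
        Wc <- coef / dm
        gB <- clash_pb * colSums(Wc) - crossprod(Wc, clashA)
        rng <- bindex[[clash_idx]]
        gmoved[rng[1]:rng[2], ] <- gmoved[rng[1]:rng[2], ] + gB
      }
    }
    # map point gradients to pose: dt = column sums; dphi via g x (p - t)
    gt <- colSums(gmoved)
    x <- moved
    x[, 1] <- x[, 1] - tv[1]; x[, 2] <- x[, 2] - tv[2]; x[, 3] <- x[, 3] - tv[3]
    gphi <- -c(
      sum(gmoved[, 2] * x[, 3] - gmoved[, 3] * x[, 2]),
      sum(gmoved[, 3] * x[, 1] - gmoved[, 1] * x[, 3]),
      sum(gmoved[, 1] * x[, 2] - gmoved[, 2] * x[, 1]))
    out$grad_phi <- gphi
    out$grad_t <- gt
    out
  }
}

# left Jacobian of SO(3): maps d(rotation vector) to the left-trivialized
# angular perturbation dphi for R(w) = exp(w^) R0
so3_left_jacobian <- function(w) {
  th <- sqrt(sum(w^2))
  W <- rbind(c(0, -w[3], w[2]), c(w[3], 0, -w[1]), c(-w[2], w[1], 0))
  if (th < 1e-6) diag(3) + W / 2 + (W %*% W) / 6
  else diag(3) + (1 - cos(th)) / th^2 * W + (th - sin(th)) / th^3 * (W %*% W)
}

#' Energies of a candidate pose
#'
#' For each restraint the model distance `d` is the weighted ensemble-mean
#' distance (PELDOR sites) or the atom-atom distance (cross-link sites);
#' the violation is `max(0, d - upper, lower - d)` and
#' `e_noe = sum(w * violation^2)`. The clash term is a soft quadratic
#' repulsion between inter-body atoms closer than `d_clash`.
#'
#' @param bodyA,bodyB `rigid_body` objects (A fixed, B posed).
#' @param pose `spindock_transform` placing body B (and its ensembles) in
#'   body A's frame.
#' @param restraints list of `distance_restraint`.
#' @param labels named list of `spin_ensemble` objects (in the frame of the
#'   body they are attached to).
#' @param params [docking_params()].
#' @param resolved pre-resolved sites (internal, for speed).
#' @param clashA,clashB pre-extracted clash coordinate matrices (internal).
#' @return list with `e_noe`, `e_clash`, `e_total`, `deviations` (signed
#'   d - target where target defined, else signed violation), `violations`
#'   (distance outside the flat bottom), `distances`.
#' @export
pose_energy <- function(bodyA, bodyB, pose, restraints, labels = list(),
                        params = docking_params(), energy_fn = NULL) {
  if (is.null(energy_fn))
    energy_fn <- make_energy_fn(bodyA, bodyB, restraints, labels, params)
  energy_fn(pose$R, pose$t)
}

clash_coords <- function(body, params) {
  if (is.null(params$clash_atoms)) return(body_coords(body))
  as.matrix(select_atoms(body, atom = params$clash_atoms)[, c("x", "y", "z")])
}

#' Locally minimize the pose energy over the 6 rigid-body degrees of freedom
#'
#' Quasi-Newton (BFGS) minimization of `e_total` with the rotation
#' parameterized as an axis-angle update to the starting rotation
#' (singularity-free near the optimum). Divergent minimizations (NaN energy)
#' are returned as failed solutions, not errors.
#'
#' @inheritParams pose_energy
#' @param start starting `spindock_transform`.
#' @param maxit BFGS iteration cap.
#' @return a `docking_solution`: list with `pose`, `e_noe`, `e_clash`,
#'   `e_total`, `deviations`, `violations`, `distances`, `converged`,
#'   `failed`.
#' @export
minimize_pose <- function(bodyA, bodyB, start, restraints, labels = list(),
                          params = docking_params(), maxit = 60L,
                          energy_fn = NULL, soft_fn = NULL) {
  if (is.null(energy_fn))
    energy_fn <- make_energy_fn(bodyA, bodyB, restraints, labels, params)
  # stage 1 on a softened repulsion lets the pose slide along restraint-
  # satisfying directions through mild steric overlap (a cheap stand-in for
  # the dynamics step of the original protocol); stage 2 refines with the
  # full repulsion
  if (!is.null(soft_fn)) {
    pre <- minimize_pose(bodyA, bodyB, start, restraints, labels, params,
                         maxit = maxit, energy_fn = soft_fn)
    if (!pre$failed) start <- pre$pose
  }
  R0 <- start$R; t0 <- start$t
  obj <- function(par)
    energy_fn(rotvec_to_matrix(par[1:3]) %*% R0, t0 + par[4:6])$objective
  grad <- function(par) {
    e <- energy_fn(rotvec_to_matrix(par[1:3]) %*% R0, t0 + par[4:6],
                   with_grad = TRUE)
    c(as.vector(t(so3_left_jacobian(par[1:3])) %*% e$grad_phi), e$grad_t)
  }
  opt <- tryCatch(
    stats::optim(rep(0, 6), obj, grad, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value)) {
    sol <- list(pose = start, e_noe = NA_real_, e_clash = NA_real_,
                e_total = NA_real_, deviations = NA_real_,
                violations = NA_real_, distances = NA_real_,
                converged = FALSE, failed = TRUE)
    class(sol) <- "docking_solution"
    return(sol)
  }
  pose <- new_transform(rotvec_to_matrix(opt$par[1:3]) %*% R0,
                        t0 + opt$par[4:6])
  e <- energy_fn(pose$R, pose$t)
  sol <- c(list(pose = pose), e,
           list(converged = opt$convergence == 0, failed = FALSE))
  class(sol) <- "docking_solution"
  sol
}

#' @export
print.docking_solution <- function(x, ...) {
  if (x$failed) { cat("<docking solution: FAILED (divergent)>\n"); return(invisible(x)) }
  cat(sprintf("<docking solution> e_noe = %.3g, e_clash = %.3g, max violation = %.2f A\n",
              x$e_noe, x$e_clash, max(x$violations)))
  invisible(x)
}

# starting translation for a given random orientation: first place body B so
# one randomly chosen restraint is exactly satisfied along a random
# direction, then Gauss-Newton refine the translation alone against all
# restraint targets (site ensembles approximated by their centroids). The
# orientation itself stays random, as in the original protocol.
start_translation <- function(resolved, Rstart, refine_iter = 12L) {
  cents <- lapply(resolved, function(r) {
    list(a = colSums(r$a$pts * r$a$w / sum(r$a$w)),
         b = colSums(r$b$pts * r$b$w / sum(r$b$w)),
         a_on_A = r$a$body == "A",
         tgt = if (!is.na(r$target)) r$target else (r$lower + r$upper) / 2)
  })
  # seed from one restraint along a random direction
  r1 <- cents[[sample.int(length(cents), 1L)]]
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  tv <- if (r1$a_on_A) r1$a + r1$tgt * u - as.vector(Rstart %*% r1$b)
        else r1$b + r1$tgt * u - as.vector(Rstart %*% r1$a)
  # translation-only least squares on all restraint targets
  pa <- t(vapply(cents, function(cc) if (cc$a_on_A) cc$a else cc$b,
                 numeric(3)))
  pb <- t(vapply(cents, function(cc)
    as.vector(Rstart %*% (if (cc$a_on_A) cc$b else cc$a)), numeric(3)))
  tgt <- vapply(cents, `[[`, 0, "tgt")
  for (it in seq_len(refine_iter)) {
    rel <- pa - sweep(pb, 2L, tv, "+")
    dn <- sqrt(rowSums(rel^2))
    dn[dn < 1e-6] <- 1e-6
    f <- dn - tgt
    U <- rel / dn
    JtJ <- crossprod(U) + diag(1e-8, 3)
    tv <- tv + as.vector(solve(JtJ, crossprod(U, f)))
  }
  tv
}

#' Restraint-driven rigid-body docking from randomized starts
#'
#' Repeats: draw a uniformly random orientation for body B, place it so one
#' randomly chosen restraint is initially satisfiable, minimize the combined
#' restraint + clash energy, and accept the solution if the maximum
#' restraint violation is at most `d_acc` and the clash energy at most
#' `clash_max`. Deterministic for a fixed seed.
#'
#' @inheritParams pose_energy
#' @param n_starts number of random starts (500 mirrors the original
#'   protocol; scale down for speed).
#' @param seed integer seed (set once; `NULL` leaves the RNG alone).
#' @return object of class `docking_run`: list with `solutions` (all),
#'   `accepted` (accepted subset), `n_starts`, `seed`, `params`.
#' @export
run_docking <- function(bodyA, bodyB, restraints, labels = list(),
                        n_starts = 500L, seed = NULL,
                        params = docking_params()) {
  if (length(restraints) == 0L)
    stop("unconstrained docking refused: need at least one restraint")
  if (!is.null(seed)) set.seed(seed)
  resolved <- resolve_sites(bodyA, bodyB, restraints, labels, params)
  energy_fn <- make_energy_fn(bodyA, bodyB, restraints, labels, params)
  soft_params <- params; soft_params$k_rep <- 0.02 * params$k_rep
  soft_fn <- make_energy_fn(bodyA, bodyB, restraints, labels, soft_params)
  solutions <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    rot <- sample_rotation()
    tr0 <- new_transform(rot$R, start_translation(resolved, rot$R))
    solutions[[i]] <- minimize_pose(bodyA, bodyB, tr0, restraints, labels,
                                    params, energy_fn = energy_fn,
                                    soft_fn = soft_fn)
  }
  ok <- vapply(solutions, function(s) !s$failed, TRUE)
  acc <- vapply(solutions, function(s)
    !s$failed && max(s$violations) <= params$d_acc &&
      s$e_clash <= params$clash_max, TRUE)
  structure(list(solutions = solutions, accepted = solutions[acc],
                 n_starts = n_starts, n_failed = sum(!ok),
                 seed = seed, params = params),
            class = "docking_run")
}

#' @export
print.docking_run <- function(x, ...) {
  cat(sprintf("<docking run> %d/%d accepted (%d failed starts)\n",
              length(x$accepted), x$n_starts, x$n_failed))
  invisible(x)
}

#' Align accepted solutions and compute the ensemble average
#'
#' All accepted complexes are superposed on body A's backbone (body A is the
#' fixed frame, so this is the shared reference), averaged atom-wise, and
#' each member's RMSD to the average is computed for backbone and for all
#' heavy atoms.
#'
#' @param run `docking_run` (or list of `docking_solution`).
#' @param bodyA,bodyB the docked bodies.
#' @return object of class `model_ensemble`: `average` (complex
#'   `rigid_body`), `members` (list of complex bodies), `rmsd_backbone`,
#'   `rmsd_heavy` (per member), `rmsd_backbone_mean`, `rmsd_heavy_mean`.
#' @export
average_models <- function(run, bodyA, bodyB) {
  accepted <- if (inherits(run, "docking_run")) run$accepted else run
  if (length(accepted) == 0L) stop("empty accepted set")
  complexes <- lapply(accepted, function(s)
    merge_bodies(list(bodyA, transform_body(bodyB, s$pose)), name = "complex"))
  refbb <- backbone_coords(bodyA)
  aligned <- lapply(complexes, function(cx) {
    bb <- backbone_coords(rigid_body(cx$atoms[seq_len(nrow(bodyA$atoms)), ],
                                     name = "A"))
    fit <- superpose(bb, refbb)
    set_body_coords(cx, apply_transform(fit$transform, body_coords(cx)))
  })
  coords <- lapply(aligned, body_coords)
  avg <- Reduce(`+`, coords) / length(coords)
  average <- set_body_coords(aligned[[1]], avg)
  average$name <- "average"
  is_bb <- average$atoms$atom %in% BACKBONE_ATOMS
  rmsd_bb <- vapply(coords, function(m)
    coord_rmsd(m[is_bb, , drop = FALSE], avg[is_bb, , drop = FALSE]), 0)
  rmsd_all <- vapply(coords, function(m) coord_rmsd(m, avg), 0)
  structure(list(average = average, members = aligned,
                 rmsd_backbone = rmsd_bb, rmsd_heavy = rmsd_all,
                 rmsd_backbone_mean = mean(rmsd_bb),
                 rmsd_heavy_mean = mean(rmsd_all)),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("<model ensemble> %d members; mean RMSD to average: %.2f A (backbone), %.2f A (heavy)\n",
              length(x$members), x$rmsd_backbone_mean, x$rmsd_heavy_mean))
  invisible(x)
}

#' Validate a model against its restraints
#'
#' Reports the signed deviation `d_model - d_target` per restraint (for
#' bound-only restraints, the signed distance outside the flat bottom) and
#' the maximum absolute deviation.
#'
#' @inheritParams pose_energy
#' @return list with `table` (data.frame: label, source, distance, target,
#'   deviation) and `max_abs_deviation`.
#' @export
validate_model <- function(bodyA, bodyB, pose, restraints, labels = list(),
                           params = docking_params()) {
  e <- pose_energy(bodyA, bodyB, pose, restraints, labels, params)
  tab <- data.frame(
    label = vapply(restraints, `[[`, "", "label"),
    source = vapply(restraints, `[[`, "", "source"),
    distance = e$distances,
    target = vapply(restraints, `[[`, 0, "target"),
    lower = vapply(restraints, `[[`, 0, "lower"),
    upper = vapply(restraints, `[[`, 0, "upper"),
    deviation = e$deviations)
  list(table = tab, max_abs_deviation = max(abs(e$deviations)))
}

#' Extrapolate a two-body model onto a tetramer template
#'
#' Superposes a copy of the complex onto each histone-fold dimer of a
#' template (e.g. the H3-H4 tetramer extracted from a histone octamer) via
#' shared backbone atoms, removes the capping-chaperone chains, and reports
#' inter-copy heavy-atom contacts below a clash cutoff.
#'
#' @param complex_body the averaged complex (`rigid_body`), containing the
#'   chaperone and histone chains.
#' @param template `rigid_body` holding the tetramer template.
#' @param dimer_chain_sets list of named character vectors, one per template
#'   dimer, mapping complex chain ids to template chain ids, e.g.
#'   `list(c(C = "A", D = "B"), c(C = "E", D = "F"))`.
#' @param drop_chains chains removed from each placed copy (e.g. Asf1).
#' @param keep_chains chains retained from each placed copy (the chaperone
#'   of interest plus its histone dimer); default: all but `drop_chains`.
#' @param clash_cutoff contact distance, Angstrom.
#' @param rmsd_warn warn if a dimer superposition RMSD exceeds this.
#' @return list with `composite` (`rigid_body`), `copies` (list), `rmsds`
#'   (superposition RMSD per copy), `n_clashes` (inter-copy chaperone
#'   contacts below cutoff).
#' @export
extrapolate_tetramer <- function(complex_body, template, dimer_chain_sets,
                                 drop_chains = character(),
                                 keep_chains = NULL, clash_cutoff = 3.0,
                                 rmsd_warn = 2.0) {
  copies <- list(); rmsds <- numeric(0)
  for (mapping in dimer_chain_sets) {
    mob <- list(); ref <- list()
    for (cx_chain in names(mapping)) {
      tpl_chain <- mapping[[cx_chain]]
      ma <- select_atoms(complex_body, chain = cx_chain, atom = BACKBONE_ATOMS)
      ta <- select_atoms(template, chain = tpl_chain, atom = BACKBONE_ATOMS)
      shared <- intersect(paste(ma$resnum, ma$atom), paste(ta$resnum, ta$atom))
      if (length(shared) < 3L)
        stop("chain mapping failure: too few shared backbone atoms for chain ",
             cx_chain)
      ma <- ma[paste(ma$resnum, ma$atom) %in% shared, ]
      ta <- ta[paste(ta$resnum, ta$atom) %in% shared, ]
      ord <- order(ma$resnum, ma$atom); ma <- ma[ord, ]
      ord <- order(ta$resnum, ta$atom); ta <- ta[ord, ]
      mob[[length(mob) + 1L]] <- as.matrix(ma[, c("x", "y", "z")])
      ref[[length(ref) + 1L]] <- as.matrix(ta[, c("x", "y", "z")])
    }
    fit <- superpose(do.call(rbind, mob), do.call(rbind, ref))
    if (fit$rmsd > rmsd_warn)
      warning(sprintf("dimer superposition RMSD %.2f A exceeds %.2f A",
                      fit$rmsd, rmsd_warn))
    rmsds <- c(rmsds, fit$rmsd)
    placed <- transform_body(complex_body, fit$transform)
    keep <- if (is.null(keep_chains))
      setdiff(unique(placed$atoms$chain), drop_chains) else keep_chains
    placed$atoms <- placed$atoms[placed$atoms$chain %in% keep, ]
    rownames(placed$atoms) <- NULL
    copies[[length(copies) + 1L]] <- placed
  }
  # clash report between chaperone copies (chains not shared with template)
  tpl_chains <- unique(unlist(dimer_chain_sets))
  n_clashes <- 0L
  if (length(copies) >= 2L) {
    for (i in seq_along(copies)) for (j in seq_along(copies)) {
      if (j <= i) next
      ci <- copies[[i]]$atoms[!(copies[[i]]$atoms$chain %in% tpl_chains), ]
      cj <- copies[[j]]$atoms[!(copies[[j]]$atoms$chain %in% tpl_chains), ]
      if (nrow(ci) == 0L || nrow(cj) == 0L) next
      pi_ <- as.matrix(ci[, c("x", "y", "z")])
      pj <- as.matrix(cj[, c("x", "y", "z")])
      d2 <- outer(rowSums(pi_^2), rep(1, nrow(pj))) +
        outer(rep(1, nrow(pi_)), rowSums(pj^2)) - 2 * pi_ %*% t(pj)
      n_clashes <- n_clashes + sum(d2 < clash_cutoff^2)
    }
  }
  composite <- merge_bodies(copies, name = "extrapolated_tetramer")
  list(composite = composite, copies = copies, rmsds = rmsds,
       n_clashes = n_clashes)
}

# ---- restraint table I/O -------------------------------------------------

site_to_string <- function(s) {
  if (s$kind == "atom")
    sprintf("%s:%s:%s:%s", s$body, s$chain, s$resnum, s$atom)
  else sprintf("%s:ens:%s", s$body, s$ensemble)
}

string_to_site <- function(x) {
  parts <- strsplit(x, ":")[[1]]
  if (parts[2] == "ens")
    list(body = parts[1], kind = "ensemble", ensemble = parts[3])
  else list(body = parts[1], kind = "atom", chain = parts[2],
            resnum = as.integer(parts[3]), atom = parts[4])
}

#' Write a restraint list as a tab-separated table
#' @param restraints list of `distance_restraint`.
#' @param path output file.
#' @export
write_restraints <- function(restraints, path) {
  df <- data.frame(
    label = vapply(restraints, `[[`, "", "label"),
    type = vapply(restraints, `[[`, "", "source"),
    site_a = vapply(restraints, function(r) site_to_string(r$site_a), ""),
    site_b = vapply(restraints, function(r) site_to_string(r$site_b), ""),
    target = vapply(restraints, `[[`, 0, "target"),
    lower = vapply(restraints, `[[`, 0, "lower"),
    upper = vapply(restraints, `[[`, 0, "upper"),
    weight = vapply(restraints, `[[`, 0, "weight"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a restraint table written by [write_restraints()]
#' @param path tab-separated restraint table.
#' @return list of `distance_restraint`.
#' @export
read_restraints <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    distance_restraint(site_a = string_to_site(df$site_a[i]),
                       site_b = string_to_site(df$site_b[i]),
                       target = df$target[i], lower = df$lower[i],
                       upper = df$upper[i], weight = df$weight[i],
                       source = df$type[i], label = df$label[i]))
}
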