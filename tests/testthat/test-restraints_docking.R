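two_atom_bodies <- function() {
  mk <- function(chain, x) rigid_body(data.frame(
    chain = chain, resnum = 1L, resname = "ALA", atom = "CA", element = "C",
    x = x, y = 0, z = 0), name = chain)
  list(A = mk("A", 0), B = mk("B", 0))
}

atom_restraint <- function(target, lower = target, upper = target,
                           weight = 1) {
  distance_restraint(
    site_a = list(body = "A", kind = "atom", chain = "A", resnum = 1L,
                  atom = "CA"),
    site_b = list(body = "B", kind = "atom", chain = "B", resnum = 1L,
                  atom = "CA"),
    target = target, lower = lower, upper = upper, weight = weight,
    source = "test", label = "t")
}

test_that("pose_energy implements the flat-bottom and repulsion forms", {
  tb <- two_atom_bodies()
  # satisfied restraint, bodies far apart: both terms zero
  pose <- new_transform(translation = c(10, 0, 0))
  e <- pose_energy(tb$A, tb$B, pose, list(atom_restraint(10, 8, 12)))
  expect_equal(e$e_noe, 0)
  expect_equal(e$e_clash, 0)
  expect_equal(e$e_total, e$e_noe + e$e_clash)
  # violation by delta with weight w: e_noe = w * delta^2
  e2 <- pose_energy(tb$A, tb$B, pose,
                    list(atom_restraint(15, 14, 16, weight = 2.5)))
  expect_equal(e2$e_noe, 2.5 * 4^2)
  expect_equal(e2$deviations, 10 - 15)
  # lower-bound violation
  e3 <- pose_energy(tb$A, tb$B, pose, list(atom_restraint(5, 4, 6)))
  expect_equal(e3$e_noe, 4^2)
})

test_that("the clash term matches a brute-force all-pairs oracle", {
  set.seed(14)
  a <- random_body(12)
  b <- a; b$atoms$chain <- "B"
  b <- set_body_coords(b, body_coords(a) + matrix(rnorm(36, 0, 0.7), 12, 3))
  pose <- new_transform(translation = c(1, 0.5, 0))
  params <- docking_params(clash_atoms = NULL)  # all atoms
  e <- pose_energy(a, b, pose,
                   list(distance_restraint(
                     site_a = list(body = "A", kind = "atom", chain = "A",
                                   resnum = 1L, atom = "CA"),
                     site_b = list(body = "B", kind = "atom", chain = "B",
                                   resnum = 1L, atom = "CA"),
                     target = NA, lower = 0, upper = 100, source = "t",
                     label = "t")),
                   params = params)
  pa <- body_coords(a); pb <- apply_transform(pose, body_coords(b))
  brute <- 0
  for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb))) {
    d <- sqrt(sum((pa[i, ] - pb[j, ])^2))
    if (d < 3.0) brute <- brute + (3.0 - d)^2
  }
  expect_equal(e$e_clash, brute, tolerance = 1e-12)
  expect_gt(brute, 0)  # the fixture overlaps by construction
})

test_that("pose_energy is invariant under a global rigid motion", {
  sc <- make_toy_bodies(12)
  rs <- simulate_restraints(sc, noise_sd = 0, seed = 3,
                            params = test_dock_params())
  e0 <- pose_energy(sc$bodyA, sc$bodyB, sc$truth_pose, rs$restraints,
                    rs$labels, test_dock_params())
  set.seed(10)
  g <- new_transform(sample_rotation()$R, rnorm(3, 0, 15))
  movedA <- transform_body(sc$bodyA, g)
  movedLabels <- lapply(rs$labels, function(ens) {
    if (startsWith(ens$site$label, "A")) transform_ensemble(ens, g) else ens
  })
  # B stays in its local frame: its pose in the moved world is g o pose
  e1 <- pose_energy(movedA, sc$bodyB, compose_transforms(g, sc$truth_pose),
                    rs$restraints, movedLabels, test_dock_params())
  expect_equal(e1$e_noe, e0$e_noe, tolerance = 1e-6)
  expect_equal(e1$e_clash, e0$e_clash, tolerance = 1e-6)
  expect_equal(e1$distances, e0$distances, tolerance = 1e-6)
})

test_that("minimize_pose solves a one-dimensional well and respects tol", {
  tb <- two_atom_bodies()
  r <- list(atom_restraint(10, 9, 11))
  # start already satisfied: pose essentially unchanged
  start <- new_transform(translation = c(10, 0, 0))
  sol <- minimize_pose(tb$A, tb$B, start, r)
  expect_false(sol$failed)
  expect_lt(sqrt(sum((sol$pose$t - start$t)^2)), 1e-3)
  # start violated: converges into the well
  sol2 <- minimize_pose(tb$A, tb$B, new_transform(translation = c(30, 0, 0)),
                        r)
  expect_lt(sol2$e_noe, 1e-6)
  expect_true(sol2$distances >= 9 - 1e-3 && sol2$distances <= 11 + 1e-3)
})

test_that("run_docking is deterministic, refuses empty restraints, and flags infeasible systems", {
  sc <- make_toy_bodies(13)
  p <- test_dock_params()
  rs <- simulate_restraints(sc, noise_sd = 0, seed = 5, params = p)
  expect_error(run_docking(sc$bodyA, sc$bodyB, list(), n_starts = 2),
               "refused")
  r1 <- run_docking(sc$bodyA, sc$bodyB, rs$restraints, rs$labels,
                    n_starts = 6, seed = 31, params = p)
  r2 <- run_docking(sc$bodyA, sc$bodyB, rs$restraints, rs$labels,
                    n_starts = 6, seed = 31, params = p)
  expect_equal(vapply(r1$solutions, `[[`, 0, "e_total"),
               vapply(r2$solutions, `[[`, 0, "e_total"))
  expect_equal(length(r1$accepted), length(r2$accepted))
  # mutually inconsistent targets: nothing is acceptable at tight d_acc
  bad <- rs$restraints
  for (i in seq_along(bad)) {
    bad[[i]]$target <- bad[[i]]$target + c(25, -20, 30, -25, 28)[i]
    bad[[i]]$target <- max(bad[[i]]$target, 1)
    bad[[i]]$lower <- bad[[i]]$target; bad[[i]]$upper <- bad[[i]]$target
  }
  pbad <- docking_params(ensemble_max = 16L, clash_atoms = c("CA", "CB"),
                         d_acc = 0.5)
  rbad <- run_docking(sc$bodyA, sc$bodyB, bad, rs$labels, n_starts = 6,
                      seed = 31, params = pbad)
  expect_length(rbad$accepted, 0)
  # acceptance set is non-increasing as d_acc tightens
  viol <- vapply(r1$solutions, function(s) max(s$violations), 0)
  for (dacc in c(5, 3, 1, 0.5, 0.1))
    expect_lte(sum(viol <= dacc), sum(viol <= 5))
  expect_true(all(diff(vapply(c(0.1, 0.5, 1, 3, 5), function(dacc)
    sum(viol <= dacc), 0)) >= 0))
})

test_that("average_models averages aligned complexes and reports RMSDs", {
  sc <- make_toy_bodies(14)
  pose <- sc$truth_pose
  sol <- function(p) structure(list(pose = p, failed = FALSE),
                               class = "docking_solution")
  # identical solutions: zero spread, average equals each member
  ens <- average_models(list(sol(pose), sol(pose), sol(pose)),
                        sc$bodyA, sc$bodyB)
  expect_equal(ens$rmsd_backbone_mean, 0, tolerance = 1e-9)
  expect_equal(ens$rmsd_heavy_mean, 0, tolerance = 1e-9)
  expect_equal(body_coords(ens$average),
               body_coords(ens$members[[1]]), tolerance = 1e-9)
  # two solutions: both members are equidistant from the mean, and the
  # reported means equal an independent recomputation
  pose2 <- compose_transforms(new_transform(axis_rotation("z", 0.1)$R,
                                            c(1, 0, 0)), pose)
  ens2 <- average_models(list(sol(pose), sol(pose2)), sc$bodyA, sc$bodyB)
  expect_equal(ens2$rmsd_backbone[1], ens2$rmsd_backbone[2], tolerance = 1e-9)
  avg <- body_coords(ens2$average)
  bb <- ens2$average$atoms$atom %in% c("N", "CA", "C", "O")
  recomputed <- mean(vapply(ens2$members, function(m)
    coord_rmsd(body_coords(m)[bb, ], avg[bb, ]), 0))
  expect_equal(ens2$rmsd_backbone_mean, recomputed, tolerance = 1e-12)
  expect_error(average_models(list(), sc$bodyA, sc$bodyB), "empty")
})

test_that("validate_model reports signed deviations and their maximum", {
  tb <- two_atom_bodies()
  pose <- new_transform(translation = c(12, 5, 0))  # distance = 13
  r <- list(atom_restraint(13, 12, 14), atom_restraint(10, 9, 11))
  v <- validate_model(tb$A, tb$B, pose, r)
  expect_equal(v$table$distance, c(13, 13), tolerance = 1e-12)
  expect_equal(v$table$deviation, c(0, 3), tolerance = 1e-12)
  expect_equal(v$max_abs_deviation, 3, tolerance = 1e-12)
  # model constructed exactly at all targets: zero deviation
  v0 <- validate_model(tb$A, tb$B, new_transform(translation = c(13, 0, 0)),
                       list(atom_restraint(13, 12, 14)))
  expect_equal(v0$max_abs_deviation, 0, tolerance = 1e-12)
})

test_that("tetramer extrapolation respects template symmetry and drops the capping chain", {
  # complex: chaperone chain V + histone-like dimer chains C, D
  sc <- make_toy_bodies(15)
  chap <- sc$bodyA; chap$atoms$chain <- "V"
  dimer <- transform_body(sc$bodyB, sc$truth_pose)
  dimer$atoms$chain <- rep(c("C", "D"), c(
    sum(dimer$atoms$resnum <= 18), sum(dimer$atoms$resnum > 18)))
  cap <- transform_body(sc$bodyA,
                        new_transform(translation = c(0, 40, 0)))
  cap$atoms$chain <- "S"  # stand-in for the capping chaperone (dropped)
  cx <- merge_bodies(list(chap, dimer, cap), name = "complex")
  # template: two copies of the dimer related by an exact 2-fold about z
  twofold <- axis_rotation("z", pi)
  copy1 <- dimer
  copy1$atoms$chain <- c(E = "E", F = "F")[
    ifelse(copy1$atoms$chain == "C", "E", "F")]
  copy2 <- transform_body(copy1, twofold)
  copy2$atoms$chain <- ifelse(copy2$atoms$chain == "E", "G", "H")
  template <- merge_bodies(list(copy1, copy2), name = "template")
  out <- extrapolate_tetramer(
    cx, template,
    dimer_chain_sets = list(c(C = "E", D = "F"), c(C = "G", D = "H")),
    drop_chains = "S")
  # no capping-chain atoms in the output
  expect_false("S" %in% out$composite$atoms$chain)
  expect_lt(max(out$rmsds), 1e-6)
  # the two placed chaperone copies are related by the same 2-fold
  v1 <- out$copies[[1]]$atoms
  v1 <- v1[v1$chain == "V", ]
  v2 <- out$copies[[2]]$atoms
  v2 <- v2[v2$chain == "V", ]
  expect_equal(as.matrix(v2[, c("x", "y", "z")]),
               apply_transform(twofold, as.matrix(v1[, c("x", "y", "z")])),
               tolerance = 1e-6, ignore_attr = TRUE)
  # clash report counts inter-copy chaperone contacts
  expect_true(is.finite(out$n_clashes))
})

test_that("restraint tables round-trip through the tab-separated format", {
  rs <- list(
    distance_restraint(site_a = list(body = "A", kind = "atom", chain = "A",
                                     resnum = 5L, atom = "NZ"),
                       site_b = list(body = "B", kind = "atom", chain = "B",
                                     resnum = 9L, atom = "NZ"),
                       target = 12.5, lower = 0, upper = 20, weight = 1,
                       source = "XLMS", label = "X1"),
    distance_restraint(site_a = list(body = "A", kind = "ensemble",
                                     ensemble = "A12_R1"),
                       site_b = list(body = "B", kind = "ensemble",
                                     ensemble = "B9_R1"),
                       target = 55, lower = 53, upper = 57, weight = 2,
                       source = "PELDOR", label = "E1"))
  path <- tempfile()
  write_restraints(rs, path)
  back <- read_restraints(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$upper, 20)
  expect_equal(back[[1]]$site_a$resnum, 5L)
  expect_equal(back[[2]]$site_b$ensemble, "B9_R1")
  expect_equal(back[[2]]$weight, 2)
})
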