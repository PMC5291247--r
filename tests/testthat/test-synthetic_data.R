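test_that("toy bodies are deterministic, clash-free and properly annotated", {
  s1 <- make_toy_bodies(42)
  s2 <- make_toy_bodies(42)
  expect_identical(s1$bodyA$atoms, s2$bodyA$atoms)
  expect_identical(s1$truth_pose$R, s2$truth_pose$R)
  expect_identical(s1$truth_pose$t, s2$truth_pose$t)
  # bodies at the truth pose do not clash
  pa <- body_coords(s1$bodyA)
  pb <- apply_transform(s1$truth_pose, body_coords(s1$bodyB))
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * tcrossprod(pa, pb)
  expect_gt(sqrt(min(d2)), 3.0)
  # designated lysine sites exist, are lysine-typed and carry NZ atoms
  for (r in s1$lysines_a) {
    res <- select_atoms(s1$bodyA, resnum = r)
    expect_true(all(res$resname == "LYS"))
    expect_true("NZ" %in% res$atom)
  }
  # roughly 200 atoms per body, as intended
  expect_gt(nrow(s1$bodyA$atoms), 150)
  expect_lt(nrow(s1$bodyA$atoms), 250)
})

test_that("simulated restraints hit their stated count, targets and noise", {
  sc <- make_toy_bodies(7)
  p <- test_dock_params()
  rs <- simulate_restraints(sc, noise_sd = 0, seed = 3, params = p)
  expect_length(rs$restraints, 5L)
  expect_equal(sum(vapply(rs$restraints, `[[`, "", "source") == "PELDOR"), 3L)
  expect_equal(sum(vapply(rs$restraints, `[[`, "", "source") == "XLMS"), 2L)
  # noiseless restraints validate exactly at the truth pose
  v <- validate_model(sc$bodyA, sc$bodyB, sc$truth_pose, rs$restraints,
                      rs$labels, p)
  expect_lt(v$max_abs_deviation, 1e-9)
  # empirical noise sd over repeated draws matches the requested level
  sigma <- 1.5
  devs <- unlist(lapply(1:40, function(s) {
    r <- simulate_restraints(sc, noise_sd = sigma, seed = s, params = p)
    vapply(seq_along(r$restraints), function(i)
      r$restraints[[i]]$target - r$true_distances[i], 0)
  }))
  expect_equal(sd(devs), sigma, tolerance = 0.15 * sigma)
})

test_that("dipolar datasets round-trip through the inversion", {
  r <- default_r_grid(2, 8, 96L)
  ds <- simulate_dipolar_dataset(mu = 5.49, sigma = 0.3,
                                 times = seq(0, 8, length.out = 250L),
                                 r_grid = r,
                                 background = background_model(1e-9, 0.999),
                                 noise_sd = 0, seed = 2)
  expect_equal(ds$trace$values[1], 1)
  expect_equal(modal_distance(ds$truth), 5.49, tolerance = 0.05)
  inv <- invert_tikhonov(ds$trace, r, lambda = 0.999)
  expect_lt(abs(modal_distance(inv$distribution) - modal_distance(ds$truth)),
            (r[2] - r[1]) + 1e-9)
  # zero modulation depth leaves no dipolar oscillation
  flat <- simulate_dipolar_dataset(mu = 4, times = seq(0, 4, length.out = 100),
                                   background = background_model(0.1, 1e-9),
                                   noise_sd = 0, seed = 3)
  expect_equal(flat$trace$values, exp(-0.1 * flat$trace$times),
               tolerance = 1e-6)
})

test_that("synthetic cross-link spectra carry the isotope doublet and planted ions", {
  seqs <- make_xl_sequences(n_proteins = 3, seed = 11)
  sim <- simulate_xl_spectra(seqs, n_links = 3, coverage = 1,
                             n_noise_peaks = 0, n_background = 2,
                             n_repeats = 1, seed = 11)
  expect_equal(nrow(sim$truth), 3L)
  planted <- Filter(function(s) startsWith(s$title, "planted"), sim$spectra)
  expect_length(planted, 6L)  # d0 + d4 per link
  # d0/d4 precursor masses differ by exactly the 4 x (2H - 1H) shift
  for (i in seq(1, 6, by = 2)) {
    expect_match(planted[[i]]$title, "_d0_")
    expect_match(planted[[i + 1]]$title, "_d4_")
    expect_equal(planted[[i + 1]]$precursor_mass - planted[[i]]$precursor_mass,
                 4.02510, tolerance = 1e-4)
  }
  # full coverage, no noise: the true candidate reaches the maximal score
  lk <- linker_bs2g()
  peptides <- digest_fasta(seqs, max_missed = 3)
  sp <- planted[[1]]
  cand <- enumerate_candidates(peptides, lk, sp$precursor_mass,
                               ms1_tol_ppm = 1)
  scores <- vapply(seq_len(nrow(cand)), function(i)
    score_match(cand[i, ], sp$peaks, lk,
                max_charge = sp$charge - 1L), 0)
  best <- cand[which.max(scores), ]
  key_best <- paste(sort(c(paste(best$alpha_parent,
                                 best$alpha_start + best$alpha_site - 1),
                           paste(best$beta_parent,
                                 best$beta_start + best$beta_site - 1))),
                    collapse = "--")
  tr <- sim$truth[1, ]
  key_true <- paste(sort(c(paste(tr$alpha_parent, tr$alpha_pos),
                           paste(tr$beta_parent, tr$beta_pos))),
                    collapse = "--")
  expect_equal(key_best, key_true)
})

test_that("generated fixtures round-trip through the file readers", {
  sc <- make_toy_bodies(9)
  pdb <- tempfile(fileext = ".pdb")
  write_pdb(sc$bodyA, pdb)
  back <- load_structure(pdb)
  expect_equal(body_coords(back), body_coords(sc$bodyA), tolerance = 1e-3)
  expect_equal(back$atoms$resname, sc$bodyA$atoms$resname)
  seqs <- make_xl_sequences(n_proteins = 2, seed = 5)
  fa <- tempfile(fileext = ".fasta")
  write_fasta(seqs, fa)
  peps_file <- digest_fasta(fa)
  peps_mem <- digest_fasta(seqs)
  expect_equal(peps_file$sequence, peps_mem$sequence)
  sim <- simulate_xl_spectra(seqs, n_links = 1, n_background = 1,
                             n_repeats = 1, seed = 5)
  mgf <- tempfile(fileext = ".mgf")
  write_mgf(sim$spectra, mgf)
  back_sp <- read_mgf(mgf)
  expect_length(back_sp, length(sim$spectra))
  expect_equal(back_sp[[1]]$precursor_mass, sim$spectra[[1]]$precursor_mass,
               tolerance = 1e-3)
})
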