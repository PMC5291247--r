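test_that("tryptic digestion follows the cleavage rule", {
  p0 <- digest("AKRPG", max_missed = 0)
  expect_setequal(p0$sequence, c("AK", "RPG"))  # no cleavage before proline
  p1 <- digest("AKRPG", max_missed = 1)
  expect_setequal(p1$sequence, c("AK", "RPG", "AKRPG"))
  expect_equal(digest("AGSTV", max_missed = 0)$sequence, "AGSTV")
  expect_error(digest("AKZ"), "invalid residue")
  # stored masses are recomputable, and enumeration order does not matter
  p <- digest("MKTAYIAKQRQISFVKSHFSR", max_missed = 2)
  expect_equal(p$mass, peptide_mass(p$sequence), tolerance = 1e-10)
  expect_setequal(p$sequence,
                  digest("MKTAYIAKQRQISFVKSHFSR", max_missed = 2)$sequence)
})

test_that("peptide masses match independent sums of residue masses", {
  expect_equal(peptide_mass("G"), 57.02146 + 18.0105646863, tolerance = 1e-6)
  expect_equal(peptide_mass("ACDEFGHIK"),
               sum(AA_MONO[c("A", "C", "D", "E", "F", "G", "H", "I", "K")]) +
                 MASS_WATER, tolerance = 1e-10)
})

test_that("the BS2G d4-d0 shift equals four H->2H substitutions", {
  lk <- linker_bs2g()
  expect_equal(lk$isotope_delta, 4.02510, tolerance = 1e-4)
  expect_equal(lk$bridge_mass_heavy - lk$bridge_mass_light, lk$isotope_delta)
  expect_gt(lk$isotope_delta, 0)
  # bridge composition C5H4O2
  expect_equal(lk$bridge_mass_light, 96.02113, tolerance = 1e-5)
})

test_that("candidate enumeration respects mass, form and linkable sites", {
  lk <- linker_bs2g()
  seqs <- c(p1 = "AAKAATK", p2 = "GGKGGGR")  # internal K at pos 3 of each
  peps <- digest_fasta(seqs, max_missed = 2)
  m1 <- peptide_mass("AAKAATK"); m2 <- peptide_mass("GGKGGGR")
  prec_d0 <- m1 + m2 + lk$bridge_mass_light
  cand <- enumerate_candidates(peps, lk, prec_d0, ms1_tol_ppm = 1)
  expect_true(any(cand$form == "d0" &
                    cand$alpha_seq == "AAKAATK" & cand$beta_seq == "GGKGGGR" |
                    cand$form == "d0" &
                    cand$alpha_seq == "GGKGGGR" & cand$beta_seq == "AAKAATK"))
  cand4 <- enumerate_candidates(peps, lk, prec_d0 + 4.02510, ms1_tol_ppm = 1)
  expect_true(all(cand4$form == "d4"))
  expect_gt(nrow(cand4), 0)
  # non-N-terminal peptides without an internal lysine cannot be linked
  # (a C-terminal K would have been cleaved, not cross-linked)
  seqs2 <- c(q1 = "MARAAAAATK", q2 = "GGRGGGGGGR")
  peps2 <- digest_fasta(seqs2, max_missed = 0)
  prec2 <- peptide_mass("AAAAATK") + peptide_mass("GGGGGGR") +
    lk$bridge_mass_light
  expect_equal(nrow(enumerate_candidates(peps2, lk, prec2, 1)), 0L)
})

test_that("isotope doublet detection applies charge, RT and ppm rules", {
  lk <- linker_bs2g()
  m <- 2400.1234
  mk_mz <- function(neutral, z) neutral / z + MASS_PROTON
  feats <- data.frame(
    mz = c(mk_mz(m, 4), mk_mz(m + lk$isotope_delta, 4),      # true pair
           mk_mz(m, 3), mk_mz(m + 4.5, 3),                   # wrong delta
           mk_mz(m, 2), mk_mz(m + lk$isotope_delta, 2)),     # charge 2 < 3
    charge = c(4, 4, 3, 3, 2, 2),
    rt = c(10, 10.2, 20, 20, 30, 30))
  pairs <- detect_isotope_doublets(feats, ppm = 10, rt_window = 1)
  expect_equal(nrow(pairs), 1L)
  expect_equal(c(pairs$light, pairs$heavy), c(1L, 2L))
  # non-co-eluting features are not paired
  feats$rt[2] <- 50
  expect_equal(nrow(detect_isotope_doublets(feats, ppm = 10, rt_window = 1)),
               0L)
  # tolerance boundary is inclusive: deviations just inside 10 ppm pair up
  for (frac in c(0.999, 1.001)) {
    dm <- lk$isotope_delta + frac * 10e-6 * m
    f2 <- data.frame(mz = c(mk_mz(m, 4), mk_mz(m + dm, 4)), charge = 4,
                     rt = c(5, 5))
    expect_equal(nrow(detect_isotope_doublets(f2, ppm = 10, rt_window = 1)),
                 as.integer(frac < 1))
  }
})

test_that("score_match equals the exhaustive ion-by-ion oracle", {
  lk <- linker_bs2g()
  cand <- list(alpha_seq = "AAKAATK", beta_seq = "GGKGGGR",
               alpha_site = 3L, beta_site = 3L, form = "d0")
  ions <- fragment_ions(cand$alpha_seq, cand$beta_seq, 3L, 3L,
                        lk$bridge_mass_light, max_charge = 2L)
  # complete spectrum at relative intensity 1: score = number of ions
  full <- data.frame(mz = ions$mz, intensity = 1)
  expect_equal(score_match(cand, full, lk), nrow(ions))
  # empty spectrum scores zero
  expect_equal(score_match(cand, data.frame(mz = numeric(),
                                            intensity = numeric()), lk), 0)
  # random spectra: agreement with the brute-force matcher
  set.seed(31)
  for (i in 1:5) {
    keep <- runif(nrow(ions)) < 0.6
    peaks <- data.frame(
      mz = c(ions$mz[keep], runif(25, 150, 1500)),
      intensity = runif(sum(keep) + 25, 0.05, 1))
    expect_equal(score_match(cand, peaks, lk, ms2_tol_ppm = 0.1),
                 score_oracle(ions$mz, peaks, 0.1))
  }
  # doubling intensities leaves candidate score ordering unchanged
  cand2 <- list(alpha_seq = "AAKAATK", beta_seq = "GGKGGGR",
                alpha_site = 3L, beta_site = 3L, form = "d4")
  peaks <- data.frame(mz = ions$mz[1:10], intensity = runif(10, 0.1, 1))
  peaks2 <- transform(peaks, intensity = 2 * intensity)
  s1 <- c(score_match(cand, peaks, lk), score_match(cand2, peaks, lk))
  s2 <- c(score_match(cand, peaks2, lk), score_match(cand2, peaks2, lk))
  expect_identical(order(s1), order(s2))
})

test_that("decoy FDR estimation follows the counting estimator", {
  # no decoys anywhere: all q-values are 0
  expect_equal(estimate_fdr(c(5, 3, 1), c(FALSE, FALSE, FALSE)), c(0, 0, 0))
  # 18 targets and 2 decoys above the lowest target score: FDR there = 2/18
  scores <- c(seq(10, 1, length.out = 18), 5.5, 4.5)
  decoy <- c(rep(FALSE, 18), TRUE, TRUE)
  q <- estimate_fdr(scores, decoy)
  expect_equal(min(q[!decoy][scores[!decoy] <= min(scores[!decoy])]), 2 / 18,
               tolerance = 1e-12)
  # q-values are monotone non-increasing in score
  ord <- order(scores, decreasing = TRUE)
  expect_true(all(diff(q[ord]) >= -1e-12))
})

test_that("accepted cross-links convert to NZ-NZ flat-bottom restraints", {
  sc <- make_toy_bodies(4)
  matches <- data.frame(
    alpha_parent = c("protA", "protA"),
    alpha_pos = c(sc$lysines_a[1], 999L),   # second link is unresolvable
    beta_parent = "protB", beta_pos = sc$lysines_b[1])
  chain_map <- c(protA = "A:A", protB = "B:B")
  expect_warning(
    rs <- crosslinks_to_restraints(matches, chain_map,
                                   list(A = sc$bodyA, B = sc$bodyB)),
    "dropped")
  expect_length(rs, 1L)
  expect_equal(rs[[1]]$upper, 20)
  expect_equal(rs[[1]]$lower, 0)
  expect_equal(rs[[1]]$site_a$atom, "NZ")
  # any distance at or below the upper bound has zero violation
  e <- pose_energy(sc$bodyA, sc$bodyB, sc$truth_pose, rs)
  expect_equal(e$violations, max(0, e$distances - 20))
  expect_error(crosslinks_to_restraints(
    data.frame(alpha_parent = "unknown", alpha_pos = 1,
               beta_parent = "protB", beta_pos = sc$lysines_b[1]),
    chain_map, list(A = sc$bodyA, B = sc$bodyB)), "unmappable")
})

test_that("MGF writing and reading round-trip spectra", {
  spectra <- list(list(title = "s1", precursor_mass = 2000.5, charge = 4L,
                       rt = 12.5,
                       peaks = data.frame(mz = c(200.1, 300.2),
                                          intensity = c(0.5, 1))))
  path <- tempfile(fileext = ".mgf")
  write_mgf(spectra, path)
  back <- read_mgf(path)
  expect_length(back, 1L)
  expect_equal(back[[1]]$charge, 4L)
  expect_equal(back[[1]]$precursor_mass, 2000.5, tolerance = 1e-4)
  expect_equal(back[[1]]$peaks$mz, c(200.1, 300.2), tolerance = 1e-5)
})
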