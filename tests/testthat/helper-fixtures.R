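# shared fixtures and independent oracles

# minimal hand-written PDB text (3 atoms, 2 residues)
write_mini_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CA  GLY B   2       4.000   5.000   6.000  1.00  0.00           C",
    "END"), path)
  path
}

# one atom in two alternate locations, occupancies 0.6 / 0.4
write_altloc_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "END"), path)
  path
}

random_body <- function(n = 20, seed = NULL, chain = "A") {
  if (!is.null(seed)) set.seed(seed)
  rigid_body(data.frame(
    chain = chain, resnum = seq_len(n), resname = "ALA",
    atom = "CA", element = "C",
    x = rnorm(n, 0, 10), y = rnorm(n, 0, 10), z = rnorm(n, 0, 10)))
}

# independent quaternion-eigenvalue (Horn) superposition oracle
horn_rmsd <- function(mobile, reference) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(reference, 2, colMeans(reference))
  S <- crossprod(X, Y)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[1, 3] + S[3, 1]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(N, symmetric = TRUE)$values)
  msd <- (sum(X^2) + sum(Y^2) - 2 * lam) / nrow(X)
  sqrt(max(msd, 0))
}

# brute-force powder-average quadrature for one kernel column (midpoint rule)
kernel_column_oracle <- function(times, r_nm, n = 1e5) {
  x <- (seq_len(n) - 0.5) / n
  omega <- 2 * pi * 52.041 / r_nm^3
  vapply(times, function(t) mean(cos((1 - 3 * x^2) * omega * t)), numeric(1))
}

# exhaustive ion-by-ion spectrum matcher (independent of score_match):
# each theoretical ion matches the most intense peak within tolerance
score_oracle <- function(ions_mz, peaks, tol_ppm) {
  rel <- peaks$intensity / max(peaks$intensity)
  total <- 0
  for (mz in ions_mz) {
    best <- -Inf
    for (k in seq_len(nrow(peaks))) {
      if (abs(peaks$mz[k] - mz) <= tol_ppm * 1e-6 * mz && rel[k] > best)
        best <- rel[k]
    }
    if (is.finite(best)) total <- total + 1 + log10(best)
  }
  total
}

# shared fast docking parameter set for tests
test_dock_params <- function() {
  docking_params(ensemble_max = 16L, clash_atoms = c("CA", "CB"))
}
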