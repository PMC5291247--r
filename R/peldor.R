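#' Dipolar coupling constant
#'
#' `D = (mu0 / 4 pi) g^2 beta^2 / h` for two free electrons, expressed in
#' MHz nm^3, so that the dipolar frequency at inter-spin distance `r` (nm) is
#' `nu_dd = D / r^3`. Numerically 52.041 MHz nm^3 (g = 2.0023,
#' beta = 9.27401e-24 J/T, mu0 = 4 pi e-7, h = 6.62607e-34 J s).
#' @export
DIPOLAR_D_MHZ_NM3 <- 52.041

#' Dipolar time trace
#'
#' @param times microseconds, strictly increasing, first >= 0.
#' @param values real intensities; renormalized so V at the first time point
#'   equals 1 when `normalize = TRUE`.
#' @param label sample label.
#' @param normalize divide by the first value (default TRUE).
#' @return object of class `dipolar_trace`.
#' @export
dipolar_trace <- function(times, values, label = "", normalize = TRUE) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (times[1] < 0) stop("first time must be >= 0")
  if (normalize) values <- values / values[1]
  structure(list(times = times, values = values, label = label),
            class = "dipolar_trace")
}

#' Distance distribution P(r)
#'
#' @param r_grid nm, uniform and strictly increasing.
#' @param p non-negative weights; normalized so sum(p) * dr = 1.
#' @return object of class `distance_distribution`.
#' @export
distance_distribution <- function(r_grid, p) {
  r_grid <- as.numeric(r_grid); p <- as.numeric(p)
  if (length(r_grid) != length(p)) stop("grid/weights length mismatch")
  dr <- diff(r_grid)
  if (any(dr <= 0) || max(abs(dr - dr[1])) > 1e-9 * dr[1])
    stop("r_grid must be uniform and strictly increasing")
  if (any(p < -1e-12)) stop("p must be non-negative")
  p <- pmax(p, 0)
  s <- sum(p) * dr[1]
  if (s <= 0) stop("distribution integrates to zero")
  structure(list(r = r_grid, p = p / s), class = "distance_distribution")
}

#' Default distance grid
#' @param r_min,r_max nm.
#' @param n points.
#' @return numeric vector (nm).
#' @export
default_r_grid <- function(r_min = 1.5, r_max = 10, n = 256L) {
  seq(r_min, r_max, length.out = n)
}

# Gauss-Legendre nodes/weights on [0, 1] via Golub-Welsch
gauss_legendre_01 <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1L, ]^2
  ord <- order(x)
  list(x = (x[ord] + 1) / 2, w = w[ord] / 2)
}

#' Build the dipolar kernel matrix
#'
#' `K[i, j]` is the powder-averaged dipolar signal of an isolated spin pair
#' at distance `r_grid[j]` (nm) evaluated at `times[i]` (us):
#' `K = integral_0^1 cos((1 - 3 x^2) * 2 pi * (D / r^3) * t) dx`
#' with `x = cos(theta)`. Columns equal 1 at t = 0 by construction.
#'
#' @param times microseconds.
#' @param r_grid nm; must not contain 0.
#' @param n_quad quadrature order for the powder average.
#' @return length(times) x length(r_grid) matrix.
#' @export
build_kernel <- function(times, r_grid, n_quad = 200L) {
  if (any(r_grid <= 0)) stop("r_grid must be strictly positive")
  gl <- gauss_legendre_01(n_quad)
  omega <- 2 * pi * DIPOLAR_D_MHZ_NM3 / r_grid^3  # rad/us per column
  K <- matrix(0, length(times), length(r_grid))
  for (q in seq_len(n_quad)) {
    fac <- 1 - 3 * gl$x[q]^2
    K <- K + gl$w[q] * cos(outer(times, omega * fac))
  }
  K
}

#' Background model: 3D homogeneous exponential decay
#' @param k decay rate, 1/us (>= 0).
#' @param lambda modulation depth, in (0, 1).
#' @return object of class `background_model`.
#' @export
background_model <- function(k, lambda) {
  if (k < 0) stop("k must be >= 0")
  if (lambda <= 0 || lambda >= 1) stop("lambda must be in (0, 1)")
  structure(list(k = k, lambda = lambda), class = "background_model")
}

#' Fit and divide out the intermolecular background
#'
#' Fits `V_bg(t) = (1 - lambda) * exp(-k t)` to the tail of the trace (the
#' window from `fit_start_fraction` of the trace length to its end), divides
#' the raw trace by the fitted background, and renormalizes to 1 at t = 0.
#'
#' @param raw `dipolar_trace`.
#' @param fit_start_fraction start of the fit window as a fraction of the
#'   trace length (default 0.25: the final 75% of the trace).
#' @return list with `form_factor` (`dipolar_trace`) and `background`
#'   (`background_model`).
#' @export
correct_background <- function(raw, fit_start_fraction = 0.25) {
  t <- raw$times; v <- raw$values
  i0 <- which(t >= fit_start_fraction * max(t))
  if (length(i0) < 10L) stop("fit window contains fewer than 10 points")
  tw <- t[i0]; vw <- v[i0]
  # log-linear seed, then least squares on the original scale
  pos <- vw > 0
  if (sum(pos) < 5L) stop("background fit failed: non-positive tail")
  fit0 <- stats::lm(log(vw[pos]) ~ tw[pos])
  k0 <- max(0, -stats::coef(fit0)[2])
  a0 <- min(0.99, max(0.01, exp(stats::coef(fit0)[1])))
  obj <- function(par) {
    a <- par[1]; k <- par[2]
    if (a <= 0 || a >= 1 || k < 0) return(1e10)
    sum((vw - a * exp(-k * tw))^2)
  }
  opt <- stats::optim(c(a0, k0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  a <- opt$par[1]; k <- opt$par[2]
  lambda <- 1 - a
  if (lambda <= 0 || lambda >= 1)
    stop("background fit non-convergent: lambda outside (0, 1)")
  corrected <- v / (a * exp(-k * t))
  list(form_factor = dipolar_trace(t, corrected, label = raw$label),
       background = background_model(k = k, lambda = lambda))
}

# Lawson-Hanson non-negative least squares: min ||A x - b||, x >= 0
nnls_solve <- function(A, b, tol = NULL, max_iter = NULL) {
  n <- ncol(A)
  if (is.null(max_iter)) max_iter <- 3L * n
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b - A %*% x)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * sum(abs(A)) * max(dim(A))
  iter <- 0L
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      Ap <- A[, passive, drop = FALSE]
      zp <- qr.coef(qr(Ap), b)
      zp[is.na(zp)] <- 0
      if (all(zp > 0)) {
        x[] <- 0; x[passive] <- zp
        break
      }
      xp <- x[passive]
      neg <- zp <= 0
      alpha <- min(xp[neg] / (xp[neg] - zp[neg]))
      x[passive] <- xp + alpha * (zp - xp)
      passive[passive] <- x[passive] > tol
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  as.numeric(x)
}

second_difference_operator <- function(n) {
  L <- matrix(0, n - 2L, n)
  for (i in seq_len(n - 2L)) L[i, i:(i + 2L)] <- c(1, -2, 1)
  L
}

#' Tikhonov inversion of a form factor to a distance distribution
#'
#' Solves `min ||K p - V||^2 + alpha^2 ||L2 p||^2` subject to `p >= 0`
#' (L2 = second-difference roughness operator) by non-negative least squares
#' on the stacked system. The modulated part of the form factor is isolated
#' using the fitted (or supplied) modulation depth: `V_mod = (F - (1 -
#' lambda)) / lambda`. If `alpha` is `NULL` it is chosen at the L-curve
#' corner (maximum curvature over a log-spaced grid).
#'
#' @param form_factor `dipolar_trace` after background correction.
#' @param r_grid nm grid (default [default_r_grid()]).
#' @param alpha regularization weight, or `NULL` for L-curve selection.
#' @param lambda modulation depth; if `NULL`, estimated as `1 - min(F)`
#'   clamped away from 0.
#' @param alpha_grid candidate alphas for the L-curve search.
#' @return list with `distribution` (`distance_distribution`), `alpha`,
#'   `residual` (rms misfit of the modulated part).
#' @export
invert_tikhonov <- function(form_factor, r_grid = default_r_grid(),
                            alpha = NULL, lambda = NULL,
                            alpha_grid = 10^seq(-3, 3, length.out = 40L)) {
  t <- form_factor$times; Fv <- form_factor$values
  if (is.null(lambda)) lambda <- max(1 - min(Fv), 0.02)
  Vmod <- (Fv - (1 - lambda)) / lambda
  K <- build_kernel(t, r_grid)
  L <- second_difference_operator(length(r_grid))
  zeros <- numeric(nrow(L))
  solve_one <- function(a) {
    A <- rbind(K, a * L)
    b <- c(Vmod, zeros)
    p <- nnls_solve(A, b)
    list(p = p, rho = sqrt(sum((K %*% p - Vmod)^2)),
         eta = sqrt(sum((L %*% p)^2)))
  }
  if (is.null(alpha)) {
    sols <- lapply(alpha_grid, solve_one)
    lr <- log(pmax(vapply(sols, `[[`, 0, "rho"), 1e-12))
    le <- log(pmax(vapply(sols, `[[`, 0, "eta"), 1e-12))
    # discrete curvature of the parametric L-curve (log rho, log eta)
    n <- length(alpha_grid)
    kap <- rep(-Inf, n)
    for (i in 2:(n - 1L)) {
      d1r <- (lr[i + 1] - lr[i - 1]) / 2; d1e <- (le[i + 1] - le[i - 1]) / 2
      d2r <- lr[i + 1] - 2 * lr[i] + lr[i - 1]
      d2e <- le[i + 1] - 2 * le[i] + le[i - 1]
      denom <- (d1r^2 + d1e^2)^1.5
      if (denom > 1e-14) kap[i] <- (d1r * d2e - d1e * d2r) / denom
    }
    # guard against spurious corners deep in the over-regularized limb:
    # only alphas whose misfit is in the lower half of the log-residual
    # range are corner candidates
    ok <- lr <= min(lr) + 0.5 * (max(lr) - min(lr))
    kap[!ok] <- -Inf
    if (all(!is.finite(kap))) stop("L-curve corner not found on the alpha grid")
    best <- which.max(kap)
    alpha <- alpha_grid[best]
    sol <- sols[[best]]
  } else {
    sol <- solve_one(alpha)
  }
  if (all(sol$p <= 0)) stop("all-zero Tikhonov solution")
  list(distribution = distance_distribution(r_grid, sol$p),
       alpha = alpha,
       residual = sol$rho / sqrt(length(t)))
}

#' Modal distance of a distribution
#'
#' The grid point at the global maximum of P(r); ties are broken toward the
#' smaller distance.
#' @param d `distance_distribution`.
#' @return nm.
#' @export
modal_distance <- function(d) {
  pm <- max(d$p)
  if (pm <= 0 || all(abs(d$p - pm) < 1e-12 * pm))
    stop("flat distribution: no unique mode")
  d$r[which.max(d$p)]  # which.max returns the first (smallest r) maximum
}

#' Mean distance of a distribution
#' @param d `distance_distribution`.
#' @return nm.
#' @export
mean_distance <- function(d) {
  dr <- d$r[2] - d$r[1]
  sum(d$r * d$p) * dr
}

#' Simulate a dipolar trace from a distance distribution
#'
#' `V(t) = [(1 - lambda) + lambda * K p] * exp(-k t) + noise`, with V(0) = 1
#' before noise. Uses R's RNG for the Gaussian noise.
#'
#' @param d `distance_distribution`.
#' @param times microseconds.
#' @param background `background_model`.
#' @param noise_sd Gaussian noise standard deviation (0 = noiseless).
#' @return `dipolar_trace`.
#' @export
simulate_trace <- function(d, times, background = background_model(0.05, 0.3),
                           noise_sd = 0) {
  K <- build_kernel(times, d$r)
  dr <- d$r[2] - d$r[1]
  ff <- as.vector(K %*% (d$p * dr))  # in [.. 1], equals 1 at t = 0
  v <- ((1 - background$lambda) + background$lambda * ff) *
    exp(-background$k * times)
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  dipolar_trace(times, v, normalize = FALSE)
}

#' Gaussian distance distribution on a grid
#' @param r_grid nm.
#' @param mu,sigma nm.
#' @return `distance_distribution`.
#' @export
gaussian_distribution <- function(r_grid, mu, sigma) {
  distance_distribution(r_grid, stats::dnorm(r_grid, mu, sigma))
}

#' Read a two-column dipolar trace (time us, intensity)
#' @param path whitespace- or comma-separated text file.
#' @param label sample label.
#' @return `dipolar_trace`.
#' @export
read_trace <- function(path, label = basename(path)) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          comment.char = "#",
                          col.names = c("t", "v"))
  dipolar_trace(df$t, df$v, label = label)
}

#' Write a dipolar trace as two-column text
#' @param trace `dipolar_trace`.
#' @param path output file.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(data.frame(trace$times, trace$values), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a distance distribution as two-column text (r nm, p)
#' @param d `distance_distribution`.
#' @param path output file.
#' @export
write_distribution <- function(d, path) {
  utils::write.table(data.frame(d$r, d$p), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
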