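# Independent oracles used across the test files. These deliberately avoid
# the package's own quadrature/fit/sampling code paths.

# Closed-form mean detection for the half-normal g(d) = exp(-d^2/(2 s^2))
# over [0, upper]: s * sqrt(2*pi) * (pnorm(upper/s) - 1/2) / upper.
hn_gbar_closed <- function(s, upper = 1) {
  s * sqrt(2 * pi) * (stats::pnorm(upper / s) - 0.5) / upper
}

# Plain g evaluators (duplicated on purpose, not the package's).
oracle_g <- function(name, d, theta) {
  if (name == "half_normal") exp(-d^2 / (2 * theta[1]^2))
  else 1 - exp(-pmin((d / theta[1])^(-theta[2]), 1e300))
}

# Central finite-difference gradient of g with respect to theta.
oracle_fd_grad <- function(name, d, theta, step = 1e-6) {
  vapply(seq_along(theta), function(j) {
    h <- step * max(1, abs(theta[j]))
    up <- dn <- theta
    up[j] <- up[j] + h
    dn[j] <- dn[j] - h
    (oracle_g(name, d, up) - oracle_g(name, d, dn)) / (2 * h)
  }, numeric(length(d)))
}

# Rejection sampler from the detection-conditional density (own loop).
oracle_rcond <- function(n, name, theta, w = 1) {
  out <- numeric(0)
  while (length(out) < n) {
    prop <- stats::runif(2 * n, 0, w)
    keep <- stats::runif(2 * n) < oracle_g(name, prop, theta)
    out <- c(out, prop[keep])
  }
  out[seq_len(n)]
}

# Monte-Carlo estimate of Delta = var(h(D)/g(D)) with entrywise standard
# errors, from draws of D via oracle_rcond. Returns list(est, se), each a
# p x p matrix.
oracle_delta_mc <- function(name, theta, n_draws, w = 1) {
  d <- oracle_rcond(n_draws, name, theta, w)
  g <- oracle_g(name, d, theta)
  H <- t(oracle_fd_grad(name, d, theta))      # p x n
  if (is.null(dim(H))) H <- matrix(H, nrow = 1)
  X <- H / rep(g, each = nrow(H))             # rows: components of h/g
  p <- nrow(X)
  est <- matrix(0, p, p)
  se <- matrix(0, p, p)
  cx <- X - rowMeans(X)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    prod <- cx[i, ] * cx[j, ]
    est[i, j] <- mean(prod)
    se[i, j] <- stats::sd(prod) / sqrt(n_draws)
  }
  list(est = est, se = se)
}

# Numeric inversion of the assembled (1+p) x (1+p) Fisher matrix; returns
# the (1,1) entry (asymptotic variance of the abundance estimator).
oracle_v11_numeric <- function(blocks) {
  p <- length(blocks$I_Ntheta)
  I <- matrix(0, 1 + p, 1 + p)
  I[1, 1] <- blocks$I_NN
  I[1, -1] <- blocks$I_Ntheta
  I[-1, 1] <- blocks$I_Ntheta
  I[-1, -1] <- blocks$I_thetatheta
  solve(I)[1, 1]
}

# Closed-form strip-transect MSE at c = 1 (independent uniform locations):
# the count below w' is binomial(N, q) with q = P (w'/w) gbar_[0,w'], so
# MSE(w') = N^2 (1 - gbar_[0,w'])^2 + N q (1 - q) / (P w' / w)^2.
oracle_strip_mse <- function(name, theta, N, P, w, w_prime) {
  gb_part <- vapply(w_prime, function(wp)
    stats::integrate(function(u) oracle_g(name, u, theta), 0, wp,
                     rel.tol = 1e-10)$value / wp, numeric(1))
  q <- P * (w_prime / w) * gb_part
  N^2 * (1 - gb_part)^2 + N * q * (1 - q) / (P * w_prime / w)^2
}

# Frozen printed penalty tables (hazard rate: rows (P, gbar), columns
# shape 1.1, 1.25, 1.5, 2, 2.5, 3; half-normal: single penalty column).
paper_table2 <- local({
  shapes <- c(1.1, 1.25, 1.5, 2, 2.5, 3)
  rows <- list(
    c(0.1, 0.3, 6.60, 5.28, 3.99, 2.79, 2.25, 1.94),
    c(0.3, 0.3, 6.97, 5.56, 4.19, 2.91, 2.33, 2.00),
    c(0.6, 0.3, 7.63, 6.06, 4.54, 3.12, 2.47, 2.11),
    c(0.9, 0.3, 8.44, 6.68, 4.97, 3.38, 2.65, 2.25),
    c(0.1, 0.6, 5.03, 4.25, 3.43, 2.59, 2.17, 1.92),
    c(0.3, 0.6, 5.62, 4.72, 3.78, 2.82, 2.34, 2.05),
    c(0.6, 0.6, 6.92, 5.77, 4.56, 3.33, 2.71, 2.34),
    c(0.9, 0.6, 9.23, 7.63, 5.96, 4.24, 3.38, 2.87),
    c(0.1, 0.9, 3.28, 2.93, 2.54, 2.09, 1.85, 1.70),
    c(0.3, 0.9, 3.85, 3.41, 2.91, 2.36, 2.06, 1.87),
    c(0.6, 0.9, 5.52, 4.82, 4.04, 3.16, 2.69, 2.39),
    c(0.9, 0.9, 11.94, 10.25, 8.35, 6.24, 5.08, 4.35))
  m <- do.call(rbind, rows)
  data.frame(P = rep(m[, 1], each = 6), gbar = rep(m[, 2], each = 6),
             shape = rep(shapes, 12), F = c(t(m[, -(1:2)])))
})

paper_table3 <- data.frame(
  P = rep(c(0.1, 0.3, 0.6, 0.9), 3),
  gbar = rep(c(0.3, 0.6, 0.9), each = 4),
  F = c(1.52, 1.55, 1.61, 1.69,
        1.78, 1.90, 2.15, 2.60,
        2.23, 2.54, 3.44, 6.90))

# A degenerate parameter-free family with perfect detection (g = 1, h = 0);
# exercises uniform-density and zero-gradient limits.
uniform_family <- function(w = 1) {
  det_family("uniform_perfect", w = w,
             g = function(d, theta) rep(1, length(d)),
             h = function(d, theta) matrix(0, 1, length(d)),
             n_params = 1L)
}

# Parse "label: value" lines from captured CLI output.
cli_num <- function(out, label) {
  line <- grep(paste0("^", label, ":"), out, value = TRUE)[1]
  as.numeric(sub(paste0("^", label, ": *"), "", line))
}
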