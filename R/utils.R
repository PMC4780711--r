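# Internal numeric helpers: condition classes, quadrature, symmetric solves.

stop_validation <- function(...) {
  stop(structure(class = c("ds_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_numeric <- function(...) {
  stop(structure(class = c("ds_numeric_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Adaptive quadrature over [lower, upper]; errors (numeric class) if the
# integrator fails to converge. Integrands here are bounded, so no special
# endpoint handling is needed.
quad <- function(f, lower, upper, abs.tol = 1e-10) {
  res <- tryCatch(
    stats::integrate(f, lower, upper, abs.tol = abs.tol, rel.tol = abs.tol,
                     subdivisions = 400L, stop.on.error = TRUE),
    error = function(e) stop_numeric("quadrature failed on [", lower, ", ",
                                     upper, "]: ", conditionMessage(e)))
  res$value
}

# Solve A x = b for symmetric A with a condition-number guard.
sym_solve <- function(A, b, kappa_max = 1e12) {
  A <- (A + t(A)) / 2
  kappa <- tryCatch(kappa(A, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kappa) || kappa > kappa_max)
    stop_numeric("matrix is numerically singular (condition number ",
                 format(kappa, digits = 3), " exceeds ", kappa_max, ")")
  solve(A, b)
}

# Round half away from zero (matches the printed-table convention; base
# round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
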