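#' Core matrix of the variance penalty
#'
#' `Delta = var(h(D)/g(D))` where `D` is a distance drawn from the
#' detection-conditional density. Computed by entrywise adaptive quadrature
#' as `[w^-1 int h h' / g du] / gbar - hbar hbar' / gbar^2`.
#'
#' @inheritParams grad_g
#' @return Symmetric positive semi-definite `p` x `p` matrix. If the
#'   computed matrix is indefinite beyond tolerance a warning attribute
#'   `"indefinite"` is attached.
#' @export
delta_matrix <- function(family, theta) {
  family <- as_det_family(family)
  family$validate(theta)
  p <- family$n_params
  gb <- gbar(family, theta)
  hb <- hbar(family, theta)
  E <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(i)) {
    E[i, j] <- E[j, i] <- quad(function(u) {
      H <- family$h(u, theta)
      H[i, ] * H[j, ] / family$g(u, theta)
    }, 0, family$w) / family$w
  }
  D <- E / gb - tcrossprod(hb) / gb^2
  D <- (D + t(D)) / 2
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    attr(D, "indefinite") <- min(ev)
  D
}

#' Variance of the abundance estimator with known detection parameters
#'
#' `var = N P^-1 gbar^-1 (1 - P gbar)`, the binomial-count variance of
#' `n / (P gbar)`.
#'
#' @param N true abundance.
#' @param P coverage proportion in (0, 1].
#' @param family,theta detection family and parameters (used for `gbar`),
#'   or supply `gbar_value` directly.
#' @param gbar_value optional pre-computed mean detection probability.
#' @return The variance (a single number); 0 for a census with perfect
#'   detection (`P * gbar = 1`).
#' @export
var_known_theta <- function(N, P, family = NULL, theta = NULL,
                            gbar_value = NULL) {
  if (is.null(N) || !is.numeric(N) || N <= 0)
    stop_validation("'N' (abundance) is required and must be positive")
  if (!is.numeric(P) || P <= 0 || P > 1)
    stop_validation("'P' must lie in (0, 1]")
  gb <- if (is.null(gbar_value)) gbar(family, theta) else gbar_value
  N / (P * gb) * (1 - P * gb)
}

#' Asymptotic variance penalty for unknown detection parameters
#'
#' The factor by which the asymptotic variance of the CDS abundance
#' estimator exceeds the known-parameter variance:
#' `F = 1 + hbar' Delta^-1 hbar / (gbar^2 (1 - P gbar))`, always at least 1
#' because `Delta` is a covariance matrix. When the gradient mean is zero
#' (parameter-free detection) `F = 1` by convention.
#'
#' @inheritParams grad_g
#' @param P coverage proportion in (0, 1].
#' @return The penalty factor, a single number `>= 1`.
#' @examples
#' penalty_F("half_normal", 0.502, P = 0.1)  # about 1.78
#' @export
penalty_F <- function(family, theta, P) {
  family <- as_det_family(family)
  family$validate(theta)
  if (!is.numeric(P) || P <= 0 || P > 1)
    stop_validation("'P' must lie in (0, 1]")
  gb <- gbar(family, theta)
  hb <- hbar(family, theta)
  if (all(abs(hb) < 1e-14)) return(1)
  D <- delta_matrix(family, theta)
  1 + c(crossprod(hb, sym_solve(D, hb))) / (gb^2 * (1 - P * gb))
}

#' Fisher information blocks for (N, theta)
#'
#' Approximate Fisher information of the joint abundance/detection model:
#' `I_NN = N^-1 (1 - P gbar)^-1 P gbar`,
#' `I_Ntheta = (1 - P gbar)^-1 P hbar`, and
#' `I_thetatheta = N P gbar Delta + N P hbar hbar' gbar^-1 (1 - P gbar)^-1`.
#'
#' @inheritParams penalty_F
#' @param N true abundance.
#' @return List with `I_NN` (scalar), `I_Ntheta` (p-vector),
#'   `I_thetatheta` (p x p), plus `gbar`, `hbar`, `Delta`.
#' @export
fisher_blocks <- function(family, theta, N, P) {
  family <- as_det_family(family)
  family$validate(theta)
  if (is.null(N) || !is.numeric(N) || N <= 0)
    stop_validation("'N' (abundance) is required and must be positive")
  if (!is.numeric(P) || P <= 0 || P > 1)
    stop_validation("'P' must lie in (0, 1]")
  gb <- gbar(family, theta)
  hb <- hbar(family, theta)
  D <- delta_matrix(family, theta)
  list(
    I_NN = P * gb / (N * (1 - P * gb)),
    I_Ntheta = P * hb / (1 - P * gb),
    I_thetatheta = N * P * gb * D +
      N * P * tcrossprod(hb) / (gb * (1 - P * gb)),
    gbar = gb, hbar = hb, Delta = D)
}

#' Inverse (variance) blocks of the Fisher information
#'
#' Closed-form blocks of the inverse information matrix:
#' `V22 = N^-1 P^-1 Delta^-1 gbar^-1` (variance of the detection
#' parameters), `V21 = -gbar^-2 P^-1 Delta^-1 hbar` and
#' `V11 = N (1 - P gbar) P^-1 gbar^-1 + N P^-1 gbar^-3 hbar' Delta^-1 hbar`
#' (asymptotic variance of the CDS abundance estimator).
#'
#' @param blocks result of [fisher_blocks()].
#' @param N,P abundance and coverage used to build `blocks`.
#' @return `blocks` extended with `V11`, `V21`, `V22`.
#' @export
variance_blocks <- function(blocks, N, P) {
  gb <- blocks$gbar
  hb <- blocks$hbar
  p <- length(hb)
  if (all(abs(hb) < 1e-14) && all(abs(blocks$Delta) < 1e-14)) {
    # parameter-free limit: no penalty, no information about theta
    blocks$V22 <- matrix(Inf, p, p)
    blocks$V21 <- rep(0, p)
    blocks$V11 <- N * (1 - P * gb) / (P * gb)
    return(blocks)
  }
  Dinv_h <- sym_solve(blocks$Delta, hb)
  V22 <- solve(blocks$Delta) / (N * P * gb)
  V22 <- (V22 + t(V22)) / 2
  blocks$V22 <- V22
  blocks$V21 <- -Dinv_h / (gb^2 * P)
  blocks$V11 <- N * (1 - P * gb) / (P * gb) +
    N * c(crossprod(hb, Dinv_h)) / (P * gb^3)
  blocks
}

#' Full asymptotic summary for a survey design
#'
#' Assembles the Fisher information, its inverse blocks, the known-theta
#' variance, the penalty factor `F = V11 / var_known` and the coefficient of
#' variation of the CDS abundance estimator,
#' `CV = sqrt(F (1 - E[n]/N) / E[n])` with `E[n] = N P gbar`.
#'
#' @inheritParams fisher_blocks
#' @return Object of class `"cds_asymptotics"`.
#' @examples
#' s <- asymptotic_summary("hazard_rate", c(0.448, 2), N = 1667, P = 0.1)
#' s$F_penalty
#' @export
asymptotic_summary <- function(family, theta, N, P) {
  family <- as_det_family(family)
  blocks <- fisher_blocks(family, theta, N, P)
  blocks <- variance_blocks(blocks, N, P)
  vk <- var_known_theta(N, P, gbar_value = blocks$gbar)
  Fpen <- blocks$V11 / vk
  E_n <- N * P * blocks$gbar
  out <- c(blocks, list(
    family = family$name, theta = theta, N = N, P = P, w = family$w,
    var_known = vk, F_penalty = Fpen, E_n = E_n,
    cv = sqrt(Fpen * (1 - E_n / N) / E_n)))
  class(out) <- "cds_asymptotics"
  out
}

#' @export
print.cds_asymptotics <- function(x, ...) {
  cat("Asymptotic efficiency of the CDS abundance estimator\n")
  cat("  family:", x$family, " theta = (",
      paste(signif(x$theta, 4), collapse = ", "), ")  w =", x$w, "\n")
  cat("  N =", x$N, "  P =", x$P, "  E[n] =", signif(x$E_n, 4), "\n")
  cat("  gbar =", signif(x$gbar, 4), "\n")
  cat("  var(N_hat | theta known) =", signif(x$var_known, 4), "\n")
  cat("  penalty F =", signif(x$F_penalty, 4),
      " -> var(N_hat_CDS) =", signif(x$V11, 4), "\n")
  cat("  CV(N_hat_CDS) =", signif(x$cv, 4), "\n")
  invisible(x)
}

#' Coefficient of variation of the CDS estimator
#'
#' `CV = sqrt(F (1 - E_n / N) / E_n)`.
#'
#' @param F_penalty penalty factor (>= 1).
#' @param E_n expected number of detections (0 < E_n < N).
#' @param N true abundance.
#' @return The coefficient of variation.
#' @export
cv_cds <- function(F_penalty, E_n, N) {
  if (F_penalty < 1) stop_validation("'F_penalty' must be >= 1")
  if (E_n <= 0 || E_n >= N)
    stop_validation("'E_n' must lie strictly between 0 and N")
  sqrt(F_penalty * (1 - E_n / N) / E_n)
}

#' Required expected sample size for a target CV
#'
#' Inverts the CV formula: with finite `N`,
#' `E[n] = (N^-1 + CV^2 / F)^-1`; when detections are a negligible fraction
#' of abundance this simplifies to `E[n] = F / CV^2`.
#'
#' @param cv_target target coefficient of variation (> 0).
#' @param F_penalty penalty factor (>= 1); 1 corresponds to known detection
#'   parameters.
#' @param N optional abundance for the finite-population form.
#' @return Required expected number of detections.
#' @examples
#' sample_size(0.2, F_penalty = 2)            # 50
#' sample_size(0.1, F_penalty = 2, N = 1000)  # 166.67
#' @export
sample_size <- function(cv_target, F_penalty, N = NULL) {
  if (!is.numeric(cv_target) || cv_target <= 0)
    stop_validation("'cv_target' must be positive")
  if (F_penalty < 1) stop_validation("'F_penalty' must be >= 1")
  if (is.null(N)) return(F_penalty / cv_target^2)
  1 / (1 / N + cv_target^2 / F_penalty)
}

#' Grid of asymptotic penalties
#'
#' Tabulates the penalty `F` over a grid of coverage proportions, target
#' mean detection rates and (for the hazard rate) shape parameters. The
#' scale parameter is calibrated numerically for each (gbar, shape) pair.
#'
#' @param family `"hazard_rate"` or `"half_normal"` (or a `det_family`).
#' @param P_list coverage proportions.
#' @param gbar_list target mean detection rates.
#' @param shape_list hazard-rate shape parameters; ignored (single `NA`
#'   column) for one-parameter families.
#' @param w truncation distance.
#' @param digits rounding (half away from zero) applied to the `F` column;
#'   `NULL` for unrounded values.
#' @return A data frame with columns `P`, `gbar`, `shape`, `F`, one row per
#'   grid cell; cells whose calibration fails are `NA` with a warning.
#' @export
penalty_table <- function(family, P_list = c(0.1, 0.3, 0.6, 0.9),
                          gbar_list = c(0.3, 0.6, 0.9),
                          shape_list = c(1.1, 1.25, 1.5, 2, 2.5, 3),
                          w = 1, digits = 2) {
  family <- as_det_family(family, w = w)
  if (family$n_params == 1L) shape_list <- NA_real_
  grid <- expand.grid(shape = shape_list, P = P_list, gbar = gbar_list,
                      KEEP.OUT.ATTRS = FALSE)
  # row order: gbar varies slowest, then P, then shape (printed-table layout)
  grid <- grid[order(grid$gbar, grid$P, grid$shape), c("P", "gbar", "shape")]
  rownames(grid) <- NULL
  grid$F <- vapply(seq_len(nrow(grid)), function(i) {
    tryCatch({
      shp <- if (is.na(grid$shape[i])) NULL else grid$shape[i]
      scale <- calibrate_scale(family, grid$gbar[i], shape = shp, w = w)
      penalty_F(family, c(scale, shp), grid$P[i])
    }, error = function(e) {
      warning("cell (P=", grid$P[i], ", gbar=", grid$gbar[i], ", shape=",
              grid$shape[i], ") failed: ", conditionMessage(e), call. = FALSE)
      NA_real_
    })
  }, numeric(1))
  if (!is.null(digits)) grid$F <- round_half_up(grid$F, digits)
  grid
}
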