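#' Detection-function families
#'
#' A detection family describes the probability `g(d; theta)` that an object
#' at perpendicular distance `d` from a transect line is detected, for
#' distances up to a truncation limit `w`. Two families are built in:
#'
#' * `"half_normal"`: `g(d) = exp(-d^2 / (2 theta^2))`, one scale parameter
#'   `theta > 0`.
#' * `"hazard_rate"`: `g(d) = 1 - exp(-(d / theta1)^(-theta2))`, scale
#'   `theta1 > 0` and shape `theta2 > 1`. The shape controls the width of the
#'   "shoulder" (the near-zero range over which detection stays close to 1);
#'   `theta2` near 1 gives a very narrow shoulder, large values a wide one.
#'   The shoulder condition `g'(0) = 0` requires `theta2 > 1`, so smaller
#'   shapes are rejected.
#'
#' Both satisfy `g(0) = 1` (for the hazard rate as a limit, implemented
#' exactly at `d = 0`) and are non-increasing in distance. User-defined
#' families can be created by supplying `g`; the parameter gradient then
#' defaults to central finite differences.
#'
#' @param name family identifier, `"half_normal"`, `"hazard_rate"`, or any
#'   other string for a user-defined family (in which case `g` and
#'   `n_params` are required).
#' @param w truncation distance: the largest perpendicular distance at which
#'   detection is attempted. Distances are usually rescaled so `w = 1`.
#' @param g for user-defined families, a vectorized function
#'   `g(d, theta)` returning detection probabilities in `[0, 1]`.
#' @param h optionally, a function `h(d, theta)` returning the `p` x
#'   `length(d)` matrix of partial derivatives of `g` with respect to
#'   `theta`; defaults to central differences.
#' @param n_params number of parameters `p` of a user-defined family.
#' @param validate optional function `validate(theta)` signalling an error
#'   for invalid parameter vectors.
#' @return An object of class `"det_family"`: a list with elements `name`,
#'   `n_params`, `w`, `g`, `h` and `validate`.
#' @examples
#' hn <- det_family("half_normal")
#' hn$g(0.5, 0.502)
#' gbar(hn, 0.502)   # about 0.6
#' @export
det_family <- function(name, w = 1, g = NULL, h = NULL, n_params = NULL,
                       validate = NULL) {
  if (!is.character(name) || length(name) != 1L)
    stop_validation("'name' must be a single string")
  if (!is.numeric(w) || length(w) != 1L || w <= 0)
    stop_validation("'w' must be a single positive number")
  fam <- switch(name,
    half_normal = list(
      name = "half_normal", n_params = 1L, w = w,
      g = g_half_normal, h = h_half_normal,
      validate = function(theta) {
        if (length(theta) != 1L || !is.finite(theta) || theta <= 0)
          stop_validation("half-normal requires a single positive scale")
        invisible(theta)
      }),
    hazard_rate = list(
      name = "hazard_rate", n_params = 2L, w = w,
      g = g_hazard_rate, h = h_hazard_rate,
      validate = function(theta) {
        if (length(theta) != 2L || !all(is.finite(theta)))
          stop_validation("hazard rate requires parameters (scale, shape)")
        if (theta[1] <= 0)
          stop_validation("hazard-rate scale must be positive")
        if (theta[2] <= 1)
          stop_validation("hazard-rate shape must exceed 1 (shoulder condition)")
        invisible(theta)
      }),
    {
      if (is.null(g) || is.null(n_params))
        stop_validation("user-defined family needs 'g' and 'n_params'")
      list(name = name, n_params = as.integer(n_params), w = w, g = g,
           h = if (is.null(h)) fd_gradient_fn(g) else h,
           validate = if (is.null(validate)) {
             function(theta) {
               if (!all(is.finite(theta)))
                 stop_validation("non-finite parameters")
               invisible(theta)
             }
           } else validate)
    })
  structure(fam, class = "det_family")
}

#' @export
print.det_family <- function(x, ...) {
  cat("Detection family:", x$name, "\n")
  cat("  parameters:", x$n_params, " truncation w =", x$w, "\n")
  invisible(x)
}

as_det_family <- function(family, w = 1) {
  if (inherits(family, "det_family")) return(family)
  det_family(family, w = w)
}

#' Half-normal detection probability
#'
#' `g(d) = exp(-d^2 / (2 theta^2))`, so `g(0) = 1` and `g(theta) = exp(-1/2)`.
#'
#' @param d non-negative perpendicular distance(s).
#' @param theta positive scale parameter (may be given as a length-1 vector).
#' @return Detection probabilities, same length as `d`.
#' @export
g_half_normal <- function(d, theta) {
  theta <- theta[1]
  if (!is.finite(theta) || theta <= 0)
    stop_validation("half-normal scale must be positive")
  exp(-d^2 / (2 * theta^2))
}

# gradient dg/dtheta = d^2/theta^3 * g; a 1 x length(d) matrix
h_half_normal <- function(d, theta) {
  theta <- theta[1]
  rbind(d^2 / theta^3 * exp(-d^2 / (2 * theta^2)))
}

#' Hazard-rate detection probability
#'
#' `g(d) = 1 - exp(-(d / theta1)^(-theta2))` with scale `theta1 > 0` and
#' shape `theta2 > 1`. At `d = 0` the limit value 1 is returned exactly, and
#' the inner exponent is capped to avoid overflow near zero distance.
#'
#' @param d non-negative perpendicular distance(s).
#' @param theta parameter vector `c(scale, shape)`.
#' @return Detection probabilities, same length as `d`.
#' @export
g_hazard_rate <- function(d, theta) {
  if (length(theta) != 2L || theta[1] <= 0 || theta[2] <= 1)
    stop_validation("hazard rate requires scale > 0 and shape > 1")
  out <- numeric(length(d))
  pos <- d > 0
  # log-scale evaluation of (d/theta1)^(-theta2), capped at exp(700)
  lt <- pmin(-theta[2] * (log(d[pos]) - log(theta[1])), 700)
  out[pos] <- 1 - exp(-exp(lt))
  out[!pos] <- 1
  out
}

# gradient; 2 x length(d) matrix, rows (d/dtheta1, d/dtheta2).
# With t = (d/theta1)^(-theta2):  dg/dtheta1 = exp(-t) t theta2 / theta1,
# dg/dtheta2 = exp(-t) t log(theta1/d); both -> 0 as d -> 0.
h_hazard_rate <- function(d, theta) {
  out <- matrix(0, 2L, length(d))
  pos <- d > 0
  if (any(pos)) {
    lt <- pmin(-theta[2] * (log(d[pos]) - log(theta[1])), 700)
    t <- exp(lt)
    et <- exp(-t) * t
    out[1, pos] <- et * theta[2] / theta[1]
    out[2, pos] <- et * log(theta[1] / d[pos])
  }
  out
}

# Central-difference fallback gradient for user-defined families.
fd_gradient_fn <- function(g) {
  function(d, theta) {
    p <- length(theta)
    out <- matrix(0, p, length(d))
    for (j in seq_len(p)) {
      step <- max(1e-6, 1e-6 * abs(theta[j]))
      up <- dn <- theta
      up[j] <- up[j] + step
      dn[j] <- dn[j] - step
      out[j, ] <- (g(d, up) - g(d, dn)) / (2 * step)
    }
    out
  }
}

#' Parameter gradient of a detection function
#'
#' Evaluates `h(d; theta)`, the vector of partial derivatives of the
#' detection probability with respect to the parameters, analytically for
#' the built-in families and by central differences otherwise.
#'
#' @param family a `det_family` object or family name.
#' @param d distance(s) in `[0, w]`.
#' @param theta parameter vector.
#' @return A `p` x `length(d)` matrix.
#' @export
grad_g <- function(family, d, theta) {
  family <- as_det_family(family)
  family$validate(theta)
  family$h(d, theta)
}

#' Mean detection probability over the truncation range
#'
#' The unconditional probability that an object within the covered strip is
#' detected: `gbar = w^-1 integral_0^w g(u; theta) du`, computed by adaptive
#' quadrature.
#'
#' @inheritParams grad_g
#' @return A probability in (0, 1].
#' @examples
#' gbar(det_family("hazard_rate"), c(0.405, 1.25))  # about 0.6
#' @export
gbar <- function(family, theta) {
  family <- as_det_family(family)
  family$validate(theta)
  quad(function(u) family$g(u, theta), 0, family$w) / family$w
}

#' Mean parameter gradient over the truncation range
#'
#' `hbar = w^-1 integral_0^w h(u; theta) du`, componentwise adaptive
#' quadrature. Equals the parameter gradient of [gbar()].
#'
#' @inheritParams grad_g
#' @return A numeric `p`-vector.
#' @export
hbar <- function(family, theta) {
  family <- as_det_family(family)
  family$validate(theta)
  vapply(seq_len(family$n_params), function(j)
    quad(function(u) family$h(u, theta)[j, ], 0, family$w) / family$w,
    numeric(1))
}

#' Conditional density of detected distances
#'
#' The density of the distance of a detected object:
#' `g(d; theta) / integral_0^w g(u; theta) du` on `[0, w]`.
#'
#' @inheritParams grad_g
#' @return Density values, same length as `d`.
#' @export
conditional_density <- function(family, theta, d) {
  family <- as_det_family(family)
  family$validate(theta)
  if (any(d < 0 | d > family$w))
    stop_validation("distances must lie in [0, w]")
  family$g(d, theta) / (gbar(family, theta) * family$w)
}

#' Draw distances from the detection-conditional density
#'
#' Rejection sampler: uniform proposals on `[0, w]` accepted with
#' probability `g(d; theta)` (valid because `g <= 1`).
#'
#' @param n number of draws.
#' @inheritParams grad_g
#' @return Numeric vector of `n` distances in `[0, w]`.
#' @export
rdetect <- function(n, family, theta) {
  family <- as_det_family(family)
  family$validate(theta)
  out <- numeric(0)
  gb <- gbar(family, theta)
  while (length(out) < n) {
    m <- ceiling(1.2 * (n - length(out)) / gb) + 10L
    prop <- stats::runif(m, 0, family$w)
    out <- c(out, prop[stats::runif(m) < family$g(prop, theta)])
  }
  out[seq_len(n)]
}

#' Calibrate the scale parameter to a target mean detection rate
#'
#' Finds the scale parameter (first component of `theta`) such that the mean
#' detection probability over `[0, w]` equals `gbar_target`, by bracketed
#' root-finding. For the hazard-rate family the shape is held fixed at
#' `shape`.
#'
#' @param family a `det_family` object or family name.
#' @param gbar_target target mean detection probability in (0, 1).
#' @param shape fixed non-scale parameter components (hazard-rate shape);
#'   ignored for one-parameter families.
#' @param w truncation distance when `family` is given by name.
#' @param interval search bracket for the scale.
#' @return The calibrated scale (a single number).
#' @examples
#' calibrate_scale("hazard_rate", 0.6, shape = 2)   # about 0.448
#' calibrate_scale("half_normal", 0.6)              # about 0.502
#' @export
calibrate_scale <- function(family, gbar_target, shape = NULL, w = 1,
                            interval = c(1e-4, 1e4)) {
  family <- as_det_family(family, w = w)
  if (!is.numeric(gbar_target) || gbar_target <= 0 || gbar_target >= 1)
    stop_validation("'gbar_target' must lie strictly between 0 and 1")
  obj <- function(s) gbar(family, c(s, shape)) - gbar_target
  lo <- interval[1]; hi <- interval[2]
  flo <- obj(lo); fhi <- obj(hi)
  if (flo * fhi > 0)
    stop_numeric("calibration target ", gbar_target,
                 " unattainable in bracket [", lo, ", ", hi, "]; gbar range [",
                 signif(gbar_target + flo, 4), ", ",
                 signif(gbar_target + fhi, 4), "]")
  root <- stats::uniroot(obj, c(lo, hi), f.lower = flo, f.upper = fhi,
                         tol = 1e-12)$root
  if (abs(obj(root)) > 1e-8)
    stop_numeric("calibration did not reach |gbar - target| <= 1e-8")
  root
}
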