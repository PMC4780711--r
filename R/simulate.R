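#' Configure a replicate survey simulation
#'
#' Defines the data-generating conditions of one simulation cell: the true
#' detection model, the target expected number of detections, the survey
#' geometry (coverage `P = w / M`), the overdispersion factor `c` of the
#' object-location process, and the estimators to evaluate. Abundance is
#' derived as `N = round(E_n / (P gbar(theta_true)))`.
#'
#' @param family true detection family (name or `det_family`).
#' @param theta_true true detection parameters.
#' @param E_n target expected number of detections.
#' @param P coverage proportion; the simulator's geometry sets `M = w / P`.
#' @param w truncation distance.
#' @param c overdispersion factor of interval counts (`>= 1`; 1 is the
#'   independent-uniform case).
#' @param K number of discrete support points of the Dirichlet-process
#'   approximation used when `c > 1`.
#' @param reps number of replicates.
#' @param strip_grid strip widths evaluated; default 0.01, 0.02, ..., 1
#'   times `w`.
#' @param fit_families detection families fitted by conditional ML in each
#'   replicate; `character(0)` to skip fitting (strip/known-theta only).
#' @param seed master seed; per-replicate substream seeds are derived from
#'   it so any replicate is reproducible in isolation.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(family, theta_true, E_n, P = 0.1, w = 1, c = 1,
                       K = 1000L, reps = 1000L,
                       strip_grid = seq(0.01, 1, by = 0.01) * w,
                       fit_families = NULL, seed = 1L) {
  family <- as_det_family(family, w = w)
  family$validate(theta_true)
  if (!is.numeric(P) || P <= 0 || P > 1) stop_validation("'P' must be in (0, 1]")
  if (!is.numeric(E_n) || E_n <= 0) stop_validation("'E_n' must be positive")
  if (!is.numeric(c) || length(c) != 1L || c < 1)
    stop_validation("overdispersion factor 'c' must be >= 1")
  if (K < 2L) stop_validation("'K' must be at least 2")
  gb <- gbar(family, theta_true)
  N <- round(E_n / (P * gb))
  if (N < 1) stop_validation("derived abundance N is below 1")
  if (c > 1 && c >= N) stop_validation("'c' must be smaller than N")
  if (is.null(fit_families)) fit_families <- family$name
  fit_families <- lapply(fit_families, as_det_family, w = w)
  structure(list(
    family = family, theta_true = theta_true, E_n = E_n, P = P, w = w,
    M = w / P, c = c, K = as.integer(K), reps = as.integer(reps),
    strip_grid = strip_grid, fit_families = fit_families,
    master_seed = as.integer(seed), N = N, gbar_true = gb),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat("  truth:", x$family$name, "theta = (",
      paste(signif(x$theta_true, 4), collapse = ", "), ")\n")
  cat("  E[n] =", x$E_n, " P =", x$P, " w =", x$w, " M =", x$M,
      " N =", x$N, "\n")
  cat("  overdispersion c =", x$c, " (K =", x$K, "support points )\n")
  cat("  reps =", x$reps, " seed =", x$master_seed, "\n")
  cat("  fitted families:",
      if (length(x$fit_families))
        paste(vapply(x$fit_families, `[[`, "", "name"), collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Uniform object distances
#'
#' The non-overdispersed location model: `N` independent distances uniform
#' on `(0, M)`.
#'
#' @param N abundance.
#' @param M maximum possible distance from a transect line.
#' @return List with element `distances` (length `N`) and `phi = NULL`.
#' @export
draw_uniform_distances <- function(N, M) {
  if (N < 1 || M <= 0) stop_validation("need N >= 1 and M > 0")
  list(distances = stats::runif(N, 0, M), phi = NULL)
}

#' Dirichlet concentration for a target overdispersion factor
#'
#' Inverts `c = (alpha + N) / (alpha + 1)`: `alpha = (N - c) / (c - 1)`.
#' As `c` decreases to 1, `alpha` grows without bound and the generator
#' reduces to independent uniforms.
#'
#' @param N abundance.
#' @param c overdispersion factor, `1 < c < N`.
#' @return The concentration parameter `alpha`.
#' @export
overdispersion_alpha <- function(N, c) {
  if (!is.numeric(c) || c <= 1)
    stop_validation("'c' must exceed 1 (use the uniform generator at c = 1)")
  if (c >= N) stop_validation("'c' must be smaller than N")
  (N - c) / (c - 1)
}

#' Overdispersed object distances (discrete Dirichlet process)
#'
#' Approximates a Dirichlet process with uniform base measure on `(0, M)`:
#' category probabilities `phi` are drawn from a Dirichlet distribution with
#' concentration `alpha / K` in each of `K` categories (via normalized gamma
#' variates), and the `N` distances are independent draws from the `K`
#' evenly spaced support points, taken as bin midpoints
#' `(2k - 1) M / (2K)`. The count falling in any interval of length `v M`
#' is then beta-binomial with variance inflated by
#' `c = (alpha + N) / (alpha + 1)` relative to the binomial. `phi` must be
#' redrawn for every replicate.
#'
#' @inheritParams draw_uniform_distances
#' @param c overdispersion factor, `1 < c < N`.
#' @param K number of support points.
#' @return List with `distances` (length `N`) and `phi` (length `K`,
#'   summing to 1).
#' @export
draw_overdispersed_distances <- function(N, M, c, K = 1000L) {
  if (N < 1 || M <= 0) stop_validation("need N >= 1 and M > 0")
  if (K < 2L) stop_validation("'K' must be at least 2")
  alpha <- overdispersion_alpha(N, c)
  conc <- alpha / K
  for (try in 1:10) {
    gam <- stats::rgamma(K, shape = conc)
    if (sum(gam) > 0) break
    if (try == 10) stop_numeric("Dirichlet sampler returned all zeros")
    warning("degenerate Dirichlet draw (all zeros); resampling")
  }
  phi <- gam / sum(gam)
  support <- (2 * seq_len(K) - 1) * M / (2 * K)
  idx <- sample.int(K, N, replace = TRUE, prob = phi)
  list(distances = support[idx], phi = phi)
}

#' Thin a population by the detection process
#'
#' Objects beyond the truncation distance are never detected; each object
#' with `d <= w` is detected independently with probability
#' `g(d; theta_true)`.
#'
#' @param distances object distances (any range).
#' @inheritParams grad_g
#' @param w truncation distance.
#' @return The detected distances (a subset of `distances`, all `<= w`).
#' @export
thin_by_detection <- function(distances, family, theta, w = NULL) {
  family <- as_det_family(family)
  family$validate(theta)
  if (is.null(w)) w <- family$w
  d0 <- distances[distances <= w]
  d0[stats::runif(length(d0)) < family$g(d0, theta)]
}

#' Run the replicate simulation harness
#'
#' For each replicate: draw a population of object distances (uniform at
#' `c = 1`, Dirichlet-overdispersed otherwise, with fresh category weights
#' every replicate), thin by the true detection function, then compute the
#' known-theta estimator, the strip-transect estimator at every grid width,
#' and — for each requested fit family — the conditional-ML fit and CDS
#' estimator. Replicates whose fit does not converge (or has fewer than 10
#' detections) are recorded as failures and excluded from that estimator's
#' summary moments.
#'
#' Summary moments use the population (divide-by-reps) variance so that
#' `MSE = variance + bias^2` holds exactly;
#' `RRMSE% = 100 sqrt(MSE) / N` with `N` the true abundance.
#'
#' @param config a [sim_config()].
#' @return Object of class `"cds_sim"`: the config, per-replicate estimate
#'   streams (`known`, `cds` per family, `n`, strip matrix), a tidy
#'   `summary` data frame (columns `estimator`, `w_prime`, `mean`, `var`,
#'   `bias`, `mse`, `rrmse_pct`, `n_used`), and per-family failure counts.
#'   A warning is attached if any fit family fails in more than 5% of
#'   replicates.
#' @examples
#' cfg <- sim_config("half_normal", 0.502, E_n = 50, reps = 50, seed = 7)
#' sim <- run_simulation(cfg)
#' head(summary(sim))
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  reps <- config$reps
  N <- config$N
  P <- config$P
  w <- config$w
  grid <- config$strip_grid
  nfit <- length(config$fit_families)
  fit_names <- vapply(config$fit_families, `[[`, "", "name")

  set.seed(config$master_seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)

  n_det <- integer(reps)
  known <- numeric(reps)
  strip <- matrix(NA_real_, reps, length(grid))
  cds <- matrix(NA_real_, reps, max(nfit, 1L))
  failures <- integer(nfit)

  sorted_counts <- function(d) findInterval(grid, sort(d))

  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    pop <- if (config$c > 1)
      draw_overdispersed_distances(N, config$M, config$c, config$K)
    else draw_uniform_distances(N, config$M)
    det <- thin_by_detection(pop$distances, config$family,
                             config$theta_true, w)
    n <- length(det)
    n_det[r] <- n
    known[r] <- n / (P * config$gbar_true)
    strip[r, ] <- sorted_counts(det) / (P * grid / w)
    for (j in seq_len(nfit)) {
      fit <- tryCatch(
        fit_cml(det, config$fit_families[[j]], P = P),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        failures[j] <- failures[j] + 1L
      } else {
        cds[r, j] <- fit$N_cds
      }
    }
  }

  summarize <- function(x, label, w_prime = NA_real_) {
    x <- x[!is.na(x)]
    m <- mean(x)
    v <- mean((x - m)^2)
    b <- m - N
    mse <- mean((x - N)^2)
    data.frame(estimator = label, w_prime = w_prime, mean = m, var = v,
               bias = b, mse = mse, rrmse_pct = 100 * sqrt(mse) / N,
               n_used = length(x))
  }

  summ <- do.call(rbind, c(
    list(summarize(known, "known_theta")),
    lapply(seq_len(nfit), function(j)
      summarize(cds[, j], paste0("cds_", fit_names[j]))),
    lapply(seq_along(grid), function(k)
      summarize(strip[, k], "strip", grid[k]))))
  rownames(summ) <- NULL

  out <- list(config = config, N = N, n_det = n_det, known = known,
              cds = if (nfit) structure(cds[, seq_len(nfit), drop = FALSE],
                                        dimnames = list(NULL, fit_names))
                    else NULL,
              strip = strip, summary = summ,
              failures = if (nfit) stats::setNames(failures, fit_names)
                         else integer(0))
  if (nfit && any(failures > 0.05 * reps)) {
    out$warning <- paste0("fit failure rate above 5% for: ",
                          paste(fit_names[failures > 0.05 * reps],
                                collapse = ", "))
    warning(out$warning, call. = FALSE)
  }
  class(out) <- "cds_sim"
  out
}

#' @export
print.cds_sim <- function(x, ...) {
  cat("CDS simulation result —", x$config$reps, "replicates\n")
  print(x$config)
  top <- x$summary[x$summary$estimator != "strip", ]
  cat("\nEstimator summaries (strip curve omitted; see summary()):\n")
  print(top, digits = 4, row.names = FALSE)
  if (!is.null(x$cds)) {
    pen <- tryCatch(empirical_penalty(x), error = function(e) NULL)
    if (!is.null(pen))
      cat("\nEmpirical variance penalty (CDS / known-theta):",
          signif(pen, 4), "\n")
  }
  if (!is.null(x$warning)) cat("\nWARNING:", x$warning, "\n")
  invisible(x)
}

#' @export
summary.cds_sim <- function(object, ...) object$summary

#' Empirical variance penalty from a simulation
#'
#' Ratio of the empirical variance of the CDS estimator to that of the
#' known-theta estimator, both computed over the replicates in which the
#' fit converged (so the two streams stay paired).
#'
#' @param result a `cds_sim` object.
#' @param fit_family which fitted family to use; defaults to the first.
#' @return The variance ratio.
#' @export
empirical_penalty <- function(result, fit_family = NULL) {
  stopifnot(inherits(result, "cds_sim"))
  if (is.null(result$cds)) stop_validation("no CDS fits in this result")
  if (is.null(fit_family)) fit_family <- colnames(result$cds)[1]
  x <- result$cds[, fit_family]
  ok <- !is.na(x)
  vk <- stats::var(result$known[ok])
  if (!is.finite(vk) || vk == 0)
    stop_numeric("known-theta estimator has zero variance")
  stats::var(x[ok]) / vk
}

#' MSE-optimal strip width
#'
#' The strip-grid width minimizing the empirical MSE of the strip-transect
#' estimator; ties break toward the smaller width.
#'
#' @param result a `cds_sim` object.
#' @return A single width from the configured grid.
#' @export
optimal_strip_width <- function(result) {
  stopifnot(inherits(result, "cds_sim"))
  s <- result$summary[result$summary$estimator == "strip", ]
  s$w_prime[which.min(s$mse)]
}

#' Range of strip widths where the strip beats CDS
#'
#' The smallest and largest grid widths at which the strip-transect MSE is
#' strictly below the CDS MSE.
#'
#' @inheritParams empirical_penalty
#' @return Named numeric vector `c(low, high)`, both `NA` when the strip
#'   never beats CDS.
#' @export
crossing_range <- function(result, fit_family = NULL) {
  stopifnot(inherits(result, "cds_sim"))
  if (is.null(result$cds)) stop_validation("no CDS fits in this result")
  if (is.null(fit_family)) fit_family <- colnames(result$cds)[1]
  mse_cds <- result$summary$mse[
    result$summary$estimator == paste0("cds_", fit_family)]
  s <- result$summary[result$summary$estimator == "strip", ]
  below <- s$w_prime[s$mse < mse_cds]
  if (length(below) == 0L) return(c(low = NA_real_, high = NA_real_))
  c(low = min(below), high = max(below))
}
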