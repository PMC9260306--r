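#' Fit beta shape parameters from clade summary statistics
#'
#' For a set of variants assumed to come from one subclone, the VAF is
#' modelled as Beta(alpha, beta) where `alpha + beta` equals the mean
#' sequencing depth and `alpha / (alpha + beta)` equals the mean VAF. This is
#' the method-of-moments solution `alpha = vbar * ebar`,
#' `beta = (1 - vbar) * ebar`, which ties the within-cluster variance of VAF
#' to both depth and mean VAF (see [expected_variance()]).
#'
#' @param mean_depth Mean sequencing depth of the clade (reads, > 0).
#' @param mean_vaf Mean VAF of the clade, strictly inside (0, 1). Callers
#'   must clip boundary values first.
#' @return An object of class `beta_params`: a list with elements `alpha`
#'   and `beta`.
#' @examples
#' fit_beta(100, 0.3)   # alpha = 30, beta = 70
#' @seealso [expected_variance()], [tail_probability()]
#' @export
fit_beta <- function(mean_depth, mean_vaf) {
  if (any(!is.finite(mean_depth)) || any(mean_depth <= 0))
    stop("mean_depth must be positive")
  if (any(!is.finite(mean_vaf)) || any(mean_vaf <= 0) || any(mean_vaf >= 1))
    stop("mean_vaf must lie strictly inside (0, 1); clip boundary values")
  structure(list(alpha = mean_vaf * mean_depth,
                 beta  = (1 - mean_vaf) * mean_depth),
            class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  cat(sprintf("Beta(alpha = %.4g, beta = %.4g): mean %.4g, depth %.4g\n",
              x$alpha, x$beta, x$alpha / (x$alpha + x$beta),
              x$alpha + x$beta))
  invisible(x)
}

#' Expected within-cluster variance of VAF under the beta error model
#'
#' Returns `alpha * beta / ((alpha + beta)^2 (alpha + beta + 1))`, which for
#' parameters fitted by [fit_beta()] simplifies to
#' `vbar * (1 - vbar) / (ebar + 1)`: variance shrinks with sequencing depth
#' and, for mean VAF below 0.5, grows with mean VAF.
#'
#' @param params A `beta_params` object from [fit_beta()].
#' @return Expected variance (scalar, or vector if the params are vectors).
#' @export
expected_variance <- function(params) {
  a <- params$alpha
  b <- params$beta
  a * b / ((a + b)^2 * (a + b + 1))
}

#' Log-density of a VAF under a fitted beta distribution
#'
#' Natural-log density. The density can exceed 1 for concentrated
#' distributions, so the log-density (and hence a negative log-likelihood
#' distance built from it) can be positive or negative by design.
#'
#' @param params A `beta_params` object.
#' @param v VAF value(s) strictly inside (0, 1) (clip first).
#' @return Log-density value(s).
#' @export
log_density <- function(params, v) {
  stats::dbeta(v, params$alpha, params$beta, log = TRUE)
}

#' Tail probability of a VAF under a fitted beta distribution
#'
#' The confidence score for assigning a variant to a cluster: the left tail
#' probability `P(X <= v)` when `v` lies below the cluster mean, and the
#' right tail probability `P(X >= v)` otherwise. Scores are in [0, 1], equal
#' 0.5 at the mean of a symmetric distribution, and decrease monotonically
#' as `v` moves away from the mean on either side.
#'
#' @param params A `beta_params` object.
#' @param v VAF value(s) in (0, 1).
#' @return Tail probability value(s) in [0, 1].
#' @export
tail_probability <- function(params, v) {
  a <- params$alpha
  b <- params$beta
  mu <- a / (a + b)
  ifelse(v < mu,
         stats::pbeta(v, a, b),
         stats::pbeta(v, a, b, lower.tail = FALSE))
}

#' Parametric-bootstrap null distribution of within-clade variance
#'
#' Draws `m` values from Beta(alpha, beta) and records their sample variance
#' (unbiased, m - 1 denominator); repeated `R` times this yields the null
#' distribution of the within-clade VAF variance used by the adaptive
#' partitioning test.
#'
#' @param params A `beta_params` object.
#' @param m Clade size (number of variants, >= 2).
#' @param R Number of bootstrap repetitions (default 1000).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return A list of class `null_variance_draws` with elements `values`
#'   (length `R`), `m`, `R` and `seed`.
#' @export
null_variance_sample <- function(params, m, R = 1000, seed = NULL) {
  if (m < 2) stop("m must be >= 2: variance of a single draw is undefined")
  if (R < 2) stop("R must be >= 2")
  values <- with_seed(seed, {
    x <- matrix(stats::rbeta(R * m, params$alpha, params$beta), nrow = R)
    (rowSums(x^2) - rowSums(x)^2 / m) / (m - 1)
  })
  structure(list(values = values, m = m, R = R, seed = seed),
            class = "null_variance_draws")
}
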