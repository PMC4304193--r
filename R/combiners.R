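#' Validate a vector of per-study p-values
#'
#' Checks that every element is a finite probability and clips exact 0s and
#' 1s into the open interval so that downstream quantile transforms stay
#' finite. The result carries the study count `K` and is accepted by every
#' combiner in the package.
#'
#' @param raw numeric vector of per-study p-values, one per study.
#' @param epsilon clipping bound; raw values below `epsilon` or above
#'   `1 - epsilon` are moved to the boundary (with a warning). Default
#'   `1e-15`, close to the smallest p for which `qnorm`/`qgamma` are finite.
#' @return a numeric vector of class `"study_pvalues"` with attribute `K`.
#' @examples
#' validate_pvalues(c(0.94, 0.0015, 0.97, 0.79, 0.81))
#' @export
validate_pvalues <- function(raw, epsilon = 1e-15) {
  if (inherits(raw, "study_pvalues")) return(raw)
  if (length(raw) == 0L) stop_input("no studies")
  if (!is.numeric(raw)) stop_input("p-values must be numeric")
  bad <- which(!is.finite(raw) | raw < 0 | raw > 1)
  if (length(bad) > 0L)
    stop_input("invalid p-value at index ", bad[1L],
               " (value ", format(raw[bad[1L]]), ")")
  clipped <- pmin(pmax(raw, epsilon), 1 - epsilon)
  n_clip <- sum(clipped != raw)
  if (n_clip > 0L)
    warning(n_clip, " p-value(s) clipped into [", format(epsilon), ", 1 - ",
            format(epsilon), "]", call. = FALSE)
  structure(clipped, K = length(clipped), class = "study_pvalues")
}

#' Weight specification for weighted z-tests
#'
#' Describes how per-study weights for [weighted_z_combine()] are derived:
#' all-equal (`"unit"`, the Stouffer test), proportional to sample size
#' (`"sample_size"`, the Mosteller-Bush test), to its square root
#' (`"sqrt_sample_size"`), to the inverse of the per-study standard error
#' (`"inverse_se"`), or given explicitly (`"explicit"`). Only weight ratios
#' matter; no normalization is applied.
#'
#' @param mode one of `"unit"`, `"sample_size"`, `"sqrt_sample_size"`,
#'   `"inverse_se"`, `"explicit"`.
#' @param weights positive numeric vector, required iff `mode = "explicit"`.
#' @param sample_sizes positive integers, required for the sample-size modes.
#' @param standard_errors positive reals, required for `mode = "inverse_se"`.
#' @return an object of class `"weight_spec"`.
#' @export
weight_spec <- function(mode = c("unit", "sample_size", "sqrt_sample_size",
                                 "inverse_se", "explicit"),
                        weights = NULL, sample_sizes = NULL,
                        standard_errors = NULL) {
  mode <- match.arg(mode)
  if (mode == "explicit" && is.null(weights))
    stop_input("mode 'explicit' requires weights")
  if (mode %in% c("sample_size", "sqrt_sample_size") && is.null(sample_sizes))
    stop_input("mode '", mode, "' requires sample_sizes")
  if (mode == "inverse_se" && is.null(standard_errors))
    stop_input("mode 'inverse_se' requires standard_errors")
  structure(list(mode = mode, weights = weights,
                 sample_sizes = sample_sizes,
                 standard_errors = standard_errors),
            class = "weight_spec")
}

#' Resolve a weight specification to a numeric weight vector
#'
#' @param spec a [weight_spec()], or a bare positive numeric vector (treated
#'   as explicit weights).
#' @param K number of studies the weights must match.
#' @return numeric vector of `K` positive weights.
#' @export
resolve_weights <- function(spec, K) {
  if (is.numeric(spec)) spec <- weight_spec("explicit", weights = spec)
  if (!inherits(spec, "weight_spec")) stop_input("not a weight_spec")
  w <- switch(spec$mode,
    unit            = rep(1, K),
    sample_size     = as.numeric(spec$sample_sizes),
    sqrt_sample_size = sqrt(as.numeric(spec$sample_sizes)),
    inverse_se      = 1 / as.numeric(spec$standard_errors),
    explicit        = as.numeric(spec$weights))
  if (length(w) != K)
    stop_input("weight vector length ", length(w), " does not match K = ", K)
  if (any(!is.finite(w) | w <= 0))
    stop_input("all resolved weights must be positive and finite")
  w
}

# method token for a resolved weight mode
.weight_token <- c(unit = "z", sample_size = "z_n",
                   sqrt_sample_size = "z_sqrt_n", inverse_se = "z_se",
                   explicit = "z_w")

combine_result <- function(method, statistic, null_description, combined_p,
                           mc_stderr = NULL) {
  structure(list(method = method, statistic = statistic,
                 null_description = null_description,
                 combined_p = combined_p, mc_stderr = mc_stderr),
            class = "combine_result")
}

#' @export
print.combine_result <- function(x, ...) {
  cat(sprintf("%-8s statistic = %.6g, combined p = %.4g  [%s]\n",
              x$method, x$statistic, x$combined_p, x$null_description))
  if (!is.null(x$mc_stderr))
    cat(sprintf("         MC stderr = %.3g\n", x$mc_stderr))
  invisible(x)
}

#' @export
as.data.frame.combine_result <- function(x, ...) {
  data.frame(method = x$method, statistic = x$statistic,
             combined_p = x$combined_p,
             mc_stderr = if (is.null(x$mc_stderr)) NA_real_ else x$mc_stderr,
             null_description = x$null_description,
             stringsAsFactors = FALSE)
}

#' Stouffer's unweighted z-test
#'
#' Combines one-sided p-values by summing their standard-normal quantiles:
#' `Z = sum(qnorm(p_i)) / sqrt(K)`, referred to the standard normal.
#' Small input p-values (evidence for the common alternative) give negative
#' `Z` and a small combined p, so `combined_p = pnorm(Z)`.
#'
#' @param p per-study p-values (vector or [validate_pvalues()] result).
#' @return a `combine_result` with method token `"z"`.
#' @examples
#' stouffer_combine(c(0.05, 0.05))   # combined p ~ 0.01
#' @export
stouffer_combine <- function(p) {
  p <- validate_pvalues(p)
  K <- attr(p, "K")
  z <- sum(qnorm(as.numeric(p))) / sqrt(K)
  combine_result("z", z, "standard normal", pnorm(z))
}

#' Weighted z-test (Mosteller-Bush and variants)
#'
#' `Z = sum(w_i * qnorm(p_i)) / sqrt(sum(w_j^2))` with `combined_p =
#' pnorm(Z)`. With all weights equal this is the Stouffer test; with
#' `w_i = n_i` it is the Mosteller-Bush test; `sqrt(n_i)` and `1/se_i`
#' weightings are also in common use.
#'
#' @inheritParams stouffer_combine
#' @param w a [weight_spec()] or a positive numeric weight vector.
#' @return a `combine_result`; the method token reflects the weighting mode.
#' @examples
#' weighted_z_combine(c(0.05, 0.05),
#'   weight_spec("sample_size", sample_sizes = c(100, 400)))
#' @export
weighted_z_combine <- function(p, w) {
  p <- validate_pvalues(p)
  K <- attr(p, "K")
  mode <- if (inherits(w, "weight_spec")) w$mode else "explicit"
  wv <- resolve_weights(w, K)
  z <- sum(wv * qnorm(as.numeric(p))) / sqrt(sum(wv^2))
  combine_result(.weight_token[[mode]], z, "standard normal", pnorm(z))
}

#' Fisher's method
#'
#' `X = -2 * sum(log(p_i))`, chi-square with `2K` degrees of freedom under
#' the global null; `combined_p` is the upper-tail probability.
#'
#' @inheritParams stouffer_combine
#' @return a `combine_result` with method token `"fisher"`.
#' @examples
#' fisher_combine(c(0.94, 0.0015, 0.97, 0.79, 0.81))  # ~ 0.17
#' @export
fisher_combine <- function(p) {
  p <- validate_pvalues(p)
  K <- attr(p, "K")
  stat <- -2 * sum(log(as.numeric(p)))
  combine_result("fisher", stat, sprintf("chi-square df=%d", 2L * K),
                 pchisq(stat, df = 2 * K, lower.tail = FALSE))
}

#' Lancaster's chi-square-quantile method
#'
#' Generalizes Fisher's method by assigning each study its own chi-square
#' degrees of freedom `d_i`: the statistic is
#' `sum(qchisq(1 - p_i, df = d_i))`, chi-square with `sum(d_i)` df under the
#' null. With all `d_i = 2` this is Fisher's method; with all `d_i = 1` it
#' is the Chen-Nadarajah test.
#'
#' @inheritParams stouffer_combine
#' @param d positive per-study degrees of freedom, length `K` (a scalar is
#'   recycled).
#' @return a `combine_result` with method token `"lancaster"`.
#' @export
lancaster_combine <- function(p, d) {
  p <- validate_pvalues(p)
  K <- attr(p, "K")
  if (length(d) == 1L) d <- rep(d, K)
  if (length(d) != K)
    stop_input("df vector length ", length(d), " does not match K = ", K)
  if (any(!is.finite(d) | d <= 0)) stop_input("all df must be positive")
  stat <- sum(qchisq(as.numeric(p), df = d, lower.tail = FALSE))
  combine_result("lancaster", stat,
                 sprintf("chi-square df=%g", sum(d)),
                 pchisq(stat, df = sum(d), lower.tail = FALSE))
}

#' Chen-Nadarajah test
#'
#' The Lancaster combiner with one degree of freedom per study. Its per-study
#' term `qchisq(1 - p_i, 1)` equals `qnorm(p_i)^2`, so the test can also be
#' read as a z-test weighted by the absolute estimated effect.
#'
#' @inheritParams stouffer_combine
#' @return a `combine_result` with method token `"cn"`.
#' @export
chen_nadarajah_combine <- function(p) {
  res <- lancaster_combine(p, 1)
  res$method <- "cn"
  res
}

#' Gamma-quantile combiner with fixed shapes
#'
#' `T = sum(qgamma(1 - p_i, shape = alpha_i, scale = beta))`; under the
#' global null `T` is gamma with shape `sum(alpha_i)` and the same scale.
#' With `alpha_i = v/2, beta = 2` this is Lancaster's method with `v` df per
#' study (`v = 2`: Fisher; `v = 1`: Chen-Nadarajah). The combined p-value
#' does not depend on `beta`, which rescales statistic and null together.
#'
#' @inheritParams stouffer_combine
#' @param shapes positive per-study gamma shapes, length `K` (scalar
#'   recycled).
#' @param scale positive common scale parameter `beta` (default 1).
#' @return a `combine_result` with method token `"gamma"`.
#' @export
gamma_combine <- function(p, shapes, scale = 1) {
  p <- validate_pvalues(p)
  K <- attr(p, "K")
  if (length(shapes) == 1L) shapes <- rep(shapes, K)
  if (length(shapes) != K)
    stop_input("shape vector length ", length(shapes),
               " does not match K = ", K)
  if (any(!is.finite(shapes) | shapes <= 0))
    stop_input("all shapes must be positive")
  if (!is.finite(scale) || scale <= 0) stop_input("scale must be positive")
  stat <- sum(qgamma(as.numeric(p), shape = shapes, scale = scale,
                     lower.tail = FALSE))
  combine_result("gamma", stat,
                 sprintf("gamma(shape=%g, scale=%g)", sum(shapes), scale),
                 pgamma(stat, shape = sum(shapes), scale = scale,
                        lower.tail = FALSE))
}

# upper-tail gamma quantile at probability p for (possibly huge) shapes.
# For shape >= wh_threshold the inverse-incomplete-gamma route loses
# accuracy/speed, so we switch to the Wilson-Hilferty cube-root normal
# approximation, whose relative error is O(1/shape).
.gamma_upper_quantile <- function(p, shape, wh_threshold = 1e8) {
  q <- numeric(length(p))
  big <- shape >= wh_threshold
  if (any(!big))
    q[!big] <- qgamma(p[!big], shape = shape[!big], scale = 1,
                      lower.tail = FALSE)
  if (any(big)) {
    z <- qnorm(p[big], lower.tail = FALSE)
    a <- shape[big]
    q[big] <- a * (1 - 1 / (9 * a) + z / (3 * sqrt(a)))^3
  }
  q
}

#' Adaptive-shape gamma statistic
#'
#' The per-study term is the upper-tail gamma quantile at `1 - p_i` with
#' shape `1/p_i` and scale 1: `T = sum(qgamma(1 - p_i, shape = 1/p_i))`.
#' Because a gamma(shape, 1) variable has mean equal to its shape, a small
#' p-value both picks a large shape and a far upper quantile, so small
#' p-values dominate the sum; `T` is strictly decreasing in every `p_i`.
#' The shape adapts to the data, so `T` has no closed-form null; see
#' [adaptive_gamma_combine()] for the Monte-Carlo p-value.
#'
#' For `1/p_i >= 1e8` the quantile is evaluated by the Wilson-Hilferty
#' cube-root normal approximation, which is accurate to `O(p_i)` relative
#' error there and keeps the evaluation stable.
#'
#' @inheritParams stouffer_combine
#' @return the statistic `T` (a single finite number).
#' @examples
#' adaptive_gamma_statistic(c(0.5, 0.5))  # ~ 3.3567
#' @export
adaptive_gamma_statistic <- function(p) {
  p <- validate_pvalues(p)
  pv <- as.numeric(p)
  terms <- .gamma_upper_quantile(pv, 1 / pv)
  bad <- which(!is.finite(terms))
  if (length(bad) > 0L)
    stop_numeric("gamma quantile evaluation failed for study ", bad[1L],
                 " (p = ", format(pv[bad[1L]]), ")")
  sum(terms)
}

#' Apply several p-value combiners at once
#'
#' Dispatches on method tokens and returns one `combine_result` per method.
#' Weighted z variants require `sample_sizes` or `standard_errors`; the
#' `"new"` (adaptive gamma) method uses a Monte-Carlo null of `null_n` draws
#' (see [adaptive_gamma_combine()]).
#'
#' @inheritParams stouffer_combine
#' @param methods character vector of method tokens among `"z"`, `"z_n"`,
#'   `"z_sqrt_n"`, `"z_se"`, `"fisher"`, `"cn"`, `"new"`.
#' @param sample_sizes per-study sample sizes for `"z_n"`/`"z_sqrt_n"`.
#' @param standard_errors per-study standard errors for `"z_se"`.
#' @param null_n Monte-Carlo null size for `"new"` (default `1e6`).
#' @param seed RNG seed for the Monte-Carlo null.
#' @param store optional prebuilt [build_null_store()] result for `"new"`.
#' @param cache_dir optional directory for caching null stores on disk.
#' @return a named list of `combine_result` objects, in request order.
#' @export
combine_pvalues <- function(p, methods = c("z", "fisher", "cn", "new"),
                            sample_sizes = NULL, standard_errors = NULL,
                            null_n = 1e6, seed = 1, store = NULL,
                            cache_dir = NULL) {
  p <- validate_pvalues(p)
  if (length(methods) == 0L) stop_input("no methods requested")
  out <- lapply(methods, function(m) {
    switch(m,
      z        = stouffer_combine(p),
      z_n      = weighted_z_combine(p, weight_spec("sample_size",
                   sample_sizes = sample_sizes)),
      z_sqrt_n = weighted_z_combine(p, weight_spec("sqrt_sample_size",
                   sample_sizes = sample_sizes)),
      z_se     = weighted_z_combine(p, weight_spec("inverse_se",
                   standard_errors = standard_errors)),
      fisher   = fisher_combine(p),
      cn       = chen_nadarajah_combine(p),
      new      = adaptive_gamma_combine(p, N = null_n, seed = seed,
                   store = store, cache_dir = cache_dir),
      stop_input("unknown method token '", m, "'"))
  })
  names(out) <- methods
  out
}

#' Tabulate a list of combine results
#'
#' @param results a list of `combine_result` objects (e.g. from
#'   [combine_pvalues()]).
#' @return a data.frame with columns method, statistic, combined_p,
#'   mc_stderr, null_description.
#' @export
combine_results_table <- function(results) {
  if (inherits(results, "combine_result")) results <- list(results)
  do.call(rbind, lapply(results, as.data.frame))
}
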