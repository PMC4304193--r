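#' Per-study sample-size specification
#'
#' Study group sizes are either fixed at `n` or drawn per study and
#' replicate from Poisson(`lambda`), redrawing any value below `n_min` so
#' the two-sample t-test is always defined.
#'
#' @param mode `"fixed"` or `"poisson"`.
#' @param n fixed per-group size (mode `"fixed"`).
#' @param lambda Poisson mean (mode `"poisson"`).
#' @param n_min floor for drawn sizes (default 2).
#' @return an object of class `"sample_size_spec"`.
#' @export
sample_size_spec <- function(mode = c("fixed", "poisson"), n = 20,
                             lambda = 20, n_min = 2) {
  mode <- match.arg(mode)
  if (mode == "fixed" && (!is.finite(n) || n < 2))
    stop_input("fixed sample size must be >= 2")
  if (mode == "poisson" && (!is.finite(lambda) || lambda <= 0))
    stop_input("lambda must be positive")
  if (n_min < 2) stop_input("n_min must be >= 2")
  structure(list(mode = mode, n = as.integer(n), lambda = lambda,
                 n_min = as.integer(n_min)), class = "sample_size_spec")
}

#' Per-study standard-deviation specification
#'
#' The common within-group standard deviation is either fixed at `sigma` or
#' drawn per study and replicate from a gamma distribution with the given
#' shape and scale (the heterogeneous-variance condition uses
#' gamma(10, 0.1), mean 1).
#'
#' @param mode `"fixed"` or `"gamma"`.
#' @param sigma fixed standard deviation (mode `"fixed"`).
#' @param shape,scale gamma parameters (mode `"gamma"`).
#' @return an object of class `"sigma_spec"`.
#' @export
sigma_spec <- function(mode = c("fixed", "gamma"), sigma = 1, shape = 10,
                       scale = 0.1) {
  mode <- match.arg(mode)
  if (mode == "fixed" && (!is.finite(sigma) || sigma <= 0))
    stop_input("sigma must be positive")
  if (mode == "gamma" && (shape <= 0 || scale <= 0))
    stop_input("gamma shape and scale must be positive")
  structure(list(mode = mode, sigma = sigma, shape = shape, scale = scale),
            class = "sigma_spec")
}

#' Simulation scenario
#'
#' One condition of the power study: `K` independent studies, study `i`
#' comparing a control group N(0, sigma^2) with a treatment group
#' N(effects[i], sigma^2), both of the same per-group size; a one-sided
#' two-sample t-test p-value per study feeds the combiners.
#'
#' @param K number of studies.
#' @param effects numeric vector of `K` treatment-group means (a scalar is
#'   recycled); all zero is the global null.
#' @param n_spec a [sample_size_spec()].
#' @param s_spec a [sigma_spec()].
#' @param reps Monte-Carlo replicates (default `1e4`).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed.
#' @return an object of class `"scenario"`.
#' @export
scenario <- function(K, effects = 0, n_spec = sample_size_spec(),
                     s_spec = sigma_spec(), reps = 1e4, alpha = 0.05,
                     seed = 1) {
  K <- as.integer(K)
  if (K < 1L) stop_input("K must be >= 1")
  if (length(effects) == 1L) effects <- rep(effects, K)
  if (length(effects) != K)
    stop_input("effects length ", length(effects), " does not match K = ", K)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop_input("alpha must be in (0, 1)")
  if (reps < 1) stop_input("reps must be >= 1")
  structure(list(K = K, effects = as.numeric(effects), n_spec = n_spec,
                 s_spec = s_spec, reps = as.integer(reps), alpha = alpha,
                 seed = as.integer(seed)), class = "scenario")
}

#' Split a total effect between two studies at a given ratio
#'
#' For `K = 2` heterogeneity designs: returns `(mu1, mu2)` with
#' `mu1/mu2 = ratio` and `mu1 + mu2 = total`, i.e. `mu2 = total/(1+ratio)`.
#' `ratio = 0` puts the whole effect in study 2; `ratio = 1` splits it
#' evenly.
#'
#' @param total total effect size (positive).
#' @param ratio ratio of study-1 to study-2 effect, in \[0, 1\].
#' @return numeric vector `c(mu1, mu2)`.
#' @export
allocate_effects_ratio <- function(total, ratio) {
  if (!is.finite(total) || total <= 0) stop_input("total must be positive")
  if (!is.finite(ratio) || ratio < 0 || ratio > 1)
    stop_input("ratio must be in [0, 1]")
  mu2 <- total / (1 + ratio)
  c(total - mu2, mu2)
}

#' Concentrate a total effect in a few of K studies
#'
#' Sparse-signal designs: `i_active` studies share the total equally
#' (`total / i_active` each) and the remaining `K - i_active` have zero
#' effect.
#'
#' @param K number of studies.
#' @param total total effect size.
#' @param i_active number of studies carrying the effect (1..K).
#' @return numeric vector of `K` effects.
#' @export
allocate_effects_sparse <- function(K, total, i_active) {
  K <- as.integer(K); i_active <- as.integer(i_active)
  if (i_active < 1L || i_active > K)
    stop_input("i_active must be between 1 and K")
  c(rep(total / i_active, i_active), rep(0, K - i_active))
}

#' One simulated study p-value
#'
#' Draws two samples of size `n` from N(0, sigma^2) and N(mu, sigma^2) and
#' returns the pooled-variance two-sample t-test p-value, one-sided for
#' mean2 > mean1 by default (small p when the treatment mean is raised).
#'
#' @param n per-group sample size (>= 2).
#' @param mu treatment-group mean.
#' @param sigma common standard deviation.
#' @param two_sided if `TRUE`, return the two-sided p-value instead.
#' @return a single p-value.
#' @export
simulate_study_pvalue <- function(n, mu, sigma, two_sided = FALSE) {
  if (n < 2) stop_input("n must be >= 2")
  if (sigma <= 0) stop_input("sigma must be positive")
  x1 <- rnorm(n, 0, sigma)
  x2 <- rnorm(n, mu, sigma)
  sp2 <- (var(x1) + var(x2)) / 2
  tval <- (mean(x2) - mean(x1)) / sqrt(sp2 * 2 / n)
  df <- 2 * n - 2
  if (two_sided) 2 * pt(abs(tval), df, lower.tail = FALSE)
  else pt(tval, df, lower.tail = FALSE)
}

# Vectorized study simulation via sufficient statistics: the two group
# means are N(mu_g, sigma^2/n) and each (n-1)s_g^2/sigma^2 is chi-square
# with n-1 df, independently -- distributionally identical to drawing the
# 2n observations. Returns per-study p-values, realized n, and the
# estimated standard error of the mean difference (used for z_se weights).
.draw_study_stats <- function(ns, mus, sigmas, two_sided = FALSE) {
  M <- length(ns)
  m1 <- rnorm(M, 0, sigmas / sqrt(ns))
  m2 <- rnorm(M, mus, sigmas / sqrt(ns))
  df <- 2 * ns - 2
  sp2 <- sigmas^2 * (rchisq(M, ns - 1) + rchisq(M, ns - 1)) / df
  se <- sqrt(sp2 * 2 / ns)
  tval <- (m2 - m1) / se
  p <- if (two_sided) 2 * pt(abs(tval), df, lower.tail = FALSE)
       else pt(tval, df, lower.tail = FALSE)
  list(p = p, n = ns, se = se)
}

.draw_sizes <- function(spec, M) {
  if (spec$mode == "fixed") return(rep(spec$n, M))
  ns <- rpois(M, spec$lambda)
  low <- ns < spec$n_min
  while (any(low)) {
    ns[low] <- rpois(sum(low), spec$lambda)
    low <- ns < spec$n_min
  }
  ns
}

.draw_sigmas <- function(spec, M) {
  if (spec$mode == "fixed") return(rep(spec$sigma, M))
  rgamma(M, shape = spec$shape, scale = spec$scale)
}

.power_methods <- c("z", "z_n", "z_sqrt_n", "z_se", "fisher", "cn", "new")

#' Estimate type-I error or power for a scenario
#'
#' Runs `reps` replicates of the scenario: per replicate, draw each study's
#' per-group size and standard deviation from their specs, simulate the
#' one-sided two-sample t-test p-value for every study, apply every
#' requested combiner, and record rejection at level `alpha`. Under an
#' all-zero effect vector the rejection proportion estimates the type-I
#' error; otherwise the power.
#'
#' The weighted z-tests use each replicate's realized per-study sizes
#' (`z_n`, `z_sqrt_n`) or estimated standard errors of the mean difference
#' (`z_se`). The `"new"` test compares each replicate's statistic against a
#' single Monte-Carlo null store of `null_n` draws built once per run (null
#' draws are independent of the data stream).
#'
#' @param sc a [scenario()].
#' @param methods method tokens among `"z"`, `"z_n"`, `"z_sqrt_n"`,
#'   `"z_se"`, `"fisher"`, `"cn"`, `"new"`.
#' @param null_n null-store size for `"new"` (default `1e5`).
#' @param store optional prebuilt [build_null_store()] for `"new"` (must
#'   match `sc$K`).
#' @param two_sided feed two-sided t-test p-values instead (sensitivity
#'   analysis; the z-family is not directional under this choice).
#' @return a data.frame of class `"power_result"` with columns `method`,
#'   `reject` (rejection proportion), `se` (binomial Monte-Carlo standard
#'   error); attributes `scenario` and `reps`.
#' @export
run_power_study <- function(sc, methods = c("z", "z_n", "z_se", "fisher",
                                            "cn", "new"),
                            null_n = 1e5, store = NULL, two_sided = FALSE) {
  if (!inherits(sc, "scenario")) stop_input("sc must be a scenario")
  if (length(methods) == 0L) stop_input("no methods requested")
  unknown <- setdiff(methods, .power_methods)
  if (length(unknown) > 0L)
    stop_input("unknown method token '", unknown[1L], "'")

  K <- sc$K; reps <- sc$reps
  if ("new" %in% methods && is.null(store))
    store <- build_null_store(K, null_n, seed = sc$seed + 1L)
  if ("new" %in% methods && store$K != K)
    stop_input("null store built for K = ", store$K, ", scenario K = ", K)

  sim <- with_seed(sc$seed, {
    M <- reps * K
    ns <- .draw_sizes(sc$n_spec, M)
    sigmas <- .draw_sigmas(sc$s_spec, M)
    mus <- rep(sc$effects, times = reps)
    .draw_study_stats(ns, mus, sigmas, two_sided = two_sided)
  })
  pm <- matrix(pmin(pmax(sim$p, 1e-15), 1 - 1e-15), nrow = K)
  nm <- matrix(sim$n, nrow = K)
  sem <- matrix(sim$se, nrow = K)

  reject_z <- function(w) {
    zq <- matrix(qnorm(pm), nrow = K)
    z <- colSums(w * zq) / sqrt(colSums(w^2))
    pnorm(z) <= sc$alpha
  }
  rej <- lapply(methods, function(m) {
    switch(m,
      z        = reject_z(matrix(1, K, reps)),
      z_n      = reject_z(nm),
      z_sqrt_n = reject_z(sqrt(nm)),
      z_se     = reject_z(1 / sem),
      fisher   = {
        stat <- colSums(-2 * log(pm))
        pchisq(stat, 2 * K, lower.tail = FALSE) <= sc$alpha
      },
      cn       = {
        stat <- colSums(matrix(qchisq(pm, 1, lower.tail = FALSE), nrow = K))
        pchisq(stat, K, lower.tail = FALSE) <= sc$alpha
      },
      new      = {
        stat <- colSums(matrix(.gamma_upper_quantile(pm, 1 / pm), nrow = K))
        .mc_pvalues(stat, store) <= sc$alpha
      })
  })
  prop <- vapply(rej, mean, numeric(1))
  out <- data.frame(method = methods, reject = prop,
                    se = sqrt(prop * (1 - prop) / reps),
                    stringsAsFactors = FALSE)
  attr(out, "scenario") <- sc
  attr(out, "reps") <- reps
  class(out) <- c("power_result", "data.frame")
  out
}
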