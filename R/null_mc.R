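#' Build a Monte-Carlo null store for the adaptive gamma statistic
#'
#' Under the global null each study's p-value is Uniform(0,1). The null
#' distribution of the adaptive statistic [adaptive_gamma_statistic()] is
#' therefore estimated by drawing `N` vectors of `K` i.i.d. uniforms,
#' computing the statistic for each, and keeping the sorted sample. The
#' result is deterministic given `(K, N, seed)` and can be cached on disk.
#'
#' Generation proceeds in blocks of `block_size` draws so memory stays
#' bounded at roughly `8 * K * block_size` bytes per block.
#'
#' @param K number of studies.
#' @param N number of null draws (default `1e6`; larger N shrinks the
#'   Monte-Carlo standard error of downstream p-values as `1/sqrt(N)`).
#' @param seed integer RNG seed; the caller's RNG state is left untouched.
#' @param cache_dir optional directory; if given, the sorted sample is
#'   stored as (and reloaded from) a little-endian 64-bit float binary file
#'   named `nullstore_K<K>_N<N>_seed<seed>.bin`.
#' @param block_size draws generated per block (internal tuning constant).
#' @return an object of class `"null_store"`: list with `K`, `N`, `seed`,
#'   and `samples` (sorted ascending, length `N`).
#' @export
build_null_store <- function(K, N, seed, cache_dir = NULL,
                             block_size = 1e5) {
  K <- as.integer(K); N <- as.integer(N)
  if (is.na(K) || K < 1L) stop_input("K must be a positive integer")
  if (is.na(N) || N < 1L) stop_input("N must be a positive integer")

  cache_file <- NULL
  if (!is.null(cache_dir)) {
    if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
    cache_file <- file.path(cache_dir,
      sprintf("nullstore_K%d_N%d_seed%d.bin", K, N, as.integer(seed)))
    if (file.exists(cache_file) && file.info(cache_file)$size == 8 * N) {
      con <- file(cache_file, "rb")
      on.exit(close(con), add = TRUE)
      samples <- readBin(con, "double", n = N, size = 8, endian = "little")
      return(structure(list(K = K, N = N, seed = as.integer(seed),
                            samples = samples), class = "null_store"))
    }
  }

  samples <- with_seed(seed, {
    out <- numeric(N)
    done <- 0L
    while (done < N) {
      nb <- min(as.integer(block_size), N - done)
      u <- matrix(runif(nb * K), nrow = K)
      tb <- colSums(matrix(.gamma_upper_quantile(u, 1 / u), nrow = K))
      out[(done + 1L):(done + nb)] <- tb
      done <- done + nb
    }
    out
  })
  samples <- sort(samples)

  if (!is.null(cache_file)) {
    con <- file(cache_file, "wb")
    writeBin(samples, con, size = 8, endian = "little")
    close(con)
  }
  structure(list(K = K, N = N, seed = as.integer(seed), samples = samples),
            class = "null_store")
}

#' @export
print.null_store <- function(x, ...) {
  cat(sprintf("Monte-Carlo null store: K = %d, N = %d, seed = %d\n",
              x$K, x$N, x$seed))
  cat(sprintf("  statistic range [%.4g, %.4g], median %.4g\n",
              x$samples[1L], x$samples[x$N], stats::median(x$samples)))
  invisible(x)
}

#' Monte-Carlo p-value from a null store
#'
#' Estimates the upper-tail probability of an observed statistic against a
#' sorted Monte-Carlo null sample. Exceedance is inclusive (`>=`, the
#' conservative tie choice) and located by binary search; the estimator is
#' `(exceed + 1) / (N + 1)`, which is never zero and differs from the raw
#' exceedance proportion by `O(1/N)`.
#'
#' @param t_obs observed statistic (finite).
#' @param store a [build_null_store()] result.
#' @return an object of class `"mc_result"`: list with `p_hat`, `stderr`
#'   (`sqrt(p_hat (1 - p_hat) / N)`), `N`, and `exceed_count`.
#' @export
mc_pvalue <- function(t_obs, store) {
  if (!inherits(store, "null_store")) stop_input("store is not a null_store")
  if (!is.finite(t_obs)) stop_input("t_obs must be finite")
  exceed <- store$N - findInterval(t_obs, store$samples, left.open = TRUE)
  p_hat <- (exceed + 1) / (store$N + 1)
  structure(list(p_hat = p_hat,
                 stderr = sqrt(p_hat * (1 - p_hat) / store$N),
                 N = store$N, exceed_count = as.integer(exceed)),
            class = "mc_result")
}

# vectorized exceedance p-values for many observed statistics at once
.mc_pvalues <- function(t_obs, store) {
  exceed <- store$N - findInterval(t_obs, store$samples, left.open = TRUE)
  (exceed + 1) / (store$N + 1)
}

#' Adaptive-shape gamma test with Monte-Carlo null
#'
#' Computes the adaptive statistic `T = sum(qgamma(1 - p_i, shape = 1/p_i))`
#' and estimates its p-value against a uniform-resampling null of `N` draws
#' (built on the fly or reused from `store`).
#'
#' @inheritParams stouffer_combine
#' @param N null sample size (default `1e6`; ignored when `store` is given).
#' @param seed RNG seed for the null draws (ignored when `store` is given).
#' @param store optional prebuilt [build_null_store()]; its `K` must match.
#' @param cache_dir optional on-disk cache directory for the null store.
#' @return a `combine_result` with method token `"new"`, `combined_p` set to
#'   the Monte-Carlo estimate and `mc_stderr` to its standard error.
#' @examples
#' \donttest{
#' adaptive_gamma_combine(c(0.94, 0.0015, 0.97, 0.79, 0.81),
#'                        N = 1e5, seed = 1)
#' }
#' @export
adaptive_gamma_combine <- function(p, N = 1e6, seed = 1, store = NULL,
                                   cache_dir = NULL) {
  p <- validate_pvalues(p)
  K <- attr(p, "K")
  if (!is.null(store)) {
    if (!inherits(store, "null_store")) stop_input("store is not a null_store")
    if (store$K != K)
      stop_input("null store built for K = ", store$K,
                 " but input has K = ", K)
  } else {
    store <- build_null_store(K, N, seed, cache_dir = cache_dir)
  }
  t_obs <- adaptive_gamma_statistic(p)
  mc <- mc_pvalue(t_obs, store)
  combine_result("new", t_obs,
                 sprintf("MC null, %d samples, seed %d", store$N, store$seed),
                 mc$p_hat, mc_stderr = mc$stderr)
}
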