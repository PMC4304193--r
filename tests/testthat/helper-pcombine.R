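# shared helpers for the test suite

# random p-vectors bounded away from 0/1 so quantile transforms are
# well-conditioned for exact-identity checks
random_pvec <- function(K, lo = 1e-6, hi = 1 - 1e-6) {
  lo + (hi - lo) * runif(K)
}

expect_rel_equal <- function(x, y, rel_tol = 1e-10) {
  scale <- pmax(abs(x), abs(y), 1e-300)
  expect_lt(max(abs(x - y) / scale), rel_tol)
}

# the five reported per-study p-values of the packaged five-study
# depression meta-analysis
five_pvalues <- c(0.94, 0.0015, 0.97, 0.79, 0.81)

depression_counts <- function() {
  read_count_table(system.file("extdata", "depression_counts.tsv",
                               package = "pcombine"))
}
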