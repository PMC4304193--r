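test_that("p-value validation clips boundaries and rejects bad input", {
  v <- validate_pvalues(five_pvalues)
  expect_identical(as.numeric(v), five_pvalues)
  expect_identical(attr(v, "K"), 5L)

  expect_warning(v2 <- validate_pvalues(c(0, 1), epsilon = 1e-15), "clipped")
  expect_equal(as.numeric(v2), c(1e-15, 1 - 1e-15))

  expect_identical(as.numeric(validate_pvalues(0.5)), 0.5)

  expect_error(validate_pvalues(numeric(0)), "no studies")
  expect_error(validate_pvalues(c(0.5, 1.2)), "invalid p-value at index 2")
  expect_error(validate_pvalues(c(NA_real_, 0.5)),
               "invalid p-value at index 1")
})

test_that("Stouffer test matches its normal-quantile definition", {
  r <- stouffer_combine(c(0.5, 0.5))
  expect_equal(r$statistic, 0)
  expect_equal(r$combined_p, 0.5)

  # frozen from direct evaluation of 2 * qnorm(0.05) / sqrt(2)
  r2 <- stouffer_combine(c(0.05, 0.05))
  expect_equal(r2$statistic, -2.32617430735, tolerance = 1e-10)
  expect_equal(r2$combined_p, 0.0100046268581, tolerance = 1e-10)
  expect_identical(r2$method, "z")
})

test_that("weighted z-test resolves weights and honors their ratios only", {
  p <- c(0.05, 0.05)
  # frozen from (100+400) * qnorm(0.05) / sqrt(100^2 + 400^2)
  r <- weighted_z_combine(p, weight_spec("sample_size",
                                         sample_sizes = c(100, 400)))
  expect_equal(r$statistic, -1.99467801253, tolerance = 1e-10)
  expect_equal(r$combined_p, 0.0230390044842, tolerance = 1e-10)
  expect_identical(r$method, "z_n")

  # only ratios matter: rescaling the weights changes nothing
  set.seed(41)
  pv <- random_pvec(6)
  w <- runif(6, 0.5, 4)
  expect_equal(weighted_z_combine(pv, w)$combined_p,
               weighted_z_combine(pv, 10 * w)$combined_p,
               tolerance = 1e-12)

  # a vanishing second weight recovers the first study's p-value
  r_lim <- weighted_z_combine(c(0.05, 0.5), c(1, 1e-12))
  expect_equal(r_lim$combined_p, 0.05, tolerance = 1e-6)

  expect_error(weighted_z_combine(c(0.05, 0.5), c(1, 0)), "positive")
  expect_error(weighted_z_combine(c(0.05, 0.5), c(1, 1, 1)),
               "does not match K")
  expect_error(weight_spec("sample_size"), "requires sample_sizes")
})

test_that("Fisher's method matches the chi-square 2K null", {
  # closed-form chi-square(4) survival oracle: exp(-x/2) * (1 + x/2)
  r <- fisher_combine(c(0.05, 0.05))
  x <- -2 * sum(log(c(0.05, 0.05)))
  expect_equal(r$statistic, x, tolerance = 1e-12)
  expect_equal(r$combined_p, exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)

  r5 <- fisher_combine(five_pvalues)
  expect_equal(r5$combined_p, 0.169277979557, tolerance = 1e-9)
})

test_that("Lancaster generalizes Fisher across degrees of freedom", {
  # frozen from 2 * qchisq(0.95, 1) and its chi-square(2) upper tail
  r <- lancaster_combine(c(0.05, 0.05), c(1, 1))
  expect_equal(r$statistic, 7.68291764139, tolerance = 1e-10)
  expect_equal(r$combined_p, 0.0214622688944, tolerance = 1e-10)

  expect_error(lancaster_combine(c(0.1, 0.2), c(1, 2, 3)),
               "does not match K")
  expect_error(lancaster_combine(c(0.1, 0.2), c(1, -1)), "positive")
})

test_that("gamma combiner: exponential special case and beta invariance", {
  # all shapes 1, scale 1: per-study terms are -log(p), Erlang(2) null
  p <- c(0.05, 0.05)
  r <- gamma_combine(p, shapes = 1, scale = 1)
  t_exp <- -2 * log(0.05)
  expect_equal(r$statistic, t_exp, tolerance = 1e-12)
  expect_equal(r$combined_p, exp(-t_exp) * (1 + t_exp), tolerance = 1e-12)

  # combined p does not depend on the scale parameter
  set.seed(7)
  for (i in 1:20) {
    pv <- random_pvec(4)
    sh <- runif(4, 0.2, 5)
    p1 <- gamma_combine(pv, sh, scale = 1)$combined_p
    p2 <- gamma_combine(pv, sh, scale = 17.3)$combined_p
    expect_equal(p1, p2, tolerance = 1e-10)
  }

  expect_error(gamma_combine(p, c(1, 2, 3)), "does not match K")
  expect_error(gamma_combine(p, c(1, 1), scale = -1), "positive")
})

test_that("single-study combination returns the input p-value", {
  set.seed(13)
  for (p in c(1e-8, 1e-4, 0.05, 0.5, 0.9, 1 - 1e-8, runif(10))) {
    expect_rel_equal(stouffer_combine(p)$combined_p, p)
    expect_rel_equal(fisher_combine(p)$combined_p, p)
    expect_rel_equal(chen_nadarajah_combine(p)$combined_p, p)
    expect_rel_equal(lancaster_combine(p, 3.5)$combined_p, p)
    expect_rel_equal(gamma_combine(p, 2.2, scale = 0.7)$combined_p, p)
  }
})

test_that("family collapses hold to ten significant digits", {
  set.seed(1234)
  for (i in 1:1000) {
    K <- sample(1:8, 1)
    pv <- random_pvec(K)
    f <- fisher_combine(pv)$combined_p
    expect_rel_equal(lancaster_combine(pv, 2)$combined_p, f)
    expect_rel_equal(chen_nadarajah_combine(pv)$combined_p,
                     lancaster_combine(pv, 1)$combined_p)
    v <- runif(1, 0.5, 6)
    expect_rel_equal(gamma_combine(pv, v / 2, scale = 2)$combined_p,
                     lancaster_combine(pv, v)$combined_p)
    expect_rel_equal(weighted_z_combine(pv, rep(2.5, K))$combined_p,
                     stouffer_combine(pv)$combined_p)
  }
})

test_that("adaptive gamma statistic matches quantile oracle and is
           decreasing in each p-value", {
  # 2 * qgamma(0.5, shape = 2), frozen
  expect_equal(adaptive_gamma_statistic(c(0.5, 0.5)), 3.35669398003,
               tolerance = 1e-8)
  # frozen regression value for the five-study example; the 0.0015 study
  # contributes ~745.9 of it
  expect_equal(adaptive_gamma_statistic(five_pvalues), 746.723544167,
               tolerance = 1e-8)

  set.seed(5)
  for (i in 1:25) {
    pv <- random_pvec(4, lo = 1e-4, hi = 0.999)
    t0 <- adaptive_gamma_statistic(pv)
    j <- sample(4, 1)
    pv2 <- pv
    pv2[j] <- pv[j] * runif(1, 0.05, 0.95)
    expect_gt(adaptive_gamma_statistic(pv2), t0)
  }
})

test_that("Wilson-Hilferty branch agrees with the direct gamma quantile
           at the switchover", {
  # evaluate both branches for shapes around the default threshold
  for (p in c(2e-8, 1.2e-8, 1.01e-8)) {
    direct <- pcombine:::.gamma_upper_quantile(p, 1 / p,
                                               wh_threshold = Inf)
    wh <- pcombine:::.gamma_upper_quantile(p, 1 / p, wh_threshold = 0)
    expect_equal(wh, direct, tolerance = 1e-6)
  }
})

test_that("closed-form combined p-values are uniform under the null", {
  set.seed(2024)
  K <- 3
  reps <- 4000
  u <- matrix(runif(reps * K), nrow = K)
  comb <- list(
    z      = apply(u, 2, function(p) stouffer_combine(p)$combined_p),
    fisher = apply(u, 2, function(p) fisher_combine(p)$combined_p),
    cn     = apply(u, 2, function(p) chen_nadarajah_combine(p)$combined_p),
    gamma  = apply(u, 2, function(p)
      gamma_combine(p, c(0.7, 1.3, 2.1))$combined_p))
  for (nm in names(comb)) {
    ks <- suppressWarnings(stats::ks.test(comb[[nm]], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("closed-form tails agree with brute-force uniform resampling", {
  set.seed(31)
  draws <- 2e5
  for (K in c(2, 5)) {
    pv <- random_pvec(K, lo = 0.01, hi = 0.6)
    u <- matrix(runif(draws * K), nrow = K)
    check <- function(p_closed, mc_stats, obs, lower = FALSE) {
      frac <- if (lower) mean(mc_stats <= obs) else mean(mc_stats >= obs)
      se <- sqrt(max(frac, 1 / draws) * (1 - min(frac, 1 - 1 / draws)) /
                 draws)
      expect_lt(abs(p_closed - frac), 3 * se + 1e-12)
    }
    rz <- stouffer_combine(pv)
    check(rz$combined_p, colSums(qnorm(u)) / sqrt(K), rz$statistic,
          lower = TRUE)
    rf <- fisher_combine(pv)
    check(rf$combined_p, colSums(-2 * log(u)), rf$statistic)
    rc <- chen_nadarajah_combine(pv)
    check(rc$combined_p,
          colSums(matrix(qchisq(u, 1, lower.tail = FALSE), nrow = K)),
          rc$statistic)
  }
})

test_that("combine_pvalues dispatches tokens and rejects unknown ones", {
  res <- combine_pvalues(five_pvalues, methods = c("z", "fisher", "cn"))
  expect_named(res, c("z", "fisher", "cn"))
  tab <- combine_results_table(res)
  expect_identical(tab$method, c("z", "fisher", "cn"))
  expect_error(combine_pvalues(five_pvalues, methods = "bogus"),
               "unknown method token")
  expect_error(combine_pvalues(five_pvalues, methods = character(0)),
               "no methods")
})
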