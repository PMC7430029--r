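test_that("log Bayes factor vanishes when the null equals the Jeffreys alternative", {
  set.seed(13)
  for (rep in 1:20) {
    x <- as.integer(rmultinom(1, sample(10:5000, 1), runif(4)))
    expect_equal(log_bayes_factor(x, rep(0.5, 4)), 0, tolerance = 1e-12)
  }
})

test_that("log Bayes factor is negative at the tight null's modal composition", {
  alpha <- c(3000, 1, 1, 1)
  expect_lt(log_bayes_factor(c(2000, 0, 0, 0), alpha), 0)
})

test_that("log Bayes factor increases strictly with the alt count at fixed depth", {
  alpha <- c(4000, 1, 1, 1)
  depth <- 2000
  lbf <- vapply(0:60, function(k)
    log_bayes_factor(c(depth - k, k, 0, 0), alpha), 0)
  expect_true(all(diff(lbf) > 0))
})

test_that("log Bayes factor is invariant to jointly permuting non-reference components", {
  set.seed(17)
  x <- c(1900, 40, 7, 3)
  alpha <- c(3800, 9, 4, 2)
  for (perm in list(c(1, 3, 4, 2), c(1, 4, 2, 3), c(1, 2, 4, 3))) {
    expect_equal(log_bayes_factor(x[perm], alpha[perm]),
                 log_bayes_factor(x, alpha))
  }
})

test_that("a non-converged null refuses to score", {
  fake <- structure(list(alpha = rep(1, 4), converged = FALSE), class = "dm_null")
  expect_error(log_bayes_factor(c(10, 0, 0, 0), fake), "converge")
})

test_that("MAP VAF equals the Beta posterior mode, numerically cross-checked", {
  # hand value: (50 - 0.5) / 500
  expect_equal(map_vaf(c(450, 50, 0, 0), "C"), 0.099)
  # boundaries: clamped at 0; strictly below 1 when all reads are alt
  expect_equal(map_vaf(c(1000, 0, 0, 0), "C"), 0)
  expect_lt(map_vaf(c(0, 1000, 0, 0), "C"), 1)
  expect_error(map_vaf(c(0, 0, 0, 0), "C"), "depth")
  expect_error(map_vaf(c(1, 0, 0, 0), "N"), "one of")

  set.seed(19)
  for (rep in 1:20) {
    n <- sample(20:5000, 1)
    k <- sample(1:(n - 1), 1)
    x <- c(n - k, k, 0, 0)
    # independent oracle: maximize the marginal Beta(k + 1/2, n - k + 3/2)
    o <- optimize(function(v) dbeta(v, k + 0.5, n - k + 1.5, log = TRUE),
                  c(0, 1), maximum = TRUE, tol = 1e-10)
    expect_equal(map_vaf(x, "C"), o$maximum, tolerance = 1e-6)
  }
})

test_that("call_locus sets the paper's filter flags with inclusive boundaries", {
  alpha <- c(3985, 5, 5, 5)
  th <- call_thresholds()
  # depth 499 with overwhelming variant evidence: only the depth flag
  cl <- call_locus(c(449, 50, 0, 0), "A", alpha, pop_af = 0, thresholds = th)
  expect_true(cl$flag_depth)
  expect_false(cl$flag_bayes_factor)
  expect_gt(cl$log_bf, 6)
  expect_identical(cl$alt, "C")
  # deep all-reference sample: only the Bayes-factor flag
  cl <- call_locus(c(2000, 0, 0, 0), "A", alpha, 0, th)
  expect_false(cl$flag_depth)
  expect_true(cl$flag_bayes_factor)
  # strong variant at population frequency 2%: population flag only
  cl <- call_locus(c(1900, 100, 0, 0), "A", alpha, pop_af = 0.02, thresholds = th)
  expect_true(cl$flag_population_frequency)
  expect_false(cl$flag_depth || cl$flag_bayes_factor)
  # frequency exactly 1% is retained ("greater than 1%" is strict)
  cl <- call_locus(c(1900, 100, 0, 0), "A", alpha, pop_af = 0.01, thresholds = th)
  expect_false(cl$flag_population_frequency)
  # alt allele: largest non-reference count, lexicographic ties
  cl <- call_locus(c(100, 5, 5, 2), "A", alpha, 0, th)
  expect_identical(cl$alt, "C")
  expect_error(call_locus(c(1, 1, 1, 1), "N", alpha), "A, C, G, T")
})

test_that("cohort filter flags variants recurring in four or more samples, idempotently", {
  base <- data.frame(
    sample_id = sprintf("case_%02d", 1:5),
    chrom = "chr17", pos = 100L, ref = "A", alt = "C",
    alt_count = 50L, depth = 2000L, log_bf = 20, vaf_map = 0.025,
    flag_depth = FALSE, flag_bayes_factor = FALSE,
    flag_population_frequency = FALSE, flag_cohort_frequency = NA,
    pass = NA, stringsAsFactors = FALSE
  )
  in3 <- base[1:3, ]
  in3 <- apply_cohort_filter(in3)
  expect_false(any(in3$flag_cohort_frequency))
  expect_true(all(in3$pass))

  in4 <- base[1:4, ]
  out4 <- apply_cohort_filter(in4)
  expect_true(all(out4$flag_cohort_frequency))
  expect_false(any(out4$pass))
  # samples counted toward recurrence must themselves satisfy depth + BF
  in4b <- base[1:4, ]
  in4b$flag_bayes_factor[4] <- TRUE
  out4b <- apply_cohort_filter(in4b)
  expect_false(any(out4b$flag_cohort_frequency))
  expect_identical(sum(out4b$pass), 3L)
  # idempotence
  expect_identical(apply_cohort_filter(out4), out4)
})

test_that("samples are positive iff they carry a passing call", {
  calls <- data.frame(
    sample_id = c("s1", "s2", "s2"),
    chrom = "chr17", pos = c(1L, 1L, 2L), ref = "A", alt = "C",
    alt_count = 1L, depth = 1000L, log_bf = 1, vaf_map = 0.001,
    flag_depth = FALSE, flag_bayes_factor = c(TRUE, TRUE, FALSE),
    flag_population_frequency = FALSE, flag_cohort_frequency = FALSE,
    pass = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE
  )
  st <- classify_samples(calls, sample_ids = c("s1", "s2", "s3"))
  expect_identical(st$status[st$sample_id == "s1"], "ctDNA_negative")
  expect_identical(st$status[st$sample_id == "s2"], "ctDNA_positive")
  expect_identical(st$status[st$sample_id == "s3"], "ctDNA_negative")
  expect_identical(st$n_passing[st$sample_id == "s2"], 1L)
  calls$pass <- NA
  expect_error(classify_samples(calls), "cohort")
})

test_that("thresholds validate and default to the published values", {
  th <- call_thresholds()
  expect_identical(th$min_depth, 500)
  expect_identical(th$min_log_bf, 6)
  expect_identical(th$max_cohort_count, 3)
  expect_identical(th$max_pop_af, 0.01)
  expect_error(call_thresholds(min_depth = -1), "non-negative")
})
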