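test_that("BMIS scoring arithmetic and invariances", {
  it <- bmis_items()$item
  all1 <- stats::setNames(rep(1, 16), it)
  s <- bmis_scores(all1)
  expect_equal(s$overall, 0)                       # symmetric minimum
  hi <- stats::setNames(c(rep(4, 8), rep(1, 8)), it)
  expect_equal(bmis_scores(hi)$overall, 8 * 4 - 8 * 1)
  # order invariance
  perm <- sample(16)
  expect_equal(bmis_scores(hi[perm]), bmis_scores(hi))
  # bounds under the 8/8 split
  set.seed(1)
  for (i in 1:25) {
    sc <- stats::setNames(sample(1:4, 16, replace = TRUE), it)
    ov <- bmis_scores(sc)$overall
    expect_gte(ov, -24); expect_lte(ov, 24)
  }
  expect_error(bmis_scores(hi[-1]), "16")
  bad <- hi; bad[1] <- 5
  expect_error(bmis_scores(bad), "1-4")
})

test_that("ZEF scoring: overall mean, dimension means, range", {
  it <- zef_items()$item
  expect_equal(zef_scores(stats::setNames(rep(5, 18), it))$overall, 5)
  expect_equal(zef_scores(stats::setNames(rep(1, 18), it))$overall, 1)
  # constructed dimensions: items of dimension d all equal d's index
  zm <- zef_items()
  dims <- unique(zm$dimension)
  sc <- stats::setNames(pmin(match(zm$dimension, dims), 5), it)
  z <- zef_scores(sc)
  expect_equal(unname(z$dimensions["general"]), 1)
  expect_equal(unname(z$dimensions["emotional"]), 5)
  expect_equal(z$overall, mean(sc))
  expect_error(zef_scores(sc[-3]), "18")
})

test_that("Cronbach's alpha: perfect, null, and closed-form two-item cases", {
  set.seed(2)
  x <- rnorm(100)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1)
  # independent items -> alpha near 0
  alphas <- vapply(1:50, function(s) {
    set.seed(s)
    cronbach_alpha(matrix(rnorm(500 * 18), 500))
  }, 0)
  expect_lt(abs(mean(alphas)), 0.1)
  # standardized two-item alpha = 2 rho / (1 + rho)
  set.seed(3)
  z <- rnorm(2000)
  m <- cbind(z + rnorm(2000), z + rnorm(2000))   # rho = 0.5
  expect_lt(abs(cronbach_alpha(m) - 2 / 3), 0.05)
  # degenerate: zero total variance
  expect_true(is.na(cronbach_alpha(matrix(1, 10, 3))))
})

test_that("paired Wilcoxon tests: null, strong shift, BH arithmetic", {
  set.seed(4)
  a <- matrix(rnorm(35 * 5), 35)
  r0 <- paired_condition_tests(a, a)
  expect_true(all(r0$p == 1))
  expect_true(all(r0$stars == ""))
  r1 <- paired_condition_tests(a + 1, a)
  expect_true(all(r1$p_adj < 0.001))
  expect_true(all(r1$stars == "***"))
  # BH step-up by hand
  expect_equal(vcfatigue:::bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  # BH adjusted p monotone in raw-p rank
  p <- sort(runif(12))
  expect_true(all(diff(vcfatigue:::bh_adjust(p)) >= 0))
  # shift invariance: adding a common constant to both conditions
  # (integer-valued scores so the paired differences are float-exact)
  ai <- matrix(sample(1:5, 35 * 3, replace = TRUE), 35)
  bi <- matrix(sample(1:5, 35 * 3, replace = TRUE), 35)
  expect_equal(paired_condition_tests(ai, bi)$p,
               paired_condition_tests(ai + 3, bi + 3)$p)
})

test_that("significance stars encode the thresholds", {
  expect_equal(vcfatigue:::significance_stars(c(0.04, 0.009, 0.0009, 0.2)),
               c("*", "**", "***", ""))
})

test_that("order-effect model: type-I, recovery, specificity", {
  ns <- 20
  base <- data.frame(
    subject = rep(seq_len(ns), 2),
    lec = rep(c("videoconference", "face_to_face"), each = ns),
    ord = rep(rep(c("vc_first", "f2f_first"), ns / 2), 2))
  sim <- function(seed, order_d = 0, lecture_d = 0) {
    set.seed(seed)
    subj_int <- rnorm(ns)[base$subject]
    y <- subj_int + rnorm(2 * ns, sd = 0.7) +
      order_d * (base$ord == "vc_first") +
      lecture_d * (base$lec == "videoconference")
    order_effect_check(y, base$subject, base$lec, base$ord)
  }
  # type-I on the order term (null), 100 replicates (scaled from 200)
  p_ord <- vapply(1:100, function(s) sim(s)$p[1], 0)
  expect_lt(mean(p_ord < 0.05), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 100))
  # recovery of an injected pure order effect (sum coding: estimate = d/2)
  est <- vapply(1:40, function(s) sim(s, order_d = 1)$estimate[1], 0)
  got <- 2 * abs(mean(est))
  expect_lt(abs(got - 1), 3 * 2 * stats::sd(est))
  # specificity: large lecture effect, zero order effect
  hits <- vapply(1:40, function(s) {
    r <- sim(s + 500, lecture_d = 1.5)
    c(r$p[r$term == "lecture"] < 0.05, r$p[r$term == "order"] >= 0.05)
  }, c(TRUE, TRUE))
  expect_gte(mean(hits[1, ]), 0.9)
  expect_gte(mean(hits[2, ]), 0.9)
})
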