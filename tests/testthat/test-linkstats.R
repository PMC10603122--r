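test_that("summarize_index: constant, linear, and missing-window cases", {
  expect_equal(summarize_index(rep(3.2, 16)), 3.2)
  t <- (1:16) * 180 - 90
  y <- 2 + 0.01 * t
  expect_equal(summarize_index(y), 2 + 0.01 * mean(t))
  v <- c(1, 2, NA, 4)
  expect_equal(summarize_index(v), mean(c(1, 2, 4)))
  expect_true(is.na(summarize_index(c(NA_real_, NA_real_))))
})

test_that("index-item LME: constructed truth, OLS oracle, null FDR", {
  ns <- 20
  smry <- data.frame(subject = rep(seq_len(ns), 2),
                     condition = rep(c("videoconference", "face_to_face"),
                                     each = ns))
  set.seed(1)
  ia <- normalize_item_scores(rnorm(2 * ns))
  u <- rnorm(ns)[smry$subject]
  smry$idx <- 1.3 * ia + u                       # exact linear truth
  r <- fit_index_item_lme(smry, "idx", data.frame(item1 = ia), model = "zef")
  expect_equal(r$estimate, 1.3, tolerance = 1e-6)
  # zero random-intercept variance by construction -> OLS
  e <- rnorm(2 * ns); e <- e - ave(e, smry$subject)
  smry$idx2 <- 0.5 * ia + e
  r2 <- fit_index_item_lme(smry, "idx2", data.frame(item1 = ia),
                           model = "zef")
  ols <- stats::lm(smry$idx2 ~ ia)
  expect_lt(abs(r2$estimate - stats::coef(ols)[2]), 1e-6)
  # null simulation: BH-significant cell rate <= alpha (60 replicates,
  # scaled down from 200)
  hits <- vapply(1:60, function(s) {
    set.seed(s)
    sm <- smry
    sm$a <- rnorm(2 * ns); sm$b <- rnorm(2 * ns)
    items <- data.frame(i1 = normalize_item_scores(rnorm(2 * ns)),
                        i2 = normalize_item_scores(rnorm(2 * ns)))
    any(fit_index_item_lme(sm, c("a", "b"), items, model = "zef")$significant)
  }, TRUE)
  expect_lt(mean(hits), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 60))
})

test_that("bmis variant controls for the before score", {
  ns <- 30
  smry <- data.frame(subject = rep(seq_len(ns), 2),
                     condition = rep(c("videoconference", "face_to_face"),
                                     each = ns))
  set.seed(2)
  ib <- normalize_item_scores(rnorm(2 * ns))
  ia <- normalize_item_scores(0.6 * ib + rnorm(2 * ns))
  smry$idx <- 0.9 * ia + 0.4 * ib
  r <- fit_index_item_lme(smry, "idx", data.frame(i = ia),
                          item_before = data.frame(i = ib), model = "bmis")
  expect_equal(r$estimate, 0.9, tolerance = 1e-6)
})

test_that("window-wise condition test localizes an injected late effect", {
  set.seed(3)
  r0 <- windowwise_condition_test(matrix(rnorm(35 * 16), 35),
                                  matrix(rnorm(35 * 16), 35))
  expect_equal(nrow(r0), 16)
  a <- matrix(rnorm(35 * 16), 35)
  expect_false(any(windowwise_condition_test(a, a)$significant))
  hits <- vapply(1:30, function(s) {       # scaled down from 100
    set.seed(s)
    a <- matrix(rnorm(35 * 16), 35)
    b <- a + rnorm(35 * 16, sd = 0.2)
    b[, 12:16] <- b[, 12:16] + 2
    r <- windowwise_condition_test(a, b)
    sig <- which(r$significant)
    length(sig) > 0 && mean(sig >= 12) >= 0.8
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  # constant strong offset: all windows significant
  b2 <- a + 3
  expect_true(all(windowwise_condition_test(a, b2)$significant))
  expect_error(windowwise_condition_test(a, a[, 1:8]), "unequal")
})

test_that("average condition test: stars and monotone power in shift size", {
  set.seed(5)
  a <- matrix(rnorm(35 * 3), 35, dimnames = list(NULL, c("hr", "rmssd", "sdrr")))
  r0 <- average_condition_test(a, a)
  expect_true(all(r0$p == 1) && all(r0$stars == ""))
  shifts <- c(0.1, 0.3, 0.6, 1, 2)
  meanp <- vapply(shifts, function(d) {
    mean(vapply(1:30, function(s) {
      set.seed(s)
      x <- matrix(rnorm(35), 35, 1)
      average_condition_test(x + d + matrix(rnorm(35, sd = 1), 35),
                             x, indices = "ix")$p
    }, 0))
  }, 0)
  expect_true(all(diff(meanp) < 0))
})
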