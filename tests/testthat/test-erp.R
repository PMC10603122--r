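make_epochs <- function(n_trials, peak = 5) {
  rec <- zero_rec(n_trials + 2, channels = c("Fz", "Cz"))
  ev <- data.frame(onset_s = seq_len(n_trials), duration_s = 0.5,
                   label = "target")
  tpl <- default_erp_template()
  tpl$amplitude <- tpl$amplitude / max(abs(tpl$amplitude)) * peak
  epoch(embed_erp(rec, ev, tpl), ev)
}

test_that("epoching produces one trial per in-span target and drops boundary events", {
  ep <- make_epochs(50)
  expect_equal(dim(ep$data)[1], 50)
  rec <- zero_rec(3)
  ev <- data.frame(onset_s = c(0, 1.5), duration_s = 0.5, label = "target")
  ep2 <- epoch(embed_erp(rec, ev[2, ], default_erp_template()), ev)
  expect_equal(dim(ep2$data)[1], 1)
  expect_equal(attr(ep2, "dropped"), 0)
})

test_that("amplitude rejection follows the +-100 uV rule and is monotone", {
  ep <- make_epochs(3)
  ep$data[2, 1, 10] <- 150
  r <- reject_amplitude(ep, 100)
  expect_equal(sum(r$retained), 2)
  expect_false(r$retained[2])
  # idempotent
  expect_identical(reject_amplitude(r, 100)$retained, r$retained)
  # all-zero trials retained
  ez <- epoch(zero_rec(3), data.frame(onset_s = 1.5, duration_s = 0.5,
                                      label = "target"))
  expect_true(all(reject_amplitude(ez)$retained))
  # threshold sweep: retained count non-increasing as threshold decreases
  ep2 <- make_epochs(10)
  for (i in 1:10) ep2$data[i, 1, 20] <- i * 12
  counts <- vapply(c(150, 100, 70, 40, 20),
                   function(th) sum(reject_amplitude(ep2, th)$retained), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("grand average: subject-first averaging and symmetry", {
  ep <- make_epochs(5)
  ga1 <- grand_average(list(ep))
  ga3 <- grand_average(list(ep, ep, ep))
  expect_equal(ga1$waveforms, ga3$waveforms, tolerance = 1e-12)
  neg <- ep; neg$data <- -neg$data
  ga <- grand_average(list(ep, neg))
  expect_lt(max(abs(ga$waveforms)), 1e-12)
  # subject with zero retained trials is excluded
  dead <- ep; dead$retained[] <- FALSE
  expect_message(ga2 <- grand_average(list(ep, dead)), "excluded")
  expect_equal(ga2$n_subjects, 1)
})

test_that("onset latency finds a constructed onset and misses a flat line", {
  t <- seq(-0.2, 0.8, by = 1 / 512)
  amp <- ifelse(t >= 0.25, sin(pi * pmin(t - 0.25, 0.3) / 0.3), 0)
  expect_lt(abs(onset_latency(amp, t, c(0.2, 0.5)) - 0.25), 1.5 / 512)
  expect_message(v <- onset_latency(numeric(length(t)), t, c(0.2, 0.5)),
                 "never met")
  expect_true(is.na(v))
})

test_that("phase LME: null, constructed shift, and OLS equivalence", {
  set.seed(4)
  before <- matrix(rnorm(12 * 5), 12)
  # null: after == before
  r0 <- fit_phase_lme(before, before)
  expect_true(all(abs(r0$estimate) < 1e-10))
  expect_false(any(r0$significant))
  # constructed shift
  r2 <- fit_phase_lme(before, before + 2)
  expect_equal(r2$estimate, rep(2, 5), tolerance = 1e-8)
  # zero random-intercept variance by construction -> OLS oracle
  ns <- 16
  e <- matrix(rnorm(ns * 2), ns); e <- e - rowMeans(e)
  bef <- matrix(e[, 1]); aft <- matrix(e[, 2] + 0.4)
  r <- fit_phase_lme(bef, aft)
  ols <- stats::lm(c(bef, aft) ~ rep(0:1, each = ns))
  expect_lt(abs(r$estimate[1] - stats::coef(ols)[2]), 1e-6)
  expect_lt(abs(r$p[1] - summary(ols)$coefficients[2, 4]), 0.05)
})

test_that("eq-1 fixed effect equals the mean paired difference on balanced data", {
  set.seed(8)
  ns <- 10
  before <- matrix(rnorm(ns * 3), ns)
  after <- before + matrix(rnorm(ns * 3, mean = 1, sd = 0.2), ns)
  r <- fit_phase_lme(before, after)
  expect_equal(r$estimate, colMeans(after - before), tolerance = 1e-6)
})

test_that("item LME: constructed linear truth and noise scaling", {
  set.seed(5)
  n <- 30
  subj <- factor(1:n)
  item <- normalize_item_scores(rnorm(n))
  before <- matrix(rnorm(n * 3), n)
  beta <- 1.7
  after <- before + beta * item
  r <- fit_item_lme(after, before, item, subj, model = "zef")
  expect_equal(r$estimate, rep(beta, 3), tolerance = 1e-6)
  # doubling residual noise halves the standardized effect (ratio of means
  # over seeds; the per-seed ratio is heavy-tailed)
  ss <- vapply(1:60, function(s) {
    set.seed(s)
    n2 <- 200
    it <- normalize_item_scores(rnorm(n2))
    bef <- matrix(rnorm(n2))
    eps <- rnorm(n2)
    a1 <- bef + 0.5 * it + matrix(eps)
    a2 <- bef + 0.5 * it + matrix(2 * eps)
    c(fit_item_lme(a1, bef, it, factor(1:n2), model = "zef")$std_effect,
      fit_item_lme(a2, bef, it, factor(1:n2), model = "zef")$std_effect)
  }, c(0, 0))
  expect_lt(abs(mean(ss[1, ]) / mean(ss[2, ]) - 2), 0.2)
  # constant scores -> warning + missing
  expect_warning(rc <- fit_item_lme(after, before, rep(0, n), subj,
                                    model = "zef"), "constant")
  expect_true(all(is.na(rc$estimate)))
})

test_that("bmis item model controls for the before-score", {
  set.seed(6)
  n <- 40
  ib <- normalize_item_scores(rnorm(n))
  ia <- normalize_item_scores(0.5 * ib + rnorm(n))
  before <- matrix(rnorm(n))
  after <- before + 0.8 * ia + 0.3 * ib
  r <- fit_item_lme(after, before, ia, factor(1:n), item_before = ib,
                    model = "bmis")
  expect_equal(r$estimate[1], 0.8, tolerance = 1e-6)
})
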