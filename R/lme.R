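# Shared linear mixed-effects wrapper.
#
# Fits  response ~ fixed effects + (1 | group)  by REML with lme4; singular /
# boundary or failed fits fall back to the fixed-effects-only OLS model with a
# `fallback` flag (at a zero random-intercept variance the two coincide).
# Fixed-effect p-values use t statistics on n - rank(X) - (n_groups - 1)
# degrees of freedom, the residual df of the within-group analysis (equal to
# the paired-t df for the balanced two-phase design).
#
# fit_lme_all returns the full fixed-effect table (term, estimate, se, p)
# plus residual sd and fallback flag; fit_lme_term extracts one coefficient.
fit_lme_all <- function(formula, data, group) {
  data$.grp <- factor(group)
  f_mixed <- stats::update(formula, . ~ . + (1 | .grp))
  n_grp <- nlevels(data$.grp)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(f_mixed, data = data, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")))),
    error = function(e) NULL)
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-6)
  if (singular) {
    ols <- stats::lm(formula, data = data)
    co <- summary(ols)$coefficients
    df <- nrow(data) - ols$rank - (n_grp - 1)
    sig <- stats::sigma(ols)
    fallback <- TRUE
  } else {
    co <- summary(fit)$coefficients
    df <- nrow(data) - nrow(co) - (n_grp - 1)
    sig <- stats::sigma(fit)
    fallback <- FALSE
  }
  tval <- co[, "Estimate"] / co[, "Std. Error"]
  list(table = data.frame(term = rownames(co),
                          estimate = unname(co[, "Estimate"]),
                          se = unname(co[, "Std. Error"]),
                          p = 2 * stats::pt(-abs(tval), df = max(df, 1)),
                          row.names = NULL),
       sigma = sig, fallback = fallback)
}

# Returns, for the coefficient named `term`: estimate, se, p, residual sd,
# fallback flag.
fit_lme_term <- function(formula, data, group, term) {
  data$.grp <- factor(group)
  f_mixed <- stats::update(formula, . ~ . + (1 | .grp))
  n_grp <- nlevels(data$.grp)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(f_mixed, data = data, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")))),
    error = function(e) NULL)
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-6)
  if (singular) {
    ols <- stats::lm(formula, data = data)
    co <- summary(ols)$coefficients
    if (!term %in% rownames(co))
      return(list(estimate = NA_real_, se = NA_real_, p = NA_real_,
                  sigma = stats::sigma(ols), fallback = TRUE))
    df <- nrow(data) - ols$rank - (n_grp - 1)
    tval <- co[term, "Estimate"] / co[term, "Std. Error"]
    return(list(estimate = unname(co[term, "Estimate"]),
                se = unname(co[term, "Std. Error"]),
                p = 2 * stats::pt(-abs(tval), df = max(df, 1)),
                sigma = stats::sigma(ols), fallback = TRUE))
  }
  co <- summary(fit)$coefficients
  if (!term %in% rownames(co))
    return(list(estimate = NA_real_, se = NA_real_, p = NA_real_,
                sigma = stats::sigma(fit), fallback = FALSE))
  df <- nrow(data) - nrow(co) - (n_grp - 1)
  tval <- co[term, "t value"]
  list(estimate = unname(co[term, "Estimate"]),
       se = unname(co[term, "Std. Error"]),
       p = 2 * stats::pt(-abs(tval), df = max(df, 1)),
       sigma = stats::sigma(fit), fallback = FALSE)
}
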