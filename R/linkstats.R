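#' Average a windowed feature or HRV series within subject
#'
#' Unweighted mean over complete, non-missing windows; `NA` when no window is
#' valid.
#'
#' @param value numeric per-window values.
#' @return numeric scalar.
#' @export
summarize_index <- function(value) {
  v <- value[is.finite(value)]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' Link an averaged physiological index to questionnaire items (mixed model)
#'
#' For each index x item cell fits the session-average index on the
#' z-normalized item score(s) with a by-subject random intercept, pooling
#' both lecture conditions (condition itself is not a fixed effect unless
#' `condition_covariate = TRUE`):
#' model "bmis": index ~ item_before + item_after + (1 | subject);
#' model "zef":  index ~ item_after + (1 | subject).
#' The after-score effect is standardized by the residual SD; BH correction
#' runs across all index x item cells supplied in one call (one family per
#' model).
#'
#' @param summaries data.frame with columns `subject`, `condition`, one row
#'   per subject x condition, plus one numeric column per index.
#' @param indices character vector of index column names to test.
#' @param item_after,item_before data.frames aligned to `summaries` rows, one
#'   column per item (z-normalized; `item_before` only for "bmis").
#' @param model "bmis" or "zef".
#' @param condition_covariate include condition as a fixed covariate.
#' @return data.frame: `index`, `item`, `estimate`, `std_effect`, `p`,
#'   `p_adj`, `significant`, `fallback`.
#' @export
fit_index_item_lme <- function(summaries, indices, item_after,
                               item_before = NULL,
                               model = c("bmis", "zef"),
                               condition_covariate = FALSE) {
  model <- match.arg(model)
  item_after <- as.data.frame(item_after)
  if (model == "bmis") {
    assert_that(!is.null(item_before), "bmis model needs item_before")
    item_before <- as.data.frame(item_before)
    assert_that(identical(colnames(item_after), colnames(item_before)),
                "item_before/item_after columns must match")
  }
  rows <- list()
  for (ix in indices) {
    for (it in colnames(item_after)) {
      d <- data.frame(y = summaries[[ix]], ia = item_after[[it]])
      if (condition_covariate) d$cond <- factor(summaries$condition)
      if (model == "bmis") d$ib <- item_before[[it]]
      if (stats::sd(d$ia) == 0) {
        warning(sprintf("constant scores for item %s; effect undefined", it))
        rows[[paste(ix, it)]] <- data.frame(index = ix, item = it,
                                            estimate = NA_real_,
                                            std_effect = NA_real_,
                                            p = NA_real_, fallback = FALSE)
        next
      }
      rhs <- if (model == "bmis") "ib + ia" else "ia"
      if (condition_covariate) rhs <- paste(rhs, "+ cond")
      f <- fit_lme_term(stats::as.formula(paste("y ~", rhs)), d,
                        summaries$subject, "ia")
      rows[[paste(ix, it)]] <- data.frame(index = ix, item = it,
                                          estimate = f$estimate,
                                          std_effect = if (is.finite(f$sigma) &&
                                                           f$sigma > 0)
                                            f$estimate / f$sigma else NA_real_,
                                          p = f$p, fallback = f$fallback)
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$p_adj <- bh_adjust(out$p)
  out$significant <- !is.na(out$p_adj) & out$p_adj < 0.05
  out
}

#' Window-wise paired condition comparison of a feature series
#'
#' Wilcoxon signed-rank per window between the two conditions (paired by
#' subject), BH correction across windows (family per index x channel), and
#' the significant-window mask.
#'
#' @param a,b numeric matrices subjects x windows on the same window grid.
#' @param window_index optional window labels.
#' @return data.frame: `window_index`, `p`, `p_adj`, `significant`.
#' @export
windowwise_condition_test <- function(a, b, window_index = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  assert_that(all(dim(a) == dim(b)), "unequal window grids")
  wi <- window_index %||% seq_len(ncol(a))
  p <- vapply(seq_len(ncol(a)), function(j) paired_wilcoxon(a[, j], b[, j])$p, 0)
  padj <- bh_adjust(p)
  data.frame(window_index = wi, p = p, p_adj = padj,
             significant = !is.na(padj) & padj < 0.05)
}

#' Average (over time) paired condition comparison across an index family
#'
#' Wilcoxon signed-rank on per-subject session averages for each index, BH
#' across the index family, star encoding at 0.05 / 0.01 / 0.001.
#'
#' @param a,b data.frames or matrices subjects x indices of session averages
#'   (paired rows).
#' @param indices index labels (default: column names).
#' @return data.frame: `index`, `statistic`, `p`, `p_adj`, `stars`.
#' @export
average_condition_test <- function(a, b, indices = NULL) {
  res <- paired_condition_tests(a, b, items = indices)
  names(res)[names(res) == "item"] <- "index"
  res
}
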