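#' Goodness-of-fit metrics for surrogate predictions
#'
#' The three comparison statistics used throughout the package:
#' `r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`,
#' `mae = mean(|y - yhat|)` and `rmse = sqrt(mean((y - yhat)^2))`.
#'
#' @param actual Observed values.
#' @param predicted Model predictions of the same length.
#' @return An object of class `fit_metrics`: list with `r2`, `mae`, `rmse`,
#'   `n`. When `actual` is constant, `r2` is `NA` and the object carries
#'   `r2_undefined = TRUE`.
#' @examples
#' fit_metrics(c(0, 2), c(1, 1))  # r2 0, mae 1, rmse 1
#' @export
fit_metrics <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop_invalid("length mismatch: %d actual vs %d predicted",
                 length(actual), length(predicted))
  }
  if (length(actual) < 1L) stop_invalid("need at least one observation")
  e <- actual - predicted
  ss_tot <- sum((actual - mean(actual))^2)
  r2_undefined <- ss_tot == 0
  structure(
    list(r2 = if (r2_undefined) NA_real_ else 1 - sum(e^2) / ss_tot,
         mae = mean(abs(e)),
         rmse = sqrt(mean(e^2)),
         n = length(actual),
         r2_undefined = r2_undefined),
    class = "fit_metrics"
  )
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("<fit_metrics> n = %d: R2 %.4f  MAE %.4f  RMSE %.4f\n",
              x$n, x$r2, x$mae, x$rmse))
  invisible(x)
}

#' Stratified train/validation split
#'
#' Partitions a design table into training and validation subsets,
#' stratified on the observed yield: runs are sorted by yield, banded into
#' `n_valid` quantile strata, and one validation run is drawn per stratum.
#' The split is disjoint and exhaustive, and deterministic for a fixed seed.
#'
#' @param design A [design_table()] with observed yields.
#' @param n_train,n_valid Subset sizes; must sum to `nrow(design)`.
#' @param seed RNG seed for the within-stratum draws.
#' @return List with `train` and `validation` (both `design_table`s) and the
#'   corresponding row indices `train_idx`, `valid_idx`.
#' @examples
#' sp <- stratified_split(thd_runs(), 21, 8, seed = 1)
#' nrow(sp$train)
#' @export
stratified_split <- function(design, n_train = 21L, n_valid = 8L, seed) {
  n <- nrow(design)
  if (n_train + n_valid != n) {
    stop_invalid("n_train + n_valid = %d does not match table size %d",
                 n_train + n_valid, n)
  }
  if (n_valid < 1L || n_train < 1L) stop_invalid("both subsets must be non-empty")
  idx <- with_seed(seed, {
    o <- order(design$yield_pct)
    strata <- split(o, cut(seq_along(o), n_valid, labels = FALSE))
    vapply(strata, function(s) s[sample.int(length(s), 1L)], integer(1))
  })
  valid_idx <- sort(unname(idx))
  train_idx <- setdiff(seq_len(n), valid_idx)
  doms <- design_domains(design)
  sub <- function(i) design_table(as.data.frame(design)[i, , drop = FALSE],
                                  domains = doms, bbd = FALSE)
  list(train = sub(train_idx), validation = sub(valid_idx),
       train_idx = train_idx, valid_idx = valid_idx)
}

#' Compare surrogate models on a common dataset
#'
#' Computes [fit_metrics()] for each model's predictions over all runs of a
#' design table and ranks the models by R-squared, flagging the winner.
#'
#' @param design A [design_table()] with observed yields.
#' @param models Named list; each element is either a numeric vector of
#'   predictions for every run, or a fitted model with a [predict()] method
#'   over the design's factor columns (`quad_rsm`, `mlp_surrogate`).
#' @param paired_test Also run a paired t-test on absolute errors of the
#'   first-ranked vs each other model.
#' @return An object of class `model_comparison`: data frame with one row
#'   per model (columns `model`, `r2`, `mae`, `rmse`, `rank`, `winner`),
#'   with the optional t-test results in attribute `"paired_tests"`.
#' @export
compare_models <- function(design, models, paired_test = FALSE) {
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    stop_invalid("`models` must be a fully named list")
  }
  fm <- as.data.frame(design)[names(design_domains(design))]
  preds <- lapply(models, function(m) {
    p <- if (is.numeric(m)) m else as.numeric(predict(m, fm))
    if (length(p) != nrow(design)) {
      stop_invalid("model predictions must cover all %d runs", nrow(design))
    }
    p
  })
  mets <- lapply(preds, fit_metrics, actual = design$yield_pct)
  tab <- data.frame(
    model = names(models),
    r2 = vapply(mets, `[[`, numeric(1), "r2"),
    mae = vapply(mets, `[[`, numeric(1), "mae"),
    rmse = vapply(mets, `[[`, numeric(1), "rmse"),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$r2), ]
  tab$rank <- seq_len(nrow(tab))
  tab$winner <- tab$rank == 1L
  rownames(tab) <- NULL
  if (paired_test && nrow(tab) > 1L) {
    best <- tab$model[1L]
    tests <- lapply(tab$model[-1L], function(other) {
      stats::t.test(abs(design$yield_pct - preds[[best]]),
                    abs(design$yield_pct - preds[[other]]), paired = TRUE)
    })
    names(tests) <- tab$model[-1L]
    attr(tab, "paired_tests") <- tests
  }
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (ranked by R2)\n")
  df <- as.data.frame(x)
  df$r2 <- sprintf("%.4f", df$r2)
  df$mae <- sprintf("%.4f", df$mae)
  df$rmse <- sprintf("%.4f", df$rmse)
  print(df, row.names = FALSE)
  invisible(x)
}
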