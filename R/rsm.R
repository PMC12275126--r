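quad_term_names <- function() {
  letters4 <- c("A", "B", "C", "D")
  inter <- utils::combn(letters4, 2L, paste0, collapse = "")
  c("(Intercept)", letters4, inter, paste0(letters4, "2"))
}

# full second-order model matrix from a 4-column factor matrix
quad_model_matrix <- function(m) {
  A <- m[, 1L]; B <- m[, 2L]; C <- m[, 3L]; D <- m[, 4L]
  X <- cbind(1, A, B, C, D,
             A * B, A * C, A * D, B * C, B * D, C * D,
             A^2, B^2, C^2, D^2)
  colnames(X) <- quad_term_names()
  X
}

#' Fit the full quadratic response-surface model
#'
#' Ordinary-least-squares fit of the 15-term second-order polynomial
#' (intercept, 4 linear, 6 two-way interaction and 4 pure quadratic terms)
#' to the observed yields of a four-factor design. The model can be
#' expressed on coded (-1/0/+1) or actual factor units; fitted values and
#' predictions are identical under either coding, only the reported
#' coefficients differ.
#'
#' @param design A [design_table()] with observed yields.
#' @param coding `"coded"` (default) or `"actual"`; the scale on which the
#'   reported coefficients live.
#' @return An object of class `quad_rsm` with components `coefficients`
#'   (named, 15 terms A..D, AB..CD, A2..D2), `fitted`, `residuals`,
#'   `coding`, `domains` and the factor legend.
#' @examples
#' fit <- fit_quadratic(thd_runs())
#' round(summary(fit)$r2, 3)
#' @export
fit_quadratic <- function(design, coding = c("coded", "actual")) {
  coding <- match.arg(coding)
  if (nrow(design) < 16L) {
    stop_invalid("need at least 16 runs to fit 15 coefficients with residual df, got %d",
                 nrow(design))
  }
  domains <- design_domains(design)
  fm <- as.matrix(as.data.frame(design)[names(domains)])
  y <- design$yield_pct
  if (any(!is.finite(y))) stop_invalid("design has missing yields; fit requires observed responses")
  coded <- encode_points(fm, domains)
  Xc <- quad_model_matrix(coded)
  qrc <- qr(Xc)
  if (qrc$rank < ncol(Xc)) {
    stop_invalid("singular design: quadratic model matrix has rank %d < %d (too few distinct design points)",
                 qrc$rank, ncol(Xc))
  }
  beta_c <- qr.coef(qrc, y)
  fitted <- drop(Xc %*% beta_c)
  coefs <- if (coding == "coded") beta_c else {
    Xa <- quad_model_matrix(fm)
    qr.coef(qr(Xa), y)
  }
  structure(
    list(coefficients = coefs, coding = coding, domains = domains,
         fitted = fitted, residuals = y - fitted, y = y,
         factors = fm, coded = coded, qr = qrc, coef_coded = beta_c,
         legend = stats::setNames(names(domains), c("A", "B", "C", "D"))),
    class = "quad_rsm"
  )
}

#' Predict yield from a fitted quadratic model
#'
#' Evaluates the 15-term polynomial at new factor settings given in actual
#' units (encoding internally when the model is coded). Points outside the
#' design box are evaluated anyway and flagged in the `"extrapolated"`
#' attribute of the result.
#'
#' @param object A `quad_rsm` model.
#' @param newdata Data frame/matrix with one column per factor, or a
#'   4-vector for a single point (actual units). Defaults to the training
#'   points.
#' @param ... Unused.
#' @return Numeric vector of predicted yields (%), with a logical
#'   `"extrapolated"` attribute.
#' @export
predict.quad_rsm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  m <- as_point_matrix(newdata, object$domains)
  coded <- encode_points(m, object$domains)
  out <- drop(quad_model_matrix(coded) %*% object$coef_coded)
  attr(out, "extrapolated") <- apply(abs(coded) > 1 + 1e-8, 1L, any)
  out
}

#' @export
print.quad_rsm <- function(x, ...) {
  cat(sprintf("<quad_rsm> second-order response surface (%s coding)\n", x$coding))
  cat("factors:", paste(sprintf("%s = %s", names(x$legend), x$legend), collapse = ", "), "\n")
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
summary.quad_rsm <- function(object, ...) {
  y <- object$y
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(object$residuals^2)
  n <- length(y)
  df_res <- n - length(object$coefficients)
  list(r2 = 1 - ss_res / ss_tot,
       adj_r2 = 1 - (ss_res / df_res) / (ss_tot / (n - 1)),
       rmse = sqrt(ss_res / n),
       mae = mean(abs(object$residuals)),
       ss_res = ss_res, ss_tot = ss_tot, n = n)
}

#' Leave-one-out PRESS statistic
#'
#' Prediction error sum of squares, computed through the hat-matrix
#' shortcut `sum((e_i / (1 - h_ii))^2)`, which is algebraically identical to
#' refitting the model n times with one run left out each time.
#'
#' @param model A fitted `quad_rsm`.
#' @return The PRESS statistic (scalar).
#' @export
press_stat <- function(model) {
  h <- rowSums(qr.Q(model$qr)[, seq_len(model$qr$rank), drop = FALSE]^2)
  if (any(h >= 1 - 1e-10)) {
    stop_invalid("degenerate leverage: a run with h_ii = 1 cannot be left out")
  }
  sum((model$residuals / (1 - h))^2)
}

#' Full response-surface ANOVA
#'
#' The complete analysis-of-variance partition for a fitted second-order
#' model: the overall model test, one row per term, residual, lack-of-fit
#' against pure error from replicated runs, and the summary statistics
#' (R-squared, adjusted and predicted R-squared, PRESS, C.V.%).
#'
#' Per-term sums of squares are computed on the coded factors. The default
#' (`type = "III"`) is the extra sum of squares from dropping the term from
#' the full model, the convention of standard response-surface software; for
#' the mutually orthogonal linear and interaction columns of a Box-Behnken
#' design it coincides with the sequential (`type = "I"`) partition, while
#' the pure quadratic columns differ slightly between the two.
#'
#' @param model A fitted `quad_rsm`.
#' @param type `"III"` (drop-one-term, default) or `"I"` (sequential).
#' @return An object of class `rsm_anova`: a list with `table` (data frame
#'   with columns source, ss, df, ms, f, p) and scalars `r2`, `adj_r2`,
#'   `pred_r2`, `press`, `cv_pct`.
#' @examples
#' a <- rsm_anova(fit_quadratic(thd_runs()))
#' a$table[a$table$source == "B", ]
#' @export
rsm_anova <- function(model, type = c("III", "I")) {
  type <- match.arg(type)
  X <- quad_model_matrix(model$coded)
  y <- model$y
  n <- length(y)
  p <- ncol(X)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(model$residuals^2)
  ss_mod <- ss_tot - ss_res
  df_mod <- p - 1L
  df_res <- n - p
  ms_res <- ss_res / df_res

  terms <- colnames(X)[-1L]
  ss_term <- numeric(length(terms))
  if (type == "III") {
    for (j in seq_along(terms)) {
      rss_drop <- sum(qr.resid(qr(X[, -(j + 1L), drop = FALSE]), y)^2)
      ss_term[j] <- rss_drop - ss_res
    }
  } else {
    rss_prev <- sum((y - mean(y))^2)
    for (j in seq_along(terms)) {
      rss_j <- sum(qr.resid(qr(X[, seq_len(j + 1L), drop = FALSE]), y)^2)
      ss_term[j] <- rss_prev - rss_j
      rss_prev <- rss_j
    }
  }

  # pure error from replicated design points
  key <- apply(model$factors, 1L, paste, collapse = "\r")
  groups <- split(y, key)
  reps <- groups[lengths(groups) > 1L]
  has_reps <- length(reps) > 0L
  if (has_reps) {
    ss_pe <- sum(vapply(reps, function(g) sum((g - mean(g))^2), numeric(1)))
    df_pe <- sum(lengths(reps) - 1L)
    ss_lof <- ss_res - ss_pe
    df_lof <- df_res - df_pe
  } else {
    ss_pe <- df_pe <- NA_real_
    ss_lof <- df_lof <- NA_real_
  }

  f_of <- function(ss, df) (ss / df) / ms_res
  p_of <- function(f, df1) stats::pf(f, df1, df_res, lower.tail = FALSE)

  rows <- data.frame(
    source = c("Model", terms, "Residual"),
    ss = c(ss_mod, ss_term, ss_res),
    df = c(df_mod, rep(1L, length(terms)), df_res),
    stringsAsFactors = FALSE
  )
  rows$ms <- rows$ss / rows$df
  rows$f <- c(f_of(ss_mod, df_mod), f_of(ss_term, 1L), NA)
  rows$p <- c(p_of(rows$f[1], df_mod), p_of(rows$f[seq_along(terms) + 1L], 1L), NA)

  lof <- data.frame(
    source = c("Lack of Fit", "Pure Error", "Cor Total"),
    ss = c(ss_lof, ss_pe, ss_tot),
    df = c(df_lof, df_pe, n - 1L),
    ms = c(if (has_reps) ss_lof / df_lof else NA, if (has_reps) ss_pe / df_pe else NA, NA),
    f = c(if (has_reps && df_pe > 0) (ss_lof / df_lof) / (ss_pe / df_pe) else NA, NA, NA),
    p = NA_real_,
    stringsAsFactors = FALSE
  )
  if (has_reps && df_pe > 0 && df_lof > 0) {
    lof$p[1] <- stats::pf(lof$f[1], df_lof, df_pe, lower.tail = FALSE)
  }
  tab <- rbind(rows, lof)

  press <- press_stat(model)
  structure(
    list(table = tab,
         r2 = 1 - ss_res / ss_tot,
         adj_r2 = 1 - (ss_res / df_res) / (ss_tot / (n - 1L)),
         pred_r2 = 1 - press / ss_tot,
         press = press,
         cv_pct = 100 * sqrt(ms_res) / mean(y),
         type = type, legend = model$legend),
    class = "rsm_anova"
  )
}

format_p <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 1e-4, "< 0.0001", sprintf("%.4f", p)))
}

#' @export
print.rsm_anova <- function(x, ...) {
  cat(sprintf("Response-surface ANOVA (type %s term SS)\n", x$type))
  tab <- x$table
  out <- data.frame(
    Source = tab$source,
    `Sum of Squares` = sprintf("%.4g", tab$ss),
    df = tab$df,
    `Mean Square` = ifelse(is.na(tab$ms), "", sprintf("%.4g", tab$ms)),
    `F-value` = ifelse(is.na(tab$f), "", sprintf("%.4g", tab$f)),
    `p-value` = format_p(tab$p),
    check.names = FALSE
  )
  print(out, row.names = FALSE, right = FALSE)
  cat(sprintf("R2 %.4f   Adjusted R2 %.4f   Predicted R2 %.4f\n",
              x$r2, x$adj_r2, x$pred_r2))
  cat(sprintf("PRESS %.4g   C.V.%% %.2f\n", x$press, x$cv_pct))
  cat("legend:", paste(sprintf("%s = %s", names(x$legend), x$legend), collapse = ", "), "\n")
  invisible(x)
}
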