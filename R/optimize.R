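default_box <- function(domains) {
  domains <- check_domains(domains)
  out <- lapply(domains, function(d) c(d$low, d$high))
  names(out) <- names(domains)
  out
}

check_box <- function(box) {
  if (!is.list(box) || length(box) != 4L || is.null(names(box))) {
    stop_invalid("box must be a named list of 4 c(low, high) ranges")
  }
  for (nm in names(box)) {
    b <- box[[nm]]
    if (!is.numeric(b) || length(b) != 2L || b[1] > b[2]) {
      stop_invalid("box range for '%s' must be c(low, high) with low <= high", nm)
    }
  }
  box
}

surrogate_id <- function(surrogate) {
  if (inherits(surrogate, "quad_rsm")) "quadratic-rsm"
  else if (inherits(surrogate, "mlp_surrogate")) sprintf("mlp-4-%d-1", surrogate$n_hidden)
  else class(surrogate)[1]
}

# evaluate a surrogate on a 4-column matrix of actual settings, chunked so
# dense grids never materialize a full model matrix at once
eval_surrogate <- function(surrogate, m, chunk = 250000L) {
  n <- nrow(m)
  if (n <= chunk) return(as.numeric(predict(surrogate, m)))
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out[s:e] <- as.numeric(predict(surrogate, m[s:e, , drop = FALSE]))
  }
  out
}

# Dense-grid scan over `axes` (named list of axis values, actual units).
# Slices along the fourth axis; within a slice the evaluation reuses the
# precomputed contribution of the first three factors, which makes a
# 101^4 grid tractable. Returns the best cell per slice and the value span.
grid_scan <- function(surrogate, axes) {
  nms <- names(axes)
  g3 <- as.matrix(expand.grid(axes[1:3], KEEP.OUT.ATTRS = FALSE))
  colnames(g3) <- nms[1:3]
  slice_fn <- slice_evaluator(surrogate, g3, nms)
  starts <- NULL
  span <- c(Inf, -Inf)
  for (v4 in axes[[4L]]) {
    v <- slice_fn(v4)
    span <- c(min(span[1], min(v)), max(span[2], max(v)))
    i <- which.max(v)
    starts <- rbind(starts, c(g3[i, ], v4, v[i]))
  }
  colnames(starts) <- c(nms, "value")
  list(starts = starts[order(-starts[, "value"]), , drop = FALSE], span = span)
}

# returns function(v4) -> predictions over the g3 x v4 slice
slice_evaluator <- function(surrogate, g3, nms) {
  UseMethod("slice_evaluator")
}

#' @export
slice_evaluator.default <- function(surrogate, g3, nms) {
  function(v4) {
    m <- cbind(g3, v4)
    colnames(m) <- nms
    eval_surrogate(surrogate, m)
  }
}

#' @export
slice_evaluator.quad_rsm <- function(surrogate, g3, nms) {
  doms <- surrogate$domains
  c3 <- encode_points(cbind(g3, 0)[, seq_len(4L)], doms)[, 1:3, drop = FALSE]
  b <- surrogate$coef_coded
  A <- c3[, 1L]; B <- c3[, 2L]; C <- c3[, 3L]
  base <- b["(Intercept)"] + b["A"] * A + b["B"] * B + b["C"] * C +
    b["AB"] * A * B + b["AC"] * A * C + b["BC"] * B * C +
    b["A2"] * A^2 + b["B2"] * B^2 + b["C2"] * C^2
  lin4 <- b["D"] + b["AD"] * A + b["BD"] * B + b["CD"] * C
  d4 <- doms[[4L]]
  function(v4) {
    z <- (v4 - d4$mid) / ((d4$high - d4$low) / 2)
    base + z * lin4 + b["D2"] * z^2
  }
}

#' @export
slice_evaluator.mlp_surrogate <- function(surrogate, g3, nms) {
  norm <- surrogate$norm
  if (is.null(norm)) stop_invalid("network has no frozen normalization; train it first")
  h <- surrogate$n_hidden
  p <- unpack_weights(surrogate$weights, h)
  x3 <- sweep(sweep(g3, 2L, norm$x_lo[1:3]), 2L,
              (norm$x_hi[1:3] - norm$x_lo[1:3]) / 2, "/") - 1
  Z3 <- x3 %*% t(p$W1[, 1:3, drop = FALSE]) +
    matrix(p$b1, nrow(g3), h, byrow = TRUE)
  w14 <- p$W1[, 4L]
  function(v4) {
    z4 <- 2 * (v4 - norm$x_lo[4L]) / (norm$x_hi[4L] - norm$x_lo[4L]) - 1
    A <- 1 / (1 + exp(-(Z3 + matrix(w14 * z4, nrow(Z3), h, byrow = TRUE))))
    denorm_y(norm, drop(A %*% p$w2 + p$b2))
  }
}

#' Maximize a fitted surrogate over the experimental region
#'
#' Dense grid search at `resolution` points per axis over the box, followed
#' by coordinate-ascent polishing: starting from the best grid cells (the
#' best `n_starts`, useful for non-convex network surrogates), each factor
#' is line-maximized in turn by golden-section search over its box range
#' until a full sweep improves the objective by less than the polish
#' tolerance. Settings that end up within one grid step of a box edge are
#' flagged; flags are suppressed when the surface is constant.
#'
#' @param surrogate A fitted `quad_rsm` or trained `mlp_surrogate` (any
#'   object with a conforming [predict()] method works).
#' @param box Named list of `c(low, high)` ranges per factor; defaults to
#'   the design region of `domains`.
#' @param domains Factor domains used for the default box.
#' @param resolution Grid points per axis (default 101).
#' @param n_starts Polish starts taken from the best grid cells.
#' @param tol Polish convergence tolerance on the predicted yield.
#' @return An object of class `optimum_result`: `settings` (named, actual
#'   units), `predicted` (% yield), `surrogate`, `resolution` and
#'   `boundary` (named logical flags).
#' @examples
#' maximize_surrogate(fit_quadratic(thd_runs()), resolution = 21)
#' @export
maximize_surrogate <- function(surrogate, box = NULL, domains = thd_domains(),
                               resolution = 101L, n_starts = 5L, tol = 1e-6) {
  if (is.null(box)) box <- default_box(domains)
  box <- check_box(box)
  if (!is_count(resolution) || resolution < 1) stop_invalid("resolution must be >= 1")
  nms <- names(box)
  axes <- lapply(box, function(b) {
    if (resolution == 1L) mean(b) else seq(b[1], b[2], length.out = resolution)
  })

  # dense grid pass, sliced along the fourth axis
  scan <- grid_scan(surrogate, axes)
  vals_span <- scan$span
  starts <- scan$starts[seq_len(min(n_starts, nrow(scan$starts))),
                        seq_len(4L), drop = FALSE]

  f1 <- function(x) as.numeric(predict(surrogate, x))
  polish <- function(x0) {
    x <- x0
    val <- f1(x)
    repeat {
      improved <- FALSE
      for (j in seq_len(4L)) {
        b <- box[[j]]
        if (b[1] == b[2]) next
        opt <- stats::optimize(function(z) { xx <- x; xx[j] <- z; f1(xx) },
                               interval = b, maximum = TRUE, tol = tol / 10)
        if (opt$objective > val + tol / 10) {
          x[j] <- opt$maximum
          val <- opt$objective
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    list(x = x, val = val)
  }
  res <- lapply(seq_len(nrow(starts)), function(i) polish(starts[i, ]))
  best <- res[[which.max(vapply(res, `[[`, numeric(1), "val"))]]

  step <- vapply(box, function(b) {
    if (resolution == 1L) diff(b) else diff(b) / (resolution - 1L)
  }, numeric(1))
  flat <- diff(vals_span) <= 1e-12
  boundary <- !flat &
    (abs(best$x - vapply(box, `[[`, numeric(1), 1L)) <= step |
     abs(best$x - vapply(box, `[[`, numeric(1), 2L)) <= step)
  names(boundary) <- nms
  settings <- stats::setNames(as.numeric(best$x), nms)
  structure(list(settings = settings, predicted = best$val,
                 surrogate = surrogate_id(surrogate),
                 resolution = as.integer(resolution), boundary = boundary),
            class = "optimum_result")
}

#' @export
print.optimum_result <- function(x, ...) {
  cat(sprintf("<optimum_result> %s: predicted yield %.3f %%\n",
              x$surrogate, x$predicted))
  for (nm in names(x$settings)) {
    cat(sprintf("  %-12s %.4g%s\n", nm, x$settings[[nm]],
                if (x$boundary[[nm]]) "  [at box edge]" else ""))
  }
  invisible(x)
}

#' Response-surface grid for a factor pair
#'
#' Predictions of a surrogate over a 2-D grid of two factors with the
#' remaining factors fixed, for contour/perspective plots.
#'
#' @param surrogate A fitted surrogate.
#' @param pair Character vector of the two varying factor names.
#' @param others_at Named settings of the remaining factors (actual units).
#' @param box Named list of ranges; defaults to the `domains` design region.
#' @param domains Factor domains for the default box.
#' @param resolution Grid points per axis.
#' @return Numeric `resolution x resolution` matrix of predicted yields;
#'   the first factor varies along rows. Axis values are in the `"axes"`
#'   attribute.
#' @export
surface_grid <- function(surrogate, pair, others_at, box = NULL,
                         domains = thd_domains(), resolution = 101L) {
  if (is.null(box)) box <- default_box(domains)
  box <- check_box(box)
  nms <- names(box)
  if (length(pair) != 2L || !all(pair %in% nms)) {
    stop_invalid("pair must name two of: %s", paste(nms, collapse = ", "))
  }
  fixed <- setdiff(nms, pair)
  if (!all(fixed %in% names(others_at))) {
    stop_invalid("others_at must provide settings for: %s",
                 paste(fixed, collapse = ", "))
  }
  ax <- lapply(box[pair], function(b) {
    if (resolution == 1L) mean(b) else seq(b[1], b[2], length.out = resolution)
  })
  g <- expand.grid(ax, KEEP.OUT.ATTRS = FALSE)
  m <- matrix(0, nrow(g), 4L, dimnames = list(NULL, nms))
  m[, pair[1]] <- g[[1]]; m[, pair[2]] <- g[[2]]
  for (f in fixed) m[, f] <- others_at[[f]]
  v <- eval_surrogate(surrogate, m)
  out <- matrix(v, length(ax[[1]]), length(ax[[2]]))
  dimnames(out) <- list(format(ax[[1]], trim = TRUE), format(ax[[2]], trim = TRUE))
  attr(out, "axes") <- ax
  out
}
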