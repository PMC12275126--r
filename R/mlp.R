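#' Backpropagation training configuration
#'
#' @param max_epochs Epoch cap (default 1000).
#' @param target_error Stop once the epoch mean-squared error of the
#'   normalized outputs falls below this threshold (default 1e-5).
#' @param learning_rate Batch gradient-descent step size (default 0.05).
#' @param momentum Momentum coefficient in \[0, 1); 0 (default) is plain
#'   gradient descent.
#' @param seed Optional RNG seed (used only where the caller draws random
#'   initial weights).
#' @return A `train_config` list.
#' @export
train_config <- function(max_epochs = 1000L, target_error = 1e-5,
                         learning_rate = 0.05, momentum = 0, seed = NULL) {
  if (!is_count(max_epochs) || max_epochs < 1) stop_invalid("max_epochs must be >= 1")
  if (!is.numeric(target_error) || target_error <= 0) stop_invalid("target_error must be > 0")
  if (momentum < 0 || momentum >= 1) stop_invalid("momentum must lie in [0, 1)")
  structure(list(max_epochs = as.integer(max_epochs), target_error = target_error,
                 learning_rate = learning_rate, momentum = momentum, seed = seed),
            class = "train_config")
}

#' Number of weights of a 4-h-1 network
#'
#' Input-to-hidden matrix (4h), hidden biases (h), hidden-to-output vector
#' (h) and output bias (1): `6h + 1` in total.
#'
#' @param n_hidden Hidden-layer size.
#' @return Integer weight count.
#' @export
n_weights <- function(n_hidden) 6L * as.integer(n_hidden) + 1L

#' Initial weight vector for the surrogate network
#'
#' Either draws uniform random weights in \[-1, 1\] from a seed, or adopts an
#' externally supplied vector verbatim (the GA-ACO hand-off), checking its
#' length.
#'
#' @param n_hidden Hidden-layer size (>= 1).
#' @param seed RNG seed for the random draw (ignored when `weights` given).
#' @param weights Optional external weight vector of length
#'   [n_weights()]`(n_hidden)`.
#' @return Numeric weight vector.
#' @export
init_weights <- function(n_hidden, seed = NULL, weights = NULL) {
  if (!is_count(n_hidden) || n_hidden < 1) stop_invalid("n_hidden must be >= 1")
  nw <- n_weights(n_hidden)
  if (!is.null(weights)) {
    if (length(weights) != nw) {
      stop_invalid("external weight vector has length %d; a 4-%d-1 network needs %d",
                   length(weights), n_hidden, nw)
    }
    return(as.numeric(weights))
  }
  with_seed(seed, stats::runif(nw, -1, 1))
}

#' Construct an (untrained) MLP surrogate
#'
#' A feedforward 4-h-1 network with logistic-sigmoid hidden units and a
#' linear output, operating on per-feature min-max normalized inputs and
#' outputs (both mapped to \[-1, 1\]). Normalization parameters are frozen
#' when the network is trained.
#'
#' @param n_hidden Hidden-layer size.
#' @param weights Weight vector from [init_weights()]; drawn randomly from
#'   `seed` when omitted.
#' @param seed Seed for the random draw.
#' @return An object of class `mlp_surrogate`.
#' @export
mlp_surrogate <- function(n_hidden = 4L, weights = NULL, seed = NULL) {
  weights <- if (is.null(weights)) init_weights(n_hidden, seed = seed)
             else init_weights(n_hidden, weights = weights)
  structure(list(n_hidden = as.integer(n_hidden), weights = weights,
                 norm = NULL, trace = NULL, trained = FALSE),
            class = "mlp_surrogate")
}

#' @export
print.mlp_surrogate <- function(x, ...) {
  cat(sprintf("<mlp_surrogate> 4-%d-1 (%d weights)%s\n", x$n_hidden,
              length(x$weights),
              if (x$trained) sprintf(", trained (final MSE %.3g, %d epochs)",
                                     x$best_mse, length(x$trace)) else ", untrained"))
  invisible(x)
}

unpack_weights <- function(w, h) {
  list(W1 = matrix(w[seq_len(4L * h)], h, 4L),
       b1 = w[(4L * h + 1L):(5L * h)],
       w2 = w[(5L * h + 1L):(6L * h)],
       b2 = w[6L * h + 1L])
}

# forward pass on normalized inputs; X is n x 4
mlp_forward <- function(w, h, X) {
  p <- unpack_weights(w, h)
  A <- 1 / (1 + exp(-(X %*% t(p$W1) + matrix(p$b1, nrow(X), h, byrow = TRUE))))
  drop(A %*% p$w2 + p$b2)
}

# analytic gradient of mean((forward - y)^2) wrt the packed weight vector
mlp_grad <- function(w, h, X, y) {
  p <- unpack_weights(w, h)
  n <- nrow(X)
  Z <- X %*% t(p$W1) + matrix(p$b1, n, h, byrow = TRUE)
  A <- 1 / (1 + exp(-Z))
  yhat <- drop(A %*% p$w2 + p$b2)
  err <- yhat - y
  d_out <- 2 * err / n
  dA <- outer(d_out, p$w2) * A * (1 - A)
  list(gradient = c(as.vector(t(dA) %*% X), colSums(dA),
                    drop(crossprod(A, d_out)), sum(d_out)),
       mse = mean(err^2))
}

make_norm <- function(fm, y, factor_names) {
  x_lo <- apply(fm, 2L, min); x_hi <- apply(fm, 2L, max)
  # constant columns (e.g. a single training point) get a unit half-width
  # band around the value, mapping it to 0
  flat <- x_hi - x_lo <= 0
  x_lo[flat] <- x_lo[flat] - 1; x_hi[flat] <- x_hi[flat] + 1
  y_lo <- min(y); y_hi <- max(y)
  if (y_hi - y_lo <= 0) { y_lo <- y_lo - 1; y_hi <- y_hi + 1 }
  list(x_lo = x_lo, x_hi = x_hi, y_lo = y_lo, y_hi = y_hi,
       factors = factor_names)
}

norm_x <- function(norm, fm) {
  sweep(sweep(fm, 2L, norm$x_lo), 2L, (norm$x_hi - norm$x_lo) / 2, "/") - 1
}
norm_y <- function(norm, y) 2 * (y - norm$y_lo) / (norm$y_hi - norm$y_lo) - 1
denorm_y <- function(norm, yn) (yn + 1) / 2 * (norm$y_hi - norm$y_lo) + norm$y_lo

design_xy <- function(data) {
  doms <- design_domains(data)
  if (is.null(doms)) stop_invalid("training data must be a design_table")
  list(fm = as.matrix(as.data.frame(data)[names(doms)]),
       y = data$yield_pct, factors = names(doms))
}

#' Train the surrogate by batch backpropagation
#'
#' Plain batch gradient descent (optionally with momentum) on the
#' mean-squared error of the min-max-normalized outputs. Training stops at
#' `max_epochs` or as soon as the epoch MSE falls below `target_error`,
#' whichever comes first, and the best weights seen across all epochs are
#' returned. Normalization parameters are computed from `data` on the first
#' training call and frozen thereafter.
#'
#' @param net An [mlp_surrogate()].
#' @param data A non-empty [design_table()] with observed yields.
#' @param config A [train_config()].
#' @return The trained `mlp_surrogate`, with the per-epoch error trace in
#'   `$trace` and the best epoch MSE in `$best_mse`.
#' @export
train_bp <- function(net, data, config = train_config()) {
  stopifnot(inherits(net, "mlp_surrogate"))
  if (nrow(data) < 1L) stop_invalid("training data is empty")
  dxy <- design_xy(data)
  if (is.null(net$norm)) net$norm <- make_norm(dxy$fm, dxy$y, dxy$factors)
  X <- norm_x(net$norm, dxy$fm)
  y <- norm_y(net$norm, dxy$y)
  h <- net$n_hidden
  w <- net$weights
  v <- numeric(length(w))
  best_w <- w; best_mse <- Inf
  trace <- numeric(config$max_epochs)
  e <- 0L
  while (e < config$max_epochs) {
    e <- e + 1L
    g <- mlp_grad(w, h, X, y)
    if (!is.finite(g$mse)) {
      stop_invalid("training diverged (non-finite loss) at epoch %d", e)
    }
    trace[e] <- g$mse
    if (g$mse < best_mse) { best_mse <- g$mse; best_w <- w }
    if (g$mse < config$target_error) break
    v <- config$momentum * v - config$learning_rate * g$gradient
    w <- w + v
  }
  net$weights <- best_w
  net$best_mse <- best_mse
  net$trace <- trace[seq_len(e)]
  net$trained <- TRUE
  net
}

#' Predict yield with a trained surrogate network
#'
#' Forward pass at new factor settings (actual units), using the frozen
#' normalization; the output is denormalized back to percent yield.
#'
#' @param object A trained `mlp_surrogate`.
#' @param newdata Data frame/matrix of factor settings, or a 4-vector.
#' @param ... Unused.
#' @return Numeric vector of predicted yields (%).
#' @export
predict.mlp_surrogate <- function(object, newdata, ...) {
  if (is.null(object$norm)) {
    stop_invalid("network has no frozen normalization; train it first")
  }
  fm <- if (is.null(dim(newdata)) && is.numeric(newdata)) {
    matrix(newdata, nrow = 1L, dimnames = list(NULL, object$norm$factors))
  } else {
    m <- as.matrix(as.data.frame(newdata))
    if (!is.null(colnames(m)) && all(object$norm$factors %in% colnames(m))) {
      m <- m[, object$norm$factors, drop = FALSE]
    }
    m
  }
  denorm_y(object$norm, mlp_forward(object$weights, object$n_hidden,
                                    norm_x(object$norm, fm)))
}

#' Serialize / restore a surrogate network
#'
#' Plain-list representations round-trip through JSON without loss of
#' predictive behaviour.
#'
#' @param net A `mlp_surrogate`.
#' @return `as_mlp_list()`: a named list; `mlp_from_list()`: the restored
#'   `mlp_surrogate`.
#' @export
as_mlp_list <- function(net) {
  list(n_hidden = net$n_hidden, weights = net$weights, norm = net$norm,
       trained = net$trained,
       best_mse = if (is.null(net$best_mse)) NULL else net$best_mse)
}

#' @rdname as_mlp_list
#' @param x A list produced by `as_mlp_list()` (possibly via JSON).
#' @export
mlp_from_list <- function(x) {
  net <- mlp_surrogate(n_hidden = x$n_hidden, weights = as.numeric(x$weights))
  if (!is.null(x$norm)) {
    net$norm <- list(x_lo = as.numeric(x$norm$x_lo), x_hi = as.numeric(x$norm$x_hi),
                     y_lo = as.numeric(x$norm$y_lo), y_hi = as.numeric(x$norm$y_hi),
                     factors = as.character(x$norm$factors))
  }
  net$trained <- isTRUE(x$trained)
  if (!is.null(x$best_mse)) net$best_mse <- as.numeric(x$best_mse)
  net
}

# golden-section minimization of f over the integers lo..hi; memoized.
# Returns list(best, evaluations) with all probed (h, value) pairs.
golden_section_int <- function(f, lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (lo > hi) stop_invalid("empty search range [%d, %d]", lo, hi)
  memo <- new.env(parent = emptyenv())
  fx <- function(x) {
    key <- as.character(x)
    if (is.null(memo[[key]])) memo[[key]] <- f(x)
    memo[[key]]
  }
  invphi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  while (b - a > 2L) {
    x1 <- as.integer(round(b - (b - a) * invphi))
    x2 <- as.integer(round(a + (b - a) * invphi))
    if (x1 <= a) x1 <- a + 1L
    if (x2 >= b) x2 <- b - 1L
    if (x1 >= x2) x2 <- x1 + 1L
    if (fx(x1) <= fx(x2)) b <- x2 else a <- x1
  }
  for (x in a:b) fx(x)
  probed <- sort(as.integer(ls(memo)))
  vals <- vapply(probed, function(x) memo[[as.character(x)]], numeric(1))
  list(best = probed[which.min(vals)],
       evaluations = data.frame(n_hidden = probed, value = vals))
}

#' Golden-section search over hidden-layer size
#'
#' Selects the hidden-layer size minimizing seed-averaged validation MSE:
#' each probed integer h is scored by training a 4-h-1 network on a
#' stratified split for `n_seeds` seeds and averaging the validation-set
#' mean-squared error (in yield percent). Probes follow golden-section
#' bracketing over the integer interval; the final bracket is scanned
#' exhaustively.
#'
#' @param data A [design_table()] with observed yields.
#' @param h_range Integer interval `c(h_lo, h_hi)` to search.
#' @param config A [train_config()] used for every training run.
#' @param n_seeds Seeds averaged per probe.
#' @param n_valid Validation-set size of the stratified split.
#' @param seed Base seed for splits and initializations.
#' @return List with `best_h` and `evaluations` (data frame of probed sizes
#'   and their mean validation MSE).
#' @export
golden_section_hidden_search <- function(data, h_range = c(6L, 12L),
                                         config = train_config(),
                                         n_seeds = 3L, n_valid = 8L, seed = 1L) {
  if (h_range[1] > h_range[2]) stop_invalid("empty range: h_lo > h_hi")
  score <- function(h) {
    mean(vapply(seq_len(n_seeds), function(i) {
      si <- derive_seed(seed, 3L, i)
      sp <- stratified_split(data, nrow(data) - n_valid, n_valid, seed = si)
      net <- mlp_surrogate(h, seed = derive_seed(seed, 4L, i))
      net <- train_bp(net, sp$train, config)
      mean((predict(net, sp$validation) - sp$validation$yield_pct)^2)
    }, numeric(1)))
  }
  res <- golden_section_int(score, h_range[1], h_range[2])
  list(best_h = res$best, evaluations = res$evaluations)
}
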