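#' Define a design factor and its levels
#'
#' A factor domain records the three actual levels (`low`, `mid`, `high`)
#' used in a three-level Box-Behnken design, together with the factor's name,
#' physical unit and, optionally, the equidistant levels screened in the
#' preceding single-factor experiments.
#'
#' @param name Factor identifier, e.g. `"temperature"`.
#' @param unit Unit text, e.g. `"degC"`.
#' @param low,mid,high The three design levels in actual units. `mid` must be
#'   the midpoint of `low` and `high` up to rounding.
#' @param screen_levels Optional increasing vector of single-factor screening
#'   levels.
#' @return An object of class `factor_domain`.
#' @examples
#' factor_domain("temperature", "degC", 80, 90, 100)
#' @export
factor_domain <- function(name, unit, low, mid, high, screen_levels = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  for (v in list(low, mid, high)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_invalid("factor '%s': levels must be finite numbers", name)
    }
  }
  if (!(low < mid && mid < high)) {
    stop_invalid("factor '%s': need low < mid < high (got %g, %g, %g)",
                 name, low, mid, high)
  }
  if (abs(mid - (low + high) / 2) > 0.5 + 1e-8) {
    stop_invalid("factor '%s': mid level %g is not the midpoint of (%g, %g)",
                 name, mid, low, high)
  }
  if (!is.null(screen_levels)) {
    if (!is.numeric(screen_levels) || length(screen_levels) < 3L ||
        any(diff(screen_levels) <= 0)) {
      stop_invalid("factor '%s': screen_levels must be >= 3 strictly increasing values",
                   name)
    }
  }
  structure(
    list(name = name, unit = unit, low = low, mid = mid, high = high,
         screen_levels = screen_levels),
    class = "factor_domain"
  )
}

#' @export
print.factor_domain <- function(x, ...) {
  cat(sprintf("<factor_domain> %s [%s]: levels %g / %g / %g\n",
              x$name, x$unit, x$low, x$mid, x$high))
  if (!is.null(x$screen_levels)) {
    cat("  screened at:", paste(x$screen_levels, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Factor domains of the ultrasonic extraction study
#'
#' The four process factors of the Tetrastigma hemsleyanum polysaccharide
#' extraction: liquid-to-solid ratio (mL/g), extraction temperature (degC),
#' extraction time (min) and ultrasonic power (W), with the Box-Behnken
#' levels chosen after single-factor screening and the screened levels
#' themselves.
#'
#' @return A named list of four [factor_domain()] objects, in the canonical
#'   order ratio, temperature, time, power (coded A, B, C, D).
#' @examples
#' thd_domains()$temperature
#' @export
thd_domains <- function() {
  list(
    ratio       = factor_domain("ratio", "mL/g", 20, 25, 30,
                                screen_levels = c(15, 20, 25, 30)),
    temperature = factor_domain("temperature", "degC", 80, 90, 100,
                                screen_levels = c(40, 60, 80, 100)),
    time        = factor_domain("time", "min", 60, 75, 90,
                                screen_levels = c(30, 60, 90, 120)),
    power       = factor_domain("power", "W", 250, 300, 350,
                                screen_levels = c(250, 350, 450, 550))
  )
}

check_domains <- function(domains) {
  if (!is.list(domains) || length(domains) != 4L ||
      !all(vapply(domains, inherits, logical(1), "factor_domain"))) {
    stop_invalid("expected a list of exactly 4 factor_domain objects")
  }
  names(domains) <- vapply(domains, `[[`, character(1), "name")
  domains
}

#' Convert between actual and coded factor levels
#'
#' Standard design-of-experiments coding: `low` maps to -1, `mid` to 0 and
#' `high` to +1, linearly, per factor. `decode_points()` is the exact
#' inverse. Values outside the design range are allowed (extrapolation) and
#' simply map outside \[-1, 1\].
#'
#' @param points A data frame or matrix with one column per factor (matched
#'   to `domains` by name when named, by position otherwise), or a numeric
#'   vector for a single point.
#' @param domains A list of four [factor_domain()] objects.
#' @return A numeric matrix of the same shape with coded (or actual) values.
#' @examples
#' encode_points(c(25, 90, 75, 340), thd_domains())  # power 340 -> +0.8
#' @export
encode_points <- function(points, domains) {
  domains <- check_domains(domains)
  m <- as_point_matrix(points, domains)
  for (j in seq_along(domains)) {
    d <- domains[[j]]
    m[, j] <- (m[, j] - d$mid) / ((d$high - d$low) / 2)
  }
  m
}

#' @rdname encode_points
#' @export
decode_points <- function(points, domains) {
  domains <- check_domains(domains)
  m <- as_point_matrix(points, domains)
  for (j in seq_along(domains)) {
    d <- domains[[j]]
    m[, j] <- m[, j] * (d$high - d$low) / 2 + d$mid
  }
  m
}

as_point_matrix <- function(points, domains) {
  nms <- names(domains)
  if (is.null(dim(points))) {
    if (length(points) != length(domains)) {
      stop_invalid("point has %d coordinates; expected %d",
                   length(points), length(domains))
    }
    m <- matrix(as.numeric(points), nrow = 1L)
    colnames(m) <- nms
    return(m)
  }
  m <- as.matrix(as.data.frame(points))
  if (!is.null(colnames(m)) && all(nms %in% colnames(m))) {
    m <- m[, nms, drop = FALSE]
  } else if (ncol(m) == length(nms)) {
    colnames(m) <- nms
  } else {
    stop_invalid("points must have one column per factor (%d)", length(nms))
  }
  storage.mode(m) <- "double"
  m
}

#' Choose Box-Behnken levels from a single-factor screening curve
#'
#' Selects the screened level with the highest mean response together with
#' its two adjacent levels. When the peak sits at an endpoint of the
#' screened range, the endpoint and its two nearest interior neighbours are
#' returned, so the peak becomes an extreme (not the centre) of the triple.
#' Ties are broken toward the lower level, so a response that plateaus picks
#' the earliest plateau level.
#'
#' @param screen_curve A two-column data frame or matrix of
#'   `(level, mean_yield)` pairs, or a named numeric vector of mean yields
#'   with levels as names. At least 3 levels are required; levels must be
#'   strictly increasing.
#' @return Numeric vector `c(low, mid, high)` of the three selected levels.
#' @examples
#' select_bbd_levels(data.frame(level = c(40, 60, 80, 100),
#'                              mean_yield = c(9, 11, 13, 12)))
#' @export
select_bbd_levels <- function(screen_curve) {
  if (is.numeric(screen_curve) && !is.null(names(screen_curve))) {
    lv <- as.numeric(names(screen_curve))
    yv <- as.numeric(screen_curve)
  } else {
    m <- as.matrix(as.data.frame(screen_curve))
    if (ncol(m) != 2L) stop_invalid("screen_curve needs exactly 2 columns (level, mean_yield)")
    lv <- as.numeric(m[, 1L]); yv <- as.numeric(m[, 2L])
  }
  if (length(lv) < 3L) stop_invalid("need at least 3 screening levels, got %d", length(lv))
  if (any(diff(lv) <= 0)) stop_invalid("screening levels must be strictly increasing")
  peak <- which.max(yv)           # which.max takes the first (lowest) on ties
  n <- length(lv)
  idx <- if (peak == 1L) 1:3 else if (peak == n) (n - 2L):n else (peak - 1L):(peak + 1L)
  sort(lv[idx])
}

#' Construct a four-factor Box-Behnken design
#'
#' Builds the standard 4-factor, 3-level Box-Behnken design: for each of the
#' 6 factor pairs, all four combinations of coded levels (-1, +1) with the
#' remaining two factors held at 0 (24 edge-midpoint runs), plus `n_center`
#' replicated all-zero centre runs, decoded to actual units. Runs are
#' ordered deterministically: factor pairs in lexicographic order, the four
#' sign combinations as (-,-), (-,+), (+,-), (+,+), centre points last.
#'
#' @param domains A list of four [factor_domain()] objects.
#' @param n_center Number of centre-point replicates (>= 1).
#' @return A [design_table()] without observed yields (`yield_pct` all `NA`),
#'   flagged as a BBD.
#' @examples
#' nrow(build_bbd(thd_domains(), n_center = 5))  # 29
#' @export
build_bbd <- function(domains, n_center = 5L) {
  domains <- check_domains(domains)
  if (!is_count(n_center) || n_center < 1) {
    stop_invalid("n_center must be a positive integer, got %s", format(n_center))
  }
  k <- 4L
  pairs <- utils::combn(k, 2L)
  # rows are (-,-), (-,+), (+,-), (+,+)
  signs <- matrix(c(-1, -1, -1, 1, 1, -1, 1, 1), ncol = 2L, byrow = TRUE)
  coded <- matrix(0, nrow = 4L * ncol(pairs) + n_center, ncol = k)
  r <- 0L
  for (p in seq_len(ncol(pairs))) {
    for (s in seq_len(nrow(signs))) {
      r <- r + 1L
      coded[r, pairs[, p]] <- signs[s, ]
    }
  }
  actual <- decode_points(coded, domains)
  df <- as.data.frame(actual)
  names(df) <- names(domains)
  df <- cbind(run = seq_len(nrow(df)), df, yield_pct = NA_real_)
  design_table(df, domains = domains, bbd = TRUE, validate_yield = FALSE)
}
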