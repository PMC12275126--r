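#' Specification of a synthetic quadratic response surface
#'
#' Defines the generating truth for simulated design tables: the 15
#' coefficients of a full second-order polynomial on coded factors, the
#' standard deviation of additive i.i.d. Gaussian response noise (in yield
#' percent), and the number of replicated centre points.
#'
#' @param coefficients Named numeric vector of the 15 coded-scale
#'   coefficients, names as in [fit_quadratic()]
#'   (`"(Intercept)", "A", ..., "D2"`). Missing terms default to 0; an
#'   unnamed vector of length 15 is taken in canonical order.
#' @param noise_sd Response noise standard deviation (>= 0), yield percent.
#' @param n_center Centre-point replicates of the generated design.
#' @param seed Default RNG seed carried by the spec.
#' @return An object of class `surface_spec`.
#' @export
surface_spec <- function(coefficients, noise_sd = 0, n_center = 5L, seed = NULL) {
  nms <- quad_term_names()
  if (is.null(names(coefficients))) {
    if (length(coefficients) != length(nms)) {
      stop_invalid("unnamed coefficient vector must have length %d", length(nms))
    }
    names(coefficients) <- nms
  } else {
    unknown <- setdiff(names(coefficients), nms)
    if (length(unknown)) stop_invalid("unknown term(s): %s", paste(unknown, collapse = ", "))
    full <- stats::setNames(numeric(length(nms)), nms)
    full[names(coefficients)] <- coefficients
    coefficients <- full
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  structure(list(coefficients = coefficients, noise_sd = noise_sd,
                 n_center = as.integer(n_center), seed = seed),
            class = "surface_spec")
}

#' @export
print.surface_spec <- function(x, ...) {
  cat(sprintf("<surface_spec> noise_sd %.4g, %d centre replicates\n",
              x$noise_sd, x$n_center))
  print(round(x$coefficients, 6))
  invisible(x)
}

eval_spec_coded <- function(spec, coded) {
  drop(quad_model_matrix(coded) %*% spec$coefficients)
}

#' Simulate a Box-Behnken design table
#'
#' Builds the four-factor Box-Behnken design for `domains` (with the spec's
#' centre replication), evaluates the spec's true polynomial at each run and
#' adds i.i.d. Gaussian noise, producing a table shaped exactly like the
#' experimental one.
#'
#' @param spec A [surface_spec()].
#' @param domains Factor domains; defaults to [thd_domains()].
#' @param seed RNG seed; defaults to the spec's own.
#' @return A [design_table()] flagged as a BBD.
#' @examples
#' tab <- simulate_table(paperlike_spec(), seed = 1)
#' @export
simulate_table <- function(spec, domains = thd_domains(), seed = spec$seed) {
  stopifnot(inherits(spec, "surface_spec"))
  design <- build_bbd(domains, n_center = spec$n_center)
  domains <- design_domains(design)
  fm <- as.matrix(as.data.frame(design)[names(domains)])
  mu <- eval_spec_coded(spec, encode_points(fm, domains))
  y <- mu + with_seed(seed, stats::rnorm(length(mu), 0, spec$noise_sd))
  df <- as.data.frame(design)
  df$yield_pct <- y
  design_table(df, domains = domains, bbd = TRUE, validate_yield = FALSE)
}

#' Reference surface spec matching the extraction study
#'
#' The generating truth used for study-scale simulations: the coefficients
#' re-fitted from the 29-run extraction table (coded scale) with response
#' noise equal to the residual standard deviation of that fit and 5 centre
#' replicates. Everything is computed from the shipped table at call time;
#' nothing is hard-coded.
#'
#' @param seed Default seed stored in the spec.
#' @return A [surface_spec()].
#' @examples
#' round(paperlike_spec()$noise_sd, 2)
#' @export
paperlike_spec <- function(seed = NULL) {
  d <- thd_runs()
  fit <- fit_quadratic(d, coding = "coded")
  ms_res <- sum(fit$residuals^2) / (nrow(d) - length(fit$coefficients))
  surface_spec(fit$coefficients, noise_sd = sqrt(ms_res), n_center = 5L,
               seed = seed)
}

#' Simulate single-factor screening curves
#'
#' Generates the mean-response-per-level curves produced by one-factor-at-
#' a-time screening, for exercising [select_bbd_levels()]: a unimodal
#' (`"peaked"`) shape, a monotone increasing shape, or a response that
#' rises and then plateaus (`"plateau"`), plus Gaussian noise.
#'
#' @param shape `"peaked"`, `"monotone"` or `"plateau"`.
#' @param levels Increasing numeric vector of screened settings (>= 3).
#' @param noise_sd Noise standard deviation added to the curve.
#' @param seed RNG seed.
#' @param peak_index Index of the peak (peaked) or plateau onset (plateau);
#'   defaults to the middle level / second level respectively.
#' @param base,amplitude Curve location and scale, yield percent.
#' @return Data frame with columns `level` and `mean_yield`.
#' @export
simulate_screening <- function(shape = c("peaked", "monotone", "plateau"),
                               levels, noise_sd = 0, seed = NULL,
                               peak_index = NULL, base = 10, amplitude = 4) {
  shape <- match.arg(shape)
  if (length(levels) < 3L) stop_invalid("need at least 3 screening levels")
  if (any(diff(levels) <= 0)) stop_invalid("levels must be strictly increasing")
  n <- length(levels)
  mu <- switch(shape,
    peaked = {
      pk <- if (is.null(peak_index)) ceiling(n / 2) else peak_index
      base + amplitude * (1 - ((seq_len(n) - pk) / max(pk - 1, n - pk, 1))^2)
    },
    monotone = base + amplitude * (seq_len(n) - 1) / (n - 1),
    plateau = {
      on <- if (is.null(peak_index)) 2L else peak_index
      base + amplitude * pmin(seq_len(n) - 1, on - 1) / max(on - 1, 1)
    }
  )
  y <- mu + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  data.frame(level = levels, mean_yield = y)
}
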