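#' Polysaccharide yield from assay readings
#'
#' Computes extraction yield as the mass of polysaccharide recovered in the
#' extract relative to the dry plant material:
#' `yield (%) = 100 * concentration (g/mL) * volume (mL) / material mass (g)`.
#'
#' @param concentration Polysaccharide concentration of the extract, g/mL.
#' @param volume Extract volume, mL.
#' @param material_mass Dry plant material mass, g.
#' @return Yield in percent. Vectorized over its arguments.
#' @examples
#' yield_from_assay(0.001, 100, 1)  # 10 %
#' @export
yield_from_assay <- function(concentration, volume, material_mass) {
  for (nm in c("concentration", "volume", "material_mass")) {
    v <- get(nm)
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop_invalid("%s must be strictly positive and finite", nm)
    }
  }
  100 * concentration * volume / material_mass
}

canonical_columns <- c(
  run = "run", ratio = "ratio_ml_per_g", temperature = "temperature_c",
  time = "time_min", power = "power_w", yield_pct = "yield_pct"
)

#' Design tables of extraction runs
#'
#' A `design_table` is a data frame of extraction runs with columns `run`,
#' `ratio`, `temperature`, `time`, `power` and `yield_pct`, carrying the
#' four [factor_domain()] objects as an attribute. When flagged as a
#' Box-Behnken design, every factor value must be one of that factor's three
#' design levels.
#'
#' @param df Data frame with the six canonical columns (internal names).
#' @param domains List of four [factor_domain()] objects.
#' @param bbd Logical; is this a Box-Behnken design table?
#' @param validate_yield Logical; require yields present and in (0, 100)?
#' @return The validated `design_table`.
#' @export
design_table <- function(df, domains, bbd = FALSE, validate_yield = TRUE) {
  domains <- check_domains(domains)
  need <- c("run", names(domains), "yield_pct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_invalid("design table missing column(s): %s",
                                 paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (anyDuplicated(df$run)) {
    stop_invalid("duplicate run id(s): %s",
                 paste(unique(df$run[duplicated(df$run)]), collapse = ", "))
  }
  if (any(df$run <= 0 | df$run != round(df$run))) {
    stop_invalid("run ids must be positive integers")
  }
  for (f in names(domains)) {
    v <- df[[f]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop_invalid("column '%s' must be numeric and finite", f)
    }
    if (any(v <= 0)) stop_invalid("column '%s' must be strictly positive", f)
    if (bbd) {
      lev <- with(domains[[f]], c(low, mid, high))
      bad <- which(!v %in% lev)
      if (length(bad)) {
        stop_invalid("BBD table: row %d has %s = %g, not a design level (%s)",
                     bad[1], f, v[bad[1]], paste(lev, collapse = "/"))
      }
    }
  }
  if (validate_yield) {
    y <- df$yield_pct
    if (any(!is.finite(y)) || any(y <= 0 | y >= 100)) {
      stop_invalid("yield_pct must lie in (0, 100) for every run")
    }
  }
  structure(df, domains = domains, bbd = bbd,
            class = c("design_table", "data.frame"))
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("<design_table> %d runs, %d factors%s\n", nrow(x), 4L,
              if (isTRUE(attr(x, "bbd"))) " (Box-Behnken)" else ""))
  print.data.frame(x, ...)
  invisible(x)
}

#' @rdname design_table
#' @param x A `design_table`.
#' @export
design_domains <- function(x) attr(x, "domains")

#' Read a design table from CSV
#'
#' Reads a comma-separated design table (header row, period decimal
#' separator, UTF-8) and validates it. The canonical header is
#' `run,ratio_ml_per_g,temperature_c,time_min,power_w,yield_pct`; other
#' headers can be mapped with `column_map`.
#'
#' @param path Path to the CSV file.
#' @param domains Factor domains; defaults to [thd_domains()].
#' @param column_map Named character vector mapping internal names
#'   (`run`, `ratio`, `temperature`, `time`, `power`, `yield_pct`) to the
#'   file's column names. Defaults to the canonical header.
#' @param bbd Validate factor values against the three design levels.
#' @return A [design_table()]. Row order of the file is preserved.
#' @export
load_design_csv <- function(path, domains = thd_domains(), column_map = NULL,
                            bbd = FALSE) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  map <- canonical_columns
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop_invalid("cannot parse '%s': %s", path, conditionMessage(e))
  )
  if (nrow(raw) == 0L) stop_invalid("'%s' contains no data rows", path)
  miss <- map[!map %in% names(raw)]
  if (length(miss)) {
    stop_invalid("'%s' is missing required column(s): %s", path,
                 paste(sprintf("%s (for %s)", miss, names(miss)), collapse = ", "))
  }
  df <- stats::setNames(raw[unname(map)], names(map))
  for (col in names(df)) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop_invalid("'%s': non-numeric value '%s' in column '%s', row %d",
                     path, v[bad[1]], map[[col]], bad[1])
      }
      df[[col]] <- num
    }
  }
  design_table(df, domains = domains, bbd = bbd)
}

#' Write a design table to CSV
#'
#' Writes the canonical CSV dialect (comma separator, header row, period
#' decimals, UTF-8). Values are written with [format()] at full precision so
#' a write/load round trip reproduces the table exactly.
#'
#' @param design A [design_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  out <- as.data.frame(design)
  names(out) <- unname(canonical_columns[names(out)])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' The 29-run ultrasonic extraction dataset
#'
#' The Box-Behnken experimental table for ultrasonic-assisted extraction of
#' Tetrastigma hemsleyanum polysaccharide: 29 runs over liquid-to-solid
#' ratio (20/25/30 mL/g), temperature (80/90/100 degC), time (60/75/90 min)
#' and ultrasonic power (250/300/350 W), with observed yield (%) and, as an
#' auxiliary attribute, the per-run predictions of the three published
#' surrogate models (quadratic response surface, BP network, GA-ACO-BP
#' network).
#'
#' In the published table the factor column headings are internally
#' inconsistent with the printed values (e.g. the column headed "power"
#' holds values 80-100). Columns are therefore assigned by matching each
#' column's value set to the stated design levels, which is unambiguous
#' because the four level sets are disjoint. Yields are stored exactly as
#' printed (2 decimals).
#'
#' @return A [design_table()] with 29 rows, flagged as a BBD. The attribute
#'   `"predictions"` holds a data frame with columns `pred_rsm`, `pred_bp`
#'   and `pred_gaaco_bp` (opaque reference vectors; their provenance on
#'   coded vs actual units is not documented in the source).
#' @examples
#' d <- thd_runs()
#' range(d$yield_pct)  # 8.08 .. 18.07
#' @export
thd_runs <- function() {
  path <- system.file("extdata", "thd_bbd_runs.csv", package = "extractopt",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- load_design_csv(path, bbd = TRUE)
  attr(d, "predictions") <- raw[c("pred_rsm", "pred_bp", "pred_gaaco_bp")]
  d
}

#' Published per-run model predictions
#'
#' Convenience accessor for the auxiliary prediction columns shipped with
#' [thd_runs()].
#'
#' @param design The fixture table returned by [thd_runs()].
#' @return Data frame with columns `pred_rsm`, `pred_bp`, `pred_gaaco_bp`.
#' @export
thd_predictions <- function(design = thd_runs()) {
  p <- attr(design, "predictions")
  if (is.null(p)) stop_invalid("design table carries no prediction columns")
  p
}
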