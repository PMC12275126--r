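report_type <- function(report) {
  for (cl in c("rsm_anova", "fit_metrics", "optimum_result",
               "model_comparison", "surface_spec")) {
    if (inherits(report, cl)) return(cl)
  }
  stop_invalid("unsupported report class: %s", paste(class(report), collapse = "/"))
}

#' Write an analysis report to disk
#'
#' Serializes ANOVA tables, fit metrics, optimum results, model comparisons
#' and surface specs either as JSON (machine-readable; reloadable with
#' [read_report()] without loss) or as aligned human-readable text.
#'
#' @param report The report object.
#' @param path Output file path.
#' @param format `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  type <- report_type(report)
  if (format == "text") {
    txt <- utils::capture.output(print(report))
    ok <- tryCatch({ writeLines(txt, path); TRUE },
                   error = function(e) stop_invalid("cannot write '%s': %s",
                                                    path, conditionMessage(e)))
    return(invisible(path))
  }
  payload <- unclass(report)
  if (type == "model_comparison") {
    payload <- list(table = as.data.frame(report))
  }
  # named atomic vectors must become JSON objects, not bare arrays
  for (nm in c("settings", "boundary", "legend", "coefficients")) {
    if (!is.null(payload[[nm]])) payload[[nm]] <- as.list(payload[[nm]])
  }
  obj <- list(type = type, payload = payload)
  tryCatch(
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", null = "null"),
    error = function(e) stop_invalid("cannot write '%s': %s", path,
                                     conditionMessage(e))
  )
  invisible(path)
}

#' Reload a JSON report written by [write_report()]
#'
#' @param path Path to the JSON file.
#' @return The restored report object, field-by-field equal to the one
#'   written.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  type <- obj$type
  p <- obj$payload
  switch(type,
    rsm_anova = structure(list(
      table = as.data.frame(p$table),
      r2 = p$r2, adj_r2 = p$adj_r2, pred_r2 = p$pred_r2, press = p$press,
      cv_pct = p$cv_pct, type = p$type,
      legend = stats::setNames(unlist(p$legend), names(p$legend))
    ), class = "rsm_anova"),
    fit_metrics = structure(list(
      r2 = p$r2, mae = p$mae, rmse = p$rmse, n = as.integer(p$n),
      r2_undefined = isTRUE(p$r2_undefined)
    ), class = "fit_metrics"),
    optimum_result = structure(list(
      settings = stats::setNames(unlist(p$settings), names(p$settings)),
      predicted = p$predicted, surrogate = p$surrogate,
      resolution = as.integer(p$resolution),
      boundary = stats::setNames(unlist(p$boundary), names(p$boundary))
    ), class = "optimum_result"),
    surface_spec = surface_spec(
      stats::setNames(unlist(p$coefficients), names(p$coefficients)),
      noise_sd = p$noise_sd, n_center = p$n_center,
      seed = p$seed
    ),
    model_comparison = {
      tab <- as.data.frame(p$table)
      class(tab) <- c("model_comparison", "data.frame")
      tab
    },
    stop_invalid("unknown report type '%s' in %s", type, path)
  )
}
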