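#' Configuration of the full dual-model pipeline
#'
#' Bundles every stage's settings. A seed is mandatory because the network
#' stages are stochastic; all stage seeds are derived deterministically
#' from it.
#'
#' @param seed Global seed (mandatory).
#' @param n_train,n_valid Stratified split sizes.
#' @param n_hidden Hidden-layer size of both networks.
#' @param tcfg A [train_config()].
#' @param gcfg A [gaaco_config()].
#' @param resolution Optimizer grid resolution per axis.
#' @param box Optimization box; defaults to the design region.
#' @param out_dir Optional directory for JSON artifacts.
#' @param verbose Log stage progress and timings to stderr.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed, n_train = 21L, n_valid = 8L, n_hidden = 4L,
                            tcfg = train_config(), gcfg = gaaco_config(),
                            resolution = 101L, box = NULL, out_dir = NULL,
                            verbose = TRUE) {
  if (missing(seed) || is.null(seed) || !is_count(seed)) {
    stop_invalid("pipeline_config: a global integer seed is mandatory (stochastic stages)")
  }
  structure(list(seed = as.integer(seed), n_train = n_train, n_valid = n_valid,
                 n_hidden = n_hidden, tcfg = tcfg, gcfg = gcfg,
                 resolution = resolution, box = box, out_dir = out_dir,
                 verbose = verbose),
            class = "pipeline_config")
}

#' Run the full dual-model optimization pipeline
#'
#' Executes, on one design table: the quadratic response-surface fit with
#' full ANOVA; backpropagation training from random initial weights; the
#' GA-ACO-initialized network; the three-way model comparison over all
#' runs; and box-constrained maximization of both the quadratic surface and
#' the GA-ACO-BP network. All stages are driven by seeds derived from the
#' config's global seed, so repeated runs are identical. When `out_dir` is
#' set, each report is also written as JSON.
#'
#' @param design A [design_table()]; defaults to the shipped 29-run table.
#' @param config A [pipeline_config()].
#' @return A list bundle: `anova`, `rsm` (the fit), `bp`, `gaaco_bp`,
#'   `comparison`, `optimum_rsm`, `optimum_gaaco_bp`, `timings` (seconds per
#'   stage) and `seed`.
#' @export
run_pipeline <- function(design = thd_runs(), config) {
  if (!inherits(config, "pipeline_config")) {
    stop_invalid("config must be a pipeline_config()")
  }
  log_msg <- function(...) if (config$verbose) message(sprintf(...))
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop_invalid("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    dt <- proc.time()[["elapsed"]] - t0
    timings[[name]] <<- dt
    log_msg("[%s] done in %.2fs (seed %d)", name, dt, config$seed)
    out
  }

  fit <- stage("rsm", fit_quadratic(design, coding = "coded"))
  anova_rep <- stage("anova", rsm_anova(fit))

  tcfg <- config$tcfg
  sp_seed <- derive_seed(config$seed, 10L)
  bp <- stage("bp", {
    sp <- stratified_split(design, config$n_train, config$n_valid, seed = sp_seed)
    net <- mlp_surrogate(config$n_hidden, seed = derive_seed(config$seed, 11L))
    net <- train_bp(net, sp$train, tcfg)
    fm <- as.data.frame(design)[names(design_domains(design))]
    list(net = net, metrics = fit_metrics(design$yield_pct, predict(net, fm)),
         split = sp)
  })
  gb <- stage("gaaco_bp", {
    gcfg <- config$gcfg
    gcfg$seed <- derive_seed(config$seed, 12L)
    train_gaaco_bp(design, config$n_train, config$n_valid, config$n_hidden,
                   gcfg = gcfg, tcfg = tcfg, split_seed = sp_seed)
  })
  comparison <- stage("compare", {
    fm <- as.data.frame(design)[names(design_domains(design))]
    compare_models(design, list(
      `Box-Behnken` = as.numeric(predict(fit, fm)),
      BP = as.numeric(predict(bp$net, fm)),
      `GA-ACO-BP` = as.numeric(predict(gb$net, fm))
    ))
  })
  opt_rsm <- stage("optimize_rsm",
    maximize_surrogate(fit, box = config$box,
                       domains = design_domains(design),
                       resolution = config$resolution))
  opt_gb <- stage("optimize_gaaco_bp",
    maximize_surrogate(gb$net, box = config$box,
                       domains = design_domains(design),
                       resolution = config$resolution))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(obj, name) write_report(obj, file.path(config$out_dir, name))
    wr(anova_rep, "anova.json")
    wr(bp$metrics, "bp_metrics.json")
    wr(gb$metrics, "gaaco_bp_metrics.json")
    wr(comparison, "comparison.json")
    wr(opt_rsm, "optimum_rsm.json")
    wr(opt_gb, "optimum_gaaco_bp.json")
    jsonlite::write_json(as_mlp_list(bp$net),
                         file.path(config$out_dir, "bp_net.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(as_mlp_list(gb$net),
                         file.path(config$out_dir, "gaaco_bp_net.json"),
                         auto_unbox = TRUE, digits = NA)
    log_msg("[artifacts] written to %s", config$out_dir)
  }

  list(anova = anova_rep, rsm = fit, bp = bp, gaaco_bp = gb,
       comparison = comparison, optimum_rsm = opt_rsm,
       optimum_gaaco_bp = opt_gb, timings = timings, seed = config$seed)
}
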