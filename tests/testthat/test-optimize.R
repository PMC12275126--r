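test_that("grid search plus polish recovers an interior analytic maximum", {
  spec <- concave_spec()
  tab <- simulate_table(spec, seed = 1)
  fit <- fit_quadratic(tab)
  # closed-form stationary point of the generating polynomial (coded):
  # gradient zero => 2*A2*a + AB*b + A = 0 etc.; solve the 2x2 block in (A,B)
  b <- spec$coefficients
  M <- matrix(c(2 * b[["A2"]], b[["AB"]], b[["AB"]], 2 * b[["B2"]]), 2, 2)
  ab <- solve(M, -c(b[["A"]], b[["B"]]))
  cc <- -b[["C"]] / (2 * b[["C2"]])
  stationary_coded <- c(ab, cc, 0)
  truth <- spec_value(spec, stationary_coded)
  opt <- maximize_surrogate(fit, resolution = 21)
  expect_equal(opt$predicted, truth, tolerance = 1e-6)
  want <- decode_points(stationary_coded, thd_domains())[1, ]
  # D is flat up to its pure quadratic: optimum at the centre of the range
  expect_equal(opt$settings[c("ratio", "temperature", "time")],
               want[c("ratio", "temperature", "time")], tolerance = 1e-3)
  expect_false(any(opt$boundary))
})

test_that("the experimental-table optimum agrees with an independent optimizer", {
  fit <- fit_quadratic(thd_runs())
  opt <- maximize_surrogate(fit)
  # independent oracle: multi-start constrained quasi-Newton maximization
  f <- function(p) -unname(predict(fit, p))
  best <- -Inf
  for (s in 1:5) {
    set.seed(s)
    p0 <- c(runif(1, 20, 30), runif(1, 80, 100), runif(1, 60, 90),
            runif(1, 250, 350))
    o <- optim(p0, f, method = "L-BFGS-B", lower = c(20, 80, 60, 250),
               upper = c(30, 100, 90, 350))
    best <- max(best, -o$value)
  }
  expect_equal(opt$predicted, best, tolerance = 1e-6)
  # ratio and time pinned at the upper box edges
  expect_equal(unname(opt$settings["ratio"]), 30, tolerance = 1e-6)
  expect_equal(unname(opt$settings["time"]), 90, tolerance = 1e-6)
  expect_true(opt$boundary[["ratio"]])
  expect_true(opt$boundary[["time"]])
  expect_false(opt$boundary[["temperature"]])
})

test_that("a constant surface returns its level with no boundary flags", {
  flat <- simulate_table(surface_spec(c("(Intercept)" = 11)), seed = 2)
  opt <- maximize_surrogate(fit_quadratic(flat), resolution = 11)
  expect_equal(opt$predicted, 11, tolerance = 1e-8)
  expect_false(any(opt$boundary))
})

test_that("the optimum dominates every design point and finer grids", {
  fit <- fit_quadratic(thd_runs())
  opt <- maximize_surrogate(fit, resolution = 51)
  d <- thd_runs()
  at_design <- predict(fit, as.data.frame(d)[names(thd_domains())])
  expect_true(all(opt$predicted >= at_design - 1e-9))
  finer <- maximize_surrogate(fit, resolution = 101)
  expect_gte(finer$predicted, opt$predicted - 1e-6)
})

test_that("surface grids restrict the surrogate correctly", {
  # additive truth: rows of any pair grid differ by constant offsets
  add <- simulate_table(surface_spec(
    c("(Intercept)" = 12, A = 1, B = 2, C = 0.5, D = 0.25)), seed = 3)
  fit <- fit_quadratic(add)
  g <- surface_grid(fit, c("ratio", "temperature"),
                    others_at = c(time = 75, power = 300), resolution = 9)
  offsets <- sweep(g, 1, g[, 1])
  expect_equal(offsets, matrix(rep(offsets[1, ], each = 9), 9, 9),
               tolerance = 1e-10, ignore_attr = TRUE)

  # grid maximum never exceeds the global maximum
  ffull <- fit_quadratic(thd_runs())
  g2 <- surface_grid(ffull, c("temperature", "power"),
                     others_at = c(ratio = 25, time = 75), resolution = 21)
  opt <- maximize_surrogate(ffull, resolution = 21)
  expect_lte(max(g2), opt$predicted + 1e-9)

  # 1x1 grid is a single prediction
  g3 <- surface_grid(ffull, c("ratio", "time"),
                     others_at = c(temperature = 90, power = 300),
                     resolution = 1)
  expect_equal(dim(g3), c(1L, 1L))
  expect_equal(g3[1, 1], as.numeric(predict(ffull, c(25, 90, 75, 300))),
               tolerance = 1e-10)
  expect_error(surface_grid(ffull, c("ratio", "banana"),
                            others_at = c(temperature = 90, power = 300)),
               "pair must name")
})

test_that("network surrogates are maximized with multi-start polish", {
  d <- thd_runs()
  sp <- stratified_split(d, 21, 8, seed = 1)
  net <- train_bp(mlp_surrogate(4, seed = 1), sp$train,
                  train_config(max_epochs = 150))
  opt <- maximize_surrogate(net, resolution = 21)
  expect_true(all(opt$settings >= c(20, 80, 60, 250) - 1e-9))
  expect_true(all(opt$settings <= c(30, 100, 90, 350) + 1e-9))
  # the reported value is the surrogate evaluated at the settings
  expect_equal(opt$predicted, unname(predict(net, opt$settings)),
               tolerance = 1e-9)
  # and dominates the design points
  expect_true(all(opt$predicted >=
                    predict(net, as.data.frame(d)[names(thd_domains())]) - 1e-9))
})
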