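test_that("OLS recovers the generating coefficients exactly without noise", {
  spec <- concave_spec()
  tab <- simulate_table(spec, seed = 1)
  fit <- fit_quadratic(tab, coding = "coded")
  expect_equal(fit$coefficients, spec$coefficients, tolerance = 1e-8)
})

test_that("the quadratic fit reproduces the published fit statistics", {
  fit <- fit_quadratic(thd_runs(), coding = "actual")
  s <- summary(fit)
  expect_rel_equal(s$r2, 0.896, 0.02)
  expect_rel_equal(s$rmse, 0.8852, 0.02)
})

test_that("coded and actual codings give identical fitted values", {
  d <- thd_runs()
  fc <- fit_quadratic(d, "coded")
  fa <- fit_quadratic(d, "actual")
  expect_lt(max(abs(fc$fitted - fa$fitted)), 1e-8)
  pts <- as.data.frame(d)[names(thd_domains())][c(1, 7, 20), ]
  expect_equal(predict(fc, pts), predict(fa, pts), tolerance = 1e-10)
})

test_that("prediction evaluates the polynomial at arbitrary points", {
  # intercept-only truth predicts its intercept everywhere
  flat <- simulate_table(surface_spec(c("(Intercept)" = 12)), seed = 2)
  ffit <- fit_quadratic(flat)
  expect_equal(as.numeric(predict(ffit, c(22, 83, 61, 320))), 12,
               tolerance = 1e-8)

  # pure interaction y = A*B (coded): value 6 at coded A=2, B=3
  ab <- simulate_table(surface_spec(c(AB = 1)), seed = 3)
  abfit <- fit_quadratic(ab)
  pt <- decode_points(c(2, 3, 0, 0), thd_domains())
  expect_equal(as.numeric(predict(abfit, pt)), 6, tolerance = 1e-8)
  expect_true(attr(predict(abfit, pt), "extrapolated"))

  # identical inputs give identical outputs: the 5 centre replicates share
  # one fitted value, the mean of the fitted centre responses
  d <- thd_runs()
  fit <- fit_quadratic(d)
  ctr <- d$ratio == 25 & d$temperature == 90 & d$time == 75 & d$power == 300
  expect_equal(diff(range(fit$fitted[ctr])), 0, tolerance = 1e-10)
  expect_equal(unname(fit$fitted[ctr][1]), mean(fit$fitted[ctr]))
})

test_that("a rank-deficient design is rejected", {
  d <- thd_runs()
  # rows 1..16 span only 13 distinct design points: too few for 15 terms
  few <- design_table(as.data.frame(d)[1:16, ], thd_domains(), bbd = TRUE)
  expect_error(fit_quadratic(few), "singular")
})

test_that("the ANOVA partition conserves sums of squares", {
  spec <- paperlike_spec()
  for (s in 1:5) {
    tab <- simulate_table(spec, seed = s)
    fit <- fit_quadratic(tab)
    a <- rsm_anova(fit)
    g <- function(src) a$table$ss[a$table$source == src]
    expect_rel_equal(g("Model") + g("Residual"), g("Cor Total"), 1e-8)
    expect_rel_equal(g("Lack of Fit") + g("Pure Error"), g("Residual"), 1e-8)
    # df bookkeeping: 14 model + 14 residual = 28 total
    expect_equal(a$table$df[a$table$source == "Model"], 14)
    expect_equal(a$table$df[a$table$source == "Cor Total"], 28)
    expect_lte(a$pred_r2, a$r2)
  }
})

test_that("type I and type III term partitions agree on orthogonal terms", {
  fit <- fit_quadratic(thd_runs())
  a3 <- rsm_anova(fit, type = "III")$table
  a1 <- rsm_anova(fit, type = "I")$table
  lin_int <- c("A", "B", "C", "D", "AB", "AC", "AD", "BC", "BD", "CD")
  expect_equal(a3$ss[a3$source %in% lin_int], a1$ss[a1$source %in% lin_int],
               tolerance = 1e-8)
  # both partitions account for the same model SS overall
  terms <- setdiff(a1$source, c("Model", "Residual", "Lack of Fit",
                                "Pure Error", "Cor Total"))
  expect_rel_equal(sum(a1$ss[a1$source %in% terms]),
                   a1$ss[a1$source == "Model"], 1e-8)
})

test_that("hat-matrix PRESS equals the explicit leave-one-out computation", {
  for (s in c(11, 12)) {
    tab <- simulate_table(paperlike_spec(), seed = s)
    fit <- fit_quadratic(tab)
    press <- press_stat(fit)
    # independent oracle: n refits, each predicting the held-out run
    doms <- design_domains(tab)
    X <- extractopt:::quad_model_matrix(encode_points(
      as.data.frame(tab)[names(doms)], doms))
    y <- tab$yield_pct
    loo <- sum(vapply(seq_len(nrow(X)), function(i) {
      b <- qr.coef(qr(X[-i, , drop = FALSE]), y[-i])
      (y[i] - drop(X[i, ] %*% b))^2
    }, numeric(1)))
    expect_equal(press, loo, tolerance = 1e-10)
    expect_gte(press, sum(fit$residuals^2))
  }
  # duplicate-rich design with constant response: PRESS collapses to zero
  const <- simulate_table(surface_spec(c("(Intercept)" = 10)), seed = 1)
  expect_equal(press_stat(fit_quadratic(const)), 0, tolerance = 1e-16)
})

test_that("95 % t-intervals for the coefficients attain nominal coverage", {
  spec <- paperlike_spec()
  n_rep <- 500L
  hits <- 0L; total <- 0L
  for (s in seq_len(n_rep)) {
    tab <- simulate_table(spec, seed = 20000 + s)
    fit <- fit_quadratic(tab)
    X <- extractopt:::quad_model_matrix(fit$coded)
    sigma2 <- sum(fit$residuals^2) / (nrow(X) - ncol(X))
    se <- sqrt(diag(chol2inv(chol(crossprod(X)))) * sigma2)
    tq <- qt(0.975, nrow(X) - ncol(X))
    covered <- abs(fit$coefficients - spec$coefficients) <= tq * se
    hits <- hits + sum(covered); total <- total + length(covered)
  }
  expect_lt(abs(hits / total - 0.95), 0.03)
})
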