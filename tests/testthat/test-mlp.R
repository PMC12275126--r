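test_that("weight initialization is seeded and dimension-checked", {
  expect_identical(init_weights(4, seed = 7), init_weights(4, seed = 7))
  expect_length(init_weights(4, seed = 1), 25L)
  expect_equal(n_weights(6), 37L)
  ext <- seq_len(25) / 25
  expect_equal(init_weights(4, weights = ext), ext)
  expect_error(init_weights(4, weights = numeric(24)), "length 24")
  expect_error(init_weights(0, seed = 1), "n_hidden")
})

test_that("the forward pass matches a hand-computed two-neuron example", {
  # 4-2-1 net: W1 rows (0.5,-0.25,0.1,0), (1,0,0,-0.5); b1 (0.1,-0.2);
  # w2 (2,-1); b2 0.3, evaluated at normalized input (1, -1, 0.5, 0.25)
  w <- c(0.5, 1, -0.25, 0, 0.1, 0, 0, -0.5,  # W1 column-major (2x4)
         0.1, -0.2,                          # b1
         2, -1,                              # w2
         0.3)                                # b2
  x <- c(1, -1, 0.5, 0.25)
  z1 <- 0.5 * 1 + (-0.25) * (-1) + 0.1 * 0.5 + 0 * 0.25 + 0.1
  z2 <- 1 * 1 + 0 * (-1) + 0 * 0.5 + (-0.5) * 0.25 - 0.2
  by_hand <- 2 / (1 + exp(-z1)) - 1 / (1 + exp(-z2)) + 0.3
  got <- extractopt:::mlp_forward(w, 2L, matrix(x, 1))
  expect_equal(got, by_hand, tolerance = 1e-12)
})

test_that("a zero-weight network predicts the denormalized output bias", {
  net <- mlp_surrogate(4, weights = rep(0, 25))
  net$norm <- list(x_lo = c(20, 80, 60, 250), x_hi = c(30, 100, 90, 350),
                   y_lo = 8, y_hi = 18,
                   factors = c("ratio", "temperature", "time", "power"))
  # normalized output is b2 + sum(w2 * 0.5) = 0 -> midpoint of the y range
  p <- predict(net, rbind(c(20, 80, 60, 250), c(30, 100, 90, 350)))
  expect_equal(unname(p), c(13, 13))
})

test_that("training fits a single point and is bit-reproducible", {
  d <- thd_runs()
  one <- design_table(as.data.frame(d)[13, , drop = FALSE], thd_domains(),
                      bbd = FALSE)
  cfg <- train_config(max_epochs = 1000, learning_rate = 0.5, momentum = 0.9)
  net <- train_bp(mlp_surrogate(4, seed = 3), one, cfg)
  expect_lt(net$best_mse, 1e-4)
  expect_equal(unname(predict(net, c(25, 90, 75, 300))), one$yield_pct,
               tolerance = 0.05)
  # identical seed, identical result
  net2 <- train_bp(mlp_surrogate(4, seed = 3), one, cfg)
  expect_identical(net$weights, net2$weights)
  expect_identical(net$trace, net2$trace)
  # best-so-far error is the minimum of the trace
  expect_equal(net$best_mse, min(net$trace))
  expect_true(all(diff(cummin(net$trace)) <= 0))
})

test_that("training errors out on empty data and diverging losses", {
  d <- thd_runs()
  empty <- as.data.frame(d)[0, ]
  expect_error(train_bp(mlp_surrogate(4, seed = 1),
                        design_table(empty, thd_domains())), "empty")
  sp <- stratified_split(d, 21, 8, seed = 1)
  expect_error(
    train_bp(mlp_surrogate(4, seed = 1), sp$train,
             train_config(learning_rate = 1e6)),
    "diverged.*epoch")
})

test_that("the network approximates a linear response well", {
  spec <- surface_spec(c("(Intercept)" = 13, A = 2, B = 1.5, C = 1, D = 0.5))
  tab <- simulate_table(spec, seed = 5)
  sp <- stratified_split(tab, 21, 8, seed = 5)
  net <- train_bp(mlp_surrogate(4, seed = 2), sp$train,
                  train_config(learning_rate = 0.2, momentum = 0.9))
  r2 <- fit_metrics(sp$validation$yield_pct, predict(net, sp$validation))$r2
  expect_gt(r2, 0.95)
})

test_that("predictions survive a serialization round trip", {
  d <- thd_runs()
  sp <- stratified_split(d, 21, 8, seed = 2)
  net <- train_bp(mlp_surrogate(4, seed = 4), sp$train,
                  train_config(max_epochs = 50))
  json <- jsonlite::toJSON(as_mlp_list(net), auto_unbox = TRUE, digits = NA)
  back <- mlp_from_list(jsonlite::fromJSON(json))
  pts <- as.data.frame(d)[names(thd_domains())]
  expect_equal(predict(back, pts), predict(net, pts), tolerance = 1e-12)
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(99)
  for (h in c(2L, 4L)) {
    nw <- n_weights(h)
    w <- runif(nw, -0.5, 0.5)
    X <- matrix(runif(20, -1, 1), 5, 4)
    y <- runif(5, -1, 1)
    g <- extractopt:::mlp_grad(w, h, X, y)$gradient
    eps <- 1e-6
    fd <- vapply(seq_len(nw), function(j) {
      wp <- w; wm <- w
      wp[j] <- wp[j] + eps; wm[j] <- wm[j] - eps
      (mean((extractopt:::mlp_forward(wp, h, X) - y)^2) -
       mean((extractopt:::mlp_forward(wm, h, X) - y)^2)) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-6)
  }
})

test_that("golden-section bracketing finds the argmin of unimodal profiles", {
  profiles <- list(
    function(h) (h - 8)^2,        # interior minimum
    function(h) h,                # minimum at the lower end
    function(h) -h,               # minimum at the upper end
    function(h) abs(h - 6.4)      # non-integer valley
  )
  for (f in profiles) {
    res <- extractopt:::golden_section_int(f, 4, 15)
    exhaustive <- which.min(vapply(4:15, f, numeric(1))) + 3L
    expect_equal(res$best, exhaustive)
  }
  # degenerate single-point range: one evaluation
  res1 <- extractopt:::golden_section_int(function(h) h^2, 5, 5)
  expect_equal(res1$best, 5L)
  expect_equal(nrow(res1$evaluations), 1L)
  expect_error(extractopt:::golden_section_int(identity, 6, 5), "empty")
})

test_that("hidden-size search returns a size in range with its probe table", {
  tab <- simulate_table(paperlike_spec(), seed = 9)
  res <- golden_section_hidden_search(
    tab, h_range = c(2, 5), config = train_config(max_epochs = 100),
    n_seeds = 2, seed = 11)
  expect_true(res$best_h >= 2 && res$best_h <= 5)
  expect_true(all(res$evaluations$value > 0))
  expect_true(res$best_h %in% res$evaluations$n_hidden)
})
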