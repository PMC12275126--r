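#' GA-ACO hybrid configuration
#'
#' Tuning knobs of the hybrid genetic-algorithm / ant-colony search over
#' candidate network weight vectors. The pheromone dynamics follow the
#' published setting (volatilization rho = 0.9, transition constant
#' alpha = 0.2, unit initial concentration); the remaining values are
#' package defaults, all exposed here.
#'
#' @param n_ants Ants constructed per generation.
#' @param n_generations Generation cap.
#' @param m Candidate values per weight slot.
#' @param candidate_range Range spanned uniformly by the candidate grid.
#' @param crossover_rate,mutation_rate GA operator probabilities.
#' @param mutation_sd Standard deviation of the per-gene Gaussian mutation.
#' @param n_ga_steps Genetic-refinement steps applied per generation.
#' @param n_elite Ants depositing pheromone each generation.
#' @param Q Deposit constant; each elite ant deposits `Q / fitness`.
#' @param rho Pheromone volatilization coefficient.
#' @param alpha Transition probability constant. Under the default
#'   `alpha_mode = "greedy"` it is the probability of greedily selecting the
#'   max-pheromone candidate; under `"exponent"` it is the pheromone
#'   exponent of the roulette probabilities.
#' @param alpha_mode Interpretation of `alpha` (see above).
#' @param fitness `"rmse"` (default) or `"mse"` of the candidate network's
#'   forward-pass predictions on the validation subset.
#' @param plateau_tol,plateau_window Stop early once the relative
#'   improvement of the best fitness over `plateau_window` generations falls
#'   below `plateau_tol`.
#' @param seed RNG seed for the whole search.
#' @return A `gaaco_config` list.
#' @export
gaaco_config <- function(n_ants = 30L, n_generations = 100L, m = 10L,
                         candidate_range = c(-1, 1),
                         crossover_rate = 0.8, mutation_rate = 0.05,
                         mutation_sd = 0.2, n_ga_steps = 20L, n_elite = 5L,
                         Q = 1, rho = 0.9, alpha = 0.2,
                         alpha_mode = c("greedy", "exponent"),
                         fitness = c("rmse", "mse"),
                         plateau_tol = 1e-4, plateau_window = 10L,
                         seed = NULL) {
  for (nm in c("n_ants", "n_generations", "m", "n_ga_steps", "n_elite")) {
    if (!is_count(get(nm)) || get(nm) < 1) stop_invalid("%s must be a positive integer", nm)
  }
  for (nm in c("crossover_rate", "mutation_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1) stop_invalid("%s must lie in [0, 1]", nm)
  }
  if (rho <= 0 || rho > 1) stop_invalid("rho must lie in (0, 1]")
  structure(list(n_ants = as.integer(n_ants), n_generations = as.integer(n_generations),
                 m = as.integer(m), candidate_range = candidate_range,
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 mutation_sd = mutation_sd, n_ga_steps = as.integer(n_ga_steps),
                 n_elite = as.integer(n_elite), Q = Q, rho = rho, alpha = alpha,
                 alpha_mode = match.arg(alpha_mode), fitness = match.arg(fitness),
                 plateau_tol = plateau_tol, plateau_window = as.integer(plateau_window),
                 seed = seed),
            class = "gaaco_config")
}

#' Pheromone field over discrete weight candidates
#'
#' One list of `m` discrete candidate values per weight slot, spanning
#' `range` uniformly, each carrying a pheromone concentration initialized
#' at unity.
#'
#' @param n_slots Number of weight slots (use [n_weights()]).
#' @param m Candidates per slot.
#' @param range Numeric `c(lo, hi)` spanned by the candidates.
#' @param rho Volatilization coefficient.
#' @param alpha Transition probability constant.
#' @return An object of class `pheromone_field` with matrices `candidates`
#'   and `tau` (both `n_slots x m`).
#' @export
pheromone_field <- function(n_slots, m = 10L, range = c(-1, 1),
                            rho = 0.9, alpha = 0.2) {
  if (!is_count(n_slots) || n_slots < 1) stop_invalid("n_slots must be >= 1")
  if (!is_count(m) || m < 1) stop_invalid("m must be >= 1")
  vals <- if (m == 1L) mean(range) else seq(range[1], range[2], length.out = m)
  structure(
    list(candidates = matrix(rep(vals, each = n_slots), n_slots, m),
         tau = matrix(1, n_slots, m), rho = rho, alpha = alpha),
    class = "pheromone_field"
  )
}

#' @export
print.pheromone_field <- function(x, ...) {
  cat(sprintf("<pheromone_field> %d slots x %d candidates, rho %.3g, alpha %.3g\n",
              nrow(x$tau), ncol(x$tau), x$rho, x$alpha))
  invisible(x)
}

#' Construct candidate weight vectors from the pheromone field
#'
#' For each weight slot, a candidate is chosen by pheromone-proportional
#' roulette; with probability `alpha` the max-pheromone candidate is taken
#' greedily instead (the transition-constant rule). With
#' `alpha_mode = "exponent"` all selections are roulette draws with
#' probabilities proportional to `tau^alpha`.
#'
#' @param field A [pheromone_field()].
#' @param n Number of ants (rows of the result).
#' @param seed Optional RNG seed.
#' @param alpha_mode `"greedy"` (default) or `"exponent"`.
#' @return Numeric matrix `n x n_slots` of assembled weight vectors.
#' @export
ant_construct <- function(field, n = 1L, seed = NULL,
                          alpha_mode = c("greedy", "exponent")) {
  alpha_mode <- match.arg(alpha_mode)
  stopifnot(inherits(field, "pheromone_field"))
  m <- ncol(field$tau)
  with_seed(seed, {
    out <- matrix(0, n, nrow(field$tau))
    for (s in seq_len(nrow(field$tau))) {
      tau_s <- field$tau[s, ]
      j <- if (alpha_mode == "exponent") {
        sample.int(m, n, replace = TRUE, prob = tau_s^field$alpha)
      } else if (m == 1L) {
        rep(1L, n)
      } else {
        greedy <- stats::runif(n) < field$alpha
        idx <- sample.int(m, n, replace = TRUE, prob = tau_s)
        idx[greedy] <- which.max(tau_s)
        idx
      }
      out[, s] <- field$candidates[s, j]
    }
    out
  })
}

#' Volatilize and reinforce the pheromone field
#'
#' Every pheromone concentration decays by the factor `rho`; then the
#' candidates used by the best (`n_elite`) evaluated ants are reinforced by
#' a deposit `Q / fitness`, so lower-error ants deposit more. Ant weight
#' values that do not coincide with a grid candidate (e.g. after Gaussian
#' mutation) reinforce the nearest candidate. Ants with non-finite fitness
#' are skipped with a warning.
#'
#' @param field A [pheromone_field()].
#' @param ants Matrix of evaluated weight vectors (one row per ant).
#' @param fitness Error value per ant (lower is better).
#' @param n_elite Number of depositing ants.
#' @param Q Deposit constant.
#' @return The updated `pheromone_field`.
#' @export
update_pheromone <- function(field, ants, fitness, n_elite = 5L, Q = 1) {
  stopifnot(inherits(field, "pheromone_field"))
  if (is.null(dim(ants))) ants <- matrix(ants, nrow = 1L)
  if (nrow(ants) < 1L) stop_invalid("need at least one evaluated ant")
  if (nrow(ants) != length(fitness)) stop_invalid("one fitness value per ant required")
  bad <- !is.finite(fitness)
  if (any(bad)) {
    warning(sprintf("skipping %d ant(s) with non-finite fitness", sum(bad)))
    ants <- ants[!bad, , drop = FALSE]
    fitness <- fitness[!bad]
  }
  field$tau <- field$tau * field$rho
  if (length(fitness)) {
    elite <- order(fitness)[seq_len(min(n_elite, length(fitness)))]
    for (a in elite) {
      for (s in seq_len(nrow(field$tau))) {
        j <- which.min(abs(field$candidates[s, ] - ants[a, s]))
        field$tau[s, j] <- field$tau[s, j] + Q / fitness[a]
      }
    }
  }
  field
}

#' One genetic-refinement step
#'
#' Fitness-proportional selection (selection weight `max(f) - f`, so lower
#' error means higher weight), single-point crossover and per-gene Gaussian
#' mutation over a population of weight vectors; elitism copies the best
#' individual into the next population unchanged. With both operator rates
#' at zero the step is the identity.
#'
#' @param pop Population matrix (>= 2 rows).
#' @param fitness Error per individual (lower is better).
#' @param crossover_rate,mutation_rate,mutation_sd GA operator parameters.
#' @param seed Optional RNG seed.
#' @return The next population matrix (same shape).
#' @export
ga_step <- function(pop, fitness, crossover_rate = 0.8, mutation_rate = 0.05,
                    mutation_sd = 0.2, seed = NULL) {
  if (is.null(dim(pop)) || nrow(pop) < 2L) {
    stop_invalid("population must contain at least 2 individuals")
  }
  if (nrow(pop) != length(fitness)) stop_invalid("one fitness value per individual required")
  if (crossover_rate == 0 && mutation_rate == 0) return(pop)
  nw <- ncol(pop)
  with_seed(seed, {
    wts <- (max(fitness) - fitness) + 1e-12
    wts <- wts / sum(wts)
    new_pop <- pop
    new_pop[1L, ] <- pop[which.min(fitness), ]   # elitism
    for (i in 2:nrow(pop)) {
      pa <- pop[sample.int(nrow(pop), 1L, prob = wts), ]
      child <- pa
      if (stats::runif(1) < crossover_rate) {
        pb <- pop[sample.int(nrow(pop), 1L, prob = wts), ]
        cp <- sample.int(nw - 1L, 1L)
        child <- c(pa[seq_len(cp)], pb[(cp + 1L):nw])
      }
      mut <- stats::runif(nw) < mutation_rate
      if (any(mut)) child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, mutation_sd)
      new_pop[i, ] <- child
    }
    new_pop
  })
}

# fitness closure: forward-pass error of a candidate weight vector on the
# validation subset, in yield percent (no backpropagation involved)
gaaco_fitness_fn <- function(train, validation, n_hidden, type = "rmse") {
  txy <- design_xy(train)
  norm <- make_norm(txy$fm, txy$y, txy$factors)
  vxy <- design_xy(validation)
  Xv <- norm_x(norm, vxy$fm)
  yv <- vxy$y
  function(w) {
    pred <- denorm_y(norm, mlp_forward(w, n_hidden, Xv))
    if (type == "mse") mean((pred - yv)^2) else sqrt(mean((pred - yv)^2))
  }
}

#' Run the GA-ACO hybrid weight search
#'
#' Iterates ant construction from the pheromone field, fitness evaluation of
#' every candidate (forward-pass error on the validation subset; no
#' backpropagation), genetic refinement of the candidate population, and
#' pheromone volatilization plus elite reinforcement. The genetic population
#' persists across generations, with each generation's ants injected into
#' it before refinement. Stops at the generation cap or once the best
#' fitness plateaus.
#'
#' @param train,validation [design_table()] subsets from
#'   [stratified_split()]. Normalization is frozen from `train`.
#' @param n_hidden Hidden-layer size of the 4-h-1 candidate networks.
#' @param config A [gaaco_config()] (its `seed` drives all randomness).
#' @return An object of class `gaaco_result`: `best_weights`,
#'   `best_fitness`, `trace` (data frame iteration/best/mean),
#'   `n_iterations`, and the final `field`.
#' @export
run_gaaco <- function(train, validation, n_hidden = 4L,
                      config = gaaco_config()) {
  fit_of <- gaaco_fitness_fn(train, validation, n_hidden, config$fitness)
  nw <- n_weights(n_hidden)
  with_seed(config$seed, {
    field <- pheromone_field(nw, m = config$m, range = config$candidate_range,
                             rho = config$rho, alpha = config$alpha)
    pop <- NULL; pop_fit <- NULL
    best_w <- NULL; best_f <- Inf
    trace <- data.frame(iteration = integer(), best = numeric(), mean = numeric())
    for (g in seq_len(config$n_generations)) {
      ants <- ant_construct(field, n = config$n_ants, alpha_mode = config$alpha_mode)
      ant_fit <- apply(ants, 1L, fit_of)
      pool <- rbind(pop, ants)
      pool_fit <- c(pop_fit, ant_fit)
      if (nrow(pool) >= 2L) {
        for (k in seq_len(config$n_ga_steps)) {
          pool <- ga_step(pool, pool_fit, config$crossover_rate,
                          config$mutation_rate, config$mutation_sd)
          # elitism guarantees row 1 keeps the previous best
          pool_fit <- apply(pool, 1L, fit_of)
        }
        keep <- order(pool_fit)[seq_len(min(config$n_ants, nrow(pool)))]
        pop <- pool[keep, , drop = FALSE]
        pop_fit <- pool_fit[keep]
      } else {
        pop <- pool; pop_fit <- pool_fit
      }
      if (min(pop_fit) < best_f) {
        best_f <- min(pop_fit)
        best_w <- pop[which.min(pop_fit), ]
      }
      trace <- rbind(trace, data.frame(iteration = g, best = best_f,
                                       mean = mean(pop_fit)))
      field <- update_pheromone(field, pop, pop_fit,
                                n_elite = config$n_elite, Q = config$Q)
      if (g > config$plateau_window) {
        prev <- trace$best[g - config$plateau_window]
        if (prev > 0 && (prev - best_f) / prev < config$plateau_tol) break
      }
    }
    structure(list(best_weights = best_w, best_fitness = best_f, trace = trace,
                   n_iterations = nrow(trace), field = field),
              class = "gaaco_result")
  })
}

#' @export
print.gaaco_result <- function(x, ...) {
  cat(sprintf("<gaaco_result> %d iterations, best fitness %.4g\n",
              x$n_iterations, x$best_fitness))
  invisible(x)
}

#' Train the GA-ACO-initialized surrogate
#'
#' Runs the GA-ACO hybrid on a stratified split and hands its best weight
#' vector to the backpropagation trainer (epochs and error threshold
#' mirrored from the standard network), then scores the trained network on
#' the full table.
#'
#' @param design A [design_table()] with observed yields.
#' @param n_train,n_valid Split sizes.
#' @param n_hidden Hidden-layer size.
#' @param gcfg A [gaaco_config()]; its seed also seeds the split when
#'   `split_seed` is missing.
#' @param tcfg A [train_config()] for the refinement.
#' @param split_seed Seed of the stratified split.
#' @return List with `net` (trained surrogate), `metrics` (full-table
#'   [fit_metrics()]), `gaaco` (the search result) and `split`.
#' @export
train_gaaco_bp <- function(design, n_train = 21L, n_valid = 8L, n_hidden = 4L,
                           gcfg = gaaco_config(), tcfg = train_config(),
                           split_seed = gcfg$seed) {
  sp <- stratified_split(design, n_train, n_valid, seed = split_seed)
  ga <- run_gaaco(sp$train, sp$validation, n_hidden = n_hidden, config = gcfg)
  net <- mlp_surrogate(n_hidden, weights = ga$best_weights)
  net <- train_bp(net, sp$train, tcfg)
  fm <- as.data.frame(design)[names(design_domains(design))]
  list(net = net,
       metrics = fit_metrics(design$yield_pct, predict(net, fm)),
       gaaco = ga, split = sp)
}

#' Paired comparison of random vs GA-ACO initialization
#'
#' For each seed: draw the stratified split, train one network from random
#' uniform weights and one from the GA-ACO hand-off under the identical
#' training configuration, and record full-table R-squared/MAE/RMSE and
#' validation RMSE for both.
#'
#' @param design A [design_table()] with observed yields.
#' @param seeds Integer vector of seeds (one paired run each).
#' @param n_train,n_valid Split sizes.
#' @param n_hidden Hidden-layer size.
#' @param gcfg,tcfg Search and training configurations (seeds inside are
#'   overridden per run).
#' @return Data frame with one row per seed: `bp_r2`, `gaaco_r2`, `bp_mae`,
#'   `gaaco_mae`, `bp_val_rmse`, `gaaco_val_rmse`, plus a `"summary"`
#'   attribute (wins, best R-squared and its seed).
#' @export
compare_bp_inits <- function(design, seeds = 1:10, n_train = 21L, n_valid = 8L,
                             n_hidden = 4L, gcfg = gaaco_config(),
                             tcfg = train_config()) {
  fm <- as.data.frame(design)[names(design_domains(design))]
  rows <- lapply(seeds, function(s) {
    sp <- stratified_split(design, n_train, n_valid, seed = s)
    bp <- mlp_surrogate(n_hidden, seed = derive_seed(s, 1L))
    bp <- train_bp(bp, sp$train, tcfg)
    gcfg$seed <- derive_seed(s, 2L)
    ga <- run_gaaco(sp$train, sp$validation, n_hidden = n_hidden, config = gcfg)
    gb <- mlp_surrogate(n_hidden, weights = ga$best_weights)
    gb <- train_bp(gb, sp$train, tcfg)
    met <- function(net) fit_metrics(design$yield_pct, predict(net, fm))
    vrmse <- function(net) {
      sqrt(mean((predict(net, sp$validation) - sp$validation$yield_pct)^2))
    }
    mb <- met(bp); mg <- met(gb)
    data.frame(seed = s, bp_r2 = mb$r2, gaaco_r2 = mg$r2,
               bp_mae = mb$mae, gaaco_mae = mg$mae,
               bp_rmse = mb$rmse, gaaco_rmse = mg$rmse,
               bp_val_rmse = vrmse(bp), gaaco_val_rmse = vrmse(gb))
  })
  out <- do.call(rbind, rows)
  best <- which.max(out$gaaco_r2)
  attr(out, "summary") <- list(
    wins = sum(out$gaaco_val_rmse < out$bp_val_rmse),
    n = length(seeds),
    best_gaaco_r2 = out$gaaco_r2[best],
    best_gaaco_mae = out$gaaco_mae[best],
    best_seed = out$seed[best]
  )
  out
}
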