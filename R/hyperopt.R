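# Genetic hyperparameter search. Fitness is validation MSE (scaled units)
# of a short training run; the canonical operator set is tournament
# selection, uniform crossover, per-gene resampling mutation and elitism,
# which guarantees a nonincreasing best-so-far fitness curve.

#' Hyperparameter search space
#'
#' Each gene's domain is either a categorical set (an atomic vector) or a
#' numeric range `list(min =, max =, log = FALSE, integer = FALSE)`.
#' A `constraint` predicate over whole candidates (default: `d_model`
#' divisible by `n_heads` whenever both genes are present) is enforced at
#' sampling and after mutation by resampling.
#'
#' @param ... Named gene domains.
#' @param constraint Function `(candidate) -> logical(1)`.
#' @return A `search_space`.
#' @export
search_space <- function(..., constraint = default_constraint) {
  domains <- list(...)
  if (length(domains) == 1 && is.null(names(domains)) && is.list(domains[[1]])) {
    domains <- domains[[1]]
  }
  if (length(domains) == 0 || is.null(names(domains)) || any(names(domains) == "")) {
    stop_cgm("search_space needs named gene domains", class = "cgm_parameter_error")
  }
  for (nm in names(domains)) {
    d <- domains[[nm]]
    ok <- (is.atomic(d) && length(d) >= 1) ||
      (is.list(d) && all(c("min", "max") %in% names(d)) && d$min <= d$max)
    if (!ok) stop_cgm("invalid domain for gene '%s'", nm, class = "cgm_parameter_error")
  }
  structure(list(domains = domains, constraint = constraint), class = "search_space")
}

default_constraint <- function(cand) {
  if (!is.null(cand$d_model) && !is.null(cand$n_heads)) {
    return(cand$d_model %% cand$n_heads == 0)
  }
  TRUE
}

#' Default search space over the hybrid model's hyperparameters
#' @return A [search_space()].
#' @export
default_search_space <- function() {
  search_space(
    d_model = c(8L, 16L, 32L),
    n_heads = c(2L, 4L),
    n_encoder_layers = c(1L, 2L),
    lstm_hidden = c(16L, 32L, 64L),
    dropout = list(min = 0, max = 0.3),
    lr = list(min = 1e-4, max = 1e-2, log = TRUE),
    lookback = c(6L, 12L, 18L)
  )
}

sample_gene <- function(d) {
  if (is.atomic(d)) return(d[[sample.int(length(d), 1)]])
  if (isTRUE(d$log)) {
    v <- exp(stats::runif(1, log(d$min), log(d$max)))
  } else {
    v <- stats::runif(1, d$min, d$max)
  }
  if (isTRUE(d$integer)) v <- as.integer(round(v))
  v
}

sample_candidate <- function(space, max_tries = 200L) {
  for (k in seq_len(max_tries)) {
    cand <- lapply(space$domains, sample_gene)
    if (isTRUE(space$constraint(cand))) return(cand)
  }
  stop_cgm("could not sample a feasible candidate in %d tries", max_tries,
           class = "cgm_sampling_error")
}

repair_candidate <- function(space, cand, max_tries = 200L) {
  if (isTRUE(space$constraint(cand))) return(cand)
  for (k in seq_len(max_tries)) {
    nm <- sample(names(space$domains), 1)
    cand[[nm]] <- sample_gene(space$domains[[nm]])
    if (isTRUE(space$constraint(cand))) return(cand)
  }
  stop_cgm("could not repair candidate in %d tries", max_tries, class = "cgm_sampling_error")
}

#' Genetic algorithm control settings
#'
#' @param pop_size Population size (>= 2).
#' @param n_iter Number of generations (>= 1).
#' @param elite_k Candidates copied unchanged each generation.
#' @param tournament_k Tournament size for parent selection.
#' @param crossover_rate Probability a child undergoes uniform crossover.
#' @param mutation_rate Per-gene probability of resampling from its domain.
#' @return A `ga_control` list.
#' @export
ga_control <- function(pop_size = 8L, n_iter = 10L, elite_k = 2L,
                       tournament_k = 2L, crossover_rate = 0.9,
                       mutation_rate = 0.1) {
  if (!is_count(pop_size, min = 2)) stop_cgm("pop_size must be >= 2", class = "cgm_parameter_error")
  if (!is_count(n_iter)) stop_cgm("n_iter must be >= 1", class = "cgm_parameter_error")
  if (elite_k < 0 || elite_k > pop_size) stop_cgm("elite_k must be in [0, pop_size]", class = "cgm_parameter_error")
  structure(list(pop_size = as.integer(pop_size), n_iter = as.integer(n_iter),
                 elite_k = as.integer(elite_k), tournament_k = as.integer(tournament_k),
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate),
            class = "ga_control")
}

#' Genetic hyperparameter search
#'
#' Minimizes `fitness(candidate)` (lower is better; for the forecasting use
#' case, validation MSE in scaled units, see [cgm_fitness()]). Each
#' generation: tournament selection, uniform crossover per gene, per-gene
#' mutation by domain resampling, then elitism copies the `elite_k` best
#' unchanged, so the best-so-far curve never increases. Fully seeded.
#'
#' @param space A [search_space()].
#' @param fitness Function `(candidate) -> numeric(1)`.
#' @param ga A [ga_control()].
#' @param seed Integer seed.
#' @return `list(best_candidate, best_fitness, history)`; `history` is a
#'   `fitness_history` (one entry per generation with the population's
#'   fitness values, the generation best and its candidate digest).
#' @export
genetic_search <- function(space, fitness, ga = ga_control(), seed = 1L) {
  stopifnot(inherits(space, "search_space"), is.function(fitness),
            inherits(ga, "ga_control"))
  with_seed(seed, {
    pop <- lapply(seq_len(ga$pop_size), function(i) sample_candidate(space))
    fit <- vapply(pop, function(c) as.numeric(fitness(c)), numeric(1))
    history <- list()
    record <- function(pop, fit) {
      b <- which.min(fit)
      history[[length(history) + 1L]] <<- list(
        fitness = fit, best_fitness = fit[b],
        best_candidate = pop[[b]],
        best_digest = config_digest(pop[[b]])
      )
    }
    record(pop, fit)
    if (ga$n_iter > 1) {
      for (iter in 2:ga$n_iter) {
        ord <- order(fit)
        elite <- pop[ord[seq_len(ga$elite_k)]]
        elite_fit <- fit[ord[seq_len(ga$elite_k)]]
        n_child <- ga$pop_size - ga$elite_k
        children <- list()
        if (n_child > 0) {
          tournament <- function() {
            idx <- sample.int(ga$pop_size, min(ga$tournament_k, ga$pop_size))
            pop[[idx[which.min(fit[idx])]]]
          }
          for (c in seq_len(n_child)) {
            p1 <- tournament()
            child <- p1
            if (stats::runif(1) < ga$crossover_rate) {
              p2 <- tournament()
              for (nm in names(child)) {
                if (stats::runif(1) < 0.5) child[[nm]] <- p2[[nm]]
              }
            }
            for (nm in names(child)) {
              if (stats::runif(1) < ga$mutation_rate) {
                child[[nm]] <- sample_gene(space$domains[[nm]])
              }
            }
            children[[c]] <- repair_candidate(space, child)
          }
        }
        child_fit <- vapply(children, function(c) as.numeric(fitness(c)), numeric(1))
        pop <- c(elite, children)
        fit <- c(elite_fit, child_fit)
        record(pop, fit)
      }
    }
    class(history) <- "fitness_history"
    b <- which.min(fit)
    list(best_candidate = pop[[b]], best_fitness = fit[b], history = history)
  })
}

#' Running minimum of the per-generation best fitness
#'
#' The monotone curve of the iteration-fitness plot: element k is the
#' minimum of the first k generation bests.
#'
#' @param history A `fitness_history` from [genetic_search()].
#' @return Numeric vector of running minima.
#' @export
best_so_far <- function(history) {
  stopifnot(inherits(history, "fitness_history"))
  if (length(history) == 0) stop_cgm("empty fitness history", class = "cgm_parameter_error")
  cummin(vapply(history, `[[`, numeric(1), "best_fitness"))
}

#' @export
print.fitness_history <- function(x, ...) {
  b <- best_so_far(x)
  cat(sprintf("<fitness_history> %d generations, best %.6g -> %.6g\n",
              length(x), b[1], b[length(b)]))
  invisible(x)
}

#' Forecast-validation fitness for the genetic search
#'
#' Returns a closure mapping a hyperparameter candidate (genes among
#' `d_model`, `n_heads`, `n_encoder_layers`, `lstm_hidden`, `dropout`,
#' `lr`, `lookback`) to the validation MSE, in scaled units, of a shortened
#' hybrid-model training on the cohort's training split. Final models
#' should be retrained at full budget with the best candidate.
#'
#' @param cohort List of [glucose_series()].
#' @param horizon_min Forecast horizon in minutes.
#' @param base_model_cfg,base_train_cfg Defaults that candidate genes
#'   override; `base_train_cfg$max_epochs` is the shortened search budget.
#' @param train_frac Chronological split fraction.
#' @param seed Seed for the fitness evaluations.
#' @param interval_min Sampling interval in minutes.
#' @return Function `(candidate) -> numeric(1)`.
#' @export
cgm_fitness <- function(cohort, horizon_min = 15,
                        base_model_cfg = hybrid_config(),
                        base_train_cfg = train_config(max_epochs = 30L,
                                                      patience = 5L,
                                                      max_train_windows = 512),
                        train_frac = 0.8, seed = 1L, interval_min = 5L) {
  force(cohort)
  function(cand) {
    mc <- unclass(base_model_cfg)
    for (nm in intersect(names(cand), c("d_model", "n_heads", "n_encoder_layers",
                                        "ffn_width", "lstm_hidden", "lstm_layers",
                                        "dropout", "lookback", "pooling"))) {
      mc[[nm]] <- cand[[nm]]
    }
    mcfg <- do.call(hybrid_config, mc)
    tcfg <- base_train_cfg
    if (!is.null(cand$lr)) tcfg$lr <- cand$lr
    tcfg$seed <- derive_seed(seed, 1L)
    spec <- window_spec(mcfg$lookback, horizon_min %/% interval_min, interval_min)
    sp <- cohort_split_windows(cohort, spec, train_frac, interval_min)
    scaler <- fit_scaler(sp$train)
    tr_s <- apply_scaler(sp$train, scaler)
    m <- build_model("transformer_lstm", mcfg, seed = derive_seed(seed, 2L))
    fit <- train(m, tr_s, tcfg)
    min(fit$log$val_loss)
  }
}
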