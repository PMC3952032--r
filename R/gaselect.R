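# Bit-string genetic algorithm over channel subsets. Individuals are
# boolean channel masks; fitness is the median inner-cross-validation
# decoding correlation using only the masked channels. Configuration
# mirrors a standard bit-string GA: uniform creation, rank fitness
# scaling, stochastic-universal-sampling selection, scattered crossover,
# uniform mutation, elitism, and a stall-based stopping rule on the
# weighted improvement of the best fitness.

#' Genetic algorithm configuration
#'
#' @param population_size individuals per generation (default 20).
#' @param crossover_fraction fraction of non-elite slots filled by
#'   crossover (default 0.5); the remainder are mutated parents.
#' @param elite_count individuals copied unchanged (default 2).
#' @param mutation_rate per-bit flip probability (default 0.01).
#' @param stall_generations window of the stall rule (default 30).
#' @param function_tolerance minimum weighted improvement of the best
#'   fitness over the stall window (default 0.01).
#' @param max_generations hard generation cap (default 100).
#' @return object of class `ga_config`.
#' @export
ga_config <- function(population_size = 20, crossover_fraction = 0.5,
                      elite_count = 2, mutation_rate = 0.01,
                      stall_generations = 30, function_tolerance = 0.01,
                      max_generations = 100) {
  if (elite_count >= population_size)
    stop("elite_count must be smaller than population_size")
  if (crossover_fraction < 0 || crossover_fraction > 1)
    stop("crossover_fraction must be in [0, 1]")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must be in [0, 1]")
  structure(list(population_size = as.integer(population_size),
                 crossover_fraction = crossover_fraction,
                 elite_count = as.integer(elite_count),
                 mutation_rate = mutation_rate,
                 stall_generations = as.integer(stall_generations),
                 function_tolerance = function_tolerance,
                 max_generations = as.integer(max_generations)),
            class = "ga_config")
}

#' Uniform initial population
#'
#' Each bit is set independently with probability 0.5; all-zero
#' individuals (no channels) are resampled.
#'
#' @param n_bits channels per individual.
#' @param cfg a [ga_config()].
#' @return logical matrix, `population_size` x `n_bits`.
#' @export
init_population <- function(n_bits, cfg = ga_config()) {
  pop <- matrix(stats::runif(cfg$population_size * n_bits) < 0.5,
                cfg$population_size, n_bits)
  for (i in seq_len(nrow(pop))) {
    while (!any(pop[i, ])) pop[i, ] <- stats::runif(n_bits) < 0.5
  }
  pop
}

# rank-based scaled expectations: expectation proportional to 1/sqrt(rank)
rank_expectations <- function(fitness, n_parents) {
  r <- rank(-fitness, ties.method = "first")
  e <- 1 / sqrt(r)
  e * n_parents / sum(e)
}

#' Parent selection: rank scaling + stochastic universal sampling
#'
#' Fitness values are converted to rank-based expectations (proportional
#' to `1/sqrt(rank)`), then `n` parents are drawn with a single equally
#' spaced comb of pointers over the cumulative expectations.
#'
#' @param fitness numeric fitness per individual (higher is better).
#' @param n number of parents to draw.
#' @return integer vector of parent indices (in random order).
#' @export
select_parents <- function(fitness, n) {
  e <- rank_expectations(fitness, n)
  cum <- cumsum(e)
  pts <- stats::runif(1, 0, 1) + 0:(n - 1)
  idx <- findInterval(pts, cum) + 1L
  idx[idx > length(fitness)] <- length(fitness)
  sample(idx)          # shuffle so pairing is not rank-ordered
}

#' Scattered crossover
#'
#' Each bit of the child is copied from parent `a` or parent `b` by an
#' independent fair coin.
#'
#' @param a,b equal-length logical masks.
#' @return child mask.
#' @export
crossover_scattered <- function(a, b) {
  if (length(a) != length(b)) stop("parent masks differ in length")
  coin <- stats::runif(length(a)) < 0.5
  ifelse(coin, a, b)
}

#' Uniform mutation
#'
#' Flips each bit independently with probability `rate`.
#'
#' @param mask logical mask.
#' @param rate per-bit flip probability.
#' @return mutated mask.
#' @export
mutate_uniform <- function(mask, rate = 0.01) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  xor(mask, stats::runif(length(mask)) < rate)
}

#' Run the genetic algorithm
#'
#' Generational GA with elitism. Each new generation consists of the
#' `elite_count` best individuals, `round(crossover_fraction * rest)`
#' scattered-crossover children, and mutated selected parents for the
#' remaining slots. The run stops when the weighted average improvement of
#' the best fitness over the previous `stall_generations` generations
#' (weights halving per generation into the past) is strictly below
#' `function_tolerance`, or at `max_generations`. Fitness evaluations are
#' memoized, so re-evaluating a converged population is free.
#'
#' @param fitness_fn function(logical mask) -> scalar fitness; should
#'   return `-1` for degenerate masks.
#' @param n_bits number of channels.
#' @param cfg a [ga_config()].
#' @param seed optional seed for the whole run.
#' @return list with `best_mask`, `best_fitness`, `history` (data.frame
#'   with per-generation best/mean/median fitness), `generations`,
#'   `evaluations` (unique fitness evaluations) and `final_population`.
#' @export
run_ga <- function(fitness_fn, n_bits, cfg = ga_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  eval_mask <- function(mask) {
    key <- paste0(as.integer(mask), collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (!any(mask)) -1 else fitness_fn(mask)
    if (!is.finite(val)) val <- -1
    n_eval <<- n_eval + 1L
    cache[[key]] <- val
    val
  }
  pop <- init_population(n_bits, cfg)
  best_mask <- NULL
  best_fit <- -Inf
  hist_best <- hist_mean <- hist_median <- numeric(0)
  for (gen in seq_len(cfg$max_generations)) {
    fit <- apply(pop, 1, eval_mask)
    g_best <- which.max(fit)
    if (fit[g_best] > best_fit) {
      best_fit <- fit[g_best]
      best_mask <- pop[g_best, ]
    }
    hist_best <- c(hist_best, best_fit)
    hist_mean <- c(hist_mean, mean(fit))
    hist_median <- c(hist_median, stats::median(fit))
    # stall rule: once a full window is available, stop when the weighted
    # average of best-fitness improvements over the last stall_generations
    # generations (weights halving per generation into the past) drops
    # strictly below the function tolerance
    if (gen >= cfg$stall_generations + 1L) {
      imp <- diff(hist_best)[(gen - cfg$stall_generations):(gen - 1L)]
      wts <- 0.5^(rev(seq_along(imp)) - 1L)
      if (sum(wts * imp) / sum(wts) < cfg$function_tolerance) break
    }
    if (gen == cfg$max_generations) break
    # next generation
    ord <- order(fit, decreasing = TRUE)
    elites <- pop[ord[seq_len(cfg$elite_count)], , drop = FALSE]
    n_rest <- cfg$population_size - cfg$elite_count
    n_cross <- round(cfg$crossover_fraction * n_rest)
    n_mut <- n_rest - n_cross
    parents <- select_parents(fit, 2L * n_cross + n_mut)
    children <- matrix(FALSE, n_rest, n_bits)
    p <- 1L
    if (n_cross > 0) for (i in seq_len(n_cross)) {
      children[i, ] <- crossover_scattered(pop[parents[p], ],
                                           pop[parents[p + 1L], ])
      p <- p + 2L
    }
    if (n_mut > 0) for (i in seq_len(n_mut)) {
      children[n_cross + i, ] <- mutate_uniform(pop[parents[p], ],
                                                cfg$mutation_rate)
      p <- p + 1L
    }
    for (i in seq_len(n_rest)) {
      if (!any(children[i, ]))
        children[i, sample.int(n_bits, 1L)] <- TRUE
    }
    pop <- rbind(elites, children)
  }
  list(best_mask = best_mask, best_fitness = best_fit,
       history = data.frame(generation = seq_along(hist_best),
                            best = hist_best, mean = hist_mean,
                            median = hist_median),
       generations = length(hist_best), evaluations = n_eval,
       final_population = pop)
}

#' Exact binomial tail probability of repeated channel selection
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`: the chance that an uninformative
#' selection (each channel included with probability `p`) picks the same
#' channel at least `k` times in `n` runs.
#'
#' @param k selection count.
#' @param n number of runs.
#' @param p per-run inclusion probability (default 0.5).
#' @return tail probability.
#' @export
binom_tail <- function(k, n, p = 0.5) {
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Selection histogram across GA runs with binomial significance flags
#'
#' Counts how often each channel appears in the best masks across runs
#' (e.g. the 10 outer cross-validation folds) and flags channels selected
#' more often than expected by chance at inclusion probability `p`: the
#' flag threshold is the smallest count whose binomial tail probability
#' falls below `alpha`.
#'
#' @param masks logical matrix (runs x channels) or list of masks.
#' @param labels optional channel labels.
#' @param p chance inclusion probability (default 0.5).
#' @param alpha tail-probability bound (default 0.06).
#' @return data.frame with `channel`, `count`, `n_runs`, `tail_p`,
#'   `selected` flag; the threshold count is attached as attribute
#'   `"threshold"`.
#' @export
selection_histogram <- function(masks, labels = NULL, p = 0.5,
                                alpha = 0.06) {
  if (is.list(masks)) masks <- do.call(rbind, masks)
  n_runs <- nrow(masks)
  counts <- colSums(masks)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(masks)))
  thr <- which(binom_tail(0:n_runs, n_runs, p) < alpha)[1] - 1L
  out <- data.frame(channel = labels, count = as.integer(counts),
                    n_runs = n_runs,
                    tail_p = binom_tail(counts, n_runs, p),
                    selected = counts >= thr,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  out
}
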