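#' Control settings for the differential-evolution optimizer
#'
#' @param np Population size.
#' @param max_gen Maximum number of generations.
#' @param f Differential weight (mutation scale).
#' @param cr Crossover probability.
#' @param reseed_every How many generations share one evaluation seed.
#'   1 rotates the common-random-number seed every generation (most robust
#'   to overfitting a noise draw); `Inf` fixes one seed for the whole run,
#'   making the objective surface deterministic so the search can converge
#'   tightly (parent scores are cached while the seed is unchanged).
#' @param trace Record per-generation best/mean objective values.
#' @return A list of class `de_control`.
#' @export
de_control <- function(np = 32L, max_gen = 50L, f = 0.8, cr = 0.9,
                       reseed_every = 1, trace = TRUE) {
  stopifnot(np >= 4, max_gen >= 1, f > 0, cr >= 0, cr <= 1,
            reseed_every >= 1)
  structure(list(np = as.integer(np), max_gen = as.integer(max_gen),
                 f = f, cr = cr, reseed_every = reseed_every,
                 trace = isTRUE(trace)),
            class = "de_control")
}

#' Differential-evolution minimisation over a box
#'
#' A compact best/1/bin differential-evolution optimizer for noisy
#' simulation-based objectives. The objective `fn(par, eval_seed)` receives
#' an integer seed; all candidates within a generation are evaluated under
#' the same seed (common random numbers, so comparisons between candidates
#' are meaningful) and the seed changes across generations so the search
#' does not overfit one noise realisation. Parents are re-evaluated each
#' generation under the current seed before selection. Candidates leaving
#' the box are reflected back inside.
#'
#' @param fn Objective `function(par, eval_seed)`, returning a scalar.
#' @param lower,upper Numeric bounds (equal length); dimensions with
#'   `lower == upper` are held fixed. A fully degenerate box returns it
#'   immediately.
#' @param control A [de_control()] object.
#' @param seed Integer seed (drives initialisation and the per-generation
#'   evaluation seeds).
#' @return List with `par`, `value`, `converged` (best value improved over
#'   the initial generation), `trace` (data frame of generation summaries or
#'   `NULL`), `n_eval`.
#' @export
de_optim <- function(fn, lower, upper, control = de_control(), seed = 1L) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  seed <- as.integer(seed)
  if (all(upper == lower)) {
    val <- fn(lower, seed)
    return(list(par = lower, value = val, converged = TRUE, trace = NULL,
                n_eval = 1L))
  }
  np <- control$np
  set.seed(seed)
  rng_range <- upper - lower
  pop <- matrix(stats::runif(np * d), nrow = np) *
    matrix(rng_range, np, d, byrow = TRUE) +
    matrix(lower, np, d, byrow = TRUE)
  n_eval <- 0L
  trace <- if (control$trace) vector("list", control$max_gen) else NULL
  best_par <- NULL
  best_val <- Inf
  first_gen_best <- NA_real_

  reflect <- function(x) {
    for (j in seq_len(d)) {
      if (rng_range[j] == 0) { x[j] <- lower[j]; next }
      while (x[j] < lower[j] || x[j] > upper[j]) {
        if (x[j] < lower[j]) x[j] <- 2 * lower[j] - x[j]
        if (x[j] > upper[j]) x[j] <- 2 * upper[j] - x[j]
      }
    }
    x
  }

  scores <- NULL
  es_prev <- NA_real_
  for (g in seq_len(control$max_gen)) {
    block <- if (is.finite(control$reseed_every))
      ceiling(g / control$reseed_every) else 1
    es <- (seed + 1009 * block) %% .Machine$integer.max
    if (is.null(scores) || !identical(es, es_prev)) {
      scores <- apply(pop, 1L, fn, es)   # (re)score parents under this seed
      n_eval <- n_eval + np
      es_prev <- es
    }
    ib <- which.min(scores)
    if (g == 1L) first_gen_best <- scores[ib]
    base <- pop[ib, ]

    trials <- pop
    for (i in seq_len(np)) {
      rs <- sample(setdiff(seq_len(np), i), 2L)
      mut <- base + control$f * (pop[rs[1L], ] - pop[rs[2L], ])
      jrand <- sample.int(d, 1L)
      mask <- stats::runif(d) < control$cr
      mask[jrand] <- TRUE
      cand <- pop[i, ]
      cand[mask] <- mut[mask]
      trials[i, ] <- reflect(cand)
    }
    tscores <- apply(trials, 1L, fn, es)
    n_eval <- n_eval + np
    take <- tscores <= scores
    pop[take, ] <- trials[take, ]
    scores[take] <- tscores[take]

    ib <- which.min(scores)
    if (scores[ib] < best_val) {
      best_val <- scores[ib]
      best_par <- pop[ib, ]
    }
    if (control$trace)
      trace[[g]] <- data.frame(gen = g, best = scores[ib],
                               mean = mean(scores))
  }
  list(par = best_par, value = best_val,
       converged = isTRUE(best_val < first_gen_best),
       trace = if (control$trace) do.call(rbind, trace) else NULL,
       n_eval = n_eval)
}
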