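#' Simulate first-passage decisions of the pre-decisional accumulator
#'
#' Runs the Euler-Maruyama discretisation of the Wiener accumulation process
#' `e <- e + stimulus * drift * dt + sigma * sqrt(dt) * N(0, 1)`, starting at
#' `start`, until the first step at which `e <= 0` or `e >= bound`. The
#' evidence is clamped to the bound that was hit; the response time is the
#' first-passage time plus the nondecision time. Trials that do not reach a
#' bound within `max_t` seconds are flagged as `capped` (never silently
#' dropped) and carry `NA` choice and times.
#'
#' @param params A [model_params()] object.
#' @param stimulus Stimulus direction(s), each +1 or -1 (+1 means the upper
#'   bound is the correct answer). Recycled to length `n` if scalar.
#' @param n Number of trials; defaults to `length(stimulus)`.
#' @param dt Euler time step (s).
#' @param max_t Maximum simulated decision time (s).
#' @param seed Integer seed for the simulator's random stream.
#'
#' @return A data frame with columns `stimulus`, `choice` (+1/-1),
#'   `decision_time`, `rt`, `evidence` (0 or `bound`), `capped`.
#' @examples
#' d <- simulate_decisions(model_params(), stimulus = 1, n = 100, seed = 1)
#' mean(d$choice == 1)
#' @export
simulate_decisions <- function(params, stimulus = c(1L, -1L), n = NULL,
                               dt = 0.001, max_t = 10, seed = 1L) {
  stim <- check_stimulus(stimulus, n)
  out <- cpp_simulate_decisions(par_vector(params), stim, dt, max_t,
                                as.integer(seed))
  as.data.frame(out)
}

check_stimulus <- function(stimulus, n = NULL) {
  stimulus <- as.integer(stimulus)
  if (any(!stimulus %in% c(-1L, 1L))) stop("stimulus values must be +1 or -1")
  if (!is.null(n)) stimulus <- rep_len(stimulus, n)
  stimulus
}

#' Post-decisional drift rate
#'
#' The drift at which evidence keeps accumulating after the decision:
#' `v_ratio * (stimulus * drift) + choice * v_bias`. The first term rescales
#' the objective evidence stream (metacognitive efficiency); the second adds
#' a decision-contingent bias in favour of (`v_bias > 0`) or against
#' (`v_bias < 0`) the choice just made.
#'
#' @param params A [model_params()] object.
#' @param stimulus Stimulus direction(s), +1/-1.
#' @param choice Decision(s), +1/-1.
#' @return Numeric drift (evidence units / s), vectorised over inputs.
#' @export
post_decision_drift <- function(params, stimulus, choice) {
  validate_model_params(params)
  if (any(!choice %in% c(-1, 1))) stop("choice values must be +1 or -1")
  if (any(!stimulus %in% c(-1, 1))) stop("stimulus values must be +1 or -1")
  params$v_ratio * (stimulus * params$drift) + choice * params$v_bias
}

#' Draw post-decisional confidence evidence
#'
#' The evidence available at the time of the confidence report is the bound
#' value at decision plus a Wiener increment over the confidence response
#' time: one draw from
#' `Normal(evidence + drift * t_conf, sigma^2 * t_conf)`.
#' `t_conf = 0` returns `evidence` exactly.
#'
#' @param evidence Evidence at decision (0 or `bound`), vectorised.
#' @param post_drift Post-decisional drift (see [post_decision_drift()]).
#' @param t_conf Confidence response time(s), seconds, `>= 0`.
#' @param sigma Accumulation noise; default 1.
#' @return Numeric vector of final evidence values. Uses R's RNG (respects
#'   `set.seed()`).
#' @export
sample_confidence_evidence <- function(evidence, post_drift, t_conf, sigma = 1) {
  if (any(t_conf < 0)) stop("t_conf must be non-negative")
  k <- max(length(evidence), length(post_drift), length(t_conf))
  evidence <- rep_len(evidence, k)
  post_drift <- rep_len(post_drift, k)
  t_conf <- rep_len(t_conf, k)
  evidence + post_drift * t_conf + sigma * sqrt(t_conf) * stats::rnorm(k)
}

#' Map final evidence to a confidence report
#'
#' Choice-relative evidence is centred at the bound midpoint,
#' `x = choice * (evidence - bound / 2)`, and passed through a logistic
#' transform with an additive criterion shift and a multiplicative slope:
#' `confidence = 1 / (1 + exp(-(m_bias * x - a_bias)))`. The map is strictly
#' increasing in `x`; positive `a_bias` lowers confidence at every evidence
#' level (underconfidence), and `m_bias` controls how steeply evidence is
#' converted into extreme confidence values.
#'
#' @param evidence Final (post-decisional) evidence, vectorised.
#' @param choice Decision(s), +1/-1.
#' @param params A [model_params()] object.
#' @return Confidence in (0, 1); extreme arguments saturate without
#'   overflow (clamped to `[1e-12, 1 - 1e-12]`).
#' @export
evidence_to_confidence <- function(evidence, choice, params) {
  validate_model_params(params)
  if (any(!choice %in% c(-1, 1))) stop("choice values must be +1 or -1")
  x <- choice * (evidence - params$bound / 2)
  v <- stats::plogis(params$m_bias * x - params$a_bias)
  pmin(pmax(v, 1e-12), 1 - 1e-12)
}

#' Simulate full confidence trials
#'
#' Runs the complete generative model per trial: pre-decisional accumulation
#' to a bound, a confidence response time resampled with replacement from
#' `conf_rt_pool`, post-decisional accumulation at the (possibly biased)
#' post-decisional drift, and the logistic evidence-to-confidence transform.
#'
#' @param params A [model_params()] object.
#' @param n Number of trials.
#' @param conf_rt_pool Non-empty vector of positive confidence response
#'   times (s) resampled with replacement per trial.
#' @param stimulus Stimulus schedule; defaults to alternating +1/-1 in equal
#'   proportion.
#' @param dt,max_t,seed As in [simulate_decisions()].
#' @param resample If `FALSE`, `conf_rt_pool` is used cyclically instead of
#'   resampled (useful for deterministic fixtures).
#'
#' @return A data frame with columns `stimulus`, `choice`, `accuracy`,
#'   `decision_time`, `rt`, `confidence`, `confidence_rt`, `evidence`,
#'   `capped`. The fraction of capped (non-terminated) trials is attached as
#'   attribute `capped_frac`. `n = 0` returns an empty table with the full
#'   schema. Bitwise-reproducible under a fixed seed.
#' @examples
#' tr <- simulate_trials(model_params(), n = 200,
#'                       conf_rt_pool = c(0.8, 1.2, 2.0), seed = 7)
#' mean(tr$confidence)
#' @export
simulate_trials <- function(params, n, conf_rt_pool,
                            stimulus = rep_len(c(1L, -1L), n),
                            dt = 0.001, max_t = 10, seed = 1L,
                            resample = TRUE) {
  if (length(conf_rt_pool) == 0) stop("confidence-RT pool is empty")
  if (any(!is.finite(conf_rt_pool)) || any(conf_rt_pool <= 0))
    stop("confidence-RT pool entries must be positive and finite")
  if (n == 0) {
    out <- data.frame(stimulus = integer(), choice = integer(),
                      accuracy = integer(), decision_time = numeric(),
                      rt = numeric(), confidence = numeric(),
                      confidence_rt = numeric(), evidence = numeric(),
                      capped = logical())
    attr(out, "capped_frac") <- NA_real_
    attr(out, "seed") <- as.integer(seed)
    return(out)
  }
  stim <- check_stimulus(stimulus, n)
  out <- as.data.frame(cpp_simulate_trials(par_vector(params), stim,
                                           as.numeric(conf_rt_pool), resample,
                                           dt, max_t, as.integer(seed)))
  attr(out, "capped_frac") <- mean(out$capped)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Analytic first-passage choice probability of the Wiener accumulator
#'
#' Probability that a Wiener process with drift `mu`, noise `sigma`,
#' absorbing bounds at 0 and `bound`, and start `start` is absorbed at the
#' upper bound: `(1 - exp(-2 mu z / sigma^2)) / (1 - exp(-2 mu a / sigma^2))`,
#' reducing to `z / a` at zero drift. Used as the independent oracle for the
#' simulated accumulator.
#'
#' @param mu Signed drift (evidence units / s).
#' @param bound,start,sigma As in [model_params()].
#' @return Probability of hitting the upper bound.
#' @export
first_passage_prob_upper <- function(mu, bound, start, sigma = 1) {
  if (abs(mu) < 1e-12) return(start / bound)
  k <- 2 * mu / sigma^2
  (1 - exp(-k * start)) / (1 - exp(-k * bound))
}

#' Analytic mean decision time for an unbiased start
#'
#' For `start = bound / 2` the closed-form mean first-passage time is
#' `(bound / (2 mu)) * tanh(mu * bound / (2 sigma^2))`.
#'
#' @inheritParams first_passage_prob_upper
#' @return Mean decision time (s), excluding nondecision time.
#' @export
first_passage_mean_time <- function(mu, bound, sigma = 1) {
  if (abs(mu) < 1e-12) return((bound / 2)^2 / sigma^2)
  (bound / (2 * mu)) * tanh(mu * bound / (2 * sigma^2))
}
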