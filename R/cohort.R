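#' Design of a synthetic study cohort
#'
#' Describes how individual-difference scores couple to model parameters in
#' a simulated population: anxiety is standard normal, gender is
#' Bernoulli(`gender_p_woman`) over {man, woman}, age is uniform over
#' `age_range`. Each coupling row shifts one model parameter by
#' `gain * score` per subject (gender enters as woman = 1, man = 0).
#' Confidence-RT pools are log-normal with a subject-specific location so
#' that subjects differ in their typical report time.
#'
#' @param n_subjects,n_trials Cohort dimensions (`n_subjects >= 2`).
#' @param base Base [model_params()] shared by all subjects.
#' @param couplings Data frame with columns `score` (one of `"anxiety"`,
#'   `"gender"`), `param` (a [model_params()] field), `gain` (finite).
#' @param gender_p_woman Probability of `"woman"`.
#' @param age_range Uniform age range in years.
#' @param conf_rt_meanlog,conf_rt_sdlog,conf_rt_subject_sd Log-normal
#'   confidence-RT model (median about 1.5 s by default).
#' @param difficulty_mean,difficulty_sd Near-constant staircase difficulty
#'   emitted as a nuisance column (higher = easier).
#' @param dataset_id,task_id Labels for the emitted cohort.
#' @param dt,max_t Simulator settings.
#' @param seed Integer seed.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = 60, n_trials = 400,
                          base = model_params(),
                          couplings = data.frame(score = character(),
                                                 param = character(),
                                                 gain = numeric()),
                          gender_p_woman = 0.5, age_range = c(18, 65),
                          conf_rt_meanlog = log(1.5), conf_rt_sdlog = 0.5,
                          conf_rt_subject_sd = 0.4,
                          difficulty_mean = 20, difficulty_sd = 1,
                          dataset_id = "synthetic1", task_id = "task1",
                          dt = 0.001, max_t = 10, seed = 1L) {
  design <- structure(as.list(environment()), class = "cohort_design")
  validate_cohort_design(design)
  design
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("Cohort design: %d subjects x %d trials (seed %d)\n",
              x$n_subjects, x$n_trials, x$seed))
  if (nrow(x$couplings)) {
    cat("Couplings:\n")
    print(x$couplings, row.names = FALSE)
  } else cat("No couplings (null design)\n")
  invisible(x)
}

validate_cohort_design <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  if (design$n_subjects < 2) stop("n_subjects must be >= 2")
  if (design$n_trials < 1) stop("n_trials must be >= 1")
  validate_model_params(design$base)
  cp <- design$couplings
  if (nrow(cp)) {
    if (!all(c("score", "param", "gain") %in% names(cp)))
      stop("couplings must have columns score, param, gain")
    if (!all(cp$score %in% c("anxiety", "gender")))
      stop("coupling scores must be 'anxiety' or 'gender'")
    bad <- setdiff(cp$param, setdiff(names(design$base), "sigma"))
    if (length(bad)) stop("unknown coupled parameter(s): ",
                          paste(bad, collapse = ", "))
    if (any(!is.finite(cp$gain))) stop("coupling gains must be finite")
  }
  invisible(design)
}

#' The canonical study design
#'
#' The coupling pattern motivating the whole pipeline: the anxiety score
#' loads negatively on the accumulative bias `v_bias` (gain -0.5),
#' positively on the additive criterion shift `a_bias` (+0.2), and
#' negatively on metacognitive efficiency `v_ratio` (-0.15); being a woman
#' loads positively on `a_bias` only (+0.6). Gains are documented package
#' constants, calibrated once so the planted effects are detectable at
#' fixture scale and so the accumulative component dominates the anxiety
#' time course (anxiety-related underconfidence must deepen with
#' post-decision time while the gender effect fades; with equal gain
#' magnitudes the additive and accumulative contributions to the anxiety
#' time interaction would cancel).
#'
#' @param ... Overrides forwarded to [cohort_design()].
#' @return A `cohort_design`.
#' @export
default_study_design <- function(...) {
  cohort_design(
    couplings = data.frame(
      score = c("anxiety", "anxiety", "anxiety", "gender"),
      param = c("v_bias", "a_bias", "v_ratio", "a_bias"),
      gain = c(-0.5, 0.2, -0.15, 0.6)),
    ...)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject scores, applies the design's couplings to the base
#' parameters, and simulates each subject's trials through the full
#' generative model. `m_bias` (and `v_ratio`) are floored at 0.05 (0) if a
#' coupling would drive them out of range.
#'
#' @param design A [cohort_design()].
#' @return Cohort trial data frame: `subject_id`, `dataset_id`, `task_id`,
#'   `stimulus`, `choice`, `accuracy`, `rt`, `confidence` (model scale),
#'   `confidence_rt`, `difficulty`, `anxiety`, `gender`, `age`, `capped`.
#'   The per-subject [model_params()] list is attached as attribute
#'   `subject_params`, and the design as attribute `design`.
#' @export
generate_cohort <- function(design) {
  validate_cohort_design(design)
  set.seed(design$seed)
  n <- design$n_subjects
  anxiety <- stats::rnorm(n)
  gender <- ifelse(stats::runif(n) < design$gender_p_woman, "woman", "man")
  age <- stats::runif(n, design$age_range[1], design$age_range[2])
  mls <- stats::rnorm(n, design$conf_rt_meanlog, design$conf_rt_subject_sd)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)

  score_value <- function(which, i)
    if (which == "anxiety") anxiety[i] else as.numeric(gender[i] == "woman")

  params <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- design$base
    cp <- design$couplings
    if (nrow(cp)) for (r in seq_len(nrow(cp)))
      p[[cp$param[r]]] <- p[[cp$param[r]]] +
        cp$gain[r] * score_value(cp$score[r], i)
    if (p$m_bias <= 0) p$m_bias <- 0.05
    if (p$v_ratio < 0) p$v_ratio <- 0
    validate_model_params(p)
    params[[i]] <- p

    set.seed(subj_seeds[2L * i - 1L])
    pool <- stats::rlnorm(design$n_trials, mls[i], design$conf_rt_sdlog)
    difficulty <- stats::rnorm(design$n_trials, design$difficulty_mean,
                               design$difficulty_sd)
    tr <- simulate_trials(p, design$n_trials, conf_rt_pool = pool,
                          dt = design$dt, max_t = design$max_t,
                          seed = subj_seeds[2L * i])
    rows[[i]] <- data.frame(
      subject_id = sprintf("s%03d", i), dataset_id = design$dataset_id,
      task_id = design$task_id, stimulus = tr$stimulus, choice = tr$choice,
      accuracy = tr$accuracy, rt = tr$rt, confidence = tr$confidence,
      confidence_rt = tr$confidence_rt, difficulty = difficulty,
      anxiety = anxiety[i], gender = gender[i], age = age[i],
      capped = tr$capped)
  }
  out <- do.call(rbind, rows)
  attr(out, "subject_params") <- params
  attr(out, "design") <- design
  out
}
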