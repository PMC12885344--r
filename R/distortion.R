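#' Confidence-distortion mechanism
#'
#' One of the three candidate mechanisms by which an individual-difference
#' score distorts confidence: D1 (accumulative) couples the score to the
#' decision-contingent post-decisional drift bias `v_bias`; D2 (additive)
#' couples it to the confidence-criterion shift `a_bias`; D3
#' (multiplicative) couples it to the sigmoid slope `m_bias`. Each mechanism
#' affects exactly one parameter.
#'
#' @param kind `"D1"`, `"D2"` or `"D3"`.
#' @param coupling Signed gain from the (z-scored) score to the affected
#'   parameter. For the anxiety-like case the conventional signs are
#'   negative for D1, positive for D2 and negative for D3 (slope inversely
#'   related to the score).
#' @return An object of class `mechanism` with fields `kind`, `coupling`,
#'   `param`.
#' @export
mechanism <- function(kind = c("D1", "D2", "D3"), coupling) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(coupling), length(coupling) == 1, is.finite(coupling))
  structure(list(kind = kind, coupling = coupling,
                 param = switch(kind, D1 = "v_bias", D2 = "a_bias",
                                D3 = "m_bias")),
            class = "mechanism")
}

#' Build a distorted population of parameter sets
#'
#' Subject `i` receives the base parameters with the mechanism's target
#' parameter shifted by `coupling * scores[i]`; all other parameters are
#' identical across subjects. A D3 coupling that would drive `m_bias` to or
#' below zero is clipped at 0.05 with a warning.
#'
#' @param base A [model_params()] object.
#' @param scores Numeric vector of (typically z-scored) individual scores.
#' @param mech A [mechanism()].
#' @return List of [model_params()], one per score.
#' @export
build_population <- function(base, scores, mech) {
  validate_model_params(base)
  stopifnot(inherits(mech, "mechanism"), all(is.finite(scores)))
  clipped <- 0L
  pop <- lapply(scores, function(s) {
    p <- base
    p[[mech$param]] <- p[[mech$param]] + mech$coupling * s
    if (mech$param == "m_bias" && p$m_bias <= 0) {
      p$m_bias <- 0.05
      clipped <<- clipped + 1L
    }
    validate_model_params(p)
    p
  })
  if (clipped > 0L)
    warning(sprintf("m_bias clipped at 0.05 for %d subject(s)", clipped))
  pop
}

#' Simulate a population under one distortion mechanism
#'
#' Draws standard-normal scores (unless supplied), applies
#' [build_population()], and simulates each subject's trials with a
#' subject-specific log-normal confidence-RT pool (the subject-level median
#' confidence RT varies across subjects, so between-subject time analyses
#' have support).
#'
#' @param base Base [model_params()].
#' @param mech A [mechanism()].
#' @param n_subjects,n_trials Population dimensions.
#' @param scores Optional score vector (length `n_subjects`).
#' @param conf_rt_meanlog,conf_rt_sdlog,conf_rt_subject_sd Log-normal
#'   confidence-RT model: within-subject `lnN(meanlog_i, sdlog)` with
#'   subject locations `meanlog_i ~ N(meanlog, subject_sd)`.
#' @param dt,max_t Simulator settings.
#' @param seed Integer seed.
#' @return Trial data frame with `subject`, `score`, and all trial columns.
#' @export
simulate_mechanism_population <- function(base, mech, n_subjects = 60,
                                          n_trials = 400, scores = NULL,
                                          conf_rt_meanlog = log(1.5),
                                          conf_rt_sdlog = 0.5,
                                          conf_rt_subject_sd = 0.4,
                                          dt = 0.001, max_t = 10, seed = 1L) {
  set.seed(seed)
  if (is.null(scores)) scores <- stats::rnorm(n_subjects)
  stopifnot(length(scores) == n_subjects)
  pop <- suppressWarnings(build_population(base, scores, mech))
  mls <- stats::rnorm(n_subjects, conf_rt_meanlog, conf_rt_subject_sd)
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    pool <- stats::rlnorm(n_trials, mls[i], conf_rt_sdlog)
    tr <- simulate_trials(pop[[i]], n_trials, conf_rt_pool = pool, dt = dt,
                          max_t = max_t,
                          seed = (seed + 2654435761 * i) %% .Machine$integer.max)
    tr$subject <- i
    tr$score <- scores[i]
    out[[i]] <- tr
  }
  do.call(rbind, out)
}

#' Slope difference of confidence over post-decision time
#'
#' Per subject, the ordinary least-squares slope of confidence on
#' confidence RT; the slope difference is the mean slope of the high-score
#' half minus the mean slope of the low-score half (median split on score;
#' ties go to the low group). A subject with constant confidence
#' contributes slope 0 (with a warning). An accumulative distortion (D1,
#' negative coupling) makes distortion grow with time, a negative slope
#' difference; an additive criterion shift (D2, positive coupling) fades
#' with time, a positive slope difference.
#'
#' @param trials Trial table with `subject`, `score`, `confidence`,
#'   `confidence_rt` (capped trials dropped if flagged).
#' @return List with `delta` (confidence / s), and `slopes` (per-subject
#'   data frame with `subject`, `score`, `slope`, `group`).
#' @export
slope_difference <- function(trials) {
  if (!is.null(trials$capped)) trials <- trials[!trials$capped, , drop = FALSE]
  stopifnot(all(c("subject", "score", "confidence", "confidence_rt")
                %in% names(trials)))
  subj <- unique(trials$subject)
  n_const <- 0L
  rows <- lapply(subj, function(s) {
    tr <- trials[trials$subject == s, , drop = FALSE]
    vt <- stats::var(tr$confidence_rt)
    vc <- stats::var(tr$confidence)
    slope <- if (!is.finite(vc) || vc == 0 || !is.finite(vt) || vt == 0) {
      n_const <<- n_const + 1L
      0
    } else {
      stats::cov(tr$confidence, tr$confidence_rt) / vt
    }
    data.frame(subject = s, score = tr$score[1], slope = slope)
  })
  slopes <- do.call(rbind, rows)
  if (n_const > 0L)
    warning(sprintf("%d subject(s) with degenerate confidence; slope set to 0",
                    n_const))
  med <- stats::median(slopes$score)
  slopes$group <- ifelse(slopes$score > med, "high", "low")
  delta <- mean(slopes$slope[slopes$group == "high"]) -
    mean(slopes$slope[slopes$group == "low"])
  list(delta = delta, slopes = slopes)
}

#' Default base-parameter grid for phase diagrams
#'
#' For D1/D2, a 3 x 3 x 2 grid over (`v_ratio`, `bound`, `drift`) around
#' the default parameter set, with `v_ratio` kept in the (0, 1) range
#' typical of fitted metacognitive efficiency (above 1, baseline confidence
#' saturates so quickly that time-course signatures distort). For D3, a
#' wider grid that also varies the baseline criterion `a_bias`: the
#' multiplicative mechanism produces overconfidence only when a liberal
#' (negative) criterion keeps error-trial evidence in the responsive range
#' of the sigmoid.
#'
#' @param kind Mechanism kind.
#' @return Data frame of base-parameter overrides, one row per grid point.
#' @export
default_phase_grid <- function(kind = c("D1", "D2", "D3")) {
  kind <- match.arg(kind)
  if (kind %in% c("D1", "D2"))
    expand.grid(v_ratio = c(0.3, 0.55, 0.8), bound = c(1.5, 2, 2.5),
                drift = c(0.8, 1.2))
  else
    expand.grid(v_ratio = c(0.4, 1.2), bound = c(1.5, 2.5),
                a_bias = c(-2.5, 0, 1.5))
}

#' Phase diagram of a distortion mechanism
#'
#' For each grid point (a row of base-parameter overrides), simulates a
#' population under the mechanism and records the sign of the
#' score-to-mean-confidence correlation (negative = underconfidence for
#' higher scores) and the sign of the slope difference.
#'
#' @param mech A [mechanism()].
#' @param grid Data frame of parameter overrides; columns must be
#'   [model_params()] field names. Defaults to [default_phase_grid()].
#' @param base Base parameters the overrides are applied to.
#' @param n_subjects,n_trials Population per grid point.
#' @param dt,seed As elsewhere; grid point `g` uses seed `seed + g`.
#' @return Tidy data frame: grid columns plus `conf_effect` (correlation of
#'   score with subject mean confidence), `conf_effect_sign`, `dslope`,
#'   `dslope_sign`.
#' @export
phase_diagram <- function(mech, grid = default_phase_grid(mech$kind),
                          base = model_params(), n_subjects = 60,
                          n_trials = 200, dt = 0.001, seed = 1L) {
  stopifnot(inherits(mech, "mechanism"), nrow(grid) >= 1)
  bad <- setdiff(names(grid), names(base))
  if (length(bad)) stop("unknown parameter columns in grid: ",
                        paste(bad, collapse = ", "))
  res <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    b <- base
    for (nm in names(grid)) b[[nm]] <- grid[[nm]][g]
    if (!("start" %in% names(grid))) b$start <- b$bound / 2
    validate_model_params(b)
    trials <- simulate_mechanism_population(b, mech, n_subjects = n_subjects,
                                            n_trials = n_trials, dt = dt,
                                            seed = seed + g)
    keep <- !trials$capped
    mc <- tapply(trials$confidence[keep], trials$subject[keep], mean)
    sc <- tapply(trials$score, trials$subject, unique)[names(mc)]
    eff <- stats::cor(as.numeric(sc), as.numeric(mc))
    ds <- suppressWarnings(slope_difference(trials))$delta
    res[[g]] <- cbind(grid[g, , drop = FALSE],
                      data.frame(conf_effect = eff,
                                 conf_effect_sign = sign(eff),
                                 dslope = ds, dslope_sign = sign(ds)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
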