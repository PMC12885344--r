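#' Quantile summary of observed choices, RTs and confidence
#'
#' Builds the fitting target: RT quantile-bin counts computed separately
#' within correct and error trials, plus confidence distributions computed
#' in four classes crossing accuracy with report speed -- trials with
#' confidence RTs below versus at-or-above the subject's median confidence
#' RT ("fast" and "slow" halves), each split into correct and error trials.
#' The accuracy split of the confidence classes is what identifies the
#' post-decisional drift parameters (`v_ratio` versus `v_bias`), since for
#' correct trials only their sum shapes confidence while error trials pull
#' them apart. Continuous confidence scales use quantile bins like the RTs;
#' Likert scales count each rating level instead.
#'
#' @param trials Trial table with columns `accuracy` (0/1), `rt`,
#'   `confidence` (model scale in (0,1)), `confidence_rt`. Capped trials
#'   (column `capped`, if present) are dropped first.
#' @param scale_kind `"continuous"` or `"likert"`.
#' @param levels Number of Likert levels (required for `"likert"`).
#' @param probs Quantile probabilities; default `c(.1, .3, .5, .7, .9)`.
#' @return An object of class `quantile_summary`: per-class RT edges and
#'   counts, confidence edges/counts (or per-level counts) for the classes
#'   `fast_correct`, `fast_error`, `slow_correct`, `slow_error`,
#'   `median_conf_rt`, `n_trials`, and the names of any classes dropped for
#'   having fewer trials than bins (each dropped with a warning).
#' @export
summarize_observed <- function(trials, scale_kind = c("continuous", "likert"),
                               levels = NULL,
                               probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  scale_kind <- match.arg(scale_kind)
  if (scale_kind == "likert" && (is.null(levels) || levels < 2))
    stop("likert mode requires `levels` >= 2")
  if (!is.null(trials$capped)) trials <- trials[!trials$capped, , drop = FALSE]
  if (nrow(trials) < 20) stop("need at least 20 trials to summarise")
  stopifnot(all(is.finite(probs)), !is.unsorted(probs))
  n_bins <- length(probs) + 1L
  dropped <- character()

  rt_class <- function(x, label) {
    if (length(x) < n_bins) {
      dropped <<- c(dropped, label)
      warning(sprintf("class '%s' has %d trials (< %d bins); dropped from the objective",
                      label, length(x), n_bins))
      return(NULL)
    }
    edges <- unname(stats::quantile(x, probs, type = 7))
    list(edges = edges, counts = bin_counts(x, edges), n = length(x))
  }
  conf_class <- function(x, label) {
    if (length(x) == 0 ||
        (scale_kind == "continuous" && length(x) < n_bins)) {
      dropped <<- c(dropped, label)
      warning(sprintf("confidence class '%s' has too few trials; dropped from the objective",
                      label))
      return(NULL)
    }
    if (scale_kind == "continuous") {
      edges <- unname(stats::quantile(x, probs, type = 7))
      list(edges = edges, counts = bin_counts(x, edges), n = length(x))
    } else {
      lev <- confidence_to_level(x, levels)
      list(edges = NULL, counts = tabulate(lev, nbins = levels), n = length(x))
    }
  }

  med <- stats::median(trials$confidence_rt)
  fast <- trials$confidence_rt < med
  acc <- trials$accuracy == 1
  conf <- trials$confidence
  structure(list(
    probs = probs,
    rt = list(correct = rt_class(trials$rt[acc], "correct"),
              error = rt_class(trials$rt[!acc], "error")),
    conf = list(
      fast_correct = conf_class(conf[fast & acc], "fast_correct"),
      fast_error = conf_class(conf[fast & !acc], "fast_error"),
      slow_correct = conf_class(conf[!fast & acc], "slow_correct"),
      slow_error = conf_class(conf[!fast & !acc], "slow_error")),
    scale_kind = scale_kind, levels = levels,
    median_conf_rt = med, n_trials = nrow(trials), dropped = dropped),
    class = "quantile_summary")
}

# Half-open [lo, hi) bin membership against fixed edges; length(edges)+1 bins.
bin_counts <- function(x, edges) {
  tabulate(findInterval(x, edges) + 1L, nbins = length(edges) + 1L)
}

# Map model-scale confidence in (0,1) back to Likert levels 1..k
# (inverse of the (level - 0.5) / k midpoint convention).
confidence_to_level <- function(confidence, levels) {
  pmin(levels, pmax(1L, as.integer(round(confidence * levels + 0.5))))
}

#' @export
print.quantile_summary <- function(x, ...) {
  cat(sprintf("Quantile summary: %d trials, %s confidence scale\n",
              x$n_trials, x$scale_kind))
  cat(sprintf("  median confidence RT: %.3f s\n", x$median_conf_rt))
  if (length(x$dropped))
    cat("  dropped classes:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Quantile chi-squared objective
#'
#' Compares an observed [summarize_observed()] summary against a table of
#' simulated trials. Simulated trials are binned by the observed quantile
#' edges (RT bins within each accuracy class; confidence bins or Likert
#' levels within the four accuracy-by-speed classes, split at the observed
#' median confidence RT). Within each modality (RT, confidence) the classes
#' form one multinomial: expected counts are the simulated proportions over
#' all cells of the modality's active classes, scaled to the total observed
#' count, so the simulated accuracy rate is fitted alongside the
#' distribution shapes (a choice model that matches RT quantiles with the
#' wrong proportion correct is penalised in every cell). The objective is
#' `sum((O - E)^2 / (E + eps))` over all cells. A simulated class with no
#' trials contributes its maximal penalty `sum(O^2) / eps` rather than
#' `NaN`; observed classes dropped at summary time are excluded from both
#' sides.
#'
#' @param obs A `quantile_summary`.
#' @param sim Simulated trial table (capped trials are dropped).
#' @param eps Small-count guard added to every expected count; default 1.
#' @return Non-negative scalar.
#' @export
chi_squared_objective <- function(obs, sim, eps = 1) {
  stopifnot(inherits(obs, "quantile_summary"))
  if (!is.null(sim$capped)) {
    keep <- !sim$capped
    sim <- lapply(sim, function(col) col[keep])
  }
  if (length(sim$rt) == 0) stop("simulated table is empty")

  # one modality = a list of (obs class, sim values) pairs forming a single
  # multinomial over all cells of the classes present in the observed summary
  modality <- function(pairs, kind) {
    active <- !vapply(pairs, function(p) is.null(p$obs), TRUE)
    if (!any(active)) return(0)
    pairs <- pairs[active]
    n_obs_tot <- sum(vapply(pairs, function(p) p$obs$n, 0))
    counts <- lapply(pairs, function(p) {
      if (length(p$sim) == 0) return(rep(0, length(p$obs$counts)))
      if (kind == "level")
        tabulate(confidence_to_level(p$sim, obs$levels), nbins = obs$levels)
      else bin_counts(p$sim, p$obs$edges)
    })
    n_sim_tot <- sum(unlist(counts))
    chi <- 0
    for (j in seq_along(pairs)) {
      O <- pairs[[j]]$obs$counts
      E <- if (n_sim_tot == 0) rep(0, length(O))
           else counts[[j]] / n_sim_tot * n_obs_tot
      chi <- chi + sum((O - E)^2 / (E + eps))
    }
    chi
  }

  acc <- sim$accuracy == 1
  fast <- sim$confidence_rt < obs$median_conf_rt
  ck <- if (obs$scale_kind == "likert") "level" else "edges"
  modality(list(list(obs = obs$rt$correct, sim = sim$rt[acc]),
                list(obs = obs$rt$error, sim = sim$rt[!acc])), "edges") +
  modality(list(
    list(obs = obs$conf$fast_correct, sim = sim$confidence[fast & acc]),
    list(obs = obs$conf$fast_error, sim = sim$confidence[fast & !acc]),
    list(obs = obs$conf$slow_correct, sim = sim$confidence[!fast & acc]),
    list(obs = obs$conf$slow_error, sim = sim$confidence[!fast & !acc])),
    ck)
}

#' Default parameter search box for fitting
#'
#' The starting point is searched as the fraction `start_frac = start /
#' bound`. Ranges bracket behavioural regimes typical of staircased 2-AFC
#' tasks with confidence ratings.
#'
#' @return Named list of `c(lower, upper)` pairs for the 8 free parameters.
#' @export
default_fit_bounds <- function() {
  list(drift = c(0, 5), bound = c(0.5, 4), start_frac = c(0.2, 0.8),
       ndt = c(0.05, 1.5), v_ratio = c(0, 2), v_bias = c(-2, 2),
       a_bias = c(-5, 5), m_bias = c(0.1, 5))
}

bounds_matrix <- function(bounds) {
  nm <- c("drift", "bound", "start_frac", "ndt", "v_ratio", "v_bias",
          "a_bias", "m_bias")
  miss <- setdiff(nm, names(bounds))
  if (length(miss)) stop("missing bounds for: ", paste(miss, collapse = ", "))
  m <- vapply(bounds[nm], function(b) as.numeric(b[1:2]), numeric(2))
  rownames(m) <- c("lower", "upper")
  m
}

theta_to_params <- function(theta, sigma = 1) {
  theta <- unname(theta)
  model_params(drift = theta[1], bound = theta[2],
               start = max(1e-6, min(1 - 1e-6, theta[3])) * theta[2],
               ndt = theta[4], v_ratio = theta[5], v_bias = theta[6],
               a_bias = theta[7], m_bias = theta[8], sigma = sigma)
}

#' Fit the model to one subject's trials
#'
#' Minimises the quantile chi-squared objective over the 8-parameter box
#' with differential evolution. Each candidate evaluation simulates `n_sim`
#' trials under a seed shared by all candidates of the generation (common
#' random numbers), with confidence RTs resampled from the subject's own
#' observed confidence RTs.
#'
#' @param trials Subject trial table (post-preprocessing) with `accuracy`,
#'   `rt`, `confidence`, `confidence_rt`.
#' @param bounds Search box, see [default_fit_bounds()].
#' @param n_sim Simulated trials per objective evaluation.
#' @param dt,max_t Simulator discretisation settings for the fit.
#' @param de A [de_control()] object (optimizer budget).
#' @param scale_kind,levels,probs Passed to [summarize_observed()].
#' @param eps Chi-squared small-count guard.
#' @param seed Integer seed; the fit is deterministic given data and seed.
#' @return An object of class `fit_result`: `params_hat` ([model_params()]),
#'   `start_frac`, `objective`, `n_sim`, `trace`, `seed`, `converged`,
#'   `bounds`.
#' @export
fit_subject <- function(trials, bounds = default_fit_bounds(), n_sim = 4000,
                        dt = 0.002, max_t = 10, de = de_control(),
                        scale_kind = "continuous", levels = NULL,
                        probs = c(0.1, 0.3, 0.5, 0.7, 0.9), eps = 1,
                        seed = 1L) {
  obs <- summarize_observed(trials, scale_kind = scale_kind, levels = levels,
                            probs = probs)
  pool <- as.numeric(trials$confidence_rt)
  if (!is.null(trials$capped)) pool <- pool[!trials$capped]
  stim <- rep_len(c(1L, -1L), n_sim)
  bm <- bounds_matrix(bounds)

  objective <- function(theta, eval_seed) {
    p <- theta_to_params(theta)
    sim <- cpp_simulate_trials(par_vector(p), stim, pool, TRUE, dt, max_t,
                               as.integer(eval_seed))
    chi_squared_objective(obs, sim, eps = eps)
  }

  opt <- de_optim(objective, bm["lower", ], bm["upper", ], control = de,
                  seed = seed)
  structure(list(params_hat = theta_to_params(opt$par),
                 start_frac = unname(opt$par[3]), objective = opt$value,
                 n_sim = n_sim, trace = opt$trace, seed = as.integer(seed),
                 converged = opt$converged, bounds = bounds,
                 n_eval = opt$n_eval),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Model fit (chi-squared = %.2f, %s, %d evals, seed %d)\n",
              x$objective, if (x$converged) "converged" else "budget exhausted",
              x$n_eval, x$seed))
  print(x$params_hat)
  invisible(x)
}

#' Extract fitted parameters as a one-row data frame
#'
#' @param fit A `fit_result`.
#' @return One-row data frame of the eight fitted parameters plus the
#'   objective value and convergence flag.
#' @export
fit_to_row <- function(fit) {
  p <- fit$params_hat
  data.frame(drift = p$drift, bound = p$bound, start_frac = fit$start_frac,
             ndt = p$ndt, v_ratio = p$v_ratio, v_bias = p$v_bias,
             a_bias = p$a_bias, m_bias = p$m_bias,
             objective = fit$objective, converged = fit$converged)
}

#' Combine per-task fits by z-scoring then averaging
#'
#' When a subject performed several tasks, the model is fitted separately
#' per task; each parameter is z-scored across subjects within task and the
#' z-scores are averaged across tasks per subject. With a single task the
#' result is that task's z-scored parameters.
#'
#' @param fits Data frame with columns `subject`, `task`, and the parameter
#'   columns named in `params`.
#' @param params Parameter columns to combine.
#' @return Data frame with one row per subject and the averaged z-scored
#'   parameter columns.
#' @export
fit_multitask <- function(fits, params = c("drift", "bound", "start_frac",
                                           "ndt", "v_ratio", "v_bias",
                                           "a_bias", "m_bias")) {
  stopifnot(all(c("subject", "task") %in% names(fits)),
            all(params %in% names(fits)))
  z <- fits
  for (pc in params) {
    z[[pc]] <- stats::ave(fits[[pc]], fits$task, FUN = function(x) {
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) stop("zero variance in parameter '", pc,
                                        "' within a task; cannot z-score")
      (x - mean(x)) / s
    })
  }
  out <- stats::aggregate(z[params], by = list(subject = z$subject), FUN = mean)
  out[order(out$subject), , drop = FALSE]
}

#' Parameter-recovery and identifiability study
#'
#' Samples ground-truth parameter sets, simulates data from each, refits the
#' model, and tabulates truth against estimates. Identifiability is
#' assessed via the full cross-correlation matrix between true and
#' recovered parameters: for an identifiable parameter the diagonal entry
#' dominates its row.
#'
#' @param sampler `function()` returning a [model_params()] draw within the
#'   fitting bounds.
#' @param n_subjects,n_trials Number of synthetic subjects and trials each.
#' @param conf_rt_meanlog,conf_rt_sdlog Log-normal confidence-RT pool used
#'   for data generation.
#' @param bounds,n_sim,dt,de,seed Passed to [fit_subject()]; `dt` is also
#'   used for data generation.
#' @return Object of class `recovery_report`: `truth` and `estimate` data
#'   frames, `cor_matrix` (rows = truth, cols = estimates, over parameters
#'   with truth variance), `diag_cor`, `n_failed`.
#' @export
recovery_study <- function(sampler, n_subjects = 20, n_trials = 800,
                           conf_rt_meanlog = log(1.5), conf_rt_sdlog = 0.5,
                           bounds = default_fit_bounds(), n_sim = 2000,
                           dt = 0.002, de = de_control(np = 24, max_gen = 40),
                           seed = 1L) {
  pn <- c("drift", "bound", "start_frac", "ndt", "v_ratio", "v_bias",
          "a_bias", "m_bias")
  truth <- est <- as.data.frame(matrix(NA_real_, n_subjects, length(pn),
                                       dimnames = list(NULL, pn)))
  failed <- logical(n_subjects)
  for (i in seq_len(n_subjects)) {
    set.seed(seed + 7717L * i)
    p <- sampler()
    validate_model_params(p)
    pool <- stats::rlnorm(n_trials, conf_rt_meanlog, conf_rt_sdlog)
    trials <- simulate_trials(p, n_trials, conf_rt_pool = pool, dt = dt,
                              seed = (seed + 104729L * i) %% .Machine$integer.max)
    fit <- fit_subject(trials, bounds = bounds, n_sim = n_sim, dt = dt,
                       de = de, seed = (seed + 15485863L + i) %% .Machine$integer.max)
    truth[i, ] <- c(p$drift, p$bound, p$start / p$bound, p$ndt, p$v_ratio,
                    p$v_bias, p$a_bias, p$m_bias)
    if (!is.finite(fit$objective)) { failed[i] <- TRUE; next }
    est[i, ] <- unlist(fit_to_row(fit)[pn])
  }
  ok <- !failed
  varied <- pn[vapply(truth[ok, , drop = FALSE], stats::sd, 0) > 1e-12]
  cm <- stats::cor(truth[ok, varied, drop = FALSE],
                   est[ok, , drop = FALSE])
  rownames(cm) <- paste0("true_", varied)
  colnames(cm) <- paste0("est_", pn)
  dc <- vapply(varied, function(v) cm[paste0("true_", v), paste0("est_", v)], 0)
  structure(list(truth = truth, estimate = est, cor_matrix = cm,
                 diag_cor = dc, n_failed = sum(failed),
                 n_subjects = n_subjects, n_trials = n_trials),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d subjects x %d trials (%d failed fits)\n",
              x$n_subjects, x$n_trials, x$n_failed))
  cat("Truth-vs-estimate correlations:\n")
  print(round(x$diag_cor, 3))
  invisible(x)
}
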