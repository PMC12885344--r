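#' Build the subject-level analysis table from cohort trials
#'
#' Standardises confidence, RTs and difficulty within (dataset, task) at
#' the trial level, then aggregates per subject: mean z-scored confidence,
#' RT and difficulty, and the median confidence RT. The anxiety score and
#' the median confidence RT are then z-scored across subjects within
#' dataset; gender and age pass through untransformed. Gender is coded
#' numerically as woman = 1, man = 0 (so positive coefficients mean
#' "higher in women").
#'
#' @param trials Cohort table from [generate_cohort()] / [read_trials()]
#'   (after trial-level exclusions), with `subject_id`, `dataset_id`,
#'   `task_id`, `confidence`, `rt`, `confidence_rt`, `difficulty`,
#'   `anxiety`, `gender`, `age`.
#' @return Subject-level data frame with `conf_z`, `rt_z`, `difficulty_z`,
#'   `med_conf_rt` (raw seconds), `med_conf_rt_z`, `anxiety_z`,
#'   `gender_num`, `age`, `dataset_id`, `task_id`.
#' @export
summarize_subjects <- function(trials) {
  if (!is.null(trials$capped)) trials <- trials[!trials$capped, , drop = FALSE]
  tz <- zscore_within(trials, c("confidence", "rt", "confidence_rt",
                                "difficulty"))
  key <- interaction(tz$subject_id, tz$dataset_id, tz$task_id, drop = TRUE)
  agg <- function(x, f) as.numeric(tapply(x, key, f))
  first <- function(x) unlist(tapply(x, key, function(v) v[1]),
                              use.names = FALSE)
  out <- data.frame(
    subject_id = first(as.character(tz$subject_id)),
    dataset_id = first(as.character(tz$dataset_id)),
    task_id = first(as.character(tz$task_id)),
    conf_z = agg(tz$confidence, mean),
    rt_z = agg(tz$rt, mean),
    difficulty_z = agg(tz$difficulty, mean),
    med_conf_rt = as.numeric(tapply(trials$confidence_rt, key, stats::median)),
    anxiety = first(tz$anxiety),
    gender = first(as.character(tz$gender)),
    age = first(tz$age))
  out$gender_num <- ifelse(out$gender == "woman", 1, 0)
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  out$anxiety_z <- stats::ave(out$anxiety, out$dataset_id, FUN = zs)
  out$med_conf_rt_z <- stats::ave(out$med_conf_rt, out$dataset_id, FUN = zs)
  out
}

# Per-coefficient Wald table from an lm fit.
wald_table <- function(fit, n, n_excluded = 0L) {
  sm <- summary(fit)$coefficients
  out <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                    chisq = (sm[, 1] / sm[, 2])^2, row.names = NULL)
  out$p <- stats::pchisq(out$chisq, df = 1, lower.tail = FALSE)
  structure(out, class = c("regression_result", "data.frame"),
            n = n, n_excluded = n_excluded)
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Regression (n = %d, %d excluded)\n", attr(x, "n"),
              attr(x, "n_excluded")))
  df <- as.data.frame(x)
  df$estimate <- signif(df$estimate, 4)
  df$se <- signif(df$se, 4)
  df$chisq <- signif(df$chisq, 4)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

# Append dataset-task fixed-effect indicators when there is more than one cell.
with_fixed_effects <- function(formula_str, subjects) {
  cells <- interaction(subjects$dataset_id, subjects$task_id, drop = TRUE)
  if (nlevels(cells) > 1) {
    subjects$dataset_task <- cells
    formula_str <- paste(formula_str, "+ dataset_task")
  }
  list(formula = stats::as.formula(formula_str), data = subjects)
}

run_ols <- function(formula_str, subjects, n_excluded = 0L) {
  design <- with_fixed_effects(formula_str, subjects)
  fit <- stats::lm(design$formula, data = design$data)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  wald_table(fit, n = nrow(design$data), n_excluded = n_excluded)
}

#' Regress subject confidence on individual-difference factors
#'
#' Least squares of subject-mean z-scored confidence on the z-scored
#' anxiety score, gender (woman = 1), age, and mean z-scored staircase
#' difficulty (higher = easier), with dataset-task fixed-effect indicators
#' when more than one cell is present. Reports a per-term Wald chi-squared.
#'
#' @param subjects Output of [summarize_subjects()].
#' @return A `regression_result` data frame.
#' @export
regress_confidence <- function(subjects) {
  run_ols("conf_z ~ anxiety_z + gender_num + age + difficulty_z", subjects)
}

#' Factor-by-time interactions on confidence
#'
#' Adds two-way interactions of each individual-difference factor with the
#' subject's z-scored median confidence RT. The `anxiety_z:med_conf_rt_z`
#' and `gender_num:med_conf_rt_z` coefficients are the regression analogue
#' of the slope differences between score groups: a negative anxiety-time
#' interaction means anxiety-related underconfidence grows with
#' post-decision time, a positive gender-time interaction means
#' gender-related underconfidence fades with it.
#'
#' @param subjects Output of [summarize_subjects()].
#' @return A `regression_result` data frame.
#' @export
regress_time_interactions <- function(subjects) {
  run_ols(paste("conf_z ~ (anxiety_z + gender_num + age) * med_conf_rt_z",
                "+ difficulty_z"), subjects)
}

#' Regress fitted model parameters on individual-difference factors
#'
#' For each requested parameter, removes extreme outliers (values more than
#' `sd_limit` sample SDs from the mean, computed within each dataset-task
#' cell) for `v_ratio`, `v_bias` and `a_bias`, then regresses the parameter
#' on anxiety, gender and age (plus dataset-task fixed effects when
#' present).
#'
#' @param fit_table Data frame with one row per subject: parameter columns,
#'   `anxiety_z`, `gender_num`, `age`, and `dataset_id` / `task_id`.
#' @param params Parameters to analyse.
#' @param sd_limit Outlier threshold in SD units (default 5).
#' @return Named list of `regression_result` objects (one per parameter);
#'   each carries its `n_excluded` attribute.
#' @export
regress_params_on_factors <- function(fit_table,
                                      params = c("v_ratio", "v_bias",
                                                 "a_bias", "m_bias"),
                                      sd_limit = 5) {
  stopifnot(all(params %in% names(fit_table)),
            all(c("anxiety_z", "gender_num", "age") %in% names(fit_table)))
  if (is.null(fit_table$dataset_id)) fit_table$dataset_id <- "d1"
  if (is.null(fit_table$task_id)) fit_table$task_id <- "t1"
  outlier_rule <- c("v_ratio", "v_bias", "a_bias")
  cells <- interaction(fit_table$dataset_id, fit_table$task_id, drop = TRUE)
  out <- list()
  for (pc in params) {
    keep <- rep(TRUE, nrow(fit_table))
    if (pc %in% outlier_rule) {
      z <- stats::ave(fit_table[[pc]], cells, FUN = function(x) {
        s <- stats::sd(x)
        if (!is.finite(s) || s == 0) return(rep(0, length(x)))
        (x - mean(x)) / s
      })
      keep <- abs(z) <= sd_limit
    }
    sub <- fit_table[keep, , drop = FALSE]
    out[[pc]] <- run_ols(paste(pc, "~ anxiety_z + gender_num + age"), sub,
                         n_excluded = sum(!keep))
  }
  out
}

#' Bin subjects into post-decision time bins with bootstrap CIs
#'
#' Tiles subjects into `n_bins` equal-count bins of median confidence RT
#' and reports per-bin, per-group mean confidence with percentile-bootstrap
#' 95% confidence intervals. Bins with fewer than `min_per_bin` subjects
#' are merged with their left neighbour (with a warning).
#'
#' @param subjects Output of [summarize_subjects()].
#' @param group Name of a subject column to split groups on: a numeric
#'   column is median-split into `"low"`/`"high"` (ties to low), a
#'   character/factor column is used as-is.
#' @param n_bins Number of time bins (default 6).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param min_per_bin Minimum subjects per bin before merging.
#' @param seed Seed for the bootstrap.
#' @return Data frame: `bin`, `bin_center` (mean median-RT, s), `group`,
#'   `mean_conf`, `ci_lo`, `ci_hi`, `n`.
#' @export
bin_time_marginals <- function(subjects, group = "anxiety_z", n_bins = 6,
                               n_boot = 2000, min_per_bin = 3, seed = 1L) {
  x <- subjects$med_conf_rt
  if (length(unique(x)) < n_bins)
    stop("need at least n_bins distinct median confidence RTs")
  gv <- subjects[[group]]
  grp <- if (is.numeric(gv))
    ifelse(gv > stats::median(gv), "high", "low")
  else as.character(gv)
  edges <- stats::quantile(x, probs = seq_len(n_bins - 1) / n_bins, type = 7)
  bin <- findInterval(x, unname(edges)) + 1L
  # merge undersized bins leftward
  repeat {
    sizes <- tabulate(bin, n_bins)
    small <- which(sizes > 0 & sizes < min_per_bin)
    if (!length(small) || max(bin) == 1) break
    b <- small[1]
    warning(sprintf("bin %d has %d subjects; merging with neighbour", b,
                    sizes[b]))
    bin[bin == b] <- if (b == 1) 2L else b - 1L
  }
  set.seed(seed)
  rows <- list()
  for (b in sort(unique(bin))) for (g in sort(unique(grp))) {
    v <- subjects$conf_z[bin == b & grp == g]
    if (!length(v)) next
    bm <- vapply(seq_len(n_boot),
                 function(i) mean(v[sample.int(length(v), replace = TRUE)]), 0)
    qs <- stats::quantile(bm, c(0.025, 0.975), type = 7)
    rows[[length(rows) + 1L]] <-
      data.frame(bin = b, bin_center = mean(x[bin == b]), group = g,
                 mean_conf = mean(v), ci_lo = unname(qs[1]),
                 ci_hi = unname(qs[2]), n = length(v))
  }
  do.call(rbind, rows)
}
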