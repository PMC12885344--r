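#' Trial-level exclusion rules
#'
#' Applies the behavioural trial filters: (1) choice RTs below 100 ms are
#' removed; (2) within each (dataset, task) group, trials whose choice RT
#' or confidence RT deviates from the group median by more than 3 median
#' absolute deviations (MAD, with the 1.4826 normal-consistency factor) are
#' removed. The MAD rule is computed on the trials surviving the 100 ms
#' rule. Groups with fewer than 5 trials skip the MAD rule (logged), as do
#' groups whose MAD is exactly 0 (a degenerate spread under which any
#' deviation would be excluded).
#'
#' @param trials Cohort trial table with `dataset_id`, `task_id`, `rt`,
#'   `confidence_rt`.
#' @param rt_min Minimum choice RT in seconds (default 0.1).
#' @param n_mad MAD multiplier (default 3).
#' @return List with `trials` (filtered) and `log` (data frame of per-group
#'   per-rule removal counts, plus `skipped` flags for groups where the MAD
#'   rule could not be applied).
#' @export
exclude_trials <- function(trials, rt_min = 0.1, n_mad = 3) {
  stopifnot(all(c("dataset_id", "task_id", "rt", "confidence_rt")
                %in% names(trials)))
  if (any(trials$rt <= 0) || any(trials$confidence_rt <= 0))
    stop("RTs must be positive")
  grp <- interaction(trials$dataset_id, trials$task_id, drop = TRUE)
  fast <- trials$rt < rt_min
  kept <- trials[!fast, , drop = FALSE]
  grp_kept <- grp[!fast]

  logs <- list()
  keep_mask <- rep(TRUE, nrow(kept))
  for (g in levels(grp_kept)) {
    idx <- which(grp_kept == g)
    row <- data.frame(group = g, n_in = sum(grp == g),
                      removed_fast = sum(fast[grp == g]),
                      removed_rt_mad = 0L, removed_conf_rt_mad = 0L,
                      mad_skipped = FALSE)
    if (length(idx) < 5) {
      row$mad_skipped <- TRUE
    } else {
      out_rt <- mad_outlier(kept$rt[idx], n_mad)
      out_crt <- mad_outlier(kept$confidence_rt[idx], n_mad)
      if (is.null(out_rt) || is.null(out_crt)) {
        row$mad_skipped <- TRUE
      } else {
        row$removed_rt_mad <- sum(out_rt)
        row$removed_conf_rt_mad <- sum(out_crt & !out_rt)
        keep_mask[idx] <- !(out_rt | out_crt)
      }
    }
    logs[[g]] <- row
  }
  log <- do.call(rbind, logs)
  rownames(log) <- NULL
  list(trials = kept[keep_mask, , drop = FALSE], log = log)
}

# TRUE where |x - median| > n_mad * MAD; NULL when MAD == 0 (degenerate).
mad_outlier <- function(x, n_mad) {
  m <- stats::median(x)
  s <- stats::mad(x)  # 1.4826 consistency factor
  if (s == 0) return(NULL)
  abs(x - m) > n_mad * s
}

#' Subject-level exclusion rules
#'
#' Drops subjects whose confidence-rating variability (sample SD across all
#' of their confidence reports, on the model's (0, 1) scale) is below the
#' resolution of their dataset's discrete rating scale (1/k for a k-point
#' scale); the rule does not apply to continuous-scale datasets.
#' Optionally drops subjects with `gender == "nonbinary"`, which is done
#' only for gender analyses.
#'
#' @param trials Cohort trial table with `subject_id`, `dataset_id`,
#'   `confidence`, and (if `drop_nonbinary`) `gender`.
#' @param resolution Named numeric vector mapping dataset ids to scale
#'   resolutions (datasets absent from the map are treated as continuous
#'   and skipped), or a single unnamed value applied to every dataset.
#' @param drop_nonbinary Drop nonbinary subjects (default `FALSE`).
#' @return List with `trials`, and `log`: data frame of excluded subjects
#'   with the rule that removed them.
#' @export
exclude_subjects <- function(trials, resolution = NULL,
                             drop_nonbinary = FALSE) {
  stopifnot(all(c("subject_id", "dataset_id", "confidence") %in% names(trials)))
  drop <- data.frame(subject_id = character(), rule = character())
  if (!is.null(resolution)) {
    stopifnot(all(resolution > 0))
    for (ds in unique(trials$dataset_id)) {
      res <- if (is.null(names(resolution))) resolution[1]
             else resolution[as.character(ds)]
      if (is.null(res) || is.na(res)) next
      sub <- trials[trials$dataset_id == ds, , drop = FALSE]
      sds <- tapply(sub$confidence, sub$subject_id, stats::sd)
      low <- names(sds)[!is.na(sds) & sds < res]
      if (length(low))
        drop <- rbind(drop, data.frame(subject_id = low,
                                       rule = "confidence_variability"))
    }
  }
  if (drop_nonbinary) {
    if (is.null(trials$gender)) stop("drop_nonbinary requires a gender column")
    nb <- unique(trials$subject_id[trials$gender == "nonbinary"])
    if (length(nb))
      drop <- rbind(drop, data.frame(subject_id = as.character(nb),
                                     rule = "nonbinary_gender"))
  }
  keep <- !(as.character(trials$subject_id) %in% drop$subject_id)
  list(trials = trials[keep, , drop = FALSE], log = drop)
}

#' Z-score variables within dataset-task groups
#'
#' Standardises each named variable to mean 0 and sample SD 1 (n - 1
#' denominator) within each grouping cell, so values pool across datasets
#' and tasks. Gender and age are conventionally passed through untouched
#' (simply leave them out of `vars`).
#'
#' @param trials Data frame.
#' @param vars Character vector of numeric columns to standardise.
#' @param by Grouping columns; default `c("dataset_id", "task_id")`.
#' @return `trials` with the named columns standardised group-wise.
#' @export
zscore_within <- function(trials, vars, by = c("dataset_id", "task_id")) {
  stopifnot(all(vars %in% names(trials)), all(by %in% names(trials)))
  grp <- interaction(trials[by], drop = TRUE)
  for (v in vars) {
    sds <- tapply(trials[[v]], grp, stats::sd)
    bad <- names(sds)[is.na(sds) | sds == 0]
    if (length(bad))
      stop(sprintf("variable '%s' has zero variance in group(s): %s", v,
                   paste(bad, collapse = ", ")))
    trials[[v]] <- stats::ave(trials[[v]], grp,
                              FUN = function(x) (x - mean(x)) / stats::sd(x))
  }
  trials
}
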