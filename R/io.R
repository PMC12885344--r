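#' Read a cohort trial file
#'
#' Reads the comma-separated trial format (UTF-8, '.' decimal, header
#' required) and validates every row. Required columns: `subject_id`,
#' `dataset_id`, `task_id`, `stimulus` (+1/-1), `choice` (+1/-1),
#' `accuracy` (0/1, consistent with stimulus and choice), `rt_s`,
#' `confidence_raw`, `confidence_scale` (one of `continuous_0_100`,
#' `likert_5`, `likert_11`), `confidence_rt_s`, `difficulty`. Raw
#' confidence is mapped onto the model's (0, 1) scale: continuous `x ->
#' x / 100` clipped to 0.001..0.999; a k-point Likert level `l ->
#' (l - 0.5) / k` (interval midpoints, never exactly 0 or 1). Optional
#' columns `anxiety`, `gender`, `age` are carried through.
#'
#' @param path File path.
#' @return Cohort data frame with internal column names (`rt`,
#'   `confidence`, `confidence_rt`, plus `confidence_raw` and
#'   `confidence_scale` retained for round-tripping).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "dataset_id", "task_id", "stimulus", "choice",
            "accuracy", "rt_s", "confidence_raw", "confidence_scale",
            "confidence_rt_s", "difficulty")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  fail <- function(mask, what) {
    if (any(mask))
      stop(sprintf("%s in row(s): %s", what,
                   paste(utils::head(which(mask), 10), collapse = ", ")))
  }
  fail(!df$stimulus %in% c(-1, 1), "stimulus must be +1 or -1")
  fail(!df$choice %in% c(-1, 1), "choice must be +1 or -1")
  fail(!df$accuracy %in% c(0, 1), "accuracy must be 0 or 1")
  fail(df$accuracy != as.integer(df$stimulus == df$choice),
       "accuracy inconsistent with stimulus and choice")
  fail(!is.finite(df$rt_s) | df$rt_s <= 0, "rt_s must be positive seconds")
  fail(!is.finite(df$confidence_rt_s) | df$confidence_rt_s <= 0,
       "confidence_rt_s must be positive seconds")
  known <- c("continuous_0_100", "likert_5", "likert_11")
  fail(!df$confidence_scale %in% known, "unknown confidence_scale tag")

  conf <- numeric(nrow(df))
  for (sc in unique(df$confidence_scale)) {
    i <- df$confidence_scale == sc
    x <- df$confidence_raw[i]
    if (sc == "continuous_0_100") {
      bad <- !is.finite(x) | x < 0 | x > 100
      if (any(bad)) fail(replace(logical(nrow(df)), which(i)[bad], TRUE),
                         "confidence_raw outside [0, 100]")
      conf[i] <- pmin(0.999, pmax(0.001, x / 100))
    } else {
      k <- if (sc == "likert_5") 5L else 11L
      bad <- !is.finite(x) | x != round(x) | x < 1 | x > k
      if (any(bad)) fail(replace(logical(nrow(df)), which(i)[bad], TRUE),
                         sprintf("confidence_raw outside 1..%d", k))
      conf[i] <- (x - 0.5) / k
    }
  }
  df$confidence <- conf
  df$rt <- df$rt_s
  df$confidence_rt <- df$confidence_rt_s
  df$rt_s <- NULL
  df$confidence_rt_s <- NULL
  df
}

#' Write a cohort trial file
#'
#' Inverse of [read_trials()]: writes the external column layout. If
#' `confidence_raw` / `confidence_scale` are absent (model-generated
#' cohorts), model-scale confidence is exported as a continuous 0-100
#' rating.
#'
#' @param trials Cohort data frame (internal column names).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  df <- trials
  if (is.null(df$confidence_scale)) {
    df$confidence_scale <- "continuous_0_100"
    df$confidence_raw <- round(df$confidence * 100, 6)
  }
  df$rt_s <- df$rt
  df$confidence_rt_s <- df$confidence_rt
  cols <- c("subject_id", "dataset_id", "task_id", "stimulus", "choice",
            "accuracy", "rt_s", "confidence_raw", "confidence_scale",
            "confidence_rt_s", "difficulty")
  extra <- intersect(c("anxiety", "gender", "age"), names(df))
  utils::write.csv(df[c(cols, extra)], path, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' All tunable run settings in one structure: simulator discretisation,
#' quantile probabilities, fitting budget and box, analysis bins and
#' bootstrap size, and the master seed.
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(dt = 0.001, max_t = 10,
       quantiles = c(0.1, 0.3, 0.5, 0.7, 0.9),
       n_sim = 4000, eps = 1,
       de = list(np = 32, max_gen = 50, f = 0.8, cr = 0.9),
       bounds = default_fit_bounds(),
       n_bins = 6, n_boot = 2000, seed = 1)
}

#' Read and validate a run configuration
#'
#' YAML key-value configuration. Keys absent from the file keep their
#' defaults; unknown keys (including misspellings, at any nesting level)
#' are rejected rather than silently ignored.
#'
#' @param path YAML file path.
#' @return Full configuration list (defaults merged with the file).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_checked(default_config(), user, "config")
}

merge_checked <- function(defaults, user, where) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown %s key(s): %s", where,
                 paste(unknown, collapse = ", ")))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      merge_checked(defaults[[k]], as.list(user[[k]]), paste0(where, "$", k))
    else user[[k]]
  }
  defaults
}

#' Write a run configuration
#' @param config Configuration list (see [default_config()]).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write fit results with a metadata sidecar
#'
#' Writes one CSV row per subject fit and a YAML sidecar
#' (`<path>.meta.yaml`) recording the search bounds, seeds, optimizer
#' budget, and the fitted-file MD5 so reruns can be compared.
#'
#' @param fits Named list of `fit_result` objects (names = subject ids).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_results <- function(fits, path) {
  stopifnot(length(fits) > 0, all(vapply(fits, inherits, TRUE, "fit_result")))
  rows <- do.call(rbind, lapply(fits, fit_to_row))
  rows <- cbind(subject_id = names(fits), rows)
  utils::write.csv(rows, path, row.names = FALSE)
  meta <- list(n_subjects = length(fits),
               seeds = vapply(fits, function(f) f$seed, 1L),
               n_sim = fits[[1]]$n_sim,
               bounds = lapply(fits[[1]]$bounds, as.numeric),
               results_md5 = unname(tools::md5sum(path)))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read fit results written by [write_fit_results()]
#' @param path CSV path.
#' @return Data frame of fitted parameters, one row per subject.
#' @export
read_fit_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a run log
#'
#' Key-value text log carrying package version, seed, the configuration
#' hash (MD5 of the config file), and any named counts (e.g. exclusion
#' tallies), so two runs can be diffed except for the timestamp.
#'
#' @param path Output path.
#' @param config_path Path of the configuration used (hashed), or `NULL`.
#' @param seed Seed used.
#' @param counts Named integer vector of counts to record.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, config_path = NULL, seed = NA,
                          counts = integer()) {
  lines <- c(sprintf("package_version: %s",
                     as.character(utils::packageVersion("confdrift"))),
             sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             sprintf("seed: %s", seed))
  if (!is.null(config_path))
    lines <- c(lines, sprintf("config_md5: %s",
                              unname(tools::md5sum(config_path))))
  if (length(counts))
    lines <- c(lines, sprintf("%s: %d", names(counts), counts))
  writeLines(lines, path)
  invisible(path)
}
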