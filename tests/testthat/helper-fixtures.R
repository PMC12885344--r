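# Shared fixtures built in code at test time.

# log-normal confidence-RT pool (median ~1.5 s)
make_pool <- function(n = 200, seed = 100) {
  set.seed(seed)
  stats::rlnorm(n, log(1.5), 0.5)
}

# quick synthetic subject for fitting tests
make_subject_trials <- function(params = model_params(), n = 400, seed = 1,
                                dt = 0.002) {
  simulate_trials(params, n, conf_rt_pool = make_pool(seed = seed + 1),
                  dt = dt, seed = seed)
}

# minimal cohort-format table wrapped around simulator output
make_cohort_rows <- function(n = 60, subject = "s1", dataset = "d1",
                             task = "t1", seed = 1) {
  tr <- make_subject_trials(n = n, seed = seed)
  data.frame(subject_id = subject, dataset_id = dataset, task_id = task,
             stimulus = tr$stimulus, choice = tr$choice,
             accuracy = tr$accuracy, rt = tr$rt, confidence = tr$confidence,
             confidence_rt = tr$confidence_rt,
             difficulty = stats::rnorm(n, 20, 1), anxiety = 0,
             gender = "man", age = 30, capped = tr$capped)
}

# fast DE settings for determinism/degenerate-box tests
tiny_de <- function() de_control(np = 8, max_gen = 3, trace = FALSE)
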