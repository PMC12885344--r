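test_that("quantile summary matches a hand-computed recount", {
  # 20 correct trials with RTs 1..10 repeated; 20 errors at RTs 11..30;
  # confidence RTs make the fast half exactly the first 20 rows
  rt <- c(rep(1:10, 2), 11:30)
  trials <- data.frame(
    accuracy = rep(c(1, 0), each = 20), rt = rt,
    confidence = seq(0.05, 0.95, length.out = 40),
    confidence_rt = c(rep(0.5, 20), rep(2, 20)))
  s <- suppressWarnings(summarize_observed(trials))
  # type-7 quantiles of 1..10 (each twice): same as of 1..10 scaled by rank
  q <- unname(quantile(c(rep(1:10, 2)), c(.1, .3, .5, .7, .9), type = 7))
  expect_equal(s$rt$correct$edges, q)
  # brute-force recount of half-open bins
  recount <- function(x, edges) {
    lo <- c(-Inf, edges); hi <- c(edges, Inf)
    vapply(seq_along(lo), function(i) sum(x >= lo[i] & x < hi[i]), 0L)
  }
  expect_equal(s$rt$correct$counts, recount(rep(1:10, 2), q))
  expect_equal(sum(s$rt$correct$counts), 20)
  expect_equal(s$rt$error$counts, recount(11:30, s$rt$error$edges))
  expect_equal(s$median_conf_rt, median(trials$confidence_rt))
  # fast half = accuracy 1 rows here, so fast_error is dropped with a warning
  w <- capture_warnings(summarize_observed(trials))
  expect_true(any(grepl("fast_error", w)))
  # per-class confidence counts sum to the class sizes
  expect_equal(s$conf$fast_correct$n + s$conf$slow_error$n, 40)
})

test_that("likert summaries count levels, degenerate raters occupy one level", {
  trials <- data.frame(accuracy = rep(c(1, 0), 20),
                       rt = runif(40, 0.5, 2),
                       confidence = rep((3 - 0.5) / 5, 40),  # everyone says 3/5
                       confidence_rt = rep(c(0.5, 2), each = 20))
  s <- summarize_observed(trials, scale_kind = "likert", levels = 5)
  for (cls in s$conf[!vapply(s$conf, is.null, TRUE)]) {
    expect_equal(sum(cls$counts > 0), 1)
    expect_equal(which(cls$counts > 0), 3)
  }
})

test_that("chi-squared objective reproduces hand arithmetic", {
  # two RT bins: O = (8, 2); simulated proportions 50/50 -> E = (5, 5)
  obs <- structure(list(
    probs = 0.5,
    rt = list(correct = list(edges = 1, counts = c(8L, 2L), n = 10),
              error = NULL),
    conf = list(fast_correct = NULL, fast_error = NULL,
                slow_correct = NULL, slow_error = NULL),
    scale_kind = "continuous", levels = NULL,
    median_conf_rt = 1, n_trials = 10, dropped = character()),
    class = "quantile_summary")
  sim <- data.frame(accuracy = rep(1, 100), rt = rep(c(0.5, 1.5), 50),
                    confidence = runif(100), confidence_rt = rep(1, 100))
  expect_equal(chi_squared_objective(obs, sim, eps = 0), 9 / 5 + 9 / 5)
  # perfect agreement of proportions gives exactly zero at eps = 0
  sim2 <- data.frame(accuracy = 1, rt = c(rep(0.5, 80), rep(1.5, 20)),
                     confidence = runif(100), confidence_rt = 1)
  expect_equal(chi_squared_objective(obs, sim2, eps = 0), 0)
  # a simulated class with no trials draws the maximal penalty, never NaN
  sim3 <- data.frame(accuracy = rep(0, 50), rt = runif(50, 0.2, 2),
                     confidence = runif(50), confidence_rt = rep(1, 50))
  obs3 <- obs
  expect_equal(chi_squared_objective(obs3, sim3, eps = 1), sum(c(8, 2)^2))
})

test_that("objective is invariant to trial order and stimulus relabelling", {
  tr <- make_subject_trials(n = 300, seed = 21)
  obs <- summarize_observed(tr)
  sim <- make_subject_trials(n = 1000, seed = 22)
  v1 <- chi_squared_objective(obs, sim)
  perm <- sample(nrow(sim))
  expect_equal(chi_squared_objective(obs, sim[perm, ]), v1)
  flipped <- sim
  flipped$stimulus <- -flipped$stimulus
  flipped$choice <- -flipped$choice
  expect_equal(chi_squared_objective(obs, flipped), v1)
})

test_that("differential evolution minimises a known function and honours a degenerate box", {
  fn <- function(par, eval_seed) sum((par - c(1, -2, 0.5))^2)
  opt <- de_optim(fn, lower = rep(-5, 3), upper = rep(5, 3),
                  control = de_control(np = 20, max_gen = 60), seed = 2)
  expect_lt(opt$value, 1e-4)
  expect_equal(opt$par, c(1, -2, 0.5), tolerance = 0.01)
  deg <- de_optim(fn, lower = c(1, 1, 1), upper = c(1, 1, 1), seed = 2)
  expect_identical(deg$par, c(1, 1, 1))
  # per-dimension degenerate bounds are held fixed
  opt2 <- de_optim(fn, lower = c(-5, -2, -5), upper = c(5, -2, 5),
                   control = de_control(np = 15, max_gen = 30), seed = 3)
  expect_identical(opt2$par[2], -2)
})

test_that("fitting is deterministic and a degenerate box returns its corner", {
  tr <- make_subject_trials(n = 200, seed = 31)
  fixed <- list(drift = c(1, 1), bound = c(2, 2), start_frac = c(0.5, 0.5),
                ndt = c(0.3, 0.3), v_ratio = c(0.8, 0.8), v_bias = c(0, 0),
                a_bias = c(0, 0), m_bias = c(1, 1))
  f <- suppressWarnings(
    fit_subject(tr, bounds = fixed, n_sim = 300, de = tiny_de(), seed = 5))
  expect_equal(f$params_hat$drift, 1)
  expect_equal(f$params_hat$v_ratio, 0.8)
  expect_equal(f$start_frac, 0.5)

  f1 <- suppressWarnings(fit_subject(tr, n_sim = 300, de = tiny_de(), seed = 7))
  f2 <- suppressWarnings(fit_subject(tr, n_sim = 300, de = tiny_de(), seed = 7))
  expect_identical(fit_to_row(f1), fit_to_row(f2))
})

test_that("objective at the generating truth beats single-parameter displacements", {
  truth <- model_params(drift = 1, bound = 2, ndt = 0.3, v_ratio = 0.8,
                        v_bias = -0.6, a_bias = 0.8, m_bias = 1.5)
  tr <- simulate_trials(truth, 1000, conf_rt_pool = make_pool(seed = 41),
                        dt = 0.002, seed = 40)
  obs <- summarize_observed(tr)
  stim <- rep_len(c(1L, -1L), 4000)
  evalobj <- function(p, s) {
    sim <- confdrift:::cpp_simulate_trials(confdrift:::par_vector(p), stim,
                                           tr$confidence_rt, TRUE, 0.002, 10, s)
    chi_squared_objective(obs, sim)
  }
  fields <- c("drift", "bound", "start", "ndt", "v_ratio", "v_bias",
              "a_bias", "m_bias")
  wins <- total <- 0L
  for (s in 1:6) {
    base_val <- evalobj(truth, 1000 + s)
    for (f in fields) for (mult in c(0.5, 1.5)) {
      p <- truth
      p[[f]] <- p[[f]] * mult
      if (f == "bound") p$start <- p$start * mult  # keep start fraction fixed
      total <- total + 1L
      if (base_val <= evalobj(p, 1000 + s)) wins <- wins + 1L
    }
  }
  expect_gte(wins / total, 0.9)
})

test_that("multitask combination matches a hand-computed z-score-then-average", {
  fits <- data.frame(
    subject = rep(1:3, 2), task = rep(c("a", "b"), each = 3),
    v_bias = c(1, 2, 3, 10, 30, 20), a_bias = c(0, 1, 2, 5, 5.5, 4.5))
  out <- fit_multitask(fits, params = c("v_bias", "a_bias"))
  # hand: task a v_bias z = (-1, 0, 1); task b (10,30,20) -> (-1, 1, 0)
  expect_equal(out$v_bias, c((-1 + -1) / 2, (0 + 1) / 2, (1 + 0) / 2))
  expect_equal(out$a_bias, c((-1 + 0) / 2, (0 + 1) / 2, (1 + -1) / 2))
  # single task: identity on the z-scored parameters
  one <- fit_multitask(fits[fits$task == "a", ], params = c("v_bias", "a_bias"))
  expect_equal(one$v_bias, c(-1, 0, 1))
  # two identical tasks average to either
  dup <- fits
  dup$v_bias <- rep(c(1, 2, 3), 2)
  dup$a_bias <- rep(c(0, 1, 2), 2)
  two <- fit_multitask(dup, params = c("v_bias", "a_bias"))
  expect_equal(two$v_bias, c(-1, 0, 1))
})

test_that("recovery harness produces a complete report on a tiny budget", {
  sampler <- function() model_params(v_bias = runif(1, -1, 1),
                                     a_bias = runif(1, -1.5, 1.5))
  rep <- suppressWarnings(
    recovery_study(sampler, n_subjects = 3, n_trials = 120, n_sim = 200,
                   dt = 0.004, de = tiny_de(), seed = 3))
  expect_s3_class(rep, "recovery_report")
  expect_equal(nrow(rep$truth), 3)
  expect_equal(nrow(rep$estimate), 3)
  expect_setequal(names(rep$diag_cor), c("v_bias", "a_bias"))
  expect_true(all(is.finite(as.matrix(rep$estimate))))
  expect_equal(rep$n_failed, 0)
})
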