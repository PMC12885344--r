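test_that("parameter validation rejects invalid sets", {
  expect_error(model_params(bound = -1), "bound")
  expect_error(model_params(start = 0), "start")
  expect_error(model_params(start = 2, bound = 2), "start")
  expect_error(model_params(ndt = -0.1), "nondecision")
  expect_error(model_params(m_bias = 0), "m_bias")
  expect_error(model_params(drift = NA), "finite")
})

test_that("post-decisional drift composes ratio and decision-contingent bias", {
  p <- model_params(drift = 1.3, v_ratio = 0.6, v_bias = 0)
  expect_identical(post_decision_drift(p, 1, 1), 0.6 * 1.3)
  expect_identical(post_decision_drift(p, -1, 1), -0.6 * 1.3)

  p2 <- model_params(drift = 1, v_ratio = 1, v_bias = -0.5)
  expect_equal(post_decision_drift(p2, 1, 1), 0.5)

  # sign symmetry: negating both stimulus and choice negates the drift
  for (vb in c(-0.7, 0, 0.4)) {
    p3 <- model_params(drift = 1.2, v_ratio = 0.8, v_bias = vb)
    for (s in c(-1, 1)) for (d in c(-1, 1))
      expect_equal(post_decision_drift(p3, -s, -d),
                   -post_decision_drift(p3, s, d))
  }
})

test_that("logistic confidence transform has midpoint, slope and shift properties", {
  p <- model_params(bound = 2, m_bias = 1, a_bias = 0)
  # midpoint: m_bias * x == a_bias gives exactly 0.5
  expect_equal(evidence_to_confidence(1, 1, p), 0.5)
  # direct evaluation at x = 1
  expect_equal(evidence_to_confidence(2, 1, p), 1 / (1 + exp(-1)))
  # positive a_bias lowers confidence everywhere; large shift saturates to ~0
  pc <- model_params(bound = 2, a_bias = 1.5)
  xs <- seq(-3, 3, length.out = 21)
  expect_true(all(evidence_to_confidence(xs + 1, 1, pc) <
                  evidence_to_confidence(xs + 1, 1, p)))
  pbig <- model_params(bound = 2, a_bias = 500)
  expect_lt(evidence_to_confidence(2, 1, pbig), 1e-9)
  expect_true(is.finite(evidence_to_confidence(1e6, 1, p)))
  # monotone in choice-relative evidence
  conf <- evidence_to_confidence(xs + 1, 1, model_params(m_bias = 2.5, a_bias = -1))
  expect_true(all(diff(conf) > 0))
  # criterion-shift equivariance: conf(x; m, c) == conf(x - delta; m, c - m delta)
  for (delta in c(-1.3, 0.4, 2)) {
    m <- 1.7; cc <- 0.6
    p1 <- model_params(bound = 2, m_bias = m, a_bias = cc)
    p2 <- model_params(bound = 2, m_bias = m, a_bias = cc - m * delta)
    expect_equal(evidence_to_confidence(xs + 1, 1, p1),
                 evidence_to_confidence(xs - delta + 1, 1, p2))
  }
})

test_that("confidence evidence is an exact Wiener increment", {
  expect_identical(sample_confidence_evidence(2, 5, 0), 2)
  expect_error(sample_confidence_evidence(2, 0, -1), "non-negative")
  set.seed(42)
  x <- sample_confidence_evidence(rep(2, 30000), 0.4, 2)
  se_mean <- sqrt(2 / 30000)
  expect_lt(abs(mean(x) - (2 + 0.8)), 3 * se_mean)
  expect_lt(abs(var(x) - 2), 3 * 2 * sqrt(2 / 29999))
  # zero drift: symmetric about the starting evidence
  set.seed(43)
  y <- sample_confidence_evidence(rep(1, 30000), 0, 1)
  expect_lt(abs(mean(y) - 1), 3 * sqrt(1 / 30000))
})

test_that("decision simulator respects timing, symmetry and capping contracts", {
  p <- model_params(ndt = 0.3)
  d <- simulate_decisions(p, stimulus = 1, n = 2000, seed = 3)
  expect_true(all(d$rt >= 0.3))
  expect_true(all(d$evidence %in% c(0, p$bound)))
  expect_true(all((d$choice == 1) == (d$evidence == p$bound)))
  # zero drift from the midpoint: both bounds equally likely
  p0 <- model_params(drift = 0)
  d0 <- simulate_decisions(p0, stimulus = 1, n = 20000, seed = 4)
  expect_lt(abs(mean(d0$choice == 1, na.rm = TRUE) - 0.5),
            3 * sqrt(0.25 / 20000))
  # unreachable bound within the cap: trials flagged, not dropped
  dc <- simulate_decisions(model_params(drift = 0), stimulus = 1, n = 50,
                           max_t = 0.005, seed = 5)
  expect_equal(nrow(dc), 50)
  expect_true(all(dc$capped))
  expect_true(all(is.na(dc$choice)))
})

test_that("full trial simulator is deterministic with a complete schema", {
  p <- model_params()
  a <- simulate_trials(p, 500, conf_rt_pool = make_pool(), seed = 9)
  b <- simulate_trials(p, 500, conf_rt_pool = make_pool(), seed = 9)
  expect_identical(a, b)
  e <- simulate_trials(p, 0, conf_rt_pool = 1)
  expect_equal(nrow(e), 0)
  expect_setequal(names(e), c("stimulus", "choice", "accuracy",
                              "decision_time", "rt", "confidence",
                              "confidence_rt", "evidence", "capped"))
  expect_error(simulate_trials(p, 10, conf_rt_pool = numeric()), "empty")
  expect_error(simulate_trials(p, 10, conf_rt_pool = c(1, -1)), "positive")
})

test_that("negative accumulative bias lowers mean confidence", {
  pool <- make_pool()
  base <- simulate_trials(model_params(v_bias = 0), 20000, conf_rt_pool = pool,
                          seed = 11, dt = 0.002)
  neg <- simulate_trials(model_params(v_bias = -1), 20000, conf_rt_pool = pool,
                         seed = 11, dt = 0.002)
  expect_lt(mean(neg$confidence, na.rm = TRUE),
            mean(base$confidence, na.rm = TRUE))
})

test_that("compiled post-decisional increments are standard normal after whitening", {
  # invert the logistic transform on upper-bound trials to expose the raw
  # Wiener increment generated by the compiled sampler
  tc <- 1.7
  p <- model_params(drift = 1.5, bound = 2, v_ratio = 0.5, v_bias = 0.3,
                    m_bias = 1, a_bias = 0)
  tr <- simulate_trials(p, 20000, conf_rt_pool = tc, seed = 13,
                        resample = FALSE, dt = 0.002)
  up <- tr$stimulus == 1 & tr$choice == 1 & !tr$capped
  x <- qlogis(tr$confidence[up])              # = evidence_final - bound/2
  efin <- x + p$bound / 2
  vpost <- post_decision_drift(p, 1, 1)
  z <- (efin - p$bound - vpost * tc) / sqrt(tc)
  z <- z[abs(z) < 6]                          # clamp tails excluded
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_lt(abs(sd(z) - 1), 0.02)
  expect_gt(suppressWarnings(ks.test(z, "pnorm"))$p.value, 0.01)
})

test_that("halving the time step leaves simulated accuracy nearly unchanged", {
  p <- model_params()
  a1 <- simulate_trials(p, 30000, conf_rt_pool = 1, seed = 17, dt = 0.001)
  a2 <- simulate_trials(p, 30000, conf_rt_pool = 1, seed = 18, dt = 0.0005)
  expect_lt(abs(mean(a1$accuracy, na.rm = TRUE) -
                mean(a2$accuracy, na.rm = TRUE)), 0.01)
})
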