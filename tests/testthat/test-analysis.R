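# small subject table with controlled structure
make_subject_table <- function(n = 40, seed = 81, anx_effect = 0,
                               interaction = 0) {
  set.seed(seed)
  anx <- rnorm(n)
  gender <- rep(c("man", "woman"), length.out = n)
  g <- as.numeric(gender == "woman")
  rt <- rlnorm(n, log(1.5), 0.4)
  rtz <- (rt - mean(rt)) / sd(rt)
  conf <- anx_effect * anx + interaction * anx * rtz + rnorm(n, 0, 0.3)
  data.frame(subject_id = sprintf("s%02d", 1:n), dataset_id = "d1",
             task_id = "t1", conf_z = conf, rt_z = rnorm(n),
             difficulty_z = rnorm(n, 0, 0.1), med_conf_rt = rt,
             med_conf_rt_z = rtz, anxiety_z = anx, gender = gender,
             gender_num = g, age = runif(n, 18, 65))
}

test_that("the OLS engine agrees with hand-solved normal equations", {
  st <- make_subject_table(n = 5, seed = 82)
  res <- suppressWarnings(regress_confidence(st))  # 5 rows, near-perfect fit
  X <- cbind(1, st$anxiety_z, st$gender_num, st$age, st$difficulty_z)
  beta <- solve(t(X) %*% X, t(X) %*% st$conf_z)
  expect_equal(res$estimate, as.numeric(beta), tolerance = 1e-10)
  # duplicating every row leaves point estimates unchanged
  res2 <- suppressWarnings(regress_confidence(rbind(st, st)))
  expect_equal(res2$estimate, res$estimate, tolerance = 1e-10)
})

test_that("a planted anxiety-confidence coupling is recovered with its sign", {
  st <- make_subject_table(n = 80, seed = 83, anx_effect = -0.2)
  res <- regress_confidence(st)
  est <- res$estimate[res$term == "anxiety_z"]
  se <- res$se[res$term == "anxiety_z"]
  expect_lt(est, 0)
  expect_lt(abs(est - (-0.2)), 2 * se)
})

test_that("null cohorts give null-consistent factor terms in most replicates", {
  hits <- 0L
  for (s in 1:5) {
    st <- make_subject_table(n = 60, seed = 830 + s)
    res <- regress_time_interactions(st)
    tt <- abs(res$estimate / res$se)
    ok <- tt[res$term == "anxiety_z:med_conf_rt_z"] < 2 &&
          tt[res$term == "gender_num:med_conf_rt_z"] < 2
    hits <- hits + ok
  }
  expect_gte(hits, 4)
})

test_that("a planted time interaction appears in the interaction term", {
  st <- make_subject_table(n = 100, seed = 84, interaction = -0.25)
  res <- regress_time_interactions(st)
  expect_lt(res$estimate[res$term == "anxiety_z:med_conf_rt_z"], 0)
})

test_that("the 5-SD rule removes planted parameter outliers and nothing else", {
  set.seed(85)
  n <- 60
  ft <- data.frame(subject_id = sprintf("s%02d", 1:n), dataset_id = "d1",
                   task_id = "t1", anxiety_z = rnorm(n),
                   gender_num = rep(0:1, n / 2), age = runif(n, 18, 65),
                   v_ratio = rnorm(n, 0.8, 0.1), v_bias = rnorm(n, 0, 0.2),
                   a_bias = rnorm(n, 0, 0.3), m_bias = rnorm(n, 1, 0.2))
  clean <- regress_params_on_factors(ft)
  expect_equal(attr(clean$v_bias, "n_excluded"), 0L)
  spiked <- ft
  spiked$v_bias[1] <- mean(ft$v_bias) + 8 * sd(ft$v_bias)
  res <- regress_params_on_factors(spiked)
  expect_equal(attr(res$v_bias, "n_excluded"), 1L)
  expect_equal(attr(res$a_bias, "n_excluded"), 0L)
  # with no outliers, exclusion is a no-op
  expect_equal(clean$v_ratio$estimate,
               regress_params_on_factors(ft, sd_limit = 100)$v_ratio$estimate)
})

test_that("a planted anxiety-to-parameter coupling is recovered in sign", {
  set.seed(86)
  n <- 80
  anx <- rnorm(n)
  ft <- data.frame(subject_id = sprintf("s%02d", 1:n), dataset_id = "d1",
                   task_id = "t1", anxiety_z = anx,
                   gender_num = rep(0:1, n / 2), age = runif(n, 18, 65),
                   v_ratio = rnorm(n, 0.8, 0.1),
                   v_bias = -0.3 * anx + rnorm(n, 0, 0.2),
                   a_bias = rnorm(n, 0, 0.3), m_bias = rnorm(n, 1, 0.2))
  res <- regress_params_on_factors(ft)
  expect_lt(res$v_bias$estimate[res$v_bias$term == "anxiety_z"], 0)
})

test_that("time bins are equal-count with honest bootstrap intervals", {
  st <- make_subject_table(n = 60, seed = 87)
  bins <- bin_time_marginals(st, group = "anxiety_z", n_bins = 6,
                             n_boot = 300, seed = 2)
  per_bin <- tapply(bins$n, bins$bin, sum)
  expect_true(all(per_bin == 10))
  expect_true(all(bins$ci_lo <= bins$mean_conf & bins$mean_conf <= bins$ci_hi))
  # constant confidence: all means equal, zero-width intervals
  stc <- st
  stc$conf_z <- 0.37
  binc <- bin_time_marginals(stc, group = "anxiety_z", n_bins = 6,
                             n_boot = 100, seed = 2)
  expect_true(all(binc$mean_conf == 0.37))
  expect_true(all(binc$ci_hi - binc$ci_lo == 0))
})

test_that("rank-deficient designs fail loudly", {
  st <- make_subject_table(n = 30, seed = 88)
  st$difficulty_z <- st$anxiety_z     # perfectly collinear
  expect_error(regress_confidence(st), "collinear")
})
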