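test_that("survival presets respect class supports, weights and determinism", {
  supports <- list(c(0, 2), c(2, 5), c(5, Inf))
  for (preset in c("marginal", "clustered")) {
    d <- generate_survival_times(5000, preset, seed = 11)
    expect_true(all(d$survival_years > 0))
    for (cl in 1:3) {
      t_cl <- d$survival_years[d$true_class == cl]
      expect_true(all(t_cl > supports[[cl]][1] - 1e-12))
      expect_true(all(t_cl <= supports[[cl]][2] + 1e-12))
    }
    # class frequencies within binomial sampling error (4 sigma)
    w <- c(255, 124, 39) / 418
    freq <- tabulate(d$true_class, 3) / 5000
    expect_true(all(abs(freq - w) < 4 * sqrt(w * (1 - w) / 5000)))
  }
  one <- generate_survival_times(1, "marginal", seed = 5)
  expect_equal(nrow(one), 1L)
  expect_gt(one$survival_years, 0)
  expect_identical(generate_survival_times(100, "clustered", seed = 3),
                   generate_survival_times(100, "clustered", seed = 3))
  expect_false(identical(generate_survival_times(100, "clustered", seed = 3),
                         generate_survival_times(100, "clustered", seed = 4)))
})

test_that("marginal preset converges to the cohort's pooled quantiles", {
  d <- generate_survival_times(1e5, "marginal", seed = 21)
  q <- quantile(d$survival_years, c(0.25, 0.5, 0.75), type = 7)
  expect_equal(unname(q), c(0.61, 1.45, 3.27), tolerance = 0.1 / 1.45)
})

test_that("clustered preset class means match numeric integration", {
  d <- generate_survival_times(10000, "clustered", seed = 31)
  m_exp <- c(tnorm_mean_oracle(1.0, 0.35, 0, 2),
             tnorm_mean_oracle(3.4, 0.5, 2, 5),
             texp_mean_oracle(5, 0.8, 8))
  for (cl in 1:3) {
    t_cl <- d$survival_years[d$true_class == cl]
    se <- sd(t_cl) / sqrt(length(t_cl))
    expect_lt(abs(mean(t_cl) - m_exp[cl]), 4 * se)
  }
})

test_that("clustered preset true partition explains over 92% of variance", {
  ves <- vapply(1:20, function(s) {
    d <- generate_survival_times(418, "clustered", seed = 500 + s)
    compute_ve(d$survival_years, d$true_class)$ve
  }, numeric(1))
  expect_gt(mean(ves), 0.92)
})

test_that("malformed presets are rejected", {
  expect_error(survival_preset("bogus"))
  expect_error(survival_preset("marginal", class_weights = c(0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(
    survival_preset("marginal", class_generators = list(
      list(type = "plinear", u = c(0, 0.8, 0.4, 1), t = c(0, 1, 2, 3)),
      list(type = "plinear", u = c(0, 1), t = c(2, 5)),
      list(type = "texp", offset = 5, mean = 2, cap = Inf))),
    "monotone")
})

test_that("clinical covariates follow the class-conditional calibration", {
  # class 2: expected King's counts (62, 37, 21, 4) out of 124
  cl2 <- rep(2L, 124 * 50)
  cov2 <- generate_clinical_covariates(cl2, seed = 41)
  freq <- tabulate(cov2$kings_stage, 4) / length(cl2)
  p <- c(62, 37, 21, 4) / 124
  expect_true(all(abs(freq - p) < 4 * sqrt(p * (1 - p) / length(cl2))))
  # class 3 never draws King's stage 4
  cov3 <- generate_clinical_covariates(rep(3L, 5000), seed = 42)
  expect_false(any(cov3$kings_stage == 4))
  # deterministic under a fixed seed
  expect_identical(generate_clinical_covariates(rep(1:3, 20), seed = 9),
                   generate_clinical_covariates(rep(1:3, 20), seed = 9))
})

test_that("female fraction and age gradients run in the calibrated direction", {
  cov <- generate_clinical_covariates(rep(1:3, each = 4000), seed = 43)
  cls <- rep(1:3, each = 4000)
  f_frac <- tapply(cov$sex == "F", cls, mean)
  expect_true(all(diff(f_frac) > 0))
  age_mean <- tapply(cov$age_years, cls, mean)
  expect_true(all(diff(age_mean) < 0))
})

test_that("noiseless phantoms reproduce the planted construction exactly", {
  les <- data.frame(class_id = 1L, cx = 15, cy = 18, cz = 15,
                    radius = 4, effect = -0.1)
  cfg <- phantom_config(noise_sd = 0, severity_sd = 0, lesions = les)
  cohort <- data.frame(subject_id = "S1", true_class = 1L)
  ph <- generate_phantom_volumes(cfg, cohort, seed = 1)
  v <- ph$volumes[[1]]$data
  inside <- ph$lesion_truth[[1]]$mask
  expect_equal(unique(v[inside]), 0.9 * 100)
  expect_equal(unique(v[ph$mask$data & !inside]), 100)
  expect_true(all(v[!ph$mask$data] == 0))
})

test_that("null lesions leave class-conditional means identical up to noise", {
  les <- default_lesions()
  les$effect <- 0
  cfg <- phantom_config(lesions = les, noise_sd = 2)
  cohort <- data.frame(subject_id = sprintf("S%d", 1:30),
                       true_class = rep(1:3, each = 10))
  ph <- generate_phantom_volumes(cfg, cohort, seed = 7)
  means <- vapply(1:3, function(cl) {
    mean(sapply(which(cohort$true_class == cl),
                function(s) mean(ph$volumes[[s]]$data[ph$mask$data])))
  }, numeric(1))
  # noise-only variation: se of each class mean ~ 2/sqrt(10 * n_voxels)
  expect_lt(max(means) - min(means), 0.05)
})

test_that("ground-truth lesion extents match a brute-force voxel scan", {
  cfg <- phantom_config()
  dims <- cfg$grid_shape
  ph <- generate_phantom_volumes(cfg,
          data.frame(subject_id = "S1", true_class = 1L), seed = 1)
  for (lt in ph$lesion_truth) {
    cnt <- 0L
    for (i in 0:(dims[1] - 1)) for (j in 0:(dims[2] - 1)) for (k in 0:(dims[3] - 1))
      if ((i - lt$center[1])^2 + (j - lt$center[2])^2 + (k - lt$center[3])^2 <=
          lt$radius^2) cnt <- cnt + 1L
    expect_identical(lt$extent, cnt)
  }
  # default lesions are pairwise disjoint
  expect_false(ph$overlap_flag)
})

test_that("lesions escaping the mask are rejected at configuration", {
  expect_error(
    phantom_config(lesions = data.frame(class_id = 1L, cx = 2, cy = 2, cz = 2,
                                        radius = 4, effect = 0.1)),
    "not fully inside")
})

test_that("phantom volumes regenerate bit-identically under one seed", {
  cfg <- phantom_config(n_subjects = 3)
  cohort <- simulate_cohort(3, seed = 2)
  a <- generate_phantom_volumes(cfg, cohort, seed = 10)
  b <- generate_phantom_volumes(cfg, cohort, seed = 10)
  expect_identical(a$volumes[[3]]$data, b$volumes[[3]]$data)
  c <- generate_phantom_volumes(cfg, cohort, seed = 11)
  expect_false(identical(a$volumes[[3]]$data, c$volumes[[3]]$data))
})
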