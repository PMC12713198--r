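test_that("config validation names the offending field", {
  expect_error(cohort_config(n_eyes = 0), "n_eyes")
  expect_error(cohort_config(p_zero_rotation = 1.3), "p_zero_rotation")
  expect_error(cohort_config(rotation_max = -2), "rotation_max")
  expect_error(cohort_config(efficacy = 0), "efficacy")
  expect_error(cohort_config(noise_sd_1m = -0.1), "noise_sd_1m")
})

test_that("rotation sampler: zero-inflation, truncation and calibration", {
  set.seed(1)
  all_zero <- sample_rotation(200, cohort_config(p_zero_rotation = 1))
  expect_true(all(all_zero == 0))
  set.seed(2)
  x <- sample_rotation(20000, cohort_config())
  expect_true(all(x >= 0 & x <= 11))
  expect_equal(mean(x == 0), 27 / 153, tolerance = 0.1)
  expect_equal(mean(x), 2.44, tolerance = 0.05)
  expect_equal(sd(x), 1.93, tolerance = 0.06)
})

test_that("preop sampler honours truncation bounds and calibration", {
  set.seed(3)
  p <- sample_preop(20000, cohort_config())
  expect_true(all(p$sphere_D <= -0.25))
  expect_true(all(-p$cyl_D >= 0.75))  # inclusion floor on magnitude
  expect_true(all(p$axis_deg >= 0 & p$axis_deg < 180))
  # realized means equal the analytic truncated-normal means (the design
  # normals are pre-truncation; the inclusion floor shifts the cylinder up)
  a_sph <- (-0.25 - (-4.26)) / 1.46
  m_sph <- -4.26 - 1.46 * dnorm(a_sph) / pnorm(a_sph)
  expect_equal(mean(p$sphere_D), m_sph, tolerance = 0.05)
  a_cyl <- (0.75 - 1.10) / 0.70
  m_cyl <- 1.10 + 0.70 * dnorm(a_cyl) / (1 - pnorm(a_cyl))
  expect_equal(mean(-p$cyl_D), m_cyl, tolerance = 0.05)
})

test_that("cohort generation is deterministic given config seed", {
  cfg <- cohort_config(n_eyes = 40, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  tmp1 <- tempfile(fileext = ".csv")
  tmp2 <- tempfile(fileext = ".csv")
  write_cohort(a, tmp1)
  write_cohort(b, tmp2)
  expect_identical(readLines(tmp1), readLines(tmp2))
  expect_identical(unname(tools::md5sum(tmp1)), unname(tools::md5sum(tmp2)))
})

test_that("noise-free, full-efficacy cohorts reproduce the closed form exactly", {
  cfg <- cohort_config(n_eyes = 120, efficacy = 1, noise_sd_1m = 0,
                       noise_sd_3m = 0, quantize_step = 0, seed = 5)
  coh <- generate_cohort(cfg)
  C <- abs(coh$pre_cyl_D)
  expected <- 2 * C * sin(coh$rotation_deg * pi / 180)
  expect_equal(abs(coh$post1m_cyl_D), expected, tolerance = 1e-9)
  expect_equal(abs(coh$post3m_cyl_D), expected, tolerance = 1e-9)
  # visits coincide when there is no noise
  expect_equal(coh$post1m_axis_deg, coh$post3m_axis_deg, tolerance = 1e-9)

  zero_rot <- generate_cohort(cohort_config(n_eyes = 30, efficacy = 1,
                                            noise_sd_1m = 0, noise_sd_3m = 0,
                                            quantize_step = 0,
                                            p_zero_rotation = 1, seed = 6))
  expect_true(all(zero_rot$post3m_cyl_D == 0))
  expect_true(all(zero_rot$post3m_sphere_D == 0))
})

test_that("rotation-residual correlation matches the brute-force oracle on the same draw", {
  cfg <- cohort_config(n_eyes = 300, efficacy = 1, noise_sd_1m = 0,
                       noise_sd_3m = 0, quantize_step = 0, seed = 8)
  coh <- generate_cohort(cfg)
  r_pipe <- pearson_r(coh$rotation_deg, abs(coh$post3m_cyl_D))$r
  oracle <- cor(coh$rotation_deg,
                2 * abs(coh$pre_cyl_D) * sin(coh$rotation_deg * pi / 180))
  expect_equal(r_pipe, oracle, tolerance = 1e-12)
})

test_that("increasing noise weakens the rotation-residual correlation", {
  rs <- vapply(c(0, 0.15, 0.6), function(ns) {
    coh <- generate_cohort(cohort_config(n_eyes = 400, efficacy = 1,
                                         noise_sd_1m = ns, noise_sd_3m = ns,
                                         quantize_step = 0, seed = 99))
    pearson_r(coh$rotation_deg, abs(coh$post3m_cyl_D))$r
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("quantization rounds powers to the clinical step", {
  coh <- generate_cohort(cohort_config(n_eyes = 50, seed = 12))
  expect_true(all(abs(coh$post3m_cyl_D / 0.25 -
                        round(coh$post3m_cyl_D / 0.25)) < 1e-9))
  expect_true(all(coh$post3m_axis_deg == round(coh$post3m_axis_deg)))
})

test_that("CSV round trip preserves every field; centi-diopter flag rescales", {
  coh <- generate_cohort(cohort_config(n_eyes = 25, seed = 13))
  tmp <- tempfile(fileext = ".csv")
  write_cohort(coh, tmp)
  back <- read_cohort(tmp)
  expect_equal(as.data.frame(coh), as.data.frame(back), tolerance = 1e-12,
               ignore_attr = TRUE)
  cd <- tempfile(fileext = ".csv")
  write_cohort(coh, cd, centi_diopters = TRUE)
  disp <- utils::read.csv(cd)
  expect_equal(disp$pre_cyl_D, 100 * coh$pre_cyl_D, tolerance = 1e-9)
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(eye_id = "e1", rotation_deg = 2), bad,
                   row.names = FALSE)
  expect_error(read_cohort(bad), "missing required columns")
})

test_that("default cohort reproduces the study's headline descriptive statistics", {
  coh <- generate_cohort(cohort_config(seed = 20))
  s <- cohort_summary(coh)
  val <- function(k) s$value[s$statistic == k]
  expect_equal(val("n_eyes"), 153)
  expect_gt(val("rotation_incidence_pct"), 70)
  expect_lt(val("rotation_incidence_pct"), 95)
  expect_equal(val("rotation_mean_deg"), 2.44, tolerance = 0.5)
  expect_equal(val("sphere_mean_D"), -4.26, tolerance = 0.5)
  expect_equal(val("cyl_mean_D"), 1.46, tolerance = 0.25)  # truncated-normal mean
  # systematic undercorrection leaves a small mean residual
  expect_gt(val("residual_3m_mean_D"), 0.05)
  expect_lt(val("residual_3m_mean_D"), 0.6)
})
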