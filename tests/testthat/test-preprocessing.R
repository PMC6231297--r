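make_vol <- function(data, id = "s") brain_volume(data, id)

test_that("histogram matching: fixed point, shift removal, monotonicity", {
  set.seed(1)
  tpl <- make_vol(array(rnorm(20^3, 100, 15), c(20, 20, 20)), "tpl")
  # subject identical to template -> unchanged (up to interpolation)
  same <- match_histogram(tpl, tpl)
  expect_lt(max(abs(same$data - tpl$data)), 1e-6)

  # uniform +100 shift: output quantiles realign with the template's
  shifted <- make_vol(tpl$data + 100, "sub")
  matched <- match_histogram(shifted, tpl)
  qs <- quantile(matched$data, c(.05, .25, .5, .75, .95))
  qt <- quantile(tpl$data, c(.05, .25, .5, .75, .95))
  expect_lt(max(abs(qs - qt)), 0.5)

  # monotone map: voxel ordering preserved
  o1 <- order(shifted$data); o2 <- order(matched$data)
  expect_true(all(diff(matched$data[o1]) >= -1e-12))
  expect_identical(matched$subject_id, "sub")

  expect_error(match_histogram(make_vol(array(5, c(20, 20, 20))), tpl),
               "constant")
  expect_error(match_histogram(make_vol(array(1, c(4, 4, 4))), tpl),
               "different grids")
})

test_that("voxelwise aging fit recovers exact linear relations", {
  ages <- c(60, 70, 80, 90)
  # volume where every voxel follows y = 2*age + 5 exactly
  vols <- lapply(ages, function(a) make_vol(array(2 * a + 5, c(6, 6, 6))))
  m <- fit_age_correction(vols, ages)
  expect_equal(max(abs(m$slope - 2)), 0, tolerance = 1e-10)
  expect_equal(max(abs(m$intercept - 5)), 0, tolerance = 1e-9)
  expect_equal(m$reference_age, 75)   # default reference age

  # identical volumes across ages -> zero slope, correction is identity
  vols0 <- lapply(ages, function(a) make_vol(array(7, c(5, 5, 5))))
  m0 <- fit_age_correction(vols0, ages)
  expect_equal(max(abs(m0$slope)), 0, tolerance = 1e-12)
  v <- make_vol(array(7, c(5, 5, 5)))
  expect_equal(apply_age_correction(m0, v, 90)$data, v$data)

  expect_error(fit_age_correction(vols[1:2], ages[1:2]), "at least 3")
  expect_error(fit_age_correction(vols0, rep(70, 4)), "identical")
})

test_that("correction formula y' = w*(C - age) + y evaluates as printed", {
  shape <- c(4L, 4L, 4L)
  model <- structure(list(slope = rep(2, prod(shape)),
                          intercept = rep(5, prod(shape)),
                          reference_age = 75, shape = shape,
                          mask_index = NULL),
                     class = "age_correction_model")
  v <- make_vol(array(165, shape))
  out <- apply_age_correction(model, v, 80)
  expect_equal(unique(as.vector(out$data)), 155)   # 2*(75-80) + 165

  # subject at exactly C is unchanged
  expect_equal(apply_age_correction(model, v, 75)$data, v$data)
})

test_that("aging model fit on a cohort nulls its own slopes after correction", {
  cfg <- synthetic_config(n_per_group = c(AD = 0, NC = 12, MCIc = 0, MCInc = 0),
                          age_slope = -0.006, noise_sd = 0, seed = 4)
  co <- generate_cohort(cfg)
  ages <- co$records$age
  m <- fit_age_correction(co$volumes, ages)
  corrected <- lapply(seq_along(co$volumes), function(i)
    apply_age_correction(m, co$volumes[[i]], ages[i]))
  m2 <- fit_age_correction(corrected, ages)
  expect_lt(max(abs(m2$slope)), 1e-10)
})

test_that("correction is linear in (C - age): negated slopes un-correct", {
  cfg <- tiny_synth(seed = 13)
  co <- generate_cohort(cfg)
  nc <- which(co$records$group == "NC")
  m <- fit_age_correction(co$volumes[nc], co$records$age[nc])
  v <- co$volumes[[1]]; age <- co$records$age[1]
  corrected <- apply_age_correction(m, v, age)
  m_neg <- m; m_neg$slope <- -m$slope
  restored <- apply_age_correction(m_neg, corrected, age)
  expect_equal(restored$data, v$data, tolerance = 1e-12)
})

test_that("feature-level age correction fits on NC and applies to all rows", {
  set.seed(6)
  n <- 40
  records <- data.frame(
    subject_id = sprintf("s%02d", 1:n),
    group = factor(rep(c("NC", "MCIc"), each = n / 2), levels = GROUP_LEVELS),
    age = runif(n, 55, 91))
  # col 1: exact trend 0.5*age; col 2: no trend
  fm <- feature_matrix(cbind(0.5 * records$age, rep(3, n)),
                       records$subject_id, c("trend", "flat"))
  out <- fit_and_apply_feature_age_correction(fm, records)
  expect_equal(unique(round(out[, "trend"], 9)), 0.5 * 75)
  expect_equal(out[, "flat"], fm[, "flat"])

  # after correction the NC slope of every column is ~0
  nc <- records$group == "NC"
  slopes <- apply(out[nc, ], 2, function(col) coef(lm(col ~ records$age[nc]))[2])
  expect_lt(max(abs(slopes)), 1e-10)

  few <- records[c(1, 2, 21, 22), ]
  expect_error(fit_and_apply_feature_age_correction(fm[c(1, 2, 21, 22), ], few),
               "at least 3 NC")
})
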