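test_that("calibration sets have the requested size and variance structure", {
  spec <- subject_spec(seed = 1)
  cal <- generate_calibration(spec)
  expect_equal(dim(cal$signals), c(8, 5000))
  expect_equal(cal$sample_rate, 75)
  # top-2 variance share emulates the study's calibration statistic
  shares <- vapply(1:5, function(sd)
    build_map_pca(generate_calibration(subject_spec(seed = sd)), 2)$variance_share,
    0)
  expect_true(all(abs(shares - 0.73) < 0.05))
})

test_that("a near rank-1 babbling spectrum yields a dominant first component", {
  spec <- subject_spec(seed = 3, babble_spectrum = c(1, rep(1e-9, 7)))
  map <- build_map_pca(generate_calibration(spec), 1)
  expect_gt(map$variance_share, 0.999)
})

test_that("synthetic subjects are reproducible and measurement noise only touches logs", {
  spec <- subject_spec(seed = 4)
  s1 <- generate_subject(spec)
  s2 <- generate_subject(spec)
  expect_identical(s1$log, s2$log)
  expect_identical(s1$map$H, s2$map$H)
  # zero measurement noise: logged q equals the dynamics' q bit-exactly
  expect_identical(s1$log, s1$session$log)
  specn <- subject_spec(seed = 4, measurement_noise_sd = 0.1)
  sn <- generate_subject(specn)
  qcols <- paste0("q", 1:8)
  other <- setdiff(names(sn$log), qcols)
  expect_identical(sn$log[other], sn$session$log[other])
  expect_false(identical(sn$log[qcols], sn$session$log[qcols]))
  expect_identical(sn$session$log, s1$session$log)  # dynamics untouched
})

test_that("cohorts are distinct, reproducible, and round-trip through CSV", {
  co <- make_cohort(4, master_seed = 7)
  co2 <- make_cohort(4, master_seed = 7)
  expect_equal(length(co), 4)
  maps <- vapply(co, function(s) s$map$H[1, 1], 0)
  expect_equal(length(unique(maps)), 4)
  expect_identical(lapply(co, `[[`, "log"), lapply(co2, `[[`, "log"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_log_csv(co[[1]], path)
  back <- read_trial_log_csv(path)
  keep <- !grepl("^xi", names(co[[1]]$log))
  expect_equal(as.data.frame(back), as.data.frame(co[[1]]$log[, keep]),
               tolerance = 1e-12)
})

test_that("subject parameters are drawn within the declared ranges", {
  specs <- lapply(1:20, function(i) subject_spec(seed = i * 13))
  eta <- vapply(specs, function(s) s$params$eta, 0)
  eps <- vapply(specs, function(s) s$params$epsilon, 0)
  sig <- vapply(specs, function(s) s$params$sigma, 0)
  expect_true(all(eta >= 0.006 & eta <= 0.036))
  expect_true(all(eps >= 0.15 & eps <= 0.25))
  expect_true(all(sig >= 0.65 & sig <= 0.83))
})

test_that("trials to criterion sit at the study's scale", {
  subs <- lapply(1:6, function(i) {
    spec <- subject_spec(params = learner_params(subject_table$eta[i],
                                                 subject_table$epsilon[i],
                                                 subject_table$sigma[i],
                                                 seed = i),
                         seed = i)
    generate_subject(spec)
  })
  ttc <- vapply(subs, function(s) as.numeric(s$session$trials_to_criterion), 0)
  ttc[is.na(ttc)] <- Inf  # did not plateau within the session
  expect_gte(sum(is.finite(ttc)), 4)
  expect_gte(median(ttc), 50)
  expect_lte(median(ttc), 350)
})
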