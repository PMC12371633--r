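test_that("the null generator emits identical pre/post spectra up to noise", {
  cfg <- cohort_config(n_responders = 2, n_nonresponders = 2,
                       effects = list(), between_sd = 0, noise_sd = 0,
                       seed = 7)
  gen <- generate_cohort(cfg)
  meta <- gen$dataset$meta
  for (pat in unique(meta$patient)) {
    pre <- gen$dataset$spectra[[which(meta$patient == pat & meta$condition == "pre")]]
    post <- gen$dataset$spectra[[which(meta$patient == pat & meta$condition == "post")]]
    expect_equal(pre$values, post$values)
  }
  # all-null cohort: every patient generates from the defaults
  expect_equal(gen$dataset$spectra[[1]]$values,
               predict_spectrum(default_parameters())$values)
})

test_that("generation is deterministic and serializes byte-for-byte", {
  g1 <- generate_cohort(cohort_config(n_responders = 2, n_nonresponders = 2,
                                      seed = 12))
  g2 <- generate_cohort(cohort_config(n_responders = 2, n_nonresponders = 2,
                                      seed = 12))
  expect_identical(g1$dataset$spectra, g2$dataset$spectra)
  expect_identical(g1$ground_truth$theta, g2$ground_truth$theta)
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  cohort_manifest(g1$dataset, d1)
  cohort_manifest(g2$dataset, d2)
  f1 <- setdiff(list.files(d1, full.names = TRUE),
                file.path(d1, "manifest.csv"))
  f2 <- setdiff(list.files(d2, full.names = TRUE),
                file.path(d2, "manifest.csv"))
  expect_equal(basename(f1), basename(f2))
  for (k in seq_along(f1))
    expect_identical(readBin(f1[k], "raw", file.size(f1[k])),
                     readBin(f2[k], "raw", file.size(f2[k])))
})

test_that("ground truth reconstructs from effects plus recorded deviations", {
  cfg <- cohort_config(n_responders = 2, n_nonresponders = 1, seed = 19)
  gen <- generate_cohort(cfg)
  meta <- gen$dataset$meta
  beta <- gen$ground_truth$beta
  vn <- cmc_variable_names()
  for (pat in unique(meta$patient)) {
    rows <- which(meta$patient == pat)
    r <- if (meta$group[rows[1]] == "responder") 1 else -1
    th_pre <- gen$ground_truth$theta[[rows[meta$condition[rows] == "pre"]]][vn]
    th_post <- gen$ground_truth$theta[[rows[meta$condition[rows] == "post"]]][vn]
    # the deviation cancels in the within-patient difference
    expect_equal(th_post - th_pre,
                 drop(c(0, 0, 2, 2 * r) %*% beta),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("default cohort shifts responder delta power downward after treatment", {
  gen <- generate_cohort(cohort_config(seed = 3))
  meta <- gen$dataset$meta
  dp <- vapply(seq_len(nrow(meta)), function(i)
    band_power(gen$dataset$spectra[[i]], "delta"), numeric(1))
  pre <- mean(dp[meta$group == "responder" & meta$condition == "pre"])
  post <- mean(dp[meta$group == "responder" & meta$condition == "post"])
  expect_lt(post, pre)
})

test_that("manifests have one row per first-level model and round-trip", {
  gen <- generate_cohort(cohort_config(seed = 5))
  man <- cohort_manifest(gen$dataset)
  expect_equal(nrow(man), 34)   # 8 + 9 patients, two conditions each
  g1 <- generate_cohort(cohort_config(n_responders = 1, n_nonresponders = 1,
                                      seed = 6))
  d <- file.path(tempdir(), "coh_rt")
  man1 <- cohort_manifest(g1$dataset, d)
  expect_equal(nrow(man1), 4)
  back <- utils::read.csv(file.path(d, "manifest.csv"))
  expect_equal(back$patient, man1$patient)
  expect_equal(back$condition, man1$condition)
  sp <- read_spectrum_csv(man1$path[1])
  expect_equal(sp$values, g1$dataset$spectra[[1]]$values)
})

test_that("unknown effect names and invalid configs are rejected", {
  expect_error(cohort_config(effects = list(resp = c(not_a_param = 1))),
               "unknown")
  expect_error(cohort_config(n_responders = 0), "n_responders")
})

test_that("time-series mode emits event-annotated continuous recordings", {
  cfg <- cohort_config(n_responders = 1, n_nonresponders = 1,
                       mode = "timeseries", seed = 9)
  gen <- generate_cohort(cfg)
  recs <- gen$dataset$recordings
  expect_length(recs, 2)
  expect_equal(length(recs[[1]]$signal) / recs[[1]]$fs, 1260)
  expect_true("bzp_admin" %in% recs[[1]]$events$label)
  expect_true("se_termination" %in% recs[[1]]$events$label)  # responder
  expect_false("se_termination" %in% recs[[2]]$events$label) # nonresponder
  # the epoch rules apply directly to the generated recording
  ep <- extract_medication_epochs(recs[[1]], "responder")
  expect_equal(length(ep$pre$signal) / 256, 300)
})
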