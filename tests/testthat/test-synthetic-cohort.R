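test_that("simulated subjects follow the stated distributions", {
  spec <- region_spec(1:3, mu = c(1, 1, 1), sigma = c(0.1, 0.1, 0.1), n_voxels = 500)
  s <- simulate_subject(spec, jitter_sd = 0, seed = 1)
  expect_equal(s$R, 3)
  expect_true(all(vapply(s$samples, length, 1L) == 500))
  # law of large numbers: sample means within 3*sigma/sqrt(n) of mu
  expect_true(all(abs(s$mean_uptake - 1) < 3 * 0.1 / sqrt(500)))

  # degenerate noise: sigma tiny, no jitter -> means equal mu to 1e-4
  tiny <- region_spec(1:3, mu = c(0.8, 1.0, 1.2), sigma = rep(1e-6, 3),
                      n_voxels = 100)
  st <- simulate_subject(tiny, jitter_sd = 0, seed = 7)
  expect_true(all(abs(st$mean_uptake - c(0.8, 1.0, 1.2)) < 1e-4))

  # determinism: same seed twice is bit-identical
  s2 <- simulate_subject(spec, jitter_sd = 0.05, seed = 11)
  s3 <- simulate_subject(spec, jitter_sd = 0.05, seed = 11)
  expect_identical(s2$samples, s3$samples)

  # lognormal alternative stays positive
  sl <- simulate_subject(spec, seed = 3, family = "lognormal")
  expect_true(all(unlist(sl$samples) > 0))
})

test_that("region spec validation rejects degenerate inputs", {
  expect_error(region_spec(1:2, mu = c(1, 1), sigma = c(0.1, 0), n_voxels = 100),
               "sigma")
  expect_error(region_spec(c(1, 1), mu = c(1, 1), sigma = c(0.1, 0.1),
                           n_voxels = 100), "unique")
  expect_error(region_spec(1:2, mu = c(1, 1), sigma = c(0.1, 0.1), n_voxels = 5),
               "n_voxels")
})

test_that("cohorts honour group sizes and inject differences only where asked", {
  base <- gauss_region_spec(4, n_voxels = 120)
  cs <- cohort_spec(base, groups = list(A = list(n = 2), B = list(n = 2)),
                    jitter_sd = 0, seed = 5)
  cohort <- simulate_cohort(cs)
  expect_equal(nrow(cohort), 4)
  expect_equal(as.integer(table(cohort$group)[c("A", "B")]), c(2L, 2L))

  # identical seeds give byte-identical cohorts
  cohort2 <- simulate_cohort(cs)
  expect_identical(
    lapply(cohort$subject, `[[`, "samples"),
    lapply(cohort2$subject, `[[`, "samples")
  )

  # difference appears only in the overridden region
  shift <- cohort_spec(
    base,
    groups = list(
      A = list(n = 12),
      B = list(n = 12, override = tibble::tibble(region_id = 2, mu = base$mu[2] + 0.3))
    ),
    jitter_sd = 0, seed = 9
  )
  ch <- simulate_cohort(shift)
  mu_hat <- vapply(ch$subject, function(s) s$mean_uptake, numeric(4))
  diff <- rowMeans(mu_hat[, ch$group == "B"]) - rowMeans(mu_hat[, ch$group == "A"])
  expect_gt(diff[2], 0.25)
  expect_true(all(abs(diff[-2]) < 0.02))

  expect_error(cohort_spec(base, groups = list(A = list(n = 1))), "n >= 2")
})

test_that("conversion times follow the proportional-hazards generator", {
  set.seed(21)
  feats <- tibble::tibble(subject_id = sprintf("s%03d", 1:500), f1 = rnorm(500))

  # single feature, beta = log(2) per SD: fitted HR near 2
  hz <- hazard_spec(c(f1 = log(2)), baseline_rate = 1 / 40, censor_time = 60)
  rec <- simulate_conversion(feats, hz, seed = 2)
  expect_true(all(rec$time_months <= 60))
  fit <- fit_cox(cbind(rec, f1 = feats$f1), "f1")
  expect_gt(fit$coefficients$hazard_ratio, 1.6)
  expect_lt(fit$coefficients$hazard_ratio, 2.5)

  # null betas: fitted coefficient within 3 SE of zero
  hz0 <- hazard_spec(c(f1 = 0), baseline_rate = 1 / 40, censor_time = 60)
  rec0 <- simulate_conversion(feats, hz0, seed = 3)
  fit0 <- fit_cox(cbind(rec0, f1 = feats$f1), "f1")
  expect_lt(abs(fit0$coefficients$estimate), 3 * fit0$coefficients$std_error)

  # extreme censoring: nearly everything censored
  hzc <- hazard_spec(c(f1 = 0), baseline_rate = 1 / 40, censor_time = 0.04)
  recc <- simulate_conversion(feats, hzc, seed = 4)
  expect_lt(mean(recc$event), 0.01)

  expect_error(
    simulate_conversion(feats, hazard_spec(c(nope = 1), 0.1, 10), seed = 1),
    "nope"
  )
})

test_that("NIfTI fixtures round-trip losslessly through parcellation", {
  spec <- region_spec(1:3, mu = c(0.9, 1.0, 1.1), sigma = rep(0.05, 3),
                      n_voxels = 64)
  s <- simulate_subject(spec, seed = 13, subject_id = "rt")
  layout <- block_atlas_layout(3, 64, dim = c(12, 12, 12))
  expect_equal(as.integer(table(as.vector(layout$labels))[c("1", "2", "3")]),
               rep(64L, 3))

  dir <- withr::local_tempdir()
  paths <- write_nifti_fixture(s, layout, dir)
  back <- load_parcellation(paths["pet"], paths["atlas"], subject_id = "rt")
  for (r in c("1", "2", "3")) {
    expect_equal(sort(back$samples[[r]]), sort(s$samples[[r]]), tolerance = 1e-6)
  }
  # background voxels (label 0) never leak into any region
  expect_equal(sum(vapply(back$samples, length, 1L)), 3 * 64)

  # a NaN voxel in region 2 is excluded
  vol <- RNifti::readNifti(paths["pet"])
  idx2 <- which(as.vector(layout$labels) == 2L)[1]
  vol[idx2] <- NaN
  RNifti::writeNifti(vol, paths[["pet"]])
  back2 <- load_parcellation(paths["pet"], paths["atlas"])
  expect_length(back2$samples[["2"]], 63)
  expect_length(back2$samples[["1"]], 64)

  expect_error(block_atlas_layout(3, 200, dim = c(4, 4, 4)), "too small")
})

test_that("larger injected shifts produce larger targeted edge statistics", {
  # effect propagation: median |t| of the targeted edge grows with the shift
  R <- 4
  base <- gauss_region_spec(R, n_voxels = 150)
  med_t <- vapply(c(0, 0.3, 0.8), function(shift) {
    tt <- vapply(1:6, function(rep) {
      cs <- cohort_spec(
        base,
        groups = list(
          A = list(n = 6),
          B = list(n = 6, override = tibble::tibble(
            region_id = 1, mu = base$mu[1] + shift * base$sigma[1]
          ))
        ),
        jitter_sd = 0.01, seed = 1000 * shift + rep
      )
      ch <- simulate_cohort(cs)
      ch$subject <- lapply(ch$subject, global_normalize)
      nets <- lapply(ch$subject, klse_connectome)
      pat <- edgewise_difference(nets[ch$group == "A"], nets[ch$group == "B"])
      abs(pat$t_stat[1, 2])
    }, numeric(1))
    median(tt)
  }, numeric(1))
  expect_true(med_t[1] < med_t[2] && med_t[2] < med_t[3])
})
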