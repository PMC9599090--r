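test_that("ground-truth networks are deterministic, PSD and hub-structured", {
  net <- generate_ground_truth_network(20, hub_exponent = 2, seed = 5)
  net2 <- generate_ground_truth_network(20, hub_exponent = 2, seed = 5)
  expect_identical(net$covariance, net2$covariance)
  expect_true(plfcs:::is_psd(net$covariance))
  expect_true(all(diag(net$covariance) > 0))
  expect_equal(net$covariance, t(net$covariance))

  # hubness is the node strength of the implied correlation matrix
  r <- cov2cor(net$covariance); diag(r) <- 0
  expect_equal(net$hubness, rowSums(abs(r)))

  # two nodes: symmetry forces identical hubness equal to |r12|
  n2 <- generate_ground_truth_network(2, hub_exponent = 3, seed = 1)
  r12 <- cov2cor(n2$covariance)[1, 2]
  expect_equal(unname(n2$hubness), rep(abs(r12), 2))

  # larger exponent spreads hubness (same seed)
  cv <- function(x) sd(x) / mean(x)
  flat <- generate_ground_truth_network(40, hub_exponent = 0, seed = 9)
  steep <- generate_ground_truth_network(40, hub_exponent = 2, seed = 9)
  expect_lt(cv(flat$hubness), cv(steep$hubness))

  expect_error(generate_ground_truth_network(1), "n_regions")
})

test_that("subject time series match the generating covariance", {
  net <- generate_ground_truth_network(6, hub_exponent = 1.5, seed = 3)
  ts <- simulate_subject_timeseries(net, 10000, noise_sd = 0, seed = 8)
  ts2 <- simulate_subject_timeseries(net, 10000, noise_sd = 0, seed = 8)
  expect_identical(ts$data, ts2$data)

  truth <- cov2cor(net$covariance)
  sample_r <- cor(ts$data)
  expect_lt(max(abs(sample_r - truth)), 0.05)

  # diagonal covariance: independent columns
  dnet <- plfcs:::new_ground_truth_network(diag(2, 5))
  dts <- simulate_subject_timeseries(dnet, 4000, seed = 2)
  r <- cor(dts$data); diag(r) <- 0
  expect_lt(max(abs(r)), 3 / sqrt(4000))

  expect_error(simulate_subject_timeseries(net, 1), "n_timepoints")
})

test_that("hub-proportional attenuation weakens hubs and preserves validity", {
  net <- generate_ground_truth_network(25, hub_exponent = 2, seed = 4)
  att <- attenuate_network(net, 0.5)
  expect_true(plfcs:::is_psd(att$covariance))
  expect_equal(diag(att$covariance), diag(net$covariance))
  expect_true(all(att$attenuation >= 0 & att$attenuation <= 1))
  # every node's designed strength shrinks, hubs shrink proportionally more
  mu0 <- designed_strength(net)
  mu1 <- designed_strength(att)
  expect_true(all(mu1 <= mu0 + 1e-12))
  loss <- (mu1 - mu0) / mu0
  expect_lt(cor(mu0, loss), -0.5)
  expect_error(attenuate_network(net, -1), "beta")
})

test_that("cohorts encode the designed group structure", {
  spec <- tiny_spec(n_regions = 16, n = 3, n_timepoints = 40, seed = 21,
                    beta = c(MCI = 0.2, AD = 0.4))
  b <- simulate_cohort(spec)
  b2 <- simulate_cohort(spec)
  expect_identical(b$suvr, b2$suvr)
  expect_identical(b$timeseries[["AD_02"]]$data,
                   b2$timeseries[["AD_02"]]$data)

  # designed mean strength ordering NC > MCI > AD
  ds <- rowMeans(b$designed$group_strength)
  expect_gt(ds[["NC"]], ds[["MCI"]])
  expect_gt(ds[["MCI"]], ds[["AD"]])

  # no attenuation -> designed loss identically 0
  b0 <- simulate_cohort(tiny_spec(n_regions = 10, n = 2, n_timepoints = 20,
                                  seed = 3, beta = c(MCI = 0, AD = 0)))
  expect_equal(max(abs(b0$designed$group_loss)), 0)
  expect_equal(max(abs(b0$designed$subject_loss)), 0)

  # rho = +1 everywhere: designed loss and designed tau mean perfectly
  # rank-correlated at the ground-truth (noise-free) level
  spec_r <- tiny_spec(n_regions = 10, n = 2, n_timepoints = 20, seed = 3,
                      rho_region = rep(1, 10), suvr_noise_sd = 0)
  br <- simulate_cohort(spec_r)
  tau_mean_ad <- colMeans(br$suvr[br$manifest$group == "AD", ])
  loss_ad <- colMeans(
    br$designed$subject_loss[br$manifest$group == "AD", ])
  expect_equal(cor(tau_mean_ad, loss_ad, method = "spearman"), 1)

  # clinical scores move with disease burden and stay in range
  mm <- tapply(b$manifest$mmse, b$manifest$group, mean)
  cd <- tapply(b$manifest$cdr_sb, b$manifest$group, mean)
  expect_gt(mm[["NC"]], mm[["AD"]])
  expect_lt(cd[["NC"]], cd[["AD"]])
  expect_true(all(b$manifest$mmse >= 0 & b$manifest$mmse <= 30))
  expect_true(all(b$manifest$cdr_sb >= 0 & b$manifest$cdr_sb <= 18))
})

test_that("cohort specs validate their invariants", {
  expect_error(cohort_spec(n_regions = 1), "n_regions")
  expect_error(tiny_spec(beta = c(MCI = -0.1, AD = 0.2)), "beta")
  expect_error(tiny_spec(n_regions = 6, rho_region = rep(2, 6)),
               "rho_region")
  expect_error(cohort_spec(n_subjects = c(NC = 1, MCI = 2, AD = 2)),
               "group sizes")
})

test_that("rendered volumes round-trip through atlas extraction", {
  spec <- tiny_spec(n_regions = 4, n = 2, n_timepoints = 12, seed = 6)
  b <- simulate_cohort(spec)
  out <- withr::local_tempdir()
  geom <- make_toy_geometry(4, voxels_per_region = 3)
  man <- render_volumes(b, geom, out, voxel_noise_sd = 0,
                        reference_uptake = 5)
  atlas <- load_atlas(man$atlas, man$table)
  expect_equal(nrow(atlas$table), 4)

  sid <- "MCI_01"
  ts <- extract_roi_timeseries(man$func[[sid]], atlas, subject_id = sid)
  expect_lt(max(abs(ts$data - b$timeseries[[sid]]$data)), 1e-6)

  means <- extract_roi_means(man$pet[[sid]], atlas)
  ref <- extract_mask_mean(man$pet[[sid]], man$reference_mask)
  expect_equal(ref, 5)
  sv <- compute_suvr(means, ref, subject_id = sid)
  expect_lt(max(abs(sv$values - b$suvr[sid, ])), 1e-6)

  # a region with zero voxels is rejected up front
  bad_geom <- geom
  bad_geom$labels[bad_geom$labels == 2] <- 1L
  expect_error(render_volumes(b, bad_geom, out), "zero voxels")
})
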