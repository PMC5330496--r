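test_that("resampling collapses to the direct value when the pool is the sample", {
  set.seed(12)
  cm <- random_cm(6, 40)
  rs <- beta_sample(cm, rownames(cm), sample_size = 6L, n_samples = 25L, seed = 1)
  direct <- multisite_sorensen_family(cm)
  expect_equal(unname(rs$mean["beta_sor"]), direct$beta_sor)
  expect_equal(unname(rs$mean["beta_sim"]), direct$beta_sim)
  expect_equal(unname(rs$sd), rep(0, 4))
  expect_equal(unname(rs$mean["beta_w_minus1"]), whittaker_beta(cm)$beta_w_minus1)
})

test_that("resampling is deterministic under a fixed seed and errors on a small pool", {
  set.seed(13)
  cm <- random_cm(8, 30)
  a <- beta_sample(cm, sample_size = 4L, n_samples = 30L, seed = 99)
  b <- beta_sample(cm, sample_size = 4L, n_samples = 30L, seed = 99)
  expect_identical(a, b)
  expect_error(beta_sample(cm, sample_size = 9L, n_samples = 2L), "smaller")
  expect_error(beta_sample(cm, c(rownames(cm), "ghost"), 4L), "absent")
})

test_that("resampled means match exhaustive subset enumeration", {
  set.seed(14)
  cm <- random_cm(6, 30)
  subsets <- utils::combn(rownames(cm), 4L)
  exact <- rowMeans(apply(subsets, 2L, function(ids) {
    ms <- multisite_sorensen_family(cm[ids, , drop = FALSE])
    c(ms$beta_sor, ms$beta_sim)
  }))
  rs <- beta_sample(cm, sample_size = 4L, n_samples = 10000L, seed = 3)
  mc_se <- rs$sd / sqrt(rs$n_samples)
  expect_lt(abs(rs$mean[["beta_sor"]] - exact[1L]), 3 * mc_se[["beta_sor"]])
  expect_lt(abs(rs$mean[["beta_sim"]] - exact[2L]), 3 * mc_se[["beta_sim"]])
})

test_that("per-location dissimilarities are zero for identical communities", {
  st <- toy_site_table(paste0("q", 1:8),
                       lon = rep(c(118, 118.01, 119, 119.01), each = 2),
                       lat = rep(c(-34, -33, -32, -31), each = 2),
                       location = rep(1:4, each = 2))
  m <- matrix(rep(c(1L, 1L, 0L, 1L), 8), 8, byrow = TRUE,
              dimnames = list(paste0("q", 1:8), paste0("sp", 1:4)))
  lb <- location_betas(as_community_matrix(m), st)
  expect_equal(nrow(lb), 4L)
  expect_equal(lb$beta_sor, rep(0, 4))
  expect_equal(lb$beta_w_minus1, rep(0, 4))
  expect_equal(lb$location_id, 1:4)
})

test_that("latitudinal trend test recovers exact fits and degenerate cases", {
  lat <- seq(-34, -27, length.out = 10)
  flat <- beta_latitude_trend(rep(0.8, 10), lat)
  expect_equal(flat$slope, 0)
  expect_equal(flat$F, 0)
  # a perfect linear trend (lm warns about the perfect fit; expected here)
  exact <- suppressWarnings(beta_latitude_trend(0.5 + 0.02 * lat, lat))
  expect_equal(exact$slope, 0.02)
  expect_lt(exact$p_value, 1e-12)
  expect_equal(exact$df, c(1L, 8L))
  expect_error(beta_latitude_trend(runif(10), rep(-30, 10)), "constant")
  expect_error(beta_latitude_trend(c(.1, .2), c(-30, -29)), "at least 3")
})

test_that("latitudinal F-test holds its nominal size under the null", {
  set.seed(15)
  reps <- 2000
  p <- vapply(seq_len(reps), function(i)
    beta_latitude_trend(rnorm(10, 0.8, 0.05), seq(-34, -27, length.out = 10))$p_value,
    numeric(1))
  # binomial 3-sigma band around 0.05 at 2000 draws
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("extent profile rows follow the nested design protocol", {
  scen <- generate_scenario(seed = 6, occurrences = FALSE)
  prof <- incremental_extent_profile(scen$community, scen$sites,
                                     n_samples = 30L, seed = 11)
  expect_s3_class(prof, "extent_profile")
  expect_equal(nrow(prof), 3L + 9L)
  # anchor extents of the within-location rows
  expect_equal(prof$extent_km[1:3], c(0.141, 1.5, 10.5))
  expect_true(all(diff(prof$extent_km) > 0))
  # decomposition identity survives averaging because components are
  # averaged per replicate
  expect_equal(prof$beta_nes_mean,
               prof$beta_sor_mean - prof$beta_sim_mean)
  expect_equal(prof$n_quadrats_per_sample[1L], 4)
  expect_true(all(prof$n_quadrats_per_sample[-(1:2)] == 16))
  # reproducible under the same seed
  prof2 <- incremental_extent_profile(scen$community, scen$sites,
                                      n_samples = 30L, seed = 11)
  expect_identical(prof, prof2)
})

test_that("reversed extent profile covers the same maximal extent", {
  scen <- generate_scenario(seed = 6, occurrences = FALSE)
  s2n <- incremental_extent_profile(scen$community, scen$sites,
                                    n_samples = 20L, seed = 1)
  n2s <- incremental_extent_profile(scen$community, scen$sites,
                                    n_samples = 20L,
                                    direction = "north_to_south", seed = 1)
  expect_equal(max(s2n$extent_km), max(n2s$extent_km), tolerance = 1e-9)
  expect_equal(unique(n2s$direction), "north_to_south")
})

test_that("extent profile is flat at zero for identical communities", {
  scen <- generate_scenario(seed = 6, occurrences = FALSE)
  m <- matrix(rep(c(1L, 0L, 1L, 1L, 0L), each = 160), 160,
              dimnames = list(scen$sites$quadrat_id, paste0("sp", 1:5)))
  prof <- incremental_extent_profile(as_community_matrix(m), scen$sites,
                                     n_samples = 10L, seed = 2)
  expect_equal(prof$beta_sor_mean, rep(0, nrow(prof)))
  expect_equal(prof$beta_w_minus1, rep(0, nrow(prof)))
})
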