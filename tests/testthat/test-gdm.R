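# helper: site pairs whose dissimilarity follows an exact model
# d = 1 - exp(-(a0 + |g(x1) - g(x2)|)) with g in the I-spline span
realizable_pairs <- function(n = 50, a0 = 0.2, w_true = c(0.3, 0.1, 0.4),
                             seed = 11) {
  set.seed(seed)
  st <- toy_site_table(paste0("Q", seq_len(n)), lon = runif(n, 118, 120),
                       lat = runif(n, -34, -28), x1 = runif(n, 0, 10))
  cm <- random_cm(n, 30)
  spt <- build_site_pairs(cm, st)
  b <- ispline_basis(st$x1, 3)
  g <- as.vector(eval_ispline(b, st$x1) %*% w_true)
  i1 <- match(spt$quadrat_1, st$quadrat_id)
  i2 <- match(spt$quadrat_2, st$quadrat_id)
  spt$dissimilarity <- 1 - exp(-(a0 + abs(g[i1] - g[i2])))
  list(spt = spt, st = st, a0 = a0, w_true = w_true)
}

test_that("site-pair table enumerates all unordered pairs with attached predictors", {
  st <- toy_site_table(c("a", "b", "c"), c(118, 118, 118), c(-34, -33, -32),
                       pH = c(5, 6, 7))
  cm <- cm_from_sets(list(a = c("A", "B"), b = c("B", "C"), c = c("C", "D")))
  spt <- build_site_pairs(cm, st)
  expect_equal(nrow(spt), 3L)
  # {A,B} vs {B,C}: a=1, b=1, c=1 -> Sorensen (b+c)/(2a+b+c) = 1/2
  expect_equal(spt$dissimilarity[spt$quadrat_1 == "a" & spt$quadrat_2 == "b"], 1 / 2)
  expect_equal(spt$pH_1, c(5, 5, 6))
  # distances attached from quadrat coordinates
  expect_equal(spt$distance_km[1:2],
               c(great_circle_km(c(118, -34), c(118, -33)),
                 great_circle_km(c(118, -34), c(118, -32))))
  same <- toy_site_table(c("a", "b", "c"), rep(118, 3), rep(-34, 3))
  expect_equal(build_site_pairs(cm, same, character(0))$distance_km, rep(0, 3))
  # C(160, 2) rows on the full design
  scen <- generate_scenario(seed = 4, occurrences = FALSE)
  expect_equal(nrow(build_site_pairs(scen$community, scen$sites)), 12720L)
})

test_that("I-spline basis is monotone, normalized and boundary-exact", {
  set.seed(16)
  for (i in 1:10) {
    v <- runif(50, -3, 7)
    b <- ispline_basis(v, 3)
    grid <- seq(min(v), max(v), length.out = 400)
    M <- eval_ispline(b, grid)
    expect_equal(dim(M), c(400L, 3L))
    expect_true(all(diff(M) > -1e-12))          # non-decreasing everywhere
    expect_equal(unname(M[1L, ]), rep(0, 3))    # zero at the minimum
    expect_equal(unname(M[400L, ]), rep(1, 3))  # one at the maximum
  }
  expect_error(ispline_basis(rep(1, 10)), "distinct")
  # pair design values: equal endpoints give zero, extremes give one
  b <- ispline_basis(0:10, 3)
  expect_equal(unname(abs(eval_ispline(b, 0) - eval_ispline(b, 10))[1, ]),
               rep(1, 3))
})

test_that("a realizable noiseless model is recovered essentially exactly", {
  rp <- realizable_pairs()
  m <- fit_gdm(rp$spt, predictors = "x1")
  expect_gt(m$deviance_explained, 99.9)
  expect_equal(m$intercept, rp$a0, tolerance = 1e-4)
  expect_equal(unname(m$coefficients[, "x1"]), rp$w_true, tolerance = 1e-3)
  expect_equal(unname(variable_importance(m)["x1"]), sum(rp$w_true),
               tolerance = 1e-4)
  crv <- spline_curves(m)
  expect_true(all(diff(crv$partial_distance) > -1e-10))
  expect_equal(crv$partial_distance[1L], 0)
  expect_equal(max(crv$partial_distance), unname(variable_importance(m)["x1"]),
               tolerance = 1e-10)
})

test_that("constant dissimilarity yields an intercept-only-quality fit", {
  rp <- realizable_pairs()
  spt <- rp$spt
  spt$dissimilarity <- rep(0.6, nrow(spt))
  m <- fit_gdm(spt, predictors = "x1")
  expect_lt(abs(m$deviance_explained), 0.5)
  # constant predictors are dropped and flagged
  spt$dissimilarity <- rp$spt$dissimilarity
  attr(spt, "quadrat_values")[, "x1"] <- 1
  expect_warning(m0 <- fit_gdm(spt, predictors = "x1"), "distinct")
  expect_true(m0$intercept_only)
  expect_equal(m0$deviance_explained, 0)
})

test_that("fits are invariant to predictor ordering", {
  set.seed(17)
  n <- 40
  st <- toy_site_table(paste0("Q", 1:n), runif(n, 118, 120), runif(n, -34, -28),
                       x1 = runif(n), x2 = runif(n))
  cm <- random_cm(n, 40, p = 0.3)
  spt <- build_site_pairs(cm, st)
  m12 <- fit_gdm(spt, predictors = c("x1", "x2"))
  m21 <- fit_gdm(spt, predictors = c("x2", "x1"))
  expect_equal(m12$coefficients[, c("x1", "x2")],
               m21$coefficients[, c("x1", "x2")], tolerance = 1e-6)
  expect_equal(m12$deviance_explained, m21$deviance_explained,
               tolerance = 1e-8)
  # predictions stay inside [0, 1) and match the training fit
  expect_true(all(m12$fitted >= 0 & m12$fitted < 1))
  expect_equal(predict(m12, spt), m12$fitted, tolerance = 1e-12)
})

test_that("deviance explained never decreases when predictors are added", {
  set.seed(18)
  scen <- generate_scenario(config = scenario_config(n_locations = 4L,
    adjacent_spacing_km = c(60, 100, 80)), seed = 2, occurrences = FALSE)
  spt <- build_site_pairs(scen$community, scen$sites)
  d_geo <- fit_gdm(spt, "geographic_distance")$deviance_explained
  d_gc <- fit_gdm(spt, c("geographic_distance", "precip_driest_q"))$deviance_explained
  d_gcs <- fit_gdm(spt, c("geographic_distance", "precip_driest_q",
                          "pH"))$deviance_explained
  expect_gte(d_gc, d_geo - 1e-6)
  expect_gte(d_gcs, d_gc - 1e-6)
})

test_that("permutation test flags the sole informative predictor and is reproducible", {
  rp <- realizable_pairs(n = 30)
  ps <- permutation_significance(rp$spt, "x1", predictors = "x1",
                                 n_perm = 49, seed = 5)
  expect_equal(ps$p_value, 1 / 50)
  ps2 <- permutation_significance(rp$spt, "x1", predictors = "x1",
                                  n_perm = 49, seed = 5)
  expect_identical(ps, ps2)
  expect_error(permutation_significance(rp$spt, "zz", predictors = "x1"),
               "not in the model")
})

test_that("backward elimination separates signal from noise and logs its steps", {
  set.seed(19)
  rp <- realizable_pairs(n = 40, seed = 23)
  spt <- rp$spt
  # add a pure-noise predictor at quadrat level
  qv <- attr(spt, "quadrat_values")
  noise <- rnorm(nrow(qv))
  attr(spt, "quadrat_values") <- cbind(qv, noise = noise)
  attr(spt, "predictors") <- c("x1", "noise")
  attr(spt, "group_map") <- c(x1 = "soil", noise = "soil")
  m <- backward_eliminate(spt, predictors = c("x1", "noise"), n_perm = 49,
                          seed = 31)
  expect_identical(m$predictors, "x1")
  expect_true(all(m$p_values < 0.05))
  expect_lte(nrow(m$elimination_log), 2L * 2L)
  expect_identical(m$elimination_log$action[m$elimination_log$predictor == "noise"],
                   "drop")
  # all-constant predictors collapse to a flagged intercept-only model
  attr(spt, "quadrat_values")[, c("x1", "noise")] <- 1
  expect_warning(m0 <- backward_eliminate(spt, predictors = c("x1", "noise"),
                                          n_perm = 9, seed = 1), "distinct")
  expect_true(m0$intercept_only)
})

test_that("deviance partition fractions sum to the full model and expose collinearity", {
  set.seed(20)
  n <- 40
  x <- runif(n, 0, 10)
  st <- toy_site_table(paste0("Q", 1:n), runif(n, 118, 120), runif(n, -34, -28),
                       clim = x, soil_copy = x, other = runif(n))
  st2 <- as_site_table(as.data.frame(st),
                       c(clim = "climate", soil_copy = "soil", other = "soil"))
  cm <- random_cm(n, 40, p = 0.3)
  spt <- build_site_pairs(cm, st2)
  b <- ispline_basis(x, 3)
  g <- as.vector(eval_ispline(b, x) %*% c(0.4, 0.2, 0.3))
  i1 <- match(spt$quadrat_1, st2$quadrat_id); i2 <- match(spt$quadrat_2, st2$quadrat_id)
  spt$dissimilarity <- 1 - exp(-(0.3 + abs(g[i1] - g[i2])))
  dp <- deviance_partition(spt, groups = list(G = "geographic_distance",
                                              C = "clim", S = "soil_copy"))
  expect_equal(sum(dp$fractions), dp$total, tolerance = 1e-8)
  # the two identical groups share their explained deviance
  expect_lt(abs(dp$fractions[["C"]]), 0.5)
  expect_lt(abs(dp$fractions[["S"]]), 0.5)
  expect_gt(dp$fractions[["CS"]] + dp$fractions[["GCS"]], 90)
  expect_error(deviance_partition(spt, groups = list(G = "geographic_distance",
                                                     C = character(0), S = "x")),
               "empty")
})
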