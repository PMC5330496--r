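test_that("pair components and pairwise indices match hand counts", {
  x <- c(A = 1, B = 1, C = 1, D = 0)
  y <- c(A = 0, B = 1, C = 1, D = 1)
  pc <- pair_components(x, y)
  expect_equal(pc, list(a = 2L, b = 1L, c = 1L))
  expect_equal(sorensen_pair(pc), 2 / 6)
  expect_equal(jaccard_pair(pc), 2 / 4)
  expect_equal(simpson_pair(pc), 1 / 3)

  expect_equal(sorensen_pair(pair_components(x, x)), 0)
  expect_equal(pair_components(x, x)[c("b", "c")], list(b = 0L, c = 0L))
  disj <- pair_components(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(disj$a, 0L)
  expect_equal(sorensen_pair(disj), 1)
  expect_equal(simpson_pair(disj), 1)

  expect_error(pair_components(c(1, 0), c(1, 0, 1)), "length")
  expect_error(sorensen_pair(pair_components(c(0, 0), c(0, 0))), "empty")
})

test_that("pairwise turnover/nestedness decomposition isolates replacement", {
  # nested pair: all dissimilarity is nestedness-resultant
  nested <- pair_components(c(1, 1, 1), c(1, 1, 0))
  d <- baselga_pair_decomposition(nested)
  expect_equal(d$beta_sim, 0)
  expect_equal(d$beta_nes, 1 / 5)
  # symmetric replacement: no nestedness component
  even <- baselga_pair_decomposition(list(a = 2L, b = 1L, c = 1L))
  expect_equal(even$beta_sim, 1 / 3)
  expect_equal(even$beta_nes, 0)
  # disjoint equal-size pair is pure replacement
  dd <- baselga_pair_decomposition(pair_components(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  expect_equal(dd$beta_sim, 1)
  expect_equal(dd$beta_nes, 0)
})

test_that("replacement + richness difference equals Jaccard dissimilarity exactly", {
  p <- podani_pair_decomposition(list(a = 2L, b = 1L, c = 1L))
  expect_equal(p$replacement, 0.5)
  expect_equal(p$richness_difference, 0)
  p2 <- podani_pair_decomposition(pair_components(c(1, 1, 1), c(1, 0, 0)))
  expect_equal(p2$replacement, 0)
  expect_equal(p2$richness_difference, 2 / 3)
  set.seed(1)
  for (i in 1:1000) {
    pc <- list(a = rbinom(1, 20, .3), b = rbinom(1, 20, .3), c = rbinom(1, 20, .3))
    if (pc$a + pc$b + pc$c == 0) next
    pd <- podani_pair_decomposition(pc)
    expect_identical(pd$replacement + pd$richness_difference, jaccard_pair(pc))
  }
})

test_that("multiple-site measures reduce to pairwise formulas at n = 2", {
  set.seed(3)
  for (i in 1:20) {
    cm <- random_cm(2, 25)
    pc <- pair_components(unclass(cm)[1L, ], unclass(cm)[2L, ])
    ms <- multisite_sorensen_family(cm)
    expect_equal(ms$beta_sor, sorensen_pair(pc))
    expect_equal(ms$beta_sim, simpson_pair(pc))
    mj <- multisite_jaccard_family(cm)
    expect_equal(mj$beta_jac, jaccard_pair(pc))
  }
})

test_that("multiple-site measures handle nested chains and disjoint sets", {
  chain <- cm_from_sets(list(q1 = "A", q2 = c("A", "B"), q3 = c("A", "B", "C")))
  ms <- multisite_sorensen_family(chain)
  expect_equal(ms$beta_sim, 0)
  expect_gt(ms$beta_nes, 0)
  expect_equal(ms$beta_nes, ms$beta_sor)

  disj <- cm_from_sets(list(q1 = c("A", "B"), q2 = c("C", "D"), q3 = c("E", "F")))
  msd <- multisite_sorensen_family(disj)
  expect_equal(msd$beta_sor, 1)
  expect_equal(msd$beta_sim, 1)

  expect_error(multisite_sorensen_family(chain[1L, , drop = FALSE]), "at least 2")
  empty <- as_community_matrix(rbind(q1 = c(A = 1L, B = 0L), q2 = c(0L, 0L)))
  expect_error(multisite_sorensen_family(empty), "empty quadrat")
})

test_that("multiple-site values agree with a set-operation brute force", {
  set.seed(7)
  for (i in 1:50) {
    cm <- random_cm(sample(3:10, 1), sample(10:40, 1))
    bf <- bf_multisite(cm)
    ms <- multisite_sorensen_family(cm)
    expect_equal(ms$beta_sim, bf$beta_sim, tolerance = 1e-14)
    expect_equal(ms$beta_sor, bf$beta_sor, tolerance = 1e-14)
  }
})

test_that("multiple-site values agree with vegan's independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(9)
  for (i in 1:10) {
    cm <- random_cm(8, 30)
    v <- vegan::nestedbetasor(unclass(cm))
    ms <- multisite_sorensen_family(cm)
    expect_equal(ms$beta_sim, unname(v["turnover"]), tolerance = 1e-12)
    expect_equal(ms$beta_nes, unname(v["nestedness"]), tolerance = 1e-12)
    expect_equal(ms$beta_sor, unname(v["sorensen"]), tolerance = 1e-12)
  }
})

test_that("multiple-site measures obey their structural invariants", {
  set.seed(21)
  for (i in 1:25) {
    cm <- random_cm(6, 30)
    ms <- multisite_sorensen_family(cm)
    expect_true(0 <= ms$beta_sim && ms$beta_sim <= ms$beta_sor &&
                ms$beta_sor <= 1)
    expect_gte(ms$beta_nes, -1e-15)
    # order invariance
    perm <- multisite_sorensen_family(cm[sample(nrow(cm)),
                                         sample(ncol(cm)), drop = FALSE])
    expect_equal(perm$beta_sor, ms$beta_sor)
    expect_equal(perm$beta_sim, ms$beta_sim)
    # a ubiquitous taxon only adds to the matching component, so it can
    # never raise either measure
    aug <- as_community_matrix(cbind(unclass(cm), ubiq = 1L))
    msa <- multisite_sorensen_family(aug)
    expect_lte(msa$beta_sim, ms$beta_sim + 1e-15)
    expect_lte(msa$beta_sor, ms$beta_sor + 1e-15)
  }
})

test_that("Whittaker's beta_W-1 equals gamma over alpha-bar minus one", {
  ident <- cm_from_sets(list(q1 = c("A", "B"), q2 = c("A", "B")))
  expect_equal(whittaker_beta(ident)$beta_w_minus1, 0)
  disj <- cm_from_sets(list(q1 = c("A", "B", "C"), q2 = c("D", "E", "F")))
  expect_equal(whittaker_beta(disj)$beta_w_minus1, 1)
  w <- whittaker_beta(cm_from_sets(list(q1 = c("A", "B"), q2 = c("C", "D"),
                                        q3 = c("E", "F"))))
  expect_equal(w$gamma, 6L)
  expect_equal(w$alpha_bar, 2)
  expect_equal(w$beta_w_minus1, 2)
})

test_that("dissimilarity matrices are symmetric, zero-diagonal and match the pair loop", {
  cm <- cm_from_sets(list(q1 = c("A", "B", "C"), q2 = c("B", "C", "D")))
  expect_equal(dissimilarity_matrix(cm, "sorensen")["q1", "q2"], 1 / 3)
  set.seed(5)
  cm <- random_cm(20, 50)
  for (metric in c("sorensen", "jaccard", "simpson")) {
    dm <- dissimilarity_matrix(cm, metric)
    expect_equal(dm, t(dm))
    expect_equal(unname(diag(dm)), rep(0, 20))
    expect_true(all(dm >= 0 & dm <= 1))
    fn <- switch(metric, sorensen = sorensen_pair, jaccard = jaccard_pair,
                 simpson = simpson_pair)
    for (k in 1:10) {
      ij <- sample(20, 2)
      expect_equal(dm[ij[1L], ij[2L]],
                   fn(pair_components(unclass(cm)[ij[1L], ],
                                      unclass(cm)[ij[2L], ])))
    }
  }
})
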