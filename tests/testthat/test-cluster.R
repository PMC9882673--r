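test_that("Kabsch superposition nulls exact rigid copies", {
  set.seed(11)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_rmsd(a, a)$rmsd, 0, tolerance = 1e-12)

  R <- nucarray:::random_rotation()
  b <- sweep(a %*% t(R), 2, c(5, -2, 9), "+")
  res <- kabsch_rmsd(a, b)
  expect_lt(res$rmsd, 1e-9)
  # returned transform actually superposes a onto b
  moved <- sweep(a %*% t(res$rotation), 2, res$translation, "+")
  expect_lt(max(abs(moved - b)), 1e-9)
  expect_equal(det(res$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch RMSD matches a brute-force rotational minimiser", {
  set.seed(12)
  for (i in 1:4) {
    a <- matrix(rnorm(30, sd = 5), 10, 3)
    b <- matrix(rnorm(30, sd = 5), 10, 3)
    expect_equal(kabsch_rmsd(a, b)$rmsd, brute_force_rmsd(a, b),
                 tolerance = 1e-3)
  }
})

test_that("RMSD is symmetric and rigid-motion invariant", {
  set.seed(13)
  a <- matrix(rnorm(60, sd = 8), 20, 3)
  b <- matrix(rnorm(60, sd = 8), 20, 3)
  expect_equal(kabsch_rmsd(a, b)$rmsd, kabsch_rmsd(b, a)$rmsd,
               tolerance = 1e-9)
  R <- nucarray:::random_rotation()
  b2 <- sweep(b %*% t(R), 2, c(-4, 7, 1), "+")
  expect_equal(kabsch_rmsd(a, b2)$rmsd, kabsch_rmsd(a, b)$rmsd,
               tolerance = 1e-9)
  expect_error(kabsch_rmsd(a, b[1:10, ]), "matching")
})

test_that("the RMSD matrix agrees with pairwise calls and its invariants", {
  p <- preset_table("mono_5mM", noise_sd = 2)
  models <- generate_population(p, 5, seed = 21)
  M <- rmsd_matrix(models)
  expect_equal(M, t(M))
  expect_equal(diag(M), setNames(rep(0, 5), rownames(M)))
  expect_equal(M[2, 4],
               kabsch_rmsd(models[[2]]$trace, models[[4]]$trace)$rmsd)
  # duplicated models give a zero matrix
  M0 <- rmsd_matrix(list(models[[1]], models[[1]], models[[1]]))
  expect_true(all(M0 < 1e-9))
  m_di <- generate_array(preset_table("di_5mM", noise_sd = 0), rng_seed = 1)
  expect_error(rmsd_matrix(c(models, list(m_di))), "share a template")
})

test_that("single linkage reproduces a brute-force agglomeration and MST", {
  set.seed(14)
  x <- matrix(rnorm(10), 5, 2)
  d <- as.matrix(dist(x))
  cl <- single_linkage_order(d)
  expect_equal(sort(cl$height), brute_force_single_linkage(d),
               tolerance = 1e-12)
  expect_equal(sort(cl$height), unname(mst_edge_weights(d)),
               tolerance = 1e-12)
  expect_setequal(cl$order, 1:5)
  expect_true(all(diff(cl$height) >= 0))
})

test_that("near-duplicate models sit on adjacent dendrogram leaves", {
  p <- preset_table("mono_5mM", noise_sd = 2)
  a <- generate_array(p, rng_seed = 31)
  a2 <- a
  a2$trace <- a$trace + matrix(rnorm(length(a$trace), 0, 0.1),
                               ncol = 3)
  b <- generate_array(p, rng_seed = 35)
  M <- rmsd_matrix(list(a, a2, b))
  cl <- single_linkage_order(M)
  pos <- match(c(1, 2), cl$order)
  expect_equal(abs(diff(pos)), 1L)
  expect_error(single_linkage_order(M[1, 1, drop = FALSE]), "at least 2")
})

test_that("dendrograms export to parseable Newick", {
  skip_if_not_installed("ape")
  p <- preset_table("mono_5mM", noise_sd = 2)
  models <- generate_population(p, 4, seed = 41)
  cl <- single_linkage_order(rmsd_matrix(models))
  txt <- cluster_newick(cl)
  phy <- ape::read.tree(text = txt)
  expect_equal(length(phy$tip.label), 4L)
})
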