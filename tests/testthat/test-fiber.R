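test_that("sampled units honour their seed and angle conventions", {
  p <- preset_table("tetra_5mM")
  u1 <- sample_unit(p, rng_seed = 5)
  u2 <- sample_unit(p, rng_seed = 5)
  expect_identical(u1, u2)
  expect_equal(sqrt(sum(u1$entry_dir^2)), 1, tolerance = 1e-9)
  expect_equal(sqrt(sum(u1$exit_dir^2)), 1, tolerance = 1e-9)

  # zero-variance alpha = beta = 0 arms lie along the local away tangents
  p0 <- mono_params_fixed(0L, 0L, alpha = 0, beta = 0)
  u <- sample_unit(p0, rng_seed = 1, unwrap = FALSE)
  # alpha/beta are defined against the in-plane (XY-projected) tangent
  xy_unit <- function(v) { v[3] <- 0; v / sqrt(sum(v^2)) }
  tan_en <- xy_unit(nucarray:::superhelix_tangent(0)[1, ])
  expect_equal(as.vector(u$entry_dir), -tan_en, tolerance = 1e-6)
  tan_ex <- xy_unit(nucarray:::superhelix_tangent(146)[1, ])
  expect_equal(as.vector(u$exit_dir), tan_ex, tolerance = 1e-6)
})

test_that("sampled unit angles follow the generating distribution", {
  p <- preset_table("tetra_5mM")
  set.seed(9)
  alphas <- vapply(1:1000, function(i) sample_unit(p)$alpha_entry,
                   numeric(1))
  ref <- nucarray:::sample_mixture(1000, p$alpha)
  expect_gt(suppressWarnings(stats::ks.test(alphas, ref))$p.value, 0.01)
})

test_that("fibers assemble clash-free and deterministically", {
  p <- preset_table("tetra_5mM")
  f <- build_fiber(p, n_ncp = 40, rng_seed = 3)
  expect_equal(f$n_ncp, 40L)
  expect_gte(min(dist(f$centers)), 100)
  f2 <- build_fiber(p, n_ncp = 40, rng_seed = 3)
  expect_identical(f$centers, f2$centers)
  f3 <- build_fiber(p, n_ncp = 40, rng_seed = 4)
  expect_false(identical(f$centers, f3$centers))
  expect_error(build_fiber(p, n_ncp = 1, rng_seed = 1), ">= 2")
})

test_that("fiber dimensions match analytic values on a straight chain", {
  f <- structure(list(centers = cbind(seq(0, 99) * 230, 0, 0),
                      n_ncp = 100L, radius_A = 50),
                 class = "nuca_fiber")
  dims <- fiber_dimensions(f)
  expect_equal(dims$contour_length_nm, 99 * 23, tolerance = 0.01 * 99 * 23)
  expect_equal(dims$width_nm, 2 * 5, tolerance = 1e-6)
  f_short <- structure(list(centers = cbind(0:2 * 230, 0, 0), n_ncp = 3L,
                            radius_A = 50), class = "nuca_fiber")
  expect_error(fiber_dimensions(f_short), "too-short")
})

test_that("persistence length of a straight line reports the cap", {
  line <- cbind(seq(0, 1500, by = 10), 0, 0)
  expect_equal(persistence_length(line), 1e5)
  expect_error(persistence_length(cbind(c(0, 15), 0, 0)), "too-short")
})

test_that("the WLC estimator recovers a known persistence length", {
  set.seed(15)
  chains <- lapply(1:100, function(i) simulate_wlc(100, d_nm = 15,
                                                   p_nm = 50))
  p_hat <- persistence_length(chains, d_nm = 15)
  expect_lt(abs(p_hat - 50) / 50, 0.15)
})

test_that("WLC metrics evaluate the closed-form expressions", {
  m <- wlc_metrics(50, 50, 100)
  expect_equal(m$gyration_radius_nm, 17.51, tolerance = 0.005)
  expect_equal(m$hydrodynamic_radius_nm / m$gyration_radius_nm, 0.662)

  # flexible-chain limit: R_g^2 -> P L / 3
  mf <- wlc_metrics(1, 1000, 100)
  expect_equal(mf$gyration_radius_nm^2, 1000 / 3,
               tolerance = 0.01 * 1000 / 3)

  # density arithmetic: 100 NCPs in a 100-nm-Rg sphere is 39.65 uM
  m2 <- wlc_metrics(50, 50, 100)
  vol <- (4 / 3) * pi * m2$gyration_radius_nm^3
  expect_equal(m2$ncp_density_uM, 1e6 / 0.602214076 * 100 / vol)
  expect_error(wlc_metrics(-1, 100, 10), "invalid")
  expect_error(wlc_metrics(50, 0, 10), "invalid")
})

test_that("fiber centers export to a pseudo-atom PDB", {
  p <- preset_table("tetra_5mM")
  f <- build_fiber(p, n_ncp = 12, rng_seed = 8)
  path <- withr::local_tempfile(fileext = ".pdb")
  export_fiber_pdb(f, path)
  txt <- readLines(path)
  expect_equal(sum(startsWith(txt, "HETATM")), 12L)
})

test_that("fiber JSON export preserves centers and frames", {
  p <- preset_table("tetra_5mM")
  f <- build_fiber(p, n_ncp = 10, rng_seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_fiber(f, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(obj$centers), 10)
  expect_equal(unname(obj$centers), unname(f$centers), tolerance = 1e-12)
})
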