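test_that("seamless density is the mean fiber density, tagged upper", {
  fm <- wlc_metrics(50, 746.5, 100)   # R_g comes out near 100 nm
  # construct the arithmetic reference directly
  ref <- 1e6 / 0.602214076 * 100 / ((4 / 3) * pi * fm$gyration_radius_nm^3)
  est <- seamless_density(list(fm))
  expect_equal(est$value_uM, ref)
  expect_equal(est$bound, "upper")
  est3 <- seamless_density(list(fm, fm, fm))
  expect_equal(est3$value_uM, est$value_uM)
  expect_error(seamless_density(list()), "empty")
})

test_that("a single fiber docks and the concentration arithmetic holds", {
  p <- preset_table("tetra_50mM")
  f <- build_fiber(p, n_ncp = 10, rng_seed = 6)
  cond <- random_dock(list(f), sphere_diameter_nm = 200,
                      spacing_nm = list(mean = 11.4, sd = 1), rng_seed = 1)
  expect_equal(length(cond$placements), 1L)
  expect_equal(cond$total_ncp, 10)
  vol <- (4 / 3) * pi * 100^3
  expect_equal(cond$concentration_uM, 1e6 / 0.602214076 * 10 / vol)
  expect_equal(condensate_concentration(cond), cond$concentration_uM)
  # all placed centers inside the sphere
  expect_lt(max(rowSums(cond$centers_nm^2)), 100^2)
  # determinism
  cond2 <- random_dock(list(f), sphere_diameter_nm = 200,
                       spacing_nm = list(mean = 11.4, sd = 1), rng_seed = 1)
  expect_identical(cond$centers_nm, cond2$centers_nm)
})

test_that("a fiber larger than the sphere cannot be docked", {
  f <- structure(list(centers = cbind(seq(0, 39) * 300, 0, 0), n_ncp = 40L,
                      radius_A = 50), class = "nuca_fiber")
  expect_error(random_dock(list(f), sphere_diameter_nm = 200,
                           spacing_nm = list(mean = 11.4, sd = 1),
                           rng_seed = 1, attempts = 50),
               "no fiber could be placed")
})

test_that("slab crops partition the condensate", {
  p <- preset_table("tetra_50mM")
  fibers <- lapply(1:4, function(s) build_fiber(p, n_ncp = 15,
                                                rng_seed = s))
  cond <- random_dock(fibers, spacing_nm = list(mean = 11.4, sd = 1),
                      rng_seed = 3)
  full <- slab_crop(cond, -100, 200)
  expect_equal(full$total_ncp, cond$total_ncp)
  lower <- slab_crop(cond, -100, 100)
  upper <- slab_crop(cond, 0, 100)
  expect_equal(lower$total_ncp + upper$total_ncp, cond$total_ncp)
  thin <- slab_crop(cond, 0, 1e-9)
  expect_lte(thin$total_ncp, 1)
  expect_error(slab_crop(cond, 0, 0), "> 0")
})

test_that("condensates export placements and centers", {
  p <- preset_table("tetra_50mM")
  fibers <- lapply(1:3, function(s) build_fiber(p, n_ncp = 12,
                                                rng_seed = s))
  cond <- random_dock(fibers, spacing_nm = list(mean = 11.4, sd = 1),
                      rng_seed = 4)
  jp <- withr::local_tempfile(fileext = ".json")
  pp <- withr::local_tempfile(fileext = ".pdb")
  write_condensate(cond, jp, pp)
  obj <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(obj$total_ncp, cond$total_ncp)
  expect_equal(length(obj$placements$fiber), length(cond$placements))
  expect_equal(sum(startsWith(readLines(pp), "HETATM")), cond$total_ncp)
})

test_that("the seamless estimate bounds the docking estimate from above", {
  p <- preset_table("tetra_50mM")
  fibers <- lapply(1:6, function(s) build_fiber(p, n_ncp = 15,
                                                rng_seed = s))
  fms <- lapply(fibers, fiber_metrics)
  seam <- seamless_density(fms)
  dock <- random_dock(fibers, spacing_nm = list(mean = 11.4, sd = 1),
                      rng_seed = 2)
  expect_gte(seam$value_uM, dock$concentration_uM)
})
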