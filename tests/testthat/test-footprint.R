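test_that("ideal fully wrapped populations give a 0/1 footprint", {
  pars <- mono_params_fixed(0L, 0L)
  models <- generate_population(pars, 3, seed = 5)
  models <- lapply(models, detect_model)
  fp <- unwrap_footprint(models, mode = "path8A")
  tpl <- models[[1]]$template
  iv <- tpl$nps_intervals[[1]]
  expect_equal(fp$prob[(iv[1] + 1):iv[2]], rep(1, 147))
  expect_equal(fp$prob[1:iv[1]], rep(0, iv[1]))
  expect_equal(sum(fp$prob), 147)
})

test_that("constant exit unwrapping zeroes the final bp of the repeat", {
  pars <- mono_params_fixed(0L, -11L)
  models <- generate_population(pars, 3, seed = 9)
  models <- lapply(models, detect_model)
  fp <- unwrap_footprint(models)
  iv <- models[[1]]$template$nps_intervals[[1]]
  expect_equal(fp$prob[(iv[2] - 10):iv[2]], rep(0, 11))
  expect_equal(fp$prob[(iv[1] + 1):(iv[2] - 11)], rep(1, 147 - 11))
})

test_that("single-model footprints are binary; input errors are caught", {
  pars <- mono_params_fixed(-2L, -4L)
  m <- detect_model(generate_array(pars, rng_seed = 2))
  fp <- unwrap_footprint(list(m))
  expect_true(all(fp$prob %in% c(0, 1)))
  expect_error(unwrap_footprint(list()), "empty")
  m2 <- generate_array(preset_table("di_5mM", noise_sd = 0), rng_seed = 1)
  expect_error(unwrap_footprint(list(m, m2)), "share a template")
})

test_that("atomic PDB input maps chains to roles through the YAML config", {
  skip_if_not_installed("bio3d")
  pdb <- withr::local_tempfile(fileext = ".pdb")
  fmt <- "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  lines <- c(
    sprintf(fmt, "ATOM", 1, " C1", "", " DG", "I", 1, "", 0, 0, 0, 1, 0, "C"),
    sprintf(fmt, "ATOM", 2, " C1", "", " DC", "I", 2, "", 10, 0, 0, 1, 0, "C"),
    sprintf(fmt, "ATOM", 3, " CA", "", "ALA", "A", 5, "", 0, 0, 3, 1, 0, "C"),
    "END")
  writeLines(lines, pdb)
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("chains:", "  I: dna", "  A: histone", "bp_offset: -1"), cfg)
  at <- read_atomic_pdb(pdb, cfg)
  expect_equal(at$dna_bp, c(0L, 1L))
  expect_equal(nrow(at$histone_xyz), 1L)
  # bp 0 is within 4 A of the histone atom, bp 1 is not
  sc <- nucarray:::atomic_contact_scores(at, 5L)
  expect_equal(sc[1:2], c(1, 0))
})

test_that("atomic contact mode scores any-atom pairs within 4 A", {
  pars <- mono_params_fixed(0L, 0L)
  m <- generate_array(pars, rng_seed = 3)
  # synthetic atoms: 3 bp, one histone atom close to bp 0 and 2 only
  m$atoms <- list(
    dna_bp = c(0L, 0L, 1L, 2L),
    dna_xyz = rbind(c(0, 0, 0), c(1, 0, 0), c(10, 0, 0), c(0, 5, 0)),
    histone_xyz = rbind(c(0, 0, 3.5), c(0, 2, 0)))
  sc <- nucarray:::atomic_contact_scores(m$atoms, 10L)
  expect_equal(sc[1:3], c(1, 0, 1))
  fp <- unwrap_footprint(list(m), mode = "atomic4A")
  expect_equal(fp$prob[1:3], c(1, 0, 1))
})
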