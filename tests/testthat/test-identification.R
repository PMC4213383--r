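test_that("ppm_error is exact arithmetic and scale-invariant", {
  expect_equal(ppm_error(100.0010, 100.0000), 10, tolerance = 1e-6)
  expect_equal(ppm_error(500.0025, 500.0000), 5, tolerance = 1e-6)
  expect_equal(ppm_error(123.456, 123.456), 0)
  expect_error(ppm_error(-1, 100), "positive")
  set.seed(2)
  for (k in 1:10) {
    a <- runif(1, 50, 900); b <- a * (1 + runif(1, -1e-5, 1e-5))
    s <- runif(1, 0.5, 3)
    expect_equal(ppm_error(s * a, s * b), ppm_error(a, b), tolerance = 1e-9)
  }
})

make_lib <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  if (is.null(df$ref_rt)) df$ref_rt <- NA_real_
  if (is.null(df$standard_available)) df$standard_available <- FALSE
  class(df) <- c("compound_library", "data.frame")
  df
}

grouped_table <- function(masses, rts) {
  feature_table(
    data.frame(feature_id = sprintf("G%02d", seq_along(masses)),
               mz = masses + 1.007276, rt = rts, ion_mode = "positive",
               neutral_mass = masses, stringsAsFactors = FALSE),
    matrix(100, length(masses), 2, dimnames = list(NULL, c("A_1_1", "B_1_1")))
  )
}

test_that("library matching enforces the strict 10 ppm bound", {
  lib <- make_lib(compound_id = c("C1", "C2"), name = c("glucose", "other"),
                  monoisotopic_mass = c(180.0634, 300.1))
  tab <- grouped_table(c(180.0634, 300.1 * (1 + 11e-6)), c(650, 300))
  m <- match_library(tab, lib)
  g1 <- m[m$group_id == "G01", ]
  expect_equal(g1$compound_id, "C1")
  expect_lt(g1$ppm_error, 0.01)
  expect_equal(g1$msi_level, 2L)
  # 11 ppm deviation: no candidate, unknown at MSI 4
  g2 <- m[m$group_id == "G02", ]
  expect_true(is.na(g2$compound_id))
  expect_equal(g2$msi_level, 4L)
  expect_equal(unname(attr(m, "summary")["n_unknown"]), 1L)
})

test_that("isobaric candidates are both returned, ranked by ppm error", {
  lib <- make_lib(compound_id = c("C1", "C2"),
                  name = c("leucine", "isoleucine"),
                  monoisotopic_mass = c(131.09462, 131.09460))
  tab <- grouped_table(131.09461, 400)
  m <- match_library(tab, lib)
  expect_equal(nrow(m), 2)
  expect_true(m$ppm_error[1] <= m$ppm_error[2])
})

test_that("MSI levels require a standard plus retention-time agreement", {
  cfg <- default_config()
  expect_equal(assign_msi_level(TRUE, 15, cfg), 1L)
  expect_equal(assign_msi_level(TRUE, 30, cfg), 1L)   # closed 30 s default
  expect_equal(assign_msi_level(TRUE, 31, cfg), 2L)
  expect_equal(assign_msi_level(FALSE, 5, cfg), 2L)
  expect_equal(assign_msi_level(TRUE, NA, cfg), 2L)

  lib <- make_lib(compound_id = "C1", name = "glucose",
                  monoisotopic_mass = 180.0634, ref_rt = 650,
                  standard_available = TRUE)
  m1 <- match_library(grouped_table(180.0634, 660), lib)
  expect_equal(m1$msi_level, 1L)
  m2 <- match_library(grouped_table(180.0634, 710), lib)
  expect_equal(m2$msi_level, 2L)
})

test_that("true library identities are recovered from simulated groups", {
  sim <- simulate_metabolome(zero_noise_spec(seed = 21))
  g <- annotate_ions(sim$table)
  col <- collapse_to_group_matrix(sim$table, g)
  m <- match_library(col, sim$library)
  top <- m[!duplicated(m$group_id), ]
  # map groups back to their generating metabolite via the representative ion
  rep_met <- sim$truth$ions$metabolite_id[
    match(vapply(g, `[[`, "", "representative"), sim$truth$ions$feature_id)]
  truth_cpd <- sim$truth$metabolites$compound_id[
    match(rep_met, sim$truth$metabolites$metabolite_id)]
  has_lib <- !is.na(truth_cpd)
  expect_equal(top$compound_id[match(vapply(g, `[[`, "", "group_id"),
                                     top$group_id)][has_lib],
               truth_cpd[has_lib])
})

test_that("noisy-mass identification still ranks the truth on top", {
  sim <- simulate_metabolome(metabolome_sim_spec(seed = 22, mz_noise_ppm = 5))
  g <- annotate_ions(sim$table)
  col <- collapse_to_group_matrix(sim$table, g)
  m <- match_library(col, sim$library)
  top <- m[!duplicated(m$group_id), ]
  rep_met <- sim$truth$ions$metabolite_id[
    match(vapply(g, `[[`, "", "representative"), sim$truth$ions$feature_id)]
  truth_cpd <- sim$truth$metabolites$compound_id[
    match(rep_met, sim$truth$metabolites$metabolite_id)]
  sel <- !is.na(truth_cpd)
  got <- top$compound_id[match(vapply(g, `[[`, "", "group_id"), top$group_id)][sel]
  expect_gte(mean(got == truth_cpd[sel], na.rm = TRUE), 0.95)
})
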