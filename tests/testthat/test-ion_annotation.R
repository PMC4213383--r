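# correlated two-ion profiles across 2x2 bioreps x duplicate injections
two_ion_matrix <- function(scale2 = 0.4) {
  base <- c(A_1_1 = 100, A_1_2 = 102, A_2_1 = 140, A_2_2 = 138,
            B_1_1 = 90, B_1_2 = 92, B_2_1 = 120, B_2_2 = 118)
  rbind(base, base * scale2)
}

test_that("a co-eluting [M+H]+/[M+Na]+ pair forms one group at the glucose mass", {
  mat <- two_ion_matrix()
  tab <- make_table(mat, mz = c(181.0707, 203.0526), rt = c(650, 651))
  g <- annotate_ions(tab)
  expect_length(g, 1)
  expect_setequal(g[[1]]$members, c("F001", "F002"))
  expect_equal(g[[1]]$neutral_mass, 180.0634, tolerance = 1e-3)
  expect_setequal(g[[1]]$species, c("[M+H]+", "[M+Na]+"))
  # representative is the highest-mean-intensity member
  expect_equal(g[[1]]$representative, "F001")
})

test_that("an isotope-spaced pair with lighter peak more intense is grouped", {
  mat <- two_ion_matrix(scale2 = 0.1)
  tab <- make_table(mat, mz = c(181.0707, 181.0707 + 1.0034), rt = c(650, 650))
  g <- annotate_ions(tab)
  expect_length(g, 1)
  expect_setequal(g[[1]]$species, c("[M+H]+", "M+1"))

  # heavier peak more intense: isotope interpretation rejected
  # (fragment-correlation linking disabled to isolate the isotope rule)
  mat2 <- two_ion_matrix(scale2 = 10)
  tab2 <- make_table(mat2, mz = c(181.0707, 181.0707 + 1.0034), rt = c(650, 650))
  expect_length(annotate_ions(tab2, fragment_correlation_floor = 1.1), 2)
})

test_that("co-elution violations yield singleton groups", {
  mat <- two_ion_matrix()
  tab <- make_table(mat, mz = c(181.0707, 203.0526), rt = c(650, 770))
  g <- annotate_ions(tab)  # 120 s apart, 10 s tolerance
  expect_length(g, 2)
  expect_true(all(lengths(lapply(g, `[[`, "members")) == 1))
})

test_that("grouping is invariant to feature input order", {
  sim <- simulate_metabolome(metabolome_sim_spec(seed = 6, n_metabolites = 60))
  tab <- sim$table
  g1 <- annotate_ions(tab)
  perm <- sample(nrow(tab$features))
  tab2 <- feature_table(tab$features[perm, ], tab$matrix[perm, ])
  g2 <- annotate_ions(tab2)
  part <- function(g) sort(vapply(g, function(x) paste(sort(x$members), collapse = ","), ""))
  expect_identical(part(g1), part(g2))
})

test_that("empty tables annotate to an empty group list", {
  tab <- make_table(matrix(numeric(0), 0, 2,
                           dimnames = list(NULL, c("A_1_1", "B_1_1"))),
                    mz = numeric(0), rt = numeric(0), ids = character(0))
  expect_length(annotate_ions(tab), 0)
})

test_that("collapsing produces one row per group and preserves singletons", {
  sim <- simulate_metabolome(zero_noise_spec(seed = 5, n_metabolites = 30,
                                             n_exclusive_B = 2))
  g <- annotate_ions(sim$table)
  col <- collapse_to_group_matrix(sim$table, g)
  expect_equal(nrow(col$features), length(g))
  expect_lte(nrow(col$features), nrow(sim$table$features))

  # singleton-only grouping: collapse is the identity on the matrix
  mat <- two_ion_matrix()
  tab <- make_table(mat, mz = c(100.05, 407.13), rt = c(100, 500))
  gs <- annotate_ions(tab)
  expect_length(gs, 2)
  ident <- collapse_to_group_matrix(tab, gs)
  expect_equal(unname(ident$matrix), unname(tab$matrix))

  # non-partition input is a hard error
  broken <- gs
  broken[[1]]$members <- c(broken[[1]]$members, "F002")
  expect_error(collapse_to_group_matrix(tab, broken), "partition")
})

test_that("implied neutral masses agree within every multi-adduct group", {
  sim <- simulate_metabolome(metabolome_sim_spec(seed = 8))
  cfg <- default_config()
  g <- annotate_ions(sim$table, config = cfg)
  rules <- default_ion_rules()
  for (grp in g) {
    adducts <- grp$species %in% rules$species
    if (sum(adducts) < 2) next
    idx <- match(grp$members[adducts], sim$table$features$feature_id)
    sp <- match(grp$species[adducts], rules$species)
    implied <- (sim$table$features$mz[idx] - rules$delta[sp]) / rules$multiplicity[sp]
    spread_ppm <- (max(implied) - min(implied)) / mean(implied) * 1e6
    expect_lt(spread_ppm, 2 * cfg$grouping_mz_tolerance_ppm)
  }
})

test_that("blank subtraction drops medium features at the closed threshold", {
  smat <- matrix(c(100, 100, 0, NA, 50, 50), nrow = 3, byrow = TRUE,
                 dimnames = list(NULL, c("A_1_1", "B_1_1")))
  bmat <- matrix(c(0, 0, 80, 80, 25, 25), nrow = 3, byrow = TRUE,
                 dimnames = list(NULL, c("A_1_1", "A_1_2")))
  tab <- make_table(smat)
  blank <- make_table(bmat)
  out <- subtract_blank(tab, blank, default_config(blank_fraction = 0.5))
  # F001 absent from blank: retained; F002 blank-only: dropped;
  # F003 blank mean exactly half the sample mean: dropped (closed bound)
  expect_setequal(out$features$feature_id, "F001")
  expect_setequal(attr(out, "dropped"), c("F002", "F003"))
})
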