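test_that("fieller_ci handles the zero-variance and symmetric limits", {
  zv <- fieller_ci(c(2, 2, 2, 2), c(1, 1, 1, 1))
  expect_equal(zv$ratio, 2)
  expect_equal(zv$ci_low, 2)
  expect_equal(zv$ci_high, 2)

  x <- c(3.2, 4.1, 5.3, 4.4)
  sym <- fieller_ci(x, x)
  expect_equal(sym$ratio, 1)
  expect_lte(sym$ci_low, 1)
  expect_gte(sym$ci_high, 1)

  expect_error(fieller_ci(c(1, 2), c(3)), "at least two")
  expect_error(fieller_ci(c(1, 2), c(-1, 1)), "denominator mean is zero")
})

test_that("fieller_ci matches frozen values for the 6-vs-4 worked example", {
  fc <- fieller_ci(c(9, 10, 11, 12, 13, 14), c(2, 3, 4, 5), alpha = 0.05)
  expect_equal(fc$ratio, 3.285714, tolerance = 1e-6)
  expect_equal(fc$ci_low, 2.047793, tolerance = 1e-3)
  expect_equal(fc$ci_high, 7.003413, tolerance = 1e-3)
  expect_equal(fc$df, 3.790278, tolerance = 1e-5)
})

test_that("closed-form interval equals the numeric inversion oracle", {
  set.seed(42)
  n_checked <- 0
  for (k in 1:100) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- rnorm(nx, runif(1, 5, 50), runif(1, 0.5, 5))
    y <- rnorm(ny, runif(1, 5, 50), runif(1, 0.5, 5))
    fc <- fieller_ci(x, y)
    if (!is.finite(fc$ci_low) || !is.finite(fc$ci_high)) next
    orc <- oracle_fieller(x, y, df_mode = "fixed")
    expect_equal(fc$ci_low, orc$ci_low, tolerance = 1e-6)
    expect_equal(fc$ci_high, orc$ci_high, tolerance = 1e-6)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 80)
})

test_that("plug-in df bounds stay close to the local-df inversion", {
  # the closed form fixes the Satterthwaite df at the point estimate; the
  # fully local inversion recomputes it along rho — document the bound
  set.seed(7)
  rel_gap <- c()
  for (k in 1:30) {
    x <- rnorm(6, 30, 4); y <- rnorm(4, 10, 2)
    fc <- fieller_ci(x, y)
    if (!is.finite(fc$ci_low) || !is.finite(fc$ci_high)) next
    orc <- oracle_fieller(x, y, df_mode = "local")
    if (!is.finite(orc$ci_low) || !is.finite(orc$ci_high)) next
    rel_gap <- c(rel_gap,
                 abs(fc$ci_low - orc$ci_low) / abs(orc$ci_low),
                 abs(fc$ci_high - orc$ci_high) / abs(orc$ci_high))
  }
  expect_lt(stats::median(rel_gap), 0.15)
})

test_that("an unbounded Fieller set is reported with infinite bounds", {
  # denominator indistinguishable from zero at this variance
  fc <- fieller_ci(c(10, 11, 12, 9), c(-5, 6, -4, 5))
  expect_equal(fc$ci_low, -Inf)
  expect_equal(fc$ci_high, Inf)
})

test_that("ratio scale-equivariance: scaling x scales ratio and bounds", {
  set.seed(3)
  x <- rnorm(6, 30, 5); y <- rnorm(4, 10, 2)
  base <- fieller_ci(x, y)
  for (c_ in c(0.5, 2, 10)) {
    sc <- fieller_ci(c_ * x, y)
    expect_equal(sc$ratio, c_ * base$ratio, tolerance = 1e-10)
    expect_equal(sc$ci_low, c_ * base$ci_low, tolerance = 1e-8)
    expect_equal(sc$ci_high, c_ * base$ci_high, tolerance = 1e-8)
  }
})

test_that("ratio_test covers equal, separated and degenerate groups", {
  x <- c(3.1, 4.2, 5.0, 3.8)
  expect_equal(ratio_test(x, x), 1, tolerance = 1e-10)
  p <- ratio_test(c(100, 101, 99, 100, 100, 100), c(1, 1.1, 0.9, 1))
  expect_lt(p, 1e-4)
  # zero-variance unequal groups: p -> 0 limit without division error
  expect_equal(ratio_test(c(5, 5, 5), c(2, 2, 2)), 0)
  expect_equal(ratio_test(c(5, 5, 5), c(5, 5, 5)), 1)
  expect_true(is.na(ratio_test(c(1, 2), c(3))))
})

test_that("classification applies the threefold / alpha rule exactly", {
  cfg <- default_config()
  expect_equal(classify_metabolite(3.5, 0.01, 6, 4, cfg), "increased")
  expect_equal(classify_metabolite(2.9, 0.001, 6, 4, cfg), "unchanged")
  expect_equal(classify_metabolite(3.0, 0.049, 6, 4, cfg), "increased")
  expect_equal(classify_metabolite(1 / 3, 0.01, 6, 4, cfg), "decreased")
  expect_equal(classify_metabolite(0.5, 0.2, 6, 4, cfg), "unchanged")
  expect_equal(classify_metabolite(Inf, NA, 0, 4, cfg), "exclusive_B")
  expect_equal(classify_metabolite(0, NA, 6, 0, cfg), "exclusive_A")
  # fewer detected bioreps than the exclusivity guard: unevaluable
  expect_equal(classify_metabolite(Inf, NA, 0, 2, cfg), "unevaluable")
})

test_that("condition swap maps labels symmetrically", {
  set.seed(11)
  cfg <- default_config()
  flip <- c(increased = "decreased", decreased = "increased",
            unchanged = "unchanged", exclusive_A = "exclusive_B",
            exclusive_B = "exclusive_A", unevaluable = "unevaluable")
  for (k in 1:40) {
    a <- rlnorm(6, log(100), 0.4)
    b <- rlnorm(4, log(100), 0.4) * sample(c(1, 5, 0.2), 1)
    p <- ratio_test(b, a)
    lab <- classify_metabolite(mean(b) / mean(a), p, length(a), length(b), cfg)
    lab_sw <- classify_metabolite(mean(a) / mean(b), ratio_test(a, b),
                                  length(b), length(a), cfg)
    expect_equal(lab_sw, unname(flip[lab]))
  }
})

test_that("diff_table classifies a simulated averaged matrix coherently", {
  sim <- simulate_metabolome(metabolome_sim_spec(seed = 12, n_metabolites = 120,
                                                 n_exclusive_B = 8))
  g <- annotate_ions(sim$table)
  avg <- average_injections(collapse_to_group_matrix(sim$table, g))
  d <- diff_table(avg)
  expect_equal(nrow(d), length(g))
  # bounded CIs bracket the point estimate
  ok <- is.finite(d$ci_low) & is.finite(d$ci_high)
  expect_true(all(d$ci_low[ok] <= d$ratio[ok] + 1e-8))
  expect_true(all(d$ratio[ok] <= d$ci_high[ok] + 1e-8))
  # exclusivity labels match detection counts
  expect_true(all(d$n_A[d$label == "exclusive_B"] == 0))
  expect_true(all(d$n_B[d$label == "exclusive_B"] >= 3))
  expect_gt(sum(d$label == "exclusive_B"), 0)

  empty <- diff_table(average_injections(make_table(
    matrix(numeric(0), 0, 2, dimnames = list(NULL, c("A_1_1", "B_1_1"))),
    mz = numeric(0), rt = numeric(0), ids = character(0))))
  expect_equal(nrow(empty), 0)
})

test_that("the all-null simulation keeps the raw type-I error near alpha", {
  spec <- metabolome_sim_spec(seed = 13, n_metabolites = 300,
                              fraction_differential = 0, n_exclusive_A = 0,
                              n_exclusive_B = 0, p_isotope = 0, p_adduct = 0,
                              p_dimer = 0)
  sim <- simulate_metabolome(spec)
  avg <- average_injections(sim$table)
  d <- diff_table(avg)
  fp <- mean(d$p_value < 0.05, na.rm = TRUE)
  expect_lt(fp, 0.12)
  expect_gt(fp, 0.005)
})
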