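test_that("size factors satisfy the median-of-ratios contracts", {
  m <- matrix(rep(c(10L, 40L, 200L), 4), ncol = 4,
              dimnames = list(NULL, c("A_1", "A_2", "B_1", "B_2")))
  expect_equal(unname(size_factors(m)), rep(1, 4))
  m2 <- m
  m2[, 3] <- m2[, 3] * 2L
  expect_equal(unname(size_factors(m2)), c(1, 1, 2, 1))
  # invariance to gene order
  sim <- simulate_counts(n_genes = 400, n_reps = 3, seed = 8)
  cm <- sim$counts$counts
  perm <- sample(nrow(cm))
  expect_equal(size_factors(cm), size_factors(cm[perm, ]))
  expect_error(size_factors(matrix(0L, 2, 2,
                                   dimnames = list(NULL, c("A_1", "B_1")))),
               "no gene")
})

test_that("estimated size factors track the simulated library sizes", {
  sim <- simulate_counts(n_genes = 2000, n_reps = 3, fraction_up = 0.03,
                         fraction_down = 0.03, seed = 9)
  est <- size_factors(sim$counts)
  truth <- attr(sim$truth, "size_factors")
  truth <- truth / median(truth)
  expect_equal(unname(est), unname(truth), tolerance = 0.05)
})

test_that("gene classification follows the threefold / padj rule", {
  # six tightly measured 10-fold genes over a null background
  n <- 50
  base <- rep(1000L, 6)
  cm <- cbind(A_1 = base, A_2 = base + 3L, A_3 = base - 2L,
              B_1 = base * 10L, B_2 = base * 10L + 5L, B_3 = base * 10L - 4L)
  filler <- simulate_counts(n_genes = n, n_reps = 3, fraction_up = 0,
                            fraction_down = 0, seed = 10)$counts$counts
  counts <- gene_counts(
    data.frame(gene_id = sprintf("g%02d", 1:(n + 6)),
               class = "enzyme", stringsAsFactors = FALSE),
    rbind(cm, filler)
  )
  res <- gene_diff(counts)
  expect_true(all(res$label[1:6] == "up"))
  expect_true(all(res$fold[1:6] >= 3))
  expect_true(all(res$padj[1:6] < 0.05))
  expect_true(all(res$padj >= res$p_value - 1e-12))

  # identical counts in every replicate: unchanged
  flat <- counts
  flat$counts[10, ] <- 500L
  res2 <- gene_diff(flat)
  expect_equal(res2$label[10], "unchanged")
})

test_that("a sub-threshold fold stays unchanged regardless of significance", {
  # 2.5-fold with tiny dispersion: padj tiny but fold below 3
  set.seed(11)
  n <- 50
  base <- rep(1000L, 6)
  cm <- cbind(A_1 = base, A_2 = base + 3L, A_3 = base - 2L,
              B_1 = base * 2.5, B_2 = base * 2.5 + 3, B_3 = base * 2.5 - 2)
  cm <- matrix(as.integer(cm), nrow = 6,
               dimnames = list(NULL, colnames(cm)))
  filler <- simulate_counts(n_genes = n, n_reps = 3, seed = 12)$counts$counts
  counts <- gene_counts(
    data.frame(gene_id = sprintf("g%02d", 1:(n + 6)),
               class = "enzyme", stringsAsFactors = FALSE),
    rbind(cm, filler)
  )
  res <- gene_diff(counts)
  strong <- res[1:6, ]
  expect_true(all(strong$padj < 0.05))
  expect_true(all(strong$fold < 3))
  expect_true(all(strong$label == "unchanged"))
})

test_that("labels swap up/down under condition relabelling", {
  sim <- simulate_counts(n_genes = 500, n_reps = 3, seed = 13)
  res <- gene_diff(sim$counts)
  swapped <- sim$counts
  colnames(swapped$counts) <- sub("^A", "X", colnames(swapped$counts))
  colnames(swapped$counts) <- sub("^B", "A", colnames(swapped$counts))
  colnames(swapped$counts) <- sub("^X", "B", colnames(swapped$counts))
  swapped <- gene_counts(swapped$genes, swapped$counts)
  res_sw <- gene_diff(swapped)
  flip <- c(up = "down", down = "up", unchanged = "unchanged",
            low_expression = "low_expression")
  expect_equal(res_sw$label, unname(flip[res$label]))
})

test_that("functional summaries conserve label totals", {
  sim <- simulate_counts(n_genes = 800, n_reps = 3, seed = 14)
  res <- gene_diff(sim$counts)
  fs <- functional_summary(res)
  expect_equal(sum(fs$up), sum(res$label == "up"))
  expect_equal(sum(fs$down), sum(res$label == "down"))
  expect_equal(fs$total, fs$up + fs$down)

  res$label <- "unchanged"
  expect_equal(nrow(functional_summary(res)), 0)
})

test_that("neighbor reports respect the window and degenerate inputs", {
  genes <- data.frame(
    gene_id = c("reg", "near_up", "far", "inside"),
    class = "regulator",
    start = c(10000, 11500, 40000, 10100),
    end = c(11000, 12500, 41000, 10400),
    strand = "+", stringsAsFactors = FALSE
  )
  res <- data.frame(gene_id = genes$gene_id, class = genes$class,
                    fold = c(1, 34, 1, 2), label = c("unchanged", "up",
                                                     "unchanged", "unchanged"),
                    start = genes$start, end = genes$end,
                    stringsAsFactors = FALSE)
  rep1 <- neighbor_report(res, "reg", window_bp = 2000)
  expect_setequal(rep1$gene_id, c("near_up", "inside"))
  expect_equal(rep1$fold[rep1$gene_id == "near_up"], 34)
  expect_equal(rep1$label[rep1$gene_id == "near_up"], "up")

  rep0 <- neighbor_report(res, "reg", window_bp = 0)
  expect_equal(rep0$gene_id, "inside")

  expect_equal(nrow(neighbor_report(res, character(0))), 0)
  res_nc <- res[setdiff(names(res), c("start", "end"))]
  expect_warning(out <- neighbor_report(res_nc, "reg"), "coordinates missing")
  expect_equal(nrow(out), 0)
})
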