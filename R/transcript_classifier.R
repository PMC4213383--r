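#' Median-of-ratios size factors
#'
#' Per-replicate normalization factor: for genes with a nonzero count in
#' every replicate, the ratio of the gene's count to its geometric mean
#' across replicates; the factor is the median of those ratios, rescaled
#' by the median factor so that unperturbed replicates sit at 1 (relative
#' factors — the only thing normalization uses — are unchanged by the
#' rescaling). Invariant to gene order.
#'
#' @param counts integer matrix (genes x replicates) or a `gene_counts`.
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "gene_counts")) counts$counts else as.matrix(counts)
  keep <- rowSums(m == 0) == 0
  if (!any(keep)) stop("no gene has nonzero counts in all replicates")
  lm_ <- log(m[keep, , drop = FALSE])
  geo <- rowMeans(lm_)
  f <- apply(exp(sweep(lm_, 1, geo, `-`)), 2, stats::median)
  f / stats::median(f)
}

#' Differential expression surrogate with threshold classification
#'
#' Normalizes counts by [size_factors()], estimates the B/A fold from
#' normalized condition means with a pseudocount, tests each gene with a
#' Welch t-test on log2 normalized counts, adjusts p-values by
#' Benjamini-Hochberg, and applies the study's rule: up when fold >= 3
#' with padj < 0.05, down when fold <= 1/3 with padj < 0.05. This is
#' deliberately not a negative-binomial shrinkage test; the module's
#' contract is the normalization formula and the classification rule, with
#' the per-gene test pluggable.
#'
#' @param counts a `gene_counts` (see [read_counts()], [simulate_counts()]).
#' @param config a [default_config()]; uses `fold_threshold`, `alpha`,
#'   `pseudocount`, `low_count_threshold`.
#' @return data.frame of class `gene_diff_results`: `gene_id`, `class`,
#'   `mean_A`, `mean_B` (normalized), `fold`, `p_value`, `padj`, `label`
#'   in up/down/unchanged/low_expression.
#' @export
gene_diff <- function(counts, config = default_config()) {
  stopifnot(inherits(counts, "gene_counts"))
  sf <- size_factors(counts)
  norm <- sweep(counts$counts, 2, sf, `/`)
  condA <- counts$samples$condition == "A"
  condB <- counts$samples$condition == "B"
  if (sum(condA) < 2 || sum(condB) < 2) {
    stop("need at least 2 replicates per condition")
  }
  mean_A <- rowMeans(norm[, condA, drop = FALSE])
  mean_B <- rowMeans(norm[, condB, drop = FALSE])
  ps <- config$pseudocount
  fold <- (mean_B + ps) / (mean_A + ps)
  lg <- log2(norm + ps)
  p <- vapply(seq_len(nrow(lg)), function(i) {
    a <- lg[i, condA]; b <- lg[i, condB]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    }
    stats::t.test(b, a, var.equal = FALSE)$p.value
  }, numeric(1))
  padj <- stats::p.adjust(p, method = "BH")
  low <- mean_A < config$low_count_threshold & mean_B < config$low_count_threshold
  label <- rep("unchanged", nrow(norm))
  label[fold >= config$fold_threshold & padj < config$alpha] <- "up"
  label[fold <= 1 / config$fold_threshold & padj < config$alpha] <- "down"
  label[low] <- "low_expression"
  res <- data.frame(gene_id = counts$genes$gene_id, class = counts$genes$class,
                    mean_A = mean_A, mean_B = mean_B, fold = fold,
                    p_value = p, padj = padj, label = label,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(counts$genes$start)) {
    res$start <- counts$genes$start
    res$end <- counts$genes$end
    res$strand <- counts$genes$strand
  }
  attr(res, "size_factors") <- sf
  class(res) <- c("gene_diff_results", "data.frame")
  res
}

#' Up/down counts per functional class
#'
#' Contingency of classification label by functional class, restricted to
#' differential labels. Returns a zero-row data.frame when no gene is
#' differential.
#'
#' @param results a `gene_diff_results` from [gene_diff()].
#' @return data.frame with columns `class`, `up`, `down`, `total`.
#' @export
functional_summary <- function(results) {
  d <- results[results$label %in% c("up", "down"), ]
  if (!nrow(d)) {
    return(data.frame(class = character(), up = integer(), down = integer(),
                      total = integer(), stringsAsFactors = FALSE))
  }
  tab <- table(d$class, factor(d$label, levels = c("up", "down")))
  data.frame(class = rownames(tab), up = as.integer(tab[, "up"]),
             down = as.integer(tab[, "down"]),
             total = as.integer(rowSums(tab)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Transcription status of genes neighboring candidate regulators
#'
#' For each regulator gene, lists the genes whose genomic span lies within
#' `window_bp` of the regulator's span, with their fold and label —
#' useful because the target of a transcriptional regulator is often
#' adjacent to the regulator gene itself.
#'
#' @param results a `gene_diff_results` carrying `start`/`end` coordinates.
#' @param regulator_ids character vector of regulator gene ids.
#' @param window_bp distance (bp) around the regulator span; 0 keeps only
#'   overlapping genes.
#' @return data.frame: `regulator_id`, `gene_id`, `distance_bp`, `fold`,
#'   `label`. Empty when no regulators are supplied; skipped with a
#'   warning when coordinates are missing.
#' @export
neighbor_report <- function(results, regulator_ids, window_bp = 5000) {
  empty <- data.frame(regulator_id = character(), gene_id = character(),
                      distance_bp = numeric(), fold = numeric(),
                      label = character(), stringsAsFactors = FALSE)
  if (!length(regulator_ids)) return(empty)
  if (is.null(results$start) || is.null(results$end)) {
    warning("gene coordinates missing; neighbor report skipped")
    return(empty)
  }
  rows <- list()
  for (reg in regulator_ids) {
    ri <- match(reg, results$gene_id)
    if (is.na(ri)) {
      warning("regulator ", reg, " not found; skipped")
      next
    }
    lo <- results$start[ri] - window_bp
    hi <- results$end[ri] + window_bp
    nb <- which(results$gene_id != reg &
                  results$start >= lo & results$end <= hi)
    if (!length(nb)) next
    dist <- pmax(0, pmax(results$start[nb] - results$end[ri],
                         results$start[ri] - results$end[nb]))
    rows[[length(rows) + 1]] <- data.frame(
      regulator_id = reg, gene_id = results$gene_id[nb],
      distance_bp = dist, fold = results$fold[nb],
      label = results$label[nb], stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
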