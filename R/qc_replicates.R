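#' Relative standard deviation (percent)
#'
#' Sample (n-1 denominator) standard deviation divided by the mean, times
#' 100. Undefined (returned as `NA`) when fewer than two finite values are
#' supplied or the mean is zero; never reported as 0 in that case. With
#' duplicate injections this equals `|x1 - x2| / (sqrt(2) * mean) * 100`.
#'
#' @param values numeric vector of non-negative intensities; `NA`s dropped.
#' @return RSD in percent, or `NA_real_` when undefined.
#' @export
rsd <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2) return(NA_real_)
  m <- mean(v)
  if (m == 0) return(NA_real_)
  stats::sd(v) / m * 100
}

#' Average analytical replicates into biological replicate columns
#'
#' Collapses the injections of each biological replicate to their mean,
#' ignoring missing injections; a replicate with all injections missing
#' stays missing. Output columns are named `<condition>_<biorep>`.
#'
#' @param table a [feature_table()] at injection level.
#' @return a [feature_table()] with one column per biological replicate.
#' @export
average_injections <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  key <- paste(table$samples$condition, table$samples$biorep, sep = "_")
  keys <- unique(key)
  out <- matrix(NA_real_, nrow(table$matrix), length(keys),
                dimnames = list(rownames(table$matrix), keys))
  for (k in seq_along(keys)) {
    cols <- which(key == keys[k])
    m <- rowMeans(table$matrix[, cols, drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    out[, k] <- m
  }
  feature_table(table$features, out)
}

#' Replicate-reproducibility QC table
#'
#' Computes the analytical RSD (between injections, per biological
#' replicate) and the biological RSD (between biological replicates, per
#' condition, on injection-averaged values) for every feature/group.
#'
#' @param table injection-level [feature_table()].
#' @return data.frame of class `qc_table`: `group_id`, per-biorep
#'   analytical RSDs (columns `arsd_<cond>_<rep>`), per-condition
#'   biological RSDs (`brsd_A`, `brsd_B`). Undefined RSDs are `NA`.
#' @export
qc_table <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  s <- table$samples
  key <- paste(s$condition, s$biorep, sep = "_")
  keys <- unique(key)
  res <- data.frame(group_id = table$features$feature_id,
                    stringsAsFactors = FALSE)
  for (k in keys) {
    cols <- which(key == k)
    res[[paste0("arsd_", k)]] <- apply(table$matrix[, cols, drop = FALSE], 1, rsd)
  }
  avg <- average_injections(table)
  for (cond in unique(s$condition)) {
    cols <- which(avg$samples$condition == cond)
    res[[paste0("brsd_", cond)]] <-
      apply(avg$matrix[, cols, drop = FALSE], 1, rsd)
  }
  class(res) <- c("qc_table", "data.frame")
  res
}

#' Flag features with high biological RSD for manual review
#'
#' A feature is flagged when its biological RSD in any condition reaches
#' the threshold (closed bound: RSD of exactly 40 % is flagged at the
#' default). Flags annotate only; nothing is dropped automatically. Rows
#' whose RSDs are all undefined are reported as unevaluable, not flagged.
#'
#' @param qc a `qc_table` from [qc_table()].
#' @param config a [default_config()]; uses `rsd_flag_threshold_percent`.
#' @return the QC table with logical columns `flagged` and `unevaluable`.
#' @export
flag_by_biological_rsd <- function(qc, config = default_config()) {
  bcols <- grep("^brsd_", names(qc), value = TRUE)
  if (!length(bcols)) stop("qc table has no biological RSD columns")
  b <- as.matrix(qc[bcols])
  max_rsd <- suppressWarnings(apply(b, 1, max, na.rm = TRUE))
  allna <- !is.finite(max_rsd)
  qc$flagged <- !allna & max_rsd >= config$rsd_flag_threshold_percent
  qc$unevaluable <- allna
  qc
}
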