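#' Fit a nucleotide calibration curve
#'
#' Ordinary least-squares line `area = slope * concentration + intercept`
#' per analyte. An optional `1/x` weighting is available for
#' heteroscedastic areas. A non-positive slope marks the curve unusable.
#'
#' @param series a `calibration_series` data.frame (one analyte).
#' @param weighting `"none"` (default) or `"1/x"`.
#' @return list of class `calibration_curve`: `analyte`, `slope` (area per
#'   uM), `intercept`, `r_squared`, `range` (valid concentration range),
#'   `usable`, `n_levels`.
#' @export
fit_calibration <- function(series, weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(series),
            all(c("analyte", "concentration", "area") %in% names(series)))
  analyte <- unique(series$analyte)
  if (length(analyte) != 1) stop("fit one analyte at a time")
  conc <- series$concentration
  if (length(unique(conc)) < 2) {
    stop("calibration series for ", analyte,
         " has no concentration spread; cannot fit a line")
  }
  w <- if (weighting == "1/x") 1 / pmax(conc, min(conc[conc > 0])) else NULL
  fit <- stats::lm(area ~ concentration, data = series, weights = w)
  slope <- unname(stats::coef(fit)[2])
  ss_tot <- sum((series$area - mean(series$area))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  usable <- TRUE
  if (slope <= 0) {
    warning("calibration slope for ", analyte, " is not positive; curve unusable")
    usable <- FALSE
  }
  structure(list(analyte = analyte, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, range = range(conc),
                 usable = usable, n_levels = length(unique(conc))),
            class = "calibration_curve")
}

#' Inverse-predict a concentration from a peak area
#'
#' `(area - intercept) / slope`; predictions outside the calibrated range
#' are flagged `extrapolated`, and negative predictions (area below the
#' intercept) are clamped to 0 with flag `below_range`.
#'
#' @param area numeric vector of peak areas.
#' @param curve a `calibration_curve` from [fit_calibration()].
#' @return list with `concentration` (uM) and `flag` (`"ok"`,
#'   `"extrapolated"` or `"below_range"` per element).
#' @export
quantify <- function(area, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!curve$usable) stop("calibration curve for ", curve$analyte, " is unusable")
  conc <- (area - curve$intercept) / curve$slope
  flag <- rep("ok", length(conc))
  flag[conc > curve$range[2] | conc < curve$range[1]] <- "extrapolated"
  below <- conc < 0
  flag[below] <- "below_range"
  conc[below] <- 0
  list(concentration = conc, flag = flag)
}

#' Adenylate energy charge
#'
#' `AEC = ([ATP] + 0.5 [ADP]) / ([ATP] + [ADP] + [AMP])`, the index of
#' metabolically available energy (0 = all AMP, 1 = all ATP). Invariant to
#' common scaling of the three concentrations; `NA` when the adenylate
#' pool is zero.
#'
#' @param atp,adp,amp non-negative concentrations (any common unit);
#'   vectorized.
#' @return AEC in `[0, 1]`, `NA_real_` for an all-zero pool.
#' @export
compute_aec <- function(atp, adp, amp) {
  if (any(c(atp, adp, amp) < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative")
  }
  total <- atp + adp + amp
  ifelse(total > 0, (atp + 0.5 * adp) / total, NA_real_)
}

#' Energy charge per condition from nucleotide peak areas
#'
#' Quantifies AMP, ADP and ATP per biological replicate through their
#' calibration curves, computes the per-replicate AEC, and summarises each
#' condition as mean and sample standard deviation. Replicates missing any
#' of the three nucleotides are excluded and listed in the `excluded`
#' attribute.
#'
#' @param areas data.frame with columns `analyte` (AMP/ADP/ATP),
#'   `condition` (A/B), `biorep`, `area` — injection-averaged areas, e.g.
#'   extracted from an [average_injections()] table via a nucleotide
#'   mapping.
#' @param curves named list of `calibration_curve`s (`AMP`, `ADP`, `ATP`).
#' @return list of class `aec_result`: `replicates` (per-replicate
#'   concentrations and AEC) and `conditions` (mean, sd, n per condition).
#' @export
aec_by_condition <- function(areas, curves) {
  stopifnot(all(c("analyte", "condition", "biorep", "area") %in% names(areas)))
  need <- c("AMP", "ADP", "ATP")
  if (!all(need %in% names(curves))) {
    stop("curves must be a named list with AMP, ADP and ATP")
  }
  reps <- unique(areas[c("condition", "biorep")])
  rows <- list(); excluded <- character()
  for (r in seq_len(nrow(reps))) {
    sel <- areas$condition == reps$condition[r] & areas$biorep == reps$biorep[r]
    sub <- areas[sel, ]
    conc <- stats::setNames(rep(NA_real_, 3), need)
    for (a in need) {
      ar <- sub$area[sub$analyte == a]
      ar <- ar[is.finite(ar)]
      if (length(ar)) conc[a] <- quantify(mean(ar), curves[[a]])$concentration
    }
    if (anyNA(conc)) {
      excluded <- c(excluded,
                    sprintf("%s_%s", reps$condition[r], reps$biorep[r]))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      condition = reps$condition[r], biorep = reps$biorep[r],
      AMP = conc[["AMP"]], ADP = conc[["ADP"]], ATP = conc[["ATP"]],
      aec = compute_aec(conc[["ATP"]], conc[["ADP"]], conc[["AMP"]]),
      stringsAsFactors = FALSE
    )
  }
  replicates <- if (length(rows)) do.call(rbind, rows) else
    data.frame(condition = character(), biorep = integer(), AMP = numeric(),
               ADP = numeric(), ATP = numeric(), aec = numeric())
  conditions <- do.call(rbind, lapply(split(replicates, replicates$condition),
    function(d) data.frame(condition = d$condition[1], n = nrow(d),
                           aec_mean = mean(d$aec),
                           aec_sd = if (nrow(d) > 1) stats::sd(d$aec) else NA_real_,
                           stringsAsFactors = FALSE)))
  rownames(conditions) <- NULL
  out <- list(replicates = replicates, conditions = conditions)
  attr(out, "excluded") <- excluded
  class(out) <- "aec_result"
  out
}

#' @export
print.aec_result <- function(x, ...) {
  cat("aec_result:\n")
  for (i in seq_len(nrow(x$conditions))) {
    cat(sprintf("  condition %s: AEC %.3f +/- %.3f (n = %d)\n",
                x$conditions$condition[i], x$conditions$aec_mean[i],
                x$conditions$aec_sd[i], x$conditions$n[i]))
  }
  ex <- attr(x, "excluded")
  if (length(ex)) cat("  excluded replicates:", paste(ex, collapse = ", "), "\n")
  invisible(x)
}
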