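#' Parts-per-million mass error
#'
#' `|observed - theoretical| / theoretical * 1e6`. Scale-invariant under
#' common rescaling of both masses.
#'
#' @param observed_mass,theoretical_mass positive masses (Da).
#' @return ppm error (vectorized).
#' @export
ppm_error <- function(observed_mass, theoretical_mass) {
  if (any(observed_mass <= 0) || any(theoretical_mass <= 0)) {
    stop("masses must be positive")
  }
  abs(observed_mass - theoretical_mass) / theoretical_mass * 1e6
}

#' Assign an MSI identification confidence level
#'
#' Metabolomics Standards Initiative tiers as used here: level 1 when the
#' compound has an authentic standard and the observed retention time lies
#' within `rt_match_tolerance_s` of the standard's; level 2 for a
#' mass-only (putative) match; level 4 for unknowns. Level 3
#' (compound-class) is not modelled.
#'
#' @param standard_available does the library entry have an authentic
#'   standard with a reference retention time?
#' @param rt_delta_s observed minus reference retention time (s); `NA`
#'   when no reference exists.
#' @param config a [default_config()]; uses `rt_match_tolerance_s`.
#' @return integer MSI level (1 or 2; 4 is assigned by [match_library()]
#'   for groups with no candidate).
#' @export
assign_msi_level <- function(standard_available, rt_delta_s,
                             config = default_config()) {
  if (isTRUE(standard_available) && !is.na(rt_delta_s) &&
      abs(rt_delta_s) <= config$rt_match_tolerance_s) {
    1L
  } else {
    2L
  }
}

#' Match feature groups against a compound library
#'
#' Putative identification by accurate neutral mass: candidates are library
#' entries with ppm error strictly below `ppm_tolerance` (the study's
#' "<10 ppm" bound), ranked by ppm error. Groups without adduct evidence
#' have already had their neutral mass inferred assuming the principal
#' species for their mode. Groups with no candidate are reported as
#' unknown, MSI level 4.
#'
#' @param groups a `feature_groups` list or the collapsed
#'   [feature_table()] carrying a `neutral_mass` feature column.
#' @param library a `compound_library` (see [read_compound_library()]).
#' @param config a [default_config()].
#' @return data.frame of class `match_candidates`: `group_id`,
#'   `compound_id`, `name`, `ppm_error`, `rt_delta_s`, `msi_level` (rows
#'   with `NA` compound are unknowns at level 4). Summary counts (n
#'   identified / putative / unknown) attached as attribute `summary`.
#' @export
match_library <- function(groups, library, config = default_config()) {
  if (inherits(groups, "feature_groups")) {
    gt <- groups_table(groups)
    gdf <- data.frame(group_id = gt$group_id, neutral_mass = gt$neutral_mass,
                      rt = gt$rt, stringsAsFactors = FALSE)
  } else if (inherits(groups, "feature_table")) {
    if (is.null(groups$features$neutral_mass)) {
      stop("feature table carries no neutral_mass column; run annotate_ions")
    }
    gdf <- data.frame(group_id = groups$features$feature_id,
                      neutral_mass = groups$features$neutral_mass,
                      rt = groups$features$rt, stringsAsFactors = FALSE)
  } else {
    stop("groups must be feature_groups or a collapsed feature_table")
  }
  out <- vector("list", nrow(gdf))
  for (i in seq_len(nrow(gdf))) {
    ppm <- ppm_error(gdf$neutral_mass[i], library$monoisotopic_mass)
    hit <- which(ppm < config$ppm_tolerance)
    if (!length(hit)) {
      out[[i]] <- data.frame(group_id = gdf$group_id[i],
                             compound_id = NA_character_, name = NA_character_,
                             ppm_error = NA_real_, rt_delta_s = NA_real_,
                             msi_level = 4L, stringsAsFactors = FALSE)
      next
    }
    hit <- hit[order(ppm[hit])]
    rt_delta <- gdf$rt[i] - library$ref_rt[hit]
    msi <- vapply(seq_along(hit), function(k) {
      assign_msi_level(library$standard_available[hit[k]], rt_delta[k], config)
    }, integer(1))
    out[[i]] <- data.frame(group_id = gdf$group_id[i],
                           compound_id = library$compound_id[hit],
                           name = library$name[hit],
                           ppm_error = ppm[hit],
                           rt_delta_s = rt_delta,
                           msi_level = msi, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("match_candidates", "data.frame")
  top <- res[!duplicated(res$group_id), ]
  attr(res, "summary") <- c(
    n_groups = nrow(gdf),
    n_identified = sum(top$msi_level == 1L),
    n_putative = sum(top$msi_level == 2L),
    n_unknown = sum(top$msi_level == 4L)
  )
  res
}

#' @export
print.match_candidates <- function(x, ...) {
  s <- attr(x, "summary")
  cat("match_candidates:", s[["n_groups"]], "groups;",
      s[["n_identified"]], "identified (MSI 1),",
      s[["n_putative"]], "putative (MSI 2),",
      s[["n_unknown"]], "unknown (MSI 4)\n")
  invisible(x)
}
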