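# Mass of a neutron-induced isotope spacing (13C - 12C), Da.
.ISOTOPE_SPACING <- 1.003355

#' Default electrospray ion-species rules
#'
#' Signed mass deltas (Da) relative to the neutral monoisotopic mass M, for
#' the common singly charged ESI species: `m/z = multiplicity * M + delta`.
#' Positive mode: `[M+H]+`, `[M+Na]+`, `[M+NH4]+`, `[M+K]+`, `[2M+H]+`.
#' Negative mode: `[M-H]-`, `[M+Cl]-`, `[2M-H]-`. The table is
#' config-extensible: pass any data.frame with columns `species`, `mode`,
#' `delta`, `multiplicity` to [annotate_ions()].
#'
#' @return data.frame with columns `species`, `mode`, `delta` (Da),
#'   `multiplicity`.
#' @export
default_ion_rules <- function() {
  data.frame(
    species = c("[M+H]+", "[M+Na]+", "[M+NH4]+", "[M+K]+", "[2M+H]+",
                "[M-H]-", "[M+Cl]-", "[2M-H]-"),
    mode = c(rep("positive", 5), rep("negative", 3)),
    delta = c(1.007276, 22.989218, 18.033823, 38.963158, 1.007276,
              -1.007276, 34.969402, -1.007276),
    multiplicity = c(1, 1, 1, 1, 2, 1, 1, 2),
    stringsAsFactors = FALSE
  )
}

# Pearson correlation of two intensity profiles over pairwise-complete
# injections, computed on within-condition residuals: ions of one
# metabolite share replicate-level (biological + analytical) covariation,
# whereas two different metabolites responding to the treatment share only
# the condition means — centering each condition removes that confounder.
# NA when fewer than 3 complete pairs or either residual profile is
# constant; NA is treated as non-blocking by the caller (a constant
# profile carries no evidence against co-origin).
profile_correlation <- function(a, b, condition = NULL) {
  ok <- !is.na(a) & !is.na(b) & a > 0 & b > 0
  if (sum(ok) < 3) return(NA_real_)
  # intensity noise is multiplicative: correlate on the log scale, where
  # the lognormal replicate covariation is linear and well conditioned
  a <- log(a[ok]); b <- log(b[ok])
  if (!is.null(condition)) {
    condition <- condition[ok]
    a <- a - stats::ave(a, condition)
    b <- b - stats::ave(b, condition)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Group redundant ion signals into feature groups
#'
#' Collapses isotopes, adducts, dimers and co-eluting correlated signals
#' into feature groups, one per putative metabolite. Two features are
#' linked when (a) their retention times differ by at most
#' `rt_coelution_tolerance_s`, (b) their m/z pair is explained by a single
#' neutral mass under two ion-species rules within
#' `grouping_mz_tolerance_ppm`, or by the isotope spacing 1.003355 Da with
#' the lighter peak more intense, and (c) their intensity profiles across
#' injections correlate above `correlation_floor` (undefined correlations,
#' e.g. constant profiles, do not block). Pairs satisfying only (a) and a
#' correlation above `fragment_correlation_floor` (default 0.9) are linked
#' as putative in-source fragments. Transitive closure over links forms the
#' groups; unexplained features become singleton groups. Output is
#' invariant to feature input order.
#'
#' @param table a [feature_table()].
#' @param rules ion-species rule table, see [default_ion_rules()].
#' @param config a [default_config()] list.
#' @param fragment_correlation_floor correlation needed to link co-eluting
#'   features with no mass-rule explanation.
#' @param correlation_floor profile-correlation requirement for mass-rule
#'   pairs; see Details.
#' @return list of class `feature_groups`; each element has `group_id`,
#'   `members`, `species` (per-member labels), `representative` (highest
#'   mean intensity member), `neutral_mass` (Da) and `rt` (consensus
#'   seconds).
#' @export
annotate_ions <- function(table, rules = default_ion_rules(),
                          config = default_config(),
                          correlation_floor = 0.3,
                          fragment_correlation_floor = 0.9) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$features)
  if (n == 0) return(structure(list(), class = "feature_groups"))

  ord <- order(table$features$mz, table$features$rt, table$features$feature_id)
  feats <- table$features[ord, , drop = FALSE]
  mat <- table$matrix[ord, , drop = FALSE]
  mz <- feats$mz
  rt <- feats$rt
  mode <- feats$ion_mode
  mean_int <- rowMeans(mat, na.rm = TRUE)
  mean_int[is.nan(mean_int)] <- 0

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  rt_ord <- order(rt)
  rt_tol <- config$rt_coelution_tolerance_s
  ppm_tol <- config$grouping_mz_tolerance_ppm

  # implied neutral masses per feature under every same-mode rule
  rule_by_mode <- split(rules, rules$mode)
  implied <- lapply(seq_len(n), function(i) {
    rr <- rule_by_mode[[mode[i]]]
    m <- (mz[i] - rr$delta) / rr$multiplicity
    stats::setNames(m[m > 0], rr$species[m > 0])
  })

  for (a in seq_len(n)) {
    i <- rt_ord[a]
    b <- a + 1L
    while (b <= n && rt[rt_ord[b]] - rt[i] <= rt_tol) {
      j <- rt_ord[b]
      b <- b + 1L
      if (mode[i] != mode[j]) next
      light <- if (mz[i] <= mz[j]) i else j
      heavy <- if (mz[i] <= mz[j]) j else i
      linked <- FALSE
      # (b1) shared neutral mass under two rules
      mi <- implied[[i]]; mj <- implied[[j]]
      for (u in seq_along(mi)) {
        dm <- abs(mj - mi[u]) / mi[u] * 1e6
        dm[names(mj) == names(mi)[u]] <- Inf  # same species implies same m/z
        if (any(dm <= ppm_tol)) { linked <- TRUE; break }
      }
      # (b2) isotope spacing, lighter more intense
      if (!linked) {
        d <- mz[heavy] - mz[light]
        if (abs(d - .ISOTOPE_SPACING) <= ppm_tol * 1e-6 * mz[light] &&
            mean_int[light] > mean_int[heavy]) {
          linked <- TRUE
        }
      }
      cc <- profile_correlation(mat[i, ], mat[j, ], table$samples$condition)
      if (linked) {
        if (is.na(cc) || cc >= correlation_floor) union_(i, j)
      } else if (!is.na(cc) && cc >= fragment_correlation_floor) {
        union_(i, j)  # putative in-source fragment pair
      }
    }
  }

  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), roots)
  comp <- comp[order(vapply(comp, min, integer(1)))]

  principal <- c(positive = "[M+H]+", negative = "[M-H]-")
  groups <- vector("list", length(comp))
  for (g in seq_along(comp)) {
    members <- comp[[g]]
    rep_i <- members[which.max(mean_int[members])]
    gm <- .assign_species(members, mz, mode, implied, mean_int, ppm_tol,
                          principal, rep_i)
    groups[[g]] <- list(
      group_id = sprintf("G%04d", g),
      members = feats$feature_id[members],
      species = gm$species,
      representative = feats$feature_id[rep_i],
      neutral_mass = gm$neutral_mass,
      rt = stats::median(rt[members])
    )
  }
  structure(groups, class = "feature_groups")
}

# Consensus neutral mass and per-member species labels for one group:
# pick the implied neutral mass explained by at least two members under
# different rules (ties: explains most members, contains the
# representative, smallest mass). Without any two-member agreement there
# is no adduct evidence, so the representative falls back to the
# principal-species assumption; remaining members are labelled by isotope
# spacing off an explained member or as 'unassigned'.
.assign_species <- function(members, mz, mode, implied, mean_int, ppm_tol,
                            principal, rep_i) {
  cands <- unlist(lapply(members, function(i) implied[[i]]), use.names = FALSE)
  best <- NULL
  best_n <- 1L
  best_has_rep <- FALSE
  for (u in seq_along(cands)) {
    m0 <- cands[u]
    hit <- lapply(members, function(i) {
      d <- abs(implied[[i]] - m0) / m0 * 1e6
      if (length(d) && min(d) <= ppm_tol) names(implied[[i]])[which.min(d)]
      else NA_character_
    })
    nn <- sum(!is.na(unlist(hit)))
    has_rep <- !is.na(hit[[which(members == rep_i)]])
    better <- nn > best_n ||
      (!is.null(best) && nn == best_n &&
         ((has_rep && !best_has_rep) ||
            (has_rep == best_has_rep && m0 < best$m0)))
    if (better) {
      best <- list(m0 = m0, hit = unlist(hit))
      best_n <- nn
      best_has_rep <- has_rep
    }
  }
  if (!is.null(best)) {
    species <- best$hit
    # refine consensus mass as the median over explained members
    masses <- vapply(seq_along(members), function(k) {
      i <- members[k]
      if (is.na(species[k])) NA_real_ else implied[[i]][[species[k]]]
    }, numeric(1))
    m0 <- stats::median(masses, na.rm = TRUE)
    expl <- which(!is.na(species))
  } else {
    species <- rep(NA_character_, length(members))
    m0 <- implied[[rep_i]][[principal[[mode[rep_i]]]]]
    species[which(members == rep_i)] <- principal[[mode[rep_i]]]
    expl <- which(!is.na(species))
  }
  # isotopologue labels for the rest
  for (k in which(is.na(species))) {
    i <- members[k]
    for (e in expl) {
      j <- members[e]
      d <- mz[i] - mz[j]
      for (iso in 1:2) {
        if (abs(d - iso * .ISOTOPE_SPACING) <= ppm_tol * 1e-6 * mz[j] &&
            mean_int[j] > mean_int[i]) {
          species[k] <- paste0("M+", iso)
          break
        }
      }
      if (!is.na(species[k])) break
    }
    if (is.na(species[k])) species[k] <- "unassigned"
  }
  list(neutral_mass = m0,
       species = stats::setNames(species, NULL))
}

#' @export
print.feature_groups <- function(x, ...) {
  sizes <- lengths(lapply(x, `[[`, "members"))
  cat("feature_groups:", length(x), "groups over", sum(sizes), "features\n")
  cat("  group sizes:", paste(names(table(sizes)), table(sizes),
                              sep = "x", collapse = ", "), "\n")
  invisible(x)
}

#' Summarise feature groups as a data.frame
#'
#' @param groups a `feature_groups` list.
#' @return data.frame with one row per group: id, representative, neutral
#'   mass, consensus rt, member count, comma-separated members and species.
#' @export
groups_table <- function(groups) {
  data.frame(
    group_id = vapply(groups, `[[`, "", "group_id"),
    representative = vapply(groups, `[[`, "", "representative"),
    neutral_mass = vapply(groups, `[[`, 0, "neutral_mass"),
    rt = vapply(groups, `[[`, 0, "rt"),
    n_members = vapply(groups, function(g) length(g$members), 0L),
    members = vapply(groups, function(g) paste(g$members, collapse = ";"), ""),
    species = vapply(groups, function(g) paste(g$species, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
}

#' Collapse a feature table to one row per feature group
#'
#' Each group is represented by its highest-mean-intensity member ion; the
#' output row carries that ion's peak areas under the group id, with the
#' group's inferred neutral mass as an extra feature column.
#'
#' @param table the [feature_table()] that was annotated.
#' @param groups the `feature_groups` from [annotate_ions()].
#' @return a [feature_table()] with one row per group.
#' @export
collapse_to_group_matrix <- function(table, groups) {
  stopifnot(inherits(table, "feature_table"))
  all_members <- unlist(lapply(groups, `[[`, "members"))
  if (anyDuplicated(all_members) ||
      !setequal(all_members, table$features$feature_id) ||
      length(all_members) != nrow(table$features)) {
    stop("groups do not partition the features of the table")
  }
  reps <- vapply(groups, `[[`, "", "representative")
  idx <- match(reps, table$features$feature_id)
  features <- data.frame(
    feature_id = vapply(groups, `[[`, "", "group_id"),
    mz = table$features$mz[idx],
    rt = vapply(groups, `[[`, 0, "rt"),
    ion_mode = table$features$ion_mode[idx],
    neutral_mass = vapply(groups, `[[`, 0, "neutral_mass"),
    stringsAsFactors = FALSE
  )
  feature_table(features, table$matrix[idx, , drop = FALSE])
}

#' Remove features attributable to the culture medium
#'
#' Drops features whose mean area in the blank (medium) table reaches the
#' configured fraction of their mean sample area (closed threshold); the
#' drop list is attached as attribute `dropped` for audit.
#'
#' @param table sample [feature_table()].
#' @param blank_table blank/medium table sharing the feature schema.
#' @param config a [default_config()]; uses `blank_fraction`.
#' @return filtered `feature_table` with attribute `dropped`.
#' @export
subtract_blank <- function(table, blank_table, config = default_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(blank_table, "feature_table"))
  bm <- rowMeans(blank_table$matrix, na.rm = TRUE)[table$features$feature_id]
  bm[is.na(bm) | is.nan(bm)] <- 0
  sm <- rowMeans(table$matrix, na.rm = TRUE)
  sm[is.nan(sm)] <- 0
  drop <- bm > 0 & bm >= config$blank_fraction * sm
  out <- feature_table(table$features[!drop, , drop = FALSE],
                       table$matrix[!drop, , drop = FALSE])
  attr(out, "dropped") <- table$features$feature_id[drop]
  out
}
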