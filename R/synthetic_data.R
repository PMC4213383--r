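# Multiplicative lognormal noise parameterized by coefficient of variation,
# mean 1 so that the expected intensity equals the generating truth.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulation specification for a two-condition metabolome
#'
#' Defaults encode the study design this package targets: 451 metabolites
#' of which 227 are differential (28 of those exclusive to condition B),
#' 6 condition-A vs 4 condition-B biological replicates each injected
#' twice, m/z 62-955, with lognormal biological (25 %) and analytical
#' (10 %) relative standard deviations and redundant adduct/isotope/dimer
#' ions per metabolite.
#'
#' @param n_metabolites number of simulated metabolites.
#' @param fraction_differential fraction with a true fold change
#'   (condition-exclusive metabolites are drawn from this set).
#' @param n_exclusive_A,n_exclusive_B metabolites detected in only one
#'   condition.
#' @param fold_range range of the true fold magnitude for differential
#'   metabolites; folds are `10^U` with `U` uniform on `log10(fold_range)`,
#'   direction chosen at random.
#' @param biological_rsd_percent,analytical_rsd_percent lognormal noise
#'   levels (percent CV) between cultures and between injections.
#' @param n_bioreps integer vector `c(A = 6, B = 4)`.
#' @param n_injections analytical replicates per biological replicate.
#' @param mz_range,rt_range neutral-mass window (Da) and retention window (s).
#' @param p_isotope,p_adduct,p_dimer probability that a metabolite emits an
#'   M+1 isotopologue, an extra adduct, a proton-bound dimer.
#' @param mz_noise_ppm Gaussian m/z error (ppm) on each feature.
#' @param rt_jitter_s,rt_drift_s within-group RT scatter and between-ion
#'   drift (s).
#' @param library_fraction fraction of metabolites present in the emitted
#'   compound library; `n_decoys` extra library entries with no
#'   counterpart in the data.
#' @param n_decoys decoy library entries.
#' @param seed integer RNG seed; the same seed reproduces the output
#'   byte-identically.
#' @return list of class `metabolome_sim_spec`.
#' @export
metabolome_sim_spec <- function(n_metabolites = 451,
                                fraction_differential = 227 / 451,
                                n_exclusive_A = 0,
                                n_exclusive_B = 28,
                                fold_range = c(3, 30),
                                biological_rsd_percent = c(A = 25, B = 25),
                                analytical_rsd_percent = 10,
                                n_bioreps = c(A = 6, B = 4),
                                n_injections = 2,
                                mz_range = c(62, 955),
                                rt_range = c(60, 1740),
                                p_isotope = 0.7,
                                p_adduct = 0.4,
                                p_dimer = 0.1,
                                mz_noise_ppm = 2,
                                rt_jitter_s = 1,
                                rt_drift_s = 2,
                                library_fraction = 0.6,
                                n_decoys = 150,
                                seed = 1L) {
  spec <- as.list(environment())
  if (fraction_differential < 0 || fraction_differential > 1) {
    stop("fraction_differential must lie in [0, 1]")
  }
  n_diff <- round(fraction_differential * n_metabolites)
  if (n_exclusive_A + n_exclusive_B > n_diff) {
    stop("exclusive metabolite count (", n_exclusive_A + n_exclusive_B,
         ") exceeds the differential count (", n_diff, ")")
  }
  if (any(c(biological_rsd_percent, analytical_rsd_percent) < 0)) {
    stop("RSD percentages must be non-negative")
  }
  if (any(n_bioreps < 1) || n_injections < 1) stop("replicate counts must be >= 1")
  class(spec) <- "metabolome_sim_spec"
  spec
}

# Adduct constants shared with ion_annotation; exported there.
.sim_species <- function(mode) {
  rules <- default_ion_rules()
  rules[rules$mode == mode, ]
}

#' Simulate a two-condition LC/MS metabolome
#'
#' Generates a feature table with the statistical structure the analysis
#' pipeline assumes, together with a compound library and the generating
#' ground truth. Biological replicate intensity = true condition mean x
#' lognormal(biological RSD); each injection = biological value x
#' lognormal(analytical RSD). Every metabolite emits a principal ion
#' (`[M+H]+` or `[M-H]-`) and, at the configured probabilities, an M+1
#' isotopologue (+1.003355 Da), an extra adduct and a dimer, all co-eluting
#' up to the configured drift. Condition-exclusive metabolites have
#' all-missing cells in the other condition.
#'
#' @param spec a [metabolome_sim_spec()].
#' @return list with components `table` ([feature_table()]), `library`
#'   (compound_library), and `truth` (list with `metabolites` and `ions`
#'   data.frames; member ions partition the generated feature ids).
#' @export
simulate_metabolome <- function(spec = metabolome_sim_spec()) {
  stopifnot(inherits(spec, "metabolome_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_metabolites
  n_diff <- round(spec$fraction_differential * n)

  status <- rep("null", n)
  idx <- sample.int(n, n_diff)
  excl_A <- utils::head(idx, spec$n_exclusive_A)
  excl_B <- utils::head(setdiff(idx, excl_A), spec$n_exclusive_B)
  plain <- setdiff(idx, c(excl_A, excl_B))
  status[excl_A] <- "exclusive_A"
  status[excl_B] <- "exclusive_B"
  status[plain] <- sample(c("up", "down"), length(plain), replace = TRUE)

  lfr <- log10(spec$fold_range)
  fold <- rep(1, n)
  fold[plain] <- 10^stats::runif(length(plain), lfr[1], lfr[2])
  fold[status == "down"] <- 1 / fold[status == "down"]
  fold[excl_A] <- 0      # detected in A only: B/A ratio 0
  fold[excl_B] <- Inf    # detected in B only

  base <- stats::rlnorm(n, meanlog = log(1e6), sdlog = 1)
  mean_A <- base
  mean_B <- base * ifelse(is.finite(fold), fold, 1)
  mean_A[excl_B] <- NA_real_
  mean_B[excl_A] <- NA_real_

  neutral_mass <- stats::runif(n, spec$mz_range[1], spec$mz_range[2] * 0.93)
  rt <- stats::runif(n, spec$rt_range[1], spec$rt_range[2])
  mode <- sample(c("positive", "negative"), n, replace = TRUE, prob = c(0.6, 0.4))

  # ion roster per metabolite
  ions <- list()
  for (i in seq_len(n)) {
    sp <- .sim_species(mode[i])
    principal <- if (mode[i] == "positive") "[M+H]+" else "[M-H]-"
    roster <- data.frame(species = principal, rel = 1, stringsAsFactors = FALSE)
    if (stats::runif(1) < spec$p_isotope) {
      roster <- rbind(roster, data.frame(species = "M+1", rel = stats::runif(1, 0.1, 0.3)))
    }
    if (stats::runif(1) < spec$p_adduct) {
      extra <- setdiff(sp$species[sp$multiplicity == 1], principal)
      roster <- rbind(roster, data.frame(species = sample(extra, 1),
                                         rel = stats::runif(1, 0.1, 0.5)))
    }
    if (stats::runif(1) < spec$p_dimer) {
      dim_sp <- sp$species[sp$multiplicity == 2][1]
      roster <- rbind(roster, data.frame(species = dim_sp,
                                         rel = stats::runif(1, 0.05, 0.15)))
    }
    roster$metabolite <- i
    ions[[i]] <- roster
  }
  ions <- do.call(rbind, ions)
  ions$feature_id <- sprintf("F%04d", seq_len(nrow(ions)))

  rules <- default_ion_rules()
  theo_mz <- numeric(nrow(ions))
  for (k in seq_len(nrow(ions))) {
    m <- neutral_mass[ions$metabolite[k]]
    if (ions$species[k] == "M+1") {
      principal <- rules[rules$species == ifelse(mode[ions$metabolite[k]] == "positive",
                                                 "[M+H]+", "[M-H]-"), ]
      theo_mz[k] <- m * principal$multiplicity + principal$delta + 1.003355
    } else {
      r <- rules[rules$species == ions$species[k], ]
      theo_mz[k] <- m * r$multiplicity + r$delta
    }
  }
  obs_mz <- theo_mz * (1 + stats::rnorm(nrow(ions), 0, spec$mz_noise_ppm * 1e-6))
  obs_rt <- rt[ions$metabolite] +
    stats::rnorm(nrow(ions), 0, spec$rt_jitter_s) +
    stats::runif(nrow(ions), -spec$rt_drift_s / 2, spec$rt_drift_s / 2)
  obs_rt <- pmax(obs_rt, 0)

  # injection design
  design <- do.call(rbind, lapply(c("A", "B"), function(cond) {
    expand.grid(injection = seq_len(spec$n_injections),
                biorep = seq_len(spec$n_bioreps[[cond]]),
                condition = cond, stringsAsFactors = FALSE)
  }))
  inj_ids <- sprintf("%s_%d_%d", design$condition, design$biorep, design$injection)

  bio_cv <- spec$biological_rsd_percent / 100
  ana_cv <- spec$analytical_rsd_percent / 100

  # per-metabolite biological replicate values, shared by its member ions
  bio_val <- matrix(NA_real_, n, nrow(design))
  for (cond in c("A", "B")) {
    cm <- if (cond == "A") mean_A else mean_B
    for (b in seq_len(spec$n_bioreps[[cond]])) {
      noise <- cm * rlnorm_cv(n, bio_cv[[cond]])
      cols <- which(design$condition == cond & design$biorep == b)
      for (cc in cols) bio_val[, cc] <- noise
    }
  }
  mat <- matrix(NA_real_, nrow(ions), nrow(design),
                dimnames = list(ions$feature_id, inj_ids))
  for (k in seq_len(nrow(ions))) {
    v <- bio_val[ions$metabolite[k], ] * ions$rel[k] *
      rlnorm_cv(nrow(design), ana_cv)
    mat[k, ] <- v
  }

  features <- data.frame(feature_id = ions$feature_id, mz = obs_mz, rt = obs_rt,
                         ion_mode = mode[ions$metabolite],
                         stringsAsFactors = FALSE)
  tab <- feature_table(features, mat)

  # compound library: true entries for a fraction of metabolites plus decoys
  lib_idx <- sort(sample.int(n, round(spec$library_fraction * n)))
  with_std <- lib_idx[stats::runif(length(lib_idx)) < 0.3]
  lib <- data.frame(
    compound_id = sprintf("CPD%04d", lib_idx),
    name = sprintf("compound_%04d", lib_idx),
    formula = NA_character_,
    monoisotopic_mass = neutral_mass[lib_idx],
    ref_rt = ifelse(lib_idx %in% with_std, rt[lib_idx], NA_real_),
    standard_available = lib_idx %in% with_std,
    stringsAsFactors = FALSE
  )
  if (spec$n_decoys > 0) {
    decoys <- data.frame(
      compound_id = sprintf("DEC%04d", seq_len(spec$n_decoys)),
      name = sprintf("decoy_%04d", seq_len(spec$n_decoys)),
      formula = NA_character_,
      monoisotopic_mass = stats::runif(spec$n_decoys, spec$mz_range[1],
                                       spec$mz_range[2] * 0.93),
      ref_rt = NA_real_,
      standard_available = FALSE,
      stringsAsFactors = FALSE
    )
    lib <- rbind(lib, decoys)
  }
  class(lib) <- c("compound_library", "data.frame")

  truth <- list(
    metabolites = data.frame(
      metabolite_id = sprintf("MET%04d", seq_len(n)),
      status = status,
      true_ratio = fold,
      mean_A = mean_A,
      mean_B = mean_B,
      neutral_mass = neutral_mass,
      rt = rt,
      ion_mode = mode,
      compound_id = ifelse(seq_len(n) %in% lib_idx,
                           sprintf("CPD%04d", seq_len(n)), NA_character_),
      stringsAsFactors = FALSE
    ),
    ions = data.frame(
      feature_id = ions$feature_id,
      metabolite_id = sprintf("MET%04d", ions$metabolite),
      species = ions$species,
      stringsAsFactors = FALSE
    )
  )
  list(table = tab, library = lib, truth = truth)
}

#' Simulate a nucleotide calibration series
#'
#' Areas follow `slope * concentration + intercept + N(0, noise_sd)`.
#' Default levels are the study's calibration solutions: 0.1, 0.5, 1, 2.5,
#' 5, 7.5, 10 uM for AMP and ADP; 2, 5, 10, 15, 20 uM for ATP.
#'
#' @param analyte one of `"AMP"`, `"ADP"`, `"ATP"`.
#' @param true_slope,true_intercept generating line (area per uM, area).
#' @param noise_sd Gaussian area noise.
#' @param levels concentration levels (uM); defaults per analyte.
#' @return a `calibration_series` data.frame.
#' @export
simulate_calibration <- function(analyte = c("AMP", "ADP", "ATP"),
                                 true_slope = 1e5, true_intercept = 0,
                                 noise_sd = 0, levels = NULL) {
  analyte <- match.arg(analyte)
  if (is.null(levels)) {
    levels <- if (analyte == "ATP") c(2, 5, 10, 15, 20)
              else c(0.1, 0.5, 1, 2.5, 5, 7.5, 10)
  }
  if (length(levels) < 2) stop("need at least 2 calibration levels")
  if (any(levels < 0)) stop("negative concentrations are not allowed")
  area <- true_slope * levels + true_intercept +
    stats::rnorm(length(levels), 0, noise_sd)
  df <- data.frame(analyte = analyte, concentration = levels,
                   area = pmax(area, 0), stringsAsFactors = FALSE)
  class(df) <- c("calibration_series", "data.frame")
  df
}

#' Simulate an RNA-seq count table
#'
#' Negative-binomial counts for two conditions with per-replicate library
#' size factors (drawn lognormal, recorded in the ground truth) and a
#' chosen fraction of truly up-/down-regulated genes.
#'
#' @param n_genes number of genes (study scale: 3303, duplicate libraries).
#' @param n_reps replicates per condition (>= 2).
#' @param fraction_up,fraction_down fractions of genes with a true fold
#'   change in condition B relative to A.
#' @param fold_range magnitude range of true folds, as in
#'   [metabolome_sim_spec()].
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2); must
#'   be > 0.
#' @param base_mean_log mean/sd of log gene abundance.
#' @param seed RNG seed.
#' @return list with `counts` (a `gene_counts`) and `truth` (data.frame of
#'   gene-level true folds, plus `size_factors` attribute).
#' @export
simulate_counts <- function(n_genes = 3303, n_reps = 2,
                            fraction_up = 0.06, fraction_down = 0.06,
                            fold_range = c(3, 30), dispersion = 0.01,
                            base_mean_log = c(5, 1.5), seed = 1L) {
  if (n_reps < 2) stop("need at least 2 replicates per condition")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (fraction_up + fraction_down > 1) stop("fractions sum to more than 1")
  set.seed(seed)
  status <- rep("null", n_genes)
  n_up <- round(fraction_up * n_genes)
  n_dn <- round(fraction_down * n_genes)
  idx <- sample.int(n_genes, n_up + n_dn)
  status[utils::head(idx, n_up)] <- "up"
  status[utils::tail(idx, n_dn)] <- "down"
  lfr <- log10(fold_range)
  fold <- rep(1, n_genes)
  chg <- status != "null"
  fold[chg] <- 10^stats::runif(sum(chg), lfr[1], lfr[2])
  fold[status == "down"] <- 1 / fold[status == "down"]

  base <- exp(stats::rnorm(n_genes, base_mean_log[1], base_mean_log[2]))
  classes <- sample(c("enzyme", "ribosomal_protein", "unknown_function",
                      "stress_response", "transport", "regulator"),
                    n_genes, replace = TRUE)
  sf <- stats::rlnorm(2 * n_reps, 0, 0.15)
  cols <- c(sprintf("A_%d", seq_len(n_reps)), sprintf("B_%d", seq_len(n_reps)))
  mu <- cbind(matrix(base, n_genes, n_reps),
              matrix(base * fold, n_genes, n_reps))
  mu <- sweep(mu, 2, sf, `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   n_genes, 2 * n_reps, dimnames = list(NULL, cols))
  gene_len <- sample(300:3000, n_genes, replace = TRUE)
  start <- cumsum(gene_len + sample(50:400, n_genes, replace = TRUE))
  genes <- data.frame(
    gene_id = sprintf("GENE%04d", seq_len(n_genes)),
    class = classes,
    start = start,
    end = start + gene_len,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(gene_id = genes$gene_id, status = status,
                      true_fold = fold, base_mean = base,
                      stringsAsFactors = FALSE)
  attr(truth, "size_factors") <- stats::setNames(sf, cols)
  list(counts = gene_counts(genes, counts), truth = truth)
}
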