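#' @keywords internal
"_PACKAGE"

# Monoisotopic masses of the elements handled by the formula parser (Da).
# CHNOPS plus the halogens and the common salt-adduct metals.
.MONO_MASS <- c(
  C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  P = 30.97376151, S = 31.97207069, F = 18.99840322, Cl = 34.96885268,
  Br = 78.9183376, I = 126.904468, Na = 22.98976928, K = 38.9637069,
  Se = 79.9165218
)

#' Monoisotopic mass of an elemental formula
#'
#' Parses a Hill-style elemental formula (e.g. `"C6H12O6"`) and returns the
#' monoisotopic neutral mass in daltons, summing standard monoisotopic
#' atomic masses. Supported elements: C, H, N, O, P, S, F, Cl, Br, I, Na,
#' K, Se.
#'
#' @param formula character vector of formulas.
#' @return numeric vector of masses (Da).
#' @examples
#' monoisotopic_mass("C6H12O6") # glucose, 180.0634
#' @export
monoisotopic_mass <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_real_)
    tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", f, perl = TRUE)[[1]]
    parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f, perl = TRUE))[[1]]
    if (!nzchar(paste(parts, collapse = "")) ||
        nchar(paste(parts, collapse = "")) != nchar(f)) {
      stop("cannot parse elemental formula: '", f, "'", call. = FALSE)
    }
    mass <- 0
    for (p in parts) {
      el <- sub("[0-9]*$", "", p)
      n <- sub("^[A-Za-z]+", "", p)
      n <- if (nzchar(n)) as.numeric(n) else 1
      if (!el %in% names(.MONO_MASS)) {
        stop("unknown element '", el, "' in formula '", f, "'", call. = FALSE)
      }
      mass <- mass + .MONO_MASS[[el]] * n
    }
    mass
  }, numeric(1), USE.NAMES = FALSE)
}

#' Default run configuration
#'
#' Returns the pipeline configuration with the study defaults: a 3-fold
#' change threshold at alpha 0.05, a strict 10 ppm mass-matching tolerance,
#' and a 40 % biological RSD review flag. All tolerances can be overridden
#' via `load_config()` or by passing modified lists to the stage functions.
#'
#' @param ... named overrides of individual fields.
#' @return a named list of class `run_config`.
#' @details Fields (units):
#' \describe{
#'   \item{fold_threshold}{ratio threshold for increased/decreased calls (3)}
#'   \item{alpha}{significance level (0.05)}
#'   \item{ppm_tolerance}{strict library-match bound, ppm (10)}
#'   \item{rsd_flag_threshold_percent}{biological RSD review flag, closed bound (40)}
#'   \item{rt_coelution_tolerance_s}{max RT gap within a feature group, s (10)}
#'   \item{grouping_mz_tolerance_ppm}{neutral-mass agreement for adduct pairs, ppm (10)}
#'   \item{rt_match_tolerance_s}{RT window against an authentic standard, s (30)}
#'   \item{correlation_floor}{min intensity-profile correlation for grouping (0.9)}
#'   \item{blank_fraction}{drop feature if blank mean >= this fraction of sample mean (0.5)}
#'   \item{min_detected_exclusive}{bioreps required to call condition exclusivity (3)}
#'   \item{multiple_testing_method}{"none" for metabolites; "BH" optional}
#'   \item{test_scale}{"raw" or "log" intensities for the ratio test}
#'   \item{pareto_mode}{"pareto" or "auto" (unit-variance) scaling}
#'   \item{low_count_threshold}{normalized-mean floor below which genes are
#'     labelled low_expression (10)}
#'   \item{pseudocount}{added to normalized means before the gene fold ratio (0.5)}
#'   \item{run_length_s}{declared chromatographic run length, s}
#'   \item{random_seed}{integer seed used by `run_pipeline()`}
#' }
#' @export
default_config <- function(...) {
  cfg <- list(
    fold_threshold = 3,
    alpha = 0.05,
    ppm_tolerance = 10,
    rsd_flag_threshold_percent = 40,
    rt_coelution_tolerance_s = 10,
    grouping_mz_tolerance_ppm = 10,
    rt_match_tolerance_s = 30,
    correlation_floor = 0.9,
    blank_fraction = 0.5,
    min_detected_exclusive = 3,
    multiple_testing_method = "none",
    test_scale = "raw",
    pareto_mode = "pareto",
    low_count_threshold = 10,
    pseudocount = 0.5,
    run_length_s = 2100,
    random_seed = 1L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  tol_fields <- c("fold_threshold", "ppm_tolerance", "rsd_flag_threshold_percent",
                  "rt_coelution_tolerance_s", "grouping_mz_tolerance_ppm",
                  "rt_match_tolerance_s", "run_length_s")
  for (f in tol_fields) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("config field '", f, "' must be > 0", call. = FALSE)
    }
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("config field 'alpha' must lie in (0, 1)", call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML or JSON
#'
#' Flat keys as in [default_config()]; omitted keys take the defaults.
#'
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return a `run_config` list.
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be YAML or JSON, got extension '.", ext, "'")
  )
  if (is.null(vals)) vals <- list()
  do.call(default_config, vals)
}

# ---- FeatureTable ----------------------------------------------------------

#' Construct a feature table
#'
#' The central container of the metabolomics stages: a features x injections
#' matrix of non-negative peak areas (NA = not detected), feature metadata
#' (m/z in Da, retention time in seconds, ion mode), and the injection
#' design. Injection columns are named `<condition>_<biorep>_<injection>`
#' with condition labels A and B (in the bundled study configuration A is
#' succinate, B is quinate).
#'
#' @param features data.frame with columns `feature_id`, `mz`, `rt`,
#'   `ion_mode` (`"positive"`/`"negative"`); extra columns are preserved.
#' @param matrix numeric matrix, rows matching `features`, columns named by
#'   injection id.
#' @return object of class `feature_table` with components `features`,
#'   `samples` (parsed design) and `matrix`.
#' @export
feature_table <- function(features, matrix) {
  stopifnot(is.data.frame(features))
  req <- c("feature_id", "mz", "rt", "ion_mode")
  miss <- setdiff(req, names(features))
  if (length(miss)) stop("features missing column(s): ", paste(miss, collapse = ", "))
  features$feature_id <- as.character(features$feature_id)
  if (anyDuplicated(features$feature_id)) {
    dup <- unique(features$feature_id[duplicated(features$feature_id)])
    stop("duplicate feature ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (any(!is.finite(features$mz) | features$mz <= 0)) {
    stop("feature m/z must be positive (row ",
         which(!is.finite(features$mz) | features$mz <= 0)[1], ")")
  }
  if (any(!is.finite(features$rt) | features$rt < 0)) {
    stop("feature rt must be non-negative seconds (row ",
         which(!is.finite(features$rt) | features$rt < 0)[1], ")")
  }
  if (!all(features$ion_mode %in% c("positive", "negative"))) {
    stop("ion_mode must be 'positive' or 'negative' (row ",
         which(!features$ion_mode %in% c("positive", "negative"))[1], ")")
  }
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (nrow(matrix) != nrow(features)) {
    stop("matrix has ", nrow(matrix), " rows but features has ", nrow(features))
  }
  rownames(matrix) <- features$feature_id
  neg <- which(!is.na(matrix) & matrix < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop("negative peak area at feature '", rownames(matrix)[neg[1, 1]],
         "', injection '", colnames(matrix)[neg[1, 2]], "'")
  }
  samples <- parse_injection_ids(colnames(matrix))
  structure(list(features = features, samples = samples, matrix = matrix),
            class = "feature_table")
}

parse_injection_ids <- function(ids) {
  if (is.null(ids) || any(!nzchar(ids))) stop("injection columns must be named")
  parts <- strsplit(ids, "_", fixed = TRUE)
  ok <- lengths(parts) %in% c(2L, 3L)
  if (any(!ok)) {
    stop("injection id '", ids[which(!ok)[1]],
         "' is not of the form <condition>_<biorep>[_<injection>]")
  }
  cond <- vapply(parts, `[[`, "", 1L)
  if (!all(cond %in% c("A", "B"))) {
    stop("unknown condition label '", cond[which(!cond %in% c("A", "B"))[1]],
         "' in injection id '", ids[which(!cond %in% c("A", "B"))[1]], "'")
  }
  biorep <- as.integer(vapply(parts, `[[`, "", 2L))
  inj <- vapply(parts, function(p) if (length(p) == 3L) as.integer(p[[3]]) else 1L,
                integer(1))
  if (anyNA(biorep) || anyNA(inj)) {
    stop("non-integer biorep/injection index in injection ids")
  }
  data.frame(injection_id = ids, condition = cond, biorep = biorep,
             injection = inj, stringsAsFactors = FALSE)
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$features), "features x",
      ncol(x$matrix), "injections\n")
  cat("  conditions:",
      paste(sprintf("%s (%d bioreps)", unique(x$samples$condition),
                    tapply(x$samples$biorep, x$samples$condition,
                           function(b) length(unique(b)))[unique(x$samples$condition)]),
            collapse = ", "), "\n")
  cat("  m/z range:", paste(round(range(x$features$mz), 4), collapse = " - "), "\n")
  invisible(x)
}

#' Read / write a feature table CSV
#'
#' The CSV carries columns `feature_id`, `mz`, `rt`, `ion_mode`, optionally
#' `neutral_mass`, followed by one column per injection named
#' `<condition>_<biorep>_<injection>`. Empty cells are preserved as missing
#' (not detected), never coerced to zero.
#'
#' @param path CSV file path.
#' @return `read_feature_table()` returns a [feature_table()];
#'   `write_feature_table()` returns `path` invisibly.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- intersect(c("feature_id", "mz", "rt", "ion_mode", "neutral_mass"),
                         names(df))
  if (!all(c("feature_id", "mz", "rt", "ion_mode") %in% meta_cols)) {
    stop("feature CSV must have columns feature_id, mz, rt, ion_mode")
  }
  inj_cols <- setdiff(names(df), meta_cols)
  if (!length(inj_cols)) stop("feature CSV has no injection columns")
  mat <- as.matrix(df[inj_cols])
  storage.mode(mat) <- "double"
  neg <- which(!is.na(mat) & mat < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop("negative area in row ", neg[1, 1], " (feature '",
         df$feature_id[neg[1, 1]], "'), column '", inj_cols[neg[1, 2]], "'")
  }
  feature_table(df[meta_cols], mat)
}

#' @rdname read_feature_table
#' @param x a `feature_table`.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  df <- cbind(x$features, as.data.frame(x$matrix, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# ---- Compound library ------------------------------------------------------

#' Read a compound library TSV
#'
#' Columns: `compound_id`, `name`, optionally `formula`,
#' `monoisotopic_mass` (Da), `ref_rt` (s) and `standard_available`
#' (TRUE/FALSE). When the mass column is absent or empty it is derived from
#' the elemental formula.
#'
#' @param path TSV file.
#' @return data.frame of class `compound_library`.
#' @export
read_compound_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "name") %in% names(df))) {
    stop("compound library must have columns compound_id and name")
  }
  if (is.null(df$monoisotopic_mass)) df$monoisotopic_mass <- NA_real_
  if (is.null(df$formula)) df$formula <- NA_character_
  need <- is.na(df$monoisotopic_mass)
  if (any(need)) {
    if (any(need & (is.na(df$formula) | !nzchar(df$formula)))) {
      stop("library row ", which(need & (is.na(df$formula) | !nzchar(df$formula)))[1],
           " has neither monoisotopic_mass nor formula")
    }
    df$monoisotopic_mass[need] <- monoisotopic_mass(df$formula[need])
  }
  if (any(df$monoisotopic_mass <= 0)) {
    stop("non-positive monoisotopic mass in library row ",
         which(df$monoisotopic_mass <= 0)[1])
  }
  if (is.null(df$ref_rt)) df$ref_rt <- NA_real_
  if (is.null(df$standard_available)) df$standard_available <- FALSE
  df$standard_available <- as.logical(df$standard_available) & !is.na(df$ref_rt)
  class(df) <- c("compound_library", "data.frame")
  df
}

#' @rdname read_compound_library
#' @param x a `compound_library` data.frame.
#' @export
write_compound_library <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

# ---- Calibration series ----------------------------------------------------

#' Read a nucleotide calibration CSV
#'
#' Columns `analyte` (AMP/ADP/ATP), `concentration` (uM), `area`. Each
#' analyte needs at least two distinct concentration levels (a line cannot
#' be fitted otherwise) and non-negative areas.
#'
#' @param path CSV file.
#' @return data.frame of class `calibration_series`.
#' @export
read_calibration <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("analyte", "concentration", "area") %in% names(df))) {
    stop("calibration CSV must have columns analyte, concentration, area")
  }
  if (any(df$concentration < 0)) {
    stop("negative concentration in calibration row ",
         which(df$concentration < 0)[1])
  }
  if (any(df$area < 0)) {
    stop("negative area in calibration row ", which(df$area < 0)[1])
  }
  for (a in unique(df$analyte)) {
    if (length(unique(df$concentration[df$analyte == a])) < 2) {
      stop("calibration series for ", a,
           " has a single concentration level; cannot fit a line")
    }
  }
  class(df) <- c("calibration_series", "data.frame")
  df
}

#' @rdname read_calibration
#' @param x a `calibration_series` data.frame.
#' @export
write_calibration <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

# ---- Gene counts -----------------------------------------------------------

#' Read a gene count TSV
#'
#' Columns: `gene_id`, `class` (functional class label), optionally
#' `start`, `end`, `strand` genome coordinates, then one integer count
#' column per replicate named `<condition>_<rep>` with condition A or B.
#'
#' @param path TSV file.
#' @return list of class `gene_counts` with `genes` (metadata data.frame),
#'   `samples` (design) and `counts` (integer matrix).
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- intersect(c("gene_id", "class", "start", "end", "strand"), names(df))
  if (!all(c("gene_id", "class") %in% meta_cols)) {
    stop("count TSV must have columns gene_id and class")
  }
  cnt_cols <- setdiff(names(df), meta_cols)
  if (!length(cnt_cols)) stop("count TSV has no replicate columns")
  mat <- as.matrix(df[cnt_cols])
  bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("counts must be non-negative integers: row ", bad[1, 1],
         ", column '", cnt_cols[bad[1, 2]], "'")
  }
  storage.mode(mat) <- "integer"
  gene_counts(df[meta_cols], mat)
}

#' @rdname read_counts
#' @param genes gene metadata data.frame (`gene_id`, `class`, optional
#'   coordinates).
#' @param counts integer matrix with replicate columns `<condition>_<rep>`.
#' @export
gene_counts <- function(genes, counts) {
  genes$gene_id <- as.character(genes$gene_id)
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(genes)) stop("counts/genes row mismatch")
  rownames(counts) <- genes$gene_id
  samples <- parse_injection_ids(colnames(counts))
  structure(list(genes = genes, samples = samples, counts = counts),
            class = "gene_counts")
}

#' @rdname read_counts
#' @param x a `gene_counts` object.
#' @export
write_counts <- function(x, path) {
  df <- cbind(x$genes, as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
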