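#' Multi-modal feature table
#'
#' The central data container of the package: a numeric subjects-by-features
#' matrix with explicit missing entries, a modality label per feature, and a
#' scale state that records how far along the preprocessing path the values
#' are (`"raw"`, `"log"`, or `"standardized"`).
#'
#' @param values Numeric matrix, subjects in rows and features in columns,
#'   with row and column names set to subject and feature identifiers.
#'   `NA` entries mark missing measurements.
#' @param modality Named character vector mapping every feature identifier to
#'   one of `"protein"`, `"lipid"`, `"acylcarnitine"`, `"imaging"`,
#'   `"clinical"`.
#' @param scale_state One of `"raw"`, `"log"`, `"standardized"`.
#' @param provenance Free-text note on where the values came from.
#'
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, modality,
                          scale_state = c("raw", "log", "standardized"),
                          provenance = "") {
  scale_state <- match.arg(scale_state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry subject (row) and feature (column) names")
  dup_s <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_s))
    stop("duplicate subject identifiers: ", paste(dup_s, collapse = ", "))
  dup_f <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_f))
    stop("duplicate feature identifiers: ", paste(dup_f, collapse = ", "))
  modality <- unlist(modality)
  missing_mod <- setdiff(colnames(values), names(modality))
  if (length(missing_mod))
    stop("features without a modality label: ",
         paste(missing_mod, collapse = ", "))
  bad <- setdiff(unique(modality), netomics_modalities())
  if (length(bad))
    stop("unknown modality label(s): ", paste(bad, collapse = ", "))
  structure(
    list(values = values,
         modality = modality[colnames(values)],
         scale_state = scale_state,
         provenance = provenance),
    class = "feature_table")
}

netomics_modalities <- function() {
  c("protein", "lipid", "acylcarnitine", "imaging", "clinical")
}

#' @export
print.feature_table <- function(x, ...) {
  v <- x$values
  cat(sprintf("feature_table: %d subjects x %d features [%s]\n",
              nrow(v), ncol(v), x$scale_state))
  cat("  modalities:",
      paste(sprintf("%s=%d", names(table(x$modality)), table(x$modality)),
            collapse = ", "), "\n")
  cat(sprintf("  missing entries: %d (%.1f%%)\n", sum(is.na(v)),
              100 * mean(is.na(v))))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subject identifiers of a feature table
#' @param table A `feature_table`.
#' @return Character vector of subject ids.
#' @export
subject_ids <- function(table) rownames(table$values)

#' Feature identifiers of a feature table
#' @param table A `feature_table`.
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(table) colnames(table$values)

# Values accepted as missing in input files; anything else that fails to
# parse as a number is a hard error, not silent missingness.
MISSING_SENTINELS <- c("NA", "NaN", "", ".")

#' Read a delimited feature matrix with a modality map
#'
#' Reads a TSV/CSV numeric matrix (one header row, first column holds
#' identifiers) and attaches modality labels from a two-column map file
#' (`feature_id`, `modality`). Cells equal to `"NA"`, `"NaN"`, `"."` or empty
#' become missing; any other unparseable cell is an error.
#'
#' @param path Path to the delimited matrix.
#' @param orientation `"subjects_in_rows"` (default) or `"features_in_rows"`.
#' @param modality_map Path to the modality map file, or a data frame with
#'   columns `feature_id` and `modality`.
#' @param sep Field separator; guessed from the file extension when `NULL`
#'   (`.csv` means comma, anything else tab).
#'
#' @return A `feature_table` with `scale_state = "raw"`.
#' @export
read_feature_table <- function(path,
                               orientation = c("subjects_in_rows",
                                               "features_in_rows"),
                               modality_map, sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL, quote = "\"",
                           comment.char = "")
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate row identifiers in ", path, ": ",
         paste(dup, collapse = ", "))
  hdr <- colnames(raw)[-1L]
  dup <- unique(hdr[duplicated(hdr)])
  if (length(dup))
    stop("duplicate column identifiers in ", path, ": ",
         paste(dup, collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  dimnames(cells) <- list(ids, hdr)
  vals <- parse_numeric_cells(cells, path)
  if (orientation == "features_in_rows") vals <- t(vals)

  mm <- if (is.character(modality_map)) {
    utils::read.table(modality_map, sep = sep, header = TRUE,
                      check.names = FALSE, colClasses = "character")
  } else as.data.frame(modality_map, stringsAsFactors = FALSE)
  if (!all(c("feature_id", "modality") %in% colnames(mm)))
    stop("modality map needs columns `feature_id` and `modality`")
  modality <- stats::setNames(mm$modality, mm$feature_id)
  uncovered <- setdiff(colnames(vals), names(modality))
  if (length(uncovered))
    stop("modality map does not cover feature(s): ",
         paste(uncovered, collapse = ", "))
  feature_table(vals, modality, scale_state = "raw",
                provenance = paste0("read from ", path))
}

parse_numeric_cells <- function(cells, path) {
  flat <- trimws(as.vector(cells))
  # read.table already maps the literal string "NA" to NA at read time
  is_missing <- is.na(flat) | flat %in% MISSING_SENTINELS
  num <- suppressWarnings(as.numeric(flat))
  bad <- !is_missing & is.na(num)
  if (any(bad)) {
    idx <- which(bad)[1L]
    stop(sprintf("unparseable cell %s in %s (row %d, column %d)",
                 dQuote(flat[idx]), path,
                 (idx - 1L) %% nrow(cells) + 1L,
                 (idx - 1L) %/% nrow(cells) + 1L))
  }
  num[is_missing] <- NA_real_
  matrix(num, nrow = nrow(cells), dimnames = dimnames(cells))
}

#' Merge per-modality tables into one analysis matrix
#'
#' Subjects are the union across tables (entries absent from a source table
#' become missing); features are concatenated and must be disjoint.
#'
#' @param tables List of `feature_table` objects sharing a `scale_state`.
#' @return A single merged `feature_table`.
#' @export
merge_modalities <- function(tables) {
  stopifnot(length(tables) >= 1L)
  lapply(tables, function(t) stopifnot(inherits(t, "feature_table")))
  states <- unique(vapply(tables, `[[`, "", "scale_state"))
  if (length(states) > 1L)
    stop("tables have incompatible scale_state: ",
         paste(states, collapse = " vs "))
  all_feats <- unlist(lapply(tables, feature_ids))
  dup <- unique(all_feats[duplicated(all_feats)])
  if (length(dup))
    stop("feature id(s) present in more than one table: ",
         paste(dup, collapse = ", "))
  subjects <- unique(unlist(lapply(tables, subject_ids)))
  out <- matrix(NA_real_, length(subjects), length(all_feats),
                dimnames = list(subjects, all_feats))
  for (t in tables)
    out[subject_ids(t), feature_ids(t)] <- t$values
  modality <- do.call(c, lapply(tables, `[[`, "modality"))
  feature_table(out, modality, scale_state = states,
                provenance = paste0("merged(",
                  paste(vapply(tables, `[[`, "", "provenance"),
                        collapse = "; "), ")"))
}

#' Unit conversion map
#'
#' @param feature_id Character vector of feature identifiers.
#' @param factor Positive multiplicative conversion factors.
#' @param from_unit,to_unit Unit labels (documentation only).
#' @return A data frame of class `unit_conversion_map`.
#' @export
unit_conversion_map <- function(feature_id, factor, from_unit = "",
                                to_unit = "") {
  if (any(factor <= 0)) stop("conversion factors must be positive")
  structure(data.frame(feature_id = as.character(feature_id),
                       factor = as.numeric(factor),
                       from_unit = from_unit, to_unit = to_unit,
                       stringsAsFactors = FALSE),
            class = c("unit_conversion_map", "data.frame"))
}

#' Invert a unit conversion map
#' @param map A `unit_conversion_map`.
#' @return The inverse map (reciprocal factors, units swapped).
#' @export
invert_unit_map <- function(map) {
  unit_conversion_map(map$feature_id, 1 / map$factor,
                      from_unit = map$to_unit, to_unit = map$from_unit)
}

#' Harmonize measurement units across cohorts
#'
#' Multiplies the mapped features by their conversion factor. Used to bring
#' natriuretic-peptide assays reported in pmol/L or nmol/L onto the pg/ml and
#' ng/ml scales used elsewhere (e.g. ANP 3.081 pg/ml per pmol/L, BNP 3.47,
#' NT-proBNP 8.475, NT-proANP 12.7 ng/ml per nmol/L).
#'
#' @param table A raw-scale `feature_table`.
#' @param map A `unit_conversion_map` (or data frame with `feature_id` and
#'   `factor` columns).
#' @return The converted `feature_table`; missing entries stay missing.
#' @export
harmonize_units <- function(table, map) {
  stopifnot(inherits(table, "feature_table"))
  if (table$scale_state != "raw")
    stop("unit harmonization applies to raw-scale tables only")
  if (nrow(map) == 0L) return(table)
  unknown <- setdiff(map$feature_id, feature_ids(table))
  if (length(unknown))
    stop("unit map references unknown feature(s): ",
         paste(unknown, collapse = ", "))
  for (i in seq_len(nrow(map)))
    table$values[, map$feature_id[i]] <-
      table$values[, map$feature_id[i]] * map$factor[i]
  table
}

#' Drop features with too many missing measurements
#'
#' Keeps features whose observed fraction is at least `min_fraction`
#' (boundary inclusive), mirroring the 70% completeness rule commonly applied
#' to echocardiographic variables.
#'
#' @param table A `feature_table`.
#' @param min_fraction Minimum observed fraction in `(0, 1]`.
#' @return The filtered table, with the dropped feature ids in attribute
#'   `"dropped"`.
#' @export
filter_completeness <- function(table, min_fraction = 0.7) {
  stopifnot(inherits(table, "feature_table"),
            min_fraction > 0, min_fraction <= 1)
  frac <- colMeans(!is.na(table$values))
  keep <- frac >= min_fraction
  if (!any(keep))
    stop("completeness filter at ", min_fraction, " drops every feature")
  dropped <- feature_ids(table)[!keep]
  table$values <- table$values[, keep, drop = FALSE]
  table$modality <- table$modality[keep]
  attr(table, "dropped") <- dropped
  table
}

#' Log2-transform selected features
#'
#' Molecular abundances enter the co-expression machinery on the log scale;
#' imaging/clinical variables (ratios, velocities, possibly negative) are
#' typically left untouched, so the transform is restricted by modality.
#'
#' @param table A raw-scale `feature_table`.
#' @param offset Non-negative pseudo-count added before taking logs.
#' @param modalities Modalities to transform (default: the molecular ones).
#' @return The table with transformed columns and `scale_state = "log"`.
#' @export
log_transform <- function(table, offset = 0,
                          modalities = c("protein", "lipid",
                                         "acylcarnitine")) {
  stopifnot(inherits(table, "feature_table"), offset >= 0)
  if (table$scale_state != "raw")
    stop("log transform applies to raw-scale tables only")
  sel <- which(table$modality %in% modalities)
  for (j in sel) {
    x <- table$values[, j]
    bad <- which(!is.na(x) & x + offset <= 0)
    if (length(bad))
      stop(sprintf(
        "non-positive value for feature %s (subject %s) with offset %g",
        feature_ids(table)[j], subject_ids(table)[bad[1L]], offset))
    table$values[, j] <- log2(x + offset)
  }
  table$scale_state <- "log"
  table
}

#' Pareto-scale every feature
#'
#' Mean-centers each feature and divides by the square root of its sample
#' standard deviation (n-1 denominator), computed over observed entries only.
#' Milder than unit-variance scaling; the post-scaling variance of a feature
#' equals its pre-scaling standard deviation.
#'
#' @param table A `feature_table` on the raw or log scale.
#' @return The standardized table (`scale_state = "standardized"`).
#' @export
pareto_scale <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (!table$scale_state %in% c("raw", "log"))
    stop("table is already standardized")
  v <- table$values
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    obs <- !is.na(x)
    if (sum(obs) < 2L)
      stop("feature ", colnames(v)[j], " has fewer than 2 observed values")
    s <- stats::sd(x[obs])
    if (s == 0)
      stop("constant feature cannot be pareto-scaled: ", colnames(v)[j])
    v[, j] <- (x - mean(x[obs])) / sqrt(s)
  }
  table$values <- v
  table$scale_state <- "standardized"
  table
}

#' Flag outlying entries as missing
#'
#' Marks observed entries farther than `k` robust deviations from the feature
#' median (median +/- k * MAD, MAD scaled by 1.4826) as missing. Features with
#' zero MAD are skipped with a warning rather than wiped out.
#'
#' @param table A `feature_table` on the raw or log scale.
#' @param k Robust-deviation multiplier (default 5).
#' @return The table with outliers set missing; the number of flagged entries
#'   is in attribute `"n_flagged"`.
#' @export
flag_outliers <- function(table, k = 5) {
  stopifnot(inherits(table, "feature_table"), k > 0)
  if (!table$scale_state %in% c("raw", "log"))
    stop("outlier flagging applies before standardization")
  v <- table$values
  n_flagged <- 0L
  skipped <- character()
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    obs <- which(!is.na(x))
    if (!length(obs)) next
    med <- stats::median(x[obs])
    mad <- stats::mad(x[obs], center = med)   # 1.4826 scaling is mad()'s default
    if (mad == 0) {
      skipped <- c(skipped, colnames(v)[j])
      next
    }
    out <- obs[abs(x[obs] - med) > k * mad]
    if (length(out)) {
      v[out, j] <- NA_real_
      n_flagged <- n_flagged + length(out)
    }
  }
  if (length(skipped))
    warning("zero MAD, outlier rule skipped for: ",
            paste(skipped, collapse = ", "))
  table$values <- v
  attr(table, "n_flagged") <- n_flagged
  table
}

#' Fill missing entries by a simple rule
#'
#' Plumbing utility (not a multiple-imputation procedure): replaces missing
#' entries by the feature median, or by the mean over the `k` nearest
#' subjects in Euclidean distance on jointly observed features.
#'
#' @param table A `feature_table`.
#' @param method `"median"` or `"knn"`.
#' @param k Number of neighbours for `method = "knn"`.
#' @return A complete `feature_table`.
#' @export
impute_simple <- function(table, method = c("median", "knn"), k = 5L) {
  stopifnot(inherits(table, "feature_table"))
  method <- match.arg(method)
  v <- table$values
  all_missing <- colSums(!is.na(v)) == 0L
  if (any(all_missing))
    stop("feature(s) entirely missing, cannot impute: ",
         paste(colnames(v)[all_missing], collapse = ", "))
  if (!anyNA(v)) return(table)
  if (method == "median") {
    med <- apply(v, 2L, stats::median, na.rm = TRUE)
    for (j in seq_len(ncol(v))) {
      miss <- is.na(v[, j])
      if (any(miss)) v[miss, j] <- med[j]
    }
  } else {
    med <- apply(v, 2L, stats::median, na.rm = TRUE)
    for (i in seq_len(nrow(v))) {
      miss <- which(is.na(v[i, ]))
      if (!length(miss)) next
      d <- knn_distances(v, i)
      ord <- order(d)
      for (j in miss) {
        donors <- ord[!is.na(v[ord, j])]
        donors <- donors[seq_len(min(k, length(donors)))]
        v[i, j] <- if (length(donors)) mean(v[donors, j]) else med[j]
      }
    }
  }
  table$values <- v
  table
}

# Mean squared difference over shared observed features between subject i and
# every other subject; Inf where nothing is shared.
knn_distances <- function(v, i) {
  xi <- v[i, ]
  d <- rep(Inf, nrow(v))
  for (r in seq_len(nrow(v))) {
    if (r == i) next
    shared <- !is.na(xi) & !is.na(v[r, ])
    if (any(shared)) d[r] <- mean((xi[shared] - v[r, shared])^2)
  }
  d
}
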