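# Per-sequence feature vectors: intrinsic features plus per-megabase
# evidence densities, with versioned TSV serialization.

FEATURE_SCHEMA_VERSION <- "organellr/1"

ORGANELLR_CLASSES <- c("nuclear", "mitochondrion", "plastid")

# Fixed column order; `label` is appended only when labels are attached.
.feature_columns <- c(
  "seq_id", "length_bp", "gc", "gc_delta", "gc_zscore", "gc_outlier_flag",
  "repeat_density", "repeat_frac", "rrna_density", "trna_density",
  "cpg_density", "mito_hit_density", "plastid_hit_density",
  "mito_hit_count", "plastid_hit_count",
  "best_mito_bitscore", "best_plastid_bitscore"
)

# Numeric columns the classifier consumes (everything except seq_id/label).
.model_columns <- setdiff(.feature_columns, "seq_id")

#' Feature density per megabase
#'
#' Scales a feature count to occurrences per 1 Mb of sequence:
#' `count * 1e6 / length_bp`.
#'
#' @param count Non-negative count vector.
#' @param length_bp Sequence length(s) in bp, all at least 1.
#' @return Numeric per-Mb rate.
#' @export
density_per_mb <- function(count, length_bp) {
  if (any(length_bp < 1)) stop("length_bp must be >= 1", call. = FALSE)
  if (any(count < 0)) stop("count must be >= 0", call. = FALSE)
  count * 1e6 / length_bp
}

#' Build the per-sequence feature table
#'
#' Assembles one numeric feature vector per assembly sequence from the
#' sequence itself (length, GC, assembly-relative GC deviation) and its
#' evidence counts (densitised per Mb; raw homology-hit counts and best
#' bitscores are kept as additional columns). The result is deterministic
#' and fully determined by its inputs.
#'
#' @param seqs Assembly as a named `DNAStringSet` (see [read_assembly()]).
#' @param stats Optional `assembly_gc_stats`; computed from `seqs` when
#'   `NULL`.
#' @param evidence Optional evidence data.frame from [collapse_evidence()];
#'   `NULL` means no evidence (all-zero counts). Must cover exactly the
#'   assembly's sequences.
#' @param z_cutoff GC-outlier z-score cutoff passed to [gc_deviation()].
#' @return A `data.frame` of class `odna_features` with attribute
#'   `schema_version`, one row per sequence, columns in fixed schema order.
#' @export
build_features <- function(seqs, stats = NULL, evidence = NULL, z_cutoff = 2) {
  seqs <- .as_dna_set(seqs)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("assembly sequences must be named", call. = FALSE)
  }
  if (is.null(stats)) stats <- assembly_gc_stats(seqs)
  if (is.null(evidence)) {
    evidence <- collapse_evidence(ids)
  }
  unknown <- setdiff(evidence$seq_id, ids)
  if (length(unknown) > 0L) {
    stop("evidence refers to sequences not in the assembly: ",
         paste(head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(ids, evidence$seq_id)
  if (length(missing) > 0L) {
    stop("evidence is missing assembly sequences: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  ev <- evidence[match(ids, evidence$seq_id), , drop = FALSE]

  len <- as.numeric(Biostrings::width(seqs))
  gc <- gc_content(seqs)
  dev <- gc_deviation(gc, stats, z_cutoff = z_cutoff)

  tab <- data.frame(
    seq_id = ids,
    length_bp = len,
    gc = gc,
    gc_delta = dev$delta,
    gc_zscore = dev$zscore,
    gc_outlier_flag = as.integer(dev$flag),
    repeat_density = density_per_mb(ev$repeat_count, len),
    repeat_frac = ev$repeat_bp / len,
    rrna_density = density_per_mb(ev$rrna_count, len),
    trna_density = density_per_mb(ev$trna_count, len),
    cpg_density = density_per_mb(ev$cpg_island_count, len),
    mito_hit_density = density_per_mb(ev$mito_hit_count, len),
    plastid_hit_density = density_per_mb(ev$plastid_hit_count, len),
    mito_hit_count = as.numeric(ev$mito_hit_count),
    plastid_hit_count = as.numeric(ev$plastid_hit_count),
    best_mito_bitscore = ev$best_mito_bitscore,
    best_plastid_bitscore = ev$best_plastid_bitscore,
    stringsAsFactors = FALSE
  )
  structure(tab, class = c("odna_features", "data.frame"),
            schema_version = FEATURE_SCHEMA_VERSION)
}

#' Attach class labels to a feature table
#'
#' @param table Feature table from [build_features()] or
#'   [read_feature_table()].
#' @param labels Named character vector (seq_id -> class) or two-column
#'   data.frame; classes must be among nuclear/mitochondrion/plastid.
#' @return The table with a `label` column appended.
#' @export
attach_labels <- function(table, labels) {
  if (is.data.frame(labels)) {
    labels <- setNames(as.character(labels[[2]]), as.character(labels[[1]]))
  }
  bad <- setdiff(unique(labels), ORGANELLR_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(table$seq_id, names(labels))
  extra <- setdiff(names(labels), table$seq_id)
  if (length(missing) > 0L || length(extra) > 0L) {
    stop("label/table id mismatch; missing labels: ",
         paste(head(missing, 5L), collapse = ", "),
         "; labels without rows: ",
         paste(head(extra, 5L), collapse = ", "), call. = FALSE)
  }
  table$label <- unname(labels[table$seq_id])
  table
}

.fmt_num <- function(x) {
  # 17 significant digits: lossless decimal round-trip for doubles
  out <- sprintf("%.17g", x)
  out[x == floor(x) & abs(x) < 1e15] <- sprintf("%.0f", x[x == floor(x) & abs(x) < 1e15])
  out
}

#' Write / read a feature table as TSV
#'
#' The table is written with a schema-version header line
#' (`#schema=organellr/1`) and floats at 17 significant digits so that
#' `read_feature_table(write_feature_table(x))` is bit-exact. Columns are
#' realigned by header name on read, so column order in the file is free;
#' a file with a different schema version is rejected.
#'
#' @param table Feature table (optionally with a `label` column).
#' @param path File path.
#' @return `write_feature_table`: `path` invisibly; `read_feature_table`:
#'   the table.
#' @export
write_feature_table <- function(table, path) {
  cols <- intersect(c(.feature_columns, "label"), colnames(table))
  tab <- as.data.frame(table)[, cols, drop = FALSE]
  num <- vapply(tab, is.numeric, logical(1))
  for (j in which(num)) tab[[j]] <- .fmt_num(tab[[j]])
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#schema=", FEATURE_SCHEMA_VERSION), con)
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(tab) > 0L) {
    writeLines(do.call(paste, c(unname(tab), sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  ver <- sub("^#schema=", "", first)
  if (!startsWith(first, "#schema=") || ver != FEATURE_SCHEMA_VERSION) {
    stop("incompatible feature-table schema: expected ", FEATURE_SCHEMA_VERSION,
         ", found ", if (startsWith(first, "#schema=")) ver else "no schema header",
         call. = FALSE)
  }
  tab <- read.delim(path, skip = 1L, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  need <- .feature_columns
  missing <- setdiff(need, colnames(tab))
  if (length(missing) > 0L) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cols <- intersect(c(.feature_columns, "label"), colnames(tab))
  tab <- tab[, cols, drop = FALSE]
  for (cn in setdiff(cols, c("seq_id", "label"))) tab[[cn]] <- as.numeric(tab[[cn]])
  tab$gc_outlier_flag <- as.integer(tab$gc_outlier_flag)
  structure(tab, class = c("odna_features", "data.frame"),
            schema_version = FEATURE_SCHEMA_VERSION)
}

#' Read / write per-sequence class labels
#'
#' Plain two-column TSV (seq_id, class), no header; classes must be among
#' nuclear/mitochondrion/plastid.
#'
#' @param path File path.
#' @param labels Named character vector (seq_id -> class).
#' @return `read_labels`: named character vector; `write_labels`: `path`
#'   invisibly.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path, call. = FALSE)
  tab <- read.delim(path, header = FALSE, sep = "\t", colClasses = "character")
  if (ncol(tab) < 2L) stop("labels file needs two columns (seq_id, class)", call. = FALSE)
  labels <- setNames(tab[[2]], tab[[1]])
  bad <- setdiff(unique(labels), ORGANELLR_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown class label(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  labels
}

#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  write.table(data.frame(names(labels), unname(labels)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
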