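# Readers for the annotation-evidence files produced by external tools
# (repeat finder and rRNA scanner GFF3, tRNA scanner tabular output,
# blast-style protein homology tables) and the reduction of all evidence
# to one per-sequence count set.

#' Read intervals of selected feature types from a GFF3 file
#'
#' Parses a GFF3 file and returns, per sequence id, the intervals of the
#' requested feature types converted from GFF's 1-based inclusive
#' coordinates to 0-based half-open. Comment/directive lines and unknown
#' feature types are skipped. This deliberately ingests only
#' (seqid, type, start, end); attributes are not interpreted.
#'
#' @param path Path to a GFF3 file.
#' @param feature_types Character vector of feature types to keep
#'   (e.g. `"rRNA"`, `"dispersed_repeat"`); `NULL` keeps every type.
#' @return Named list: for each seq_id a data.frame with 0-based half-open
#'   `start`, `end` columns.
#' @export
read_gff_intervals <- function(path, feature_types = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) return(list())
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != 9L)) {
    bad <- idx[which(nfield != 9L)[1]]
    stop(sprintf("malformed GFF3 line %d in %s: expected 9 tab-separated columns, found %d",
                 bad, path, nfield[which(nfield != 9L)[1]]), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  seqid <- m[, 1]
  type <- m[, 3]
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start1) || anyNA(end1)) {
    bad <- idx[which(is.na(start1) | is.na(end1))[1]]
    stop(sprintf("malformed GFF3 line %d in %s: non-integer coordinates",
                 bad, path), call. = FALSE)
  }
  if (!is.null(feature_types)) {
    sel <- type %in% feature_types
    seqid <- seqid[sel]; start1 <- start1[sel]; end1 <- end1[sel]
  }
  if (length(seqid) == 0L) return(list())
  df <- data.frame(start = start1 - 1L, end = end1)  # 0-based half-open
  split(df, factor(seqid, levels = unique(seqid)))
}

#' Read tRNA scanner tabular output
#'
#' Reads the classical tRNA-scanner tabular dialect: three header lines,
#' then whitespace-delimited rows whose first column is the sequence name.
#' Returns the number of tRNA rows per sequence.
#'
#' @param path Path to the tabular file.
#' @param count_pseudogenes Count rows whose tRNA type is `"Pseudo"`.
#' @return Named integer vector of tRNA counts per sequence id; empty (with
#'   a warning) when the file holds no data rows.
#' @export
read_trna_tabular <- function(path, count_pseudogenes = TRUE) {
  if (!file.exists(path)) stop("tRNA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) <= 3L || all(!nzchar(trimws(lines[-(1:3)])))) {
    warning("tRNA file has no data rows: ", path, call. = FALSE)
    return(setNames(integer(0), character(0)))
  }
  rows <- lines[-(1:3)]
  rows <- rows[nzchar(trimws(rows))]
  fields <- strsplit(trimws(rows), "\\s+")
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (!count_pseudogenes) {
    type <- vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else "", character(1))
    ids <- ids[type != "Pseudo"]
  }
  tab <- table(ids)
  setNames(as.integer(tab), names(tab))
}

#' Read blast-style 12-column homology hits
#'
#' Reads a tab-separated table in the standard 12-column blast/diamond
#' tabular layout (qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore). Rows with an e-value above `max_evalue`
#' are dropped.
#'
#' @param path Path to the hits file.
#' @param target_db Which gene set the hits are against: `"mito"` or
#'   `"plastid"`.
#' @param max_evalue E-value ceiling; hits above it are discarded.
#' @return Data.frame with columns `seq_id`, `subject_id`,
#'   `percent_identity`, `align_len`, `evalue`, `bitscore`, `target_db`.
#' @export
read_homology_tabular <- function(path, target_db = c("mito", "plastid"),
                                  max_evalue = 1e-5) {
  target_db <- match.arg(target_db)
  if (!file.exists(path)) stop("hits file not found: ", path, call. = FALSE)
  empty <- data.frame(seq_id = character(0), subject_id = character(0),
                      percent_identity = numeric(0), align_len = integer(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      target_db = character(0))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  if (!any(keep)) return(empty)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != 12L)) {
    bad <- idx[which(nfield != 12L)[1]]
    stop(sprintf("malformed hits line %d in %s: expected 12 tab-separated columns",
                 bad, path), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  evalue <- suppressWarnings(as.numeric(m[, 11]))
  bitscore <- suppressWarnings(as.numeric(m[, 12]))
  if (anyNA(evalue) || anyNA(bitscore)) {
    bad <- idx[which(is.na(evalue) | is.na(bitscore))[1]]
    stop(sprintf("malformed hits line %d in %s: non-numeric e-value or bitscore",
                 bad, path), call. = FALSE)
  }
  out <- data.frame(
    seq_id = m[, 1], subject_id = m[, 2],
    percent_identity = as.numeric(m[, 3]), align_len = as.integer(m[, 4]),
    evalue = evalue, bitscore = bitscore, target_db = target_db
  )
  out[out$evalue <= max_evalue, , drop = FALSE]
}

# Union length (bp) of a set of 0-based half-open intervals.
.interval_union_bp <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(0L)
  r <- IRanges::reduce(IRanges::IRanges(start = df$start + 1L, end = df$end))
  sum(IRanges::width(r))
}

#' Collapse all evidence into one record per assembly sequence
#'
#' Reduces interval maps (repeats, rRNA), tRNA counts, homology hits, and
#' CpG islands to one evidence record per sequence of the assembly. Every
#' assembly sequence gets exactly one row (all-zero when it occurs in no
#' evidence file); evidence naming sequences absent from the assembly is
#' dropped with a reconciliation warning. Repeat bp is the length of the
#' union of the repeat intervals.
#'
#' @param seq_ids Character vector: the authoritative assembly sequence ids.
#' @param repeat_intervals,rrna_intervals Named lists of interval
#'   data.frames as returned by [read_gff_intervals()] (may be `NULL`).
#' @param trna_counts Named integer vector from [read_trna_tabular()]
#'   (may be `NULL`).
#' @param hits Data.frame of homology hits, rows from one or more calls to
#'   [read_homology_tabular()] (may be `NULL`).
#' @param islands CpG island data.frame from [find_cpg_islands()]
#'   (may be `NULL`).
#' @return Data.frame with one row per `seq_id` and columns `repeat_count`,
#'   `repeat_bp`, `rrna_count`, `trna_count`, `cpg_island_count`,
#'   `mito_hit_count`, `plastid_hit_count`, `best_mito_bitscore`,
#'   `best_plastid_bitscore`.
#' @export
collapse_evidence <- function(seq_ids, repeat_intervals = NULL,
                              rrna_intervals = NULL, trna_counts = NULL,
                              hits = NULL, islands = NULL) {
  stopifnot(is.character(seq_ids), length(seq_ids) >= 1L,
            !anyDuplicated(seq_ids))
  n <- length(seq_ids)
  ev <- data.frame(
    seq_id = seq_ids,
    repeat_count = integer(n), repeat_bp = integer(n),
    rrna_count = integer(n), trna_count = integer(n),
    cpg_island_count = integer(n),
    mito_hit_count = integer(n), plastid_hit_count = integer(n),
    best_mito_bitscore = numeric(n), best_plastid_bitscore = numeric(n),
    stringsAsFactors = FALSE
  )
  rownames(ev) <- seq_ids

  warn_unknown <- function(ids, what) {
    unknown <- setdiff(unique(ids), seq_ids)
    if (length(unknown) > 0L) {
      warning(sprintf("%s evidence for %d id(s) not in the assembly dropped: %s",
                      what, length(unknown),
                      paste(head(unknown, 5L), collapse = ", ")),
              call. = FALSE)
    }
    ids %in% seq_ids
  }

  if (!is.null(repeat_intervals) && length(repeat_intervals) > 0L) {
    ok <- warn_unknown(names(repeat_intervals), "repeat")
    for (id in names(repeat_intervals)[ok]) {
      df <- repeat_intervals[[id]]
      ev[id, "repeat_count"] <- nrow(df)
      ev[id, "repeat_bp"] <- .interval_union_bp(df)
    }
  }
  if (!is.null(rrna_intervals) && length(rrna_intervals) > 0L) {
    ok <- warn_unknown(names(rrna_intervals), "rRNA")
    for (id in names(rrna_intervals)[ok]) {
      ev[id, "rrna_count"] <- nrow(rrna_intervals[[id]])
    }
  }
  if (!is.null(trna_counts) && length(trna_counts) > 0L) {
    ok <- warn_unknown(names(trna_counts), "tRNA")
    ids <- names(trna_counts)[ok]
    ev[ids, "trna_count"] <- as.integer(trna_counts[ok])
  }
  if (!is.null(hits) && nrow(hits) > 0L) {
    ok <- warn_unknown(hits$seq_id, "homology")
    hits <- hits[ok, , drop = FALSE]
    for (db in c("mito", "plastid")) {
      h <- hits[hits$target_db == db, , drop = FALSE]
      if (nrow(h) == 0L) next
      cnt <- table(h$seq_id)
      best <- tapply(h$bitscore, h$seq_id, max)
      ccol <- paste0(db, "_hit_count")
      bcol <- paste0("best_", db, "_bitscore")
      ev[names(cnt), ccol] <- as.integer(cnt)
      ev[names(best), bcol] <- as.numeric(best)
    }
  }
  if (!is.null(islands) && nrow(islands) > 0L) {
    ok <- warn_unknown(islands$seq_id, "CpG island")
    isl <- islands[ok, , drop = FALSE]
    cnt <- table(isl$seq_id)
    ev[names(cnt), "cpg_island_count"] <- as.integer(cnt)
  }
  rownames(ev) <- NULL
  ev
}
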