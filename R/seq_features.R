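# Intrinsic per-sequence features: GC content, assembly-relative GC
# deviation, and CpG islands. All coordinates inside the package are
# 0-based half-open; conversion to 1-based inclusive happens only when
# writing GFF3.

.as_dna_set <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  if (is.character(x)) return(Biostrings::DNAStringSet(toupper(x)))
  stop("expected a DNAStringSet, DNAString, or character vector", call. = FALSE)
}

#' GC content of sequences
#'
#' Fraction of unambiguous bases that are G or C, computed case-insensitively.
#' N and other ambiguity codes are excluded from both numerator and
#' denominator; a sequence with no unambiguous base has GC content 0.
#'
#' @param x A `DNAStringSet`, `DNAString`, or character vector of sequences.
#' @return Numeric vector of GC fractions in \[0, 1\].
#' @examples
#' gc_content(c("AAAA", "GCGC", "ACGTN"))
#' @export
gc_content <- function(x) {
  seqs <- .as_dna_set(x)
  if (length(seqs) == 0L) stop("no sequences given", call. = FALSE)
  if (any(Biostrings::width(seqs) == 0L)) {
    stop("empty sequence: GC content undefined", call. = FALSE)
  }
  counts <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T"))
  denom <- rowSums(counts)
  gcn <- counts[, "G"] + counts[, "C"]
  out <- ifelse(denom == 0L, 0, gcn / denom)
  unname(out)
}

#' Length-weighted assembly GC statistics
#'
#' Mean and standard deviation of per-sequence GC content, each sequence
#' weighted by its length, so the statistics describe the assembly's base
#' composition rather than its contig count. Permutation-invariant in the
#' sequence order.
#'
#' @param seqs A `DNAStringSet` or character vector (the whole assembly).
#' @return An object of class `assembly_gc_stats`: list with `mean_gc`,
#'   `sd_gc`, and `n_sequences`.
#' @export
assembly_gc_stats <- function(seqs) {
  seqs <- .as_dna_set(seqs)
  if (length(seqs) == 0L) stop("assembly has no sequences", call. = FALSE)
  gc <- gc_content(seqs)
  w <- as.numeric(Biostrings::width(seqs))
  mean_gc <- sum(w * gc) / sum(w)
  sd_gc <- sqrt(sum(w * (gc - mean_gc)^2) / sum(w))
  structure(
    list(mean_gc = mean_gc, sd_gc = sd_gc, n_sequences = length(seqs)),
    class = "assembly_gc_stats"
  )
}

#' @export
print.assembly_gc_stats <- function(x, ...) {
  cat(sprintf("Assembly GC: mean %.4f, sd %.4f (%d sequences, length-weighted)\n",
              x$mean_gc, x$sd_gc, x$n_sequences))
  invisible(x)
}

#' Deviation of sequence GC from the assembly average
#'
#' Returns both the continuous deviation (difference and z-score against the
#' length-weighted assembly GC distribution) and a binary outlier flag
#' (|z| > `z_cutoff`), so a downstream model can use either encoding.
#' When the assembly GC standard deviation is zero the z-score is defined
#' as 0 and the flag is FALSE.
#'
#' @param gc Numeric vector of per-sequence GC fractions, or sequences
#'   (anything [gc_content()] accepts).
#' @param stats An `assembly_gc_stats` object for the containing assembly.
#' @param z_cutoff Absolute z-score above which a sequence is flagged.
#' @return A data.frame with columns `delta`, `zscore`, `flag`.
#' @export
gc_deviation <- function(gc, stats, z_cutoff = 2) {
  stopifnot(inherits(stats, "assembly_gc_stats"))
  if (!is.numeric(gc)) gc <- gc_content(gc)
  delta <- gc - stats$mean_gc
  zscore <- if (stats$sd_gc > 0) delta / stats$sd_gc else rep(0, length(delta))
  data.frame(delta = delta, zscore = zscore, flag = abs(zscore) > z_cutoff)
}

# Sliding-window CpG scan of one sequence. Cumulative-count arithmetic gives
# per-window C, G, and CG-dinucleotide counts for every start offset in one
# vectorised pass, so shift = 1 is affordable on multi-megabase contigs.
.cpg_scan_one <- function(seq_chr, window, shift, min_len, min_gc, min_oe) {
  n <- nchar(seq_chr)
  empty <- data.frame(start = integer(0), end = integer(0),
                      gc_fraction = numeric(0), obs_exp_cpg = numeric(0))
  if (window > n) return(empty)
  r <- charToRaw(toupper(seq_chr))
  is_c <- r == charToRaw("C")
  is_g <- r == charToRaw("G")
  is_cg <- c(is_c[-n] & is_g[-1L], FALSE)  # CG dinucleotide starting at i
  cum_c <- c(0L, cumsum(is_c))    # zero-padded so windows at position 1 work
  cum_g <- c(0L, cumsum(is_g))
  cum_cg <- c(0L, cumsum(is_cg))

  starts <- seq.int(1L, n - window + 1L, by = shift)
  win_count <- function(cum, from, to) cum[to + 1L] - cum[from]
  nc <- win_count(cum_c, starts, starts + window - 1L)
  ng <- win_count(cum_g, starts, starts + window - 1L)
  # CG pairs fully inside the window start at offsets [s, s + window - 2]
  ncg <- win_count(cum_cg, starts, starts + window - 2L)
  gc_frac <- (nc + ng) / window
  oe <- ifelse(nc * ng > 0, ncg * window / (nc * ng), 0)
  ok <- gc_frac >= min_gc & oe >= min_oe
  if (!any(ok)) return(empty)

  hits <- IRanges::IRanges(start = starts[ok], width = window)
  merged <- IRanges::reduce(hits)  # overlapping and adjacent windows merged
  merged <- merged[IRanges::width(merged) >= min_len]
  if (length(merged) == 0L) return(empty)

  s1 <- IRanges::start(merged)  # 1-based inclusive
  e1 <- IRanges::end(merged)
  len <- IRanges::width(merged)
  nc_i <- win_count(cum_c, s1, e1)
  ng_i <- win_count(cum_g, s1, e1)
  ncg_i <- win_count(cum_cg, s1, e1 - 1L)
  data.frame(
    start = s1 - 1L,                       # 0-based half-open
    end = e1,
    gc_fraction = (nc_i + ng_i) / len,
    obs_exp_cpg = ifelse(nc_i * ng_i > 0, ncg_i * len / (nc_i * ng_i), 0)
  )
}

#' Find CpG islands by a sliding-window scan
#'
#' A window of `window` bp advanced by `shift` bp qualifies when its GC
#' fraction is at least `min_gc` and its observed/expected CpG ratio —
#' (#CG dinucleotides × window) / (#C × #G), 0 when #C·#G = 0 — is at least
#' `min_oe`. Overlapping or adjacent qualifying windows are merged, and
#' merged regions shorter than `min_len` bp are discarded. Defaults are the
#' classical Gardiner-Garden & Frommer criteria. Island coordinates are
#' 0-based half-open; `gc_fraction` and `obs_exp_cpg` are recomputed over
#' the merged region.
#'
#' @param seqs A `DNAStringSet` (one row of output per island, with a
#'   `seq_id` column), or a single sequence as character/`DNAString`.
#' @param window Window size in bp.
#' @param shift Window step in bp.
#' @param min_len Minimum merged island length in bp.
#' @param min_gc Minimum window GC fraction.
#' @param min_oe Minimum window observed/expected CpG ratio.
#' @return A data.frame with columns `seq_id`, `start`, `end`,
#'   `gc_fraction`, `obs_exp_cpg`, islands sorted by start within each
#'   sequence. A window longer than the sequence yields no islands.
#' @export
find_cpg_islands <- function(seqs, window = 100L, shift = 1L, min_len = 200L,
                             min_gc = 0.5, min_oe = 0.6) {
  stopifnot(window >= 1L, shift >= 1L, min_len >= 1L)
  seqs <- .as_dna_set(seqs)
  if (any(Biostrings::width(seqs) == 0L)) {
    stop("empty sequence: CpG scan undefined", call. = FALSE)
  }
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  res <- lapply(seq_along(seqs), function(i) {
    isl <- .cpg_scan_one(as.character(seqs[[i]]), as.integer(window),
                         as.integer(shift), as.integer(min_len), min_gc, min_oe)
    if (nrow(isl) > 0L) cbind(seq_id = ids[i], isl, stringsAsFactors = FALSE)
    else cbind(seq_id = character(0), isl)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export CpG islands as GFF3
#'
#' Writes islands (0-based half-open, as returned by [find_cpg_islands()])
#' as GFF3 features of type `CpG_island` with 1-based inclusive coordinates.
#'
#' @param islands Data.frame from [find_cpg_islands()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpg_gff3 <- function(islands, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(islands) > 0L) {
    attrs <- sprintf("ID=cpg_%d;gc=%.4f;obs_exp=%.4f",
                     seq_len(nrow(islands)), islands$gc_fraction,
                     islands$obs_exp_cpg)
    writeLines(paste(islands$seq_id, "organellr", "CpG_island",
                     islands$start + 1L, islands$end, ".", ".", ".",
                     attrs, sep = "\t"), con)
  }
  invisible(path)
}
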