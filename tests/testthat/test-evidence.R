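write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("GFF3 reader converts coordinates and rejects malformed lines", {
  # directives only -> empty mapping
  p <- write_lines_tmp("##gff-version 3")
  expect_equal(length(read_gff_intervals(p)), 0L)
  # one rRNA at 1-based [10, 109] -> 0-based half-open [9, 109)
  p2 <- write_lines_tmp(c(
    "##gff-version 3",
    "chr1\tbarnapish\trRNA\t10\t109\t0.9\t+\t.\tID=r1",
    "# a comment",
    "chr2\trep\tdispersed_repeat\t1\t50\t.\t.\t.\tID=d1"))
  iv <- read_gff_intervals(p2, feature_types = "rRNA")
  expect_equal(names(iv), "chr1")
  expect_equal(iv$chr1$start, 9L)
  expect_equal(iv$chr1$end, 109L)
  # unfiltered read keeps both features
  expect_equal(length(read_gff_intervals(p2)), 2L)
  # malformed column count -> parse error naming the line
  p3 <- write_lines_tmp(c("##gff-version 3",
                          "chr1\tx\trRNA\t10\t109\t.\t+\t.",
                          "chr1\tx\trRNA\t10\t109\t.\t+\t.\tID=ok"))
  expect_error(read_gff_intervals(p3), "line 2")
})

test_that("tRNA tabular reader counts rows per sequence", {
  hdr <- c("Sequence\t\ttRNA #\tBegin\tEnd\ttype\tAnticodon", "Name\t\t",
           "--------\t------")
  # headers only -> empty with warning
  p <- write_lines_tmp(hdr)
  expect_warning(counts <- read_trna_tabular(p), "no data rows")
  expect_equal(length(counts), 0L)
  # two rows naming contig7, one naming contig9
  p2 <- write_lines_tmp(c(hdr,
                          "contig7\t1\t100\t172\tLeu\tCAA\t0\t0\t55.1",
                          "contig9\t1\t5\t77\tSer\tAGC\t0\t0\t60.0",
                          "contig7\t2\t900\t972\tPseudo\tGCC\t0\t0\t30.0"))
  expect_equal(read_trna_tabular(p2)[["contig7"]], 2L)
  expect_equal(read_trna_tabular(p2)[["contig9"]], 1L)
  expect_equal(read_trna_tabular(p2, count_pseudogenes = FALSE)[["contig7"]], 1L)
})

test_that("homology reader applies the e-value ceiling and flags bad rows", {
  p <- write_lines_tmp(character(0))
  expect_equal(nrow(read_homology_tabular(p, "mito")), 0L)
  row <- function(id, ev, bits = 200) {
    sprintf("%s\tmito_gene_01\t88.0\t120\t4\t0\t1\t120\t1\t120\t%s\t%.1f",
            id, ev, bits)
  }
  p2 <- write_lines_tmp(c(row("c1", "1e-10"), row("c2", "1e-3"),
                          row("c1", "1e-20", 300)))
  hits <- read_homology_tabular(p2, "mito")
  expect_equal(nrow(hits), 2L)            # the 1e-3 row is over the ceiling
  expect_setequal(hits$seq_id, "c1")
  expect_equal(max(hits$bitscore), 300)
  expect_equal(unique(hits$target_db), "mito")
  p3 <- write_lines_tmp(c(row("c1", "1e-10"), row("c2", "not_a_number")))
  expect_error(read_homology_tabular(p3, "plastid"), "line 2")
})

test_that("collapse_evidence yields all-zero records without evidence", {
  ev <- collapse_evidence(c("a", "b"))
  expect_equal(nrow(ev), 2L)
  num <- vapply(ev[-1], is.numeric, logical(1))
  expect_true(all(as.matrix(ev[, -1]) == 0))
})

test_that("collapse_evidence merges overlapping repeats and reconciles ids", {
  rep_iv <- list(a = data.frame(start = c(0L, 50L), end = c(100L, 150L)))
  ev <- collapse_evidence(c("a", "b"), repeat_intervals = rep_iv)
  expect_equal(ev$repeat_bp[ev$seq_id == "a"], 150L)  # union, not sum
  expect_equal(ev$repeat_count[ev$seq_id == "a"], 2L)
  # evidence for an unknown id is dropped with a warning, output unchanged
  expect_warning(
    ev2 <- collapse_evidence(c("a", "b"), repeat_intervals = rep_iv,
                             trna_counts = c(ghost = 3L)),
    "not in the assembly")
  expect_equal(ev2$trna_count, c(0L, 0L))
  expect_equal(ev2$repeat_bp, ev$repeat_bp)
})

test_that("collapse_evidence is idempotent and order-invariant", {
  withr::with_seed(5, {
    ids <- sprintf("s%02d", 1:8)
    rep_iv <- lapply(setNames(ids[1:5], ids[1:5]), function(id) {
      s <- sort(sample(0:500, 4))
      data.frame(start = s, end = s + sample(20:120, 4, replace = TRUE))
    })
    hits <- data.frame(seq_id = sample(ids, 10, replace = TRUE),
                       subject_id = "g", percent_identity = 90,
                       align_len = 100L, evalue = 1e-9,
                       bitscore = runif(10, 50, 300), target_db = "mito")
    a <- collapse_evidence(ids, repeat_intervals = rep_iv, hits = hits)
    b <- collapse_evidence(ids, repeat_intervals = rev(rep_iv),
                           hits = hits[sample(nrow(hits)), ])
    expect_identical(a[order(a$seq_id), ], b[order(b$seq_id), ])
    expect_identical(a, collapse_evidence(ids, repeat_intervals = rep_iv,
                                          hits = hits))
    # union bp can never exceed total span
    expect_true(all(a$repeat_bp <= 620))
  })
})
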