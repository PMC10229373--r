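# Seeded synthetic assemblies with matching evidence files, labels, and an
# independently computed expected feature table, so the whole pipeline is
# testable without running external annotators.

#' Simulation configuration
#'
#' Defaults describe a desk-scale assembly with a strong organellar signal:
#' nuclear contigs around GC 0.41 with log-normal lengths, organellar
#' contigs AT-shifted by 0.20 in GC, shorter and uniform in length, with
#' class-specific Poisson rates of annotation evidence (organelles carry
#' homology hits against their gene set and dense tRNA/rRNA annotations;
#' nuclear contigs carry repeats and, when `cpg_enrichment` is on, planted
#' CpG-rich segments).
#'
#' @param n_sequences Number of contigs in the assembly.
#' @param organellar_fraction Fraction of contigs that are organellar.
#' @param mito_plastid_ratio Fraction of organellar contigs that are
#'   mitochondrial (the rest are plastid).
#' @param organellar_count Optional explicit number of organellar contigs,
#'   overriding `organellar_fraction` (used for sparse corpora).
#' @param nuclear_gc Numeric `c(mean, sd)` of nuclear per-contig GC.
#' @param organellar_gc_shift Signed GC shift of organellar contigs
#'   relative to the nuclear mean (negative = AT-rich organelles).
#' @param nuclear_length Numeric `c(meanlog, sdlog)` of the log-normal
#'   nuclear contig length (bp).
#' @param organellar_length Numeric `c(min, max)` of the uniform organellar
#'   contig length (bp), or `NULL` to reuse the nuclear length
#'   distribution.
#' @param evidence_rates Named list per class, each a named numeric vector
#'   of expected per-contig counts for `repeat`, `rrna`, `trna`,
#'   `mito_hit`, `plastid_hit`.
#' @param cpg_enrichment Plant CpG-rich segments into nuclear contigs.
#' @param decoy_hit_fraction Fraction of contigs that additionally receive
#'   a homology row above the e-value ceiling (must be filtered out by the
#'   reader; excluded from expected counts).
#' @param seed Integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sequences = 2000L,
                       organellar_fraction = 0.05,
                       mito_plastid_ratio = 0.5,
                       organellar_count = NULL,
                       nuclear_gc = c(0.41, 0.02),
                       organellar_gc_shift = -0.20,
                       nuclear_length = c(log(12000), 0.6),
                       organellar_length = c(12000, 120000),
                       evidence_rates = NULL,
                       cpg_enrichment = TRUE,
                       decoy_hit_fraction = 0.05,
                       seed = 1L) {
  if (is.null(evidence_rates)) {
    evidence_rates <- list(
      nuclear       = c("repeat" = 10, rrna = 0.1, trna = 0.2,
                        mito_hit = 0, plastid_hit = 0),
      mitochondrion = c("repeat" = 1, rrna = 2, trna = 15,
                        mito_hit = 5, plastid_hit = 0),
      plastid       = c("repeat" = 1, rrna = 4, trna = 25,
                        mito_hit = 0, plastid_hit = 5)
    )
  }
  stopifnot(n_sequences >= 1L,
            organellar_fraction >= 0, organellar_fraction <= 1,
            mito_plastid_ratio >= 0, mito_plastid_ratio <= 1,
            all(sort(names(evidence_rates)) %in% sort(ORGANELLR_CLASSES)))
  structure(list(
    n_sequences = as.integer(n_sequences),
    organellar_fraction = organellar_fraction,
    mito_plastid_ratio = mito_plastid_ratio,
    organellar_count = organellar_count,
    nuclear_gc = nuclear_gc,
    organellar_gc_shift = organellar_gc_shift,
    nuclear_length = nuclear_length,
    organellar_length = organellar_length,
    evidence_rates = evidence_rates,
    cpg_enrichment = isTRUE(cpg_enrichment),
    decoy_hit_fraction = decoy_hit_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' A configuration with every class signal disabled
#'
#' All classes share the nuclear GC, length distribution, evidence rates,
#' and CpG treatment; labels remain, so any classifier trained on such a
#' corpus should perform near chance.
#'
#' @param ... Passed to [sim_config()] (e.g. `n_sequences`, `seed`).
#' @return A `sim_config`.
#' @export
sim_config_no_signal <- function(...) {
  cfg <- sim_config(...)
  cfg$organellar_gc_shift <- 0
  cfg$organellar_length <- NULL
  cfg$cpg_enrichment <- FALSE   # planted islands are nuclear-only, a signal
  base_rates <- cfg$evidence_rates$nuclear
  cfg$evidence_rates <- list(nuclear = base_rates,
                             mitochondrion = base_rates,
                             plastid = base_rates)
  cfg
}

.random_seq <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Plant a CpG-rich segment ("CG" repeats) inside a sequence.
.plant_cpg <- function(seq_chr, seg_len) {
  n <- nchar(seq_chr)
  if (seg_len >= n) return(seq_chr)
  at <- sample.int(n - seg_len, 1L)
  seg <- paste(rep("CG", ceiling(seg_len / 2)), collapse = "")
  seg <- substr(seg, 1L, seg_len)
  paste0(substr(seq_chr, 1L, at - 1L), seg,
         substr(seq_chr, at + seg_len, n))
}

# Independent interval-union length (plain sweep, no IRanges).
.union_bp_sweep <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  total <- 0L; cur_s <- starts[1L]; cur_e <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= cur_e) cur_e <- max(cur_e, ends[i])
    else { total <- total + (cur_e - cur_s); cur_s <- starts[i]; cur_e <- ends[i] }
  }
  as.integer(total + (cur_e - cur_s))
}

.count_gc_chr <- function(seq_chr) {
  r <- charToRaw(seq_chr)
  ngc <- sum(r == charToRaw("G")) + sum(r == charToRaw("C"))
  ngc / length(r)
}

#' Simulate one assembly with evidence files and ground truth
#'
#' Draws per-class contig GC (per-base Bernoulli) and lengths, Poisson
#' evidence counts at class-specific rates, writes the assembly FASTA and
#' every evidence file in the dialect the package's readers expect (GFF3
#' for repeats and rRNA, three-header-line tRNA tabular, 12-column
#' blast-style hit tables, two-column labels TSV), and computes the
#' expected per-sequence feature table by direct arithmetic on the drawn
#' counts (CpG island counts come from the package's scanner, since
#' islands are intrinsic to the realised sequence). Deterministic given
#' the config seed.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if absent).
#' @return A fixture bundle: list with `fasta_path`, `repeat_gff`,
#'   `rrna_gff`, `trna_path`, `mito_hits_path`, `plastid_hits_path`,
#'   `labels_path`, `expected_table_path`, `expected_feature_table`
#'   (data.frame), `labels` (named character), and `config`.
#' @export
simulate_assembly <- function(config, dir = tempfile("sim_")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(config$seed, .simulate_assembly_impl(config, dir))
}

.simulate_assembly_impl <- function(config, dir) {
  n <- config$n_sequences
  n_org <- if (!is.null(config$organellar_count)) {
    as.integer(config$organellar_count)
  } else {
    round(n * config$organellar_fraction)
  }
  if (is.null(config$organellar_count) &&
      config$organellar_fraction > 0 && n_org < 1L) {
    warning("organellar_fraction * n_sequences < 1: emitting no organellar sequences",
            call. = FALSE)
    n_org <- 0L
  }
  n_mito <- round(n_org * config$mito_plastid_ratio)
  n_plastid <- n_org - n_mito
  classes <- sample(c(rep("nuclear", n - n_org),
                      rep("mitochondrion", n_mito),
                      rep("plastid", n_plastid)))
  ids <- sprintf("contig_%05d", seq_len(n))

  nuc_gc <- config$nuclear_gc
  gc_target <- ifelse(classes == "nuclear",
                      rnorm(n, nuc_gc[1], nuc_gc[2]),
                      rnorm(n, nuc_gc[1] + config$organellar_gc_shift,
                            nuc_gc[2]))
  gc_target <- pmin(pmax(gc_target, 0.05), 0.95)

  len <- integer(n)
  nuc <- classes == "nuclear"
  len[nuc] <- pmax(500L, as.integer(round(
    rlnorm(sum(nuc), config$nuclear_length[1], config$nuclear_length[2]))))
  if (any(!nuc)) {
    if (is.null(config$organellar_length)) {
      len[!nuc] <- pmax(500L, as.integer(round(
        rlnorm(sum(!nuc), config$nuclear_length[1], config$nuclear_length[2]))))
    } else {
      len[!nuc] <- as.integer(round(runif(sum(!nuc),
                                          config$organellar_length[1],
                                          config$organellar_length[2])))
    }
  }

  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- .random_seq(len[i], gc_target[i])
    if (config$cpg_enrichment && classes[i] == "nuclear") {
      for (j in seq_len(rpois(1L, 0.3))) {
        s <- .plant_cpg(s, sample(250:600, 1L))
      }
    }
    seqs[i] <- s
  }
  names(seqs) <- ids

  # evidence counts per type, Poisson at the class rate
  rates <- config$evidence_rates
  draw_counts <- function(type) {
    vapply(seq_len(n), function(i) rpois(1L, rates[[classes[i]]][[type]]),
           integer(1))
  }
  repeat_n <- draw_counts("repeat")
  rrna_n <- draw_counts("rrna")
  trna_n <- draw_counts("trna")
  mito_n <- draw_counts("mito_hit")
  plastid_n <- draw_counts("plastid_hit")

  rand_intervals <- function(L, k, min_w, max_w) {
    if (k == 0L) return(data.frame(start = integer(0), end = integer(0)))
    w <- pmin(sample(min_w:max_w, k, replace = TRUE), L)
    s <- vapply(w, function(wi) sample.int(L - wi + 1L, 1L) - 1L, integer(1))
    data.frame(start = s, end = s + w)   # 0-based half-open
  }

  gff_line <- function(id, src, type, iv) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t+\t.\tID=%s_%s", id, src, type,
            iv$start + 1L, iv$end, type, id)
  }

  repeat_iv <- vector("list", n)
  rrna_iv <- vector("list", n)
  repeat_lines <- character(0)
  rrna_lines <- character(0)
  for (i in seq_len(n)) {
    repeat_iv[[i]] <- rand_intervals(len[i], repeat_n[i], 50L, 500L)
    rrna_iv[[i]] <- rand_intervals(len[i], rrna_n[i], 100L, 1500L)
    if (repeat_n[i] > 0L) {
      repeat_lines <- c(repeat_lines,
                        gff_line(ids[i], "repeatscan", "dispersed_repeat",
                                 repeat_iv[[i]]))
    }
    if (rrna_n[i] > 0L) {
      rrna_lines <- c(rrna_lines,
                      gff_line(ids[i], "rrnascan", "rRNA", rrna_iv[[i]]))
    }
  }

  trna_lines <- c("Sequence\t\ttRNA #\tBegin\tEnd\ttype\tAnticodon",
                  "Name\t\t\t\t\t\t",
                  "--------\t\t------\t-----\t---\t----\t---------")
  amino <- c("Ala", "Gly", "Leu", "Ser", "Val", "Thr", "Pro", "Met")
  for (i in seq_len(n)) {
    if (trna_n[i] == 0L) next
    iv <- rand_intervals(len[i], trna_n[i], 70L, 90L)
    trna_lines <- c(trna_lines, sprintf(
      "%s\t%d\t%d\t%d\t%s\t%s\t0\t0\t%.1f",
      ids[i], seq_len(trna_n[i]), iv$start + 1L, iv$end,
      sample(amino, trna_n[i], replace = TRUE),
      sample(c("AGC", "GCC", "CAA", "TGA"), trna_n[i], replace = TRUE),
      runif(trna_n[i], 30, 90)))
  }

  hit_rows <- function(counts, db) {
    rows <- character(0)
    best <- numeric(n)
    for (i in seq_len(n)) {
      k <- counts[i]
      if (k == 0L) next
      alen <- sample(50:500, k, replace = TRUE)
      bits <- round(runif(k, 60, 400), 1)
      ev <- signif(10^runif(k, -30, -6), 3)
      qs <- vapply(alen, function(a) sample.int(max(len[i] - a, 1L), 1L),
                   integer(1))
      rows <- c(rows, sprintf(
        "%s\t%s_gene_%02d\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
        ids[i], db, sample.int(40L, k, replace = TRUE),
        runif(k, 60, 100), alen, sample(0:10, k, TRUE), sample(0:2, k, TRUE),
        qs, qs + alen - 1L, 1L, alen, sprintf("%.3e", ev), bits))
      best[i] <- max(bits)
    }
    # decoy rows above the e-value ceiling: present in the file, absent
    # from the expected counts
    n_decoy <- round(config$decoy_hit_fraction * n)
    if (n_decoy > 0L) {
      di <- sample.int(n, n_decoy)
      rows <- c(rows, sprintf(
        "%s\t%s_gene_%02d\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
        ids[di], db, sample.int(40L, n_decoy, replace = TRUE),
        runif(n_decoy, 30, 60), 60L, 5L, 1L, 1L, 60L, 1L, 60L,
        sprintf("%.3e", 10^runif(n_decoy, -4, -2)),
        runif(n_decoy, 20, 40)))
    }
    list(rows = rows, best = best)
  }
  mito_hits <- hit_rows(mito_n, "mito")
  plastid_hits <- hit_rows(plastid_n, "plastid")

  # --- write files ---
  paths <- list(
    fasta_path = file.path(dir, "assembly.fasta"),
    repeat_gff = file.path(dir, "repeats.gff3"),
    rrna_gff = file.path(dir, "rrna.gff3"),
    trna_path = file.path(dir, "trna.tsv"),
    mito_hits_path = file.path(dir, "mito_hits.tsv"),
    plastid_hits_path = file.path(dir, "plastid_hits.tsv"),
    labels_path = file.path(dir, "labels.tsv"),
    expected_table_path = file.path(dir, "expected_features.tsv")
  )
  write_assembly(seqs, paths$fasta_path)
  writeLines(c("##gff-version 3", repeat_lines), paths$repeat_gff)
  writeLines(c("##gff-version 3", rrna_lines), paths$rrna_gff)
  writeLines(trna_lines, paths$trna_path)
  writeLines(mito_hits$rows, paths$mito_hits_path)
  writeLines(plastid_hits$rows, paths$plastid_hits_path)
  labels <- setNames(classes, ids)
  write_labels(labels, paths$labels_path)

  # --- expected feature table by direct arithmetic on the drawn truth ---
  gc_real <- vapply(seqs, .count_gc_chr, numeric(1))
  wlen <- as.numeric(len)
  mean_gc <- sum(wlen * gc_real) / sum(wlen)
  sd_gc <- sqrt(sum(wlen * (gc_real - mean_gc)^2) / sum(wlen))
  delta <- gc_real - mean_gc
  z <- if (sd_gc > 0) delta / sd_gc else rep(0, n)
  repeat_bp <- vapply(repeat_iv, function(iv) .union_bp_sweep(iv$start, iv$end),
                      integer(1))
  cpg_n <- vapply(seq_len(n), function(i) {
    isl <- find_cpg_islands(seqs[[i]])
    nrow(isl)
  }, integer(1))

  expected <- data.frame(
    seq_id = ids,
    length_bp = wlen,
    gc = unname(gc_real),
    gc_delta = unname(delta),
    gc_zscore = unname(z),
    gc_outlier_flag = as.integer(abs(z) > 2),
    repeat_density = repeat_n * 1e6 / wlen,
    repeat_frac = repeat_bp / wlen,
    rrna_density = rrna_n * 1e6 / wlen,
    trna_density = trna_n * 1e6 / wlen,
    cpg_density = cpg_n * 1e6 / wlen,
    mito_hit_density = mito_n * 1e6 / wlen,
    plastid_hit_density = plastid_n * 1e6 / wlen,
    mito_hit_count = as.numeric(mito_n),
    plastid_hit_count = as.numeric(plastid_n),
    best_mito_bitscore = mito_hits$best,
    best_plastid_bitscore = plastid_hits$best,
    stringsAsFactors = FALSE
  )
  expected <- structure(expected, class = c("odna_features", "data.frame"),
                        schema_version = FEATURE_SCHEMA_VERSION)
  write_feature_table(expected, paths$expected_table_path)

  c(paths, list(expected_feature_table = expected, labels = labels,
                config = config))
}

#' Simulate a corpus of assemblies with rare organellar contigs
#'
#' Per-assembly seeds are derived deterministically from the master seed.
#' With `sparse = TRUE` each assembly carries 0-2 organellar contigs
#' (drawn with mean 1), mimicking corpora where organellar sequences are a
#' vanishing fraction of all contigs.
#'
#' @param config Base [sim_config()]; its `seed` is the master seed.
#' @param n_assemblies Number of assemblies.
#' @param sparse Draw organellar contig counts from \{0, 1, 2\}.
#' @param dir Parent output directory.
#' @return List of fixture bundles (see [simulate_assembly()]).
#' @export
imbalanced_corpus <- function(config, n_assemblies, sparse = FALSE,
                              dir = tempfile("corpus_")) {
  stopifnot(n_assemblies >= 1L)
  seeds <- (as.numeric(config$seed) + 10007 * seq_len(n_assemblies)) %%
    .Machine$integer.max
  org_counts <- if (sparse) {
    .with_seed(config$seed,
               sample(0:2, n_assemblies, replace = TRUE,
                      prob = c(0.25, 0.5, 0.25)))
  } else {
    rep(NA_integer_, n_assemblies)
  }
  lapply(seq_len(n_assemblies), function(i) {
    cfg <- config
    cfg$seed <- as.integer(seeds[i])
    if (sparse) cfg$organellar_count <- org_counts[i]
    simulate_assembly(cfg, dir = file.path(dir, sprintf("assembly_%03d", i)))
  })
}
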