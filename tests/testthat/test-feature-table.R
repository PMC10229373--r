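test_that("density_per_mb is count * 1e6 / length", {
  expect_equal(density_per_mb(0, 123), 0)
  expect_equal(density_per_mb(5, 5e5), 10)
  expect_equal(density_per_mb(3, 1e6), 3)
  expect_error(density_per_mb(1, 0), "length_bp")
})

test_that("build_features on a bare assembly gives zero densities", {
  seqs <- Biostrings::DNAStringSet(c(only = "ACGTACGTACGT"))
  tab <- build_features(seqs)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$gc_delta, 0)      # single sequence is the assembly mean
  expect_equal(tab$gc_zscore, 0)
  dens <- c("repeat_density", "repeat_frac", "rrna_density", "trna_density",
            "cpg_density", "mito_hit_density", "plastid_hit_density")
  expect_true(all(unlist(tab[dens]) == 0))
})

test_that("build_features is deterministic and order-equivariant", {
  withr::with_seed(17, {
    seqs <- Biostrings::DNAStringSet(vapply(
      1:6, function(i) random_dna(sample(300:900, 1), runif(1, 0.3, 0.6)),
      character(1)))
    names(seqs) <- sprintf("c%d", 1:6)
  })
  tab1 <- build_features(seqs)
  tab2 <- build_features(seqs)
  expect_identical(tab1, tab2)
  perm <- c(4, 2, 6, 1, 3, 5)
  tabp <- build_features(seqs[perm])
  expect_equal(as.data.frame(tabp), as.data.frame(tab1[perm, ]),
               ignore_attr = TRUE)
  expect_equal(tabp$seq_id, tab1$seq_id[perm])
  expect_equal(tabp$gc, tab1$gc[perm])
  # evidence for an id not in the assembly is a hard error here
  ev <- collapse_evidence(c(names(seqs), "ghost"))
  expect_error(build_features(seqs, evidence = ev), "not in the assembly")
})

test_that("densities in a simulated fixture match independent arithmetic", {
  cfg <- sim_config(n_sequences = 25, organellar_fraction = 0.2,
                    organellar_length = c(2000, 9000),
                    nuclear_length = c(log(4000), 0.4), seed = 31)
  bundle <- simulate_assembly(cfg)
  tab <- cmd_extract(bundle$fasta_path, withr::local_tempfile(),
                     repeat_gff = bundle$repeat_gff,
                     rrna_gff = bundle$rrna_gff, trna = bundle$trna_path,
                     mito_hits = bundle$mito_hits_path,
                     plastid_hits = bundle$plastid_hits_path)
  # densities recomputed as count * 1e6 / len from the raw count columns
  expect_equal(tab$mito_hit_density, tab$mito_hit_count * 1e6 / tab$length_bp)
  expect_equal(tab$plastid_hit_density,
               tab$plastid_hit_count * 1e6 / tab$length_bp)
  expect_true(all(tab$repeat_frac >= 0 & tab$repeat_frac <= 1))
})

test_that("feature table TSV round-trips bit-exactly", {
  withr::with_seed(13, {
    seqs <- Biostrings::DNAStringSet(vapply(
      1:8, function(i) random_dna(sample(250:2000, 1), runif(1, 0.2, 0.8)),
      character(1)))
    names(seqs) <- sprintf("ctg%02d", 1:8)
  })
  tab <- build_features(seqs)
  tab$gc <- tab$gc + 1e-13 * (1:8)   # exercise full double precision
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_identical(as.data.frame(back), as.data.frame(tab))
  # with labels attached the label column round-trips too
  lab <- setNames(rep(c("nuclear", "mitochondrion"), 4), tab$seq_id)
  tabl <- attach_labels(tab, lab)
  write_feature_table(tabl, path)
  expect_identical(as.data.frame(read_feature_table(path)),
                   as.data.frame(tabl))
})

test_that("feature table reader realigns shuffled columns and checks schema", {
  seqs <- Biostrings::DNAStringSet(c(x = "ACGTACGTACGTACGT", y = "AATTAATT"))
  tab <- build_features(seqs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, path)
  lines <- readLines(path)
  hdr <- strsplit(lines[2], "\t")[[1]]
  rows <- strsplit(lines[-(1:2)], "\t")
  perm <- rev(seq_along(hdr))
  shuffled <- c(lines[1], paste(hdr[perm], collapse = "\t"),
                vapply(rows, function(r) paste(r[perm], collapse = "\t"),
                       character(1)))
  writeLines(shuffled, path)
  expect_identical(as.data.frame(read_feature_table(path)),
                   as.data.frame(tab))
  # wrong schema version is an explicit incompatibility
  writeLines(c("#schema=organellr/999", lines[-1]), path)
  expect_error(read_feature_table(path), "incompatible")
  # empty table round-trips as an empty table
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab[0, ], p2)
  expect_equal(nrow(read_feature_table(p2)), 0L)
})

test_that("label attachment validates classes and id coverage", {
  seqs <- Biostrings::DNAStringSet(c(x = "ACGTACGT", y = "AATTAATT"))
  tab <- build_features(seqs)
  expect_error(attach_labels(tab, c(x = "nuclear", y = "golgi")), "unknown class")
  expect_error(attach_labels(tab, c(x = "nuclear")), "mismatch")
  labs <- c(x = "nuclear", y = "plastid")
  path <- withr::local_tempfile()
  write_labels(labs, path)
  expect_equal(read_labels(path), labs)
})
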