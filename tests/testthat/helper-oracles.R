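# Independent brute-force references used to check the fast implementations.

# Naive O(n * window) CpG-island scan: literal per-window substring
# counting, manual interval merging. Returns 0-based half-open start/end.
naive_cpg_islands <- function(seq_chr, window = 100L, shift = 1L,
                              min_len = 200L, min_gc = 0.5, min_oe = 0.6) {
  s <- toupper(seq_chr)
  n <- nchar(s)
  if (window > n) return(data.frame(start = integer(0), end = integer(0)))
  chars <- strsplit(s, "")[[1]]
  qual <- list()
  for (st in seq(1L, n - window + 1L, by = shift)) {
    win <- chars[st:(st + window - 1L)]
    nc <- sum(win == "C")
    ng <- sum(win == "G")
    ncg <- sum(win[-window] == "C" & win[-1L] == "G")
    gc <- (nc + ng) / window
    oe <- if (nc * ng > 0) ncg * window / (nc * ng) else 0
    if (gc >= min_gc && oe >= min_oe) {
      qual[[length(qual) + 1L]] <- c(st - 1L, st - 1L + window)
    }
  }
  if (length(qual) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  merged <- list()
  cur <- qual[[1L]]
  for (iv in qual[-1L]) {
    if (iv[1] <= cur[2]) cur[2] <- max(cur[2], iv[2])
    else { merged[[length(merged) + 1L]] <- cur; cur <- iv }
  }
  merged[[length(merged) + 1L]] <- cur
  out <- do.call(rbind, merged)
  out <- out[out[, 2] - out[, 1] >= min_len, , drop = FALSE]
  data.frame(start = as.integer(out[, 1]), end = as.integer(out[, 2]))
}

# Random DNA of given length and GC fraction.
random_dna <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Small labeled, strongly separable feature table built directly (not via
# the simulator): organellar rows have shifted GC z-scores and nonzero hit
# densities.
separable_table <- function(n_nuc = 60L, n_mito = 12L, n_plastid = 12L,
                            seed = 42L) {
  withr::with_seed(seed, {
    n <- n_nuc + n_mito + n_plastid
    cls <- c(rep("nuclear", n_nuc), rep("mitochondrion", n_mito),
             rep("plastid", n_plastid))
    zs <- ifelse(cls == "nuclear", rnorm(n, 0, 0.5), rnorm(n, -4, 0.5))
    tab <- data.frame(
      seq_id = sprintf("s%03d", seq_len(n)),
      length_bp = ifelse(cls == "nuclear", round(runif(n, 5e4, 5e5)),
                         round(runif(n, 1.5e4, 1e5))),
      gc = 0.41 + 0.02 * zs,
      gc_delta = 0.02 * zs,
      gc_zscore = zs,
      gc_outlier_flag = as.integer(abs(zs) > 2),
      repeat_density = ifelse(cls == "nuclear", runif(n, 100, 600),
                              runif(n, 0, 50)),
      repeat_frac = runif(n, 0, 0.4),
      rrna_density = ifelse(cls == "nuclear", 0, runif(n, 10, 100)),
      trna_density = ifelse(cls == "nuclear", runif(n, 0, 5),
                            runif(n, 100, 900)),
      cpg_density = runif(n, 0, 20),
      mito_hit_density = ifelse(cls == "mitochondrion", runif(n, 50, 400), 0),
      plastid_hit_density = ifelse(cls == "plastid", runif(n, 50, 400), 0),
      mito_hit_count = ifelse(cls == "mitochondrion", rpois(n, 5), 0),
      plastid_hit_count = ifelse(cls == "plastid", rpois(n, 5), 0),
      best_mito_bitscore = ifelse(cls == "mitochondrion", runif(n, 100, 400), 0),
      best_plastid_bitscore = ifelse(cls == "plastid", runif(n, 100, 400), 0),
      stringsAsFactors = FALSE
    )
    tab$label <- cls
    tab
  })
}
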