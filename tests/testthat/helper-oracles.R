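# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately naive and share no code with the package.

DNA <- c("A", "C", "G", "T")

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

all_kmers <- function(k) {
  g <- expand.grid(rep(list(DNA), k), stringsAsFactors = FALSE)
  do.call(paste0, g[, rev(seq_len(k)), drop = FALSE])
}

# Naive string-scan k-mer counter: per read, overlapping windows,
# windows containing N skipped; optionally also scans reverse complements.
naive_count_oligos <- function(seqs, k, symmetrize) {
  if (symmetrize) seqs <- c(seqs, revcomp_chr(seqs))
  counts <- setNames(numeric(4^k), all_kmers(k))
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (!grepl("N", w, fixed = TRUE)) counts[w] <- counts[w] + 1
    }
  }
  counts
}

random_read <- function(len, n_prob = 0) {
  paste(sample(c(DNA, "N"), len, replace = TRUE,
               prob = c(rep((1 - n_prob) / 4, 4), n_prob)),
        collapse = "")
}

# Brute-force Ward agglomeration via the Lance-Williams recurrence
# applied to the dissimilarities as supplied (classic "ward.D");
# lexicographically smallest pair wins ties.
brute_ward <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  sz <- rep(1, n)
  D <- d
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    bi <- 1L; bj <- 2L; bv <- Inf
    for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
      if (D[i, j] < bv - 1e-12) { bv <- D[i, j]; bi <- i; bj <- j }
    }
    heights <- c(heights, bv)
    coph[clusters[[bi]], clusters[[bj]]] <- bv
    coph[clusters[[bj]], clusters[[bi]]] <- bv
    ks <- setdiff(seq_len(m), c(bi, bj))
    upd <- vapply(ks, function(k)
      ((sz[bi] + sz[k]) * D[bi, k] + (sz[bj] + sz[k]) * D[bj, k] -
         sz[k] * D[bi, bj]) / (sz[bi] + sz[bj] + sz[k]), 0)
    m2 <- length(ks) + 1L
    D2 <- matrix(0, m2, m2)
    if (length(ks)) {
      D2[seq_along(ks), seq_along(ks)] <- D[ks, ks]
      D2[m2, seq_along(ks)] <- upd
      D2[seq_along(ks), m2] <- upd
    }
    clusters <- c(clusters[ks],
                  list(c(clusters[[bi]], clusters[[bj]])))
    sz <- c(sz[ks], sz[bi] + sz[bj])
    D <- D2
  }
  list(heights = heights, coph = coph)
}

random_distance_matrix <- function(n, dim = 3) {
  pts <- matrix(runif(n * dim), n)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  d
}

# Signature object with arbitrary rho values, for metric-axiom checks.
fake_signature <- function(rho, id) {
  structure(list(rho = setNames(rho, all_kmers(2L)),
                 symmetrized = TRUE, source_library = id),
            class = "dinuc_signature")
}

fake_zscores <- function(z, id) {
  structure(list(z = setNames(z, all_kmers(4L)),
                 symmetrized = TRUE, source_library = id),
            class = "tetra_zscores")
}

toy_manifest <- function(library_id, sample_id) {
  data.frame(library_id = library_id, sample_id = sample_id,
             replicate = seq_along(library_id),
             day = "14", habitat = "seawater", health = "n/a",
             stringsAsFactors = FALSE)
}

write_fasta_file <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

# Two-group order-level centroid pair used in clustering recovery runs:
# 12 taxa, each group dominated by its own taxa block.
recovery_centroids <- function() {
  cent <- cbind(
    g1 = c(0.40, 0.25, 0.15, 0.10, 0.05, 0.02, 0.02, 0.01, 0, 0, 0, 0),
    g2 = c(0, 0, 0, 0, 0.01, 0.02, 0.02, 0.05, 0.10, 0.15, 0.25, 0.40))
  rownames(cent) <- sprintf("order_%02d", seq_len(nrow(cent)))
  cent
}

# Scaled-down two-community experiment: returns within/between means of
# the Karlin delta matrix and the z-score correlation matrix.
separation_experiment <- function(seed, reads_per_library = 300,
                                  genome_length = 30000,
                                  n_libraries = 2) {
  mods <- contrasting_genome_models()
  sA <- community_spec(mods["A"], n_libraries = n_libraries,
                       reads_per_library = reads_per_library,
                       genome_length = genome_length, seed = seed,
                       label = "A")
  sB <- community_spec(mods["B"], n_libraries = n_libraries,
                       reads_per_library = reads_per_library,
                       genome_length = genome_length,
                       seed = seed + 50000L, label = "B")
  libs <- c(simulate_community(sA), simulate_community(sB))
  sigs <- lapply(libs, function(rs)
    dinuc_signature(count_oligos(rs, 1L), count_oligos(rs, 2L)))
  m <- delta_matrix(sigs)
  r <- zscore_correlation(lapply(libs, tetra_zscores))
  ia <- seq_len(n_libraries); ib <- seq_len(n_libraries) + n_libraries
  within_idx <- rbind(t(utils::combn(ia, 2L)), t(utils::combn(ib, 2L)))
  list(delta_within = mean(m[within_idx]),
       delta_between = mean(m[ia, ib]),
       r_within = mean(r[within_idx]),
       r_between = mean(r[ia, ib]))
}
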