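test_that("hand-enumerated dinucleotide counts are reproduced", {
  polyA <- read_set(c(r = "AAAA"), "polyA")
  co <- count_oligos(polyA, 2L, symmetrize = TRUE)
  expect_equal(unname(co$counts[c("AA", "TT")]), c(3, 3))
  expect_equal(sum(co$counts), 6)

  rep3 <- read_set(c(r = "ACGTACGTACGT"), "acgt")
  co2 <- count_oligos(rep3, 2L, symmetrize = TRUE)
  expect_equal(unname(co2$counts[c("AC", "CG", "GT", "TA")]),
               c(6, 6, 6, 4))
  expect_equal(sum(co2$counts), 22)

  expect_error(count_oligos(qc_filter(polyA, min_length = 10), 2L),
               "empty read set")
})

test_that("k-mer counting matches the naive scan oracle on random reads", {
  set.seed(101)
  seqs <- vapply(sample(3:80, 210, replace = TRUE), random_read, "",
                 n_prob = 0.06)
  names(seqs) <- sprintf("r%d", seq_along(seqs))
  rs <- read_set(seqs, "lib")
  for (k in 1:4) {
    for (sym in c(FALSE, TRUE)) {
      got <- count_oligos(rs, k, symmetrize = sym)$counts
      want <- naive_count_oligos(as.character(rs$reads), k, sym)
      expect_equal(as.numeric(got[names(want)]), as.numeric(want),
                   info = sprintf("k=%d sym=%s", k, sym))
    }
  }
})

test_that("unsymmetrized counts conserve the number of valid windows", {
  set.seed(7)
  seqs <- vapply(sample(1:40, 50, replace = TRUE), random_read, "",
                 n_prob = 0.1)
  names(seqs) <- sprintf("r%d", seq_along(seqs))
  rs <- read_set(seqs, "lib")
  for (k in 1:4) {
    chars <- strsplit(as.character(rs$reads), "")
    n_windows <- sum(vapply(chars, function(ch) {
      n <- length(ch)
      if (n < k) return(0L)
      sum(vapply(seq_len(n - k + 1L), function(i)
        !any(ch[i:(i + k - 1L)] == "N"), NA))
    }, 0L))
    expect_equal(sum(count_oligos(rs, k, symmetrize = FALSE)$counts),
                 n_windows)
  }
})

test_that("odds ratios match hand arithmetic on the toy libraries", {
  polyA <- read_set(c(r = "AAAA"), "polyA")
  sig <- dinuc_signature(count_oligos(polyA, 1L), count_oligos(polyA, 2L))
  expect_equal(unname(sig$rho[c("AA", "TT")]), c(2, 2))
  expect_equal(sum(sig$rho), 4)  # every other rho is 0

  rep3 <- read_set(c(r = "ACGTACGTACGT"), "acgt")
  sig2 <- dinuc_signature(count_oligos(rep3, 1L), count_oligos(rep3, 2L))
  expect_equal(unname(sig2$rho[c("AC", "CG", "GT")]), rep(96 / 22, 3))
  expect_equal(unname(sig2$rho["TA"]), 64 / 22)

  other <- count_oligos(read_set(c(r = "ACGT"), "other"), 2L)
  expect_error(dinuc_signature(count_oligos(polyA, 1L), other),
               "different libraries")
})

test_that("odds ratios of a long i.i.d. sequence are near 1", {
  g <- simulate_genome(genome_model(matrix(0.25, 4, 4), label = "unif"),
                       1e6, seed = 11)
  rs <- read_set(c(g = g), "unif")
  sig <- dinuc_signature(count_oligos(rs, 1L), count_oligos(rs, 2L))
  expect_true(all(abs(sig$rho - 1) < 0.05))
})

test_that("strand symmetrization yields complement-symmetric odds ratios", {
  set.seed(5)
  for (i in 1:10) {
    seqs <- vapply(sample(30:90, 20, replace = TRUE), random_read, "",
                   n_prob = 0.02)
    names(seqs) <- sprintf("r%d", seq_along(seqs))
    rs <- read_set(seqs, "lib")
    sig <- dinuc_signature(count_oligos(rs, 1L), count_oligos(rs, 2L))
    din <- names(sig$rho)
    mirror <- chartr("ACGT", "TGCA",
                     paste0(substr(din, 2, 2), substr(din, 1, 1)))
    expect_equal(unname(sig$rho), unname(sig$rho[mirror]))
  }
})

test_that("karlin_delta reproduces the worked example and scale convention", {
  polyA <- read_set(c(r = "AAAA"), "polyA")
  rep3 <- read_set(c(r = "ACGTACGTACGT"), "acgt")
  a <- dinuc_signature(count_oligos(polyA, 1L), count_oligos(polyA, 2L))
  b <- dinuc_signature(count_oligos(rep3, 1L), count_oligos(rep3, 2L))
  expect_identical(karlin_delta(a, a), 0)
  expect_equal(karlin_delta(a, b), 1250.0)
  expect_equal(karlin_delta(b, a), karlin_delta(a, b))
  expect_equal(karlin_delta(a, b, scale = 1000),
               1000 * karlin_delta(a, b, scale = 1))
})

test_that("delta matrices are metric: symmetry, identity, triangle inequality", {
  a <- fake_signature(rep(1, 16), "x")
  expect_equal(unname(delta_matrix(list(a, fake_signature(rep(1, 16), "y")))),
               matrix(0, 2, 2))
  expect_error(delta_matrix(list(a, fake_signature(rep(2, 16), "x"))),
               "duplicate")

  set.seed(19)
  for (i in 1:100) {
    sigs <- lapply(1:3, function(j)
      fake_signature(runif(16, 0, 3), c("x", "y", "z")[j]))
    m <- delta_matrix(sigs)
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0))
    expect_lte(m[1, 3], m[1, 2] + m[2, 3] + 1e-9)
    expect_lte(m[1, 2], m[1, 3] + m[3, 2] + 1e-9)
    expect_lte(m[2, 3], m[2, 1] + m[1, 3] + 1e-9)
    # entries equal direct pairwise calls
    expect_equal(m[1, 2], karlin_delta(sigs[[1]], sigs[[2]]))
  }
})

test_that("group averages use replicate pairs within and all pairs between", {
  m <- matrix(c(0, 10, 10, 0), 2, 2,
              dimnames = list(c("L1", "L2"), c("L1", "L2")))
  ga <- group_average_delta(m, toy_manifest(c("L1", "L2"), c("S1", "S2")))
  expect_equal(nrow(ga), 1L)
  expect_equal(ga$mean_delta, 10)
  expect_equal(ga$n_pairs, 1L)

  m3 <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  m3["x", "y"] <- m3["y", "x"] <- 6
  m3["x", "z"] <- m3["z", "x"] <- 9
  m3["y", "z"] <- m3["z", "y"] <- 12
  ga3 <- group_average_delta(m3, toy_manifest(c("x", "y", "z"),
                                              rep("A", 3)))
  expect_equal(ga3$mean_delta, 9.0)
  expect_equal(ga3$n_pairs, 3L)
  expect_equal(ga3$category, "high_similarity")

  expect_error(group_average_delta(m3, toy_manifest("x", "A")),
               "missing from manifest")
})

test_that("delta categories use closed-interval boundaries and configurable thresholds", {
  expect_equal(classify_delta(0), "high_similarity")
  expect_equal(classify_delta(11), "intermediate")
  expect_equal(classify_delta(30), "intermediate")
  expect_equal(classify_delta(50.6), "low_similarity")
  expect_equal(classify_delta(25, thresholds = c(11, 20)),
               "low_similarity")
  expect_error(classify_delta(5, thresholds = c(30, 11)),
               "configuration error")
  expect_error(classify_delta(-1), "non-negative")
})

test_that("tetranucleotide expectations follow the maximal-order Markov formula", {
  polyA <- read_set(c(r = strrep("A", 20)), "polyA")
  c2 <- count_oligos(polyA, 2L); c3 <- count_oligos(polyA, 3L)
  e <- tetra_expected(c2, c3)
  expect_equal(unname(e["AAAA"]),
               unname(c3$counts["AAA"]^2 / c2$counts["AA"]))
  # any word whose middle dinucleotide was never seen has E = 0
  expect_equal(unname(e["ACGT"]), 0)
  expect_length(e, 256L)

  g <- simulate_genome(contrasting_genome_models()$A, 1e6, seed = 21)
  rs <- read_set(c(g = g), "A")
  obs <- count_oligos(rs, 4L)$counts
  exp4 <- tetra_expected(count_oligos(rs, 2L), count_oligos(rs, 3L))
  expect_lt(sum(abs(obs - exp4)) / sum(obs), 0.05)
})

test_that("z-scores are null-centred under a matching Markov model", {
  g <- simulate_genome(contrasting_genome_models()$A, 1e6, seed = 23)
  z <- tetra_zscores(read_set(c(g = g), "A"))
  expect_length(z$z, 256L)
  expect_true(all(is.finite(z$z)))
  expect_lt(abs(mean(z$z)), 0.3)
})

test_that("degenerate denominators give zero z-scores", {
  z <- tetra_zscores(read_set(c(r = "AAAA"), "polyA"))
  # words whose middle dinucleotide (or expectation) is absent get z = 0
  expect_equal(unname(z$z["ACGT"]), 0)
  expect_equal(sum(z$z != 0), 2L)  # only AAAA and TTTT carry signal
  expect_true(all(is.finite(z$z)))
})

test_that("doubling a read set preserves the sign pattern of z", {
  set.seed(31)
  seqs <- vapply(rep(60, 80), random_read, "")
  names(seqs) <- sprintf("r%d", seq_along(seqs))
  rs1 <- read_set(seqs, "lib")
  rs2 <- read_set(setNames(rep(seqs, 2), sprintf("r%d", 1:160)), "lib")
  z1 <- tetra_zscores(rs1)$z
  z2 <- tetra_zscores(rs2)$z
  expect_identical(sign(z1), sign(z2))
})

test_that("z-score correlation has unit diagonal, symmetry and exact negation", {
  set.seed(37)
  z <- rnorm(256)
  r <- zscore_correlation(list(fake_zscores(z, "a"),
                               fake_zscores(-z, "b"),
                               fake_zscores(z + rnorm(256, 0, 0.5), "c")))
  expect_equal(diag(r), setNames(c(1, 1, 1), c("a", "b", "c")))
  expect_equal(r, t(r))
  expect_equal(unname(r["a", "b"]), -1)
  expect_true(all(r >= -1 - 1e-12 & r <= 1 + 1e-12))
})

test_that("independent libraries off one genome correlate strongly in z", {
  # two read libraries drawn independently from the same realized genome
  # share its tetranucleotide idiosyncrasies, so their z-vectors agree
  g <- simulate_genome(contrasting_genome_models()$A, 5e4, seed = 41)
  r1 <- simulate_reads(g, 2000, 361, 128, seed = 1, library_id = "rep1")
  r2 <- simulate_reads(g, 2000, 361, 128, seed = 2, library_id = "rep2")
  r <- zscore_correlation(list(tetra_zscores(r1), tetra_zscores(r2)))
  expect_gt(r["rep1", "rep2"], 0.8)
})

test_that("zero-variance z-score vectors are flagged and zeroed, not fatal", {
  z <- rnorm(256)
  expect_warning(
    r <- zscore_correlation(list(fake_zscores(z, "a"),
                                 fake_zscores(rep(0, 256), "flat"))),
    "zero-variance")
  expect_equal(unname(r["a", "flat"]), 0)
  expect_equal(unname(diag(r)), c(1, 1))
  expect_equal(attr(r, "degenerate"), "flat")
})

test_that("square and long TSV exports round-trip matrix values", {
  m <- matrix(c(0, 1.5, 1.5, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_square_tsv(m, f)
  expect_equal(read_square_tsv(f), m)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_long_tsv(m, f2)
  long <- read.delim(f2)
  expect_equal(long$value, 1.5)
})
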