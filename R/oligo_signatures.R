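# Annotation-independent genomic signatures: dinucleotide odds ratios,
# Karlin delta distances, tetranucleotide z-scores and their Pearson
# correlation matrices.

kmer_names <- function(k) {
  g <- expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE)
  # first position varies slowest (AA, AC, AG, AT, CA, ...)
  do.call(paste0, g[, rev(seq_len(k)), drop = FALSE])
}

#' Count overlapping k-mers in a read set
#'
#' Words are counted within each read independently (none span a read
#' boundary) and windows containing `N` are skipped. With
#' `symmetrize = TRUE` the reverse complement of every read is counted
#' as well — the convention of computing signature frequencies on the
#' sequence concatenated with its inverted complement, which makes the
#' resulting signatures strand-independent.
#'
#' @param rs A [read_set()] with at least one read.
#' @param k Word length, 1 to 4.
#' @param symmetrize Also count reverse-complemented reads (default
#'   `TRUE`).
#' @return An object of class `oligo_counts`: list with `k`, `counts`
#'   (named vector over all `4^k` words; absent words are 0),
#'   `symmetrized` and `source_library`.
#' @examples
#' co <- count_oligos(read_set(c(r = "ACGTACGTACGT"), "toy"), k = 2)
#' co$counts[c("AC", "CG", "GT", "TA")]
#' @export
count_oligos <- function(rs, k, symmetrize = TRUE) {
  stopifnot(inherits(rs, "read_set"))
  if (k < 1 || k > 4) stop("'k' must be between 1 and 4")
  k <- as.integer(k)
  if (length(rs$reads) == 0L)
    stop("cannot count oligonucleotides in an empty read set (library '",
         rs$library_id, "')")
  counts <- colSums(Biostrings::oligonucleotideFrequency(rs$reads, width = k))
  if (symmetrize) {
    rc <- Biostrings::reverseComplement(rs$reads)
    counts <- counts + colSums(Biostrings::oligonucleotideFrequency(rc, width = k))
  }
  structure(list(k = k, counts = counts, symmetrized = isTRUE(symmetrize),
                 source_library = rs$library_id),
            class = "oligo_counts")
}

check_same_source <- function(...) {
  objs <- list(...)
  src <- unique(vapply(objs, `[[`, "", "source_library"))
  if (length(src) != 1L)
    stop("oligo counts derive from different libraries: ",
         paste(src, collapse = " vs "))
  sym <- unique(vapply(objs, `[[`, NA, "symmetrized"))
  if (length(sym) != 1L)
    stop("oligo counts mix symmetrize conventions")
  invisible(NULL)
}

#' Dinucleotide relative-abundance odds ratios
#'
#' Computes the 16 odds ratios `rho*_XY = f*_XY / (f*_X * f*_Y)`, where
#' `f*` are the mono- and dinucleotide frequencies of a library
#' (conventionally taken over each read together with its inverted
#' complement). `rho*` is close to 1 for every dinucleotide of an
#' independent-letter sequence, so deviations capture genuine
#' neighbour-dependence structure — a genomic signature that is stable
#' across fragments of one genome and needs no annotation.
#'
#' @param c1 `oligo_counts` with `k = 1`.
#' @param c2 `oligo_counts` with `k = 2`, from the same library and
#'   symmetrize convention.
#' @return Object of class `dinuc_signature`: list with `rho` (named
#'   16-vector), `symmetrized`, `source_library`. `rho` is defined as 0
#'   where `f*_X * f*_Y = 0`.
#' @export
dinuc_signature <- function(c1, c2) {
  stopifnot(inherits(c1, "oligo_counts"), inherits(c2, "oligo_counts"))
  if (c1$k != 1L || c2$k != 2L)
    stop("'c1' must hold mononucleotide and 'c2' dinucleotide counts")
  check_same_source(c1, c2)
  f1 <- c1$counts / sum(c1$counts)
  f2 <- c2$counts / sum(c2$counts)
  din <- names(f2)
  denom <- f1[substr(din, 1L, 1L)] * f1[substr(din, 2L, 2L)]
  rho <- ifelse(denom == 0, 0, f2 / denom)
  names(rho) <- din
  structure(list(rho = rho, symmetrized = c1$symmetrized,
                 source_library = c1$source_library),
            class = "dinuc_signature")
}

#' @export
print.dinuc_signature <- function(x, ...) {
  cat(sprintf("<dinuc_signature> library '%s'%s\n", x$source_library,
              if (x$symmetrized) " (strand-symmetrized)" else ""))
  print(round(x$rho, 3))
  invisible(x)
}

#' Karlin delta distance between two dinucleotide signatures
#'
#' The mean absolute difference of the 16 odds ratios,
#' `delta = (1/16) * sum_XY |rho_a - rho_b|`, multiplied by `scale`
#' (1000 by default, for easier comparison of the typically small raw
#' values).
#'
#' @param a,b `dinuc_signature` objects built under the same symmetrize
#'   convention.
#' @param scale Multiplier applied to the raw distance (default 1000).
#' @return A single non-negative number; `karlin_delta(a, a)` is 0.
#' @export
karlin_delta <- function(a, b, scale = 1000) {
  stopifnot(inherits(a, "dinuc_signature"), inherits(b, "dinuc_signature"))
  if (!identical(a$symmetrized, b$symmetrized))
    stop("signatures were built under different symmetrize conventions")
  scale * mean(abs(a$rho - b$rho[names(a$rho)]))
}

#' Pairwise Karlin delta matrix
#'
#' @param sigs List of at least two `dinuc_signature` objects with
#'   unique source libraries.
#' @param scale Passed to [karlin_delta()].
#' @return A symmetric numeric matrix with zero diagonal, rows/columns
#'   named by library id.
#' @export
delta_matrix <- function(sigs, scale = 1000) {
  stopifnot(is.list(sigs), length(sigs) >= 2L)
  ids <- vapply(sigs, `[[`, "", "source_library")
  if (anyDuplicated(ids))
    stop("duplicate library ids in signature list: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n <- length(sigs)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      m[i, j] <- m[j, i] <- karlin_delta(sigs[[i]], sigs[[j]], scale = scale)
    }
  }
  m
}

#' Group-averaged Karlin distances
#'
#' Averages the entries of a delta matrix within and between sample
#' groups (e.g. replicate libraries of one seawater sample). Within-group
#' means use the distinct unordered replicate pairs; between-group means
#' use all pairs across the two groups. Groups with a single library
#' yield no within-group row.
#'
#' @param m Symmetric delta matrix with library ids as dimnames.
#' @param manifest A [load_manifest()] result (or data.frame with
#'   `library_id` and `sample_id`) covering every library in `m`.
#' @param thresholds Passed to [classify_delta()] for the category
#'   column.
#' @return `data.frame` with columns `group_a`, `group_b`, `mean_delta`,
#'   `n_pairs`, `category`.
#' @export
group_average_delta <- function(m, manifest, thresholds = c(11, 30)) {
  ids <- rownames(m)
  if (is.null(ids) || !identical(ids, colnames(m)))
    stop("'m' must have matching row and column library ids")
  miss <- setdiff(ids, manifest$library_id)
  if (length(miss))
    stop("library missing from manifest: ", paste(miss, collapse = ", "))
  grp <- manifest$sample_id[match(ids, manifest$library_id)]
  groups <- unique(grp)
  out <- list()
  for (a in seq_along(groups)) {
    for (b in seq.int(a, length(groups))) {
      ia <- which(grp == groups[a]); ib <- which(grp == groups[b])
      if (a == b) {
        if (length(ia) < 2L) next
        pr <- utils::combn(ia, 2L)
        vals <- m[cbind(pr[1L, ], pr[2L, ])]
      } else {
        vals <- as.vector(m[ia, ib, drop = FALSE])
      }
      out[[length(out) + 1L]] <- data.frame(
        group_a = groups[a], group_b = groups[b],
        mean_delta = mean(vals), n_pairs = length(vals),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$category <- classify_delta(res$mean_delta, thresholds = thresholds)
  res
}

#' Classify a Karlin delta value into similarity categories
#'
#' Values (on the x1000 scale) below `t_low` indicate a high degree of
#' genetic similarity, values above `t_high` low similarity, and the
#' closed interval between them intermediate similarity. The default
#' boundaries `(11, 30)` fit seawater-style comparisons; habitats with
#' tighter signatures may warrant a lower `t_high` (e.g. 20).
#'
#' @param delta Non-negative delta value(s) on the x1000 scale.
#' @param thresholds Numeric `c(t_low, t_high)` with `t_low <= t_high`.
#' @return Character vector over `high_similarity`, `intermediate`,
#'   `low_similarity`.
#' @export
classify_delta <- function(delta, thresholds = c(11, 30)) {
  if (length(thresholds) != 2L || thresholds[1L] > thresholds[2L])
    stop("configuration error: thresholds must be c(t_low, t_high) with t_low <= t_high")
  if (any(delta < 0)) stop("'delta' must be non-negative")
  ifelse(delta < thresholds[1L], "high_similarity",
         ifelse(delta > thresholds[2L], "low_similarity", "intermediate"))
}

tetra_parts <- function() {
  w <- kmer_names(4L)
  list(w = w,
       pre = substr(w, 1L, 3L),    # n1 n2 n3
       suf = substr(w, 2L, 4L),    # n2 n3 n4
       mid = substr(w, 2L, 3L))    # n2 n3
}

#' Expected tetranucleotide counts under the maximal-order Markov model
#'
#' For a word `n1 n2 n3 n4` the expectation given the trinucleotide
#' composition is `E = N(n1 n2 n3) * N(n2 n3 n4) / N(n2 n3)`; by
#' convention `E = 0` when the middle dinucleotide count is 0.
#'
#' @param c2 `oligo_counts` with `k = 2`.
#' @param c3 `oligo_counts` with `k = 3`, same library and symmetrize
#'   convention.
#' @return Named numeric vector of 256 expected counts.
#' @export
tetra_expected <- function(c2, c3) {
  stopifnot(inherits(c2, "oligo_counts"), inherits(c3, "oligo_counts"))
  if (c2$k != 2L || c3$k != 3L)
    stop("'c2' must hold dinucleotide and 'c3' trinucleotide counts")
  check_same_source(c2, c3)
  p <- tetra_parts()
  n2 <- as.numeric(c2$counts[p$mid])
  e <- ifelse(n2 == 0, 0,
              as.numeric(c3$counts[p$pre]) * as.numeric(c3$counts[p$suf]) / n2)
  names(e) <- p$w
  e
}

#' Tetranucleotide z-scores of a read set
#'
#' Standardizes the divergence between observed and expected
#' tetranucleotide counts: `Z = (N - E) / sqrt(V)` with the conditional
#' variance approximation
#' `V = E * (N(n2n3) - N(n1n2n3)) * (N(n2n3) - N(n2n3n4)) / N(n2n3)^2`.
#' `Z` is set to 0 wherever `V <= 0` or a required count is 0, so the
#' vector is finite everywhere.
#'
#' @param rs A non-empty [read_set()].
#' @param symmetrize Count reverse-complemented reads as well (default
#'   `TRUE`).
#' @return Object of class `tetra_zscores`: list with `z` (named
#'   256-vector), `symmetrized`, `source_library`.
#' @export
tetra_zscores <- function(rs, symmetrize = TRUE) {
  c2 <- count_oligos(rs, 2L, symmetrize)
  c3 <- count_oligos(rs, 3L, symmetrize)
  c4 <- count_oligos(rs, 4L, symmetrize)
  p <- tetra_parts()
  n2 <- as.numeric(c2$counts[p$mid])
  n3a <- as.numeric(c3$counts[p$pre])
  n3b <- as.numeric(c3$counts[p$suf])
  n4 <- as.numeric(c4$counts[p$w])
  e <- ifelse(n2 == 0, 0, n3a * n3b / n2)
  v <- ifelse(n2 == 0, 0, e * (n2 - n3a) * (n2 - n3b) / n2^2)
  z <- ifelse(v > 0 & e > 0, (n4 - e) / sqrt(v), 0)
  z[!is.finite(z)] <- 0
  names(z) <- p$w
  structure(list(z = z, symmetrized = isTRUE(symmetrize),
                 source_library = rs$library_id),
            class = "tetra_zscores")
}

#' Pearson correlation matrix of tetranucleotide z-score vectors
#'
#' Pairwise Pearson correlation over the 256 z-score components. A
#' zero-variance vector cannot be correlated; its entries are defined as
#' 0 against all other libraries (with a warning, and the affected ids
#' recorded in the `"degenerate"` attribute) so whole-matrix runs
#' complete.
#'
#' @param zs List of at least two `tetra_zscores` objects with unique
#'   source libraries.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
zscore_correlation <- function(zs) {
  stopifnot(is.list(zs), length(zs) >= 2L)
  ids <- vapply(zs, `[[`, "", "source_library")
  if (anyDuplicated(ids))
    stop("duplicate library ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  zmat <- vapply(zs, `[[`, numeric(256L), "z")
  colnames(zmat) <- ids
  sds <- apply(zmat, 2L, stats::sd)
  degenerate <- ids[sds == 0]
  r <- suppressWarnings(stats::cor(zmat))
  if (length(degenerate)) {
    warning("zero-variance z-score vector(s): ",
            paste(degenerate, collapse = ", "),
            "; correlations set to 0")
    r[ids %in% degenerate, ] <- 0
    r[, ids %in% degenerate] <- 0
  }
  diag(r) <- 1
  attr(r, "degenerate") <- degenerate
  r
}

#' Write a square matrix as TSV
#'
#' Square layout with a leading id column; the companion
#' [write_long_tsv()] emits `(lib_a, lib_b, value)` rows for the upper
#' triangle.
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_square_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_square_tsv
#' @export
write_long_tsv <- function(m, path) {
  idx <- which(upper.tri(m), arr.ind = TRUE)
  df <- data.frame(lib_a = rownames(m)[idx[, 1L]],
                   lib_b = colnames(m)[idx[, 2L]],
                   value = m[idx], stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square TSV matrix written by [write_square_tsv()]
#'
#' @param path Input path.
#' @return Numeric matrix with dimnames.
#' @export
read_square_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
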