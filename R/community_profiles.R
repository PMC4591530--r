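# Taxa-by-sample abundance tables: normalization, top taxa,
# autotroph:heterotroph ratios, and Pearson + Ward clustering.

#' Construct an abundance table
#'
#' A taxa-by-samples matrix of non-negative counts or proportions with a
#' recorded normalization state.
#'
#' @param mat Numeric matrix, taxa in rows (unique rownames), samples in
#'   columns (unique colnames).
#' @param state `"counts"` or `"relative"`.
#' @param groups Optional group label per sample (used by the
#'   synthetic-data generator to carry the planted truth).
#' @return Object of class `abundance_table`.
#' @export
abundance_table <- function(mat, state = c("counts", "relative"),
                            groups = NULL) {
  state <- match.arg(state)
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("'mat' must be a numeric matrix")
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("taxa labels must be present and unique")
  if (is.null(colnames(mat)) || anyDuplicated(colnames(mat)))
    stop("sample ids must be present and unique")
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative abundance for taxon '", rownames(mat)[neg[1L, 1L]],
         "' in sample '", colnames(mat)[neg[1L, 2L]], "'")
  if (state == "relative") {
    cs <- colSums(mat)
    if (any(abs(cs - 1) > 1e-9))
      stop("relative-state columns must sum to 1; offending sample '",
           colnames(mat)[which.max(abs(cs - 1))], "'")
  }
  structure(list(abund = mat, state = state, groups = groups),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d taxa x %d samples (%s)\n",
              nrow(x$abund), ncol(x$abund), x$state))
  invisible(x)
}

#' Load an abundance table from TSV
#'
#' First column holds taxon labels, remaining columns one sample each.
#' The result is in counts state; see [relative_abundance()].
#'
#' @param path Path to the TSV file.
#' @return An `abundance_table` in counts state.
#' @export
load_abundance_table <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("validation error: expected a taxa column plus >= 1 sample column")
  taxa <- as.character(df[[1L]])
  if (anyDuplicated(taxa))
    stop("validation error: duplicate taxon '",
         taxa[duplicated(taxa)][1L], "'")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- taxa
  abundance_table(mat, state = "counts")
}

#' Write an abundance table as TSV
#'
#' @param t An `abundance_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(t, path) {
  stopifnot(inherits(t, "abundance_table"))
  df <- data.frame(taxon = rownames(t$abund), t$abund,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides each sample column by its sum. Already-relative tables are
#' returned unchanged with a warning (idempotent by design).
#'
#' @param t An `abundance_table`.
#' @return The table in relative state; each column sums to 1.
#' @export
relative_abundance <- function(t) {
  stopifnot(inherits(t, "abundance_table"))
  if (t$state == "relative") {
    warning("table is already in relative state; returning unchanged")
    return(t)
  }
  cs <- colSums(t$abund)
  if (any(cs == 0))
    stop("all-zero sample column '", colnames(t$abund)[which(cs == 0)[1L]],
         "' cannot be normalized")
  abundance_table(sweep(t$abund, 2L, cs, "/"), state = "relative",
                  groups = t$groups)
}

#' Most abundant taxa
#'
#' With `scope = "overall"` taxa are ranked by mean relative abundance
#' across samples; with `scope = "per_sample"` each sample is ranked
#' separately. Ties are broken lexicographically by taxon label. Counts
#' tables are normalized internally for ranking.
#'
#' @param t An `abundance_table`.
#' @param n Number of taxa to return (default 10, the usual
#'   presentation depth for order-level profiles). If `n` exceeds the
#'   number of taxa all are returned with a warning.
#' @param scope `"overall"` or `"per_sample"`.
#' @return Character vector of taxa (`overall`) or a named list of such
#'   vectors (`per_sample`).
#' @export
top_taxa <- function(t, n = 10, scope = c("overall", "per_sample")) {
  stopifnot(inherits(t, "abundance_table"))
  scope <- match.arg(scope)
  if (n < 1) stop("'n' must be >= 1")
  rel <- if (t$state == "counts")
    sweep(t$abund, 2L, colSums(t$abund), "/") else t$abund
  if (n > nrow(rel)) {
    warning("'n' exceeds the number of taxa (", nrow(rel),
            "); returning all taxa")
    n <- nrow(rel)
  }
  rank_one <- function(v) {
    ord <- order(-v, rownames(rel), method = "radix")
    rownames(rel)[ord][seq_len(n)]
  }
  if (scope == "overall") {
    rank_one(rowMeans(rel))
  } else {
    res <- lapply(seq_len(ncol(rel)), function(j) rank_one(rel[, j]))
    names(res) <- colnames(rel)
    res
  }
}

#' Abundance ratio between two taxon sets
#'
#' Sums the abundances of a numerator set and a denominator set within
#' one sample and returns their ratio — e.g. the
#' Cyanobacteria:Proteobacteria (or cyanobacteria:heterotrophs) index
#' used to track the balance between autotrophy and heterotrophy.
#'
#' @param t An `abundance_table`.
#' @param numerator,denominator Non-empty, disjoint character vectors of
#'   taxon labels. Labels absent from the table contribute 0.
#' @param sample Sample id.
#' @return A single unit-free ratio; 0 when the numerator mass is 0.
#' @export
group_ratio <- function(t, numerator, denominator, sample) {
  stopifnot(inherits(t, "abundance_table"))
  if (length(numerator) == 0L || length(denominator) == 0L)
    stop("numerator and denominator taxon sets must be non-empty")
  if (length(intersect(numerator, denominator)))
    stop("numerator and denominator taxon sets must be disjoint")
  if (!sample %in% colnames(t$abund))
    stop("unknown sample '", sample, "'")
  v <- t$abund[, sample]
  num <- sum(v[intersect(numerator, rownames(t$abund))])
  den <- sum(v[intersect(denominator, rownames(t$abund))])
  if (den == 0)
    stop("denominator mass is zero in sample '", sample, "'")
  num / den
}

#' Pearson correlation distance between sample profiles
#'
#' `d(i, j) = 1 - r(i, j)` where `r` is the Pearson correlation between
#' the relative-abundance columns of samples `i` and `j`; `d` lies in
#' `[0, 2]` with zero diagonal.
#'
#' @param t An `abundance_table` in relative state with at least two
#'   samples.
#' @return Symmetric distance matrix.
#' @export
pearson_distance <- function(t) {
  stopifnot(inherits(t, "abundance_table"))
  if (t$state != "relative")
    stop("pearson_distance expects a relative-state table; ",
         "call relative_abundance() first")
  if (ncol(t$abund) < 2L) stop("need at least two samples")
  sds <- apply(t$abund, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance profile for sample '",
         colnames(t$abund)[which(sds == 0)[1L]], "'")
  d <- 1 - stats::cor(t$abund)
  d[d < 0] <- 0           # clip numeric fuzz on identical profiles
  diag(d) <- 0
  d
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering under the Ward minimum-variance criterion
#' via Lance–Williams updates. The default `"classic"` variant applies
#' the update to the distances as supplied (the behaviour of the
#' historical R/ape `"ward"` method); `"squared"` squares the
#' dissimilarities first and returns square-rooted heights.
#'
#' @param d Symmetric distance matrix with zero diagonal and sample ids
#'   as dimnames.
#' @param variant `"classic"` or `"squared"`.
#' @return An [stats::hclust] tree; merge heights are non-decreasing.
#' @export
ward_clustering <- function(d, variant = c("classic", "squared")) {
  variant <- match.arg(variant)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("'d' must be a square matrix")
  if (nrow(d) < 2L) stop("need at least two samples")
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("'d' must be symmetric")
  if (any(d < 0)) stop("'d' must be non-negative")
  method <- if (variant == "classic") "ward.D" else "ward.D2"
  stats::hclust(stats::as.dist(d), method = method)
}

newick_escape <- function(label) {
  if (grepl("[][(),:;'\"\\s]", label, perl = TRUE))
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  else label
}

#' Serialize an hclust dendrogram to newick
#'
#' Branch lengths are differences of merge heights (a leaf sits at
#' height 0, so a two-leaf tree at height `h` serializes as
#' `(A:h,B:h);`). Labels containing newick metacharacters are quoted per
#' the standard.
#'
#' @param tree An [stats::hclust] object.
#' @param digits Significant digits for branch lengths.
#' @return A single newick string terminated by `;`.
#' @export
to_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "hclust"))
  lab <- vapply(tree$labels, newick_escape, "")
  fmt <- function(x) sprintf("%.*g", digits, x)
  node <- function(i, parent_h) {
    if (i < 0L) return(paste0(lab[-i], ":", fmt(parent_h)))
    h <- tree$height[i]
    paste0("(", node(tree$merge[i, 1L], h), ",",
           node(tree$merge[i, 2L], h), "):", fmt(parent_h - h))
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  paste0("(", node(tree$merge[root, 1L], h), ",",
         node(tree$merge[root, 2L], h), ");")
}
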