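# Reading, normalizing and filtering metagenomic read libraries.

DNA_BASES <- c("A", "C", "G", "T")

normalize_sequences <- function(x) {
  # uppercase, then collapse everything outside {A,C,G,T} (IUPAC codes,
  # gaps, stray characters) to N; downstream k-mer counting skips
  # N-containing windows, so ambiguity never biases a signature
  gsub("[^ACGT]", "N", toupper(x), perl = TRUE)
}

#' Construct a read set
#'
#' A read set is one metagenomic library: a collection of identified
#' nucleotide reads plus the total base count used as the normalization
#' denominator by downstream summaries.
#'
#' @param reads A named character vector of sequences, or a
#'   [Biostrings::DNAStringSet]. Sequences are uppercased and characters
#'   outside `A/C/G/T` are mapped to `N`.
#' @param library_id Single string identifying the library.
#' @return An object of class `read_set`: a list with elements
#'   `library_id`, `reads` (a `DNAStringSet`) and `total_bases`.
#' @examples
#' rs <- read_set(c(r1 = "ACGTACGT", r2 = "acgtn"), "toy")
#' total_bases(rs)
#' @export
read_set <- function(reads, library_id) {
  if (length(library_id) != 1L || !nzchar(library_id))
    stop("'library_id' must be a single non-empty string")
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read_%d", seq_along(reads))
    reads <- Biostrings::DNAStringSet(normalize_sequences(reads))
    names(reads) <- ids
  }
  if (!methods::is(reads, "DNAStringSet"))
    stop("'reads' must be a character vector or a DNAStringSet")
  if (length(reads) && any(Biostrings::width(reads) < 1L))
    stop("every read must have length >= 1")
  structure(
    list(library_id = as.character(library_id),
         reads = reads,
         total_bases = sum(as.numeric(Biostrings::width(reads)))),
    class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> library '%s': %d reads, %s bp\n",
              x$library_id, length(x$reads),
              format(x$total_bases, big.mark = ",")))
  invisible(x)
}

#' Load reads from FASTA or FASTQ
#'
#' Parses a sequence file into a [read_set()]. Sequences are uppercased
#' and characters outside `A/C/G/T` become `N`.
#'
#' @param path Path to the sequence file.
#' @param format `"fasta"` or `"fastq"` (Sanger offset-33 qualities are
#'   accepted but unused).
#' @param library_id Library identifier; defaults to the file name
#'   without extension.
#' @return A `read_set`.
#' @export
load_reads <- function(path, format = c("fasta", "fastq"),
                       library_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (is.null(library_id))
    library_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "fasta") {
    seqs <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fasta"),
      error = function(e) stop("parse error in FASTA file '", path,
                               "': ", conditionMessage(e), call. = FALSE))
    reads <- as.character(seqs)
    names(reads) <- sub("\\s.*$", "", names(seqs))
  } else {
    reads <- parse_fastq(path)
  }
  if (length(reads) == 0L)
    return(structure(list(library_id = library_id,
                          reads = Biostrings::DNAStringSet(),
                          total_bases = 0),
                     class = "read_set"))
  read_set(reads, library_id)
}

# Minimal strict FASTQ reader: 4 lines per record, validated so that a
# malformed record is reported by its record index.
parse_fastq <- function(path) {
  lines <- readLines(path)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L) return(character(0))
  if (length(lines) %% 4L != 0L)
    stop("parse error in FASTQ file '", path, "': record ",
         length(lines) %/% 4L + 1L, " is truncated (missing lines)")
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seqs) == 0L | nchar(seqs) != nchar(qual))
  if (length(bad))
    stop("parse error in FASTQ file '", path, "': malformed record ",
         bad[1L])
  names(seqs) <- sub("\\s.*$", "", substring(hdr, 2L))
  seqs
}

#' Write a read set to FASTA
#'
#' @param rs A `read_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  Biostrings::writeXStringSet(rs$reads, filepath = path, format = "fasta")
  invisible(path)
}

#' Length / ambiguity filter for a read set
#'
#' Retains reads with length at least `min_length` and an N fraction of
#' at most `max_n_fraction`; `total_bases` is recomputed. Applying the
#' filter twice with the same parameters is a no-op. The defaults are a
#' conservative quality-control stand-in for pyrosequencing libraries.
#'
#' @param rs A `read_set`.
#' @param min_length Minimum read length in bp (default 50).
#' @param max_n_fraction Maximum tolerated proportion of N (default 0.05).
#' @return A filtered `read_set`; the input is unmodified.
#' @export
qc_filter <- function(rs, min_length = 50, max_n_fraction = 0.05) {
  stopifnot(inherits(rs, "read_set"))
  if (min_length < 1) stop("'min_length' must be >= 1")
  if (max_n_fraction < 0 || max_n_fraction > 1)
    stop("'max_n_fraction' must be in [0, 1]")
  if (length(rs$reads) == 0L) return(rs)
  w <- Biostrings::width(rs$reads)
  nfrac <- as.vector(Biostrings::letterFrequency(rs$reads, "N")) / w
  keep <- w >= min_length & nfrac <= max_n_fraction
  structure(
    list(library_id = rs$library_id,
         reads = rs$reads[keep],
         total_bases = sum(as.numeric(w[keep]))),
    class = "read_set")
}

#' Total base count of a read set
#'
#' @param rs A `read_set`.
#' @return Sum of read lengths in bp (0 for an empty set).
#' @export
total_bases <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  rs$total_bases
}

MANIFEST_COLUMNS <- c("library_id", "sample_id", "replicate", "day",
                      "habitat", "health")
HABITAT_LEVELS <- c("seawater", "coral")
HEALTH_LEVELS <- c("healthy", "bleached", "n/a")

#' Load and validate a sample manifest
#'
#' The manifest maps each library to its sample, replicate, sampling day,
#' habitat (`seawater` or `coral`) and health status (`healthy`,
#' `bleached` or `n/a`). Tab-separated, UTF-8, header row required.
#'
#' @param path Path to the TSV manifest.
#' @return A validated `data.frame` with class `sample_manifest`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  raw <- readLines(path, encoding = "UTF-8")
  if (length(raw) == 0L || all(!nzchar(raw)))
    stop("manifest validation error: '", path, "' is empty")
  m <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character", fileEncoding = "UTF-8")
  missing <- setdiff(MANIFEST_COLUMNS, names(m))
  if (length(missing))
    stop("manifest validation error: missing column(s) ",
         paste(missing, collapse = ", "))
  if (nrow(m) == 0L)
    stop("manifest validation error: no entries in '", path, "'")
  dup <- unique(m$library_id[duplicated(m$library_id)])
  if (length(dup))
    stop("manifest validation error: duplicate library_id ",
         paste(dup, collapse = ", "))
  bad_hab <- unique(m$habitat[!m$habitat %in% HABITAT_LEVELS])
  if (length(bad_hab))
    stop("manifest validation error: unknown habitat token(s) ",
         paste(bad_hab, collapse = ", "))
  bad_hea <- unique(m$health[!m$health %in% HEALTH_LEVELS])
  if (length(bad_hea))
    stop("manifest validation error: unknown health token(s) ",
         paste(bad_hea, collapse = ", "))
  m <- m[MANIFEST_COLUMNS]
  class(m) <- c("sample_manifest", "data.frame")
  m
}
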