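# Seeded generators for every input the pipeline consumes: Markov-chain
# genomes, fragment read libraries, replicate community mixtures,
# group-structured abundance tables and category-structured hit tables.

MIN_READ_LENGTH <- 30L

#' Construct an order-1 Markov genome model
#'
#' Dinucleotide structure — the quantity the Karlin delta measures — is
#' fully determined by an order-1 Markov chain over A/C/G/T, so these
#' models are sufficient to generate genomes with controlled,
#' distinguishable signatures.
#'
#' @param transition 4x4 row-stochastic matrix (rows/columns ordered
#'   A, C, G, T; each row must sum to 1 within 1e-12).
#' @param initial Initial base distribution; defaults to the chain's
#'   stationary distribution.
#' @param label Model label.
#' @return Object of class `genome_model`.
#' @export
genome_model <- function(transition, initial = NULL, label = "genome") {
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(4L, 4L)))
    stop("'transition' must be a 4x4 matrix")
  if (any(transition < 0))
    stop("transition probabilities must be non-negative")
  if (any(abs(rowSums(transition) - 1) > 1e-12))
    stop("each transition row must sum to 1 (within 1e-12)")
  dimnames(transition) <- list(DNA_BASES, DNA_BASES)
  if (is.null(initial)) {
    e <- eigen(t(transition))
    i <- which.min(abs(e$values - 1))
    v <- abs(Re(e$vectors[, i]))
    initial <- v / sum(v)
  }
  if (length(initial) != 4L || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-9)
    stop("'initial' must be a length-4 probability vector")
  names(initial) <- DNA_BASES
  structure(list(transition = transition, initial = initial,
                 label = label),
            class = "genome_model")
}

#' Two built-in genome models with contrasting dinucleotide structure
#'
#' Model `A` favours homopolymer runs (same-base persistence 0.55),
#' model `B` favours base alternation (same-base persistence 0.10).
#' Both are GC-balanced, so they differ only in neighbour dependence —
#' exactly the axis the odds-ratio signature and the Karlin delta
#' resolve; at realistic depth the pair is separated by deltas in the
#' hundreds on the x1000 scale.
#'
#' @return Named list of two `genome_model` objects.
#' @examples
#' mods <- contrasting_genome_models()
#' mods$A$transition
#' @export
contrasting_genome_models <- function() {
  persist <- function(p) {
    m <- matrix((1 - p) / 3, 4L, 4L)
    diag(m) <- p
    m
  }
  list(A = genome_model(persist(0.55), label = "A"),
       B = genome_model(persist(0.10), label = "B"))
}

# Markov sampling with the current RNG stream (callers own the seed).
markov_chain_sample <- function(model, length) {
  cm <- t(apply(model$transition, 1L, cumsum))
  rows <- lapply(1:4, function(i) cm[i, 1:3])
  u <- stats::runif(length)
  s <- integer(length)
  ini <- cumsum(model$initial)[1:3]
  s[1L] <- 1L + (u[1L] > ini[1L]) + (u[1L] > ini[2L]) + (u[1L] > ini[3L])
  for (i in seq.int(2L, length)) {
    r <- rows[[s[i - 1L]]]
    s[i] <- 1L + (u[i] > r[1L]) + (u[i] > r[2L]) + (u[i] > r[3L])
  }
  paste(DNA_BASES[s], collapse = "")
}

#' Simulate a genome sequence from a Markov model
#'
#' @param model A [genome_model()].
#' @param length Sequence length in bp (>= 10).
#' @param seed Integer seed; identical `(seed, model, length)` give
#'   byte-identical sequences.
#' @return A single character string over A/C/G/T.
#' @export
simulate_genome <- function(model, length, seed) {
  stopifnot(inherits(model, "genome_model"))
  if (length < 10) stop("'length' must be >= 10")
  withr::with_seed(as.integer(seed), markov_chain_sample(model, length))
}

# Fragment reads off source sequences with the current RNG stream.
fragment_reads <- function(sequences, n_reads, length_mean, length_sd,
                           id_prefix = "read") {
  src_len <- nchar(sequences)
  if (any(src_len < MIN_READ_LENGTH))
    stop("every source sequence must be at least ", MIN_READ_LENGTH, " bp")
  src <- if (length(sequences) == 1L) rep(1L, n_reads)
  else sample.int(length(sequences), n_reads, replace = TRUE,
                  prob = src_len / sum(src_len))
  len <- round(stats::rnorm(n_reads, length_mean, length_sd))
  len <- pmax(MIN_READ_LENGTH, pmin(len, src_len[src]))
  start <- 1L + floor(stats::runif(n_reads) * (src_len[src] - len + 1))
  reads <- substring(sequences[src], start, start + len - 1L)
  names(reads) <- sprintf("%s_%05d", id_prefix, seq_len(n_reads))
  reads
}

#' Simulate a shotgun read library
#'
#' Reads are fragments of the source sequence(s): start positions are
#' uniform, lengths are normal with the given mean and SD, truncated to
#' a 30 bp floor and to the source length — emulating the
#' pyrosequencing-style length profiles of real libraries (typically a
#' few hundred bp, e.g. 361 +/- 128).
#'
#' @param sequences Character vector of source sequences (each >= 30
#'   bp), or a `DNAStringSet`. With several sources, each read picks its
#'   source with probability proportional to source length.
#' @param n_reads Number of reads (>= 1).
#' @param length_mean,length_sd Read length mean and SD in bp.
#' @param seed Integer seed.
#' @param library_id Library id for the resulting read set.
#' @return A [read_set()].
#' @export
simulate_reads <- function(sequences, n_reads, length_mean = 361,
                           length_sd = 128, seed, library_id = "simlib") {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  if (n_reads < 1) stop("'n_reads' must be >= 1")
  if (length_mean <= 0) stop("'length_mean' must be > 0")
  reads <- withr::with_seed(
    as.integer(seed),
    fragment_reads(sequences, n_reads, length_mean, length_sd))
  read_set(reads, library_id)
}

#' Specify a synthetic community
#'
#' Defaults mirror the study design the generator emulates: three
#' replicate libraries per community (one per filter membrane) and
#' pyrosequencing-style read lengths of 361 +/- 128 bp.
#'
#' @param genomes List of [genome_model()] objects.
#' @param proportions Mixing proportions (default equal); must sum to 1.
#' @param n_libraries Replicate libraries to generate (default 3).
#' @param reads_per_library Reads per library (default 10000).
#' @param read_length_mean,read_length_sd Read length distribution in
#'   bp (default 361 and 128).
#' @param genome_length Length of each simulated source genome (default
#'   1e5 bp).
#' @param seed Integer seed.
#' @param label Community label used in library ids.
#' @return Object of class `community_spec`.
#' @export
community_spec <- function(genomes,
                           proportions = rep(1 / length(genomes),
                                             length(genomes)),
                           n_libraries = 3, reads_per_library = 10000,
                           read_length_mean = 361, read_length_sd = 128,
                           genome_length = 1e5, seed, label = "community") {
  if (length(genomes) == 0L) stop("'genomes' must be non-empty")
  if (!all(vapply(genomes, inherits, NA, "genome_model")))
    stop("'genomes' must be a list of genome_model objects")
  if (length(proportions) != length(genomes) ||
      abs(sum(proportions) - 1) > 1e-9 || any(proportions < 0))
    stop("'proportions' must be non-negative and sum to 1")
  if (reads_per_library < 1) stop("'reads_per_library' must be >= 1")
  structure(list(genomes = genomes, proportions = proportions,
                 n_libraries = as.integer(n_libraries),
                 reads_per_library = as.integer(reads_per_library),
                 read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd,
                 genome_length = as.integer(genome_length),
                 seed = as.integer(seed), label = label),
            class = "community_spec")
}

#' Simulate replicate read libraries from a community specification
#'
#' One genome sequence is realized per model; each library then draws
#' its per-read source genome from the mixing proportions and fragments
#' reads independently, so replicate libraries share the community but
#' differ in sampling noise.
#'
#' @param spec A [community_spec()].
#' @return List of [read_set()] objects, named
#'   `<label>_lib1 ... <label>_libL`.
#' @export
simulate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  withr::with_seed(spec$seed, {
    genomes <- vapply(spec$genomes, markov_chain_sample, "",
                      length = spec$genome_length)
    libs <- lapply(seq_len(spec$n_libraries), function(l) {
      counts <- as.vector(stats::rmultinom(1L, spec$reads_per_library,
                                           spec$proportions))
      reads <- character(0)
      for (g in seq_along(genomes)) {
        if (counts[g] == 0L) next
        # read ids carry the source genome (..._g<g>_...) so recovery
        # experiments can check realized mixing proportions
        reads <- c(reads,
                   fragment_reads(genomes[g], counts[g],
                                  spec$read_length_mean,
                                  spec$read_length_sd,
                                  id_prefix = sprintf("%s_lib%d_g%d",
                                                      spec$label, l, g)))
      }
      read_set(reads, sprintf("%s_lib%d", spec$label, l))
    })
    names(libs) <- vapply(libs, `[[`, "", "library_id")
    libs
  })
}

#' Specify a group-structured abundance-table simulation
#'
#' @param centroids Taxa-by-groups matrix of group centroid proportions
#'   (each column non-negative, summing to 1), with taxa rownames.
#' @param samples_per_group Samples drawn per group (default 5).
#' @param concentration Dirichlet concentration controlling replicate
#'   noise: samples are drawn from
#'   `Dirichlet(concentration * centroid)`, so larger values give
#'   tighter replicates (default 100, moderately tight profiles).
#' @param seed Integer seed.
#' @return Object of class `profile_spec`.
#' @export
profile_spec <- function(centroids, samples_per_group = 5,
                         concentration = 100, seed) {
  centroids <- as.matrix(centroids)
  if (is.null(rownames(centroids)))
    rownames(centroids) <- sprintf("taxon_%02d", seq_len(nrow(centroids)))
  if (is.null(colnames(centroids)))
    colnames(centroids) <- sprintf("group_%d", seq_len(ncol(centroids)))
  if (any(centroids < 0) || any(abs(colSums(centroids) - 1) > 1e-9))
    stop("each centroid column must be non-negative and sum to 1")
  if (concentration <= 0) stop("'concentration' must be > 0")
  structure(list(centroids = centroids,
                 samples_per_group = as.integer(samples_per_group),
                 concentration = concentration, seed = as.integer(seed)),
            class = "profile_spec")
}

#' Simulate a group-structured abundance table
#'
#' Each sample is a Dirichlet draw around its group centroid; columns
#' sum to 1 (relative state). The planted group labels travel in the
#' table's `groups` field for recovery experiments.
#'
#' @param spec A [profile_spec()].
#' @return An [abundance_table()] in relative state.
#' @export
simulate_abundance_table <- function(spec) {
  stopifnot(inherits(spec, "profile_spec"))
  withr::with_seed(spec$seed, {
    cols <- list(); groups <- character(0)
    for (g in seq_len(ncol(spec$centroids))) {
      shape <- spec$concentration * spec$centroids[, g]
      for (s in seq_len(spec$samples_per_group)) {
        x <- stats::rgamma(nrow(spec$centroids), shape = shape)
        if (sum(x) == 0) x <- spec$centroids[, g]  # degenerate guard
        cols[[length(cols) + 1L]] <- x / sum(x)
        groups <- c(groups, colnames(spec$centroids)[g])
      }
    }
    mat <- do.call(cbind, cols)
    rownames(mat) <- rownames(spec$centroids)
    colnames(mat) <- sprintf("%s_s%d", groups,
                             stats::ave(seq_along(groups), groups,
                                        FUN = seq_along))
    abundance_table(mat, state = "relative", groups = groups)
  })
}

#' Simulate a category-structured virulence hit table
#'
#' Per-category hit counts are Poisson with mean
#' `rate * total_bp / 1e5`; each hit is given a subject id, an
#' annotation phrased so the default category rules recover the planted
#' category, and an e-value below 1e-4. The analytically expected
#' summary row (built from the drawn counts) is returned alongside for
#' test comparison.
#'
#' @param rates Named numeric vector of hits per 1e5 bp for the
#'   categories `iron_related` (non-Haemophilus), `haemophilus_iron`,
#'   `vibrio_cholerae`, `other`; missing names default to 0.
#' @param total_bp Library size in bp (> 0).
#' @param seed Integer seed.
#' @param sample Sample id used in the expected summary.
#' @return List with `hits` (a hit data frame matching [parse_hits()]
#'   plus `category_truth`) and `expected` (a `vf_summary` row).
#' @export
simulate_vf_hits <- function(rates, total_bp, seed, sample = "sim") {
  if (total_bp <= 0) stop("'total_bp' must be > 0")
  full <- c(iron_related = 0, haemophilus_iron = 0,
            vibrio_cholerae = 0, other = 0)
  full[names(rates)] <- rates
  if (any(full < 0)) stop("rates must be non-negative")
  templates <- list(
    iron_related = c("ferric iron(III) dicitrate transport system permease",
                     "siderophore biosynthesis protein IucA",
                     "heme utilization outer membrane receptor"),
    haemophilus_iron = c(
      "Haemophilus influenzae iron-utilization periplasmic protein HitA",
      "Haemophilus influenzae hemoglobin-binding protein HgpA"),
    vibrio_cholerae = c(
      "Vibrio cholerae toxin-coregulated pilus biosynthesis protein TcpA",
      "Vibrio cholerae cholera enterotoxin subunit B"),
    other = c("flagellar motor switch protein FliG",
              "type III secretion system needle protein"))
  withr::with_seed(as.integer(seed), {
    n <- stats::rpois(4L, full * total_bp / 1e5)
    names(n) <- names(full)
    rows <- list()
    for (catg in names(n)) {
      if (n[catg] == 0L) next
      ann <- sample(templates[[catg]], n[catg], replace = TRUE)
      rows[[catg]] <- data.frame(
        query = sprintf("read_%06d",
                        sample.int(1e6, n[catg], replace = TRUE)),
        subject = sprintf("VFG%06d", sample.int(5000L, n[catg],
                                                replace = TRUE)),
        annotation = ann,
        evalue = 10^stats::runif(n[catg], -40, -4.05),
        bitscore = round(stats::runif(n[catg], 50, 300), 1),
        category_truth = catg, stringsAsFactors = FALSE)
    }
    hits <- if (length(rows)) do.call(rbind, rows)
    else data.frame(query = character(0), subject = character(0),
                    annotation = character(0), evalue = numeric(0),
                    bitscore = numeric(0), category_truth = character(0),
                    stringsAsFactors = FALSE)
    if (nrow(hits)) {
      hits <- hits[sample.int(nrow(hits)), , drop = FALSE]
      rownames(hits) <- NULL
    }
    expected <- vf_row(sample,
                       total = sum(n),
                       iron = n[["iron_related"]] + n[["haemophilus_iron"]],
                       haemophilus = n[["haemophilus_iron"]],
                       vibrio = n[["vibrio_cholerae"]],
                       total_bp = total_bp)
    list(hits = hits, expected = expected)
  })
}

#' Write a hit data frame in 13-column tabular format
#'
#' Emits the standard 12 alignment columns (with placeholder alignment
#' statistics) plus the annotation column, for round-tripping through
#' [parse_hits()].
#'
#' @param hits Data frame with `query`, `subject`, `annotation`,
#'   `evalue`, `bitscore`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  n <- nrow(hits)
  tab <- data.frame(hits$query, hits$subject,
                    rep(90, n), rep(50, n), rep(3, n), rep(0, n),
                    rep(1, n), rep(50, n), rep(1, n), rep(150, n),
                    format(hits$evalue, scientific = TRUE, digits = 3),
                    hits$bitscore, hits$annotation,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
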