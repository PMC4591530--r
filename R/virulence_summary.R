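# Virulence-factor hit tables: parsing, e-value filtering, category
# assignment and per-sample / aggregate summaries.

VF_CATEGORIES <- c("haemophilus_iron", "iron_related", "vibrio_cholerae",
                   "other")

#' Parse a tabular similarity-hit file
#'
#' Reads the standard 12-column tabular output of a protein similarity
#' search (query, subject, identity, alignment length, mismatches, gap
#' opens, coordinates, e-value, bit score), with an optional 13th
#' column carrying the subject annotation text. Malformed lines are
#' rejected with their line number.
#'
#' @param path Path to the TSV hit file.
#' @return `data.frame` with columns `query`, `subject`, `annotation`,
#'   `evalue`, `bitscore`; zero rows for an empty file.
#' @export
parse_hits <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(query = character(0), subject = character(0),
                      annotation = character(0), evalue = numeric(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(!nf %in% c(12L, 13L))
  if (length(bad))
    stop("parse error at line ", lineno[bad[1L]], ": expected 12 or 13 ",
         "tab-separated fields, found ", nf[bad[1L]])
  pick <- function(i) vapply(fields, `[`, "", i)
  ev <- suppressWarnings(as.numeric(pick(11L)))
  if (anyNA(ev))
    stop("parse error at line ", lineno[which(is.na(ev))[1L]],
         ": non-numeric e-value")
  bs <- suppressWarnings(as.numeric(pick(12L)))
  if (anyNA(bs))
    stop("parse error at line ", lineno[which(is.na(bs))[1L]],
         ": non-numeric bit score")
  if (any(ev < 0))
    stop("parse error at line ", lineno[which(ev < 0)[1L]],
         ": negative e-value")
  ann <- vapply(fields, function(f) if (length(f) >= 13L) f[13L] else "", "")
  data.frame(query = pick(1L), subject = pick(2L), annotation = ann,
             evalue = ev, bitscore = bs, stringsAsFactors = FALSE)
}

#' Filter hits by e-value
#'
#' Retains hits with `evalue` strictly below the threshold (the
#' conventional `E < 1e-4` screening cut-off), preserving input order.
#'
#' @param hits Data frame from [parse_hits()].
#' @param threshold Positive e-value cut-off (default `1e-4`).
#' @return The surviving rows of `hits`.
#' @export
filter_evalue <- function(hits, threshold = 1e-4) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("'threshold' must be a single positive number")
  hits[hits$evalue < threshold, , drop = FALSE]
}

#' Category rules for virulence-factor hits
#'
#' Rules are an ordered pattern table (first matching rule wins) mapping
#' hit text to the categories `haemophilus_iron`, `iron_related`,
#' `vibrio_cholerae`; unmatched hits fall through to `other`. The
#' default rule file shipped with the package keys on common
#' virulence-catalogue gene-family wording (iron/siderophore/haem
#' acquisition, Haemophilus (Pasteurellales) iron systems, V. cholerae
#' toxin and colonization factors) and is user-editable: patterns are
#' case-insensitive regular expressions applied to the `subject` id, the
#' `annotation` text, or both (`any`).
#'
#' @param path Path to a rule TSV with columns `pattern`, `field`
#'   (`subject`, `annotation` or `any`) and `category`; `NULL` loads the
#'   packaged defaults.
#' @return `data.frame` of ordered rules.
#' @export
load_category_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "vf_category_rules.tsv",
                        package = "metasig", mustWork = TRUE)
  rules <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pattern", "field", "category")
  if (!all(need %in% names(rules)))
    stop("rule file must have columns ", paste(need, collapse = ", "))
  bad <- setdiff(rules$category, VF_CATEGORIES)
  if (length(bad))
    stop("unknown category label(s): ", paste(bad, collapse = ", "))
  if (!all(rules$field %in% c("subject", "annotation", "any")))
    stop("rule 'field' must be one of subject, annotation, any")
  rules
}

#' Assign a category to every hit
#'
#' Applies the ordered rules; each hit gets exactly one primary label.
#' The containment of Haemophilus iron-related hits inside the
#' iron-related class is enforced at counting time (see
#' [summarize_sample()]), not in the label.
#'
#' @param hits Data frame from [parse_hits()] (usually after
#'   [filter_evalue()]).
#' @param rules Rule table from [load_category_rules()].
#' @return `hits` with an added `category` column.
#' @export
assign_categories <- function(hits, rules = load_category_rules()) {
  category <- rep("other", nrow(hits))
  open <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(rules))) {
    if (!any(open)) break
    txt <- switch(rules$field[i],
                  subject = hits$subject,
                  annotation = hits$annotation,
                  any = paste(hits$subject, hits$annotation))
    hit <- open & grepl(rules$pattern[i], txt, ignore.case = TRUE,
                        perl = TRUE)
    category[hit] <- rules$category[i]
    open <- open & !hit
  }
  hits$category <- category
  hits
}

#' Build one summary row from category counts
#'
#' Central constructor behind [summarize_sample()] and useful directly
#' when only printed per-sample counts are available. The iron-related
#' count already includes the Haemophilus iron-related hits
#' (`haemophilus <= iron <= total`). Percentages use the table's
#' conventions: iron and V. cholerae hits as a percentage of total hits,
#' Haemophilus iron hits as a percentage of iron-related hits; all are
#' rounded half-even to one decimal.
#'
#' @param sample Sample id.
#' @param total,iron,haemophilus,vibrio Non-negative hit counts.
#' @param total_bp Total library size in bp (used for the
#'   hits-per-1e5-bp normalization), or `NULL` if `normalized` is given
#'   directly.
#' @param normalized Hits per 1e5 bp, if precomputed.
#' @return One-row `data.frame` of class `vf_summary`.
#' @export
vf_row <- function(sample, total, iron, haemophilus, vibrio,
                   total_bp = NULL, normalized = NULL) {
  if (any(c(total, iron, haemophilus, vibrio) < 0))
    stop("hit counts must be non-negative")
  if (haemophilus > iron || iron > total || vibrio > total)
    stop("count containment violated: need haemophilus <= iron <= total ",
         "and vibrio <= total")
  if (is.null(normalized)) {
    if (is.null(total_bp))
      stop("supply either 'total_bp' or 'normalized'")
    if (total_bp <= 0) stop("'total_bp' must be > 0")
    normalized <- total / total_bp * 1e5
  }
  pct <- function(num, den) if (den == 0) 0 else round(100 * num / den, 1)
  out <- data.frame(
    sample = sample,
    total_hits = total,
    hits_per_1e5bp = normalized,
    iron = iron,
    iron_pct = pct(iron, total),
    haemophilus_iron = haemophilus,
    haemophilus_pct = pct(haemophilus, iron),
    vibrio = vibrio,
    vibrio_pct = pct(vibrio, total),
    total_bp = if (is.null(total_bp)) NA_real_ else total_bp,
    stringsAsFactors = FALSE)
  class(out) <- c("vf_summary", "data.frame")
  out
}

#' Summarize categorized hits for one sample
#'
#' Counts every filtered hit (no best-hit-per-read collapse by default,
#' matching the raw-hit convention; set `best_hit_per_query = TRUE` to
#' keep only the lowest-e-value hit per query) and normalizes the total
#' to hits per 1e5 bp of library.
#'
#' @param hits Data frame with a `category` column (see
#'   [assign_categories()]).
#' @param total_bp Library size in bp; must be positive.
#' @param sample Sample id for the output row.
#' @param best_hit_per_query Collapse to one hit per query first
#'   (default `FALSE`).
#' @return One-row `vf_summary` data frame.
#' @export
summarize_sample <- function(hits, total_bp, sample = "sample",
                             best_hit_per_query = FALSE) {
  if (is.null(hits$category))
    stop("'hits' lacks a category column; run assign_categories() first")
  if (total_bp <= 0) stop("'total_bp' must be > 0")
  if (best_hit_per_query && nrow(hits)) {
    ord <- order(hits$evalue, -hits$bitscore)
    hits <- hits[ord, , drop = FALSE]
    hits <- hits[!duplicated(hits$query), , drop = FALSE]
  }
  n_haem <- sum(hits$category == "haemophilus_iron")
  n_iron <- sum(hits$category == "iron_related") + n_haem
  n_vib <- sum(hits$category == "vibrio_cholerae")
  vf_row(sample, total = nrow(hits), iron = n_iron,
         haemophilus = n_haem, vibrio = n_vib, total_bp = total_bp)
}

#' Aggregate per-sample virulence summaries
#'
#' Counts are summed and aggregate percentages recomputed from the
#' summed counts (never averaged). The aggregate `hits_per_1e5bp` cell
#' is the column sum of the per-sample normalized values, matching the
#' convention of published per-sample tables; a bp-weighted alternative
#' (`hits_per_1e5bp_weighted` = summed hits over summed bp) is emitted
#' alongside when library sizes are known.
#'
#' @param summaries A `vf_summary` data frame (one or more rows, e.g.
#'   `rbind` of [summarize_sample()] / [vf_row()] results).
#' @return One-row `vf_summary` data frame with `sample = "Total"`.
#' @export
vf_aggregate <- function(summaries) {
  if (nrow(summaries) < 1L) stop("need at least one summary row")
  bp <- if (anyNA(summaries$total_bp)) NULL else sum(summaries$total_bp)
  out <- vf_row("Total",
                total = sum(summaries$total_hits),
                iron = sum(summaries$iron),
                haemophilus = sum(summaries$haemophilus_iron),
                vibrio = sum(summaries$vibrio),
                normalized = sum(summaries$hits_per_1e5bp))
  out$total_bp <- if (is.null(bp)) NA_real_ else bp
  out$hits_per_1e5bp_weighted <-
    if (is.null(bp)) NA_real_ else sum(summaries$total_hits) / bp * 1e5
  out
}

#' Rebuild summary rows from a table of printed counts
#'
#' Convenience for replaying a published per-sample count table through
#' [vf_aggregate()]: expects columns `sample`, `total_hits`,
#' `hits_per_1e5bp`, `iron`, `haemophilus_iron`, `vibrio`.
#'
#' @param df Data frame of per-sample counts.
#' @return `vf_summary` data frame with recomputed percentages.
#' @export
vf_rows_from_counts <- function(df) {
  need <- c("sample", "total_hits", "hits_per_1e5bp", "iron",
            "haemophilus_iron", "vibrio")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  rows <- lapply(seq_len(nrow(df)), function(i)
    vf_row(df$sample[i], df$total_hits[i], df$iron[i],
           df$haemophilus_iron[i], df$vibrio[i],
           normalized = df$hits_per_1e5bp[i]))
  do.call(rbind, rows)
}

#' Write a virulence summary table as TSV
#'
#' @param summaries `vf_summary` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vf_table <- function(summaries, path) {
  utils::write.table(summaries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
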