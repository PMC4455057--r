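# Internal all-vs-all protein similarity search.
#
# A contract-level stand-in for an external homology search: exhaustive
# Smith-Waterman local alignment (affine gaps, BLOSUM62 with the X row and
# column zeroed so ambiguous residues contribute nothing) of each query
# against every visible database record. All downstream thresholds are
# identity / HSP-length / coverage based, so raw alignment scores are used
# directly and no e-value model is needed.

search_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- get_blosum62()
      m["X", ] <- 0L
      m[, "X"] <- 0L
      cache <<- m
    }
    cache
  }
})

get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Build a sequence database with taxonomy and an optional year view
#'
#' @param proteins protein table (`protein_id`, `organism_id`, `sequence`).
#' @param taxa taxonomy table; every organism referenced by `proteins`
#'   must resolve.
#' @param year_view optional integer year; organisms of the masked domains
#'   sequenced after this year are invisible to [search_proteins()].
#' @param mask_domains domains the year view applies to (default
#'   `"Archaea"`, the database-growth scenario for an archaeal recipient;
#'   set to both domains for a control in which the whole database grows).
#' @return an object of class `seq_db`.
#' @export
seq_db <- function(proteins, taxa, year_view = NULL,
                   mask_domains = "Archaea") {
  missing <- setdiff(unique(proteins$organism_id), taxa$organism_id)
  if (length(missing))
    stop("organism(s) not in taxonomy: ", paste(missing, collapse = ", "))
  structure(list(proteins = proteins, taxa = taxa,
                 year_view = year_view, mask_domains = mask_domains),
            class = "seq_db")
}

#' @export
print.seq_db <- function(x, ...) {
  vis <- visible_organisms(x)
  cat("<seq_db> ", nrow(x$proteins), " proteins from ",
      nrow(x$taxa), " organisms (", length(vis), " visible",
      if (!is.null(x$year_view)) paste0(", year view ", x$year_view), ")\n",
      sep = "")
  invisible(x)
}

visible_organisms <- function(db) {
  taxa <- db$taxa
  if (is.null(db$year_view)) return(taxa$organism_id)
  hide <- taxa$domain %in% db$mask_domains & taxa$year > db$year_view
  taxa$organism_id[!hide]
}

#' Restrict a database to organisms sequenced up to a given year
#'
#' Returns a view: records are never mutated, only visibility changes.
#' Organisms whose domain is in `domains_to_mask` and whose
#' `year_sequenced` exceeds `year` become invisible.
#'
#' @param db a [seq_db()].
#' @param year integer calendar year (>= 1995).
#' @param domains_to_mask character vector of domains to mask.
#' @return a `seq_db` view.
#' @export
mask_by_year <- function(db, year, domains_to_mask = "Archaea") {
  stopifnot(year >= 1995)
  db$year_view <- year
  db$mask_domains <- domains_to_mask
  db
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             identity = numeric(), hsp_length = integer(),
             query_coverage = numeric(), score = numeric(),
             rank = integer(), stringsAsFactors = FALSE)
}

#' Search one query protein against a database
#'
#' Smith-Waterman local alignment of the query against every visible
#' record except the query itself (hits to other proteins of the same
#' organism are retained; the paralog rule needs them). Hits are sorted by
#' score descending, ties broken by subject id ascending, and ranked 1..n.
#'
#' Identity is the percentage of identical residue pairs over aligned
#' columns excluding gap columns; `hsp_length` counts aligned columns
#' including gaps; `query_coverage` is the aligned query span over the
#' query length, in percent.
#'
#' @param query a single-row protein table or a protein id present in `db`.
#' @param db a [seq_db()].
#' @param min_score keep hits with score >= `min_score` (default 0; empty
#'   alignments are always dropped).
#' @return hit data.frame (possibly empty, with a warning if the masked
#'   database is empty).
#' @export
search_proteins <- function(query, db, min_score = 0) {
  if (is.character(query)) {
    i <- match(query, db$proteins$protein_id)
    if (is.na(i)) stop("query protein not in database: ", query)
    query <- db$proteins[i, ]
  }
  res <- search_all(query, db, min_score = min_score)
  res[[query$protein_id[1]]]
}

#' Search many queries against a database
#'
#' Vectorised over subjects per query; the workhorse behind the orthology
#' and screening stages.
#'
#' @param queries protein table of queries (need not be part of `db`).
#' @param db a [seq_db()].
#' @param min_score minimum retained score.
#' @param verbose print progress every 50 queries.
#' @return named list of hit data.frames, keyed by query id.
#' @export
search_all <- function(queries, db, min_score = 0, verbose = FALSE) {
  vis <- visible_organisms(db)
  subjects <- db$proteins[db$proteins$organism_id %in% vis, ]
  out <- vector("list", nrow(queries))
  names(out) <- queries$protein_id
  if (!nrow(subjects)) {
    warning("database is empty after masking")
    for (i in seq_along(out)) out[[i]] <- empty_hits()
    return(out)
  }
  subj_set <- Biostrings::AAStringSet(subjects$sequence)
  names(subj_set) <- subjects$protein_id
  mat <- search_matrix()
  for (i in seq_len(nrow(queries))) {
    qid <- queries$protein_id[i]
    qseq <- queries$sequence[i]
    keep <- subjects$protein_id != qid
    if (!any(keep)) { out[[i]] <- empty_hits(); next }
    pa <- pairwiseAlignment2(subj_set[keep], qseq, mat)
    hits <- hits_from_alignment(qid, nchar(qseq), subjects$protein_id[keep],
                                pa)
    hits <- hits[hits$score >= min_score & hits$hsp_length >= 1, ]
    hits <- hits[order(-hits$score, hits$subject_id), ]
    hits$rank <- seq_len(nrow(hits))
    rownames(hits) <- NULL
    out[[i]] <- hits
    if (verbose && i %% 50 == 0)
      message("searched ", i, "/", nrow(queries), " queries")
  }
  out
}

pairwiseAlignment2 <- function(patterns, subject, mat) {
  Biostrings::pairwiseAlignment(patterns, subject, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = 11, gapExtension = 1)
}

hits_from_alignment <- function(qid, qlen, subject_ids, pa) {
  # identity excludes gap columns: nmatch/nmismatch count non-gap columns
  # only; nchar() is the alignment length including gaps.
  nm <- Biostrings::nmatch(pa)
  nn <- nm + Biostrings::nmismatch(pa)
  identity <- ifelse(nn > 0, 100 * nm / nn, 0)
  # the query was passed as the alignment subject; its aligned span gives
  # coverage
  qspan <- Biostrings::width(Biostrings::subject(pa))
  data.frame(query_id = qid, subject_id = subject_ids,
             identity = identity, hsp_length = Biostrings::nchar(pa),
             query_coverage = 100 * qspan / qlen,
             score = Biostrings::score(pa),
             rank = NA_integer_, stringsAsFactors = FALSE)
}

#' Write hits in the 12-column tabular format
#'
#' Columns not tracked internally (mismatches, gap opens, subject span,
#' e-value) are written as 0; the score column carries the raw alignment
#' score.
#' @param hits hit data.frame or list of them.
#' @param path output file.
#' @param query_lengths named integer vector (query id -> length), used to
#'   recover the aligned query span from the coverage.
#' @export
write_hit_table <- function(hits, path, query_lengths) {
  if (is.data.frame(hits)) hits <- list(hits)
  con <- file(path, "w")
  on.exit(close(con))
  for (h in hits) {
    if (!nrow(h)) next
    span <- round(h$query_coverage / 100 * query_lengths[h$query_id])
    writeLines(paste(h$query_id, h$subject_id, sprintf("%.2f", h$identity),
                     h$hsp_length, 0L, 0L, 1L, span, 0L, 0L, 0,
                     h$score, sep = "\t"), con)
  }
  invisible(path)
}
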