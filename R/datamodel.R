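# Domain types and file readers/writers shared by every pipeline stage.
#
# Internal conventions: all coordinates are 1-based inclusive (the Genbank
# convention); gene length is end - start + 1. Organism metadata lives in a
# sidecar taxonomy table, never in FASTA headers, so the same FASTA can
# serve several runs.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Analysis configuration: focal clades and numeric thresholds
#'
#' Bundles the focal genus (`focal_species`) and focal family
#' (`focal_family`) organism sets with every numeric cutoff used by the
#' orthology, screening, tree and operon stages. Defaults follow the
#' census procedure: bidirectional-best-hit identity 50 % within the genus
#' and 40 % within the family, aligned region at least 2/3 of the shorter
#' protein, bacterial-type screening at identity >= 30 %, HSP length >= 50
#' and query coverage >= 75 %, 100 homologs per group member, 100 bootstrap
#' replicates with a support threshold of 70, and a 150 bp operon gap.
#' `search_min_score` (raw alignment score, default 100, about 40 bits
#' under BLOSUM62) is the significance floor the similarity search applies
#' before reporting a hit — the stand-in for the e-value cutoff of an
#' external search tool, below which local alignments of unrelated
#' proteins start to appear.
#'
#' @param focal_species character vector of organism ids forming the focal
#'   genus (the recipient clade whose ancestor-level transfers are dated).
#' @param focal_family character vector of organism ids forming the focal
#'   family; must contain `focal_species`.
#' @param ... named threshold overrides, see Details.
#' @return an object of class `focal_config` (a named list).
#' @export
focal_config <- function(focal_species, focal_family, ...) {
  if (!all(focal_species %in% focal_family))
    stop("focal_species must be a subset of focal_family")
  thresholds <- list(
    search_min_score    = 100,
    bbh_identity_genus  = 50,
    bbh_identity_family = 40,
    bbh_len_ratio       = 2 / 3,
    screen_identity     = 30,
    screen_hsp_len      = 50,
    screen_coverage     = 75,
    top_n_strict        = 3L,
    top_n_window        = 20L,
    max_archaeal_in_window = 3L,
    homologs_per_member = 100L,
    bootstrap_reps      = 100L,
    support_min         = 70,
    operon_max_gap      = 150,
    alignment_column_reliability = 0.5
  )
  over <- list(...)
  bad <- setdiff(names(over), names(thresholds))
  if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
  thresholds[names(over)] <- over
  stopifnot(thresholds$bbh_identity_genus >= 0,
            thresholds$bbh_identity_genus <= 100,
            thresholds$bbh_len_ratio > 0, thresholds$bbh_len_ratio <= 1,
            thresholds$operon_max_gap >= 0,
            thresholds$support_min >= 0, thresholds$support_min <= 100)
  structure(list(focal_species = unique(focal_species),
                 focal_family  = unique(focal_family),
                 thresholds    = thresholds),
            class = "focal_config")
}

#' Read a focal configuration from a YAML or key=value file
#'
#' The file mirrors the `focal_config()` field names: `focal_species`,
#' `focal_family` and any threshold name.
#' @param path file path.
#' @return a `focal_config`.
#' @export
read_focal_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (requireNamespace("yaml", quietly = TRUE) &&
      any(grepl(":", txt, fixed = TRUE)) && !any(grepl("=", txt, fixed = TRUE))) {
    vals <- yaml::yaml.load(paste(txt, collapse = "\n"))
  } else {
    kv <- txt[grepl("=", txt, fixed = TRUE)]
    pieces <- strsplit(kv, "=", fixed = TRUE)
    vals <- lapply(pieces, function(p) {
      v <- strsplit(trimws(p[2]), ",", fixed = TRUE)[[1]]
      num <- suppressWarnings(as.numeric(v))
      if (!anyNA(num)) num else v
    })
    names(vals) <- vapply(pieces, function(p) trimws(p[1]), "")
  }
  args <- vals[setdiff(names(vals), c("focal_species", "focal_family"))]
  do.call(focal_config, c(list(focal_species = vals$focal_species,
                               focal_family = vals$focal_family), args))
}

validate_sequence <- function(seq, id) {
  bad <- regmatches(seq, gregexpr(paste0("[^", paste(AA_LETTERS, collapse = ""),
                                         "X]"), seq))[[1]]
  if (length(bad)) {
    pos <- which(!strsplit(seq, "")[[1]] %in% c(AA_LETTERS, "X"))
    stop("protein ", id, ": non-amino-acid character '", bad[1],
         "' at position ", pos[1])
  }
  invisible(TRUE)
}

#' Read protein sequences with organism labels
#'
#' Headers must be `proteinid|organismid`; alternatively a two-column
#' sidecar table (`protein_id`, `organism_id`) can supply the mapping.
#' Sequences are uppercased; only the 20 amino-acid letters plus `X` are
#' accepted.
#'
#' @param path FASTA file.
#' @param mapping optional data.frame with columns `protein_id`,
#'   `organism_id` used when headers carry no organism.
#' @return data.frame with columns `protein_id`, `organism_id`, `sequence`,
#'   in input order.
#' @export
parse_fasta <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- names(ss)
  seqs <- toupper(as.character(ss))
  if (is.null(mapping)) {
    parts <- strsplit(ids, "|", fixed = TRUE)
    if (any(vapply(parts, length, 1L) < 2L))
      stop("FASTA header without organism (expected 'proteinid|organismid'): ",
           ids[vapply(parts, length, 1L) < 2L][1])
    pid <- vapply(parts, `[`, "", 1L)
    org <- vapply(parts, `[`, "", 2L)
  } else {
    pid <- vapply(strsplit(ids, "|", fixed = TRUE), `[`, "", 1L)
    org <- mapping$organism_id[match(pid, mapping$protein_id)]
    if (anyNA(org)) stop("protein missing from mapping: ", pid[is.na(org)][1])
  }
  if (anyDuplicated(pid))
    stop("duplicate protein_id: ", pid[duplicated(pid)][1])
  if (any(!nzchar(seqs)))
    stop("empty sequence for protein ", pid[!nzchar(seqs)][1])
  for (i in seq_along(seqs)) validate_sequence(seqs[i], pid[i])
  data.frame(protein_id = pid, organism_id = org, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write proteins as FASTA with `proteinid|organismid` headers
#' @param proteins data.frame as returned by [parse_fasta()].
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$protein_id[i], "|",
                      proteins$organism_id[i]), con)
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene coordinates from a TSV or GFF3-like file
#'
#' TSV columns: `gene_id`, `replicon_id`, `start`, `end`, `strand`.
#' GFF3 rows of type `gene` or `CDS` are accepted with the gene id taken
#' from an `ID=` or `gene_id=` attribute; GFF3 is already 1-based inclusive
#' so coordinates pass through unshifted.
#'
#' @param path input file.
#' @return data.frame with columns `gene_id`, `replicon_id`, `start`,
#'   `end`, `strand`.
#' @export
parse_gene_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol9 <- vapply(fields, length, 1L) >= 8L
  if (length(lines) && all(ncol9)) {  # GFF3 dialect
    keep <- vapply(fields, function(f) f[3] %in% c("gene", "CDS"), TRUE)
    fields <- fields[keep]
    gid <- vapply(fields, function(f) {
      attrs <- if (length(f) >= 9) f[9] else ""
      m <- regmatches(attrs, regexec("(?:^|;)\\s*(?:ID|gene_id)=([^;]+)", attrs))[[1]]
      if (length(m) == 2) m[2] else NA_character_
    }, "")
    if (anyNA(gid)) stop("GFF3 row without ID/gene_id attribute")
    out <- data.frame(gene_id = gid,
                      replicon_id = vapply(fields, `[`, "", 1L),
                      start = as.integer(vapply(fields, `[`, "", 4L)),
                      end = as.integer(vapply(fields, `[`, "", 5L)),
                      strand = vapply(fields, `[`, "", 7L),
                      stringsAsFactors = FALSE)
  } else {
    if (length(fields) && identical(fields[[1]][1], "gene_id"))
      fields <- fields[-1]
    if (any(vapply(fields, length, 1L) != 5L))
      stop("gene table row does not have 5 columns")
    out <- data.frame(gene_id = vapply(fields, `[`, "", 1L),
                      replicon_id = vapply(fields, `[`, "", 2L),
                      start = as.integer(vapply(fields, `[`, "", 3L)),
                      end = as.integer(vapply(fields, `[`, "", 4L)),
                      strand = vapply(fields, `[`, "", 5L),
                      stringsAsFactors = FALSE)
  }
  if (!all(out$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         out$strand[!out$strand %in% c("+", "-")][1])
  if (any(out$start > out$end)) {
    i <- which(out$start > out$end)[1]
    stop("start > end for gene ", out$gene_id[i])
  }
  if (any(out$start < 1L)) stop("coordinates must be >= 1")
  out
}

#' Write a gene coordinate table (TSV)
#' @param loci data.frame as returned by [parse_gene_table()].
#' @param path output file.
#' @export
write_gene_table <- function(loci, path) {
  utils::write.table(loci[, c("gene_id", "replicon_id", "start", "end",
                              "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the organism taxonomy table
#'
#' TSV columns: `organism_id`, `name`, `domain`, `year`, `lineage` where
#' lineage is a semicolon-separated `rank:name` list starting at the
#' domain. Lineage rank order is validated against the conventional
#' ranking (domain > phylum > class > order > family > genus > species,
#' gaps allowed).
#'
#' @param path TSV file.
#' @param proteins optional protein table; if given, every referenced
#'   organism must be present (hard error otherwise).
#' @return data.frame with columns `organism_id`, `name`, `domain`,
#'   `year`, `lineage`.
#' @export
parse_taxonomy <- function(path, proteins = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  need <- c("organism_id", "name", "domain", "year", "lineage")
  if (!all(need %in% names(tab)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$organism_id))
    stop("duplicate organism_id: ",
         tab$organism_id[duplicated(tab$organism_id)][1])
  if (!all(tab$domain %in% c("Bacteria", "Archaea")))
    stop("domain must be Bacteria or Archaea")
  if (any(tab$year < 1995)) stop("year_sequenced must be >= 1995")
  for (i in seq_len(nrow(tab))) {
    lin <- parse_lineage(tab$lineage[i])
    if (names(lin)[1] != "domain" || lin[[1]] != tab$domain[i])
      stop("lineage of ", tab$organism_id[i],
           " does not begin with its stated domain")
  }
  if (!is.null(proteins)) {
    missing <- setdiff(unique(proteins$organism_id), tab$organism_id)
    if (length(missing))
      stop("protein(s) reference organism(s) absent from taxonomy: ",
           paste(missing, collapse = ", "))
  }
  tab[, need]
}

#' Write a taxonomy table (TSV)
#' @param taxa data.frame as returned by [parse_taxonomy()].
#' @param path output file.
#' @export
write_taxonomy <- function(taxa, path) {
  utils::write.table(taxa, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a 12-column tabular similarity-hit file
#'
#' The de-facto standard tabular search output: query, subject, %identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' e-value, bit score. Query coverage is computed as
#' `(qend - qstart + 1) / query_length` when query lengths are supplied and
#' left `NA` otherwise.
#'
#' @param path tabular file.
#' @param query_lengths optional named integer vector of query lengths.
#' @param subject_organisms optional named character vector mapping subject
#'   ids to organism ids; unknown subjects are an error unless
#'   `permissive = TRUE`, in which case they map to organism
#'   `"unclassified"`.
#' @param permissive allow unknown subject organisms.
#' @return data.frame with columns `query_id`, `subject_id`, `identity`,
#'   `hsp_length`, `query_coverage`, `score`, `rank` (rank within query,
#'   by descending score).
#' @export
parse_hit_table <- function(path, query_lengths = NULL,
                            subject_organisms = NULL, permissive = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(query_id = character(), subject_id = character(),
                      identity = numeric(), hsp_length = integer(),
                      query_coverage = numeric(), score = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- vapply(fields, length, 1L)
  if (any(nc != 12L))
    stop("hit table line ", which(nc != 12L)[1], " has ", nc[nc != 12L][1],
         " columns, expected 12")
  ident <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(ident))
    stop("non-numeric identity on line ", which(is.na(ident))[1])
  out <- data.frame(query_id = vapply(fields, `[`, "", 1L),
                    subject_id = vapply(fields, `[`, "", 2L),
                    identity = ident,
                    hsp_length = as.integer(vapply(fields, `[`, "", 4L)),
                    qstart = as.integer(vapply(fields, `[`, "", 7L)),
                    qend = as.integer(vapply(fields, `[`, "", 8L)),
                    score = as.numeric(vapply(fields, `[`, "", 12L)),
                    stringsAsFactors = FALSE)
  if (!is.null(subject_organisms)) {
    known <- out$subject_id %in% names(subject_organisms)
    if (!all(known) && !permissive)
      stop("unknown subject organism for hit subject: ",
           out$subject_id[!known][1])
  }
  out$query_coverage <- if (!is.null(query_lengths)) {
    100 * (out$qend - out$qstart + 1) / query_lengths[out$query_id]
  } else NA_real_
  out <- out[order(out$query_id, -out$score, out$subject_id), ]
  out$rank <- stats::ave(out$score, out$query_id,
                         FUN = function(x) seq_along(x))
  rownames(out) <- NULL
  out[, c("query_id", "subject_id", "identity", "hsp_length",
          "query_coverage", "score", "rank")]
}
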