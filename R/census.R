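# Census statistics: year-stamped trajectory, donor tallies, COG
# enrichment, 2x2 chi-square comparisons and expression tallies.

#' Candidate-HGT fraction against year-stamped database views
#'
#' For each year, archaeal organisms sequenced after that year are masked
#' (configurable to both domains for a whole-database-growth control), the
#' bacterial-type screen is re-run on every GOP using the masked hit
#' lists, and the focal organism's genes in passing GOPs are counted and
#' divided by its genes in GOPs. No trees are built — this is the
#' search-only estimate whose drift with database growth the trajectory
#' quantifies.
#'
#' @param gops GOP table (list-column `members`).
#' @param hits named list of full-database hit data.frames.
#' @param db a [seq_db()] carrying the taxonomy with year stamps.
#' @param years ascending integer years.
#' @param focal a [focal_config()].
#' @param focal_organism organism id whose genes are counted.
#' @param domains_to_mask domains the year mask applies to.
#' @return data.frame with columns `year`, `candidate_genes`, `fraction`
#'   (percent).
#' @export
hgt_trajectory <- function(gops, hits, db, years, focal, focal_organism,
                           domains_to_mask = "Archaea") {
  stopifnot(!is.unsorted(years))
  taxa <- db$taxa
  protein_orgs <- stats::setNames(db$proteins$organism_id,
                                  db$proteins$protein_id)
  genes_in_gops <- unlist(gops$members)
  denom <- sum(protein_orgs[genes_in_gops] == focal_organism)
  min_year <- min(taxa$year)
  out <- lapply(years, function(y) {
    if (y < min_year)
      warning("year ", y, " predates every organism's year stamp")
    hidden <- taxa$organism_id[taxa$domain %in% domains_to_mask &
                                 taxa$year > y]
    masked <- lapply(hits, function(h) {
      h <- h[!(protein_orgs[h$subject_id] %in% hidden), , drop = FALSE]
      if (nrow(h)) h$rank <- seq_len(nrow(h))
      h
    })
    cand <- 0L
    for (i in seq_len(nrow(gops))) {
      m <- gops$members[[i]]
      v <- screen_gop(m, masked, protein_orgs, taxa, focal)
      if (v$passed) cand <- cand + sum(protein_orgs[m] == focal_organism)
    }
    data.frame(year = y, candidate_genes = cand,
               fraction = if (denom > 0) 100 * cand / denom else 0)
  })
  do.call(rbind, out)
}

#' Donor tallies normalised by genomes sequenced
#'
#' Counts called GOPs per donor taxon and divides by the number of
#' sequenced genomes in that taxon (derived from the taxonomy table) to
#' offset the head start of well-sequenced taxa. Donors with no genome
#' denominator — unclassified bacteria — are reported with `overrep` `NA`.
#'
#' @param calls data.frame of HGT calls with `donor_rank`, `donor_name`.
#' @param taxa taxonomy table.
#' @param include_zero also report taxa with zero called GOPs (every
#'   phylum present in the taxonomy), with `overrep` 0.
#' @return data.frame: `donor_rank`, `donor_name`, `gop_count`,
#'   `genomes_sequenced`, `overrep`.
#' @export
donor_overrepresentation <- function(calls, taxa, include_zero = FALSE) {
  lins <- lineage_table(taxa)
  genomes_in <- function(rank, name) {
    sum(vapply(lins, function(l)
      rank %in% names(l) && identical(l[[rank]], name), TRUE))
  }
  key <- paste(calls$donor_rank, calls$donor_name, sep = "\r")
  tab <- table(key)
  rows <- lapply(names(tab), function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    rank <- parts[1]; name <- parts[2]
    unclassified <- identical(name, "unclassified bacteria")
    g <- if (unclassified) NA_integer_ else genomes_in(rank, name)
    data.frame(donor_rank = rank, donor_name = name,
               gop_count = as.integer(tab[[k]]),
               genomes_sequenced = g,
               overrep = if (!is.na(g) && g > 0) as.integer(tab[[k]]) / g
               else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (include_zero) {
    phyla <- unique(vapply(lins[taxa$organism_id[taxa$domain == "Bacteria"]],
                           function(l) l[["phylum"]] %||% NA_character_, ""))
    phyla <- setdiff(stats::na.omit(phyla), out$donor_name)
    if (length(phyla)) {
      extra <- do.call(rbind, lapply(phyla, function(p) {
        g <- genomes_in("phylum", p)
        data.frame(donor_rank = "phylum", donor_name = p, gop_count = 0L,
                   genomes_sequenced = g,
                   overrep = if (g > 0) 0 else NA_real_,
                   stringsAsFactors = FALSE)
      }))
      out <- rbind(out, extra)
    }
  }
  out[order(-out$gop_count, out$donor_name), ]
}

#' COG-category overrepresentation among transferred genes
#'
#' O = (observed - expected) / expected, where the expected count is the
#' category's reference fraction times the number of transferred genes
#' with a COG assignment.
#'
#' @param cog_obs observed count of HT genes in the category.
#' @param category_fraction_reference the category's fraction among the
#'   reference gene set, in `(0, 1]`; a zero fraction leaves O undefined
#'   (`NA`).
#' @param n_ht_with_cog number of HT genes with any COG assignment (>= 1).
#' @return list with `cog_obs`, `cog_exp`, `O`.
#' @export
cog_overrepresentation <- function(cog_obs, category_fraction_reference,
                                   n_ht_with_cog) {
  stopifnot(cog_obs >= 0, n_ht_with_cog >= 1,
            category_fraction_reference >= 0,
            category_fraction_reference <= 1)
  if (category_fraction_reference == 0)
    return(list(cog_obs = cog_obs, cog_exp = 0, O = NA_real_))
  cog_exp <- category_fraction_reference * n_ht_with_cog
  list(cog_obs = cog_obs, cog_exp = cog_exp,
       O = (cog_obs - cog_exp) / cog_exp)
}

#' Pearson chi-square comparison of two fractions (2x2, 1 df)
#'
#' Tests whether a feature's fraction among transferred genes equals its
#' fraction in the genome at large. The table contrasts the HT counts
#' with the non-HT remainder: `[[x1, x2], [N1 - x1, N2 - x2]]`. No
#' continuity correction is applied.
#'
#' @param ht_counts integer vector `(x1, x2)` — e.g. enzymes and
#'   transporters among HT genes, or single genes and genes in operons
#'   among HT genes.
#' @param genome_counts integer vector `(N1, N2)` of the corresponding
#'   whole-genome counts, `x_i <= N_i`.
#' @return object of class `contingency_result`: list with `table`,
#'   `chi2`, `p`.
#' @export
compare_fractions_2x2 <- function(ht_counts, genome_counts) {
  x1 <- ht_counts[1]; x2 <- ht_counts[2]
  N1 <- genome_counts[1]; N2 <- genome_counts[2]
  stopifnot(length(ht_counts) == 2, length(genome_counts) == 2,
            x1 >= 0, x2 >= 0, x1 <= N1, x2 <= N2)
  tab <- matrix(c(x1, N1 - x1, x2, N2 - x2), nrow = 2,
                dimnames = list(c("HT", "non-HT"), c("f1", "f2")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square statistic undefined: zero marginal total")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(table = tab, chi2 = unname(ct$statistic),
                 p = unname(ct$p.value)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi-square = %.4f, df = 1, p = %.4g\n", x$chi2, x$p))
  invisible(x)
}

#' Fraction of transferred GOPs with an expressed member
#'
#' @param ht_gops GOP table of called (HT) GOPs (list-column `members`).
#' @param expression_status named logical vector protein id -> was the
#'   protein found differentially expressed; absent proteins count as not
#'   expressed.
#' @return percentage of HT GOPs with at least one expressed member.
#' @export
expression_tally <- function(ht_gops, expression_status) {
  if (!nrow(ht_gops)) return(0)
  hit <- vapply(ht_gops$members, function(m) {
    fl <- expression_status[m]
    any(fl %in% TRUE)
  }, TRUE)
  100 * mean(hit)
}
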