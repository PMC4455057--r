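# Operon prediction from intergenic distances and transferred-fragment
# lengths.
#
# Intergenic gap convention: gap(g_i, g_{i+1}) = start_{i+1} - end_i - 1,
# the number of bases strictly between the two genes, so abutting genes
# have gap 0. Overlapping genes (negative gap) are treated as gap 0 with
# a warning. Circular replicons are treated as linear.

#' Predict operons as runs of adjacent codirectional genes
#'
#' Each replicon's genes (sorted by start) are partitioned into maximal
#' runs of codirectional genes whose internal intergenic gaps are all at
#' most `max_gap`. Runs of one gene are single genes; runs of two or more
#' are non-trivial operons.
#'
#' @param loci gene table (`gene_id`, `replicon_id`, `start`, `end`,
#'   `strand`).
#' @param max_gap maximum intergenic distance within an operon, in bp
#'   (default 150).
#' @return data.frame: `operon_id`, `replicon_id`, `strand`, `n_genes`,
#'   list-column `gene_ids` (ordered along the replicon).
#' @export
predict_operons <- function(loci, max_gap = 150) {
  runs <- list()
  for (rep_id in unique(loci$replicon_id)) {
    g <- loci[loci$replicon_id == rep_id, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) {
      gaps <- g$start[-1] - g$end[-nrow(g)] - 1L
      if (any(gaps < 0)) {
        warning("overlapping genes on ", rep_id, "; gap treated as 0")
        gaps[gaps < 0] <- 0L
      }
      split_here <- gaps > max_gap | g$strand[-1] != g$strand[-nrow(g)]
      run_id <- cumsum(c(0L, as.integer(split_here)))
    } else run_id <- 0L
    for (r in split(seq_len(nrow(g)), run_id))
      runs[[length(runs) + 1L]] <-
        list(replicon_id = rep_id, strand = g$strand[r[1]],
             gene_ids = g$gene_id[r])
  }
  data.frame(operon_id = sprintf("op%04d", seq_along(runs)),
             replicon_id = vapply(runs, `[[`, "", "replicon_id"),
             strand = vapply(runs, `[[`, "", "strand"),
             n_genes = vapply(runs, function(r) length(r$gene_ids), 1L),
             gene_ids = I(lapply(runs, `[[`, "gene_ids")),
             stringsAsFactors = FALSE)
}

#' Operon/singleton statistics, overall and for transferred genes
#'
#' @param operons run table from [predict_operons()] (one genome).
#' @param ht_flags named logical vector gene id -> is the gene
#'   horizontally transferred; absent genes count as not transferred.
#' @return list with genome-wide counts (`single_genes`,
#'   `genes_in_operons`, `n_operons`, `pct_in_operons`,
#'   `mean_operon_size`), the same restricted to HT genes (`ht_*`; an HT
#'   gene is in an operon iff its run has >= 2 genes), `n_ht_operons`
#'   (non-trivial operons with >= 1 HT gene), `n_mosaic_operons`
#'   (containing both HT and vertical genes), and two mean sizes of
#'   HT-containing operons: `mean_ht_operon_size_all_genes` (all genes of
#'   those operons) and `mean_ht_operon_size_ht_genes` (their HT genes
#'   only). The run table is returned as `operons` with `contains_ht` and
#'   `is_mosaic` flags added.
#' @export
operon_stats <- function(operons, ht_flags) {
  is_ht <- function(genes) {
    fl <- ht_flags[genes]
    fl %in% TRUE
  }
  ht_counts <- vapply(operons$gene_ids, function(g) sum(is_ht(g)), 1L)
  operons$contains_ht <- ht_counts > 0L
  operons$is_mosaic <- ht_counts > 0L & ht_counts < operons$n_genes
  nontrivial <- operons$n_genes >= 2L
  single <- sum(operons$n_genes == 1L)
  in_op <- sum(operons$n_genes[nontrivial])
  ht_single <- sum(ht_counts[!nontrivial])
  ht_in_op <- sum(ht_counts[nontrivial])
  ht_ops <- nontrivial & operons$contains_ht
  list(
    single_genes = single,
    genes_in_operons = in_op,
    n_operons = sum(nontrivial),
    pct_in_operons = if (single + in_op > 0)
      100 * in_op / (single + in_op) else 0,
    mean_operon_size = if (any(nontrivial))
      mean(operons$n_genes[nontrivial]) else NA_real_,
    ht_single_genes = ht_single,
    ht_genes_in_operons = ht_in_op,
    n_ht_operons = sum(ht_ops),
    ht_pct_in_operons = if (ht_single + ht_in_op > 0)
      100 * ht_in_op / (ht_single + ht_in_op) else 0,
    n_mosaic_operons = sum(operons$is_mosaic & nontrivial),
    mean_ht_operon_size_all_genes = if (any(ht_ops))
      mean(operons$n_genes[ht_ops]) else NA_real_,
    mean_ht_operon_size_ht_genes = if (any(ht_ops))
      mean(ht_counts[ht_ops]) else NA_real_,
    operons = operons)
}

#' Lengths of transferred fragments
#'
#' Within each codirectional run, maximal sub-runs of consecutive
#' transferred genes become fragments whose length is the sum of the gene
#' lengths plus the intergenic gaps enclosed between them; a lone
#' transferred gene in a trivial run contributes its own gene length.
#' Species-specific (singleton) transfers are excluded before fragments
#' are formed.
#'
#' @param loci gene table.
#' @param ht_flags named logical vector gene id -> transferred.
#' @param operons run table from [predict_operons()].
#' @param exclude gene ids to drop from the HT set first (the
#'   species-specific transfers).
#' @return data.frame: `fragment_id`, `operon_id`, `n_genes`,
#'   `length_nt`, list-column `gene_ids`.
#' @export
ht_fragment_lengths <- function(loci, ht_flags, operons,
                                exclude = character(0)) {
  start_of <- stats::setNames(loci$start, loci$gene_id)
  end_of <- stats::setNames(loci$end, loci$gene_id)
  frags <- list()
  for (i in seq_len(nrow(operons))) {
    genes <- operons$gene_ids[[i]]
    ht <- (ht_flags[genes] %in% TRUE) & !(genes %in% exclude)
    if (!any(ht)) next
    rl <- rle(ht)
    run_id <- rep(seq_along(rl$lengths), rl$lengths)
    for (r in split(seq_along(genes), run_id)) {
      if (!ht[r[1]]) next
      sub <- genes[r]
      glen <- sum(end_of[sub] - start_of[sub] + 1L)
      gaps <- if (length(sub) > 1)
        sum(pmax(start_of[sub[-1]] - end_of[sub[-length(sub)]] - 1L, 0L))
      else 0L
      frags[[length(frags) + 1L]] <-
        list(operon_id = operons$operon_id[i], gene_ids = sub,
             n_genes = length(sub), length_nt = glen + gaps)
    }
  }
  if (!length(frags))
    return(data.frame(fragment_id = character(), operon_id = character(),
                      n_genes = integer(), length_nt = integer(),
                      gene_ids = I(list()), stringsAsFactors = FALSE))
  data.frame(fragment_id = sprintf("frag%03d", seq_along(frags)),
             operon_id = vapply(frags, `[[`, "", "operon_id"),
             n_genes = vapply(frags, `[[`, 1L, "n_genes"),
             length_nt = vapply(frags, function(f)
               as.integer(f$length_nt), 1L),
             gene_ids = I(lapply(frags, `[[`, "gene_ids")),
             stringsAsFactors = FALSE)
}
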