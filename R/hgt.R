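# Screening GOPs for bacterial-type similarity profiles and calling HGT
# events on rooted bootstrap trees.

# Apply the bacterial-type thresholds to one hit list. Coverage that could
# not be computed (no query length available) is not held against a hit.
screen_filter_hits <- function(h, thr) {
  cov_ok <- is.na(h$query_coverage) | h$query_coverage >= thr$screen_coverage
  h <- h[h$identity >= thr$screen_identity &
           h$hsp_length >= thr$screen_hsp_len & cov_ok, , drop = FALSE]
  if (nrow(h)) {
    h <- h[order(-h$score, h$subject_id), ]
    h$rank <- seq_len(nrow(h))
  }
  h
}

#' Screen a GOP for a bacterial-type similarity profile
#'
#' For each member, hits to focal-family organisms and to fellow GOP
#' members are removed first (the group's own relatives would otherwise
#' always occupy the top ranks), then hits failing identity >= 30 %, HSP
#' length >= 50 or query coverage >= 75 % are removed and ranks are
#' recomputed. A member passes when its top three surviving hits are all
#' bacterial, or when at most three of its top twenty are archaeal while
#' all other top-twenty hits are bacterial. The GOP passes when every
#' member passes; a member with no surviving hits fails.
#'
#' @param members character vector of GOP member protein ids.
#' @param hits named list of ranked hit data.frames (one per member).
#' @param protein_orgs named character vector protein id -> organism id
#'   for every subject that can appear in a hit list.
#' @param taxa taxonomy table.
#' @param focal a [focal_config()].
#' @return list with `passed` (logical) and `per_member` (data.frame:
#'   `protein_id`, `top3_all_bacterial`, `archaeal_in_top20`,
#'   `surviving_hits`, `passed`).
#' @export
screen_gop <- function(members, hits, protein_orgs, taxa, focal) {
  thr <- focal$thresholds
  doms <- domain_of(taxa)
  per <- lapply(members, function(m) {
    h <- hits[[m]]
    if (is.null(h) || !nrow(h))
      return(data.frame(protein_id = m, top3_all_bacterial = FALSE,
                        archaeal_in_top20 = 0L, surviving_hits = 0L,
                        passed = FALSE, stringsAsFactors = FALSE))
    sub_org <- protein_orgs[h$subject_id]
    h <- h[!(sub_org %in% focal$focal_family) &
             !(h$subject_id %in% members), , drop = FALSE]
    h <- screen_filter_hits(h, thr)
    if (!nrow(h))
      return(data.frame(protein_id = m, top3_all_bacterial = FALSE,
                        archaeal_in_top20 = 0L, surviving_hits = 0L,
                        passed = FALSE, stringsAsFactors = FALSE))
    dom <- doms[protein_orgs[h$subject_id]]
    top3 <- utils::head(dom, thr$top_n_strict)
    top20 <- utils::head(dom, thr$top_n_window)
    t3 <- length(top3) >= 1L && all(top3 == "Bacteria")
    n_arch <- sum(top20 == "Archaea")
    window_ok <- n_arch <= thr$max_archaeal_in_window &&
      all(top20[top20 != "Archaea"] == "Bacteria")
    data.frame(protein_id = m, top3_all_bacterial = t3,
               archaeal_in_top20 = n_arch, surviving_hits = nrow(h),
               passed = t3 || window_ok, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(passed = all(per$passed), per_member = per)
}

#' Collect the homolog set of a screened GOP
#'
#' The union, over members, of each member's top `homologs_per_member`
#' hits that pass the identity / HSP-length / coverage thresholds, plus
#' the members themselves. Focal-family homologs are retained here (the
#' timing rules need them on the tree); only the screening verdict
#' excludes them.
#'
#' @inheritParams screen_gop
#' @return character vector of protein ids.
#' @export
collect_homolog_set <- function(members, hits, focal) {
  thr <- focal$thresholds
  picked <- lapply(members, function(m) {
    h <- hits[[m]]
    if (is.null(h) || !nrow(h)) return(character(0))
    h <- screen_filter_hits(h, thr)
    utils::head(h$subject_id, thr$homologs_per_member)
  })
  sort(unique(c(members, unlist(picked))))
}

#' Call a candidate HGT event from rooted trees
#'
#' A call is emitted iff, on the rooted NJ tree, (a) the focal-family
#' leaves form a monophyletic clade, (b) the bipartition subtending that
#' clade has bootstrap support above `support_min` (a single-leaf clade is
#' trivially supported), and (c) the smallest clade properly containing it
#' contains only bacterial leaves besides it — no archaea from outside the
#' family may sit in the transferred clade's context. When an ML tree is
#' supplied, (a) and (c) must hold there too (topology agreement only; ML
#' supports are not required).
#'
#' @param nj a rooted `support_tree` from [build_nj_bootstrap()] +
#'   [root_tree()].
#' @param ml optional rooted `ape::phylo` with the same leaf set.
#' @param members GOP member protein ids (must be NJ leaves).
#' @param leaf_orgs named character vector: leaf -> organism id.
#' @param taxa taxonomy table.
#' @param focal a [focal_config()].
#' @return `NULL` (no call) or a list with `clade_leaves`,
#'   `context_leaves`, `focal_clade_support`, `agreeing_trees`, `timing`,
#'   `donor_rank`, `donor_name`.
#' @export
call_hgt <- function(nj, ml = NULL, members, leaf_orgs, taxa, focal) {
  phy <- nj$tree
  if (!all(members %in% phy$tip.label))
    stop("GOP member(s) missing from the NJ tree")
  if (!is.null(ml) && !setequal(ml$tip.label, phy$tip.label))
    stop("leaf sets of NJ and ML trees differ")
  doms <- domain_of(taxa)
  fam_leaves <- phy$tip.label[leaf_orgs[phy$tip.label] %in%
                                focal$focal_family]
  chk <- focal_clade_context(phy, fam_leaves, leaf_orgs, doms)
  if (is.null(chk)) return(NULL)
  supp <- split_support(nj, fam_leaves)
  if (!(supp > focal$thresholds$support_min)) return(NULL)
  agreeing <- "NJ"
  if (!is.null(ml)) {
    chk_ml <- focal_clade_context(ml, fam_leaves, leaf_orgs, doms)
    if (is.null(chk_ml)) return(NULL)
    agreeing <- c("NJ", "ML")
  }
  # the donor is read from the smallest *stable* clade containing the
  # focal clade: containing clades whose own bipartition lacks bootstrap
  # support are skipped so a single waywardly placed leaf cannot name the
  # donor on its own
  stable_ctx <- stable_donor_context(nj, fam_leaves, leaf_orgs, doms,
                                     focal$thresholds$support_min)
  td <- classify_timing_and_donor(chk$clade, stable_ctx %||% chk$context,
                                  leaf_orgs, taxa, focal)
  c(list(clade_leaves = chk$clade, context_leaves = chk$context,
         focal_clade_support = supp, agreeing_trees = agreeing), td)
}

# Walk rootward from the focal clade and return the bacterial leaves of
# the smallest containing clade whose bipartition has bootstrap support
# above the threshold; the root (the whole tree) counts as supported.
stable_donor_context <- function(st, fam_leaves, leaf_orgs, doms,
                                 support_min) {
  phy <- st$tree
  tips <- phy$tip.label
  node <- if (length(fam_leaves) == 1L) which(tips == fam_leaves)
  else ape::getMRCA(phy, fam_leaves)
  root <- length(tips) + 1L
  repeat {
    parent <- phy$edge[phy$edge[, 2] == node, 1]
    if (!length(parent)) return(NULL)
    under <- tips_under(phy, parent)
    if (parent == root || length(under) == length(tips) ||
        split_support(st, under) > support_min) {
      ctx <- setdiff(under, fam_leaves)
      ctx <- ctx[doms[leaf_orgs[ctx]] == "Bacteria"]
      return(if (length(ctx)) ctx else NULL)
    }
    node <- parent
  }
}

# Conditions (a) and (c): focal-family monophyly and an all-bacterial
# context. Returns NULL if either fails, else the clade and context
# leaves.
focal_clade_context <- function(phy, fam_leaves, leaf_orgs, doms) {
  tips <- phy$tip.label
  if (!length(fam_leaves) || length(fam_leaves) == length(tips))
    return(NULL)
  if (length(fam_leaves) == 1L) {
    node <- which(tips == fam_leaves)
  } else {
    if (!ape::is.monophyletic(phy, fam_leaves)) return(NULL)
    node <- ape::getMRCA(phy, fam_leaves)
  }
  parent <- phy$edge[phy$edge[, 2] == node, 1]
  if (!length(parent)) return(NULL)  # clade is the whole tree
  context <- setdiff(tips_under(phy, parent), fam_leaves)
  if (!length(context)) return(NULL)
  if (!all(doms[leaf_orgs[context]] == "Bacteria")) return(NULL)
  list(clade = fam_leaves, context = context)
}

#' Classify the timing of a called transfer and assign its donor
#'
#' Timing: `family_ancestor` when the focal clade holds proteins from at
#' least two distinct focal (genus) species and at least one other family
#' species; `genus_ancestor` when it holds at least two focal species and
#' no other family species; `species_specific` when exactly one focal
#' species is present (the singleton path). The donor is the deepest
#' taxonomic rank shared by all bacterial leaves of the smallest bacterial
#' clade containing the focal clade; when only the domain is shared the
#' donor is recorded as unclassified bacteria.
#'
#' @param clade_leaves leaves of the focal clade.
#' @param context_leaves bacterial leaves of the containing clade.
#' @inheritParams call_hgt
#' @return list with `timing`, `donor_rank`, `donor_name`.
#' @export
classify_timing_and_donor <- function(clade_leaves, context_leaves,
                                      leaf_orgs, taxa, focal) {
  orgs <- unique(leaf_orgs[clade_leaves])
  n_focal <- length(intersect(orgs, focal$focal_species))
  n_other_fam <- length(intersect(setdiff(orgs, focal$focal_species),
                                  focal$focal_family))
  timing <- if (n_focal >= 2 && n_other_fam >= 1) "family_ancestor"
  else if (n_focal >= 2) "genus_ancestor"
  else "species_specific"
  lins <- lineage_table(taxa)
  donor <- shared_donor_taxon(lins[unique(leaf_orgs[context_leaves])])
  list(timing = timing, donor_rank = donor$rank, donor_name = donor$name)
}

# Deepest rank at which all lineages carry the same taxon name.
shared_donor_taxon <- function(lineages) {
  for (rank in rev(RANK_ORDER)) {
    vals <- vapply(lineages, function(l)
      if (rank %in% names(l)) l[[rank]] else NA_character_, "")
    if (anyNA(vals)) next
    if (length(unique(vals)) == 1L) {
      if (rank == "domain")
        return(list(rank = "domain", name = "unclassified bacteria"))
      return(list(rank = rank, name = vals[[1]]))
    }
  }
  list(rank = "domain", name = "unclassified bacteria")
}
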