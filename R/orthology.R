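# Groups of orthologous proteins (GOPs): bidirectional best hits, the
# paralog rule, connected components and group-level filters.

#' Find bidirectional best hits between two organisms
#'
#' Hits failing the identity cutoff or whose aligned region is shorter
#' than `min_len_ratio` of the shorter protein are discarded first; a pair
#' (a, b) is reported iff b is a's top surviving hit in organism B and a
#' is b's top surviving hit in organism A. Hit lists are assumed
#' score-sorted with lexicographic tie-break, so "top" is the first
#' surviving row.
#'
#' @param hits_ab named list of hit data.frames for organism-A queries,
#'   restricted to subjects in organism B (extra subjects are tolerated if
#'   `subject_filter` is given).
#' @param hits_ba the reverse direction.
#' @param protein_lengths named integer vector over all proteins involved.
#' @param min_identity identity cutoff in percent (50 within the genus, 40
#'   within the family).
#' @param min_len_ratio minimum aligned-region / shorter-protein ratio
#'   (default 2/3).
#' @param subject_filter optional character vector: keep only hits whose
#'   subject is in this set (used to restrict to one organism pair).
#' @return data.frame with columns `protein_a`, `protein_b`, `identity`,
#'   `len_ratio`, `score`.
#' @export
find_bbh <- function(hits_ab, hits_ba, protein_lengths,
                     min_identity, min_len_ratio = 2 / 3,
                     subject_filter = NULL) {
  top_surviving <- function(hits, qid) {
    h <- hits
    if (!is.null(subject_filter)) h <- h[h$subject_id %in% subject_filter, ]
    if (!nrow(h)) return(NULL)
    h$len_ratio <- h$hsp_length /
      pmin(protein_lengths[qid], protein_lengths[h$subject_id])
    h <- h[h$identity >= min_identity & h$len_ratio >= min_len_ratio, ]
    if (!nrow(h)) return(NULL)
    h[order(-h$score, h$subject_id), ][1, , drop = FALSE]
  }
  best_ab <- lapply(names(hits_ab), function(q) top_surviving(hits_ab[[q]], q))
  names(best_ab) <- names(hits_ab)
  best_ba <- lapply(names(hits_ba), function(q) top_surviving(hits_ba[[q]], q))
  names(best_ba) <- names(hits_ba)
  rows <- list()
  for (a in names(best_ab)) {
    ta <- best_ab[[a]]
    if (is.null(ta)) next
    b <- ta$subject_id
    tb <- best_ba[[b]]
    if (is.null(tb) || tb$subject_id != a) next
    rows[[length(rows) + 1L]] <-
      data.frame(protein_a = a, protein_b = b, identity = ta$identity,
                 len_ratio = ta$len_ratio, score = ta$score,
                 stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(protein_a = character(), protein_b = character(),
                      identity = numeric(), len_ratio = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Add paralog edges to a set of BBH pairs
#'
#' For every BBH pair (a, b) and every same-organism partner a' of a whose
#' alignment score to a exceeds score(a, b), the edge (a, a') is added
#' ("two paralogous genes from one genome more similar to each other than
#' to a BBH partner from another genome"). Similarity is compared on
#' alignment score, the ranking key of the search stage. The rule is
#' applied one step from each BBH anchor, to both endpoints, and not
#' chained transitively.
#'
#' @param pairs data.frame from [find_bbh()] (must carry `score`).
#' @param intra_hits named list of hit data.frames restricted to
#'   same-organism subjects (scores comparable to cross-organism scores).
#' @return edge data.frame (`from`, `to`): BBH edges plus paralog edges.
#' @export
expand_with_paralogs <- function(pairs, intra_hits = list()) {
  edges <- data.frame(from = pairs$protein_a, to = pairs$protein_b,
                      stringsAsFactors = FALSE)
  extra <- list()
  add_side <- function(x, partner_score) {
    h <- intra_hits[[x]]
    if (is.null(h) || !nrow(h)) return(NULL)
    close <- h$subject_id[h$score > partner_score]
    if (!length(close)) return(NULL)
    data.frame(from = x, to = close, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(pairs))) {
    extra[[length(extra) + 1L]] <- add_side(pairs$protein_a[i],
                                            pairs$score[i])
    extra[[length(extra) + 1L]] <- add_side(pairs$protein_b[i],
                                            pairs$score[i])
  }
  extra <- extra[!vapply(extra, is.null, TRUE)]
  if (length(extra)) edges <- rbind(edges, do.call(rbind, extra))
  unique(edges)
}

#' Build GOPs as connected components of the orthology graph
#'
#' GOPs are the maximal connected components with at least two members;
#' proteins appearing in no edge are reported separately as orphans.
#'
#' @param edges data.frame (`from`, `to`) over protein ids.
#' @param proteins protein table (defines the orphan universe and the
#'   organism of each member).
#' @param scope label recorded on each GOP (`"genus"` or `"family"`).
#' @return list with `gops` (data.frame: `gop_id`, `scope`, `n_members`,
#'   `has_paralogs`, list-columns `members` and `species`) and `orphans`
#'   (character vector of protein ids).
#' @export
build_gops <- function(edges, proteins, scope = "genus") {
  org_of <- stats::setNames(proteins$organism_id, proteins$protein_id)
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    comp <- igraph::components(g)
    members <- split(names(comp$membership), comp$membership)
  } else members <- list()
  members <- members[order(vapply(members, min, ""))]
  if (!length(members)) {
    gops <- data.frame(gop_id = character(), scope = character(),
                       n_members = integer(), stringsAsFactors = FALSE)
    gops$members <- I(list()); gops$species <- I(list())
    gops$has_paralogs <- logical(0)
    return(list(gops = gops, orphans = sort(proteins$protein_id)))
  }
  gops <- data.frame(
    gop_id = sprintf("%s_gop%03d", scope, seq_along(members)),
    scope = scope,
    n_members = vapply(members, length, 1L),
    stringsAsFactors = FALSE)
  gops$members <- I(lapply(members, function(m) sort(m)))
  gops$species <- I(lapply(members, function(m) sort(unique(org_of[m]))))
  gops$has_paralogs <- vapply(members, function(m)
    anyDuplicated(org_of[m]) > 0, TRUE)
  orphans <- setdiff(proteins$protein_id, unlist(members))
  list(gops = gops, orphans = sort(orphans))
}

#' Apply the GOP-level filters
#'
#' Three rules: (1) drop any GOP in which strictly more than half of the
#' members are flagged as transposases or transposon-associated; (2) drop
#' any family-scope GOP whose member set is contained in some genus-scope
#' GOP (it adds nothing beyond the stricter-cutoff group); (3) keep a
#' family-scope GOP only if it contains at least one protein from a focal
#' species.
#'
#' @param genus_gops,family_gops GOP tables from [build_gops()].
#' @param annotations data.frame with `protein_id` and logical
#'   `is_transposase`.
#' @param focal a [focal_config()].
#' @return list with filtered `genus` and `family` GOP tables.
#' @export
filter_gops <- function(genus_gops, family_gops, annotations, focal) {
  is_tx <- stats::setNames(as.logical(annotations$is_transposase),
                           annotations$protein_id)
  tx_frac <- function(m) {
    fl <- is_tx[m]
    fl[is.na(fl)] <- FALSE
    mean(fl)
  }
  keep_tx <- function(gops) {
    if (!nrow(gops)) return(gops)
    gops[vapply(gops$members, tx_frac, 1) <= 0.5, , drop = FALSE]
  }
  genus <- keep_tx(genus_gops)
  family <- keep_tx(family_gops)
  if (nrow(family)) {
    redundant <- vapply(family$members, function(m)
      any(vapply(genus$members, function(g) all(m %in% g), TRUE)), TRUE)
    family <- family[!redundant, , drop = FALSE]
  }
  if (nrow(family)) {
    org_in_focal <- function(sp) any(sp %in% focal$focal_species)
    family <- family[vapply(family$species, org_in_focal, TRUE), ,
                     drop = FALSE]
  }
  list(genus = genus, family = family)
}

#' Write a GOP table as TSV
#' @param gops GOP data.frame.
#' @param path output file.
#' @export
write_gop_table <- function(gops, path) {
  flat <- data.frame(gop_id = gops$gop_id, scope = gops$scope,
                     members = vapply(gops$members, paste, "",
                                      collapse = ","),
                     species = vapply(gops$species, paste, "",
                                      collapse = ","),
                     has_paralogs = gops$has_paralogs,
                     stringsAsFactors = FALSE)
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
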