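# End-to-end census: searches -> orthology -> screening -> trees -> calls.

#' Run the full HGT census pipeline
#'
#' Orchestrates every stage: all-vs-all similarity search of the focal
#' family's proteins against the database, bidirectional-best-hit
#' orthology at the genus (50 %) and family (40 %) cutoffs with the
#' paralog rule and GOP filters, bacterial-type screening of every final
#' GOP and of the focal-species singletons, homolog collection, multiple
#' alignment with a reliability gate, bootstrapped NJ trees, taxonomy
#' rooting and the final transfer calls with timing and donor.
#'
#' @param universe an `hgt_universe`, or a list with elements `proteins`,
#'   `taxa`, `annotations` in the shapes the readers produce.
#' @param focal a [focal_config()]; defaults to the universe's focal sets.
#' @param seed integer seed driving the bootstrap resampling.
#' @param ml_trees optional named list of rooted `ape::phylo` trees
#'   (names = unit ids) used as the ML cross-check.
#' @param hits optional precomputed hit lists (named by query protein id),
#'   e.g. from [parse_hit_table()]; skips the internal search.
#' @param verbose report stage progress.
#' @return object of class `hgt_census`; see [print.hgt_census()].
#' @export
hgt_census <- function(universe, focal = NULL, seed = 1L, ml_trees = NULL,
                       hits = NULL, verbose = FALSE) {
  proteins <- universe$proteins
  taxa <- universe$taxa
  annotations <- universe$annotations
  if (is.null(focal)) {
    if (is.null(universe$focal_species))
      stop("supply a focal_config for non-simulated inputs")
    focal <- focal_config(universe$focal_species, universe$focal_family)
  }
  db <- seq_db(proteins, taxa)
  protein_orgs <- stats::setNames(proteins$organism_id,
                                  proteins$protein_id)
  protein_lengths <- stats::setNames(nchar(proteins$sequence),
                                     proteins$protein_id)
  fam_prot <- proteins[proteins$organism_id %in% focal$focal_family, ]
  if (is.null(hits)) {
    if (verbose) message("searching ", nrow(fam_prot),
                         " focal-family proteins against ",
                         nrow(proteins), " database proteins")
    hits <- search_all(fam_prot, db,
                       min_score = focal$thresholds$search_min_score,
                       verbose = verbose)
  }
  gopsets <- build_orthology(fam_prot, hits, protein_orgs,
                             protein_lengths, focal)
  filtered <- filter_gops(gopsets$genus$gops, gopsets$family$gops,
                          annotations, focal)
  # singleton path: focal-species proteins never connected at either
  # scope (and not transposase-flagged) are analysed as one-member units
  in_any <- unique(c(unlist(gopsets$genus$gops$members),
                     unlist(gopsets$family$gops$members)))
  tx_flag <- stats::setNames(as.logical(annotations$is_transposase),
                             annotations$protein_id)
  singles <- setdiff(fam_prot$protein_id[fam_prot$organism_id %in%
                                           focal$focal_species], in_any)
  singles <- singles[!(tx_flag[singles] %in% TRUE)]
  units <- rbind(filtered$genus, filtered$family)
  if (length(singles)) {
    su <- data.frame(gop_id = paste0("single_", singles),
                     scope = "singleton", n_members = 1L,
                     stringsAsFactors = FALSE)
    su$members <- I(as.list(singles))
    su$species <- I(as.list(protein_orgs[singles]))
    su$has_paralogs <- FALSE
    units <- rbind(units, su)
  }
  if (verbose) message("screening ", nrow(units), " units")
  screens <- lapply(seq_len(nrow(units)), function(i)
    screen_gop(units$members[[i]], hits, protein_orgs, taxa, focal))
  names(screens) <- units$gop_id
  passed <- vapply(screens, `[[`, TRUE, "passed")
  seq_of <- stats::setNames(proteins$sequence, proteins$protein_id)
  trees <- list(); calls <- list(); notes <- character(0)
  for (i in which(passed)) {
    uid <- units$gop_id[i]
    members <- units$members[[i]]
    homs <- collect_homolog_set(members, hits, focal)
    if (length(homs) < 4) {
      notes[uid] <- "fewer than 4 homologs; no tree"
      next
    }
    aln <- align_homologs(seq_of[homs], focal, anchors = members)
    if (!aln$keep) {
      notes[uid] <- "alignment failed the reliability gate"
      next
    }
    st <- build_nj_bootstrap(aln$alignment,
                             reps = focal$thresholds$bootstrap_reps,
                             seed = substream_seed(seed, "gop-boot", i))
    st <- root_tree(st, protein_orgs, taxa, focal)
    trees[[uid]] <- st
    ml <- ml_trees[[uid]]
    if (!is.null(ml) && is.null(ml$root.edge) && !ape::is.rooted(ml))
      ml <- root_tree(ml, protein_orgs, taxa, focal)
    cl <- call_hgt(st, ml, members, protein_orgs, taxa, focal)
    if (!is.null(cl)) {
      calls[[uid]] <- data.frame(
        gop_id = uid, scope = units$scope[i],
        n_members = length(members),
        timing = cl$timing, donor_rank = cl$donor_rank,
        donor_name = cl$donor_name,
        focal_clade_support = cl$focal_clade_support,
        agreeing_trees = paste(cl$agreeing_trees, collapse = "+"),
        members = paste(members, collapse = ","),
        stringsAsFactors = FALSE)
    }
    if (verbose) message("unit ", uid, ": ",
                         if (is.null(cl)) "no call" else cl$timing)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(gop_id = character(), scope = character(),
               n_members = integer(), timing = character(),
               donor_rank = character(), donor_name = character(),
               focal_clade_support = numeric(),
               agreeing_trees = character(), members = character(),
               stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  structure(list(focal = focal, units = units, screens = screens,
                 trees = trees, calls = calls, notes = notes,
                 hits = hits, db = db,
                 genus_gops = filtered$genus, family_gops = filtered$family,
                 orphans = list(genus = gopsets$genus$orphans,
                                family = gopsets$family$orphans),
                 singletons = singles),
            class = "hgt_census")
}

# BBH + paralog-rule orthology at both scopes.
build_orthology <- function(fam_prot, hits, protein_orgs, protein_lengths,
                            focal) {
  scope_edges <- function(orgs, min_identity) {
    ids_of <- function(o) fam_prot$protein_id[fam_prot$organism_id == o]
    intra <- list()
    for (p in fam_prot$protein_id[fam_prot$organism_id %in% orgs]) {
      h <- hits[[p]]
      intra[[p]] <- h[protein_orgs[h$subject_id] == protein_orgs[p], ,
                      drop = FALSE]
    }
    pairs <- list()
    for (a in seq_along(orgs)) for (b in seq_along(orgs)) {
      if (a >= b) next
      ha <- hits[ids_of(orgs[a])]
      hb <- hits[ids_of(orgs[b])]
      # restrict each direction to the partner organism
      ha2 <- lapply(ha, function(h)
        h[protein_orgs[h$subject_id] == orgs[b], , drop = FALSE])
      hb2 <- lapply(hb, function(h)
        h[protein_orgs[h$subject_id] == orgs[a], , drop = FALSE])
      bbh <- find_bbh(ha2, hb2, protein_lengths, min_identity,
                      focal$thresholds$bbh_len_ratio)
      if (nrow(bbh))
        pairs[[length(pairs) + 1L]] <- expand_with_paralogs(bbh, intra)
    }
    if (!length(pairs))
      return(data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE))
    unique(do.call(rbind, pairs))
  }
  genus_orgs <- sort(focal$focal_species)
  family_orgs <- sort(focal$focal_family)
  genus_edges <- scope_edges(genus_orgs,
                             focal$thresholds$bbh_identity_genus)
  family_edges <- scope_edges(family_orgs,
                              focal$thresholds$bbh_identity_family)
  genus_prot <- fam_prot[fam_prot$organism_id %in% genus_orgs, ]
  list(genus = build_gops(genus_edges, genus_prot, scope = "genus"),
       family = build_gops(family_edges, fam_prot, scope = "family"))
}

#' @export
print.hgt_census <- function(x, ...) {
  cat("<hgt_census>\n")
  cat("  final GOPs: ", nrow(x$genus_gops), " genus-scope, ",
      nrow(x$family_gops), " family-scope; ",
      length(x$singletons), " focal singletons\n", sep = "")
  passed <- sum(vapply(x$screens, `[[`, TRUE, "passed"))
  cat("  bacterial-type screen: ", passed, "/", length(x$screens),
      " units passed\n", sep = "")
  cat("  HGT calls: ", nrow(x$calls), "\n", sep = "")
  if (nrow(x$calls)) print(table(x$calls$timing))
  invisible(x)
}

#' @export
summary.hgt_census <- function(object, ...) {
  x <- object
  print(x)
  if (nrow(x$calls)) {
    cat("\nDonor taxa:\n")
    print(table(paste(x$calls$donor_rank, x$calls$donor_name)))
    cat("\nSupports: ")
    print(summary(x$calls$focal_clade_support))
  }
  invisible(x)
}

#' Write the calls table as TSV
#' @param census an `hgt_census`.
#' @param path output file.
#' @export
write_calls <- function(census, path) {
  utils::write.table(census$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
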