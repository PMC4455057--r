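# Homolog alignment, bootstrapped neighbor-joining trees and
# taxonomy-aware rooting.

#' Align a homolog set and decide whether it is reliable enough
#'
#' Runs a progressive multiple aligner (MAFFT, pairwise-distance guide
#' tree with profile-profile merging) and scores each column with a
#' reliability proxy: non-gap occupancy times one minus the normalised
#' residue entropy. The set is discarded when more than half of the
#' columns fall below the configured reliability threshold — badly
#' alignable groups produce meaningless trees.
#'
#' Alongside the column score, sequences themselves are quality-gated:
#' when `anchors` (the GOP members) are given, any other sequence whose
#' aligned identity to every anchor falls below the screening identity
#' floor is dropped and the rest realigned — a homolog admitted by one
#' lucky local alignment but globally unalignable to the group carries no
#' usable signal and only destabilises the tree.
#'
#' @param seqs named character vector of amino-acid sequences (>= 4).
#' @param focal a [focal_config()]; supplies
#'   `alignment_column_reliability` (default 0.5 on the proxy scale) and
#'   the sequence-level identity floor (`screen_identity`).
#' @param anchors names of sequences that are always kept (GOP members).
#' @return list with `alignment` (character matrix, rows = sequences),
#'   `reliability` (per-column score in `[0, 1]`), `frac_unreliable`,
#'   `dropped` (discarded sequence names), and `keep` (logical).
#' @export
align_homologs <- function(seqs, focal, anchors = NULL) {
  if (length(seqs) < 4)
    stop("alignment needs >= 4 sequences (the tree stage needs >= 4 leaves)")
  aln <- run_mafft(seqs)
  dropped <- character(0)
  anchors <- intersect(anchors, rownames(aln))
  if (length(anchors)) {
    ids <- rownames(aln)
    floor_id <- focal$thresholds$screen_identity
    keep_seq <- vapply(ids, function(s) {
      if (s %in% anchors) return(TRUE)
      best <- max(vapply(anchors, function(a) {
        share <- aln[s, ] != "-" & aln[a, ] != "-"
        if (!any(share)) return(0)
        100 * mean(aln[s, share] == aln[a, share])
      }, 0))
      best >= floor_id
    }, TRUE)
    dropped <- ids[!keep_seq]
    if (length(dropped) && sum(keep_seq) >= 4)
      aln <- run_mafft(seqs[ids[keep_seq]])
    else dropped <- character(0)
  }
  rel <- column_reliability(aln)
  thr <- focal$thresholds$alignment_column_reliability
  frac_bad <- mean(rel < thr)
  list(alignment = aln, reliability = rel, frac_unreliable = frac_bad,
       dropped = dropped, keep = frac_bad <= 0.5)
}

run_mafft <- function(seqs) {
  if (Sys.which("mafft") == "")
    stop("the 'mafft' executable is required for multiple alignment ",
         "but was not found on PATH")
  ids <- names(seqs)
  tmp_in <- tempfile(fileext = ".fa")
  on.exit(unlink(tmp_in), add = TRUE)
  writeLines(paste0(">s", seq_along(seqs), "\n", unname(seqs)), tmp_in)
  out <- suppressWarnings(
    system2("mafft", c("--quiet", "--auto", "--amino", shQuote(tmp_in)),
            stdout = TRUE, stderr = FALSE))
  if (!length(out)) stop("mafft produced no output")
  tmp_out <- tempfile(fileext = ".fa")
  on.exit(unlink(tmp_out), add = TRUE)
  writeLines(out, tmp_out)
  ss <- Biostrings::readAAStringSet(tmp_out)
  idx <- as.integer(sub("^s", "", names(ss)))
  mat <- do.call(rbind, strsplit(toupper(as.character(ss)), ""))
  mat <- mat[order(idx), , drop = FALSE]
  rownames(mat) <- ids
  mat
}

column_reliability <- function(aln) {
  apply(aln, 2, function(col) {
    res <- col[col != "-"]
    occ <- length(res) / length(col)
    if (!length(res)) return(0)
    p <- table(res) / length(res)
    h <- -sum(p * log(p))
    occ * (1 - h / log(20))
  })
}

#' Poisson-corrected protein distances from an alignment
#'
#' Pairwise p-distances over columns where both rows are non-gap,
#' corrected as d = -ln(1 - p) with p capped at 0.95 to keep distances
#' finite. A pair sharing no non-gap column gets 1.5 times the largest
#' observed distance (with a warning).
#'
#' @param aln character matrix (rows = sequences, gaps as `-`).
#' @return symmetric numeric distance matrix.
#' @export
poisson_dist <- function(aln) {
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  nogap <- aln != "-"
  none_shared <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    share <- nogap[i, ] & nogap[j, ]
    if (!any(share)) {
      d[i, j] <- d[j, i] <- NA_real_
      none_shared <- TRUE
      next
    }
    p <- min(mean(aln[i, share] != aln[j, share]), 0.95)
    d[i, j] <- d[j, i] <- -log(1 - p)
  }
  if (none_shared) {
    warning("sequence pair(s) share no aligned columns; ",
            "distance set to 1.5 x the maximum observed")
    mx <- max(d, na.rm = TRUE)
    d[is.na(d)] <- 1.5 * mx
  }
  d
}

canonical_split <- function(tips, ref_tip) {
  if (ref_tip %in% tips) return(NULL)  # caller supplies the complement
  paste(sort(tips), collapse = "\r")
}

# All non-trivial bipartitions of a tree, encoded canonically as the side
# not containing the reference tip.
tree_split_set <- function(phy, ref_tip, all_tips) {
  parts <- ape::prop.part(phy)
  labs <- attr(parts, "labels")
  out <- character(0)
  n <- length(all_tips)
  for (p in parts) {
    tips <- labs[p]
    if (length(tips) <= 1L || length(tips) >= n - 1L) next
    if (ref_tip %in% tips) tips <- setdiff(all_tips, tips)
    out <- c(out, paste(sort(tips), collapse = "\r"))
  }
  unique(out)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the NJ tree from Poisson-corrected distances and assesses every
#' internal edge by column-resampling bootstrap: the support of an edge is
#' the percentage of replicate NJ trees containing the same bipartition.
#' Replicates draw their column resamples from per-replicate sub-seeds so
#' results do not depend on evaluation order.
#'
#' @param aln character alignment matrix (>= 4 rows).
#' @param reps number of bootstrap replicates (default 100).
#' @param seed integer seed; fixed seed gives a deterministic tree and
#'   supports.
#' @return an object of class `support_tree`: list with `tree` (an
#'   `ape::phylo` whose internal node labels carry supports in percent),
#'   `boot_splits` (encoded bipartition sets of each replicate), `reps`.
#' @export
build_nj_bootstrap <- function(aln, reps = 100L, seed = 1L) {
  if (nrow(aln) < 4) stop("need >= 4 sequences for a tree")
  if (ncol(aln) < 1) stop("alignment has no columns")
  d <- poisson_dist(aln)
  tree <- ape::nj(d)
  all_tips <- tree$tip.label
  ref <- min(all_tips)
  boot_splits <- vector("list", reps)
  for (r in seq_len(reps)) {
    cols <- with_seed(substream_seed(seed, "bootstrap", r),
                      sample.int(ncol(aln), ncol(aln), replace = TRUE))
    dr <- suppressWarnings(poisson_dist(aln[, cols, drop = FALSE]))
    tr <- ape::nj(dr)
    boot_splits[[r]] <- tree_split_set(tr, ref, all_tips)
  }
  st <- structure(list(tree = tree, boot_splits = boot_splits,
                       reps = reps, ref_tip = ref), class = "support_tree")
  st$tree <- label_supports(st)
  st
}

# Write per-internal-node supports (percent) into the node labels of the
# reference tree.
label_supports <- function(st) {
  phy <- st$tree
  labs <- character(phy$Nnode)
  ntip <- length(phy$tip.label)
  for (node in seq_len(phy$Nnode) + ntip) {
    tips <- tips_under(phy, node)
    if (length(tips) == ntip) { labs[node - ntip] <- ""; next }
    labs[node - ntip] <- as.character(round(split_support(st, tips)))
  }
  phy$node.label <- labs
  phy
}

#' Bootstrap support of an arbitrary bipartition
#'
#' @param st a `support_tree`.
#' @param leaves character vector of tip labels forming one side of the
#'   split. Trivial splits (single leaf, or all but one) are supported by
#'   every replicate and return 100.
#' @return support in percent.
#' @export
split_support <- function(st, leaves) {
  all_tips <- st$tree$tip.label
  leaves <- intersect(all_tips, leaves)
  n <- length(all_tips)
  if (length(leaves) <= 1L || length(leaves) >= n - 1L) return(100)
  if (st$ref_tip %in% leaves) leaves <- setdiff(all_tips, leaves)
  key <- paste(sort(leaves), collapse = "\r")
  100 * mean(vapply(st$boot_splits, function(s) key %in% s, TRUE))
}

# Does the (possibly unrooted) tree contain the bipartition (leaves | rest)?
has_split <- function(phy, leaves) {
  all_tips <- phy$tip.label
  leaves <- intersect(all_tips, leaves)
  if (length(leaves) %in% c(1L, length(all_tips) - 1L)) return(TRUE)
  if (!length(leaves) || length(leaves) == length(all_tips)) return(FALSE)
  ref <- min(all_tips)
  if (ref %in% leaves) leaves <- setdiff(all_tips, leaves)
  key <- paste(sort(leaves), collapse = "\r")
  key %in% tree_split_set(phy, ref, all_tips)
}

tips_under <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_under, phy = phy))
}

#' Root a tree by the census rooting rules
#'
#' Rule 1: if the non-focal-family archaeal leaves form a clade of the
#' unrooted tree, root on the edge subtending that clade (between those
#' archaea and the bacteria). Rule 2 (no such clade, or no archaea
#' outside the family): root on the internal edge that best separates the
#' two largest phylum-level bacterial groups; among equally separating
#' edges the one maximising the smaller side's leaf count wins, ties
#' broken by the longer edge, then by the lexicographically smallest leaf
#' label on the child side.
#'
#' @param st a `support_tree` (or bare `phylo`).
#' @param leaf_orgs named character vector: tip label -> organism id.
#' @param taxa taxonomy table resolving every organism.
#' @param focal a [focal_config()].
#' @return the input with its tree rooted (a `support_tree` is returned as
#'   a `support_tree`).
#' @export
root_tree <- function(st, leaf_orgs, taxa, focal) {
  phy <- if (inherits(st, "support_tree")) st$tree else st
  if (length(phy$tip.label) < 4) stop("tree has fewer than 4 leaves")
  doms <- domain_of(taxa)
  lins <- lineage_table(taxa)
  tips <- phy$tip.label
  orgs <- leaf_orgs[tips]
  arch_out <- tips[doms[orgs] == "Archaea" & !(orgs %in% focal$focal_family)]
  rooted <- NULL
  if (length(arch_out) >= 1L && length(arch_out) < length(tips) &&
      has_split(phy, arch_out)) {
    rooted <- ape::root(phy, outgroup = arch_out, resolve.root = TRUE)
  } else {
    side <- balance_root_side(phy, orgs, doms, lins)
    rooted <- ape::root(phy, outgroup = side, resolve.root = TRUE)
  }
  if (inherits(st, "support_tree")) {
    st$tree <- rooted
    st$tree <- label_supports(st)  # ape::root permutes node labels
    st
  } else rooted
}

balance_root_side <- function(phy, orgs, doms, lins) {
  tips <- phy$tip.label
  ntip <- length(tips)
  bact <- tips[doms[orgs] == "Bacteria"]
  phylum <- vapply(bact, function(tp) {
    lin <- lins[[orgs[tp]]]
    if ("phylum" %in% names(lin)) lin[["phylum"]] else lin[[1]]
  }, "")
  grp <- sort(table(phylum), decreasing = TRUE)
  p1 <- if (length(grp) >= 1) names(grp)[1] else NA_character_
  p2 <- if (length(grp) >= 2) names(grp)[2] else NA_character_
  # with a single bacterial group the divergence point lies between that
  # group and everything else (here: the transferred clade)
  grp2_tips <- if (!is.na(p2)) bact[phylum == p2] else setdiff(tips, bact)
  in_grp <- function(set, g) {
    if (is.na(g)) return(0L)
    if (g == "..rest") return(sum(set %in% grp2_tips))
    sum(set %in% bact[phylum == g])
  }
  if (is.na(p2) && length(grp2_tips)) p2 <- "..rest"
  internal <- phy$edge[, 2] > ntip
  cand <- which(internal)
  if (!length(cand)) cand <- seq_len(nrow(phy$edge))  # degenerate star
  best <- NULL
  for (e in cand) {
    side <- tips_under(phy, phy$edge[e, 2])
    if (length(side) == 0L || length(side) == ntip) next
    other <- setdiff(tips, side)
    sep <- max(in_grp(side, p1) + in_grp(other, p2),
               in_grp(side, p2) + in_grp(other, p1))
    bal <- min(length(side), length(other))
    len <- if (!is.null(phy$edge.length)) phy$edge.length[e] else 0
    key <- list(sep = sep, bal = bal, len = len, lab = min(side),
                side = side)
    if (is.null(best) || sep > best$sep ||
        (sep == best$sep && len > best$len) ||
        (sep == best$sep && len == best$len && bal > best$bal) ||
        (sep == best$sep && len == best$len && bal == best$bal &&
         key$lab < best$lab))
      best <- key
  }
  best$side
}
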