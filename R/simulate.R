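# Truth-labelled synthetic universes: taxonomy with year stamps, a
# species tree with a focal genus nested in a focal family, gene families
# evolved along the tree with planted transfers regrafted inside donor
# clades, and genome layouts with operon structure.
#
# The generator uses an equal-rates 20-state substitution model (uniform
# root, each site substitutes along a branch of length b with probability
# 1 - exp(-b), drawing a uniformly different residue). Its closed-form
# pairwise identity makes the generator itself testable; realism is
# carried by the branch-length geometry, not the substitution matrix.

#' Configuration for a synthetic universe
#'
#' Defaults describe the strong-signal census regime: 3 focal (genus)
#' species and 3 other family species, 4 outgroup archaeal genomes, 4
#' bacterial phyla of 4 single-genus genomes each, 30 gene families
#' (one of them transposase-flagged), and 10 planted transfer events
#' spanning all three timings. Branch lengths are chosen so that
#' within-genus identity is ~85 %, within-family ~50-75 %, donor-clade
#' identity for transferred genes >= 60 %, and archaeal/bacterial deep
#' divergences fall below the 30 % screening cutoff.
#'
#' @param seed master integer seed; every stage draws from named
#'   substreams of it, so equal seeds give byte-identical universes.
#' @param n_bacterial_phyla,genomes_per_taxon bacterial taxonomy shape
#'   (each genome is its own genus within its phylum).
#' @param n_focal_species,n_other_family,outgroup_archaea archaeal layout.
#' @param year_range years over which genome year stamps are spread.
#' @param n_families number of gene families.
#' @param n_transposase_families families whose members are
#'   transposase-flagged (exercises the GOP filter).
#' @param hgt_spec data.frame with columns `timing`
#'   (`family_ancestor` / `genus_ancestor` / `species_specific`),
#'   `donor_name` (a bacterial phylum) and `count`; `NULL` gives the
#'   default 4 genus + 3 family + 3 species-specific events.
#' @param seq_params list: `length` (range of family protein lengths, in
#'   residues), `branch_scale` (multiplier on all branch lengths,
#'   expected substitutions/site), `jitter_sd` (lognormal branch-length
#'   jitter between families), `transfer_stem` (stem branch of the
#'   regrafted clade; short, so the clade sits inside the donor clade).
#' @param layout_params list: `fraction_in_operons`, `operon_size_range`,
#'   `intra_gap_range` (<= 150 bp), `inter_gap_range` (> 150 bp).
#' @param confounders list `n`, `year`: archaeal genomes year-stamped
#'   `year` whose copies of planted families sit next to the transferred
#'   clade — the database-growth scenario in which later archaeal
#'   sequencing deflates the search-only HGT estimate. Default `n = 0`.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_bacterial_phyla = 4L, genomes_per_taxon = 4L,
                       n_focal_species = 3L, n_other_family = 3L,
                       outgroup_archaea = 4L,
                       year_range = c(2001L, 2011L),
                       n_families = 30L,
                       n_transposase_families = 1L,
                       hgt_spec = NULL,
                       seq_params = list(),
                       layout_params = list(),
                       confounders = list(n = 0L, year = 2006L)) {
  sp <- utils::modifyList(list(length = c(160L, 240L), branch_scale = 1,
                               jitter_sd = 0.08, transfer_stem = 0.12),
                          seq_params)
  lp <- utils::modifyList(list(fraction_in_operons = 0.66,
                               operon_size_range = c(2L, 6L),
                               intra_gap_range = c(0L, 120L),
                               inter_gap_range = c(200L, 400L)),
                          layout_params)
  if (is.null(hgt_spec)) {
    phy <- function(i) sprintf("BactPhy%d", (i - 1L) %% n_bacterial_phyla + 1L)
    hgt_spec <- data.frame(
      timing = c(rep("genus_ancestor", 4), rep("family_ancestor", 3),
                 rep("species_specific", 3)),
      donor_name = c(phy(1:4), phy(1:3), phy(2:4)),
      count = 1L, stringsAsFactors = FALSE)
    # small universes: keep a majority of vertical families
    keep <- min(nrow(hgt_spec),
                max(0L, n_families - n_transposase_families - 2L))
    hgt_spec <- hgt_spec[seq_len(keep), , drop = FALSE]
  }
  stopifnot(all(hgt_spec$timing %in%
                  c("family_ancestor", "genus_ancestor", "species_specific")),
            n_families >= 1, n_focal_species >= 2,
            sum(hgt_spec$count) + n_transposase_families <= n_families)
  structure(list(seed = as.integer(seed),
                 n_bacterial_phyla = n_bacterial_phyla,
                 genomes_per_taxon = genomes_per_taxon,
                 n_focal_species = n_focal_species,
                 n_other_family = n_other_family,
                 outgroup_archaea = outgroup_archaea,
                 year_range = year_range, n_families = n_families,
                 n_transposase_families = n_transposase_families,
                 hgt_spec = hgt_spec, seq_params = sp, layout_params = lp,
                 confounders = confounders),
            class = "sim_config")
}

# balanced clade of consecutive pairs; avoids the long pendant tips a
# caterpillar shape gives its last leaves
balanced_nwk <- function(tips, tip_len, step) {
  n <- length(tips)
  pairs <- character(0)
  i <- 1L
  while (i + 1L <= n) {
    pairs <- c(pairs, paste0("(", tips[i], ":", tip_len, ",", tips[i + 1L],
                             ":", tip_len, ")"))
    i <- i + 2L
  }
  if (length(pairs) == 0) return(paste0(tips, ":", tip_len))
  out <- caterpillar_nwk_str(pairs, step, step)
  if (i == n)  # odd leftover
    out <- paste0("(", out, ":", step, ",", tips[n], ":", tip_len + step,
                  ")")
  out
}

caterpillar_nwk <- function(tips, tip_len, step) {
  if (length(tips) == 1) return(paste0(tips, ":", tip_len))
  cur <- paste0("(", tips[1], ":", tip_len, ",", tips[2], ":", tip_len, ")")
  depth <- tip_len
  for (t in tips[-(1:2)]) {
    depth <- depth + step
    cur <- paste0("(", cur, ":", step, ",", t, ":", depth, ")")
  }
  cur
}

#' Taxonomy and species tree of a synthetic universe
#' @param cfg a [sim_config()].
#' @return list with `taxa` (taxonomy data.frame) and `tree`
#'   (`ape::phylo`, tips are organism ids).
#' @export
sim_taxonomy <- function(cfg) {
  foc <- sprintf("foc%d", seq_len(cfg$n_focal_species))
  fam <- sprintf("fam%d", seq_len(cfg$n_other_family))
  arc <- sprintf("arc%d", seq_len(cfg$outgroup_archaea))
  conf <- if (cfg$confounders$n > 0)
    sprintf("conf%d", seq_len(cfg$confounders$n)) else character(0)
  bact <- list()
  for (p in seq_len(cfg$n_bacterial_phyla))
    bact[[p]] <- sprintf("b%d_%d", p, seq_len(cfg$genomes_per_taxon))
  lin <- function(domain, phylum, class = NULL, family = NULL,
                  genus = NULL, species = NULL) {
    parts <- c(domain = domain, phylum = phylum, class = class,
               family = family, genus = genus, species = species)
    paste(paste0(names(parts), ":", parts), collapse = ";")
  }
  rows <- list()
  years_arch <- rep(seq(cfg$year_range[1], length.out = 4),
                    length.out = length(c(foc, fam, arc)))
  for (i in seq_along(foc)) rows[[length(rows) + 1L]] <- data.frame(
    organism_id = foc[i], name = paste("Focal genus sp.", i),
    domain = "Archaea", year = years_arch[i],
    lineage = lin("Archaea", "ArchPhy1", "ArchClass1", "FocalFam",
                  "FocalGen", paste0("FocalGen_sp", i)))
  for (i in seq_along(fam)) rows[[length(rows) + 1L]] <- data.frame(
    organism_id = fam[i], name = paste("Focal family sp.", i),
    domain = "Archaea", year = years_arch[length(foc) + i],
    lineage = lin("Archaea", "ArchPhy1", "ArchClass1", "FocalFam",
                  paste0("FamGen", i), paste0("FamGen", i, "_sp")))
  for (i in seq_along(arc)) rows[[length(rows) + 1L]] <- data.frame(
    organism_id = arc[i], name = paste("Outgroup archaeon", i),
    domain = "Archaea", year = years_arch[length(foc) + length(fam) + i],
    lineage = lin("Archaea", "ArchPhy2", "ArchClass2", "OutFam",
                  paste0("OutGen", (i + 1L) %/% 2L),
                  paste0("OutGen", (i + 1L) %/% 2L, "_sp", i)))
  for (i in seq_along(conf)) rows[[length(rows) + 1L]] <- data.frame(
    organism_id = conf[i], name = paste("Confounding archaeon", i),
    domain = "Archaea", year = cfg$confounders$year,
    lineage = lin("Archaea", "ArchPhy2", "ArchClass2", "ConfFam",
                  paste0("ConfGen", i), paste0("ConfGen", i, "_sp")))
  yrs_b <- rep(seq(cfg$year_range[1], cfg$year_range[2]),
               length.out = cfg$n_bacterial_phyla * cfg$genomes_per_taxon)
  k <- 0L
  for (p in seq_len(cfg$n_bacterial_phyla)) for (g in bact[[p]]) {
    k <- k + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      organism_id = g, name = paste("Bacterium", g), domain = "Bacteria",
      year = yrs_b[k],
      # class/family deliberately absent: within a phylum the genomes
      # share no rank below phylum, so a whole-phylum donor clade
      # resolves to the phylum itself
      lineage = lin("Bacteria", sprintf("BactPhy%d", p),
                    genus = paste0("Gen_", g),
                    species = paste0("Gen_", g, "_sp")))
  }
  taxa <- do.call(rbind, rows)
  # species tree: lengths give the identity regime documented above
  focal_clade <- caterpillar_nwk(foc, 0.05, 0.04)
  fam_clade <- caterpillar_nwk(fam, 0.10, 0.06)
  family_clade <- paste0("(", focal_clade, ":0.18,", fam_clade, ":0.10)")
  out_clade <- balanced_nwk(arc, 0.12, 0.08)
  arch_other <- if (length(conf)) {
    paste0("(", out_clade, ":0.25,", caterpillar_nwk(conf, 0.05, 0.05),
           ":0.25)")
  } else out_clade
  archaea <- paste0("(", family_clade, ":0.8,", arch_other, ":0.5)")
  # long exterior branches: the inter-phylum backbone is deep enough
  # that a transferred gene keeps >= 30 % identity only to its donor
  # phylum, never to the other phyla
  phyla <- vapply(bact, function(g) balanced_nwk(g, 0.12, 0.08), "")
  bacteria <- caterpillar_nwk_str(paste0(phyla), 0.85, 0.35)
  nwk <- paste0("(", archaea, ":0.7,", bacteria, ":0.7);")
  tree <- ape::read.tree(text = nwk)
  tree$edge.length <- tree$edge.length * cfg$seq_params$branch_scale
  list(taxa = taxa, tree = tree)
}

# caterpillar over pre-built subtree strings (they already end in ")"),
# attaching each at the same stem length
caterpillar_nwk_str <- function(subs, stem, step) {
  if (length(subs) == 1) return(paste0(subs, ":", stem))
  cur <- paste0("(", subs[1], ":", stem, ",", subs[2], ":", stem, ")")
  for (s in subs[-(1:2)])
    cur <- paste0("(", cur, ":", step, ",", s, ":", stem + step, ")")
  cur
}

subtree_string <- function(phy, tips) {
  if (length(tips) == 1) {
    i <- which(phy$tip.label == tips)
    edge <- phy$edge.length[phy$edge[, 2] == i]
    return(paste0(tips, ":", edge))
  }
  sub <- ape::keep.tip(phy, tips)
  sub("; *$", "", ape::write.tree(sub))
}

#' Build one family's gene tree, regrafting a planted transfer
#'
#' The gene tree is the species tree with per-branch lognormal rate
#' jitter; for a planted event the recipient clade (focal genus, focal
#' family, or one focal species) is pruned and reattached, with a short
#' stem, onto the stem edge of the donor clade — so the transferred
#' genes sit inside a bacterial clade, the geometry the detector looks
#' for. Confounding archaea, when present, attach next to the transferred
#' clade.
#'
#' @param sptree species tree (`ape::phylo`).
#' @param taxa taxonomy table.
#' @param event `NULL` for a vertical family, else a list with `timing`,
#'   `donor_name`, `recipients` (organism ids), `confounders` (organism
#'   ids or empty).
#' @param cfg a [sim_config()].
#' @param seed substream seed for the jitter.
#' @return `ape::phylo` over the organisms present in this family.
#' @export
sim_gene_tree <- function(sptree, taxa, event, cfg, seed) {
  phy <- sptree
  phy$edge.length <- phy$edge.length *
    with_seed(seed, exp(stats::rnorm(length(phy$edge.length), 0,
                                     cfg$seq_params$jitter_sd)))
  if (is.null(event)) return(phy)
  rec <- event$recipients
  conf <- event$confounders %||% character(0)
  sub_str <- subtree_string(phy, rec)
  if (length(conf)) {
    conf_str <- subtree_string(phy, conf)
    sub_str <- paste0("(", sub_str, ":0.04,", conf_str, ":0.06)")
  }
  sub <- if (startsWith(sub_str, "("))
    ape::read.tree(text = paste0(sub_str, ";"))
  else ape::read.tree(text = paste0("(", sub_str, ");"))
  sub$root.edge <- cfg$seq_params$transfer_stem
  main <- ape::drop.tip(phy, c(rec, conf))
  donor_tips <- taxa$organism_id[grepl(paste0("phylum:", event$donor_name,
                                              "(;|$)"), taxa$lineage)]
  donor_tips <- intersect(donor_tips, main$tip.label)
  node <- ape::getMRCA(main, donor_tips)
  stem <- main$edge.length[main$edge[, 2] == node]
  # attach just above the donor clade root so the transferred genes keep
  # high identity to the whole donor clade
  g <- ape::bind.tree(main, sub, where = node,
                      position = min(0.1, stem / 2))
  ape::collapse.singles(g)
}

#' Evolve one family's sequences along its gene tree
#'
#' Root sequence uniform over the 20 amino acids; along each branch of
#' length b every site substitutes with probability 1 - exp(-b) to a
#' uniformly chosen different residue.
#'
#' @param gene_tree `ape::phylo` with nonnegative branch lengths.
#' @param length protein length in residues.
#' @param seed substream seed.
#' @return named character vector of leaf sequences (names = tip labels).
#' @export
evolve_family <- function(gene_tree, length, seed) {
  if (any(gene_tree$edge.length < 0)) stop("negative branch length")
  with_seed(seed, {
    ntip <- base::length(gene_tree$tip.label)
    root <- ntip + 1L
    seqs <- vector("list", ntip + gene_tree$Nnode)
    seqs[[root]] <- sample(AA_LETTERS, length, replace = TRUE)
    # preorder: parents before children
    ord <- ape::reorder.phylo(gene_tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      b <- ord$edge.length[e]
      s <- seqs[[par]]
      mut <- stats::runif(length) < 1 - exp(-b)
      if (any(mut)) {
        cur <- match(s[mut], AA_LETTERS)
        s[mut] <- AA_LETTERS[(cur - 1L +
                                sample.int(19L, sum(mut), replace = TRUE)) %%
                               20L + 1L]
      }
      seqs[[child]] <- s
    }
    out <- vapply(seqs[seq_len(ntip)], paste, "", collapse = "")
    names(out) <- gene_tree$tip.label
    out
  })
}

#' Expected pairwise identity under the generator's substitution model
#'
#' Closed form: along a path of branches b_i, a site is identical at the
#' two ends with probability 1/20 + (19/20) * prod(lambda_i) where
#' lambda_i = exp(-b_i) - (1 - exp(-b_i)) / 19.
#'
#' @param branches numeric vector of branch lengths along the path.
#' @return expected fraction of identical sites.
#' @export
expected_identity <- function(branches) {
  lam <- exp(-branches) - (1 - exp(-branches)) / 19
  1 / 20 + (19 / 20) * prod(lam)
}

#' Lay out one genome's genes with operon structure
#'
#' Genes are placed sequentially on a single replicon in seeded random
#' order; unit sizes are drawn so the expected fraction of genes in
#' multi-gene units matches `fraction_in_operons`; gaps within units are
#' drawn from `intra_gap_range` (<= the 150 bp prediction threshold) and
#' gaps between units from `inter_gap_range` (> threshold); strands are
#' constant within a unit.
#'
#' @param organism_id organism the genes belong to.
#' @param genes data.frame with `gene_id` and `length_nt`.
#' @param layout_params see [sim_config()].
#' @param seed substream seed.
#' @return list with `loci` (gene table rows) and `runs` (the true unit
#'   partition, a list of gene-id vectors).
#' @export
layout_genome <- function(organism_id, genes, layout_params, seed) {
  lp <- layout_params
  with_seed(seed, {
    ord <- sample.int(nrow(genes))
    gid <- genes$gene_id[ord]
    glen <- genes$length_nt[ord]
    ek <- mean(seq(lp$operon_size_range[1], lp$operon_size_range[2]))
    f <- lp$fraction_in_operons
    q <- if (f >= 1) 1 else f / (ek * (1 - f) + f)
    runs <- list(); i <- 1L
    while (i <= length(gid)) {
      size <- if (stats::runif(1) < q)
        sample(seq(lp$operon_size_range[1], lp$operon_size_range[2]), 1L)
      else 1L
      size <- min(size, length(gid) - i + 1L)
      runs[[length(runs) + 1L]] <- seq(i, i + size - 1L)
      i <- i + size
    }
    pos <- 1L
    rows <- list(); truth <- list()
    for (r in runs) {
      strand <- sample(c("+", "-"), 1L)
      ids <- gid[r]
      starts <- integer(length(r)); ends <- integer(length(r))
      for (j in seq_along(r)) {
        starts[j] <- pos
        ends[j] <- pos + glen[r[j]] - 1L
        gap <- if (j < length(r))
          sample(seq(lp$intra_gap_range[1], lp$intra_gap_range[2]), 1L)
        else sample(seq(lp$inter_gap_range[1], lp$inter_gap_range[2]), 1L)
        pos <- ends[j] + gap + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = ids, replicon_id = paste0(organism_id, "_chr"),
        start = starts, end = ends, strand = strand,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- ids
    }
    list(loci = do.call(rbind, rows), runs = truth)
  })
}

#' Generate a complete truth-labelled universe
#'
#' @param cfg a [sim_config()].
#' @return object of class `hgt_universe`: list with `proteins`, `taxa`,
#'   `loci`, `annotations` (incl. transposase flags, COG categories,
#'   functional classes, expression flags), `truth` (planted events,
#'   orthology truth, operon truth, year stamps), `species_tree`,
#'   `focal_species`, `focal_family`, `config`.
#' @export
simulate_universe <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  tx <- sim_taxonomy(cfg)
  taxa <- tx$taxa; sptree <- tx$tree
  foc <- sprintf("foc%d", seq_len(cfg$n_focal_species))
  fam_other <- sprintf("fam%d", seq_len(cfg$n_other_family))
  conf <- if (cfg$confounders$n > 0)
    sprintf("conf%d", seq_len(cfg$confounders$n)) else character(0)
  fam_ids <- sprintf("F%02d", seq_len(cfg$n_families))
  n_tx <- cfg$n_transposase_families
  tx_fams <- utils::tail(fam_ids, n_tx)
  events <- list()
  spec_rows <- cfg$hgt_spec[rep(seq_len(nrow(cfg$hgt_spec)),
                                cfg$hgt_spec$count), ]
  plantable <- setdiff(fam_ids, tx_fams)
  planted_fams <- with_seed(substream_seed(cfg$seed, "plant"),
                            sample(plantable, nrow(spec_rows)))
  sp_i <- 0L
  for (i in seq_len(nrow(spec_rows))) {
    timing <- spec_rows$timing[i]
    recipients <- switch(timing,
                         genus_ancestor = foc,
                         family_ancestor = c(foc, fam_other),
                         species_specific = {
                           sp_i <- sp_i + 1L
                           foc[(sp_i - 1L) %% length(foc) + 1L]
                         })
    events[[planted_fams[i]]] <-
      list(family_id = planted_fams[i], timing = timing,
           donor_rank = "phylum", donor_name = spec_rows$donor_name[i],
           recipients = recipients, confounders = conf)
  }
  prot_rows <- list(); fam_lens <- integer(0); orth <- list()
  for (f in fam_ids) {
    ev <- events[[f]]
    gt <- sim_gene_tree(sptree, taxa, ev,
                        cfg, substream_seed(cfg$seed, "tree", match(f, fam_ids)))
    # vertical families keep confounders at their (deep) species-tree spot
    len <- with_seed(substream_seed(cfg$seed, "len", match(f, fam_ids)),
                     sample(seq(cfg$seq_params$length[1],
                                cfg$seq_params$length[2]), 1L))
    fam_lens[f] <- len
    seqs <- evolve_family(gt, len,
                          substream_seed(cfg$seed, "seq", match(f, fam_ids)))
    pid <- paste0(f, "_", names(seqs))
    prot_rows[[f]] <- data.frame(protein_id = pid,
                                 organism_id = names(seqs),
                                 sequence = unname(seqs),
                                 stringsAsFactors = FALSE)
    orth[[f]] <- pid
  }
  proteins <- do.call(rbind, prot_rows)
  rownames(proteins) <- NULL
  # annotations: transposase flags by family; COG / functional classes /
  # expression drawn at random (they exercise the census statistics, the
  # detector never reads them)
  ann_seed <- substream_seed(cfg$seed, "annot")
  annotations <- with_seed(ann_seed, {
    fam_of <- sub("_.*$", "", proteins$protein_id)
    data.frame(
      protein_id = proteins$protein_id,
      cog_category = sample(c("C", "E", "G", "P", "R", "S", "V", "J", "K",
                              "L"), nrow(proteins), replace = TRUE),
      functional_class = sample(c("enzyme", "transporter",
                                  "transcription_factor", "housekeeping",
                                  "other"), nrow(proteins), replace = TRUE,
                                prob = c(0.35, 0.12, 0.05, 0.18, 0.30)),
      is_transposase = fam_of %in% tx_fams,
      is_differentially_expressed = stats::runif(nrow(proteins)) < 0.5,
      stringsAsFactors = FALSE)
  })
  loci_rows <- list(); operon_truth <- list()
  for (org in taxa$organism_id) {
    p <- proteins[proteins$organism_id == org, ]
    genes <- data.frame(gene_id = p$protein_id,
                        length_nt = 3L * nchar(p$sequence) + 3L,
                        stringsAsFactors = FALSE)
    lay <- layout_genome(org, genes, cfg$layout_params,
                         substream_seed(cfg$seed, "layout",
                                        match(org, taxa$organism_id)))
    loci_rows[[org]] <- lay$loci
    operon_truth[[org]] <- lay$runs
  }
  loci <- do.call(rbind, loci_rows)
  rownames(loci) <- NULL
  truth <- list(
    planted_events = events,
    orthology_truth = orth,
    operon_truth = operon_truth,
    year_stamps = stats::setNames(taxa$year, taxa$organism_id))
  structure(list(proteins = proteins, taxa = taxa, loci = loci,
                 annotations = annotations, truth = truth,
                 species_tree = sptree,
                 focal_species = foc,
                 focal_family = c(foc, fam_other),
                 config = cfg),
            class = "hgt_universe")
}

#' @export
print.hgt_universe <- function(x, ...) {
  cat("<hgt_universe> ", nrow(x$proteins), " proteins, ",
      nrow(x$taxa), " organisms, ", length(x$truth$orthology_truth),
      " families, ", length(x$truth$planted_events),
      " planted transfer events\n", sep = "")
  invisible(x)
}

#' Write a universe to disk in the formats the readers accept
#'
#' Emits `proteins.fasta`, `taxonomy.tsv`, `genes.tsv`,
#' `annotations.tsv` and `truth.json` into `dir`. Deterministic given
#' the universe.
#'
#' @param universe an `hgt_universe`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_universe <- function(universe, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(universe$proteins, file.path(dir, "proteins.fasta"))
  write_taxonomy(universe$taxa, file.path(dir, "taxonomy.tsv"))
  write_gene_table(universe$loci, file.path(dir, "genes.tsv"))
  utils::write.table(universe$annotations,
                     file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- universe$truth
  truth$operon_truth <- lapply(truth$operon_truth, function(r) r)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
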