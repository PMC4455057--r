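# Bacterial-type screening, homolog collection, alignment gating, NJ
# bootstrap trees, rooting rules and the transfer-call conditions.

test_that("the screen applies its thresholds and the top-3 / top-20 rules", {
  cfg <- toy_focal()
  taxa <- toy_taxa()
  orgs <- c(ma_1 = "ma", c1_1 = "c1", c2_1 = "c2", p1_1 = "p1",
            p2_1 = "p2", f1_1 = "f1", ar1_1 = "ar1", ar2_1 = "ar2",
            ar3_1 = "ar3", ar4_1 = "ar4", fx_1 = "fx", mb_1 = "mb")
  # top 3 all bacterial -> pass
  h <- list(ma_1 = hit_list(hit_row("ma_1", "c1_1", 300),
                            hit_row("ma_1", "c2_1", 280),
                            hit_row("ma_1", "p1_1", 260),
                            hit_row("ma_1", "ar1_1", 240)))
  v <- screen_gop("ma_1", h, orgs, taxa, cfg)
  expect_true(v$passed)
  expect_true(v$per_member$top3_all_bacterial)

  # 4 archaeal among the filtered top 20 and an archaeon in the top 3 -> fail
  h2 <- list(ma_1 = hit_list(hit_row("ma_1", "ar1_1", 300),
                             hit_row("ma_1", "ar2_1", 290),
                             hit_row("ma_1", "ar3_1", 280),
                             hit_row("ma_1", "ar4_1", 270),
                             hit_row("ma_1", "c1_1", 260)))
  v2 <- screen_gop("ma_1", h2, orgs, taxa, cfg)
  expect_false(v2$passed)
  expect_equal(v2$per_member$archaeal_in_top20, 4L)

  # 3 archaeal among top 20, everything else bacterial -> pass
  h3 <- list(ma_1 = hit_list(hit_row("ma_1", "ar1_1", 300),
                             hit_row("ma_1", "ar2_1", 290),
                             hit_row("ma_1", "ar3_1", 280),
                             hit_row("ma_1", "c1_1", 260),
                             hit_row("ma_1", "c2_1", 250)))
  v3 <- screen_gop("ma_1", h3, orgs, taxa, cfg)
  expect_true(v3$passed)

  # focal-family and fellow-member hits are removed before counting
  h4 <- list(ma_1 = hit_list(hit_row("ma_1", "fx_1", 500),
                             hit_row("ma_1", "mb_1", 450),
                             hit_row("ma_1", "c1_1", 300),
                             hit_row("ma_1", "c2_1", 280),
                             hit_row("ma_1", "p1_1", 260)),
             mb_1 = hit_list(hit_row("mb_1", "c1_1", 300),
                             hit_row("mb_1", "c2_1", 280),
                             hit_row("mb_1", "p1_1", 260)))
  v4 <- screen_gop(c("ma_1", "mb_1"), h4, orgs, taxa, cfg)
  expect_true(v4$passed)

  # threshold edges: identity 29.9, short HSPs and low coverage never count
  h5 <- list(ma_1 = hit_list(
    hit_row("ma_1", "c1_1", 300, identity = 29.9),
    hit_row("ma_1", "c2_1", 280, hsp_length = 49),
    hit_row("ma_1", "p1_1", 260, coverage = 74.9)))
  v5 <- screen_gop("ma_1", h5, orgs, taxa, cfg)
  expect_false(v5$passed)
  expect_equal(v5$per_member$surviving_hits, 0L)
})

test_that("homolog collection unions top filtered hits with the members", {
  cfg <- toy_focal(homologs_per_member = 2L)
  h <- list(
    ma_1 = hit_list(hit_row("ma_1", "c1_1", 300),
                    hit_row("ma_1", "c2_1", 280),
                    hit_row("ma_1", "p1_1", 260)),
    mb_1 = hit_list(hit_row("mb_1", "c1_1", 300),
                    hit_row("mb_1", "f1_1", 290)))
  out <- collect_homolog_set(c("ma_1", "mb_1"), h, cfg)
  expect_setequal(out, c("ma_1", "mb_1", "c1_1", "c2_1", "f1_1"))
  # a member with few hits contributes what it has
  out2 <- collect_homolog_set("mb_1", h, cfg)
  expect_setequal(out2, c("mb_1", "c1_1", "f1_1"))
})

test_that("alignment reliability gates pathological homolog sets", {
  cfg <- toy_focal()
  set.seed(31)
  base <- random_protein(60)
  idseq <- stats::setNames(rep(base, 4), paste0("s", 1:4))
  a <- align_homologs(idseq, cfg)
  expect_true(a$keep)
  expect_true(all(a$reliability == 1))

  expect_error(align_homologs(idseq[1:3], cfg), ">= 4")

  # half the sequences share nothing with the other half: the merged
  # alignment is mostly gap columns and must be discarded
  weird <- stats::setNames(
    c(base, base, strrep("W", 70), strrep("H", 80)), paste0("s", 1:4))
  b <- align_homologs(weird, cfg)
  expect_false(b$keep)
})

test_that("NJ recovers the generating topology from clean alignments", {
  # additive distances on ((A,B),(C,D)): NJ is consistent
  set.seed(32)
  anc <- random_protein(300)
  ab <- mutate_protein(anc, 0.25)
  cd <- mutate_protein(anc, 0.25)
  aln <- rbind(A = strsplit(mutate_protein(ab, 0.05), "")[[1]],
               B = strsplit(mutate_protein(ab, 0.05), "")[[1]],
               C = strsplit(mutate_protein(cd, 0.05), "")[[1]],
               D = strsplit(mutate_protein(cd, 0.05), "")[[1]])
  st <- build_nj_bootstrap(aln, reps = 50, seed = 1)
  expect_true(hgtcensus:::has_split(st$tree, c("A", "B")))
  expect_gt(split_support(st, c("A", "B")), 95)
})

test_that("NJ topology matches the generating tree on additive distance matrices", {
  set.seed(33)
  for (k in 1:20) {
    ntax <- sample(4:6, 1)
    tr <- ape::rtree(ntax, br = function(n) runif(n, 0.2, 1))
    d <- ape::cophenetic.phylo(tr)
    got <- ape::nj(d)
    ref <- min(tr$tip.label)
    expect_setequal(
      hgtcensus:::tree_split_set(got, ref, got$tip.label),
      hgtcensus:::tree_split_set(ape::unroot(tr), ref, tr$tip.label))
  }
})

test_that("bootstrap support is exact under exhaustive enumeration of tiny resamples", {
  # 4 columns, every one of the 4^4 = 256 equally likely resamples is
  # enumerated; a clean two-clade signal in every column yields support
  # 100 for the (A,B) split in every resample, so the estimate must be 100
  aln <- rbind(A = c("A", "C", "D", "E"),
               B = c("A", "C", "D", "E"),
               C = c("W", "Y", "F", "H"),
               D = c("W", "Y", "F", "H"))
  combos <- expand.grid(rep(list(1:4), 4))
  all_support <- all(apply(combos, 1, function(cols) {
    tr <- ape::nj(poisson_dist(aln[, as.integer(cols), drop = FALSE]))
    hgtcensus:::has_split(tr, c("A", "B"))
  }))
  expect_true(all_support)
  st <- build_nj_bootstrap(aln, reps = 100, seed = 5)
  expect_equal(split_support(st, c("A", "B")), 100)
})

test_that("bootstrap trees are deterministic under a fixed seed", {
  set.seed(34)
  aln <- do.call(rbind, lapply(1:5, function(i)
    strsplit(random_protein(40), "")[[1]]))
  rownames(aln) <- paste0("s", 1:5)
  s1 <- build_nj_bootstrap(aln, reps = 30, seed = 9)
  s2 <- build_nj_bootstrap(aln, reps = 30, seed = 9)
  expect_equal(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_equal(s1$boot_splits, s2$boot_splits)
})

test_that("rooting uses an archaeal outgroup clade when one exists", {
  taxa <- toy_taxa()
  cfg <- toy_focal()
  leaf_orgs <- c(ma_1 = "ma", mb_1 = "mb", c1_1 = "c1", c2_1 = "c2",
                 ar1_1 = "ar1", ar2_1 = "ar2")
  phy <- ape::read.tree(
    text = "(((ma_1:1,mb_1:1):1,(c1_1:1,c2_1:1):1):1,(ar1_1:1,ar2_1:1):2);")
  rooted <- root_tree(ape::unroot(phy), leaf_orgs, taxa, cfg)
  kids <- lapply(rooted$edge[rooted$edge[, 1] ==
                               length(rooted$tip.label) + 1L, 2],
                 function(n) sort(hgtcensus:::tips_under(rooted, n)))
  expect_true(any(vapply(kids, identical, TRUE,
                         y = c("ar1_1", "ar2_1"))))
})

test_that("rooting falls back to the divergence of the two largest bacterial groups", {
  taxa <- toy_taxa()
  cfg <- toy_focal()
  # two phyla (Firmicutes: c*, f*; Proteobacteria: p*) split by one edge
  leaf_orgs <- c(c1_1 = "c1", c2_1 = "c2", f1_1 = "f1",
                 p1_1 = "p1", p2_1 = "p2", ma_1 = "ma")
  phy <- ape::read.tree(text = paste0(
    "((c1_1:1,(c2_1:1,f1_1:1):0.5):2,((p1_1:1,p2_1:1):1,ma_1:3):2);"))
  rooted <- root_tree(ape::unroot(phy), leaf_orgs, taxa, cfg)
  kids <- lapply(rooted$edge[rooted$edge[, 1] ==
                               length(rooted$tip.label) + 1L, 2],
                 function(n) sort(hgtcensus:::tips_under(rooted, n)))
  expect_true(any(vapply(kids, identical, TRUE,
                         y = c("c1_1", "c2_1", "f1_1"))))
  expect_error(root_tree(ape::read.tree(text = "(a:1,(b:1,c:1):1);"),
                         leaf_orgs, taxa, cfg), "fewer than 4")
})

# Build a support_tree directly from a newick string with full support on
# every split, so call conditions can be tested in isolation.
fake_support_tree <- function(nwk, support = 100) {
  phy <- ape::read.tree(text = nwk)
  ref <- min(phy$tip.label)
  splits <- hgtcensus:::tree_split_set(phy, ref, phy$tip.label)
  n_yes <- support          # out of 100 replicates
  boot <- c(rep(list(splits), n_yes),
            rep(list(character(0)), 100 - n_yes))
  structure(list(tree = phy, boot_splits = boot, reps = 100, ref_tip = ref),
            class = "support_tree")
}

test_that("transfer calls require monophyly, support and a bacterial context", {
  taxa <- toy_taxa()
  cfg <- toy_focal()
  leaf_orgs <- c(ma_1 = "ma", mb_1 = "mb", c1_1 = "c1", c2_1 = "c2",
                 p1_1 = "p1", ar1_1 = "ar1", ar2_1 = "ar2")
  nwk <- "((((ma_1:1,mb_1:1):1,(c1_1:1,c2_1:1):1):1,p1_1:2):1,(ar1_1:1,ar2_1:1):1);"
  members <- c("ma_1", "mb_1")

  st <- fake_support_tree(nwk, support = 86)
  cl <- call_hgt(st, NULL, members, leaf_orgs, taxa, cfg)
  expect_equal(cl$timing, "genus_ancestor")
  expect_equal(cl$focal_clade_support, 86)
  expect_setequal(cl$context_leaves, c("c1_1", "c2_1"))
  # donor: two Firmicutes genomes sharing class Clostridia
  expect_equal(cl$donor_rank, "class")
  expect_equal(cl$donor_name, "Clostridia")

  # same topology at support 65: below the threshold, no call
  expect_null(call_hgt(fake_support_tree(nwk, support = 65), NULL,
                       members, leaf_orgs, taxa, cfg))

  # an archaeon inside the containing clade kills the call
  nwk_bad <- "((((ma_1:1,mb_1:1):1,(ar1_1:1,c2_1:1):1):1,p1_1:2):1,(c1_1:1,ar2_1:1):1);"
  expect_null(call_hgt(fake_support_tree(nwk_bad, support = 99), NULL,
                       members, leaf_orgs, taxa, cfg))

  # non-monophyletic focal leaves: no call
  nwk_split <- "(((ma_1:1,c1_1:1):1,(mb_1:1,c2_1:1):1):1,(ar1_1:1,ar2_1:1):1);"
  expect_null(call_hgt(fake_support_tree(nwk_split, support = 99), NULL,
                       members, leaf_orgs, taxa, cfg))

  # an agreeing ML tree is recorded; a disagreeing one vetoes
  ml_ok <- ape::read.tree(text = nwk)
  cl2 <- call_hgt(st, ml_ok, members, leaf_orgs, taxa, cfg)
  expect_equal(cl2$agreeing_trees, c("NJ", "ML"))
  nwk_split7 <- "((((ma_1:1,c1_1:1):1,(mb_1:1,c2_1:1):1):1,p1_1:2):1,(ar1_1:1,ar2_1:1):1);"
  ml_bad <- ape::read.tree(text = nwk_split7)
  expect_null(call_hgt(st, ml_bad, members, leaf_orgs, taxa, cfg))
  expect_error(call_hgt(st, ape::read.tree(text = "(a:1,(b:1,(c1_1:1,ma_1:1):1):1);"),
                        members, leaf_orgs, taxa, cfg), "leaf sets")
})

test_that("timing classification distinguishes the three event classes", {
  taxa <- toy_taxa()
  cfg <- toy_focal()
  leaf_orgs <- c(ma_1 = "ma", mb_1 = "mb", fx_1 = "fx",
                 c1_1 = "c1", c2_1 = "c2", f1_1 = "f1", p1_1 = "p1")
  ctx <- c("c1_1", "c2_1")
  # two focal species, no other family: genus ancestor
  td <- classify_timing_and_donor(c("ma_1", "mb_1"), ctx, leaf_orgs, taxa,
                                  cfg)
  expect_equal(td$timing, "genus_ancestor")
  # two focal plus another family species: family ancestor
  td2 <- classify_timing_and_donor(c("ma_1", "mb_1", "fx_1"), ctx,
                                   leaf_orgs, taxa, cfg)
  expect_equal(td2$timing, "family_ancestor")
  # one focal species: species specific
  td3 <- classify_timing_and_donor("ma_1", ctx, leaf_orgs, taxa, cfg)
  expect_equal(td3$timing, "species_specific")
  # donor from mixed phyla collapses to unclassified bacteria
  td4 <- classify_timing_and_donor("ma_1", c("c1_1", "p1_1"), leaf_orgs,
                                   taxa, cfg)
  expect_equal(td4$donor_rank, "domain")
  expect_equal(td4$donor_name, "unclassified bacteria")
  # Firmicutes of different classes share the phylum
  td5 <- classify_timing_and_donor("ma_1", c("c1_1", "f1_1"), leaf_orgs,
                                   taxa, cfg)
  expect_equal(td5$donor_rank, "phylum")
  expect_equal(td5$donor_name, "Firmicutes")
})

test_that("no call ever fires when archaea contaminate the focal context", {
  # property over random labelled topologies
  taxa <- toy_taxa()
  cfg <- toy_focal()
  set.seed(35)
  bact <- c("c1", "c2", "p1", "p2", "f1", "f2")
  for (k in 1:40) {
    n_extra <- sample(3:6, 1)
    orgs <- c("ma", "mb", sample(c(bact, "ar1", "ar2"), n_extra,
                                 replace = TRUE))
    ids <- sprintf("%s_%d", orgs, seq_along(orgs))
    leaf_orgs <- stats::setNames(orgs, ids)
    tr <- ape::rtree(length(ids), tip.label = sample(ids))
    st <- fake_support_tree(ape::write.tree(tr))
    cl <- call_hgt(st, NULL, ids[1:2], leaf_orgs, taxa, cfg)
    if (!is.null(cl))
      expect_true(all(leaf_orgs[cl$context_leaves] %in% bact))
  }
})

test_that("support thresholds act monotonically on calls", {
  taxa <- toy_taxa()
  leaf_orgs <- c(ma_1 = "ma", mb_1 = "mb", c1_1 = "c1", c2_1 = "c2",
                 p1_1 = "p1", ar1_1 = "ar1", ar2_1 = "ar2")
  nwk <- "((((ma_1:1,mb_1:1):1,(c1_1:1,c2_1:1):1):1,p1_1:2):1,(ar1_1:1,ar2_1:1):1);"
  members <- c("ma_1", "mb_1")
  calls_at <- function(minsup, support) {
    cfg <- toy_focal(support_min = minsup)
    !is.null(call_hgt(fake_support_tree(nwk, support = support), NULL,
                      members, leaf_orgs, taxa, cfg))
  }
  for (support in c(40, 71, 90)) {
    fired <- vapply(c(10, 30, 50, 70, 90), calls_at, TRUE,
                    support = support)
    expect_true(all(diff(as.integer(fired)) <= 0))  # never re-fires
  }
})

test_that("rooting and calling are invariant to leaf-order permutations", {
  taxa <- toy_taxa()
  cfg <- toy_focal()
  leaf_orgs <- c(ma_1 = "ma", mb_1 = "mb", c1_1 = "c1", c2_1 = "c2",
                 ar1_1 = "ar1", ar2_1 = "ar2")
  phy <- ape::read.tree(
    text = "(((ma_1:1,mb_1:1):1,(c1_1:1,c2_1:1):1):1,(ar1_1:1,ar2_1:1):2);")
  base <- NULL
  set.seed(36)
  for (k in 1:5) {
    p <- ape::rotateConstr(phy, sample(phy$tip.label))
    st <- fake_support_tree(ape::write.tree(p))
    st <- root_tree(st, leaf_orgs, taxa, cfg)
    cl <- call_hgt(st, NULL, c("ma_1", "mb_1"), leaf_orgs, taxa, cfg)
    expect_false(is.null(cl))
    key <- list(cl$timing, sort(cl$context_leaves), cl$donor_name)
    if (is.null(base)) base <- key else expect_equal(key, base)
  }
})
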