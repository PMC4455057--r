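# BBH pairing, the paralog rule, connected components and GOP filters.

test_that("find_bbh keeps mutual best pairs passing identity and length filters", {
  lens <- c(a1 = 100L, a2 = 100L, b1 = 100L, b2 = 100L)
  hits_ab <- list(
    a1 = hit_list(hit_row("a1", "b1", 300, identity = 60, hsp_length = 80),
                  hit_row("a1", "b2", 200, identity = 55, hsp_length = 80)),
    a2 = hit_list(hit_row("a2", "b2", 250, identity = 58, hsp_length = 80)))
  hits_ba <- list(
    b1 = hit_list(hit_row("b1", "a1", 300, identity = 60, hsp_length = 80)),
    b2 = hit_list(hit_row("b2", "a2", 250, identity = 58, hsp_length = 80),
                  hit_row("b2", "a1", 200, identity = 55, hsp_length = 80)))
  bbh <- find_bbh(hits_ab, hits_ba, lens, min_identity = 50)
  expect_setequal(paste(bbh$protein_a, bbh$protein_b),
                  c("a1 b1", "a2 b2"))

  # non-mutual: a1's best is b1, but b1's best is a2 -> no pair for a1
  hits_ba2 <- list(
    b1 = hit_list(hit_row("b1", "a2", 400, identity = 70, hsp_length = 80),
                  hit_row("b1", "a1", 300, identity = 60, hsp_length = 80)))
  bbh2 <- find_bbh(hits_ab["a1"], hits_ba2, lens, min_identity = 50)
  expect_equal(nrow(bbh2), 0L)
})

test_that("the genus and family identity cutoffs act as specified", {
  # mutual top with identity 45: rejected at 50, accepted at 40
  lens <- c(a1 = 90L, b1 = 90L)
  hab <- list(a1 = hit_list(hit_row("a1", "b1", 200, identity = 45,
                                    hsp_length = 80)))
  hba <- list(b1 = hit_list(hit_row("b1", "a1", 200, identity = 45,
                                    hsp_length = 80)))
  expect_equal(nrow(find_bbh(hab, hba, lens, min_identity = 50)), 0L)
  expect_equal(nrow(find_bbh(hab, hba, lens, min_identity = 40)), 1L)

  # aligned region shorter than 2/3 of the shorter protein: rejected
  hab2 <- list(a1 = hit_list(hit_row("a1", "b1", 200, identity = 60,
                                     hsp_length = 50)))
  hba2 <- list(b1 = hit_list(hit_row("b1", "a1", 200, identity = 60,
                                     hsp_length = 50)))
  expect_equal(nrow(find_bbh(hab2, hba2, lens, min_identity = 50)), 0L)
  expect_equal(nrow(find_bbh(hab2, hba2, c(a1 = 60L, b1 = 90L),
                             min_identity = 50)), 1L)
})

test_that("find_bbh is symmetric in organism order", {
  set.seed(21)
  lens <- c(a1 = 100L, a2 = 100L, b1 = 100L, b2 = 100L)
  hits_ab <- list(
    a1 = hit_list(hit_row("a1", "b1", 310), hit_row("a1", "b2", 190)),
    a2 = hit_list(hit_row("a2", "b1", 220), hit_row("a2", "b2", 260)))
  hits_ba <- list(
    b1 = hit_list(hit_row("b1", "a1", 310), hit_row("b1", "a2", 220)),
    b2 = hit_list(hit_row("b2", "a1", 190), hit_row("b2", "a2", 260)))
  fwd <- find_bbh(hits_ab, hits_ba, lens, 50)
  rev <- find_bbh(hits_ba, hits_ab, lens, 50)
  expect_setequal(paste(fwd$protein_a, fwd$protein_b),
                  paste(rev$protein_b, rev$protein_a))
})

test_that("the paralog rule adds same-organism partners closer than the BBH partner", {
  pairs <- find_bbh(
    list(a1 = hit_list(hit_row("a1", "b1", 300))),
    list(b1 = hit_list(hit_row("b1", "a1", 300))),
    c(a1 = 100L, b1 = 100L), 50)
  # paralog a1p closer to a1 (500) than a1 to b1 (300): added
  intra <- list(a1 = hit_list(hit_row("a1", "a1p", 500)))
  edges <- expand_with_paralogs(pairs, intra)
  expect_true(any(edges$from == "a1" & edges$to == "a1p"))
  # weaker paralog (200 < 300): not added
  intra2 <- list(a1 = hit_list(hit_row("a1", "a1p", 200)))
  edges2 <- expand_with_paralogs(pairs, intra2)
  expect_false(any(edges2$to == "a1p"))
  # no intra hits: output equals the BBH edges
  edges3 <- expand_with_paralogs(pairs, list())
  expect_equal(nrow(edges3), 1L)
})

test_that("GOPs are connected components; singletons become orphans", {
  prot <- data.frame(
    protein_id = c("a", "b", "c", "d", "e", "lonely"),
    organism_id = c("ma", "mb", "mc", "ma", "mb", "mc"),
    sequence = "MK", stringsAsFactors = FALSE)
  edges <- data.frame(from = c("a", "b", "d"), to = c("b", "c", "e"),
                      stringsAsFactors = FALSE)
  res <- build_gops(edges, prot)
  expect_equal(nrow(res$gops), 2L)
  expect_setequal(res$gops$members[[1]], c("a", "b", "c"))
  expect_setequal(res$gops$members[[2]], c("d", "e"))
  expect_equal(res$orphans, "lonely")
  expect_false(any(res$gops$has_paralogs))

  # paralog flag: two members from one organism
  edges2 <- data.frame(from = "a", to = "d", stringsAsFactors = FALSE)
  res2 <- build_gops(edges2, prot)
  expect_true(res2$gops$has_paralogs[1])

  # no edges at all: zero GOPs, all orphans
  res3 <- build_gops(edges[0, ], prot)
  expect_equal(nrow(res3$gops), 0L)
  expect_equal(length(res3$orphans), 6L)
})

test_that("components agree with a union-find oracle on random graphs", {
  set.seed(22)
  for (k in 1:30) {
    n <- sample(5:25, 1)
    ids <- sprintf("p%02d", 1:n)
    orgs <- sample(c("ma", "mb", "mc", "fx", "fy"), n, replace = TRUE)
    prot <- data.frame(protein_id = ids, organism_id = orgs,
                       sequence = "MK", stringsAsFactors = FALSE)
    m <- sample(0:(2 * n), 1)
    edges <- data.frame(from = sample(ids, m, replace = TRUE),
                        to = sample(ids, m, replace = TRUE),
                        stringsAsFactors = FALSE)
    edges <- edges[edges$from != edges$to, , drop = FALSE]
    res <- build_gops(edges, prot)
    got <- lapply(res$gops$members, sort)
    oracle <- union_find_components(unique(c(edges$from, edges$to)), edges)
    oracle <- oracle[vapply(oracle, length, 1L) >= 2L]
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(oracle, paste, "", collapse = ","))
    # partition property: non-orphans covered exactly once
    expect_equal(sort(unname(c(unlist(got), res$orphans))), sort(ids))
  }
})

test_that("GOP filters drop transposase majorities, redundant and non-focal family GOPs", {
  mk_gop <- function(id, scope, members, orgs) {
    g <- data.frame(gop_id = id, scope = scope,
                    n_members = length(members), stringsAsFactors = FALSE)
    g$members <- I(list(members))
    g$species <- I(list(unique(orgs)))
    g$has_paralogs <- FALSE
    g
  }
  ann <- data.frame(
    protein_id = c("t1", "t2", "t3", "n1", "ma_1", "mb_1", "fx_1", "fy_1"),
    is_transposase = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  cfg <- toy_focal()

  # 3 of 4 transposases: dropped; 2 of 4: kept (strict majority required)
  g_tx <- rbind(mk_gop("g1", "genus", c("t1", "t2", "t3", "n1"),
                       c("ma", "mb", "mc", "ma")),
                mk_gop("g2", "genus", c("t1", "t2", "ma_1", "mb_1"),
                       c("ma", "mb", "ma", "mb")))
  f_empty <- g_tx[0, ]
  out <- filter_gops(g_tx, f_empty, ann, cfg)
  expect_equal(out$genus$gop_id, "g2")

  genus <- mk_gop("g3", "genus", c("ma_1", "mb_1"), c("ma", "mb"))
  fam <- rbind(
    # same member set as a genus GOP: redundant, dropped
    mk_gop("f1", "family", c("ma_1", "mb_1"), c("ma", "mb")),
    # extends the genus GOP with a family member: kept
    mk_gop("f2", "family", c("ma_1", "mb_1", "fx_1"), c("ma", "mb", "fx")),
    # no focal-species member: dropped
    mk_gop("f3", "family", c("fx_1", "fy_1"), c("fx", "fy")))
  out2 <- filter_gops(genus, fam, ann, cfg)
  expect_equal(out2$family$gop_id, "f2")
  expect_equal(out2$genus$gop_id, "g3")
})
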