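test_that("edge list reading collapses symmetric duplicates and keeps max score", {
  p <- tempfile()
  writeLines(c("P1 P2 700", "P2 P1 700", "P1 P3 150", "P2 P3 301",
               "P1 P2 650"), p)
  el <- load_edge_list(p)
  expect_equal(nrow(el), 3)
  r <- el[el$protein_a == "P1" & el$protein_b == "P2", ]
  expect_equal(r$combined_score, 700L)
  expect_setequal(el$combined_score, c(700L, 150L, 301L))
})

test_that("edge list reading tolerates a header and reads scores back verbatim", {
  p <- tempfile()
  writeLines(c("protein1 protein2 combined_score",
               "A B 150", "A C 301", "B C 999"), p)
  el <- load_edge_list(p)
  expect_equal(nrow(el), 3)
  expect_setequal(el$combined_score, c(150L, 301L, 999L))
})

test_that("malformed edge rows produce parse errors naming the line", {
  p <- tempfile()
  writeLines(c("P1 P2 700", "P1 P2 abc"), p)
  expect_error(load_edge_list(p), "line 2")
  writeLines(c("P1 P2 700", "P1 P2"), p)
  expect_error(load_edge_list(p), "line 2.*3 columns")
  writeLines(c("P1 P2 1700"), p)
  expect_error(load_edge_list(p), "\\[0, 1000\\]")
})

test_that("true path propagation closes a chain and a diamond", {
  chain <- make_dag(list(root = character(0), A = "root", B = "A"))
  ann <- data.frame(protein = "g1", term = "B")
  out <- propagate_true_path(ann, chain)
  expect_setequal(out$term, c("B", "A", "root"))
  expect_true(attr(out, "propagated"))

  diamond <- make_dag(list(root = character(0), B = "root", C = "root",
                           D = c("B", "C")))
  out2 <- propagate_true_path(data.frame(protein = "g1", term = "D"), diamond)
  expect_equal(nrow(out2), 4)
  expect_setequal(out2$term, c("root", "B", "C", "D"))
})

test_that("propagation is idempotent and errors on unknown terms", {
  dag <- make_dag(list(root = character(0), A = "root"))
  once <- propagate_true_path(data.frame(protein = "g1", term = "A"), dag)
  twice <- propagate_true_path(once, dag)
  expect_equal(as.data.frame(once), as.data.frame(twice))
  expect_error(
    propagate_true_path(data.frame(protein = "g1", term = "ZZZ"), dag),
    "ZZZ")
})

test_that("propagation matches a transitive-closure oracle on random DAGs", {
  for (seed in 1:10) {
    parents <- random_dag(8, seed)
    dag <- make_dag(parents)
    R <- closure_oracle(parents)
    ann <- withr::with_seed(seed + 100, {
      data.frame(
        protein = sample(paste0("g", 1:4), 6, replace = TRUE),
        term = sample(names(parents), 6, replace = TRUE))
    })
    out <- propagate_true_path(ann, dag)
    # oracle: each pair plus all reachable ancestors
    expected <- unique(do.call(rbind, lapply(seq_len(nrow(ann)), function(i) {
      anc <- names(which(R[ann$term[i], ]))
      data.frame(protein = ann$protein[i], term = c(ann$term[i], anc))
    })))
    expect_setequal(paste(out$protein, out$term),
                    paste(expected$protein, expected$term))
    # monotonicity: output at least as large, per-term counts non-decreasing
    # from child to parent
    expect_gte(nrow(out), nrow(unique(ann)))
    cnt <- table(factor(out$term, levels = names(parents)))
    for (tt in names(parents)) {
      for (pp in parents[[tt]]) expect_gte(cnt[[pp]], cnt[[tt]])
    }
  }
})

test_that("frequency filter removes terms at the boundary count", {
  # term T10 has exactly 10 proteins (removed), T11 has 11 (kept)
  ann <- rbind(
    data.frame(protein = paste0("p", 1:10), term = "T10"),
    data.frame(protein = paste0("p", 1:11), term = "T11")
  )
  out <- filter_terms_by_frequency(ann, 10)
  expect_equal(out$removed, "T10")
  expect_setequal(unique(out$annotations$term), "T11")

  all_gone <- filter_terms_by_frequency(
    data.frame(protein = "p1", term = "T1"), 10)
  expect_equal(nrow(all_gone$annotations), 0)
  expect_equal(all_gone$removed, "T1")
})

test_that("frequency groups split at the documented bracket boundaries", {
  mk <- function(n, tt) data.frame(protein = paste0("p", seq_len(n)), term = tt)
  ann <- rbind(mk(1, "a1"), mk(3, "a3"), mk(4, "a4"), mk(10, "a10"),
               mk(11, "a11"), mk(30, "a30"), mk(31, "a31"), mk(100, "a100"),
               mk(101, "a101"), mk(300, "a300"), mk(301, "a301"))
  g <- group_terms_by_frequency(ann)
  expect_equal(unname(g[c("a1", "a3")]), rep("Very rare", 2))
  expect_equal(unname(g[c("a4", "a10")]), rep("Rare", 2))
  expect_equal(unname(g[c("a11", "a30")]), rep("Uncommon", 2))
  expect_equal(unname(g[c("a31", "a100")]), rep("Common", 2))
  expect_equal(unname(g[c("a101", "a300")]), rep("Very common", 2))
  expect_equal(unname(g["a301"]), "Extremely common")
  # partition: every term gets exactly one label
  expect_equal(sort(names(g)), sort(unique(ann$term)))
})

test_that("negative sampling is balanced, disjoint, seeded, and fails when infeasible", {
  uni <- paste0("p", 1:20)
  pos <- data.frame(protein = paste0("p", 1:5), term = "T1")
  neg1 <- sample_negatives(pos, uni, seed = 11)
  neg2 <- sample_negatives(pos, uni, seed = 11)
  neg3 <- sample_negatives(pos, uni, seed = 12)
  expect_equal(nrow(neg1), 5)
  expect_length(intersect(neg1$protein, pos$protein), 0)
  expect_identical(neg1, neg2)
  expect_false(identical(neg1$protein, neg3$protein))
  expect_error(sample_negatives(pos, paste0("p", 1:8), seed = 1),
               "T1")
})

test_that("OBO parsing recovers terms, is_a edges and roots", {
  path <- write_obo(list(root = character(0), A = "root", B = "A"))
  dag <- load_ontology(path)
  expect_setequal(dag$terms, c("root", "A", "B"))
  expect_equal(dag$roots, "root")
  expect_equal(dag$parents[["B"]], "A")
  # trailing "! name" comments are stripped
  p2 <- tempfile()
  writeLines(c("[Term]", "id: HP:1", "", "[Term]", "id: HP:2",
               "is_a: HP:1 ! some name"), p2)
  dag2 <- load_ontology(p2)
  expect_equal(dag2$parents[["HP:2"]], "HP:1")
  # cycles are rejected
  p3 <- write_obo(list(A = "B", B = "A"))
  expect_error(load_ontology(p3), "cycle")
})

test_that("universe alignment intersects sources and errors when empty", {
  expect_message(
    uni <- align_universe(c("P1", "P2", "P3"), c("P2", "P3", "P4")),
    "dropped")
  expect_equal(uni, c("P2", "P3"))
  expect_error(align_universe("P1", "P2"), "no proteins shared")
})

test_that("gold standard invariants hold on the synthetic fixture", {
  sf <- small_fixture(1)
  gold <- sf$gold
  # positives and negatives disjoint; balanced per term
  key_pos <- paste(gold$positives$protein, gold$positives$term)
  key_neg <- paste(gold$negatives$protein, gold$negatives$term)
  expect_length(intersect(key_pos, key_neg), 0)
  np <- table(gold$positives$term)
  nn <- table(gold$negatives$term)
  expect_equal(np[order(names(np))], nn[order(names(nn))])
  # every retained term exceeds the frequency cutoff
  expect_true(all(np > 10))
  # term universe is lexicographic and matches the positives
  expect_equal(gold$term_universe, sort(unique(gold$positives$term)))
  # closed under ancestors within the retained term set
  anc <- term_ancestors(sf$onto, gold$term_universe)
  for (tt in gold$term_universe) {
    kept_anc <- intersect(anc[[tt]], gold$term_universe)
    if (!length(kept_anc)) next
    prot <- gold$positives$protein[gold$positives$term == tt]
    for (aa in kept_anc) {
      expect_true(all(prot %in%
        gold$positives$protein[gold$positives$term == aa]))
    }
  }
})
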