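# Shared helpers: tiny in-code fixtures and independent oracles.

# Build an ontology_dag directly from a named parent list, e.g.
# make_dag(list(root = character(0), A = "root", B = "A")).
make_dag <- function(parents) {
  ids <- sort(names(parents))
  structure(
    list(terms = ids, parents = parents[ids],
         roots = ids[lengths(parents[ids]) == 0]),
    class = "ontology_dag"
  )
}

# Write a parent list as a minimal OBO file and return the path.
write_obo <- function(parents, path = tempfile(fileext = ".obo")) {
  lines <- c("format-version: 1.2", "")
  for (id in names(parents)) {
    lines <- c(lines, "[Term]", paste0("id: ", id),
               paste0("name: ", id),
               if (length(parents[[id]])) paste0("is_a: ", parents[[id]]),
               "")
  }
  writeLines(lines, path)
  path
}

# Random DAG over n terms: term i > 1 gets 1-2 parents among earlier terms.
random_dag <- function(n, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("T%02d", seq_len(n))
    parents <- stats::setNames(vector("list", n), ids)
    parents[[1]] <- character(0)
    for (i in seq(2, n)) {
      k <- sample(1:min(2, i - 1), 1)
      parents[[ids[i]]] <- ids[sample(i - 1, k)]
    }
    parents
  })
}

# Independent ancestor-closure oracle: boolean reachability by repeated
# multiplication of the parent adjacency matrix.
closure_oracle <- function(parents) {
  ids <- names(parents)
  n <- length(ids)
  P <- matrix(FALSE, n, n, dimnames = list(ids, ids)) # child -> parent
  for (id in ids) P[id, parents[[id]]] <- TRUE
  R <- P
  repeat {
    R2 <- R | (R %*% P > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

# Independent Mann-Whitney AUC oracle: pairwise concordance counting with
# half-credit for ties.
mw_auc_oracle <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Naive triple-loop conjoint-triad counter used as the encoding oracle.
ct_oracle <- function(sequence) {
  cls <- amino_class(strsplit(toupper(sequence), "")[[1]])
  cls <- cls[!is.na(cls)]
  v <- numeric(343)
  if (length(cls) >= 3) {
    for (i in seq_len(length(cls) - 2)) {
      idx <- (cls[i] - 1) * 49 + (cls[i + 1] - 1) * 7 + cls[i + 2]
      v[idx] <- v[idx] + 1
    }
  }
  v
}

# Small labeled toy gold standard over explicit pairs.
toy_gold <- function(proteins, terms, positives, negatives) {
  structure(
    list(positives = positives, negatives = negatives,
         term_universe = sort(terms), protein_universe = sort(proteins),
         removed_rare = character(0), removed_common = character(0),
         seed = 1),
    class = "gold_standard"
  )
}

# A small planted fixture parsed back through the loaders; memoized per
# session so several test files can share it cheaply.
small_fixture_env <- new.env()
small_fixture <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(small_fixture_env[[key]])) {
    dir <- file.path(tempdir(), paste0("gaephen_fx_", seed))
    fx <- make_fixture(fixture_config(seed = seed), dir = dir)
    el <- load_edge_list(fx$paths[["edges"]])
    seqs <- load_sequences(fx$paths[["fasta"]])
    onto <- load_ontology(fx$paths[["obo"]])
    ann <- load_annotations(fx$paths[["annotations"]])
    uni <- suppressMessages(
      align_universe(c(el$protein_a, el$protein_b), names(seqs), ann$protein))
    gold <- suppressMessages(
      build_gold_standard(ann, onto, uni, seed = seed))
    small_fixture_env[[key]] <- list(
      fx = fx, edges = el, seqs = seqs, onto = onto, ann = ann,
      universe = uni, gold = gold,
      X = ct_encode_matrix(seqs[uni]),
      graph = build_adjacency(el, uni))
  }
  small_fixture_env[[key]]
}
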