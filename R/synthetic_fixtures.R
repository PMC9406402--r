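# Self-contained synthetic inputs with planted, recoverable signal: a
# stochastic-block-model interaction graph, sequences with block-specific
# residue-class composition, a random tree ontology, and block-aligned term
# annotations. Everything the pipeline consumes can be generated here, so
# the package builds and tests without any download.

#' Fixture generator configuration
#'
#' Defaults describe the benchmark conditions used throughout the test
#' suite: a 60-protein, two-block stochastic block model (within-block edge
#' probability 0.5, between-block 0.05) with confidence scores uniform on
#' 400-999, sequences of 80-120 residues whose residue-class composition is
#' biased by block, a 40-term tree ontology of depth 3, and 20 annotated
#' leaf terms whose positives concentrate in one block with probability
#' `label_block_alignment`.
#'
#' @param n_proteins number of proteins.
#' @param n_blocks number of blocks (communities).
#' @param within_edge_prob,between_edge_prob SBM edge probabilities.
#' @param score_low,score_high inclusive integer bounds for sampled
#'   combined scores (within 0-1000).
#' @param seq_length_range inclusive residue-count range for sequences.
#' @param n_terms total ontology terms (including the root).
#' @param ontology_depth tree depth (root at depth 0).
#' @param n_annotated_terms number of leaf terms receiving direct
#'   annotations.
#' @param positives_range inclusive range of directly annotated proteins
#'   per term.
#' @param label_block_alignment probability that a term's positives are
#'   drawn entirely from its home block (otherwise from all proteins).
#' @param seq_class_bias multiplicative weight on the block's favored
#'   residue classes.
#' @param seed integer seed; the whole fixture is a deterministic function
#'   of the configuration.
#' @return object of class `fixture_config`.
#' @export
fixture_config <- function(n_proteins = 60, n_blocks = 2,
                           within_edge_prob = 0.5, between_edge_prob = 0.05,
                           score_low = 400, score_high = 999,
                           seq_length_range = c(80, 120),
                           n_terms = 40, ontology_depth = 3,
                           n_annotated_terms = 20,
                           positives_range = c(12, 18),
                           label_block_alignment = 0.9,
                           seq_class_bias = 2, seed = 1) {
  cfg <- list(n_proteins = n_proteins, n_blocks = n_blocks,
              within_edge_prob = within_edge_prob,
              between_edge_prob = between_edge_prob,
              score_low = score_low, score_high = score_high,
              seq_length_range = seq_length_range, n_terms = n_terms,
              ontology_depth = ontology_depth,
              n_annotated_terms = n_annotated_terms,
              positives_range = positives_range,
              label_block_alignment = label_block_alignment,
              seq_class_bias = seq_class_bias, seed = seed)
  if (any(c(within_edge_prob, between_edge_prob,
            label_block_alignment) < 0) ||
      any(c(within_edge_prob, between_edge_prob,
            label_block_alignment) > 1)) {
    stop("fixture_config: probabilities must lie in [0, 1]")
  }
  if (score_low < 0 || score_high > 1000 || score_low > score_high) {
    stop("fixture_config: score bounds must satisfy 0 <= low <= high <= 1000")
  }
  if (n_blocks < 1 || n_proteins < n_blocks) {
    stop("fixture_config: need at least one protein per block")
  }
  if (ontology_depth < 1 || n_terms < 1 + n_blocks + 1) {
    stop("fixture_config: ontology too small for the requested structure")
  }
  block_size <- floor(n_proteins / n_blocks)
  if (max(positives_range) > block_size) {
    stop("fixture_config: positives_range exceeds the block size; terms cannot concentrate in one block")
  }
  n_internal_per_branch <- if (ontology_depth >= 3) 3L else 0L
  n_leaves <- n_terms - 1 - n_blocks - n_blocks * n_internal_per_branch
  if (n_leaves < n_annotated_terms) {
    stop("fixture_config: not enough leaf terms to annotate; increase n_terms or decrease n_annotated_terms")
  }
  structure(cfg, class = "fixture_config")
}

#' Generate a synthetic input bundle
#'
#' Writes the four pipeline inputs to `dir`: `edges.txt` (scored edge list
#' with header), `proteins.fasta`, `ontology.obo`, `annotations.tsv`
#' (un-propagated direct annotations). The planted structure: proteins are
#' split into equally sized blocks; edges follow the SBM; each sequence's
#' residue classes are biased toward the block's favored classes (block b
#' favors three of the seven conjoint-triad classes), so sequence features
#' also carry block signal; the ontology is a tree whose depth-1 branches
#' are each assigned a home block inherited by their descendants; each
#' annotated leaf term draws its positives entirely from its branch's home
#' block with probability `label_block_alignment`, otherwise uniformly
#' from all proteins. Fully deterministic given `config$seed`.
#'
#' @param config a [fixture_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `paths` (named file paths), `truth`
#'   (block membership, per-term home block and alignment flags, annotated
#'   terms), and `config`.
#' @export
make_fixture <- function(config = fixture_config(), dir = tempfile("fixture")) {
  cfg <- config
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- cfg$n_proteins
  nb <- cfg$n_blocks
  proteins <- sprintf("P%03d", seq_len(n))
  block <- rep(seq_len(nb), length.out = n)
  block <- sort(block) # contiguous blocks
  names(block) <- proteins

  # sample from the values of x even when x has length 1
  pick <- function(x, size, replace = FALSE, prob = NULL) {
    x[sample.int(length(x), size, replace = replace, prob = prob)]
  }

  with_seed(cfg$seed, {
    ## --- graph: stochastic block model with uniform confidence scores ---
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    p_edge <- ifelse(block[ut[, 1]] == block[ut[, 2]],
                     cfg$within_edge_prob, cfg$between_edge_prob)
    is_edge <- stats::runif(nrow(ut)) < p_edge
    e <- ut[is_edge, , drop = FALSE]
    scores <- pick(seq(cfg$score_low, cfg$score_high), nrow(e),
                   replace = TRUE)
    edges <- data.frame(protein1 = proteins[e[, 1]],
                        protein2 = proteins[e[, 2]],
                        combined_score = scores, stringsAsFactors = FALSE)

    ## --- sequences: block-biased residue-class composition ---
    classes <- ct_class_table()
    residues_by_class <- split(names(classes), classes)
    favored <- lapply(seq_len(nb), function(b) {
      # block b favors a contiguous band of three of the seven classes
      ((3 * (b - 1) + seq_len(3) - 1) %% 7) + 1
    })
    seqs <- vapply(seq_len(n), function(i) {
      w <- rep(1, 7)
      w[favored[[block[i]]]] <- cfg$seq_class_bias
      L <- pick(seq(cfg$seq_length_range[1], cfg$seq_length_range[2]), 1)
      cls <- sample.int(7, L, replace = TRUE, prob = w / sum(w))
      paste(vapply(cls, function(cc) {
        r <- residues_by_class[[cc]]
        r[sample.int(length(r), 1)]
      }, ""), collapse = "")
    }, "")
    names(seqs) <- proteins

    ## --- ontology: rooted tree; branches own home blocks ---
    root <- "HP:0000001"
    term_id <- function(i) sprintf("HP:%07d", i + 1)
    branches <- term_id(seq_len(nb))
    n_internal_per_branch <- if (cfg$ontology_depth >= 3) 3L else 0L
    internals <- list()
    next_id <- nb + 1L
    for (b in seq_len(nb)) {
      ids <- if (n_internal_per_branch > 0) {
        term_id(seq(next_id, length.out = n_internal_per_branch))
      } else character(0)
      next_id <- next_id + n_internal_per_branch
      internals[[b]] <- ids
    }
    n_leaves <- cfg$n_terms - 1 - nb - nb * n_internal_per_branch
    leaves <- term_id(seq(next_id, length.out = n_leaves))
    leaf_branch <- sample(rep_len(seq_len(nb), n_leaves))
    parent <- character(0)
    parent[branches] <- root
    for (b in seq_len(nb)) parent[internals[[b]]] <- branches[b]
    for (i in seq_len(n_leaves)) {
      b <- leaf_branch[i]
      cand <- if (length(internals[[b]])) internals[[b]] else branches[b]
      parent[leaves[i]] <- cand[sample.int(length(cand), 1)]
    }
    all_terms <- c(root, branches, unlist(internals), leaves)

    ## --- annotations: block-aligned leaf terms ---
    ann_terms <- sort(sample(leaves, cfg$n_annotated_terms))
    home <- stats::setNames(leaf_branch[match(ann_terms, leaves)], ann_terms)
    aligned <- stats::setNames(
      stats::runif(length(ann_terms)) < cfg$label_block_alignment, ann_terms)
    ann <- do.call(rbind, lapply(ann_terms, function(tt) {
      npos <- pick(seq(cfg$positives_range[1], cfg$positives_range[2]), 1)
      pool <- if (aligned[tt]) proteins[block == home[tt]] else proteins
      data.frame(protein = pick(pool, npos), term = tt,
                 stringsAsFactors = FALSE)
    }))
    ann <- ann[order(ann$protein, ann$term), ]

    ## --- write files ---
    paths <- c(edges = file.path(dir, "edges.txt"),
               fasta = file.path(dir, "proteins.fasta"),
               obo = file.path(dir, "ontology.obo"),
               annotations = file.path(dir, "annotations.tsv"))
    writeLines(c("protein1 protein2 combined_score",
                 sprintf("%s %s %d", edges$protein1, edges$protein2,
                         edges$combined_score)),
               paths[["edges"]])
    fasta <- unlist(lapply(proteins, function(p) {
      s <- seqs[[p]]
      c(paste0(">", p),
        substring(s, seq(1, nchar(s), 60), pmin(seq(60, nchar(s) + 59, 60), nchar(s))))
    }))
    writeLines(fasta, paths[["fasta"]])
    obo <- c("format-version: 1.2", "")
    for (tt in all_terms) {
      obo <- c(obo, "[Term]", paste0("id: ", tt),
               paste0("name: synthetic term ", tt),
               if (tt != root) paste0("is_a: ", parent[tt]), "")
    }
    writeLines(obo, paths[["obo"]])
    utils::write.table(ann, paths[["annotations"]], sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)

    invisible(list(
      paths = paths,
      truth = list(blocks = block, home_block = home, aligned = aligned,
                   annotated_terms = ann_terms, parent = parent),
      config = cfg
    ))
  })
}
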