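# The six comparison methods used in the ablation: term-frequency Naive,
# alignment-hit transfer, interaction-partner voting, sequence-only and
# graph-only autoencoder embeddings, and plain embedding concatenation.

#' Naive term-frequency baseline
#'
#' Scores every protein identically per term by the term's annotation count
#' normalized to the most frequent term, so ranking depends only on term
#' frequency. Because the score is constant across proteins, term-centric
#' AUC is degenerate for this baseline; it is meaningful only under
#' protein-centric evaluation.
#'
#' @param term_counts named integer vector of annotated-protein counts.
#' @return named numeric vector of per-term scores in (0, 1].
#' @export
naive_score <- function(term_counts) {
  if (!length(term_counts)) stop("naive_score: empty term counts")
  term_counts / max(term_counts)
}

#' Naive baseline score matrix
#'
#' @param gold a `gold_standard` (counts taken from its positives).
#' @param proteins row order (default the gold universe).
#' @return protein x term matrix with identical rows.
#' @export
naive_score_matrix <- function(gold, proteins = gold$protein_universe) {
  s <- naive_score(term_counts(gold$positives)[gold$term_universe])
  matrix(s, length(proteins), length(s), byrow = TRUE,
         dimnames = list(proteins, gold$term_universe))
}

#' Interaction-partner voting score
#'
#' Fraction of the query protein's interaction partners (self-loop
#' excluded) that are annotated to the term in the training set; zero for
#' proteins without partners.
#'
#' @param query protein id.
#' @param term term id.
#' @param graph a `protein_graph`.
#' @param train_annotations annotation data.frame of training positives.
#' @return score in [0, 1].
#' @export
neighbor_vote_score <- function(query, term, graph, train_annotations) {
  if (!query %in% graph$proteins) stop("neighbor_vote_score: unknown query protein")
  a <- graph$A[query, ]
  a[query] <- 0
  nb <- graph$proteins[a > 0]
  if (!length(nb)) return(0)
  annotated <- unique(train_annotations$protein[train_annotations$term == term])
  sum(nb %in% annotated) / length(nb)
}

#' Interaction-partner voting score matrix
#'
#' Vectorized [neighbor_vote_score()] over all proteins and terms.
#'
#' @param graph a `protein_graph`.
#' @param train_annotations annotation data.frame of training positives.
#' @param terms term order of the output columns.
#' @return protein x term score matrix in [0, 1].
#' @export
neighbor_vote_matrix <- function(graph, train_annotations,
                                 terms = sort(unique(train_annotations$term))) {
  nb <- (graph$A > 0) * 1
  diag(nb) <- 0
  deg <- rowSums(nb)
  P <- annotation_matrix(train_annotations, graph$proteins, terms)
  S <- (nb %*% P) / pmax(deg, 1)
  S[deg == 0, ] <- 0
  dimnames(S) <- list(graph$proteins, terms)
  S
}

#' Similarity hit table from k-mer cosine similarity
#'
#' A bundled surrogate for an external sequence-alignment run: proteins are
#' represented by k-mer count vectors and each query's `top_n` most
#' cosine-similar other proteins (similarity > 0) become its hits. An
#' externally produced hit table with the same shape (named list of
#' data.frames with `subject` and `score`) can be used interchangeably.
#'
#' @param sequences named character vector of amino-acid sequences.
#' @param k k-mer length.
#' @param top_n maximum number of hits per query.
#' @return named list mapping each protein to a data.frame (`subject`,
#'   `score`) sorted by decreasing similarity.
#' @export
kmer_hit_table <- function(sequences, k = 3, top_n = 10) {
  ids <- names(sequences)
  kmers <- lapply(sequences, function(s) {
    if (nchar(s) < k) return(character(0))
    substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
  })
  vocab <- sort(unique(unlist(kmers, use.names = FALSE)))
  M <- matrix(0, length(ids), length(vocab), dimnames = list(ids, vocab))
  for (i in seq_along(ids)) {
    tb <- table(kmers[[i]])
    M[i, names(tb)] <- as.numeric(tb)
  }
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm == 0] <- 1
  S <- tcrossprod(M / nrm)
  diag(S) <- -Inf # never hit yourself
  out <- lapply(seq_along(ids), function(i) {
    o <- order(S[i, ], decreasing = TRUE)
    o <- o[S[i, o] > 0][seq_len(min(top_n, sum(S[i, ] > 0)))]
    data.frame(subject = ids[o], score = S[i, o], stringsAsFactors = FALSE)
  })
  stats::setNames(out, ids)
}

#' Annotation transfer from similarity hits
#'
#' Fraction of the query's hits annotated to the term in the training set;
#' zero for queries without hits.
#'
#' @param query protein id.
#' @param term term id.
#' @param hits hit table (see [kmer_hit_table()]).
#' @param train_annotations annotation data.frame of training positives.
#' @return score in [0, 1].
#' @export
blast_transfer_score <- function(query, term, hits, train_annotations) {
  h <- hits[[query]]
  if (is.null(h) || !nrow(h)) return(0)
  annotated <- unique(train_annotations$protein[train_annotations$term == term])
  sum(h$subject %in% annotated) / nrow(h)
}

#' Annotation-transfer score matrix
#'
#' @param hits hit table.
#' @param train_annotations annotation data.frame of training positives.
#' @param proteins row order.
#' @param terms column order.
#' @return protein x term score matrix in [0, 1].
#' @export
blast_transfer_matrix <- function(hits, train_annotations, proteins,
                                  terms = sort(unique(train_annotations$term))) {
  S <- matrix(0, length(proteins), length(terms),
              dimnames = list(proteins, terms))
  P <- annotation_matrix(train_annotations,
                         unique(train_annotations$protein), terms)
  for (q in proteins) {
    h <- hits[[q]]
    if (is.null(h) || !nrow(h)) next
    subj <- intersect(h$subject, rownames(P))
    if (length(subj)) {
      S[q, ] <- colSums(P[subj, , drop = FALSE]) / nrow(h)
    }
  }
  S
}

#' Sequence-only embedding (graph-free autoencoder)
#'
#' Runs the autoencoder machinery with an identity adjacency, so the GCN
#' layers reduce to dense layers and only the sequence features inform the
#' embedding. This is the sequence-only ablation arm.
#'
#' @param X conjoint-triad feature matrix.
#' @param ... settings passed to [train_vgae()].
#' @return a `vgae_fit`.
#' @export
sequence_only_embedding <- function(X, ...) {
  n <- nrow(X)
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("p", seq_len(n))
  g <- structure(list(proteins = ids,
                      A = diag(n) * 1 + 0 * diag(n)),
                 class = "protein_graph")
  dimnames(g$A) <- list(ids, ids)
  train_vgae(X, g, ...)
}

#' Graph-only embedding (featureless autoencoder)
#'
#' Runs the graph autoencoder with one-hot identity node features, so only
#' the interaction topology informs the embedding. This is the network-only
#' ablation arm.
#'
#' @param graph a `protein_graph`.
#' @param ... settings passed to [train_vgae()].
#' @return a `vgae_fit`.
#' @export
ppi_only_embedding <- function(graph, ...) {
  n <- length(graph$proteins)
  X <- diag(n)
  rownames(X) <- graph$proteins
  train_vgae(X, graph, ...)
}

#' Concatenated embedding
#'
#' Column-binds two embeddings (e.g., the sequence-only and graph-only
#' arms), the simple integration protocol the autoencoder fusion is
#' compared against.
#'
#' @param fit_a,fit_b `vgae_fit` objects or embedding matrices with
#'   matching protein rownames.
#' @return matrix of width `ncol(a) + ncol(b)`.
#' @export
concat_embedding <- function(fit_a, fit_b) {
  ma <- if (inherits(fit_a, "vgae_fit")) fit_a$mu else fit_a
  mb <- if (inherits(fit_b, "vgae_fit")) fit_b$mu else fit_b
  if (!identical(rownames(ma), rownames(mb))) {
    mb <- mb[rownames(ma), , drop = FALSE]
  }
  cbind(ma, mb)
}
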