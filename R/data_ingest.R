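# Readers for the four input formats (scored edge list, FASTA, OBO, annotation
# TSV) and construction of the annotation gold standard: true-path-rule
# propagation, low-frequency term removal, frequency grouping and balanced
# negative sampling.

#' Read a scored protein-protein interaction edge list
#'
#' Parses the STRING protein-links dialect: whitespace-separated columns
#' `protein1 protein2 combined_score`, where the combined score is an integer
#' on a 0-1000 confidence scale. A single header line is tolerated (detected
#' by a non-numeric third field). Duplicate `(a,b)` / `(b,a)` rows are
#' collapsed keeping the maximum score. No confidence filtering happens here;
#' see [build_adjacency()].
#'
#' @param path path to the edge-list file.
#' @return a data.frame with columns `protein_a`, `protein_b`,
#'   `combined_score` (integer), one row per unordered protein pair.
#' @export
load_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- trimws(lines[keep])
  empty <- data.frame(protein_a = character(0), protein_b = character(0),
                      combined_score = integer(0), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "[[:space:]]+")
  start <- 1L
  f1 <- fields[[1]]
  if (length(f1) >= 3 && is.na(suppressWarnings(as.numeric(f1[3])))) {
    start <- 2L # header line
  }
  if (start > length(fields)) return(empty)
  fields <- fields[start:length(fields)]
  lineno <- lineno[start:length(lineno)]
  nfield <- lengths(fields)
  if (any(nfield < 3)) {
    bad <- lineno[which(nfield < 3)[1]]
    stop(sprintf("malformed edge row at line %d: fewer than 3 columns", bad))
  }
  a <- vapply(fields, `[`, "", 1L)
  b <- vapply(fields, `[`, "", 2L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(s) || any(s != round(s))) {
    bad <- lineno[which(is.na(s) | s != round(s))[1]]
    stop(sprintf("combined_score at line %d does not parse as an integer", bad))
  }
  if (any(s < 0 | s > 1000)) {
    bad <- lineno[which(s < 0 | s > 1000)[1]]
    stop(sprintf("combined_score at line %d outside [0, 1000]", bad))
  }
  # collapse symmetric duplicates, keeping the maximum score
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  smax <- tapply(s, key, max)
  first <- !duplicated(key)
  out <- data.frame(protein_a = lo[first], protein_b = hi[first],
                    combined_score = as.integer(smax[key[first]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read protein amino-acid sequences from FASTA
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences; names are the first
#'   whitespace-delimited token of each FASTA header.
#' @export
load_sequences <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read a phenotype ontology from an OBO 1.2 file
#'
#' Parses `[Term]` stanzas, keeping `id:` and `is_a:` fields; all other
#' relationship types are ignored (traversal of the term hierarchy uses
#' `is_a` only, the ontology convention for the true path rule). Terms
#' flagged `is_obsolete: true` are dropped, and `is_a` references to unknown
#' terms are discarded with a warning. The DAG is validated to be acyclic.
#'
#' @param path path to an OBO file.
#' @return an object of class `ontology_dag`: list with `terms` (sorted
#'   character vector), `parents` (named list of parent term ids) and
#'   `roots` (terms with no parents).
#' @export
load_ontology <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- c(trimws(readLines(path, warn = FALSE)), "[eof]")
  ids <- character(0)
  parents <- list()
  cur_id <- NA_character_
  cur_parents <- character(0)
  cur_obsolete <- FALSE
  in_term <- FALSE
  for (l in lines) {
    if (startsWith(l, "[")) {
      if (in_term && !is.na(cur_id) && !cur_obsolete) {
        ids <- c(ids, cur_id)
        parents[[cur_id]] <- unique(cur_parents)
      }
      in_term <- identical(l, "[Term]")
      cur_id <- NA_character_
      cur_parents <- character(0)
      cur_obsolete <- FALSE
      next
    }
    if (!in_term) next
    if (startsWith(l, "id:")) {
      cur_id <- trimws(sub("^id:", "", l))
    } else if (startsWith(l, "is_a:")) {
      v <- trimws(sub("!.*$", "", sub("^is_a:", "", l)))
      v <- strsplit(v, "[[:space:]]+")[[1]][1]
      if (!is.na(v) && nzchar(v)) cur_parents <- c(cur_parents, v)
    } else if (startsWith(l, "is_obsolete:") && grepl("true", l)) {
      cur_obsolete <- TRUE
    }
  }
  if (anyDuplicated(ids)) {
    stop("duplicate term ids in OBO file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  # drop is_a references to unknown (e.g., obsolete) terms
  n_dangling <- 0L
  for (id in ids) {
    known <- parents[[id]] %in% ids
    n_dangling <- n_dangling + sum(!known)
    parents[[id]] <- parents[[id]][known]
  }
  if (n_dangling > 0) {
    warning(sprintf("%d is_a reference(s) to unknown terms dropped", n_dangling))
  }
  ord <- order(ids)
  ids <- ids[ord]
  parents <- parents[ids]
  dag <- structure(
    list(terms = ids, parents = parents,
         roots = ids[lengths(parents) == 0]),
    class = "ontology_dag"
  )
  assert_acyclic(dag)
  if (!length(dag$roots) && length(ids)) stop("ontology has no root term")
  dag
}

# Kahn-style check that parent edges contain no cycle.
assert_acyclic <- function(ontology) {
  remaining <- ontology$terms
  parents <- ontology$parents
  repeat {
    removable <- remaining[vapply(parents[remaining], function(p) {
      !any(p %in% remaining)
    }, logical(1))]
    if (!length(removable)) break
    remaining <- setdiff(remaining, removable)
  }
  if (length(remaining)) {
    stop("ontology is_a graph contains a cycle involving: ",
         paste(utils::head(remaining, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("ontology_dag: %d terms, %d is_a edges, %d root(s)\n",
              length(x$terms), sum(lengths(x$parents)), length(x$roots)))
  invisible(x)
}

#' Ancestor sets for ontology terms
#'
#' @param ontology an `ontology_dag`.
#' @param terms terms to compute ancestors for (default all).
#' @return named list mapping each term to the character vector of its
#'   (proper) ancestors, i.e., all terms reachable via `is_a` edges.
#' @export
term_ancestors <- function(ontology, terms = ontology$terms) {
  unknown <- setdiff(terms, ontology$terms)
  if (length(unknown)) {
    stop("unknown ontology term(s): ", paste(unknown, collapse = ", "))
  }
  cache <- new.env(parent = emptyenv())
  anc <- function(t) {
    hit <- get0(t, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    ps <- ontology$parents[[t]]
    out <- if (!length(ps)) character(0) else {
      unique(c(ps, unlist(lapply(ps, anc), use.names = FALSE)))
    }
    assign(t, out, envir = cache)
    out
  }
  stats::setNames(lapply(terms, anc), terms)
}

#' Read a two-column protein-term annotation table
#'
#' Tab-separated `protein<TAB>term` pairs, one per line; an optional header
#' line naming the columns is tolerated.
#'
#' @param path path to the TSV file.
#' @return annotation data.frame with columns `protein` and `term`
#'   (unpropagated; `attr(, "propagated")` is `FALSE`).
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          col.names = c("protein", "term"))
  if (nrow(df) && tolower(df$protein[1]) %in% c("protein", "gene") ) {
    df <- df[-1, , drop = FALSE]
  }
  df <- unique(df)
  rownames(df) <- NULL
  attr(df, "propagated") <- FALSE
  df
}

#' Read an optional two-column identifier mapping table
#'
#' Maps source identifiers (e.g., gene symbols) onto the opaque protein id
#' space used throughout the package. The package itself performs no id
#' conversion; callers pre-map via this table when their annotation and
#' graph files use different id spaces.
#'
#' @param path path to a two-column TSV (`from<TAB>to`).
#' @return named character vector (`names` = from, values = to).
#' @export
load_id_mapping <- function(path) {
  if (!file.exists(path)) stop("id mapping file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          col.names = c("from", "to"))
  stats::setNames(df$to, df$from)
}

#' Propagate annotations under the true path rule
#'
#' If a protein is annotated with a term, it is inherently annotated with
#' every ancestor of that term; this returns the ancestor closure of the
#' input annotation set. The operation is idempotent.
#'
#' @param annotations data.frame with columns `protein`, `term`.
#' @param ontology an `ontology_dag`; every annotated term must exist in it.
#' @return annotation data.frame closed under ancestors, with
#'   `attr(, "propagated") = TRUE`.
#' @export
propagate_true_path <- function(annotations, ontology) {
  ann <- unique(as.data.frame(annotations)[, c("protein", "term")])
  if (!nrow(ann)) {
    attr(ann, "propagated") <- TRUE
    return(ann)
  }
  uterms <- unique(ann$term)
  unknown <- setdiff(uterms, ontology$terms)
  if (length(unknown)) {
    stop("annotations reference term(s) missing from the ontology: ",
         paste(sort(unknown), collapse = ", "))
  }
  anc <- term_ancestors(ontology, uterms)
  ext <- lapply(uterms, function(tt) c(tt, anc[[tt]]))
  names(ext) <- uterms
  idx <- match(ann$term, uterms)
  out <- data.frame(
    protein = rep(ann$protein, lengths(ext)[idx]),
    term = unlist(ext[idx], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  out <- unique(out)
  out <- out[order(out$protein, out$term), ]
  rownames(out) <- NULL
  attr(out, "propagated") <- TRUE
  out
}

# Distinct annotated-protein count per term.
term_counts <- function(annotations) {
  vapply(split(annotations$protein, annotations$term),
         function(p) length(unique(p)), integer(1))
}

#' Remove low-frequency terms
#'
#' Terms with no more than `min_exclusive` annotated proteins are removed
#' from the annotation set (the surviving terms all have a strictly greater
#' count), so that per-term performance can be assessed on reasonably
#' populated terms.
#'
#' @param annotations propagated annotation data.frame.
#' @param min_exclusive exclusive lower bound on the annotated-protein count
#'   (default 10: terms with 10 or fewer proteins are removed).
#' @return list with `annotations` (filtered set, propagation flag kept) and
#'   `removed` (sorted ids of removed terms).
#' @export
filter_terms_by_frequency <- function(annotations, min_exclusive = 10) {
  cnt <- term_counts(annotations)
  keep <- names(cnt)[cnt > min_exclusive]
  removed <- sort(names(cnt)[cnt <= min_exclusive])
  out <- annotations[annotations$term %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "propagated") <- attr(annotations, "propagated")
  list(annotations = out, removed = removed)
}

#' Group terms by annotation frequency
#'
#' Assigns each annotated term one of six frequency labels by its
#' annotated-protein count: Very rare (1-3), Rare (4-10), Uncommon (11-30),
#' Common (31-100), Very common (101-300), Extremely common (>300).
#'
#' @param annotations propagated annotation data.frame.
#' @return named character vector mapping term id to group label; terms with
#'   zero annotations do not appear.
#' @export
group_terms_by_frequency <- function(annotations) {
  cnt <- term_counts(annotations)
  cnt <- cnt[cnt > 0]
  lab <- cut(cnt, breaks = c(0, 3, 10, 30, 100, 300, Inf),
             labels = c("Very rare", "Rare", "Uncommon", "Common",
                        "Very common", "Extremely common"),
             right = TRUE)
  stats::setNames(as.character(lab), names(cnt))
}

#' Sample balanced negative annotations
#'
#' For each term, draws as many negative proteins as it has positives,
#' uniformly without replacement from the proteins of the universe not
#' annotated to that term (there is no experimentally verified negative set,
#' so unannotated proteins stand in for negatives).
#'
#' @param positives annotation data.frame of positive pairs.
#' @param protein_universe character vector of candidate proteins.
#' @param seed integer seed making the draw reproducible.
#' @return annotation data.frame of negative pairs, `|negatives| ==
#'   |positives|` per term and disjoint from the positives.
#' @export
sample_negatives <- function(positives, protein_universe, seed = NULL) {
  pos_by_term <- lapply(split(positives$protein, positives$term), unique)
  pos_by_term <- pos_by_term[order(names(pos_by_term))]
  with_seed(seed, {
    res <- lapply(names(pos_by_term), function(tt) {
      p <- pos_by_term[[tt]]
      cand <- setdiff(protein_universe, p)
      if (length(cand) < length(p)) {
        stop(sprintf(
          "cannot sample %d negatives for term %s: only %d unannotated proteins in the universe",
          length(p), tt, length(cand)))
      }
      data.frame(protein = sample(cand, length(p)), term = tt,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    attr(out, "propagated") <- FALSE
    out
  })
}

#' Align the protein universe across data sources
#'
#' The working universe is the sorted intersection of the proteins present
#' in the interaction graph and those with a sequence; proteins missing from
#' either source are dropped with a logged count.
#'
#' @param graph_proteins proteins appearing in the edge list.
#' @param sequence_proteins proteins with a FASTA sequence.
#' @param annotated_proteins optional proteins appearing in the annotation
#'   table, reported on if some fall outside the universe.
#' @return sorted character vector of retained protein ids.
#' @export
align_universe <- function(graph_proteins, sequence_proteins,
                           annotated_proteins = NULL) {
  g <- unique(graph_proteins)
  s <- unique(sequence_proteins)
  uni <- sort(intersect(g, s))
  if (!length(uni)) {
    stop("no proteins shared between the interaction graph and the sequence set")
  }
  drop_g <- length(g) - length(uni)
  drop_s <- length(s) - length(uni)
  if (drop_g || drop_s) {
    message(sprintf(
      "align_universe: dropped %d graph-only and %d sequence-only protein(s); %d retained",
      drop_g, drop_s, length(uni)))
  }
  if (!is.null(annotated_proteins)) {
    out <- setdiff(unique(annotated_proteins), uni)
    if (length(out)) {
      message(sprintf(
        "align_universe: %d annotated protein(s) fall outside the universe", length(out)))
    }
  }
  uni
}

#' Build the gold-standard positive/negative annotation sets
#'
#' Restricts annotations to the protein universe, propagates them under the
#' true path rule, removes terms with no more than `min_count` annotated
#' proteins, and samples a balanced negative set per term. Terms annotated
#' to more than half of the universe are also dropped (with a message):
#' a balanced negative set cannot be drawn for them because fewer
#' unannotated than annotated proteins remain. At realistic corpus sizes,
#' where annotated proteins are a small fraction of the universe, this never
#' triggers; it matters only for small benchmark universes where near-root
#' terms cover most proteins.
#'
#' @param annotations raw (unpropagated) annotation data.frame.
#' @param ontology an `ontology_dag`.
#' @param protein_universe aligned protein universe (see [align_universe()]).
#' @param seed integer seed for negative sampling.
#' @param min_count exclusive minimum annotated-protein count per term.
#' @return an object of class `gold_standard`: list with `positives`,
#'   `negatives` (annotation data.frames), `term_universe` (lexicographic),
#'   `protein_universe`, `removed_rare`, `removed_common`, `seed`.
#' @export
build_gold_standard <- function(annotations, ontology, protein_universe,
                                seed = 1, min_count = 10) {
  ann <- annotations[annotations$protein %in% protein_universe, , drop = FALSE]
  n_out <- length(setdiff(unique(annotations$protein), protein_universe))
  if (n_out) {
    message(sprintf("build_gold_standard: %d annotated protein(s) outside the universe dropped", n_out))
  }
  prop <- propagate_true_path(ann, ontology)
  flt <- filter_terms_by_frequency(prop, min_count)
  pos <- flt$annotations
  cnt <- term_counts(pos)
  too_common <- sort(names(cnt)[cnt > length(protein_universe) / 2])
  if (length(too_common)) {
    message(sprintf(
      "build_gold_standard: %d term(s) annotated to more than half the universe dropped (balanced negatives infeasible)",
      length(too_common)))
    pos <- pos[!pos$term %in% too_common, , drop = FALSE]
    rownames(pos) <- NULL
    attr(pos, "propagated") <- TRUE
  }
  if (!nrow(pos)) stop("no terms survive frequency filtering")
  neg <- sample_negatives(pos, protein_universe, seed)
  structure(
    list(positives = pos, negatives = neg,
         term_universe = sort(unique(pos$term)),
         protein_universe = protein_universe,
         removed_rare = flt$removed,
         removed_common = too_common,
         seed = seed),
    class = "gold_standard"
  )
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf(
    "gold_standard: %d proteins x %d terms; %d positive and %d negative pairs\n",
    length(x$protein_universe), length(x$term_universe),
    nrow(x$positives), nrow(x$negatives)))
  cat(sprintf("  removed: %d low-frequency, %d near-universal term(s)\n",
              length(x$removed_rare), length(x$removed_common)))
  invisible(x)
}

#' Binary annotation matrix
#'
#' @param pairs annotation data.frame (`protein`, `term`).
#' @param proteins row order.
#' @param terms column order.
#' @return binary `length(proteins) x length(terms)` matrix with dimnames.
#' @export
annotation_matrix <- function(pairs, proteins, terms) {
  M <- matrix(0, length(proteins), length(terms),
              dimnames = list(proteins, terms))
  keep <- pairs$protein %in% proteins & pairs$term %in% terms
  p <- pairs[keep, , drop = FALSE]
  M[cbind(match(p$protein, proteins), match(p$term, terms))] <- 1
  M
}

# Label (Y) and mask (M) matrices over the gold-standard pair set, optionally
# restricted to a subset of pairs (data.frame protein/term/label).
label_matrices <- function(gold, pairs = NULL) {
  proteins <- gold$protein_universe
  terms <- gold$term_universe
  if (is.null(pairs)) {
    pairs <- rbind(
      data.frame(gold$positives[, c("protein", "term")], label = 1),
      data.frame(gold$negatives[, c("protein", "term")], label = 0)
    )
  }
  Y <- matrix(0, length(proteins), length(terms),
              dimnames = list(proteins, terms))
  M <- Y
  i <- cbind(match(pairs$protein, proteins), match(pairs$term, terms))
  if (anyNA(i)) stop("label_matrices: pair outside the gold-standard universe")
  Y[i] <- pairs$label
  M[i] <- 1
  list(Y = Y, M = M)
}
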