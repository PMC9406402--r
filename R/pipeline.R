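# End-to-end pipeline and staged command entry points. Each cmd_* stage
# reads its inputs from a run directory, writes plain-text checkpoints
# (TSV/JSON) plus the resolved configuration, and fails with an actionable
# message when an upstream artifact is missing. A thin Rscript wrapper
# around these functions ships in inst/cli/gaephen.R.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

require_file <- function(path, hint) {
  if (!file.exists(path)) {
    stop(sprintf("missing input %s; run `%s` first", path, hint))
  }
  path
}

# Merge stage options into the run directory's resolved config.
update_run_config <- function(dir, stage, opts) {
  cfg_path <- file.path(dir, "config.json")
  cfg <- if (file.exists(cfg_path)) {
    jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  } else list()
  cfg[[stage]] <- opts
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(cfg)
}

save_gold <- function(gold, dir) {
  write_tsv(gold$positives, file.path(dir, "gold_positives.tsv"))
  write_tsv(gold$negatives, file.path(dir, "gold_negatives.tsv"))
  writeLines(gold$protein_universe, file.path(dir, "universe.txt"))
  writeLines(gold$term_universe, file.path(dir, "terms.txt"))
}

load_gold <- function(dir) {
  for (f in c("gold_positives.tsv", "gold_negatives.tsv", "universe.txt",
              "terms.txt")) {
    require_file(file.path(dir, f), "cmd_encode")
  }
  pos <- utils::read.table(file.path(dir, "gold_positives.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  neg <- utils::read.table(file.path(dir, "gold_negatives.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  attr(pos, "propagated") <- TRUE
  structure(
    list(positives = pos, negatives = neg,
         term_universe = readLines(file.path(dir, "terms.txt")),
         protein_universe = readLines(file.path(dir, "universe.txt")),
         removed_rare = character(0), removed_common = character(0),
         seed = NA_integer_),
    class = "gold_standard"
  )
}

save_graph <- function(graph, dir) {
  A <- graph$A
  ut <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  write_tsv(data.frame(protein_a = graph$proteins[ut[, 1]],
                       protein_b = graph$proteins[ut[, 2]],
                       weight = A[ut]),
            file.path(dir, "graph.tsv"))
}

load_graph <- function(dir) {
  require_file(file.path(dir, "graph.tsv"), "cmd_encode")
  universe <- readLines(require_file(file.path(dir, "universe.txt"),
                                     "cmd_encode"))
  e <- utils::read.table(file.path(dir, "graph.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE)
  n <- length(universe)
  A <- matrix(0, n, n, dimnames = list(universe, universe))
  A[cbind(match(e$protein_a, universe), match(e$protein_b, universe))] <- e$weight
  A[cbind(match(e$protein_b, universe), match(e$protein_a, universe))] <- e$weight
  diag(A) <- 1
  structure(list(proteins = universe, A = A), class = "protein_graph")
}

save_classifier <- function(fit, dir) {
  mdir <- file.path(dir, "model")
  if (!dir.exists(mdir)) dir.create(mdir)
  p <- fit$params
  for (nm in c("W0", "W1")) {
    utils::write.table(p[[nm]], file.path(mdir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  for (nm in c("b0", "gamma", "beta", "b1", "running_mean", "running_var")) {
    writeLines(format(p[[nm]], digits = 17), file.path(mdir, paste0(nm, ".txt")))
  }
  jsonlite::write_json(c(fit$config, list(terms = fit$terms)),
                       file.path(mdir, "model_config.json"),
                       auto_unbox = TRUE, digits = NA)
}

load_classifier <- function(dir) {
  mdir <- file.path(dir, "model")
  require_file(file.path(mdir, "model_config.json"), "cmd_train")
  cfg <- jsonlite::read_json(file.path(mdir, "model_config.json"),
                             simplifyVector = TRUE)
  terms <- cfg$terms
  cfg$terms <- NULL
  p <- list()
  for (nm in c("W0", "W1")) {
    p[[nm]] <- as.matrix(utils::read.table(file.path(mdir, paste0(nm, ".tsv")),
                                           sep = "\t", header = FALSE))
    dimnames(p[[nm]]) <- NULL
  }
  for (nm in c("b0", "gamma", "beta", "b1", "running_mean", "running_var")) {
    p[[nm]] <- as.numeric(readLines(file.path(mdir, paste0(nm, ".txt"))))
  }
  colnames(p$W1) <- terms
  structure(list(params = structure(p, class = "mlp_params"),
                 loss_history = numeric(0), terms = terms, config = cfg),
            class = "mlp_fit")
}

#' Stage: generate a synthetic input bundle
#'
#' @param out output directory.
#' @param ... overrides passed to [fixture_config()].
#' @return invisibly, the [make_fixture()] result.
#' @export
cmd_fixture <- function(out, ...) {
  fx <- make_fixture(fixture_config(...), dir = out)
  update_run_config(out, "fixture", unclass(fx$config))
  invisible(fx)
}

#' Stage: ingest inputs, build the gold standard, features and graph
#'
#' Reads the four inputs, aligns the protein universe, writes the
#' conjoint-triad feature matrix, the filtered weighted graph and the
#' gold-standard positive/negative pair tables into `out`.
#'
#' @param edges,fasta,obo,annotations input file paths.
#' @param out run directory (created if needed).
#' @param score_min exclusive combined-score cutoff.
#' @param min_term_count exclusive annotated-protein minimum per term.
#' @param seed seed for negative sampling.
#' @return invisibly, a list with the gold standard, graph and features.
#' @export
cmd_encode <- function(edges, fasta, obo, annotations, out,
                       score_min = 300, min_term_count = 10, seed = 1) {
  for (f in c(edges, fasta, obo, annotations)) {
    if (!file.exists(f)) stop("missing input file: ", f)
  }
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  el <- load_edge_list(edges)
  seqs <- load_sequences(fasta)
  onto <- load_ontology(obo)
  ann <- load_annotations(annotations)
  universe <- align_universe(c(el$protein_a, el$protein_b), names(seqs),
                             ann$protein)
  gold <- build_gold_standard(ann, onto, universe, seed = seed,
                              min_count = min_term_count)
  X <- ct_encode_matrix(seqs[universe])
  graph <- build_adjacency(el, universe, score_min)
  save_gold(gold, out)
  save_graph(graph, out)
  write_tsv(data.frame(protein = rownames(X), X, check.names = FALSE),
            file.path(out, "features.tsv"))
  update_run_config(out, "encode",
                    list(edges = edges, fasta = fasta, obo = obo,
                         annotations = annotations, score_min = score_min,
                         min_term_count = min_term_count, seed = seed))
  invisible(list(gold = gold, graph = graph, features = X))
}

#' Stage: train the graph autoencoder and export the embedding
#'
#' @param out run directory holding the [cmd_encode()] outputs.
#' @param latent_dim,hidden_dim,epochs,lr,seed autoencoder settings (see
#'   [train_vgae()]).
#' @return invisibly, the `vgae_fit`.
#' @export
cmd_embed <- function(out, latent_dim = 64, hidden_dim = 256, epochs = 200,
                      lr = 0.01, seed = 1) {
  fpath <- require_file(file.path(out, "features.tsv"), "cmd_encode")
  fdf <- utils::read.table(fpath, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(fdf[, -1, drop = FALSE])
  rownames(X) <- fdf[[1]]
  graph <- load_graph(out)
  fit <- train_vgae(X, graph, latent_dim = latent_dim,
                    hidden_dim = hidden_dim, epochs = epochs, lr = lr,
                    seed = seed)
  write_embedding(fit$mu, file.path(out, "embedding.tsv"))
  update_run_config(out, "embed",
                    list(latent_dim = latent_dim, hidden_dim = hidden_dim,
                         epochs = epochs, lr = lr, seed = seed))
  invisible(fit)
}

#' Stage: cross-validate and train the final classifier
#'
#' Runs k-fold cross-validation over the gold pairs (writing the pooled
#' held-out report and per-term Youden thresholds derived from the pooled
#' held-out scores), then trains the final classifier on all pairs.
#'
#' @param out run directory holding embedding and gold standard.
#' @param hidden_dim,dropout,epochs,lr classifier settings.
#' @param folds number of CV folds.
#' @param seed seed for folds and training.
#' @return invisibly, list with the final `mlp_fit`, the CV result and the
#'   threshold table.
#' @export
cmd_train <- function(out, hidden_dim = 512, dropout = 0.3, epochs = 500,
                      lr = 0.01, folds = 5, seed = 1) {
  Z <- read_embedding(require_file(file.path(out, "embedding.tsv"),
                                   "cmd_embed"))
  gold <- load_gold(out)
  cv <- crossvalidate(Z, gold, k = folds, seed = seed,
                      hidden_dim = hidden_dim, dropout = dropout,
                      epochs = epochs, lr = lr)
  th <- suppressWarnings(youden_thresholds(cv$pooled_scores, gold))
  fit <- train_classifier(Z, gold, hidden_dim = hidden_dim,
                          dropout = dropout, epochs = epochs, lr = lr,
                          seed = seed)
  save_classifier(fit, out)
  write_tsv(data.frame(term = names(th), threshold = unname(th)),
            file.path(out, "thresholds.tsv"))
  jsonlite::write_json(
    list(macro_auc = cv$pooled$macro_auc,
         fmax = cv$pooled$fmax$fmax,
         fmax_threshold = cv$pooled$fmax$threshold,
         per_term_auc = as.list(cv$pooled$per_term_auc)),
    file.path(out, "cv_report.json"), auto_unbox = TRUE, digits = NA)
  update_run_config(out, "train",
                    list(hidden_dim = hidden_dim, dropout = dropout,
                         epochs = epochs, lr = lr, folds = folds,
                         seed = seed))
  invisible(list(fit = fit, cv = cv, thresholds = th))
}

#' Stage: score every protein-term pair
#'
#' Writes `scores.tsv` with one row per protein-term pair: the predicted
#' probability and the Youden-thresholded binary call.
#'
#' @param out run directory holding embedding, model and thresholds.
#' @return invisibly, the score matrix.
#' @export
cmd_predict <- function(out) {
  Z <- read_embedding(require_file(file.path(out, "embedding.tsv"),
                                   "cmd_embed"))
  fit <- load_classifier(out)
  tpath <- require_file(file.path(out, "thresholds.tsv"), "cmd_train")
  tdf <- utils::read.table(tpath, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  th <- stats::setNames(tdf$threshold, tdf$term)
  scores <- predict_scores(fit, Z)
  calls <- binarize(scores, th)
  long <- data.frame(
    protein = rep(rownames(scores), times = ncol(scores)),
    term = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores),
    call = as.vector(calls), stringsAsFactors = FALSE
  )
  write_tsv(long, file.path(out, "scores.tsv"))
  invisible(scores)
}

#' Stage: evaluate predictions against the gold standard
#'
#' Computes protein-centric F-max and term-centric (macro) AUC over the
#' gold-standard labeled pairs and writes `report.json`.
#'
#' @param out run directory holding `scores.tsv` and the gold standard.
#' @return invisibly, the report list.
#' @export
cmd_evaluate <- function(out) {
  spath <- require_file(file.path(out, "scores.tsv"), "cmd_predict")
  long <- utils::read.table(spath, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  gold <- load_gold(out)
  proteins <- gold$protein_universe
  terms <- gold$term_universe
  scores <- matrix(NA_real_, length(proteins), length(terms),
                   dimnames = list(proteins, terms))
  keep <- long$protein %in% proteins & long$term %in% terms
  scores[cbind(match(long$protein[keep], proteins),
               match(long$term[keep], terms))] <- long$score[keep]
  pairs <- gold_pairs(gold)
  lab_scores <- matrix(NA_real_, length(proteins), length(terms),
                       dimnames = dimnames(scores))
  idx <- cbind(match(pairs$protein, proteins), match(pairs$term, terms))
  lab_scores[idx] <- scores[idx]
  truth <- annotation_matrix(gold$positives, proteins, terms)
  aucs <- suppressWarnings(term_auc_by_pairs(lab_scores, pairs, terms))
  report <- list(
    fmax = fmax(lab_scores, truth)$fmax,
    macro_auc = suppressWarnings(macro_auc(aucs)),
    n_proteins = length(proteins), n_terms = length(terms)
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Run the full pipeline in memory
#'
#' Convenience wrapper chaining ingest, feature encoding, graph autoencoder
#' embedding, cross-validated classification, Youden thresholding and
#' final prediction. All stages are seeded from `seed`.
#'
#' @param edges,fasta,obo,annotations input file paths.
#' @param score_min exclusive combined-score cutoff.
#' @param min_term_count term frequency cutoff.
#' @param latent_dim,hidden_dim,vgae_epochs,vgae_lr autoencoder settings.
#' @param classifier_hidden,dropout,classifier_epochs,classifier_lr
#'   classifier settings.
#' @param folds number of CV folds.
#' @param seed master seed.
#' @param out optional run directory; when given, stage outputs are also
#'   written as by the cmd_* stages.
#' @return list with `gold`, `graph`, `features`, `vgae`, `cv`,
#'   `thresholds`, `scores`, `calls`, and the pooled CV `report`.
#' @export
run_pipeline <- function(edges, fasta, obo, annotations,
                         score_min = 300, min_term_count = 10,
                         latent_dim = 64, hidden_dim = 256,
                         vgae_epochs = 200, vgae_lr = 0.01,
                         classifier_hidden = 512, dropout = 0.3,
                         classifier_epochs = 500, classifier_lr = 0.01,
                         folds = 5, seed = 1, out = NULL) {
  el <- load_edge_list(edges)
  seqs <- load_sequences(fasta)
  onto <- load_ontology(obo)
  ann <- load_annotations(annotations)
  universe <- align_universe(c(el$protein_a, el$protein_b), names(seqs),
                             ann$protein)
  gold <- build_gold_standard(ann, onto, universe, seed = seed,
                              min_count = min_term_count)
  X <- ct_encode_matrix(seqs[universe])
  graph <- build_adjacency(el, universe, score_min)
  vgae <- train_vgae(X, graph, latent_dim = latent_dim,
                     hidden_dim = hidden_dim, epochs = vgae_epochs,
                     lr = vgae_lr, seed = seed)
  cv <- crossvalidate(vgae$mu, gold, k = folds, seed = seed,
                      hidden_dim = classifier_hidden, dropout = dropout,
                      epochs = classifier_epochs, lr = classifier_lr)
  thresholds <- suppressWarnings(youden_thresholds(cv$pooled_scores, gold))
  final <- train_classifier(vgae$mu, gold, hidden_dim = classifier_hidden,
                            dropout = dropout, epochs = classifier_epochs,
                            lr = classifier_lr, seed = seed)
  scores <- predict_scores(final, vgae$mu[gold$protein_universe, , drop = FALSE])
  calls <- binarize(scores, thresholds)
  if (!is.null(out)) {
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    save_gold(gold, out)
    save_graph(graph, out)
    write_embedding(vgae$mu, file.path(out, "embedding.tsv"))
    save_classifier(final, out)
    write_tsv(data.frame(term = names(thresholds),
                         threshold = unname(thresholds)),
              file.path(out, "thresholds.tsv"))
    long <- data.frame(
      protein = rep(rownames(scores), times = ncol(scores)),
      term = rep(colnames(scores), each = nrow(scores)),
      score = as.vector(scores), call = as.vector(calls),
      stringsAsFactors = FALSE)
    write_tsv(long, file.path(out, "scores.tsv"))
    update_run_config(out, "pipeline",
                      list(score_min = score_min,
                           min_term_count = min_term_count,
                           latent_dim = latent_dim, hidden_dim = hidden_dim,
                           vgae_epochs = vgae_epochs, vgae_lr = vgae_lr,
                           classifier_hidden = classifier_hidden,
                           dropout = dropout,
                           classifier_epochs = classifier_epochs,
                           classifier_lr = classifier_lr,
                           folds = folds, seed = seed))
  }
  list(gold = gold, graph = graph, features = X, vgae = vgae, cv = cv,
       thresholds = thresholds, scores = scores, calls = calls,
       report = cv$pooled)
}
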