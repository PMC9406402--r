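# CAFA-style evaluation: protein-centric precision/recall and F-max,
# term-centric ROC AUC macro-averaged over terms, five-fold cross-validation
# over labeled pairs, percentile bootstrap confidence intervals, and the
# smallest-shared-annotation pair statistic.

#' Protein-centric precision and recall at a threshold
#'
#' For protein i let `P_i(t)` be the terms with score >= t and `T_i` its
#' ground-truth terms. Precision averages `|P_i ∩ T_i| / |P_i|` over the
#' `m(t)` proteins with at least one prediction at t; recall averages
#' `|P_i ∩ T_i| / |T_i|` over all proteins with ground-truth terms (a
#' protein with an empty `P_i(t)` contributes zero recall but is excluded
#' from the precision average). `NA` score cells are treated as
#' never-predicted, which lets callers evaluate on a labeled subset of the
#' matrix.
#'
#' @param scores protein x term score matrix (may contain `NA`).
#' @param truth binary protein x term ground-truth matrix, same shape.
#' @param t threshold in [0, 1].
#' @return list with `precision`, `recall`, `m` (proteins with predictions)
#'   and `precision_defined` (`FALSE` with precision 0 when `m(t) = 0`).
#' @export
precision_recall_at <- function(scores, truth, t) {
  if (t < 0 || t > 1) stop("threshold must lie in [0, 1]")
  if (!identical(dim(scores), dim(truth))) {
    stop("scores and truth matrices must have identical shapes")
  }
  pred <- !is.na(scores) & scores >= t
  pos <- truth == 1
  tp <- rowSums(pred & pos)
  npred <- rowSums(pred)
  ntruth <- rowSums(pos)
  has_pred <- npred > 0
  has_truth <- ntruth > 0
  m_t <- sum(has_pred)
  precision <- if (m_t > 0) mean(tp[has_pred] / npred[has_pred]) else 0
  recall <- if (any(has_truth)) {
    mean(tp[has_truth] / ntruth[has_truth])
  } else 0
  list(precision = precision, recall = recall, m = m_t,
       precision_defined = m_t > 0)
}

#' Protein-centric F-max
#'
#' Maximum over thresholds of the harmonic mean of protein-centric
#' precision and recall. The default grid is 101 evenly spaced thresholds
#' (0, 0.01, ..., 1); `thresholds = "exact"` scans every observed score
#' value instead. Ties are broken by the smallest maximizing threshold.
#'
#' @param scores protein x term score matrix (may contain `NA`).
#' @param truth binary ground-truth matrix, same shape.
#' @param thresholds numeric grid in [0, 1], or `"exact"`.
#' @return list with `fmax`, `threshold`, and the `precision`/`recall`
#'   attained there.
#' @export
fmax <- function(scores, truth, thresholds = seq(0, 1, by = 0.01)) {
  if (identical(thresholds, "exact")) {
    obs <- scores[!is.na(scores)]
    thresholds <- sort(unique(c(0, obs, 1)))
  }
  thresholds <- sort(thresholds)
  best <- list(fmax = -Inf, threshold = NA_real_,
               precision = NA_real_, recall = NA_real_)
  for (t in thresholds) {
    pr <- precision_recall_at(scores, truth, t)
    f <- if (pr$precision + pr$recall > 0) {
      2 * pr$precision * pr$recall / (pr$precision + pr$recall)
    } else 0
    if (f > best$fmax + 1e-12) {
      best <- list(fmax = f, threshold = t,
                   precision = pr$precision, recall = pr$recall)
    }
  }
  best
}

#' Term-centric ROC AUC
#'
#' Sweeps the decision threshold over the observed scores, tracing the ROC
#' curve of sensitivity against one minus specificity, and integrates it
#' with the trapezoidal rule. Tied scores cross the threshold
#' simultaneously, making the result identical to the rank-based
#' Mann-Whitney statistic with tie correction.
#'
#' @param pos_scores scores of proteins annotated to the term.
#' @param neg_scores scores of negative proteins.
#' @return AUC in [0, 1]; `NA` with a warning when either class is empty.
#' @export
term_auc <- function(pos_scores, neg_scores) {
  pos_scores <- pos_scores[!is.na(pos_scores)]
  neg_scores <- neg_scores[!is.na(neg_scores)]
  if (!length(pos_scores) || !length(neg_scores)) {
    warning("term_auc: undefined (no positives or no negatives)")
    return(NA_real_)
  }
  u <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  sn <- cumsum(tabulate(match(pos_scores, u), length(u))) / length(pos_scores)
  fp <- cumsum(tabulate(match(neg_scores, u), length(u))) / length(neg_scores)
  x <- c(0, fp)
  y <- c(0, sn)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Macro-averaged AUC
#'
#' Unweighted mean over per-term AUCs; undefined (`NA`) terms are excluded
#' with a warning.
#'
#' @param per_term_auc named numeric vector of per-term AUCs.
#' @return mean AUC.
#' @export
macro_auc <- function(per_term_auc) {
  defined <- per_term_auc[!is.na(per_term_auc)]
  if (!length(defined)) stop("macro_auc: no defined per-term AUCs")
  n_na <- sum(is.na(per_term_auc))
  if (n_na) {
    warning(sprintf("macro_auc: %d undefined term AUC(s) excluded", n_na))
  }
  mean(defined)
}

# Per-term AUCs over a labeled pair set (data.frame protein/term/label).
term_auc_by_pairs <- function(scores, pairs, terms = sort(unique(pairs$term))) {
  out <- stats::setNames(rep(NA_real_, length(terms)), terms)
  for (tt in terms) {
    p <- pairs[pairs$term == tt, , drop = FALSE]
    pos_id <- p$protein[p$label == 1]
    neg_id <- p$protein[p$label == 0]
    if (!length(pos_id) || !length(neg_id)) next
    out[tt] <- term_auc(scores[pos_id, tt], scores[neg_id, tt])
  }
  out
}

# Full gold-standard pair table (protein, term, label).
gold_pairs <- function(gold) {
  rbind(
    data.frame(gold$positives[, c("protein", "term")], label = 1,
               stringsAsFactors = FALSE),
    data.frame(gold$negatives[, c("protein", "term")], label = 0,
               stringsAsFactors = FALSE)
  )
}

#' Stratified fold assignment for labeled pairs
#'
#' Partitions the gold-standard pairs into `k` folds, stratified per term
#' and label so each fold holds approximately 1/k of every term's positives
#' and negatives. Terms with fewer than `k` positives are assigned by the
#' same shuffled round-robin deal (with a warning).
#'
#' @param gold a `gold_standard`.
#' @param k number of folds.
#' @param seed integer seed.
#' @return data.frame `protein`, `term`, `label`, `fold`.
#' @export
make_cv_folds <- function(gold, k = 5, seed = 1) {
  pairs <- gold_pairs(gold)
  pairs$fold <- NA_integer_
  npos <- table(pairs$term[pairs$label == 1])
  scarce <- names(npos)[npos < k]
  if (length(scarce)) {
    warning(sprintf("make_cv_folds: %d term(s) have fewer than %d positives; folds assigned round-robin",
                    length(scarce), k))
  }
  with_seed(seed, {
    groups <- split(seq_len(nrow(pairs)),
                    list(pairs$term, pairs$label), drop = TRUE)
    for (g in groups) {
      idx <- if (length(g) > 1) sample(g) else g
      pairs$fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  pairs
}

#' Cross-validated evaluation of the classifier stage
#'
#' The unsupervised embedding is trained once on the full graph upstream
#' (transductive setting); here the classifier is retrained on the training
#' pairs of each fold and each pair is scored by the model of the fold that
#' holds it out. Reported per fold and pooled: per-term AUC on held-out
#' pairs, macro AUC, and protein-centric F-max computed over the held-out
#' labeled cells (held-out positives as truth; unlabeled cells are `NA` and
#' never predicted).
#'
#' @param Z embedding matrix (protein rownames covering the gold universe).
#' @param gold a `gold_standard`.
#' @param k number of folds.
#' @param seed seed for fold assignment and classifier training.
#' @param fold_unit `"pair"` splits labeled pairs (the default);
#'   `"protein"` holds out whole proteins instead.
#' @param ... classifier settings passed to [train_classifier()].
#' @return list with `folds` (pair/fold table), `per_fold` reports,
#'   `pooled` report (`per_term_auc`, `macro_auc`, `fmax`), and
#'   `pooled_scores` (matrix of held-out scores, `NA` outside labeled cells).
#' @export
crossvalidate <- function(Z, gold, k = 5, seed = 1,
                          fold_unit = c("pair", "protein"), ...) {
  fold_unit <- match.arg(fold_unit)
  if (fold_unit == "pair") {
    pairs <- make_cv_folds(gold, k, seed)
  } else {
    pairs <- gold_pairs(gold)
    prot <- gold$protein_universe
    pf <- with_seed(seed, stats::setNames(
      rep_len(seq_len(k), length(prot))[sample(length(prot))], prot))
    pairs$fold <- pf[pairs$protein]
  }
  proteins <- gold$protein_universe
  terms <- gold$term_universe
  pooled <- matrix(NA_real_, length(proteins), length(terms),
                   dimnames = list(proteins, terms))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    train <- pairs[pairs$fold != f, , drop = FALSE]
    test <- pairs[pairs$fold == f, , drop = FALSE]
    fit <- train_classifier(Z, gold, train_pairs = train, seed = seed + f, ...)
    sc <- predict_scores(fit, Z[proteins, , drop = FALSE])
    idx <- cbind(match(test$protein, proteins), match(test$term, terms))
    pooled[idx] <- sc[idx]
    aucs <- term_auc_by_pairs(sc, test, terms)
    test_scores <- matrix(NA_real_, length(proteins), length(terms),
                          dimnames = dimnames(pooled))
    test_scores[idx] <- sc[idx]
    truth <- annotation_matrix(test[test$label == 1, , drop = FALSE],
                               proteins, terms)
    per_fold[[f]] <- list(
      per_term_auc = aucs,
      macro_auc = suppressWarnings(macro_auc(aucs)),
      fmax = fmax(test_scores, truth)
    )
  }
  pooled_aucs <- term_auc_by_pairs(pooled, pairs, terms)
  pooled_truth <- annotation_matrix(pairs[pairs$label == 1, , drop = FALSE],
                                    proteins, terms)
  pooled_report <- list(
    per_term_auc = pooled_aucs,
    macro_auc = suppressWarnings(macro_auc(pooled_aucs)),
    fmax = fmax(pooled, pooled_truth)
  )
  list(folds = pairs, per_fold = per_fold, pooled = pooled_report,
       pooled_scores = pooled)
}

#' Percentile bootstrap confidence interval
#'
#' Recomputes a statistic on resampled evaluation units (with replacement)
#' and returns the percentile interval.
#'
#' @param stat_fn function taking a vector of unit indices (with
#'   replacement) and returning a scalar statistic.
#' @param n_units number of resampling units.
#' @param iterations bootstrap iterations.
#' @param level confidence level.
#' @param seed integer seed.
#' @return list with `low`, `high`, and the vector of bootstrap `replicates`.
#' @export
bootstrap_ci <- function(stat_fn, n_units, iterations = 100, level = 0.95,
                         seed = 1) {
  reps <- with_seed(seed, {
    vapply(seq_len(iterations), function(i) {
      stat_fn(sample.int(n_units, n_units, replace = TRUE))
    }, numeric(1))
  })
  a <- (1 - level) / 2
  q <- stats::quantile(reps, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(low = q[1], high = q[2], replicates = reps)
}

#' Bootstrap interval for F-max (resampling proteins)
#'
#' @param scores,truth as in [fmax()].
#' @param iterations,level,seed see [bootstrap_ci()].
#' @param thresholds threshold grid passed to [fmax()].
#' @return list with `low`, `high`, `replicates`.
#' @export
bootstrap_ci_fmax <- function(scores, truth, iterations = 100, level = 0.95,
                              seed = 1, thresholds = seq(0, 1, by = 0.01)) {
  bootstrap_ci(function(idx) {
    fmax(scores[idx, , drop = FALSE], truth[idx, , drop = FALSE],
         thresholds)$fmax
  }, n_units = nrow(scores), iterations = iterations, level = level,
  seed = seed)
}

#' Bootstrap interval for the macro AUC (resampling terms)
#'
#' @param per_term_auc named per-term AUC vector.
#' @param iterations,level,seed see [bootstrap_ci()].
#' @return list with `low`, `high`, `replicates`.
#' @export
bootstrap_ci_macro_auc <- function(per_term_auc, iterations = 100,
                                   level = 0.95, seed = 1) {
  aucs <- per_term_auc[!is.na(per_term_auc)]
  bootstrap_ci(function(idx) mean(aucs[idx]), n_units = length(aucs),
               iterations = iterations, level = level, seed = seed)
}

#' Smallest shared annotation between two proteins
#'
#' Among the terms annotating both proteins in the corpus, returns the one
#' with the fewest annotated proteins (ties broken by the lexicographically
#' smallest term id). Protein pairs with a smaller count share a more
#' specific annotation, indicating closer functional similarity.
#'
#' @param protein_a,protein_b protein ids.
#' @param corpus annotation data.frame (`protein`, `term`).
#' @return list with `term` and `count`, or `NULL` when no term is shared.
#' @export
smallest_shared_annotation <- function(protein_a, protein_b, corpus) {
  ta <- unique(corpus$term[corpus$protein == protein_a])
  tb <- unique(corpus$term[corpus$protein == protein_b])
  shared <- intersect(ta, tb)
  if (!length(shared)) return(NULL)
  cnt <- term_counts(corpus)[shared]
  m <- min(cnt)
  list(term = sort(names(cnt)[cnt == m])[1], count = unname(m))
}
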