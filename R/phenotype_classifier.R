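# Supervised stage: a two-layer multi-label neural network on the latent
# protein embeddings. Layer order is fully-connected -> batch normalization
# -> leaky rectifier -> dropout, followed by a linear output layer and an
# elementwise sigmoid, so every protein gets a probability for every
# retained ontology term. The loss is binary cross-entropy masked to the
# labeled (positive or sampled-negative) pairs only: unlabeled protein-term
# cells contribute no gradient. Per-term decision thresholds are chosen by
# the Youden index.

#' Initialize classifier parameters
#'
#' @param input_dim embedding width.
#' @param hidden_dim hidden layer width.
#' @param n_terms output width (number of retained terms).
#' @param seed integer seed for the Glorot draws.
#' @return object of class `mlp_params`: weights `W0`, `b0`, batch-norm
#'   `gamma`/`beta`, `W1`, `b1`, plus running batch-norm statistics
#'   (`running_mean`, `running_var`) used at inference.
#' @export
mlp_params <- function(input_dim, hidden_dim = 512, n_terms, seed = NULL) {
  with_seed(seed, {
    structure(
      list(W0 = glorot(input_dim, hidden_dim), b0 = numeric(hidden_dim),
           gamma = rep(1, hidden_dim), beta = numeric(hidden_dim),
           W1 = glorot(hidden_dim, n_terms), b1 = numeric(n_terms),
           running_mean = numeric(hidden_dim),
           running_var = rep(1, hidden_dim)),
      class = "mlp_params"
    )
  })
}

#' Classifier forward pass
#'
#' `hidden = act(BN(Z W0 + b0))` with dropout applied to the hidden layer
#' only when `training = TRUE`; `scores = sigmoid(hidden W1 + b1)`. At
#' inference batch normalization uses the stored running statistics and
#' dropout is disabled, so repeated calls are identical.
#'
#' @param Z `n x d` embedding matrix.
#' @param params an `mlp_params`.
#' @param training use batch statistics and dropout.
#' @param dropout dropout rate in [0, 1) (active only when training).
#' @param dropout_mask optional pre-drawn binary hidden mask (overrides the
#'   RNG; used internally for reproducible training).
#' @param batchnorm apply batch normalization (disable for a plain dense
#'   network).
#' @param activation,slope hidden nonlinearity.
#' @param bn_eps numerical floor inside the batch-norm denominator.
#' @return `n x n_terms` score matrix with entries in (0, 1).
#' @export
mlp_forward <- function(Z, params, training = FALSE, dropout = 0,
                        dropout_mask = NULL, batchnorm = TRUE,
                        activation = "leaky_relu", slope = 0.01,
                        bn_eps = 1e-5) {
  if (ncol(Z) != nrow(params$W0)) {
    stop(sprintf("mlp_forward: embedding width %d does not match W0 rows %d",
                 ncol(Z), nrow(params$W0)))
  }
  act <- activation_funs(activation, slope)
  pre <- add_bias(Z %*% params$W0, params$b0)
  if (batchnorm) {
    if (training) {
      mu_b <- colMeans(pre)
      var_b <- colMeans(pre^2) - mu_b^2
    } else {
      mu_b <- params$running_mean
      var_b <- params$running_var
    }
    xhat <- sweep(sweep(pre, 2, mu_b, "-"), 2, sqrt(var_b + bn_eps), "/")
    bn <- add_bias(sweep(xhat, 2, params$gamma, "*"), params$beta)
  } else {
    bn <- pre
  }
  hid <- act$f(bn)
  if (training && dropout > 0) {
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix(stats::runif(length(hid)) >= dropout,
                             nrow(hid), ncol(hid))
    }
    hid <- hid * dropout_mask / (1 - dropout)
  }
  logits <- add_bias(hid %*% params$W1, params$b1)
  scores <- stats::plogis(logits)
  dimnames(scores) <- list(rownames(Z), colnames(params$W1))
  scores
}

# Forward + backward pass for one full-batch step with fixed dropout mask.
# Y/M are label and mask matrices; loss = sum(M * bce) / sum(M). Returns the
# loss, gradients and batch statistics. Exposed internally for gradient
# tests.
mlp_grad_step <- function(params, Z, Y, M, dropout_mask = NULL, dropout = 0,
                          batchnorm = TRUE, act, bn_eps = 1e-5) {
  n <- nrow(Z)
  pre <- add_bias(Z %*% params$W0, params$b0)
  if (batchnorm) {
    mu_b <- colMeans(pre)
    var_b <- colMeans(pre^2) - mu_b^2
    sd_b <- sqrt(var_b + bn_eps)
    xhat <- sweep(sweep(pre, 2, mu_b, "-"), 2, sd_b, "/")
    bn <- add_bias(sweep(xhat, 2, params$gamma, "*"), params$beta)
  } else {
    bn <- pre
  }
  hid0 <- act$f(bn)
  if (dropout > 0) {
    if (is.null(dropout_mask)) dropout_mask <- matrix(1, n, ncol(hid0))
    hid <- hid0 * dropout_mask / (1 - dropout)
  } else {
    hid <- hid0
  }
  logits <- add_bias(hid %*% params$W1, params$b1)
  nlab <- sum(M)
  if (nlab == 0) stop("mlp_grad_step: no labeled pairs")
  bce <- Y * softplus(-logits) + (1 - Y) * softplus(logits)
  loss <- sum(M * bce) / nlab

  P <- stats::plogis(logits)
  dlogits <- M * (P - Y) / nlab
  dW1 <- crossprod(hid, dlogits)
  db1 <- colSums(dlogits)
  dhid <- dlogits %*% t(params$W1)
  if (dropout > 0) dhid <- dhid * dropout_mask / (1 - dropout)
  dbn <- dhid * act$grad(bn)
  if (batchnorm) {
    dgamma <- colSums(dbn * xhat)
    dbeta <- colSums(dbn)
    dxhat <- sweep(dbn, 2, params$gamma, "*")
    # standard batch-norm backward over the batch dimension
    sum_dxhat <- colSums(dxhat)
    sum_dxhat_xhat <- colSums(dxhat * xhat)
    dpre <- sweep(
      n * dxhat - matrix(sum_dxhat, n, length(sum_dxhat), byrow = TRUE) -
        xhat * matrix(sum_dxhat_xhat, n, length(sum_dxhat), byrow = TRUE),
      2, n * sd_b, "/")
  } else {
    dgamma <- params$gamma * 0
    dbeta <- params$beta * 0
    dpre <- dbn
    mu_b <- NULL
    var_b <- NULL
  }
  dW0 <- crossprod(Z, dpre)
  db0 <- colSums(dpre)
  list(loss = loss,
       grads = list(W0 = dW0, b0 = db0, gamma = dgamma, beta = dbeta,
                    W1 = dW1, b1 = db1),
       batch_mean = mu_b, batch_var = var_b)
}

#' Train the multi-label phenotype classifier
#'
#' Full-batch training with the Adam update rule on the masked binary
#' cross-entropy: only (protein, term) pairs present in the gold-standard
#' positives or sampled negatives (optionally restricted to `train_pairs`)
#' contribute to the loss; unlabeled cells are ignored, matching the
#' explicit negative-set construction rather than treating every unlabeled
#' pair as negative. Deterministic given `seed`.
#'
#' @param Z `n x d` embedding matrix with protein rownames covering the
#'   gold-standard universe.
#' @param gold a `gold_standard`.
#' @param train_pairs optional data.frame (`protein`, `term`, `label`)
#'   restricting training to a subset of the gold pairs (e.g., CV folds).
#' @param hidden_dim,dropout architecture settings.
#' @param epochs,lr,seed,optimizer optimization settings (0 epochs returns
#'   the initialization).
#' @param batchnorm,activation,slope see [mlp_forward()].
#' @param bn_momentum running-statistics update rate.
#' @return object of class `mlp_fit`: `params` (with running batch-norm
#'   statistics), `loss_history`, `config`, and `terms` (output order,
#'   the gold term universe).
#' @export
train_classifier <- function(Z, gold, train_pairs = NULL, hidden_dim = 512,
                             dropout = 0.3, epochs = 500, lr = 0.01, seed = 1,
                             optimizer = c("adam", "sgd"), batchnorm = TRUE,
                             activation = "leaky_relu", slope = 0.01,
                             bn_momentum = 0.1) {
  optimizer <- match.arg(optimizer)
  missing_p <- setdiff(gold$protein_universe, rownames(Z))
  if (length(missing_p)) {
    stop("train_classifier: embedding lacks rows for ",
         paste(utils::head(missing_p, 5), collapse = ", "))
  }
  Z <- Z[gold$protein_universe, , drop = FALSE]
  lm <- label_matrices(gold, train_pairs)
  empty_terms <- colnames(lm$M)[colSums(lm$M) == 0]
  if (length(empty_terms)) {
    warning(sprintf("train_classifier: %d term(s) without training pairs are skipped in the loss",
                    length(empty_terms)))
  }
  act <- activation_funs(activation, slope)
  n <- nrow(Z)
  with_seed(seed, {
    params <- unclass(mlp_params(ncol(Z), hidden_dim,
                                 length(gold$term_universe), seed = NULL))
    colnames(params$W1) <- gold$term_universe
    trainable <- c("W0", "b0", "gamma", "beta", "W1", "b1")
    state <- optim_state(params[trainable])
    loss_hist <- numeric(epochs)
    if (epochs > 0) {
      for (ep in seq_len(epochs)) {
        mask <- if (dropout > 0) {
          matrix(stats::runif(n * hidden_dim) >= dropout, n, hidden_dim)
        } else NULL
        step <- mlp_grad_step(params, Z, lm$Y, lm$M, dropout_mask = mask,
                              dropout = dropout, batchnorm = batchnorm,
                              act = act)
        if (!is.finite(step$loss)) {
          stop(sprintf("train_classifier: training diverged at epoch %d", ep))
        }
        loss_hist[ep] <- step$loss
        upd <- optim_step(params[trainable], step$grads, state, lr, optimizer)
        params[trainable] <- upd$params
        state <- upd$state
        if (batchnorm) {
          params$running_mean <- (1 - bn_momentum) * params$running_mean +
            bn_momentum * step$batch_mean
          params$running_var <- (1 - bn_momentum) * params$running_var +
            bn_momentum * step$batch_var
        }
      }
    }
    structure(
      list(params = structure(params, class = "mlp_params"),
           loss_history = loss_hist,
           terms = gold$term_universe,
           config = list(hidden_dim = hidden_dim, dropout = dropout,
                         epochs = epochs, lr = lr, seed = seed,
                         optimizer = optimizer, batchnorm = batchnorm,
                         activation = activation, slope = slope)),
      class = "mlp_fit"
    )
  })
}

#' Score all protein-term pairs with a trained classifier
#'
#' @param fit an `mlp_fit`.
#' @param Z embedding matrix (protein rownames).
#' @return protein x term score matrix in (0, 1).
#' @export
predict_scores <- function(fit, Z) {
  cfg <- fit$config
  mlp_forward(Z, fit$params, training = FALSE, batchnorm = cfg$batchnorm,
              activation = cfg$activation, slope = cfg$slope)
}

#' Youden-index decision thresholds
#'
#' For each term, scans candidate cut-points (the term's observed labeled
#' scores plus 0 and 1) and returns the threshold maximizing the Youden
#' index `J(t) = Sn(t) + Sp(t) - 1`, where a protein is called positive when
#' its score is greater than or equal to `t`. Ties are broken by the
#' smallest maximizing threshold.
#'
#' @param scores protein x term score matrix.
#' @param gold a `gold_standard` supplying the labeled pairs.
#' @param pairs optional data.frame (`protein`, `term`, `label`) overriding
#'   the gold pairs (e.g., cross-validation scores).
#' @return named numeric vector of per-term thresholds; `NA` (with a
#'   warning) for terms lacking positives or negatives.
#' @export
youden_thresholds <- function(scores, gold, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- rbind(
      data.frame(gold$positives[, c("protein", "term")], label = 1),
      data.frame(gold$negatives[, c("protein", "term")], label = 0)
    )
  }
  terms <- gold$term_universe
  out <- stats::setNames(rep(NA_real_, length(terms)), terms)
  n_flagged <- 0L
  for (tt in terms) {
    p <- pairs[pairs$term == tt, , drop = FALSE]
    pos_id <- p$protein[p$label == 1]
    neg_id <- p$protein[p$label == 0]
    pos <- if (length(pos_id)) scores[pos_id, tt] else numeric(0)
    neg <- if (length(neg_id)) scores[neg_id, tt] else numeric(0)
    if (!length(pos) || !length(neg)) {
      n_flagged <- n_flagged + 1L
      next
    }
    cand <- sort(unique(c(0, pos, neg, 1)))
    j <- vapply(cand, function(t) mean(pos >= t) + mean(neg < t) - 1, 0)
    out[tt] <- cand[which.max(j)] # which.max takes the first (smallest) maximizer
  }
  if (n_flagged) {
    warning(sprintf("youden_thresholds: %d term(s) lacked positives or negatives; threshold undefined", n_flagged))
  }
  out
}

#' Binary calls from scores and per-term thresholds
#'
#' A pair is called positive when its score is greater than or equal to the
#' term's threshold (boundary scores count as positive).
#'
#' @param scores protein x term score matrix.
#' @param thresholds named per-term threshold vector (see
#'   [youden_thresholds()]); terms with `NA` thresholds yield `NA` calls.
#' @return binary matrix of the same shape as `scores`.
#' @export
binarize <- function(scores, thresholds) {
  th <- thresholds[colnames(scores)]
  calls <- sweep(scores, 2, th, ">=") * 1
  calls
}
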