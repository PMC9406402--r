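# Weighted PPI adjacency construction, symmetric normalization, and the
# variational graph autoencoder (two-layer GCN encoder with Gaussian
# posteriors, inner-product decoder, ELBO objective). Training is full-batch
# gradient descent with analytically derived gradients; graphs at the scale
# this package targets (up to a few thousand nodes) fit comfortably in dense
# matrices.

#' Build the weighted protein interaction adjacency
#'
#' Edges with combined score strictly greater than `score_min_exclusive`
#' (default 300, the conventional medium-confidence cutoff) contribute
#' symmetric off-diagonal weights `combined_score / 1000`; every protein is
#' additionally connected to itself (unit diagonal). Edges touching proteins
#' outside the universe are dropped with a logged count.
#'
#' @param edges edge-list data.frame from [load_edge_list()].
#' @param universe ordered protein universe (row/column order of `A`).
#' @param score_min_exclusive exclusive combined-score cutoff.
#' @return object of class `protein_graph`: list with `proteins` and the
#'   symmetric weighted adjacency `A` (unit diagonal, entries in [0, 1]).
#' @export
build_adjacency <- function(edges, universe, score_min_exclusive = 300) {
  if (!length(universe)) stop("protein universe is empty")
  if (anyDuplicated(universe)) stop("protein universe contains duplicates")
  n <- length(universe)
  A <- matrix(0, n, n, dimnames = list(universe, universe))
  e <- edges[edges$combined_score > score_min_exclusive, , drop = FALSE]
  inside <- e$protein_a %in% universe & e$protein_b %in% universe
  if (any(!inside)) {
    message(sprintf(
      "build_adjacency: %d edge(s) touching proteins outside the universe dropped",
      sum(!inside)))
  }
  e <- e[inside & e$protein_a != e$protein_b, , drop = FALSE]
  if (nrow(e)) {
    ia <- match(e$protein_a, universe)
    ib <- match(e$protein_b, universe)
    w <- e$combined_score / 1000
    A[cbind(ia, ib)] <- w
    A[cbind(ib, ia)] <- w
  }
  diag(A) <- 1
  structure(list(proteins = universe, A = A), class = "protein_graph")
}

#' @export
print.protein_graph <- function(x, ...) {
  n <- length(x$proteins)
  cat(sprintf("protein_graph: %d proteins, %d weighted edges\n",
              n, sum(x$A[upper.tri(x$A)] > 0)))
  invisible(x)
}

#' Symmetrically normalized adjacency
#'
#' Computes `D^{-1/2} A D^{-1/2}` with `D = diag(rowSums(A))`. The self-loop
#' is already present once in `A` (unit diagonal from [build_adjacency()]),
#' so no identity matrix is added by default; `double_self_loop = TRUE`
#' additionally adds `I` before normalizing, reproducing the variant in
#' which the self-loop is counted twice.
#'
#' @param graph a `protein_graph` or a raw adjacency matrix.
#' @param double_self_loop add the identity a second time before normalizing.
#' @return symmetric normalized adjacency matrix with row sums at most 1.
#' @export
normalize_adjacency <- function(graph, double_self_loop = FALSE) {
  A <- if (inherits(graph, "protein_graph")) graph$A else as.matrix(graph)
  if (double_self_loop) A <- A + diag(nrow(A))
  d <- rowSums(A)
  if (any(d <= 0)) stop("zero row sum in adjacency; expected a unit diagonal")
  dm <- 1 / sqrt(d)
  A * outer(dm, dm)
}

#' One graph-convolution layer
#'
#' Computes `activation(A_norm %*% Z_in %*% W)`: neighborhood aggregation
#' over the normalized adjacency followed by a linear filter and pointwise
#' nonlinearity.
#'
#' @param Z_in `n x k` input matrix.
#' @param A_norm `n x n` normalized adjacency.
#' @param W `k x m` filter matrix.
#' @param activation one of `"leaky_relu"` (default, negative slope `slope`),
#'   `"relu"`, `"linear"`.
#' @param slope negative slope of the leaky rectifier.
#' @return `n x m` output matrix.
#' @export
gcn_layer <- function(Z_in, A_norm, W, activation = "leaky_relu",
                      slope = 0.01) {
  if (ncol(A_norm) != nrow(Z_in)) {
    stop(sprintf("gcn_layer: adjacency is %dx%d but input has %d rows",
                 nrow(A_norm), ncol(A_norm), nrow(Z_in)))
  }
  if (ncol(Z_in) != nrow(W)) {
    stop(sprintf("gcn_layer: input width %d does not match filter rows %d",
                 ncol(Z_in), nrow(W)))
  }
  act <- activation_funs(activation, slope)
  act$f(A_norm %*% Z_in %*% W)
}

#' Initialize encoder parameters
#'
#' Glorot-uniform weights for the shared first GCN layer (`W0`) and the two
#' second-layer heads producing the posterior mean (`W_mu`) and log standard
#' deviation (`W_logsig`).
#'
#' @param input_dim feature width (343 for conjoint-triad features).
#' @param hidden_dim shared hidden width.
#' @param latent_dim latent embedding width.
#' @param seed integer seed for the draw.
#' @return object of class `vgae_params` (named list of matrices).
#' @export
vgae_params <- function(input_dim, hidden_dim = 256, latent_dim = 64,
                        seed = NULL) {
  with_seed(seed, {
    structure(
      list(W0 = glorot(input_dim, hidden_dim),
           W_mu = glorot(hidden_dim, latent_dim),
           W_logsig = glorot(hidden_dim, latent_dim)),
      class = "vgae_params"
    )
  })
}

#' Deterministic encoder pass
#'
#' `hidden = act(A_norm X W0)`; the posterior mean is the linear head
#' `mu = A_norm hidden W_mu` and the posterior scale is
#' `sigma = exp(A_norm hidden W_logsig)` (diagonal Gaussian per node).
#'
#' @param X `n x input_dim` feature matrix (rows in graph order).
#' @param A_norm normalized adjacency.
#' @param params a `vgae_params`.
#' @param activation,slope hidden-layer nonlinearity (see [gcn_layer()]).
#' @return list with `mu`, `sigma`, `log_sigma`, `hidden`.
#' @export
vgae_encode <- function(X, A_norm, params, activation = "leaky_relu",
                        slope = 0.01) {
  act <- activation_funs(activation, slope)
  pre <- A_norm %*% X %*% params$W0
  H <- act$f(pre)
  AH <- A_norm %*% H
  mu <- AH %*% params$W_mu
  log_sigma <- AH %*% params$W_logsig
  sigma <- exp(log_sigma)
  if (!all(is.finite(mu)) || !all(is.finite(sigma))) {
    stop("vgae_encode: non-finite encoder output (check feature scaling / learning rate)")
  }
  list(mu = mu, sigma = sigma, log_sigma = log_sigma, hidden = H)
}

#' Reparameterized latent sample
#'
#' Draws `Z = mu + sigma * epsilon` with `epsilon ~ N(0, 1)` elementwise.
#' A fixed `epsilon` (e.g., all zeros) makes the pass deterministic.
#'
#' @param mu,sigma posterior mean and scale (`n x d`).
#' @param seed integer seed for the standard-normal draw.
#' @param epsilon optional pre-drawn `n x d` noise matrix overriding `seed`.
#' @return `n x d` sampled latent codes.
#' @export
reparameterize <- function(mu, sigma, seed = NULL, epsilon = NULL) {
  if (is.null(epsilon)) {
    epsilon <- with_seed(seed, matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)))
  }
  mu + sigma * epsilon
}

#' Inner-product decoder
#'
#' Edge probability `sigmoid(z_i . z_j)` for every node pair.
#'
#' @param Z `n x d` latent codes.
#' @return symmetric `n x n` matrix of probabilities in (0, 1).
#' @export
decode_inner_product <- function(Z) {
  stats::plogis(tcrossprod(Z))
}

#' Negative evidence lower bound of the graph autoencoder
#'
#' Reconstruction term: mean weighted binary cross-entropy between the
#' decoded edge probabilities and the binarized target adjacency (positive
#' class reweighted by `pos_weight`, overall scaled by `norm`; defaults
#' counteract edge sparsity as `pos_weight = #zeros/#ones` and
#' `norm = n^2 / (2 #zeros)`). KL term: `KL(N(mu, sigma^2) || N(0, 1))
#' = 1/2 sum(mu^2 + sigma^2 - 1 - 2 log sigma)`, scaled by `kl_scale`
#' (default `1/n^2`, which averages the divergence over the same number of
#' entries as the reconstruction mean — the conventional graph-autoencoder
#' objective scaling; a per-node weight of `1/n` over-regularizes small
#' graphs and collapses the posterior onto the prior). The KL term is
#' non-negative and zero exactly at `mu = 0, sigma = 1`. The returned
#' `loss` (recon + kl) is minimized during training.
#'
#' @param Z sampled latent codes.
#' @param mu,sigma posterior parameters (`sigma > 0`).
#' @param A_target adjacency to reconstruct; entries > 0 count as edges
#'   (the unit diagonal counts as self-edges).
#' @param pos_weight,norm reconstruction weighting overrides.
#' @param kl_scale multiplier on the summed KL divergence (default
#'   `1 / n^2`).
#' @return list with `loss`, `recon`, `kl`.
#' @export
vgae_loss <- function(Z, mu, sigma, A_target, pos_weight = NULL, norm = NULL,
                      kl_scale = NULL) {
  if (any(sigma <= 0)) stop("vgae_loss: sigma must be strictly positive")
  Tgt <- (A_target > 0) * 1
  n2 <- length(Tgt)
  npos <- sum(Tgt)
  if (npos == 0 || npos == n2) {
    if (is.null(pos_weight)) pos_weight <- 1
    if (is.null(norm)) norm <- 1
  } else {
    if (is.null(pos_weight)) pos_weight <- (n2 - npos) / npos
    if (is.null(norm)) norm <- n2 / (2 * (n2 - npos))
  }
  if (is.null(kl_scale)) kl_scale <- 1 / nrow(mu)^2
  logits <- tcrossprod(Z)
  bce <- pos_weight * Tgt * softplus(-logits) + (1 - Tgt) * softplus(logits)
  recon <- norm * mean(bce)
  kl <- kl_scale * 0.5 * sum(mu^2 + sigma^2 - 1 - 2 * log(sigma))
  list(loss = recon + kl, recon = recon, kl = kl)
}

# One forward/backward pass with a fixed noise draw E. Returns the loss
# components and analytic gradients w.r.t. W0, W_mu, W_logsig. Factored out
# so tests can compare the gradients against finite differences.
vgae_grad_step <- function(params, AX, A_norm, Tgt, E, act,
                           pos_weight, norm, kl_scale = NULL) {
  pre <- AX %*% params$W0
  H <- act$f(pre)
  AH <- A_norm %*% H
  mu <- AH %*% params$W_mu
  log_sigma <- AH %*% params$W_logsig
  sigma <- exp(log_sigma)
  Z <- mu + sigma * E
  n <- nrow(mu)
  n2 <- length(Tgt)
  if (is.null(kl_scale)) kl_scale <- 1 / n^2

  logits <- tcrossprod(Z)
  bce <- pos_weight * Tgt * softplus(-logits) + (1 - Tgt) * softplus(logits)
  recon <- norm * mean(bce)
  kl <- kl_scale * 0.5 * sum(mu^2 + sigma^2 - 1 - 2 * log_sigma)
  loss <- recon + kl

  P <- stats::plogis(logits)
  G <- (norm / n2) * ((1 - Tgt) * P - pos_weight * Tgt * (1 - P))
  dZ <- (G + t(G)) %*% Z
  dmu <- dZ + kl_scale * mu
  dlog_sigma <- dZ * sigma * E + kl_scale * (sigma^2 - 1)
  dW_mu <- crossprod(AH, dmu)
  dW_logsig <- crossprod(AH, dlog_sigma)
  dH <- A_norm %*% (dmu %*% t(params$W_mu) + dlog_sigma %*% t(params$W_logsig))
  dpre <- dH * act$grad(pre)
  dW0 <- crossprod(AX, dpre)

  list(loss = loss, recon = recon, kl = kl,
       grads = list(W0 = dW0, W_mu = dW_mu, W_logsig = dW_logsig))
}

#' Train the variational graph autoencoder
#'
#' Full-batch training of the two-layer GCN encoder and inner-product
#' decoder by gradient descent on the negative ELBO; the default update
#' rule is Adam, with plain SGD selectable. One fresh reparameterization
#' noise draw is used per epoch. The run is deterministic given `seed`.
#'
#' @param X `n x p` feature matrix, rows aligned with `graph$proteins`
#'   (checked via rownames when present).
#' @param graph a `protein_graph` (or adjacency matrix with unit diagonal).
#' @param latent_dim,hidden_dim encoder widths.
#' @param epochs number of full-batch epochs (0 returns the initialization).
#' @param lr learning rate.
#' @param seed seed covering initialization and noise draws.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param activation,slope hidden nonlinearity.
#' @param pos_weight reconstruction positive-class weight override.
#' @param double_self_loop see [normalize_adjacency()].
#' @param verbose print the loss every 50 epochs.
#' @return object of class `vgae_fit`: `params`, posterior `mu` and `sigma`,
#'   a final sampled `Z`, `loss_history`, and the resolved `config`. The
#'   posterior mean `mu` is the deterministic embedding used downstream.
#' @export
train_vgae <- function(X, graph, latent_dim = 64, hidden_dim = 256,
                       epochs = 200, lr = 0.01, seed = 1,
                       optimizer = c("adam", "sgd"),
                       activation = "leaky_relu", slope = 0.01,
                       pos_weight = NULL, double_self_loop = FALSE,
                       verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  A <- if (inherits(graph, "protein_graph")) graph$A else as.matrix(graph)
  X <- as.matrix(X)
  if (nrow(X) != nrow(A)) {
    stop("train_vgae: feature rows do not match the number of graph nodes")
  }
  if (!is.null(rownames(X)) && !is.null(rownames(A)) &&
      !identical(rownames(X), rownames(A))) {
    stop("train_vgae: feature row order does not match graph protein order")
  }
  act <- activation_funs(activation, slope)
  A_norm <- normalize_adjacency(A, double_self_loop = double_self_loop)
  Tgt <- (A > 0) * 1
  n <- nrow(A)
  n2 <- length(Tgt)
  npos <- sum(Tgt)
  if (is.null(pos_weight)) {
    pos_weight <- if (npos > 0 && npos < n2) (n2 - npos) / npos else 1
  }
  norm <- if (npos > 0 && npos < n2) n2 / (2 * (n2 - npos)) else 1

  with_seed(seed, {
    params <- unclass(vgae_params(ncol(X), hidden_dim, latent_dim, seed = NULL))
    AX <- A_norm %*% X
    state <- optim_state(params)
    loss_hist <- numeric(epochs)
    if (epochs > 0) {
      for (ep in seq_len(epochs)) {
        E <- matrix(stats::rnorm(n * latent_dim), n, latent_dim)
        step <- vgae_grad_step(params, AX, A_norm, Tgt, E, act,
                               pos_weight, norm)
        if (!is.finite(step$loss)) {
          stop(sprintf("train_vgae: training diverged (non-finite loss at epoch %d)", ep))
        }
        loss_hist[ep] <- step$loss
        upd <- optim_step(params, step$grads, state, lr, optimizer)
        params <- upd$params
        state <- upd$state
        if (verbose && (ep %% 50 == 0 || ep == 1)) {
          message(sprintf("epoch %4d  loss %.4f", ep, step$loss))
        }
      }
    }
    enc <- vgae_encode(X, A_norm, params, activation, slope)
    Z <- reparameterize(enc$mu, enc$sigma,
                        epsilon = matrix(stats::rnorm(n * latent_dim), n, latent_dim))
    rownames(enc$mu) <- rownames(enc$sigma) <- rownames(Z) <- rownames(A)
    structure(
      list(params = structure(params, class = "vgae_params"),
           mu = enc$mu, sigma = enc$sigma, Z = Z,
           loss_history = loss_hist,
           config = list(latent_dim = latent_dim, hidden_dim = hidden_dim,
                         epochs = epochs, lr = lr, seed = seed,
                         optimizer = optimizer, activation = activation,
                         slope = slope, pos_weight = pos_weight,
                         double_self_loop = double_self_loop)),
      class = "vgae_fit"
    )
  })
}

#' @export
print.vgae_fit <- function(x, ...) {
  cat(sprintf(
    "vgae_fit: %d nodes -> %d latent dims (hidden %d, %d epochs, final loss %s)\n",
    nrow(x$mu), ncol(x$mu), x$config$hidden_dim, x$config$epochs,
    if (length(x$loss_history)) sprintf("%.4f", utils::tail(x$loss_history, 1)) else "n/a"))
  invisible(x)
}

#' Split a graph into training graph and held-out link-prediction sets
#'
#' Removes a fraction of the (off-diagonal) edges uniformly at random and
#' samples an equal number of non-edges (pairs absent from the full graph)
#' as negatives for link-prediction evaluation.
#'
#' @param graph a `protein_graph`.
#' @param test_fraction fraction of edges held out.
#' @param seed integer seed.
#' @return list with `train_graph` (held-out edge weights zeroed), `test_edges`
#'   and `test_nonedges` (two-column index matrices, i < j).
#' @export
split_edges <- function(graph, test_fraction = 0.1, seed = 1) {
  A <- graph$A
  n <- nrow(A)
  ut <- which(upper.tri(A), arr.ind = TRUE)
  is_edge <- A[ut] > 0
  edges <- ut[is_edge, , drop = FALSE]
  nonedges <- ut[!is_edge, , drop = FALSE]
  n_test <- max(1L, round(nrow(edges) * test_fraction))
  if (nrow(nonedges) < n_test) {
    stop("split_edges: not enough non-edges to match the held-out edge count")
  }
  with_seed(seed, {
    te <- edges[sample(nrow(edges), n_test), , drop = FALSE]
    tn <- nonedges[sample(nrow(nonedges), n_test), , drop = FALSE]
    At <- A
    At[te] <- 0
    At[te[, c(2, 1), drop = FALSE]] <- 0
    list(train_graph = structure(list(proteins = graph$proteins, A = At),
                                 class = "protein_graph"),
         test_edges = te, test_nonedges = tn)
  })
}

#' Held-out link reconstruction AUC
#'
#' Trains the autoencoder on a graph with a fraction of edges removed, then
#' measures how well the decoded probabilities separate the held-out edges
#' from an equal number of sampled non-edges (ROC AUC).
#'
#' @param X feature matrix aligned with the graph.
#' @param graph a `protein_graph`.
#' @param test_fraction fraction of edges held out.
#' @param seed seed for both the split and the training run.
#' @param ... passed to [train_vgae()].
#' @return list with `auc`, the `fit`, and the split.
#' @export
evaluate_link_reconstruction <- function(X, graph, test_fraction = 0.1,
                                         seed = 1, ...) {
  sp <- split_edges(graph, test_fraction, seed)
  fit <- train_vgae(X, sp$train_graph, seed = seed, ...)
  P <- decode_inner_product(fit$mu)
  auc <- term_auc(P[sp$test_edges], P[sp$test_nonedges])
  list(auc = auc, fit = fit, split = sp)
}

#' Export an embedding as TSV
#'
#' @param embedding matrix with protein rownames (e.g., `fit$mu`).
#' @param path output path.
#' @export
write_embedding <- function(embedding, path) {
  df <- data.frame(protein = rownames(embedding), embedding,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("protein", paste0("d", seq_len(ncol(embedding))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import an embedding written by [write_embedding()]
#'
#' @param path TSV path.
#' @return numeric matrix with protein rownames.
#' @export
read_embedding <- function(path) {
  if (!file.exists(path)) stop("embedding file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
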