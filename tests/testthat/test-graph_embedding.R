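test_that("adjacency construction applies the strict score cutoff and unit diagonal", {
  edges <- data.frame(protein_a = c("P1", "P1", "P2"),
                      protein_b = c("P2", "P3", "P3"),
                      combined_score = c(700L, 300L, 301L))
  g <- build_adjacency(edges, c("P1", "P2", "P3"))
  expect_equal(g$A["P1", "P2"], 0.7) # combined score / 1000
  expect_equal(g$A["P2", "P1"], 0.7)
  expect_equal(g$A["P1", "P3"], 0)   # score 300 dropped (strictly greater rule)
  expect_equal(g$A["P2", "P3"], 0.301)
  expect_equal(unname(diag(g$A)), rep(1, 3))
  expect_true(isSymmetric(g$A))
})

test_that("edges outside the universe are dropped and isolated nodes keep self-loops", {
  edges <- data.frame(protein_a = c("P1", "P8"), protein_b = c("P2", "P9"),
                      combined_score = c(500L, 900L))
  expect_message(g <- build_adjacency(edges, c("P1", "P2", "P3")), "dropped")
  expect_equal(sum(g$A) - 3, 2 * 0.5) # only the P1-P2 edge remains
  g0 <- build_adjacency(edges[0, ], c("A", "B", "C"))
  expect_equal(g0$A, diag(3), ignore_attr = TRUE)
})

test_that("symmetric normalization matches hand computations and stays bounded", {
  expect_equal(normalize_adjacency(matrix(1)), matrix(1))
  A2 <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(normalize_adjacency(A2), matrix(0.5, 2, 2))
  withr::with_seed(3, {
    for (i in 1:10) {
      n <- sample(3:12, 1)
      A <- matrix(0, n, n)
      A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, 0.4) *
        stats::runif(n * (n - 1) / 2, 0.3, 1)
      A <- A + t(A)
      diag(A) <- 1
      An <- normalize_adjacency(A)
      expect_true(isSymmetric(An, tol = 1e-12))
      # the normalized operator is similar to a row-stochastic matrix,
      # so its spectral radius is bounded by one
      expect_lte(max(abs(eigen(An, only.values = TRUE)$values)), 1 + 1e-10)
    }
  })
  # the double-self-loop variant adds I before normalizing
  Ad <- normalize_adjacency(matrix(1), double_self_loop = TRUE)
  expect_equal(Ad, matrix(1))
})

test_that("a GCN layer reduces to identity or a dense product as expected", {
  Z <- matrix(rnorm(12), 4, 3)
  expect_equal(gcn_layer(Z, diag(4), diag(3), activation = "linear"), Z)
  expect_equal(gcn_layer(Z * 0, diag(4), matrix(rnorm(9), 3, 3)),
               matrix(0, 4, 3))
  withr::with_seed(5, {
    A <- matrix(runif(16), 4, 4); A <- (A + t(A)) / 2; diag(A) <- 1
    An <- normalize_adjacency(A)
    W <- matrix(rnorm(6), 3, 2)
    out <- gcn_layer(Z, An, W, activation = "linear")
    expect_equal(out, An %*% Z %*% W) # dense matmul oracle
  })
  expect_error(gcn_layer(Z, diag(4), matrix(0, 4, 2)), "width")
  expect_error(gcn_layer(Z, diag(3), diag(3)), "rows")
})

test_that("the encoder honors zero log-sigma heads and permutation equivariance", {
  withr::with_seed(8, {
    n <- 5; p <- 6
    A <- matrix(runif(n * n, 0, 0.5), n, n); A <- (A + t(A)) / 2; diag(A) <- 1
    An <- normalize_adjacency(A)
    X <- matrix(rnorm(n * p), n, p)
    params <- vgae_params(p, 4, 3, seed = 1)
    params$W_logsig[] <- 0
    enc <- vgae_encode(X, An, params)
    expect_equal(enc$sigma, matrix(1, n, 3), ignore_attr = TRUE)
    # two-step oracle for mu
    H <- gaephen:::activation_funs("leaky_relu", 0.01)$f(An %*% X %*% params$W0)
    expect_equal(enc$mu, (An %*% H) %*% params$W_mu)
    # permuting nodes permutes the posterior rows identically
    perm <- sample(n)
    encp <- vgae_encode(X[perm, ], normalize_adjacency(A[perm, perm]), params)
    expect_equal(encp$mu, enc$mu[perm, ], tolerance = 1e-10)
  })
})

test_that("reparameterization is seeded and collapses to the mean without noise", {
  mu <- matrix(1:6, 2, 3) * 1.0
  sig <- matrix(0.5, 2, 3)
  expect_equal(reparameterize(mu, sig, epsilon = mu * 0), mu)
  expect_equal(reparameterize(mu, sig * 1e-12, seed = 4), mu, tolerance = 1e-9)
  expect_identical(reparameterize(mu, sig, seed = 9),
                   reparameterize(mu, sig, seed = 9))
  # Monte-Carlo: sample mean approaches mu
  draws <- sapply(1:2000, function(i) reparameterize(mu, sig, seed = i)[1, 1])
  expect_lt(abs(mean(draws) - mu[1, 1]), 3 * 0.5 / sqrt(2000))
})

test_that("the inner-product decoder matches its sigmoid oracle", {
  z <- rbind(c(1, 0), c(0, 1), c(20, 20))
  P <- decode_inner_product(z)
  expect_equal(P[1, 2], 0.5)       # orthogonal codes
  expect_gt(P[3, 3], 1 - 1e-10)    # saturation at large norm
  expect_true(isSymmetric(P))
  withr::with_seed(2, {
    Z <- matrix(rnorm(9), 3, 3)
    expect_equal(decode_inner_product(Z), plogis(Z %*% t(Z)))
  })
})

test_that("the loss decomposes into a hand-computable BCE plus a non-negative KL", {
  # prior match: mu = 0, sigma = 1 gives zero KL
  Z <- matrix(0, 2, 2)
  l0 <- vgae_loss(Z, Z, Z + 1, diag(2))
  expect_equal(l0$kl, 0)
  # KL non-negativity on random posteriors
  withr::with_seed(6, {
    for (i in 1:20) {
      mu <- matrix(rnorm(4), 2, 2)
      sig <- matrix(exp(rnorm(4)), 2, 2)
      expect_gte(vgae_loss(matrix(0, 2, 2), mu, sig, diag(2))$kl, 0)
    }
  })
  expect_error(vgae_loss(Z, Z, Z, diag(2)), "positive")

  # 2-node hand oracle with explicit weights and scale
  A <- matrix(c(1, 0.6, 0.6, 1), 2)
  Zs <- rbind(c(0.5, -0.2), c(0.1, 0.3))
  mu <- rbind(c(0.4, 0), c(0, 0.2))
  sig <- rbind(c(1.1, 0.9), c(1, 1.2))
  l <- vgae_loss(Zs, mu, sig, A, pos_weight = 2, norm = 0.7, kl_scale = 0.25)
  logits <- Zs %*% t(Zs)
  bce_el <- -(2 * log(plogis(logits))) # all four entries are edges/self-loops
  recon_oracle <- 0.7 * mean(bce_el)
  kl_oracle <- 0.25 * 0.5 * sum(mu^2 + sig^2 - 1 - 2 * log(sig))
  expect_equal(l$recon, recon_oracle, tolerance = 1e-12)
  expect_equal(l$kl, kl_oracle, tolerance = 1e-12)
  expect_equal(l$loss, recon_oracle + kl_oracle, tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  withr::with_seed(13, {
    n <- 5; p <- 4; h <- 3; d <- 2
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, 0.5) *
      runif(n * (n - 1) / 2, 0.3, 1)
    A <- A + t(A); diag(A) <- 1
    An <- normalize_adjacency(A)
    X <- matrix(rnorm(n * p), n, p)
    E <- matrix(rnorm(n * d), n, d)
    params <- unclass(vgae_params(p, h, d, seed = 2))
    act <- gaephen:::activation_funs("leaky_relu", 0.01)
    Tgt <- (A > 0) * 1
    pw <- 1.7; nrm <- 0.9; ks <- 1 / n^2
    AX <- An %*% X
    st <- gaephen:::vgae_grad_step(params, AX, An, Tgt, E, act, pw, nrm, ks)
    lossf <- function(pr) {
      H <- act$f(AX %*% pr$W0)
      AH <- An %*% H
      mu <- AH %*% pr$W_mu
      sig <- exp(AH %*% pr$W_logsig)
      vgae_loss(mu + sig * E, mu, sig, A, pos_weight = pw, norm = nrm,
                kl_scale = ks)$loss
    }
    eps <- 1e-6
    for (nm in names(st$grads)) {
      idx <- sample(length(params[[nm]]), 4) # spot-check entries
      for (i in idx) {
        pp <- params
        pp[[nm]][i] <- pp[[nm]][i] + eps
        up <- lossf(pp)
        pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
        dn <- lossf(pp)
        expect_equal(st$grads[[nm]][i], (up - dn) / (2 * eps),
                     tolerance = 1e-4)
      }
    }
  })
})

test_that("training is seeded, reduces the loss, and zero epochs return the init", {
  sf <- small_fixture(1)
  f0 <- train_vgae(sf$X, sf$graph, epochs = 0, seed = 3,
                   hidden_dim = 16, latent_dim = 8)
  p0 <- vgae_params(ncol(sf$X), 16, 8, seed = 3)
  expect_equal(unclass(f0$params), unclass(p0))
  f1 <- train_vgae(sf$X, sf$graph, epochs = 60, seed = 3,
                   hidden_dim = 16, latent_dim = 8)
  f2 <- train_vgae(sf$X, sf$graph, epochs = 60, seed = 3,
                   hidden_dim = 16, latent_dim = 8)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$Z, f2$Z)
  expect_lt(tail(f1$loss_history, 1), f1$loss_history[1])
})

test_that("held-out links are recovered well above chance on the planted graph", {
  sf <- small_fixture(1)
  r <- evaluate_link_reconstruction(sf$X, sf$graph, test_fraction = 0.1,
                                    seed = 1)
  expect_gt(r$auc, 0.65)
})

test_that("embeddings round-trip through the TSV exchange format", {
  m <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("P", 1:4), NULL))
  p <- tempfile(fileext = ".tsv")
  write_embedding(m, p)
  m2 <- read_embedding(p)
  expect_equal(unname(m2), unname(m), tolerance = 1e-12)
  expect_equal(rownames(m2), rownames(m))
})
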