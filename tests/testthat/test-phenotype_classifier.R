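test_that("zero weights yield 0.5 scores and inference is deterministic", {
  p <- mlp_params(4, 8, 3, seed = 1)
  for (nm in c("W0", "b0", "beta", "W1", "b1")) p[[nm]][] <- 0
  Z <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("P", 1:5), NULL))
  s <- mlp_forward(Z, p)
  expect_equal(unname(s), matrix(0.5, 5, 3))
  p2 <- mlp_params(4, 8, 3, seed = 2)
  s1 <- mlp_forward(Z, p2, training = FALSE)
  s2 <- mlp_forward(Z, p2, training = FALSE)
  expect_identical(s1, s2) # dropout disabled outside training
  expect_true(all(s1 > 0 & s1 < 1))
  expect_error(mlp_forward(matrix(0, 2, 7), p2), "width")
})

test_that("the forward pass without batch norm matches a dense-algebra oracle", {
  withr::with_seed(21, {
    Z <- matrix(rnorm(8), 2, 4)
    p <- mlp_params(4, 5, 3, seed = 3)
    p$b0[] <- rnorm(5); p$b1[] <- rnorm(3)
    s <- mlp_forward(Z, p, batchnorm = FALSE)
    act <- gaephen:::activation_funs("leaky_relu", 0.01)
    hid <- act$f(sweep(Z %*% p$W0, 2, p$b0, "+"))
    oracle <- plogis(sweep(hid %*% p$W1, 2, p$b1, "+"))
    expect_equal(unname(s), oracle)
  })
})

test_that("batch-norm training pass standardizes the hidden pre-activations", {
  withr::with_seed(22, {
    Z <- matrix(rnorm(40), 10, 4)
    p <- mlp_params(4, 6, 2, seed = 4)
    pre <- sweep(Z %*% p$W0, 2, p$b0, "+")
    mu_b <- colMeans(pre)
    var_b <- colMeans(pre^2) - mu_b^2
    xhat <- sweep(sweep(pre, 2, mu_b, "-"), 2, sqrt(var_b + 1e-5), "/")
    act <- gaephen:::activation_funs("leaky_relu", 0.01)
    oracle <- plogis(sweep(act$f(xhat) %*% p$W1, 2, p$b1, "+"))
    s <- mlp_forward(Z, p, training = TRUE, dropout = 0)
    expect_equal(unname(s), oracle)
  })
})

test_that("classifier gradients agree with finite differences (with batch norm)", {
  withr::with_seed(23, {
    n <- 6; d <- 3; h <- 4; Tn <- 2
    Z <- matrix(rnorm(n * d), n, d)
    Y <- matrix(rbinom(n * Tn, 1, 0.5), n, Tn)
    M <- matrix(rbinom(n * Tn, 1, 0.7), n, Tn)
    if (sum(M) == 0) M[1, 1] <- 1
    params <- unclass(mlp_params(d, h, Tn, seed = 5))
    act <- gaephen:::activation_funs("leaky_relu", 0.01)
    st <- gaephen:::mlp_grad_step(params, Z, Y, M, dropout = 0,
                                  batchnorm = TRUE, act = act)
    lossf <- function(pr) {
      s <- mlp_forward(Z, structure(pr, class = "mlp_params"),
                       training = TRUE, dropout = 0, batchnorm = TRUE)
      eps <- 1e-12
      sum(M * -(Y * log(s + eps) + (1 - Y) * log(1 - s + eps))) / sum(M)
    }
    fd <- 1e-6
    for (nm in c("W0", "b0", "gamma", "beta", "W1", "b1")) {
      idx <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
      for (i in idx) {
        pp <- params
        pp[[nm]][i] <- pp[[nm]][i] + fd
        up <- lossf(pp)
        pp[[nm]][i] <- pp[[nm]][i] - 2 * fd
        dn <- lossf(pp)
        expect_equal(st$grads[[nm]][i], (up - dn) / (2 * fd),
                     tolerance = 1e-3)
      }
    }
  })
})

test_that("unlabeled pairs contribute no gradient to the output layer", {
  withr::with_seed(24, {
    n <- 5; d <- 3; h <- 4; Tn <- 3
    Z <- matrix(rnorm(n * d), n, d)
    Y <- matrix(rbinom(n * Tn, 1, 0.5), n, Tn)
    M <- matrix(1, n, Tn)
    M[, 3] <- 0 # third term entirely unlabeled
    params <- unclass(mlp_params(d, h, Tn, seed = 6))
    act <- gaephen:::activation_funs("leaky_relu", 0.01)
    st <- gaephen:::mlp_grad_step(params, Z, Y, M, dropout = 0,
                                  batchnorm = FALSE, act = act)
    expect_equal(st$grads$W1[, 3], rep(0, h))
    expect_equal(st$grads$b1[3], 0)
    # flipping labels of masked cells leaves the loss unchanged
    Y2 <- Y; Y2[, 3] <- 1 - Y2[, 3]
    st2 <- gaephen:::mlp_grad_step(params, Z, Y2, M, dropout = 0,
                                   batchnorm = FALSE, act = act)
    expect_equal(st$loss, st2$loss)
  })
})

test_that("training is seeded, zero epochs return the init, and planted labels are learned", {
  sf <- small_fixture(1)
  emb <- train_vgae(sf$X, sf$graph, seed = 1) # default embedding settings
  f0 <- train_classifier(emb$mu, sf$gold, epochs = 0, hidden_dim = 16, seed = 2)
  p0 <- mlp_params(ncol(emb$mu), 16, length(sf$gold$term_universe), seed = 2)
  expect_equal(unname(f0$params$W0), unname(p0$W0))
  f1 <- train_classifier(emb$mu, sf$gold, seed = 2) # default classifier settings
  f2 <- train_classifier(emb$mu, sf$gold, seed = 2)
  expect_identical(f1$params, f2$params)
  sc <- predict_scores(f1, emb$mu[sf$gold$protein_universe, ])
  expect_true(all(sc > 0 & sc < 1))
  tr_auc <- suppressWarnings(
    macro_auc(gaephen:::term_auc_by_pairs(sc, gaephen:::gold_pairs(sf$gold))))
  expect_gt(tr_auc, 0.9) # separable planted signal is fit on training pairs
})

test_that("Youden thresholds maximize Sn + Sp - 1 with smallest-tie convention", {
  gold <- toy_gold(paste0("p", 1:4), "T1",
                   data.frame(protein = c("p1", "p2"), term = "T1"),
                   data.frame(protein = c("p3", "p4"), term = "T1"))
  # perfect separation: smallest maximizing candidate is the lowest positive
  sc <- matrix(c(0.9, 0.9, 0.1, 0.1), 4, 1,
               dimnames = list(paste0("p", 1:4), "T1"))
  expect_equal(unname(youden_thresholds(sc, gold)["T1"]), 0.9)
  # hand-worked four-point case: pos {0.8, 0.6}, neg {0.7, 0.2}
  sc2 <- matrix(c(0.8, 0.6, 0.7, 0.2), 4, 1,
                dimnames = list(paste0("p", 1:4), "T1"))
  cand <- c(0, 0.2, 0.6, 0.7, 0.8, 1)
  j <- sapply(cand, function(t) {
    mean(c(0.8, 0.6) >= t) + mean(c(0.7, 0.2) < t) - 1
  })
  best <- min(cand[j == max(j)]) # exhaustive-scan oracle
  expect_equal(unname(youden_thresholds(sc2, gold)["T1"]), best)
  expect_equal(best, 0.6)
})

test_that("Youden thresholds match an exhaustive scan on random instances", {
  withr::with_seed(31, {
    for (i in 1:25) {
      npos <- sample(2:8, 1); nneg <- sample(2:8, 1)
      prot <- paste0("p", seq_len(npos + nneg))
      gold <- toy_gold(prot, "T",
                       data.frame(protein = prot[1:npos], term = "T"),
                       data.frame(protein = prot[(npos + 1):(npos + nneg)],
                                  term = "T"))
      s <- round(runif(npos + nneg), 2)
      sc <- matrix(s, ncol = 1, dimnames = list(prot, "T"))
      pos <- s[1:npos]; neg <- s[-(1:npos)]
      cand <- sort(unique(c(0, s, 1)))
      j <- sapply(cand, function(t) mean(pos >= t) + mean(neg < t) - 1)
      expect_equal(unname(youden_thresholds(sc, gold)["T"]),
                   min(cand[j >= max(j) - 1e-12]))
    }
  })
})

test_that("terms without both classes get flagged NA thresholds", {
  gold <- toy_gold(c("p1", "p2"), c("T1", "T2"),
                   data.frame(protein = c("p1", "p1"), term = c("T1", "T2")),
                   data.frame(protein = "p2", term = "T1"))
  sc <- matrix(0.5, 2, 2, dimnames = list(c("p1", "p2"), c("T1", "T2")))
  expect_warning(th <- youden_thresholds(sc, gold), "undefined")
  expect_true(is.na(th["T2"]))
  expect_false(is.na(th["T1"]))
})

test_that("binarization calls scores at or above the per-term threshold", {
  sc <- matrix(c(0.5, 0.3, 0.8, 0.2), 2, 2,
               dimnames = list(c("a", "b"), c("T1", "T2")))
  th <- c(T1 = 0.5, T2 = 0)
  calls <- binarize(sc, th)
  expect_equal(unname(calls[, "T1"]), c(1, 0)) # boundary score is positive
  expect_equal(unname(calls[, "T2"]), c(1, 1)) # zero threshold calls all
  # elementwise comparison oracle
  expect_equal(unname(calls), unname((sweep(sc, 2, th[colnames(sc)], ">=")) * 1))
})
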