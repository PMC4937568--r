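# Brute-force valid cross-correlation used as the convolution oracle.
conv_oracle <- function(filter_cw, xmat) {
  K <- ncol(filter_cw)
  vapply(seq_len(ncol(xmat) - K + 1), function(p) {
    sum(filter_cw * xmat[, p:(p + K - 1)])
  }, numeric(1))
}

test_that("convolution equals brute-force window dot products", {
  # indicator filter for TGA scanned over CCTGACC
  f <- matrix(0, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  f["T", 1] <- 1; f["G", 2] <- 1; f["A", 3] <- 1
  x <- one_hot_encode("CCTGACC")
  W <- matrix(as.vector(f), nrow = 1)
  cv <- conv_forward(W, 0, array(x, c(4, 7, 1)))
  expect_equal(as.vector(cv$Z), c(0, 0, 3, 0, 0))   # full match only at TGA
  expect_equal(as.vector(cv$Z), conv_oracle(f, x))

  # all-zero filter
  cv0 <- conv_forward(matrix(0, 1, 12), 0, array(x, c(4, 7, 1)))
  expect_equal(as.vector(cv0$Z), rep(0, 5))

  # single-position filter counts its base
  w1 <- matrix(c(1, 0, 0, 0), nrow = 1)
  cv1 <- conv_forward(w1, 0, array(one_hot_encode("AAC"), c(4, 3, 1)))
  expect_equal(as.vector(cv1$Z), c(1, 1, 0))

  # random filters against random sequences, batched
  set.seed(5)
  for (i in 1:10) {
    L <- sample(8:30, 1); K <- sample(2:min(7, L), 1)
    Wr <- matrix(rnorm(2 * 4 * K), nrow = 2)
    xs <- lapply(1:3, function(j) one_hot_encode(random_dna(L)))
    X <- array(unlist(xs), c(4, L, 3))
    cv <- conv_forward(Wr, c(0.5, -0.2), X)
    Z <- array(cv$Z, c(2, L - K + 1, 3))
    for (j in 1:3) {
      expect_equal(Z[1, , j], conv_oracle(matrix(Wr[1, ], 4), xs[[j]]) + 0.5)
      expect_equal(Z[2, , j], conv_oracle(matrix(Wr[2, ], 4), xs[[j]]) - 0.2)
    }
  }
})

test_that("relu clamps negatives and is idempotent", {
  expect_equal(relu(c(-2, 0, 3)), c(0, 0, 3))
  expect_equal(relu(c(-5, -1)), c(0, 0))
  x <- rnorm(100)
  expect_equal(relu(relu(x)), relu(x))
})

test_that("max pooling takes window maxima and keeps the trailing remainder", {
  expect_equal(max_pool(c(1, 5, 2, 4), 2), c(5, 4))
  expect_equal(max_pool(c(1, 5, 2, 4), 1), c(1, 5, 2, 4))
  expect_equal(max_pool(c(1, 5, 2), 2), c(5, 2))
  # matches a naive split-apply on random arrays
  set.seed(9)
  x <- array(rnorm(3 * 11 * 2), c(3, 11, 2))
  got <- max_pool(x, 4)
  for (b in 1:2) for (c in 1:3) {
    expect_equal(got[c, , b],
                 vapply(split(x[c, , b], rep(1:3, c(4, 4, 3))), max,
                        numeric(1), USE.NAMES = FALSE))
  }
})

test_that("pool backward routes gradient to the argmax positions only", {
  x <- array(c(1, 5, 2, 4, 9, 3), c(1, 6, 1))
  pl <- max_pool(x, 3, want_argmax = TRUE)
  expect_equal(as.vector(pl$out), c(5, 9))
  d <- accessnet:::max_pool_backward(array(c(10, 20), c(1, 2, 1)), pl$arg, 6, 3)
  expect_equal(as.vector(d), c(0, 10, 0, 0, 20, 0))
})

test_that("a zeroed output layer predicts exactly 0.5 everywhere", {
  spec <- architecture_spec(20, 3, conv_layers = list(c(4, 5, 2)),
                            fc_layers = 6, dropout = 0)
  m <- new_model(spec, seed = 2)
  m$params$out$W[] <- 0
  m$params$out$b[] <- 0
  X <- encode_sequences(replicate(4, random_dna(20)))
  p <- predict(m, X)
  expect_equal(unname(p), matrix(0.5, 4, 3))
})

test_that("eval-mode forward matches an independent naive composition", {
  set.seed(31)
  spec <- architecture_spec(26, 2, conv_layers = list(c(3, 5, 2), c(2, 3, 2)),
                            fc_layers = c(4), dropout = 0.5)
  m <- random_eval_model(spec, seed = 4)
  for (i in 1:5) {
    x <- one_hot_encode(random_dna(26))
    got <- predict(m, x)
    expect_equal(as.vector(got), naive_forward(m, x), tolerance = 1e-10)
  }
})

test_that("a hand-built single-motif network computes the expected probability", {
  # one filter recognizing TGA; pool over all positions; identity-ish fc
  spec <- architecture_spec(6, 1, conv_layers = list(c(1, 3, 4)),
                            fc_layers = 1, dropout = 0)
  m <- new_model(spec, seed = 1)
  f <- matrix(0, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  f["T", 1] <- 1; f["G", 2] <- 1; f["A", 3] <- 1
  m$params$conv[[1]]$W <- matrix(as.vector(f), nrow = 1)
  m$params$conv[[1]]$b <- 0
  # neutral batch norm everywhere (gamma 1, beta 0, moments 0/1 -> scale 1/sqrt(1+eps))
  m$params$fc[[1]]$W <- matrix(2, 1, 1)
  m$params$fc[[1]]$b <- 0
  m$params$out$W <- matrix(1.5, 1, 1)
  m$params$out$b <- -1
  # CTGAGT: conv activations (0,3,0,0) -> pooled max 3 (one window of 4)
  s <- 1 / sqrt(1 + 1e-5)
  h1 <- max(0, 2 * (3 * s)) * s          # fc linear + bn + relu
  expect_equal(as.vector(predict(m, one_hot_encode("CTGAGT"))),
               plogis(1.5 * h1 - 1), tolerance = 1e-12)
})

test_that("binary cross entropy matches closed forms", {
  expect_equal(bce_loss(matrix(0.5, 3, 4), matrix(rbinom(12, 1, 0.5), 3, 4)),
               4 * log(2))
  expect_equal(bce_loss(matrix(c(0.9, 0.2), 1, 2), matrix(c(1, 0), 1, 2)),
               -(log(0.9) + log(0.8)))
  expect_equal(-(log(0.9) + log(0.8)), 0.3285, tolerance = 1e-4)
  # near-perfect predictions: loss near 0
  y <- matrix(c(1, 0, 1), 1, 3)
  expect_lt(bce_loss(abs(y - 1e-9), y), 1e-6)
  # logit-space evaluation agrees with the probability-space definition
  set.seed(2)
  logits <- matrix(rnorm(12, sd = 2), 4, 3)
  y <- matrix(rbinom(12, 1, 0.5), 3, 4)
  expect_equal(accessnet:::bce_loss_logits(logits, y),
               bce_loss(t(plogis(logits)), y))
})

test_that("backpropagated gradients match finite differences", {
  set.seed(17)
  spec <- architecture_spec(12, 2, conv_layers = list(c(3, 4, 2)),
                            fc_layers = 5, dropout = 0)
  m <- new_model(spec, seed = 3)
  X <- encode_sequences(replicate(4, random_dna(12)))
  Y <- matrix(rbinom(8, 1, 0.5), 4, 2)
  fwd <- net_forward(m, X, mode = "train", keep_cache = TRUE)
  g <- accessnet:::net_backward(m, fwd, Y)
  lossfn <- function(mm) {
    accessnet:::bce_loss_logits(net_forward(mm, X, mode = "train")$logits, Y)
  }
  h <- 1e-5
  check_tensor <- function(get, set, gmat) {
    p <- get(m)
    for (i in sample(seq_along(p), min(8, length(p)))) {
      m1 <- m; p1 <- p; p1[i] <- p[i] + h; m1 <- set(m1, p1)
      m2 <- m; p2 <- p; p2[i] <- p[i] - h; m2 <- set(m2, p2)
      num <- (lossfn(m1) - lossfn(m2)) / (2 * h)
      if (abs(num) + abs(gmat[i]) > 1e-6) {
        expect_lt(abs(num - gmat[i]) / (abs(num) + abs(gmat[i])), 1e-4)
      }
    }
  }
  check_tensor(function(m) m$params$conv[[1]]$W,
               function(m, p) { m$params$conv[[1]]$W[] <- p; m },
               g$conv[[1]]$W)
  check_tensor(function(m) m$params$conv[[1]]$gamma,
               function(m, p) { m$params$conv[[1]]$gamma[] <- p; m },
               g$conv[[1]]$gamma)
  check_tensor(function(m) m$params$fc[[1]]$W,
               function(m, p) { m$params$fc[[1]]$W[] <- p; m },
               g$fc[[1]]$W)
  check_tensor(function(m) m$params$fc[[1]]$beta,
               function(m, p) { m$params$fc[[1]]$beta[] <- p; m },
               g$fc[[1]]$beta)
  check_tensor(function(m) m$params$out$W,
               function(m, p) { m$params$out$W[] <- p; m },
               g$out$W)
  check_tensor(function(m) m$params$out$b,
               function(m, p) { m$params$out$b[] <- p; m },
               g$out$b)
})

test_that("eval-mode predictions are deterministic and strictly inside (0,1)", {
  spec <- architecture_spec(30, 4, conv_layers = list(c(5, 7, 3)),
                            fc_layers = 8, dropout = 0.4)
  m <- random_eval_model(spec, seed = 6)
  X <- encode_sequences(replicate(6, random_dna(30)))
  p1 <- predict(m, X)
  p2 <- predict(m, X)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
})

test_that("raising a target's output bias strictly raises its probability", {
  spec <- architecture_spec(20, 3, conv_layers = list(c(4, 5, 2)),
                            fc_layers = 6, dropout = 0)
  m <- random_eval_model(spec, seed = 8)
  X <- encode_sequences(replicate(3, random_dna(20)))
  p0 <- predict(m, X)
  m$params$out$b[2] <- m$params$out$b[2] + 0.7
  p1 <- predict(m, X)
  expect_true(all(p1[, 2] > p0[, 2]))
  expect_equal(p1[, -2], p0[, -2])
})

test_that("small motif shifts move at most two pooled windows of an exact-match filter", {
  # a filter that only fires on a perfect 7-mer match (bias subtracts 6)
  motif <- "TGACTCA"
  spec <- architecture_spec(60, 1, conv_layers = list(c(1, 7, 4)),
                            fc_layers = 2, dropout = 0)
  m <- new_model(spec, seed = 9)
  m$params$conv[[1]]$W <- matrix(as.vector(one_hot_encode(motif)), nrow = 1)
  m$params$conv[[1]]$b <- -6
  set.seed(10)
  bg <- random_dna(60)
  plant_at <- function(sq, pos) {
    substr(sq, pos, pos + 6) <- motif
    sq
  }
  pooled <- function(sq) {
    cv <- conv_forward(m$params$conv[[1]]$W, m$params$conv[[1]]$b,
                       array(one_hot_encode(sq), c(4, 60, 1)))
    as.vector(max_pool(array(relu(cv$Z), c(1, cv$P_out, 1)), 4))
  }
  for (shift in 1:3) {            # shifts below the pool width of 4
    a <- pooled(plant_at(bg, 20))
    b <- pooled(plant_at(bg, 20 + shift))
    expect_lte(sum(a != b), 2)
  }
})
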