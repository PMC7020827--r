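# SDAE-LSTM building blocks: corruption, the LSTM cell against a hand-written
# unroll, analytic gradients against finite differences and the compiled
# kernels against the pure-R reference, pretraining behaviour, and training
# determinism.

test_that("masking corruption zeroes the documented fraction and is seedable", {
  x <- matrix(1, 200, 50)
  xc <- corrupt(x, p = 0.3, seed = 5L)
  frac <- mean(xc == 0)
  # 10000 Bernoulli(0.3) draws: allow 5 binomial SDs around the mean
  expect_lt(abs(frac - 0.3), 5 * sqrt(0.3 * 0.7 / length(x)))
  expect_identical(xc, corrupt(x, p = 0.3, seed = 5L))
  expect_identical(corrupt(x, p = 0), x)
  expect_error(corrupt(x, p = 1), "\\[0, 1\\)")
})

test_that("lstm_cell matches a hand-unrolled evaluation of the gate equations", {
  set.seed(31)
  d <- 3L; hd <- 4L
  w <- list(Wxi = matrix(rnorm(d * hd), d), Whi = matrix(rnorm(hd * hd), hd),
            bi = rnorm(hd),
            Wxf = matrix(rnorm(d * hd), d), Whf = matrix(rnorm(hd * hd), hd),
            bf = rnorm(hd),
            Wxo = matrix(rnorm(d * hd), d), Who = matrix(rnorm(hd * hd), hd),
            bo = rnorm(hd),
            Wxc = matrix(rnorm(d * hd), d), Whc = matrix(rnorm(hd * hd), hd),
            bc = rnorm(hd))
  x <- rnorm(d); h0 <- rnorm(hd); c0 <- rnorm(hd)
  sig <- function(z) 1 / (1 + exp(-z))
  i <- sig(drop(x %*% w$Wxi + h0 %*% w$Whi) + w$bi)
  f <- sig(drop(x %*% w$Wxf + h0 %*% w$Whf) + w$bf)
  o <- sig(drop(x %*% w$Wxo + h0 %*% w$Who) + w$bo)
  g <- tanh(drop(x %*% w$Wxc + h0 %*% w$Whc) + w$bc)
  c1 <- f * c0 + i * g
  h1 <- o * tanh(c1)
  st <- lstm_cell(x, h0, c0, w)
  expect_equal(st$h, h1, tolerance = 1e-12)
  expect_equal(st$c, c1, tolerance = 1e-12)
  expect_equal(st$i, i, tolerance = 1e-12)
  expect_equal(st$f, f, tolerance = 1e-12)
})

test_that("lstm_cell with zero weights reduces to its closed form", {
  d <- 2L; hd <- 3L
  w <- list(Wxi = matrix(0, d, hd), Whi = matrix(0, hd, hd), bi = numeric(hd),
            Wxf = matrix(0, d, hd), Whf = matrix(0, hd, hd), bf = numeric(hd),
            Wxo = matrix(0, d, hd), Who = matrix(0, hd, hd), bo = numeric(hd),
            Wxc = matrix(0, d, hd), Whc = matrix(0, hd, hd), bc = numeric(hd))
  st <- lstm_cell(rnorm(d), numeric(hd), rep(2, hd), w)
  # i = f = o = 1/2, g = 0: c = c_prev / 2, h = tanh(1) / 2
  expect_equal(st$c, rep(1, hd))
  expect_equal(st$h, rep(0.5 * tanh(1), hd))
  expect_error(lstm_cell(rnorm(5), numeric(hd), numeric(hd), w), "shape")
})

test_that("autoencoder gradients match finite differences and the compiled kernel", {
  set.seed(32)
  p <- list(W1 = doaindex:::.init_mat(6, 4), b1 = rnorm(4) * 0.1,
            W2 = doaindex:::.init_mat(4, 6), b2 = rnorm(6) * 0.1)
  X <- matrix(rnorm(48), 8, 6)
  Xc <- corrupt(X, 0.3, seed = 2L)
  ref <- doaindex:::.dae_loss_grads_r(p, Xc, X, 0.05, 0.1, 1e-3)
  num <- numeric_grads(function(q)
    doaindex:::.dae_loss_grads_r(q, Xc, X, 0.05, 0.1, 1e-3)$loss, p)
  expect_lt(max_rel_err(ref$grads, num), 1e-6)
  cpp <- doaindex:::.dae_loss_grads(p, Xc, X, 0.05, 0.1, 1e-3)
  expect_equal(cpp$loss, ref$loss, tolerance = 1e-12)
  expect_lt(max_rel_err(cpp$grads, ref$grads), 1e-12)
})

test_that("full-stack gradients match finite differences and the compiled kernel", {
  set.seed(33)
  d_in <- 5L; h1 <- 7L; h2 <- 4L; dh <- 3L
  feats <- matrix(rnorm(9 * d_in), 9, d_in)
  targets <- rnorm(9)
  seq_mat <- matrix(1:9, 3, 3)
  params <- list(enc1 = list(W = doaindex:::.init_mat(d_in, h1), b = rnorm(h1) * 0.1),
                 enc2 = list(W = doaindex:::.init_mat(h1, h2), b = rnorm(h2) * 0.1),
                 lstm = doaindex:::.init_lstm(h2, dh),
                 out = list(W = doaindex:::.init_mat(dh, 1L), b = 0.1))
  ref <- doaindex:::.stack_loss_grads_r(params, feats, targets, seq_mat,
                                        1e-3, encode = TRUE)
  num <- numeric_grads(function(q)
    doaindex:::.stack_loss_grads_r(q, feats, targets, seq_mat,
                                   1e-3, encode = TRUE)$loss, params)
  expect_lt(max_rel_err(ref$grads, num), 1e-4)
  cpp <- doaindex:::.stack_loss_grads(params, feats, targets, seq_mat,
                                      1e-3, encode = TRUE)
  expect_equal(cpp$loss, ref$loss, tolerance = 1e-12)
  expect_lt(max_rel_err(cpp$grads, ref$grads), 1e-12)
  # gradient structure must mirror the parameter structure (Adam pairs them)
  expect_identical(rapply(cpp$grads, dim, how = "list"),
                   rapply(params, dim, how = "list"))
  # LSTM-only variant (encode = FALSE)
  lp <- params[c("lstm", "out")]
  refl <- doaindex:::.stack_loss_grads_r(lp, matrix(rnorm(9 * h2), 9, h2),
                                         targets, seq_mat, 1e-3, encode = FALSE)
  expect_true(is.finite(refl$loss))
})

test_that("sequence construction covers subjects without overlap", {
  set.seed(34)
  sm <- doaindex:::.make_sequences(list(1:70, 71:134), 32L,
                                   random_offset = FALSE)
  expect_identical(dim(sm), c(4L, 32L))
  expect_identical(sm[1, ], 1:32)
  expect_identical(sm[3, ], 71:102 - 0L)
  expect_false(anyDuplicated(as.vector(sm)) > 0)
  expect_null(doaindex:::.make_sequences(list(1:10), 32L))
  smr <- doaindex:::.make_sequences(list(1:100), 32L, random_offset = TRUE)
  expect_true(all(diff(t(smr)) == 1L))
})

test_that("pretraining reduces reconstruction loss and returns the documented shapes", {
  set.seed(35)
  x <- matrix(rnorm(120 * 46), 120, 46)
  sp <- network_spec(pretrain_epochs = 15L, batch_size = 32L, seed = 3L)
  pre <- pretrain_sdae(x, sp)
  expect_identical(dim(pre$dae1$W1), c(46L, 92L))
  expect_identical(dim(pre$dae2$W1), c(92L, 12L))
  l1 <- pre$log[pre$log$phase == "sdae1", "loss"]
  expect_lt(l1[length(l1)], l1[1])
  expect_error(pretrain_sdae(x[, 1:10], sp), "46")
})

test_that("training is deterministic in the seed and fits a learnable signal", {
  set.seed(36)
  # two small synthetic subjects with a feature-encoded trend
  make_subject <- function(seed) {
    set.seed(seed)
    n <- 64L
    trend <- seq(0, 5, length.out = n)
    F <- matrix(rnorm(n * 46, sd = 0.3), n, 46)
    F[, 1:10] <- F[, 1:10] + trend          # label is readable from features
    colnames(F) <- feature_names()
    list(F = F, y = trend)
  }
  subs <- lapply(c(101, 102), make_subject)
  feats <- lapply(subs, `[[`, "F"); labs <- lapply(subs, `[[`, "y")
  sp <- network_spec(pretrain_epochs = 5L, lstm_epochs = 60L,
                     finetune_epochs = 30L, seed = 8L)
  net1 <- train_network(feats, labs, sp)
  net2 <- train_network(feats, labs, sp)
  p1 <- predict(net1, feats[[1]])
  expect_identical(p1, predict(net2, feats[[1]]))
  expect_length(p1, 64L)
  # the fitted index recovers the training trend almost perfectly
  expect_gt(pk_statistic(p1, labs[[1]])$pk, 0.95)
  expect_lt(mean((p1 - labs[[1]])^2) / var(labs[[1]]), 0.25)
  # predictions are on the label scale, not the standardized scale
  expect_lt(abs(mean(p1) - mean(labs[[1]])), 1)
  expect_s3_class(net1, "doa_network")
  expect_output(print(net1), "46-92-12-18-1")
})

test_that("the ablation variant without the SDAE front end trains and predicts", {
  set.seed(37)
  n <- 64L
  trend <- seq(0, 4, length.out = n)
  F <- matrix(rnorm(n * 46, sd = 0.3), n, 46) + trend
  sp <- network_spec(use_sdae = FALSE, lstm_epochs = 60L,
                     finetune_epochs = 20L, seed = 4L)
  net <- train_network(list(F), list(trend), sp)
  expect_null(net$params$enc1)
  expect_gt(pk_statistic(predict(net, F), trend)$pk, 0.95)
  expect_output(print(net), "46-18-1")
})

test_that("SDAE pretraining does not hurt cross-validated accuracy", {
  coh <- cohort_fixture(6L, master_seed = 11L)
  seeds <- 1:3
  m_sdae <- mean(vapply(seeds, function(s)
    loso_cv(coh$features, coh$labels, network_spec(), seed = s)$mean,
    numeric(1)))
  m_plain <- mean(vapply(seeds, function(s)
    loso_cv(coh$features, coh$labels, network_spec(use_sdae = FALSE),
            seed = s)$mean, numeric(1)))
  expect_gte(m_sdae, m_plain - 0.01)
  expect_gte(m_sdae, 0.85)
})

test_that("training validates its inputs", {
  F <- matrix(rnorm(40 * 46), 40, 46)
  expect_error(train_network(list(F), list(rnorm(10))), "aligned")
  expect_error(train_network(list(F[, 1:5]), list(rnorm(40))), "46")
  Fb <- F; Fb[1, 1] <- NA
  expect_error(train_network(list(Fb), list(rnorm(40))), "non-finite")
  net <- train_network(list(F), list(rnorm(40)),
                       network_spec(pretrain_epochs = 2L, lstm_epochs = 5L,
                                    finetune_epochs = 2L, seq_len = 8L))
  expect_error(predict(net, F[, 1:9]), "46")
})
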