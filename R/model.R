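# SDAE-LSTM depth-of-anesthesia regressor.
#
# Two sparse denoising autoencoders (46 -> 92 and 92 -> 12) are pretrained
# greedily on the hybrid feature matrix; their encoders feed a single-layer
# LSTM (hidden size 18) with a linear output head regressing effect-site
# concentration, and the whole stack is then fine-tuned end to end.
# Forward passes, backpropagation (including BPTT) and the Adam optimizer
# are implemented directly on base-R matrices; analytic gradients are
# verified against finite differences in the test suite.

.sigmoid <- function(z) 1 / (1 + exp(-z))
.addb <- function(M, b) M + rep(b, each = nrow(M))

.init_mat <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# ---- nested-list parameter utilities (params are lists of numeric arrays) --

.map_params <- function(f, ...) {
  args <- list(...)
  if (is.numeric(args[[1L]])) return(do.call(f, args))
  out <- lapply(seq_along(args[[1L]]), function(i) {
    do.call(.map_params, c(list(f), lapply(args, `[[`, i)))
  })
  names(out) <- names(args[[1L]])
  out
}

.zeros_like <- function(p) .map_params(function(x) x * 0, p)

.adam_init <- function(params) list(m = .zeros_like(params),
                                    v = .zeros_like(params), t = 0L)

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .map_params(function(m, g) beta1 * m + (1 - beta1) * g,
                         state$m, grads)
  state$v <- .map_params(function(v, g) beta2 * v + (1 - beta2) * g^2,
                         state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- .map_params(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

# ---- network specification --------------------------------------------------

#' SDAE-LSTM network specification
#'
#' Architecture and training hyperparameters of the depth-of-anesthesia
#' regressor: a 46-node input layer, sparse denoising autoencoder hidden
#' layers of 92 and 12 nodes, an LSTM layer of 18 units, and a single
#' linear output node.
#'
#' @param input_dim input feature dimension (46 hybrid features).
#' @param sdae_dims hidden sizes of the two stacked autoencoders.
#' @param lstm_hidden LSTM hidden-state size.
#' @param output_dim output dimension (1: the depth index).
#' @param corruption_p masking probability in `[0, 1)`: each autoencoder
#'   input element is independently zeroed with this probability during
#'   denoising pretraining.
#' @param sparsity_target target mean hidden activation `rho` of the
#'   KL-divergence sparsity penalty.
#' @param sparsity_weight coefficient of the sparsity penalty (>= 0).
#' @param seq_len windows per truncated-BPTT training sequence; the default
#'   spans a full default-length session (180 windows), so each gradient
#'   step sees the whole induction-maintenance-emergence arc. Capped at the
#'   longest training session.
#' @param pretrain_epochs,lstm_epochs,finetune_epochs epochs per training
#'   phase. Pretraining iterates minibatches of `batch_size`; the LSTM and
#'   fine-tuning phases take one full-batch Adam step per epoch over all
#'   training sequences (the sequence count is small).
#' @param lr,finetune_lr Adam learning rates (pretraining/LSTM phase and
#'   fine-tuning).
#' @param batch_size pretraining minibatch size.
#' @param weight_decay L2 penalty on weight matrices.
#' @param use_sdae train the SDAE front end? With `FALSE` the LSTM consumes
#'   the 46 raw (standardized) features directly — the ablation baseline.
#' @param seed integer seed for weight initialization, corruption masks and
#'   batch shuffling.
#' @return a `network_spec` object.
#' @export
network_spec <- function(input_dim = 46L, sdae_dims = c(92L, 12L),
                         lstm_hidden = 18L, output_dim = 1L,
                         corruption_p = 0.3, sparsity_target = 0.05,
                         sparsity_weight = 0.1, seq_len = 180L,
                         pretrain_epochs = 30L, lstm_epochs = 200L,
                         finetune_epochs = 100L, lr = 0.01,
                         finetune_lr = 0.003, batch_size = 64L,
                         weight_decay = 1e-4, use_sdae = TRUE, seed = 1L) {
  stopifnot(input_dim >= 1L, all(sdae_dims >= 1L), length(sdae_dims) == 2L,
            lstm_hidden >= 1L, output_dim == 1L,
            corruption_p >= 0, corruption_p < 1,
            sparsity_target > 0, sparsity_target < 1, sparsity_weight >= 0,
            seq_len >= 1L, lr > 0, finetune_lr > 0, weight_decay >= 0)
  structure(as.list(environment()), class = "network_spec")
}

# ---- corruption -------------------------------------------------------------

#' Masking corruption for denoising autoencoders
#'
#' Independently sets each element of the input to zero with probability
#' `p`, the corruption applied to autoencoder inputs during denoising
#' pretraining.
#'
#' @param x numeric vector or matrix.
#' @param p masking probability in `[0, 1)`.
#' @param seed optional seed; the same seed reproduces the same mask.
#' @return object of the same shape as `x`.
#' @export
corrupt <- function(x, p, seed = NULL) {
  if (p < 0 || p >= 1) stop("p must lie in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x * (stats::runif(length(x)) >= p)
}

# ---- LSTM cell --------------------------------------------------------------

#' One LSTM cell step
#'
#' Evaluates the standard gated update for one time step:
#' forget gate `f = sigmoid(Wxf x + Whf h + bf)`, input gate
#' `i = sigmoid(Wxi x + Whi h + bi)`, candidate
#' `g = tanh(Wxc x + Whc h + bc)`, cell state `c_t = f * c_prev + i * g`,
#' output gate `o = sigmoid(Wxo x + Who h + bo)` and hidden state
#' `h_t = o * tanh(c_t)`.
#'
#' @param x_t input, a vector of length `d` or a `batch x d` matrix.
#' @param h_prev,c_prev previous hidden and cell state (vector of length `h`
#'   or `batch x h` matrix).
#' @param weights list with matrices `Wxi, Whi, Wxf, Whf, Wxo, Who, Wxc,
#'   Whc` (`d x h` / `h x h`) and bias vectors `bi, bf, bo, bc`.
#' @return list with `h`, `c` and the gate activations `i`, `f`, `o`, `g`.
#' @export
lstm_cell <- function(x_t, h_prev, c_prev, weights) {
  as_m <- function(v, d) if (is.matrix(v)) v else matrix(v, 1L, d)
  x <- as_m(x_t, length(x_t))
  h <- as_m(h_prev, length(h_prev))
  cc <- as_m(c_prev, length(c_prev))
  if (nrow(x) != nrow(h) || ncol(x) != nrow(weights$Wxi) ||
      ncol(h) != nrow(weights$Whi) || ncol(cc) != ncol(h)) {
    stop("shape mismatch between inputs and weights", call. = FALSE)
  }
  i <- .sigmoid(.addb(x %*% weights$Wxi + h %*% weights$Whi, weights$bi))
  f <- .sigmoid(.addb(x %*% weights$Wxf + h %*% weights$Whf, weights$bf))
  o <- .sigmoid(.addb(x %*% weights$Wxo + h %*% weights$Who, weights$bo))
  g <- tanh(.addb(x %*% weights$Wxc + h %*% weights$Whc, weights$bc))
  c_t <- f * cc + i * g
  h_t <- o * tanh(c_t)
  if (!is.matrix(x_t)) {
    list(h = drop(h_t), c = drop(c_t), i = drop(i), f = drop(f),
         o = drop(o), g = drop(g))
  } else {
    list(h = h_t, c = c_t, i = i, f = f, o = o, g = g)
  }
}

.init_lstm <- function(d_in, d_h) {
  list(Wxi = .init_mat(d_in, d_h), Whi = .init_mat(d_h, d_h), bi = numeric(d_h),
       Wxf = .init_mat(d_in, d_h), Whf = .init_mat(d_h, d_h),
       bf = rep(1, d_h),                 # positive forget bias: remember early
       Wxo = .init_mat(d_in, d_h), Who = .init_mat(d_h, d_h), bo = numeric(d_h),
       Wxc = .init_mat(d_in, d_h), Whc = .init_mat(d_h, d_h), bc = numeric(d_h))
}

# ---- autoencoder loss & gradients ------------------------------------------

# Denoising autoencoder with sigmoid encoder, linear decoder, squared
# reconstruction loss, KL sparsity penalty on mean hidden activation and L2
# weight decay. Returns loss and analytic gradients.
.dae_loss_grads <- function(p, x_corrupt, x_clean, rho, beta, wd) {
  .dae_loss_grads_cpp(p, x_corrupt, x_clean, rho, beta, wd)
}

# Reference R implementation of the autoencoder loss/gradients, kept as an
# independent route for the finite-difference and C++ cross-checks.
.dae_loss_grads_r <- function(p, x_corrupt, x_clean, rho, beta, wd) {
  n <- nrow(x_corrupt)
  H <- .sigmoid(.addb(x_corrupt %*% p$W1, p$b1))
  Xhat <- .addb(H %*% p$W2, p$b2)
  err <- Xhat - x_clean
  loss <- sum(err^2) / (n * ncol(x_clean))
  rho_hat <- colMeans(H)
  rho_hat <- pmin(pmax(rho_hat, 1e-8), 1 - 1e-8)
  kl <- sum(rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat)))
  loss <- loss + beta * kl + wd * (sum(p$W1^2) + sum(p$W2^2))
  dXhat <- 2 * err / (n * ncol(x_clean))
  gW2 <- t(H) %*% dXhat + 2 * wd * p$W2
  gb2 <- colSums(dXhat)
  dH <- dXhat %*% t(p$W2)
  dH <- sweep(dH, 2L, beta * (-rho / rho_hat + (1 - rho) / (1 - rho_hat)) / n, "+")
  dZ1 <- dH * H * (1 - H)
  gW1 <- t(x_corrupt) %*% dZ1 + 2 * wd * p$W1
  gb1 <- colSums(dZ1)
  list(loss = loss,
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
       hidden_mean = mean(H))
}

.train_dae <- function(X, hidden, spec, phase_name, log_env) {
  p <- list(W1 = .init_mat(ncol(X), hidden), b1 = numeric(hidden),
            W2 = .init_mat(hidden, ncol(X)), b2 = numeric(ncol(X)))
  st <- .adam_init(p)
  n <- nrow(X)
  bs <- min(spec$batch_size, n)
  for (ep in seq_len(spec$pretrain_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = bs)) {
      rows <- ord[start:min(start + bs - 1L, n)]
      Xb <- X[rows, , drop = FALSE]
      Xc <- corrupt(Xb, spec$corruption_p)
      lg <- .dae_loss_grads(p, Xc, Xb, spec$sparsity_target,
                            spec$sparsity_weight, spec$weight_decay)
      up <- .adam_step(p, lg$grads, st, spec$lr)
      p <- up$params; st <- up$state
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    log_env$entries[[length(log_env$entries) + 1L]] <-
      list(phase = phase_name, epoch = ep, loss = ep_loss / nb)
  }
  p
}

.collect_log <- function(log_env) {
  data.frame(phase = vapply(log_env$entries, `[[`, character(1), "phase"),
             epoch = vapply(log_env$entries, `[[`, integer(1), "epoch"),
             loss = vapply(log_env$entries, `[[`, numeric(1), "loss"))
}

#' Greedy layerwise pretraining of the stacked autoencoders
#'
#' Trains the first sparse denoising autoencoder (46 -> 92 -> 46) on
#' corrupted feature vectors, encodes the clean inputs with its encoder, and
#' trains the second autoencoder (92 -> 12 -> 92) on those encodings. Inputs
#' are expected already standardized (as done by [train_network()]).
#'
#' @param x numeric matrix of feature rows (windows x features).
#' @param spec a [network_spec()]; `spec$seed` makes the result
#'   reproducible.
#' @return list with encoder/decoder parameter sets `dae1`, `dae2` (each
#'   `W1, b1, W2, b2`) and the per-epoch reconstruction `log`.
#' @export
pretrain_sdae <- function(x, spec = network_spec()) {
  stopifnot(is.matrix(x), nrow(x) >= 1L, inherits(spec, "network_spec"))
  if (ncol(x) != spec$input_dim) {
    stop("expected ", spec$input_dim, " feature columns", call. = FALSE)
  }
  set.seed(spec$seed)
  log_env <- new.env(); log_env$entries <- list()
  dae1 <- .train_dae(x, spec$sdae_dims[1L], spec, "sdae1", log_env)
  A1 <- .sigmoid(.addb(x %*% dae1$W1, dae1$b1))
  dae2 <- .train_dae(A1, spec$sdae_dims[2L], spec, "sdae2", log_env)
  list(dae1 = dae1, dae2 = dae2, log = .collect_log(log_env))
}

# ---- stacked network loss & gradients --------------------------------------

# Full-stack squared loss and analytic gradients. feats: standardized
# feature matrix; targets: standardized labels; seq_mat: B x T matrix of row
# indices forming the training sequences. params holds $lstm and $out, plus
# $enc1/$enc2 when encode = TRUE. Row indices are assumed unique within the
# batch (non-overlapping sequences).
.stack_loss_grads <- function(params, feats, targets, seq_mat, wd,
                              encode = TRUE) {
  storage.mode(seq_mat) <- "integer"
  .stack_loss_grads_cpp(params, feats, as.numeric(targets), seq_mat, wd, encode)
}

# Reference R implementation of the full-stack loss/gradients (see
# src/doa_grads.cpp for the production kernel).
.stack_loss_grads_r <- function(params, feats, targets, seq_mat, wd,
                                encode = TRUE) {
  B <- nrow(seq_mat); Tn <- ncol(seq_mat)
  if (encode) {
    A1 <- .sigmoid(.addb(feats %*% params$enc1$W, params$enc1$b))
    A2 <- .sigmoid(.addb(A1 %*% params$enc2$W, params$enc2$b))
    Z <- A2
  } else {
    Z <- feats
  }
  lw <- params$lstm
  d_h <- ncol(lw$Whi)
  # fuse the four gate products into single matmuls (gate order i, f, o, c')
  Wx <- cbind(lw$Wxi, lw$Wxf, lw$Wxo, lw$Wxc)
  Wh <- cbind(lw$Whi, lw$Whf, lw$Who, lw$Whc)
  bg <- c(lw$bi, lw$bf, lw$bo, lw$bc)
  si <- seq_len(d_h); sf <- si + d_h; so <- sf + d_h; sg <- so + d_h
  h <- matrix(0, B, d_h); cc <- matrix(0, B, d_h)
  cache <- vector("list", Tn)
  loss <- 0
  err_list <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    X_t <- Z[seq_mat[, t], , drop = FALSE]
    za <- .addb(X_t %*% Wx + h %*% Wh, bg)
    gi <- .sigmoid(za[, si, drop = FALSE])
    gf <- .sigmoid(za[, sf, drop = FALSE])
    go <- .sigmoid(za[, so, drop = FALSE])
    gg <- tanh(za[, sg, drop = FALSE])
    c_t <- gf * cc + gi * gg
    tc <- tanh(c_t)
    h_t <- go * tc
    y_t <- .addb(h_t %*% params$out$W, params$out$b)
    err <- y_t - targets[seq_mat[, t]]
    loss <- loss + sum(err^2)
    cache[[t]] <- list(i = gi, f = gf, o = go, g = gg, c = c_t, tc = tc,
                       h = h_t, x = X_t, h_prev = h, c_prev = cc)
    err_list[[t]] <- err
    h <- h_t; cc <- c_t
  }
  denom <- B * Tn
  loss <- loss / denom
  g <- .zeros_like(params)
  gWx <- matrix(0, nrow(Wx), ncol(Wx))
  gWh <- matrix(0, nrow(Wh), ncol(Wh))
  gbg <- numeric(length(bg))
  dZ <- matrix(0, nrow(Z), ncol(Z))
  dh_next <- matrix(0, B, d_h); dc_next <- matrix(0, B, d_h)
  for (t in rev(seq_len(Tn))) {
    ca <- cache[[t]]
    dy <- 2 * err_list[[t]] / denom
    g$out$W <- g$out$W + t(ca$h) %*% dy
    g$out$b <- g$out$b + colSums(dy)
    dh <- dh_next + dy %*% t(params$out$W)
    do_ <- dh * ca$tc
    dc <- dc_next + dh * ca$o * (1 - ca$tc^2)
    dc_next <- dc * ca$f
    dz <- cbind(dc * ca$g * ca$i * (1 - ca$i),
                dc * ca$c_prev * ca$f * (1 - ca$f),
                do_ * ca$o * (1 - ca$o),
                dc * ca$i * (1 - ca$g^2))
    gWx <- gWx + t(ca$x) %*% dz
    gWh <- gWh + t(ca$h_prev) %*% dz
    gbg <- gbg + colSums(dz)
    dh_next <- dz %*% t(Wh)
    dx <- dz %*% t(Wx)
    rows <- seq_mat[, t]
    dZ[rows, ] <- dZ[rows, , drop = FALSE] + dx
  }
  g$lstm$Wxi <- gWx[, si, drop = FALSE]; g$lstm$Whi <- gWh[, si, drop = FALSE]
  g$lstm$Wxf <- gWx[, sf, drop = FALSE]; g$lstm$Whf <- gWh[, sf, drop = FALSE]
  g$lstm$Wxo <- gWx[, so, drop = FALSE]; g$lstm$Who <- gWh[, so, drop = FALSE]
  g$lstm$Wxc <- gWx[, sg, drop = FALSE]; g$lstm$Whc <- gWh[, sg, drop = FALSE]
  g$lstm$bi <- gbg[si]; g$lstm$bf <- gbg[sf]
  g$lstm$bo <- gbg[so]; g$lstm$bc <- gbg[sg]
  if (encode) {
    dZ2 <- dZ * A2 * (1 - A2)
    g$enc2$W <- t(A1) %*% dZ2 + 2 * wd * params$enc2$W
    g$enc2$b <- colSums(dZ2)
    dA1 <- dZ2 %*% t(params$enc2$W)
    dZ1 <- dA1 * A1 * (1 - A1)
    g$enc1$W <- t(feats) %*% dZ1 + 2 * wd * params$enc1$W
    g$enc1$b <- colSums(dZ1)
    loss <- loss + wd * (sum(params$enc1$W^2) + sum(params$enc2$W^2))
  }
  for (nm in c("Wxi", "Whi", "Wxf", "Whf", "Wxo", "Who", "Wxc", "Whc")) {
    g$lstm[[nm]] <- g$lstm[[nm]] + 2 * wd * lw[[nm]]
    loss <- loss + wd * sum(lw[[nm]]^2)
  }
  g$out$W <- g$out$W + 2 * wd * params$out$W
  loss <- loss + wd * sum(params$out$W^2)
  list(loss = loss, grads = g)
}

# Non-overlapping length-T sequences over each subject's window rows, with a
# per-call random start offset so successive epochs cover different
# alignments. Returns a B x T index matrix (NULL when no subject is long
# enough).
.make_sequences <- function(subject_rows, seq_len, random_offset = TRUE) {
  out <- list()
  for (rows in subject_rows) {
    n <- length(rows)
    if (n < seq_len) next
    off <- if (random_offset && n > seq_len) {
      sample.int(min(seq_len, n - seq_len + 1L), 1L) - 1L
    } else 0L
    n_chunks <- (n - off) %/% seq_len
    for (k in seq_len(n_chunks)) {
      out[[length(out) + 1L]] <- rows[off + ((k - 1L) * seq_len + 1L):(k * seq_len)]
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# ---- training ---------------------------------------------------------------

#' Train the SDAE-LSTM depth-of-anesthesia network
#'
#' Three phases: (1) greedy layerwise pretraining of the two sparse
#' denoising autoencoders on the pooled training features; (2) training of
#' the LSTM and linear output head on the encoded window sequences against
#' effect-site concentration labels (squared loss, truncated BPTT over
#' `seq_len`-window sequences); (3) end-to-end fine-tuning of encoders, LSTM
#' and output head jointly. Features and labels are standardized internally
#' (statistics stored in the returned network and inverted at prediction).
#'
#' @param features_list list of `doa_features` objects (or plain numeric
#'   matrices with 46 columns), one per training subject, windows in
#'   temporal order.
#' @param labels_list list of per-window effect-site label vectors aligned
#'   to `features_list` (see [align_labels()]).
#' @param spec a [network_spec()].
#' @return a `doa_network` object with the fitted parameters, the
#'   standardization statistics and the per-epoch `training_log`.
#' @export
train_network <- function(features_list, labels_list, spec = network_spec()) {
  stopifnot(inherits(spec, "network_spec"),
            length(features_list) >= 1L,
            length(labels_list) == length(features_list))
  mats <- lapply(features_list, function(f) {
    if (inherits(f, "doa_features")) f$values else as.matrix(f)
  })
  for (i in seq_along(mats)) {
    if (ncol(mats[[i]]) != spec$input_dim) {
      stop("subject ", i, ": expected ", spec$input_dim, " feature columns",
           call. = FALSE)
    }
    if (nrow(mats[[i]]) != length(labels_list[[i]])) {
      stop("subject ", i, ": labels not aligned to windows", call. = FALSE)
    }
  }
  F_all <- do.call(rbind, mats)
  y_all <- unlist(labels_list)
  if (any(!is.finite(F_all)) || any(!is.finite(y_all))) {
    stop("non-finite features or labels", call. = FALSE)
  }
  mu <- colMeans(F_all)
  sdv <- apply(F_all, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Fz <- sweep(sweep(F_all, 2L, mu), 2L, sdv, "/")
  ymu <- mean(y_all); ysd <- stats::sd(y_all)
  if (!is.finite(ysd) || ysd == 0) ysd <- 1
  yz <- (y_all - ymu) / ysd
  n_per <- vapply(mats, nrow, integer(1))
  ends <- cumsum(n_per)
  subject_rows <- lapply(seq_along(n_per), function(i) {
    (ends[i] - n_per[i] + 1L):ends[i]
  })
  log_env <- new.env(); log_env$entries <- list()

  set.seed(spec$seed)
  if (spec$use_sdae) {
    dae1 <- .train_dae(Fz, spec$sdae_dims[1L], spec, "sdae1", log_env)
    A1 <- .sigmoid(.addb(Fz %*% dae1$W1, dae1$b1))
    dae2 <- .train_dae(A1, spec$sdae_dims[2L], spec, "sdae2", log_env)
    enc1 <- list(W = dae1$W1, b = dae1$b1)
    enc2 <- list(W = dae2$W1, b = dae2$b1)
    Z <- .sigmoid(.addb(A1 %*% enc2$W, enc2$b))
    lstm_in <- spec$sdae_dims[2L]
  } else {
    enc1 <- enc2 <- NULL
    Z <- Fz
    lstm_in <- spec$input_dim
  }

  run_phase <- function(params, feats, epochs, lr, encode, phase_name) {
    st <- .adam_init(params)
    seq_len_eff <- min(spec$seq_len, max(n_per))
    for (ep in seq_len(epochs)) {
      seq_mat <- .make_sequences(subject_rows, seq_len_eff)
      if (is.null(seq_mat)) stop("no subject has enough windows for seq_len",
                                 call. = FALSE)
      lg <- .stack_loss_grads(params, feats, yz, seq_mat,
                              spec$weight_decay, encode = encode)
      if (!is.finite(lg$loss)) stop("training loss became non-finite",
                                    call. = FALSE)
      up <- .adam_step(params, lg$grads, st, lr)
      params <- up$params; st <- up$state
      log_env$entries[[length(log_env$entries) + 1L]] <-
        list(phase = phase_name, epoch = ep, loss = lg$loss)
    }
    params
  }

  lstm_params <- list(lstm = .init_lstm(lstm_in, spec$lstm_hidden),
                      out = list(W = .init_mat(spec$lstm_hidden, 1L),
                                 b = numeric(1L)))
  lstm_params <- run_phase(lstm_params, Z, spec$lstm_epochs, spec$lr,
                           encode = FALSE, phase_name = "lstm")

  if (spec$use_sdae) {
    full <- c(list(enc1 = enc1, enc2 = enc2), lstm_params)
    full <- run_phase(full, Fz, spec$finetune_epochs, spec$finetune_lr,
                      encode = TRUE, phase_name = "finetune")
  } else {
    full <- run_phase(lstm_params, Z, spec$finetune_epochs, spec$finetune_lr,
                      encode = FALSE, phase_name = "finetune")
  }

  structure(list(spec = spec,
                 scaler = list(mu = mu, sd = sdv, ymu = ymu, ysd = ysd),
                 params = full,
                 training_log = .collect_log(log_env)),
            class = "doa_network")
}

#' @export
print.doa_network <- function(x, ...) {
  arch <- if (x$spec$use_sdae) {
    paste(c(x$spec$input_dim, x$spec$sdae_dims, x$spec$lstm_hidden, 1L),
          collapse = "-")
  } else {
    paste(c(x$spec$input_dim, x$spec$lstm_hidden, 1L), collapse = "-")
  }
  cat(sprintf("<doa_network> %s, final training loss %.4g\n",
              arch, utils::tail(x$training_log$loss, 1L)))
  invisible(x)
}

#' Predict the depth-of-anesthesia index
#'
#' Streams the feature windows, in temporal order, through the trained
#' encoders and the LSTM from a zero initial state and returns one index
#' value per window on the effect-site concentration scale (label
#' standardization inverted). The index increases with anesthetic depth.
#'
#' @param object a `doa_network` from [train_network()].
#' @param features a `doa_features` object or numeric matrix with 46
#'   columns, windows in temporal order.
#' @param ... unused.
#' @return numeric index series, one value per window.
#' @export
predict.doa_network <- function(object, features, ...) {
  X <- if (inherits(features, "doa_features")) features$values else as.matrix(features)
  if (ncol(X) != object$spec$input_dim) {
    stop("expected ", object$spec$input_dim, " feature columns", call. = FALSE)
  }
  sc <- object$scaler
  Xz <- sweep(sweep(X, 2L, sc$mu), 2L, sc$sd, "/")
  p <- object$params
  Z <- if (object$spec$use_sdae) {
    A1 <- .sigmoid(.addb(Xz %*% p$enc1$W, p$enc1$b))
    .sigmoid(.addb(A1 %*% p$enc2$W, p$enc2$b))
  } else Xz
  d_h <- ncol(p$lstm$Whi)
  h <- matrix(0, 1L, d_h); cc <- matrix(0, 1L, d_h)
  out <- numeric(nrow(Z))
  for (t in seq_len(nrow(Z))) {
    st <- lstm_cell(Z[t, , drop = FALSE], h, cc, p$lstm)
    out[t] <- st$h %*% p$out$W + p$out$b
    h <- st$h; cc <- st$c
  }
  out * sc$ysd + sc$ymu
}
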