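# Pk statistic against exhaustive pair enumeration and its documented
# invariances; single-feature baselines; LOSO protocol arithmetic.

test_that("pk_statistic reproduces the worked three-point example", {
  r <- pk_statistic(c(1, 1, 2), c(1, 2, 3))
  expect_equal(r$pk, 5 / 6)
  expect_equal(r$pc, 2 / 3)
  expect_equal(r$ptx, 1 / 3)
  expect_identical(r$pd, 0)
  expect_identical(r$n_pairs_used, 3L)
  expect_false(r$reflected)
  expect_output(print(r), "pk_result")
})

test_that("pk_statistic matches the brute-force oracle on tie-laden instances", {
  set.seed(41)
  for (k in 1:50) {
    n <- sample(5:40, 1)
    x <- sample(1:6, n, replace = TRUE) + if (k %% 2) 0 else rnorm(n, sd = 0.1)
    y <- sample(1:5, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    tol <- if (k %% 3 == 0) 0.25 else 0
    ref <- pk_oracle(x, y, tie_tol = tol)
    got <- pk_statistic(x, y, tie_tol = tol, reflect = FALSE)
    expect_identical(got$pk_raw, ref$pk_raw)
    expect_identical(got$pc, ref$pc)
    expect_identical(got$pd, ref$pd)
    expect_identical(got$ptx, ref$ptx)
    expect_identical(got$n_pairs_used, as.integer(ref$n_pairs_used))
  }
})

test_that("reflection maps anticorrelated indices onto [0.5, 1]", {
  set.seed(42)
  y <- 1:50
  x <- -y + rnorm(50, sd = 3)
  r <- pk_statistic(x, y)
  expect_true(r$reflected)
  expect_equal(r$pk, 1 - r$pk_raw)
  expect_equal(pk_statistic(-x, y)$pk, r$pk)          # reflection symmetry
  expect_equal(pk_statistic(x, y, reflect = FALSE)$pk, r$pk_raw)
})

test_that("Pk is invariant under strictly increasing transforms of the index", {
  set.seed(43)
  y <- rep(1:10, each = 4)
  x <- y + rnorm(40)
  expect_equal(pk_statistic(exp(x / 2), y)$pk, pk_statistic(x, y)$pk)
  expect_equal(pk_statistic(rank(x), y)$pk, pk_statistic(x, y)$pk)
})

test_that("y-tied pairs are excluded and degenerate depth errors", {
  x <- c(1, 2, 3, 10); y <- c(1, 2, 3, 3)
  r1 <- pk_statistic(x, y)
  expect_identical(r1$n_pairs_used, 5L)     # 6 pairs minus the one y-tie
  # the two y-tied points (x = 3 and 10) both exceed every other x, so
  # swapping them changes only their mutual, excluded pair
  expect_equal(pk_statistic(c(1, 2, 10, 3), y)$pk, r1$pk)
  expect_error(pk_statistic(rnorm(5), rep(3, 5)), "tied in depth")
  expect_error(pk_statistic(c(1, NA), c(1, 2)), "finite")
  expect_error(pk_statistic(1, 1))
})

test_that("baseline_pk scores single features with reflection", {
  f <- structure(list(values = matrix(rnorm(30 * 46), 30, 46,
                                      dimnames = list(NULL, feature_names())),
                      centers_s = seq_len(30), fs = 100, subject_id = "S01"),
                 class = "doa_features")
  depth <- seq(0, 5, length.out = 30)
  f$values[, "sampen"] <- -depth                      # anticorrelated feature
  f$values[, "peen"] <- depth                         # correlated feature
  expect_equal(baseline_pk(f, depth, "sampen")$pk, 1)
  expect_true(baseline_pk(f, depth, "sampen")$reflected)
  expect_equal(baseline_pk(f, depth, "peen")$pk, 1)
  expect_error(baseline_pk(f, depth, "nope"), "unknown feature")
})

test_that("LOSO cross-validation follows the protocol and is deterministic", {
  set.seed(45)
  make_subject <- function(seed, n = 64L) {
    set.seed(seed)
    trend <- seq(0, 5, length.out = n)
    F <- matrix(rnorm(n * 46, sd = 0.3), n, 46) + trend
    colnames(F) <- feature_names()
    structure(list(values = F, centers_s = seq_len(n), fs = 100,
                   subject_id = sprintf("T%02d", seed)),
              class = "doa_features")
  }
  feats <- lapply(1:2, make_subject)
  labs <- lapply(feats, function(f) seq(0, 5, length.out = 64))
  sp <- network_spec(pretrain_epochs = 3L, lstm_epochs = 40L,
                     finetune_epochs = 15L)
  r1 <- loso_cv(feats, labs, sp, seed = 6L)
  expect_s3_class(r1, "cv_report")
  expect_identical(dim(r1$pk_values), c(1L, 2L))      # 2 subjects -> 2 folds
  expect_identical(r1$per_subject$subject, c("T01", "T02"))
  expect_equal(r1$mean, mean(r1$per_subject$pk))
  expect_true(all(r1$pk_values >= 0.5 & r1$pk_values <= 1))
  r2 <- loso_cv(feats, labs, sp, seed = 6L)           # same master seed
  expect_identical(r1$pk_values, r2$pk_values)
  expect_output(print(r1), "cv_report")
})

test_that("a fold with degenerate labels is skipped with a warning", {
  set.seed(46)
  F <- matrix(rnorm(64 * 46), 64, 46)
  as_feats <- function(v, id) structure(
    list(values = v, centers_s = seq_len(nrow(v)), fs = 100, subject_id = id),
    class = "doa_features")
  feats <- list(as_feats(F, "A"), as_feats(F + seq(0, 5, length.out = 64), "B"))
  labs <- list(rep(2, 64), seq(0, 5, length.out = 64))
  sp <- network_spec(pretrain_epochs = 2L, lstm_epochs = 10L,
                     finetune_epochs = 5L)
  expect_warning(r <- loso_cv(feats, labs, sp, seed = 1L), "degenerate")
  expect_true(is.na(r$pk_values[1, 1]))
  expect_false(is.na(r$pk_values[1, 2]))
})
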