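# Prediction probability (Pk) and the leave-one-subject-out cross-validation
# protocol used to score a candidate depth-of-anesthesia index against
# effect-site concentration.

#' Prediction probability (Pk) of an index against anesthetic depth
#'
#' Smith's concordance statistic: the probability that the index correctly
#' orders a randomly drawn pair of observations by true anesthetic depth.
#' Over all unordered pairs with distinct depth `y`, a pair is concordant
#' when index and depth move the same way, discordant when they move
#' opposite ways, and an x-only tie when the index difference is within
#' `tie_tol`; pairs tied in `y` are excluded. Then
#' `Pk = (Pc + Ptx/2) / (Pc + Pd + Ptx)`. A perfectly concordant index gives
#' 1, a depth-independent index gives 0.5 in expectation. Because a good
#' index may correlate negatively with depth (entropies fall under
#' anesthesia), a raw value below 0.5 is reflected to `1 - Pk` when
#' `reflect = TRUE`.
#'
#' @param index numeric index values, one per observation.
#' @param depth true anesthetic depth (effect-site concentration), same
#'   length.
#' @param tie_tol absolute tolerance below which two index values count as
#'   tied; default 0 (exact equality).
#' @param reflect apply the `1 - Pk` reflection when the raw value is below
#'   0.5?
#' @return a `pk_result` object: `pk` (reported value), `pk_raw`, pair
#'   probabilities `pc`, `pd`, `ptx` (fractions of all unordered pairs, so
#'   `pc + pd + ptx <= 1` with the remainder tied in depth), `n_pairs_used`,
#'   `reflected`.
#' @export
pk_statistic <- function(index, depth, tie_tol = 0, reflect = TRUE) {
  n <- length(index)
  stopifnot(length(depth) == n, n >= 2L, tie_tol >= 0)
  if (any(!is.finite(index)) || any(!is.finite(depth))) {
    stop("index and depth must be finite", call. = FALSE)
  }
  ut <- upper.tri(matrix(0, n, n))
  dx <- outer(index, index, "-")[ut]
  dy <- outer(depth, depth, "-")[ut]
  n_pairs <- length(dx)
  valid <- dy != 0
  if (!any(valid)) stop("all pairs are tied in depth; Pk undefined", call. = FALSE)
  dx <- dx[valid]; dy <- dy[valid]
  xtie <- abs(dx) <= tie_tol
  nc <- sum(!xtie & dx * dy > 0)
  nd <- sum(!xtie & dx * dy < 0)
  ntx <- sum(xtie)
  pk_raw <- (nc + ntx / 2) / (nc + nd + ntx)
  reflected <- reflect && pk_raw < 0.5
  structure(list(pk = if (reflected) 1 - pk_raw else pk_raw,
                 pk_raw = pk_raw,
                 pc = nc / n_pairs, pd = nd / n_pairs, ptx = ntx / n_pairs,
                 n_pairs_used = nc + nd + ntx,
                 reflected = reflected),
            class = "pk_result")
}

#' @export
print.pk_result <- function(x, ...) {
  cat(sprintf("<pk_result> Pk = %.4f%s (Pc %.3f, Pd %.3f, Ptx %.3f; %d pairs)\n",
              x$pk, if (x$reflected) " [reflected]" else "",
              x$pc, x$pd, x$ptx, x$n_pairs_used))
  invisible(x)
}

#' Pk of a single raw feature
#'
#' Scores one column of the feature matrix directly against effect-site
#' concentration, the standard single-parameter baselines (permutation
#' entropy, sample entropy, wavelet entropy, band spectra, alpha-ratio).
#' Reflection is applied, so negatively correlated features (the entropies)
#' report their discrimination ability on the usual `[0.5, 1]` scale.
#'
#' @param features a `doa_features` object.
#' @param depth per-window effect-site concentration (see [align_labels()]).
#' @param feature_name one of [feature_names()].
#' @inheritParams pk_statistic
#' @return a `pk_result`.
#' @export
baseline_pk <- function(features, depth, feature_name, tie_tol = 0) {
  stopifnot(inherits(features, "doa_features"))
  if (!feature_name %in% colnames(features$values)) {
    stop("unknown feature: ", feature_name, call. = FALSE)
  }
  pk_statistic(features$values[, feature_name], depth, tie_tol = tie_tol)
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject in turn, trains the network on all other subjects
#' (their order shuffled per repeat) and scores the held-out subject's
#' predicted index against its effect-site labels with [pk_statistic()].
#' Repeats rerun the whole protocol with fresh training seeds and are
#' averaged per subject.
#'
#' @param features_list list of `doa_features`, one per subject.
#' @param labels_list list of per-window label vectors, aligned to
#'   `features_list`.
#' @param spec a [network_spec()].
#' @param repeats number of repetitions of the full protocol.
#' @param seed master seed controlling shuffling and training seeds.
#' @return a `cv_report`: `per_subject` data frame (subject, mean Pk over
#'   repeats), `pk_values` (repeats x subjects matrix), `mean`, `sd` (across
#'   subjects of per-subject means).
#' @export
loso_cv <- function(features_list, labels_list, spec = network_spec(),
                    repeats = 1L, seed = 1L) {
  n_sub <- length(features_list)
  stopifnot(n_sub >= 2L, length(labels_list) == n_sub, repeats >= 1L)
  ids <- vapply(seq_len(n_sub), function(i) {
    sid <- features_list[[i]]$subject_id
    if (is.null(sid)) sprintf("S%02d", i) else as.character(sid)
  }, character(1))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, repeats)
  pk_mat <- matrix(NA_real_, repeats, n_sub, dimnames = list(NULL, ids))
  for (r in seq_len(repeats)) {
    set.seed(rep_seeds[r])
    fold_seeds <- sample.int(.Machine$integer.max, n_sub)
    for (held in seq_len(n_sub)) {
      train_idx <- setdiff(seq_len(n_sub), held)
      set.seed(fold_seeds[held])
      train_idx <- sample(train_idx)     # shuffle training-subject order
      y_test <- labels_list[[held]]
      if (length(unique(y_test)) < 2L) {
        warning("fold ", ids[held], " has degenerate labels; skipped", call. = FALSE)
        next
      }
      sp <- spec
      sp$seed <- fold_seeds[held]
      net <- train_network(features_list[train_idx], labels_list[train_idx], sp)
      idx <- predict(net, features_list[[held]])
      pk_mat[r, held] <- pk_statistic(idx, y_test)$pk
    }
  }
  per_subject <- data.frame(subject = ids, pk = colMeans(pk_mat, na.rm = TRUE),
                            row.names = NULL)
  structure(list(per_subject = per_subject, pk_values = pk_mat,
                 mean = mean(per_subject$pk, na.rm = TRUE),
                 sd = stats::sd(per_subject$pk, na.rm = TRUE),
                 repeats = repeats, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d subjects, %d repeat(s): Pk = %.4f +/- %.4f\n",
              nrow(x$per_subject), x$repeats, x$mean, x$sd))
  invisible(x)
}
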