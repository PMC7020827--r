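# Independent brute-force oracles and shared expensive fixtures.
# The oracles deliberately take a different computational route from the
# package implementations (explicit loops / exhaustive enumeration) so the
# comparisons are meaningful.

# -- session-level fixture cache ----------------------------------------------
# Helpers are sourced once per test run; this environment keeps expensive
# fixtures (simulated cohorts with extracted features) shared across files.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_env, inherits = FALSE)) {
    assign(key, expr, envir = .fixture_env)
  }
  get(key, envir = .fixture_env, inherits = FALSE)
}

# n-subject cohort at generator defaults: features + aligned labels.
cohort_fixture <- function(n_subjects, master_seed) {
  fixture(sprintf("cohort_%d_%d", n_subjects, master_seed), {
    sessions <- simulate_cohort(n_subjects, seed = master_seed)
    fl <- lapply(sessions, function(s) suppressMessages(session_features(s)))
    list(features = lapply(fl, `[[`, "features"),
         labels = lapply(fl, `[[`, "labels"),
         sessions = sessions)
  })
}

# A single short session (120 s) for fast feature-level tests.
short_session <- function() {
  fixture("short_session", {
    sp <- session_spec(duration_s = 120,
                       cet_profile = data.frame(time_s = c(0, 30, 120),
                                                vol = c(0, 5, 5)),
                       seed = 7L)
    simulate_session(sp, subject_id = "SX")
  })
}

# -- sample entropy: exhaustive pairwise template counting --------------------
sampen_oracle <- function(x, m = 2L, r = 0.2, relative_r = TRUE) {
  n <- length(x)
  r_abs <- if (relative_r) r * stats::sd(x) else r
  nt <- n - m                      # templates i = 1..n-m at both lengths
  a <- 0L
  b <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      dm <- max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)]))
      if (dm <= r_abs) {
        b <- b + 1L
        if (max(dm, abs(x[i + m] - x[j + m])) <= r_abs) a <- a + 1L
      }
    }
  }
  if (a == 0L || b == 0L) return(NA_real_)
  -log(a / b)
}

# -- permutation entropy: explicit pattern table over all m! permutations -----
peen_oracle <- function(x, m = 4L, tau = 1L) {
  n_vec <- length(x) - (m - 1L) * tau
  pats <- character(n_vec)
  for (i in seq_len(n_vec)) {
    v <- x[i + (0:(m - 1L)) * tau]
    # stable ranking: ties broken by position, as order() does
    pats[i] <- paste(order(v), collapse = ",")
  }
  counts <- table(pats)
  p <- as.numeric(counts) / n_vec
  -sum(p * log(p)) / log(factorial(m))
}

# -- Pk: explicit enumeration of every unordered pair -------------------------
pk_oracle <- function(x, y, tie_tol = 0) {
  n <- length(x)
  nc <- nd <- ntx <- nty <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (y[i] == y[j]) {
        nty <- nty + 1L
      } else if (abs(x[i] - x[j]) <= tie_tol) {
        ntx <- ntx + 1L
      } else if ((x[i] - x[j]) * (y[i] - y[j]) > 0) {
        nc <- nc + 1L
      } else {
        nd <- nd + 1L
      }
    }
  }
  tot <- n * (n - 1L) / 2
  list(pk_raw = (nc + ntx / 2) / (nc + nd + ntx),
       pc = nc / tot, pd = nd / tot, ptx = ntx / tot,
       n_pairs_used = nc + nd + ntx)
}

# -- generic finite-difference gradient over a nested parameter list ----------
numeric_grads <- function(loss_fn, params, eps = 1e-5) {
  flat_idx <- function(p) rapply(p, function(a) seq_along(a), how = "replace")
  g <- params
  walk <- function(path) {
    node <- params[[path]]
    if (is.list(node)) {
      for (nm in seq_along(node)) walk(c(path, nm))
    } else {
      gn <- node
      for (k in seq_along(node)) {
        pp <- params; pm <- params
        pp[[path]][k] <- pp[[path]][k] + eps
        pm[[path]][k] <- pm[[path]][k] - eps
        gn[k] <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      }
      g[[path]] <<- gn
    }
  }
  for (nm in seq_along(params)) walk(nm)
  g
}

max_rel_err <- function(a, b) {
  av <- unlist(a); bv <- unlist(b)
  max(abs(av - bv) / pmax(abs(av), abs(bv), 1e-4))
}
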