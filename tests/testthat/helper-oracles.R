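# Independent brute-force oracles, written loop-by-loop on purpose so they
# share no code path with the implementation they check.

# Shrunken-centroid ingredients computed per gene with explicit loops.
oracle_nsc <- function(vals, lab, classes, delta) {
  P <- nrow(vals)
  n <- length(lab)
  s <- numeric(P)
  overall <- numeric(P)
  cent <- matrix(0, P, 2)
  for (i in seq_len(P)) {
    overall[i] <- mean(vals[i, ])
    ss <- 0
    for (k in 1:2) {
      idx <- which(lab == classes[k])
      cent[i, k] <- mean(vals[i, idx])
      ss <- ss + sum((vals[i, idx] - cent[i, k])^2)
    }
    s[i] <- if (n > 2) sqrt(ss / (n - 2)) else 0
  }
  s0 <- median(s)
  d <- matrix(0, P, 2)
  dprime <- matrix(0, P, 2)
  shrunk <- matrix(0, P, 2)
  for (k in 1:2) {
    nk <- sum(lab == classes[k])
    mk <- sqrt(1 / nk - 1 / n)
    for (i in seq_len(P)) {
      d[i, k] <- (cent[i, k] - overall[i]) / (mk * (s[i] + s0))
      dprime[i, k] <- sign(d[i, k]) * max(abs(d[i, k]) - delta, 0)
      shrunk[i, k] <- overall[i] + mk * (s[i] + s0) * dprime[i, k]
    }
  }
  list(overall = overall, cent = cent, s = s, s0 = s0, d = d,
       dprime = dprime, shrunk = shrunk)
}

# Discriminant prediction evaluated sample by sample.
oracle_nsc_predict <- function(oracle, priors, classes, newx) {
  denom <- oracle$s + oracle$s0
  out <- character(ncol(newx))
  for (j in seq_len(ncol(newx))) {
    sc <- numeric(2)
    for (k in 1:2) {
      sc[k] <- sum((newx[, j] - oracle$shrunk[, k])^2 / denom^2) -
        2 * log(priors[k])
    }
    out[j] <- if (sc[1] <= sc[2]) classes[1] else classes[2]
  }
  out
}

# Lexicographic sort oracle for gene ranking: R desc, T desc, index asc.
oracle_rank <- function(R, Tn) {
  key <- order(-R, -Tn, seq_along(R))
  out <- integer(length(R))
  for (pos in seq_along(key)) out[key[pos]] <- pos
  out
}

# Closed-form Spearman for two permutations (all ranks distinct).
oracle_spearman <- function(a, b) {
  P <- length(a)
  1 - 6 * sum((a - b)^2) / (P * (P^2 - 1))
}

# Confusion tally, element by element.
oracle_confusion <- function(pred, truth, positive) {
  tp <- fn <- fp <- tn <- 0
  for (j in seq_along(pred)) {
    if (truth[j] == positive) {
      if (pred[j] == positive) tp <- tp + 1 else fn <- fn + 1
    } else {
      if (pred[j] == positive) fp <- fp + 1 else tn <- tn + 1
    }
  }
  c(TP = tp, FN = fn, FP = fp, TN = tn)
}

# The three informative-transcript rules, re-derived gene by gene with
# stats::t.test.
oracle_filter <- function(treated, vehicle, min_mean, min_fc, max_p) {
  keep <- character(0)
  for (g in rownames(treated)) {
    a <- treated[g, ]; b <- vehicle[g, ]
    m <- mean(a)
    r <- mean(a) / mean(b)
    fc <- max(r, 1 / r)
    p <- if (sd(a) == 0 && sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else {
      stats::t.test(a, b, var.equal = TRUE)$p.value
    }
    if (m > min_mean && fc >= min_fc && p < max_p) keep <- c(keep, g)
  }
  keep
}

# Small planted scenario used across unit tests (cheap to run).
small_sim <- function(seed = 1, P = 60, q = 6) {
  simulate_two_class(P = P, n_pos = 12, n_neg = 12, q = q, effect = 3,
                     seed = seed)
}
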