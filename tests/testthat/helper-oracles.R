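# Independent brute-force oracles, written naively and kept separate from
# the package implementations they check.

# exhaustive peak scan: local maxima, transitive clustering by the
# min-separation window, highest-per-cluster representative (ties earlier),
# then the noise threshold on representatives
oracle_peak_indices <- function(v, threshold, min_sep, margin) {
  n <- length(v)
  cand <- c()
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      if (v[i] > v[i - 1] && v[i] >= v[i + 1]) cand <- c(cand, i)
    }
  }
  if (!length(cand)) return(integer(0))
  clusters <- list(cand[1])
  if (length(cand) > 1) {
    for (i in cand[-1]) {
      last <- clusters[[length(clusters)]]
      if (i - last[length(last)] < min_sep) {
        clusters[[length(clusters)]] <- c(last, i)
      } else {
        clusters[[length(clusters) + 1]] <- i
      }
    }
  }
  reps <- integer(0)
  for (cl in clusters) {
    best <- cl[1]
    for (i in cl) if (v[i] > v[best]) best <- i
    reps <- c(reps, best)
  }
  level <- median(v) + margin * threshold
  sort(reps[v[reps] > level])
}

# Kruskal-Wallis H from the rank-sum formula with tie correction
oracle_kw_H <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  off <- 0
  S <- 0
  for (g in groups) {
    rg <- r[seq_along(g) + off]
    S <- S + sum(rg)^2 / length(g)
    off <- off + length(g)
  }
  H <- 12 / (N * (N + 1)) * S - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / C
}

# Dunn z statistics written from scratch (pairwise loop over mean ranks)
oracle_dunn_z <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- sapply(seq_along(groups), function(i) mean(r[idx == i]))
  ties <- table(x)
  A <- (N * (N + 1) / 12) - sum(ties^3 - ties) / (12 * (N - 1))
  out <- c()
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i) next
      se <- sqrt(A * (1 / length(groups[[i]]) + 1 / length(groups[[j]])))
      out <- c(out, (rbar[i] - rbar[j]) / se)
    }
  }
  out
}

# closed-form damped Gaussian pulse train evaluated directly on a grid
oracle_pulse_train <- function(times, baseline, amp, damp, tau, sigma) {
  v <- rep(baseline, length(times))
  for (k in seq_along(tau))
    v <- v + amp * damp^(k - 1) * exp(-(times - tau[k])^2 / (2 * sigma^2))
  v
}
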