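# Independent brute-force / closed-form oracles used to freeze expected
# values. These deliberately share no code with the package implementations.

oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Harrell's c by pair enumeration (fixture times assumed distinct)
oracle_harrell <- function(scores, time, event) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      num <- num + if (scores[i] > scores[j]) 1 else
        if (scores[i] == scores[j]) 0.5 else 0
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# hand product-limit estimator of the censoring distribution G(t-) at t
oracle_censor_km_minus <- function(t, time, event) {
  # censoring "events" are event == 0
  ts <- sort(unique(time))
  g <- 1
  for (u in ts) {
    if (u >= t) break
    at_risk <- sum(time >= u)
    d <- sum(time == u & event == 0)
    if (at_risk > 0) g <- g * (1 - d / at_risk)
  }
  g
}

# Uno's IPCW concordance by direct double sum
oracle_uno <- function(scores, time, event, tau) {
  n <- length(time)
  num <- den <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1 || time[i] > tau) next
    g <- oracle_censor_km_minus(time[i], time, event)
    w <- 1 / g^2
    for (j in seq_len(n)) {
      if (time[i] >= time[j]) next
      den <- den + w
      num <- num + w * (if (scores[i] > scores[j]) 1 else
        if (scores[i] == scores[j]) 0.5 else 0)
    }
  }
  num / den
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rep(NA_real_, m)
  prev <- Inf
  for (i in m:1) {
    val <- min(prev, m * p[o[i]] / i, 1)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# tie-corrected Spearman rho = Pearson correlation of the rank vectors
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exact Shapley values of f(x) = w.x + b against a background point, by
# enumeration over all coalitions
oracle_linear_shapley <- function(w, x, bg) {
  d <- length(w)
  f <- function(S) {
    z <- bg
    z[S] <- x[S]
    sum(w * z)
  }
  phi <- numeric(d)
  feats <- seq_len(d)
  for (k in feats) {
    others <- setdiff(feats, k)
    for (sz in 0:length(others)) {
      subsets <- if (sz == 0) list(integer(0)) else
        utils::combn(others, sz, simplify = FALSE)
      wgt <- factorial(sz) * factorial(d - sz - 1) / factorial(d)
      for (S in subsets) {
        phi[k] <- phi[k] + wgt * (f(c(S, k)) - f(S))
      }
    }
  }
  phi
}

# single-event-time log-rank O-E / V closed form
oracle_logrank_single <- function(n1_at_risk, n2_at_risk, death_in_1) {
  n <- n1_at_risk + n2_at_risk
  e1 <- n1_at_risk / n
  o1 <- as.numeric(death_in_1)
  v <- n1_at_risk * n2_at_risk * 1 * (n - 1) / (n^2 * (n - 1))
  (o1 - e1)^2 / v
}
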