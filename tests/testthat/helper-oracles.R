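# Independent oracles: scalar-loop evaluations of the update rules and the
# divergence, and a linear-scan block planner. No matrix algebra, so they
# stay independent of the vectorized implementation they check.

oracle_update_h <- function(V, W, H, epsilon = .Machine$double.eps) {
  n <- nrow(V); m <- ncol(V); k <- ncol(W)
  out <- matrix(0, k, m)
  for (p in seq_len(k)) {
    denom <- 0
    for (r in seq_len(n)) denom <- denom + W[r, p]
    for (j in seq_len(m)) {
      num <- 0
      for (i in seq_len(n)) {
        wh <- 0
        for (q in seq_len(k)) wh <- wh + W[i, q] * H[q, j]
        num <- num + W[i, p] * V[i, j] / (wh + epsilon)
      }
      out[p, j] <- H[p, j] * num / (denom + epsilon)
    }
  }
  out
}

oracle_update_w <- function(V, W, H, epsilon = .Machine$double.eps) {
  n <- nrow(V); m <- ncol(V); k <- ncol(W)
  out <- matrix(0, n, k)
  for (p in seq_len(k)) {
    denom <- 0
    for (t in seq_len(m)) denom <- denom + H[p, t]
    for (i in seq_len(n)) {
      num <- 0
      for (j in seq_len(m)) {
        wh <- 0
        for (q in seq_len(k)) wh <- wh + W[i, q] * H[q, j]
        num <- num + V[i, j] * H[p, j] / (wh + epsilon)
      }
      out[i, p] <- W[i, p] * num / (denom + epsilon)
    }
  }
  out
}

oracle_kl <- function(V, W, H) {
  n <- nrow(V); m <- ncol(V); k <- ncol(W)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    wh <- 0
    for (q in seq_len(k)) wh <- wh + W[i, q] * H[q, j]
    v <- V[i, j]
    if (v > 0 && wh == 0) return(Inf)
    total <- total + (if (v > 0) v * log(v / wh) else 0) - v + wh
  }
  total
}

# largest column-block width whose footprint fits the budget, by linear scan
oracle_bm <- function(n, m, k, es, budget) {
  best <- NA_integer_
  for (b in seq_len(m)) {
    fp <- es * (n * k + k * m + n * b + n * b + k * b + k)
    if (fp <= budget) best <- b
  }
  best
}

random_instance <- function(n, m, k, scale = 5) {
  list(V = matrix(runif(n * m, 0.01, scale), n, m),
       W = matrix(runif(n * k, 0.01, 1), n, k),
       H = matrix(runif(k * m, 0.01, 1), k, m))
}

max_rel_diff <- function(a, b) max(abs(a - b) / pmax(abs(b), .Machine$double.eps))

# assignments agree up to a relabeling of factors
perm_match <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
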