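# Independent brute-force oracles. These deliberately use naive loops and
# direct counting, sharing no code path with the package implementations.

oracle_k2p <- function(a, b) {
  ts_pairs <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  n_eff <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(a)) {
    x <- a[i]; y <- b[i]
    if (x %in% c("-", "N") || y %in% c("-", "N")) next
    n_eff <- n_eff + 1L
    if (x != y) {
      if (any(vapply(ts_pairs, function(p) p[1] == x && p[2] == y,
                     logical(1)))) ts <- ts + 1L else tv <- tv + 1L
    }
  }
  P <- ts / n_eff; Q <- tv / n_eff
  d <- if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) NA_real_ else
    -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
  list(d = d, P = P, Q = Q, n_eff = n_eff)
}

# chi-square of one 2x2 table built by explicit counting
oracle_chi_table <- function(left, right) {
  a <- sum(left); b <- length(left) - a
  c <- sum(right); d <- length(right) - c
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(0)
  n * (a * d - b * c)^2 / denom
}

# maximum cut chi-square over one or more 0/1 rows (exhaustive cuts)
oracle_max_cut_chi <- function(B) {
  m <- ncol(B)
  best <- -Inf
  for (r in seq_len(nrow(B))) {
    for (k in seq_len(m - 1)) {
      chi <- oracle_chi_table(B[r, 1:k], B[r, (k + 1):m])
      if (chi > best) best <- chi
    }
  }
  best
}

# maximum ascent and descent of a +/-1 walk by exhaustive pair enumeration
oracle_walk_extremes <- function(s) {
  W <- c(0, cumsum(s))
  asc <- -Inf; desc <- -Inf
  for (i in seq_along(W)) {
    for (j in seq_along(W)) {
      if (j <= i) next
      asc <- max(asc, W[j] - W[i])
      desc <- max(desc, W[i] - W[j])
    }
  }
  list(ascent = asc, descent = desc, stat = max(asc, desc))
}

# best constant-label interval score (length * column span), exhaustive
oracle_best_run_stat <- function(lab, cols) {
  m <- length(lab)
  best <- -Inf
  for (i in seq_len(m)) {
    for (j in i:m) {
      if (length(unique(lab[i:j])) > 1) next
      best <- max(best, (j - i + 1) * (cols[j] - cols[i] + 1))
    }
  }
  best
}

# per-window quartet NJ score by direct counting: sum over the window's
# fully-resolved columns of the four-point contrast
oracle_quartet_window_scores <- function(cc, s1, s2, oo, starts, w) {
  acgt <- c("A", "C", "G", "T")
  vapply(starts, function(s) {
    cols <- s:min(s + w - 1, length(cc))
    tot <- 0L; n <- 0L
    for (j in cols) {
      if (!(cc[j] %in% acgt && s1[j] %in% acgt && s2[j] %in% acgt &&
            oo[j] %in% acgt)) next
      n <- n + 1L
      tot <- tot + ((cc[j] != s2[j]) + (s1[j] != oo[j])) -
        ((cc[j] != s1[j]) + (s2[j] != oo[j]))
    }
    tot
  }, numeric(1))
}

# random aligned triplet with a bounded number of informative sites;
# returns the triplet object for child = first row
random_triplet <- function(L = 120, max_inf = 30, seed = 1) {
  phagewo:::with_seed(seed, {
    acgt <- c("A", "C", "G", "T")
    p1 <- sample(acgt, L, replace = TRUE)
    p2 <- p1
    k <- sample(2:max_inf, 1)
    pos <- sample(L, k)
    for (j in pos) p2[j] <- sample(setdiff(acgt, p1[j]), 1)
    child <- ifelse(stats::runif(L) < 0.5, p1, p2)
    noise <- sample(L, sample(0:3, 1))
    for (j in noise) child[j] <- sample(acgt, 1)
    reps <- rbind(child, p1, p2)
    rownames(reps) <- c("C", "P1", "P2")
    build_triplets(reps)[[1]]
  })
}
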