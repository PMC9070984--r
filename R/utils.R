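# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic integer hash of strings (djb2, folded into [0, 2^31 - 2])
#' @noRd
hash_string <- function(x) {
  x <- paste(x, collapse = "\x1f")
  h <- 5381
  for (v in utf8ToInt(x)) {
    h <- (h * 33 + v) %% 2147483647
  }
  as.integer(h)
}

#' Derive a child RNG seed from a base seed and a set of labels.
#'
#' Keeps derived seeds below 2^31 and independent of input record order
#' (labels are sorted before hashing where order should not matter).
#' @noRd
derive_seed <- function(base, ..., sort_labels = FALSE) {
  labels <- unlist(list(...), use.names = FALSE)
  if (sort_labels) labels <- sort(labels)
  as.integer((as.numeric(base) * 7919 + hash_string(labels)) %% 2147483647)
}

#' Evaluate `expr` under a temporary RNG state seeded with `seed`.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Pearson chi-square of a 2x2 table, no continuity correction.
#'
#' Returns 0 when any margin is empty (the table carries no signal).
#' Vectorised over the four cell-count vectors.
#' @noRd
chisq2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  denom <- r1 * r2 * c1 * c2
  out <- ifelse(denom > 0, n * (a * d - b * c)^2 / denom, 0)
  out
}

#' Sequential (early-stopping) permutation p-value.
#'
#' `gen` must return a numeric vector of `n` permuted statistics. Runs in
#' batches; stops once `k_stop` exceedances have accumulated, since the
#' p-value is then already far above any usable significance level. The
#' estimate (1 + k) / (1 + n_done) is conservative.
#' @noRd
perm_pvalue <- function(stat_obs, gen, n_perm, batch = 100L, k_stop = 25L) {
  if (!is.finite(stat_obs)) return(1)
  k <- 0L
  done <- 0L
  while (done < n_perm) {
    nb <- min(batch, n_perm - done)
    stats <- gen(nb)
    k <- k + sum(stats >= stat_obs - 1e-12)
    done <- done + nb
    if (k >= k_stop) break
  }
  (1 + k) / (1 + done)
}

stop_codons <- c("TAA", "TAG", "TGA")
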