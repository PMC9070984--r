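# Kimura two-parameter distances with pairwise deletion.

.base_code <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# integer-coded matrix: 1..4 for A,C,G,T; 0 for '-' and 'N'
encode_aln <- function(mat) {
  m <- matrix(0L, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (b in names(.base_code)) m[mat == b] <- .base_code[[b]]
  m
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Columns where either sequence carries a gap (\code{-}) or an ambiguity
#' (\code{N}) are dropped (pairwise deletion). With P the transition and Q
#' the transversion proportion over the remaining \code{n_eff} sites,
#' \deqn{d = -\frac{1}{2}\ln\left((1-2P-Q)\sqrt{1-2Q}\right).}
#' When the log argument is non-positive the distance is undefined
#' (\code{NA}); undefined distances are treated as larger than any
#' clustering threshold downstream.
#'
#' @param a,b equal-length character vectors (or single strings) over
#'   \code{A,C,G,T,N,-}
#' @return list with elements \code{d}, \code{P}, \code{Q}, \code{n_eff}
#' @export
k2p_distance <- function(a, b) {
  if (length(a) == 1L && nchar(a) > 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L && nchar(b) > 1L) b <- strsplit(b, "")[[1]]
  a <- toupper(a); b <- toupper(b)
  if (length(a) != length(b)) stop("sequences differ in length")
  ca <- .base_code[a]; cb <- .base_code[b]
  keep <- !is.na(ca) & !is.na(cb)
  n_eff <- sum(keep)
  if (n_eff == 0L) stop("undefined distance: no comparable sites")
  ca <- ca[keep]; cb <- cb[keep]
  diff <- ca != cb
  ts <- diff & (abs(ca - cb) == 2L)   # A<->G (1,3) and C<->T (2,4)
  P <- sum(ts) / n_eff
  Q <- (sum(diff) - sum(ts)) / n_eff
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- if (w1 <= 0 || w2 <= 0) NA_real_ else -0.5 * log(w1 * sqrt(w2))
  list(d = d, P = P, Q = Q, n_eff = n_eff)
}

#' Pairwise K2P distance matrix for an aligned set
#'
#' Computes, for every pair of sequences under pairwise deletion, the K2P
#' distance \code{d}, the transition proportion \code{P}, the transversion
#' proportion \code{Q}, the number of effective (ungapped, unambiguous)
#' sites \code{n_eff}, and the raw mismatch count \code{n_diff} (used by
#' the strict-identity transfer tally). Implemented with indicator-matrix
#' cross-products so the cost is one pass of dense linear algebra.
#'
#' @param aln an \code{\link{aligned_set}} or a character matrix
#' @return object of class \code{k2p_dist}: list of \code{ids} and the
#'   matrices \code{d, P, Q, n_eff, n_diff}. Undefined distances are
#'   \code{NA} in \code{d}.
#' @export
k2p_matrix <- function(aln) {
  mat <- if (inherits(aln, "aligned_set")) aln$mat else aln
  ids <- rownames(mat)
  n <- nrow(mat)
  m <- encode_aln(mat)
  ind <- lapply(1:4, function(k) (m == k) * 1)
  valid <- (m != 0L) * 1
  n_eff <- tcrossprod(valid)
  same <- Reduce(`+`, lapply(ind, tcrossprod))
  ts <- tcrossprod(ind[[1]], ind[[3]]) + tcrossprod(ind[[3]], ind[[1]]) +
    tcrossprod(ind[[2]], ind[[4]]) + tcrossprod(ind[[4]], ind[[2]])
  n_diff <- n_eff - same
  if (n > 1L) {
    off <- n_eff[upper.tri(n_eff)]
    if (any(off == 0)) {
      w <- which(n_eff == 0 & upper.tri(n_eff), arr.ind = TRUE)[1L, ]
      stop(sprintf("undefined distance: no comparable sites between '%s' and '%s'",
                   ids[w[1L]], ids[w[2L]]))
    }
  }
  P <- ts / n_eff
  Q <- (n_diff - ts) / n_eff
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- matrix(NA_real_, n, n)
  ok <- w1 > 0 & w2 > 0
  d[ok] <- -0.5 * log(w1[ok] * sqrt(w2[ok]))
  diag(d) <- 0
  dimnames(d) <- dimnames(P) <- dimnames(Q) <- dimnames(n_eff) <-
    dimnames(n_diff) <- list(ids, ids)
  structure(list(ids = ids, d = d, P = P, Q = Q, n_eff = n_eff,
                 n_diff = n_diff),
            class = "k2p_dist")
}

#' Uncorrected distance matrix used by the p-identity clustering mode
#' @param dm a \code{k2p_dist}
#' @return matrix of p-distances (1 - identity)
#' @export
p_distance <- function(dm) {
  stopifnot(inherits(dm, "k2p_dist"))
  dm$n_diff / dm$n_eff
}
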