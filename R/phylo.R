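# Bootstrap neighbor-joining trees and phage/symbiont congruence.

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper around \code{ape::nj} with deterministic handling of
#' negative branch lengths: a negative edge is clamped to zero and its
#' magnitude transferred to its sibling edge, preserving path lengths
#' through the parent node as closely as possible.
#'
#' @param d symmetric numeric distance matrix (>= 3 taxa, no undefined
#'   entries) or a \code{\link{k2p_matrix}} result
#' @return an \code{ape::phylo} tree
#' @export
nj_tree <- function(d) {
  if (inherits(d, "k2p_dist")) d <- d$d
  stopifnot(is.matrix(d))
  if (nrow(d) < 3L) stop("neighbor-joining needs at least 3 taxa")
  if (any(is.na(d))) {
    w <- which(is.na(d), arr.ind = TRUE)[1L, ]
    stop(sprintf("undefined distance between '%s' and '%s'",
                 rownames(d)[w[1L]], colnames(d)[w[2L]]))
  }
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sibs <- setdiff(which(tr$edge[, 1L] == parent), e)
    amt <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs)) {
      tr$edge.length[sibs[1L]] <- max(0, tr$edge.length[sibs[1L]] + amt)
    }
  }
  tr
}

#' Bootstrap NJ tree with branch supports
#'
#' Builds the NJ tree on the K2P distances of the full alignment, then
#' resamples alignment columns \code{cfg$bootstrap_reps} times (seeded),
#' rebuilds the NJ tree per replicate and scores each internal
#' bipartition by the percentage of replicates containing it. Supports
#' are stored in \code{$node.label} (percent, rounded to one decimal).
#'
#' @param aln an \code{\link{aligned_set}} (e.g. of type representatives
#'   or MLST concatenates) or a character matrix
#' @param cfg a \code{\link{run_config}}
#' @return an \code{ape::phylo} with node labels carrying supports
#' @export
bootstrap_support <- function(aln, cfg = run_config()) {
  mat <- if (inherits(aln, "aligned_set")) aln$mat else aln
  tr <- nj_tree(k2p_matrix(mat))
  B <- cfg$bootstrap_reps
  L <- ncol(mat)
  boots <- with_seed(derive_seed(cfg$rng_seed, "bootstrap"), {
    lapply(seq_len(B), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      dm <- k2p_matrix(mat[, cols, drop = FALSE])
      dd <- dm$d
      dd[is.na(dd)] <- max(dd, na.rm = TRUE) + 1
      nj_tree(dd)
    })
  })
  counts <- ape::prop.clades(tr, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tr$node.label <- round(100 * counts / B, 1)
  tr
}

# bipartitions (as canonical strings over tip labels) of the internal
# edges of an unrooted tree
.bipartitions <- function(tr) {
  tips <- sort(tr$tip.label)
  parts <- ape::prop.part(tr)
  labs <- attr(parts, "labels")
  out <- character(0)
  for (p in parts) {
    side <- sort(labs[p])
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    other <- setdiff(tips, side)
    key <- if (paste(side, collapse = ",") < paste(other, collapse = ",")) {
      paste(paste(side, collapse = ","), paste(other, collapse = ","), sep = "|")
    } else {
      paste(paste(other, collapse = ","), paste(side, collapse = ","), sep = "|")
    }
    out <- c(out, key)
  }
  unique(out)
}

#' Normalised Robinson-Foulds distance
#'
#' Symmetric-difference distance between the non-trivial bipartition sets
#' of two unrooted trees on the same label set, normalised by the total
#' number of bipartitions in both trees (0 = identical splits, 1 =
#' no shared split). Multifurcating trees are handled by bipartition
#' semantics.
#'
#' @param t1,t2 \code{ape::phylo} trees with identical tip label sets
#' @export
nrf_distance <- function(t1, t2) {
  stopifnot(setequal(t1$tip.label, t2$tip.label))
  b1 <- .bipartitions(t1)
  b2 <- .bipartitions(t2)
  denom <- length(b1) + length(b2)
  if (denom == 0L) return(0)
  length(setdiff(b1, b2)) / denom + length(setdiff(b2, b1)) / denom
}

#' Phage/symbiont congruence report
#'
#' Collapses the phage-type tree to strain labels (keeping the
#' first-encountered tip per strain), computes the normalised
#' Robinson-Foulds distance to the symbiont tree, and lists the
#' tanglegram crossing candidates: phage types that sit strictly closer
#' (cophenetic distance) to a type carried by a foreign strain than to
#' any type of their own strain. Types whose strain carries no other
#' type offer no within-strain yardstick and are never flagged.
#'
#' @param phage_tree \code{ape::phylo} with phage type names as tips
#' @param symbiont_tree \code{ape::phylo} with strain keys as tips
#' @param link named character vector mapping phage type -> strain key
#' @return list with \code{nrf}, \code{crossings} (character vector of
#'   phage types) and \code{collapsed_tree}
#' @export
congruence <- function(phage_tree, symbiont_tree, link) {
  unmapped <- setdiff(phage_tree$tip.label, names(link))
  if (length(unmapped)) {
    stop("phage tips without a strain mapping: ",
         paste(unmapped, collapse = ", "))
  }
  strains <- link[phage_tree$tip.label]
  missing <- setdiff(unique(strains), symbiont_tree$tip.label)
  if (length(missing)) {
    stop("strains absent from symbiont tree: ",
         paste(missing, collapse = ", "))
  }
  keep <- phage_tree$tip.label[!duplicated(strains)]
  collapsed <- ape::keep.tip(phage_tree, keep)
  collapsed$tip.label <- unname(link[collapsed$tip.label])
  sym <- ape::keep.tip(symbiont_tree,
                       intersect(symbiont_tree$tip.label,
                                 collapsed$tip.label))
  nrf <- if (length(collapsed$tip.label) >= 4L &&
             setequal(collapsed$tip.label, sym$tip.label)) {
    nrf_distance(collapsed, sym)
  } else 0
  crossings <- character(0)
  if (length(phage_tree$tip.label) >= 3L) {
    coph <- stats::cophenetic(phage_tree)
    for (tip in phage_tree$tip.label) {
      others <- setdiff(colnames(coph), tip)
      same <- others[link[others] == link[[tip]]]
      foreign <- others[link[others] != link[[tip]]]
      if (!length(same) || !length(foreign)) next
      if (min(coph[tip, foreign]) < min(coph[tip, same])) {
        crossings <- c(crossings, tip)
      }
    }
  }
  list(nrf = nrf, crossings = crossings, collapsed_tree = collapsed)
}
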