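# Pseudogene flagging by internal stop codons.

# codons of one ungapped sequence read in `frame` (1..3); incomplete
# trailing codon discarded
.codons <- function(chars, frame) {
  s <- chars[chars != "-"]
  if (length(s) < frame + 2L) return(character(0))
  s <- s[frame:length(s)]
  k <- length(s) %/% 3L
  if (k == 0L) return(character(0))
  s <- s[seq_len(3L * k)]
  apply(matrix(s, nrow = 3L), 2L, paste, collapse = "")
}

.has_internal_stop <- function(chars, frame) {
  cod <- .codons(chars, frame)
  k <- length(cod)
  if (k <= 1L) return(FALSE)
  any(cod[seq_len(k - 1L)] %in% stop_codons)
}

#' Flag orf7-like pseudogenes by internal stop codons
#'
#' A record is a pseudogene when, read in the chosen frame on alignment
#' columns with its own gaps removed, it contains a stop codon (TAA, TAG,
#' TGA) strictly before its final complete codon. The amplicon is an
#' internal gene fragment, so a stop in the final codon does not
#' disqualify a sequence. When \code{frame} is \code{NULL} the frame is
#' auto-detected as the lowest frame in which the majority-consensus
#' sequence is free of internal stops.
#'
#' Pseudogenes are excluded from typing and all downstream stages but
#' retained in reports.
#'
#' @param aln an annotated \code{\link{aligned_set}}
#' @param frame reading frame 1, 2 or 3, or \code{NULL} to auto-detect
#' @return the \code{aligned_set} with \code{meta$is_pseudogene} set; the
#'   chosen frame is attached as attribute \code{frame}
#' @export
flag_pseudogenes <- function(aln, frame = NULL) {
  stopifnot(inherits(aln, "aligned_set"))
  if (is.null(aln$meta)) stop("metadata must be joined before pseudogene flagging")
  cons <- apply(aln$mat, 2L, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (!length(col)) return("N")
    names(sort(table(col), decreasing = TRUE))[1L]
  })
  if (is.null(frame)) {
    ok <- !vapply(1:3, function(f) .has_internal_stop(cons, f), logical(1))
    if (!any(ok)) {
      stop("no reading frame yields a stop-free consensus; supply `frame`")
    }
    frame <- which(ok)[1L]
  } else {
    stopifnot(frame %in% 1:3)
  }
  flags <- vapply(seq_along(aln$ids),
                  function(i) .has_internal_stop(aln$mat[i, ], frame),
                  logical(1))
  aln$meta$is_pseudogene <- flags
  attr(aln, "frame") <- as.integer(frame)
  aln
}

#' Drop flagged pseudogenes from an aligned set
#' @param aln an \code{aligned_set} after \code{\link{flag_pseudogenes}}
#' @export
functional_only <- function(aln) {
  stopifnot(!is.null(aln$meta))
  subset_aln(aln, aln$ids[!aln$meta$is_pseudogene])
}
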