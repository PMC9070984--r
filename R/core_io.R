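#' Aligned sequence set
#'
#' Container for an alignment of orf7 (or MLST) sequences together with
#' per-sequence host annotations. Sequences are stored as an n x L character
#' matrix over the alphabet \code{A,C,G,T,N,-}; positions are 1-based,
#' inclusive alignment columns throughout the package.
#'
#' @param mat character matrix (one row per sequence, one column per
#'   alignment position), rownames are sequence ids.
#' @param meta data.frame of per-sequence annotations (see
#'   \code{\link{read_metadata}}); may be \code{NULL} until joined.
#' @return An object of class \code{aligned_set} with elements \code{ids},
#'   \code{mat}, \code{length} and \code{meta}.
#' @export
aligned_set <- function(mat, meta = NULL) {
  stopifnot(is.matrix(mat), is.character(mat))
  ids <- rownames(mat)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("sequence ids must be present and unique")
  }
  if (ncol(mat) == 0L) stop("sequences must be non-empty")
  bad <- !(mat %in% c("A", "C", "G", "T", "N", "-"))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("illegal character '%s' in sequence '%s' at position %d",
                 mat[w[1L], w[2L]], ids[w[1L]], w[2L]))
  }
  structure(list(ids = ids, mat = mat, length = ncol(mat), meta = meta),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("aligned_set: %d sequences x %d columns\n",
              length(x$ids), x$length))
  if (!is.null(x$meta)) {
    cat(sprintf("  annotated species: %d; pseudogenes flagged: %s\n",
                length(unique(x$meta$species)),
                if (any(x$meta$is_pseudogene)) sum(x$meta$is_pseudogene)
                else "none"))
  }
  invisible(x)
}

#' Number of sequences in an aligned set
#' @param x an \code{aligned_set}
#' @export
n_seqs <- function(x) length(x$ids)

#' Subset an aligned set by sequence id
#' @param x an \code{aligned_set}
#' @param ids character vector of ids to keep (order preserved)
#' @export
subset_aln <- function(x, ids) {
  stopifnot(all(ids %in% x$ids))
  mat <- x$mat[ids, , drop = FALSE]
  meta <- if (!is.null(x$meta)) x$meta[match(ids, x$meta$id), , drop = FALSE]
  aligned_set(mat, meta)
}

#' Read an aligned multi-FASTA
#'
#' Headers are truncated at the first whitespace to form sequence ids.
#' Nucleotides are case-insensitive; \code{U} is rejected. All records must
#' have identical length (the pipeline consumes alignments, it does not
#' align).
#'
#' @param path path to a FASTA file
#' @return an \code{\link{aligned_set}} (metadata unset)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  if (!any(startsWith(txt, ">"))) stop("no records in FASTA file: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE,
                             set.attributes = FALSE)
  if (length(recs) == 0L) stop("no records in FASTA file: ", path)
  seqs <- lapply(recs, function(s) toupper(as.character(s)))
  lens <- lengths(seqs)
  if (any(lens == 0L)) {
    stop("empty sequence for id(s): ",
         paste(names(recs)[lens == 0L], collapse = ", "))
  }
  if (length(unique(lens)) != 1L) {
    ref <- lens[[1L]]
    off <- names(recs)[lens != ref]
    stop("alignment error: sequences of unequal length (expected ", ref,
         "): ", paste(off, collapse = ", "))
  }
  for (i in seq_along(seqs)) {
    bad <- which(!(seqs[[i]] %in% c("A", "C", "G", "T", "N", "-")))
    if (length(bad)) {
      stop(sprintf("parse error: illegal character '%s' in '%s' at position %d",
                   seqs[[i]][bad[1L]], names(recs)[i], bad[1L]))
    }
  }
  mat <- do.call(rbind, seqs)
  rownames(mat) <- names(recs)
  aligned_set(mat)
}

#' Write an aligned set as FASTA
#'
#' One line per sequence (no wrapping), so that read/write round-trips are
#' exact.
#'
#' @param x an \code{aligned_set}
#' @param path output path
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "aligned_set"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(x$ids)) {
    writeLines(c(paste0(">", x$ids[i]),
                 paste(x$mat[i, ], collapse = "")), con)
  }
  invisible(path)
}

.meta_cols <- c("id", "species", "family", "strain_st", "wsp_allele",
                "supergroup")

#' Join host metadata onto an alignment
#'
#' Reads a tab-delimited table with header columns \code{id, species,
#' family, strain_st, wsp_allele, supergroup} (\code{#} comment lines
#' ignored) and joins it onto the alignment by sequence id. A missing
#' strain (empty, \code{-} or an en-dash, as used for "no data obtained")
#' is recorded as \code{UNKNOWN}. Metadata ids absent from the alignment
#' raise a warning; alignment ids absent from the metadata are an error,
#' because every typed sequence needs a host.
#'
#' @param path path to the TSV metadata file
#' @param aln an \code{\link{aligned_set}}
#' @return the \code{aligned_set} with its \code{meta} slot populated
#' @export
read_metadata <- function(path, aln) {
  stopifnot(inherits(aln, "aligned_set"))
  tab <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  missing_cols <- setdiff(.meta_cols, names(tab))
  if (length(missing_cols)) {
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  join_metadata(tab, aln)
}

#' Join an in-memory metadata table onto an alignment
#' @param tab data.frame with the columns of \code{\link{read_metadata}}
#' @param aln an \code{\link{aligned_set}}
#' @export
join_metadata <- function(tab, aln) {
  tab <- tab[, .meta_cols, drop = FALSE]
  tab$id <- as.character(tab$id)
  if (anyDuplicated(tab$id)) stop("duplicated ids in metadata")
  extra <- setdiff(tab$id, aln$ids)
  if (length(extra)) {
    warning("metadata ids absent from alignment: ",
            paste(extra, collapse = ", "))
  }
  absent <- setdiff(aln$ids, tab$id)
  if (length(absent)) {
    stop("alignment ids absent from metadata: ",
         paste(absent, collapse = ", "))
  }
  meta <- tab[match(aln$ids, tab$id), , drop = FALSE]
  rownames(meta) <- NULL
  st <- as.character(meta$strain_st)
  st[is.na(st) | st %in% c("", "-", "–", "NA")] <- "UNKNOWN"
  meta$strain_st <- st
  sg <- toupper(as.character(meta$supergroup))
  sg[is.na(sg) | !(sg %in% c("A", "B"))] <- "UNKNOWN"
  meta$supergroup <- sg
  meta$is_pseudogene <- FALSE
  aln$meta <- meta
  aln
}

#' Strain key for transfer analysis
#'
#' Resolved strains are keyed by their MLST sequence type (ST). Species
#' whose ST could not be determined are treated as their own pseudo-strain
#' keyed by (species, wsp allele), so that they can still participate in
#' transfer enumeration.
#'
#' @param meta a metadata data.frame (rows of \code{aligned_set$meta})
#' @return character vector of strain keys, one per row
#' @export
strain_key <- function(meta) {
  ifelse(meta$strain_st == "UNKNOWN",
         paste0("pseudo:", meta$species, "|", meta$wsp_allele),
         meta$strain_st)
}

#' Run configuration
#'
#' Central knobs of the pipeline. The type threshold of 0.015 (1.5\%
#' divergence, equivalently 98.5\% identity), the 0.05 significance cutoff
#' and the 1,000 bootstrap replicates are the field-standard settings for
#' orf7 typing; window/step control the BootScan scan grid.
#'
#' @param type_threshold K2P distance defining phage-type membership
#' @param identity_mode \code{"k2p_distance"} (default) or
#'   \code{"p_identity"} (cluster on uncorrected identity >= 1 - threshold)
#' @param linkage \code{"single"} (default) or \code{"complete"}
#' @param consensus_min_methods minimum number of significant methods for a
#'   recombination consensus call (1..5)
#' @param alpha significance level for recombination methods
#' @param bootstrap_reps bootstrap replicates (tree support and BootScan)
#' @param window,step BootScan sliding-window width and stride (columns)
#' @param n_perm permutation replicates for recombination p-values
#' @param rng_seed integer seed driving all stochastic steps
#' @return a list of class \code{run_config}
#' @export
run_config <- function(type_threshold = 0.015,
                       identity_mode = c("k2p_distance", "p_identity"),
                       linkage = c("single", "complete"),
                       consensus_min_methods = 3L,
                       alpha = 0.05,
                       bootstrap_reps = 1000L,
                       window = 200L,
                       step = 20L,
                       n_perm = 1000L,
                       rng_seed = 1L) {
  identity_mode <- match.arg(identity_mode)
  linkage <- match.arg(linkage)
  stopifnot(type_threshold > 0, type_threshold < 1,
            consensus_min_methods >= 1L, consensus_min_methods <= 5L,
            alpha > 0, alpha < 1,
            bootstrap_reps >= 1L, window >= 4L, step >= 1L, n_perm >= 1L)
  structure(list(type_threshold = type_threshold,
                 identity_mode = identity_mode,
                 linkage = linkage,
                 consensus_min_methods = as.integer(consensus_min_methods),
                 alpha = alpha,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 window = as.integer(window),
                 step = as.integer(step),
                 n_perm = as.integer(n_perm),
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}
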