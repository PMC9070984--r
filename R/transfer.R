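# Horizontal-transfer enumeration: global phage types spanning distinct
# Wolbachia strains.

#' Enumerate horizontal-transfer events
#'
#' A transfer event is one global phage type whose host species carry at
#' least two distinct Wolbachia strain keys (resolved STs, or
#' species-level pseudo-strains where the ST is unknown). Events are
#' sorted by the number of strains involved (descending) then by type id.
#' \code{mode = "strict_identity"} re-groups sequences by the stricter
#' field rule "identical or at most one base substitution"
#' (\code{max_diff} mismatches) instead of the clustering threshold, and
#' tallies events under that grouping.
#'
#' @param global_types global-scope result of \code{\link{cluster_types}}
#'   (ignored when \code{mode = "strict_identity"})
#' @param aln the annotated \code{\link{aligned_set}} (pseudogenes flagged)
#' @param cfg a \code{\link{run_config}}
#' @param dm optional precomputed \code{\link{k2p_matrix}} over functional
#'   sequences
#' @param mode \code{"cluster"} (default) or \code{"strict_identity"}
#' @param max_diff mismatch cap for strict-identity grouping
#' @return list of \code{transfer_event} objects with fields
#'   \code{global_type_id}, \code{member_type_names}, \code{strains},
#'   \code{species}, \code{supergroups} (counts per supergroup),
#'   \code{cross_supergroup}, \code{st_unresolved},
#'   \code{min_interhost_distance}
#' @export
enumerate_transfers <- function(global_types, aln, cfg = run_config(),
                                dm = NULL, mode = c("cluster", "strict_identity"),
                                max_diff = 1L) {
  mode <- match.arg(mode)
  stopifnot(!is.null(aln$meta))
  fun <- if (any(aln$meta$is_pseudogene)) functional_only(aln) else aln
  if (is.null(dm)) dm <- k2p_matrix(fun)
  if (mode == "strict_identity") {
    memb <- .cut_membership(dm$n_diff[fun$ids, fun$ids, drop = FALSE],
                            max_diff, "single")
    groups <- split(fun$ids, memb)
    first_id <- vapply(groups, function(g) sort(g)[1L], character(1))
    ord <- order(-lengths(groups), first_id)
    groups <- groups[ord]
    global_types <- lapply(seq_along(groups), function(k) {
      members <- groups[[k]]
      rows <- fun$meta[match(members, fun$meta$id), , drop = FALSE]
      structure(list(name = sprintf("I-%d", k), member_ids = members,
                     representative_id = members[1L],
                     species = unique(rows$species),
                     hosts = unique(paste(rows$species, rows$strain_st,
                                          sep = "|"))),
                class = "phage_type")
    })
  }
  events <- list()
  for (t in global_types) {
    rows <- fun$meta[match(t$member_ids, fun$meta$id), , drop = FALSE]
    keys <- unique(strain_key(rows))
    if (length(keys) < 2L) next
    resolved <- unique(rows$strain_st[rows$strain_st != "UNKNOWN"])
    sg <- table(factor(unique(rows[, c("species", "supergroup")])$supergroup,
                       levels = c("A", "B", "UNKNOWN")))
    cross <- sg[["A"]] > 0L && sg[["B"]] > 0L
    min_d <- NA_real_
    sp <- rows$species
    if (length(unique(sp)) > 1L) {
      dsub <- dm$d[t$member_ids, t$member_ids, drop = FALSE]
      other <- outer(sp, sp, `!=`)
      vals <- dsub[other]
      min_d <- if (all(is.na(vals))) NA_real_ else min(vals, na.rm = TRUE)
    }
    events[[length(events) + 1L]] <- structure(list(
      global_type_id = t$name,
      member_type_names = t$member_type_names %||% character(0),
      strains = sort(keys),
      species = sort(unique(sp)),
      supergroups = sg,
      cross_supergroup = cross,
      st_unresolved = length(resolved) < 2L,
      min_interhost_distance = min_d
    ), class = "transfer_event")
  }
  if (!length(events)) return(events)
  ns <- vapply(events, function(e) length(e$strains), integer(1))
  ids <- vapply(events, `[[`, character(1), "global_type_id")
  events[order(-ns, ids)]
}

#' Transfer events as a data.frame
#' @param events list of \code{transfer_event}
#' @export
transfers_table <- function(events) {
  if (!length(events)) {
    return(data.frame(global_type_id = character(0), n_strains = integer(0),
                      strains = character(0), species = character(0),
                      member_type_names = character(0),
                      cross_supergroup = logical(0),
                      st_unresolved = logical(0),
                      min_interhost_distance = numeric(0)))
  }
  data.frame(
    global_type_id = vapply(events, `[[`, character(1), "global_type_id"),
    n_strains = vapply(events, function(e) length(e$strains), integer(1)),
    strains = vapply(events, function(e) paste(e$strains, collapse = ","),
                     character(1)),
    species = vapply(events, function(e) paste(e$species, collapse = ","),
                     character(1)),
    member_type_names = vapply(events, function(e)
      paste(e$member_type_names, collapse = ","), character(1)),
    cross_supergroup = vapply(events, `[[`, logical(1), "cross_supergroup"),
    st_unresolved = vapply(events, `[[`, logical(1), "st_unresolved"),
    min_interhost_distance = vapply(events, `[[`, numeric(1),
                                    "min_interhost_distance"),
    stringsAsFactors = FALSE)
}

#' Type x strain incidence matrix
#' @param global_types global typing result
#' @param aln annotated aligned set
#' @return 0/1 integer matrix, rows = global type ids, cols = strain keys
#' @export
type_strain_incidence <- function(global_types, aln) {
  fun <- if (any(aln$meta$is_pseudogene)) functional_only(aln) else aln
  keys <- sort(unique(strain_key(fun$meta)))
  m <- matrix(0L, length(global_types), length(keys),
              dimnames = list(vapply(global_types, `[[`, character(1), "name"),
                              keys))
  for (t in global_types) {
    rows <- fun$meta[match(t$member_ids, fun$meta$id), , drop = FALSE]
    m[t$name, unique(strain_key(rows))] <- 1L
  }
  m
}

#' Shared and private phage types within one Wolbachia strain
#'
#' For the host species carrying a given strain, lists each global type
#' present in any of them and whether it is shared by two or more of those
#' species or private to one.
#'
#' @param global_types global typing result
#' @param aln annotated aligned set
#' @param strain a strain key (ST)
#' @return data.frame with columns type, n_species, species, shared
#' @export
shared_types_within_strain <- function(global_types, aln, strain) {
  fun <- if (any(aln$meta$is_pseudogene)) functional_only(aln) else aln
  keys <- strain_key(fun$meta)
  if (!strain %in% keys) stop("strain not present in metadata: ", strain)
  sp_of_strain <- unique(fun$meta$species[keys == strain])
  out <- list()
  for (t in global_types) {
    rows <- fun$meta[match(t$member_ids, fun$meta$id), , drop = FALSE]
    sp <- unique(rows$species[strain_key(rows) == strain])
    if (!length(sp)) next
    out[[length(out) + 1L]] <- data.frame(
      type = t$name, n_species = length(sp),
      species = paste(sort(sp), collapse = ","),
      shared = length(sp) >= 2L, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(type = character(0), n_species = integer(0),
               species = character(0), shared = logical(0))
  attr(res, "strain_species") <- sort(sp_of_strain)
  res
}
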