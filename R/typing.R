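# Clustering functional orf7 sequences into phage WO types.

#' Host abbreviation used in phage type names
#'
#' First letter of the genus plus the first two letters of the species
#' epithet ("Pseudozizeeria maha" -> "Pma", "Isoteinon sp." -> "Isp").
#' Entries of \code{override} (named by full species name) take precedence.
#'
#' @param species character vector of binomial names
#' @param override optional named character vector of abbreviations
#' @export
species_abbrev <- function(species, override = NULL) {
  out <- vapply(species, function(s) {
    if (!is.null(override) && s %in% names(override)) {
      return(unname(override[[s]]))
    }
    parts <- strsplit(trimws(s), "\\s+")[[1]]
    genus <- substr(parts[1], 1, 1)
    epithet <- if (length(parts) > 1) gsub("[^A-Za-z]", "", parts[2]) else ""
    paste0(toupper(genus), substr(epithet, 1, 2))
  }, character(1))
  unname(out)
}

# threshold-graph / agglomerative membership for one id set.
# d: distance matrix (NA = undefined, never merged). Returns integer
# membership vector in input order.
.cut_membership <- function(d, threshold, linkage) {
  n <- nrow(d)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  dfix <- d
  dfix[is.na(dfix)] <- threshold * 2 + 10   # undefined: beyond any merge
  h <- stats::hclust(stats::as.dist(dfix), method = linkage)
  stats::cutree(h, h = threshold)
}

#' Cluster functional sequences into phage WO types
#'
#' Sequences closer than the type threshold (1.5\% K2P divergence by
#' default, equivalently >= 98.5\% identity) belong to the same type.
#' Under \code{linkage = "single"} (default) types are the connected
#' components of the graph with edges \code{d <= type_threshold}; under
#' \code{"complete"} they are complete-linkage clusters cut at the
#' threshold. Undefined distances never merge. Output is deterministic:
#' types ordered by (member count descending, lexicographically smallest
#' first-seen id), and named per species as \code{WO<abbrev>-<index>} in
#' that order. With \code{scope = "global"} all species are clustered
#' jointly (the grouping used for transfer detection) and types carry ids
#' \code{G-<index>} plus cross-references to per-species names when
#' supplied.
#'
#' @param aln an annotated \code{\link{aligned_set}}; pseudogenes (if
#'   flagged) are excluded
#' @param cfg a \code{\link{run_config}}
#' @param scope \code{"per_species"} or \code{"global"}
#' @param dm optional precomputed \code{\link{k2p_matrix}} over the
#'   functional sequences
#' @param per_species_types for \code{scope = "global"}, the per-species
#'   typing result used to cross-reference member type names
#' @return list of \code{phage_type} objects; each has \code{name},
#'   \code{member_ids}, \code{representative_id}, \code{species},
#'   \code{hosts} (unique species/strain pairs) and, for global types,
#'   \code{member_type_names}
#' @export
cluster_types <- function(aln, cfg = run_config(),
                          scope = c("per_species", "global"),
                          dm = NULL, per_species_types = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(aln, "aligned_set"), !is.null(aln$meta))
  fun <- if (any(aln$meta$is_pseudogene)) functional_only(aln) else aln
  if (n_seqs(fun) == 0L) return(list())
  if (is.null(dm)) dm <- k2p_matrix(fun)
  dmat <- if (cfg$identity_mode == "p_identity") p_distance(dm) else dm$d
  thr <- cfg$type_threshold

  make_types <- function(ids, membership, namer) {
    groups <- split(ids, membership)
    first_idx <- vapply(groups, function(g) min(match(g, ids)), numeric(1))
    sizes <- lengths(groups)
    first_id <- vapply(groups, function(g) sort(g)[1L], character(1))
    ord <- order(-sizes, first_id)
    groups <- groups[ord]
    first_idx <- first_idx[ord]
    lapply(seq_along(groups), function(k) {
      members <- groups[[k]]
      rep_id <- ids[min(match(members, ids))]
      rows <- fun$meta[match(members, fun$meta$id), , drop = FALSE]
      structure(list(
        name = namer(k, rows),
        member_ids = members,
        representative_id = rep_id,
        species = unique(rows$species),
        hosts = unique(paste(rows$species, rows$strain_st, sep = "|"))
      ), class = "phage_type")
    })
  }

  if (scope == "per_species") {
    out <- list()
    for (sp in unique(fun$meta$species)) {
      ids <- fun$meta$id[fun$meta$species == sp]
      memb <- .cut_membership(dmat[ids, ids, drop = FALSE], thr, cfg$linkage)
      ab <- species_abbrev(sp)
      out <- c(out, make_types(ids, memb,
                               function(k, rows) sprintf("WO%s-%d", ab, k)))
    }
    out
  } else {
    ids <- fun$meta$id
    memb <- .cut_membership(dmat[ids, ids, drop = FALSE], thr, cfg$linkage)
    types <- make_types(ids, memb, function(k, rows) sprintf("G-%d", k))
    if (!is.null(per_species_types)) {
      id2name <- type_of_ids(per_species_types)
      for (k in seq_along(types)) {
        types[[k]]$member_type_names <-
          sort(unique(stats::na.omit(id2name[types[[k]]$member_ids])))
      }
    }
    types
  }
}

#' Map sequence id -> type name for a list of phage types
#' @param types list of \code{phage_type}
#' @return named character vector
#' @export
type_of_ids <- function(types) {
  if (!length(types)) return(character(0))
  ids <- unlist(lapply(types, `[[`, "member_ids"), use.names = FALSE)
  nm <- rep(vapply(types, `[[`, character(1), "name"),
            vapply(types, function(t) length(t$member_ids), integer(1)))
  stats::setNames(nm, ids)
}

#' Per-host phage type summary
#'
#' One row per host species with its strain annotations, the number of
#' phage WO types it carries and the multiple-infection flag (strictly
#' more than two types).
#'
#' @param types per-species typing result from \code{\link{cluster_types}}
#' @param meta the alignment metadata (\code{aligned_set$meta})
#' @return data.frame with columns species, family, strain_st, wsp_allele,
#'   supergroup, n_types, multi_infection
#' @export
summarize_types <- function(types, meta) {
  species <- unique(meta$species)
  type_sp <- vapply(types, function(t) t$species[1L], character(1))
  n_types <- vapply(species, function(sp) sum(type_sp == sp), integer(1))
  rows <- meta[match(species, meta$species), , drop = FALSE]
  data.frame(species = species,
             family = rows$family,
             strain_st = rows$strain_st,
             wsp_allele = rows$wsp_allele,
             supergroup = rows$supergroup,
             n_types = unname(n_types),
             multi_infection = unname(n_types) > 2L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Intra-type distance audit
#'
#' Under single linkage a type may legitimately contain pairs beyond the
#' threshold (chaining); this reports any such pair for inspection.
#'
#' @param types result of \code{\link{cluster_types}}
#' @param dm a \code{\link{k2p_matrix}} over the clustered sequences
#' @param cfg a \code{\link{run_config}}
#' @return data.frame (possibly empty) of type, id1, id2, d
#' @export
overlimit_pairs <- function(types, dm, cfg = run_config()) {
  out <- list()
  for (t in types) {
    ids <- t$member_ids
    if (length(ids) < 2L) next
    d <- dm$d[ids, ids, drop = FALSE]
    w <- which((is.na(d) | d > cfg$type_threshold) & upper.tri(d),
               arr.ind = TRUE)
    if (nrow(w)) {
      out[[length(out) + 1L]] <- data.frame(
        type = t$name, id1 = ids[w[, 1L]], id2 = ids[w[, 2L]],
        d = d[w], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(type = character(0), id1 = character(0),
                      id2 = character(0), d = numeric(0)))
  }
  do.call(rbind, out)
}
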