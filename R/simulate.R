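# Synthetic orf7-like data with planted types, transfers, recombinants
# and pseudogenes, plus a machine-readable truth record.

.nonstop_codons <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

# K80 per-site change probabilities at distance d: (same, transition,
# transversion1, transversion2)
.k80_probs <- function(d, kappa) {
  b <- d / (kappa + 2)
  a <- kappa * b
  e1 <- exp(-4 * b)
  e2 <- exp(-2 * (a + b))
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1
  c(1 - p_ts - 2 * p_tv, p_ts, p_tv, p_tv)
}

.ts_partner <- c(3L, 4L, 1L, 2L)        # A<->G, C<->T
.tv_partner1 <- c(2L, 1L, 2L, 1L)
.tv_partner2 <- c(4L, 3L, 4L, 3L)

# evolve an integer-coded sequence by expected K2P distance d under
# K80(kappa); env$ts / env$tv accumulate realised substitution draws
.evolve_k80 <- function(seq, d, kappa, counter = NULL) {
  p <- .k80_probs(d, kappa)
  idx <- sample.int(4L, length(seq), replace = TRUE, prob = p)
  out <- seq
  out[idx == 2L] <- .ts_partner[seq[idx == 2L]]
  out[idx == 3L] <- .tv_partner1[seq[idx == 3L]]
  out[idx == 4L] <- .tv_partner2[seq[idx == 4L]]
  if (!is.null(counter)) {
    counter$ts <- counter$ts + sum(idx == 2L)
    counter$tv <- counter$tv + sum(idx == 3L | idx == 4L)
  }
  out
}

.int2char <- function(seq) c("A", "C", "G", "T")[seq]
.char2int <- function(chars) unname(.base_code[chars])

# revert any internal stop codon to the fallback sequence's codon
# (purifying selection against nonsense changes in functional sequences)
.fix_stops <- function(seq, fallback) {
  k <- length(seq) %/% 3L
  if (k <= 1L) return(seq)
  for (j in seq_len(k - 1L)) {
    cols <- (3L * (j - 1L) + 1L):(3L * j)
    cod <- paste(.int2char(seq[cols]), collapse = "")
    if (cod %in% stop_codons) seq[cols] <- fallback[cols]
  }
  seq
}

# introduce one internal stop codon by a single substitution
.plant_stop <- function(seq) {
  k <- length(seq) %/% 3L
  for (j in seq_len(k - 1L)) {
    cols <- (3L * (j - 1L) + 1L):(3L * j)
    cod <- .int2char(seq[cols])
    for (stop in stop_codons) {
      tgt <- strsplit(stop, "")[[1]]
      nd <- sum(cod != tgt)
      if (nd == 1L) {
        seq[cols] <- .char2int(tgt)
        return(seq)
      }
    }
  }
  stop("could not plant a stop codon")   # unreachable for realistic ORFs
}

#' Synthetic-study configuration
#'
#' Defaults describe the study conditions the generator emulates: several
#' butterfly species each carrying a single Wolbachia strain, per-strain
#' pools of phage types diverging well beyond the 1.5\% type threshold
#' between types and well below it within types, planted cross-strain
#' transfers (a donor type's ancestor copied into a host with a different
#' strain), one planted recombinant spliced at a known breakpoint, and
#' planted pseudogenes carrying an internal stop codon.
#'
#' @param species character vector of host species names
#' @param families named character vector: species -> family
#' @param species_to_strain named character vector: species -> ST key
#' @param strain_to_supergroup named character vector: ST -> A/B
#' @param wsp_alleles named character vector: species -> wsp allele
#' @param types_per_species named integer vector of base (untransferred,
#'   non-recombinant) type counts
#' @param members_per_type sequences sampled per type
#' @param seq_length alignment columns (multiple of 3)
#' @param kappa transition/transversion rate ratio of the K80 model
#' @param within_type_div expected pairwise K2P within a type
#' @param between_type_div expected pairwise K2P between types
#' @param min_type_separation guaranteed realised K2P distance between the
#'   ancestors of distinct planted types (including recombinant children
#'   against every other type); ancestors are redrawn until the floor
#'   holds, so the planted structure always respects the 1.5\% typing
#'   threshold with a safety margin
#' @param transfers data.frame(donor, type, recipient): donor species'
#'   type index copied into the recipient species (different strain)
#' @param recombinants data.frame(species, parent1, parent2, breakpoint):
#'   type indices within the species and the 1-based column where the
#'   child switches to parent2
#' @param pseudogenes data.frame(species, type): source type from which a
#'   pseudogene copy (one internal stop) is derived
#' @param rng_seed integer seed
#' @return list of class \code{sim_config}
#' @export
sim_config <- function(
    species = c("Aglais synthetica", "Bicyclus fictus",
                "Coliasina simulata", "Delias artificialis"),
    families = stats::setNames(c("Nymphalidae", "Nymphalidae",
                                 "Pieridae", "Pieridae"), species),
    species_to_strain = stats::setNames(c("ST-1", "ST-2", "ST-2", "ST-3"),
                                        species),
    strain_to_supergroup = c("ST-1" = "A", "ST-2" = "B", "ST-3" = "B"),
    wsp_alleles = stats::setNames(c("wsp-1", "wsp-2", "wsp-2", "wsp-3"),
                                  species),
    types_per_species = stats::setNames(c(3L, 3L, 3L, 2L), species),
    members_per_type = 5L,
    seq_length = 399L,
    kappa = 2,
    within_type_div = 0.003,
    between_type_div = 0.08,
    min_type_separation = 0.0225,
    transfers = data.frame(donor = c(species[1], species[4]),
                           type = c(1L, 1L),
                           recipient = c(species[2], species[3]),
                           stringsAsFactors = FALSE),
    recombinants = data.frame(species = species[1], parent1 = 2L,
                              parent2 = 3L, breakpoint = 200L,
                              stringsAsFactors = FALSE),
    pseudogenes = data.frame(species = c(species[1], species[2]),
                             type = c(1L, 1L), stringsAsFactors = FALSE),
    rng_seed = 1L) {
  stopifnot(seq_length %% 3L == 0L, seq_length > 0L,
            within_type_div < between_type_div,
            min_type_separation < between_type_div,
            all(names(species_to_strain) == species),
            all(species_to_strain %in% names(strain_to_supergroup)),
            all(types_per_species >= 1L), members_per_type >= 1L)
  if (nrow(transfers)) {
    stopifnot(all(transfers$donor %in% species),
              all(transfers$recipient %in% species),
              all(species_to_strain[transfers$donor] !=
                    species_to_strain[transfers$recipient]),
              all(transfers$type <= types_per_species[transfers$donor]))
  }
  if (nrow(recombinants)) {
    stopifnot(all(recombinants$species %in% species),
              all(recombinants$breakpoint > 1L),
              all(recombinants$breakpoint <= seq_length),
              all(recombinants$parent1 <= types_per_species[recombinants$species]),
              all(recombinants$parent2 <= types_per_species[recombinants$species]))
  }
  structure(list(species = species, families = families,
                 species_to_strain = species_to_strain,
                 strain_to_supergroup = strain_to_supergroup,
                 wsp_alleles = wsp_alleles,
                 types_per_species = types_per_species,
                 members_per_type = as.integer(members_per_type),
                 seq_length = as.integer(seq_length), kappa = kappa,
                 within_type_div = within_type_div,
                 between_type_div = between_type_div,
                 min_type_separation = min_type_separation,
                 transfers = transfers, recombinants = recombinants,
                 pseudogenes = pseudogenes,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Simulate an aligned orf7-like dataset with planted ground truth
#'
#' An ancestral stop-free open reading frame is sampled; each planted
#' type's ancestor evolves from it (half the between-type divergence per
#' branch) under K80, and members evolve from the type ancestor (half the
#' within-type divergence). Nonsense changes in functional sequences are
#' reverted, so only planted pseudogenes carry internal stops. Transfers
#' copy a donor type's ancestor into a recipient species with a different
#' strain before member noise is applied, so transferred types are
#' identical or near-identical across strains. Recombinant type ancestors
#' are spliced from two parent ancestors at the stated breakpoint. All
#' output is a deterministic function of the configuration and its seed.
#'
#' @param cfg a \code{\link{sim_config}}
#' @return list with \code{aln} (an annotated \code{\link{aligned_set}}),
#'   \code{meta} (the metadata data.frame) and \code{truth}: planted type
#'   assignment per sequence, expected functional type counts per
#'   species, transfer events, recombinants, pseudogene ids and realised
#'   substitution counts
#' @export
simulate_phage_data <- function(cfg = sim_config()) with_seed(cfg$rng_seed, {
  L <- cfg$seq_length
  counter <- new.env()
  counter$ts <- 0L; counter$tv <- 0L
  root <- .char2int(unlist(strsplit(
    paste(sample(.nonstop_codons, L / 3L, replace = TRUE), collapse = ""), "")))

  half_between <- cfg$between_type_div / 2
  half_within <- cfg$within_type_div / 2

  # Planted type ancestors, per species. Ancestors are redrawn until
  # every pair of distinct planted types (recombinant children included)
  # is at least min_type_separation apart, so the planted structure
  # respects the typing threshold by construction rather than on average.
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    if (attempt > 100L) stop("could not achieve the planted type separation")
    anc <- list()      # anc[[species]][[type_idx]]
    label <- list()    # planted type label, shared across transfers
    for (sp in cfg$species) {
      anc[[sp]] <- list()
      label[[sp]] <- character(0)
      for (k in seq_len(cfg$types_per_species[[sp]])) {
        a <- .fix_stops(.evolve_k80(root, half_between, cfg$kappa, counter),
                        root)
        anc[[sp]][[k]] <- a
        label[[sp]][k] <- sprintf("%s.t%d", species_abbrev(sp), k)
      }
    }
    # transfers: copy donor ancestor as an extra type of the recipient
    transfer_truth <- list()
    if (nrow(cfg$transfers)) {
      for (i in seq_len(nrow(cfg$transfers))) {
        don <- cfg$transfers$donor[i]; rec <- cfg$transfers$recipient[i]
        k <- cfg$transfers$type[i]
        idx <- length(anc[[rec]]) + 1L
        anc[[rec]][[idx]] <- anc[[don]][[k]]
        label[[rec]][idx] <- label[[don]][k]
        transfer_truth[[i]] <- list(
          type = label[[don]][k],
          strains = sort(unique(cfg$species_to_strain[c(don, rec)])),
          species = sort(c(don, rec)))
      }
    }
    # recombinants: spliced child ancestor as an extra type
    recomb_truth <- list()
    if (nrow(cfg$recombinants)) {
      for (i in seq_len(nrow(cfg$recombinants))) {
        sp <- cfg$recombinants$species[i]
        p1 <- cfg$recombinants$parent1[i]; p2 <- cfg$recombinants$parent2[i]
        bp <- cfg$recombinants$breakpoint[i]
        child <- c(anc[[sp]][[p1]][seq_len(bp - 1L)],
                   anc[[sp]][[p2]][bp:L])
        child <- .fix_stops(child, anc[[sp]][[p2]])
        idx <- length(anc[[sp]]) + 1L
        anc[[sp]][[idx]] <- child
        label[[sp]][idx] <- sprintf("%s.r%d", species_abbrev(sp), i)
        recomb_truth[[i]] <- list(
          species = sp, child_type = label[[sp]][idx],
          parent_types = c(label[[sp]][p1], label[[sp]][p2]),
          breakpoint = bp)
      }
    }
    # separation check over one representative ancestor per planted label
    all_labels <- unlist(label, use.names = FALSE)
    reps_int <- do.call(rbind, unlist(anc, recursive = FALSE))
    keep <- !duplicated(all_labels)
    if (sum(keep) < 2L) break
    rep_mat <- t(apply(reps_int[keep, , drop = FALSE], 1L, .int2char))
    rownames(rep_mat) <- all_labels[keep]
    dsep <- k2p_matrix(rep_mat)$d
    off <- dsep[upper.tri(dsep)]
    if (all(!is.na(off)) && min(off) >= cfg$min_type_separation) break
  }

  # members
  ids <- character(0); seqs <- list(); type_assignment <- character(0)
  meta_rows <- list()
  for (sp in cfg$species) {
    ab <- species_abbrev(sp)
    for (k in seq_along(anc[[sp]])) {
      for (m in seq_len(cfg$members_per_type)) {
        s <- .fix_stops(.evolve_k80(anc[[sp]][[k]], half_within, cfg$kappa,
                                    counter), anc[[sp]][[k]])
        id <- sprintf("%s_t%d_m%d", ab, k, m)
        ids <- c(ids, id); seqs[[id]] <- s
        type_assignment[id] <- label[[sp]][k]
        meta_rows[[id]] <- sp
      }
    }
  }
  # pseudogenes: one member copy with a planted internal stop
  pseudo_ids <- character(0)
  if (nrow(cfg$pseudogenes)) {
    for (i in seq_len(nrow(cfg$pseudogenes))) {
      sp <- cfg$pseudogenes$species[i]; k <- cfg$pseudogenes$type[i]
      s <- .fix_stops(.evolve_k80(anc[[sp]][[k]], half_within, cfg$kappa,
                                  counter), anc[[sp]][[k]])
      s <- .plant_stop(s)
      id <- sprintf("%s_ps%d", species_abbrev(sp), i)
      ids <- c(ids, id); seqs[[id]] <- s
      type_assignment[id] <- label[[sp]][k]
      meta_rows[[id]] <- sp
      pseudo_ids <- c(pseudo_ids, id)
    }
  }

  mat <- do.call(rbind, lapply(seqs[ids], .int2char))
  rownames(mat) <- ids
  meta <- data.frame(
    id = ids,
    species = unlist(meta_rows[ids], use.names = FALSE),
    stringsAsFactors = FALSE)
  meta$family <- unname(cfg$families[meta$species])
  meta$strain_st <- unname(cfg$species_to_strain[meta$species])
  meta$wsp_allele <- unname(cfg$wsp_alleles[meta$species])
  meta$supergroup <- unname(cfg$strain_to_supergroup[meta$strain_st])
  aln <- join_metadata(meta, aligned_set(mat))

  expected_counts <- vapply(cfg$species,
                            function(sp) length(anc[[sp]]), integer(1))
  truth <- list(type_assignment = type_assignment,
                expected_type_counts = expected_counts,
                n_global_types = length(unique(unlist(label))),
                transfer_events = transfer_truth,
                recombinants = recomb_truth,
                pseudogene_ids = pseudo_ids,
                sub_counts = c(ts = counter$ts, tv = counter$tv))
  list(aln = aln, meta = meta, truth = truth)
})

#' Write a simulated dataset to disk (FASTA + TSV metadata + truth JSON)
#' @param sim result of \code{\link{simulate_phage_data}}
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "sequences.fasta")
  tsv <- file.path(dir, "metadata.tsv")
  js <- file.path(dir, "truth.json")
  write_fasta(sim$aln, fa)
  utils::write.table(sim$meta, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(sim$truth, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(fasta = fa, metadata = tsv, truth = js))
}

#' Packaged host survey table
#'
#' The 19-row host table of the butterfly survey: species, family,
#' Wolbachia MLST sequence type (\code{-} where loci failed to amplify),
#' wsp allele, supergroup and the number of phage WO types recovered per
#' species.
#'
#' @return data.frame with one row per host species; \code{strain_st} is
#'   \code{UNKNOWN} where no ST was obtained
#' @export
fixture_table1 <- function() {
  path <- system.file("extdata", "table1_hosts.tsv", package = "phagewo",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  tab$strain_st[tab$strain_st %in% c("-", "–", "")] <- "UNKNOWN"
  tab
}
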