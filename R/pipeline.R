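# End-to-end orchestration and report assembly.

#' Percentage of hosts with multiple phage infections
#'
#' A host shows a multiple phage infection when its Wolbachia strain
#' displays strictly more than two phage types. Returns the percentage of
#' such hosts, rounded to the nearest integer for display.
#'
#' @param hosts data.frame with an \code{n_types} column (one row per
#'   host species), e.g. from \code{\link{summarize_types}} or
#'   \code{\link{fixture_table1}}
#' @export
multi_infection_pct <- function(hosts) {
  if (is.null(hosts) || nrow(hosts) == 0L) stop("no host records")
  round(100 * sum(hosts$n_types > 2L) / nrow(hosts))
}

#' Run the full phage WO analysis pipeline
#'
#' Executes pseudogene flagging, per-species and global typing, per-host
#' summaries, horizontal-transfer enumeration, within-species
#' recombination detection and the phage phylogeny (plus phage/symbiont
#' congruence when a symbiont alignment is supplied), in that order.
#'
#' @param fasta path to an aligned multi-FASTA, or an
#'   \code{\link{aligned_set}}
#' @param metadata path to the host metadata TSV, or a data.frame
#' @param cfg a \code{\link{run_config}}
#' @param outdir optional directory; when given, writes
#'   \code{table1.tsv}, \code{table2.tsv}, \code{transfers.json} and
#'   \code{report.json}
#' @param mlst optional aligned MLST concatenates (path or
#'   \code{aligned_set}) with strain keys as sequence ids, used for the
#'   symbiont tree and the congruence report
#' @param quiet suppress per-stage progress messages
#' @return a \code{run_report} list: sequence/pseudogene counts, host
#'   summary, multiple-infection percentage, transfer events (plus the
#'   strict-identity tally), recombination events, congruence summary and
#'   provenance
#' @export
run_all <- function(fasta, metadata, cfg = run_config(), outdir = NULL,
                    mlst = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "read sequences"
  report <- tryCatch({
    aln <- if (inherits(fasta, "aligned_set")) fasta else read_fasta(fasta)
    stage <- "join metadata"
    aln <- if (is.data.frame(metadata)) join_metadata(metadata, aln)
    else read_metadata(metadata, aln)
    say("read %d sequences x %d columns from %d species",
        n_seqs(aln), aln$length, length(unique(aln$meta$species)))

    stage <- "flag pseudogenes"
    aln <- flag_pseudogenes(aln)
    n_pseudo <- sum(aln$meta$is_pseudogene)
    say("flagged %d pseudogene(s) in frame %d", n_pseudo, attr(aln, "frame"))

    stage <- "typing"
    fun <- functional_only(aln)
    dm <- k2p_matrix(fun)
    per_species <- cluster_types(aln, cfg, scope = "per_species", dm = dm)
    global <- cluster_types(aln, cfg, scope = "global", dm = dm,
                            per_species_types = per_species)
    hosts <- summarize_types(per_species, aln$meta)
    say("typed %d functional sequences into %d per-species types (%d global)",
        n_seqs(fun), length(per_species), length(global))

    stage <- "transfer enumeration"
    transfers <- enumerate_transfers(global, aln, cfg, dm = dm)
    strict <- enumerate_transfers(global, aln, cfg, dm = dm,
                                  mode = "strict_identity")
    say("%d transfer event(s) (%d under strict identity)",
        length(transfers), length(strict))

    stage <- "recombination"
    recomb <- detect_recombination(aln, per_species, cfg)
    say("%d consensus recombination event(s); %d species skipped (<3 types)",
        length(recomb$events), length(recomb$skipped))

    stage <- "phylogeny"
    phage_tree <- NULL
    cong <- NULL
    reps_ids <- vapply(per_species, `[[`, character(1), "representative_id")
    if (length(reps_ids) >= 3L) {
      reps_mat <- fun$mat[reps_ids, , drop = FALSE]
      rownames(reps_mat) <- vapply(per_species, `[[`, character(1), "name")
      phage_tree <- bootstrap_support(reps_mat, cfg)
      if (!is.null(mlst)) {
        sym_aln <- if (inherits(mlst, "aligned_set")) mlst else read_fasta(mlst)
        sym_tree <- bootstrap_support(sym_aln$mat, cfg)
        link <- stats::setNames(
          strain_key(fun$meta[match(reps_ids, fun$meta$id), ]),
          rownames(reps_mat))
        cong <- congruence(phage_tree, sym_tree, link)
        say("congruence: nRF = %.3f, %d crossing candidate(s)",
            cong$nrf, length(cong$crossings))
      }
    }

    list(
      n_sequences = n_seqs(aln),
      n_pseudogenes = n_pseudo,
      hosts = hosts,
      pct_multi_infected = multi_infection_pct(hosts),
      per_species_types = per_species,
      global_types = global,
      transfer_events = transfers,
      transfer_events_strict = strict,
      n_cross_supergroup = sum(vapply(transfers, `[[`, logical(1),
                                      "cross_supergroup")),
      recombination = recomb,
      phage_tree = phage_tree,
      congruence = cong,
      provenance = list(
        seed = cfg$rng_seed,
        config = unclass(cfg),
        package_version = as.character(utils::packageVersion("phagewo")))
    )
  }, error = function(e) {
    stop(sprintf("pipeline aborted at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  class(report) <- "run_report"
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(paste0(
    "phage WO run report\n",
    "  sequences: %d (%d pseudogenes)\n",
    "  host species: %d; multiple infections (>2 types): %d%%\n",
    "  per-species types: %d; transfer events: %d (%d cross-supergroup)\n",
    "  recombination events: %d\n"),
    x$n_sequences, x$n_pseudogenes, nrow(x$hosts), x$pct_multi_infected,
    length(x$per_species_types), length(x$transfer_events),
    x$n_cross_supergroup, length(x$recombination$events)))
  invisible(x)
}

#' Write the report files of a pipeline run
#' @param report a \code{run_report}
#' @param outdir output directory (created if needed)
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$hosts, file.path(outdir, "table1.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(recomb_table(report$recombination$events),
                     file.path(outdir, "table2.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(report$transfer_events, function(e) {
      list(global_type_id = e$global_type_id,
           member_type_names = e$member_type_names,
           strains = e$strains, species = e$species,
           supergroups = as.list(e$supergroups),
           cross_supergroup = e$cross_supergroup,
           st_unresolved = e$st_unresolved,
           min_interhost_distance = e$min_interhost_distance)
    }),
    file.path(outdir, "transfers.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  summary <- list(
    n_sequences = report$n_sequences,
    n_pseudogenes = report$n_pseudogenes,
    pct_multi_infected = report$pct_multi_infected,
    n_per_species_types = length(report$per_species_types),
    n_global_types = length(report$global_types),
    n_transfer_events = length(report$transfer_events),
    n_cross_supergroup = report$n_cross_supergroup,
    n_recombination_events = length(report$recombination$events),
    nrf = if (!is.null(report$congruence)) report$congruence$nrf else NULL,
    provenance = report$provenance)
  jsonlite::write_json(summary, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
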