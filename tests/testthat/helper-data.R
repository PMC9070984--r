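# Small in-code fixtures shared across test files.

make_aln <- function(seqs, species = NULL, strain = NULL, supergroup = NULL) {
  mat <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
  rownames(mat) <- names(seqs)
  n <- length(seqs)
  meta <- data.frame(
    id = names(seqs),
    species = if (is.null(species)) rep("Testia examplaris", n) else species,
    family = "Testidae",
    strain_st = if (is.null(strain)) rep("ST-1", n) else strain,
    wsp_allele = "wsp-1",
    supergroup = if (is.null(supergroup)) rep("B", n) else supergroup,
    stringsAsFactors = FALSE)
  join_metadata(meta, aligned_set(mat))
}

# standard simulated dataset, typed; memoised per seed to keep tests fast
typed_sim <- local({
  cache <- list()
  function(seed = 1, cfg = sim_config(rng_seed = seed)) {
    key <- paste0("s", seed, "_", phagewo:::hash_string(as.character(cfg$rng_seed)))
    if (!is.null(cache[[key]])) return(cache[[key]])
    sim <- simulate_phage_data(cfg)
    aln <- flag_pseudogenes(sim$aln)
    dm <- k2p_matrix(functional_only(aln))
    ps <- cluster_types(aln, run_config(), dm = dm)
    gl <- cluster_types(aln, run_config(), scope = "global", dm = dm,
                        per_species_types = ps)
    out <- list(sim = sim, aln = aln, dm = dm, ps = ps, gl = gl)
    cache[[key]] <<- out
    out
  }
})
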