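# phagewo

Typing, horizontal transfer and intragenic recombination of bacteriophage
WO from *orf7* marker sequences.

Phage WO is the only bacteriophage known to infect *Wolbachia*, the
intracellular symbiont of a large share of insect species. Surveys of
*Wolbachia*-infected hosts amplify a fragment of the phage's minor capsid
gene *orf7* and ask three questions of the resulting haplotype sample:
how many phage types does each host's *Wolbachia* strain carry, which
types recur across *different* strains (direct evidence of horizontal
phage transfer), and which types are intragenic recombinants of other
types in the same host. `phagewo` is an R package implementing that
analysis end to end, for researchers studying phage/endosymbiont
evolutionary dynamics.

The pipeline:

1. **Pseudogene filter** — *orf7*-like sequences with a stop codon (TAA/
   TAG/TGA) strictly before their final codon, read in an auto-detected
   frame, are flagged and excluded from typing.
2. **Typing** — pairwise Kimura 2-parameter distances with pairwise
   deletion, `d = -½ ln[(1-2P-Q)√(1-2Q)]`; sequences within 1.5%
   divergence (≥ 98.5% identity) form one phage WO type (single-linkage
   default, complete linkage and p-identity modes available). Types are
   named `WO` + host abbreviation + index (e.g. `WOPma-1`).
3. **Horizontal transfer** — one event per global type whose hosts span
   ≥ 2 distinct *Wolbachia* strains (MLST STs; unresolved strains become
   pseudo-strains), with supergroup composition and a strict-identity
   alternative tally.
4. **Recombination** — five per-triplet statistics (MaxChi, Chimaera, a
   3Seq-style maximum-descent walk, a GENECONV-style run scan, BootScan
   over sliding-window NJ quartet support), seeded permutation p-values,
   Bonferroni correction per species, and a ≥ 3-method consensus rule
   with begin-breakpoint estimates.
5. **Phylogeny / congruence** — bootstrap neighbor-joining trees for
   phage types and symbiont MLST concatenates, normalised Robinson–Foulds
   distance and tanglegram crossing candidates.
6. **Synthetic data** — a seeded K80 generator that plants types,
   cross-strain transfers, spliced recombinants and pseudogenes, with a
   machine-readable truth record for recovery testing.

See `vignettes/phagewo-methods.Rmd` for the full model description and
design rationale.

## Worked example

```r
library(phagewo)
sim    <- simulate_phage_data(sim_config(rng_seed = 42))
report <- run_all(sim$aln, sim$meta, run_config(rng_seed = 42), quiet = TRUE)
print(report)
#> phage WO run report
#>   sequences: 72 (2 pseudogenes)
#>   host species: 4; multiple infections (>2 types): 75%
#>   per-species types: 14; transfer events: 2 (1 cross-supergroup)
#>   recombination events: 1
```

72 simulated *orf7* sequences from four butterfly species were read; two
carried internal stop codons and were set aside as pseudogenes. The
remaining 70 cluster into 14 per-species phage types, so three of the
four species carry "multiple" infections (more than two types = 75%).

```r
transfers_table(report$transfer_events)[, c(1, 3, 5, 6)]
#>   global_type_id   strains member_type_names cross_supergroup
#> 1            G-1 ST-1,ST-2   WOAsy-1,WOBfi-4             TRUE
#> 2            G-2 ST-2,ST-3   WOCsi-4,WODar-1            FALSE
```

Two global types span two *Wolbachia* strains each — two horizontal
transfer events, one of them crossing supergroups A and B; both planted
transfers are recovered exactly.

```r
recomb_table(report$recombination$events)[, 2:6]
#>   recombinant major_parent minor_parents breakpoint                                  methods
#> 1     WOAsy-4      WOAsy-2       WOAsy-3        210 MAXCHI CHIMAERA THREESEQ GENECONV_LIKE BOOTSCAN
```

The planted recombinant (`WOAsy-4`, spliced from its two parent types at
column 200) reaches consensus on all five methods with an estimated
begin-breakpoint of 210.

A thin command-line wrapper is installed with the package:

```sh
phagewo_exec=$(Rscript -e 'cat(file.path(find.package("phagewo"), "exec", "phagewo"))')
Rscript "$phagewo_exec" simulate --seed 3 --out sim/
Rscript "$phagewo_exec" run --fasta sim/sequences.fasta --meta sim/metadata.tsv \
        --seed 3 --outdir out/       # writes table1.tsv, table2.tsv,
                                     # transfers.json, report.json
```

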