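test_that("internal stop codons are flagged, terminal stops are not", {
  clean <- strrep("ATGGCA", 15)                      # 90 bp, stop-free
  mid <- paste0(substr(clean, 1, 27), "TAA", substr(clean, 31, 90))
  last <- paste0(substr(clean, 1, 87), "TGA")        # stop only in codon 30
  aln <- make_aln(c(ok = clean, mid = mid, last = last))
  flagged <- flag_pseudogenes(aln, frame = 1)
  expect_equal(flagged$meta$is_pseudogene, c(FALSE, TRUE, FALSE))

  # auto-detection picks the frame whose consensus is stop-free
  auto <- flag_pseudogenes(aln)
  expect_equal(attr(auto, "frame"), 1L)

  # gaps are removed before reading codons
  gapped <- paste0("---", substr(mid, 1, 87))
  aln2 <- make_aln(c(ok = clean, gapped = gapped))
  expect_true(flag_pseudogenes(aln2, frame = 1)$meta$is_pseudogene[2])

  # stops in every frame of the consensus: advise manual frame
  allstop <- paste0("TAAATAAATAAA", strrep("A", 6))
  aln3 <- make_aln(c(a = allstop, b = allstop))
  expect_error(flag_pseudogenes(aln3), "frame")
})

test_that("K2P distance matches its closed form and handles pairwise deletion", {
  a <- strrep("ACGT", 25)
  r <- k2p_distance(a, a)
  expect_equal(r[c("d", "P", "Q", "n_eff")],
               list(d = 0, P = 0, Q = 0, n_eff = 100L))

  # 2 transitions + 1 transversion over 100 sites
  b <- strsplit(a, "")[[1]]
  b[1] <- "G"; b[5] <- "G"; b[2] <- "A"   # A->G, A->G, C->A
  r <- k2p_distance(a, b)
  expect_equal(r$P, 0.02)
  expect_equal(r$Q, 0.01)
  expect_equal(r$d, -0.5 * log((1 - 2 * 0.02 - 0.01) * sqrt(1 - 2 * 0.01)))
  expect_equal(round(r$d, 5), 0.03070)

  # pairwise deletion: gap columns dropped, distance unaffected
  g <- strsplit(a, "")[[1]]; g[3] <- "-"; g[7] <- "-"
  r <- k2p_distance(strsplit(a, "")[[1]], g)
  expect_equal(r$n_eff, 98L)
  expect_equal(r$d, 0)

  # saturation: all-transition pair has an undefined distance
  ts <- chartr("ACGT", "GTAC", a)
  expect_true(is.na(k2p_distance(a, ts)$d))
  expect_error(k2p_distance("N-", "AN"), "no comparable sites")
})

test_that("matrix K2P agrees with the brute-force oracle and ape on random pairs", {
  set.seed(42)
  acgt <- c("A", "C", "G", "T", "N", "-")
  for (rep in 1:25) {
    L <- sample(60:200, 1)
    mat <- rbind(sample(acgt, L, TRUE, prob = c(rep(0.23, 4), 0.04, 0.04)),
                 sample(acgt, L, TRUE, prob = c(rep(0.23, 4), 0.04, 0.04)))
    rownames(mat) <- c("x", "y")
    o <- oracle_k2p(mat[1, ], mat[2, ])
    if (o$n_eff == 0) next
    dm <- k2p_matrix(mat)
    expect_equal(dm$P["x", "y"], o$P, tolerance = 1e-12)
    expect_equal(dm$Q["x", "y"], o$Q, tolerance = 1e-12)
    expect_equal(dm$n_eff["x", "y"], o$n_eff)
    expect_equal(dm$d["x", "y"], o$d, tolerance = 1e-12)
    if (!is.na(o$d)) {
      dape <- suppressWarnings(
        ape::dist.dna(ape::as.DNAbin(tolower(mat)), model = "K80",
                      pairwise.deletion = TRUE))
      expect_equal(dm$d["x", "y"], as.numeric(dape), tolerance = 1e-9)
    }
  }
})

test_that("threshold clustering separates and chains as each linkage dictates", {
  base <- strrep("ACGTAAGGCC", 40)                    # 400 bp
  mutate <- function(s, pos) {
    v <- strsplit(s, "")[[1]]
    v[pos] <- chartr("ACGT", "CAAA", v[pos])          # transversions
    paste(v, collapse = "")
  }
  # A,B identical; C far beyond the threshold
  aln <- make_aln(c(A = base, B = base, C = mutate(base, 1:30)))
  types <- cluster_types(aln, run_config())
  expect_length(types, 2)
  expect_setequal(types[[1]]$member_ids, c("A", "B"))
  expect_equal(types[[2]]$member_ids, "C")
  expect_equal(types[[1]]$representative_id, "A")

  # chain A-B and B-C near the threshold, A-C beyond it
  fake_d <- matrix(c(0, .012, .024, .012, 0, .012, .024, .012, 0), 3,
                   dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dm <- structure(list(ids = c("A", "B", "C"), d = fake_d,
                       n_diff = fake_d * 400, n_eff = fake_d * 0 + 400),
                  class = "k2p_dist")
  aln3 <- make_aln(c(A = base, B = base, C = base))
  expect_length(cluster_types(aln3, run_config(linkage = "single"), dm = dm), 1)
  expect_length(cluster_types(aln3, run_config(linkage = "complete"), dm = dm), 2)

  # undefined distances never merge
  ts_all <- chartr("ACGT", "GTAC", base)
  aln4 <- make_aln(c(A = base, B = base, C = ts_all))
  expect_length(cluster_types(aln4, run_config()), 2)
})

test_that("cluster count is monotone non-increasing in the threshold", {
  sim <- simulate_phage_data(sim_config(rng_seed = 11))
  aln <- flag_pseudogenes(sim$aln)
  dm <- k2p_matrix(functional_only(aln))
  for (linkage in c("single", "complete")) {
    counts <- vapply(c(0.001, 0.005, 0.015, 0.05, 0.2), function(th) {
      length(cluster_types(aln, run_config(type_threshold = th,
                                           linkage = linkage), dm = dm))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0), info = linkage)
  }
})

test_that("planted type counts are recovered and naming is deterministic", {
  for (seed in 1:25) {
    sim <- simulate_phage_data(sim_config(rng_seed = seed))
    aln <- flag_pseudogenes(sim$aln)
    dm <- k2p_matrix(functional_only(aln))
    ps <- cluster_types(aln, run_config(), dm = dm)
    hosts <- summarize_types(ps, aln$meta)
    expect_equal(hosts$n_types[match(names(sim$truth$expected_type_counts),
                                     hosts$species)],
                 unname(sim$truth$expected_type_counts), info = seed)
    # clusters match the planted assignment exactly
    id2type <- type_of_ids(ps)
    planted <- sim$truth$type_assignment[names(id2type)]
    expect_equal(length(unique(paste(id2type, planted))),
                 length(unique(id2type)), info = seed)
  }
  # multiple-infection flag: strictly more than two types
  sim <- simulate_phage_data(sim_config(rng_seed = 1))
  aln <- flag_pseudogenes(sim$aln)
  hosts <- summarize_types(cluster_types(aln, run_config()), aln$meta)
  expect_equal(hosts$multi_infection, hosts$n_types > 2)

  # shuffling the input rows does not change the type composition
  sim <- simulate_phage_data(sim_config(rng_seed = 2))
  aln <- flag_pseudogenes(sim$aln)
  perm <- phagewo:::with_seed(99, sample(aln$ids))
  aln_p <- subset_aln(aln, perm)
  comp <- function(types) {
    sort(vapply(types, function(t) paste(sort(t$member_ids), collapse = ","),
                character(1)))
  }
  expect_equal(comp(cluster_types(aln, run_config())),
               comp(cluster_types(aln_p, run_config())))
})

test_that("p-identity and K2P modes agree in the small-distance regime", {
  base <- strrep("ACGTAAGGCC", 40)
  mutate <- function(s, pos) {
    v <- strsplit(s, "")[[1]]; v[pos] <- chartr("ACGT", "CAAA", v[pos])
    paste(v, collapse = "")
  }
  base <- strrep("ACGTAAGGCC", 70)            # 700 bp: keeps every pair
  seqs <- c(A = base, B = mutate(base, 15),   # clear of the 1.5% boundary
            C = mutate(base, 1:11),
            D = mutate(base, c(1:11, 21)))    # all pairwise p-distances < 0.02
  aln <- make_aln(seqs)
  comp <- function(types) {
    sort(vapply(types, function(t) paste(sort(t$member_ids), collapse = ","),
                character(1)))
  }
  expect_equal(comp(cluster_types(aln, run_config(identity_mode = "k2p_distance"))),
               comp(cluster_types(aln, run_config(identity_mode = "p_identity"))))
})

test_that("species abbreviations follow the genus + epithet rule", {
  expect_equal(species_abbrev(c("Pseudozizeeria maha", "Ypthima praenubila",
                                "Isoteinon sp.", "Eurema blanda")),
               c("Pma", "Ypr", "Isp", "Ebl"))
  expect_equal(species_abbrev("Pseudozizeeria maha",
                              override = c("Pseudozizeeria maha" = "Pz")),
               "Pz")
})
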