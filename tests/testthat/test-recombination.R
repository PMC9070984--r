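# A perfectly spliced triplet: child = parent1 left of the breakpoint,
# parent2 from it on, with n_inf informative sites split evenly.
spliced_triplet <- function(L = 400, bp = 200, n_inf = 20, seed = 1) {
  phagewo:::with_seed(seed, {
    acgt <- c("A", "C", "G", "T")
    p1 <- sample(acgt, L, replace = TRUE)
    p2 <- p1
    pos <- sort(c(sample(1:(bp - 1), n_inf / 2),
                  sample(bp:L, n_inf / 2)))
    for (j in pos) p2[j] <- sample(setdiff(acgt, p1[j]), 1)
    child <- p1
    child[bp:L] <- p2[bp:L]
    reps <- rbind(child, p1, p2)
    rownames(reps) <- c("C", "P1", "P2")
    build_triplets(reps)[[1]]
  })
}

test_that("triplet construction enumerates child/parent combinations", {
  reps <- matrix("A", 3, 30, dimnames = list(c("x", "y", "z"), NULL))
  expect_length(build_triplets(reps), 3)
  reps5 <- matrix("A", 5, 30, dimnames = list(letters[1:5], NULL))
  expect_length(build_triplets(reps5), 5 * choose(4, 2))

  # identical parents give no informative sites and p = 1 everywhere
  t0 <- build_triplets(rbind(C = strsplit(strrep("ACGT", 10), "")[[1]],
                             P1 = strsplit(strrep("ACGT", 10), "")[[1]],
                             P2 = strsplit(strrep("ACGT", 10), "")[[1]]))[[1]]
  expect_length(t0$informative_sites, 0)
  for (f in list(maxchi, chimaera, threeseq_walk, geneconv_like)) {
    expect_equal(f(t0, run_config())$p_value, 1)
  }
})

test_that("MaxChi and Chimaera match exhaustive cut enumeration and hand values", {
  t <- spliced_triplet(n_inf = 20, seed = 3)
  expect_length(t$informative_sites, 20)
  cfg <- run_config()

  r <- maxchi(t, cfg)
  B <- rbind(t$var_match_p1, t$var_match_p2) * 1
  expect_equal(r$statistic, oracle_max_cut_chi(B))
  expect_lte(abs(r$breakpoints[1] - 200), 30)
  expect_lte(r$p_value, 0.01)

  rc <- chimaera(t, cfg)
  # perfect 10/10 split: 2x2 table (10,0;0,10) has chi-square 20
  expect_equal(rc$statistic, 20)
  expect_equal(rc$statistic,
               oracle_max_cut_chi(matrix(t$inf_match_p1 * 1, 1)))
  expect_lte(rc$p_value, 0.01)

  # a child identical to one parent carries no breakpoint signal
  tt <- spliced_triplet(n_inf = 20, seed = 4)
  reps <- rbind(C = tt$inf_match_p1, P1 = tt$inf_match_p1)  # placeholder
  t1 <- local({
    phagewo:::with_seed(8, {
      acgt <- c("A", "C", "G", "T")
      p1 <- sample(acgt, 200, replace = TRUE)
      p2 <- p1
      pos <- sample(200, 16)
      for (j in pos) p2[j] <- sample(setdiff(acgt, p1[j]), 1)
      m <- rbind(C = p1, P1 = p1, P2 = p2)
      build_triplets(m)[[1]]
    })
  })
  expect_gte(maxchi(t1, cfg)$p_value, 0.5)
  expect_gte(chimaera(t1, cfg)$p_value, 0.5)
})

test_that("the 3Seq walk statistic matches exhaustive enumeration", {
  cfg <- run_config()
  # block labels: -1 x10 then +1 x10 -> maximum ascent 10, tiny p
  t <- spliced_triplet(n_inf = 20, seed = 5)
  r <- threeseq_walk(t, cfg)
  s <- ifelse(t$inf_match_p1, -1, 1)
  o <- oracle_walk_extremes(s)
  expect_equal(r$statistic, 10)
  expect_equal(r$statistic, o$stat)
  expect_lte(r$p_value, 0.005)
  expect_lte(abs(r$breakpoints[1] - 200), 30)

  # alternating labels: ascent 1, no significance
  talt <- local({
    acgt <- c("A", "C", "G", "T")
    p1 <- rep("A", 100); p2 <- p1
    pos <- seq(5, 95, by = 5)
    p2[pos] <- "C"
    child <- p1
    child[pos[seq(1, length(pos), 2)]] <- "C"   # alternate match partner
    m <- rbind(C = child, P1 = p1, P2 = p2)
    build_triplets(m)[[1]]
  })
  ralt <- threeseq_walk(talt, cfg)
  salt <- ifelse(talt$inf_match_p1, -1, 1)
  expect_equal(ralt$statistic, oracle_walk_extremes(salt)$stat)
  expect_gte(ralt$p_value, 0.5)

  # random triplets agree with the oracle exactly
  for (seed in 1:20) {
    tr <- random_triplet(seed = seed)
    if (length(tr$informative_sites) < 2) next
    sr <- ifelse(tr$inf_match_p1, -1, 1)
    expect_equal(phagewo:::.walk_extremes(sr)$stat,
                 oracle_walk_extremes(sr)$stat, info = seed)
  }
})

test_that("the GENECONV-style run scan finds the spliced segment", {
  cfg <- run_config()
  t <- spliced_triplet(n_inf = 20, seed = 6)
  r <- geneconv_like(t, cfg)
  lab <- ifelse(t$inf_match_p1, 1L, 2L)
  expect_equal(r$statistic,
               oracle_best_run_stat(lab, t$informative_sites))
  expect_lte(r$p_value, 0.01)
  # reported endpoints bracket one flank of the splice
  expect_true(any(abs(r$breakpoints - 200) <= 40))

  # single informative site: no test possible
  one <- local({
    p1 <- rep("A", 60); p2 <- p1; p2[30] <- "G"
    m <- rbind(C = p2, P1 = p1, P2 = p2)
    build_triplets(m)[[1]]
  })
  expect_equal(geneconv_like(one, cfg)$p_value, 1)
})

test_that("permutation p-values are seed-stable, order-invariant and calibrated", {
  t <- spliced_triplet(n_inf = 16, seed = 9)
  cfg <- run_config()
  expect_identical(maxchi(t, cfg)$p_value, maxchi(t, cfg)$p_value)

  # swapping the parent roles leaves every method's p-value unchanged
  swapped <- t
  swapped$parent1 <- t$parent2; swapped$parent2 <- t$parent1
  swapped$inf_match_p1 <- !t$inf_match_p1
  swapped$var_match_p1 <- t$var_match_p2
  swapped$var_match_p2 <- t$var_match_p1
  for (f in list(maxchi, chimaera, threeseq_walk, geneconv_like)) {
    expect_equal(f(t, cfg)$p_value, f(swapped, cfg)$p_value)
  }

  # under the null, small p-values stay rare and the bulk is high
  ps <- vapply(1:100, function(seed) {
    tr <- local({
      phagewo:::with_seed(1000 + seed, {
        acgt <- c("A", "C", "G", "T")
        p1 <- sample(acgt, 150, replace = TRUE)
        p2 <- p1
        pos <- sample(150, 20)
        for (j in pos) p2[j] <- sample(setdiff(acgt, p1[j]), 1)
        child <- ifelse(stats::runif(150) < 0.5, p1, p2)  # no spatial signal
        m <- rbind(C = child, P1 = p1, P2 = p2)
        build_triplets(m)[[1]]
      })
    })
    geneconv_like(tr, run_config(rng_seed = seed))$p_value
  }, numeric(1))
  expect_lte(mean(ps <= 0.05), 0.10)
  expect_gte(stats::median(ps), 0.25)
})

test_that("statistics are monotone when the maximal segment grows coherently", {
  lab <- c(1L, 1L, 2L, 2L, 2L, 1L, 2L, 1L, 1L)
  cols <- seq_along(lab) * 10L
  base <- phagewo:::.best_run(lab, cols)$stat
  grown <- phagewo:::.best_run(c(lab[1:5], 2L, lab[6:9]),
                               c(cols[1:5], 55L, cols[6:9] + 10L))$stat
  expect_gte(grown, base)

  s <- c(-1, -1, -1, 1, 1, -1, 1, 1)
  base_w <- phagewo:::.walk_extremes(s)$stat
  expect_gte(phagewo:::.walk_extremes(c(s[1:5], 1, s[6:8]))$stat, base_w)
})

test_that("BootScan sees the support switch at the planted breakpoint", {
  cfg <- run_config()
  phagewo:::with_seed(21, {
    acgt <- c("A", "C", "G", "T")
    L <- 400
    anc <- sample(acgt, L, replace = TRUE)
    mut <- function(s, rate) {
      pos <- which(stats::runif(L) < rate)
      s[pos] <- vapply(s[pos], function(b) sample(setdiff(acgt, b), 1), "x")
      s
    }
    # parents and outgroup radiate from one ancestor, so the outgroup is
    # equidistant from both parents and the support profile is symmetric
    p1 <- mut(anc, 0.04)
    p2 <- mut(anc, 0.04)
    og <- mut(anc, 0.06)
    child <- c(p1[1:199], p2[200:L])
    reps <- rbind(C = child, P1 = p1, P2 = p2, OG = og)
    tr <- build_triplets(reps[1:3, ])[[1]]
    r <- bootscan(tr, reps["OG", , drop = FALSE], reps, cfg)
    expect_lte(r$p_value, 0.05)
    expect_true(length(r$breakpoints) == 1)
    expect_lte(abs(r$breakpoints - 200), 40)
    sup <- attr(r, "support")
    expect_gte(max(sup), 0.9)
    expect_lte(min(sup), 0.1)

    # window scores match direct per-window counting
    starts <- seq(1L, L - cfg$window + 1L, by = cfg$step)
    q <- phagewo:::.quartet_u(child, p1, p2, og)
    lo <- findInterval(starts - 1L, q$cols) + 1L
    hi <- findInterval(starts + cfg$window - 1L, q$cols)
    c1 <- c(0, cumsum(q$u))
    expect_equal(c1[hi + 1] - c1[lo],
                 oracle_quartet_window_scores(child, p1, p2, og, starts,
                                              cfg$window))

    # a clonal triplet shows no switch
    child2 <- mut(p1, 0.005)
    reps2 <- rbind(C = child2, P1 = p1, P2 = p2, OG = og)
    tr2 <- build_triplets(reps2[1:3, ])[[1]]
    r2 <- bootscan(tr2, reps2["OG", , drop = FALSE], reps2, cfg)
    expect_length(r2$breakpoints, 0)

    # no outgroup available: scan skipped
    r3 <- bootscan(tr, reps[0, , drop = FALSE], reps, cfg)
    expect_equal(r3$p_value, 1)

    # alignment shorter than the window shrinks it with a warning
    short <- reps[, 1:100]
    trs <- build_triplets(short[1:3, ])[[1]]
    expect_warning(bootscan(trs, short["OG", , drop = FALSE], short, cfg),
                   "shrunk")
  })
})

test_that("Gaussian window support tracks Monte-Carlo bootstrap support", {
  cases <- list(c(5L, 10L, 150L, 20L, 15L),
                c(0L, 0L, 180L, 10L, 10L),
                c(30L, 5L, 100L, 5L, 10L),
                c(10L, 10L, 160L, 10L, 10L))
  for (cnt in cases) {
    u <- rep(-2:2, cnt)
    exact <- phagewo:::.bootscan_profile(u, 1L, length(u))
    mc <- phagewo:::with_seed(7, phagewo:::.window_support_mc(cnt, 20000L))
    expect_lte(abs(exact - mc), 0.03)
  }
})

test_that("consensus merges candidates and assigns major/minor parents", {
  mk <- function(method, p, bp) {
    structure(list(method = method, statistic = 1, p_value = p,
                   breakpoints = bp), class = "method_result")
  }
  trip <- function(child, p1, p2) {
    structure(list(child = child, parent1 = p1, parent2 = p2,
                   informative_sites = 1:10), class = "triplet")
  }
  # three candidate triplets for child X, breakpoints within 10 columns;
  # parent A appears in all three -> major parent
  scan <- list(
    triplets = list(trip("X", "A", "B"), trip("X", "A", "C"),
                    trip("X", "A", "D"), trip("Y", "A", "B")),
    results = list(
      list(M1 = mk("M1", 1e-6, 100), M2 = mk("M2", 1e-6, 103),
           M3 = mk("M3", 1e-6, 98), M4 = mk("M4", 1, 1), M5 = mk("M5", 1, 1)),
      list(M1 = mk("M1", 1e-6, 101), M2 = mk("M2", 1e-6, 99),
           M3 = mk("M3", 1e-6, 102), M4 = mk("M4", 1, 1), M5 = mk("M5", 1, 1)),
      list(M1 = mk("M1", 1e-6, 104), M2 = mk("M2", 1e-6, 100),
           M3 = mk("M3", 1e-6, 97), M4 = mk("M4", 1, 1), M5 = mk("M5", 1, 1)),
      list(M1 = mk("M1", 0.2, 50), M2 = mk("M2", 0.9, 60),
           M3 = mk("M3", 1, 1), M4 = mk("M4", 1, 1), M5 = mk("M5", 1, 1))))
  ev <- consensus_events(scan, run_config())
  expect_length(ev, 1)
  expect_equal(ev[[1]]$recombinant, "X")
  expect_equal(ev[[1]]$major_parent, "A")
  expect_setequal(ev[[1]]$minor_parents, c("B", "C", "D"))
  expect_gte(ev[[1]]$n_methods, 3)
  expect_lte(abs(ev[[1]]$breakpoints - 100), 5)

  # Bonferroni: borderline raw p-values no longer reach consensus once
  # corrected for the four triplets
  scan2 <- scan
  scan2$results[[1]] <- list(M1 = mk("M1", 0.02, 100), M2 = mk("M2", 0.02, 101),
                             M3 = mk("M3", 0.02, 99), M4 = mk("M4", 1, 1),
                             M5 = mk("M5", 1, 1))
  scan2$results[[2]] <- scan2$results[[4]]
  scan2$results[[3]] <- scan2$results[[4]]
  expect_length(consensus_events(scan2, run_config()), 0)
})

test_that("the planted recombinant reaches multi-method consensus in the pipeline", {
  ts <- typed_sim(1)
  rec <- detect_recombination(ts$aln, ts$ps, run_config())
  rt <- ts$sim$truth$recombinants[[1]]
  id2type <- type_of_ids(ts$ps)
  child_ids <- names(ts$sim$truth$type_assignment)[
    ts$sim$truth$type_assignment == rt$child_type]
  child_name <- unique(id2type[intersect(child_ids, names(id2type))])
  parent_names <- unique(id2type[names(ts$sim$truth$type_assignment)[
    ts$sim$truth$type_assignment %in% rt$parent_types]])
  hits <- Filter(function(e) e$recombinant == child_name, rec$events)
  expect_gte(length(hits), 1)
  best <- hits[[which.max(vapply(hits, `[[`, integer(1), "n_methods"))]]
  expect_gte(best$n_methods, run_config()$consensus_min_methods)
  # recovered parents are the planted ones (order-insensitive)
  found_parents <- unlist(lapply(hits, function(e)
    c(e$major_parent, e$minor_parents)))
  expect_true(all(parent_names %in% found_parents))
  expect_lte(min(abs(vapply(hits, function(e) e$breakpoints[1], numeric(1)) -
                       rt$breakpoint)), 30)
  # species with fewer than three types are skipped and reported
  expect_true("Delias artificialis" %in% names(rec$n_triplets) ||
                "Delias artificialis" %in% rec$skipped)
  # the recombination table carries one row per event
  tab <- recomb_table(rec$events)
  expect_equal(nrow(tab), length(rec$events))
  expect_true(all(c("insect", "recombinant", "major_parent", "breakpoint")
                  %in% names(tab)))
})
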