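# Intragenic recombination detection among a species' phage types:
# five statistics, seeded permutation significance, >=3-method consensus.

#' Build all child/parent-pair triplets from type representatives
#'
#' For every ordered child and unordered parent pair among the
#' representative sequences, records the informative sites (1-based
#' alignment columns where the parents differ and the child matches
#' exactly one of them) and the variable sites (columns where the three
#' sequences are not all identical), restricted to columns where all
#' three carry an unambiguous base.
#'
#' @param reps character matrix of representative sequences (rows named by
#'   type)
#' @return list of \code{triplet} objects with fields \code{child},
#'   \code{parent1}, \code{parent2}, \code{informative_sites},
#'   \code{inf_match_p1} (logical, child matches parent1 at each
#'   informative site), \code{var_sites}, \code{var_match_p1},
#'   \code{var_match_p2}
#' @export
build_triplets <- function(reps) {
  stopifnot(is.matrix(reps), nrow(reps) >= 3L)
  nm <- rownames(reps)
  out <- list()
  for (ci in seq_len(nrow(reps))) {
    others <- setdiff(seq_len(nrow(reps)), ci)
    prs <- utils::combn(others, 2L)
    for (j in seq_len(ncol(prs))) {
      p1 <- prs[1L, j]; p2 <- prs[2L, j]
      cc <- reps[ci, ]; s1 <- reps[p1, ]; s2 <- reps[p2, ]
      ok <- cc %in% c("A", "C", "G", "T") & s1 %in% c("A", "C", "G", "T") &
        s2 %in% c("A", "C", "G", "T")
      inf <- which(ok & s1 != s2 & (cc == s1 | cc == s2))
      var <- which(ok & !(cc == s1 & cc == s2))
      out[[length(out) + 1L]] <- structure(list(
        child = nm[ci], parent1 = nm[p1], parent2 = nm[p2],
        informative_sites = inf,
        inf_match_p1 = cc[inf] == s1[inf],
        var_sites = var,
        var_match_p1 = cc[var] == s1[var],
        var_match_p2 = cc[var] == s2[var]
      ), class = "triplet")
    }
  }
  out
}

method_result <- function(method, statistic, p_value, breakpoints = integer(0)) {
  structure(list(method = method, statistic = statistic,
                 p_value = p_value, breakpoints = breakpoints),
            class = "method_result")
}

.null_result <- function(method) method_result(method, NA_real_, 1)

.triplet_seed <- function(cfg, method, t) {
  derive_seed(cfg$rng_seed, method, t$child,
              sort(c(t$parent1, t$parent2)))
}

# maximum 2x2 chi-square over all cuts of one or more binary match rows.
# B: logical/0-1 matrix (rows scanned independently). Returns stat, row,
# cut index (cut k separates columns 1..k from k+1..m).
.chi_cut_max <- function(B) {
  m <- ncol(B)
  if (m < 2L) return(list(stat = -Inf, row = NA_integer_, cut = NA_integer_))
  best <- -Inf; brow <- NA_integer_; bcut <- NA_integer_
  k <- seq_len(m - 1L)
  for (r in seq_len(nrow(B))) {
    cs <- cumsum(B[r, ])
    tot <- cs[m]
    chi <- chisq2x2(cs[k], k - cs[k], tot - cs[k], (m - k) - (tot - cs[k]))
    i <- which.max(chi)
    if (chi[i] > best) { best <- chi[i]; brow <- r; bcut <- i }
  }
  list(stat = best, row = brow, cut = bcut)
}

#' MaxChi recombination statistic
#'
#' Scans the child-versus-parent match/mismatch vectors over the
#' triplet's variable sites: for every cut between consecutive sites the
#' 2x2 chi-square (match/mismatch x left/right, no continuity correction)
#' is computed, for each parent; the statistic is the maximum. The
#' breakpoint is the midpoint of the two variable sites bracketing the
#' maximising cut (the switch lies between them). Significance is a
#' seeded permutation p-value over random site-order shuffles.
#'
#' @param t a \code{triplet}
#' @param cfg a \code{\link{run_config}}
#' @return a \code{method_result}
#' @export
maxchi <- function(t, cfg = run_config()) {
  if (length(t$informative_sites) < 2L) return(.null_result("MAXCHI"))
  B <- rbind(t$var_match_p1, t$var_match_p2) * 1
  obs <- .chi_cut_max(B)
  m <- ncol(B)
  p <- with_seed(.triplet_seed(cfg, "MAXCHI", t), {
    perm_pvalue(obs$stat, function(nb) {
      vapply(seq_len(nb), function(i) {
        .chi_cut_max(B[, sample.int(m), drop = FALSE])$stat
      }, numeric(1))
    }, cfg$n_perm)
  })
  bp <- as.integer(round((t$var_sites[obs$cut] +
                            t$var_sites[obs$cut + 1L]) / 2))
  method_result("MAXCHI", obs$stat, p, bp)
}

#' Chimaera recombination statistic
#'
#' As \code{\link{maxchi}}, but the scanned vector is "child matches
#' parent1 (1) versus parent2 (0)" over informative sites only.
#'
#' @inheritParams maxchi
#' @return a \code{method_result}
#' @export
chimaera <- function(t, cfg = run_config()) {
  if (length(t$informative_sites) < 2L) return(.null_result("CHIMAERA"))
  B <- matrix(t$inf_match_p1 * 1, nrow = 1L)
  obs <- .chi_cut_max(B)
  m <- ncol(B)
  p <- with_seed(.triplet_seed(cfg, "CHIMAERA", t), {
    perm_pvalue(obs$stat, function(nb) {
      vapply(seq_len(nb), function(i) {
        .chi_cut_max(B[, sample.int(m), drop = FALSE])$stat
      }, numeric(1))
    }, cfg$n_perm)
  })
  bp <- as.integer(round((t$informative_sites[obs$cut] +
                            t$informative_sites[obs$cut + 1L]) / 2))
  method_result("CHIMAERA", obs$stat, p, bp)
}

# maximum ascent/descent of the +/-1 cumulative walk; returns the
# extremes and the bracketing indices of the best segment (1-based site
# indices start..end).
.walk_extremes <- function(s) {
  W0 <- c(0, cumsum(s))
  m <- length(s)
  j <- seq_len(m) + 1L
  premin <- cummin(W0)[seq_len(m)]
  premax <- cummax(W0)[seq_len(m)]
  asc <- W0[j] - premin
  desc <- premax - W0[j]
  ja <- which.max(asc); ia <- which.min(W0[seq_len(ja)])
  jd <- which.max(desc); id <- which.max(W0[seq_len(jd)])
  if (max(asc) >= max(desc)) {
    list(stat = max(asc), start = ia, end = ja, ascent = max(asc),
         descent = max(desc))
  } else {
    list(stat = max(desc), start = id, end = jd, ascent = max(asc),
         descent = max(desc))
  }
}

# Begin breakpoint of the transferred segment. The true splice lies
# somewhere between the last site of one parental tract and the first
# site of the next, so the midpoint of the bracketing sites is reported
# (halving the expected error relative to either endpoint). A segment
# anchored at the first informative site describes the complementary
# segment's start instead, since the switch happens at its end.
.begin_breakpoint <- function(start_idx, end_idx, cols) {
  m <- length(cols)
  if (start_idx > 1L) {
    as.integer(round((cols[start_idx - 1L] + cols[start_idx]) / 2))
  } else if (end_idx < m) {
    as.integer(round((cols[end_idx] + cols[end_idx + 1L]) / 2))
  } else {
    cols[start_idx]
  }
}

#' 3Seq-style maximum-descent walk statistic
#'
#' Informative sites are encoded +1 (child matches parent2) / -1 (child
#' matches parent1); the statistic is the larger of the maximum ascent
#' and maximum descent of the cumulative walk. Significance is by seeded
#' Monte-Carlo permutation of the labels (not the exact hypergeometric
#' tables of the original method). Breakpoints are the alignment columns
#' bracketing the extremal segment.
#'
#' @inheritParams maxchi
#' @return a \code{method_result}
#' @export
threeseq_walk <- function(t, cfg = run_config()) {
  m <- length(t$informative_sites)
  if (m < 2L) return(.null_result("THREESEQ"))
  s <- ifelse(t$inf_match_p1, -1L, 1L)
  if (length(unique(s)) == 1L) {
    return(method_result("THREESEQ", m, 1))
  }
  obs <- .walk_extremes(s)
  p <- with_seed(.triplet_seed(cfg, "THREESEQ", t), {
    perm_pvalue(obs$stat, function(nb) {
      vapply(seq_len(nb), function(i) {
        .walk_extremes(s[sample.int(m)])$stat
      }, numeric(1))
    }, cfg$n_perm)
  })
  bp <- unique(c(.begin_breakpoint(obs$start, obs$end, t$informative_sites),
                 t$informative_sites[obs$end]))
  method_result("THREESEQ", obs$stat, p, bp)
}

# best run of constant parent label: score = run length (sites) * span
# (columns). lab in {1,2}; cols = alignment columns of the sites.
.best_run <- function(lab, cols) {
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  span <- cols[ends] - cols[starts] + 1L
  score <- r$lengths * span
  i <- which.max(score)
  list(stat = score[i], start_col = cols[starts[i]],
       end_col = cols[ends[i]], start_idx = starts[i], end_idx = ends[i],
       n_run = r$lengths[i])
}

#' GENECONV-style longest-run statistic
#'
#' The statistic is the best maximal run of informative sites at which
#' the child matches the same single parent, scored as run length (in
#' informative sites) weighted by the run's span in alignment columns.
#' Significance is by seeded permutation of the informative-site labels
#' over the same column grid; breakpoints are the run endpoints.
#'
#' @inheritParams maxchi
#' @return a \code{method_result}
#' @export
geneconv_like <- function(t, cfg = run_config()) {
  m <- length(t$informative_sites)
  if (m < 2L) return(.null_result("GENECONV_LIKE"))
  lab <- ifelse(t$inf_match_p1, 1L, 2L)
  cols <- t$informative_sites
  obs <- .best_run(lab, cols)
  p <- with_seed(.triplet_seed(cfg, "GENECONV_LIKE", t), {
    perm_pvalue(obs$stat, function(nb) {
      vapply(seq_len(nb), function(i) {
        .best_run(lab[sample.int(m)], cols)$stat
      }, numeric(1))
    }, cfg$n_perm)
  })
  bp <- unique(c(.begin_breakpoint(obs$start_idx, obs$end_idx, cols),
                 obs$end_col))
  method_result("GENECONV_LIKE", obs$stat, p, bp)
}

# --- BootScan -------------------------------------------------------------

# Per-column quartet score for taxa (child, p1, p2, outgroup): the
# four-point (NJ) criterion on uncorrected window distances reduces to the
# window sum of u = [mm(c,p2)+mm(p1,o)] - [mm(c,p1)+mm(p2,o)]; positive
# sums group (child, parent1).
.quartet_u <- function(cc, s1, s2, oo) {
  ok <- cc %in% c("A", "C", "G", "T") & s1 %in% c("A", "C", "G", "T") &
    s2 %in% c("A", "C", "G", "T") & oo %in% c("A", "C", "G", "T")
  u <- ((cc != s2) + (s1 != oo)) - ((cc != s1) + (s2 != oo))
  list(u = as.integer(u[ok]), cols = which(ok))
}

# Bootstrap support for grouping (child, parent1) in each window: the
# probability that a column bootstrap of the window gives a positive u
# sum. The bootstrap sum is a sum of iid per-column scores, so its
# distribution is evaluated by its Gaussian limit, which makes supports
# deterministic (no resampling noise) and identical between the observed
# profile and the permutation null. Windows are index ranges on the
# valid-column positions; degenerate windows get support 1/2.
.bootscan_profile <- function(u, win_lo, win_hi) {
  c1 <- c(0, cumsum(u))
  c2 <- c(0, cumsum(u * u))
  n <- win_hi - win_lo + 1L
  s <- c1[win_hi + 1L] - c1[win_lo]
  ss <- c2[win_hi + 1L] - c2[win_lo]
  sup <- rep(0.5, length(n))
  ok <- n >= 5L
  v <- ss - s^2 / pmax(n, 1L)          # n * var of per-column scores
  sup[ok & v > 0] <- stats::pnorm(s[ok & v > 0] / sqrt(v[ok & v > 0]))
  deg <- ok & v <= 0 & s != 0          # all scores equal and nonzero
  sup[deg] <- ifelse(s[deg] > 0, 1, 0)
  sup
}

# Monte-Carlo check version of the window support (used in tests): B
# seeded multinomial column resamples of one window's u-class counts.
.window_support_mc <- function(cnt5, B) {
  n <- sum(cnt5)
  if (n < 5L) return(0.5)
  draws <- stats::rmultinom(B, n, cnt5 / n)
  U <- colSums(draws * (-2L:2L))
  mean(U > 0) + 0.5 * mean(U == 0)
}

#' BootScan recombination scan
#'
#' Slides a window across the alignment; in each window, the support for
#' the neighbor-joining grouping of the child with parent1 versus parent2
#' (in the quartet formed with one outgroup taken from the species'
#' remaining types) is the probability that a column bootstrap of the
#' window favours that grouping, evaluated in closed form via the
#' Gaussian limit of the bootstrap sum. A recombination signal is a
#' partner switch with at least 70\% support on both flanks; the
#' statistic is the range of the support profile, its significance a
#' seeded permutation of column order (which destroys spatial structure),
#' and the breakpoint the column where the interpolated support profile
#' crosses 1/2 between the extreme windows.
#'
#' @param t a \code{triplet}
#' @param background character matrix of outgroup candidate sequences
#'   (representatives of the species' remaining types); the first row is
#'   used. With no outgroup available the scan is skipped with p = 1.
#' @param reps character matrix holding the triplet's sequences (rows
#'   named by type)
#' @param cfg a \code{\link{run_config}}
#' @return a \code{method_result}; the support profile and window centres
#'   are attached as attributes \code{support} and \code{centers}
#' @export
bootscan <- function(t, background, reps, cfg = run_config()) {
  if (is.null(background) || nrow(background) < 1L) {
    return(.null_result("BOOTSCAN"))
  }
  if (length(t$informative_sites) < 2L) return(.null_result("BOOTSCAN"))
  cc <- reps[t$child, ]; s1 <- reps[t$parent1, ]; s2 <- reps[t$parent2, ]
  oo <- background[1L, ]
  L <- length(cc)
  w <- cfg$window
  if (L < w) {
    w <- max(4L, L %/% 4L)
    warning(sprintf("alignment (%d) shorter than window; window shrunk to %d",
                    L, w))
  }
  q <- .quartet_u(cc, s1, s2, oo)
  u <- q$u
  if (length(u) < 4L) return(.null_result("BOOTSCAN"))
  starts <- seq(1L, max(1L, L - w + 1L), by = cfg$step)
  win_lo <- findInterval(starts - 1L, q$cols) + 1L
  win_hi <- findInterval(starts + w - 1L, q$cols)
  centers <- starts + (w - 1L) / 2
  res <- with_seed(.triplet_seed(cfg, "BOOTSCAN", t), {
    sup <- .bootscan_profile(u, win_lo, win_hi)
    stat <- max(sup) - min(sup)
    p <- perm_pvalue(stat, function(nb) {
      vapply(seq_len(nb), function(i) {
        sp <- .bootscan_profile(u[sample.int(length(u))], win_lo, win_hi)
        max(sp) - min(sp)
      }, numeric(1))
    }, cfg$n_perm)
    list(sup = sup, stat = stat, p = p)
  })
  sup <- res$sup
  bp <- integer(0)
  if (max(sup) >= 0.7 && min(sup) <= 0.3) {
    i1 <- which.max(sup); i2 <- which.min(sup)
    lo <- min(i1, i2); hi <- max(i1, i2)
    for (i in lo:(hi - 1L)) {
      if ((sup[i] - 0.5) * (sup[i + 1L] - 0.5) <= 0) {
        frac <- if (sup[i + 1L] == sup[i]) 0.5 else
          (0.5 - sup[i]) / (sup[i + 1L] - sup[i])
        bp <- as.integer(round(centers[i] + frac * (centers[i + 1L] - centers[i])))
        break
      }
    }
  }
  out <- method_result("BOOTSCAN", res$stat, res$p, bp)
  attr(out, "support") <- sup
  attr(out, "centers") <- centers
  out
}

#' Run all five methods on every triplet of one species
#'
#' @param reps character matrix of the species' type representatives
#' @param cfg a \code{\link{run_config}}
#' @return list with \code{triplets} and \code{results} (per triplet, a
#'   named list of \code{method_result})
#' @export
scan_species <- function(reps, cfg = run_config()) {
  triplets <- build_triplets(reps)
  results <- lapply(triplets, function(t) {
    in_triplet <- rownames(reps) %in% c(t$child, t$parent1, t$parent2)
    bg <- reps[!in_triplet, , drop = FALSE]
    list(MAXCHI = maxchi(t, cfg),
         CHIMAERA = chimaera(t, cfg),
         THREESEQ = threeseq_walk(t, cfg),
         GENECONV_LIKE = geneconv_like(t, cfg),
         BOOTSCAN = bootscan(t, bg, reps, cfg))
  })
  list(triplets = triplets, results = results)
}

#' Consensus recombination events for one species
#'
#' Per-method p-values are Bonferroni-corrected for the species' triplet
#' count; triplets with at least \code{cfg$consensus_min_methods} methods
#' at adjusted p <= alpha become candidates. Candidates sharing the same
#' child and the same begin-breakpoint (within 10 columns) are merged:
#' the parent appearing most often across the merged candidates becomes
#' the major parent, the others minor parents (at most four).
#'
#' @param scan result of \code{\link{scan_species}}
#' @param cfg a \code{\link{run_config}}
#' @return list of \code{recombination_event} objects (fields
#'   \code{recombinant}, \code{major_parent}, \code{minor_parents},
#'   \code{breakpoints}, \code{supporting}, \code{n_methods})
#' @export
consensus_events <- function(scan, cfg = run_config()) {
  n_trip <- length(scan$triplets)
  if (!n_trip) return(list())
  cands <- list()
  for (i in seq_len(n_trip)) {
    res <- scan$results[[i]]
    padj <- vapply(res, function(r) min(1, r$p_value * n_trip), numeric(1))
    sig <- names(res)[padj <= cfg$alpha]
    if (length(sig) < cfg$consensus_min_methods) next
    bps <- unlist(lapply(res[sig], function(r) r$breakpoints[1L]),
                  use.names = FALSE)
    bps <- bps[!is.na(bps)]
    t <- scan$triplets[[i]]
    cands[[length(cands) + 1L]] <- list(
      child = t$child, parents = c(t$parent1, t$parent2),
      breakpoint = if (length(bps)) stats::median(bps) else NA_real_,
      methods = sig, padj = padj[sig], results = res[sig],
      n_sig = length(sig))
  }
  if (!length(cands)) return(list())
  children <- vapply(cands, `[[`, character(1), "child")
  events <- list()
  for (ch in unique(children)) {
    cs <- cands[children == ch]
    bps <- vapply(cs, `[[`, numeric(1), "breakpoint")
    grp <- if (length(cs) == 1L) 1L else
      .cut_membership(as.matrix(stats::dist(ifelse(is.na(bps), -1e6, bps))),
                      10, "single")
    for (g in unique(grp)) {
      sub <- cs[grp == g]
      parents <- unlist(lapply(sub, `[[`, "parents"), use.names = FALSE)
      tab <- sort(table(parents), decreasing = TRUE)
      major <- names(tab)[order(-tab, names(tab))][1L]
      minors <- utils::head(setdiff(names(tab)[order(-tab, names(tab))], major), 4L)
      best <- sub[[which.max(vapply(sub, `[[`, integer(1), "n_sig"))]]
      gb <- vapply(sub, `[[`, numeric(1), "breakpoint")
      gb <- gb[!is.na(gb)]
      events[[length(events) + 1L]] <- structure(list(
        recombinant = ch, major_parent = major, minor_parents = minors,
        breakpoints = if (length(gb)) as.integer(round(stats::median(gb)))
          else integer(0),
        supporting = best$results, p_adjusted = best$padj,
        n_methods = best$n_sig
      ), class = "recombination_event")
    }
  }
  events
}

#' Detect recombination within every species of an aligned set
#'
#' Runs the five-method scan and consensus rule on the type
#' representatives of every species with at least three functional phage
#' types (the within-species design of the analysis); species with fewer
#' types are skipped and reported.
#'
#' @param aln annotated \code{\link{aligned_set}} (pseudogenes flagged)
#' @param per_species_types per-species typing result
#' @param cfg a \code{\link{run_config}}
#' @return list with \code{events} (all species pooled), \code{scans}
#'   (per species), \code{skipped} (species with < 3 types) and
#'   \code{n_triplets} per species
#' @export
detect_recombination <- function(aln, per_species_types, cfg = run_config()) {
  fun <- if (any(aln$meta$is_pseudogene)) functional_only(aln) else aln
  type_sp <- vapply(per_species_types, function(t) t$species[1L], character(1))
  events <- list()
  scans <- list()
  skipped <- character(0)
  n_triplets <- integer(0)
  for (sp in unique(fun$meta$species)) {
    types_sp <- per_species_types[type_sp == sp]
    if (length(types_sp) < 3L) {
      skipped <- c(skipped, sp)
      next
    }
    reps <- do.call(rbind, lapply(types_sp, function(t) fun$mat[t$representative_id, ]))
    rownames(reps) <- vapply(types_sp, `[[`, character(1), "name")
    sc <- scan_species(reps, cfg)
    ev <- lapply(consensus_events(sc, cfg),
                 function(e) { e$species <- sp; e })
    scans[[sp]] <- sc
    n_triplets[sp] <- length(sc$triplets)
    events <- c(events, ev)
  }
  list(events = events, scans = scans, skipped = skipped,
       n_triplets = n_triplets)
}

#' Recombination events as a report table (one row per event)
#' @param events list of \code{recombination_event}
#' @export
recomb_table <- function(events) {
  if (!length(events)) {
    return(data.frame(insect = character(0), recombinant = character(0),
                      major_parent = character(0), minor_parents = character(0),
                      breakpoint = character(0), methods = character(0),
                      p_values = character(0)))
  }
  data.frame(
    insect = vapply(events, function(e) e$species %||% NA_character_,
                    character(1)),
    recombinant = vapply(events, `[[`, character(1), "recombinant"),
    major_parent = vapply(events, `[[`, character(1), "major_parent"),
    minor_parents = vapply(events, function(e)
      paste(e$minor_parents, collapse = " "), character(1)),
    breakpoint = vapply(events, function(e)
      paste(e$breakpoints, collapse = "/"), character(1)),
    methods = vapply(events, function(e)
      paste(names(e$supporting), collapse = " "), character(1)),
    p_values = vapply(events, function(e)
      paste(signif(vapply(e$supporting, `[[`, numeric(1), "p_value"), 3),
            collapse = " "), character(1)),
    stringsAsFactors = FALSE)
}
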