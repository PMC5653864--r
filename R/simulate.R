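#' Simulation scenarios for synthetic fossil clades
#'
#' A `sim_scenario` bundles every parameter of the synthetic-clade
#' generator: a constant-rate birth-death tree process, symmetric Mk
#' character evolution whose instantaneous rate is modulated
#' piecewise-constantly by per-bin multipliers, random missing data, and
#' posterior-like node-age jitter.  All rates are per lineage (or per
#' character) per Myr.
#'
#' The base change rate `r0` may be given directly or left `NULL`, in
#' which case it is calibrated against each realized tree so that the
#' expected number of changes per character over the whole tree (ignoring
#' multipliers) equals `target_changes_per_character`.
#'
#' @param birth,death speciation and extinction rates (events/lineage/Myr)
#' @param recovery probability that a lineage's fossil tip is recovered;
#'   tips are dropped independently with probability `1 - recovery`
#' @param origin_ma clade origin age (Ma)
#' @param timescale a [timescale()] spanning the simulated interval; the
#'   youngest boundary is the stopping time of the process
#' @param n_characters number of discrete characters
#' @param state_range integer vector of allowed state counts per
#'   character; each character draws its `k` uniformly from this set
#' @param r0 base change rate (changes/character/Myr) or `NULL` to
#'   calibrate from `target_changes_per_character`
#' @param target_changes_per_character expected changes per character over
#'   the tree used when `r0` is `NULL`
#' @param multipliers per-bin rate multipliers (length `nrow(timescale)`,
#'   all `>= 0`)
#' @param p_miss probability that a cell is recoded as missing
#' @param min_tips,max_tips accepted tip-count window; realizations whose
#'   recovered tip count falls outside it are discarded and redrawn, so
#'   the birth-death distribution is conditioned on clade size (the usual
#'   convention in simulation studies that fix a taxon-sampling design)
#' @param max_retries birth-death retries before giving up
#' @return a `sim_scenario` list
#' @export
sim_scenario <- function(birth = 0.036, death = 0.026, recovery = 1,
                         origin_ma = 453,
                         timescale = sim_timescale(453, 254, 13),
                         n_characters = 92, state_range = 2:5, r0 = NULL,
                         target_changes_per_character = 2,
                         multipliers = rep(1, nrow(timescale)),
                         p_miss = 0.2, min_tips = 60, max_tips = 100,
                         max_retries = 200) {
  stopifnot(birth > 0, death >= 0, recovery > 0, recovery <= 1,
            n_characters >= 1, all(state_range >= 2),
            p_miss >= 0, p_miss <= 1, min_tips >= 4,
            max_tips >= min_tips,
            length(multipliers) == nrow(timescale), all(multipliers >= 0),
            origin_ma <= timescale$start_ma[1] + 1e-9,
            origin_ma > timescale$end_ma[nrow(timescale)])
  s <- list(birth = birth, death = death, recovery = recovery,
            origin_ma = origin_ma, timescale = timescale,
            n_characters = n_characters, state_range = state_range,
            r0 = r0,
            target_changes_per_character = target_changes_per_character,
            multipliers = multipliers, p_miss = p_miss,
            min_tips = min_tips, max_tips = max_tips,
            max_retries = max_retries)
  class(s) <- "sim_scenario"
  s
}

#' Preset scenarios
#'
#' `paper_like_scenario()` emulates a Palaeozoic-scale study clade: origin
#' 453 Ma, 13 equal bins to 254 Ma, 60-100 recovered taxa, 92 unordered
#' characters with 2-5 states, 20\% missing cells, and one late bin (the
#' 10th, roughly the position of the Moscovian) at rate multiplier 2.5.
#' `scaled_scenario()` is the same design at reduced resolution for fast
#' simulation studies: ~24-40 taxa, 40 characters, 8 bins, spike in the
#' 6th bin.  Preset values are simulator choices, not estimates from any
#' empirical dataset.
#'
#' @param spike_bin index of the bin carrying the rate spike (`NA` for a
#'   constant-rate clade)
#' @param spike_multiplier rate multiplier of the spike bin
#' @param ... overrides passed on to [sim_scenario()]
#' @return a [sim_scenario()]
#' @export
paper_like_scenario <- function(spike_bin = 10, spike_multiplier = 2.5, ...) {
  m <- rep(1, 13)
  if (!is.na(spike_bin)) m[spike_bin] <- spike_multiplier
  args <- list(multipliers = m)
  args[names(list(...))] <- list(...)
  do.call(sim_scenario, args)
}

#' @rdname paper_like_scenario
#' @export
scaled_scenario <- function(spike_bin = 6, spike_multiplier = 2.5, ...) {
  ts <- sim_timescale(453, 254, 8)
  m <- rep(1, 8)
  if (!is.na(spike_bin)) m[spike_bin] <- spike_multiplier
  args <- list(birth = 0.03, death = 0.02, timescale = ts,
               n_characters = 40, multipliers = m, min_tips = 24,
               max_tips = 40)
  args[names(list(...))] <- list(...)
  do.call(sim_scenario, args)
}

#' Early-burst multiplier profile
#'
#' Geometrically declining per-bin multipliers emulating maximal rates at
#' the base of a clade's history followed by a slowdown.
#'
#' @param n_bins number of bins
#' @param start multiplier of the oldest bin
#' @param decay per-bin geometric decay factor in (0, 1)
#' @return numeric vector of length `n_bins`
#' @export
early_burst_multipliers <- function(n_bins, start = 3, decay = 0.7) {
  start * decay^(seq_len(n_bins) - 1)
}

#' Simulate a fossil birth-death tree
#'
#' Constant-rate birth-death realization started from one lineage at the
#' scenario origin and stopped at the youngest timescale boundary.  Every
#' extinct lineage leaves a fossil tip at its extinction age and lineages
#' alive at the stopping time leave tips there (complete-tree convention);
#' incomplete fossil recovery and tip-count capping are applied as
#' subsequent subsampling filters.
#'
#' @param s a [sim_scenario()]
#' @param seed RNG seed
#' @return a [time_tree()]; the stem length from the origin to the root
#'   node is stored in attribute `"stem_length"`
#' @export
simulate_tree <- function(s, seed = NULL) with_seed(seed, {
  t_end <- s$timescale$end_ma[nrow(s$timescale)]
  for (try in seq_len(s$max_retries)) {
    lin <- bd_realization(s$birth, s$death, s$origin_ma, t_end)
    if (is.null(lin)) next
    # accept only clades that persist to the end of the timescale, so the
    # realized tree spans the study interval like the clade it emulates
    if (!any(lin$fate == "surviving")) next
    tr <- lineages_to_tree(lin, s$origin_ma)
    if (is.null(tr)) next
    # fossil-recovery filter, then accept only trees inside the size window
    keep <- seq_len(n_tips(tr))
    if (s$recovery < 1)
      keep <- keep[runif(length(keep)) < s$recovery]
    if (length(keep) < s$min_tips || length(keep) > s$max_tips) next
    if (length(keep) < n_tips(tr)) tr <- subsample_tips(tr, keep)
    return(tr)
  }
  stop("birth-death process failed to yield >= ", s$min_tips,
       " recovered tips in ", s$max_retries, " retries")
})

# one birth-death realization; returns a data.frame of lineages
# (parent lineage id, start/end ages, fate) or NULL when the clade dies
# out as a single lineage immediately (handled by retry)
bd_realization <- function(birth, death, origin, t_end, max_lineages = 20000) {
  n_alloc <- 256L
  parent <- integer(n_alloc); start <- numeric(n_alloc)
  end <- numeric(n_alloc); fate <- character(n_alloc)
  parent[1] <- NA_integer_; start[1] <- origin
  n <- 1L
  stack <- 1L  # lineage ids awaiting their next event
  rate <- birth + death
  while (length(stack)) {
    id <- stack[length(stack)]; stack <- stack[-length(stack)]
    a <- start[id] - rexp(1L, rate)
    if (a <= t_end) {
      end[id] <- t_end; fate[id] <- "surviving"
      next
    }
    if (runif(1L) < birth / rate) {
      end[id] <- a; fate[id] <- "split"
      if (n + 2L > n_alloc) {
        n_alloc <- n_alloc * 2L
        length(parent) <- n_alloc; length(start) <- n_alloc
        length(end) <- n_alloc; length(fate) <- n_alloc
      }
      parent[n + 1L] <- id; start[n + 1L] <- a
      parent[n + 2L] <- id; start[n + 2L] <- a
      stack <- c(stack, n + 1L, n + 2L)
      n <- n + 2L
      if (n > max_lineages) stop("birth-death realization exploded (",
                                 max_lineages, " lineages)")
    } else {
      end[id] <- a; fate[id] <- "extinct"
    }
  }
  data.frame(parent = parent[seq_len(n)], start = start[seq_len(n)],
             end = end[seq_len(n)], fate = fate[seq_len(n)])
}

# convert the lineage table to a time_tree; NULL if the stem never splits
lineages_to_tree <- function(lin, origin) {
  if (lin$fate[1] != "split") return(NULL)
  L <- nrow(lin)
  kids <- split(seq_len(L)[-1L], lin$parent[-1L])
  is_tip <- lin$fate != "split"
  ntip <- sum(is_tip)
  if (ntip < 2L) return(NULL)
  num <- integer(L)
  next_int <- ntip + 1L; next_tip <- 1L
  stack <- 1L
  order_seen <- integer(0)
  while (length(stack)) {
    j <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (is_tip[j]) {
      num[j] <- next_tip; next_tip <- next_tip + 1L
    } else {
      num[j] <- next_int; next_int <- next_int + 1L
      stack <- c(stack, rev(kids[[as.character(j)]]))
    }
    order_seen <- c(order_seen, j)
  }
  idx <- order_seen[-1L]  # every lineage but the stem is an edge
  edge <- cbind(num[lin$parent[idx]], num[idx])
  phy <- list(edge = edge,
              edge.length = lin$start[idx] - lin$end[idx],
              tip.label = paste0("t", seq_len(ntip)),
              Nnode = L - ntip)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  ages <- numeric(ntip + phy$Nnode)
  ages[num] <- lin$end
  out <- structure(list(phy = phy, ages = ages), class = "time_tree")
  attr(out, "stem_length") <- origin - lin$end[1L]
  validate_time_tree(out)
}

#' Subsample tips of a time tree
#'
#' @param t a [time_tree()]
#' @param keep integer indices or labels of tips to keep
#' @return a [time_tree()] on the retained tips
#' @export
subsample_tips <- function(t, keep) {
  if (is.numeric(keep)) keep <- t$phy$tip.label[keep]
  kept_ages <- tip_ages(t)[keep]
  phy <- ape::keep.tip(t$phy, keep)
  time_tree(phy, tip_ages = kept_ages)
}

#' Simulate discrete characters on a time tree
#'
#' Each character evolves under a symmetric k-state Mk process whose
#' event rate while a lineage traverses bin `b` is `r0 * multipliers[b]`;
#' branches are sliced exactly at bin boundaries.  Every substitution
#' event moves to a uniformly chosen different state.  The root state is
#' uniform over states.  All realized events are recorded in a truth
#' ledger.
#'
#' @param t a [time_tree()]
#' @param s a [sim_scenario()]
#' @param seed RNG seed
#' @return list with elements `matrix` (a complete [character_matrix()]),
#'   and `ledger` (a `truth_ledger`: per-branch per-character change
#'   counts, per-bin totals, opportunity in character-Myr, true per-bin
#'   rates, and the base rate used)
#' @export
simulate_characters <- function(t, s, seed = NULL) with_seed(seed, {
  ts <- s$timescale
  ov <- edge_bin_overlap(t, ts)              # edges x bins, Myr
  dur <- branch_durations(t)
  r0 <- s$r0
  if (is.null(r0)) {
    tot <- sum(dur)
    if (tot <= 0) stop("tree has zero total branch time")
    r0 <- s$target_changes_per_character / tot
  }
  lam <- r0 * sweep(ov, 2L, s$multipliers, `*`)  # expected events per segment
  ne <- nrow(ov); nb <- ncol(ov); nc <- s$n_characters
  phy <- ape::reorder.phylo(t$phy, "cladewise")  # parents before children
  ntip <- n_tips(t)
  kvec <- if (length(s$state_range) == 1L) rep(s$state_range, nc)
          else sample(s$state_range, nc, replace = TRUE)
  tipmat <- matrix(NA_character_, ntip, nc,
                   dimnames = list(phy$tip.label, NULL))
  per_branch <- matrix(0L, ne, nc)               # rows follow t$phy$edge
  per_bin_changes <- matrix(0L, nb, nc)
  eo <- match(paste(phy$edge[, 1], phy$edge[, 2]),
              paste(t$phy$edge[, 1], t$phy$edge[, 2]))
  for (ch in seq_len(nc)) {
    k <- kvec[ch]
    nev <- matrix(rpois(ne * nb, lam), ne, nb)
    per_branch[, ch] <- rowSums(nev)
    per_bin_changes[, ch] <- colSums(nev)
    state <- integer(ntip + phy$Nnode)
    state[ntip + 1L] <- sample.int(k, 1L)
    for (e in seq_len(nrow(phy$edge))) {
      stt <- state[phy$edge[e, 1]]
      n_ev <- per_branch[eo[e], ch]
      if (n_ev > 0L) for (i in seq_len(n_ev)) {
        j <- sample.int(k - 1L, 1L)      # uniform over the other k-1 states
        stt <- j + (j >= stt)
      }
      state[phy$edge[e, 2]] <- stt
    }
    tipmat[, ch] <- as.character(state[seq_len(ntip)] - 1L)
  }
  ledger <- list(per_branch = per_branch,
                 per_bin = data.frame(
                   bin = ts$name,
                   changes = rowSums(per_bin_changes),
                   branch_time_myr = colSums(ov),
                   opportunity = colSums(ov) * nc,
                   true_rate = ifelse(colSums(ov) > 0,
                                      rowSums(per_bin_changes) /
                                        (colSums(ov) * nc), NA_real_)),
                 total_changes = sum(per_branch),
                 r0 = r0, multipliers = s$multipliers, k = kvec)
  class(ledger) <- "truth_ledger"
  list(matrix = character_matrix(tipmat), ledger = ledger)
})

#' @export
print.truth_ledger <- function(x, ...) {
  cat(sprintf("truth_ledger: %d realized changes, base rate %.3g /char/Myr\n",
              x$total_changes, x$r0))
  print(x$per_bin, ...)
  invisible(x)
}

#' Recode random cells as missing
#'
#' Each cell is independently set to `NA` with probability `p_miss`,
#' emulating missing or inapplicable codings.
#'
#' @param m a [character_matrix()]
#' @param p_miss per-cell missing probability
#' @param seed RNG seed
#' @return a [character_matrix()]
#' @export
inject_missing <- function(m, p_miss, seed = NULL) with_seed(seed, {
  stopifnot(p_miss >= 0, p_miss <= 1)
  x <- unclass(m)
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x[runif(length(x)) < p_miss] <- NA_character_
  character_matrix(x)
})

#' Posterior-like tree samples by node-age jitter
#'
#' Produces copies of a tree whose internal node ages are independently
#' perturbed with truncated Gaussian noise while the topology and tip
#' ages stay fixed.  Working from the root down, each internal node's new
#' age is drawn from a normal centred on its original age, truncated
#' below by the oldest tip age in its subtree and above by its parent's
#' (already jittered) age, so age monotonicity always holds.
#'
#' @param t a [time_tree()]
#' @param n_trees number of jittered copies
#' @param age_jitter_sd jitter standard deviation (Myr); `0` returns
#'   identical copies
#' @param max_root_age upper truncation for the root age (Ma), e.g. the
#'   clade origin
#' @param seed RNG seed
#' @return a list of [time_tree()]
#' @export
make_posterior_like <- function(t, n_trees, age_jitter_sd,
                                max_root_age = Inf, seed = NULL)
  with_seed(seed, {
  stopifnot(n_trees >= 1, age_jitter_sd >= 0)
  phy <- ape::reorder.phylo(t$phy, "cladewise")
  ntip <- n_tips(t)
  ntot <- ntip + phy$Nnode
  parent_of <- integer(ntot)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  # oldest tip age in each node's subtree (postorder accumulate)
  min_feasible <- c(t$ages[seq_len(ntip)], rep(-Inf, phy$Nnode))
  for (e in rev(seq_len(nrow(phy$edge)))) {
    p <- phy$edge[e, 1]; c2 <- phy$edge[e, 2]
    min_feasible[p] <- max(min_feasible[p], min_feasible[c2])
  }
  internal_preorder <- unique(phy$edge[, 1])
  out <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    ages <- t$ages
    if (age_jitter_sd > 0) {
      for (n in internal_preorder) {
        lo <- min_feasible[n]
        hi <- if (n == ntip + 1L) max_root_age else ages[parent_of[n]]
        p_lo <- pnorm(lo, ages[n], age_jitter_sd)
        p_hi <- pnorm(hi, ages[n], age_jitter_sd)
        if (p_hi - p_lo < 1e-12) {
          ages[n] <- min(max(ages[n], lo), hi)
        } else {
          ages[n] <- qnorm(runif(1L, p_lo, p_hi), ages[n], age_jitter_sd)
          ages[n] <- min(max(ages[n], lo), hi)
        }
      }
    }
    phy2 <- phy
    phy2$edge.length <- ages[phy2$edge[, 1]] - ages[phy2$edge[, 2]]
    out[[i]] <- structure(list(phy = phy2, ages = ages), class = "time_tree")
  }
  out
})

#' Stratigraphic ranges implied by a simulated tree
#'
#' Treats each tip's terminal branch as its observable stratigraphic
#' range: a taxon's first appearance is the bin containing the origin of
#' its terminal branch and its last appearance the bin containing its tip
#' age.
#'
#' @param t a [time_tree()]
#' @param ts a [timescale()]
#' @return a [strat_ranges()]
#' @export
sim_ranges <- function(t, ts) {
  ntip <- n_tips(t)
  e <- t$phy$edge
  term <- match(seq_len(ntip), e[, 2])
  top <- pmin(t$ages[e[term, 1]], ts$start_ma[1L])
  bot <- pmax(t$ages[seq_len(ntip)], ts$end_ma[nrow(ts)])
  strat_ranges(t$phy$tip.label, bin_index(ts, top), bin_index(ts, bot),
               ts = ts)
}

#' Simulate a complete synthetic study clade
#'
#' Convenience wrapper chaining [simulate_tree()],
#' [simulate_characters()], [inject_missing()], [make_posterior_like()]
#' and [sim_ranges()] under a single seed.
#'
#' @param s a [sim_scenario()]
#' @param n_trees size of the posterior-like tree sample
#' @param age_jitter_sd node-age jitter SD (Myr)
#' @param seed RNG seed
#' @return a list with `tree`, `trees` (jittered sample), `matrix` (with
#'   missing data), `matrix_complete`, `ledger`, `ranges`, and `scenario`
#' @export
simulate_clade <- function(s, n_trees = 25, age_jitter_sd = 2, seed = NULL)
  with_seed(seed, {
  tr <- simulate_tree(s)
  sim <- simulate_characters(tr, s)
  miss <- inject_missing(sim$matrix, s$p_miss)
  trees <- make_posterior_like(tr, n_trees, age_jitter_sd,
                               max_root_age = s$origin_ma)
  list(tree = tr, trees = trees, matrix = miss,
       matrix_complete = sim$matrix, ledger = sim$ledger,
       ranges = sim_ranges(tr, s$timescale), scenario = s)
})
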