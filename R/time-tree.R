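#' Time-calibrated trees
#'
#' A `time_tree` wraps an [ape::phylo] tree with absolute node ages in Ma
#' before present.  Branch durations equal `age(parent) - age(child)` and
#' are never negative; zero-length branches are legal and represent
#' sampled ancestors.  Tip ages are the assigned fossil occurrence times.
#'
#' Because Newick/NEXUS branch lengths only fix relative depths, absolute
#' ages must be anchored by exactly one of: a table of known `tip_ages`
#' (named vector, Ma), a `root_age`, or the age of the youngest tip
#' (`youngest_tip_age`).  Ages are never guessed.
#'
#' @param phy a rooted [ape::phylo] with branch lengths in Myr
#' @param tip_ages named numeric vector of tip ages (Ma); all names must
#'   be tip labels and the implied root ages must agree to `tol`
#' @param root_age numeric root age (Ma)
#' @param youngest_tip_age age of the youngest tip (Ma)
#' @param tol consistency tolerance in Myr
#' @return an object of class `time_tree`: a list with elements `phy` and
#'   `ages` (numeric vector over all nodes in ape numbering)
#' @export
time_tree <- function(phy, tip_ages = NULL, root_age = NULL,
                      youngest_tip_age = NULL, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape 'phylo' tree")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length < -tol)) stop("negative branch lengths")
  phy$edge.length[phy$edge.length < 0] <- 0
  depth <- ape::node.depth.edgelength(phy)  # root-to-node path length
  ntip <- length(phy$tip.label)
  if (!is.null(root_age)) {
    ra <- root_age
  } else if (!is.null(tip_ages)) {
    idx <- match(names(tip_ages), phy$tip.label)
    if (anyNA(idx))
      stop("tip_ages names not in tree: ",
           paste(names(tip_ages)[is.na(idx)], collapse = ", "))
    ras <- depth[idx] + tip_ages
    if (diff(range(ras)) > max(tol, 1e-6 * max(abs(ras))))
      stop("tip ages are inconsistent with branch lengths ",
           "(implied root ages differ by ", signif(diff(range(ras)), 3),
           " Myr)")
    ra <- mean(ras)
  } else if (!is.null(youngest_tip_age)) {
    ra <- max(depth[seq_len(ntip)]) + youngest_tip_age
  } else {
    stop("cannot anchor node ages: supply tip_ages, root_age or ",
         "youngest_tip_age")
  }
  ages <- ra - depth
  out <- structure(list(phy = phy, ages = ages), class = "time_tree")
  validate_time_tree(out, tol = tol)
  out
}

validate_time_tree <- function(t, tol = 1e-6) {
  e <- t$phy$edge
  dur <- t$ages[e[, 1]] - t$ages[e[, 2]]
  if (any(dur < -tol)) stop("node ages increase from root to tips")
  if (any(abs(dur - t$phy$edge.length) > max(tol, 1e-6)))
    stop("branch lengths disagree with node age differences")
  invisible(t)
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf("time_tree: %d tips, root age %.2f Ma, youngest tip %.2f Ma\n",
              n_tips(x), root_age(x), min(tip_ages(x))))
  invisible(x)
}

#' @rdname time_tree
#' @param t a `time_tree`
#' @export
n_tips <- function(t) length(t$phy$tip.label)

#' @rdname time_tree
#' @export
tip_ages <- function(t) setNames(t$ages[seq_len(n_tips(t))], t$phy$tip.label)

#' @rdname time_tree
#' @export
root_age <- function(t) t$ages[n_tips(t) + 1L]

#' @rdname time_tree
#' @export
branch_durations <- function(t) t$ages[t$phy$edge[, 1]] - t$ages[t$phy$edge[, 2]]

#' Read a sample of time-calibrated trees
#'
#' Reads NEXUS or Newick trees (auto-detected), optionally draws a random
#' subsample without replacement, and anchors absolute node ages.
#'
#' @param path tree file (NEXUS `TREES` block or plain Newick); branch
#'   lengths must be present and in Myr
#' @param n_sample number of trees to draw uniformly without replacement
#'   (all trees, if `NULL` or more than available)
#' @param seed RNG seed for the subsample
#' @inheritParams time_tree
#' @return a list of [time_tree()] objects
#' @export
read_trees <- function(path, n_sample = NULL, seed = NULL, tip_ages = NULL,
                       root_age = NULL, youngest_tip_age = NULL) {
  first <- readLines(path, n = 1L)
  trees <- if (grepl("#NEXUS", first, ignore.case = TRUE))
    ape::read.nexus(path) else ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  if (length(trees) == 0L) stop("no trees found in ", path)
  for (tr in trees) if (is.null(tr$edge.length))
    stop("tree file ", path, " has trees without branch lengths")
  if (!is.null(n_sample) && n_sample < length(trees)) {
    keep <- with_seed(seed, sample.int(length(trees), n_sample))
    trees <- trees[sort(keep)]
  }
  lapply(trees, time_tree, tip_ages = tip_ages, root_age = root_age,
         youngest_tip_age = youngest_tip_age)
}

#' Write trees to a file
#'
#' @param trees a list of [time_tree()] (or a single one)
#' @param path output path; `.nex` writes a NEXUS TREES block, anything
#'   else plain Newick
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "time_tree")) trees <- list(trees)
  phys <- lapply(trees, function(t) t$phy)
  class(phys) <- "multiPhylo"
  if (grepl("\\.nex(us)?$", path, ignore.case = TRUE))
    ape::write.nexus(phys, file = path)
  else ape::write.tree(phys, file = path)
  invisible(path)
}

# internal: per-edge overlap (Myr) with every bin of a timescale.
# Returns an edges x bins matrix.  Errors if any positive-duration branch
# lies (partly) outside the timescale span.
edge_bin_overlap <- function(t, ts, tol = 1e-8) {
  e <- t$phy$edge
  a_top <- t$ages[e[, 1]]
  a_bot <- t$ages[e[, 2]]
  span_old <- ts$start_ma[1L] + tol
  span_yng <- ts$end_ma[nrow(ts)] - tol
  out_of_span <- a_top > span_old | a_bot < span_yng
  if (any(out_of_span & (a_top - a_bot) > tol))
    stop(sprintf(paste0("branch %d (%.2f-%.2f Ma) lies outside the ",
                        "timescale span %.2f-%.2f Ma"),
                 which(out_of_span)[1L],
                 a_top[which(out_of_span)[1L]], a_bot[which(out_of_span)[1L]],
                 ts$start_ma[1L], ts$end_ma[nrow(ts)]))
  ov <- outer(a_top, ts$start_ma, pmin) - outer(a_bot, ts$end_ma, pmax)
  ov[ov < 0] <- 0
  colnames(ov) <- ts$name
  ov
}
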