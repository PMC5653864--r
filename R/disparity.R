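#' Gower distances between taxa
#'
#' Pairwise distance between two taxa: the number of comparable
#' characters (scored in both) in which their states differ, divided by
#' the number of comparable characters.  This is the complement of the
#' Gower similarity coefficient, which normalises each pairwise
#' comparison by the number of characters codable in both taxa; for a
#' complete binary matrix it reduces exactly to Hamming distance divided
#' by the number of characters.  Missing cells are excluded from both
#' numerator and denominator.
#'
#' @param m a [character_matrix()]
#' @param exclude_invariant drop invariant characters before computing
#'   distances (they cannot contribute differences)
#' @return an object of class `gower_dist`: list with `d` (symmetric
#'   matrix in `[0,1]`, `NA` where a pair shares no comparable character)
#'   and `n_comparable` (matrix of comparable-character counts).  Pairs
#'   with no comparable characters are also listed in attribute
#'   `"undefined_pairs"`.
#' @export
gower_distance <- function(m, exclude_invariant = TRUE) {
  stopifnot(nrow(m) >= 2)
  x <- unclass(m)
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  if (exclude_invariant) x <- x[, informative_characters(m), drop = FALSE]
  n <- nrow(x)
  scored <- !is.na(x)
  # comparable counts via matrix product on the scored indicator
  ncomp <- tcrossprod(scored * 1)
  diff <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (j in seq_len(ncol(x))) {
    s <- x[, j]
    ok <- !is.na(s)
    neq <- outer(s[ok], s[ok], `!=`)
    diff[ok, ok] <- diff[ok, ok] + neq
  }
  d <- ifelse(ncomp > 0, diff / ncomp, NA_real_)
  diag(d) <- 0
  und <- which(ncomp == 0 & upper.tri(ncomp), arr.ind = TRUE)
  undefined <- if (nrow(und))
    data.frame(taxon_i = rownames(x)[und[, 1]],
               taxon_j = rownames(x)[und[, 2]]) else NULL
  out <- list(d = d, n_comparable = ncomp, taxa = rownames(x))
  attr(out, "undefined_pairs") <- undefined
  class(out) <- "gower_dist"
  out
}

#' @export
print.gower_dist <- function(x, ...) {
  cat(sprintf("gower_dist: %d taxa, distances %.3f-%.3f\n",
              length(x$taxa), min(x$d, na.rm = TRUE), max(x$d, na.rm = TRUE)))
  nu <- nrow(attr(x, "undefined_pairs") %||% data.frame())
  if (nu) cat(nu, "pair(s) share no comparable character\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean-squared-distance disparity
#'
#' Morphological disparity of a taxon set: the mean of squared pairwise
#' distances over all unordered pairs.
#'
#' @param d a [gower_distance()] result (or a plain symmetric matrix)
#' @param taxa taxa to include (default: all); duplicates are allowed and
#'   arise naturally under bootstrap resampling
#' @return disparity value (`NA` for fewer than 2 taxa)
#' @export
msd_disparity <- function(d, taxa = NULL) {
  dm <- if (inherits(d, "gower_dist")) d$d else d
  if (is.null(taxa)) taxa <- rownames(dm)
  n <- length(taxa)
  if (n < 2) return(NA_real_)
  sub <- dm[taxa, taxa, drop = FALSE]
  if (anyNA(sub)) {
    bad <- which(is.na(sub) & upper.tri(sub), arr.ind = TRUE)
    stop("undefined distance for pair(s): ",
         paste(paste(taxa[bad[, 1]], taxa[bad[, 2]], sep = " / "),
               collapse = ", "))
  }
  sum(sub[upper.tri(sub)]^2) / (n * (n - 1) / 2)
}

#' Disparity through time with bootstrap intervals
#'
#' Computes mean-squared-distance disparity for the taxa occupying each
#' time bin, with uncertainty from resampling taxa (with replacement)
#' within each bin.
#'
#' @param d a [gower_distance()] result
#' @param membership named list mapping bin names to character vectors of
#'   taxa (a taxon may occupy several bins, e.g. range-through)
#' @param n_boot bootstrap replicates
#' @param seed RNG seed
#' @param conf interval coverage
#' @return a `disparity_series` data frame: per bin `n_taxa`,
#'   `disparity` (point estimate; `NA` when `n_taxa < 2`), `boot_mean`,
#'   `lo`, `hi`
#' @export
disparity_series <- function(d, membership, n_boot = 1000, seed = NULL,
                             conf = 0.95) with_seed(seed, {
  a <- (1 - conf) / 2
  rows <- lapply(names(membership), function(bn) {
    taxa <- membership[[bn]]
    n <- length(taxa)
    if (n < 2)
      return(data.frame(bin = bn, n_taxa = n, disparity = NA_real_,
                        boot_mean = NA_real_, lo = NA_real_, hi = NA_real_))
    point <- msd_disparity(d, taxa)
    boot <- vapply(seq_len(n_boot), function(i)
      msd_disparity(d, sample(taxa, n, replace = TRUE)), numeric(1))
    data.frame(bin = bn, n_taxa = n, disparity = point,
               boot_mean = mean(boot),
               lo = quantile(boot, a, names = FALSE),
               hi = quantile(boot, 1 - a, names = FALSE))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("disparity_series", "data.frame")
  out
})

#' Range-through bin membership
#'
#' Expands stratigraphic ranges into a bin -> taxa membership list: a
#' taxon occupies every bin its range crosses.
#'
#' @param r a [strat_ranges()]
#' @param ts a [timescale()]
#' @return named list of taxon vectors, one per bin
#' @export
bin_membership <- function(r, ts) {
  out <- lapply(seq_len(nrow(ts)), function(b)
    r$taxon[r$first_bin <= b & r$last_bin >= b])
  names(out) <- ts$name
  out
}
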