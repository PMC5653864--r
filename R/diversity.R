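#' Range-through taxonomic diversity
#'
#' Counts, for every bin of a timescale, the taxa whose stratigraphic
#' range (first to last appearance, inclusive) covers the bin.
#'
#' @param r a [strat_ranges()]
#' @param ts a [timescale()]
#' @return named integer vector of per-bin counts
#' @export
range_through_counts <- function(r, ts) {
  if (any(r$first_bin < 1L | r$last_bin > nrow(ts)))
    stop("ranges reference bins outside the timescale for: ",
         paste(r$taxon[r$first_bin < 1L | r$last_bin > nrow(ts)],
               collapse = ", "))
  counts <- vapply(seq_len(nrow(ts)), function(b)
    sum(r$first_bin <= b & r$last_bin >= b), integer(1))
  setNames(counts, ts$name)
}

#' Bootstrap intervals for range-through diversity
#'
#' Monte-Carlo uncertainty: taxa are resampled with replacement and the
#' range-through counts recomputed.
#'
#' @inheritParams range_through_counts
#' @param n_boot bootstrap replicates
#' @param seed RNG seed
#' @param conf interval coverage
#' @return a `diversity_series` data frame: per bin `count`, `boot_mean`,
#'   `lo`, `hi`
#' @export
bootstrap_counts <- function(r, ts, n_boot = 1000, seed = NULL,
                             conf = 0.95) with_seed(seed, {
  stopifnot(nrow(r) >= 2)
  a <- (1 - conf) / 2
  point <- range_through_counts(r, ts)
  boot <- vapply(seq_len(n_boot), function(i)
    range_through_counts(r[sample(nrow(r), replace = TRUE), ], ts),
    numeric(nrow(ts)))
  out <- data.frame(bin = ts$name, count = as.integer(point),
                    boot_mean = rowMeans(boot),
                    lo = apply(boot, 1, quantile, a, names = FALSE),
                    hi = apply(boot, 1, quantile, 1 - a, names = FALSE))
  class(out) <- c("diversity_series", "data.frame")
  out
})

#' Range standardization to [0, 1]
#'
#' Affine rescaling `(x - min(x)) / (max(x) - min(x))`; the minimum maps
#' to 0 and the maximum to 1 exactly.
#'
#' @param x numeric series with at least two distinct values (`NA`
#'   ignored for the range, preserved in the output)
#' @return rescaled series
#' @export
range_standardize <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || r[1] == r[2])
    stop("cannot range-standardize a constant series")
  (x - r[1]) / (r[2] - r[1])
}

#' Diversity-disparity trajectory
#'
#' Places each time bin in diversity-disparity space: `x` is the
#' range-standardized natural log of the range-through count, `y` the
#' range-standardized disparity.  Under constant-rate Brownian-motion
#' evolution the log transform makes the expected trajectory linear, so
#' the 1:1 diagonal is the null expectation; a bin above the line has
#' disparity outpacing diversification.  When the raw inputs (`ranges`,
#' `d`, `membership`) are supplied, a paired bootstrap (taxa resampled
#' once per replicate for diversity and within bins for disparity)
#' yields a percentile interval for the deviation `y - x`, and a bin is
#' classified `"above"`/`"below"` only when that interval excludes 0.
#'
#' @param div a [bootstrap_counts()] diversity series (or named count
#'   vector)
#' @param disp a [disparity_series()]
#' @param ranges,ts,d,membership optional raw inputs enabling the paired
#'   bootstrap (see [bootstrap_counts()], [disparity_series()])
#' @param n_boot bootstrap replicates
#' @param seed RNG seed
#' @param conf interval coverage
#' @return a `dd_trajectory` data frame: per usable bin `x`, `y`,
#'   `deviation`, `dev_lo`, `dev_hi` and `position`
#'   (`"above"`/`"on"`/`"below"`).  Bins without defined disparity or
#'   with zero diversity are excluded and listed in attribute
#'   `"excluded_bins"`.
#' @export
dd_trajectory <- function(div, disp, ranges = NULL, ts = NULL, d = NULL,
                          membership = NULL, n_boot = 1000, seed = NULL,
                          conf = 0.95) with_seed(seed, {
  counts <- if (is.data.frame(div)) setNames(div$count, div$bin) else div
  dvals <- setNames(disp$disparity, disp$bin)
  bins <- intersect(names(counts), names(dvals))
  use <- bins[!is.na(dvals[bins]) & counts[bins] >= 1]
  excluded <- setdiff(bins, use)
  if (length(use) < 2) stop("fewer than 2 usable bins")
  x <- range_standardize(log(counts[use]))
  y <- range_standardize(dvals[use])
  dev <- y - x
  out <- data.frame(bin = use, x = x, y = y, deviation = dev,
                    dev_lo = NA_real_, dev_hi = NA_real_,
                    position = "on", row.names = NULL)
  if (!is.null(ranges) && !is.null(d) && !is.null(membership)) {
    a <- (1 - conf) / 2
    devb <- matrix(NA_real_, n_boot, length(use))
    for (i in seq_len(n_boot)) {
      rb <- ranges[sample(nrow(ranges), replace = TRUE), ]
      cb <- range_through_counts(rb, ts)[use]
      db <- vapply(use, function(bn) {
        taxa <- membership[[bn]]
        if (length(taxa) < 2) return(NA_real_)
        msd_disparity(d, sample(taxa, length(taxa), replace = TRUE))
      }, numeric(1))
      ok <- cb >= 1 & !is.na(db)
      if (sum(ok) < 2) next
      xb <- yb <- rep(NA_real_, length(use))
      xb[ok] <- tryCatch(range_standardize(log(cb[ok])),
                         error = function(e) rep(NA_real_, sum(ok)))
      yb[ok] <- tryCatch(range_standardize(db[ok]),
                         error = function(e) rep(NA_real_, sum(ok)))
      devb[i, ] <- yb - xb
    }
    out$dev_lo <- apply(devb, 2, quantile, a, na.rm = TRUE, names = FALSE)
    out$dev_hi <- apply(devb, 2, quantile, 1 - a, na.rm = TRUE, names = FALSE)
    out$position <- ifelse(out$dev_lo > 0, "above",
                           ifelse(out$dev_hi < 0, "below", "on"))
  }
  attr(out, "excluded_bins") <- excluded
  class(out) <- c("dd_trajectory", "data.frame")
  out
})
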