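#' Chronostratigraphic timescales
#'
#' A `timescale` is an ordered table of contiguous, non-overlapping time
#' bins running from old to young.  Each bin has a `name`, an older
#' boundary `start_ma` and a younger boundary `end_ma` (Ma before present,
#' so `start_ma > end_ma`), and bin `i`'s `end_ma` equals bin `i + 1`'s
#' `start_ma`.
#'
#' @param name character vector of bin names
#' @param start_ma numeric vector of older boundaries (Ma)
#' @param end_ma numeric vector of younger boundaries (Ma)
#' @return a `timescale` data frame with columns `name`, `start_ma`,
#'   `end_ma`
#' @examples
#' timescale(c("old", "young"), c(100, 50), c(50, 10))
#' @export
timescale <- function(name, start_ma, end_ma) {
  ts <- data.frame(name = as.character(name),
                   start_ma = as.numeric(start_ma),
                   end_ma = as.numeric(end_ma))
  if (nrow(ts) < 1L) stop("timescale needs at least one bin")
  if (anyDuplicated(ts$name)) stop("duplicate bin names")
  if (any(ts$start_ma <= ts$end_ma))
    stop("each bin must have start_ma > end_ma (Ma before present)")
  if (nrow(ts) > 1L) {
    gap <- abs(ts$end_ma[-nrow(ts)] - ts$start_ma[-1L])
    if (any(gap > 1e-8))
      stop("bins must be contiguous and ordered old to young")
  }
  class(ts) <- c("timescale", "data.frame")
  ts
}

#' @export
print.timescale <- function(x, ...) {
  cat(sprintf("timescale: %d bins, %.2f-%.2f Ma\n",
              nrow(x), x$start_ma[1], x$end_ma[nrow(x)]))
  print.data.frame(x, ...)
  invisible(x)
}

#' @rdname timescale
#' @param ts a `timescale`
#' @export
bin_midpoints <- function(ts) setNames((ts$start_ma + ts$end_ma) / 2, ts$name)

#' @rdname timescale
#' @export
bin_durations <- function(ts) setNames(ts$start_ma - ts$end_ma, ts$name)

#' Locate the bin containing an age
#'
#' Ages on a boundary belong to the younger bin, except the oldest
#' boundary; the youngest bin is closed at both ends.
#'
#' @param ts a [timescale()]
#' @param age numeric vector of ages (Ma)
#' @return integer bin indices (`NA` outside the timescale span)
#' @export
bin_index <- function(ts, age) {
  idx <- vapply(age, function(a) {
    if (is.na(a)) return(NA_integer_)
    hit <- which(a <= ts$start_ma & a > ts$end_ma)
    if (length(hit)) return(hit[1L])
    if (abs(a - ts$end_ma[nrow(ts)]) <= 1e-9) return(nrow(ts))
    if (abs(a - ts$start_ma[1L]) <= 1e-9) return(1L)
    NA_integer_
  }, integer(1))
  idx
}

#' Default Palaeozoic timescale (Katian to Wuchiapingian)
#'
#' Stage-level bins on 2016 chronostratigraphic boundary ages, with the
#' Silurian binned at series level and the Carboniferous at subperiod
#' level (Mississippian / Pennsylvanian) so that bin durations stay
#' broadly comparable across the span.  Boundary ages are editable data,
#' not hard-coded truth: pass your own table via [timescale()] or
#' [read_timescale()] to change the binning.
#'
#' @return a [timescale()] of 23 bins spanning 453-254.2 Ma
#' @export
default_timescale <- function() {
  timescale(
    name = c("Katian", "Hirnantian",
             "Llandovery", "Wenlock", "Ludlow", "Pridoli",
             "Lochkovian", "Pragian", "Emsian", "Eifelian", "Givetian",
             "Frasnian", "Famennian",
             "Mississippian", "Pennsylvanian",
             "Asselian", "Sakmarian", "Artinskian", "Kungurian",
             "Roadian", "Wordian", "Capitanian", "Wuchiapingian"),
    start_ma = c(453.0, 445.2, 443.8, 433.4, 427.4, 423.0,
                 419.2, 410.8, 407.6, 393.3, 387.7, 382.7, 372.2,
                 358.9, 323.2,
                 298.9, 295.0, 290.1, 283.5, 272.3, 268.8, 265.1, 259.8),
    end_ma = c(445.2, 443.8, 433.4, 427.4, 423.0, 419.2,
               410.8, 407.6, 393.3, 387.7, 382.7, 372.2, 358.9,
               323.2, 298.9,
               295.0, 290.1, 283.5, 272.3, 268.8, 265.1, 259.8, 254.2))
}

#' Equal-width timescale for simulation studies
#'
#' @param origin_ma older end of the span (Ma)
#' @param end_ma younger end of the span (Ma)
#' @param n_bins number of equal-width bins
#' @return a [timescale()]
#' @export
sim_timescale <- function(origin_ma = 453, end_ma = 254, n_bins = 13) {
  b <- seq(origin_ma, end_ma, length.out = n_bins + 1L)
  timescale(sprintf("bin%02d", seq_len(n_bins)), b[-length(b)], b[-1L])
}

#' Read / write a timescale table
#'
#' Accepts tab-separated tables or JSON arrays with fields `name`,
#' `start_ma`, `end_ma`.
#'
#' @param path file path (`.json` or tab-separated text)
#' @return a [timescale()]
#' @export
read_timescale <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  }
  need <- c("name", "start_ma", "end_ma")
  if (!all(need %in% names(df)))
    stop("timescale table needs columns: ", paste(need, collapse = ", "))
  timescale(df$name, df$start_ma, df$end_ma)
}

#' @rdname read_timescale
#' @param ts a [timescale()]
#' @export
write_timescale <- function(ts, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(unclass(ts)), path, digits = NA)
  } else {
    write.table(ts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Stratigraphic ranges
#'
#' First and last appearance bins per taxon (or genus), referencing bins
#' of a [timescale()] by index (old to young).  Under the range-through
#' assumption a taxon is present in every bin between its first and last
#' appearance inclusive.
#'
#' @param taxon character vector of taxon labels
#' @param first_bin,last_bin integer bin indices (or bin names resolved
#'   against `ts`)
#' @param ts optional [timescale()] used to resolve bin names and validate
#'   indices
#' @return a `strat_ranges` data frame
#' @export
strat_ranges <- function(taxon, first_bin, last_bin, ts = NULL) {
  if (!is.null(ts)) {
    if (is.character(first_bin)) first_bin <- match(first_bin, ts$name)
    if (is.character(last_bin)) last_bin <- match(last_bin, ts$name)
    bad <- is.na(first_bin) | is.na(last_bin) |
      first_bin < 1L | last_bin > nrow(ts)
    if (any(bad))
      stop("ranges reference unknown bins for: ",
           paste(taxon[bad], collapse = ", "))
  }
  first_bin <- as.integer(first_bin)
  last_bin <- as.integer(last_bin)
  if (any(first_bin > last_bin))
    stop("first appearance after last appearance for: ",
         paste(taxon[first_bin > last_bin], collapse = ", "))
  r <- data.frame(taxon = as.character(taxon), first_bin = first_bin,
                  last_bin = last_bin)
  class(r) <- c("strat_ranges", "data.frame")
  r
}

#' @rdname strat_ranges
#' @param path tab-separated file with columns `taxon`, `first_bin`,
#'   `last_bin`
#' @export
read_strat_ranges <- function(path, ts = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  strat_ranges(df$taxon, df$first_bin, df$last_bin, ts = ts)
}
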