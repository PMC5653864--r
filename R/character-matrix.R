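#' Discrete morphological character matrices
#'
#' A `character_matrix` holds a taxa-by-characters table of discrete,
#' unordered state tokens with `NA` for missing or inapplicable cells.
#' State symbols are compared as tokens, never as numbers, so `"0"`, `"a"`
#' and `"12"` are all legal states.  Characters with fewer than two
#' distinct observed states among scored cells are flagged uninformative
#' (invariant) and are excluded from rate and disparity computations.
#'
#' @param x a character matrix (taxa in rows, characters in columns) with
#'   row names giving unique taxon labels.  `NA` marks missing cells.
#' @return an object of class `character_matrix`: a character matrix with
#'   attributes `state_symbols` (per-character sorted vector of observed
#'   symbols) and `informative` (logical per character).
#' @examples
#' m <- character_matrix(rbind(A = c("0", "1"), B = c("1", "1")))
#' informative_characters(m)
#' @export
character_matrix <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "character"
  if (is.null(rownames(x))) stop("taxon labels (row names) are required")
  if (anyDuplicated(rownames(x)))
    stop("duplicate taxon labels: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (ncol(x) < 1L) stop("matrix has no characters")
  syms <- lapply(seq_len(ncol(x)), function(j) sort(unique(x[!is.na(x[, j]), j])))
  attr(x, "state_symbols") <- syms
  attr(x, "informative") <- vapply(syms, function(s) length(s) >= 2L, logical(1))
  class(x) <- c("character_matrix", "matrix")
  x
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d taxa x %d characters (%d informative)\n",
              nrow(x), ncol(x), sum(informative_characters(x))))
  ms <- missing_data_summary(x)
  cat(sprintf("missing cells: %.1f%% overall\n", 100 * ms$overall))
  invisible(x)
}

#' @rdname character_matrix
#' @param m a `character_matrix`
#' @export
informative_characters <- function(m) attr(m, "informative")

#' @rdname character_matrix
#' @export
state_symbols <- function(m) attr(m, "state_symbols")

#' Summarise missing data in a character matrix
#'
#' @param m a [character_matrix()]
#' @return a list with `per_taxon` and `per_character` missing fractions
#'   (named numeric vectors) and the `overall` fraction.  For a rectangular
#'   matrix the overall fraction equals the mean of either marginal.
#' @export
missing_data_summary <- function(m) {
  na <- is.na(unclass(m))
  list(per_taxon = rowMeans(na),
       per_character = colMeans(na),
       overall = mean(na))
}

#' Read a NEXUS discrete character matrix
#'
#' Parses the DATA/CHARACTERS block of a NEXUS file.  `?` (missing) and
#' `-` (inapplicable/gap) are both mapped to `NA`, and polymorphic codings
#' such as `{01}` are conservatively reduced to `NA` as well; the number of
#' cells so reduced is recorded in the `"n_polymorphic"` attribute.
#'
#' @param path path to a NEXUS file
#' @return a [character_matrix()]
#' @export
read_nexus_matrix <- function(path) {
  raw <- tryCatch(ape::read.nexus.data(path),
                  error = function(e) stop("failed to parse NEXUS matrix '",
                                           path, "': ", conditionMessage(e),
                                           call. = FALSE))
  x <- do.call(rbind, lapply(raw, as.character))
  rownames(x) <- names(raw)
  poly <- grepl("/", x, fixed = TRUE)
  x[x %in% c("?", "-", "N", "n") | poly] <- NA_character_
  m <- character_matrix(x)
  attr(m, "n_polymorphic") <- sum(poly)
  m
}

#' Write a character matrix to NEXUS
#'
#' Single-token state symbols are written inline; `NA` cells are written as
#' `?`.  The output round-trips through [read_nexus_matrix()].
#'
#' @param m a [character_matrix()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_nexus_matrix <- function(m, path) {
  syms <- sort(unique(unlist(state_symbols(m))))
  if (any(nchar(syms) != 1L))
    stop("NEXUS export requires single-character state symbols")
  rows <- apply(unclass(m), 1L, function(r) {
    r[is.na(r)] <- "?"
    paste(r, collapse = "")
  })
  lab <- sprintf("%-*s", max(nchar(rownames(m))) + 2L, rownames(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
    sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
            paste(syms, collapse = " ")),
    "  MATRIX",
    paste0("    ", lab, rows),
    "  ;",
    "END;"), con)
  invisible(path)
}

# internal: integer-coded copy of the matrix for the Mk machinery.
# Returns tip_states (0-based integers, -1 = missing) and k per character,
# restricted to `characters` (indices into the original columns).
encode_states <- function(m, characters) {
  syms <- state_symbols(m)
  k <- vapply(syms, length, integer(1))[characters]
  enc <- matrix(-1L, nrow(m), length(characters))
  for (jj in seq_along(characters)) {
    j <- characters[jj]
    code <- match(unclass(m)[, j], syms[[j]]) - 1L
    code[is.na(code)] <- -1L
    enc[, jj] <- code
  }
  rownames(enc) <- rownames(m)
  list(states = enc, k = k)
}
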