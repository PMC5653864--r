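#' Maximum-likelihood ancestral states under the Mk model
#'
#' Fits a symmetric k-state Mk model (k = number of observed states)
#' independently to each informative character by one-dimensional
#' maximum likelihood on the given time tree, and computes the marginal
#' ancestral state reconstruction at every internal node by the standard
#' two-pass (pruning plus re-rooting) algorithm.  Missing tips contribute
#' a flat partial likelihood.  The root prior is uniform.
#'
#' The per-character rate is the total rate of leaving the current state
#' (expected changes per character per Myr), fitted by bounded search on
#' `[rate_bounds[1], rate_bounds[2]]`.  The MAP state at a node is the
#' state with the highest marginal probability; exact ties are broken
#' deterministically toward the lowest state-symbol index.
#'
#' @param t a [time_tree()]
#' @param m a [character_matrix()]; all tree tips must appear among its
#'   taxa
#' @param characters integer indices of characters to reconstruct
#'   (default: all informative characters)
#' @param rate optional fixed rate (single value or per-character vector)
#'   bypassing the ML fit; used mainly for validation
#' @param marginals if `TRUE`, keep full per-node marginal probability
#'   matrices
#' @param rate_bounds search bracket for the per-character rate
#'   (changes/character/Myr)
#' @return an object of class `mk_asr`: list with `characters` (indices
#'   used), `k`, `rate`, `loglik`, `map` (nodes x characters matrix of
#'   0-based state indices; `NA` for unscored tips), and optionally
#'   `marginals` (list of node x state matrices)
#' @export
fit_mk_asr <- function(t, m, characters = NULL, rate = NULL,
                       marginals = FALSE, rate_bounds = c(1e-8, 10)) {
  if (is.null(characters)) characters <- which(informative_characters(m))
  if (length(characters) == 0L) stop("no informative characters to fit")
  if (!all(informative_characters(m)[characters]))
    stop("characters ", paste(characters[!informative_characters(m)[characters]],
                              collapse = ", "),
         " are invariant; exclude them upstream")
  tips <- t$phy$tip.label
  miss <- setdiff(tips, rownames(m))
  if (length(miss))
    stop("tree tips absent from the matrix: ", paste(miss, collapse = ", "))
  enc <- encode_states(m, characters)
  states <- enc$states[tips, , drop = FALSE]
  fixed <- if (is.null(rate)) numeric(0) else rep_len(rate, length(characters))
  res <- .mk_asr_cpp(t$phy$edge, t$phy$edge.length, length(tips),
                     states, as.integer(enc$k), as.numeric(fixed),
                     rate_bounds[1], rate_bounds[2], isTRUE(marginals))
  if (any(!is.finite(res$loglik)))
    stop("non-finite Mk likelihood for character(s) ",
         paste(characters[!is.finite(res$loglik)], collapse = ", "))
  out <- list(characters = characters, k = enc$k,
              rate = setNames(res$rate, characters),
              loglik = setNames(res$loglik, characters),
              map = res$map)
  if (isTRUE(marginals)) out$marginals <- res$marginals
  class(out) <- "mk_asr"
  out
}

#' @export
print.mk_asr <- function(x, ...) {
  cat(sprintf("mk_asr: %d characters, rates %.3g-%.3g changes/char/Myr\n",
              length(x$characters), min(x$rate), max(x$rate)))
  invisible(x)
}
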