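#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: the squared distances are double-centred,
#' eigendecomposed, and taxa are scored on the axes with positive
#' eigenvalues.  The percent variance of an axis is its eigenvalue's
#' share of the positive-eigenvalue sum.  Negative eigenvalues (distances
#' that are not Euclidean-embeddable, typical of Gower distances on
#' incomplete matrices) may either be left alone (`correction = "none"`)
#' or removed with Cailliez's additive constant
#' (`correction = "additive"`).
#'
#' @param d a [gower_distance()] result or symmetric distance matrix with
#'   no undefined entries
#' @param correction `"none"` or `"additive"`
#' @return an object of class `pco_ordination`: list with `scores` (taxa
#'   x axes), `eigenvalues` (all, sorted descending), `pct_var` (per
#'   positive axis), and `correction`
#' @export
pco <- function(d, correction = c("none", "additive")) {
  correction <- match.arg(correction)
  dm <- if (inherits(d, "gower_dist")) d$d else as.matrix(d)
  if (anyNA(dm))
    stop("distance matrix has undefined entries; impute or drop taxa first")
  n <- nrow(dm)
  # cmdscale warns when fewer than k axes have positive eigenvalues;
  # that is the expected situation for non-Euclidean Gower matrices
  sc <- withCallingHandlers(
    cmdscale(as.dist(dm), k = n - 1, eig = TRUE,
             add = correction == "additive"),
    warning = function(w) {
      if (grepl("eigenvalues are > 0", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  eig <- sc$eig
  pos <- eig > max(eig) * 1e-9
  scores <- sc$points[, seq_len(min(ncol(sc$points), sum(pos))), drop = FALSE]
  colnames(scores) <- paste0("PCO", seq_len(ncol(scores)))
  out <- list(scores = scores,
              eigenvalues = eig,
              pct_var = 100 * eig[pos] / sum(eig[pos]),
              correction = correction)
  class(out) <- "pco_ordination"
  out
}

#' @export
print.pco_ordination <- function(x, ...) {
  cat(sprintf("pco_ordination: %d taxa, %d positive axes (correction: %s)\n",
              nrow(x$scores), length(x$pct_var), x$correction))
  cat(sprintf("axes 1-2 variance: %.2f%%\n", sum(x$pct_var[1:2])))
  invisible(x)
}

#' Ancestral ordination scores under Brownian motion
#'
#' Maximum-likelihood ancestral values of a continuous trait (typically a
#' principal-coordinate axis) at every internal node, assuming Brownian
#' motion along the tree; equivalent to the generalized-least-squares
#' reconstruction.  Zero-length branches are nudged to a relative length
#' of 1e-8 so that a node attached by a zero-length branch takes (in the
#' limit) the value of that neighbour.
#'
#' @param t a [time_tree()]
#' @param x named numeric vector of tip values (all tips scored)
#' @return numeric vector of ancestral values, named by internal node
#'   number
#' @export
ancestral_scores <- function(t, x) {
  phy <- t$phy
  if (!all(phy$tip.label %in% names(x)))
    stop("all tips must be scored: missing ",
         paste(setdiff(phy$tip.label, names(x)), collapse = ", "))
  eps <- max(phy$edge.length) * 1e-8
  phy$edge.length[phy$edge.length < eps] <- eps
  anc <- phytools::fastAnc(phy, x[phy$tip.label])
  setNames(as.numeric(anc), names(anc))
}

#' Phylomorphospace node coordinates
#'
#' Convenience wrapper: tip scores on the first `n_axes` ordination axes
#' together with Brownian-motion ancestral scores for every internal
#' node, ready for plotting tip-ancestor segments.
#'
#' @param t a [time_tree()]
#' @param ord a [pco()] ordination whose taxa include all tips of `t`
#' @param n_axes number of leading axes
#' @return data frame with `node`, `label` (tips only), `is_tip` and one
#'   column per axis
#' @export
phylomorphospace_scores <- function(t, ord, n_axes = 2) {
  stopifnot(n_axes >= 1, n_axes <= ncol(ord$scores))
  ntip <- n_tips(t)
  nodes <- seq_len(ntip + t$phy$Nnode)
  out <- data.frame(node = nodes,
                    label = c(t$phy$tip.label, rep(NA, t$phy$Nnode)),
                    is_tip = nodes <= ntip)
  for (j in seq_len(n_axes)) {
    tipv <- ord$scores[t$phy$tip.label, j]
    names(tipv) <- t$phy$tip.label
    anc <- ancestral_scores(t, tipv)
    out[[colnames(ord$scores)[j]]] <-
      c(tipv, anc[as.character((ntip + 1L):(ntip + t$phy$Nnode))])
  }
  out
}

#' Correlation between ordination scores and an ecological trait
#'
#' Spearman rank correlation with tie-corrected ranks; taxa missing the
#' trait are pairwise-deleted and their number reported.
#'
#' @param scores named numeric vector of per-taxon axis scores
#' @param trait named numeric vector of per-taxon trait values (matched
#'   by name to `scores`)
#' @return list with `rho`, `p`, `n_used` and `n_dropped`
#' @export
axis_trait_correlation <- function(scores, trait) {
  tr <- trait[names(scores)]
  ok <- !is.na(scores) & !is.na(tr)
  if (sum(ok) < 4) stop("need at least 4 taxa scored on both variables")
  if (length(unique(tr[ok])) < 2)
    return(list(rho = NA_real_, p = NA_real_, n_used = sum(ok),
                n_dropped = sum(!ok)))
  ct <- suppressWarnings(cor.test(scores[ok], tr[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n_used = sum(ok),
       n_dropped = sum(!ok))
}
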