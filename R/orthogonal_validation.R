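# Independent sanity checks on a predicted interactome: interolog transfer,
# subcellular co-localization enrichment, and coexpression shift.

#' Interolog-based PPI transfer
#'
#' Two proteins are predicted to interact when their orthologs interact in at
#' least one reference organism.  Supporting organisms are listed per
#' prediction.  Predictions are monotone in the reference sets: adding
#' reference PPIs never removes a prediction.
#'
#' @param ortholog_maps data frame `organism`, `protein`, `ortholog`
#'   (many-to-many allowed).
#' @param reference_ppis data frame `organism`, `idA`, `idB` of ortholog-level
#'   interactions.
#' @return data frame `idA`, `idB` (canonical target-species pairs),
#'   `organisms` (comma-separated support), `n_organisms`.
#' @export
interolog_predict <- function(ortholog_maps, reference_ppis) {
  stopifnot(all(c("organism", "protein", "ortholog") %in% names(ortholog_maps)),
            all(c("organism", "idA", "idB") %in% names(reference_ppis)))
  hits <- list()
  for (org in unique(reference_ppis$organism)) {
    om <- ortholog_maps[ortholog_maps$organism == org, , drop = FALSE]
    if (nrow(om) == 0L) next
    back <- split(om$protein, om$ortholog)   # ortholog -> target proteins
    rp <- reference_ppis[reference_ppis$organism == org, , drop = FALSE]
    for (i in seq_len(nrow(rp))) {
      p1 <- back[[rp$idA[i]]]; p2 <- back[[rp$idB[i]]]
      if (is.null(p1) || is.null(p2)) next
      grid <- expand.grid(a = p1, b = p2, stringsAsFactors = FALSE)
      grid <- grid[grid$a != grid$b, , drop = FALSE]
      if (nrow(grid) == 0L) next
      cp <- canonical_pairs(grid$a, grid$b)
      cp$organism <- org
      hits[[length(hits) + 1L]] <- cp
    }
  }
  if (length(hits) == 0L)
    return(data.frame(idA = character(), idB = character(),
                      organisms = character(), n_organisms = integer()))
  all_hits <- unique(do.call(rbind, hits))
  key <- pair_key(all_hits$idA, all_hits$idB)
  orgs <- tapply(all_hits$organism, key, function(o) sort(unique(o)))
  first <- all_hits[!duplicated(key), c("idA", "idB")]
  first <- first[order(first$idA, first$idB), , drop = FALSE]
  k2 <- pair_key(first$idA, first$idB)
  first$organisms <- vapply(orgs[k2], paste, "", collapse = ",")
  first$n_organisms <- lengths(orgs[k2])
  rownames(first) <- NULL
  first
}

#' Winner-takes-all compartment assignment
#'
#' Assigns each protein its single highest-scoring subcellular compartment.
#' Score ties are broken by a fixed priority list (first listed wins);
#' the default priority is alphabetical.
#'
#' @param assignments data frame `protein`, `compartment`, `score`.
#' @param priority optional character vector giving the tie-break order.
#' @return named character vector protein -> compartment.
#' @export
winner_takes_all <- function(assignments, priority = NULL) {
  stopifnot(all(c("protein", "compartment", "score") %in% names(assignments)))
  if (nrow(assignments) == 0L) stop("empty assignment table")
  if (is.null(priority)) priority <- sort(unique(assignments$compartment))
  pr <- match(assignments$compartment, priority)
  if (anyNA(pr)) stop("compartment missing from priority list")
  out <- vapply(split(seq_len(nrow(assignments)), assignments$protein),
                function(ix) {
                  s <- assignments$score[ix]
                  top <- ix[s == max(s)]
                  assignments$compartment[top[which.min(pr[top])]]
                }, "")
  out
}

#' Co-localization enrichment of network edges (hypergeometric test)
#'
#' Universe: all unordered pairs over the located proteins.  A pair is a
#' "success" when both partners sit in the named compartment.  The p-value is
#' the hypergeometric upper tail: drawing `n` pairs (the network edges) from
#' a universe of `N` pairs containing `K` co-localized ones, the probability
#' of seeing `k` or more co-localized edges.
#'
#' @param edges data frame `idA`, `idB` (network edges; every protein must
#'   have a location).
#' @param locs named character vector protein -> compartment (e.g. from
#'   [winner_takes_all()]).
#' @param compartment compartment to test.
#' @return list of class `enrichment_result`: `compartment`, `k`, `n`, `K`,
#'   `N`, `p`.
#' @export
localization_enrichment <- function(edges, locs, compartment) {
  prot <- names(locs)
  miss <- setdiff(unique(c(edges$idA, edges$idB)), prot)
  if (length(miss) > 0L)
    stop("edge protein(s) without location: ", paste(miss, collapse = ", "))
  if (!compartment %in% locs)
    stop("compartment '", compartment, "' absent from the universe")
  P <- length(prot)
  Pc <- sum(locs == compartment)
  N <- choose(P, 2L)
  K <- choose(Pc, 2L)
  n <- nrow(edges)
  k <- sum(locs[edges$idA] == compartment & locs[edges$idB] == compartment)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  structure(list(compartment = compartment, k = k, n = n, K = K, N = N,
                 p = p), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment '%s': k=%d of n=%d edges (universe %d/%d), p=%.4g>\n",
              x$compartment, x$k, x$n, x$K, x$N, x$p))
  invisible(x)
}

#' Coexpression shift of network pairs versus random pairs
#'
#' One-sided Wilcoxon rank-sum comparison (network > random) of coexpression
#' values.  The statistic is the Mann-Whitney U (rank-sum) of the network
#' sample; the p-value is exact for `min(n, m) <= 8` with no ties and uses
#' the normal approximation with tie correction otherwise.
#'
#' @param network_vals coexpression values of predicted interacting pairs.
#' @param random_vals coexpression values of random pairs.
#' @return list: `U`, `p`, `n`, `m`, `method`.
#' @export
coexpression_shift <- function(network_vals, random_vals) {
  x <- as.numeric(network_vals); y <- as.numeric(random_vals)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "greater", exact = exact, correct = FALSE))
  p <- wt$p.value
  # fully tied samples have zero rank variance; no evidence of shift
  if (!is.finite(p)) p <- 0.5
  list(U = unname(wt$statistic), p = p,
       n = length(x), m = length(y),
       method = if (exact) "exact" else "normal approximation, tie-corrected")
}
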