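# Quality control of predicted structures: identity/coverage filtering and
# structural similarity (least-squares RMSD, TM-score) against templates.

new_superposition <- function(rotation, translation, rmsd, n_aligned,
                              tm = NA_real_, d0 = NA_real_) {
  structure(list(rotation = rotation, translation = translation, rmsd = rmsd,
                 tm_score = tm, d0 = d0, n_aligned = n_aligned),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: n=%d rmsd=%.4f A%s>\n", x$n_aligned, x$rmsd,
              if (is.na(x$tm_score)) "" else sprintf(" TM=%.4f (d0=%.3f)",
                                                     x$tm_score, x$d0)))
  invisible(x)
}

as_coord_matrix <- function(x) {
  if (inherits(x, "protein_structure"))
    x <- as.matrix(x$atoms[x$atoms$atom == "CA", c("x", "y", "z")])
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("coordinates must be an N x 3 matrix")
  if (any(!is.finite(x))) stop("non-finite coordinates")
  x
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' coordinate sets with a given index correspondence.  Reflections are
#' excluded (the returned rotation has determinant +1).
#'
#' @param coords_a,coords_b N x 3 coordinate matrices (Angstrom), N >= 3, or
#'   `protein_structure` objects (their CA atoms are used).
#' @return a `superposition` with `rotation` R, `translation` t and `rmsd`,
#'   where `coords_a %*% t(R) + t` superposes A onto B (row vectors).
#' @details Degenerate point sets (fewer than 3 points, or collinear points,
#'   for which the optimal rotation is not unique) raise an error.
#' @examples
#' a <- matrix(rnorm(12), 4)
#' kabsch_superpose(a, a)$rmsd  # 0
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  A <- as_coord_matrix(coords_a); B <- as_coord_matrix(coords_b)
  n <- nrow(A)
  if (nrow(B) != n) stop("coordinate sets differ in length")
  if (n < 3L) stop("need at least 3 points to superpose")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2L, ca); Bc <- sweep(B, 2L, cb)
  for (M in list(Ac, Bc)) {
    sv <- svd(M, nu = 0L, nv = 0L)$d
    if (sv[2L] < 1e-8 * max(sv[1L], 1e-12))
      stop("degenerate (collinear) point set: superposition not unique")
  }
  H <- crossprod(Ac, Bc)               # sum over i of a_i b_i^T
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # x_b ~ R x_a (column vectors)
  Arot <- Ac %*% t(R)
  rmsd <- sqrt(mean(rowSums((Arot - Bc)^2)))
  tr <- as.numeric(cb - R %*% ca)
  new_superposition(R, tr, rmsd, n)
}

#' TM-score normalization length scale
#'
#' `d0(L) = 1.24 (L - 15)^(1/3) - 1.8` Angstrom, clamped below at 0.5 A so the
#' score stays defined for very short (toy) chains (the raw formula is
#' non-positive for L <= 21).
#'
#' @param l_ref reference length (residues).
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(l_ref) {
  raw <- ifelse(l_ref > 15, 1.24 * (l_ref - 15)^(1/3) - 1.8, -Inf)
  pmax(raw, 0.5)
}

#' Length-normalized topological similarity (TM-score)
#'
#' `TM = (1/L_ref) * sum_i 1 / (1 + (d_i/d0)^2)` maximized over rigid
#' superpositions, with `d0 = 1.24 (L_ref - 15)^(1/3) - 1.8`.  The score is in
#' (0, 1]; values above 0.5 indicate the same fold, while random structure
#' pairs score around 0.17 or below.
#'
#' The maximization uses iterative cutoff refinement: start from the Kabsch
#' superposition on all residue pairs, then repeatedly re-superpose on the
#' pairs with `d_i` below a d0-scaled cutoff until the score converges
#' (tolerance 1e-6, at most 20 iterations), keeping the best score seen.
#'
#' @param coords_model,coords_ref N x 3 CA coordinate matrices with residue
#'   correspondence given by row index.
#' @param l_ref normalization length (reference chain length); defaults to N
#'   and must be >= N.
#' @return a `superposition` carrying `tm_score`, `d0`, and the rmsd/rotation
#'   of the best superposition found.
#' @export
tm_score <- function(coords_model, coords_ref, l_ref = NULL) {
  A <- as_coord_matrix(coords_model); B <- as_coord_matrix(coords_ref)
  n <- nrow(A)
  if (nrow(B) != n) stop("coordinate sets differ in length")
  if (n < 3L) stop("need at least 3 residues")
  if (is.null(l_ref)) l_ref <- n
  if (l_ref < n) stop("l_ref must be >= the number of aligned residues")
  d0 <- tm_d0(l_ref)
  cutoff <- max(d0, 2.0)
  idx <- seq_len(n)
  best <- NULL; tm_prev <- -Inf
  for (iter in seq_len(20L)) {
    sup <- tryCatch(kabsch_superpose(A[idx, , drop = FALSE],
                                     B[idx, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(sup)) break
    Afit <- A %*% t(sup$rotation) +
      matrix(sup$translation, n, 3L, byrow = TRUE)
    d <- sqrt(rowSums((Afit - B)^2))
    tm <- sum(1 / (1 + (d / d0)^2)) / l_ref
    if (is.null(best) || tm > best$tm_score) {
      best <- new_superposition(sup$rotation, sup$translation,
                                sqrt(mean(d^2)), n, tm, d0)
    }
    if (abs(tm - tm_prev) < 1e-6) break
    tm_prev <- tm
    nxt <- which(d < cutoff)
    if (length(nxt) < 3L || identical(nxt, idx)) break
    idx <- nxt
  }
  if (is.null(best)) stop("TM-score superposition failed (degenerate input)")
  best
}

#' High-quality model filter on alignment identity and coverage
#'
#' A homology model passes when its sequence identity with the template
#' exceeds `id_min` *and* its alignment coverage exceeds `cov_min` (both
#' strict inequalities, defaults 50% and 80%).
#'
#' @param identity,coverage fractions in `[0, 1]`, vectorized.
#' @param id_min,cov_min strict lower bounds.
#' @return logical vector: `TRUE` = high quality.
#' @export
qc_filter <- function(identity, coverage, id_min = 0.50, cov_min = 0.80) {
  stopifnot(all(identity >= 0 & identity <= 1),
            all(coverage >= 0 & coverage <= 1))
  identity > id_min & coverage > cov_min
}

#' Template self-hit filter
#'
#' Benchmark models must not be trivially identical to their template: a model
#' with sequence identity of `id_max` (default 95%) or more to its template is
#' flagged as a self-hit and excluded.
#'
#' @param identity fraction in `[0, 1]`, vectorized.
#' @param id_max self-hit bound; models with `identity >= id_max` are flagged.
#' @return logical vector: `TRUE` = self-hit (exclude).
#' @export
is_template_self_hit <- function(identity, id_max = 0.95) {
  stopifnot(all(identity >= 0 & identity <= 1))
  identity >= id_max
}

#' Summarize structural QC over a model set
#'
#' @param tm numeric vector of TM-scores (or a list of `superposition`
#'   objects, from which `tm_score`/`rmsd` are extracted).
#' @param rmsd numeric vector of RMSDs in Angstrom.
#' @param tm_cutoff models with TM-score strictly above this count as
#'   correct-topology (default 0.5).
#' @param rmsd_cutoff models with RMSD strictly below this count as accurate
#'   (default 2 A).
#' @return list with `n`, `mean_tm`, `mean_rmsd`, `pct_tm_high`,
#'   `pct_rmsd_low` (percentages rounded to one decimal).
#' @export
summarize_qc <- function(tm, rmsd = NULL, tm_cutoff = 0.5, rmsd_cutoff = 2) {
  if (is.list(tm) && is.null(rmsd)) {
    rmsd <- vapply(tm, `[[`, 0, "rmsd")
    tm <- vapply(tm, `[[`, 0, "tm_score")
  }
  n <- length(tm)
  if (n == 0L) stop("empty QC collection")
  if (length(rmsd) != n) stop("tm and rmsd lengths differ")
  list(n = n,
       mean_tm = mean(tm),
       mean_rmsd = mean(rmsd),
       pct_tm_high = fraction_pct(sum(tm > tm_cutoff), n),
       pct_rmsd_low = fraction_pct(sum(rmsd < rmsd_cutoff), n))
}

#' Identity and coverage from a pairwise alignment
#'
#' Fixture helper: computes sequence identity and alignment coverage from two
#' equal-length gapped alignment strings (model first).  Identity = identical
#' columns / aligned (gap-free) columns; coverage = aligned columns / model
#' length.
#'
#' @param aln_model,aln_template gapped alignment strings (`-` = gap).
#' @return named numeric vector `c(identity=, coverage=)`.
#' @export
alignment_identity_coverage <- function(aln_model, aln_template) {
  a <- strsplit(toupper(aln_model), "")[[1L]]
  b <- strsplit(toupper(aln_template), "")[[1L]]
  if (length(a) != length(b)) stop("alignment strings differ in length")
  aligned <- a != "-" & b != "-"
  if (!any(aligned)) stop("no aligned columns")
  c(identity = sum(a[aligned] == b[aligned]) / sum(aligned),
    coverage = sum(aligned) / sum(a != "-"))
}
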