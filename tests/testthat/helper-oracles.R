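# Independent oracles used by the test suite.  Each is deliberately written
# against a different code path (enumeration, brute force, or an external
# library) than the implementation it checks.

# Brute-force RMSD: centered coordinate sets, nested rotation-grid search
# over ZYZ Euler angles (coarse grid, then repeated local refinement).
# Independent of the closed-form SVD solution.
rmsd_rotgrid_oracle <- function(a, b, coarse = 15, refinements = 7) {
  a <- scale(a, scale = FALSE); b <- scale(b, scale = FALSE)
  rot_zyz <- function(a1, a2, a3) {
    cz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                               0, 0, 1), 3, byrow = TRUE)
    cy <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                               -sin(t), 0, cos(t)), 3, byrow = TRUE)
    cz(a1) %*% cy(a2) %*% cz(a3)
  }
  rmsd_at <- function(ang) {
    R <- rot_zyz(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((a %*% t(R) - b)^2)))
  }
  step0 <- coarse * pi / 180
  grid <- expand.grid(a1 = seq(0, 2 * pi - step0, by = step0),
                      a2 = seq(0, pi, by = step0),
                      a3 = seq(0, 2 * pi - step0, by = step0))
  vals <- apply(grid, 1, rmsd_at)
  # refine from the best coarse candidates (multi-start avoids local minima)
  starts <- order(vals)[1:20]
  bestv <- Inf
  for (s in starts) {
    cur <- as.numeric(grid[s, ]); curv <- vals[s]
    step <- step0
    for (r in seq_len(refinements)) {
      step <- step / 2
      local <- expand.grid(a1 = cur[1] + step * (-2:2),
                           a2 = cur[2] + step * (-2:2),
                           a3 = cur[3] + step * (-2:2))
      lv <- apply(local, 1, rmsd_at)
      if (min(lv) < curv) {
        curv <- min(lv)
        cur <- as.numeric(local[which.min(lv), ])
      }
    }
    bestv <- min(bestv, curv)
  }
  bestv
}

# Mann-Whitney pair-counting AUC: P(z_pos > z_neg) + 0.5 P(z_pos = z_neg),
# by exhaustive comparison of every positive-negative pair.
auc_paircount_oracle <- function(set) {
  zp <- set$z[set$label == "positive"]
  zn <- set$z[set$label == "negative"]
  cmp <- outer(zp, zn, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
# of n items from a universe with K successes.
hyper_tail_enum_oracle <- function(k, K, N, n) {
  items <- c(rep(1L, K), rep(0L, N - K))
  draws <- utils::combn(N, n)
  tail_hits <- apply(draws, 2, function(ix) sum(items[ix]) >= k)
  mean(tail_hits)
}

# Full-transcript variant oracle: rebuild the spliced mRNA of the gene with
# Biostrings, apply the variant to the chromosome, translate both proteins
# and diff them.  Independent of the codon-coordinate arithmetic in
# annotate_substitution.
mrna_diff_oracle <- function(genome, gene, variant) {
  aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
           E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
           M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
           Y = "Tyr", V = "Val", `*` = "Ter")
  translate_gene <- function(chrom_seq) {
    dna <- Biostrings::DNAString(chrom_seq)
    lo <- pmin(gene$starts, gene$ends); hi <- pmax(gene$starts, gene$ends)
    o <- order(lo)
    segs <- lapply(o, function(i) dna[lo[i]:hi[i]])
    cds <- do.call(Biostrings::xscat, segs)
    if (gene$strand == "-") cds <- Biostrings::reverseComplement(cds)
    as.character(Biostrings::translate(Biostrings::DNAString(as.character(cds)),
                                       if.fuzzy.codon = "error",
                                       no.init.codon = TRUE))
  }
  chrom <- genome[[variant$chrom]]
  stopifnot(substr(chrom, variant$pos, variant$pos) == variant$ref)
  if (variant$chrom != gene$chrom)
    return(list(consequence = "non-coding"))
  lo <- pmin(gene$starts, gene$ends); hi <- pmax(gene$starts, gene$ends)
  if (!any(variant$pos >= lo & variant$pos <= hi))
    return(list(consequence = "non-coding"))
  alt_chrom <- chrom
  substr(alt_chrom, variant$pos, variant$pos) <- variant$alt
  p_ref <- translate_gene(chrom)
  p_alt <- translate_gene(alt_chrom)
  d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
  if (length(d) == 0L)
    return(list(consequence = "synonymous", label = NA_character_))
  stopifnot(length(d) == 1L)
  r <- substr(p_ref, d, d); a <- substr(p_alt, d, d)
  list(consequence = "nonsynonymous", protein_pos = d,
       label = sprintf("p.%s%d%s", aa3[[r]], d, aa3[[a]]))
}

# Tiny deterministic labeled set where the all-positive threshold is the
# exact F optimum (positive and negative scores identical).
degenerate_balanced_set <- function(n = 10) {
  labeled_pairs(sprintf("A%02d", 1:(2 * n)), sprintf("B%02d", 1:(2 * n)),
                z = c(1:n, 1:n),
                label = rep(c("positive", "negative"), each = n))
}
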