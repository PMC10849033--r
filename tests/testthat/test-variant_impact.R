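test_that("annotate_substitution handles the canonical worked cases", {
  # plus strand, codon 2 TAT with middle base A->G: Tyr -> Cys
  genome <- c(chr1 = "ATGTAT")
  g <- gene_model("g1", "chr1", "+", 1, 6)
  ann <- annotate_substitution(genome, g,
                               list(chrom = "chr1", pos = 5, ref = "A",
                                    alt = "G"))
  expect_equal(ann$consequence, "nonsynonymous")
  expect_equal(ann$label, "p.Tyr2Cys")

  # wobble-position change GCT -> GCC is synonymous
  genome2 <- c(chr1 = "ATGGCT")
  ann2 <- annotate_substitution(genome2, gene_model("g2", "chr1", "+", 1, 6),
                                list(chrom = "chr1", pos = 6, ref = "T",
                                     alt = "C"))
  expect_equal(ann2$consequence, "synonymous")
  expect_true(is.na(ann2$label))

  # minus strand: CDS ATG TAT lies reverse-complemented on the chromosome
  # (ATACAT); genomic C->T at position 2 edits codon-2 wobble base
  genome3 <- c(chr1 = "ATACAT")
  gm <- gene_model("g3", "chr1", "-", 1, 6)
  ann3 <- annotate_substitution(genome3, gm,
                                list(chrom = "chr1", pos = 4, ref = "C",
                                     alt = "T"))
  # oracle: hand-built mRNA diff
  oracle <- mrna_diff_oracle(genome3, gm,
                             list(chrom = "chr1", pos = 4, ref = "C",
                                  alt = "T"))
  expect_equal(ann3$consequence, oracle$consequence)
  expect_equal(ann3$label, oracle$label)

  # reference mismatch errors; outside the CDS is non-coding
  expect_error(annotate_substitution(genome, g,
                                     list(chrom = "chr1", pos = 5, ref = "C",
                                          alt = "G")), "mismatch")
  genome4 <- c(chr1 = "TTATGTATTT")
  g4 <- gene_model("g4", "chr1", "+", 3, 8)
  expect_equal(annotate_substitution(genome4, g4,
                                     list(chrom = "chr1", pos = 10, ref = "T",
                                          alt = "A"))$consequence,
               "non-coding")
})

test_that("annotate_substitution agrees with the mRNA-diff oracle on random genes", {
  # 200 random toy genes per strand, intron-split CDS, ~3 variants each
  for (strand in c("+", "-")) {
    tg <- gen_toy_genome(n_genes = 200, seed = if (strand == "+") 101 else 202,
                         n_codons_range = c(10, 30),
                         n_variants_per_gene = 3, strand = strand)
    for (i in seq_len(nrow(tg$variants))) {
      v <- tg$variants[i, ]
      gene <- tg$genes[[v$gene]]
      got <- annotate_substitution(tg$genome, gene, v)
      want <- mrna_diff_oracle(tg$genome, gene, v)
      expect_equal(got$consequence, want$consequence)
      if (got$consequence == "nonsynonymous")
        expect_equal(got$label, want$label)
      # and the generator's by-construction truth row agrees too
      truth <- tg$truth[tg$truth$id == v$id, ]
      expect_equal(got$consequence, truth$consequence)
    }
  }
})

test_that("find_interface_residues applies the heavy-atom cutoff symmetrically", {
  hs <- gen_toy_structures("half_sphere_pair", n_residues = 40, seed = 3)
  cx <- merge_structures(hs$receptor, hs$ligand)
  itf <- find_interface_residues(cx, cutoff = 5.5)
  expect_gt(length(itf$residues[["A"]]), 0)
  expect_gt(length(itf$residues[["B"]]), 0)
  # every listed residue really has a heavy atom within the cutoff
  A <- cx$atoms[cx$atoms$chain == "A", ]; B <- cx$atoms[cx$atoms$chain == "B", ]
  dmin <- function(r, from, to) {
    fa <- as.matrix(from[from$resno == r, c("x", "y", "z")])
    ta <- as.matrix(to[, c("x", "y", "z")])
    min(sqrt(outer(rowSums(fa^2), rowSums(ta^2), `+`) - 2 * fa %*% t(ta)))
  }
  for (r in itf$residues[["A"]]) expect_lte(dmin(r, A, B), 5.5 + 1e-6)
  non <- setdiff(unique(A$resno), itf$residues[["A"]])
  if (length(non) > 0) expect_gt(dmin(non[1], A, B), 5.5)

  # cutoff 0 -> empty; far-apart chains -> empty
  itf0 <- find_interface_residues(cx, cutoff = 0)
  expect_length(itf0$residues[["A"]], 0)
  far <- hs$ligand
  far$atoms$x <- far$atoms$x + 100
  itf_far <- find_interface_residues(merge_structures(hs$receptor, far))
  expect_length(itf_far$residues[["A"]], 0)
  expect_length(itf_far$residues[["B"]], 0)
  expect_error(find_interface_residues(hs$receptor), "2 chains")
})

test_that("interface sets grow monotonically with the cutoff", {
  hs <- gen_toy_structures("half_sphere_pair", n_residues = 30, seed = 6)
  cx <- merge_structures(hs$receptor, hs$ligand)
  sizes <- vapply(c(3, 4.5, 5.5, 7, 10), function(ct) {
    itf <- find_interface_residues(cx, cutoff = ct)
    length(itf$residues[["A"]]) + length(itf$residues[["B"]])
  }, 0)
  expect_true(all(diff(sizes) >= 0))
})

test_that("map_variants_to_interfaces counts hits by set membership", {
  itfs <- list(
    list(pair = c("P1", "P2"), residues = list(P1 = c(5, 9), P2 = c(3))),
    list(pair = c("P1", "P3"), residues = list(P1 = c(9), P3 = c(1))),
    list(pair = c("P1", "P4"), residues = list(P1 = c(9, 12), P4 = c(2))))
  subs <- data.frame(variant = c("v1", "v2"), protein = c("P1", "P1"),
                     protein_pos = c(9, 100))
  hits <- map_variants_to_interfaces(subs, itfs)
  # one substitution at an interface shared by 3 PPIs -> 3 hits
  expect_equal(sum(hits$variant == "v1"), 3L)
  # non-interface position -> no hit
  expect_equal(sum(hits$variant == "v2"), 0L)
  # empty interface collection -> empty table
  expect_equal(nrow(map_variants_to_interfaces(subs, list())), 0L)
})

test_that("classify_ddg uses ddG = dG_ref - dG_alt with strict +/-1 bounds", {
  expect_equal(classify_ddg(-8.0, -6.589)$ddg, -1.411)
  expect_equal(classify_ddg(-8.0, -6.589)$class, "weaken")
  expect_equal(classify_ddg(-5, -5)$class, "neutral")
  expect_equal(classify_ddg(-5, -6)$ddg, 1.0)
  expect_equal(classify_ddg(-5, -6)$class, "neutral")   # boundary is neutral
  expect_equal(classify_ddg(-5, -6.01)$class, "strengthen")

  # antisymmetry: swapping ref/alt negates ddG and swaps the signed classes
  set.seed(44)
  dg1 <- rnorm(50, -8, 2); dg2 <- rnorm(50, -8, 2)
  fwd <- classify_ddg(dg1, dg2); rev <- classify_ddg(dg2, dg1)
  expect_equal(fwd$ddg, -rev$ddg)
  swap <- c(strengthen = "weaken", weaken = "strengthen", neutral = "neutral")
  expect_equal(unname(swap[fwd$class]), rev$class)
})

test_that("summarize_perturbation counts distinct variants and PPIs per class", {
  rec <- data.frame(
    variant = c("s1", "s1", "s1", "s2", "s2", "s2", "s3"),
    idA = c("A", "B", "C", "A", "B", "C", "A"),
    idB = c("X", "X", "X", "X", "X", "X", "Y"),
    class = c(rep("strengthen", 6), "neutral"))
  s <- summarize_perturbation(rec)
  st <- s$by_class[s$by_class$class == "strengthen", ]
  expect_equal(st$n_variants, 2L)
  expect_equal(st$n_ppis, 3L)
  expect_equal(s$n_significant_variants, 2L)

  # a variant split across classes appears in both
  rec2 <- data.frame(variant = "s1", idA = c("A", "B"), idB = "X",
                     class = c("strengthen", "weaken"))
  s2 <- summarize_perturbation(rec2)
  expect_equal(s2$by_class$n_variants[s2$by_class$class %in%
                                        c("strengthen", "weaken")], c(1L, 1L))
  expect_equal(s2$n_significant_variants, 1L)

  # all neutral -> zero in both signed classes
  rec3 <- data.frame(variant = "v", idA = "A", idB = "B", class = "neutral")
  s3 <- summarize_perturbation(rec3)
  expect_equal(sum(s3$by_class$n_variants[s3$by_class$class != "neutral"]), 0L)
})
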