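# Annotate SNVs to protein substitutions, locate substitutions on
# docked-complex interfaces, and classify ddG perturbation of PPIs.

# Standard genetic code, DNA codons.
GENETIC_CODE_DNA <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

AA_THREE <- c(A="Ala",R="Arg",N="Asn",D="Asp",C="Cys",Q="Gln",E="Glu",
              G="Gly",H="His",I="Ile",L="Leu",K="Lys",M="Met",F="Phe",
              P="Pro",S="Ser",T="Thr",W="Trp",Y="Tyr",V="Val",`*`="Ter")

COMPLEMENT <- c(A="T",C="G",G="C",T="A")

revcomp <- function(s) {
  paste(rev(COMPLEMENT[strsplit(toupper(s), "")[[1L]]]), collapse = "")
}

#' Translate a DNA coding sequence
#'
#' Standard genetic code; stop codons translate to `*`.  Length must be a
#' multiple of 3.
#'
#' @param dna DNA string (5'->3' coding strand).
#' @return amino-acid string (one-letter codes).
#' @export
translate_dna <- function(dna) {
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- GENETIC_CODE_DNA[codons]
  if (anyNA(aa)) stop("invalid codon: ", codons[which(is.na(aa))[1L]])
  paste(aa, collapse = "")
}

# Spliced CDS sequence of a gene model (coding strand, 5'->3').
spliced_cds <- function(genome, gene) {
  chrom <- genome[[gene$chrom]]
  if (is.null(chrom)) stop("chromosome ", gene$chrom, " not in genome")
  segs <- mapply(function(s, e) substr(chrom, s, e),
                 pmin(gene$starts, gene$ends), pmax(gene$starts, gene$ends))
  if (gene$strand == "+") paste(segs, collapse = "")
  else paste(vapply(segs, revcomp, ""), collapse = "")
}

# 1-based CDS coordinate of genomic position `pos`, or NA if non-coding.
# Gene segments are stored in translation order.
cds_coordinate <- function(gene, pos) {
  offset <- 0L
  for (k in seq_along(gene$starts)) {
    s <- gene$starts[k]; e <- gene$ends[k]
    lo <- min(s, e); hi <- max(s, e)
    if (pos >= lo && pos <= hi) {
      within <- if (gene$strand == "+") pos - lo + 1L else hi - pos + 1L
      return(offset + within)
    }
    offset <- offset + (hi - lo + 1L)
  }
  NA_integer_
}

#' Annotate the protein consequence of a single-nucleotide variant
#'
#' Minimal SNV-only consequence caller: checks the reference base against the
#' genome, locates the variant within the gene's CDS via cumulative CDS
#' coordinates (reverse-complementing on `-` strand genes), swaps the base in
#' the affected codon and translates both codons with the standard genetic
#' code.
#'
#' @param genome named character vector (or list) of chromosome sequences.
#' @param gene a [gene_model()].
#' @param variant list or one-row data frame with `chrom`, `pos` (1-based,
#'   `+` strand), `ref`, `alt` single bases.
#' @return list with `consequence` (`"nonsynonymous"`, `"synonymous"` or
#'   `"non-coding"`) and, for coding variants, `protein_pos` (codon index),
#'   `ref_aa`/`alt_aa` (three-letter) and `label` (`"p.<Ref><Pos><Alt>"`,
#'   `NA` for synonymous).
#' @examples
#' g <- gene_model("g1", "chr1", "+", 1, 6)
#' genome <- c(chr1 = "ATGTAT")
#' annotate_substitution(genome, g,
#'   list(chrom = "chr1", pos = 5, ref = "A", alt = "G"))$label  # p.Tyr2Cys
#' @export
annotate_substitution <- function(genome, gene, variant) {
  stopifnot(inherits(gene, "gene_model"))
  v <- as.list(variant)
  v$ref <- toupper(v$ref); v$alt <- toupper(v$alt)
  if (!all(c(v$ref, v$alt) %in% c("A", "C", "G", "T")) || v$ref == v$alt)
    stop("variant must be an SNV with ref != alt")
  chrom <- genome[[v$chrom]]
  if (is.null(chrom)) stop("chromosome ", v$chrom, " not in genome")
  obs <- toupper(substr(chrom, v$pos, v$pos))
  if (obs != v$ref)
    stop("reference mismatch at ", v$chrom, ":", v$pos,
         " (genome has ", obs, ", variant says ", v$ref, ")")
  if (v$chrom != gene$chrom) return(list(consequence = "non-coding"))
  cpos <- cds_coordinate(gene, v$pos)
  if (is.na(cpos)) return(list(consequence = "non-coding"))
  cds <- spliced_cds(genome, gene)
  ref_b <- if (gene$strand == "+") v$ref else COMPLEMENT[[v$ref]]
  alt_b <- if (gene$strand == "+") v$alt else COMPLEMENT[[v$alt]]
  stopifnot(substr(cds, cpos, cpos) == ref_b)  # internal consistency
  codon_idx <- (cpos - 1L) %/% 3L + 1L
  cstart <- (codon_idx - 1L) * 3L + 1L
  ref_codon <- substr(cds, cstart, cstart + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, cpos - cstart + 1L, cpos - cstart + 1L) <- alt_b
  ref_aa <- GENETIC_CODE_DNA[[ref_codon]]
  alt_aa <- GENETIC_CODE_DNA[[alt_codon]]
  if (ref_aa == alt_aa)
    return(list(consequence = "synonymous", protein_pos = codon_idx,
                ref_aa = AA_THREE[[ref_aa]], alt_aa = AA_THREE[[alt_aa]],
                label = NA_character_))
  list(consequence = "nonsynonymous", protein_pos = codon_idx,
       ref_aa = AA_THREE[[ref_aa]], alt_aa = AA_THREE[[alt_aa]],
       label = sprintf("p.%s%d%s", AA_THREE[[ref_aa]], codon_idx,
                       AA_THREE[[alt_aa]]))
}

#' Interface residues of a docked two-chain complex
#'
#' A residue of one chain is interfacial when at least one of its heavy atoms
#' lies within `cutoff` of any heavy atom of the partner chain.  The default
#' 5.5 A is the common heavy-atom contact convention of interface predictors.
#'
#' @param complex a two-chain `protein_structure`.
#' @param cutoff contact distance, Angstrom.
#' @return list of class `interface_set`: `chains`, `residues` (named list of
#'   sorted residue-number vectors per chain), `cutoff`.
#' @export
find_interface_residues <- function(complex, cutoff = 5.5) {
  stopifnot(inherits(complex, "protein_structure"))
  at <- complex$atoms[toupper(complex$atoms$element) != "H", , drop = FALSE]
  chains <- unique(at$chain)
  if (length(chains) != 2L) stop("complex must have exactly 2 chains")
  a <- at[at$chain == chains[1L], ]; b <- at[at$chain == chains[2L], ]
  am <- as.matrix(a[, c("x", "y", "z")]); bm <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(am^2), rowSums(bm^2), `+`) - 2 * am %*% t(bm)
  close <- d2 <= cutoff^2 + 1e-9
  resA <- sort(unique(a$resno[rowSums(close) > 0]))
  resB <- sort(unique(b$resno[colSums(close) > 0]))
  if (cutoff <= 0) { resA <- integer(0); resB <- integer(0) }
  res <- list(resA, resB); names(res) <- chains
  structure(list(chains = chains, residues = res, cutoff = cutoff),
            class = "interface_set")
}

#' Map protein substitutions onto PPI interfaces
#'
#' Emits a hit for every (substitution, PPI) combination where the
#' substituted residue belongs to that PPI's interface set on the protein
#' carrying the variant.  Substitution positions absent from the docked
#' structure are skipped with a message.
#'
#' @param subs data frame with `variant` (identifier), `protein` (id matching
#'   the interface pair ids), `protein_pos` (residue number).
#' @param interfaces list; each element a list with `pair` (character 2) and
#'   `residues` (named list of residue-number vectors keyed by protein id),
#'   e.g. built from [find_interface_residues()] output.
#' @return data frame `variant`, `protein`, `protein_pos`, `idA`, `idB` with
#'   one row per hit.
#' @export
map_variants_to_interfaces <- function(subs, interfaces) {
  out <- list()
  for (i in seq_len(nrow(subs))) {
    p <- subs$protein[i]; pos <- subs$protein_pos[i]
    for (itf in interfaces) {
      if (!(p %in% itf$pair)) next
      res <- itf$residues[[p]]
      if (is.null(res)) next
      if (pos %in% res)
        out[[length(out) + 1L]] <- data.frame(
          variant = subs$variant[i], protein = p, protein_pos = pos,
          idA = min(itf$pair), idB = max(itf$pair),
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(variant = character(), protein = character(),
                      protein_pos = integer(), idA = character(),
                      idB = character()))
  do.call(rbind, out)
}

#' Classify the binding free-energy change of an allele
#'
#' `ddG = dG_ref - dG_alt` (kcal/mol): a positive ddG means the alternative
#' allele binds more strongly (its dG is more negative).  The perturbation
#' classes use strict bounds at +/- `magnitude` (default 1 kcal/mol):
#' `strengthen` when `ddG > magnitude`, `weaken` when `ddG < -magnitude`,
#' `neutral` otherwise (boundary ties are neutral).
#'
#' @param dg_ref,dg_alt numeric vectors of binding free energies, kcal/mol.
#' @param magnitude significance band half-width, kcal/mol.
#' @return data frame `dg_ref`, `dg_alt`, `ddg`, `class`.
#' @export
classify_ddg <- function(dg_ref, dg_alt, magnitude = 1.0) {
  stopifnot(all(is.finite(dg_ref)), all(is.finite(dg_alt)), magnitude >= 0)
  ddg <- dg_ref - dg_alt
  cls <- ifelse(ddg > magnitude, "strengthen",
                ifelse(ddg < -magnitude, "weaken", "neutral"))
  data.frame(dg_ref = dg_ref, dg_alt = dg_alt, ddg = ddg, class = cls,
             stringsAsFactors = FALSE)
}

#' Per-class counts of perturbed variants and PPIs
#'
#' Counts distinct variants and distinct PPIs per perturbation class.  A
#' variant perturbing different PPIs in different directions is counted in
#' each class; `n_significant_variants` is the distinct union across the two
#' signed classes.
#'
#' @param records data frame with `variant`, `idA`, `idB`, `class`.
#' @return list: `by_class` (data frame `class`, `n_variants`, `n_ppis`) and
#'   `n_significant_variants`.
#' @export
summarize_perturbation <- function(records) {
  classes <- c("strengthen", "weaken", "neutral")
  by_class <- do.call(rbind, lapply(classes, function(cl) {
    r <- records[records$class == cl, , drop = FALSE]
    data.frame(class = cl,
               n_variants = length(unique(r$variant)),
               n_ppis = length(unique(pair_key(r$idA, r$idB))),
               stringsAsFactors = FALSE)
  }))
  sig <- records$class %in% c("strengthen", "weaken")
  list(by_class = by_class,
       n_significant_variants = length(unique(records$variant[sig])))
}

#' Pluggable stub binding-energy scorer
#'
#' Exercises the ddG pipeline end-to-end without an external predictor: the
#' "binding energy" of a complex is minus the inter-chain heavy-atom contact
#' count at `cutoff`, scaled to kcal/mol-like magnitudes.  It is a stand-in,
#' not a physical model.
#'
#' @param complex a two-chain `protein_structure`.
#' @param cutoff contact distance, Angstrom.
#' @param scale kcal/mol per contact.
#' @return numeric pseudo-dG (negative = more contacts = stronger binding).
#' @export
stub_binding_energy <- function(complex, cutoff = 5.5, scale = 0.1) {
  at <- complex$atoms[toupper(complex$atoms$element) != "H", , drop = FALSE]
  chains <- unique(at$chain)
  if (length(chains) != 2L) stop("complex must have exactly 2 chains")
  am <- as.matrix(at[at$chain == chains[1L], c("x", "y", "z")])
  bm <- as.matrix(at[at$chain == chains[2L], c("x", "y", "z")])
  d2 <- outer(rowSums(am^2), rowSums(bm^2), `+`) - 2 * am %*% t(bm)
  -scale * sum(d2 <= cutoff^2 + 1e-9)
}
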