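# Generators for every input the pipeline needs: parametric decoy-score sets
# with the benchmark class separations, toy structures, and toy genomes with
# planted SNVs.  All generators are pure functions of (configuration, seed).

# Core pose-list construction, drawing from the current RNG stream.
gen_pose_list_core <- function(z_target, n_poses, decoy_mean, decoy_sd) {
  stopifnot(n_poses >= 3L, decoy_sd > 0)
  dec <- stats::rnorm(n_poses - 1L, decoy_mean, decoy_sd)
  top <- mean(dec) + z_target * stats::sd(dec)
  pose_list(c(top, dec))
}

#' Generate a pose list with a prescribed docking z-score
#'
#' Draws `n_poses - 1` decoy scores from `Normal(decoy_mean, decoy_sd)` and
#' sets the rank-1 score to `sample_mean + z_target * sample_sd` of the drawn
#' decoys, so that [dock_z_score()] (top-excluded convention) recovers
#' exactly `z_target`.  The raw score scale is arbitrary: the z statistic is
#' invariant under affine rescaling of all pose scores.
#'
#' @param z_target the z-score the pose list should produce.
#' @param n_poses total number of poses (default 2000, the usual decoy depth).
#' @param decoy_mean,decoy_sd decoy score distribution parameters.
#' @param seed RNG seed.
#' @return a [pose_list()].
#' @export
gen_pose_list <- function(z_target, n_poses = 2000L, decoy_mean = 20,
                          decoy_sd = 4, seed = 1L) {
  with_seed(seed, gen_pose_list_core(z_target, n_poses, decoy_mean, decoy_sd))
}

#' Benchmark class presets
#'
#' Class mean z-scores emulating the two benchmark regimes: docking of
#' experimental structures separates interacting pairs (mean z 10.0) from
#' random pairs (mean z 5.8) much more strongly than docking of homology
#' models (6.6 vs 5.9).
#'
#' @param preset `"experimental"` or `"model"`.
#' @return named numeric vector `c(pos = , neg = )`.
#' @export
benchmark_preset <- function(preset = c("experimental", "model")) {
  switch(match.arg(preset),
         experimental = c(pos = 10.0, neg = 5.8),
         model = c(pos = 6.6, neg = 5.9))
}

#' Generate a labeled docking benchmark
#'
#' Builds `n_pos` positive pairs (distinct synthetic proteins re-paired by
#' [shuffle_negatives()] for the negative set) and assigns each pair a target
#' z drawn from `Normal(class mean, z_sd)`.  With `return_poses = TRUE` a
#' full pose list is generated per pair and the reported z is *recomputed*
#' from it with [dock_z_score()], exercising the whole scoring path.
#'
#' The class means come from the presets (see [benchmark_preset()]); the z
#' spread `z_sd = 1.5` is a free simulator parameter (only class means are
#' constrained by the emulated benchmarks), so absolute AUC values of the
#' generated sets are simulator properties - only their ordering
#' (experimental > model) is meaningful.
#'
#' @param n_pos,n_neg class sizes.
#' @param preset `"experimental"` or `"model"`; ignored when both means are
#'   given explicitly.
#' @param z_pos_mean,z_neg_mean optional explicit class means.
#' @param z_sd z spread per class.
#' @param n_poses poses per pair when `return_poses = TRUE`.
#' @param decoy_mean,decoy_sd decoy raw-score scale.
#' @param return_poses generate and re-score full pose lists.
#' @param seed RNG seed.
#' @return list: `set` (a [labeled_pairs()] frame), `poses` (named list of
#'   pose lists or `NULL`), `z_target` (the drawn targets).
#' @export
gen_benchmark <- function(n_pos, n_neg, preset = "model",
                          z_pos_mean = NULL, z_neg_mean = NULL, z_sd = 1.5,
                          n_poses = 2000L, decoy_mean = 20, decoy_sd = 4,
                          return_poses = FALSE, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 0L, z_sd >= 0)
  pm <- benchmark_preset(preset)
  if (is.null(z_pos_mean)) z_pos_mean <- pm[["pos"]]
  if (is.null(z_neg_mean)) z_neg_mean <- pm[["neg"]]
  pos <- data.frame(idA = sprintf("P%05d", seq_len(n_pos) * 2L - 1L),
                    idB = sprintf("P%05d", seq_len(n_pos) * 2L),
                    stringsAsFactors = FALSE)
  neg <- shuffle_negatives(pos, n_neg, seed = seed)
  with_seed(seed, {
    zt <- c(stats::rnorm(n_pos, z_pos_mean, z_sd),
            if (n_neg > 0L) stats::rnorm(n_neg, z_neg_mean, z_sd))
    idA <- c(pos$idA, neg$idA); idB <- c(pos$idB, neg$idB)
    label <- rep(c("positive", "negative"), c(n_pos, n_neg))
    if (return_poses) {
      poses <- vector("list", length(zt))
      z <- numeric(length(zt))
      for (i in seq_along(zt)) {
        pl <- gen_pose_list_core(zt[i], n_poses, decoy_mean, decoy_sd)
        pl$pair <- c(idA[i], idB[i])
        poses[[i]] <- pl
        z[i] <- dock_z_score(pl)$z
      }
      names(poses) <- pair_key(idA, idB)
    } else {
      poses <- NULL
      z <- zt
    }
    list(set = labeled_pairs(idA, idB, z, label), poses = poses,
         z_target = zt)
  })
}

## ---- toy structures -------------------------------------------------------

fibonacci_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

poly_ala_structure <- function(id, chain, ca, cb, jitter) {
  n <- nrow(ca)
  if (jitter > 0) {
    ca <- ca + matrix(stats::rnorm(3L * n, 0, jitter), n, 3L)
    cb <- cb + matrix(stats::rnorm(3L * n, 0, jitter), n, 3L)
  }
  atoms <- data.frame(
    chain = chain,
    resno = rep(seq_len(n), each = 2L),
    resname = "ALA",
    atom = rep(c("CA", "CB"), n),
    element = "C",
    x = as.vector(rbind(ca[, 1], cb[, 1])),
    y = as.vector(rbind(ca[, 2], cb[, 2])),
    z = as.vector(rbind(ca[, 3], cb[, 3])),
    stringsAsFactors = FALSE)
  new_structure(id, atoms)
}

#' Generate toy poly-alanine structures
#'
#' Three deterministic geometries (plus a small seeded coordinate jitter),
#' with CA and CB atoms per residue:
#' * `"helix"`: ideal alpha-helix CA trace (radius 2.3 A, rise 1.5 A/residue,
#'   100 degrees/residue), so consecutive CA-CA distances are ~3.8 A;
#' * `"sphere"`: a closed shell (CA on a Fibonacci sphere of `radius`, CB
#'   2.5 A inward);
#' * `"half_sphere_pair"`: a complementary shell pair - the closed sphere
#'   plus a hemispherical cap shell cupping its upper half 4.6 A above the
#'   surface - returned *assembled*: the identity placement is the planted
#'   shape-complementary pose, with every cap residue in contact (within a
#'   5.5 A cutoff) but clash-free on the docking grid.
#'
#' @param kind geometry name.
#' @param n_residues residues per structure (>= 3); for the pair, per half.
#' @param seed RNG seed for the jitter.
#' @param radius shell radius, Angstrom.
#' @param jitter coordinate noise sd, Angstrom.
#' @return a `protein_structure`, or for `"half_sphere_pair"` a list
#'   `receptor`/`ligand`.
#' @export
gen_toy_structures <- function(kind = c("helix", "sphere", "half_sphere_pair"),
                               n_residues = 20L, seed = 1L, radius = 8,
                               jitter = 0.02) {
  kind <- match.arg(kind)
  stopifnot(n_residues >= 3L)
  with_seed(seed, {
    if (kind == "helix") {
      i <- seq_len(n_residues)
      ang <- i * 100 * pi / 180
      ca <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
      cb <- cbind(3.3 * cos(ang), 3.3 * sin(ang), 1.5 * i)
      poly_ala_structure("helix", "A", ca, cb, jitter)
    } else if (kind == "sphere") {
      ca <- fibonacci_sphere(n_residues, radius)
      cb <- ca * (radius - 2.5) / radius
      poly_ala_structure("sphere", "A", ca, cb, jitter)
    } else {
      # complementary pair: a closed shell ("ball") cupped by a hemispherical
      # cap shell 4.6 A above its surface, returned assembled.  4.6 A between
      # the CA layers keeps every cap residue inside the 5.5 A interface
      # cutoff while staying outside the docking grid's clash zone, so the
      # identity placement is the planted shape-complementary pose.
      sep <- 4.6
      ball <- fibonacci_sphere(n_residues, radius)
      rec <- poly_ala_structure("ball", "A", ball,
                                ball * (radius - 2.5) / radius, jitter)
      rc <- radius + sep
      cap <- fibonacci_sphere(2L * n_residues, rc)
      cap <- cap[cap[, 3] >= 0.35 * rc, , drop = FALSE]
      lig <- poly_ala_structure("cap", "B", cap,
                                cap * (rc + 2.5) / rc, jitter)
      list(receptor = rec, ligand = lig)
    }
  })
}

## ---- toy genomes ----------------------------------------------------------

sense_codons <- function() names(GENETIC_CODE_DNA)[GENETIC_CODE_DNA != "*"]

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a toy genome with planted SNVs and a truth table
#'
#' Builds `n_genes` random protein-coding genes (ATG start, random sense
#' codons, stop codon; one or two CDS segments; both strands used), plants
#' random SNVs inside the CDS, and emits a truth table classifying each
#' planted variant (nonsynonymous with its `p.<Ref><Pos><Alt>` label, or
#' synonymous) *by construction* - from the codon it edits, independently of
#' the genomic-coordinate arithmetic of the annotator the output is meant to
#' test.
#'
#' @param n_genes number of genes (each on its own chromosome).
#' @param seed RNG seed.
#' @param n_codons_range inclusive range for gene length in codons.
#' @param n_variants_per_gene planted SNVs per gene.
#' @param split_cds give each gene two CDS segments separated by an intron.
#' @param strand `NULL` (random per gene) or a fixed `"+"`/`"-"`.
#' @param plant optional list of planted codon edits, each a list
#'   `gene` (index), `codon` (index), `ref_codon`, `alt_codon` (must differ
#'   at exactly one base); forces the gene's codon to `ref_codon` and plants
#'   the corresponding SNV.
#' @return list: `genome` (named chromosome sequences), `genes` (named list
#'   of [gene_model()]), `variants` (data frame `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `gene`), `truth` (data frame `id`, `gene`, `consequence`,
#'   `protein_pos`, `label`).
#' @export
gen_toy_genome <- function(n_genes = 3L, seed = 1L,
                           n_codons_range = c(10L, 50L),
                           n_variants_per_gene = 3L, split_cds = TRUE,
                           strand = NULL, plant = NULL) {
  stopifnot(n_genes >= 1L)
  with_seed(seed, {
    genome <- character(0)
    genes <- list()
    vrows <- list(); trows <- list()
    vid <- 0L
    for (g in seq_len(n_genes)) {
      gid <- sprintf("gene%03d", g)
      chrom <- sprintf("chr%d", g)
      st <- if (is.null(strand)) sample(c("+", "-"), 1L) else strand
      nc <- sample(seq(n_codons_range[1], n_codons_range[2]), 1L)
      codons <- c("ATG", sample(sense_codons(), nc - 2L, replace = TRUE), "TAA")
      planted_here <- Filter(function(p) p$gene == g,
                             if (is.null(plant)) list() else plant)
      for (p in planted_here) {
        stopifnot(nchar(p$ref_codon) == 3L, nchar(p$alt_codon) == 3L,
                  p$codon >= 1L, p$codon <= nc)
        diffs <- which(strsplit(p$ref_codon, "")[[1L]] !=
                         strsplit(p$alt_codon, "")[[1L]])
        if (length(diffs) != 1L)
          stop("planted codons must differ at exactly one base")
        codons[p$codon] <- toupper(p$ref_codon)
      }
      cds <- paste(codons, collapse = "")
      L <- nchar(cds)
      # genomic layout: flank + exon(s with optional intron) + flank
      k <- if (split_cds && L >= 6L) sample(seq(3L, L - 3L), 1L) else L
      ilen <- if (k < L) sample(20:60, 1L) else 0L
      f <- sample(20:80, 1L)
      if (st == "+") {
        body <- if (k < L)
          paste0(substr(cds, 1L, k), random_dna(ilen), substr(cds, k + 1L, L))
        else cds
        starts <- if (k < L) c(f + 1L, f + k + ilen + 1L) else f + 1L
        ends <- if (k < L) c(f + k, f + L + ilen) else f + L
        cds2gen <- function(c) if (c <= k) f + c else f + ilen + c
      } else {
        exA <- substr(cds, 1L, k); exB <- substr(cds, k + 1L, L)
        body <- if (k < L)
          paste0(revcomp(exB), random_dna(ilen), revcomp(exA))
        else revcomp(cds)
        # segment1 (low coords) = revcomp(exB), segment2 = revcomp(exA)
        s1s <- f + 1L; s1e <- f + (L - k)
        s2s <- s1e + ilen + 1L; s2e <- s2s + k - 1L
        starts <- if (k < L) c(s1s, s2s) else f + 1L
        ends <- if (k < L) c(s1e, s2e) else f + L
        cds2gen <- function(c) if (c <= k) s2e - (c - 1L)
        else s1e - (c - k - 1L)
        if (k == L) cds2gen <- function(c) f + L - (c - 1L)
      }
      seq_chr <- paste0(random_dna(f), body, random_dna(sample(20:60, 1L)))
      genome[[chrom]] <- seq_chr
      genes[[gid]] <- gene_model(gid, chrom, st, starts, ends)
      # plant variants: specified codon edits first, then random ones
      mk_variant <- function(cpos, alt_cb) {
        vid <<- vid + 1L
        pos <- cds2gen(cpos)
        ref_g <- substr(seq_chr, pos, pos)
        alt_g <- if (st == "+") alt_cb else COMPLEMENT[[alt_cb]]
        ci <- (cpos - 1L) %/% 3L + 1L
        within <- cpos - (ci - 1L) * 3L
        ref_codon <- codons[ci]
        alt_codon <- ref_codon
        substr(alt_codon, within, within) <- alt_cb
        ra <- GENETIC_CODE_DNA[[ref_codon]]; aa <- GENETIC_CODE_DNA[[alt_codon]]
        id <- sprintf("snv%04d", vid)
        vrows[[length(vrows) + 1L]] <<- data.frame(
          chrom = chrom, pos = pos, id = id, ref = ref_g, alt = alt_g,
          gene = gid, stringsAsFactors = FALSE)
        trows[[length(trows) + 1L]] <<- data.frame(
          id = id, gene = gid,
          consequence = if (ra == aa) "synonymous" else "nonsynonymous",
          protein_pos = ci,
          label = if (ra == aa) NA_character_ else
            sprintf("p.%s%d%s", AA_THREE[[ra]], ci, AA_THREE[[aa]]),
          stringsAsFactors = FALSE)
      }
      for (p in planted_here) {
        diffp <- which(strsplit(p$ref_codon, "")[[1L]] !=
                         strsplit(p$alt_codon, "")[[1L]])
        cpos <- (p$codon - 1L) * 3L + diffp
        mk_variant(cpos, substr(toupper(p$alt_codon), diffp, diffp))
      }
      if (n_variants_per_gene > 0L) {
        for (cpos in sample(L, min(n_variants_per_gene, L))) {
          ref_cb <- substr(cds, cpos, cpos)
          alt_cb <- sample(setdiff(c("A", "C", "G", "T"), ref_cb), 1L)
          mk_variant(cpos, alt_cb)
        }
      }
    }
    list(genome = genome, genes = genes,
         variants = do.call(rbind, vrows),
         truth = do.call(rbind, trows))
  })
}

#' Write a genome as FASTA
#'
#' @param genome named character vector of chromosome sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write gene models as GFF3 (CDS subset)
#'
#' Emits one `gene` feature and its `CDS` segments per gene model, with the
#' CDS `Parent` attribute set to the gene id - the dialect consumed by
#' [read_gene_models()].
#'
#' @param genes list of [gene_model()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  out <- "##gff-version 3"
  for (g in genes) {
    lo <- pmin(g$starts, g$ends); hi <- pmax(g$starts, g$ends)
    out <- c(out,
             sprintf("%s\tdocknet\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     g$chrom, min(lo), max(hi), g$strand, g$gene_id),
             sprintf("%s\tdocknet\tCDS\t%d\t%d\t.\t%s\t0\tID=cds:%s;Parent=%s",
                     g$chrom, lo, hi, g$strand, g$gene_id, g$gene_id))
  }
  writeLines(out, path)
  invisible(path)
}
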