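# Readers/writers for the external formats the toolkit touches.
# Dialects are deliberately strict and documented per function.

## ---- Structure ------------------------------------------------------------

new_structure <- function(id, atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(atoms))) stop("atoms is missing required columns")
  if (nrow(atoms) == 0L) stop("empty structure: no atoms after filtering")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in structure '", id, "'")
  # residue numbers must be strictly increasing along each chain
  for (ch in unique(atoms$chain)) {
    rn <- atoms$resno[atoms$chain == ch]
    rn <- rn[c(TRUE, rn[-1L] != rn[-length(rn)])]   # collapse runs
    if (any(diff(rn) <= 0))
      stop("residue numbers not strictly increasing in chain ", ch)
  }
  structure(list(id = id, atoms = atoms), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  nres <- sum(!duplicated(x$atoms[c("chain", "resno")]))
  cat(sprintf("<protein_structure '%s': %d chain(s) [%s], %d residues, %d atoms>\n",
              x$id, length(ch), paste(ch, collapse = ","), nres, nrow(x$atoms)))
  invisible(x)
}

#' Read a protein structure from PDB-format text
#'
#' Parses `ATOM` records using the PDB v3.3 fixed-column layout.  `HETATM`
#' records and alternate locations other than `' '`/`'A'` are dropped; chain
#' order is preserved as encountered.  Multi-model files, insertion codes and
#' mmCIF are out of scope.
#'
#' @param x file path, a single string containing the PDB text, or a character
#'   vector of lines.
#' @param id structure identifier (defaults to the file name or "structure").
#' @return a `protein_structure`: a list with `id` and an `atoms` data frame
#'   (`chain`, `resno`, `resname`, `atom`, `element`, `x`, `y`, `z` in
#'   Angstrom).
#' @seealso [write_structure()]
#' @export
read_structure <- function(x, id = NULL) {
  if (is.null(id))
    id <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
      sub("\\.[^.]*$", "", basename(x)) else "structure"
  lines <- read_lines_flex(x)
  rec <- substr(lines, 1L, 6L)
  keep <- which(rec == "ATOM  ")
  if (length(keep) == 0L) stop("empty structure: no ATOM records")
  num <- function(s, i, what) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v)))
      stop("malformed ATOM record at line ", i[which(is.na(v))[1L]],
           ": bad ", what, " field")
    v
  }
  ln <- lines[keep]
  altloc <- substr(ln, 17L, 17L)
  ok <- altloc %in% c(" ", "A")
  ln <- ln[ok]; keep <- keep[ok]
  if (length(ln) == 0L) stop("empty structure: all atoms dropped by altloc filter")
  atoms <- data.frame(
    chain   = substr(ln, 22L, 22L),
    resno   = as.integer(num(trimws(substr(ln, 23L, 26L)), keep, "residue number")),
    resname = trimws(substr(ln, 18L, 20L)),
    atom    = trimws(substr(ln, 13L, 16L)),
    element = trimws(substr(ln, 77L, 78L)),
    x = num(trimws(substr(ln, 31L, 38L)), keep, "x"),
    y = num(trimws(substr(ln, 39L, 46L)), keep, "y"),
    z = num(trimws(substr(ln, 47L, 54L)), keep, "z"),
    stringsAsFactors = FALSE)
  # derive element from the atom name when columns 77-78 are blank
  blank <- atoms$element == ""
  atoms$element[blank] <- substr(gsub("[^A-Za-z].*$", "", atoms$atom[blank]), 1L, 1L)
  new_structure(id, atoms)
}

#' Write a structure as PDB-format text
#'
#' Inverse of [read_structure()]: coordinates are printed with three decimals,
#' so a write/read round trip reproduces them to printed precision.
#'
#' @param s a `protein_structure`.
#' @param path optional file path; when `NULL` the text is returned invisibly.
#' @return the PDB text, invisibly, as a character vector of lines.
#' @export
write_structure <- function(s, path = NULL) {
  stopifnot(inherits(s, "protein_structure"))
  a <- s$atoms
  nm <- ifelse(nchar(a$atom) < 4L, sprintf(" %-3s", a$atom), a$atom)
  ln <- sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                seq_len(nrow(a)), nm, a$resname, a$chain, a$resno,
                a$x, a$y, a$z, a$element)
  out <- c(ln, "END")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Merge two single-structure objects into one multi-chain complex
#'
#' Convenience for interface analysis: relabels the chains of `b` so that the
#' result has distinct chain identifiers.
#'
#' @param a,b `protein_structure` objects.
#' @param chains length-2 character vector of chain ids for `a` and `b`.
#' @return a two-chain `protein_structure`.
#' @export
merge_structures <- function(a, b, chains = c("A", "B")) {
  stopifnot(inherits(a, "protein_structure"), inherits(b, "protein_structure"))
  aa <- a$atoms; ba <- b$atoms
  aa$chain <- chains[1L]; ba$chain <- chains[2L]
  new_structure(paste0(a$id, "-", b$id), rbind(aa, ba))
}

## ---- Pose scores ----------------------------------------------------------

#' Construct a ranked pose list
#'
#' A `pose_list` holds the docking scores of one protein pair in rank order
#' (rank 1 first) exactly as produced by the docking engine; it is never
#' re-sorted.
#'
#' @param scores numeric vector of pose scores, rank 1 first; length >= 2.
#' @param pair character vector of the two protein ids (unordered identity).
#' @return an object of class `pose_list`.
#' @export
pose_list <- function(scores, pair = c(NA_character_, NA_character_)) {
  scores <- as.numeric(scores)
  if (length(scores) < 2L) stop("a pose list needs at least 2 poses")
  if (any(!is.finite(scores))) stop("non-finite pose score")
  structure(list(pair = as.character(pair), scores = scores,
                 n_poses = length(scores)), class = "pose_list")
}

#' @export
print.pose_list <- function(x, ...) {
  cat(sprintf("<pose_list %s: %d poses, top score %.3f>\n",
              paste(x$pair, collapse = "-"), x$n_poses, x$scores[1L]))
  invisible(x)
}

#' Read ranked docking pose scores
#'
#' Dialect: optional `#`-prefixed header lines, then one pose per line with
#' whitespace-separated fields and the score in the *last* field.  The line
#' order is the rank order (rank 1 = first pose line).  This permissive
#' "score-is-last-field" dialect covers the output-variants of common
#' rigid-docking programs and is trivially writable by the simulator.
#'
#' @param x file path, single string, or character vector of lines.
#' @param pair optional pair ids to attach.
#' @return a [pose_list()].
#' @export
read_pose_scores <- function(x, pair = c(NA_character_, NA_character_)) {
  lines <- read_lines_flex(x)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty input: no pose lines")
  last <- vapply(strsplit(trimws(lines), "[ \t]+"), function(f) f[length(f)], "")
  scores <- suppressWarnings(as.numeric(last))
  if (any(is.na(scores)))
    stop("non-numeric score field at pose line ", which(is.na(scores))[1L],
         " (dialect: score must be the last whitespace-separated field)")
  pose_list(scores, pair)
}

#' Write pose scores in the score-is-last-field dialect
#'
#' @param poses a [pose_list()].
#' @param path optional output file.
#' @param seed optional seed to record in the header comment.
#' @return the lines, invisibly.
#' @export
write_pose_scores <- function(poses, path = NULL, seed = NULL) {
  stopifnot(inherits(poses, "pose_list"))
  hdr <- sprintf("# docknet pose scores pair=%s n=%d%s",
                 paste(poses$pair, collapse = ","), poses$n_poses,
                 if (is.null(seed)) "" else sprintf(" seed=%d", as.integer(seed)))
  out <- c(hdr, sprintf("%d\t%.10g", seq_len(poses$n_poses), poses$scores))
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

## ---- Pair lists -----------------------------------------------------------

#' Read a TSV list of protein pairs
#'
#' Tab-separated, no header.  Pair identity is unordered and canonicalized
#' lexicographically; input order is preserved.  Self-pairs are rejected
#' because the network is defined without self-interactions.
#'
#' @param x file path, single string, or character vector of lines.
#' @param with_scores when `TRUE` a third numeric column `value` is required.
#' @return a data frame with columns `idA`, `idB` (and `value`).
#' @export
read_pairs_tsv <- function(x, with_scores = FALSE) {
  lines <- read_lines_flex(x)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(if (with_scores)
      data.frame(idA = character(), idB = character(), value = numeric())
      else data.frame(idA = character(), idB = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  want <- if (with_scores) 3L else 2L
  if (any(nf < want))
    stop("line ", which(nf < want)[1L], ": expected at least ", want,
         " tab-separated fields")
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  if (any(a == b))
    stop("self-pair not allowed (line ",
         paste(which(a == b), collapse = ", "), ")")
  out <- canonical_pairs(a, b)
  if (with_scores) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    if (any(is.na(v))) stop("non-numeric value field at line ", which(is.na(v))[1L])
    out$value <- v
  }
  out
}

#' Write a pair list as TSV
#'
#' @param pairs data frame with `idA`, `idB` and optionally `value`.
#' @param path optional output file.
#' @return the lines, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path = NULL) {
  stopifnot(all(c("idA", "idB") %in% names(pairs)))
  out <- if ("value" %in% names(pairs))
    sprintf("%s\t%s\t%.10g", pairs$idA, pairs$idB, pairs$value)
  else sprintf("%s\t%s", pairs$idA, pairs$idB)
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

## ---- VCF subset -----------------------------------------------------------

#' Read single-nucleotide variants from a VCF
#'
#' Minimal SNV-only subset of VCF 4.x: only CHROM, POS, ID, REF and ALT are
#' consumed.  Records that are not simple SNVs (multi-base or non-ACGT REF/ALT,
#' multi-allelic ALT) are skipped with a warning.  Genomic positions are
#' 1-based.
#'
#' @param x file path, single string, or character vector of lines.
#' @return data frame `chrom`, `pos`, `id`, `ref`, `alt`.
#' @export
read_vcf_snvs <- function(x) {
  lines <- read_lines_flex(x)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), pos = integer(), id = character(),
                      ref = character(), alt = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 5L))
    stop("line ", which(lengths(fields) < 5L)[1L], ": expected >= 5 VCF columns")
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    pos   = as.integer(vapply(fields, `[[`, "", 2L)),
    id    = vapply(fields, `[[`, "", 3L),
    ref   = toupper(vapply(fields, `[[`, "", 4L)),
    alt   = toupper(vapply(fields, `[[`, "", 5L)),
    stringsAsFactors = FALSE)
  snv <- df$ref %in% c("A", "C", "G", "T") & df$alt %in% c("A", "C", "G", "T") &
    df$ref != df$alt
  if (any(!snv))
    warning(sum(!snv), " non-SNV record(s) skipped")
  df[snv, , drop = FALSE]
}

#' Write SNVs as a minimal VCF
#'
#' @param snvs data frame as returned by [read_vcf_snvs()].
#' @param path optional output file.
#' @return the lines, invisibly.
#' @export
write_vcf_snvs <- function(snvs, path = NULL) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(snvs)))
  id <- if ("id" %in% names(snvs)) snvs$id else rep(".", nrow(snvs))
  out <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                   snvs$chrom, snvs$pos, id, snvs$ref, snvs$alt))
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

## ---- Gene models (GFF3 CDS subset) ----------------------------------------

#' Construct a gene model
#'
#' A gene model is the minimal CDS description needed to annotate SNVs:
#' 1-based closed genomic CDS intervals in *translation order* (ascending for
#' `+` strand genes, descending for `-`).  CDS phase is recomputed from the
#' segment order rather than trusted from input.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends integer vectors of CDS segment bounds (1-based closed),
#'   given in any order; they are sorted into translation order.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, starts, ends) {
  stopifnot(strand %in% c("+", "-"), length(starts) == length(ends),
            length(starts) >= 1L)
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (any(ends < starts)) stop("CDS segment with end < start")
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (any(starts[-1L] <= ends[-length(ends)]))
    stop("overlapping CDS segments in gene ", gene_id)
  if (sum(ends - starts + 1L) %% 3L != 0L)
    stop("total CDS length of gene ", gene_id, " not divisible by 3")
  if (strand == "-") { starts <- rev(starts); ends <- rev(ends) }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 starts = starts, ends = ends), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s %s(%s): %d CDS segment(s), %d bp>\n",
              x$gene_id, x$chrom, x$strand, length(x$starts),
              sum(abs(x$ends - x$starts) + 1L)))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Consumes only `CDS` features, grouped by their `Parent` attribute (the
#' gene/transcript id).  Everything else in the file is ignored.
#'
#' @param path GFF3 file path.
#' @return named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(cds) == 0L) stop("no CDS features in ", path)
  parent <- vapply(as.list(cds$Parent),
                   function(p) if (length(p)) p[[1L]] else NA_character_, "")
  if (anyNA(parent) || any(!nzchar(parent)))
    stop("CDS feature without Parent attribute")
  out <- list()
  for (g in unique(parent)) {
    sel <- cds[parent == g]
    chrom <- as.character(GenomicRanges::seqnames(sel))
    strand <- as.character(GenomicRanges::strand(sel))
    if (length(unique(chrom)) != 1L || length(unique(strand)) != 1L)
      stop("CDS segments of ", g, " span chromosomes or strands")
    out[[g]] <- gene_model(g, chrom[1L], strand[1L],
                           GenomicRanges::start(sel), GenomicRanges::end(sel))
  }
  out
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA file path.
#' @return named character vector of upper-case DNA sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
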