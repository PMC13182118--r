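#' Construct a milk-protein gene model
#'
#' A gene model holds the genomic structure of one milk-protein gene and
#' everything needed to map genomic positions to coding-sequence (CDS),
#' precursor-protein and mature-protein coordinates: exon intervals, CDS
#' bounds, strand, the reference coding sequence in transcription
#' orientation, and the length of the signal peptide that is cleaved off to
#' yield the mature protein.
#'
#' All coordinates are 1-based inclusive, matching VCF conventions. The
#' coding sequence excludes the terminal stop codon, so its length is three
#' times the precursor protein length.
#'
#' @param name gene symbol (e.g. "CSN2").
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive genomic bounds of the gene.
#' @param strand "+" (forward) or "-" (reverse).
#' @param exons two-column matrix or data.frame of exon (start, end)
#'   intervals, 1-based inclusive, non-overlapping.
#' @param cds_start,cds_end genomic bounds of the coding sequence.
#' @param signal_peptide_len number of N-terminal amino acids removed from
#'   the precursor to yield the mature protein.
#' @param cds_sequence reference coding nucleotide sequence in transcription
#'   orientation (reverse-complemented for reverse-strand genes), without the
#'   terminal stop codon; length must be a multiple of 3 and equal the summed
#'   exon/CDS overlap.
#' @param flank flanking distance in bp considered part of the gene region
#'   (default 2000).
#' @param reference_variant_name name of the protein variant encoded by the
#'   reference sequence (e.g. "B" for kappa-casein).
#' @return an object of class `gene_model`.
#' @examples
#' gm <- gene_model("TOY", "1", 100, 400, "+",
#'   exons = cbind(c(101, 201), c(160, 260)),
#'   cds_start = 110, cds_end = 251, signal_peptide_len = 2,
#'   cds_sequence = toy_cds(34), reference_variant_name = "A")
#' gene_length(gm)
#' @export
gene_model <- function(name, chrom, start, end, strand, exons,
                       cds_start, cds_end, signal_peptide_len,
                       cds_sequence, flank = 2000,
                       reference_variant_name = "REF") {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  dimnames(exons) <- list(NULL, c("start", "end"))
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-'", call. = FALSE)
  if (start > end) stop("start must be <= end", call. = FALSE)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 1] > exons[, 2]))
    stop("exon start > end", call. = FALSE)
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stop("exons overlap", call. = FALSE)
  if (exons[1, 1] < start || exons[nrow(exons), 2] > end)
    stop("exons outside gene bounds", call. = FALSE)
  cds_sequence <- toupper(cds_sequence)
  if (nchar(cds_sequence) %% 3 != 0)
    stop("cds_sequence length must be a multiple of 3", call. = FALSE)

  m <- structure(list(
    name = name, chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    strand = strand, exons = exons,
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    signal_peptide_len = as.integer(signal_peptide_len),
    cds_sequence = cds_sequence, flank = as.integer(flank),
    reference_variant_name = reference_variant_name
  ), class = "gene_model")

  m$cds_map <- cds_genomic_positions(m)
  if (length(m$cds_map) != nchar(cds_sequence))
    stop(sprintf(
      "cds_sequence length (%d) != summed exon/CDS overlap (%d) in %s",
      nchar(cds_sequence), length(m$cds_map), name), call. = FALSE)
  n_aa <- nchar(cds_sequence) / 3
  if (signal_peptide_len < 0 || signal_peptide_len >= n_aa - 1)
    stop("signal_peptide_len must be in [0, protein length - 2)", call. = FALSE)
  if (grepl("[^ACGT]", cds_sequence))
    stop("cds_sequence contains non-ACGT characters", call. = FALSE)
  if (any(grepl("\\*", translate_cds(cds_sequence))))
    stop("cds_sequence contains an internal stop codon", call. = FALSE)
  m
}

# Genomic positions of CDS bases in transcription orientation:
# element i is the genomic coordinate of CDS offset i.
cds_genomic_positions <- function(model) {
  pos <- integer(0)
  for (i in seq_len(nrow(model$exons))) {
    lo <- max(model$exons[i, 1], model$cds_start)
    hi <- min(model$exons[i, 2], model$cds_end)
    if (lo <= hi) pos <- c(pos, lo:hi)
  }
  if (model$strand == "-") pos <- rev(pos)
  pos
}

#' @export
#' @method print gene_model
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model> %s  %s:%s-%s (%s)  %d exons, CDS %d nt (%d aa, signal peptide %d aa)\n",
    x$name, x$chrom, format(x$start, big.mark = ","),
    format(x$end, big.mark = ","), x$strand, nrow(x$exons),
    nchar(x$cds_sequence), nchar(x$cds_sequence) / 3, x$signal_peptide_len))
  cat(sprintf("  reference protein variant: %s; flank: %d bp\n",
              x$reference_variant_name, x$flank))
  invisible(x)
}

#' Gene length in base pairs
#'
#' Length of the gene body as `end - start + 1` (1-based inclusive
#' coordinates).
#'
#' @param model a `gene_model`.
#' @return integer number of base pairs.
#' @export
gene_length <- function(model) {
  model$end - model$start + 1L
}

#' Map a genomic position to a CDS offset
#'
#' Returns the 1-based offset of a genomic position along the coding
#' sequence in transcription orientation, or `NA` for positions inside the
#' gene region that are non-coding. Reverse-strand genes count from the
#' high-coordinate CDS end downward.
#'
#' @param model a `gene_model`.
#' @param pos genomic position(s); must lie within the gene +/- flank.
#' @return integer vector of CDS offsets, `NA` where non-coding.
#' @export
genomic_to_cds <- function(model, pos) {
  lo <- model$start - model$flank
  hi <- model$end + model$flank
  if (any(pos < lo | pos > hi))
    stop(sprintf("position outside %s +/- %d bp", model$name, model$flank),
         call. = FALSE)
  match(as.integer(pos), model$cds_map)
}

#' Map a CDS offset back to its genomic position
#'
#' Inverse of [genomic_to_cds()].
#'
#' @param model a `gene_model`.
#' @param offset 1-based CDS offset(s).
#' @return integer genomic position(s).
#' @export
cds_to_genomic <- function(model, offset) {
  if (any(offset < 1 | offset > length(model$cds_map)))
    stop("CDS offset out of range", call. = FALSE)
  model$cds_map[offset]
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(x) {
  paste(rev(DNA_COMPLEMENT[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) stop("invalid codon: ", codon, call. = FALSE)
  aa
}

translate_cds <- function(cds) {
  n <- nchar(cds) / 3
  vapply(seq_len(n), function(i)
    translate_codon(substr(cds, 3 * i - 2, 3 * i)), character(1))
}

#' Amino-acid consequence of a single-base CDS change
#'
#' Substitutes `alt_base` (given in transcription orientation) at the given
#' CDS offset, translates the affected codon with the standard genetic code,
#' and reports the precursor-protein position and the reference/alternate
#' amino acids.
#'
#' @param model a `gene_model`.
#' @param cds_offset 1-based offset into the coding sequence.
#' @param alt_base alternate nucleotide in transcription orientation.
#' @return a list with `precursor_pos`, `ref_aa`, `alt_aa` (single-letter
#'   codes) and logical `synonymous`.
#' @export
codon_effect <- function(model, cds_offset, alt_base) {
  n <- nchar(model$cds_sequence)
  if (cds_offset < 1 || cds_offset > n)
    stop("CDS offset out of range", call. = FALSE)
  aa_pos <- ceiling(cds_offset / 3)
  codon <- substr(model$cds_sequence, 3 * aa_pos - 2, 3 * aa_pos)
  within <- cds_offset - 3 * (aa_pos - 1)
  alt_codon <- codon
  substr(alt_codon, within, within) <- toupper(alt_base)
  ref_aa <- translate_codon(codon)
  alt_aa <- translate_codon(alt_codon)
  list(precursor_pos = aa_pos, ref_aa = ref_aa, alt_aa = alt_aa,
       synonymous = identical(ref_aa, alt_aa))
}

#' Classify an SNV by gene region
#'
#' Assigns one of the region categories used in variant-type composition
#' tables: `upstream`, `five_prime_utr`, `intron`, `synonymous`, `missense`,
#' `three_prime_utr`, `downstream`, or `coding_other` (reserved for
#' stop-affecting coding changes). Upstream/downstream are relative to
#' transcription direction: on reverse-strand genes the upstream flank is the
#' higher-coordinate side.
#'
#' @param model a `gene_model`.
#' @param pos genomic position within gene +/- flank.
#' @param ref,alt single reference and alternate bases (reference-strand
#'   orientation, as in VCF).
#' @return a category string.
#' @export
classify_region <- function(model, pos, ref, alt) {
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    stop(structure(class = c("lactovar_unsupported_variant", "error",
                             "condition"),
                   list(message = "only single-base SNVs are supported",
                        call = sys.call())))
  lo <- model$start - model$flank
  hi <- model$end + model$flank
  if (pos < lo || pos > hi)
    stop(sprintf("position outside %s +/- %d bp", model$name, model$flank),
         call. = FALSE)
  fwd <- model$strand == "+"
  if (pos < model$start) return(if (fwd) "upstream" else "downstream")
  if (pos > model$end)   return(if (fwd) "downstream" else "upstream")

  offset <- match(as.integer(pos), model$cds_map)
  if (!is.na(offset)) {
    alt_tx <- if (fwd) toupper(alt) else DNA_COMPLEMENT[[toupper(alt)]]
    eff <- codon_effect(model, offset, alt_tx)
    if (eff$alt_aa == "*") return("coding_other")
    return(if (eff$synonymous) "synonymous" else "missense")
  }
  in_exon <- any(pos >= model$exons[, 1] & pos <= model$exons[, 2])
  if (in_exon) {
    before_cds <- pos < model$cds_start
    five_prime <- if (fwd) before_cds else pos > model$cds_end
    return(if (five_prime) "five_prime_utr" else "three_prime_utr")
  }
  "intron"
}

#' All region categories
#'
#' The within-gene categories used by composition tables plus the two flank
#' classes.
#' @return character vector of category names.
#' @export
region_categories <- function() {
  c("upstream", "five_prime_utr", "intron", "synonymous", "missense",
    "three_prime_utr", "downstream", "coding_other")
}

#' Read gene models from a TSV file
#'
#' Expected columns: `gene`, `chrom`, `start`, `end`, `strand`, `exons`
#' (semicolon-joined `start-end` intervals), `cds_start`, `cds_end`,
#' `signal_peptide_len`, `cds_sequence`, `reference_variant_name` and
#' optionally `flank`.
#'
#' @param path TSV file path.
#' @return named list of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  models <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    iv <- do.call(rbind, lapply(strsplit(r$exons, ";")[[1]], function(s) {
      as.integer(strsplit(s, "-")[[1]])
    }))
    gene_model(
      name = r$gene, chrom = r$chrom,
      start = as.integer(r$start), end = as.integer(r$end),
      strand = r$strand, exons = iv,
      cds_start = as.integer(r$cds_start), cds_end = as.integer(r$cds_end),
      signal_peptide_len = as.integer(r$signal_peptide_len),
      cds_sequence = r$cds_sequence,
      flank = if ("flank" %in% names(r)) as.integer(r$flank) else 2000L,
      reference_variant_name = r$reference_variant_name)
  })
  names(models) <- tab$gene
  models
}

#' Write gene models to a TSV file
#'
#' @param models named list of `gene_model` objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  rows <- lapply(models, function(m) {
    data.frame(
      gene = m$name, chrom = m$chrom, start = m$start, end = m$end,
      strand = m$strand,
      exons = paste(sprintf("%d-%d", m$exons[, 1], m$exons[, 2]),
                    collapse = ";"),
      cds_start = m$cds_start, cds_end = m$cds_end,
      signal_peptide_len = m$signal_peptide_len,
      cds_sequence = m$cds_sequence, flank = m$flank,
      reference_variant_name = m$reference_variant_name,
      stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate gene models against expected sizes
#'
#' Recomputes `end - start + 1` for each model and compares it with an
#' expected size table (e.g. published gene sizes), flagging discrepancies
#' rather than silently correcting either side.
#'
#' @param models named list of `gene_model` objects.
#' @param expected_sizes named integer vector of expected sizes in bp
#'   (names are gene symbols); optional.
#' @return data.frame with computed length, expected size and a
#'   `size_mismatch` flag.
#' @export
validate_gene_models <- function(models, expected_sizes = NULL) {
  out <- data.frame(
    gene = vapply(models, `[[`, character(1), "name"),
    length_bp = vapply(models, gene_length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(expected_sizes)) {
    out$expected_bp <- unname(expected_sizes[out$gene])
    out$size_mismatch <- !is.na(out$expected_bp) &
      out$length_bp != out$expected_bp
    for (g in out$gene[which(out$size_mismatch)])
      warning(sprintf("gene %s: computed length %d != expected %d",
                      g, out$length_bp[out$gene == g],
                      out$expected_bp[out$gene == g]), call. = FALSE)
  }
  out
}
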