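#' Read a sample-to-breed panel
#'
#' @param path TSV with columns `sample_id` and `breed`.
#' @return a `sample_panel` data.frame with one row per sample and a
#'   `small_breed` flag for breeds represented by fewer than 2 animals.
#' @export
read_panel <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  sample_panel(tab$sample_id, tab$breed)
}

#' Build a sample panel from vectors
#'
#' @param sample_id ordered sample identifiers (unique).
#' @param breed breed label per sample.
#' @return a `sample_panel` data.frame.
#' @export
sample_panel <- function(sample_id, breed) {
  if (anyDuplicated(sample_id)) stop("duplicate sample ids", call. = FALSE)
  if (length(sample_id) != length(breed))
    stop("sample_id and breed lengths differ", call. = FALSE)
  counts <- table(breed)
  p <- data.frame(sample_id = as.character(sample_id),
                  breed = as.character(breed),
                  stringsAsFactors = FALSE)
  p$small_breed <- counts[p$breed] < 2
  class(p) <- c("sample_panel", "data.frame")
  p
}

#' Breed sizes of a panel
#' @param panel a `sample_panel`.
#' @return named integer vector of animals per breed.
#' @export
breed_counts <- function(panel) {
  tab <- table(panel$breed)
  stats::setNames(as.integer(tab), names(tab))
}

variant_key <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d:%s>%s", chrom, as.integer(pos), ref, alt)
}

new_variant_set <- function(variants, gt, ad, dp, panel, n_skipped_indels = 0L) {
  structure(list(variants = variants, gt = gt, ad = ad, dp = dp,
                 panel = panel, n_skipped_indels = n_skipped_indels),
            class = "variant_set")
}

#' @export
#' @method print variant_set
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d SNVs x %d samples (%d breeds)\n",
              nrow(x$variants), nrow(x$panel),
              length(unique(x$panel$breed))))
  if (x$n_skipped_indels > 0)
    cat(sprintf("  %d non-SNV records skipped at read time\n",
                x$n_skipped_indels))
  invisible(x)
}

#' Number of variants in a variant set
#' @param vs a `variant_set`.
#' @return integer count.
#' @export
n_variants <- function(vs) nrow(vs$variants)

subset_variant_set <- function(vs, idx) {
  new_variant_set(vs$variants[idx, , drop = FALSE],
                  vs$gt[idx, , drop = FALSE],
                  vs$ad[idx, , drop = FALSE],
                  vs$dp[idx, , drop = FALSE],
                  vs$panel, vs$n_skipped_indels)
}

parse_gt_dosage <- function(gt, allele) {
  # dosage of a given alt allele index from a diploid GT string; NA if any
  # allele call is missing. Other alt alleles count as non-carrier copies.
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_integer_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_integer_)
  sum(alleles == as.character(allele))
}

#' Read gene-region SNVs from a multi-sample VCF
#'
#' Reads a VCF (plain or gzipped), keeps only single-nucleotide records whose
#' position falls within one of the gene models' regions (gene body plus
#' flank), decomposes multiallelic records into biallelic SNVs, and reorders
#' samples to panel order. Indel/MNV alleles are skipped and counted.
#'
#' For a decomposed alt allele, genotype dosage counts only copies of that
#' allele; copies of other alt alleles at the same site count as non-carrier.
#'
#' @param path VCF file path.
#' @param panel a `sample_panel`; the VCF sample set must equal the panel's.
#' @param models named list of `gene_model` objects defining the regions.
#' @return a `variant_set`: variant table (chrom, pos, id, ref, alt, qual,
#'   mq, gene), plus per-sample dosage (`gt`), alt-read (`ad`) and total
#'   depth (`dp`) matrices.
#' @export
read_variants <- function(path, panel, models) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- tryCatch(vcfR::extract.gt(vcf, element = "GT"),
                     error = function(e)
                       stop("VCF lacks a GT FORMAT field", call. = FALSE))
  if (is.null(gt_raw))
    stop("VCF lacks a GT FORMAT field", call. = FALSE)
  vcf_samples <- colnames(gt_raw)
  if (!setequal(vcf_samples, panel$sample_id))
    stop("VCF samples do not match the panel", call. = FALSE)
  ord <- match(panel$sample_id, vcf_samples)
  gt_raw <- gt_raw[, ord, drop = FALSE]
  ad_raw <- tryCatch(vcfR::extract.gt(vcf, element = "AD")[, ord, drop = FALSE],
                     error = function(e) NULL)
  dp_raw <- tryCatch(vcfR::extract.gt(vcf, element = "DP",
                                      as.numeric = TRUE)[, ord, drop = FALSE],
                     error = function(e) NULL)
  mq <- suppressWarnings(vcfR::extract.info(vcf, element = "MQ",
                                            as.numeric = TRUE))
  if (is.null(mq)) mq <- rep(NA_real_, nrow(fix))

  region <- data.frame(
    gene = vapply(models, `[[`, character(1), "name"),
    chrom = vapply(models, `[[`, character(1), "chrom"),
    lo = vapply(models, function(m) m$start - m$flank, numeric(1)),
    hi = vapply(models, function(m) m$end + m$flank, numeric(1)),
    stringsAsFactors = FALSE)

  rows <- list(); gtl <- list(); adl <- list(); dpl <- list()
  n_skipped <- 0L
  n_samp <- nrow(panel)
  for (i in seq_len(nrow(fix))) {
    chrom <- fix[i, "CHROM"]; pos <- as.integer(fix[i, "POS"])
    hit <- which(region$chrom == chrom & pos >= region$lo & pos <= region$hi)
    if (length(hit) == 0) next
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",")[[1]]
    ad_i <- if (is.null(ad_raw)) rep(NA_character_, n_samp) else ad_raw[i, ]
    dp_i <- if (is.null(dp_raw)) rep(NA_real_, n_samp) else dp_raw[i, ]
    ad_split <- lapply(ad_i, function(x)
      if (is.na(x)) NA_integer_ else suppressWarnings(
        as.integer(strsplit(x, ",")[[1]])))
    for (j in seq_along(alts)) {
      alt <- alts[j]
      if (nchar(ref) != 1L || nchar(alt) != 1L || alt == "*" ||
          !toupper(alt) %in% c("A", "C", "G", "T")) {
        n_skipped <- n_skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, pos = pos,
        id = if (fix[i, "ID"] %in% c(".", NA)) NA_character_ else fix[i, "ID"],
        ref = toupper(ref), alt = toupper(alt),
        qual = suppressWarnings(as.numeric(fix[i, "QUAL"])),
        mq = mq[i], gene = region$gene[hit[1]],
        stringsAsFactors = FALSE)
      gtl[[length(gtl) + 1L]] <-
        vapply(gt_raw[i, ], parse_gt_dosage, integer(1), allele = j)
      adl[[length(adl) + 1L]] <- vapply(ad_split, function(x)
        if (length(x) >= j + 1L) x[j + 1L] else NA_integer_, integer(1))
      dpl[[length(dpl) + 1L]] <- as.numeric(dp_i)
    }
  }
  if (length(rows) == 0) {
    empty <- matrix(NA_integer_, 0, n_samp,
                    dimnames = list(NULL, panel$sample_id))
    return(new_variant_set(
      data.frame(chrom = character(0), pos = integer(0), id = character(0),
                 ref = character(0), alt = character(0), qual = numeric(0),
                 mq = numeric(0), gene = character(0)),
      empty, empty, matrix(NA_real_, 0, n_samp,
                           dimnames = list(NULL, panel$sample_id)),
      panel, n_skipped))
  }
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL
  mk <- function(l, mode) {
    m <- do.call(rbind, l); storage.mode(m) <- mode
    colnames(m) <- panel$sample_id; m
  }
  # fall back to summed allele depths when DP is absent
  dp <- mk(dpl, "double"); ad <- mk(adl, "integer")
  new_variant_set(variants, mk(gtl, "integer"), ad, dp, panel, n_skipped)
}

#' Apply site-quality filters
#'
#' Keeps a variant only if (i) alt-supporting reads reach `min_alt_reads`
#' (summed over the cohort by default, or in at least one sample when
#' `per_sample_reads = TRUE`), (ii) site quality is at least `min_qual`,
#' (iii) mapping quality is at least `min_mq`, and (iv) the alt allele is
#' carried by at least `min_carriers` distinct individuals (a carrier has
#' >= 1 called alt allele; missing genotypes never count). Missing AD, QUAL
#' or MQ annotations pass the corresponding criterion and are logged in the
#' ledger.
#'
#' @param vs a `variant_set`.
#' @param min_alt_reads minimum alt-supporting reads (default 3).
#' @param min_qual minimum phred-scaled site quality (default 20).
#' @param min_mq minimum mapping quality (default 20).
#' @param min_carriers minimum distinct carrier individuals (default 2).
#' @param per_sample_reads if TRUE, the read criterion is per sample.
#' @return list with `kept` (a `variant_set`), `removed` (data.frame of key
#'   and semicolon-joined reasons) and `ledger` (one row per input variant
#'   with the kept flag, reasons and missing-annotation notes).
#' @export
apply_filters <- function(vs, min_alt_reads = 3, min_qual = 20,
                          min_mq = 20, min_carriers = 2,
                          per_sample_reads = FALSE) {
  v <- vs$variants
  n <- nrow(v)
  reasons <- character(n); notes <- character(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    r <- character(0); nt <- character(0)
    ad_i <- vs$ad[i, ]
    if (all(is.na(ad_i))) {
      nt <- c(nt, "no_AD")
    } else {
      ok_reads <- if (per_sample_reads)
        any(ad_i >= min_alt_reads, na.rm = TRUE)
      else sum(ad_i, na.rm = TRUE) >= min_alt_reads
      if (!ok_reads) r <- c(r, "alt_reads")
    }
    if (is.na(v$qual[i])) nt <- c(nt, "no_QUAL")
    else if (v$qual[i] < min_qual) r <- c(r, "qual")
    if (is.na(v$mq[i])) nt <- c(nt, "no_MQ")
    else if (v$mq[i] < min_mq) r <- c(r, "mq")
    carriers <- sum(vs$gt[i, ] >= 1, na.rm = TRUE)
    if (carriers < min_carriers) r <- c(r, "carriers")
    keep[i] <- length(r) == 0
    reasons[i] <- paste(r, collapse = ";")
    notes[i] <- paste(nt, collapse = ";")
  }
  ledger <- data.frame(
    key = variant_key(v$chrom, v$pos, v$ref, v$alt),
    gene = v$gene, kept = keep, reasons = reasons, notes = notes,
    stringsAsFactors = FALSE)
  list(kept = subset_variant_set(vs, which(keep)),
       removed = ledger[!keep, c("key", "gene", "reasons")],
       ledger = ledger)
}

#' Flag low-depth genotypes
#'
#' Marks genotype calls whose read depth is strictly below the threshold as
#' low-confidence, and reports the per-site mean depth across samples.
#'
#' @param vs a `variant_set` with depth information.
#' @param genotype_depth_threshold depth below which a genotype is flagged
#'   (default 6; strict `<`).
#' @return list with a logical `flags` matrix (variants x samples; `FALSE`
#'   where depth is missing) and a data.frame `site_summary` of per-site mean
#'   depth and flag counts.
#' @export
flag_low_depth <- function(vs, genotype_depth_threshold = 6) {
  flags <- vs$dp < genotype_depth_threshold
  flags[is.na(flags)] <- FALSE
  site_summary <- data.frame(
    key = variant_key(vs$variants$chrom, vs$variants$pos,
                      vs$variants$ref, vs$variants$alt),
    gene = vs$variants$gene,
    mean_depth = rowMeans(vs$dp, na.rm = TRUE),
    n_low_depth = rowSums(flags),
    stringsAsFactors = FALSE)
  list(flags = flags, site_summary = site_summary)
}

#' Label variants as known or novel
#'
#' A variant is known if its identifier, or its `chrom:pos:ref>alt` key, is
#' present in a user-supplied list of known identifiers (substituting a
#' catalog lookup against dbSNP/EVA exports).
#'
#' @param vs a `variant_set`.
#' @param known_ids character vector of known identifiers and/or keys.
#' @return `vs` with a `status` column ("known"/"novel") added to the
#'   variant table.
#' @export
label_novelty <- function(vs, known_ids) {
  v <- vs$variants
  key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  known <- (!is.na(v$id) & v$id %in% known_ids) | key %in% known_ids
  vs$variants$status <- ifelse(known, "known", "novel")
  vs
}

#' Annotate variants with region and protein consequence
#'
#' Classifies each SNV into its gene-region category and, for coding SNVs,
#' adds the CDS offset, the precursor- and mature-protein positions, and the
#' reference/alternate amino acids (alternate base taken in transcription
#' orientation).
#'
#' @param vs a `variant_set`.
#' @param models named list of `gene_model` objects (must cover all genes in
#'   `vs`).
#' @return the variant table with columns `category`, `cds_offset`,
#'   `precursor_pos`, `mature_pos`, `ref_aa`, `alt_aa` appended.
#' @export
annotate_variants <- function(vs, models) {
  v <- vs$variants
  n <- nrow(v)
  out <- cbind(v, data.frame(
    category = character(n), cds_offset = rep(NA_integer_, n),
    precursor_pos = rep(NA_integer_, n), mature_pos = rep(NA_integer_, n),
    ref_aa = rep(NA_character_, n), alt_aa = rep(NA_character_, n),
    stringsAsFactors = FALSE))
  for (i in seq_len(n)) {
    m <- models[[v$gene[i]]]
    if (is.null(m)) stop("no gene model for ", v$gene[i], call. = FALSE)
    out$category[i] <- classify_region(m, v$pos[i], v$ref[i], v$alt[i])
    off <- genomic_to_cds(m, v$pos[i])
    if (!is.na(off)) {
      alt_tx <- if (m$strand == "+") v$alt[i] else
        DNA_COMPLEMENT[[v$alt[i]]]
      eff <- codon_effect(m, off, alt_tx)
      out$cds_offset[i] <- off
      out$precursor_pos[i] <- eff$precursor_pos
      out$mature_pos[i] <- eff$precursor_pos - m$signal_peptide_len
      out$ref_aa[i] <- eff$ref_aa
      out$alt_aa[i] <- eff$alt_aa
    }
  }
  out
}
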