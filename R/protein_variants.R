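#' Canonical string form of a substitution set
#'
#' Substitution sets are represented as data.frames with columns
#' `mature_pos`, `ref_aa`, `alt_aa`. The canonical string joins
#' `pos:ref>alt` items with semicolons in increasing position order; the
#' empty set (the gene's reference variant) is the empty string.
#'
#' @param subs data.frame with `mature_pos`, `ref_aa`, `alt_aa`.
#' @return a single string.
#' @export
subs_to_string <- function(subs) {
  if (is.null(subs) || nrow(subs) == 0) return("")
  subs <- subs[order(subs$mature_pos), , drop = FALSE]
  paste(sprintf("%d:%s>%s", subs$mature_pos, subs$ref_aa, subs$alt_aa),
        collapse = ";")
}

#' Parse a canonical substitution-set string
#' @param s string like `"67:H>P;122:S>R"`; `""` gives the empty set.
#' @return data.frame with `mature_pos`, `ref_aa`, `alt_aa`.
#' @export
string_to_subs <- function(s) {
  if (is.na(s) || s == "") {
    return(data.frame(mature_pos = integer(0), ref_aa = character(0),
                      alt_aa = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(s, ";")[[1]], "[:>]")
  data.frame(
    mature_pos = as.integer(vapply(parts, `[`, character(1), 1)),
    ref_aa = vapply(parts, `[`, character(1), 2),
    alt_aa = vapply(parts, `[`, character(1), 3),
    stringsAsFactors = FALSE)
}

#' Mature-protein sequence of a gene model
#'
#' Translates the reference coding sequence and removes the signal peptide.
#'
#' @param model a `gene_model`.
#' @return character vector of single-letter residues, indexed by mature
#'   position.
#' @export
mature_protein <- function(model) {
  aa <- translate_cds(model$cds_sequence)
  if (model$signal_peptide_len > 0) aa <- aa[-seq_len(model$signal_peptide_len)]
  aa
}

#' Build a coding-site table from annotated variants
#'
#' Selects the coding sites of one gene from an annotated variant table and
#' orders them by CDS offset, producing the site metadata used for
#' haplotype construction and translation. Alternate bases are converted to
#' transcription orientation.
#'
#' @param annotated output of [annotate_variants()].
#' @param model the `gene_model` of the gene of interest.
#' @param which `"missense"` (default; what protein-variant haplotypes are
#'   built from) or `"coding"` to also include synonymous sites.
#' @return data.frame with `key`, `pos`, `cds_offset`, `ref_tx`, `alt_tx`,
#'   `precursor_pos`, `ref_aa`, `alt_aa`, sorted by `cds_offset`.
#' @export
coding_sites <- function(annotated, model, which = c("missense", "coding")) {
  which <- match.arg(which)
  cats <- if (which == "missense") "missense" else c("missense", "synonymous")
  a <- annotated[annotated$gene == model$name &
                   annotated$category %in% cats, , drop = FALSE]
  if (nrow(a) == 0) {
    return(data.frame(key = character(0), pos = integer(0),
                      cds_offset = integer(0), ref_tx = character(0),
                      alt_tx = character(0), precursor_pos = integer(0),
                      ref_aa = character(0), alt_aa = character(0),
                      stringsAsFactors = FALSE))
  }
  orient <- function(b) if (model$strand == "+") b else
    unname(DNA_COMPLEMENT[b])
  out <- data.frame(
    key = variant_key(a$chrom, a$pos, a$ref, a$alt),
    pos = a$pos, cds_offset = a$cds_offset,
    ref_tx = orient(a$ref), alt_tx = orient(a$alt),
    precursor_pos = a$precursor_pos, ref_aa = a$ref_aa, alt_aa = a$alt_aa,
    stringsAsFactors = FALSE)
  out <- out[order(out$cds_offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Translate a coding haplotype into mature-protein substitutions
#'
#' Applies the haplotype's alternate alleles to the reference coding
#' sequence, re-translates every affected codon jointly (so two SNVs inside
#' one codon are evaluated together), and returns the resulting amino-acid
#' substitutions relative to the reference variant, numbered on the mature
#' protein. Substitutions inside the signal peptide and synonymous changes
#' are excluded: they do not alter the mature protein.
#'
#' @param model a `gene_model`.
#' @param haplotype string of 0/1 alleles ordered as in `sites`.
#' @param sites site table from [coding_sites()].
#' @return data.frame of substitutions (`mature_pos`, `ref_aa`, `alt_aa`).
#' @export
haplotype_to_substitutions <- function(model, haplotype, sites) {
  alleles <- as.integer(strsplit(haplotype, "")[[1]])
  if (length(alleles) != nrow(sites))
    stop("haplotype length does not match site table", call. = FALSE)
  for (i in seq_len(nrow(sites))) {
    have <- substr(model$cds_sequence, sites$cds_offset[i], sites$cds_offset[i])
    if (have != sites$ref_tx[i])
      stop(sprintf(
        "site %s: reference allele %s inconsistent with CDS base %s",
        sites$key[i], sites$ref_tx[i], have), call. = FALSE)
  }
  alt_idx <- which(alleles == 1L)
  if (length(alt_idx) == 0) {
    return(data.frame(mature_pos = integer(0), ref_aa = character(0),
                      alt_aa = character(0), stringsAsFactors = FALSE))
  }
  codons <- ceiling(sites$cds_offset[alt_idx] / 3)
  out <- list()
  for (cd in unique(codons)) {
    ref_codon <- substr(model$cds_sequence, 3 * cd - 2, 3 * cd)
    alt_codon <- ref_codon
    for (i in alt_idx[codons == cd]) {
      within <- sites$cds_offset[i] - 3 * (cd - 1)
      substr(alt_codon, within, within) <- sites$alt_tx[i]
    }
    ref_aa <- translate_codon(ref_codon)
    alt_aa <- translate_codon(alt_codon)
    if (ref_aa == alt_aa) next                      # jointly synonymous
    if (cd <= model$signal_peptide_len) next        # signal peptide
    out[[length(out) + 1L]] <- data.frame(
      mature_pos = cd - model$signal_peptide_len,
      ref_aa = ref_aa, alt_aa = alt_aa, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(mature_pos = integer(0), ref_aa = character(0),
                      alt_aa = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Build a protein-variant catalog
#'
#' A catalog maps, per gene, variant names to mature-protein substitution
#' sets. The gene's reference variant is the entry with the empty set.
#' Dotted names record lineage: every `X.k` must have base `X` present.
#'
#' @param df data.frame with columns `gene`, `name`, `substitutions`
#'   (canonical strings, see [subs_to_string()]) and optionally `note`.
#' @return a `variant_catalog`.
#' @export
variant_catalog <- function(df) {
  if (!"note" %in% names(df)) df$note <- ""
  df <- df[, c("gene", "name", "substitutions", "note")]
  df$substitutions[is.na(df$substitutions)] <- ""
  # canonicalize ordering within each substitution string
  df$substitutions <- vapply(df$substitutions,
                             function(s) subs_to_string(string_to_subs(s)),
                             character(1), USE.NAMES = FALSE)
  for (g in unique(df$gene)) {
    sub <- df[df$gene == g, ]
    if (anyDuplicated(sub$name))
      stop("duplicate variant names for gene ", g, call. = FALSE)
    if (!any(sub$substitutions == ""))
      stop("gene ", g, " lacks a reference variant (empty substitution set)",
           call. = FALSE)
    dotted <- grep("\\.", sub$name, value = TRUE)
    for (nm in dotted) {
      base <- sub("\\.[0-9]+$", "", nm)
      if (!base %in% sub$name)
        stop(sprintf("dotted name %s (gene %s) has no base %s in catalog",
                     nm, g, base), call. = FALSE)
    }
  }
  class(df) <- c("variant_catalog", "data.frame")
  df
}

#' Read a protein-variant catalog from TSV
#' @param path TSV with columns gene, name, substitutions, note.
#' @return a `variant_catalog`.
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  variant_catalog(df)
}

#' Write a protein-variant catalog to TSV in canonical order
#' @param catalog a `variant_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  df <- as.data.frame(catalog)
  df <- df[order(df$gene, df$name), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reference variant name of a gene in a catalog
#' @param catalog a `variant_catalog`.
#' @param gene gene symbol.
#' @return the name whose substitution set is empty.
#' @export
catalog_reference <- function(catalog, gene) {
  sub <- catalog[catalog$gene == gene, ]
  sub$name[sub$substitutions == ""][1]
}

#' Match a substitution set against the catalog
#'
#' @param subs substitution data.frame or canonical string.
#' @param catalog a `variant_catalog`.
#' @param gene gene symbol.
#' @return list with `name` (NA if novel) and `status` ("known"/"novel").
#' @export
match_catalog <- function(subs, catalog, gene) {
  s <- if (is.character(subs)) subs_to_string(string_to_subs(subs))
       else subs_to_string(subs)
  sub <- catalog[catalog$gene == gene, ]
  hit <- which(sub$substitutions == s)
  if (length(hit) > 0)
    list(name = sub$name[hit[1]], status = "known")
  else list(name = NA_character_, status = "novel")
}

subs_is_subset <- function(a, b) {
  # is every substitution of a present in b (exact pos:ref>alt match)?
  if (a == "") return(TRUE)
  all(strsplit(a, ";")[[1]] %in% strsplit(b, ";")[[1]])
}

#' Name a novel protein variant hierarchically
#'
#' Novel variants are named by appending a dot and a numeric child index to
#' the name of a base variant, recording successive layers of amino-acid
#' substitutions: the first variants derived from base A1 become A1.1, A1.2,
#' ...; a variant derived from A1.1 becomes A1.1.1, and so on. The base is
#' the catalog variant whose substitution set is a subset of the novel set
#' with the largest overlap (dotted names are eligible, so lineages deepen);
#' among equally good bases the one with more observed occurrences wins,
#' then the lexicographically smaller name. The new name is appended to the
#' catalog so that later assignments see it.
#'
#' @param novel_subs substitution data.frame or canonical string matching no
#'   catalog entry.
#' @param catalog a `variant_catalog`.
#' @param gene gene symbol.
#' @param occurrences optional named numeric vector of observed occurrence
#'   counts per catalog name (used only for tie-breaking).
#' @return list with `name` (the new dotted name) and `catalog` (updated).
#' @export
assign_name <- function(novel_subs, catalog, gene, occurrences = NULL) {
  s <- if (is.character(novel_subs))
    subs_to_string(string_to_subs(novel_subs)) else subs_to_string(novel_subs)
  sub <- catalog[catalog$gene == gene, ]
  if (any(sub$substitutions == s))
    stop("substitution set already in catalog; not novel", call. = FALSE)
  is_base <- vapply(sub$substitutions, subs_is_subset, logical(1), b = s)
  cand <- sub[is_base, , drop = FALSE]
  if (nrow(cand) == 0)
    stop("internal error: no subset base (reference set is always a subset)",
         call. = FALSE)
  overlap <- vapply(cand$substitutions, function(x)
    if (x == "") 0L else length(strsplit(x, ";")[[1]]), integer(1))
  occ <- if (is.null(occurrences)) numeric(0) else occurrences
  occ_of <- function(nm) if (nm %in% names(occ)) occ[[nm]] else 0
  cand$overlap <- overlap
  cand$occ <- vapply(cand$name, occ_of, numeric(1))
  cand <- cand[order(-cand$overlap, -cand$occ, cand$name), , drop = FALSE]
  base <- cand$name[1]
  kids <- grep(paste0("^", gsub("([.\\\\])", "\\\\\\1", base), "\\.[0-9]+$"),
               sub$name, value = TRUE)
  idx <- if (length(kids) == 0) 1L else
    max(as.integer(sub(".*\\.", "", kids))) + 1L
  new_name <- sprintf("%s.%d", base, idx)
  newrow <- data.frame(gene = gene, name = new_name, substitutions = s,
                       note = "novel", stringsAsFactors = FALSE)
  upd <- rbind(as.data.frame(catalog), newrow)
  list(name = new_name, catalog = variant_catalog(upd))
}

#' Kappa-casein functional region of a mature-protein position
#'
#' Mature kappa-casein is cleaved by chymosin between Phe105 and Met106 into
#' para-kappa-casein (residues 1-95 lie in this micelle-retained,
#' conserved N-terminal part) and the soluble caseinomacropeptide, whose
#' hydrophilic C-terminal section spans residues 113-169.
#'
#' @param mature_pos position(s) in the mature kappa-casein (1..169).
#' @return character vector: `para_kappa`, `cmp`, `chymosin_site` or
#'   `other`.
#' @export
kappa_region <- function(mature_pos) {
  if (any(mature_pos < 1 | mature_pos > 169))
    stop("mature position outside kappa-casein (1..169)", call. = FALSE)
  ifelse(mature_pos %in% c(105L, 106L), "chymosin_site",
    ifelse(mature_pos <= 95, "para_kappa",
      ifelse(mature_pos >= 113, "cmp", "other")))
}

#' Call, match and name protein variants from an EM fit
#'
#' Translates every haplotype observed in the most-probable pair
#' assignments into a mature-protein substitution set, aggregates occurrence
#' counts (haplotype copies) and carrier counts per distinct protein
#' variant, matches each against the catalog, and names the novel ones with
#' the hierarchical dotted nomenclature, processing novels in descending
#' occurrence order (ties by substitution string). Novel variants need at
#' least `min_copies` haplotype copies or `min_carriers` carrier animals to
#' be admitted; the rest are reported separately as unconfirmed.
#'
#' @param model a `gene_model`.
#' @param fit a cohort [haplo_em()] fit over `sites`.
#' @param catalog a `variant_catalog`.
#' @param sites site table from [coding_sites()] matching the fit.
#' @param assignments optional assignment table from
#'   [predict.haplo_em()]; computed from `fit` when omitted.
#' @param min_copies,min_carriers admission thresholds for novel variants
#'   (defaults 2 and 2; either suffices).
#' @param posterior_weighted if TRUE, occurrences are expected haplotype
#'   counts under the EM posterior instead of hard-assignment counts.
#' @param low_depth_flags optional logical matrix (sites x samples, rows
#'   aligned to `sites`) marking low-depth genotypes; a variant whose
#'   carriers include a flagged genotype at a substitution site is marked
#'   low confidence.
#' @return list with `variants` (one row per admitted protein variant:
#'   name, status, substitutions, occurrences, carriers, low_confidence),
#'   `unconfirmed`, `haplotype_map` (haplotype to variant name), and the
#'   updated `catalog`.
#' @export
call_protein_variants <- function(model, fit, catalog, sites,
                                  assignments = NULL,
                                  min_copies = 2, min_carriers = 2,
                                  posterior_weighted = FALSE,
                                  low_depth_flags = NULL) {
  if (is.null(assignments)) assignments <- stats::predict(fit)
  haps <- unique(c(assignments$hap1, assignments$hap2))
  haps <- sort(haps)

  hard_count <- function(h)
    sum(assignments$hap1 == h) + sum(assignments$hap2 == h)
  carrier_count <- function(h)
    sum(assignments$hap1 == h | assignments$hap2 == h)
  occ_hap <- if (posterior_weighted) {
    f <- fit$frequencies
    vapply(haps, function(h)
      unname(f[h]) * fit$n_chrom, numeric(1))
  } else vapply(haps, hard_count, numeric(1))
  car_hap <- vapply(haps, carrier_count, numeric(1))

  subs_str <- vapply(haps, function(h)
    subs_to_string(haplotype_to_substitutions(model, h, sites)), character(1))
  hap_map <- data.frame(haplotype = haps, substitutions = subs_str,
                        stringsAsFactors = FALSE)

  # aggregate haplotypes coding the same protein variant
  agg <- stats::aggregate(cbind(occurrences = occ_hap, carriers = car_hap),
                          by = list(substitutions = subs_str), FUN = sum)
  agg <- agg[order(-agg$occurrences, agg$substitutions), , drop = FALSE]

  low_conf_for <- function(s) {
    if (is.null(low_depth_flags)) return(FALSE)
    hs <- hap_map$haplotype[hap_map$substitutions == s]
    carriers <- assignments$id[assignments$hap1 %in% hs |
                                 assignments$hap2 %in% hs]
    cidx <- match(carriers, colnames(low_depth_flags))
    cidx <- cidx[!is.na(cidx)]
    if (length(cidx) == 0) return(FALSE)
    # sites where any haplotype of this variant carries the alt allele
    alt_sites <- which(Reduce(`|`, lapply(hs, function(h)
      strsplit(h, "")[[1]] == "1")))
    if (length(alt_sites) == 0) return(FALSE)
    any(low_depth_flags[alt_sites, cidx, drop = FALSE])
  }

  occurrences_by_name <- stats::setNames(numeric(0), character(0))
  rows <- list(); unconf <- list()
  for (i in seq_len(nrow(agg))) {
    s <- agg$substitutions[i]
    m <- match_catalog(s, catalog, model$name)
    if (m$status == "known") {
      nm <- m$name; status <- "known"
    } else if (agg$occurrences[i] >= min_copies ||
               agg$carriers[i] >= min_carriers) {
      res <- assign_name(s, catalog, model$name,
                         occurrences = occurrences_by_name)
      nm <- res$name; catalog <- res$catalog; status <- "novel"
    } else {
      unconf[[length(unconf) + 1L]] <- data.frame(
        gene = model$name, substitutions = s,
        occurrences = agg$occurrences[i], carriers = agg$carriers[i],
        stringsAsFactors = FALSE)
      next
    }
    occurrences_by_name[nm] <- agg$occurrences[i]
    rows[[length(rows) + 1L]] <- data.frame(
      gene = model$name, name = nm, status = status, substitutions = s,
      occurrences = agg$occurrences[i], carriers = agg$carriers[i],
      low_confidence = low_conf_for(s), stringsAsFactors = FALSE)
  }
  variants <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), name = character(0),
               status = character(0), substitutions = character(0),
               occurrences = numeric(0), carriers = numeric(0),
               low_confidence = logical(0), stringsAsFactors = FALSE)
  hap_map$name <- vapply(hap_map$substitutions, function(s) {
    hit <- match(s, variants$substitutions)
    if (!is.na(hit)) variants$name[hit] else NA_character_
  }, character(1))
  list(variants = variants,
       unconfirmed = if (length(unconf)) do.call(rbind, unconf) else
         data.frame(gene = character(0), substitutions = character(0),
                    occurrences = numeric(0), carriers = numeric(0)),
       haplotype_map = hap_map, catalog = catalog)
}
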