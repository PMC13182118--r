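round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Variant-type composition report
#'
#' Tabulates annotated SNVs by region category. Within-gene categories
#' (5' UTR, missense, synonymous, intron, 3' UTR, and stop-affecting coding
#' changes) are reported with percentages of the within-gene total, rounded
#' half-up to two decimals; the two flanking classes (upstream, downstream)
#' are counted separately, as is conventional for gene-region composition
#' tables.
#'
#' @param annotated output of [annotate_variants()].
#' @return list with `within_gene` (category, count, percentage),
#'   `flank` (upstream/downstream counts) and `total_within`.
#' @export
variant_type_table <- function(annotated) {
  cats_within <- c("five_prime_utr", "missense", "synonymous", "intron",
                   "three_prime_utr", "coding_other")
  cat_col <- annotated$category
  within <- cat_col[cat_col %in% cats_within]
  total <- length(within)
  counts <- vapply(cats_within, function(cc) sum(within == cc), integer(1))
  pct <- if (total > 0) round_half_up(100 * counts / total, 2) else
    rep(NA_real_, length(counts))
  within_tab <- data.frame(category = cats_within, count = unname(counts),
                           percentage = unname(pct),
                           stringsAsFactors = FALSE)
  within_tab <- within_tab[within_tab$count > 0 |
                             within_tab$category != "coding_other", ]
  rownames(within_tab) <- NULL
  flank <- data.frame(
    upstream = sum(cat_col == "upstream"),
    downstream = sum(cat_col == "downstream"))
  list(within_gene = within_tab, flank = flank, total_within = total)
}

#' Polymorphic-site fraction of the gene set
#'
#' Percentage of base pairs in the gene bodies that are polymorphic:
#' within-gene variant count divided by the summed gene lengths, times 100.
#'
#' @param n_within_gene number of within-gene variants.
#' @param models named list of `gene_model` objects, or a numeric vector of
#'   gene sizes in bp.
#' @param digits rounding digits (half-up, default 2).
#' @return percentage.
#' @export
polymorphic_fraction <- function(n_within_gene, models, digits = 2) {
  total_bp <- if (is.numeric(models)) sum(models) else
    sum(vapply(models, gene_length, integer(1)))
  round_half_up(100 * n_within_gene / total_bp, digits)
}

#' Per-breed protein-variant frequency tables
#'
#' Converts within-breed EM haplotype frequencies into named protein-variant
#' frequencies by translating each haplotype to its substitution set and
#' summing frequencies of haplotypes coding the same variant. Variants not
#' in the (updated) catalog are reported under their canonical substitution
#' string.
#'
#' @param fits result of [haplo_em_by_breed()] for one gene.
#' @param model the `gene_model`.
#' @param sites site table from [coding_sites()] used for the fits.
#' @param catalog a `variant_catalog` (typically the updated catalog from
#'   [call_protein_variants()], so novel names resolve).
#' @param min_freq haplotypes below this estimated frequency are dropped
#'   from the tables (default 1e-6; EM zeros are never exactly zero).
#' @return data.frame with `scope`, `gene`, `variant`, `frequency`,
#'   `n_chromosomes`; scope "cohort" plus one scope per fitted breed.
#' @export
breed_frequencies <- function(fits, model, sites, catalog, min_freq = 1e-6) {
  one_scope <- function(fit, scope) {
    f <- fit$frequencies
    f <- f[f >= min_freq]
    subs <- vapply(names(f), function(h)
      subs_to_string(haplotype_to_substitutions(model, h, sites)),
      character(1))
    nm <- vapply(subs, function(s) {
      m <- match_catalog(s, catalog, model$name)
      if (m$status == "known") m$name else if (s == "") "REF" else s
    }, character(1))
    agg <- stats::aggregate(list(frequency = unname(f)),
                            by = list(variant = unname(nm)), FUN = sum)
    data.frame(scope = scope, gene = model$name, variant = agg$variant,
               frequency = agg$frequency, n_chromosomes = fit$n_chrom,
               stringsAsFactors = FALSE)
  }
  out <- one_scope(fits$cohort, "cohort")
  for (b in names(fits$breeds))
    out <- rbind(out, one_scope(fits$breeds[[b]], b))
  rownames(out) <- NULL
  out
}

#' Frequencies of key functional milk-protein variants per breed
#'
#' Reports, for every breed with at least `min_animals` animals: the
#' beta-casein A2-family frequency (all beta-casein variants carrying a
#' proline at mature position 67, computed from substitution sets so novel
#' Pro67 variants are included automatically), the kappa-casein A and B
#' frequencies, and the beta-lactoglobulin B frequency.
#'
#' @param freq_tables data.frame as produced by [breed_frequencies()],
#'   concatenated over genes (must include CSN2, CSN3 and PAEP rows).
#' @param catalog a `variant_catalog` resolving every named variant.
#' @param models named list of `gene_model` objects (for reference residues).
#' @param panel a `sample_panel` (for breed sizes).
#' @param min_animals minimum animals per reported breed (default 20).
#' @return data.frame with one row per reported breed and columns
#'   `bcn_a2_family`, `kcn_A`, `kcn_B`, `blg_B`.
#' @export
functional_report <- function(freq_tables, catalog, models, panel,
                              min_animals = 20) {
  sizes <- breed_counts(panel)
  breeds <- names(sizes)[sizes >= min_animals]

  residue_at <- function(gene, variant, pos) {
    m <- models[[gene]]
    refprot <- mature_protein(m)
    if (length(refprot) < pos)
      stop(sprintf("gene %s: mature protein shorter than position %d",
                   gene, pos), call. = FALSE)
    s <- if (variant == "REF") "" else {
      hit <- catalog$substitutions[catalog$gene == gene &
                                     catalog$name == variant]
      if (length(hit) == 0) variant else hit  # unnamed: canonical string
    }
    subs <- string_to_subs(s)
    at <- subs$alt_aa[subs$mature_pos == pos]
    if (length(at) > 0) at[1] else refprot[pos]
  }

  rows <- lapply(breeds, function(b) {
    tab <- freq_tables[freq_tables$scope == b, , drop = FALSE]
    bcn <- tab[tab$gene == "CSN2", , drop = FALSE]
    a2 <- if (nrow(bcn) == 0) NA_real_ else
      sum(bcn$frequency[vapply(bcn$variant, residue_at, character(1),
                               gene = "CSN2", pos = 67L) == "P"])
    kcn <- tab[tab$gene == "CSN3", , drop = FALSE]
    blg <- tab[tab$gene == "PAEP", , drop = FALSE]
    freq_of <- function(d, nm)
      if (nrow(d) == 0) NA_real_ else sum(d$frequency[d$variant == nm])
    data.frame(breed = b, n_animals = unname(sizes[b]),
               bcn_a2_family = a2,
               kcn_A = freq_of(kcn, "A"), kcn_B = freq_of(kcn, "B"),
               blg_B = freq_of(blg, "B"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
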