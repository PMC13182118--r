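#' Pipeline configuration
#'
#' Paths and thresholds for [run_pipeline()]. The threshold defaults are
#' the study's stated values: at least 3 alt-supporting reads, site quality
#' and mapping quality at least 20, the alt allele in at least 2 animals,
#' genotype depth flags below 6, and per-breed functional reporting for
#' breeds with at least 20 animals.
#'
#' @param vcf,panel,gene_models,catalog paths to the input VCF, the
#'   sample/breed panel TSV, the gene-model TSV and the known-variant
#'   catalog TSV.
#' @param known_ids optional path to a list of known variant IDs/keys (one
#'   per line) for novelty labeling.
#' @param out_dir output directory.
#' @param min_alt_reads,min_qual,min_mq,min_carriers site filters.
#' @param depth_flag_threshold genotype depth below which calls are flagged.
#' @param min_breed_animals minimum animals for functional reporting.
#' @param em_tol,em_max_iter EM settings.
#' @param missense_only if TRUE (default) haplotypes are built over
#'   missense sites only; FALSE also includes synonymous coding sites.
#' @param posterior_weighted if TRUE occurrence counts are EM-expected
#'   counts rather than hard-assignment counts.
#' @return a `run_config` list.
#' @export
run_config <- function(vcf, panel, gene_models, catalog,
                       known_ids = NULL, out_dir = tempfile("lactovar"),
                       min_alt_reads = 3, min_qual = 20, min_mq = 20,
                       min_carriers = 2, depth_flag_threshold = 6,
                       min_breed_animals = 20,
                       em_tol = 1e-8, em_max_iter = 1000,
                       missense_only = TRUE, posterior_weighted = FALSE) {
  structure(list(vcf = vcf, panel = panel, gene_models = gene_models,
                 catalog = catalog, known_ids = known_ids,
                 out_dir = out_dir, min_alt_reads = min_alt_reads,
                 min_qual = min_qual, min_mq = min_mq,
                 min_carriers = min_carriers,
                 depth_flag_threshold = depth_flag_threshold,
                 min_breed_animals = min_breed_animals,
                 em_tol = em_tol, em_max_iter = em_max_iter,
                 missense_only = missense_only,
                 posterior_weighted = posterior_weighted),
            class = "run_config")
}

#' Run the full variant-to-protein pipeline
#'
#' Executes filter, annotate, per-gene EM phasing, protein-variant calling
#' and naming, per-breed frequency tables, functional reporting, and
#' network construction, writing TSV/VCF-side outputs and a JSON run
#' report with stage counts.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the stage results and the run report.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = cfg[!vapply(cfg, is.null, logical(1))])

  models <- read_gene_models(cfg$gene_models)
  panel <- read_panel(cfg$panel)
  catalog <- read_catalog(cfg$catalog)

  report$n_protein_variants <- report$n_known <- report$n_novel <- 0L

  vs <- read_variants(cfg$vcf, panel, models)
  report$n_read <- n_variants(vs)
  report$n_skipped_non_snv <- vs$n_skipped_indels

  filt <- apply_filters(vs, min_alt_reads = cfg$min_alt_reads,
                        min_qual = cfg$min_qual, min_mq = cfg$min_mq,
                        min_carriers = cfg$min_carriers)
  report$n_kept <- n_variants(filt$kept)
  report$n_removed <- nrow(filt$removed)
  utils::write.table(filt$ledger, file.path(cfg$out_dir, "filter_ledger.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  kept <- filt$kept
  if (!is.null(cfg$known_ids))
    kept <- label_novelty(kept, readLines(cfg$known_ids))
  depth <- flag_low_depth(kept, cfg$depth_flag_threshold)
  utils::write.table(depth$site_summary,
                     file.path(cfg$out_dir, "site_depth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ann <- annotate_variants(kept, models)
  utils::write.table(ann, file.path(cfg$out_dir, "annotated_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  comp <- variant_type_table(ann)
  utils::write.table(comp$within_gene,
                     file.path(cfg$out_dir, "variant_type_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$composition <- comp

  site_kind <- if (cfg$missense_only) "missense" else "coding"
  per_gene <- list()
  freq_tables <- list()
  upd_catalog <- catalog
  for (g in names(models)) {
    sites <- coding_sites(ann, models[[g]], which = site_kind)
    if (nrow(sites) == 0) next
    idx <- match(sites$key,
                 variant_key(kept$variants$chrom, kept$variants$pos,
                             kept$variants$ref, kept$variants$alt))
    geno <- t(kept$gt[idx, , drop = FALSE])
    fits <- haplo_em_by_breed(geno, panel$breed, min_animals = 2,
                              tol = cfg$em_tol, max_iter = cfg$em_max_iter)
    calls <- call_protein_variants(
      models[[g]], fits$cohort, upd_catalog, sites,
      posterior_weighted = cfg$posterior_weighted,
      low_depth_flags = depth$flags[idx, , drop = FALSE])
    upd_catalog <- calls$catalog
    net <- build_network(calls$variants, upd_catalog, g)
    export_network(net, file.path(cfg$out_dir, sprintf("network_%s.graphml", g)),
                   "graphml")
    ft <- breed_frequencies(fits, models[[g]], sites, upd_catalog)
    freq_tables[[g]] <- ft
    per_gene[[g]] <- list(sites = sites, fits = fits, calls = calls,
                          network = net, frequencies = ft)
  }
  freq_all <- do.call(rbind, freq_tables)
  if (!is.null(freq_all)) {
    utils::write.table(freq_all,
                       file.path(cfg$out_dir, "breed_frequencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    func <- tryCatch(
      functional_report(freq_all, upd_catalog, models, panel,
                        min_animals = cfg$min_breed_animals),
      error = function(e) NULL)
    if (!is.null(func))
      utils::write.table(func,
                         file.path(cfg$out_dir, "functional_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    report$functional <- func
  }
  all_variants <- do.call(rbind, lapply(per_gene, function(x)
    x$calls$variants))
  if (!is.null(all_variants)) {
    utils::write.table(all_variants,
                       file.path(cfg$out_dir, "protein_variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$n_protein_variants <- nrow(all_variants)
    report$n_known <- sum(all_variants$status == "known")
    report$n_novel <- sum(all_variants$status == "novel")
  }
  write_catalog(upd_catalog, file.path(cfg$out_dir, "catalog_updated.tsv"))

  report$stage_balance <- report$n_kept + report$n_removed == report$n_read
  jsonlite::write_json(
    report[c("n_read", "n_skipped_non_snv", "n_kept", "n_removed",
             "n_protein_variants", "n_known", "n_novel", "stage_balance")],
    file.path(cfg$out_dir, "run_report.json"), auto_unbox = TRUE,
    pretty = TRUE)
  invisible(list(report = report, genes = per_gene, catalog = upd_catalog,
                 frequencies = freq_all, annotated = ann, panel = panel,
                 models = models))
}
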