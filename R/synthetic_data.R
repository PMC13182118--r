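#' Deterministic stop-free toy coding sequence
#'
#' Builds a coding sequence of `n_codons` codons starting with ATG, cycling
#' through a fixed codon set that contains no stop codons, with optional
#' per-codon overrides (used to plant specific reference residues at chosen
#' positions).
#'
#' @param n_codons number of codons.
#' @param overrides named list/vector: codon index -> codon string.
#' @return a nucleotide string of length `3 * n_codons`.
#' @export
toy_cds <- function(n_codons, overrides = NULL) {
  bank <- c("GCT", "GAT", "AAA", "CCT", "TCT", "GGA", "TTT", "CTG",
            "ATT", "GAA", "GTT", "TAC", "TGG", "AGA", "ACA", "CAA",
            "AGC", "CGT", "ATG", "CAT")
  codons <- c("ATG", rep(bank, length.out = n_codons - 1))
  if (!is.null(overrides)) {
    idx <- as.integer(names(overrides))
    codons[idx] <- unlist(overrides)
  }
  paste(codons, collapse = "")
}

# per-gene layout parameters for the six-gene synthetic fixture; genomic
# coordinates and strand follow the published reference annotation, exon
# structure and CDS content are synthetic.
toy6_params <- function() {
  list(
    CSN1S1 = list(chrom = "6", start = 85411118L, end = 85429268L,
                  strand = "+", n_codons = 60L, spl = 15L, ref_name = "B",
                  mature_pos = c(22L, 31L, 40L),
                  known1 = "C", known2 = "D", undetected = "E"),
    CSN2 = list(chrom = "6", start = 85449164L, end = 85457744L,
                strand = "-", n_codons = 105L, spl = 15L, ref_name = "B",
                mature_pos = c(36L, 67L, 80L),
                known1 = "A1", known2 = "A2", undetected = "C"),
    CSN1S2 = list(chrom = "6", start = 85529905L, end = 85548556L,
                  strand = "+", n_codons = 60L, spl = 15L, ref_name = "A",
                  mature_pos = c(22L, 31L, 40L),
                  known1 = "B", known2 = "D", undetected = "C"),
    CSN3 = list(chrom = "6", start = 85645854L, end = 85658926L,
                strand = "+", n_codons = 190L, spl = 21L, ref_name = "B",
                mature_pos = c(50L, 136L, 149L),
                known1 = "A", known2 = "E", undetected = "H"),
    LALBA = list(chrom = "5", start = 31183432L, end = 31186209L,
                 strand = "+", n_codons = 40L, spl = 19L, ref_name = "B",
                 mature_pos = c(8L, 14L, 19L),
                 known1 = "A", known2 = "E", undetected = "F"),
    PAEP = list(chrom = "11", start = 103255824L, end = 103260873L,
                strand = "+", n_codons = 60L, spl = 16L, ref_name = "B",
                mature_pos = c(20L, 30L, 40L),
                known1 = "A", known2 = "C", undetected = "D")
  )
}

# the three planted mature substitutions share a fixed design across genes:
# sub_a = S>R (codon AGC, 3rd base ->A), sub_b = H>P (CAT, 2nd base ->C),
# sub_c = G>E (GGA, 2nd base ->A); plus a signal-peptide missense at codon 5
# (GCT->CCT) and a synonymous site at codon spl+10 (GCT->GCA).
toy_sub_design <- function(p) {
  codons <- p$mature_pos + p$spl
  list(
    sub_codon = c("AGC", "CAT", "GGA"),
    sub_within = c(3L, 2L, 2L),
    sub_alt_tx = c("A", "C", "A"),
    sub_ref_aa = c("S", "H", "G"), sub_alt_aa = c("R", "P", "E"),
    codons = codons,
    sp_codon = 5L, syn_codon = p$spl + 10L)
}

make_toy_gene <- function(name, p, flank = 2000L) {
  d <- toy_sub_design(p)
  overrides <- stats::setNames(
    as.list(c("GCT", "GCT", d$sub_codon)),
    c(d$sp_codon, d$syn_codon, d$codons))
  cds <- toy_cds(p$n_codons, overrides)
  L <- nchar(cds); a <- L / 3L

  # forward layout relative to (start, end); mirrored for reverse strand
  tss <- p$start + 1000L
  e1 <- c(tss, tss + 50L + a - 1L)
  e2 <- c(e1[2] + 201L, e1[2] + 200L + a)
  e3 <- c(e2[2] + 301L, e2[2] + 300L + a + 40L)
  cdsb <- c(tss + 50L, e3[1] + a - 1L)
  stopifnot(e3[2] <= p$end)
  exons <- rbind(e1, e2, e3)
  if (p$strand == "-") {
    mirror <- function(iv) c(p$start + p$end - iv[2], p$start + p$end - iv[1])
    exons <- rbind(mirror(e3), mirror(e2), mirror(e1))
    cdsb <- mirror(cdsb)
  }
  gene_model(name, p$chrom, p$start, p$end, p$strand, exons,
             cds_start = cdsb[1], cds_end = cdsb[2],
             signal_peptide_len = p$spl, cds_sequence = cds,
             flank = flank, reference_variant_name = p$ref_name)
}

#' Synthetic six-gene fixture models
#'
#' Gene models for the six major milk-protein genes with the published
#' genomic coordinates and strands, but synthetic exon structures and toy
#' coding sequences (clearly fixture content, not the real annotation).
#'
#' @param flank flanking distance in bp (default 2000).
#' @return named list of `gene_model` objects.
#' @export
toy_gene_models <- function(flank = 2000L) {
  params <- toy6_params()
  models <- lapply(names(params), function(g)
    make_toy_gene(g, params[[g]], flank))
  names(models) <- names(params)
  models
}

#' Site table of the synthetic study design
#'
#' For each gene, the twelve planted variant sites: two upstream, one 5'
#' UTR, three intronic, one synonymous, one signal-peptide missense, three
#' mature missense, one 3' UTR and one downstream site, with their designed
#' region categories as ground truth.
#'
#' @param models output of [toy_gene_models()].
#' @return data.frame with `gene`, `label`, `chrom`, `pos`, `ref`, `alt`,
#'   `category` (designed truth) and `em_site` (missense sites used for
#'   haplotype construction).
#' @export
toy_sites <- function(models = toy_gene_models()) {
  params <- toy6_params()
  rows <- list()
  for (g in names(params)) {
    p <- params[[g]]; m <- models[[g]]; d <- toy_sub_design(p)
    fwd <- p$strand == "+"
    mirror <- function(pos) if (fwd) pos else p$start + p$end - pos
    tss <- p$start + 1000L
    a <- nchar(m$cds_sequence) / 3L
    e1_end_fwd <- tss + 50L + a - 1L
    e2_end_fwd <- e1_end_fwd + 200L + a
    e3_end_fwd <- e2_end_fwd + 300L + a + 40L

    coding_site <- function(codon, within, alt_tx) {
      off <- 3L * (codon - 1L) + within
      ref_tx <- substr(m$cds_sequence, off, off)
      pos <- cds_to_genomic(m, off)
      if (fwd) c(pos = pos, ref = ref_tx, alt = alt_tx)
      else c(pos = pos, ref = DNA_COMPLEMENT[[ref_tx]],
             alt = DNA_COMPLEMENT[[alt_tx]])
    }
    sp <- coding_site(d$sp_codon, 1L, "C")
    syn <- coding_site(d$syn_codon, 3L, "A")
    m1 <- coding_site(d$codons[1], d$sub_within[1], d$sub_alt_tx[1])
    m2 <- coding_site(d$codons[2], d$sub_within[2], d$sub_alt_tx[2])
    m3 <- coding_site(d$codons[3], d$sub_within[3], d$sub_alt_tx[3])

    site <- function(label, pos, ref, alt, category, em = FALSE)
      data.frame(gene = g, label = label, chrom = p$chrom,
                 pos = as.integer(pos), ref = ref, alt = alt,
                 category = category, em_site = em,
                 stringsAsFactors = FALSE)
    rows[[g]] <- rbind(
      site("u1", mirror(p$start - 400L), "A", "G", "upstream"),
      site("u2", mirror(p$start - 1200L), "C", "T", "upstream"),
      site("utr5", mirror(tss + 20L), "A", "C", "five_prime_utr"),
      site("i1", mirror(e1_end_fwd + 100L), "G", "A", "intron"),
      site("i2", mirror(e1_end_fwd + 150L), "T", "C", "intron"),
      site("i3", mirror(e2_end_fwd + 100L), "C", "G", "intron"),
      site("syn1", syn["pos"], syn["ref"], syn["alt"], "synonymous"),
      site("sp1", sp["pos"], sp["ref"], sp["alt"], "missense", em = TRUE),
      site("m1", m1["pos"], m1["ref"], m1["alt"], "missense", em = TRUE),
      site("m2", m2["pos"], m2["ref"], m2["alt"], "missense", em = TRUE),
      site("m3", m3["pos"], m3["ref"], m3["alt"], "missense", em = TRUE),
      site("utr3", mirror(e3_end_fwd - 20L), "T", "A", "three_prime_utr"),
      site("d1", mirror(p$end + 600L), "G", "C", "downstream"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# designed mature substitution strings per gene, in position order
toy_subs_strings <- function(g) {
  p <- toy6_params()[[g]]; d <- toy_sub_design(p)
  sprintf("%d:%s>%s", p$mature_pos, d$sub_ref_aa, d$sub_alt_aa)
}

#' Synthetic known-variant catalog for the six-gene fixture
#'
#' Catalog fixture using field-style variant names, with synthetic
#' substitution content matching [toy_gene_models()]: per gene the
#' reference variant (empty set), one single-substitution known variant,
#' one two-substitution known variant, and one known variant not present in
#' the default simulated pools.
#'
#' @return a `variant_catalog`.
#' @export
toy_catalog <- function() {
  params <- toy6_params()
  rows <- list()
  for (g in names(params)) {
    p <- params[[g]]
    s <- toy_subs_strings(g)
    rows[[g]] <- data.frame(
      gene = g,
      name = c(p$ref_name, p$known1, p$known2, p$undetected),
      substitutions = c("", s[1], paste(s[1], s[2], sep = ";"), s[3]),
      note = "synthetic fixture",
      stringsAsFactors = FALSE)
  }
  variant_catalog(do.call(rbind, rows))
}

# default haplotype pool: alt-site labels per haplotype, shared across genes
toy_pool_defs <- function() {
  list(h_ref = character(0),
       h_one = c("m1", "i1", "utr3"),
       h_two = c("m1", "m2", "u1", "i2", "d1"),
       h_three = c("m1", "m2", "m3", "syn1", "i3"),
       h_sp = c("sp1", "utr5", "u2"))
}

toy_pool_freqs <- function() {
  list(BreedA = c(h_ref = 0.45, h_one = 0.25, h_two = 0.15,
                  h_three = 0.10, h_sp = 0.05),
       BreedB = c(h_ref = 0.30, h_one = 0.10, h_two = 0.30,
                  h_three = 0.20, h_sp = 0.10),
       BreedC = c(h_ref = 0.60, h_one = 0.30, h_two = 0.05,
                  h_three = 0.05, h_sp = 0.00))
}

#' Configuration for the synthetic population simulator
#'
#' Bundles everything [simulate_population()] needs: gene models, site
#' design, per-breed haplotype pools, error and missingness rates, the
#' read-depth model (negative binomial, so low-depth genotypes occur), and
#' site-quality generators. Defaults give a three-breed cohort (60/50/40
#' animals) with mean read depth 10.
#'
#' @param seed integer seed (mandatory; the simulator is deterministic
#'   given seed and config).
#' @param models gene models (default [toy_gene_models()]).
#' @param sites site table (default [toy_sites()] for `models`).
#' @param pool_defs named list: haplotype name -> alt-site labels.
#' @param breeds named integer vector of animals per breed.
#' @param pool_freqs named list: breed -> named frequency vector over
#'   `pool_defs` (each summing to 1).
#' @param error_rate per-genotype error probability (default 0.001).
#' @param missing_rate per-genotype missingness probability (default 0.01).
#' @param depth_mean,depth_dispersion negative-binomial depth parameters
#'   (defaults 10 and 8).
#' @param qual_mean,qual_sd,mq_mean,mq_sd site-quality generators.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed,
                             models = toy_gene_models(),
                             sites = toy_sites(models),
                             pool_defs = toy_pool_defs(),
                             breeds = c(BreedA = 60L, BreedB = 50L,
                                        BreedC = 40L),
                             pool_freqs = toy_pool_freqs(),
                             error_rate = 0.001, missing_rate = 0.01,
                             depth_mean = 10, depth_dispersion = 8,
                             qual_mean = 60, qual_sd = 8,
                             mq_mean = 60, mq_sd = 3) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (any(breeds < 2)) stop("each breed needs >= 2 individuals", call. = FALSE)
  if (!setequal(names(pool_freqs), names(breeds)))
    stop("pool_freqs must name every breed", call. = FALSE)
  for (b in names(pool_freqs)) {
    f <- pool_freqs[[b]]
    if (!setequal(names(f), names(pool_defs)))
      stop("pool_freqs[[", b, "]] must cover all haplotypes", call. = FALSE)
    if (abs(sum(f) - 1) > 1e-9)
      stop("pool_freqs[[", b, "]] must sum to 1", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), models = models, sites = sites,
                 pool_defs = pool_defs, breeds = breeds,
                 pool_freqs = pool_freqs, error_rate = error_rate,
                 missing_rate = missing_rate, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 qual_mean = qual_mean, qual_sd = qual_sd,
                 mq_mean = mq_mean, mq_sd = mq_sd),
            class = "synthetic_config")
}

#' Load a synthetic-population configuration from YAML
#'
#' Reads the scalar fields (seed, breeds, rates, depth/quality parameters)
#' from YAML and fills the structural fields (models, sites, pools) with
#' the six-gene fixture defaults.
#'
#' @param path YAML file.
#' @return a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(seed = y$seed)
  if (!is.null(y$breeds)) args$breeds <- unlist(y$breeds)
  if (!is.null(y$pool_freqs))
    args$pool_freqs <- lapply(y$pool_freqs, unlist)
  for (f in c("error_rate", "missing_rate", "depth_mean",
              "depth_dispersion", "qual_mean", "qual_sd", "mq_mean",
              "mq_sd"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  do.call(synthetic_config, args)
}

write_vcf_text <- function(path, variants, gt, ad, dp, samples,
                           source = "lactovar-simulator") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=%s", source),
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    cells <- vapply(seq_along(samples), function(s) {
      g <- gt[i, s]
      if (is.na(g)) return("./.:.:.")
      sprintf("%s:%d,%d:%d",
              c("0/0", "0/1", "1/1")[g + 1L],
              dp[i, s] - ad[i, s], ad[i, s], dp[i, s])
    }, character(1))
    paste(c(variants$chrom[i], variants$pos[i], variants$id[i],
            variants$ref[i], variants$alt[i],
            format(variants$qual[i], nsmall = 1),
            "PASS", sprintf("MQ=%s", format(variants$mq[i], nsmall = 1)),
            "GT:AD:DP", cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a multi-breed diploid population
#'
#' Draws, for every gene and individual, two haplotypes independently from
#' the individual's breed pool (Hardy-Weinberg pairing within breed),
#' records the complete ground truth (haplotype pairs, site categories,
#' true pool frequencies, realized allele counts), and only then applies
#' genotype errors, missingness, and the read-depth/quality model before
#' writing a multi-sample VCF and a panel TSV. Deterministic given the
#' config seed.
#'
#' @param cfg a `synthetic_config`.
#' @param out_dir output directory (created if needed).
#' @return list with file paths (`vcf`, `panel`, `truth_dir`) and the
#'   in-memory `truth` ledger: `assignments` (gene, sample, breed, hap
#'   labels and allele strings), `sites` (with realized carrier/copy
#'   counts), `pools` (true per-breed haplotype and EM-site haplotype
#'   frequencies).
#' @export
simulate_population <- function(cfg, out_dir = tempfile("synthpop")) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  samples <- sprintf("S%03d", seq_len(sum(cfg$breeds)))
  breed_of <- rep(names(cfg$breeds), cfg$breeds)
  panel <- sample_panel(samples, breed_of)
  n <- length(samples)

  hap_names <- names(cfg$pool_defs)
  assignments <- list(); var_rows <- list()
  gt_all <- list(); ad_all <- list(); dp_all <- list()
  sites_out <- list()

  for (g in names(cfg$models)) {
    s <- cfg$sites[cfg$sites$gene == g, , drop = FALSE]
    ns <- nrow(s)
    # haplotype allele matrix: pool haplotype x site
    H <- t(vapply(cfg$pool_defs, function(lab)
      as.integer(s$label %in% lab), integer(ns)))
    colnames(H) <- s$label

    h1 <- character(n); h2 <- character(n)
    for (b in names(cfg$breeds)) {
      idx <- which(breed_of == b)
      f <- cfg$pool_freqs[[b]][hap_names]
      h1[idx] <- sample(hap_names, length(idx), replace = TRUE, prob = f)
      h2[idx] <- sample(hap_names, length(idx), replace = TRUE, prob = f)
    }
    dosage <- H[h1, , drop = FALSE] + H[h2, , drop = FALSE]  # n x site

    em_labels <- s$label[s$em_site]
    hap_string <- function(h, labels)
      paste(H[h, labels], collapse = "")
    assignments[[g]] <- data.frame(
      gene = g, sample_id = samples, breed = breed_of,
      hap1 = pmin(h1, h2), hap2 = pmax(h1, h2),
      em_hap1 = pmin(vapply(h1, hap_string, character(1), em_labels),
                     vapply(h2, hap_string, character(1), em_labels)),
      em_hap2 = pmax(vapply(h1, hap_string, character(1), em_labels),
                     vapply(h2, hap_string, character(1), em_labels)),
      stringsAsFactors = FALSE)

    s$alt_copies <- colSums(dosage)
    s$carriers <- colSums(dosage >= 1)
    sites_out[[g]] <- s

    # observational layer, applied after truth recording
    obs <- t(dosage)  # site x sample
    if (cfg$error_rate > 0) {
      err <- matrix(stats::runif(ns * n) < cfg$error_rate, ns, n)
      for (i in which(err))
        obs[i] <- sample(setdiff(0:2, obs[i]), 1)
    }
    if (cfg$missing_rate > 0) {
      mis <- matrix(stats::runif(ns * n) < cfg$missing_rate, ns, n)
      obs[mis] <- NA_integer_
    }
    dp <- matrix(pmax(stats::rnbinom(ns * n, size = cfg$depth_dispersion,
                                     mu = cfg$depth_mean), 2L), ns, n)
    ad <- matrix(0L, ns, n)
    for (i in seq_len(ns)) for (j in seq_len(n)) {
      d <- obs[i, j]
      if (is.na(d)) { ad[i, j] <- NA_integer_; next }
      ad[i, j] <- if (d == 0L) 0L else if (d == 2L) dp[i, j] else
        min(max(stats::rbinom(1, dp[i, j], 0.5), 1L), dp[i, j] - 1L)
    }
    var_rows[[g]] <- data.frame(
      chrom = s$chrom, pos = s$pos, id = ".",
      ref = s$ref, alt = s$alt,
      qual = round(pmax(25, stats::rnorm(ns, cfg$qual_mean, cfg$qual_sd)), 1),
      mq = round(pmax(30, stats::rnorm(ns, cfg$mq_mean, cfg$mq_sd)), 1),
      stringsAsFactors = FALSE)
    gt_all[[g]] <- obs; ad_all[[g]] <- ad; dp_all[[g]] <- dp
  }

  variants <- do.call(rbind, var_rows)
  gt <- do.call(rbind, gt_all); ad <- do.call(rbind, ad_all)
  dp <- do.call(rbind, dp_all)
  ord <- order(as.integer(variants$chrom), variants$pos)
  variants <- variants[ord, ]; gt <- gt[ord, , drop = FALSE]
  ad <- ad[ord, , drop = FALSE]; dp <- dp[ord, , drop = FALSE]

  # true per-breed haplotype frequencies, both as pool labels and as
  # EM-site allele strings
  pools <- list()
  for (g in names(cfg$models)) {
    s <- cfg$sites[cfg$sites$gene == g, , drop = FALSE]
    em_labels <- s$label[s$em_site]
    for (b in names(cfg$breeds)) {
      f <- cfg$pool_freqs[[b]]
      em_str <- vapply(names(f), function(h)
        paste(as.integer(em_labels %in% cfg$pool_defs[[h]]), collapse = ""),
        character(1))
      pools[[length(pools) + 1L]] <- data.frame(
        gene = g, breed = b, haplotype = names(f),
        em_haplotype = em_str, frequency = unname(f),
        stringsAsFactors = FALSE)
    }
  }

  truth <- list(assignments = do.call(rbind, assignments),
                sites = do.call(rbind, sites_out),
                pools = do.call(rbind, pools))
  rownames(truth$assignments) <- rownames(truth$sites) <-
    rownames(truth$pools) <- NULL

  vcf_path <- file.path(out_dir, "population.vcf")
  panel_path <- file.path(out_dir, "panel.tsv")
  write_vcf_text(vcf_path, variants, gt, ad, dp, samples)
  utils::write.table(panel[, c("sample_id", "breed")], panel_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_dir <- file.path(out_dir, "truth")
  dir.create(truth_dir, showWarnings = FALSE)
  for (nm in names(truth))
    utils::write.table(truth[[nm]], file.path(truth_dir,
                                              paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  list(vcf = vcf_path, panel = panel_path, truth_dir = truth_dir,
       panel_df = panel, truth = truth)
}

#' Write the canonical small fixture suite
#'
#' Writes the worked-example fixtures used across the test suite: the
#' six-gene synthetic gene-model TSV, the synthetic catalog, a five-variant
#' VCF for the quality filters (three pass, one fails on QUAL, one on
#' carriers), and the two-individual double-heterozygote EM cohort, each
#' with a README stating the expected outputs.
#'
#' @param out_dir output directory.
#' @return named list of file paths, invisibly.
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  paths$gene_models <- file.path(out_dir, "gene_models_toy6_synthetic.tsv")
  write_gene_models(toy_gene_models(), paths$gene_models)

  paths$catalog <- file.path(out_dir, "catalog_synthetic.tsv")
  write_catalog(toy_catalog(), paths$catalog)

  paths$filter_vcf <- file.path(out_dir, "filter_demo.vcf")
  writeLines(filter_demo_vcf_lines(), paths$filter_vcf)
  writeLines(c(
    "filter_demo.vcf: 5 SNVs, 4 samples, thresholds 3 reads / QUAL 20 / MQ 20 / >=2 carriers.",
    "Expected kept: 6:85646000:A>G, 6:85646300:T>C, 6:85646400:A>C (3 variants).",
    "Expected removed: 6:85646100:C>T (qual), 6:85646200:G>A (carriers)."),
    file.path(out_dir, "README_filter_demo.txt"))

  paths$em_cohort <- file.path(out_dir, "em_double_het.tsv")
  utils::write.table(
    data.frame(id = c("ind1", "ind2"), site1 = c(0L, 1L), site2 = c(0L, 1L)),
    paths$em_cohort, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(
    "em_double_het.tsv: one hom-ref/hom-ref individual and one double-het.",
    "Expected EM frequencies: 00 -> 0.75, 11 -> 0.25, 01 -> 0, 10 -> 0.",
    "Expected best pair for ind2: (00, 11) with posterior 1.0."),
    file.path(out_dir, "README_em_double_het.txt"))

  invisible(paths)
}

filter_demo_vcf_lines <- function() {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=lactovar-fixture",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3", "S4"), collapse = "\t"))
  row <- function(pos, ref, alt, qual, mq, g1, g2, g3, g4)
    paste(c("6", pos, ".", ref, alt, qual, "PASS",
            sprintf("MQ=%s", mq), "GT:AD:DP", g1, g2, g3, g4),
          collapse = "\t")
  c(hdr,
    # passes all four criteria: 2 carriers, 10 alt reads
    row(85646000, "A", "G", "50.0", "60.0",
        "0/1:5,5:10", "0/1:5,5:10", "0/0:10,0:10", "0/0:10,0:10"),
    # fails QUAL (19.9 < 20), everything else passing
    row(85646100, "C", "T", "19.9", "60.0",
        "0/1:5,5:10", "0/1:5,5:10", "0/0:10,0:10", "0/0:10,0:10"),
    # fails carriers (alt present in 1 individual)
    row(85646200, "G", "A", "50.0", "60.0",
        "0/1:6,6:12", "0/0:10,0:10", "0/0:10,0:10", "0/0:10,0:10"),
    # passes: two hom-alt carriers
    row(85646300, "T", "C", "50.0", "60.0",
        "1/1:0,12:12", "1/1:0,11:11", "0/0:10,0:10", "0/0:10,0:10"),
    # passes: three het carriers
    row(85646400, "A", "C", "50.0", "60.0",
        "0/1:4,4:8", "0/1:5,5:10", "0/1:6,6:12", "0/0:10,0:10"))
}
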