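# toy gene: 6 codons ATG GCT CAT AGC GGA AAA, signal peptide 2 aa
toy_protein_gene <- function(spl = 2L) {
  gene_model("TOYP", "1", 50, 300, "+", exons = rbind(c(95, 120)),
             cds_start = 101, cds_end = 118, signal_peptide_len = spl,
             cds_sequence = "ATGGCTCATAGCGGAAAA", flank = 40,
             reference_variant_name = "A")
}

toy_protein_sites <- function(m) {
  # three missense sites: codon3 CAT->CCT (H>P, precursor 3 / mature 1),
  # codon4 AGC->AGA (S>R, mature 2), codon5 GGA->GAA (G>E, mature 3),
  # plus a signal-peptide missense at codon2 GCT->CCT
  data.frame(
    key = c("k_sp", "k1", "k2", "k3"),
    pos = cds_to_genomic(m, c(4L, 8L, 12L, 14L)),
    cds_offset = c(4L, 8L, 12L, 14L),
    ref_tx = c("G", "A", "C", "G"), alt_tx = c("C", "C", "A", "A"),
    precursor_pos = c(2L, 3L, 4L, 5L),
    ref_aa = c("A", "H", "S", "G"), alt_aa = c("P", "P", "R", "E"),
    stringsAsFactors = FALSE)
}

test_that("haplotypes translate to mature substitutions, excluding the signal peptide", {
  m <- toy_protein_gene()
  sites <- toy_protein_sites(m)
  expect_equal(nrow(haplotype_to_substitutions(m, "0000", sites)), 0)
  # signal-peptide missense alone: no effect on the mature protein
  expect_equal(nrow(haplotype_to_substitutions(m, "1000", sites)), 0)
  s <- haplotype_to_substitutions(m, "0100", sites)
  expect_equal(s$mature_pos, 1L)   # precursor 3 - signal peptide 2
  expect_equal(paste(s$ref_aa, s$alt_aa), "H P")
  s2 <- haplotype_to_substitutions(m, "0111", sites)
  expect_equal(subs_to_string(s2), "1:H>P;2:S>R;3:G>E")
  # inconsistent site metadata is an integrity error
  bad <- sites; bad$ref_tx[2] <- "T"
  expect_error(haplotype_to_substitutions(m, "0100", bad), "inconsistent")
})

test_that("two SNVs in one codon are translated jointly", {
  m <- toy_protein_gene()
  # both changes hit codon 3 (CAT): offsets 7 and 8, C->A and A->C
  sites <- data.frame(
    key = c("a", "b"), pos = cds_to_genomic(m, c(7L, 8L)),
    cds_offset = c(7L, 8L), ref_tx = c("C", "A"), alt_tx = c("A", "C"),
    precursor_pos = c(3L, 3L), ref_aa = c("H", "H"), alt_aa = c("N", "P"),
    stringsAsFactors = FALSE)
  joint <- haplotype_to_substitutions(m, "11", sites)
  # CAT -> ACT = Thr, not the single-SNV consequences Asn or Pro
  expect_equal(joint$alt_aa, "T")
  expect_equal(joint$mature_pos, 1L)
})

test_that("catalog matching is exact and the reference maps to its name", {
  cat <- variant_catalog(data.frame(
    gene = "CSN3", name = c("B", "A", "A1"),
    substitutions = c("", "136:I>T", "136:I>T;148:A>D"),
    stringsAsFactors = FALSE))
  expect_equal(match_catalog("", cat, "CSN3"),
               list(name = "B", status = "known"))
  expect_equal(catalog_reference(cat, "CSN3"), "B")
  expect_equal(match_catalog("136:I>T;148:A>D", cat, "CSN3")$name, "A1")
  # canonicalization: order of listed substitutions does not matter
  expect_equal(match_catalog("148:A>D;136:I>T", cat, "CSN3")$name, "A1")
  expect_equal(match_catalog("136:I>V", cat, "CSN3")$status, "novel")
})

test_that("hierarchical naming appends dotted children in order", {
  cat <- variant_catalog(data.frame(
    gene = "CSN2", name = c("REF", "A1"),
    substitutions = c("", "67:H>P"), stringsAsFactors = FALSE))
  r1 <- assign_name("67:H>P;93:M>L", cat, "CSN2")
  expect_equal(r1$name, "A1.1")
  r2 <- assign_name("67:H>P;106:H>Q", r1$catalog, "CSN2")
  expect_equal(r2$name, "A1.2")
  # a later superset of A1.1 nests one level deeper
  r3 <- assign_name("67:H>P;93:M>L;122:S>R", r2$catalog, "CSN2")
  expect_equal(r3$name, "A1.1.1")
  # base selection prefers the largest contained substitution set
  expect_equal(assign_name("67:H>P;93:M>L;122:S>R;140:A>V",
                           r3$catalog, "CSN2")$name, "A1.1.1.1")
  # with two equally overlapping bases, occurrences then name break the tie
  cat2 <- variant_catalog(data.frame(
    gene = "G", name = c("R", "X", "Y"),
    substitutions = c("", "10:A>V", "20:S>T"), stringsAsFactors = FALSE))
  both <- "10:A>V;20:S>T"
  expect_equal(assign_name(both, cat2, "G")$name, "X.1")  # lexicographic
  expect_equal(assign_name(both, cat2, "G",
                           occurrences = c(Y = 5, X = 1))$name, "Y.1")
})

test_that("dotted names are strict supersets of their base sets", {
  cat <- toy_catalog()
  set.seed(77)
  # grow each gene's catalog by a few random novel supersets
  for (g in unique(cat$gene)) {
    pool <- string_to_subs(paste(lactovar:::toy_subs_strings(g),
                                 collapse = ";"))
    for (i in 1:3) {
      extra <- data.frame(mature_pos = 200L + i, ref_aa = "A",
                          alt_aa = "V", stringsAsFactors = FALSE)
      base_set <- pool[sample(nrow(pool), sample(nrow(pool), 1)), ]
      s <- subs_to_string(rbind(base_set, extra))
      if (match_catalog(s, cat, g)$status == "novel")
        cat <- assign_name(s, cat, g)$catalog
    }
  }
  dotted <- grepl("\\.", cat$name)
  for (i in which(dotted)) {
    base_name <- sub("\\.[0-9]+$", "", cat$name[i])
    base_subs <- cat$substitutions[cat$gene == cat$gene[i] &
                                     cat$name == base_name]
    expect_true(lactovar:::subs_is_subset(base_subs, cat$substitutions[i]))
    expect_gt(nchar(cat$substitutions[i]), nchar(base_subs))
  }
})

test_that("catalogs round-trip byte-identically after canonical ordering", {
  cat <- toy_catalog()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat, p1)
  write_catalog(read_catalog(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
  # catalog invariants are enforced on read
  bad <- data.frame(gene = "G", name = c("R", "X.1"),
                    substitutions = c("", "1:A>V"),
                    stringsAsFactors = FALSE)
  expect_error(variant_catalog(bad), "no base")
  expect_error(variant_catalog(data.frame(
    gene = "G", name = c("X"), substitutions = "1:A>V",
    stringsAsFactors = FALSE)), "reference")
})

test_that("kappa-casein regions follow the chymosin cleavage anatomy", {
  expect_equal(kappa_region(50L), "para_kappa")
  expect_equal(kappa_region(95L), "para_kappa")
  expect_equal(kappa_region(105L), "chymosin_site")
  expect_equal(kappa_region(106L), "chymosin_site")
  expect_equal(kappa_region(113L), "cmp")
  expect_equal(kappa_region(149L), "cmp")  # the Ser149Phe phosphorylation site
  expect_equal(kappa_region(169L), "cmp")
  expect_equal(kappa_region(100L), "other")
  expect_error(kappa_region(170L), "outside")
})

test_that("protein-variant calling is deterministic and counts occurrences", {
  m <- toy_protein_gene()
  sites <- toy_protein_sites(m)
  cat <- variant_catalog(data.frame(
    gene = "TOYP", name = c("A", "B"),
    substitutions = c("", "1:H>P"), stringsAsFactors = FALSE))
  # 6 individuals: 4 ref/ref, 1 ref/hap0100 x2, 1 hap0111/hap0100
  geno <- rbind(matrix(0L, 4, 4),
                c(0L, 1L, 0L, 0L), c(0L, 1L, 0L, 0L),
                c(0L, 2L, 1L, 1L))
  fit <- haplo_em(geno)
  # default admission (2 copies or 2 carriers): the single-copy novel
  # haplotype is reported as unconfirmed, not named
  conservative <- call_protein_variants(m, fit, cat, sites)
  expect_setequal(conservative$variants$name, c("A", "B"))
  expect_equal(conservative$unconfirmed$substitutions,
               "1:H>P;2:S>R;3:G>E")
  calls <- call_protein_variants(m, fit, cat, sites,
                                 min_copies = 1, min_carriers = 1)
  v <- calls$variants
  expect_setequal(v$name, c("A", "B", "B.1"))
  expect_equal(v$status[v$name == "B.1"], "novel")
  expect_equal(v$occurrences[v$name == "A"], 10)  # 4x2 hom + 2 het halves
  expect_equal(v$occurrences[v$name == "B"], 3)
  expect_equal(v$occurrences[v$name == "B.1"], 1)
  # rerun: byte-identical results
  again <- call_protein_variants(m, fit, cat, sites,
                                 min_copies = 1, min_carriers = 1)
  expect_identical(calls$variants, again$variants)
  expect_identical(as.data.frame(calls$catalog),
                   as.data.frame(again$catalog))
})
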