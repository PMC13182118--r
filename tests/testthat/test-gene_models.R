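test_that("gene length arithmetic matches the published sizes, PAEP off by one", {
  models <- toy_gene_models()
  expect_equal(gene_length(models$CSN3), 13073L)
  expect_equal(gene_length(models$CSN2), 8581L)
  expect_equal(gene_length(models$CSN1S1), 18151L)
  expect_equal(gene_length(models$CSN1S2), 18652L)
  expect_equal(gene_length(models$LALBA), 2778L)
  # published PAEP size is 5,049; end - start + 1 gives 5,050
  expect_equal(gene_length(models$PAEP), 5050L)

  expected <- c(CSN1S1 = 18151L, CSN2 = 8581L, CSN1S2 = 18652L,
                CSN3 = 13073L, LALBA = 2778L, PAEP = 5049L)
  expect_warning(val <- validate_gene_models(models, expected), "PAEP")
  expect_identical(val$gene[val$size_mismatch], "PAEP")

  # the convention is end - start + 1: a single-base span has length 1
  expect_equal(gene_length(list(start = 5L, end = 5L)), 1L)
})

test_that("genomic/CDS mapping agrees with an exhaustive coordinate walk", {
  tp <- toy_pair()
  fwd <- tp$fwd
  # oracle: walk every genomic position of the CDS intervals in order
  walk <- c(101:106, 201:206)
  for (o in seq_along(walk)) {
    expect_equal(genomic_to_cds(fwd, walk[o]), o)
    expect_equal(cds_to_genomic(fwd, o), walk[o])
  }
  expect_equal(genomic_to_cds(fwd, 203), 9L)
  # flip the same gene to the reverse strand: offsets count from the top,
  # so the base at former offset 9 now sits at offset 12 - 9 + 1 = 4
  flipped <- gene_model("TOYRC", "1", 50, 300, "-",
                        exons = rbind(c(95, 106), c(201, 212)),
                        cds_start = 101, cds_end = 206,
                        signal_peptide_len = 1,
                        cds_sequence = "TCCATGAGCCAT", flank = 40)
  expect_equal(genomic_to_cds(flipped, 203), 4L)
  # intron and flank positions are non-coding / out of range
  expect_true(is.na(genomic_to_cds(fwd, 150)))
  expect_error(genomic_to_cds(fwd, 5), "outside")
})

test_that("coordinate round trip is a bijection on toy genes", {
  tp <- toy_pair()
  for (m in tp) {
    offs <- seq_len(nchar(m$cds_sequence))
    pos <- cds_to_genomic(m, offs)
    expect_false(anyDuplicated(pos) > 0)
    expect_equal(genomic_to_cds(m, pos), offs)
  }
})

test_that("codon_effect translates with the standard genetic code", {
  m <- gene_model("T", "1", 90, 320, "+", exons = rbind(c(101, 106)),
                  cds_start = 101, cds_end = 106, signal_peptide_len = 0,
                  cds_sequence = "ATGGCT", flank = 20)
  e <- codon_effect(m, 6, "A")  # GCT -> GCA
  expect_equal(e[c("precursor_pos", "ref_aa", "alt_aa")],
               list(precursor_pos = 2, ref_aa = "A", alt_aa = "A"))
  expect_true(e$synonymous)
  e <- codon_effect(m, 4, "C")  # GCT -> CCT
  expect_equal(e$alt_aa, "P")
  expect_false(e$synonymous)
  # alt equal to the reference base is the identity change
  e <- codon_effect(m, 1, "A")
  expect_true(e$synonymous)
  expect_error(codon_effect(m, 7, "A"), "range")
})

test_that("region classification respects transcription direction", {
  tp <- toy_pair()
  expect_equal(classify_region(tp$fwd, tp$fwd$start - 1, "A", "G"), "upstream")
  expect_equal(classify_region(tp$fwd, tp$fwd$end + 1, "A", "G"), "downstream")
  # on the reverse-strand mirror the high-coordinate flank is upstream
  expect_equal(classify_region(tp$rev, tp$rev$end + 1, "A", "G"), "upstream")
  expect_equal(classify_region(tp$rev, tp$rev$start - 1, "A", "G"), "downstream")
  # coding SNV GAT->GAA style change is missense; third-base GCT->GCA is not
  m <- gene_model("T", "1", 90, 320, "+", exons = rbind(c(95, 110)),
                  cds_start = 101, cds_end = 106, signal_peptide_len = 0,
                  cds_sequence = "GATGCT", flank = 20)
  expect_equal(classify_region(m, 103, "T", "A"), "missense")  # GAT->GAA? pos3
  expect_equal(classify_region(m, 106, "T", "A"), "synonymous")
  expect_equal(classify_region(m, 97, "A", "G"), "five_prime_utr")
  expect_equal(classify_region(m, 108, "A", "G"), "three_prime_utr")
  expect_error(classify_region(m, 103, "TT", "A"),
               class = "lactovar_unsupported_variant")
})

test_that("strand-mirrored genes give identical protein consequences", {
  tp <- toy_pair()
  offs <- seq_len(12)
  pos_f <- cds_to_genomic(tp$fwd, offs)
  pos_r <- cds_to_genomic(tp$rev, offs)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (o in offs) {
    for (alt in setdiff(c("A", "C", "G", "T"),
                        substr(tp$fwd$cds_sequence, o, o))) {
      ef <- codon_effect(tp$fwd, o, alt)
      er <- codon_effect(tp$rev, o, alt)
      expect_identical(ef, er)
      # and via genomic classification with reference-strand alleles
      ref_f <- substr(tp$fwd$cds_sequence, o, o)
      cf <- classify_region(tp$fwd, pos_f[o], ref_f, alt)
      cr <- classify_region(tp$rev, pos_r[o], comp[[ref_f]], comp[[alt]])
      expect_identical(cf, cr)
    }
  }
})

test_that("gene model invariants hold and violations are rejected", {
  models <- toy_gene_models()
  for (m in models) {
    overlap <- sum(pmin(m$exons[, 2], m$cds_end) -
                     pmax(m$exons[, 1], m$cds_start) + 1)
    expect_equal(overlap, nchar(m$cds_sequence))
    expect_equal(nchar(m$cds_sequence) %% 3, 0)
    expect_lt(m$signal_peptide_len, nchar(m$cds_sequence) / 3 - 1)
  }
  expect_error(gene_model("B", "1", 100, 50, "+", rbind(c(100, 120)),
                          100, 111, 0, "ATGGCTCATGGA"), "start")
  expect_error(gene_model("B", "1", 50, 300, "+",
                          rbind(c(95, 110), c(100, 120)),
                          101, 112, 0, "ATGGCTCATGGA"), "overlap")
  expect_error(gene_model("B", "1", 50, 300, "+", rbind(c(95, 120)),
                          101, 112, 0, "ATGTAACATGGA"), "stop")
})

test_that("gene models round-trip through their TSV format", {
  models <- toy_gene_models()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_models(models, path)
  back <- read_gene_models(path)
  expect_identical(names(back), names(models))
  for (g in names(models)) {
    expect_identical(back[[g]]$exons, models[[g]]$exons)
    expect_identical(back[[g]]$cds_sequence, models[[g]]$cds_sequence)
    expect_identical(back[[g]]$cds_map, models[[g]]$cds_map)
  }
})
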