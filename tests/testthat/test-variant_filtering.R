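models <- toy_gene_models()

test_that("VCF reading restricts to gene regions, decomposes, and skips indels", {
  dir <- withr::local_tempdir()
  panel <- sample_panel(c("S1", "S2"), c("B1", "B1"))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1", "S2"), collapse = "\t"))
  row <- function(chrom, pos, ref, alt, g1, g2)
    paste(c(chrom, pos, ".", ref, alt, "50", "PASS", "MQ=60", "GT", g1, g2),
          collapse = "\t")
  vcf <- file.path(dir, "t.vcf")
  writeLines(c(hdr,
    row("6", 85646000, "A", "C,T", "1/2", "0/1"),   # triallelic SNV
    row("6", 85646010, "A", "AT", "0/1", "0/0"),    # indel: skipped
    row("6", 85600000, "A", "G", "0/1", "0/1"),     # outside all windows
    row("5", 31184000, "G", "A", "0/1", "./.")),    # LALBA, one missing
    vcf)
  vs <- read_variants(vcf, panel, models)
  expect_equal(n_variants(vs), 3L)  # 2 from the triallelic + 1 LALBA
  expect_equal(vs$n_skipped_indels, 1L)
  # decomposition: allele-specific dosages, other alt counts as non-carrier
  tri <- vs$variants$pos == 85646000
  expect_equal(unname(vs$gt[which(tri & vs$variants$alt == "C"), ]), c(1L, 1L))
  expect_equal(unname(vs$gt[which(tri & vs$variants$alt == "T"), ]), c(1L, 0L))
  expect_true(is.na(vs$gt[vs$variants$chrom == "5", "S2"]))
  # sample mismatch is a panel error
  bad_panel <- sample_panel(c("S1", "SX"), c("B1", "B1"))
  expect_error(read_variants(vcf, bad_panel, models), "panel")
})

test_that("quality filters match the stated thresholds at their boundaries", {
  gt <- rbind(c(0L, 1L, 1L, 0L))
  ad <- rbind(c(0L, 5L, 5L, 0L))
  dp <- rbind(c(10, 10, 10, 10))
  pass <- make_variant_set(qual = 20, mq = 20, gt = gt, ad = ad, dp = dp)
  expect_equal(n_variants(apply_filters(pass)$kept), 1L)

  for (case in list(list(qual = 19.9, mq = 60, reason = "qual"),
                    list(qual = 50, mq = 19.9, reason = "mq"))) {
    vs <- make_variant_set(qual = case$qual, mq = case$mq,
                           gt = gt, ad = ad, dp = dp)
    res <- apply_filters(vs)
    expect_equal(n_variants(res$kept), 0L)
    expect_equal(res$removed$reasons, case$reason)
  }
  # alt allele in a single individual is removed however well supported
  vs <- make_variant_set(qual = 50, mq = 60,
                         gt = rbind(c(0L, 2L, 0L, 0L)),
                         ad = rbind(c(0L, 9L, 0L, 0L)), dp = dp)
  expect_equal(apply_filters(vs)$removed$reasons, "carriers")
  # fewer than 3 cohort-wide alt reads fails the read criterion
  vs <- make_variant_set(qual = 50, mq = 60,
                         gt = rbind(c(0L, 1L, 1L, 0L)),
                         ad = rbind(c(0L, 1L, 1L, 0L)), dp = dp)
  expect_equal(apply_filters(vs)$removed$reasons, "alt_reads")
  # per-sample mode requires one sample at >= 3
  expect_equal(n_variants(apply_filters(vs, per_sample_reads = TRUE)$kept), 0L)
  vs2 <- make_variant_set(qual = 50, mq = 60,
                          gt = rbind(c(0L, 1L, 1L, 0L)),
                          ad = rbind(c(0L, 3L, 1L, 0L)), dp = dp)
  expect_equal(n_variants(apply_filters(vs2, per_sample_reads = TRUE)$kept), 1L)
  # missing annotations pass and are noted
  vs3 <- make_variant_set(qual = NA_real_, mq = NA_real_, gt = gt,
                          ad = rbind(rep(NA_integer_, 4)), dp = dp)
  res3 <- apply_filters(vs3)
  expect_equal(n_variants(res3$kept), 1L)
  expect_match(res3$ledger$notes, "no_AD")
  expect_match(res3$ledger$notes, "no_QUAL")
})

test_that("the five-variant fixture keeps exactly the hand-computed set", {
  dir <- withr::local_tempdir()
  fx <- make_fixture_suite(dir)
  panel <- sample_panel(c("S1", "S2", "S3", "S4"), c("B1", "B1", "B2", "B2"))
  vs <- read_variants(fx$filter_vcf, panel, models)
  expect_equal(n_variants(vs), 5L)
  res <- apply_filters(vs)
  kept_keys <- with(res$kept$variants,
                    sprintf("%s:%d:%s>%s", chrom, pos, ref, alt))
  expect_setequal(kept_keys, c("6:85646000:A>G", "6:85646300:T>C",
                               "6:85646400:A>C"))
  expect_setequal(res$removed$reasons, c("qual", "carriers"))
  # partition: kept and removed together are the input, disjoint
  expect_equal(nrow(res$kept$variants) + nrow(res$removed), 5L)
  expect_equal(sum(res$ledger$kept), 3L)
})

test_that("filters are monotone in their thresholds", {
  set.seed(11)
  n <- 40
  gt <- matrix(sample(0:2, n * 4, replace = TRUE, prob = c(.6, .3, .1)),
               n, 4)
  dp <- matrix(sample(2:20, n * 4, replace = TRUE), n, 4)
  ad <- matrix(0L, n, 4)
  for (i in seq_len(n * 4))
    ad[i] <- if (gt[i] == 0) 0L else if (gt[i] == 2) dp[i] else
      sample(seq_len(dp[i] - 1), 1)
  vs <- make_variant_set(qual = runif(n, 10, 60), mq = runif(n, 10, 70),
                         gt = gt, ad = ad, dp = dp)
  base_kept <- apply_filters(vs)$ledger$kept
  for (arg in c("min_alt_reads", "min_qual", "min_mq", "min_carriers")) {
    for (step in c(1, 5)) {
      args <- list(vs = vs); args[[arg]] <- formals(apply_filters)[[arg]] + step
      kept <- do.call(apply_filters, args)$ledger$kept
      expect_true(all(kept <= base_kept), info = arg)
    }
  }
})

test_that("low-depth flags use a strict threshold and report site means", {
  vs <- make_variant_set(qual = 50, mq = 60,
                         gt = rbind(c(0L, 1L, 1L, 0L)),
                         ad = rbind(c(0L, 2L, 4L, 0L)),
                         dp = rbind(c(4, 6, 8, 10)))
  res <- flag_low_depth(vs)
  expect_equal(res$site_summary$mean_depth, 7)
  # strict "< 6": depth 6 is not flagged
  expect_equal(unname(res$flags[1, ]), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$site_summary$n_low_depth, 1)
  all10 <- make_variant_set(qual = 50, mq = 60,
                            gt = rbind(c(0L, 1L, 1L, 0L)),
                            ad = rbind(c(0L, 5L, 5L, 0L)),
                            dp = rbind(rep(10, 4)))
  res10 <- flag_low_depth(all10)
  expect_equal(sum(res10$flags), 0)
  expect_equal(res10$site_summary$mean_depth, 10)
})

test_that("novelty labeling uses ids and positional keys", {
  gt <- rbind(c(0L, 1L, 1L, 0L)); ad <- rbind(c(0L, 5L, 5L, 0L))
  dp <- rbind(rep(10, 4))
  vs <- make_variant_set(qual = rep(50, 5), mq = rep(60, 5),
                         gt = gt[rep(1, 5), ], ad = ad[rep(1, 5), ],
                         dp = dp[rep(1, 5), ])
  vs$variants$id <- c("rs1", "rs2", NA, NA, NA)
  known <- c("rs1", "rs2",
             sprintf("6:%d:A>G", vs$variants$pos[3]))  # one positional key
  lab <- label_novelty(vs, known)
  expect_equal(lab$variants$status, c("known", "known", "known",
                                      "novel", "novel"))
  expect_equal(table(lab$variants$status)[["known"]], 3L)
})
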