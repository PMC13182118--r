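# small forward/reverse toy gene pair used across coordinate tests:
# CDS exons (101-106) and (201-206), 12 nt CDS = 4 codons, and its exact
# mirror on the reverse strand of the same span.
toy_pair <- function(cds = "ATGGCTCATGGA", spl = 1L) {
  fwd <- gene_model("TOYF", "1", 50, 300, "+",
                    exons = rbind(c(95, 106), c(201, 212)),
                    cds_start = 101, cds_end = 206,
                    signal_peptide_len = spl, cds_sequence = cds,
                    flank = 40, reference_variant_name = "A")
  # mirror: pos' = 50 + 300 - pos
  rev <- gene_model("TOYR", "1", 50, 300, "-",
                    exons = rbind(c(138, 149), c(244, 255)),
                    cds_start = 144, cds_end = 249,
                    signal_peptide_len = spl, cds_sequence = cds,
                    flank = 40, reference_variant_name = "A")
  list(fwd = fwd, rev = rev)
}

# in-memory variant_set builder for filter tests (bypasses VCF I/O)
make_variant_set <- function(n_samples = 4, qual, mq, gt, ad, dp,
                             gene = "CSN3", chrom = "6",
                             pos = NULL, ref = "A", alt = "G") {
  nv <- length(qual)
  if (is.null(pos)) pos <- 85646000L + seq_len(nv) * 10L
  panel <- sample_panel(sprintf("S%d", seq_len(n_samples)),
                        rep(c("B1", "B2"), length.out = n_samples))
  variants <- data.frame(chrom = chrom, pos = pos, id = NA_character_,
                         ref = ref, alt = alt, qual = qual, mq = mq,
                         gene = gene, stringsAsFactors = FALSE)
  vs <- lactovar:::new_variant_set(variants, gt, ad, dp, panel)
  vs
}
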