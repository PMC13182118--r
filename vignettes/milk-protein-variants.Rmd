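---
title: "Calling milk-protein variants from unphased genotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling milk-protein variants from unphased genotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactovar)
```

## The problem

Bovine milk-protein variants are named combinations of amino-acid
substitutions in the mature protein of one of six genes: the casein
cluster *CSN1S1*, *CSN2*, *CSN1S2* and *CSN3* on BTA6, and the whey
protein genes *LALBA* (BTA5) and *PAEP* (BTA11). Two features make variant
calling from sequence data non-trivial. First, a variant is a *haplotype*:
β-CN A2 differs from A1 at one position and from B at two, so per-site
missense annotation cannot name variants; the phase of missense alleles
within a gene must be reconstructed. Second, positions are numbered on the
*mature* protein, after removal of the N-terminal signal peptide, so
genomic coordinates must be threaded through exon structure, strand,
codon, and signal-peptide offset. `lactovar` implements both steps plus the
reporting around them.

## Coordinate model

Gene models use 1-based inclusive coordinates throughout, matching VCF and
gene-table conventions; gene length is `end - start + 1`. The coding
sequence is stored in transcription orientation without the terminal stop
codon, so its length is exactly three times the precursor length, and the
signal-peptide length must leave at least two mature residues. On
reverse-strand genes (here *CSN2*) CDS offsets count from the
high-coordinate end downward and alternate alleles are complemented before
translation; a property test checks that a gene and its reverse-complement
mirror produce identical protein consequences for corresponding variants.

Region classification assigns `upstream`/`downstream` relative to
transcription direction, resolves coding SNVs to `synonymous`/`missense`
via the standard genetic code (SNVs creating a stop codon fall into a
separate `coding_other` class), and calls exonic non-coding positions
5′/3′ UTR by their side of the CDS. Splice-region consequences are not
modelled; such SNVs classify as intronic. Only SNVs are supported — indels
and MNV alleles are rejected with a typed error, since protein variants
here are SNP haplotypes.

One deliberate arithmetic choice: the published size column for *PAEP*
(5,049 bp) disagrees by 1 with `end - start + 1` (5,050). The package keeps
the arithmetic convention — validated by the other five genes — and
`validate_gene_models()` flags the discrepancy instead of special-casing
the gene.

## Quality filters

A site passes when (i) alt-supporting reads total at least 3, (ii) site
quality ≥ 20, (iii) mapping quality ≥ 20, and (iv) at least 2 distinct
animals carry the alt allele. The read criterion is summed over the cohort
by default because the source protocol does not state a per-sample rule; a
`per_sample_reads` flag switches to requiring one sample at the threshold.
Missing annotations (no AD, QUAL or MQ) pass the corresponding criterion
and are logged rather than silently dropped; missing genotypes never count
as carriers and are never imputed. Genotypes with depth strictly below 6
are flagged low-confidence, and protein variants whose carriers include a
flagged genotype at a defining site inherit the flag. All four filters are
monotone in their thresholds, which the suite checks property-style.

## Haplotype-frequency EM

For each gene, haplotypes are built over the missense sites (the sites
that can distinguish protein variants; a flag adds synonymous sites) in
CDS order. With unphased diploid genotypes, an animal heterozygous at *k*
sites is compatible with 2^(k−1) unordered haplotype pairs. `haplo_em()`
runs the classic gene-counting EM: the E-step weights pair (h₁,h₂) by
2·f<sub>h₁</sub>·f<sub>h₂</sub> (f² when homozygous), normalized within
each animal; the M-step divides expected haplotype counts by the number of
chromosomes 2N.

Numerical choices:

* **Initialization** is uniform over the haplotypes compatible with at
  least one observed genotype, which makes the fit deterministic — there is
  no random restart by default. Any uniform start yields the same first
  E-step posteriors, so this agrees exactly with an all-haplotype uniform
  start.
* **Convergence** is declared when the largest absolute frequency change
  falls below `tol` (default 1e-8) within `max_iter` (default 1000);
  non-convergence returns the fit with `converged = FALSE` rather than
  failing. The log-likelihood trace is retained and asserted non-decreasing.
* **Missing genotypes** drop the animal for that gene (counted, not
  imputed) — the simplest faithful treatment; marginalizing over missing
  sites would be the natural extension.
* **Enumeration cap**: more than 20 heterozygous sites raises an error
  instead of attempting 2^19 pairs; milk-protein genes have far fewer
  missense sites.
* Haplotypes estimated below 1/(4N) are flagged *sub-singleton* in
  `summary()` — less than half a chromosome of expected support.

Per-breed estimates (`haplo_em_by_breed()`) re-run the EM within each
breed, initialized from the cohort fit with a small positive floor so a
haplotype absent from the cohort optimum can still be picked up; the
fixed point on well-determined data is unchanged, small breeds converge
faster. Most-probable pair assignment (`predict()`) takes the argmax of
the E-step posterior under the final frequencies, breaking exact ties
lexicographically by haplotype string so reruns are identical.

The test suite keeps an independent brute-force oracle — a direct EM over
all 2^S haplotypes and all ordered pairs, sharing no code with the
implementation — and requires agreement to 1e-10 on random instances with
up to 4 sites and 20 animals, alongside a closed-form worked example (one
homozygous-reference animal plus one double heterozygote converge to
frequencies 3/4 and 1/4).

## From haplotypes to named variants

Each haplotype's alternate alleles are applied to the reference CDS and
every affected codon is re-translated jointly, so two SNVs in one codon
give the doubly-edited codon's residue, not the union of single-SNV
effects. Substitutions whose precursor position lies inside the signal
peptide are discarded — they cannot alter the mature protein — and the
remaining positions are shifted by the signal-peptide length. Distinct
haplotypes that yield the same substitution set (e.g. reference vs
signal-peptide-only) aggregate into one protein variant.

Matching against the catalog is exact set equality on canonical
`pos:ref>alt` strings. Novel sets are named hierarchically: the base is
the catalog variant whose substitution set is contained in the novel set
with maximal size (dotted names are eligible, so lineages deepen:
A1 → A1.1 → A1.1.1); the child index is one past the highest existing
child of that base, and each new name is appended to the catalog so later
assignments see it. Novel variants are processed in descending occurrence
order with ties broken by the substitution string, making naming
deterministic. Where two unrelated bases overlap the novel set equally —
a case the nomenclature's description leaves open — the package prefers
the base with more observed occurrences, then the lexicographically
smaller name; this is a package decision, stated here because no
authoritative rule exists.

Occurrences default to hard-assignment counts (copies of chromosomes whose
best pair contains the haplotype), matching the notion of "times observed
in the dataset"; posterior-weighted expected counts are available via
`posterior_weighted = TRUE`. Novel variants are only admitted with at
least 2 haplotype copies or 2 carrier animals (configurable), mirroring
the ≥2-animal site filter; sub-threshold sets are reported in a separate
unconfirmed table rather than named.

For κ-casein, `kappa_region()` maps mature positions onto the protein's
functional anatomy: residues 1–95 belong to para-κ-casein, the
micelle-retained N-terminal part; 105/106 flank the chymosin cleavage site
(Phe105–Met106); 113–169 lie in the hydrophilic C-terminal section of the
caseinomacropeptide.

## Networks and reports

The variant network for a gene contains every detected variant plus
catalog entries not observed (three node statuses), with an edge wherever
two variants differ at exactly one mature position — added, removed, or
changed residue all count as one step, so two different substitutions at
the same position are adjacent. Edges carry `pos: aa1<->aa2` labels.
Adjacency is position-level by design; restricting edges to naming-lineage
steps would be a stricter alternative, but all distance-1 pairs is what a
substitution-step diagram shows. Export formats are GraphML (round-trips
through igraph), DOT (one fill class per status) and a TSV edge list; the
package deliberately draws nothing.

Composition tables report within-gene categories as percentages of the
within-gene total, rounded half-up to two decimals (such tables can sum to
100.01), with upstream/downstream counted separately. The functional
report computes the β-CN A2-family frequency from substitution sets —
every variant whose residue at mature position 67 is proline, so novel
Pro67 variants join automatically — plus κ-CN A and B and β-LG B
frequencies, for breeds with at least 20 animals (configurable). Whether
such summaries should use EM frequencies or hard-assignment counts is not
universally settled; the frequency tables use the EM estimates, and
hard-assignment occurrence counts are reported alongside in the variant
tables.

## The synthetic cohort: what it does and does not emulate

`simulate_population()` generates a multi-breed diploid cohort with known
ground truth. Defaults, chosen once as a realistic desk-scale analogue of
a multi-breed resequencing panel: three breeds of 60/50/40 animals; per
gene a pool of five haplotypes — reference, one known single-substitution
variant, one known two-substitution variant, a novel three-substitution
haplotype, and a signal-peptide-only haplotype — spanning upstream,
UTR, intronic, synonymous, signal-peptide and mature missense sites so
every region category is exercised; per-genotype error rate 0.001 and
missingness 0.01; read depth negative-binomial with mean 10 and dispersion
8 (so the depth-6 flag path fires occasionally, consistent with a
mean-depth-around-10 sequencing regime); site QUAL ~ N(60, 8) and
MQ ~ N(60, 3) floored well above the filter thresholds. Haplotype pairs
are drawn independently within breed (Hardy–Weinberg); truth is recorded
before errors, missingness and depths are applied; output is
deterministic given the seed, byte for byte.

The fixture gene models carry the published genomic coordinates and
strands but synthetic exon structures and toy coding sequences (the file
is named `*_synthetic.tsv` accordingly), and the bundled catalog reuses
field-style variant names over synthetic substitution content. The
simulator therefore validates coordinate arithmetic, EM calibration,
naming and reporting logic — it does not validate against real linkage
patterns (no inter-gene LD in the casein cluster), real allele frequencies,
sequencing-level artifacts (no read simulation), or the real catalog
content, so green tests certify the machinery, not biological conclusions
about any particular breed.

## Problem sizes and tolerances used in validation

The packaged checks run at deliberately small scale: EM-oracle agreement
on instances up to 4 sites × 20 animals at 1e-10; frequency-recovery
calibration on 200 replicates of 4 haplotypes (0.4/0.3/0.2/0.1) over 400
chromosomes, requiring all estimates within 3 standard errors
√(f(1−f)/2N) in at least 95% of replicates; end-to-end recovery on a
150-animal error-free cohort, exact for names, statuses, occurrence
counts and network edges, and within 3·SE + 0.01 per breed-level
frequency (the 0.01 absorbing EM dust on small breeds). Frequency tables
drop haplotypes below 1e-6 — EM never returns exact zeros — and assert
sums of 1 within 1e-6.

## Known limitations

* Phasing quality is bounded by the EM's assumptions (random pairing
  within scope); reference-panel phasing and recombination are out of
  scope.
* Individuals with any missing genotype at a gene's selected sites are
  dropped for that gene rather than marginalized.
* Splice-site and regulatory consequences are not called; indels and MNVs
  are rejected rather than decomposed.
* Novelty labeling is a lookup against a user-supplied ID list, not a
  live database query.
* The bundled catalog and gene models are synthetic fixtures; real
  analyses must supply curated CDS sequences, signal-peptide lengths and
  catalog content.
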