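# imprintomics

Calling imprinted genes and differentially methylated regions (DMRs)
from reciprocal crosses between inbred plant strains.

## What it does, and for whom

Genomic imprinting — parent-of-origin-dependent monoallelic
expression — is detected by crossing two strains reciprocally (A♀×B♂
and B♀×A♂), assigning RNA-seq reads to a parental genome via
strain-distinguishing SNPs, and asking whether the maternal:paternal
ratio deviates from the tissue's dosage expectation in *both* cross
directions. In triploid endosperm (two maternal : one paternal genome)
the non-imprinted expectation is a maternal fraction of 2/3; in embryo
it is 1/2.

This package is for epigenomics researchers who want that analysis as a
tested, reusable pipeline:

* **SNP toolkit** — derive a B/C SNP list from A/B and A/C lists
  (copy / invert / exclude rules), filter SNPs by control-library
  misclassification (one-tailed exact binomial test against a 5% error
  null), classify aligned reads by strain of origin (with
  bisulfite-aware SNP masking), deduplicate position-sorted bisulfite
  reads, and produce per-gene allele counts by strict containment.
* **Imprinting caller** — per gene, a dosage-aware Fisher exact test of
  the null p1 = 2·p2 = 0.67 (maternal counts halved; optional
  noncentral mode with null odds ratio 4), Benjamini–Hochberg
  correction (adjusted p < 0.01), imprinting factor ≥ 2, a seed-coat
  expression filter, maternal-fraction cutoffs (endosperm MEG ≥ 85%
  maternal / PEG ≥ 50% paternal; embryo 70%/30%), and a
  2-of-3-replicate consensus.
* **Allele-specific imprinting** — the parental bias factor
  b(g) = log2(m+1) − log2(2p+1) standardized over loci retained near
  the no-imprinting lines x = 2, y = 2 of the reciprocal ratio plane;
  95th/5th-percentile flags intersected across cross pairs yield
  patterns like "PEG except when strain C is the male parent".
* **DMR caller** — weighted methylation (Σme/Σtot over sites with ≥ 5
  reads) in 300-nt windows overlapping by 100 nt, two-sided Fisher test
  on shared informative cytosines, BH-adjusted q < 0.01 with
  context-specific thresholds (|Δ| ≥ 0.35 over ≥ 3 C for CG/CHG;
  ≥ 0.10 over ≥ 10 C for CHH), merging of contiguous significant
  windows, annotation, metaprofiles, and Tukey-HSD strain comparisons.
* **Population variability** — merged DMRs scored across 140 strains
  (≥ 5 CpG × ≥ 5 reads; censored when > 70 strains missing) and
  classified into five classes (very low / low range, not / weakly /
  strongly bimodal) from the score range and the fraction of strains in
  the outer quarter-bands of the range.
* **Synthetic-data generator** — every input above with planted truth
  (imprinted genes at stated effect sizes, DMRs of stated magnitude,
  population score vectors of each class, reads of known origin), so
  the whole pipeline is testable end to end without sequencing data.

## Worked example

```r
library(imprintomics)

cfg   <- truth_config(seed = 1)            # 2000 genes: 100 MEGs (95%
                                           # maternal), 50 PEGs (60%
                                           # paternal), 8 allele-specific
                                           # PEGs, 20 seed-coat genes
sim   <- simulate_allele_counts(cfg)
expr  <- simulate_tissue_expression(cfg)
calls <- call_imprinting(sim$counts, expr)
table(calls$status)
#>  MEG none  PEG
#>  300 5542  158
```

Each row of `calls` is one gene in one reciprocal cross pair: the 100
planted MEGs are recovered in all three pairs (300 calls), the 50 PEGs
likewise (150), and the 8 allele-specific PEGs appear as PEGs only in
the cross pair where strain C plays no role (158 = 150 + 8). The
ratio-plane step then names the pattern:

```r
asi <- detect_allele_specific(sim$counts, calls, expr)
unique(asi$pattern)
#> [1] "PEG except when strainC is the male parent"
nrow(asi)
#> [1] 8
```

DMRs, from a planted methylome pair (20 CG DMRs, methylation difference
0.5 over 10 CG sites at 12× coverage):

```r
anno <- simulate_annotation(cfg)
meth <- simulate_methylome_pair(cfg, anno)
win  <- compare_windows(meth$sample_a, meth$sample_b, "CG")
dmrs <- merge_dmrs(win)
nrow(dmrs)
#> [1] 18
```

At this seed 18 of the 20 planted DMRs are recovered (two fall just
under the 0.35 difference threshold after sampling noise) and no
background window is called — sensitivity 0.9 at specificity ~1, the
regime the acceptance tests assert.

The full pipeline (`run_pipeline(pipeline_config(out_dir, seed = 1))`)
writes every table as TSV/BED plus a JSON manifest; a command-line
wrapper is installed at `inst/cli/imprintomics`
(`imprintomics simulate|call-imprinting|call-allele-specific|call-dmrs|
classify-variability|derive-snps|filter-snps|classify-reads|
count-alleles|run-all`).

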