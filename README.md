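# lncdesert

Positional classification and expression characterization of **desert
lncRNAs** — long noncoding RNA genes lying more than 50 kb from any
protein-coding gene (PCG).

Most lncRNAs overlap or flank PCGs, entangling their apparent function
with *cis*-regulation of the neighbour. Desert lncRNAs are free of that
confounder, and in human endoderm differentiation they behave as a
distinct class: higher expressed than other lncRNAs, more cytoplasmic,
and strongly stage-specific. `lncdesert` implements the computational
pipeline behind that characterization for anyone analysing annotated
bulk (or fraction-resolved) RNA-seq:

* **Classification** — every lncRNA gene body is compared, strand-blind
  and chromosome-wise, against all PCG gene bodies:
  *overlapped* (shares ≥ 1 nt), *proximal* (nearest PCG within 50 kb),
  or *desert* (gap > 50 kb). Gaps count intervening nucleotides;
  a gap of exactly 50 kb is proximal.
* **Normalization** — gene-level counts to TPM
  (`TPM_g = 10^6 · (c_g/ℓ_g) / Σ_j (c_j/ℓ_j)`, with ℓ in kb) and FPKM
  (`FPKM_g = 10^9 · c_g / (ℓ_g^{nt} · N)`).
* **Subcellular localization** — the cytoplasm/nucleus relative
  concentration index from fractionated FPKM,
  `CN.RCI = log2(CE/NE) + log2(CE/NM)`
  (CE cytoplasmic elution, NE nuclear elution, NM nuclear insoluble),
  with Mann–Whitney comparisons between positional categories.
* **Specificity** — the Jensen–Shannon stage-specificity score
  `max_s (1 − √JSD₂(p, e_s))` and the Normalized Difference
  `(E₍₁₎ − E₍₂₎)/(E₍₁₎ + E₍₂₎)`, plus per-gene tissue rankings by
  median TPM.
* **Differential expression** — strict threshold filtering
  (`p < 0.05`, `|log2FC| > 1`), positional-category breakdowns of the
  calls with macro-averaging across datasets, table-vs-table overlap
  and Pearson fold-change correlation, and a minimal Welch-t stand-in
  engine for desk-scale work.
* **Synthetic data** — a seeded generator that plants known positional
  classes, stage programs, fold changes and localization ratios, so the
  whole pipeline is testable against ground truth offline.

## Worked example

```r
library(lncdesert)

spec <- synthetic_spec(seed = 42, n_pcg = 200, n_lnc = 400)
ann  <- make_annotation(spec)          # writes a GENCODE-dialect GTF
cl   <- classify_lncrnas(ann$annotation)
head(cl[, c("gene_id", "chrom", "category", "nearest_pcg_id", "gap_nt")], 4)
#>     gene_id chrom   category nearest_pcg_id gap_nt
#> 1 SYNLN0294  chr1   proximal      SYNPG0001  30893
#> 2 SYNLN0152  chr1 overlapped      SYNPG0007     NA
#> 3 SYNLN0386  chr1 overlapped      SYNPG0007     NA
#> 4 SYNLN0105  chr1   proximal      SYNPG0010  25381

round(100 * category_proportions(cl), 2)
#> overlapped   proximal     desert
#>         50         30         20
```

The generator planted a 50/30/20 overlapped/proximal/desert mix, and
classification recovers it exactly; `gap_nt` is the intergenic distance
to the nearest PCG (NA for overlapped genes, whose gap is undefined).
Localization works the same way:

```r
frac <- make_fractions(spec, ann$truth)       # CE/NE/NM FPKM per gene
rci  <- compute_rci(frac)                     # CN.RCI + expression filter
compare_rci_by_category(rci[rci$gene_id %in% cl$gene_id, ], cl)
#>             comparison n_desert n_other median_desert median_other   p_value
#> 1 desert_vs_overlapped       80     200     0.1639574 -0.006758406 0.1007826
#> 2   desert_vs_proximal       80     120     0.1639574  0.124648825 0.6634438
```

Here localization ratios were planted independently of category, so the
rank tests are (correctly) null; on data where desert lncRNAs are more
cytoplasmic the same call reports the shift and its p-value. The
end-to-end driver `run_characterization()` chains all stages from a
config (YAML or list) and writes one TSV per stage plus a JSON run
manifest; see the vignette
`vignettes/desert-lncrna-characterization.Rmd` for the full methods
account.

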