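# strandrepair

Strand-resolved analysis of genome-wide DNA damage and nucleotide excision
repair from Damage-seq and XR-seq data, with a kinetic forward simulator so
the whole pipeline is testable without external data.

## The problem

Cisplatin forms Pt-d(GpG) intra-strand crosslinks — adducts between two
adjacent guanines. Two sequencing assays read out their fate:

* **Damage-seq** captures lesions still present at harvest: the sequencing
  polymerase stalls immediately 3′ of the adduct, so the damaged GG sits
  1–2 bp upstream of the read's 5′ end.
* **XR-seq** captures the 21–31 nt oligomers excised by nucleotide excision
  repair, with the lesion 5–8 nt upstream of the read's 3′ end — a snapshot
  of repair *in progress*.

Repair is strand-asymmetric: transcription-coupled repair (TCR) acts only on
the transcribed strand (TS, the template strand) of active genes, on top of
global repair (GR) acting everywhere. Writing ΣD for the damage induced on a
gene's strand by treatment and T for the harvest time,

```
Damage_TS  = ΣD − ∫₀ᵀ GR_t(TS) dt − ∫₀ᵀ TCR_t dt      Damage_NTS = ΣD − ∫₀ᵀ GR_t(NTS) dt
XR_TS      = GR_T(TS) + TCR_T                          XR_NTS     = GR_T(NTS)
```

When GR removes a negligible share of total damage, the fraction of TS
damage cleared by TCR by harvest is estimated per gene by

```
TCR fraction ≈ 1 − Damage_TS / Damage_NTS
```

The package implements the full path to that statistic: positional GG
filtering of aligned reads against the reference, TS/NTS assignment from
gene annotations, library-size (median-of-ratios) and GG-dinucleotide
normalization, the TS/(TS+NTS) ratio, expression-quantile stratification
with Spearman correlations, pseudo-reference relative damage across samples,
mitochondrial background contrasts, and gene-level epigenomic track
association. A forward simulator (uniform Poisson damage per GG site,
exponential strand-specific repair with rate `k_TCR·e_g + k_GR` on the TS
and `k_GR` on the NTS) generates Damage-seq/XR-seq/RNA-seq data with known
truth.

## Worked example

Simulate a two-organ study (kidney damaged 1.6×, spleen 0.7×), filter the
Damage-seq reads, and estimate per-gene repair:

```r
library(strandrepair)

cfg <- sim_config(n_genes = 40, n_chromosomes = 2, chrom_length = 150000,
                  gene_length_range = c(1500, 3000),
                  n_reads_per_assay = 30000, seed = 7)
sim <- simulate_dataset(cfg, samples = c("kidney", "spleen"),
                        damage_multipliers = c(1.6, 0.7))

calls <- filter_damage_reads(sim$damage_reads, sim$genome)
filter_rejections(calls)
#>   cause             n
#> 1 mapq              0
#> 2 length            0
#> 3 out_of_bounds     0
#> 4 non_gg         2831
```

57,169 of 60,000 reads carry the positional GG signature (the rest are the
simulated 5% background). Counting, normalizing and estimating:

```r
counts <- build_count_matrix(calls, sim$genes)
nm_d <- normalize_counts(counts, size_factors(counts), sim$genes)
xr_counts <- build_count_matrix(filter_xr_reads(sim$xr_reads, sim$genome),
                                sim$genes, assay = "xr")
nm_x <- normalize_counts(xr_counts, size_factors(xr_counts), sim$genes)
est <- repair_estimates(nm_d, nm_x)
head(est[c("gene_id", "damage_ts", "damage_nts", "tcr_fraction",
           "damage_ratio", "xr_ratio")], 4)
#>   gene_id   damage_ts damage_nts tcr_fraction damage_ratio xr_ratio
#> 1 gene_0001     1.05        1.25        0.158        0.457    0.996
#> 2 gene_0002     0.830       1.13        0.265        0.424    0.997
#> 3 gene_0003     0.826       1.06        0.223        0.437    0.558
#> 4 gene_0004     0.227       1.20        0.811        0.159    1
glance(est)
#>   n_genes mean_tcr_fraction median_damage_ratio median_xr_ratio
#> 1      40             0.324               0.411           0.888
```

Gene 4 is highly expressed: 81% of its TS damage is already repaired at 4 h
and its damage strand ratio (0.159) sits well below the symmetric 0.5, while
its excision repair is almost entirely TS (xr_ratio ≈ 1). The mitochondrial
contrast shows the expected background pattern — mitochondria lack excision
repair, so mito XR-seq reads carry the GG signature only at chance rate:

```r
mito_background_contrast(sim$xr_reads, sim$genome, "xr")
#>   compartment n_reads  n_gg fraction
#> 1 mito            135    19    0.141
#> 2 nuclear       59865 57367    0.958
```

`run_pipeline()` chains all stages (simulate/load → filter → count →
normalize → analyze) from one configuration list or YAML file and writes
every stage table plus a reproducibility manifest;
`autoplot(quantile_stratify(...))`, `plot_strand_ratios()` and
`plot_relative_damage()` draw the main figures. See the methods vignette
(`vignettes/strand-repair-model.Rmd`) for the model, parameter meanings and
design choices.

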