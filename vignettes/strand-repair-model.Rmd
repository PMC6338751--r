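---
title: "Strand-resolved damage and repair: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-resolved damage and repair: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents what the package computes and why: the balance model
relating the two assays, the kinetic forward model behind the simulator, the
coordinate and signature conventions, the normalization machinery, and the
design decisions taken where more than one reasonable choice existed.

## The two assays and the balance model

Cisplatin's dominant DNA adduct is the Pt-d(GpG) intra-strand crosslink
between adjacent guanines. Two strand-specific assays read out its fate at a
harvest time $T$ (4 h by default):

* **Damage-seq** sequences fragments whose synthesis stalled immediately 3′
  of a surviving adduct, so it measures damage *remaining* at $T$: induced
  damage minus everything excised up to $T$.
* **XR-seq** sequences the 21–31 nt oligomers released by nucleotide
  excision repair near $T$, so it measures the repair *rate* at $T$.

Repair has two arms. Global repair (GR) acts on both strands everywhere;
transcription-coupled repair (TCR) acts only on the transcribed strand (TS —
the template strand, antisense to the mRNA) of active genes, with intensity
that grows with transcription. For a gene with induced per-strand damage
$\Sigma D$:

$$
\mathrm{Damage}^{TS} = \Sigma D - \int_0^T \mathrm{GR}^{TS}_t\,dt -
\int_0^T \mathrm{TCR}_t\,dt, \qquad
\mathrm{Damage}^{NTS} = \Sigma D - \int_0^T \mathrm{GR}^{NTS}_t\,dt,
$$
$$
\mathrm{XR}^{TS} = \mathrm{GR}^{TS}_T + \mathrm{TCR}_T, \qquad
\mathrm{XR}^{NTS} = \mathrm{GR}^{NTS}_T.
$$

When GR removes a negligible share of total damage over $[0, T]$,
subtracting the two damage equations and dividing by $\Sigma D$ gives the
per-gene **TCR fraction**

$$
\frac{\int_0^T \mathrm{TCR}_t\,dt}{\Sigma D} \;\approx\;
1 - \frac{\mathrm{Damage}^{TS}}{\mathrm{Damage}^{NTS}},
$$

implemented by `tcr_fraction()` on normalized counts. Sampling noise can push
the estimate below 0; the primary column is reported unclipped (clipping
would bias the estimator upward near 0), with a clipped companion column.

## The kinetic forward model

The integrals above do not pin down dynamics, so the simulator adopts the
simplest kinetics that reproduce the algebra and the observed monotonicity
of repair in expression:

* **Damage deposition is uniform.** Every GG site on either strand receives
  a Poisson(`damage_rate`) number of lesions, independent of position,
  strand and transcription.
* **Repair is exponential with strand-specific rates.** Each lesion draws an
  independent exponential waiting time with rate
  $\lambda = k_{TCR}\,e_g + k_{GR,TS}$ on the TS of gene $g$ (expression
  $e_g$), $\lambda = k_{GR,NTS}$ on the NTS and in intergenic sequence, and
  $\lambda = 0$ on the mitochondria-like chromosome — mitochondria lack
  nucleotide excision repair, which is also why their XR-seq reads are pure
  background.

Closed forms follow immediately (`repair_kinetics()`): expected damage
remaining $\Sigma D\, e^{-\lambda T}$, repaired fraction
$1 - e^{-\lambda T}$, and instantaneous excision rate
$\Sigma D\, \lambda\, e^{-\lambda T}$ at harvest. XR-seq reads are sampled
from lesions whose repair time falls in the window $(T - \delta, T]$
(default $\delta = 0.25$ h): the expected pool size is
$\Sigma D\,(e^{-\lambda(T-\delta)} - e^{-\lambda T}) \approx
\delta\,\Sigma D\,\lambda\,e^{-\lambda T}$, i.e. proportional to remaining
lesions times repair rate, which is what a finite-width snapshot of
"instantaneous" repair means operationally.

Note the snapshot is *non-monotone* in $\lambda$: a gene repaired much
faster than $1/T$ has already cleared its lesions and shows little ongoing
excision. The default `tcr_rate_coef = 0.1`/h per unit expression puts a
mean-expression gene at $\lambda T \approx 0.5$ (about a third of TS damage
repaired at 4 h, strongly expressed genes most of it), the regime in which
observed excision repair increases with expression while remaining TS damage
decreases — the behaviour the simulated studies are meant to emulate.
Raising the coefficient by a few-fold pushes highly expressed genes past the
peak and inverts the XR–expression correlation; that regime is reachable by
configuration but is not the default study condition.

### Generator defaults and what they mean

| parameter | default | meaning |
|---|---|---|
| `gc_content` | 0.42 | mammalian-like base composition; sets GG site density (~4.4% of positions per strand) |
| `gene_length_range` | 2–8 kb | compact genes so every gene comfortably exceeds the 10-GG QC floor |
| `expression_shape` | 0.6 | gamma shape (mean 1); long-tailed dynamic range typical of RNA-seq |
| `damage_rate` | 0.5 | expected lesions per GG site; gives hundreds of lesions per gene strand |
| `tcr_rate_coef` | 0.1 /h/expr | see above |
| `gr_rate_ts`, `gr_rate_nts` | 0.02 /h | ~8% of damage repaired globally by 4 h — "negligible" relative to total, as the TCR-fraction estimator assumes |
| `T_hours` | 4 | treatment-to-harvest interval |
| `xr_len_range` | 21–31 nt | excised-oligomer length range |
| `damage_read_length` | 50 nt | single-end damage read length |
| `xr_window_delta` | 0.25 h | snapshot window width |
| `background_read_fraction` | 0.05 | reads at uniform random positions |
| `rnaseq_dispersion` | 10 | NB size parameter; variance $\mu + \mu^2/10$ |

All randomness flows from one seed through labelled sub-streams
(per operation and per sample), so adding a stage or a replicate never
perturbs another's draws, and identical configurations reproduce identical
outputs byte for byte.

## Coordinates and positional signatures

All tabular coordinates are 0-based half-open; SAM (1-based) and GRanges
(1-based closed) are converted at the I/O boundary. A lesion is indexed by
its 5′ G *on the damaged strand*: for a minus-strand lesion whose GG
corresponds to CC at plus-coordinates $(p, p+1)$, that is $p+1$.

* **Damage-seq**: a read is accepted iff mapq > 20 (strict) and the 2 bases
  immediately upstream of its 5′ end in read orientation are GG — for a plus
  read `[start, end)` the genome slice `[start-2, start)`, for a minus read
  the reverse complement of `[end, end+2)`. "1–2 bp upstream" is read as the
  dinucleotide immediately preceding the alignment start, matching the
  chemistry (the polymerase stops 3′ of the adduct).
* **XR-seq**: mapq > 20, aligned length within 21–31, and the 4-mer at
  positions 5–8 counted from the 3′ end (3′-terminal base = position 1) must
  contain GG, read strictly inside the window (a G hanging out at position 4
  or 9 does not qualify). When the window holds several GG placements (e.g.
  GGG), the lesion is assigned to the 3′-most occurrence — the placement
  closest to the nominal lesion-to-3′-end distance mode.

Rejection causes are mutually exclusive with precedence
mapq → length → out-of-bounds → non-GG (cheap tests first, deterministic
tallies). Reads whose simulated placement would overrun a chromosome end are
resampled rather than truncated so positional signatures stay exact.

On the emission side, the XR placement offset is drawn uniformly — but only
from the offsets under which the 3′-most-GG localization rule recovers the
true lesion (offset 5, the 3′-most slot, always qualifies; 6 and 7 qualify
unless a chance GG sits 3′ of the lesion inside the window). This keeps the
emitted placement distribution as close to uniform as is compatible with an
exact read → lesion round trip, which the test suite asserts at 100%.

Background reads are placed uniformly at random, so they carry the GG
signature at the genomic chance rate — that is what makes the mitochondrial
XR-seq contrast (chance-level vs ~95% in nuclear DNA) a meaningful
diagnostic rather than a tautology.

## Normalization

Counts are indexed by (gene, strand class, sample). Two corrections apply:

1. **Library size**: DESeq-style median-of-ratios. The pseudo-reference is
   the per-row geometric mean across samples over rows positive in every
   sample; a sample's factor is the median ratio to it. One caveat worth
   stating: scaling one sample by $c$ moves the geometric-mean reference by
   $c^{1/n}$, so *every* factor shifts by $c^{\pm 1/n}$ and normalized
   values are depth-invariant only up to one global scalar. Every quantity
   the package reports downstream (TS/(TS+NTS), TCR fraction, correlations,
   mean-1-scaled relative damage) is invariant to that scalar, and the tests
   assert the scale-free form exactly.
2. **Target density**: division by the strand-matched GG count (`gg_ts` for
   TS cells, `gg_nts` for NTS cells). The adduct targets GG specifically, so
   GG content — not length — is the exposure; strand-matched counts are used
   because the two strands of a gene can differ in GG content. `length`
   mode (per kb) is available for comparison. The transformation is exactly
   invertible, which the tests assert cell by cell.

RNA-seq uses RPKM. QC retains genes that have expression in ≥1 sample,
appear in all assays, carry ≥10 GG on TS *or* NTS, are <100,000 bp
(strict), and have ≥20 reads summed over samples *in each assay
separately* — the last reading ("per assay" rather than pooled) being the
stricter and more natural interpretation of a per-platform threshold.
Downstream log displays use $\log_2(x + 1)$.

### Relative damage and identifiability

`relative_damage()` compares each sample's NTS Damage-seq counts to a
pseudo-reference (per-gene geometric mean of depth- and GG-adjusted counts)
by the median ratio, rescaled to mean 1 — reporting, e.g., which organ
accumulated the most adducts. A genome-uniform damage change and a
sequencing-depth change scale filtered gene counts identically, so they are
separable only through an explicit depth measure: the `library_sizes`
argument (total sequenced reads, or any depth-proportional quantity). With
it, doubling one sample's depth leaves its relative damage unchanged, while
a doubled damage rate doubles it; without an honest depth measure the
statistic is a depth-confounded ordering. Relative damage is reported
mean-1 because only the ordering and ratios are identified.

## Stratification and association

`quantile_stratify()` ranks genes by expression, splits them into
equal-count bins (sizes differ by at most 1), and summarises
$\log_2(\text{normalized}+1)$ per bin and (assay, strand class), averaging
replicates within gene before binning (log-then-average, stated here because
average-then-log differs). Gene-wise Spearman correlations against
expression accompany the profile; constant expression is flagged with a
warning and NA correlations rather than silently ranked. Default 10 bins.

`gene_track_signal()` aggregates an interval intensity track over gene
bodies (default) or a ±1 kb strand-aware promoter window as the
coverage-weighted mean with uncovered bases contributing 0.
`marker_correlations()` reports Spearman rho with two-sided p-values and
Benjamini–Hochberg adjustment across all (marker, quantity) pairs; it is
meant to be run on a caller-supplied subset of genes whose expression is not
perturbed by treatment, so pre-existing chromatin profiles are
interpretable.

## What the simulator does and does not emulate

It emulates: GG-rich genes on both strands; uniform per-GG-site damage;
expression-proportional TCR confined to the TS; slower global repair on both
strands; no repair in mitochondria; oligomer lengths 21–31 nt; exact
positional lesion signatures at read ends; a configurable uniform-background
read fraction; per-sample damage multipliers; per-lesion capture (so read
yield can scale with lesion load); negative-binomial RNA-seq.

It does not model: sequence-context bias (real Damage-seq reads show a
preference for adenine 5′ of the GG — deliberately not guessed at),
sequencing errors, PCR duplicates, adaptor read-through, ApG/GpNpG adduct
classes, inter-strand crosslinks, replication, isoform structure, or
chromatin-state heterogeneity beyond what per-gene rate overrides express.
Passing tests therefore demonstrate correctness of the *computational*
method under its stated model, not robustness to every artefact of real
libraries.

## Numerical and degenerate-input choices

* Overlapping gene annotations are refused by default; an optional
  nearest-TSS policy resolves multi-gene hits.
* A lesion belongs to a gene iff its 5′ G lies in the half-open interval;
  a lesion exactly at `end` is intergenic.
* Zero normalization denominators drop the cell with a tally rather than
  producing infinities; TS/(TS+NTS) is NA at 0/0; the TCR fraction is NA
  when NTS damage is 0.
* Mitochondrial chromosomes are recognised by name (`chrM`, `MT`;
  configurable).
* Size-factor estimation errors out (suggesting a pseudocount) when no gene
  is positive in all samples, rather than silently degenerating.

## Problem sizes used by the test suite

The simulated studies are sized so that statistical assertions are
comfortably stable: genomes of 0.1–1.8 Mb, 8–600 genes, 10⁴–2×10⁵ reads per
assay, and — for parameter-recovery checks — around 500 expected NTS lesions
per gene (8 kb genes at 50% GC with the damage rate calibrated to the
realised GG content). These are the package's chosen desk-scale study
conditions; the same code paths run unchanged on genome-scale inputs.

## Known limitations

The TCR-fraction estimator inherits the "negligible GR" assumption: with
substantial global repair it underestimates TCR by the GR share. The
relative-damage statistic requires an external depth measure (above).
Quantile profiles use the treated samples' expression; strongly
treatment-responsive genes should be excluded by the caller (the QC report
and gene subsetting hooks exist for that purpose). Gene territories are the
annotated bodies — no exon/intron or isoform resolution.
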