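---
title: "Methods: paired analysis of CRISPR cutting and CRISPR interference screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired analysis of CRISPR cutting and CRISPR interference screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duoscreen)
library(dplyr)
```

# The problem

Pooled loss-of-function screens deplete guides whose targets are required
for proliferation. Two CRISPR modalities are in common use: cutting
(CRISPRc), where active Cas9 makes a double-strand break in a coding exon
and repair indels ablate the gene, and interference (CRISPRi), where
catalytically dead Cas9 fused to the KRAB repressor silences transcription
when parked near a transcription start site (TSS). The two modalities have
distinct, mechanism-specific artifacts:

* **Cutting toxicity.** Cas9 cleavage itself arrests proliferation in
  proportion to the number of genomic cut sites, independent of any gene's
  function. Guides targeting amplified regions, or with multiple perfect
  genomic matches, deplete even when the genes they hit are dispensable.
* **Bidirectional promoters.** A KRAB-dCas9 guide occupying a promoter
  shared by two divergently transcribed genes silences both, so a
  dispensable gene sharing a sub-kilobase promoter with an essential gene
  is called essential.

`duoscreen` implements the full comparison pipeline — count normalization,
control-based essentiality testing, a distance-to-TSS guide-efficiency
model, CRISPRi library design rules, and the confound analyses — together
with a synthetic-screen generator with known ground truth, so that every
inferential step can be validated end to end without external data.

# Quantification model

Read counts $x_{ij}$ for guide $i$ in sample $j$ are converted to log
abundances

$$y_{ij} = \log_2\!\left(\frac{x_{ij}}{c_j} + \varepsilon\right),$$

where $c_j$ is the trimmed mean (10th–90th percentile, inclusive bounds,
linear interpolation) of the non-targeting control counts in sample $j$,
and $\varepsilon = 0.05$ stabilizes the transform at low counts. Trimming
makes $c_j$ robust to the handful of massively enriched guides that
dominate positive-selection screens, and $\varepsilon$ keeps zero-count
guides finite so none are filtered. Replicates are averaged in
log-transformed space and the log fold-change of a guide is
$y_{i,\mathrm{late}} - y_{i,\mathrm{early}}$; depletion is negative.

Base 2 and the placement of $\varepsilon$ inside the ratio are this
package's declared conventions (recorded in output metadata through
`attr(., "epsilon")`): with them, a guide at control-typical abundance has
$y \approx 0$ and fold-changes read directly in doublings.

# Essentiality testing

Guides targeting the AAVS1 safe-harbor locus cut (or bind) real chromatin
without any on-target fitness consequence, so they experience the
gene-independent component of each modality's effect — in particular the
single-site cutting cost under active Cas9. They therefore define the null
for gene scoring. For gene $g$ with $N_g$ scoring guides of mean
fold-change $m_g$:

$$Z_g = \frac{m_g - m_{\mathrm{AAVS}}}{\sigma_{\mathrm{AAVS}} / \sqrt{N_g}},$$

with $m_{\mathrm{AAVS}}$, $\sigma_{\mathrm{AAVS}}$ the mean and sample
standard deviation (n−1 denominator) of the AAVS1 guide fold-changes.
Scoring guides are exon guides for CRISPRc and primary-TSS guides for
CRISPRi. $P$ is the one-sided lower-tail normal probability — essentiality
manifests as depletion — and genes are called at strict $P < 0.01$ by
default. No multiple-testing adjustment is applied by default; the
threshold is exposed as a parameter.

Two deliberate consequences of this design are worth noting. First,
because every single-locus guide in a diploid region carries the same
one-site cutting cost as the AAVS1 controls, that cost cancels in $Z$ and
only *excess* cutting (amplified targets, multi-locus spacers) produces
signal. Second, $\sigma_{\mathrm{AAVS}}$ is an estimate from a few hundred
guides; its sampling error propagates multiplicatively into $Z$, so the
realized false-positive rate at $P<0.01$ fluctuates around 1% from screen
to screen. This is a property of the control-calibrated Z-test itself, not
of the implementation.

An "effective" guide is one whose fold-change falls below the $q$-quantile
(default 0.05) of the negative-control fold-change distribution. The
definition is control-calibrated rather than threshold-based so it
transfers across screens of different depth and duration.

# The distance-to-TSS efficiency model

CRISPRi efficiency depends strongly on where the guide sits relative to
the TSS. The package models an activation-score label as a non-linear
function of the signed distance $d$ between the 'N' of the NGG PAM and the
TSS (negative upstream, positive downstream, orientation following the
gene strand), using support-vector $\epsilon$-regression with a Gaussian
kernel on the scalar distance. Defaults: tube width $\epsilon = 0.1$;
kernel bandwidth (50, 100, 200 bp) and cost (1, 10) selected by an
internal 5-fold cross-validation grid. Predictions outside the training
domain are clamped to the nearest edge to avoid kernel extrapolation
artifacts, and the fitted model is a deterministic pure function of $d$
that serializes to JSON and reloads to bit-identical predictions.

Training data are refined before fitting: genes must appear in both gene
annotations in use (RefSeq- and FANTOM-style lists supplied by the
caller), contribute at least 7 guides, and show an activation-score
interquartile range strictly greater than 0.5 — i.e. contain both
efficient and inefficient guides, without which a gene contributes no
contrast. Model assessment uses a gene-level split (two thirds of genes to
train, one third to test) so guides of one gene never straddle the split;
the reported metric is the Spearman correlation between predicted and
observed scores computed within each held-out gene (≥ 3 guides,
non-constant scores) and averaged across genes. A within-gene rank metric
was chosen because activation-score scales differ between genes; it is
exactly the quantity a library designer cares about (ranking candidate
guides of one gene).

# Library design rules

For each gene, up to three TSSs are taken from a CAGE-style annotation,
ranked by peak height (rank 1, the highest peak, is the primary TSS; ties
break to the smaller genomic coordinate for determinism). Candidate guides
are every 20-mer immediately 5′ of an NGG on either strand whose PAM 'N'
lies within ±200 bp of the peak center, inclusive. Three independent
exclusion flags follow: perfect-match multiplicity > 1 anywhere in the
genome (both strands; an exhaustive exact string scan stands in for an
aligner at desk scale, and the interface accepts externally computed
multiplicities for real genomes), a TTTT run (Pol III terminator), and GC
fraction ≥ 0.80 (inclusive). Unflagged candidates are ranked by the
efficiency model and the top 7 (multi-TSS design) or top 5 (genome-scale
design) are kept. Exon guides for the cutting arm are NGG-anchored sites
inside coding exons (excluding the first exon), uniformly subsampled with
a recorded seed. Non-targeting controls are random 20-mers verified to
have zero perfect genomic matches.

# Confound analyses

* `target_multiplicity()` counts matching loci under three modes: exact,
  up to one mismatch, and a PAM-proximal 3′ 12-nt exact seed (the region
  dominating Cas9 recognition; length is a parameter).
* `multiplicity_effect()` summarises fold-change per multiplicity bin
  (default 1, 2–5, >5) and modality.
* `amplicon_scan()` scores each gene in a region as the mean fold-change
  of its scoring guides (exon for CRISPRc, primary-TSS for CRISPRi); under
  cutting toxicity an amplicon depresses every gene in CRISPRc but only
  true drivers in CRISPRi.
* `categorize_genes()` partitions genes into both / cas9-only / krab-only /
  neither given the two call sets (call sets may come from this package or
  any external caller), and `fisher_enrichment()` tests a property's
  enrichment in a category with the exact two-sided hypergeometric p
  (sum of all table probabilities not exceeding the observed one). The
  odds ratio is the sample OR with a Haldane 0.5 correction when a cell
  is zero. Amplified genes are those whose primary TSS falls in a
  copy-number segment at or above a threshold (default CN ≥ 4).
* `detect_bidirectional()` reports pairs of genes whose primary TSSs are
  within 1 kb on opposite strands in divergent orientation — each gene
  transcribing away from the other, the configuration that shares a
  promoter. Convergent or tandem arrangements at the same distance are
  not shared promoters and are excluded.
* `proximity_to_essential()` profiles the fraction of called genes by
  distance from the nearest reference-essential TSS; promoter sharing
  shows up as an elevated sub-kilobase bin.

# The synthetic-screen generator

`sim_config()` fixes the study conditions; `make_genome()` lays out random
contigs, annotation and ground truth; `simulate_library()` draws real
NGG-anchored guides from the synthetic genome; `simulate_screen()`
produces replicated early/late counts. The defaults are the conditions
under which the package's claims are tested:

| Parameter | Default | Meaning |
|---|---|---|
| `n_genes` | 300 | genes across three contigs |
| `n_essential` | 30 | fitness cost 0.2 per doubling (LFC −2 over the screen) |
| `guides_per_gene` | 4 | per class (TSS and exon) |
| `n_amplified` / `amplicon_cn` | 20 / 8 | one amplicon contig; 1 essential "driver" inside |
| `n_bidirectional_pairs` | 10 | essential gene + dispensable partner, divergent TSSs 300–900 bp apart |
| `cutting_toxicity_per_site` | 0.03 | per doubling, per cut site beyond the first |
| `doublings` | 10 | proxy for a three-week screen |
| `sequencing_depth` | 500 | mean reads per guide per sample |
| `dispersion` | 0.05 | negative-binomial overdispersion |
| `replicates` | 2 | independent infections |
| `intrinsic_efficiency` | U(0.4, 1) | per-guide multiplier, a proxy for unmodeled sequence features |
| efficiency curve | Gaussian, center +100 bp, width 150 bp | knockdown vs signed TSS distance |

Guide fitness composes as follows. CRISPRc: the on-target knockout effect
(exon guides, scaled by intrinsic efficiency) minus cutting toxicity
proportional to cut sites beyond the first, where cut sites = perfect
genomic matches × local copy number. CRISPRi: the knockdown-weighted gene
effect, where knockdown = intrinsic efficiency × efficiency curve at the
guide's distance to the primary TSS, summed over both members of a coupled
bidirectional pair; no toxicity term. Early counts are multinomial draws
over a lognormal (sdlog 0.5) library representation; abundance then grows
as $2^{\text{fitness} \times \text{doublings}}$ and late counts are
negative-binomial draws around the renormalized late representation.
`rescue_screen()` adds a positive-selection mode in which every cell is
arrested (cost 1 per doubling) unless its guide disables a sentinel gene —
exon or TSS guides under Cas9, TSS guides only under KRAB-dCas9 — which
exercises the outlier robustness of the trimmed-mean factor.

Sizes were chosen so the complete validation suite runs in minutes on one
CPU: 300 genes × 4 guides × 2 classes plus 200 controls at depth 500 gives
stable score distributions while every stage (genome, design, screen,
scoring) stays fast. Where a claim needs a dedicated regime the tests
build one (e.g. a 500-gene all-null screen for calibration; a ±500 bp
tiling window as the NGG-only baseline design, emulating a 50-guide
promoter tile, against the ±200 bp model-ranked design).

**What the simulator does and does not emulate.** It reproduces the
mechanisms under study — depth-limited counting noise, guide-to-guide
efficiency variation, distance-dependent knockdown, copy-number-scaled
cutting toxicity, promoter-sharing co-silencing, positive-selection
outliers — with seeded determinism. It does not model sequence-dependent
activity (beyond a random intrinsic multiplier), chromatin context,
off-target binding with mismatches, infection moi structure, or
genome-scale sequence composition. Passing tests therefore demonstrate
that the statistical machinery recovers truth *when the generating
mechanisms are the modeled ones*; they do not certify performance on real
screens, where guide efficiency and off-target structure are richer.

# Evaluation design

Because each modality's confound is active by design in the default
simulation, a single modality's call set has an honestly inflated false
discovery rate — amplified passengers under CRISPRc, bidirectional
partners under CRISPRi. The headline recovery metric is therefore
computed on the *combined* call set (genes called in both modalities),
which is also the practical recommendation that motivates running paired
screens: the two artifact classes are disjoint, so intersecting the calls
removes both while keeping sensitivity high. Per-modality sensitivities
are reported alongside.

# Numerical choices and degenerate inputs

* Percentiles and quantiles use R's type-7 linear interpolation
  throughout; trimmed-mean bounds are inclusive.
* All coordinates are 0-based half-open internally; BED stays native and
  1-based formats are converted at the file boundary.
* TSS peak ties and candidate score ties break toward the smaller genomic
  coordinate (then the + strand) so every ranking is deterministic.
* All-zero control counts, empty control sets, sub-2 control counts, and
  zero control spread are hard errors — each leaves the downstream
  statistic undefined.
* An SVR fit whose residuals all fall inside the tube has no support
  vectors; it degenerates gracefully to a constant prediction.
* Guides absent from a condition are dropped from fold-changes; genes
  without scoring guides are an error in scoring (listed by name) but
  reported as missing in region scans.
* Every stochastic step takes an explicit seed and restores the caller's
  RNG state; fixed seed implies byte-identical output, including FASTA.

# Known limitations

* The exact-scan multiplicity counter is exhaustive and exact but meant
  for desk-scale genomes; for real genomes, plug in aligner-derived
  multiplicities.
* The Z-test inherits the calibration noise of the estimated control SD
  (see above); with few AAVS1 guides the realized type-I rate can deviate
  noticeably from nominal.
* The efficiency model regresses on distance only; sequence and chromatin
  features are deliberately out of scope.
* Bidirectional detection uses primary TSSs only; a secondary TSS sharing
  a promoter will not be flagged.

# A worked miniature

```{r mini, eval = FALSE}
cfg <- sim_config(n_genes = 60, n_essential = 8, n_amplified = 6,
                  n_bidirectional_pairs = 3)
sim <- make_genome(cfg, seed = 1)
lib <- simulate_library(sim, seed = 2)
nt  <- lib$spacer_id[lib$target_class == "nontargeting"]

lfc_c <- counts_to_lfc(simulate_screen(lib, sim, "cas9", seed = 3), nt)
lfc_k <- counts_to_lfc(simulate_screen(lib, sim, "krab_dcas9", seed = 4), nt)

calls_c <- call_essential(score_genes(lfc_c, lib, "exon"))
calls_k <- call_essential(score_genes(lfc_k, lib, "primary_tss"))

truth <- sim$truth$genes
sensitivity(intersect(calls_c, calls_k), truth$gene[truth$essential])
```
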