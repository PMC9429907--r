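---
title: "Methods: classifying phage sporulation-like sigma factors and measuring their phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying phage sporulation-like sigma factors and measuring their phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporesigma)
```

`sporesigma` implements the computational arc of a question in phage–host
biology: endospore-forming Bacillota control dormancy through a cascade of
sporulation-specific sigma factors (sigF and sigG in the forespore, sigE and
sigK in the mother cell), and some of their phages carry homologs of these
regulators. The package classifies such homologs, tests whether they are
dispensable for lytic growth, and quantifies their effect on host
transcription and spore yield. This vignette explains each model and the
choices behind it.

## Homology classification

Each protein's profile-HMM hits are reduced to one assignment: the family
of the smallest full-sequence E-value. Two umbrella families —
`sigma70-ECF` and `SigBFG` — match nearly any sigma factor, so a best hit to
one of them carries little information; when a more specific hit exists the
best *non-general* hit is used instead and the assignment is flagged
`fallback_used`. Proteins whose only hits are general keep the general
assignment and are never counted as spore-like: a bare umbrella-family match
is not evidence of sporulation function.

Determinism matters for regression testing, so E-value ties are broken by
higher bit score, then lexicographic family id. Multi-domain rows in the
tabular input are collapsed to the best sequence-level E-value per
(protein, family) at load time, since the classification is defined on
sequence-level E-values.

The sporulation-specific family set is configuration, not code: profile
accession schemes vary between databases, so `family_catalog()` takes the
id lists and `default_family_catalog()` ships a sigF/sigE/sigG/sigK-style
default that keeps the rule exercisable out of the box. A genome counts as
spore-like when at least one of its proteins does, even if it also carries
non-spore-like sigma factors — the genome-level flag records capacity, not
composition. Host phyla with fewer than 10 genomes (configurable) are
flagged as below the display threshold but never dropped, so tabulated
counts stay complete.

## Phylogenetic clade calling

The phylogeny route asks whether a phage protein falls inside the bacterial
sporulation clade. Alignment, trimming, model selection and tree inference
are consumed, not performed: the input is a newick tree plus a tip metadata
table (source `phage`/`bacterial`, family labels for references).

Two user-supplied bacterial reference sets delimit the call: the clade is
the tip set of the most recent common ancestor of the sporulation
references, and the tip set of the MRCA of the sigB references is excluded,
because sigB and its general-stress relatives sit inside the larger clade
without being sporulation-associated. Where exactly a published figure drew
these boundaries is a display decision; making the reference tips explicit
inputs keeps the call reproducible. MRCA is defined set-wise on tip
descendants, so multifurcations are handled naturally. If the sigB MRCA is
not nested inside the sporulation clade the exclusion is still applied
set-wise, with a warning — that geometry usually signals misplaced
references.

Rooting changes MRCAs, so unrooted input requires an explicit directive
(outgroup tips or midpoint); silently midpoint-rooting would hide a
consequential assumption. Branch supports are carried but never used in
calls. Maximal phage-only clades (every tip phage-encoded, parent clade not)
partition the phage tips, singletons allowed; both operations are verified
against a brute-force clade enumeration on random trees up to 64 tips.

## Virulence index

The index summarizes an MOI dilution series into one number. Per well, OD600
is integrated by the trapezoid rule over `[0, t_end]` with linear
interpolation at the boundary; `t_end` defaults to 6 h, the time at which
the uninfected cultures in the assay this default mirrors left exponential
growth, and is configurable because that time is a property of the host and
medium. Local virulence `v = 1 − A_inf/A_ctrl` is clamped to `[0, 1]`: an
infected culture that outgrows its control is noise around "no virulence",
and clamping keeps the index a fraction of the theoretical maximum. No blank
subtraction is applied by default (the index is a ratio of areas, so a
shared baseline largely cancels); raw OD input is expected.

Replicates are averaged on the local-virulence scale before integrating over
log10(MOI), and per-replicate Vp values are emitted alongside — the Welch
comparison between strains uses the per-replicate values, which preserves
biological variance. Controls are matched to replicates by id when present,
falling back to the mean control area. Vp is invariant to uniform rescaling
of all ODs and monotone when any infected well's OD is pointwise decreased;
both properties are tested.

## Flow-cytometry spore gating

The gating chain mirrors standard automated cytometry practice for
separating spores (SYBR-green-dim: the dye cannot penetrate the spore)
from vegetative cells (bright):

1. **asinh transform**, cofactor 1 by default. The cofactor is the
   channel-scale divisor; 1 is appropriate for the generator's intensity
   scale and is configurable per dataset (typical instrument scales want
   100–150).
2. **Singlet gate.** Doublets carry roughly doubled area at unchanged
   height. A Theil–Sen line of transformed FSC-H on FSC-A is fitted (median
   pairwise slope over an evenly spaced subsample of up to 400 points, which
   keeps the fit deterministic and O(10^5) slope evaluations); events within
   k = 2.5 median-absolute-deviation scales of the line are kept. For
   Gaussian residual noise this band retains about 98.8% of true singlets —
   a retention ceiling worth remembering when comparing gated counts.
3. **Noise gate.** Sub-cellular debris forms a low-scatter mode. A kernel
   density estimate (Silverman bandwidth) of transformed FSC-A is scanned
   for local minima below the global mode and the threshold sits at the
   deepest one; if the density is unimodal the gate falls back to dropping
   the lowest 0.5% (configurable, or disabled with a warning). The deepest-
   minimum rule assumes noise is the only distinct low-scatter mode —
   spore/vegetative separation must be carried by fluorescence, which is the
   biology of the stain.
4. **Mixture model.** A two-component full-covariance bivariate Gaussian
   mixture on transformed (FSC-A, FL-A) is fitted by EM on the gated
   non-induced control of each strain × run, with 5 seeded k-means restarts
   (best log-likelihood kept, covariances ridged by 1e-8, convergence at
   relative log-likelihood change < 1e-8). Components are labelled by mean
   fluorescence — lower is the spore population — which makes the labelling
   invariant to initialization order. The trained model then classifies
   every sample of that strain and run by maximum posterior; applying a
   model across strains or runs requires an explicit override.

Training on controls only, per strain and run, isolates the classifier from
induction effects and batch drift; at least 1000 gated training events are
required by default (configurable), 500 per sample for gating. Spore yield
is the ratio of percent spores, induced over paired control, pairs given by
explicit ids; clone-level aggregation is the mean of per-pair yields.
Strain-versus-empty-vector comparisons use Welch tests with Holm adjustment
by default — conservative, since the family of strains is small — with BH
and BY selectable. Paired total-density differences use the one-sample t
test on differences.

## Expression post-processing

The pipeline consumes per-gene tables (log2 fold change, adjusted p) from an
upstream differential-expression model; it does not refit them. DEG status
uses adjusted p < 0.05 (the upstream correction is what makes the threshold
meaningful; a flag allows raw-p thresholding for comparability) and
|log2FC| > 1 with the boundary excluded, i.e. fold change strictly above 2.
Enrichment of sporulation-annotated genes in the up-regulated set — the
direction induction of a sporulation sigma factor should move its regulon —
uses the exact hypergeometric upper tail, with the universe equal to the
genes present in that strain's table, so detection differences between
strains do not distort the test. Cross-strain p values are Holm-adjusted by
default. Profile similarity between strains is Spearman's ρ of log2 fold
changes over shared genes (average ranks for ties); Spearman p values use
the t approximation, switching to exact enumeration of all n! permutations
when n ≤ 8.

## Percent identity on profile alignments

Sequence identity between cloned sigma factors is computed on a profile
alignment (hmmalign-style). Identity is `100 × identical columns /
min(residues_a, residues_b)` — the min-length denominator of the esl-alipid
convention — and, when trimming is requested, columns strictly before the
first and strictly after the last profile reference position are removed
first, dropping unaligned N/C-terminal tails. The reference mask is read
from a companion `x`/`.` FASTA record or inferred from A2M case convention.
Reproducing published identity values for specific proteins requires the
corresponding profile and sequences, which must be supplied by the user; the
implementation is verified on constructed alignments with hand-enumerated
column counts.

## Synthetic generators and what passing tests mean

Each generator plants known structure and returns a truth sidecar:

- `gen_hmm_hits`: planted family per protein, E-values log-uniform in
  [1e-40, 1e-10], decoys at ≥ 10× the planted E-value, optional winning
  general hits to force the fallback path.
- `gen_tree`: a rooted tree whose sporulation clade is exactly the span of
  the reference tips (the first two references are placed on opposite sides
  of the clade root), with a nested sigB subclade and planted phage tips
  inside, outside, and optionally inside the sigB subclade.
- `gen_growth_curves`: logistic controls (r = 0.8/h, K = 1.0 OD,
  inoculum 0.05 OD) on a 0–16 h grid at 0.25 h steps; infected wells decay
  exponentially at rate θ after an onset that advances with log10(MOI);
  Gaussian noise, floored at zero. Lysis is phenomenological by design —
  the index consumes areas, so any monotone family suffices for recovery
  tests.
- `gen_flow_events`: Gaussian clusters on the transformed scale (spores
  (3.6, 2.5), vegetative (4.0, 7.5), SD 0.35), mapped to raw intensities by
  sinh; singlets on a proportional FSC-H line, doublets at doubled area,
  noise at low scatter. The modest scatter separation keeps the FSC-A
  marginal unimodal, matching the noise gate's assumption.
- `gen_de_table`: per-gene class draws (up with probability 0.6 for
  sporulation genes vs 0.05 background in the planted-signal configuration,
  N = 4000, K = 500), fold changes and p values consistent with the class.

Because the flow clusters are Gaussian on the transformed scale, the mixture
model is correctly specified by construction; passing recovery tests
demonstrates the estimation machinery, not robustness to skewed or
autofluorescent real-world populations. Likewise the growth generator has no
resistant-subpopulation regrowth, and the DE generator draws genes
independently — regulon correlation structure is absent. Results on real
data inherit none of these guarantees; the gates and tests are the part that
transfers.

Problem sizes used by the test-suite checks were chosen to make planted
effects statistically unambiguous at desk scale: 1000 proteins for
classification recovery, 200 random trees (≤ 64 tips) against brute-force
clade enumeration, 20,000 events per flow sample with 5% doublets and 5%
noise (recovery within ±0.02 of planted fractions {0.05, 0.30, 0.70}; ±0.05
on a planted 0.5 yield), 100 random samples against closed-form t-test
oracles at 1e-10, exhaustive hypergeometric enumeration for all universes up
to N = 12 at 1e-12, and 200 null tables for type-I calibration at α = 0.05
within binomial 99% bounds.

## Known limitations

- The classifier trusts the hit table; it cannot detect profile-database
  contamination (e.g. phage-derived seeds in a bacterial profile).
- Clade calls depend on the user's reference tips and rooting; the package
  deliberately refuses to guess either.
- The noise gate can mis-place its threshold if a genuine cell population
  sits at very low scatter; the quantile fallback bounds the damage.
- The mixture is fixed at two components; samples with an intermediate
  (e.g. germinating) population violate the model and will fold that
  population into the nearer component.
- Spearman p values for 8 < n < 30 rely on the t approximation, which is
  mildly anticonservative in the extreme tails.
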