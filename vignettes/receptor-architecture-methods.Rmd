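---
title: "Methods: receptor architecture, motifs, and expansion statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: receptor architecture, motifs, and expansion statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrrscape)
```

# Model and scope

`lrrscape` analyses plant cell-surface receptors with leucine-rich-repeat
(LRR) ectodomains. Three structural classes are distinguished:

* **RLK** (receptor-like kinase): one or two transmembrane (TM) segments
  plus a cytoplasmic kinase domain;
* **RLP** (receptor-like protein): one or two TM segments, no kinase
  domain;
* **ectodomain-only**: LRR motifs but neither TM nor kinase domain.

Proteins with more than two TM segments, shorter than 150 residues, or — for
LRR-bearing kinase + TM candidates — shorter than 250 residues are filtered
to class `OTHER`, with the reason recorded. All coordinates in the package
are 1-based and inclusive.

# Rule-based detectors

The detectors are deterministic stand-ins for the external predictors a
full-scale survey would use (dedicated TM/signal-peptide predictors,
profile-HMM kinase models, plant-LRR motif models). They are simple by
design: their job in this package is to provide a fully reproducible,
self-contained annotation path whose behaviour is exactly testable.
Precomputed annotations can replace them via
`load_external_annotations()` and are treated identically downstream.

* **TM** (`detect_tm`): a sliding window (default 19 residues) of mean
  Kyte–Doolittle hydropathy; windows reaching the threshold (default 1.6)
  are merged, merged runs shorter than 15 residues are dropped, and runs
  longer than 35 residues are trimmed to their maximal-scoring 21-mer.
* **Signal peptide** (`detect_signal_peptide`): a maximal run of
  positive-hydropathy residues of length 7–15, mean at least 2.0, starting
  within the first 10 residues; the detected interval is masked before TM
  detection so the hydrophobic h-region is never mistaken for a TM.
* **Kinase** (`detect_kinase`): the ordered catalytic landmarks
  G-x-G-x-x-G, a lysine within 30 residues, HRD, then DFG, spanning
  150–350 residues; the most compact qualifying span wins, and the call
  runs from the glycine-rich loop to 30 residues past DFG.
* **LRR** (`detect_lrr`): greedy non-overlapping matches of the plant LRR
  core (hydrophobic L/I/V/F/M at positions 1, 4, 6, 8, 13 and N/T/S/C at
  11), each reported as a 24-residue motif clipped at the sequence end.

For RLK/RLP proteins the TM-free stretches are the candidate ecto- and
endodomains: the ectodomain is the stretch with the most LRR motifs (for
RLKs, the stretch opposite the kinase domain), the endodomain the
kinase-bearing or longest remaining stretch. Ties between stretches are
broken toward the N terminus and flagged via a `tie` attribute — with
two TMs and LRRs on both sides the choice is genuinely ambiguous, and
callers can inspect the flag rather than silently trusting the tie-break.

# LRR architecture

Within the ectodomain, LRR motifs closer than 13 residues fall into one
*LRR region* (`group_regions`; the bound is strict). Every stretch between
consecutive regions is a *gap* (`call_gaps`):

| length (aa) | class |
|---|---|
| 1–14 | NONE |
| 15–29 | NL (N-loopout) |
| 30–90 | ID (island domain) |
| 91+ | NONE |

Gaps containing a residual LRR match are dropped by `screen_gap` as
detector artefacts. For each gap, `n1` counts motifs N-terminal and `n2`
motifs C-terminal of it; the **ID+4LRR** flag is set when a surviving
island domain is followed by exactly four motifs (`id4_n2`, with an
at-most variant via `id4_le`). Stretches before the first and after the
last motif are not gap candidates by default
(`include_terminal_gaps = FALSE`): the length windows describe insertions
*between* repeats, and terminal stretches are dominated by the signal
peptide and juxtamembrane instead.

When at least four ectodomain motifs and a TM C-terminal of them exist,
`extract_regions` splits the membrane-proximal part: **C3** spans the last
four LRR motifs, **eJM** the stretch between C3 and the TM, and **cJM**
runs from the TM to the residue before the kinase domain for RLKs
(`cjm_mode = "to_kd"`; `"to_cterm"` extends it to the C terminus) or to
the C terminus for RLPs.

# Motif scanners

All scanners report every match, including overlapping ones; downstream
summaries count presence, not multiplicity.

* Island domains: **Kx5Y** (`K.{5}Y`) and **Yx8KG** (`Y.{8}KG`).
* Terminal LRR motif of the C3: **QxxT/S** (`Q..[TS]`), with the residue
  preceding each glutamine reported, plus a `TQ` flag for the TQxxx
  variants that lack the canonical loop.
* TM helix: **GxxxG**, with chains counted when consecutive matches share
  their terminal glycine (starts four residues apart).
* eJM: net and terminal charge as (#K + #R) − (#D + #E), histidine
  neutral; the terminal window (default 10 residues) is the stretch
  abutting the membrane.

# Expansion statistics

Family size is expressed as a percentage of the searched gene set. The
expansion rate of a species against a baseline lineage is

$$\mathrm{rate} = \frac{\mathrm{pct} - \mathrm{median}_{\mathrm{baseline}}}{\mathrm{median}_{\mathrm{baseline}}},$$

using the median for robustness to outlier genomes; a zero baseline median
yields `NA` rather than a division blow-up. Family co-expansion is Pearson
correlation over pairwise-complete genomes, classed *strong* above
r = 0.6 and *medium* in [0.3, 0.6]. `mantel_test` correlates the strict
upper triangles of two distance matrices and permutes the rows and columns
of the second simultaneously; the one-sided p-value is
(1 + #{r_perm ≥ r_obs}) / (1 + n_perm), with 10,000 permutations by
default, and is deterministic given a seed. Multiple Mantel tests are
corrected by Benjamini–Hochberg FDR, and 2×2 enrichments use the two-sided
Fisher exact test (hypergeometric summation; the reported odds ratio is
the sample ratio ad/bc, infinite when bc = 0).

# Island-domain clustering

A sequence-similarity tree is converted to cophenetic (patristic)
distances; leaf pairs strictly below the cutoff (default 0.2
substitutions/site) become weighted edges. The default weight is
1 − d/cutoff ("relative"), which maps the usable range onto (0, 1]
regardless of cutoff; 1 − d ("linear") is available. Communities are found
by weighted Louvain modularity maximization on a seeded shuffle of the
vertex order, making the greedy pass reproducible; isolated leaves remain
singleton clusters. `composition_summary` tallies clusters by the distinct
family/subgroup labels of their leaves.

# Synthetic data and its limits

The generator assembles receptors from building blocks whose alphabets are
restricted so that fillers can never create spurious LRR cores, TM
windows, kinase landmarks, or diagnostic motifs; the planted architecture
is therefore recovered exactly, and the recorded ground truth is reliable
by construction rather than by convention. Two details are worth noting:

* **TM truth is detection-realized.** A hydropathy window slides a few
  residues off a hydrophobic helix into its flanks, so planted TM
  boundaries cannot coincide with detected ones. Each TM is wrapped in
  six neutral asparagine pads, and the truth records the span the detector
  actually yields, asserted at generation time to stay inside the pads.
* **Lineage panels round losslessly.** Per-species deviation factors are
  half-integer multiples of baselines whose gene counts are multiples of
  10 at 20,000 searched genes, so realized percentages equal planted ones
  exactly and truth expansion rates follow by exact arithmetic.

The generator emulates annotation-level structure, not biology: sequences
are not evolutionarily plausible, background proteins are
composition-matched but unstructured, and planted trees encode distances,
not alignments. Panel sizes (30 species, 3 families) and cohort sizes
(300 receptors) are this package's own validation choices, selected to
cover the parameter space at desk scale.

# Numerical decisions

Kyte–Doolittle values are 0.1-granular, so achievable window means are
spaced roughly 0.005 apart; detectors compare means against thresholds
with a 1e−9 slack, which makes the ≥ decision exact regardless of
floating-point summation order. Score ties when trimming long hydrophobic
runs to a 21-mer are resolved leftmost. All stochastic steps (Mantel
permutations, Louvain vertex shuffle, every generator) take explicit
integer seeds, and the pipeline writes an md5 manifest of its outputs so
end-to-end determinism is checkable byte for byte.
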