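---
title: "Methods: multiplexed GPS/CRISPR screen analysis with multigps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplexed GPS/CRISPR screen analysis with multigps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multigps)
library(dplyr)
```

## The measurement model

A Global Protein Stability (GPS) reporter expresses a GFP–substrate fusion
and a DsRed internal control from one transcript, so the log(GFP/DsRed)
ratio of a cell reads out the degradation rate of the fused substrate. In
the multiplexed format every cell also carries one CRISPR sgRNA, so a cell
is a draw from a (substrate, guide) combination: if the guide has disrupted
the E3 ubiquitin ligase that degrades the substrate, the reporter ratio
shifts up.

Two sorting designs are supported.

* **Six-bin**: the whole population is partitioned by FACS into six equal
  bins of the reporter ratio. After sequencing each bin, the stability of an
  entity (a substrate, a substrate–guide pair, a barcode or an ORF) is
  summarised by the protein stability index
  $$\mathrm{PSI} = \sum_{b=1}^{6} p_b \, b,$$
  where $p_b$ is the entity's depth-normalised proportion of reads in bin
  $b$. PSI ranges from 1 (all reads in the least-stable bin) to 6 (all reads
  in the most-stable bin). Stability changes between conditions are
  expressed as $\Delta\mathrm{PSI}$ (treatment minus control; positive =
  stabilised).
* **One-bin**: only the top ~5% of cells is sorted, and sequenced against
  the unsorted library. Per-guide enrichment replaces PSI as the signal.

Depth normalisation (`normalize_depth()`) rescales each sequenced
population so all bin totals equal the mean bin total; PSI is then invariant
to the sequencing depth of any individual bin. This assumes bin identity is
the only systematic difference between the libraries — PCR efficiency
differences between bins are not modelled.

## Gene-level hit calling

**Six-bin mode** (`call_hits_6bin()`): for one substrate, every E3 gene is
tested by a Mann–Whitney $U$ comparison of the substrate's PSI values when
paired with that gene's guides against its PSI values with all other guides.
The test is one-sided towards stabilisation, because knockout of the cognate
E3 can only stabilise the substrate in this design; the screens' selection
direction makes a two-sided test needlessly conservative. p-values are
Benjamini–Hochberg adjusted across genes *within* each substrate — each
substrate is its own screen, and cross-substrate adjustment would couple
unrelated screens. Genes with fewer than two informative guides are skipped
and logged rather than tested.

`mann_whitney()` uses the exact null distribution of $U$ when
$|x| \le 8$, $|x| + |y| \le 25$ and there are no ties, and otherwise a
normal approximation with continuity correction and tie-corrected variance
(midranks for ties). The switch is deliberately explicit so that tests can
verify both branches: the exact branch against full enumeration, and the
approximate branch against the exact one (agreement within 0.02 on tie-free
samples).

**One-bin mode** (`call_hits_1bin()`): each guide is scored by
$\log_2$ enrichment of its pseudocount-protected library proportion in the
sorted versus reference populations, and a gene's statistic is the mean rank
of its guides among all guides. The null is label permutation: exhaustive
enumeration of guide subsets when $\binom{N}{k} \le 50{,}000$, otherwise
seeded Monte-Carlo with add-one correction. This procedure fills the role
that MAGeCK plays in conventional one-bin analyses with a fully specified,
exactly testable statistic; it is *not* a reimplementation of MAGeCK's
α-RRA and will not reproduce MAGeCK score values.

## The synthetic-data generator

`simulate_screen()` is mechanistic on purpose: it never draws "a PSI".
Cells receive latent log-reporter ratios
$x \sim \mathcal{N}(\mu_s + e\,\delta_{sg},\ \sigma^2)$, where $\mu_s$ is
the substrate baseline, $\delta_{sg}$ the planted stabilisation for cognate
(substrate, gene) pairs, and $e \sim \mathrm{Bernoulli}(\text{efficacy})$
models partial-penetrance knockouts (in-frame repair, residual protein).
Gates are set from pooled population quantiles — sextiles for six-bin, the
$1-\text{gate fraction}$ quantile for one-bin — and sequencing is a
multinomial draw of fixed depth per sorted population. PSI therefore
*emerges* from binning and sampling, so the estimator is tested against the
generative process rather than against itself.

Default parameters, and why:

| parameter | default | rationale |
|---|---|---|
| `guides_per_gene` | 6 | peptide-library sgRNA density; adaptor panels used 4 |
| `cell_noise_sd` | 0.3 | latent units; spreads one combination across 2–3 adjacent bins, matching the spread of single-substrate profiles |
| `knockout_efficacy` | 0.8 | typical fraction of loss-of-function outcomes per guide |
| `cells_per_combo` | 100 | the ~100-fold library representation the screens maintained |
| `gate_fraction` | 0.05 | the top ~5% gate of one-bin sorts |
| `filler_fraction` | 0 (0.3 when broadening) | stable filler spiked at ~30% before six-bin sorts of narrow libraries |
| baselines | $\mathrm{U}(1.5, 4.5)$ | a GPS substrate library consists of actively degraded proteins, so baselines span the unstable-to-intermediate range; substrates already at the stability ceiling could not report stabilisation, which is a property of the assay, not of the analysis. Stable filler — not the library itself — is what broadens the top of the sorted distribution |

The latent axis is scaled so that, with these defaults, adjacent sextile
gates sit roughly one unit apart; planted effects stated in PSI units
translate approximately one-to-one into latent shifts. One global integer
seed drives every stage through deterministically derived substreams, so a
configuration and seed reproduce a screen bit-identically regardless of
which other stages run.

What the generator deliberately does **not** model: PCR jackpotting and
duplicates (sequencing is a clean multinomial), UMI structure, cloning
bottlenecks, flow-cytometry spectral spillover, guide off-target effects
and fitness costs of knockouts. Passing recovery tests on these simulations
therefore demonstrates that the statistical pipeline is correct and
calibrated under the declared noise model — not that real screens are free
of these additional artefacts.

## Read simulation and deconvolution

Amplicon read pairs carry the substrate on the forward mate and the
protospacer on the reverse mate. The forward read begins with a cycling
0–7 nt stagger pad (the pooled-primer trick that keeps base diversity on
the sequencer), then a constant anchor, then the insert.
`build_count_table()` trims by scanning the stagger window for the anchor
(tolerating one mismatch), then matches the insert's reference-length
prefix exactly, falling back to a unique-best Hamming match within
tolerance 1. Ties are *ambiguous*, never resolved — Cul3 adaptor paralogues
such as KLHL9/KLHL13 share >90% identity, and resolving ties would silently
cross-contaminate their counts. `N` bases count as mismatches. A pair
increments the count matrix only when both mates assign uniquely; all other
outcomes are tallied in QC categories that must sum to the total
(`assigned + fwd_unassigned + rev_unassigned + ambiguous + filler = total`).
Stable-filler reads are recognised by reserved substrate ids and excluded
from the matrix. Indels and quality-aware matching are out of scope: the
inserts are short, fixed-length and designed to be distinguishable, which
is also why a full aligner is unnecessary here.

## Saturation-mutagenesis mapping

`build_satmut_matrix()` centres every variant on the median PSI of the
unmutated (wild-type replicate) constructs — the median, not the mean,
because a single aberrant wild-type clone (synthesis error, barcode
collision) should not shift the whole matrix. Cells where the "mutation"
equals the wild-type residue are flagged non-informative and excluded from
position summaries; the heat map draws them as dots. Positions are indexed
1-based from the N-terminus and additionally reported as negative offsets
from the C-terminus (−1 = last residue), the frame in which terminal
degrons are discussed. A position is called degron-critical when the median
$\Delta\mathrm{PSI}$ across its informative substitutions is ≥ τ (default
0.5, matching the 0.5-unit stabilisation convention used for substrate
selection; the median-over-substitutions captures "any mutation away from
the wild-type residue stabilises"). The 20 single C-terminal additions
("Add") are summarised the same way into an addition-sensitivity flag — the
hallmark of a C-degron, whose recognition requires the degron residue at
the extreme terminus. The residue axis always uses the fixed alphabetical
one-letter order (`aa_order()`) so exported matrices are byte-stable.

`generate_tiles()` emits 24-mer tiles at 6-residue steps plus a tile
anchored at the native C-terminus. Interior tiles get the inert appendage
`RIARAKASTN` so that tiling itself cannot create artificial C-terminal
degrons; the C-terminal tile retains the native terminus unappended.

## Barcode→ORF assignment

Barcoded ORF libraries average between four and five random 22-nt barcodes
per ORF. `assign_barcodes()` assigns each barcode to the plurality ORF of
its link reads, requiring ≥3 reads and ≥0.8 purity; ties and failures are
left unassigned with a recorded reason. The thresholds tolerate the
few-percent template switching seen in pooled amplifications while
rejecting genuinely ambiguous barcodes, whose downstream PSI would blend
two ORFs. Per-ORF stability is the median of barcode PSIs with the MAD as
dispersion — barcodes are internal replicates, and the median is robust to
one bad barcode.

## Interaction-overlap permutation test

`permutation_overlap_test()` asks whether called (gene, substrate) pairs
coincide with a physical-interaction edge list more often than random
screens. The default null redraws each hit's gene uniformly from the gene
universe (the sgRNA library's gene set — the genes a screen could possibly
have called) while keeping substrates fixed; a column-shuffle null that
preserves the hit-gene multiset is available behind `scheme = "shuffle"`.
The empirical p-value is $(1 + \#\{\text{null} \ge \text{obs}\})/(n_{\mathrm{perm}}+1)$,
add-one corrected so it can never be zero; 10,000 permutations is the
default. No interaction database ships with the package — edge lists are
user-supplied TSV, and `generate_interaction_edges()` builds synthetic
stand-ins with planted truth for testing.

## Numerical and policy choices

* `min_reads = 30` raw reads per entity per condition for a reported PSI: a
  variance-control filter; profiles below it are dominated by multinomial
  noise.
* Strict inequality for "stabilised > 0.5 PSI units" selection.
* Equal bin weights 1..6: bins are sorted to equal cell counts, so no
  bin-size reweighting is offered.
* Pseudocount 0.5 in one-bin enrichment scores prevents infinite log-ratios
  for guides absent from one population.
* All degenerate inputs fail loudly before work starts (all-empty bins,
  all-missing PSI, empty gene universe); per-read failures are QC states,
  not errors.
* Pipeline manifests record parameters, seed and md5 of every output;
  reruns of an identical configuration are byte-identical.

## Problem sizes used by the test suite

The packaged tests simulate at desk scale by choice: calibration uses
1,000 null gene-tests (four 5-substrate × 50-gene screens), type-I control
uses 10,000 direct null gene-tests, and recovery uses ten replicate screens
of 100 substrates × 96 genes × 6 guides with ten planted pairs at 1.5 PSI
units and 80% efficacy — about 5.8 million simulated cells per screen.
These sizes match the screens' structure while keeping a full run in
minutes.

## Known limitations

* The one-bin statistic is a documented substitute for MAGeCK's α-RRA; its
  p-values fill the same role but are not comparable to published MAGeCK
  scores.
* Gene-level error control is FDR within substrate (BH at q ≤ 0.05). Across
  ~100 substrates a handful of null substrates will carry one nominally
  significant gene each; screens wanting family-wise control across an
  entire multiplex experiment should tighten q or adjust across substrates.
* Isoform-sharing barcodes (one barcode compatible with several isoforms of
  a gene) are not disambiguated beyond the supplied barcode→ORF map.
* PSI compresses at its boundaries: a substrate already in bin 6 cannot
  report further stabilisation, and strongly stabilised entities saturate
  below the theoretical effect size.
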