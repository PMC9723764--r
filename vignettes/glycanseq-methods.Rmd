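---
title: "Methods: barcode counting and compositional analysis for lectin-based glycan profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode counting and compositional analysis for lectin-based glycan profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The assay and its computational readout

Glycan-seq profiles cell-surface glycans without fluorescence labeling:
a panel of lectins (glycan-binding proteins), each conjugated to a
unique DNA barcode through a photocleavable linker, is incubated with
cells; bound barcodes are UV-released, amplified and sequenced. The
number of reads carrying a lectin's barcode is the measure of that
lectin's binding, so the entire scientific readout is a
barcode-counting and compositional-analysis problem. This package
implements that readout: mismatch-tolerant barcode counting from
FASTQ, normalization to percentage profiles, hierarchical clustering
of samples, and a compositional differential test between two groups
of samples (e.g. gut-microbiota preparations from preweaned pups
versus adult mice), plus a simulator that generates sequencing reads
with known ground truth so every stage can be validated.

## Barcode matching

Reads are short (the assay sequences 26 bp) and structured as an
uninformative prefix followed by the lectin barcode. Matching drops
the first `prefix_trim` bases (default 3) and compares the next
`barcode_length` bases against every panel barcode by position,
counting mismatches separately in the *flanking* regions (the ends of
the barcode) and the *middle* region. A barcode is a candidate when
its flank mismatches are at most `max_flank_mismatches` (default 2,
summed over both flanks) and its middle mismatches at most
`max_middle_mismatches` (default 1). A read is

* **assigned** to the unique candidate with the smallest total
  mismatch count,
* **ambiguous** when two candidates tie on that total (ambiguous
  reads are tallied but never counted),
* **unassigned** when no candidate exists, and
* **too_short** when the trimmed read cannot cover the barcode.

`N` counts as a mismatch wherever it occurs, so low-quality reads fall
out through the budgets; there is no quality-aware or indel-tolerant
matching (the rule is positional by construction).

Three choices here were genuinely open and are worth stating:

* **Region coordinates.** The region boundaries of the barcode are a
  property of the panel, not of this method; the default layout is a
  22-base barcode with flanks `[0,7)` and `[15,22)` and middle
  `[7,15)`, which fits the 26 bp read length after the 3-base prefix.
  Every coordinate is configurable in the panel file's `#layout:`
  header.
* **Flank budget scope.** "Two mismatches in the flanking region" is
  implemented as a total over both flank spans, the stricter of the
  two possible readings; the budget is configurable.
* **Tie resolution.** Reads matching several barcodes within budget
  are resolved to the minimal-total-mismatch candidate and dropped as
  ambiguous on ties. This is deterministic and conservative, and on a
  well-separated panel (see below) multi-candidate reads are rare;
  the ambiguous tally is always reported.

`validate_separability()` checks the panel against the tolerance
exactly: for per-region Hamming budgets, some read lies within
tolerance of two barcodes if and only if, in every region, the
inter-barcode mismatch count is at most twice that region's allowance
(the differing positions can be split between the two barcodes). The
default generator enforces pairwise Hamming distance of at least 7,
which makes collisions impossible under the default budgets
(2 + 1 allow at most 2×2 + 2×1 = 6 shared differences).

The matcher's hot loop is compiled (Rcpp); the test suite holds it
against an independent pure-R brute-force scanner on tens of
thousands of randomized reads.

## Normalization and profiles

Each lectin's count is divided by the sample's total number of
*assigned* lectin barcodes and expressed as a percentage, so profile
rows sum to 100. Ambiguous, unassigned and too-short reads are
excluded from the denominator. Normalization is scale-invariant:
multiplying a sample's counts by any positive factor leaves its
profile unchanged. A sample with zero assigned reads has no defined
profile and raises an error naming the sample.

A lectin is flagged *positive* within a group when its group-mean
percentage strictly exceeds a threshold (default 15) — the screening
rule used to choose lectins for orthogonal validation such as flow
cytometry.

## Hierarchical clustering

Samples are clustered on their percentage rows with Euclidean
distance and average linkage by default. Neither the metric nor the
linkage is dictated by the assay; these defaults are the common
choice for lectin-profile heatmaps, and the question the dendrogram
answers — do the two conditions separate into two clusters? — is
robust to them. Both are configurable, and a `log10_offset` option
clusters on `log10(percent + offset)` for profiles spanning decades.
The dendrogram is emitted as Newick text plus a leaf-ordered matrix
for heatmaps; clustering on raw percentages is the default because
the strongest signals dominate group separation, which is what the
two-cluster question asks.

## Differential analysis

Percentages are compositional: an increase in one lectin forces
decreases elsewhere, so per-lectin tests on raw percentages confound
real effects with renormalization. Following the ANCOM approach, the
test works on log-ratios. For lectin $i$ with partner $j$ and
pseudocount $c$:

$$ r_{ij}^{(s)} = \log\frac{x_i^{(s)} + c}{x_j^{(s)} + c} $$

is computed per sample $s$, and each partner's ratios are compared
between the two groups with a two-sided Welch $t$-test. Within each
lectin's family of $m - 1$ partner tests the p-values are
Holm-Bonferroni adjusted, and

$$ W_i = \#\{j : \tilde p_{ij} < \alpha\} $$

counts the adjusted rejections. A lectin is called significant when
both $W_i \ge \lceil 0.7\,(m-1) \rceil$ (the usual ANCOM practice of
requiring a large fraction of partners to reject) and its smallest
adjusted partner p-value (`summary_p`) is below $\alpha = 0.05$.

Choices that the method's description leaves open, and how this
package resolves them:

* **Per-pair test.** Welch's $t$ on log-ratios is the default. With
  $n = 3$ per group — the replication of the mouse experiment — an
  exact Mann-Whitney test cannot go below $p = 0.1$ two-sided, so a
  rank test can never reach significance at this design; it is
  offered as an option (`test = "mann-whitney"`) for larger designs.
* **Pseudocount.** Default `0.001`, the percentage contributed by a
  single read at a per-sample depth of $10^5$. A pseudocount must be
  negligible relative to any observable nonzero percentage: when a
  strong effect rescales the remainder of the composition (three
  lectins at five-fold jointly shift every other percentage by a
  factor of about two), a pseudocount comparable to the small
  percentages shifts null log-ratios *systematically* between groups,
  and with three replicates of tight multinomial noise those shifts
  masquerade as significance. We observed exactly this failure mode
  with a 0.5 pseudocount on the percentage scale before settling on
  the present default.
* **Holm scope.** The correction is applied within each lectin's
  partner-test family — the natural reading of ANCOM's per-feature
  W construction — not across the whole $m(m-1)$ matrix.
* **Degenerate inputs.** When a partner log-ratio has zero variance
  in both groups, the pair contributes $p = 1$ if the group means
  agree (no evidence) and $p = 0$ if they differ (two separated
  constants); the pseudocount makes non-finite ratios impossible.
* **Tie-breaks in reports.** The report is sorted by significance,
  then $W$ descending, then `summary_p` ascending, then lectin name.

The Welch statistics for all pairs are computed at once from the
per-group covariance matrices of the log-transformed profiles
(${\rm var}(L_i - L_j) = S_{ii} + S_{jj} - 2S_{ij}$), which makes
null calibration with hundreds of Monte-Carlo replicates cheap; the
suite verifies this path against `stats::t.test` pair by pair, and
the in-package Holm step-down against `stats::p.adjust`.

## The simulator: what it emulates, and what it does not

`generate_panel()` stands in for the real panel's barcode table
(which is not public): random barcodes at pairwise Hamming distance
of at least 7, with the panel's well-characterized lectin names
(rABA, rSRL, rPVL, rGRFT, rBanana, SSA, TJAI, SNA, then generic
`LECnn`) so planted effects can be described in the field's terms.

`group_design()` encodes the two-group study (defaults: `pups` and
`adult`, $n = 3$ each). The baseline composition is a geometric decay
(ratio 0.85 over 39 lectins: largest share about 15%, smallest about
0.03%), i.e. a few dominant signals plus a long tail of minor ones —
the typical shape of a lectin profile. Effects are fold-changes on
named lectins in one group followed by renormalization; the default
scenario elevates the three α2-6-sialic-acid binders (SSA, TJAI,
SNA) five-fold in pups, mirroring the qualitative difference between
preweaned and adult gut microbiota.

`simulate_reads()` draws per-sample lectin counts multinomially over
$(1-f)\cdot\mathrm{depth}$ reads (contaminant fraction $f$, default
0.01, emits fully random sequences), adds a 3-base uniform-random
prefix, applies i.i.d. substitution errors (default 0.005 per base),
shuffles, and writes plain FASTQ with constant Phred+33 quality plus
a per-read truth table aligned record-for-record. An optional
Dirichlet overdispersion adds between-replicate compositional
variability for power studies (off by default, matching the stated
multinomial noise model).

What the simulator does **not** model: PCR amplification bias, UV
release efficiency, indels, quality-score structure, real
nonspecific-binding backgrounds, and the mate of the paired-end read
(the matching rule uses only the barcode-bearing read; a filler mate
2 can be written for interface compatibility). Consequently, passing
tests demonstrate the correctness of the *computational* pipeline
under its stated noise model — substitution errors, contaminants,
multinomial counting noise — not robustness to every artifact of real
sequencing data.

## Validation scales and numerical choices

The test suite validates at the study's own design where the property
demands it: 39 lectins, two groups of 3, $10^5$ reads per sample.
Matcher-oracle agreement uses 10,000 randomized reads over five
random panels; zero-noise identity checks that counting reproduces
the simulator's truth table exactly over six samples at depth $10^5$;
type-I error is measured over 500 Monte-Carlo null replicates
(per-lectin false-call rate bounded by $\alpha$ plus three Monte-Carlo
standard errors); planted-effect recovery requires exactly the three
boosted lectins across 20 seeded replicates; and cluster separation
requires the k = 2 cut to recover the group partition across 20
seeds. All simulation outputs are byte-deterministic given a seed;
run manifests differ between runs only in their timestamps.

## Known limitations

* The matching rule is Hamming-style: an indel near the read start
  shifts every downstream base and the read is lost to the budgets.
* With $n = 3$ per group, Welch degrees of freedom are small and the
  variance estimates noisy; the W-fraction requirement is what keeps
  the false-call rate low, and single-partner p-values should not be
  over-interpreted.
* The positivity threshold (>15%) is a screening heuristic on group
  means, not an inferential statement.
* Barcode coordinates and the exact meaning of "flanking" in the
  original assay are properties of the panel design; the defaults
  here are explicit, configurable choices.
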