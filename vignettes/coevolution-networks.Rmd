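---
title: "Weakly co-evolving residue networks: model, layout and structural validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly co-evolving residue networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevnet)
```

## The problem

Homologous proteins accumulate compensating mutations: when a substitution
at one position destabilizes the fold or the function, selection favors
lineages that also carry a rescuing substitution elsewhere. Across a
family's evolutionary history this leaves pairs of alignment positions
whose residue identities are statistically interdependent. The catch is
scale: a 300-position family over 20 amino acids plus gap offers
`choose(300, 2) * 21^2` — almost 20 million — distinct (position pair,
identity pair) combinations (`pair_space_size(300, 21)`), and the
structurally informative signal is spread over many *weak* couplings
rather than concentrated in the few strongest ones. This package
implements the statistics, the radial display geometry, the randomization
control, and the structural validation needed to work with that regime.

## The identity-pair residual

For columns $i < j$ of a multiple sequence alignment, let $f_{ab}$ be the
fraction of sequences carrying residue $a$ at $i$ and $b$ at $j$, and
$f_a$, $f_b$ the marginal fractions from the same set of sequences
(complete-case: rows whose character at either column normalizes to the
ambiguity state `X` are dropped from both counts, so marginals and joints
are always consistent). The coupling statistic is the residual

$$ r_{iajb} \;=\; f_{ab} - f_a\, f_b, $$

the unexpected fraction of the family sharing the two identities relative
to independence of the positions. Algebraically $|r| \le 1/4$ (the
maximum of $x - x^2$), and the residuals of one joint table sum to zero
over all cells, as do all row and column slices — properties the test
suite checks on random tables. The statistic deliberately stays at the
identity-pair level: an edge connects *alanine at 5* with *tryptophan at
40*, not column 5 with column 40, because different identity pairs at the
same column pair can carry different (even opposing) signals.

Significance is assessed per identity pair on the 2×2 collapse of the
joint table — (has $a$ at $i$ / has not) × (has $b$ at $j$ / has not) —
with a two-sided Fisher exact test by default (`pair_significance`);
chi-squared without continuity correction is available for large, dense
tables. Degenerate margins (an identity absent or universal at its
column) admit a single table, so the p-value is reported as 1 with a
`degenerate` flag rather than as an error. No multiple-testing correction
is applied by default: the method's point is precisely to explore
couplings at raw $p$ up to 0.1, well inside the noise floor, and let
spatial coherence in the display separate structure from noise. A
Benjamini–Hochberg option exists for users who want a corrected list.

`build_network()` scans all column pairs and keeps records passing three
filters: residual at least `tr_min`, observed count at least `min_count`
(default 2), and $p$ at most `p_max`. Filtering is positive-only by
default (co-occurrence above expectation); `signed = TRUE` admits
avoidance couplings by absolute value, since nothing in the model is
specific to the positive sign. Fisher tests are computed only for cells
that already pass the residual and count prefilters, which is what keeps
full-length families (hundreds of columns) tractable. Raising `tr_min` or
lowering `p_max` can only remove records — the preset ladder
`adk_p005`…`adk_p1` (residual ≥ 0.15 with $p \le$ 0.005, 0.01, 0.05, 0.1)
yields strictly nested networks, and the acceptance suite verifies this
nesting on simulated families.

Two conventions worth stating once: all coordinates in reports, files and
the API are 1-based alignment columns (stated in every output header),
and gaps can be treated either as a 21st identity state (`gap_mode =
"state"`, the default — indels do co-evolve) or excluded pairwise
(`gap_mode = "exclude"`).

## The cylindrical layout and its control

`cylindrical_layout()` arranges the family's per-column residue profiles
around a cylinder: column $k$ sits at angle $2\pi k / L$ from the
N-terminal marker (counterclockwise by default, pointing in the direction
of increasing sequence coordinates), and each residue observed at the
column becomes a sub-node at a fixed axial slot (alphabetical one-letter
order, gap last — the stacking order is a display convention, so it is
configurable). Sub-node radius is $\sqrt{f}$ so that drawn *area* encodes
population fraction, the perceptually honest choice. Each network record
becomes one edge between its two identity sub-nodes; opacity is linear in
the residual rescaled over `[tr_min, 0.25]` and color encodes the
significance band. Scenes export losslessly to JSON (numeric round-trip
to full double precision), and as SVG/PNG axial projections or X3D
geometry for 3D viewers.

The key methodological safeguard is `randomize_columns()`: a seeded,
uniformly random bijection of layout ranks. It permutes *placement only*
— node sizes and the multiset of edge weights are exactly those of the
original scene, and the statistics are never recomputed — so any visual
salience that survives randomization is an artifact of the display. The
permutation is drawn in a private RNG scope (the caller's random stream
is untouched), and the same seed always reproduces the same control
image.

## Structural validation

Because sequential neighbors are trivially close in space, a selected
pair's distance is only meaningful against pairs of the *same sequential
separation*. `separation_baseline()` computes, for every separation $s$,
the mean (and sd and 5/50/95 percentiles) of the representative-atom
distance over all residue pairs $(k, k+s)$ with coordinates.
`evaluate_pairs()` then maps user-selected column pairs onto the
structure and flags each as closer-than-expected when its distance is
strictly below the baseline value at its separation; ties count as not
closer, so the flag is conservative. Unmapped columns and unresolved
residues are reported but excluded from the evaluated count — a crystal
structure usually resolves fewer residues than the family covers.

Numerical and convention choices here, each genuinely open and settled as
a package default with an escape hatch:

* **Representative atom**: beta-carbon with alpha-carbon fallback
  (glycine has no beta-carbon); the common 8 Å contact convention is
  usually beta-carbon based, and the side-chain proxy reflects packing
  better than the backbone. Pure alpha-carbon is one flag away.
* **"Expected distance"**: the per-separation arithmetic mean; the median
  is available. Distance distributions are right-skewed, so the mean is
  the more permissive baseline — a pair flagged closer under the mean
  would usually also be closer under the median.
* **Separation**: measured in structure sequence indices *after* mapping,
  never in alignment-column offsets, which gaps would inflate.
* **Mapping**: the chosen family row is globally aligned (Needleman–
  Wunsch, BLOSUM62) to the structure sequence; an identity below 0.9
  aborts with advice to supply a manual `column_residue_map()` —
  silently validating distances through a wrong mapping is the failure
  mode to avoid. Mismatched but aligned positions are mapped and flagged.
* **Oligomers**: for a family whose functional unit is an assembly, the
  alignment cannot distinguish intra- from inter-subunit coupling.
  `interchain_min_distance()` scans every ordered chain assignment of a
  residue pair and reports the minimum with an intra/inter label, so
  seemingly "too distant" couplings can be re-examined against the
  neighboring subunit.

`cloud_selection()` / `load_selection()` persist the user-chosen pair
groups that drive this validation. `detect_clouds()` — connected
components of network records within Chebyshev distance `eps` in the
$(i, j)$ index plane — is explicitly exploratory: the criteria by which
human users select clouds are not formalized, and detected output is
labeled as such in its provenance. Chebyshev was chosen because clouds
appear as axis-aligned blocks of nearby column pairs; the metric is an
argument, not a commitment.

## What the synthetic generator emulates — and what it does not

`generate_msa()` draws per-column background profiles from a symmetric
Dirichlet (concentration 0.5 by default: moderately peaked,
conserved-ish columns; larger values give flatter columns) and plants
couplings by a mixture: with probability $\lambda$ a sequence carries the
coupled identity pair $(a, b)$ outright, otherwise both columns draw
independently. With background frequencies $p, q$ the realized residual
is

$$ r(\lambda) = \lambda(1-\lambda)(1-p)(1-q), $$

zero at both $\lambda = 0$ and $\lambda = 1$ (a fully coupled pair makes
both identities universal, and universal identities carry no covariation)
and maximal at $\lambda = 1/2$, where $r = (1-p)(1-q)/4$. The generator
solves $r(\lambda) = \rho$ on the increasing branch $[0, 1/2]$ and raises
a feasibility error naming the achievable maximum when $\rho$ exceeds it.
The solved mixture is verified against the closed form to $10^{-9}$ at
generation time.

Toy structures close the loop: `generate_helix()` is an ideal
alpha-helical trace (radius 2.3 Å, rise 1.5 Å, twist 100°/residue) whose
distances follow the closed form
$d(s) = \sqrt{(2r\sin(s\cdot 50°))^2 + (1.5 s)^2}$ — about 3.83 Å at
$s = 1$ — making it a self-checking fixture for the baseline code; and
`generate_chain()` is a seeded fixed-bond random walk with optional
excluded volume.

The generator targets *statistical* structure only. Real families carry
phylogenetic correlation between rows (sequences are not independent
draws), alignment errors, biased taxon sampling, and couplings that
overlap and chain through shared positions — none of which are simulated.
Passing the recovery and pipeline tests therefore demonstrates that the
statistics, filters and geometry do what they claim on data with known
ground truth; it does not by itself certify performance on any real
family, which requires curated seed alignments and deposited
structures.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run entirely on generated
data at deliberately modest sizes, chosen to exercise every code path
while completing quickly on a single core: recovery of a planted
$\rho = 0.15$ coupling uses families of 500 sequences × 60 columns over
20 seeds (and 2000 sequences for the residual-accuracy check, where the
binomial standard error is about 0.008); the filter-nesting check uses
10-sequence families, where weak identity pairs land all along the $p$
ladder instead of collapsing below it; distance baselines are verified
against brute-force enumeration on 200-residue chains; and the end-to-end
pipeline plants six couplings on spatially close pairs of a 60-residue
chain across 10 seeds. Every stochastic step takes an explicit seed, and
seeded helpers restore the caller's RNG state.

## Known limitations

* The filterable statistic is the per-identity-pair residual; no
  column-pair summary score, no average-product or direct-coupling
  corrections, and no triplet or higher-order couplings.
* Sequences are unweighted population counts; heavily redundant families
  will overweight their dense clades.
* The structural layer reads PDB-format coordinates (first model, one
  chain at a time) and does not generate assembly copies from symmetry
  operators — oligomer analysis expects the deposited chains.
* `detect_clouds()` ranks by total residual only; weight, density,
  direction-consistency and endpoint-consistency criteria that human
  selections appear to integrate are not modeled.
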