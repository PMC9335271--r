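---
title: "Element similarity networks from a growing chemical space: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Element similarity networks from a growing chemical space: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemspacer)
```

## The question and the objects

Every newly reported substance enlarges the *chemical space*: the cumulative
set of known compounds up to a given year. chemspacer asks what that growing
space implies about relations among the chemical *elements* — which elements
can stand in for which, how stable those relations are over time, and how
they would have looked through the atomic-weight systems of nineteenth-century
chemists.

The package works with four objects:

* a **substance**: an identifier, a composition formula, and a first-report
  year;
* a **chemical space**: the year-indexed cumulative collection of substances
  (`chemical_space()`, `snapshot()`);
* an **arranged formula**: a substance's canonical formula with one element's
  symbol replaced by the placeholder `X` and all symbols re-sorted
  lexicographically (`arrange_formula("C2H2Br2", "Br")` is `"C2H2X2"`);
* the **profile** `FX` of element `X` in a snapshot: the *multiset* of
  arranged formulae contributed by every substance containing `X`
  (`element_profile()`). Distinct substances with the same formula — isomers,
  allotropes, polymorphs — contribute separately, which is why `FX` is a
  multiset and why the package never deduplicates records.

## The substitutability similarity

The similarity of element `x` toward element `y` is

    s(x -> y) = #{ entries of FX whose arranged formula occurs in FY } / |FX|

counted *with multiplicity* in the numerator against *support membership* in
`FY`. It is the probability that a randomly drawn `x`-containing substance
stays a known compound when `x` is replaced by `y`. The measure is
deliberately asymmetric: numerator and denominator both depend on the
direction. A worked pair, with the profile sizes the package reports through
`similarity()`:

```{r}
round(similarity_quotient(344, 659), 2)   # a bromine-toward-chlorine ratio
round(similarity_quotient(349, 1556), 2)  # the reverse direction
```

An alternative numerator — multiset-minimum intersection — would be
symmetric in the shared count; it is not what this measure means, and the
package does not offer it. Values are exact rationals (numerator and
denominator are integers, both are kept on the result object); rounding to
two decimals happens only at the reporting layer.

The per-year **system of chemical elements** (SCE, `sce_network()`) is the
directed graph with an edge from each element to its most similar
element(s). All argmax ties are kept as parallel out-edges; an element whose
maximum similarity is 0 has no out-edge. Every element occurring in at least
one substance is a node — no minimum-compound threshold, since even
5-compound elements carry signal. Nodes are annotated with substance counts
and with their rank in ascending atomic-weight order, so a drawn SCE is an
ordering-plus-similarity structure.

```{r}
toy <- toy_space()
print(similarity(toy, 1868, "Br", "Cl"))
most_similar(toy, 1868, "K")     # an exact tie keeps both partners
edge_set(sce_network(toy, 1868))
```

## Convergence machinery

* `network_overlap(nx, ny)` is the fraction of `nx`'s directed most-similar
  pairs present in `ny`; `overlap_matrix()` arranges it column-toward-row for
  a year-by-year comparison.
* `backbone()` keeps pairs `i -> j` whose ubiquity percentage
  `100 * f(i->j) / (end_year - y)` strictly exceeds a threshold (default
  60%), where `f` counts the yearly SCEs containing the edge and `y` is the
  first year both elements are SCE nodes. The denominator is written exactly
  this way — the width of the observation window — and assumes a contiguous
  yearly series of networks; it deliberately does not add 1 for the year-`y`
  SCE itself. Edges whose window is zero (both endpoints first appear in the
  final year) are excluded and logged. For a pair-level report,
  `report = "pairs"` qualifies an unordered pair when either direction
  passes, and records every qualifying direction.
* `ubiquity()` measures how small a random fraction of the space still
  reveals each full-space most-similar relation: for each sample size (by
  default 5%..95% in steps of 5) it draws `reps = 100` uniform substance
  subsamples without replacement, rebuilds the max-similarity relations, and
  counts appearances of each full-space edge. Elements absent from a
  subsample simply drop out of that replicate. Each (size, replicate) pair
  seeds its own RNG substream from the master seed, so extending the size
  grid never perturbs existing replicates.

## Retrodiction: formulae under historical atomic weights

A chemist `A` with atomic weights `A(e)` (hydrogen-referenced unless the
table says otherwise) would have written different formulae for the same
substances. The package rescales a modern formula by multiplying each
element's coefficient with a rational multiplier derived from the weight
ratio `wa = (W(e)/W(H)) / (A(e)/A(H))`:

* if `wa <= 1`, the multiplier is the *simplest fraction* within a relative
  tolerance `tau`: the Farey fraction `p/q` with the smallest denominator
  such that `|wa - p/q| / wa <= tau` (ties at equal denominator broken by
  smaller error). `farey_best()` implements this; a global
  minimum-error-under-a-denominator-cap variant is available via
  `method = "min_error"` because the phrase "simplest fraction minimizing
  the error" admits both readings, and we default to "simplest";
* if `wa = alpha + beta` with integer `alpha >= 1`, the multiplier is
  `alpha + farey_best(beta, tau)`.

Multiplying by `wa` (rather than its reciprocal `aw`, which is computed and
reported alongside) preserves the substance's elemental mass ratios when the
formula is re-read with the chemist's weights; it is the direction that turns
Fe2O3 into FeO3 under a table whose iron weight is doubled:

```{r}
berz <- perturb_weights(elements = "Fe", factors = 2,
                        chemist = "iron_doubled", year = 1819)
rescale_coefficient("Fe", berz, tau = 0.05)
render_formula(rescale_formula("Fe2O3", berz, tau = 0.05))
```

The tolerance sweep uses 20 levels, 1%..20% in steps of 1 (`retro_score_sweep()`).
Substances containing elements absent from a chemist's table are dropped —
each system is restricted to its own elements — and the drop count is
recorded. `retro_scores()` compares three directed edge sets: `P` (SCE of the
unrescaled snapshot the year before the table's publication), `P_tau` (SCE
of the rescaled space) and `P_ref` (SCE of the reference year): the
true-positive rate is `|P_tau ∩ P_ref| / |P ∩ P_ref|` and the
false-positive (transient-similarity) rate is `|P_tau \ P_ref| / |P_tau|`.
`ordering_agreement()` quantifies how similarly two weight systems order
their shared elements as the fraction of concordant unordered pairs, with
ties discordant unless tied in both — a plain pairwise-concordance choice
made here because no more specific statistic is prescribed.

### Numerical choices

Coefficients are exact reduced rationals throughout (integer numerator and
denominator held in doubles, far below the 2^53 exactness limit), so
rescaling and round-trips never lose precision; integers appear only in
rendered output. After rescaling, a formula is normalized to the smallest
positive-integer coefficient vector: multiply through by the least common
multiple of the denominators, then divide by the greatest common divisor.
One deliberate exception: when every multiplier is exactly 1 (an identity
weight system) the formula is returned untouched, so non-reduced empirical
formulae such as C2H2Cl2 keep their coefficients and isomer records keep
their identity. Full GCD reduction in that case would silently rewrite
already-valid formulae; the cost is that scale invariance
(`F` and `2F` rescaling to the same result) holds whenever any real
rescaling occurs, but not under the identity system.

`theo_total(n) = 2^n - n - 1` exceeds exact double precision at `n = 60`;
`theo_total_exact()` therefore computes the exact decimal string with
digit-vector arithmetic.

## The synthetic generator

No redistributable historical substance table exists at the scale of the
published extracts, so the package ships a generator
(`space_config()` / `generate_space()`) whose output has known ground truth.
Substances are built from **family-indexed templates**: a skeleton
composition over elements outside the slot family plus a slot coefficient,
instantiated by *every* currently available member of the slot family. Two
members of a family therefore contribute identical arranged formulae —
substitutability itself, not abundance, is planted. A global uniqueness check
rejects any template whose arranged formulae would collide with a different
element's or template's, so arranged formulae are shared *only* through
within-family substitution; switching `distinct_profiles = FALSE` re-allows
coincidental cross-family resemblances as a stressor.

Defaults emulate the historical regime and are fixed once:

| knob | default | why |
|---|---|---|
| window | 1800–1868 | the study window of the historical record |
| roster | 60 staged elements, 9 by 1800 | discovery history, stylized |
| growth | Poisson counts, mean `20 * 1.05^(year-1800)` | ≈11,000 substances by 1868, the order of magnitude of the curated record |
| sizes | 1–8, mode at 2–3 | no reported compound exceeds eight elements |
| reuse | 0.35 before 1830, 0.65 after | combination diversity falls as existing combinations are revisited |
| organic bias | C,H,O,N weighted 5x after 1830 | the organic turn |
| isomer rate | 0.08 | isomers share one empirical formula |

Each year draws from its own RNG substream of the master seed, so one year's
volume never reshuffles another's. The generator emits the same
substance-table format the loader consumes.

What the generator does *not* emulate: valence rules, reaction networks,
absolute historical counts, or the messy coincidental similarities of real
data (by default). Consequently, passing the planted-recovery tests shows the
pipeline recovers substitutability structure when it is present; it does not
certify behavior on the weaker, noisier signal of real archives. Two
planted-structure effects are worth knowing about when reading test output:
with all family members available from the start, within-family similarities
are *exactly tied*, so every planted directed pair appears as an SCE edge;
under subsampling those ties split, which can make the mean appearance count
of the (inflated) full-space tie edges dip at intermediate sample sizes — a
property of ties, not an estimator defect. With the staggered default
roster, late-introduced members miss early templates, ties break, and only
the dominant partner is recovered — the historically honest behavior.

## Pipeline, sizes and limitations

`run_pipeline()` (and the thin `inst/cli/chemspace.R` wrapper) orchestrates
the stages — stats, SCEs, overlap, backbone, ubiquity, retrodiction — and
writes CSV/GraphML/JSON artifacts plus a manifest naming package version,
seed and parameters; stages compose, stochastic artifacts name their seed,
and a failing stage leaves a FAILED marker. The test suite exercises the
pipeline on the 13-substance toy space and the statistical properties on
synthetic spaces of roughly 500–4,000 substances with 4–12 elements; the
full default-scale generation (≈11,000 substances, 60 elements) runs in
seconds-to-minutes and is exercised by the examples rather than the suite.

Known limitations: structural chemistry (bonds, valence, isotopes, charges)
is out of scope — formulae are compositions only; element discovery dates
default to first occurrence in the data unless a discovery table is
supplied; the shipped weight tables are synthetic illustrations, not
transcriptions of historical tables; and the backbone window formula
presumes one SCE per year — feeding it a sparser series deflates ubiquity
percentages proportionally.
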