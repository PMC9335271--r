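# chemspacer

Element similarity networks from a growing chemical space — with
retrodiction under historical atomic-weight systems.

## What problem this addresses

As the set of known substances (the *chemical space*) grows year by year, it
implicitly encodes relations among the chemical elements: which element can
substitute for which and still yield a known compound. chemspacer turns a
plain substance table (`id, formula, year`) into:

1. **Growth and diversity statistics** — new substances and element
   combinations per year, the fraction of combinatorially possible element
   combinations actually realized (`theo(n, s) = C(n, s)`,
   `theo(n) = 2^n − n − 1`), coverage and span measures.
2. **Substitutability similarity.** For a snapshot year, each substance
   containing element *x* contributes an *arranged formula*: its canonical
   formula with *x* replaced by the placeholder X, symbols re-sorted
   lexicographically (C2H2Br2 → `C2H2X2` for Br). These form the multiset
   *F*<sub>X</sub>, and

   *s*(x → y) = |{entries of *F*<sub>x</sub> whose arranged formula occurs in
   *F*<sub>y</sub>}| / |*F*<sub>x</sub>|

   — counted with multiplicity against *F*<sub>y</sub>'s support. It is an
   asymmetric, exactly rational probability of substitutability.
3. **Yearly similarity networks (SCEs)** — directed graphs from each element
   to its most similar element(s) (all ties kept), nodes ranked by atomic
   weight; plus their convergence over time: year-by-year **overlap**
   matrices, the **backbone** of pairs present in more than a threshold
   share of yearly networks, and **ubiquity** under random subsampling of
   the space.
4. **Retrodiction.** Modern formulae are rescaled to a historical chemist's
   atomic weights by multiplying each coefficient with the simplest Farey
   fraction approximating the weight ratio within a tolerance τ (swept over
   1%…20%), and the resulting retrodicted networks are scored against a
   reference year via true-/false-positive edge rates.
5. **A synthetic generator** with planted element families (known ground
   truth) emulating exponential growth, staged element discovery,
   combination reuse, isomers and an organic turn — so every stage is
   testable without proprietary data.

## Worked example

The hand-auditable 13-substance toy space (two of its substances are the
isomers of C2H2Br2, which is what makes profiles multisets):

```r
library(chemspacer)
toy <- toy_space()
toy
#> <chemical_space> 13 substances, 7 elements, window [1800, 1868]

similarity(toy, 1868, "Br", "Cl")
#> s(Br -> Cl) = 4/5 = 0.80
similarity(toy, 1868, "Cl", "Br")
#> s(Cl -> Br) = 3/5 = 0.60
```

Four of the five bromine profile entries (the doubly counted `C2H2X2`, `HX`,
`NaX`) reappear in chlorine's profile, so Br can be replaced by Cl in 80% of
its substances; the reverse substitution works in only 60% — substitutability
is asymmetric. The full network keeps exact ties (potassium is equally
similar to hydrogen and sodium):

```r
most_similar(toy, 1868, "K")
#> [1] "H"  "Na"
edge_set(sce_network(toy, 1868))
#> [1] "Br->Cl" "Cl->Br" "H->Na"  "K->H"   "K->Na"  "Na->H"
```

Combinatorics and retrodiction:

```r
theo_total(11)      # possible multi-element combinations from 11 elements
#> [1] 2036

berz <- perturb_weights(elements = "Fe", factors = 2,
                        chemist = "iron_doubled", year = 1819)
render_formula(rescale_formula("Fe2O3", berz, tau = 0.05))
#> [1] "FeO3"
```

Doubling iron's hydrogen-relative weight halves its coefficients: modern
Fe2O3 reads as FeO3 in that system — the classic formula correspondence.

A full synthetic study (≈11,000 substances, 60 elements staged over
1800–1868) generates in seconds and recovers only planted structure:

```r
g <- generate_space(space_config(seed = 1))
g$space
#> <chemical_space> 11094 substances, 60 elements, window [1800, 1868]
es <- edge_set(sce_network(g$space, 1868))
mean(es %in% paste0(g$truth$source, "->", g$truth$target))  # precision
#> [1] 1
```

The whole pipeline — per-year stats, SCEs (GraphML + JSON), overlap matrix,
backbone, ubiquity, retrodiction sweep, manifest — runs from one config:

```r
run_pipeline(run_config(out_dir = "run", input = "substances.csv",
                        weight_tables = "weights.tsv", seed = 1))
```

or from the shell via `Rscript inst/cli/chemspace.R all --config cfg.yaml`.

See `vignettes/chemical-space-evolution.Rmd` for the methods: the exact
similarity semantics, the Farey approximation, tie and normalization rules,
and what the synthetic generator does and does not emulate.

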