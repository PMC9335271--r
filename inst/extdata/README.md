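# Package fixtures

All files here are small, plain-text and documented; none is historical raw
data.

- `toy_expected_similarities.csv` — the complete set of nonzero
  substitutability similarities of the 13-substance toy space returned by
  `toy_space()`, worked out by hand (numerator = shared arranged-formula
  count, denominator = profile cardinality). Every pair not listed has
  similarity 0.
- `weights_dalton_1810_synthetic.tsv` — an illustrative weight table holding
  only the classic oxygen-equals-seven relation (O = 7 on an H = 1 scale);
  synthetic
  stand-in, not a transcription of Dalton's table.
- `weights_berzelius_1819_synthetic.tsv` — modern hydrogen-relative weights
  with iron doubled, reproducing the well-known Fe2O3 -> FeO3 formula
  correspondence; synthetic stand-in, not a transcription of Berzelius'
  table.
- `substances_example.csv` — the toy space in the substance-table exchange
  format (`id, formula, year`).
- `pipeline_example.yaml` — a minimal run configuration for
  `run_pipeline()` / the `inst/cli/chemspace.R` wrapper, generating a small
  synthetic space.
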