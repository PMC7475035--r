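# extdata

Optional external inputs recognized by the test suite and examples.

- `gdl_cn_panel.tsv` (not distributed): per-individual copy-number
  genotypes of the 70-line, five-population Global Diversity Lines panel,
  available from the originating study's supplementary dataset.
  Tab-separated with a header row and columns `individual`, `population`,
  `cn`. When present, the acceptance suite recomputes the panel's V_ST
  and its Monte Carlo p-value from it.

A synthetic stand-in with the panel's shape (population sizes, copy-number
range and allele structure) is generated in code by
`tandemCNV::syntheticGdlCn()`; its per-individual values are simulated.
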