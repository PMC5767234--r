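# cotracer

Which organism in a two-species co-culture produces each induced
metabolite? Co-cultivation of fungi such as *Trametes versicolor* and
*Ganoderma applanatum* switches on silent biosynthetic gene clusters and
induces dozens of LC-MS features that neither mono-culture makes — but with
unknown structures and no biochemical handles, the producing species cannot
be read off the feature table. `cotracer` implements a ¹³C dynamic-labeling
analysis that answers the question without knowing what the molecules are:
after co-culture induction, the separated mycelia are mono-cultured on
¹³C-glucose plus spent co-culture supernatant, and whichever organism is
actively synthesizing a feature shifts its isotopologue ladder upward.

The package provides, as composable functions plus one orchestrated
pipeline:

* **Induced-feature detection** — newly synthesized (co-culture only) and
  ≥5-fold increased features from a three-group replicated feature matrix.
* **Isotopologue extraction** — M+0..M+N ladders (N = carbon count) from
  centroided MS1 spectra (mzML via `mzR`, or delimited tables) at 10 ppm /
  ±0.2 min tolerances.
* **Natural-abundance correction** — the matrix method: the measured ladder
  `m = C x` is solved for the tracer mass isotopomer distribution `x` by
  non-negative least squares, with `C` built from an embedded IUPAC isotope
  table (column *j* = natural mass-shift pattern with *j* carbons fixed as
  ¹³C).
* **Incorporation statistics** — relative isotopic abundance
  `M_i = m_i / Σ m_j`, total ¹³C incorporation
  `inc = 100 · Σ i·M_i / N` (%), replicate t-tests against an unlabeled
  baseline, and steady-state vs still-increasing kinetics between days 10
  and 20.
* **Producer assignment** — `A_only` / `B_only` / `both` / `unassigned`
  calls, supernatant-dependence flags (diffusible signaling) and
  physical-interaction candidates (high co-culture signal, no label in
  either mono-culture), with cross-polarity deduplication to compound
  level.
* **Molecular networking** — modified-cosine MS/MS similarity (cosine ≥
  0.65, ≥ 6 matched peaks, components ≤ 50, clusters ≥ 2) with GraphML
  export.
* **A seeded synthetic-data generator** whose packaged scenario encodes the
  study's ground truth (74 induced features: 58 newly synthesized + 16
  fold-increased among ~4,000; producers 20/6/5/43; 12 contact candidates),
  so every stage is testable by parameter recovery.

## Worked example

```r
library(cotracer)

report <- run_pipeline(pipeline_config(seed = 1), quiet = TRUE)
print(report)
#> <pipeline_report>
#>   features: 4074 total, 74 induced (58 newly synthesized, 16 fold-increased)
#>   producers: A_only=20, B_only=6, both=5, unassigned=43 (labeled 31)
#>   flags: 12 physical-interaction candidates, 31 supernatant-dependent
#>   kinetics: 17 steady, 12 increasing
#>   network: 14 nodes, 42 edges
#>   elapsed: 29.8 s
```

Reading the summary: of ~4,000 features, 74 are induced by the co-culture;
31 of them incorporate ¹³C in at least one post-induction mono-culture —
20 are made by organism A only, 6 by organism B only, 5 by both — while 43
incorporate no label, 12 of which carry high co-culture signal and are
therefore candidates for induction through direct mycelial contact.

The building blocks work standalone. Recovering a 19% labeled compound from
a simulated spectrum of the C₂₄H₄₅NO₉ feature:

```r
s  <- simulate_isotopologue_spectrum(490.3025, "C24H45NO9", p = 0.19,
                                     rt = 15.06, total_intensity = 3.4e4)
tg <- feature_target("m490", 490.3025, 15.06, "C24H45NO9")
m  <- extract_isotopologues(list(s), tg)
total_incorporation(correct_natural_abundance(m, correction_matrix("C24H45NO9")))
#> [1] 19
```

A command-line wrapper lives at `inst/cli/cotracer`
(`cotracer simulate | induce | run | network`).

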