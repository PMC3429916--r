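# msatma

Microsatellite composition and mutation-rate analysis from
mutation-accumulation (MA) lines.

Microsatellites — tandem repeats of 1–6 bp units — mutate by gaining or
losing repeat copies orders of magnitude faster than point mutations, which
makes them the marker of choice for dating recent divergence between wild
isolates. Doing that well requires knowing each locus's mutation rate and
spectrum. MA experiments measure both directly: many lines descend from one
homozygous selfing progenitor through single-offspring bottlenecks, so
selection is essentially off and every allele-size change observed after
`t` generations is a spontaneous mutation.

`msatma` is for researchers running (or reanalysing) such experiments in
selfing organisms (e.g. nematodes). It covers the full path from sequence
to rate:

* **Motif taxonomy** — a repeat unit, its cyclic rotations and the
  rotations of its reverse complement name the same duplex locus
  ((AC)<sub>n</sub> ≡ (GT)<sub>n</sub>). `canonical_motif()` picks the
  lexicographic minimum as class representative and
  `enumerate_motif_classes()` enumerates all primitive classes per unit
  length (4 dimer, 10 trimer, 33 tetramer classes).
* **Repeat scanning** — `scan_repeats()` finds perfect and imperfect
  tandem arrays (≥ 3 copies) with a deterministic seed–extend–score
  procedure; `scan_params("strict")` (weights 2/3/5, min score 50) and
  `scan_params("loose")` (2/7/7, min score 20) mirror the two classic
  screening regimes. `summarize_composition()` turns loci into
  genome-level statistics (loci/Mb, genome fraction, AT-rich shares,
  missing classes).
* **Mutation calling & spectrum** — `call_mutations()` converts
  progenitor-versus-line allele sizes (bp) into signed repeat-unit calls;
  `mutation_spectrum()` and `stratify_events()` compute the spectrum
  (single-step vs multistep, insertions vs deletions, per-locus net
  trends, perfect/long stratification).
* **Rate estimation** — the Poisson zero-class estimator

  &nbsp;&nbsp;&nbsp;&nbsp;μ = −ln(1 − *n*/*l*) / *t*

  where *n* is the number of mutated lines, *l* the number of lines
  assessed and *t* the generations; `estimate_rates()` applies it per
  marker with exact (Clopper–Pearson) binomial confidence intervals
  transformed through the estimator.
* **Synthetic data** — `simulate_ma_lines()` (stepwise-mutation MA
  simulator with ground-truth event logs) and `plant_repeats()`
  (planted-repeat genomes with exact truth intervals) generate every input
  the pipeline needs, for validation and power analysis.

Everything takes a data frame and returns a tibble, so analyses compose
with the pipe; results have `tidy()`/`glance()` and `autoplot()` methods.

## Worked example

The package ships a 41-marker panel (19 perfect, 22 imperfect loci)
genotyped in 82 MA lines after 142 generations, with the observed mutation
magnitudes per marker:

```r
library(msatma)

fx <- fixture_ma_markers()
sp <- mutation_spectrum(fx$calls, fx$markers)
sp
#> <msat_spectrum> 31 events at 11 loci
#>   single-step: 26 (21 insertions, 5 deletions); multistep: 5
#>   insertions vs deletions (events): 23 vs 8; net change +7 units
```

31 mutations were seen at 11 of the 41 loci. 26 of 31 changed the repeat
number by a single unit — the signature of stepwise slippage — and
insertions outnumber deletions 23 to 8, so these loci are, on balance,
growing. Rates per marker:

```r
rates <- estimate_rates(fixture_genotypes(), fx$markers, t = 142)
dplyr::filter(tidy(rates), n >= 2)[, c("marker_id", "n", "l", "mu")]
#> # A tibble: 7 × 4
#>   marker_id     n     l       mu
#>   <chr>     <int> <int>    <dbl>
#> 1 M74           2    82 0.000174
#> 2 M78           3    82 0.000262
#> 3 M79           4    82 0.000352
#> 4 M82           6    82 0.000535
#> 5 M88           3    82 0.000262
#> 6 M80           2    82 0.000174
#> 7 M83           7    82 0.000628

glance(rates)$suggested_rate
#> [1] 0.000341
```

`mu` is per allele per generation. Markers with a single event are
flagged (`single_event`) because one mutation cannot pin down a rate; the
aggregate "suggested rate" averages the perfect loci with ≥ 30 repeat
units and ≥ 2 mutated lines — the marker population stable enough to use
for divergence dating. With all 82 lines treated as assessed, that
aggregate is 3.4 × 10⁻⁴; per-locus values span ~0.9–6.3 × 10⁻⁴.

Scanning a genome works the same way:

```r
g <- plant_repeats(10000, data.frame(unit = "TTCAA", copies = 64), seed = 7)
scan_repeats(g$sequences, scan_params("strict"))
#> # A tibble: 1 × 11
#>   seq_id    start   end unit_length copy_number percent_match ... score
#> 1 synthetic  5266  5585           5          64           100 ...   640
```

A command-line wrapper with `scan`, `classes`, `call`, `report`,
`simulate-genome`, `simulate-lines` and `fixture` subcommands is installed
at `system.file("scripts", "msatma.R", package = "msatma")`.

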