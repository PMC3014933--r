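# tintr — chronology of retroposon activity from nested insertions

Mobile elements proliferate in genomes in successive waves: families,
subfamilies and subtypes of retroposons rise, peak and fall silent. Because a
retroposon can only ever insert into an element that already exists, nested
("transposition in transposition", TinT) insertions behave like fossils in
stratified layers: old, silenced subtypes are never found inside young
elements, while young subtypes occupy everything that came before them.
`tintr` turns RepeatMasker annotation reports into a relative chronology of
subfamily activity:

1. **Detection** — screen RepeatMasker `.out` reports for *unambiguously*
   nested insertions using five criteria (same query sequence; element-index
   consistency; ≥ 20 nt minimal query length per fragment; equal host-fragment
   orientation; consensus continuity of the interrupted host with ≥ 50 nt
   minimal repeat extension, or ≥ 18 nt with ≤ 35 nt maximal repeat overlay to
   absorb target-site duplications).
2. **Matrix** — tally accepted events into a directional K×K count matrix
   N (rows = inserted subtype, columns = host subtype) with per-subtype
   genomic copy numbers n_j, with optional merging of related subtypes and
   removal of subtypes interacting with fewer than two partners.
3. **Model** — fit a Gaussian activity-period model by maximum likelihood.
   Each subtype j has an activity density peaking at t_j with spread
   σ_j ∝ n_j; the number of type-j elements existing at time t is
   η_j(t) = n_j Φ((t − t_j)/σ_j). A type-i insertion lands in type j with
   probability proportional to the preexisting targets, which marginalizes in
   closed form to

   q_ij ∝ n_j Φ((t_i − t_j) / √(σ_i² + σ_j²)),

   row-normalized over the target set (self-targets included). The peaks t
   maximize the product-multinomial likelihood Σ N_ij log q_ij on a relative
   time scale (gauge Σ n_j t_j = 0); each subtype is reported with the
   central 75 / 95 / 99 % intervals of its activity density
   (t_j ± 1.150349 σ_j, ± 1.959964 σ_j, ± 2.575829 σ_j).
4. **Chart** — render the chronology as the classic panel of ovals (75 %),
   vertical lines (95 %) and whisker-capped lines (99 %), sorted by activity
   peak over a relative time axis, as SVG/PNG/PS.

The package also contains a forward **simulator** of nested retroposition
with a known ground-truth ledger (Gaussian activity windows,
length-proportional landing, TSD-induced consensus overlap, optional
annotation noise), which backs the entire test suite — no genome downloads
are needed.

Intended users: researchers studying transposable-element evolution,
retroposon-based phylogenetics, or genome architecture, with RepeatMasker
reports in hand.

## Worked example

```r
library(tintr)

# simulate six Alu-like subfamilies with known activity peaks 0, 2, ..., 10
sim <- simulate_tints(simulation_config(seed = 42))
nrow(sim$hits)                      # 8500 annotation records

events    <- detect_tints(sim$hits) # innermost-attributed nested insertions
instances <- group_elements(sim$hits)
m  <- filter_types(build_tint_matrix(events, instances))
print(m)
#> TinT matrix: 6 subtypes, 2629 nested insertions (rows = inserted, cols = host)

est <- fit_activity(m, seed = 1)
print(est)
#> Relative activity periods (6 subtypes, log-likelihood -3475.3043, oldest first)
#>   type   peak sigma     lo75     hi75    lo95    hi95    lo99    hi99 ...
#>  AluJo -4.796     1 -5.94685 -3.64615 -6.7565 -2.8365 -7.3723 -2.2207
#>  AluJb -3.351     1 -4.50131 -2.20061 -5.3109 -1.3910 -5.9268 -0.7751
#>  AluSx -1.202     1 -2.35209 -0.05139 -3.1617  0.7582 -3.7776  1.3741
#>  AluSq  1.069     1 -0.08185  2.21885 -0.8915  3.0285 -1.5073  3.6443
#>  AluSp  3.055     1  1.90475  4.20544  1.0951  5.0151  0.4793  5.6309
#>   AluY  5.226     1  4.07524  6.37594  3.2656  7.1856  2.6498  7.8014

render_chart(est, "chart.svg")
```

The fitted order AluJo → AluJb → AluSx → AluSq → AluSp → AluY reproduces the
generating chronology exactly, and the recovered peak spacing (~2 spread
units) matches the simulation. The `peak` column is on a relative scale —
only order and overlap are meaningful; `lo75`/`hi75` etc. delimit the central
intervals of each activity period drawn in the chart.

The same pipeline runs from the shell via the bundled script
(`inst/scripts/tint`):

```sh
tint run --outdir results --seed 1 genome.fa.out
tint detect --relaxed --outdir results scarce_data.out
tint simulate --outdir sim sim_config.txt
```

Every run writes a `manifest.json` recording all parameters and seeds.

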