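# mechnet

Logic-based differential equation (LDE) modeling of intracellular
signaling networks, built for studying how cardiomyocytes integrate
mechanical stretch into hypertrophic gene expression — and, more
generally, for any Netflux-style signed logic network.

Large literature-curated signaling networks rarely come with measured
kinetics. The LDE formalism sidesteps that: each node's normalized
activity $Y_c \in [0, Y_{max}]$ relaxes toward a drive computed from its
upstream regulators,

$$\dot Y_c = \frac{1}{\tau_c}\big(Y_{max,c}\,g_c(Y) - Y_c\big),$$

where activation passes through a normalized Hill function
$f(x) = B x^n/(K^n + x^n)$ constrained to $f(0)=0$, $f(EC_{50})=0.5$,
$f(1)=1$, inputs inside one reaction combine as a continuous AND
($f(x)f(y)$, inhibitors as $1-f$), and parallel reactions on one target
combine as OR ($f(x)+f(y)-f(x)f(y)$). Uniform defaults
($n = 1.4$, $EC_{50} = 0.5$, $w = 0.9$, $\tau = 1$, input 0.7) make the
formalism usable straight off a curated reaction list.

On top of the simulator the package provides the full analysis chain used
in network studies of mechano-signaling:

* **model_io** — Netflux-style two-table format (species + reactions), as
  paired CSV or `.xlsx` workbook, with rule grammar
  `A & !B => C` / `=> Input`;
* **perturb** — stretch levels, knockdowns, clamps, dose-response curves
  and two-drug dose surfaces;
* **validation** — qualitative comparison against literature observation
  tables (increase / decrease / no change at a 5% threshold), disagreement
  taxonomy, AND→OR logic variants, parameter-robustness scans,
  activation-band calibration;
* **sensitivity** — half-knockdown sensitivity matrices, influence
  rankings, UPGMA hub clustering, and a pairwise combination screen with
  an additional-benefit synergy score;
* **synthetic** — seeded random logic networks, analytic toy motifs, and
  a curated ~30-node mini mechano-signaling fixture (stretch → AT1R /
  calcium channels / integrin / gp130 → transcription factors → BNP);
* **cli** — `inst/cli/mechnet.R`, a thin Rscript exposing every step as a
  subcommand.

## Worked example

Simulate the bundled mechano-signaling fixture under stretch, validate it
against its observation table, rank influential nodes, and screen drug
pairs:

```r
library(mechnet)

m <- mini_mechano_network()
model_summary(m)
#> LDE network: 30 species, 34 reactions (2 input, 4 AND, 3 inhibitory edges)

stretch <- perturbation(set_input = c(Stretch = 0.7))
ss <- steady_state(apply_perturbation(m, stretch))
round(ss[c("Stretch", "AT1R", "Ca", "NFAT", "ERK12", "BNP")], 3)
#> Stretch    AT1R      Ca    NFAT   ERK12     BNP
#>   0.700   0.645   0.835   0.650   0.618   0.107
```

Stretch at 0.7 activates the cascade to 60–85% of maximum; BNP sits lower
(0.107) because it is the AND of five transcription factors, each
necessary but not sufficient.

```r
obs <- read_observations(system.file("extdata", "mini_observations.csv",
                                     package = "mechnet"))
validate_observations(m, obs)
#> Validation: 10/10 observations matched (100.0%)
#>   input-output       1/1 (100%)
#>   input-intermediate 4/4 (100%)
#>   inhibition         5/5 (100%)

sm <- knockdown_matrix(m, stretch, factor = 0.5)
influence_ranking(sm, rows = c("NFAT", "CREB", "GATA4", "STAT", "cFos"),
                  k = 5)
#>   species      score
#> 1 Stretch 0.41120925
#> 2    PI3K 0.16089971
#> 3     Akt 0.15524309
#> 4     Ras 0.13500303
#> 5    AT1R 0.09155054
```

The score is the mean absolute steady-state change a 50% knockdown of
that node causes across the transcription factors. The pairwise screen
then asks which *combinations* suppress BNP beyond their best single
component (negative additional benefit = synergy):

```r
res <- pairwise_screen(m, stretch, outputs = "BNP",
                       nodes = c("AT1R", "LTCC", "gp130", "Integrin", "Ras"),
                       directions = "decrease")
head(res[order(res$additional_benefit),
         c("node_a", "node_b", "combined", "additional_benefit")], 3)
#>   node_a   node_b    combined additional_benefit
#> 3   AT1R Integrin -0.10215337        -0.04258804
#> 2   AT1R    gp130 -0.09185263        -0.01886552
#> 4   AT1R      Ras -0.10502748        -0.01458125
```

Co-targeting AT1R with the integrin branch removes two independently
necessary transcription-factor inputs at once, suppressing BNP by 0.102 —
0.043 more than the better single knockdown.

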