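# tarfish — consensus in-silico target prediction for compound classes

`tarfish` is an R toolkit for *target fishing*: given a whole class of
related compounds (typically natural products and their semisynthetic
derivatives), it predicts which protein targets the class is likely to hit
by combining several independent prediction channels, subtracting what is
already known from public bioactivity records, and ranking the remaining
("unknown") compound–target interactions by a consensus score.

It is written for computational chemists and natural-product pharmacologists
who want a reproducible, desk-scale version of the consensus workflow:
similarity-ensemble prediction and a hybrid 2D/3D channel are computed
locally, proprietary or web-server channels are plugged in as prediction
matrices, and every stage is deterministic under a seed.

## The method in brief

**Chemical space.** A compound library is loaded (SMILES CSV or SDF),
standardized (salt stripping, charge neutralization, canonical SMILES), and
compounds with unspecified tetrahedral stereocenters can be expanded into
all `2^k` stereoisomers. Each structure gets a radius-2 circular
fingerprint (2048 bits) and an FP2 path fingerprint (1024 bits).

**Similarity-ensemble channel.** A target is represented by the
fingerprints of its known ligands. For a query ensemble *Q* against a
ligand set *L*, the raw score is

```
raw(Q, L) = Σ { Tc(q, l) : q ∈ Q, l ∈ L, Tc(q, l) ≥ t }        (t = 0.57)
```

with `Tc` the Tanimoto coefficient. Raw scores of random ligand ensembles
are used to fit a background model — the mean raw score linear in the
set-size product `n·m`, the standard deviation a power law `a·(n·m)^b` —
yielding a z-score `z = (raw − μ(nm)) / σ(nm)`, converted into a BLAST-style
expectation value through the standard Gumbel upper tail

```
E(z) = N · (1 − exp(−exp(−(zπ/√6 + γ))))
```

where `N` is the number of reference targets and `γ` the Euler–Mascheroni
constant.

**Hybrid 2D/3D channel.** Per target, the best FP2 Tanimoto (s2D) and the
best electroshape similarity (s3D, `1/(1 + mean |Δ|)` of 15 moment
descriptors over 4D atom coordinates x, y, z, scaled partial charge) are
fused by logistic regression into a binding probability.

**Consensus.** All channels (local ones plus ingested matrices, e.g. a
pharmacophore-database screen acting as the mandatory *anchor* method) are
binarized and overlaid. A pair predicted by the anchor and two further
methods has consensus score CS = 3. Known interactions — mined from a
bioactivity backend as active, single-protein assay records with integer
weights — are subtracted, and targets are ranked by how many library
compounds hit them at each CS level. Selection combines four criteria:
panel hits with CS ≥ 2, library-wide frequency ranks, pathway
consistency/novelty, and assay availability. Percent-inhibition assay
results are classified active only when the mean is ≥ 30%, positive, and
the relative standard deviation is ≤ 20%.

## Worked example

The package ships a ten-compound dihydrochalcone panel and its
percent-inhibition table over six targets:

```r
library(tarfish)

panel <- standardize_library(
  load_library(system.file("extdata", "dhc_panel.csv", package = "tarfish")))
panel[, c("compound_id", "name", "n_unspecified_centers")]
#>    compound_id                                      name n_unspecified_centers
#> 1            1                                 phloretin                     0
#> 7            7                                phloridzin                     0
#> 10          10             neohesperidin dihydrochalcone                     0
#> ...

tab <- read.csv(system.file("extdata", "dhc_panel_inhibition.csv",
                            package = "tarfish"))
calls <- classify_assay_results(tab)
table(calls$call)
#>   active inactive
#>       10       50

calls[calls$call == "active", c("compound_id", "target_id", "mean_inhibition_pct")]
#>  compound_id target_id mean_inhibition_pct
#>            2   HSD17B3                43.8
#>            4    AKR1C3                34.4
#>            5    AKR1C3                35.2
#>            1     ALOX5                85.4
#>            2     ALOX5                99.2
#>            7     ALOX5                40.8
#>            8     ALOX5                45.5
#>            1     PTGS1                43.5
#>            3     PTGS1                53.9
#>            5     PTGS1                49.5

confirmed_target_count(calls)
#> [1] 4
```

Ten measurements pass the activity rule, spread over four distinct
proteins — the lipoxygenase ALOX5 (5-LO), the cyclooxygenase PTGS1 (COX-1),
HSD17B3 (17β-HSD3) and AKR1C3 — so four targets count as experimentally
confirmed for the panel.

A full synthetic run (fixture generation → fingerprinting → background
calibration → ensemble prediction → mining → consensus) is one call:

```r
cfg <- run_config(list(), outdir = "my_run", seed = 42)
run_pipeline(cfg)            # writes consensus.csv, ranking.csv, enrichment.csv, ...
```

or from a shell via the driver script:

```sh
Rscript inst/cli/tarfish.R all --seed 42 --outdir my_run
```

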