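---
title: "Consensus target fishing for compound classes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus target fishing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tarfish)
```

# The problem

Polypharmacology is the rule rather than the exception for natural
products: a scaffold such as the dihydrochalcones (phloretin, phloridzin
and relatives) typically touches several proteins, most of them
undocumented. Inverse virtual screening — one compound class against many
targets — can prioritize which proteins to test, but every individual
prediction method (2D similarity ensembles, 3D shape methods, pharmacophore
screens) has blind spots. The strategy implemented here is to run several
*independent* channels over the whole class, require a hit from one
well-validated anchor channel, count how many methods agree on each
compound–target pair (the consensus score, CS), remove everything already
known from public bioactivity records, and take the frequently and
consistently predicted novel targets to the bench.

`tarfish` implements that workflow end to end at desk scale, with two
channels computed locally (a similarity-ensemble scorer and a hybrid 2D/3D
scorer), file-based ingestion for channels that cannot be recomputed
(pharmacophore databases, saved web-server downloads), a pluggable
bioactivity-mining backend, and a seeded synthetic-fixture module that
provides ground truth for every stage.

# Chemical space

## Standardization

Input structures (SMILES CSV or SDF) are canonicalized with OpenBabel.
Standardization keeps the largest covalently bonded fragment (heavy-atom
count, ties by molecular weight then lexicographic canonical SMILES),
neutralizes charges where chemically possible, and counts unspecified
tetrahedral stereocenters. Unparseable entries go to a rejects report —
they are never silently dropped, because a library assembled from
literature SMILES always contains a few broken strings and the user must
see which.

## Stereochemistry

Natural-product curation often leaves absolute configurations open, and a
class campaign should include *all* consistent stereoisomers. A record
with `k` unspecified tetrahedral centers expands into the distinct
canonical structures among the `2^k` chirality assignments; `parent_id`
links each isomer to its pre-expansion record so that downstream
known-space subtraction can operate at the compound level. Two design
choices matter:

* **Perception is delegated to the canonical SMILES writer.** A candidate
  center (an aliphatic carbon with four distinct substituents counting at
  most one implicit hydrogen) is confirmed by injecting `@` and `@@` and
  checking that the two canonical forms differ; a mark at a
  non-stereogenic atom does not survive canonicalization. This guarantees
  that enumerated isomers are exactly the ones the writer can distinguish,
  so they are distinct and stable by construction. The cost is that
  stereocenters only stereogenic in combination (some fused-ring and meso
  situations) can be missed; symmetric assignments collapse during
  deduplication rather than being predicted ahead of time.
* **Only tetrahedral centers are enumerated.** Double-bond E/Z marks are
  left as given. The package's own compound class is driven by sugar
  stereocenters (glycosides), and a robust textual treatment of cis/trans
  marks would add considerable fragility for little coverage; the
  limitation is documented here deliberately.

The expansion cap (`max_centers`, default 6, i.e. at most 64 isomers)
exists because a single unresolved pyranose contributes five centers;
records above the cap are flagged and passed through unexpanded, never
silently exploded or dropped.

## Fingerprints

Two complementary fingerprints are computed per structure: a radius-2
hashed circular substructure fingerprint (2048 bits; atom invariants are
element, heavy degree, hydrogen count, formal charge, aromaticity and ring
membership, iteratively hashed over bond-ordered neighborhoods) and
OpenBabel's FP2 linear-path fingerprint (paths up to seven atoms,
1024 bits). The circular fingerprint drives the similarity-ensemble
channel; FP2 drives the 2D part of the hybrid channel. Both are pure
functions of the canonical structure. The circular length and radius are
configurable through `fp_config()`; FP2 is used at its native length.

# The similarity-ensemble channel

A target is its set of known ligands. The raw score of a query ensemble
against a ligand set sums all pairwise Tanimoto coefficients at or above a
threshold (default **0.57**, the canonical operating point for circular
fingerprints; configurable). Raw scores grow with set sizes, so they are
standardized against random expectation:

* `fit_background()` draws disjoint random ensembles from a decoy pool for
  a ladder of size pairs, and fits the mean raw score as a linear function
  of the set-size product `n·m` and the standard deviation as a power law
  `a·(n·m)^b`. Both forms are deliberately simple, smooth interpolators;
  refitting with the same seed is bit-identical.
* `z_score()` standardizes a raw score at its size product; scoring
  outside the fitted size range extrapolates and says so.
* `e_value()` converts `z` into the expected number of equal-or-better
  scores among `N` target comparisons using the upper tail of the standard
  Gumbel law matched to zero mean and unit variance,
  `E = N (1 − exp(−exp(−(zπ/√6 + γ))))`, clamped to `[0, N]`. `N` defaults
  to the number of reference targets screened, mirroring database-size
  correction in sequence searching.

Numerical edge cases: a size pair whose raw scores have zero empirical
spread (e.g. a threshold of 1.0 over distinct decoys) is excluded from the
standard-deviation fit; if every pair is degenerate the model falls back
to a tiny positive floor with a warning, preserving the positive-σ
invariant while keeping the fitted mean meaningful. The decoy pool matters:
at threshold 0.57 uniformly random bit vectors essentially never score, so
calibration is performed on chemically structured decoys (the fixture
module's scaffold-decorated pool), where the raw-score distribution has
genuine spread. The per-channel inclusion cutoff (default E ≤ 1e−5) is a
configuration constant, not a reproduction of any server's internal
threshold — the public servers do not disclose theirs.

The second 2D similarity-ensemble server in the original campaign operates
on the same principle; it is represented by this same engine pointed at its
own reference sets and cutoff, not by a second scorer.

# The hybrid 2D/3D channel

One conformer per molecule is generated with OpenBabel's deterministic
builder ("fast" level: structure generation plus a short force-field
cleanup and no stochastic rotor search, so repeated calls are
bit-identical) and Gasteiger charges are assigned. The electroshape
descriptor lifts atoms to 4D — `(x, y, z, 25·q)`, i.e. a default
`charge_scale` of 25 distance units per elementary charge — and records
mean, standard deviation and cube-rooted third central moment of atom
distances to five deterministic reference points (4D centroid, atom
farthest from it, atom farthest from that atom, and the centroid displaced
by ±`charge_scale` along the charge axis): 15 numbers, invariant under
rigid rotation and translation of the 3D part. 3D similarity is
`1/(1 + mean |Δ|)`, a bounded strictly monotone transform of the Manhattan
distance — the logistic stage needs a bounded similarity, not a distance.

Per target, `s2D` is the best FP2 Tanimoto and `s3D` the best electroshape
similarity over the target's ligands (maximum, i.e. nearest-neighbor
logic; configurable in principle but the max matches how ligand-based
screens are read). A logistic model maps `(s2D, s3D)` to a probability;
under complete separation the fit falls back to ridge-penalized IRLS
(penalty 1e−4) with a message. Queries whose 3D embedding fails are scored
by a 2D-only fallback model trained alongside — the 2D channel never dies
with the 3D one. The shipped default threshold is 0.5. Any model used in
production should be trained on the user's own labeled pairs; the models
trained in the test suite use synthetic planted-signal data and are
documented as such.

# External channels and the known space

Prediction matrices from methods the package does not recompute are read
from wide or long CSV; blank or `nan` cells mean *no prediction* and create
no entry. Scored matrices are binarized before consensus (`≤ cutoff` for
lower-better scores such as E-values, `≥ cutoff` for higher-better scores
such as probabilities or pharmacophore fit values; the pharmacophore anchor
defaults to "any positive hit"). Target labels are harmonized through an
alias table (case-insensitive, stored uppercase); unmapped labels are a
hard error listing every offender, because silently dropping a channel's
target column corrupts consensus counts.

The known biological space is mined through a backend interface with four
lookups: structure → compound id, compound id → active assay records,
gene → protein entry, protein entry → pathway names. Assays not mapped to
exactly one protein are discarded (the single-protein rule: cell-based and
panel assays must not create protein-level edges), inactive flags are
discarded, and the surviving records aggregate into interactions weighted
by the number of distinct supporting assay ids. Interactions of a
stereoisomer are also attributed to its parent record, since subtraction
operates at the compound level. Two backends ship: a local fixture backend
over four CSV tables (used by every test) and a thin REST client for the
live public services with a 5 req/s rate limit and three retries with
exponential backoff (integration use only — the test suite never touches
the network). The known space exports as a SIF network
(`compound<TAB>binds<TAB>target`) plus an edge-attribute table, and the
export round-trips.

# Consensus, selection and activity calls

`assemble_predicted_space()` overlays the binarized channels; CS is the
number of asserting methods, anchor included (anchor + two servers ⇒
CS = 3). Records without an anchor hit keep their CS but are ineligible —
they remain visible as near-misses instead of being deleted. Exactly one
anchor per run is enforced. Known pairs (or their parents') are subtracted
idempotently, with the removal count reported.

Selection mirrors the four criteria of the original campaign: (I) eligible
panel-compound hits at CS ≥ 2 grouped by target; (II) per CS level, targets
ranked by how many library compounds hit them, ties sharing the lower rank
number; (III) novelty (no known interaction of a panel compound with the
target) and pathway consistency (other predicted or known targets sharing a
pathway); (IV) assay availability as a configuration table — it is data,
not computation. The report's `selected` flag is a convenience
(available ∧ novel ∧ supported by I or ranked in II's top 10); the
original selection also weighed literature judgment, which no boolean can
encode.

**Enrichment** is a recovery test run *without* subtraction: each channel's
surviving entries are ranked by its own scores, the consensus by descending
CS, and the enrichment factor is the fraction of known pairs in the top
`k` divided by the random expectation `k / universe`, the universe being
all pairs asserted by at least one channel. The head size defaults to the
number of consensus-supported pairs (CS ≥ `min_cs`): with a head much
smaller than the scale of the true interaction set, every reasonable
ranking saturates and the comparison between methods measures only
sampling noise.

**Activity calls** implement the stated rule literally: a measurement is
active iff mean inhibition ≥ 30%, positive, and relative standard
deviation `100·sd/|mean|` ≤ 20%. Negative means and noisy replicates are
ambiguous, hence inactive. Applied to the shipped 10 × 6 inhibition panel
this yields ten active calls on four distinct proteins. Two rows of that
table are worth knowing about: compound 2 on COX-1 (48.1 ± 12.0, relative
SD 24.9%) and compound 10 on 5-LO (7.7 ± 6.0, mean below the floor) fail
the rule although narrative accounts sometimes list them as actives — the
rule as stated is what the package computes.

# The synthetic fixture module

Every stage is testable without a download because the fixture module
generates, as a pure function of a seeded `fixture_spec()`:

* a **library** of scaffold-decorated molecules (a
  1,3-diarylpropan-1-one core with OH/OMe/glycoside-like decorations and an
  optional chain substituent that introduces a stereocenter) — the first
  entry is the bare scaffold;
* **reference ligand sets**: planted targets get ligands drawn from the
  library's own grammar (so library compounds genuinely resemble them),
  decoy targets get ligands from unrelated scaffolds (amides, biphenyls,
  piperazines, ...); every (library compound, planted target) pair is a
  truth;
* **backend tables** exposing a `known_fraction` of truths as 1–4 active
  single-protein assay records (giving the weights), plus multi-protein
  and inactive distractors that the mining filters must reject;
* **method matrices** for an anchor channel and two fallible servers,
  asserting truths with probability `1 − miss_rate` (default 0.1) and
  decoys with probability `noise_rate` (default 0.02), with independent
  seeded noise per method.

Default conditions: 60 compounds, 50 targets of which 5 planted, 8 ligands
per set, `known_fraction` 0.4. The compound and target counts are a
deliberate desk-scale reduction of a realistic campaign (hundreds of
compounds, dozens of targets) chosen so a full pipeline run takes well
under a minute; the planted/decoy ratio of 1:9 keeps ranking non-trivial.
On these defaults the full chain recovers all planted targets within the
top 10 at CS ≥ 2 and the consensus enrichment factor (~1.5) beats every
single channel (~1.3) across seeds.

What passing on fixtures does **not** show: real reference databases are
far larger and noisier, real target ligand sets are chemically
heterogeneous, real servers' score distributions are unknown, and real
bioactivity records carry organism and assay-quality issues the fixture
tables idealize away. The fixtures establish correctness of the machinery
and the statistical behavior of the scoring, not predictive performance on
live data.

# Determinism and numerical conventions

All randomness flows from explicit integer seeds (generators derive
per-stage streams by fixed offsets); two runs with one configuration are
byte-identical in their primary outputs, and each pipeline stage writes a
manifest of input/output MD5 hashes. Files are written atomically (temp
file + rename). Ties are always broken deterministically (documented at
each site: lexicographic ids, descending max Tanimoto, lower shared
ranks). Tanimoto of two empty fingerprints is defined as 0. Raw-score
sums are computed by matrix products and may differ from a naive loop in
the last floating-point ulp.

# Known limitations

* Stereo perception by canonicalization probing can miss jointly
  stereogenic centers; E/Z bonds are not enumerated.
* The circular fingerprint is an ECFP-style analog, not a bit-for-bit
  reproduction of any proprietary implementation; absolute Tanimoto values
  differ from other toolkits even though rankings are comparable.
* The background model's linear/power-law forms are interpolators; scoring
  far outside the fitted set-size range extrapolates (and warns).
* The live REST backend is a thin convenience for networked machines and
  is intentionally untested offline.
* Criterion II reproduces ranking mechanics; reproducing any historical
  campaign's literal ranks would require the original server outputs.
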