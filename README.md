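# regionprop

Region-specific propagation of protein function labels.

Most experimental Gene Ontology (GO) annotation is attached to whole
proteins, yet many molecular functions — DNA/RNA binding, metal
coordination, catalysis — are carried by one specific stretch of the chain,
often a domain, sometimes a region with no recognized domain family at all.
`regionprop` localizes protein-level GO labels to sequence **regions**: it
splits each protein into continuous candidate functional regions by
consensus over typed InterProScan annotations, encodes regions in four
TF-IDF-weighted feature spaces (3-mers, description keywords, InterPro
entry IDs, member-database signature IDs), and trains a per-GO-term
group–instance model whose region scores must explain the protein labels
through max aggregation. It is aimed at function-prediction practitioners
who want region-resolved GO predictions — including for regions with no
domain assignment — and a principled comparison against whole-protein
baselines.

## The model

Regions are scored by a logistic model ŷᵢ = σ(θᵀxᵢ) and a protein's score
is Ŷₖ = maxᵢ∈ₖ ŷᵢ. For each GO term, θ minimizes the four-term cost

J(θ) = (1/Nₚ) Σₖ Δ(Ŷₖ, Yₖ)
     + (w₁/Nᵣ²) Σᵢ Σⱼ κ(xᵢ, xⱼ) Δ(ŷᵢ, ŷⱼ)
     + (w₂/Nᵣ₊) Σᵢ∈ᵣ₊ Δ(ŷᵢ, yᵢ)
     + (λ/Nₚ) ‖θ‖²₂

where Δ is the square loss and κ is cosine similarity between region
feature vectors, thresholded at the 95th percentile of a sampled null.
Term 1 ties region scores to known protein labels (positive or negative);
term 2 propagates labels between feature-similar regions; term 3 anchors
the sparse known region-level positives r₊ (e.g. from interpro2go-style
mappings); term 4 guards against overfitting. Training is minibatch SGD
with momentum, seeded by (and compared against) an L2-regularized logistic
regression on whole-protein vectors — the whole-protein baseline θ_base,
which shares the feature space and can score regions directly.

Evaluation is region-level (structure-derived binding labels: more than 3
residues within 6 Å of the ligand, regions under 80% structural coverage
excluded) and protein-level (temporal holdout between two GAF releases),
using average-precision AUPR with paired 1000-round bootstrap and
two-tailed Wilcoxon signed rank comparisons, plus F1-max positive calling
and a CAFA-style sequence-identity baseline.

## Worked example

Everything runs offline: the package ships a seeded generator of synthetic
corpora with the structure the method assumes (proteins of 1–6 regions,
sparse region features, one planted region-specific function, protein
labels as the OR of region labels, and contact records for the
structure-based evaluation).

```r
library(regionprop)

# the canonical boundary-building example: a 511-residue protein with
# domains at 1-249 and 339-402 becomes four regions
fx <- generate_annotation_fixture()
build_regions(fx$proteins, fx$annotations)$regions
#>   region_id protein_accession index start end origin_type
#> 1  Q9UHR4:1            Q9UHR4     1     1 249      Domain
#> 2  Q9UHR4:2            Q9UHR4     2   250 338  Unassigned
#> 3  Q9UHR4:3            Q9UHR4     3   339 402      Domain
#> 4  Q9UHR4:4            Q9UHR4     4   403 511  Unassigned

# plant a region-specific function, train, and compare with the
# whole-protein baseline at region level
corpus <- generate_corpus(synthetic_spec(seed = 1))
corpus
#> synthetic_corpus: 200 proteins, 594 regions, 80 positive proteins (seed 1)

res <- run_experiment(corpus, run_config(seed = 1))
res$aupr_region          # 0.997  region-level AUPR of the trained model
res$aupr_baseline        # 0.915  same regions scored by theta_base
res$comparison
#> $delta_median  +0.082  (positive: region-specific method wins)
#> $p_value       3.3e-165 (paired Wilcoxon over 1000 bootstrap rounds)
```

The trained model recovers the planted causal regions almost perfectly,
while the whole-protein baseline — trained on the same labels but on
protein vectors, including family features that span regions —
mislocalizes part of the signal; the bootstrap comparison quantifies the
gap.

The same pipeline runs from files (FASTA, InterProScan TSV, GAF, contact
TSV) through `rp_simulate()`, `rp_regions()`, `rp_featurize()`,
`rp_train()`, `rp_predict()` and `rp_evaluate()`, or from a shell via the
thin wrapper:

```sh
Rscript inst/cli/regionprop.R simulate --dir demo --seed 1
Rscript inst/cli/regionprop.R evaluate --dir demo --go GO:0003677 --seed 1 --out demo/report.json
```

## Acceptance script

`scripts/acceptance.R` re-runs the complete pipeline from scratch against
the installed package — generates a corpus under the given seed, builds
regions and features on disk, trains the model and the baseline, and
evaluates them — then writes its results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

- `R/io_formats.R` — FASTA / InterProScan TSV / GAF 2.x / external2go /
  contact TSV readers and writers, non-IEA filtering, temporal-holdout
  assembly.
- `R/region_builder.R` — consensus region boundaries (precedence tiers,
  18/20-residue rules) and the 75%-overlap feature assignment.
- `R/feature_space.R` — k-mer/keyword/ID extraction, TF-IDF, thresholded
  cosine kernel, MatrixMarket persistence.
- `R/gicf_model.R` — the cost function, analytic gradient, seeding,
  minibatch SGD with momentum, prediction, JSON model archives.
- `R/evaluation.R` — AUPR, paired bootstrap, Wilcoxon signed rank, F1-max,
  structure-derived binding labels, identity baseline.
- `R/synthetic_fixtures.R` — the seeded corpus generator and the worked
  two-domain fixture.
- `R/pipeline.R`, `inst/cli/regionprop.R` — orchestration and the
  command-line entry point.
- `vignettes/region-specific-function-propagation.Rmd` — the methods
  vignette: model, assumptions, defaults, synthetic world, limitations.
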