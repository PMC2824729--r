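# domprior

Positional candidate gene prioritization from domain–domain interaction
networks, developed around Type 2 Diabetes (T2D) linkage intervals.

## The problem

Genome-wide linkage scans localize disease association to broad chromosomal
regions — here, 10 Mb windows around markers with LOD ≥ 2 — each harboring
hundreds of genes. Testing every positional candidate experimentally is
impractical, so candidates must be ranked by how disease-like they look.
`domprior` ranks them using the evidence carried by their protein domains'
interaction partners, on the premise that disease genes are functionally
related through the modular domain interactions that mediate protein–protein
interactions.

## The method

For a candidate protein *P\_i* with parent domain *D\_i*, every partner
domain *D\_j* (j = 1…N) in the confidence-filtered domain interaction
network (InterDom-style confidence ≥ 10) is scored against four binary
evidence classes:

* **a** — domains found in proteins carrying disease-associated
  non-synonymous variants (catalog size *T\_a* = 60);
* **b** — domains mapped via Pfam2GO to disease-relevant GO biological
  processes (*T\_b* = 15);
* **c** — domains whose harboring proteins lie in disease-linked chromosomal
  regions (*T\_c* = 64 regions);
* **d** — domains whose harboring proteins are known disease proteins
  (OMIM-style list, *T\_d* = 1746 after removing class-a overlap).

Each partner contributes `a_j + b_j + c_j + d_j` with
`a_j = D_ja / T_a, …, d_j = P_jd / T_d` (presence/absence indicators over
class totals; classes c and d consider *all* proteins harboring *D\_j*).
The raw Weight value of the parent is the sum over its N partners, min–max
normalized over the run:

    Wv(D_i) = (raw − min) / (max − min)        raw = Σ_j (a_j + b_j + c_j + d_j)

A protein takes the highest Wv among its domains. Candidates with
**Wv > 0.5** are High Weight Elements (HWEs); the HRC step keeps HWEs whose
local clustering coefficient in the domain network is **C\_i < 0.015**
(disease genes avoid densely clustered network neighborhoods), yielding the
prioritized HWEc list. Supporting modules provide benchmarking (confusion
matrix, empirical ROC/AUC, fold enrichment), network-motif significance
against degree-preserving randomized networks with Pfam2GO-based function
prediction, and a synthetic-world generator with planted high-evidence
candidates.

## Worked example

The package ships the published 19-gene benchmark table (known T2D genes
with their Wv and C_i values). Applying the two thresholds reproduces the
published decisions:

```r
library(domprior)
chk <- table3_check()
chk$hwe_count                      # 13  genes with Wv > 0.5
chk$hwec_count                     # 6   of those with C_i < 0.015
subset(chk$flags, is_hwec)$gene
# "ADAMTS9" "NOTCH2" "CDKL1" "CAMK1D" "IGF2BP2" "TSPAN8"
```

13 of the 19 known genes are HWEs and exactly 6 are prioritized by Wv + HRC
(sensitivity 6/19 = 0.32), matching the published flags gene for gene.

A full run on a generated world with 10 planted disease-like candidates:

```r
w  <- generate_world(world_config(seed = 1))
s  <- score_bundle(w$bundle)          # network + Wv scoring
pr <- prioritize(s$candidates)        # HRC filter
pr
# prioritization: 516 candidates, 18 HWE (Wv > 0.5), 10 HWEc (C_i < 0.015)
benchmark_prediction(pr$candidates$protein[pr$candidates$is_hwec],
                     w$bundle$labels,
                     scores = setNames(pr$candidates$wv, pr$candidates$protein))
# confusion matrix: TP=10 FP=0 TN=150 FN=0
#   sensitivity 1.000, specificity 1.000, accuracy 1.000, enrichment 16.00-fold
#   AUC 1.000
```

All 10 planted candidates are recovered as HWEc: their parent domains'
partners hit the evidence classes while their network neighborhoods stay
locally sparse, which is exactly the signature the method selects for.
`run_pipeline()` chains the same stages from a YAML config and writes
`scores.tsv`, `hwec.tsv`, `report.tsv`, `motifs.tsv`, `roc_points.tsv` and a
`manifest.json` with input digests and per-stage counts.

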