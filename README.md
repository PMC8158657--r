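# coattseg

Volumetric brain-tumor segmentation from four-modality MR (T1, T1c, T2,
FLAIR) with **reverse co-attention fusion**, implemented as a self-contained
R package — including its own reverse-mode autodiff engine and Rcpp kernels
for 3D convolution, trilinear resizing and exact Euclidean distance
transforms — plus a synthetic phantom generator so the whole pipeline is
trainable and testable on one CPU without any external data.

## Who this is for

Researchers and engineers who want a transparent, dependency-light
reference implementation of a multi-modal fusion segmentation architecture:
every operation (encoder, partial decoder, attention, losses, metrics) is
inspectable R/Rcpp code with independent test oracles, rather than calls
into a deep-learning framework.

## The method in brief

Modalities are grouped into pairs $X_{g1}=(T1,T1c)$ and $X_{g2}=(T2,FLAIR)$
so each pair is internally consistent and the pairs are mutually
complementary. One shared-parameter five-level 3D encoder processes both
pairs; a partial decoder aggregates the high-level features $f_3,f_4,f_5$
into a per-pair global map $M_g$ (three logit channels: WT, TC, ET). A
cascade over levels $i = 5,4,3$ then fuses the pairs under reverse
co-attention:

$$R = 1 - \sigma(M), \qquad \bar R_i = \tfrac12 (R_{g1} + R_{g2}), \qquad
\bar f_i = f_i \otimes \bar R_i + 1,$$

with the gated features concatenated, mixed, and emitted as side-output
maps $M_i$. The prediction is $\sigma(\mathrm{up}(M_3))$. Training minimises

$$L_{total} = 0.7\, L_{Dice} + 0.3\, L_{deep},$$

where $L_{deep}$ is hard-pixel-weighted binary cross-entropy deep
supervision on $M_g, M_3, M_4, M_5$. Evaluation reports per-region Dice and
the 95th-percentile Hausdorff distance (HD95). The three regions are
hierarchical (ET ⊆ TC ⊆ WT) and that invariant is enforced everywhere.

See `vignettes/coattseg-methods.Rmd` for assumptions, parameter meanings
and numerical choices.

## Worked example

```r
library(coattseg)

cohort <- generate_cohort(25, phantom_spec(), master_seed = 11L)
sp     <- split_dataset(seq_along(cohort), 0.8, seed = 11L)
fit    <- train_model(cohort[sp$train], train_config(master_seed = 11L))

test  <- cohort[sp$test]
preds <- lapply(test, function(ph) predict_study(fit, ph$study)$masks)
gts   <- lapply(test, function(ph) map_labels(ph$labels))
print(evaluate_cohort(preds, gts)$aggregate)
```

Output (desk profile: 32³ phantoms, base 4 filters, 200 Adam steps,
~3.5 min on one CPU):

```
   region      dice     hd95
1      wt 0.9222624 1.000000
2      tc 0.8714239 1.000000
3      et 0.5745140 1.860113
4 average 0.7894001 1.286704
```

Reading: whole tumor and tumor core are segmented well (Dice 0.92 / 0.87,
boundary error ~1 voxel); the enhancing core — a ~3-voxel-radius structure
predicted from a map at 4× coarser resolution — is the hard case (0.57).
Mirroring the source method's ablation table in direction, the fused model
outperforms single-pair and naive-average baselines on the same split
(region-average Dice at an equal reduced budget: full 0.716 >
average-of-pairs 0.622 > T2/FLAIR-only 0.599).

## Command line

```sh
Rscript -e 'quit(status = coattseg::cseg_main())' simulate --n 10 --out-dir data --seed 7
Rscript -e 'quit(status = coattseg::cseg_main())' train    --data-dir data --out run --seed 7
Rscript -e 'quit(status = coattseg::cseg_main())' predict  --checkpoint run/checkpoint.rds --in data/sub-001 --out pred
Rscript -e 'quit(status = coattseg::cseg_main())' evaluate --pred pred --gt data/sub-001 --out metrics.csv
Rscript -e 'quit(status = coattseg::cseg_main())' ablate   --data-dir data --out abl --modes all
```

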