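# dcra — deep coupling recurrent auto-encoders for multimodal vigilance estimation

Driver vigilance is conventionally quantified by **PERCLOS**, the fraction
of oculomotor events that are blinks or eye closures:

```
PERCLOS = (blink + CLOS) / (blink + fixation + saccade + CLOS)
```

Estimating PERCLOS from wearable physiology uses two complementary feature
streams — EEG-like features reflecting cortical state and EOG-like features
reflecting oculomotor behaviour. Each stream alone is contaminated by
modality-specific artifact drift; fusing them is consistently reported to
beat either alone.

This package implements the **deep coupling recurrent auto-encoder
(DCRA)**: two stacked GRU auto-encoders (one per modality, widths
36/25 → 20 → 16 → code 10 → 16 → 20 → 36/25) tied at the coupling layer by
the joint loss

```
L = (1 - α) (L_E + L_O) + α S,     S = (f_E - f_O)ᵀ M (f_E - f_O)
```

where `L_E`, `L_O` are squared reconstruction errors, `f_E`, `f_O` the
coupling-layer codes, and `M` either the identity (Euclidean variant,
DCRA_E) or a Mahalanobis metric learned beforehand by **PGDM**
(probabilistic global distance metric learning, a convex program over
positive semi-definite matrices) and frozen during training (DCRA_M). The
GRU recurrences, backpropagation through time (including batch
normalization and the coupling term), Adam, greedy layer-wise pretraining,
the PGDM projected-gradient solver, a linear PERCLOS head, five-fold
cross-validation with RMSE/PCC, and Friedman/Nemenyi model comparison are
all implemented here and verified against independent oracles in the test
suite. A synthetic-session generator plants a shared latent vigilance
process observed by both modalities under realistic artifact drift, so the
whole pipeline is testable end-to-end without any external recordings.

The audience is researchers in physiological state monitoring who want a
transparent, dependency-light reference implementation of coupled
recurrent auto-encoder fusion, and methodologists who want its components
(GRU auto-encoders, PGDM, rank-based model comparison) individually.

## Worked example

```r
library(dcra)

# 1. simulate a labelled session: 300 epochs, 8 steps each, 36/25 features
session <- generate_session(synthetic_config(n_epochs = 300, seed = 1))
session
#> <vigilance_session> 300 epochs, T = 8, dims 36/25
#>   PERCLOS: 0.091-0.912 (mean 0.551)

# 2. five-fold cross-validated PERCLOS estimation, coupled model (alpha 0.4)
cfg <- dcra_config(alpha = 0.4, epochs = 15, pretrain_steps = 10, seed = 1)
report <- kfold_cv(session, cfg, k = 5)
report
#> <eval_report> n = 300 ; pooled RMSE = 0.1488 , PCC = 0.7368

# 3. single-modality baselines share the harness
kfold_cv(session, dcra_config(alpha = 0, epochs = 15, pretrain_steps = 10,
                              seed = 1), k = 5, features = "e")$rmse
#> [1] 0.1708
```

The fused RMSE (0.149) beats the EEG-only auto-encoder (0.171): the
generator contaminates each modality with slow common-mode drift that is
indistinguishable from the vigilance signal within that modality but
independent across modalities, so only the fused model can average it away
— the same mechanism that makes EEG–EOG fusion effective on real
recordings.

Rank-based comparison of estimators across datasets (ties get average
ranks; `CD` is the Nemenyi critical difference):

```r
rt <- rank_algorithms(vigilance_rank_table())
rt$aov
#>       DCRA_M LSTM-CapsAtt       DCRA_E        DNNSN         LSTM         GELM
#>          1.2          1.8          3.2          4.4          5.2          5.1
nemenyi_cd(k = 6, N = 5, q_alpha = 2.850)
#> [1] 3.372344
```

Two algorithms whose average order values differ by more than the CD are
significantly different at α = 0.05; `cd_diagram(rt, 3.372)` draws the
standard critical-difference diagram and returns the pairwise table.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript exec/dcra simulate --seed 7 --n-epochs 300 --out session/
Rscript exec/dcra learn-metric --data session/ --out metric.rds
Rscript exec/dcra train --data session/ --alpha 0.4 --metric learned \
        --metric-file metric.rds --seed 1 --out model.rds
Rscript exec/dcra predict --model model.rds --data session/ --out pred.tsv
Rscript exec/dcra evaluate --data session/ --alpha 0.4 --k 5
Rscript exec/dcra alpha-sweep --data session/ --alphas 0,0.2,0.4,0.8,1
Rscript exec/dcra compare --scores scores.tsv --out cd.png
```

## Package layout

- `R/datagen.R` — synthetic sessions, PERCLOS, standardization
- `R/gru.R`, `R/dra.R` — GRU cell/stacks, batch norm, backpropagation,
  Adam, single-modal auto-encoder, layer-wise pretraining
- `R/metric.R` — Mahalanobis metrics, PSD projection, PGDM
- `R/dcra.R` — joint loss, coupled training, fusion, regression head
- `R/evaluation.R` — RMSE/PCC, cross-validation, Friedman/Nemenyi
- `R/io.R`, `R/cli.R` — session/config/model archives, CLI
- `vignettes/coupled-vigilance-estimation.Rmd` — model, assumptions,
  design decisions, limitations
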