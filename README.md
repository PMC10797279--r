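# dapehr

Contrastive pre-training and fine-tuning for post-discharge depression
and anxiety risk prediction from heterogeneous electronic health
records (EHRs), at desk scale.

Depression and anxiety are roughly twice as common in type 2 diabetes
patients as in the general population, yet the primary-care records
that could flag at-risk patients are sparse, fragmented, and almost
entirely unlabeled. `dapehr` implements a two-step framework for this
setting:

1. **Contrastive pre-training (DAPCP).** Each discharge record is
   encoded from four views: structured slots *E* (per demographic/lab
   feature, a name embedding plus a learned quantile-bin embedding,
   encoded by a transformer ψ_E), history tokens *N* (fused with *E*
   by a gated single-head linear-attention encoder f_X), and
   diagnosis/medication name sequences (text encoders f_D, f_M).
   Projection heads g_x, g_m, g_d produce L2-normalized vectors
   (x, m, d), trained with the paired InfoNCE objective

       L_CP = L(x,m) + L(m,x) + L(x,d) + L(d,x),
       L(q,k) = -log  exp(q·k⁺/τ) / Σᵢ exp(q·kᵢ/τ)

   so a record's patient state aligns with its own discharge
   diagnoses and medications against in-batch negatives.

2. **Fine-tuning (DAPFT).** A single affine head ϕ_U over [x‖m‖d],
   trained end-to-end with binary cross-entropy, predicts whether a
   depression/anxiety outcome (ICD-10 F31–F34, F39, F06.3, F40–F43,
   F06.4; ATC N06A, N05B) occurs within 30/180/365 days of discharge.

Around the models, the package provides the full study pipeline:
a seeded synthetic EHR generator with planted latent structure and
retained ground truth; isolation-forest outlier screening and quantile
discretization; case–control cohort construction with a 183-day
prior-event exclusion, 7-day repeat merging, and 1:3 propensity-score
matching; patient-disjoint stratified k-fold evaluation (ROC-AUC,
PR-AUC, Welch t-tests) against logistic/random-forest/boosting
baselines; decision curve analysis; and integrated-gradients
attribution with per-feature aggregation. All neural gradients come
from a compact tape-based reverse-mode autodiff engine validated
against finite differences.

## Worked example

```r
library(dapehr)

# a strong-signal synthetic world: ~600 records, planted latent risk
cfg <- synthetic_config(n_patients = 300, admissions_min = 2,
                        admissions_max = 2, signal_strength = 3, seed = 1)
timelines <- generate_timelines(cfg)

# how learnable is the planted signal, at most?
truth <- latent_risk_scores(timelines, cfg)
auc_roc(truth$outcome, truth$score)
#> [1] 0.9197194

# preprocess and build the 365-day matched cohort
records <- screen_lab_outliers(all_records(timelines), 0.02, seed = 1)
schema  <- fit_schema(records, embed_dim = 32)
cohort  <- build_cohort(timelines, window_days = 365)
cohort$provenance
#>        input_records          merged_away                cases
#>                  600                    0                   91
#>     control_eligible excluded_prior_event     matched_controls
#>                  489                   20                  273
#>   unmatched_controls
#>                  216

# contrastive pre-training, then fine-tuning
encoded <- assemble_records(records, schema)
ckpt <- pretrain(encoded, dapcp_config(batch_size = 8, epochs = 3, seed = 1),
                 schema)
tail(ckpt$trace, 1)
#>   epoch    loss retrieval
#> 4     3 3.95826       0.6

rec_by_id <- setNames(records, vapply(records, `[[`, "", "record_id"))
co_enc <- assemble_records(rec_by_id[cohort$records$record_id], schema)
ft <- finetune(ckpt, co_enc, cohort$records$label,
               dapft_config(epochs = 3, seed = 1))
tail(ft$metrics, 1)
#>   epoch train_loss val_roc_auc val_pr_auc
#> 3     3  0.2832937   0.7800752  0.5418274

predict_risk(ft, co_enc[1:3])
#> P00005-A01 P00097-A02 P00067-A02
#> 0.74079112 0.16648238 0.09174751
```

The retrieval column is in-batch x→d top-1 accuracy (chance = 1/8 at
batch size 8): after three epochs the fused patient-state
representation retrieves its own discharge diagnoses far above chance,
and the fine-tuned head separates future depression/anxiety cases from
matched controls (validation ROC-AUC ≈ 0.78 on this small example,
against a planted Bayes bound of ≈ 0.92; larger corpora as used in the
test suite reach ≈ 0.89).

`run_all(run_config(...))` chains the whole pipeline (generate →
preprocess → cohorts → pretrain → finetune → evaluate → interpret)
into one seeded, manifest-tracked run; `inst/cli/dap.R` is a thin
command-line wrapper over the same functions.

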