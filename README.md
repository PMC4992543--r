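# puplearn

Positive-unlabeled learning for protein pupylation site prediction.

## The problem

Pupylation — attachment of the prokaryotic ubiquitin-like protein Pup to a
substrate lysine — is the bacterial analogue of ubiquitylation and a
degradation signal in actinobacteria. Predictors of pupylation sites are
trained on the handful of experimentally verified sites; the usual practice
of treating every *nonannotated* lysine as a negative is self-defeating,
because the nonannotated pool contains real sites that have not been
validated yet. `puplearn` treats the task as **positive-unlabeled (PU)
learning**: annotated lysines are positives *P*, every other lysine is
unlabeled *U*, and no sample is ever assumed to be a clean negative.

It is aimed at computational biologists who want either a ready-made
pupylation site predictor for their own FASTA + site tables, or a tested,
composable implementation of reliable-negative PU learning to study.

## The method

Each lysine is a 21-residue window encoded as the composition of k-spaced
amino-acid pairs (CKSAAP): for gaps k = 0..4, the frequency of every
ordered residue pair (x, y) at positions (i, i+k+1), normalised per gap —
5 × 21² = 2205 features over the X-padded alphabet, reduced to the top 150
by a chi-square presence/class ranking. Training proceeds in three stages
around an RBF-kernel SVM (libsvm via `e1071`):

1. **Initial reliable negatives** RN⁰: the |P| unlabeled windows farthest
   (minimum Euclidean distance) from every known positive.
2. **Expansion**: iteratively train SVM fⁱ on P vs RNⁱ, admit unlabeled
   windows with decision value < T = −0.25 (at most 2|P| per iteration,
   most-negative first), compress the old negatives to the negative support
   vectors plus one nearest non-SV neighbour each, and repeat until
   |U| ≤ 4|P| or no candidate crosses T.
3. **Final classifier** on P vs the final RN, with (C, γ) tuned once by
   grid-searched cross-validated AUC and frozen throughout.

Evaluation reports Sn, Sp, ACC, MCC and rank-based AUC; a balanced-negative
SVM baseline (`baseline_svm_balance()`) and a support-vector-only expansion
variant (`rn_representation = "sv_only"`) are included for comparison. A
synthetic proteome generator plants motif-bearing sites and hides half of
the annotations, so the entire pipeline — including recovery of hidden
positives — is testable offline. See the vignette
(`vignettes/pu-learning-for-pupylation.Rmd`) for the model details and
design choices.

## A worked example

```r
library(puplearn)

sim <- simulate_proteome(simulation_config(seed = 1))
windows <- extract_windows(sim$proteins, sim$annotations)
model <- pup_train(windows, pu_config(seed = 1))
print(model)
#> PU-learned pupylation site model (RBF SVM)
#>   cost = 1, gamma = 1
#>   trained on 36 positives vs 148 reliable negatives; 150 features
#>   expansion iterations: 3

tidy(model$expansion)
#> # A tibble: 3 × 8
#>   iteration  n_rn   n_u n_pred  n_sv n_sv_neighbors pred_max_value pred_min_value
#>       <int> <int> <int>  <int> <int>          <int>          <dbl>          <dbl>
#> 1         1   108   285     72    34              2         -0.977          -1.09
#> 2         2   146   213     72    37             37         -0.943          -0.996
#> 3         3   148   141     72    38             38         -0.864          -1.00

cv <- pup_cross_validate(model)
print(cv)
#> 10-fold stratified cross-validation (pooled)
#>   Sn 0.6944  Sp 0.9932  ACC 0.9348  MCC 0.7832  AUC 0.9951

rank_unlabeled_sites(model, windows, top_n = 5)
#> # A tibble: 5 × 3
#>   protein_id position score
#>   <chr>         <int> <dbl>
#> 1 syn016           50 1.33
#> 2 syn066           28 1.16
#> 3 syn024           68 0.714
#> 4 syn051           15 0.704
#> 5 syn041          138 0.642
```

Reading this run: starting from 36 annotated sites and 429 unlabeled
lysines, three expansion iterations admitted 72 new reliable negatives each
(every admitted decision value below −0.25, per the `pred_max_value`
column) and stopped once the unlabeled pool (141) fell below 4·|P| = 144.
The pooled cross-validated AUC of the final positive-vs-reliable-negative
problem is 0.995; sensitivity at the raw 0-cutoff is lower (0.69) because
the final training set is deliberately negative-heavy — ranking, not the
default cutoff, is the intended readout, which is why thresholds are
calibrated separately (`calibrate_thresholds()`). The top-ranked unlabeled
sites are the method's candidate unvalidated pupylation sites; scores are
SVM decision values (higher = more site-like, 0 = decision boundary).

The model object keeps its expansion history (`tidy(model$expansion)`,
`autoplot(model$expansion)`), the tuning grid (`model$tuning`), and
broom-style summaries (`glance(model)`, `tidy(model)`). The numbers above
are from the exact commands shown (seed 1); rerunning them reproduces the
output bit for bit.

## Command line

```sh
puplearn simulate --n-proteins 72 --seed 1 --out-prefix demo
puplearn train    --fasta demo.fasta --annotations demo_annotations.tsv --out model.rds --seed 1
puplearn predict  --model model.rds --fasta demo.fasta --out scores.tsv --top 20
puplearn cv       --fasta demo.fasta --annotations demo_annotations.tsv --out cv.tsv
puplearn rank     --model model.rds --fasta demo.fasta --annotations demo_annotations.tsv --top 20
```

(`exec/puplearn` after installation; every command writes a JSON run
manifest with input checksums and the seed.) To evaluate against a curated
pupylation corpus — e.g. the published training/test sets this method was
originally measured on — supply its FASTA and a `protein_id<TAB>site`
table to `train`/`cv`; those corpora are not redistributed here.

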