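---
title: "Positive-unlabeled learning for pupylation site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positive-unlabeled learning for pupylation site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puplearn)
```

## The problem

Pupylation is the covalent attachment of the prokaryotic ubiquitin-like
protein Pup to a substrate lysine, the bacterial counterpart of
ubiquitylation and a degradation signal in actinobacteria such as
*Mycobacterium tuberculosis*. Experimentally verified pupylation sites are
scarce, so sequence-based predictors are trained on the annotated sites as
positives. The usual shortcut — treating every *nonannotated* lysine as a
negative — is wrong in a specific, consequential way: the nonannotated pool
certainly contains real sites that simply have not been validated yet. A
classifier trained against that pool learns, in part, to call true sites
negative.

`puplearn` treats the task as it actually is: **positive-unlabeled (PU)
learning**. Annotated lysines form the positive set $P$; every other lysine
forms an unlabeled set $U$ that mixes hidden positives with true negatives.
The package mines a *reliable negative* set RN from $U$, trains a final
classifier on $P$ vs RN, and never pretends $U$ is clean.

## Sequence representation

Every lysine is represented by a window of 21 residues centred on it
(10 residues either side), padded with the placeholder `X` where a window
overhangs a terminus. Windows are encoded as the **composition of k-spaced
amino-acid pairs** (CKSAAP): for each gap $k \in \{0,1,2,3,4\}$, the count
of every ordered residue pair $(x, y)$ occurring at positions $(i, i+k+1)$,
divided by the number of such slots, $21 - k - 1$. Over the 21-symbol
alphabet (20 amino acids + `X`) this gives $441$ features per gap and
$5 \times 441 = 2205$ in total; each gap block is a composition summing
to 1. The padding symbol participates in pairs deliberately — proximity to
a terminus is itself signal, and a 21-symbol alphabet is what makes the
2205-dimensional feature space come out right.

Features are then ranked by the chi-square statistic of the
2×2 table of feature *presence* (value > 0) against class, with unlabeled
windows standing in for negatives during selection (selection happens
before any PU machinery, mirroring the feature-selection protocol of the
CKSAAP predictor family). The top 150 features are retained by default;
`backward_feature_elimination()` offers the full stepwise variant (drop the
50 lowest-ranked, re-score, repeat) when a caller supplies an evaluator,
but the fixed top-150 cut is the library default because the stepwise
search's own evaluation protocol is not fully determined and 150 is the
operating point of the predictor family this package belongs to.

## The three-stage algorithm

Let $P$ and $U$ be the positive and unlabeled feature rows.

**Stage 1 — initial reliable negatives.** Every $u \in U$ is scored by
$d(u) = \min_{p \in P} \lVert u - p \rVert$ and the $|P|$ rows with the
largest $d$ become $\mathrm{RN}^0$: the unlabeled samples least like any
known positive. The set objective "choose $N \subset U$, $|N| = |P|$,
maximising distance to $P$" is combinatorial; the per-sample greedy rule is
the standard reading and coincides with exhaustive search under the
summed-min-distance scoring (the test suite verifies this on hundreds of
small instances).

**Stage 2 — expansion with support-vector compression.** Iteratively:

1. train an RBF SVM $f^i$ on $P$ vs $\mathrm{RN}^i$;
2. score $U^i$; rows with decision value $< T$ (default $T = -0.25$)
   are candidate negatives $N^i_{\mathrm{pred}}$, truncated to the
   $\lfloor 2|P| \rfloor$ most negative to keep the classes balanced;
3. compress the old negatives to $N^i_{\mathrm{sv}}$, the negative-class
   support vectors of $f^i$, plus one nearest non-SV neighbour for each
   ($\tilde N^i_{\mathrm{sv}}$, same cardinality, chosen greedily without
   replacement, ties by ascending index);
4. $\mathrm{RN}^{i+1} = N^i_{\mathrm{pred}} \cup N^i_{\mathrm{sv}} \cup
   \tilde N^i_{\mathrm{sv}}$, $U^{i+1} = U^i \setminus N^i_{\mathrm{pred}}$;
5. stop when $|U^i| \le r|P|$ (default $r = 4$), when no candidate scores
   below $T$, or at a hard cap of 100 iterations (a safety valve; it has
   never been reached in testing and raises an error carrying the history
   rather than returning silently).

Keeping the support vectors *and* a neighbour for each (rather than the
support vectors alone, as the older PSoL-style expansion does) retains more
of the negative set's geometry; `rn_representation = "sv_only"` switches to
the ablated variant for comparison.

**Stage 3 — final classifier.** An RBF SVM on $P$ vs the final RN.

The SVM cost $C$ and kernel width $\gamma$ are tuned once, by exhaustive
grid search ($16 \times 16$ log-spaced values, $C \in [0.1, 10^4]$,
$\gamma \in [10^{-5}, 1]$) with stratified cross-validated AUC on $P$ vs
$\mathrm{RN}^0$, then frozen for the whole expansion and the final fit.
Ties resolve to the smallest $C$, then the smallest $\gamma$. Tuning
happens on $P$ vs $\mathrm{RN}^0$ because that is the first two-class
problem the algorithm possesses; the data on which the original grid search
was run is not fully specified, and this choice is logged in the model's
provenance. Features are compositions in $[0,1]$ and are deliberately *not*
rescaled: the admission threshold $T = -0.25$ is defined on the decision
values of the SVM fitted in this space, and rescaling would silently change
its meaning. For the same reason no class weighting is applied inside the
SVM — imbalance is handled structurally by the $2|P|$ cap.

## Evaluation

`compute_metrics()` reports sensitivity, specificity, accuracy, Matthews
correlation and AUC from the confusion counts of the strict rule
`score > threshold`:

$$\mathrm{Sn} = \frac{TP}{TP+FN},\quad
  \mathrm{Sp} = \frac{TN}{TN+FP},\quad
  \mathrm{ACC} = \frac{TP+TN}{TP+FP+TN+FN},$$
$$\mathrm{MCC} = \frac{TP \times TN - FN \times FP}
  {\sqrt{(TP+FN)(TN+FP)(TP+FP)(TN+FN)}}.$$

MCC is reported as 0 (and flagged) when any denominator factor vanishes.
AUC is the rank-statistic (Mann–Whitney) estimator with midrank tie
handling, so it is threshold-free and exactly equals the probability that a
random positive outranks a random negative. Cross-validation is stratified
and *pooled*: held-out decision values from all folds are concatenated and
a single confusion table is formed (per-fold rows are also returned).
Pooling was chosen over fold-averaging because a single summary table is
reported; both are available from the returned object.

Named confidence tiers (high/medium/low) are supported either as fixed
cutoffs or via `calibrate_thresholds()`, which finds the smallest cutoff
achieving a requested training-set specificity — a reproducible mechanism
for stringency tiers whose published derivation is unstated.

## What the synthetic generator emulates — and what it does not

`simulate_proteome()` exists so that the entire pipeline can be exercised,
end to end, without downloading anything. It draws sequences i.i.d. from a
SwissProt-like residue composition, plants true sites at lysines, imposes a
motif around each true site, and *annotates only half of them* — the other
half stay hidden inside the unlabeled pool, which is precisely the PU
contamination the method exists to survive.

Default conditions, chosen once:

| parameter | default | why |
|---|---|---|
| `n_proteins` | 72 | with `site_rate` below, gives an unlabeled:positive ratio near 12:1, the shape of the real training corpora this method targets (~180 annotated vs ~2250 nonannotated lysines) |
| `length_range` | 60–160 | short bacterial-protein-like lengths; keeps a single-CPU benchmark run in minutes |
| `background` | SwissProt-like frequencies | lysine at ~5.8% yields a realistic density of candidate sites |
| `site_rate` | 0.15 | see `n_proteins` |
| `annotation_rate` | 0.5 | half of the true sites are hidden — a deliberately harsh PU setting |
| motif | E at −4, W at −2, D at +1, R at +3 (weights 0.90–0.95) | a strong, fixed-offset preference; fixed offsets induce exactly the k-spaced pair enrichment CKSAAP measures, and W is rare in background so the signal is unambiguous |

What the generator does **not** emulate: real mycobacterial proteome
composition, domain structure, homology between proteins (every sequence is
independent), degenerate or probabilistic motifs spread over many weak
positions, and annotation bias (real annotations cluster on well-studied
proteins; simulated ones are sampled uniformly). Passing the synthetic
benchmark therefore shows the machinery is correct and that the method
recovers hidden positives *when the signal it assumes is present*; it does
not certify performance on real proteomes, where the published evaluations
on curated datasets remain the reference.

## The synthetic benchmark

`run_pu_benchmark(seed)` runs the study design end to end: simulate under
the defaults above, hold out 30% of proteins, train the full pipeline and
the balanced-negative baseline (`baseline_svm_balance()`, which samples
$|P|$ unlabeled rows as "negatives" — contaminated by construction) on the
same training windows, then score both against *ground truth* (annotated
and hidden sites alike) on the held-out proteins. It also compares the mean
final-model score of hidden positives vs true negatives in the training
pool. The test suite runs seeds 0–9 and asserts that the PU pipeline beats
the baseline in at least 8 of 10 replicates and scores hidden positives
above true negatives in all of them. Problem sizes (72 proteins, ~450
windows, ~25 positives per replicate) were fixed once as a realistic small
corpus that a single CPU works through in a few minutes.

Two behaviours of this benchmark are worth knowing before reading its
results. First, a motif this strong pushes *both* methods towards an AUC
ceiling on held-out proteins: when either model can separate sites almost
perfectly, the baseline's contaminated negative sample costs it very
little, and the per-replicate AUC comparison becomes a near-tie decided in
the third or fourth decimal. The hidden-vs-negative score separation is
the more discriminating readout under these conditions. Second, the
max-distance stage-1 rule has a known failure mode that the generator can
reproduce: on some draws the windows farthest from every positive are
compositional outliers (e.g. terminus-padded windows), the first SVM then
learns "typical composition = positive", scores most of the unlabeled pool
positive, no candidate ever crosses \(T\), and the pipeline silently
degrades to stage 1 + stage 3. The expansion history (zero iterations,
`stopped = "no_candidates"`) makes this visible when it happens.

## Numerical choices and degenerate inputs

- Feature order is deterministic (gap ascending, then first and second
  residue in a fixed alphabet), so serialized models are portable; loading
  a model verifies feature names and scoring fails loudly on mismatch.
- Chi-square ranking breaks ties by ascending column index; Stage-1
  selection and neighbour assignment break distance ties by ascending row
  index; grid-search ties keep the smallest $(C, \gamma)$. With a fixed
  seed the whole pipeline is bit-reproducible, which the tests assert.
- The stop test uses $\le$ (`|U| <= r|P|`), and the candidate cap uses
  $\le \lfloor 2|P| \rfloor$.
- A protein with no lysine yields no windows; an empty window set, a
  single-class training set, and an annotation pointing at a non-lysine are
  all hard errors, not silent coercions.
- Cross-validation and tuning reduce their fold count (with a warning)
  when a class is smaller than the requested folds.
- On very easy tuning problems many grid points tie at cross-validated
  AUC 1, and some tied pairs underfit so heavily that every decision value
  is numerically near zero — a scale on which the admission threshold
  $T = -0.25$ could never be crossed and the expansion would be inert.
  Because $T$ is defined on the canonical libsvm decision-value scale
  (margins at $\pm 1$), AUC ties are resolved by preferring pairs whose
  held-out decision values attain that scale (reach $-1$), then pairs
  where $T$ is at least reachable, then the smallest $C$ and $\gamma$.
  `tune_svm_params()` returns the full grid with each pair's minimum
  held-out decision value so the choice is auditable.

## Known limitations

- The RBF SVM decision value is not a calibrated probability; thresholds
  are meaningful only relative to the training geometry.
- Only the RBF kernel and the CKSAAP encoding are implemented; profile or
  physicochemical encodings are out of scope.
- Published performance tables for this method were measured on a curated
  external corpus that is not redistributed here; `puplearn` reproduces the
  *procedure*, and the CLI will reproduce those numbers when pointed at
  that corpus (`puplearn train/cv` on the corresponding FASTA and site
  table).

## A worked run

```{r, eval = FALSE}
library(puplearn)

sim <- simulate_proteome(simulation_config(seed = 1))
windows <- extract_windows(sim$proteins, sim$annotations)
model <- pup_train(windows, pu_config(seed = 1))
glance(model)

cv <- pup_cross_validate(model)
glance(cv)
autoplot(cv)

rank_unlabeled_sites(model, windows, top_n = 20)
```

Each step is a plain function over tibbles, so the pieces recombine: swap
`baseline_svm_balance()` in for stage 2+3, pass
`pu_config(rn_representation = "sv_only")` for the ablated compression, or
feed `extract_windows()` from your own FASTA via `read_fasta()` and
`read_annotations()`.
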