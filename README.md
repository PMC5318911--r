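# rhsac

Supervised discovery of miRNA–mRNA regulatory modules from paired
case/control expression data, built around rough-hypercuboid supervised
attribute clustering (RH-SAC), plus signed-network motif analysis and a
kinetic model of coherent feedforward-loop repression of p21.

## Who this is for

Computational biologists with a small two-class expression study —
typically a handful of tumor/normal tissue pairs profiled for both
miRNAs and mRNAs — who want groups of co-informative markers, not
single-gene hit lists, and want those groups wired together into
regulatory modules supported by a miRNA→target interaction table
(miRTarBase-style TSV).

## The method in brief

For a feature set and class labels, each class spans an axis-aligned
*hypercuboid* between its per-feature min and max. Samples falling in
more than one class box are *confused*, and the dependency (relevance)
of the feature set is

    γ = 1 − (1/n) Σ_j v_j,   v_j ∈ {0,1} flags confusion of sample j,

so γ = 1 iff the class boxes are disjoint. Features are clustered
greedily: the most relevant remaining feature seeds a rule; features
whose supervised similarity (Dice-normalized shared dependency
S = 2(γ₁+γ₂−γ₁₂)/(γ₁+γ₂)) strictly exceeds the radius δ = 0.9 form its
coarse cluster; a finer subset is averaged — possibly sign-flipped — into
the rule's representative while that strictly improves
(relevance, class-separation margin); seed and coarse cluster leave the
pool. Rules whose representative achieves 100% leave-one-out
cross-validated accuracy with a linear-kernel SVM (C = 1) and have ≥ 2
members are selected. For each selected miRNA rule the mRNA matrix is
reduced to the rule's recorded targets and clustered the same way;
selected rules from both sides form a module whose edges are the
table-supported (miRNA, gene) pairs with Pearson correlations.

Module genes can be grown into a signed TF/miRNA/gene network
(expansion, four-pass pruning), scanned for coherent/incoherent
feedforward loops and positive/negative feedback cycles, and condensed
to the 3% most differentially altered interactions. `ffl_model()`
implements the triple coherent feedforward loop in which one miRNA
represses SP1, SP3 and p53, which are all required for p21 expression:
each direct target scales by R(φ) = (1+a)/(1+aφ) under a φ-fold miRNA
increase, and p21 by R(φ)³ — mild 20% target repression at 100-fold
amplifies to ~70% p21 repression at 200-fold.

A synthetic-data generator (`synth_expression()`) emulates the paired
8+8-sample, 126-miRNA design with planted co-expressed differential
clusters and signed planted regulation, with full ground truth for
validation.

## Worked example

```r
library(rhsac)

d  <- synth_expression(synth_config(seed = 42))   # matrices + target table + truth
pl <- run_pipeline(d$mirna, d$mrna, d$targets)
pl
#> miRNA-mRNA module discovery pipeline
#>                 stage   n
#>        mirna_features 126
#>           mirna_rules  50
#>  mirna_rules_selected   1
#>   mrna_rules_selected   1
#>               modules   1
#>          module_edges 130

head(pl$mirna_eval[order(-pl$mirna_eval$selected, -pl$mirna_eval$loocv_accuracy), ], 3)
#>  rule_id loocv_accuracy cv10_accuracy n_members selected
#>        1         100.00        100.00        14     TRUE
#>        2          87.50         87.50         1    FALSE
#>        5          81.25         87.50         2    FALSE

count_correlation_signs(pl$modules[[1]]$edges$pearson_r)
#> n_positive n_negative
#>         75         55

planted_edge_recall(pl$modules, d$truth)
#> [1] 0.8666667
```

The three planted miRNA clusters separate the classes so strongly that
they merge into one selected 14-member rule (100% LOOCV); its module
recovers 87% of the planted regulatory edges, with the mixture of
negative and positive correlations reflecting the planted sign mix.

The kinetic model's dose response:

```r
dose_response_grid(ffl_model(), mir_folds = c(100, 200), dd_levels = 1)
#>  mir_fold dd species steady_state  relative
#>       100  1     SP1    0.8000000 0.8000000   # 20% repression
#>       100  1     P53    1.6000000 0.8000000
#>       200  1     P21    0.5896097 0.2948049   # ~70% repression
```

(abridged; `relative` is normalized to the basal-miRNA state at the same
DNA damage level).

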