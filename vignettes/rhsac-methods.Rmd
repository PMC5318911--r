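---
title: "Methods: rough-hypercuboid supervised clustering and miRNA-mRNA module discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rough-hypercuboid supervised clustering and miRNA-mRNA module discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhsac)
```

# The problem

Paired case/control expression studies of microRNAs and mRNAs — e.g. a
small series of tumors with matched adjacent normal tissue — call for more
than single-marker testing: microRNAs act in functionally related groups,
and their regulatory effect is visible in the joint behaviour of a cluster
of targets. `rhsac` implements a two-step, supervised route to
miRNA–mRNA regulatory modules:

1. cluster the miRNA features into *rules* — groups of co-informative
   miRNAs whose averaged expression profile separates the two sample
   classes — and keep only rules whose representative classifies every
   sample correctly under leave-one-out cross-validation;
2. for each kept miRNA rule, restrict the mRNA matrix to recorded targets
   of the rule's miRNAs, cluster that reduced matrix the same way, keep
   the mRNA rules the same way, and join both sides into a module whose
   edges are the target-table-supported (miRNA, gene) pairs, annotated
   with Pearson correlations.

Downstream, the package expands module genes into a signed regulatory
network, prunes it, takes a census of feedforward and feedback motifs,
condenses edges by expression contrast, and provides a kinetic model of
the coherent feedforward loop through which a single miRNA can strongly
repress p21.

# The rough-hypercuboid dependency measure

For a feature (or a set of features evaluated jointly) and a class label
per sample, each class spans an axis-aligned box: the closed interval
between the class-wise minimum and maximum in every feature dimension.
Boundary values are inside the box — the class extremes are class
members, so membership tests are pure order comparisons with no epsilon.
A sample that falls inside more than one class box is *confused*; with
$v_j \in \{0,1\}$ flagging confusion of sample $j$, the dependency
(relevance) of the feature set is

$$\gamma = 1 - \frac{1}{n}\sum_j v_j .$$

$\gamma = 1$ iff the class boxes are disjoint over the observed samples;
$\gamma = 0$ for a constant feature with two or more classes. Adding a
feature can only shrink boxes, so $\gamma$ is monotone non-decreasing
under feature addition — both properties are exercised as property tests
on 1000 random instances.

Two practical consequences of this definition shape the design choices
below. First, $\gamma$ is *quantized*: it moves in steps of $1/n$, and a
single sample straying into the other class's range confuses itself
*and* at least one opposite-class sample, so with 16 samples a feature
jumps from $\gamma = 1$ to $\gamma = 0.875$. Second, $\gamma$
*saturates*: once boxes are disjoint nothing can increase it.

## Supervised similarity

The coarse clustering step needs a similarity between two features
relative to the classification task. We use redundancy — the dependency
counted twice by the two single features but only once jointly —
normalized in the Sørensen–Dice form:

$$S(f_1, f_2) = \max\!\left\{0,\;
  \frac{2\,(\gamma_1 + \gamma_2 - \gamma_{12})}{\gamma_1 + \gamma_2}
  \right\},$$

with $S = 0$ whenever either relevance is zero. $S \in [0,1]$, $S = 1$
exactly for features carrying identical dependency (a duplicated
feature), and $S = 0$ for fully complementary features whose joint box
structure separates classes that neither separates alone.

The normalizer matters. Dividing by $\min(\gamma_1, \gamma_2)$ — a
natural first choice — is degenerate: if any feature fully separates the
classes ($\gamma_1 = 1$ forces $\gamma_{12} = 1$), *every* other feature
scores $S = 1$ against it and the first cluster absorbs the entire
feature pool. Dividing by $\max(\gamma_1,\gamma_2)$ avoids that but
interacts badly with quantization: against a $\gamma = 1$ seed it reduces
to $S = \gamma_2$, so the single-stray features at $\gamma = 0.875$ fall
under a radius of $\delta = 0.9$ — a cliff, not a radius. The Dice form
reduces to $S = 2\gamma_2/(1+\gamma_2)$ in that regime, which degrades
smoothly and keeps one-stray features inside the default radius while
still excluding noise.

# The clustering algorithm

`rhsac()` is greedy and fully deterministic:

1. standardize the matrix (per sample by default: each sample column to
   zero mean, unit variance with the $n-1$ divisor; zero-variance units
   become all-zero with a warning);
2. compute $\gamma$ for every feature;
3. seed a cluster with the most relevant remaining feature (ties by
   input order);
4. form the *coarse cluster*: every remaining feature with
   $S(\text{seed}, f) > \delta$, strictly;
5. *refine*: repeatedly average one coarse member — or its complement,
   the negated profile, so anti-correlated members reinforce rather than
   cancel — into the running signed mean, adopting at each pass the
   single candidate that most improves the pair
   (relevance, class-separation margin) in lexicographic order, and
   stopping when no candidate strictly improves it;
6. emit the rule (seed, coarse members, finer members with signs,
   representative, relevance) and remove the seed and the whole coarse
   cluster from the pool;
7. repeat until the pool is empty or `max_clusters` rules exist.

The *margin* in step 5 is the smallest pairwise gap between class value
ranges of the representative (negative under overlap). It is the
tie-breaker that keeps refinement meaningful where $\gamma$ saturates: a
strong seed with $\gamma = 1$ cannot gain relevance, but averaging a
genuinely co-informative member still widens the gap between the class
ranges, while an exact duplicate changes nothing (and is therefore never
admitted) and a noise feature narrows the gap (likewise rejected). The
representative is the plain arithmetic mean of the signed standardized
member profiles and is never re-standardized.

A rule's *members* — the set used for counting, target lookup and module
edges — are the seed plus the coarse cluster: the coarse cluster is the
cluster; the finer subset exists to sharpen the representative.

Tunable parameters, all exposed with these defaults: `delta = 0.9`
(cluster radius on the $[0,1]$ similarity scale), `max_clusters = 50`,
`standardize_mode = "sample"`.

# Rule selection

Each rule is scored by its one-dimensional representative with a
soft-margin linear-kernel SVM (`e1071`, $C = 1$, no rescaling — the
input is already standardized) under leave-one-out cross-validation and,
optionally, stratified 10-fold cross-validation. Stratification matters
at 16 samples: unstratified folds can be single-class. Fold assignment
is drawn from a dedicated seed (default 42) without touching the
session RNG, so evaluations are reproducible and identical runs are
byte-identical. A rule is *selected* when its LOOCV accuracy is exactly
100% and it has at least two members; single-feature rules are excluded
regardless of accuracy. When a training fold degenerates to one class,
the classifier predicts that class.

# Module assembly and statistics

For each selected miRNA rule, the mRNA matrix — standardized once as a
whole, per sample; the per-rule reductions are row subsets and are not
re-standardized — is reduced to the union of recorded targets of the
rule's member miRNAs (identifiers matched case-insensitively after
whitespace stripping; targets absent from the matrix are dropped with a
logged count). The reduced matrix is clustered and selected identically.
A module joins the miRNA rule with its selected mRNA rules; its edges
are exactly the (miRNA, gene) pairs present in the target table, each
annotated with the Pearson correlation of the two expression profiles
across all samples (undefined for zero-variance profiles, recorded as
missing). miRNAs without selected targets stay as isolated module nodes.

Gene-set overlap against a reference list in a finite universe uses
Fisher's exact test with the two-sided minimum-likelihood rule: the sum
of hypergeometric point probabilities not exceeding the observed table's
probability (relative tolerance $1 + 10^{-7}$). The implementation is a
direct hypergeometric enumeration; the test suite checks it against
`stats::fisher.test` exhaustively for small tables and on randomized
tables up to $n = 200$.

# Network tools

Signed directed networks carry typed nodes (miRNA / gene / TF, with seed
flags) and edges signed $+1$ (activation), $-1$ (repression) or $0$
(unknown). Expansion from a seed set takes all interactions among seeds
(layer 0) and, per layer, all interactions incident to current nodes.
Pruning applies four passes, each once (a `fixpoint` flag iterates):
drop non-seed nodes of total degree $\le 1$; drop non-seed miRNAs; drop
nodes not adjacent to a seed; drop non-seed nodes of degree $\le 1$
again. Degree is in-degree plus out-degree; seeds are never removed.

The motif census enumerates feedforward loops (ordered triples
$r \to i \to t$ with shortcut $r \to t$; *coherent* iff the sign of the
shortcut equals the product along the path) and simple directed cycles
of length 2–3 (*positive* iff the edge-sign product is $+1$). Motifs
containing an unknown sign are reported with an undefined coherence and
excluded from coherent counts. The suite verifies the census against an
independent closed-walk-algebra oracle on 100 random graphs of up to 40
nodes.

Condensation contrasts, per edge, the product of the endpoints' mean
log2 expression between conditions,
$score = \bar{x}^{case}_s\bar{x}^{case}_t -
\bar{x}^{ctrl}_s\bar{x}^{ctrl}_t$; the lowest and highest
`keep_quantile` (default 3%) fractions of scores are kept (ties by edge
order, zero scores never kept), positive scores read as "startup" and
negative as "shutdown" of the interaction.

# The kinetic feedforward-loop model

`ffl_model()` encodes the circuit in which one miRNA represses, in
parallel, the transcription factors SP1 and SP3 and the tumor suppressor
p53, while p21 transcription requires all three. Each protein has linear
synthesis and first-order degradation; miRNA repression multiplies the
target's degradation rate by $(1 + a\,\phi)$ with $\phi$ the miRNA fold
over basal; DNA damage adds linearly to p53 synthesis; and p21 synthesis
is proportional to the product $p53 \cdot SP1 \cdot SP3$ — a strict AND,
which is what turns three mild parallel repressions into one strong p21
repression. Every steady state at basal inputs is normalized to 1.

At steady state each direct target scales by
$R(\phi) = (1 + a)/(1 + a\phi)$ and p21 by $R(\phi)^3$ (DNA damage
cancels in the ratio, so "moderate damage" is any positive level). The
single repression parameter is frozen at $a = 0.2/79$, the value at
which a 100-fold miRNA increase represses each direct target by 20%;
the resulting triple-loop amplification — about 70% p21 repression at
200-fold — is then a prediction of the structure, not a fitted number.
Simulation uses `deSolve::ode` from the basal fixed point; steady state
is declared when the largest derivative magnitude falls below $10^{-9}$
(warning at the `t_end` cap otherwise). Degradation rates default to
0.5/h, making the slowest relaxation time about 2 h; the grid
integrates to 500 h, far past equilibration.

# The synthetic-data generator

`synth_expression()` emulates the target study design: `n_pairs = 8`
tumor/normal pairs (16 samples), `n_mirna = 126` miRNA features,
`n_mrna = 2000` mRNA features on the log2 scale, with 3 planted
co-expressed differential miRNA clusters of 5 members and 10 target
mRNAs each. Planted miRNA features get a class-mean shift of
`effect_size` (direction alternating per cluster) plus noise of total
standard deviation `noise_sd`. `within_cluster_rho` is the *pooled*
(both classes together) pairwise correlation target: the class shift
itself contributes $\mathrm{effect}^2/4$ of shared variance, and a
shared latent factor supplies any remainder —
$\sigma^2_{shared} = \max\{0,\ \rho\,(\mathrm{effect}^2/4 +
\mathrm{noise}^2) - \mathrm{effect}^2/4\}$ — with the rest idiosyncratic
per feature. At the default settings (effect 2, $\rho$ 0.8, noise 0.5)
the shift alone reaches the target correlation, so cluster noise is
purely idiosyncratic. Planted target mRNAs follow their cluster's class
signal times a per-gene sign (negative with probability
`regulation_sign_mix = 0.6`, reflecting the predominance of repressive
miRNA action with a sizeable positively-correlated minority) with unit
coupling plus fresh noise; the target table holds every planted pair
plus 50% decoy pairs into background genes. Background features are
pure noise. Everything is deterministic given `seed`, and ground truth
(cluster membership, signed edges, differential flags) is returned
alongside.

What the generator does *not* emulate: probe-level array noise, batch
and pairing effects (pairing is recorded but the classifiers treat
samples as independent, as the pipeline itself does), heavy-tailed
intensity distributions, correlated decoy targets, and the full
43k-probe scale (configurable upward). Passing recovery tests therefore
show that the algorithmic chain recovers planted co-expression and
regulation under Gaussian noise at the study's sample size — not that it
would do so under every real-array artefact.

`synth_network()` plants a stated number of coherent feedforward loops
and positive feedback loops on disjoint node sets, optionally salted
with random edges, for exact-truth motif tests.

# Validation design and problem sizes

The test suite (all fixtures generated in code) runs, among others:
relevance bounds and monotonicity on 1000 random instances; similarity
against a first-principles recomputation on 1000 instances; refinement
against an exhaustive greedy-trace oracle; motif censuses against a
closed-walk oracle on 100 random graphs of 8–40 nodes; Fisher p-values
against `stats::fisher.test` exhaustively for $n \le 20$ and sampled up
to $n = 200$; pipeline recovery on 10 generated data sets at the
default recoverable settings with the bar at cluster and edge recall
$\ge 0.8$ on at least 8 of them; a 20-seed null (effect 0) requiring on
average at most 0.5 selected rules; and byte-identical re-runs. The
same quantities are recomputed from scratch by
`scripts/acceptance.R`.

# Known limitations

* The dependency measure is interval-based: a single outlying sample
  reshapes a class box, and at $n = 16$ the measure moves in steps of
  $2/16$. The margin tie-break mitigates, but cannot remove, this
  granularity.
* With very strong effects many features fully separate the classes and
  the similarity can no longer rank them; coarse clusters then merge
  co-informative features across planted groups. Recall is unaffected
  but cluster purity is not guaranteed.
* Selection demands *exactly* 100% LOOCV accuracy, which at 16 samples
  is a high-variance criterion; rules near the boundary flicker between
  seeds.
* The condensation score uses products of mean log2 expressions, so its
  scale depends on the normalization of the input summaries; only the
  extreme-quantile ranks are interpreted.
* The kinetic model is deliberately minimal — linear kinetics, no p53
  pulsing, no transcriptional delay — and makes no claim beyond the
  steady-state dose-response structure of the triple coherent loop.
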