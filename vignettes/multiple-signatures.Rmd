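---
title: "Dissecting molecular signature multiplicity with Markov boundaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting molecular signature multiplicity with Markov boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-throughput studies routinely report that many different, similarly
sized gene sets predict the same phenotype equally well — and that two
laboratories analyzing the same disease publish nearly disjoint signatures.
`tiestar` treats this *signature multiplicity* not as noise to be averaged
away but as a property of the underlying joint distribution to be
enumerated. The organizing idea is that the maximally predictive and
non-redundant signatures of a phenotype `T` are exactly its **Markov
boundaries**: variable sets `M` such that every other variable is
independent of `T` given `M` (a Markov blanket) and no proper subset of `M`
is itself a blanket (minimality). When the distribution violates the
intersection property, several distinct boundaries can coexist — and they
persist at any sample size, so multiplicity is not merely a small-sample
artifact.

## The algorithm

`tie_star()` turns any single-boundary inducer into an exhaustive
multiple-boundary extractor:

1. Run the base inducer on the full data; the result `M` is the reference
   signature.
2. Generate a subset `G` of the variables appearing in signatures found so
   far, and re-run the inducer on the data with `G` withheld.
3. If the new signature is predictively equivalent to `M`, output it;
   otherwise mark `G` as a dead end.
4. Repeat until no new `G` can be generated (or a configured cap is hit).

The subset generator (`new_subset_state()` / `generate_next_subset()`)
enumerates subsets of the growing union of discovered-signature variables
in order of increasing cardinality, lexicographic within a cardinality,
never repeats a subset, and prunes every superset of a dead end. The
pruning is what makes the search practical: on the 30-variable benchmark
design below, 8,191 subsets of the 13-variable union collapse to about
1,300 generated subsets. With conditional-independence answers taken from
the exact distribution (`oracle_ci()`), the procedure provably returns the
same boundary set as exhaustive enumeration
(`enumerate_markov_boundaries_exact()`); the package tests assert this
equivalence on randomized small networks.

The base inducer is **HITON-PC** (`hiton_pc()`), a semi-interleaved local
discovery algorithm from the Generalized Local Learning family: candidates
unconditionally associated with `T` (at `alpha`) are admitted in order of
association strength; after each admission any tentative member rendered
independent of `T` by a conditioning subset of the other members (size at
most `max_k`) is discarded; a final backward pass re-checks every member.
Eliminated candidates are discarded permanently, and all ties are broken by
ascending variable name, so runs are exactly reproducible. The univariate
admission screen doubles as the pre-filter that keeps the algorithm
tractable at 1,000 variables: `make_base_inducer()` memoizes it per
dataset, since withholding variables never changes univariate associations.

## Conditional-independence testing

Discrete data use the G² likelihood-ratio test (`g2_test()`), with degrees
of freedom `(|x|-1)(|t|-1)` per *nonempty* conditioning stratum — empty
strata contribute neither to the statistic nor to the degrees of freedom.
A test counts as **reliable** only when the average sample per contingency
cell is at least `h = 5`; unreliable tests are treated as "dependence not
established", never as evidence of dependence. This convention does real
work in three places:

* inside HITON-PC, it stops sparse high-order tests from spuriously
  eliminating true members;
* inside KIAMB, it is the honest accounting of that algorithm's appetite
  for sample (see below);
* inside the equivalence check, it dictates the check's very shape.

On the last point: the natural equivalence test — "is every reference
variable absent from the new signature independent of `T` given the whole
new signature?" — conditions on all of `M_new`. For a six-member ternary
signature that is a 729-stratum table, unreliable at any realistic sample
size, which would reduce the check to a rubber stamp. `check_equivalence()`
therefore screens each variable with conditioning sets drawn from `M_new`:
all subsets up to `max_k`, plus `M_new` itself whenever that test is
reliable (it always is in exact-oracle mode). A variable is screened off as
soon as one *reliable* test fails to reject at `alpha_equiv`. Because a
truly redundant variable has many separating subsets, the probability of
falsely declaring it dependent is far below `alpha_equiv` — important
because a single false dead end would prune away a whole branch of
boundaries. Continuous data use the Fisher-z test on partial correlations
(`fisher_z_test()`) throughout; the dispatch is decided once per dataset
from the declared column kinds.

A second, predictivity-based equivalence criterion is available
(`tie_config(equivalence_criterion = "predictivity")`): repeated-holdout
AUC samples of the two signatures compared by a two-sided Wilcoxon rank-sum
test at `alpha_equiv`, plus a guard that the new signature's mean AUC is
not more than 0.05 below the reference. The independence criterion is the
default for discrete simulations (cheap, matches the Markov-blanket
semantics exactly); the predictivity criterion is the natural choice for
real-valued expression data, where classifier performance is the quantity
of scientific interest.

## The synthetic benchmark generator

`build_multiplicity_network()` constructs discrete Bayesian networks whose
full boundary set is known *by construction*, which is what makes exact
end-to-end acceptance testing possible. For each group `i`, a hidden source
`S_i` takes `classes_per_group` equally likely classes. Each observed
member of the group encodes the class of its source exactly (disjoint
symbol blocks per class) but is re-randomized within the block
independently of its siblings — members of a group are therefore
informationally equivalent without being deterministic copies, the same
mechanism that makes `A` and `B` interchangeable in the three-gene pathway
example of `build_pathway_network()`. The binary phenotype is a majority vote
over the class vector, flipped with probability `target_noise`.

Design choices worth recording:

* **Majority vote, not parity.** Any function of the class vector yields
  `prod(group_sizes)` boundaries, but a parity-like function has zero
  univariate signal and would defeat every admission-ranked inducer (and
  any single-gene association screen a biologist would run). The majority
  vote keeps every group marginally associated with the phenotype and
  every group pivotal with positive probability, which is also what makes
  each boundary minimal.
* **Defaults are the benchmark conditions.** Group sizes `[1,3,3,2,2,2]`
  (72 boundaries, 13 signal variables), 17 noise variables for the
  30-variable design or 987 for the 1,000-variable design, 10% label
  noise, `n = 3000`, `alpha = 0.05`, `max_k = 3`. The singleton group
  plants one variable in *every* boundary — the configuration that defeats
  iterative removal.
* **Hidden sources never reach datasets**, so the ground-truth boundaries
  consist of observed members only.
* **Noise marginals** are drawn from a seeded Gamma(5) normalization so
  noise variables are not all uniform.

What the generator does *not* emulate: continuous expression scales,
measurement error on the predictors, correlated noise between unrelated
genes, platform or batch effects, and the tens of thousands of probes of a
real microarray. Passing tests on these fixtures therefore demonstrate the
algorithmic claims — completeness, soundness, persistence of multiplicity,
baseline failure modes — not robustness to real-data nuisance structure.

## Baselines

Three comparison families ship behind the same inducer contract:

* `iterative_removal()` — re-run the inducer after deleting all previously
  found signature variables; stops when the new signature is empty or its
  holdout AUC falls statistically below the first signature's (Wilcoxon at
  `alpha_stop`, mean lower). Its outputs are disjoint by construction, so
  it finds exactly one signature whenever all boundaries share a variable.
* `resampling_extraction()` — the bootstrap family; it addresses only
  small-sample multiplicity, and its unique-signature count shrinks as
  `n` grows.
* `kiamb()` — randomized IAMB; its forward tests condition on the whole
  current blanket estimate, so its sample requirements grow with boundary
  size, and at small `n` the reliability rule leaves it stranded with
  fragments.

## Evaluation machinery

`auc_score()` is the Mann–Whitney pair statistic (ties counted half).
`repeated_holdout_auc()` estimates a signature's predictivity with a fixed
linear-kernel SVM (`e1071`, `cost = 1`, discrete predictors one-hot
encoded) over seeded random splits (default 10 splits, 30% held out). One
fixed regularization value and no nested tuning is deliberate: the claims
being tested require a classifier that can reach the minimum-error decision
function in large samples (the majority-vote designs are linearly separable
in one-hot coordinates, so a linear margin suffices), and tuning would blur
seeded reproducibility. AUC paths require a binary phenotype; the ternary
pathway example is evaluated through the independence machinery and the
exact oracle instead. `reproducibility_protocol()` implements the
discovery/validation design: per signature, holdout AUC on discovery data
(ε₁) against the AUC of the full-discovery model on independent validation
data (ε₂); the overfitting magnitude is the mean of ε₁ − ε₂.

## Numerical conventions and limitations

* Exact computations (`exact_joint()`, CMI, boundary enumeration) refuse
  state spaces beyond 10⁶ configurations rather than approximate;
  independence at the oracle is CMI below 10⁻⁹ nats.
* Canonical ordering everywhere: variables sorted by name within a
  signature, signatures sorted lexicographically; all stochastic entry
  points take explicit integer seeds.
* Test-suite problem sizes were chosen as the smallest that exercise each
  claim with clear statistical margins: `n = 3000` and `n = 10000` for the
  72-boundary design at 30 and 1,000 variables, `n = 5000` over 100 seeds
  for soundness, 1,000 replicates for test calibration.
* The boundary count is worst-case exponential in the number of variables;
  `max_subsets` (default 10⁵) caps a run explicitly and flags it `capped`
  rather than silently truncating.
* `hiton_pc()` assumes the local composition-style conditions under which
  the Generalized Local Learning family is correct; adversarial
  distributions (e.g. pure parity mechanisms) defeat it, as they defeat
  univariate screens generally.
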