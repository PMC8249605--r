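---
title: "Joint disaster victim identification: model and algorithms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint disaster victim identification: model and algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvimatch)
```

## The statistical model

A DVI problem has two sides. The post-mortem (PM) side is a set of
victim samples $V_1,\dots,V_s$ with known sex, each genotyped at a
panel of autosomal markers. The ante-mortem (AM) side is a collection
of reference families: pedigrees that contain one or more untyped
*missing persons* $M_1,\dots,M_m$ and at least one genotyped reference
member each. A candidate solution is an **assignment** $a$: a
sex-consistent partial one-to-one map from victims to missing persons.
We write assignments as tuples, e.g. $(M_2, *, M_3)$, where the $i$-th
entry names the match for $V_i$ and $*$ leaves $V_i$ unmatched. The
empty assignment $(*,\dots,*)$ is the null model: no victim belongs to
any family.

The likelihood of an assignment is the probability of *all* data given
the pairings it asserts,
$$L(a) = P(\mathrm{PM\ and\ AM\ data} \mid a, \Phi),$$
with $\Phi$ the fixed context: pedigrees, allele frequencies, mutation
model. Under $a$, each matched victim's genotypes are substituted into
the pedigree slot of its missing person; each unmatched victim
contributes its Hardy–Weinberg (HWE) genotype probabilities as an
unrelated singleton. Markers are assumed independent and in HWE, so
log-likelihoods add over markers. All ratios are reported against
$L_0$, the likelihood of the empty assignment.

### Exact pedigree likelihoods

Single-marker pedigree likelihoods are computed by Elston–Stewart-style
peeling, implemented as sum-product variable elimination over ordered
genotypes (paternal allele, maternal allele). Founders carry the HWE
prior $p_a p_b$; a child's state is generated by drawing one allele
from each parent, each transmission passing through the mutation
matrix. On loop-free pedigrees the elimination order follows the
nuclear-family structure and the cost is linear in pedigree size.
Looped pedigrees (e.g. consanguineous marriages) are detected on the
marriage graph and rejected explicitly; none of the target use cases
require them.

Three exact reductions keep the computation fast:

* **Trimming.** Untyped members without remaining descendants
  marginalize to 1 and are removed iteratively before peeling.
* **Allele lumping.** Alleles not observed in the marker's data are
  pooled into one synthetic allele carrying their total frequency.
  This is exact for the identity model trivially, and for the
  proportional model because its transition matrix is strongly
  lumpable (rows of pooled alleles agree on and off the pool).
* **Domain restriction.** A typed individual's genotype variable is
  restricted to the one or two ordered states consistent with its
  genotype before elimination, so factor tables stay small in
  data-rich pedigrees.

A brute-force likelihood (explicit summation over all genotype
combinations of untyped members) ships in the package as an
independent oracle; the test suite checks peeling against it on the
built-in problems and on hundreds of randomized loop-free pedigrees to
$10^{-10}$.

### Mutation model

Two transmission models are provided. `"none"` is the identity. The
`"proportional"` model sets $m_{ab} = \gamma p_b$ for $b \ne a$ and
$m_{aa} = 1 - \gamma(1-p_a)$, with
$\gamma = r / \sum_a p_a (1-p_a)$ so that the expected mutation rate
per transmission is exactly the nominal rate $r$ (unitless, per
transmission; forensic STR practice uses values near $10^{-3}$, the
package default in examples). This is the standard *stationary*
proportional model: the allele frequency vector is a left fixed point
of the matrix, so founder frequencies propagate unchanged — the
property that makes results comparable across implementations and
makes lumping exact. Construction rejects rates large enough to drive
a diagonal entry negative, naming the offending marker. The model is
applied to every parent-to-child transmission, reference-family and
victim-substituted alike; transmissions are where mutations happen,
regardless of which side of the problem the child sits on.

## Counting and enumerating assignments

With unknown sexes the number of assignments of $s$ victims to $m$
missing persons is $\sum_{k=0}^{\min(s,m)} \binom{s}{k}\binom{m}{k}k!$;
with known sexes the formula applies per sex class and multiplies.
This count is the feasibility diagnostic for exhaustive ranking — it
grows factorially, and the package computes it in exact integer
arithmetic (doubles are exact far beyond any enumerable size).
Enumeration itself is deterministic — recursion over victims, `*`
first, then missing persons in declaration order — so ranked output
files are stable across runs; ties in likelihood preserve this order.

## Search strategies

Pairwise LRs $LR_{ij}$ (pairing $V_i = M_j$ versus unrelated) are
computed on the *reduced problem* — $V_i$'s profile plus $M_j$'s family
only — which equals the full-data LR because all other victims and
families are unrelated under both hypotheses and their contributions
cancel. The identity is nevertheless re-verified numerically in the
test suite on every fixture and on random problems.

* **Sequential search** (with or without conditional updates of the
  matrix after each accepted pairing) mirrors the PM-driven strategies
  used operationally. They are included as baselines and for their
  failure modes: the static variant can never identify a missing
  person whose column is uninformative (a married-in relative), and
  even the updating variant can be an order of magnitude less likely
  than the joint optimum, as the built-in second example shows.
* **Combined search** first iterates the *undisputed* rule — accept
  $LR_{ij} \ge T$ when every other entry in row $i$ and column $j$ is
  at most 1 (strict) or at most $LR_{ij}/T$ (relaxed) — conditioning
  the problem after each round until it stabilizes, then enumerates
  the remaining assignments, drops those containing a pairing whose
  conditioned pairwise LR is 0, computes conditional joint likelihoods
  and ranks. Because the fixed victims' genotypes become reference
  data, the conditional log-likelihoods are numerically identical to
  full joint log-likelihoods of the merged assignments, which is how
  they are reported.

Tie handling is explicit throughout: two likelihoods tie when within
$10^{-9}$ relative; tied selection steps branch exhaustively and
distinct terminal assignments are all returned. Zero entries are never
selection candidates. The joint enumeration is capped (default
$10^6$); exceeding the cap is an error that advises lowering $T$ so
more pairings resolve as undisputed.

## Posterior pairing probabilities

Given an enumeration with likelihoods and a prior $\pi(a)$ (flat by
default, arbitrary non-negative weights accepted and renormalized),
$$q_{ij} = \frac{\sum_{a \ni V_i = M_j} L(a)\pi(a)}
                {\sum_a L(a)\pi(a)},$$
with $q_{i*}$ defined analogously over assignments leaving $V_i$
unmatched. Sums are accumulated in log space (log-sum-exp), so widely
separated likelihood magnitudes do not underflow. Rows sum to one, and
since the assignment sets $\{a : V_i = M_j\}$ are disjoint across
victims, $q_{ij} + q_{i'j} \le 1$: two victims can never both clear a
decision threshold $\alpha > 0.5$ for the same missing person, which
is why `classify_pairings()` refuses $\alpha \le 0.5$.

When the combined search has fixed undisputed pairings before
enumerating, the reported posteriors are *conditional* on those
pairings, which consequently appear with probability 1. This is a
deliberate design choice: the conditional space is the one actually
enumerated, and renormalizing over the full a-priori space would
require likelihoods for assignments that were excluded precisely
because they are impossible or resolved. Users who want full-space
posteriors can rank exhaustively with `rank_assignments()` — feasible
whenever the a-priori count is — and feed that to `posterior_table()`.

## Simulation design

`gene_drop()` samples founders from HWE and transmits alleles through
the mutation model, founders before descendants, markers in database
order, from a single seeded generator — runs are bit-reproducible.
`simulate_problem()` generates data conditional on a ground-truth
assignment: matched victims are dropped inside their families (in
their missing person's slot), unmatched victims as independent
singletons, and the typed references keep their dropped genotypes.

`tpr_experiment()` estimates true positive rates: the fraction of
replicates in which a strategy reports exactly the true assignment
(`tpr_unique`; `tpr_among` counts the truth among tied solutions —
both are reported because tie-handling conventions differ between
implementations, and `unique` is the stricter default). For the
thresholded joint strategy the threshold applies to the top
assignment's LR against the null; below it the method reports no
identifications, i.e. the empty assignment. `joint_best` scores the
most likely assignment regardless of the threshold.

The packaged power experiment uses the three-generation grandmother
structure of `dvi_example(2)` with a synthetic panel of ten markers,
ten equifrequent alleles each — a deliberately plain panel so that no
single marker is decisive — 200 replicates, and threshold
$T = 10^4$, evaluated at 1, 3, 5 and 10 markers. Those sizes give
binomial standard errors around 0.035, and the suite's ordering
assertions (joint ≥ updating sequential ≥ static sequential; joint TPR
non-decreasing in marker count) allow two standard errors of
Monte-Carlo slack. What passing shows: the joint method's advantage is
structural, not an artifact of the hand-picked single-marker
genotypes. What it does not show: absolute power on real panels —
real STR frequency spectra are skewed and more informative per marker,
and real casework adds duplicates, partial profiles and genotyping
error, none of which the generator emulates.

## Built-in problems

`dvi_example(1)` and `dvi_example(2)` are single-marker toy problems
small enough to verify by hand; every number they produce (pairwise
matrices, full rankings, posterior tables) is pinned in the test
suite at its display precision. `synthetic_crash_problem()` and
`synthetic_family_problem()` are structure-realistic synthetic
datasets — 8 victims against 5 one-missing-person families with
15 markers, and 5 victims against a 12-missing-person three-generation
family with 6 references and 13 markers (a-priori search space 9847) —
with genotypes gene-dropped under a recorded ground truth. They are
synthetic by construction and labelled as such; they exercise the
machinery at published-case scale without shipping any real data.

## Numerical conventions and limitations

* All likelihood work is in natural-log space; $-\infty$ is a
  first-class value (Mendelian exclusion without mutation), and LRs
  against the null map it to 0.
* Frequency databases must sum to 1 per marker within $10^{-6}$;
  deviations up to $10^{-3}$ may be renormalized under an explicit
  option, larger ones are always rejected. Allele labels are opaque
  strings; nothing is inferred from STR nomenclature.
* Genotypes are unordered (`"a/b"` equals `"b/a"`); `-` is missing;
  `*` is reserved for "no match" in assignments.
* Not covered: looped pedigrees, linked markers, X/Y/mtDNA, silent
  alleles, theta correction, stepwise mutation models, duplicate
  victim samples, and priors over pedigree structures. The prior hook
  in `posterior_table()` is the supported route for non-DNA evidence.
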