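---
title: "Base-pairing entropy under a stem-constrained ensemble: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Base-pairing entropy under a stem-constrained ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triple)
```

## The model

Structural non-coding RNAs are expected to fold with more certainty than
random sequences: their base-pairing probability mass concentrates on the
native pairs. The base-pairing Shannon entropy

$$Q(x) = -\frac{1}{n}\sum_{i<j} P_{ij}(x)\,\log P_{ij}(x)$$

summarizes this — $Q$ is zero when every pair probability is 0 or 1 and
grows as the mass spreads over alternatives. Entropies computed under the
standard thermodynamic (Boltzmann) ensemble discriminate some ncRNA
families well and others poorly. This package instead computes $P_{ij}$
under a *constrained* ensemble containing only structures whose stems are
plausible building blocks of a tertiary fold: every stem must carry at
least three consecutive canonical base pairs (Watson–Crick plus G–U
wobble). Under hierarchical-folding ideas, helices stabilize before
tertiary contacts form, so one- and two-pair "stems" are mostly spurious
alternatives that inflate the entropy of genuinely structured sequences.

The constrained ensemble is generated by a stochastic context-free grammar
with nonterminals $X$ (start), $H$, $Y$:

$$\begin{aligned}
&(1)\; X \to a \quad (2)\; X \to aX \quad (3)\; X \to aHb \quad (4)\; X \to aHbX\\
&(5)\; H \to aHb \quad (6)\; H \to aYb \quad (7)\; Y \to aXb
\end{aligned}$$

Opening a stem (rules 3/4) forces one pass through $H$ and $Y$, so each stem
has $\ge 3$ nested pairs; rule 5 extends a stem; rule 4 produces parallel
substructures. Span minima follow mechanically: $Y$ derives at least 3
positions, $H$ at least 5, and a pair-bearing $X$ expansion at least 7 —
consequently sequences shorter than 7 nt cannot pair at all and a hairpin
loop always contains at least one position.

Two emission distributions complete the model: unpaired bases (uniform
$1/4$ by default) and the six canonical ordered pairs (defaults
$0.25, 0.25, 0.17, 0.17, 0.08, 0.08$ for G-C, C-G, A-U, U-A, G-U, U-G; all
non-canonical pairs exactly 0). Each derivation's probability is the
product of its rule probabilities and one emission factor per emitted
terminal or pair — the standard SCFG semantics.

## Rule probabilities by maximum entropy

The rule probabilities are deliberately not trained on structure databases
(a certainty measure should not inherit a folding model's biases). Beyond
the normalization constraints $p_1+p_2+p_3+p_4=1$, $p_5+p_6=1$, $p_7=1$,
the remaining freedom is fixed by requiring the probability contribution of
base pairs to be close to that of unpaired bases. With
$q_{bp} = (\prod_{\text{6 pairs}} q_i)^{1/6}$ the geometric mean of the
pair emissions and $u$ the unpaired emission (geometric mean for
non-uniform settings; $u = 0.25$ at the defaults):

$$p_1 = p_2,\qquad p_3 = p_4,\qquad
q_{bp}^3\,p_3 p_6 p_7 = (u\,p_1)^6,\qquad
q_{bp}^4\,p_3 p_5 p_6 p_7 = (u\,p_1)^8.$$

Dividing the two nonlinear equations isolates $p_5 = (u p_1)^2 / q_{bp}$;
substituting back gives $p_3 = (u p_1)^6 / (q_{bp}^3 (1-p_5))$ and
$p_1 = 1/2 - p_3$. `solve_rule_probabilities()` iterates these three
assignments from $p_1 = 0.5$ to a $10^{-12}$ fixed-point tolerance — the
iteration contracts strongly because $p_3 \ll 1$ — and verifies the
residuals of both nonlinear constraints are below $10^{-9}$. The tests
cross-check the fixed point against an independent `uniroot()` solve of the
scalar residual in $p_1$. The default solution:

```{r}
round(triple_model()$params$p, 3)
```

The printed three-decimal values hide a little structure: the exact fixed
point has $p_3 \approx 0.00125$, and $p_1 = 1/2 - p_3$ exactly.

## Inside–outside computation

`scfg_inside()` fills $\alpha(S,i,j)$ (probability that $S$ derives
$x_i..x_j$) over increasing span length; `scfg_outside()` fills
$\beta(S,i,j)$ (probability of deriving the full sequence with $S$ spanning
$i..j$) top-down from $\beta(X,1,n)=1$. For each pair-emitting rule
$S \to aRbT$, the pair $(i,j)$ contributes

$$\mathrm{ruleprob}\cdot\pi(x_i,x_j)\cdot
\sum_{j<k\le n}\alpha(R,i{+}1,j{-}1)\,\beta(S,i,k)\,\alpha(T,j{+}1,k),$$

normalized by $\alpha(X,1,n)$; for the rules without a trailing $T$ (3, 5,
6, 7) the sum collapses to $k=j$ and the $\alpha(T,\cdot)$ factor is
dropped. Only rule 4 keeps the $k$-sum, which is what makes the whole
computation $O(n^3)$.

Numerical choices:

* **Log space.** Individual derivation probabilities scale like
  $(p_1/4)^n$ and underflow doubles near $n \approx 340$. All charts store
  logs and accumulate with log-sum-exp, implemented in C++ (`src/scfg.cpp`)
  for speed. A plain-R linear-space implementation is kept as an
  independent reference; the two agree to $10^{-9}$ relative on spans where
  linear space is safe (tested at $n \le 60$).
* **Logarithm base.** The entropy uses the natural log. The choice is
  immaterial downstream: $Z$ standardizes $Q$, so any base change rescales
  numerator and denominator identically (asserted numerically in the
  tests).
* **Indices.** All interfaces are 1-based inclusive spans.
* **Degenerate input.** Empty sequences are rejected at construction;
  $n < 7$ or pair-free sequences process normally and give an all-zero
  matrix and $Q = 0$.

### Derivations versus structures

The grammar is ambiguous at the structure level: a helix of six or more
stacked pairs can be derived as one stem (repeated rule 5) or as two
stacked stems through the $Y \to aXb \to aHb\ldots$ path. The package
marginalizes *derivations* — that is what the inside–outside algorithm
computes — and the brute-force oracle enumerates derivations under the same
semantics, keeping identical pair sets distinct, so the equivalence test is
well-posed. Structure-level deduplication would require a different
(unambiguous) grammar and is out of scope.

## The validation oracle

`enumerate_derivations()` recursively expands every rule application for
sequences up to $n = 14$ (a hard guard: the count grows combinatorially)
and returns each derivation with its exact probability.
`oracle_pair_probabilities()` is then the definitional pair frequency:
probability-weighted occurrence over all derivations, normalized by the
total. The test suite checks, on a 200-sequence random panel with
$n \in [7,12]$, that the chart implementation matches the oracle to
$10^{-9}$ relative and that the enumerator's probability sum matches the
inside total to $10^{-12}$ relative; a memoization-free naive recursion
provides a third, independently coded route for the totals.

## Null models

* **Mononucleotide shuffle** — uniform residue permutations.
* **Dinucleotide shuffle** — the Euler-path (Altschul–Erickson)
  construction: residues are vertices, adjacent pairs are edges, a random
  in-tree toward the final residue designates each vertex's last outgoing
  edge, remaining edges are permuted, and the Eulerian walk spells the
  shuffle. This preserves the ordered dinucleotide multiset *exactly*, and
  as a consequence fixes the first and last residues — worth knowing when
  comparing against inexact (Markov-resampling) shufflers. Inputs whose
  transition graph has no branching (e.g. `GGGAAACCCUUU`, where each base's
  occurrences are contiguous) admit exactly one Euler path, so their
  "shuffles" all equal the input; the pipeline then reports an undefined
  $Z$ and flags the sequence rather than failing.
* **External backgrounds** — length-matched segments drawn uniformly over
  all (record, offset) slots of a user FASTA, the "genome background" mode.

Defaults mirror the standard protocol: 100 background members per sequence,
both shuffle modes available, thresholds $2, 1.5, 1, 0.5$ with inclusive
($\ge$) counting. $Z$ uses the sample (n−1) standard deviation — at 100
draws the population/sample distinction is immaterial, but sample sd is the
convention. The KS normality check runs against a normal with the
background's estimated mean and sd; with estimated parameters the p-value
is approximate (conservative). It is a diagnostic, not a gate. Sequences
with $\sigma = 0$ backgrounds (nothing can pair in any shuffle, e.g.
poly-A) are flagged `sigma_zero` and excluded from threshold tables;
records with non-ACGU symbols are flagged `invalid` and skipped, matching
the usual dataset-cleaning step. Per-sequence background streams are seeded
from (run seed, sequence id), so results are independent of processing
order.

## The synthetic-data generator

`sample_structure()` forward-samples (sequence, structure) jointly from the
grammar, so every fixture satisfies the model's guarantees by construction
(canonical pairs only, stems $\ge 3$). Under the maximum-entropy
parameters, though, the sampler is nearly critical-free: each $X$ expansion
terminates with probability $\approx 0.5$, so draws are short (median a few
bases) and essentially never reach ncRNA-like lengths. Fixture generation
therefore uses a fixed alternative parameterization,
`fixture_model()` ($p_{1..4} = 0.2, 0.7, 0.05, 0.05$; $p_{5,6} = 0.5, 0.5$):
a subcritical branching process with mean length $\approx 11$ whose draws
carry stems of geometric length $\ge 3$ — chosen once as a reasonable
stand-in for structured RNA of realistic stem density, and used only to
*generate* fixtures; scoring always uses the maximum-entropy model. Because
the grammar is closed under concatenation (a terminal rule 1/3 application
rewrites to its continuation twin 2/4), `sample_structured()` concatenates
independent draws to reach a target length window (80–120 nt for the
discrimination tests) without breaking any guarantee.

What the generator emulates: stem-loop architecture, canonical pairing,
realistic stem lengths, composition similar to its emissions. What it does
not: thermodynamic stability, conserved family architecture, sequence
covariation, modified bases, GC-content gradients. Passing the
discrimination test (grammar-sampled structured sequences achieve mean
$Z > 0$ against 50 dinucleotide shuffles while permuted controls sit at
$Z \approx 0$, sign test at the 5% level) therefore shows the pipeline
detects model-generated structure above composition-matched noise — it does
not by itself certify performance on real ncRNA families, whose published
threshold tables require the original curated datasets.

## Problem sizes in the shipped tests

The suite validates the chart algorithms against exhaustive enumeration at
$n \in [7, 12]$ (200 sequences), probability-mass invariants on panels up
to $n = 500$, shuffle exactness over ~10,000 draws, and the discrimination
property on 20 structured sequences of 80–120 nt with 50 dinucleotide
shuffles each — sizes chosen so the whole suite completes in a few minutes
on one core while still exercising every code path at meaningful scale.

## Known limitations

* The three-consecutive-pair requirement is a hard constraint; families
  whose helices are broken into two-pair pieces by internal loops (some
  SRP RNAs, for instance) can be missed — a grammar admitting
  energy-stable short stems would be the natural refinement.
* Pseudoknots are outside the grammar's expressive power (as for any CFG).
* Entropies are comparable across sequences of similar length; the $1/n$
  normalization does not fully remove length dependence, which is why
  scoring is always against length-matched backgrounds.
* The KS p-value with estimated parameters is approximate; a Lilliefors
  correction could be added but the diagnostic role does not warrant it.
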