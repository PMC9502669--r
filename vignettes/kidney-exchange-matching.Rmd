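---
title: "Kidney exchange matching: the model, the algorithm, and the simulated secret-sharing backend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kidney exchange matching: the model, the algorithm, and the simulated secret-sharing backend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kexmatch)
```

## The problem

A patient with end-stage renal disease often has a willing living donor who
is medically incompatible with them. Kidney exchange programmes pool such
incompatible donor–recipient pairs: if the donor of pair $i$ can give to the
recipient of pair $j$ and vice versa (or around a three-way ring), the
transplants can all go ahead. Collapsing each pair into one vertex gives a
directed graph whose edge $(i, j)$ means "donor of pair $i$ is compatible
with recipient of pair $j$"; an exchange is a vertex-disjoint set of
directed cycles, and practical programmes cap the cycle length at $L = 3$
because all operations of a cycle must be scheduled simultaneously.

`kexmatch` implements the full matching pipeline in four phases —
compatibility scoring, cycle counting, cycle evaluation, and greedy
selection of a disjoint cycle set — and can run every phase either in
cleartext or on a simulated two-party secret-sharing backend, because in
practice the medical records involved are too sensitive for hospitals to
pool in the clear.

## The compatibility model

Six criteria enter the model. One is a hard gate:

* **HLA crossmatch.** If the recipient holds an antibody against any of the
  donor's HLA antigens the transplant is immunologically contraindicated.
  The catalogue of typed split antigens covers loci HLA-A (13), HLA-B (24),
  HLA-DR (8) and HLA-DQ (5) — 50 antigens in total
  (`kex_catalogue()`).

Five are graded scores, combined as a weighted sum:

* **HLA mismatch quality.** Per locus group, the distinct donor antigens
  absent from the recipient's own antigen set, capped at two per group
  (each person carries at most two antigens per locus), summed over the
  four groups (0–8). Counts are binned 0 / 1–2 / 3–4 / $\ge 5$; the
  published bin boundaries leave a count of exactly 5 unassigned between
  "3–4" and "more than 5", and we close that gap by assigning 5 to the
  worst bin. Default bin scores 3/2/1/0.
* **ABO blood group.** O donates to everyone, A to A/AB, B to B/AB, AB to
  AB. Incompatibility is a score penalty (default 1/0), not an exclusion:
  graft pre-processing makes ABO-incompatible transplants possible at
  elevated first-year risk, so only the crossmatch excludes.
* **Age.** Junior (< 55 years) vs senior ($\ge 55$; the published
  categories "below 55" and "older than 55" leave exactly 55 open, which we
  close as senior). Same-category pairings score best (2), junior donor to
  senior recipient next (1), senior donor to junior recipient worst (0).
* **Sex.** Same-sex pairings best (2), male donor to female recipient
  next (1), female donor to male recipient worst (0).
* **Weight.** A donor lighter than the recipient (beyond a configurable
  margin, default 0 kg) risks the graft failing to support the recipient's
  body mass: favourable score 1, otherwise 0.

The edge weight of an ordered combination is
$$
w_e \;=\; \begin{cases}
0 & \text{crossmatch positive,}\\
b + \vec p \cdot \vec w & \text{otherwise,}
\end{cases}
$$
where $\vec p$ is the vector of the five criterion scores, $\vec w$ the
configurable criterion weights (default all 1) and $b$ a baseline (default
1). The baseline guarantees that every crossmatch-compatible edge has
strictly positive weight and therefore survives the $w > 0$ adjacency
threshold; without it, a configuration with all-zero score tables would
silently delete valid edges. The exact numeric score values used by any
particular programme are a clinical-policy matter; the defaults here are
the smallest non-negative integers respecting every published ordinal
constraint, and all of them are configurable through `kex_weights()`.
Scores and weights are deliberately integers: the secret-sharing backend
works in $\mathbb{Z}_{2^{32}}$, where integer arithmetic is exact.

## Cycle enumeration and selection

The number of closed walks of length $L$ equals
$\operatorname{tr}(A^L)$ for the 0/1 adjacency matrix $A$ (computed by
naive repeated multiplication, $L-1$ products). On a loop-free digraph with
$L \in \{2, 3\}$ every closed walk of length $L$ visits distinct vertices,
so the trace counts each exchange cycle exactly $L$ times — once per
"congruent" rotation. Hence the dedup identity
$\#\text{unique} = \lfloor \#\text{cycles} / L \rfloor$, which the test
suite asserts on hundreds of seeded digraphs together with agreement
between the matrix-power count, a brute-force scan over all $n^L$ vertex
sequences, and an independent pruning DFS enumerator.

`evaluate_cycles()` canonicalises each cycle by rotating its minimum vertex
to the front (rotation only — direction matters in a digraph), removes
duplicates, sorts by weight descending and truncates to the top $k$. The
sort's tie-break — lexicographically smaller canonical vertex list first —
is our choice, made for cross-platform determinism; nothing in the model
prefers one equal-weight cycle over another.

`select_solution()` is the greedy phase: one candidate set per cycle,
seeded with that cycle and extended by scanning the remaining cycles in
descending-weight order, keeping those disjoint from everything selected so
far; the candidate with the highest total weight wins. Among equal-total
candidates we prefer fewer cycles, then the earliest seed in the sorted
order. The earliest-seed rule (rather than, say, comparing concatenated
vertex lists) was chosen because the seeds are already scanned in a
deterministic order — weight descending, then lexicographic — so it is
reproducible in both backends at no extra circuit cost. The result is
locally optimal; `brute_force_optimum()` (exhaustive over all disjoint
subsets, guarded at 20 cycles) serves as the oracle showing the greedy
result is bounded by the global optimum and attains it whenever no two
cycles share a vertex. Returning the best over all seeds rather than the
first maximal set costs $O(|\text{unique}|^2)$ scans and can only improve
the objective, so we keep it in both backends.

## The simulated secret-sharing backend

The privacy model is semi-honest two-party computation: any number of
hospitals split their records into two additive shares
($x = \langle x\rangle_0 + \langle x\rangle_1 \bmod 2^{\ell}$, default
$\ell = 32$; XOR shares for bits) and send one share to each of two
non-colluding computation servers. A single share is uniform and carries no
information. `kexmatch` simulates both servers in one process but preserves
the protocol's information flow:

* multiplications use dealer-supplied Beaver triples, opening only
  uniformly masked differences; each triple is single-use and reuse raises
  an error;
* Boolean AND consumes a Boolean triple; XOR and NOT are free; OR costs one
  AND-equivalent ($\lnot(\lnot a \land \lnot b)$); branching is a
  multiplexer $b \oplus (s \land (a \oplus b))$;
* conversions between arithmetic and Boolean sharing use dealer randomness
  (a shared ring element with Boolean-shared bit decomposition and a
  ripple-carry adder for the public masked value: one AND-equivalent per
  bit); comparisons (`x > 0`, sign bits) run on the converted bits;
* every reconstruction that combines both shares outside an explicit,
  logged `declassify()` increments an audit counter that the tests assert
  to be zero over whole pipeline runs.

The deep Boolean phases (cycle evaluation and selection) correspond to
garbled-circuit phases in a deployment; the simulator executes them on the
Boolean-share engine and charges the garbled-circuit communication model:
$1.5\kappa$ bits per AND-equivalent gate with $\kappa = 128$, XOR free.

Two intermediate values are public by design. The duplicate-inclusive cycle
count (the trace) is declassified because it fixes the sizes of all later
oblivious computations — a deliberate, limited leak of one aggregate
number. The final solution is the output. Everything else — who is
compatible with whom, every weight, every rank — stays shared.

Obliviousness shapes the algorithms. The sort in the cycle-evaluation phase
is a stable rank-by-all-pairs-comparisons network: each candidate's rank is
the number of strictly heavier candidates plus the earlier equal-weight
ones, computed from $m(m-1)$ shared comparisons in one SIMD batch, followed
by an oblivious permutation through shared equality indicators. This
reproduces exactly the cleartext order (weight descending, lexicographic
tie-break) because candidates are enumerated in lexicographic order and the
rank is stable. The greedy phase advances all seed candidates in parallel,
testing disjointness as a shared occupancy dot product followed by a shared
zero test, and the final argmax over seeds is a sequential oblivious
compare-and-select. Consequently the reconstructed solution is bit-for-bit
the cleartext solution, which the acceptance suite asserts on 50 seeded
cohorts.

### Cost accounting

Two cost views are reported and deliberately kept apart:

* `closed_form_costs()` returns the analytic per-phase formulas: the
  crossmatch subprotocol at $2|\mathsf{HLA}|$ AND gates and depth
  $\log_2|\mathsf{HLA}| + 1$; the per-pair combination at 5
  multiplications, 5 additions, 1 comparison, 1 AND, 1 MUX; the
  matrix-power phase at $|\text{pairs}|^3$ multiplications; and the
  published dedup/sort and selection formulas.
* `cost_report()` tabulates what the simulator actually executed.

The counted crossmatch comes to $2|\mathsf{HLA}| - 1$ AND-equivalents per
ordered pair ($|\mathsf{HLA}|$ SIMD ANDs plus $|\mathsf{HLA}| - 1$ tree
ORs, inversion free): the closed form is the rounded bound, and we report
both rather than guess. Counted costs for the oblivious sort differ in
shape from the analytic sort formulas because the rank network replaces the
k-nearest-neighbour sort of the reference design (whose internals are not
published); share-conversion gates are likewise counted in their own
columns because no closed form covers them. The counted-versus-analytic
inequality is therefore asserted only where both sides count the same
operations (the crossmatch and the combination step).

## The synthetic cohort generator

`generate_cohort()` emulates the input a real exchange pool would provide,
under a fixed seed: two antigens per locus drawn uniformly with replacement
and deduplicated (homozygosity allowed), an antibody panel drawn
Bernoulli(PRA) per catalogue antigen excluding the recipient's own
antigens, ABO frequencies 0.43/0.40/0.12/0.05 (O/A/B/AB), ages uniform on
18–75, weights normal $80 \pm 15$ kg truncated to 40–150 kg, sex balanced.
These defaults are plausible European-pool placeholders chosen once — the
reference design publishes no cohort statistics — and every one of them is
a `CohortParams`-style argument. The generator does **not** model
population HLA haplotype frequencies, linkage disequilibrium between loci,
the correlation between PRA and prior sensitisation events, or the fact
that pools are enriched for hard-to-match (high-PRA, blood-group-O
recipient) pairs. Passing tests on generated cohorts therefore demonstrates
algorithmic correctness, not clinical performance on real registry data.

## Numerical and degenerate-case choices

* All pipeline arithmetic is integer; the backend works in
  $\mathbb{Z}_{2^{32}}$ and an analytic bound (largest possible trace,
  candidate count, weight sum) is checked before each run — instances that
  could overflow the signed comparison range are rejected with advice to
  raise the bit length.
* Weights in kg are compared at 0.1 kg resolution on the backend (scaled to
  integers), matching the generator's precision.
* An empty graph, a cohort with no cycles, or a zero declassified count all
  short-circuit to the empty solution with total weight 0.
* Problem sizes in the test suite — digraphs up to $n = 10$ for the cycle
  algebra, cohorts of 3–8 pairs for backend equivalence, instances with at
  most 15 unique cycles for the exhaustive optimality oracle — were chosen
  as the smallest sizes that still exercise every branch (both cycle
  lengths, conflicting and conflict-free selections, empty and dense
  graphs).

## Known limitations

* Cycles only, length 2–3 by default (configurable cap): altruistic-donor
  chains and longer rings are out of scope.
* The greedy selection is locally optimal; the package reports the
  optimality gap against `brute_force_optimum()` on small instances but
  offers no ILP solver.
* The backend is a simulation for correctness and cost accounting: there is
  no oblivious transfer, no garbled-table encryption, no network layer, and
  no malicious-security hardening.
* Split-antigen (2-digit) HLA typing only; allele-level typing and
  epitope-based matching are not modelled.
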