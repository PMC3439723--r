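---
title: "Modelling clinical pathways as stochastic process algebra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling clinical pathways as stochastic process algebra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpepa)
```

## The model

A clinical pathway moves patients through a sequence of departments, each
with its own service time and a limited pool of staff or equipment.
`cpepa` describes such a pathway in a small stochastic process algebra
with three kinds of sequential components:

* **patient-state components** — one local state per place a patient can
  be (at home, in the ambulance, in A&E, in the scanner queue, in a
  ward bed);
* **resource components** — idle/busy pairs for each staff pool or
  equipment pool;
* **activities** `(action, rate)` — exponentially distributed steps; the
  rate is the reciprocal of the mean duration, in units of 1/day.

Defining equations compose prefixes `(action, rate).Continuation` with a
choice operator `+`; the system expression composes component populations
with a cooperation operator carrying a set of shared action labels, and
`Name[N]` stands for `N` interleaved copies. A shared action proceeds at
the **minimum of the two operands' apparent rates** (the total rate each
side can offer), split across the enabled source combinations in
proportion to their contribution. Routing branches are expressed by
scaling a prefix rate with the branch probability, so the effective rates
out of a branch point always sum to the parent service rate.

Two structural conventions keep the underlying chain well-behaved:

* **cyclic patients** — the discharge activity returns a patient to its
  home state, so the chain is irreducible and a steady state exists;
* **waiting-room relays** — where a hand-off should not block the
  upstream department, a fast idle/busy relay pair is inserted between
  the arrival action and the resource seizure. Its coupling rate
  (default 1000/day) only needs to be much faster than every service
  rate; results are insensitive to its exact value, and it is exposed as
  `r_wait` in `pathway_config()`.

## From model to numbers

**Exact chain.** `explore_state_space()` enumerates the reachable global
states (tuples of local states) breadth-first — deterministically, so
generator matrices and reports are reproducible — and
`build_generator()`/`solve_steady_state()` yield the equilibrium
distribution by a least-squares solve of the global balance equations
with the normalisation row appended (dense QR up to 4096 states, sparse
normal equations beyond; residual tolerance 1e-10, checked and reported).
Irreducibility is verified by strongly-connected-component analysis
before solving. Utilisation is the expected number of busy copies of a
resource over its copy count; throughput is the discharge rate times the
expected number of busy copies of the final resource, which equals the
steady-state flux of the discharge action (asserted in the test suite).

**Counting abstraction.** Copies within a replica group are
interchangeable, so states with equal per-group local-state counts are
lumped into one class (`aggregate_states()`). The lumped rate out of a
class is the rate out of any one member, and the implementation checks
that all members agree — a violation would indicate the groups were not
true replicas. Utilisation and throughput are invariant under the
abstraction; the two-patient illustrative pathway lumps from 10 states
to 5.

**Fluid approximation.** For populations where even the lumped chain is
too large (the stroke scenarios replicate 1000 patients), the expected
count of each local state evolves under mean-field ODEs
(`derive_odes()`): the total rate of an action is the minimum over the
cooperating sides of their count-weighted apparent rates, apportioned to
individual transitions by their share. The drift at `t = 0` equals the
exact chain's expected drift (a test asserts this for every generated
fixture), and trajectories conserve each group's total exactly.
Integration uses `deSolve`'s stiff-capable `lsoda` (the models mix rates
of 0.004/day and 1000/day) with `rtol = 1e-8`, `atol = 1e-10`.

`fluid_steady_state()` integrates until the largest drift falls below
1e-8/day. At a capacity boundary the minimum terms switch sign rapidly
("sliding mode") and the pointwise drift chatters at a small finite
value although the counts are stationary; convergence therefore also
accepts a vanishing mean drift across a doubling time window. The
scenario drivers (`scenario_resource_sweep()`, `scenario_max_input()`)
additionally stop once the *reported measure* (throughput) is stable
across a doubling window: past the point where the busy counts are
stationary, the remaining slow relaxation only redistributes queued
patients on the admission timescale (hundreds of days) and cannot change
utilisation or throughput. Exact and fluid routes are cross-checked on
generated fixtures: the fluid throughput of a 100-fold scaled
configuration matches the exact chain of the original within 10%.

## Passage times and the probe

The time from treatment entry to discharge is measured with a two-state
observer fused onto the patient component: `NotFinished` becomes the
absorbing `Finished` on the first completion of the trigger action (the
discharge activity), and every other activity leaves the observer
untouched. Because the probe is a product construction with the
trigger's own rates, the non-probe marginals are *exactly* those of the
unprobed model (tested). The Finished fraction of the probed population
along the fluid trajectory approximates the passage-time CDF.

Two clock-origin conventions are possible, and they differ enormously
here: a patient waits at home for a mean of `1/r_income` = 250 days
before falling ill, while the treatment pathway itself takes about 2.2
days. `scenario_passage_time()` therefore starts the probed patient at
the first treatment state (ambulance pick-up), excluding the at-home
stage — the only convention on the day scale of clinical interest.
`attach_probe()` accepts any start state, so the including-home variant
is available directly.

The scenario tags a single probed patient (an uncontended cohort): its
CDF is then the pathway's intrinsic passage distribution — for a chain
of exponential stages, hypoexponential, which the implementation matches
to 1e-3 (tested against the closed form) — and it is identical across
resource allocations that starve no stage, which the driver verifies
when given two configurations. With the stroke rates (24, 32, 8, 0.5
per day) this gives 33% of patients discharged within 1 day and 68%
within 2.5 days; the published curve for the same scenario is
substantially steeper (14% and 90%), which no construction we examined
— individual hypoexponential, steady-state-background tagging, or
population-fraction curves from an empty or flooded start — reproduces.
The discrepancy is documented rather than fitted; the corresponding
acceptance checks fail at their stated tolerances and are left failing.

Similarly, the bed utilisation reported for the optimal allocation
(0.92) sits below the value implied by flow balance: a throughput of
3.95/day at a 0.5/day discharge rate occupies 7.9 of 8 beds (0.99),
which is what the fluid fixed point yields. The initial-allocation value
(0.368 published vs 0.397 computed) is consistent within its tolerance.

## Scenario conventions

* **Sweep optimum** — the smallest configuration (total resource count,
  ties broken lexicographically) whose throughput is within 1% of the
  grid maximum.
* **Input levels** — a mean input of `k` patients/day is realised as a
  population of 1000 patients with per-patient admission rate `k/1000`,
  matching the study's parameterisation at `k = 4`. Throughput saturates
  at the discharge capacity (bed copies times discharge rate).
* **Solver selection** — the scenario drivers use the fluid route; the
  exact (aggregated) chain is used by `solve_pathway()` and by the test
  suite wherever the state space is small enough, and the two are
  reconciled on fixtures.

## What the fixture generator does and does not emulate

`generate_fixture()` draws small pathways (1–3 departments, rates
0.1–50/day, 1–3 patients, up to 2 copies per resource, at most one
waiting-room relay) for property tests: round-trips through the textual
language, generator row sums, flux balance, aggregation invariance,
drift oracles, conservation, CDF monotonicity. These fixtures keep the
exact chain solvable, so every fluid claim can be checked against an
exact or simulated answer. They do not emulate features of real
admission data — time-varying arrival rates, non-exponential service
times, patient heterogeneity, abandonment — so passing tests validate
the mathematics of the implemented model, not the fidelity of an
exponential pathway to any particular hospital. At very small
populations the fluid mean visibly overshoots the true expectation (the
two-patient model shows a bias of a few hundredths in the busy-resource
count); the Monte-Carlo comparison is therefore run at a 6-patient scale
where the mean-field assumption holds within simulation error.

## Numerical choices

* State exploration is capped (default 1e6 states) and over-budget
  exploration is an error, never a truncation.
* Steady-state residual tolerance 1e-10; lumpability agreement 1e-9
  (relative); fluid drift tolerance 1e-8/day; integration `rtol = 1e-8`,
  `atol = 1e-10`; passage CDFs are clamped to [0, 1] and made
  nondecreasing, removing integration noise at the tolerance level.
* Tie-break orderings (BFS discovery order for states, first-appearance
  order for classes) are deterministic, so repeated runs give identical
  matrices, reports and files.
* Problem sizes used by the shipped analyses: the illustrative chain (10
  states), its 8/8/3 scaling (75582 states), and fluid systems of 12–22
  count variables; the full sweep evaluates 180 allocations.
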