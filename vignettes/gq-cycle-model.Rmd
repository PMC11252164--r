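---
title: "The G-protein cycle model behind gqcycle: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The G-protein cycle model behind gqcycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gqcycle)
```

## The biological problem

More than 95% of uveal melanomas carry mutually exclusive activating
mutations in one pathway: the GPCR CysLT2R (*CYSLTR2* L129Q), the
G-alpha subunits it activates (*GNAQ*/*GNA11* Q209L, Q209P, R183C), or
the downstream effector PLCB4. The two major mutation classes — receptor
vs G-alpha — are commonly assumed interchangeable, yet they sit at
different points of the same activation cycle and need not produce the
same downstream signal mix. `gqcycle` implements a mechanistic
mass-action model of that cycle to ask, quantitatively, when the two
classes diverge.

## The model

The state of the cycle is tracked with 22 species. For each G-alpha pool
$p \in \{\mathrm{WT}, \mathrm{mut}\}$ the model follows the heterotrimer
$\mathrm{G\alpha_{GDP}{\cdot}G\beta\gamma}$, free
$\mathrm{G\alpha_{GDP}}$, free $\mathrm{G\alpha_{GTP}}$, nucleotide-free
$\mathrm{G\alpha}$, the effector complexes
$\mathrm{G\alpha_{GTP}{\cdot}TRIO}$ and
$\mathrm{G\alpha_{GTP}{\cdot}PLC\beta}$, the GAP complex
$\mathrm{RGS{\cdot}G\alpha_{GTP}}$, and two drug-bound GDP-state species;
$\mathrm{G\beta\gamma}$, TRIO, PLC$\beta$ and RGS are shared pools. The
reactions, all mass action:

1. *Exchange.* Active receptor catalytically converts heterotrimer to
   free $\mathrm{G\alpha_{GTP}}$ + $\mathrm{G\beta\gamma}$ at rate
   $k_{gef} \cdot R_{act} \cdot [\mathrm{HT}_p]$. The receptor is not
   consumed; ligand kinetics and beta-arrestin desensitization are folded
   into the active fraction $f_{act}$.
2. *Intrinsic hydrolysis.* $\mathrm{G\alpha_{GTP}} \to
   \mathrm{G\alpha_{GDP}}$ at $k_{hyd}$.
3. *RGS GAP cycle.* Explicit bind/release/catalyze:
   $k_{rgs,on}, k_{rgs,off}, k_{rgs,cat}$.
4. *Effector binding.* Reversible association with TRIO
   ($k_{at1}/k_{dt1}$) and PLC$\beta$ ($k_{at2}/k_{dt2}$); the
   steady-state complex concentrations are the model readouts ("active
   TRIO", "active PLC$\beta$"), assumed monotone proxies of FAK/YAP and
   PKC/ERK signaling respectively.
5. *PLC$\beta$ as GAP.* The already-formed
   $\mathrm{G\alpha_{GTP}{\cdot}PLC\beta}$ complex hydrolyzes its GTP at
   $k_{hyd2}$, releasing $\mathrm{G\alpha_{GDP}}$ and free PLC$\beta$.
6. *Nucleotide-free branch.* GTP release at $k_{gtp,off}$ and fast
   pseudo-first-order reloading at $k_{nt,load}$ (cellular GTP is in
   excess, so only GTP loading is modeled; a GDP-loading branch would be
   unidentifiable at steady state).
7. *Heterotrimer reformation.* $\mathrm{G\alpha_{GDP}} +
   \mathrm{G\beta\gamma} \to \mathrm{HT}$ at $k_{trimer}$.

Mutant proteins are distinct species with their own kinetics: the
scalings $r_{hyd}$ and $r_{gap}$ multiply the intrinsic and
GAP-stimulated hydrolysis of the mutant pool, $r_{at1}$ and $r_{at2}$
its effector association rates, and CysLT2R L129Q raises the mutant
receptor's active fraction ($f_{act,mut} = 1$ vs $f_{act,wt} = 0.01$).
Both active-receptor pools act identically on both G-alpha pools, and
$\mathrm{G\beta\gamma}$ is one shared pool for which WT and mutant
$\mathrm{G\alpha_{GDP}}$ compete.

Zygosity enters through pool allocation only: GNAQ and GNA11 are treated
as biochemically identical genes each holding 50% of total G-alpha, so a
heterozygous G-alpha mutation makes 25% of the pool mutant and a
homozygous one 50%; heterozygous L129Q splits the receptor population
50/50. Total abundances never change with genotype.

## Parameters: units, defaults, and how they were fixed

Concentrations are nondimensionalized to the total G-alpha pool
($G\alpha_{tot} = 1$); times are seconds. All downstream readouts are
fold changes against the all-WT baseline, which are invariant to the
concentration scale. The shipped constants are round literature-scale
magnitudes: basal hydrolysis $k_{hyd} = 0.013\,\mathrm{s^{-1}}$ (the
measured order for G$\alpha_q$), association constants
$1{-}30\,\mathrm{conc^{-1} s^{-1}}$, dissociations
$1{-}100\,\mathrm{s^{-1}}$, and abundances within an order of magnitude
of the G-alpha pool.

Two presets are shipped:

* **initial** — PLC$\beta$ is a very strong GAP
  ($k_{hyd2}/k_{hyd} = 770$, the top of the measured PLC$\beta$1 range)
  and the Q209 mutants bind both effectors like WT.
* **revised** — the Q209 mutants have a four-fold TRIO-ward
  effector-association bias (`effector_bias() == 4`; co-IP data support
  a modest TRIO preference for Q209L) and PLC$\beta$ GAP activity is
  moderate ($k_{hyd2}/k_{hyd} = 20$, the log-midpoint of the 1–40 band
  that reproduces the observed activation patterns).

The exact values used in the original study are supplementary-only; the
presets here are stand-ins constructed to satisfy every constraint the
model's claims put on them *simultaneously*: under the initial preset
the mutant panel shows constitutive activation with the gene-dose
effect, R183C below Q209L/P, and near-complete loss of L129Q's
PLC$\beta$ excess (< 10% of Q209L's); under the revised preset the
L129Q-vs-Q209L experiment-match criterion holds exactly for
$k_{hyd2}/k_{hyd} \in [1, 40]$ and fails by ~77; and the GDI
dose-response log-shift between R183C and Q209L falls in the 5–50x
window under both presets. Satisfying all three at once constrains the
balance between the RGS flux and the PLC-GAP flux and the receptor
drive; the shipped base set ($k_{gef} = 1.2$, fast-cycling RGS with
$k_{rgs,on} = 30$, $k_{rgs,off} = 100$, $k_{rgs,cat} = 30$,
$RGS_{tot} = 2$, $k_{at2} = 0.2$) is one such solution, found by a
coarse grid search against those qualitative pins and then frozen. It
should not be read as an estimate of the underlying biochemistry — the
original authors make the same caveat about their own revised set.

Mutant bundles: Q209L/P use $r_{hyd} = r_{gap} = 0.001$ — slow but
deliberately nonzero, because a GDP-state-binding drug has no handle on
a mutant that *never* reaches the GDP state (the package's saturating-
dose test demonstrates that limit with $r = 0$ exactly). R183C is
partially GAP-sensitive ($r_{hyd} = 0.05$, $r_{gap} = 0.2$). All values
are overridable per variant from code or config.

## Steady-state numerics

`solve_steady_state()` integrates the stiff system with `deSolve::lsoda`
(compiled C right-hand side) from the canonical initial condition (all
G-alpha as heterotrimer, all effectors free) over expanding horizons
($10^6, 10^8, 10^{10}$ s) until $\max|dy/dt|$ falls below `atol`
(default $10^{-10} \times$ the largest abundance). A
Levenberg–Marquardt refinement on the right-hand side augmented with the
conservation constraints (`minpack.lm::nls.lm`, nonnegative bounds) is
available as `method = "root"` and as a fallback polish; the two routes
agree to $10^{-6}$ relative on the readouts across random parameter
draws (enforced in the test suite). Conservation of every protein total
holds to $10^{-8}$ relative everywhere. A pure-R right-hand side written
reaction-by-reaction is kept as the auditable reference; the C
implementation must match it to machine precision.

Degenerate inputs: zero receptor activity yields the all-heterotrimer
fixed point exactly; concentrations more negative than
$-10^{-12} \times$ scale mark the solve as failed (never silently
clipped into success); non-convergence raises an error unless the caller
opts into a flagged row (`must_converge = FALSE`, used by batch
evaluation). Multistability is screened on demand
(`check_multistable = TRUE`) by re-solving from an all-dissociated
initial condition and flagging disagreement beyond $10^{-4}$ relative;
flagged rows are excluded from batch statistics. The screen is off by
default in `evaluate_batch()` because it doubles cost and no multistable
set has been observed under the shipped ranges.

## The GDI extension

The FR900359/YM-254890 drug class is modeled as a reversible binder of
GDP-bound G-alpha — both the free subunit and the heterotrimer by
default (`gq_drug(targets =)` restricts it) — with equal affinity for WT
and mutant pools and a clamped (buffered) concentration, so dose is a
parameter rather than a conserved species. Drug-bound species enter the
G-alpha conservation sum. IC50s are log-linearly interpolated at the
50%-of-baseline crossing; curves that never reach 50% return a failure
status, and non-monotone crossings use the first crossing with a logged
warning. The emergent mutant-class log-shift in IC50 (partially
GAP-sensitive R183C inhibited at ~10x lower dose than Q209L) is a
consequence of how much time each mutant spends in the drug-bindable GDP
state, not an assumption.

## Global exploration design

Six parameters are varied by default: $k_{hyd2}$, the composite
`effector_bias` ($r_{at1}/r_{at2}$ of Q209L, moved through the mutant
TRIO association rate with dissociation rates fixed — varying the
association side only, so equilibrium constants move with it),
$TRIO_{tot}$, $PLC_{tot}$, $RGS_{tot}$, and $k_{gef}$, each log-uniform
over $\pm 1.5$ decades. The ranges are centered on the **initial**
preset because the published global batch predates the parameter
revision; this reproduces the published qualitative results (TRIO
abundance as the top total-order index for the TRIO difference,
$k_{hyd2}$ for the PLC$\beta$ difference, and the bias/$k_{hyd2}$ pair
as the leading match discriminators) without further adjustment.

Sampling uses the Saltelli cross-design ($n_{base}(2D+2)$ rows; with
$D = 6$ and $n_{base} = 800$ that is the published 11,200-set design)
for Sobol analysis and Latin-hypercube sampling for classification
batches. Total-order indices use the Jansen estimator with bootstrap
confidence intervals over the base-sample index; the estimator is
validated against the Ishigami function's closed-form indices and a
planted inert parameter. The package's test suite runs the Sobol stage
at $n_{base} = 128$ and classification at $n = 2000$ — sizes chosen so
the full suite completes in minutes on one core while the headline
rankings remain stable across seeds (the $\Delta_{PLC}$ top index held
in 5 of 6 probed seeds at this size; expect occasional flips if you
rerun at smaller sizes).

Each sampled set is solved for the WT baseline, heterozygous Q209L, and
heterozygous L129Q. The **match criterion** is the experimentally
observed pattern: L129Q's active PLC$\beta$ at least Q209L's *and* its
active TRIO strictly lower. The **behavior classes** compare excess
activation: a pathway of L129Q is "weak" when its fold-change excess is
below $\theta$ times Q209L's ($\theta = 0.5$ by default; no published
value exists, so `behavior_fractions()` reports $\theta \in \{0.25,
0.5, 0.75\}$ alongside). KS discrimination uses `stats::ks.test` with
Benjamini–Hochberg adjustment across the scanned parameters — ranking,
not significance, is the quantity of interest. ROC curves sweep the
threshold over the sampled values with the stated directions ("$\ge$"
for the bias, "$<$" for $k_{hyd2}$) and report trapezoidal AUC,
cross-checked against pROC in the tests.

## Co-mutation enrichment

The probability that an $x$-patient index-mutant set and a $y$-patient
family-mutant set, placed independently and uniformly among $N$
patients, overlap in exactly $k$ patients:

$$P(K = k) \;=\; \frac{(N-k)!}{(x-k)!\,(y-k)!\,(N+k-x-y)!}\,
\frac{\binom{N}{k}}{\binom{N}{x}\binom{N}{y}},$$

evaluated in log-gamma space (stable to $N = 10^5$). This is identical
to the hypergeometric point mass
$\binom{x}{k}\binom{N-x}{y-k}/\binom{N}{y}$; the identity is verified
exhaustively for all valid quadruples with $N \le 30$ and the value is
additionally confirmed by a seeded Monte-Carlo placement simulation.
Because "at least $k$" is the conventional enrichment question, the
right tail $P(K \ge k)$ is reported alongside, clearly labeled; the
point mass is primary. For the uveal-melanoma counts $(N, x, y, k) =
(80, 3, 4, 2)$ the point probability is $5.55 \times 10^{-3}$.

```{r enrichment}
enrichment_test(enrichment_inputs(80, 3, 4, 2), mc_draws = 0)
```

## What the synthetic data do and do not emulate

`make_cohort()` plants an exact $(N, x, y, k)$ co-mutation structure,
mutates ~170 background genes i.i.d., and nudges per-patient totals into
the 5–19 coding-mutations band typical of uveal melanoma exomes. It
emulates the *counting* structure the enrichment statistic consumes —
not mutation spectra, gene lengths, subclonality, or coverage artifacts,
so passing tests validate the statistic and its plumbing, not variant
calling. `make_parameter_sets()` emulates the log-uniform exploration
draws; `make_toy_fixture()` provides a reduced single-pool cycle (no
RGS, no PLC-GAP, no nucleotide-free branch) whose steady state reduces
to one monotone scalar balance equation, solved by bracketed
root-finding at $10^{-14}$ tolerance — the independent oracle for the
full solver.

## Known limitations

* The shipped presets are constraint-satisfying stand-ins, not the
  study's supplementary values; absolute readout levels are therefore
  not comparable to the original figures, only orderings and ratios.
* The behavior-class fractions under the default ranges come out near
  2% / 58% / 18% (strong-ERK-weak-YAP / weak-ERK-strong-YAP /
  weak-both) against the published ~5% / 50% / 25%; the first and
  second classes bracket the published ordering but the exact split is
  sensitive to the unavailable supplementary ranges and to $\theta$.
* Ligand kinetics, downstream ERK/YAP species, PLCB4 mutants, and
  pharmacokinetics are out of scope; time courses are exposed only for
  debugging, steady states are the results.
* The AUC gap between the bias and $k_{hyd2}$ classifiers is small;
  at batch sizes well below 2000 their order can invert by chance.
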