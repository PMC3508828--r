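---
title: "Kinase-phosphatase interaction designs in the MAPK cascade: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinase-phosphatase interaction designs in the MAPK cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapkdesign)
```

## The system

The mitogen-activated protein kinase (MAPK) cascade is a three-tier
phosphorylation module: an input signal phosphorylates MKKK to MKKK-P;
MKKK-P doubly phosphorylates MKK (MKK-P, MKK-PP); MKK-PP doubly
phosphorylates MK; doubly phosphorylated MK-PP is the output. The
kinase-kinase interactions are invariant, but the phosphatases that
reverse each step interact with the tiers in several experimentally
observed configurations. `mapkdesign` models four of them:

* **M1** — a dedicated phosphatase per tier (Phos1, Phos2, Phos3),
* **M2** — Phos1 shared by the MKKK and MKK tiers, Phos2 on MK,
* **M3** — Phos1 on MKKK, Phos2 shared by MKK and MK,
* **M4** — Phos1 on MKKK+MKK and Phos2 on MKK+MK, so the middle tier is
  contested by both phosphatases (the wiring of the B-cell ERK module,
  where Phos1 and Phos2 correspond to PP2A and MKP3).

Each design is built under three kinetic schemes:

* **K1** — Michaelis-Menten flux kinetics. Each conversion contributes a
  flux $k_{cat} E \,(S/K_S) / (1 + \sum_i S_i/K_i)$ whose denominator
  pools every substrate competing for the same enzyme: within a tier the
  two phosphoforms compete for their kinase, and a phosphatase's
  denominator pools all phospho-substrates it serves in the design
  (e.g. M2's Phos1 pools MKKK-P, MKK-P and MKK-PP). Free kinases are
  eliminated through the conservation relations, and the signal and
  phosphatase totals are constants. State space: the five phosphoforms.
* **K2** — elementary mass action. Every conversion is expanded into
  $E + S \rightleftharpoons ES \rightarrow E + P$, the signal is a
  species binding MKKK, and all enzyme-substrate complexes are explicit
  (22-27 species depending on design and sequestration).
* **K2_QSS** — the quasi-steady-state reduction of K2. Its flux
  equations are *identical* to K1's; the parameter map is
  $K_m = (d + k_{cat})/a$ per conversion and
  $K_{se} = k_r/k_f$ per sequestration pair (`derive_qss_params()`).
  Model instances built with scheme `"K2_QSS"` therefore share the K1
  engine code path by construction.

**Sequestration.** Unphosphorylated kinases can bind and sequester
their phosphatases (the PSEQ condition; USEQ is the unsequestrated
reference). In K1/K2_QSS, each dephosphorylation denominator gains one
$\mathrm{Kinase}/K_{se}$ term per unphosphorylated kinase of the tiers
that phosphatase serves, with one $K_{se}$ per phosphatase. In K2, the
layer-terminal dephosphorylation is rerouted: catalysis yields the
bound kinase·phosphatase complex, which releases reversibly
($k_r$, and rebinds with $k_f$). Only the fully dephosphorylated kinase
sequesters; MKK-PP $\to$ MKK-P catalysis releases free MKK-P.

## Output metrics and statistics

For a trajectory of the output MK-PP we compute the **peak** and
**steady amplitude**, the **duration** (total time above a threshold
fraction of the peak) and, for transient signals, the **memory**: the
total time taken after signal removal for the output to return to its
unstimulated level. "Returned" needs an operational cutoff; the
package uses a fraction of the peak above baseline, with
`baseline_fraction` defaulting to 0.01 (1% of the peak), configurable
and reported with all outputs.

Robustness follows the SBML-SAT convention. For a perturbed parameter
vector, the total parameter variation is
$TPV = \sum_n |\log_{10}(k_n/k_{n0})|$, and over $N$ perturbation
simulations the robustness coefficient of output $f$ is
$$R = -\frac{1}{N}\sum_{p=1}^{N}\left|\log_{10}\frac{f_p}{f_0}\right| \le 0,$$
with values closer to 0 indicating a more robust system. The absolute
value (log base 10) is used in both sums so over- and under-shoots
cannot cancel — without it $R$ could be positive, contradicting its
definition as a non-positive quantity. Outputs that collapse are
floored at $10^{-12}$ nM to keep the logarithm finite; floored runs are
counted and reported. Perturbations use the stated Latin-hypercube
protocol: per varied quantity a grid of 2000 *equidistant* (linear)
values on $[0.1, 10] \times$ reference, from which each of the 5000
simulations draws one value per quantity uniformly at random. The
hand-rolled sampler implements exactly this contract (the CRAN `lhs`
package draws stratified continuous samples, which is a different
scheme). The robustness output $f$ is the steady-state MK-PP under the
sustained default signal.

## Reference parameters

The package ships deterministic, versioned default parameter sets
(`reference_parameters()`) that emulate the Huang–Ferrell-type regime
of quantitative MAPK reconstitution work, in nM and seconds:

* totals: MKKK 100, MKK 1200, MK 1200 (MKKK well below the downstream
  pools), phosphatases 150 (K1) / 60 (K2), signal 10;
* K1: $k_1 = 2.5\,s^{-1}$ (signal layer), cascade kinase
  $k_{cat} = 1\,s^{-1}$, dephosphorylation $k_{cat} = 0.25\,s^{-1}$
  (MKKK/MKK tiers) and $1\,s^{-1}$ (MK tier); $K_m = 300$ nM except the
  MK-tier dephosphorylation $K_m = 1200$ nM; $K_{se} = 10$ nM;
* K2: $(a, d, k_{cat})$ = (0.01, 1, 2) for phosphorylation,
  (0.005, 2, 1) for MKKK/MKK-tier dephosphorylation, (0.005, 2, 4) for
  the MK tier (so $K_m$ = 300 / 600 / 1200 nM under QSS), and
  $k_f = 1\,(\mathrm{nM\,s})^{-1}$, $k_r = 0.06\,s^{-1}$, giving the
  derived quasi-steady-state $K_{se} = 0.06$ nM — four orders of
  magnitude below the dephosphorylation $K_m$, which is why K2_QSS PSEQ
  models are extremely strongly sequestrated.

Three of these choices deserve comment.

*The MK-tier dephosphorylation is faster and less saturable than the
upper tiers.* Signal memory in the shared-phosphatase designs is driven
by crowding of the upstream phosphatase: in M2, Phos1's denominator is
dominated by the large MKK phosphoform pool, so MKKK-P decays slowly
after signal removal and keeps re-driving the cascade. If the MK-tier
phosphoforms crowded their phosphatase equally strongly, the M3 design
(Phos2 shared by MKK+MK) would inherit an even longer tail and overtake
M2. With the MK tier relatively fast ($k_{cat} = 1$, $K_m = 1200$), the
designs order as the mechanism predicts: M2 has the longest and M1 the
shortest memory, with M2 > M4 (M4's contested middle tier frees Phos1
to terminate MKKK-P sooner than in M2).

*K1 and K2 defaults are independent sets*, adopted separately rather
than mapped onto each other, so K1-vs-K2 values are not directly
comparable; only comparisons among the four designs within one scheme
are meaningful.

*K2 phosphatase totals sit below the MKKK pool.* With
$K_{se} = 0.06$ nM the K2 sequestration is effectively stoichiometric:
whatever free kinase exceeds the phosphatase pool locks it away. If
Phos1 exceeded MKKK_total, the entire MKKK pool would be complexed at
rest and the PSEQ reference would be degenerate (free MKKK below 0.1
nM). With phosphatases at 60 nM the sequestrated K2 models are shielded
rather than starved, reproducing the directional finding that
sequestration improves robustness in every design.

All defaults were fixed by checking the package's own simulations
against the qualitative behaviour the models are meant to exhibit
(feedback direction and approximate two-fold amplitude ratio, memory
ordering, robustness directions), and are frozen; they are inputs of
the analysis, not fitted quantities.

## What the experiments show (and how they are tested)

**Implicit negative feedback (M4).** Only in M4 do Phos1 and Phos2
compete for the MKK-layer substrates. Raising Phos2 collapses the MKK
phosphoforms, which de-crowds Phos1's denominator and increases its
flux onto MKKK-P — steady MKKK-P falls without any physical
Phos2-MKKK interaction. Under the defaults the amplitude at Phos2 = 5
nM is ~1.8 times the amplitude at 1000 nM, with the descent
concentrated near Phos2 ≈ 220-400 nM; in M1-M3 the MKKK layer is
analytically decoupled from Phos2 and the sweep is flat to solver
tolerance. Strong sequestration abolishes the feedback: at the small
end of the $K_{se}$ grid the amplitude difference is below 1% of the
MKKK pool.

The $K_{se}$ sweep grid spans six decades ($10^{-2}$ to $10^4$ nM)
rather than a narrow band around the default: under the defaults the
feedback only falls below 1% of the MKKK pool for
$K_{se} \lesssim 0.03$ nM, and the unsequestrated limit is approached
only above $\sim 10^3$ nM, so a narrower grid would miss both ends.
One genuine feature of this regime is worth knowing: at intermediate
$K_{se}$ (~10-100 nM) the amplitude difference *crosses zero and turns
negative* (about −9 nM at its extreme) before decaying to zero. High
Phos2 lowers MKK-PP, which frees unphosphorylated MKK, which sequesters
Phos1 — a sequestration-mediated *positive* coupling that can locally
overcome the competitive negative one. The tested property is therefore
the envelope (the difference at the strong-sequestration end is far
below the weak-sequestration end, and below 1% of the pool), not
point-wise monotonicity.

**Memory.** With a 10 nM, 600 s signal, USEQ memory orders
M2 > M3 > M4 > M1 under the K1 defaults (the tested contract is M2
maximal, M1 minimal, M2 > M4), and sequestration increases the memory
of every design — by roughly two orders of magnitude at
$K_{se} = 10$ nM, and to beyond the $2\times 10^6$ s integration
horizon for the K2 models (reported as censored lower bounds).

**Robustness.** Under the defaults, the USEQ output is much more
robust to kinase-pool variation than to phosphatase-pool variation
(output collapse when phosphatases rise dominates $|R|$), and PSEQ
improves the coefficient in *every* design, scheme, and perturbation
class. The USEQ/PSEQ comparison is paired — both conditions see the
same Latin-hypercube draws — so the ordering is stable at N = 500 even
where the margin is small (the kinase-variation margin in K2 is a few
thousandths).

**Dose-response.** PSEQ lowers the activation threshold (smallest dose
reaching 5% of the saturation amplitude) by one to four orders of
magnitude, the robustness/noise-sensitivity trade-off of sequestration.

## Numerical choices

* Stiff integration: `deSolve::ode` (lsoda) with rtol $10^{-8}$ /
  atol $10^{-10}$ nM defaults; protocol discontinuities are handled by
  restarting the integration at signal-on/off.
* Steady states: doubling-chunk integration until
  $\max|dy/dt| < 10^{-9}$ nM/s, then (K1/K2_QSS, five state variables)
  a damped Newton polish on the right-hand side; K2 steady states rely
  on the integration criterion alone, since the conservation-degenerate
  Jacobian makes a raw Newton step ill-posed.
* The production right-hand sides are evaluated in C (a table-driven
  evaluator fed by flat parameter vectors); the R closures of
  `build_k1_rhs()` and `mass_action_rhs()` are the reference
  implementation and the two paths are regression-tested against each
  other to solver tolerance.
* Robustness runs use relaxed tolerances (rtol $10^{-6}$, steady
  criterion $10^{-6}$ nM/s): $R$ aggregates $\log_{10}$ ratios, for
  which three significant digits of the output are ample.
* Tiny negative free-kinase excursions produced by the solver are kept
  as-is (the flux terms are smooth through zero and self-correct);
  states overdrawing a conservation pool by more than $10^{-4}$
  relative raise an error rather than being clipped.
* The K1 signal is clamped to zero after `t_off`; in K2 the free
  signal species is clamped at `t_off` while bound signal runs to
  completion, mimicking ligand washout. (The alternative — deleting
  signal complexes instantly — was considered and rejected as
  unphysical; the clamp is the package's fixed behaviour.)

## Problem sizes used in the checks

The shipped checks run the robustness ordering at N = 500 simulations
per case (48 cases; reduced-N estimates are verified against N = 5000
within three Monte-Carlo standard errors), conservation over 5000 s
horizons for all 16 design-scheme-mode combinations, feedback sweeps on
16-30 point grids, and dose-response on 10-point dose grids. The
quasi-steady-state consistency check uses a documented
hierarchical-concentration regime (totals 5/50/500 nM, phosphatases 5
nM, signal 1 nM) in which enzyme pools are far below substrate pools;
there K2 and K2_QSS steady outputs agree within 5% (about 1% in
practice). At the packaged default concentrations the two schemes
deviate by ~4-12% because a large fraction of the MK pool is held in
enzyme-substrate complexes — a real limitation of the QSS reduction,
not a solver artefact.

## What the synthetic defaults do not capture

The defaults emulate a deterministic, well-mixed, single-compartment
cascade with constitutive phosphatases. They do not emulate
transcriptionally induced phosphatases, nuclear compartmentalisation,
explicit ERK-to-Raf feedback, or cell-to-cell variability — so passing
tests demonstrate the structural consequences of the wiring designs
under biologically plausible rates, not quantitative agreement with any
particular cell line. Alternative parameterisations — for instance
literature values for a specific cell system — can be supplied as
configuration files or SBML documents and take precedence over the
defaults.
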