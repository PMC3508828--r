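# mapkdesign

Comparative modelling of kinase–phosphatase interaction designs in the
three-tier MAPK signalling cascade.

## The problem

The MAPK cascade (MKKK → MKK → MK, with doubly phosphorylated MK-PP as
output) keeps its kinase–kinase interactions invariant across
organisms, but its phosphatases wire to the tiers in several distinct
configurations: one dedicated phosphatase per tier, a phosphatase
shared between the top two tiers, one shared between the bottom two, or
a middle tier contested by two phosphatases (as in the B-cell ERK
module, where PP2A serves MKKK+MKK and MKP3 serves MKK+MK). On top of
the wiring, unphosphorylated kinases can bind and *sequester* their
phosphatases. `mapkdesign` is for systems biologists who want to ask:
what do the wiring design and sequestration do, by themselves, to the
robustness, signal memory, and dose–response of the cascade?

The package builds all four designs (M1–M4) under Michaelis–Menten
kinetics (K1), elementary mass action (K2), and the quasi-steady-state
reduction of mass action (K2_QSS), each with (PSEQ) and without (USEQ)
phosphatase sequestration — 24 model variants from one set of
constructors — and provides:

* stiff ODE simulation under sustained or transient signal protocols,
  with output metrics: amplitude, duration, and **memory** (the total
  time taken by the output to return to its unstimulated level after
  signal removal);
* a Latin-hypercube **robustness analysis**: the total parameter
  variation `TPV = Σ |log10(k/k0)|` and the robustness coefficient

  `R = −(1/N) Σ |log10(f_p / f_0)| ≤ 0`

  of the steady MK-PP output over N perturbation simulations (closer to
  0 = more robust), plus the PSEQ−USEQ robustness difference;
* experiment drivers for the **implicit negative feedback** from Phos2
  to the MKKK layer in M4 (a pure competition effect — no physical
  Phos2–MKKK interaction), its control by sequestration strength,
  transient-signal memory tables, and dose–response/activation
  thresholds;
* SBML L2V4 import/export, JSON/YAML parameter files, and a small CLI.

## Worked example

Steady state of the contested-middle-tier design M4 under a sustained
10 nM signal, and the implicit negative feedback:

```r
library(mapkdesign)

m <- default_model("M4", "K1", "USEQ")
steady_state(m, signal_protocol(10))[c("MKKK_P", "MKK_PP", "MK_PP")]
#>  MKKK_P  MKK_PP   MK_PP
#>   72.72  553.50 1183.23

phos2_amplitude_sweep(m, phos2_grid = c(5, 220, 400, 1000))
#>   Phos2_total amplitude
#> 1           5  76.14329
#> 2         220  65.28863
#> 3         400  46.78105
#> 4        1000  41.48848
```

Raising Phos2 from 5 to 1000 nM nearly halves steady MKKK-P (76 → 41
nM) although Phos2 never touches MKKK: competition with Phos1 for the
MKK-layer substrates de-crowds Phos1, which then dephosphorylates
MKKK-P harder. In M1–M3 the same sweep is flat. The descent sits in the
220–400 nM window.

Memory of a transient signal (10 nM for 600 s) and the effect of
sequestration:

```r
transient_memory_experiment(topologies = c("M1", "M2"), scheme = "K1")
#>   topology sequestration peak_amplitude duration  memory
#> 1       M1          USEQ           1137    679.2   103.6
#> 2       M2          USEQ           1176    755.9   177.8
#> 3       M1          PSEQ           1178   9224.1  8636.6
#> 4       M2          PSEQ           1179  10923.5 10323.9
```

The shared-phosphatase design M2 remembers the signal longest (its
Phos1 is crowded by the MKK pool, so MKKK-P keeps re-driving the
cascade after the signal ends), and sequestration stretches every
design's memory by nearly two orders of magnitude.

Robustness of the output to phosphatase-concentration perturbation
(0.1–10× reference, 2000 strata, N = 500 here):

```r
spec <- perturbation_spec("phosphatases", n_simulations = 500, seed = 1)
run_robustness(default_model("M2", "K1", "USEQ"), spec)
#> robustness of M2^K1_USEQ under phosphatases variation: R = -6.096 (N = 500)
run_robustness(default_model("M2", "K1", "PSEQ"), spec)
#> robustness of M2^K1_PSEQ under phosphatases variation: R = -0.03583 (N = 500)
```

`robustness_difference(-0.036, -6.096)` ≈ 6.06: sequestration moves the
coefficient two orders of magnitude towards 0 — the unsequestrated
output collapses over much of the perturbation range, the sequestrated
one barely moves.

A command-line wrapper ships in `inst/exec/mapkcascade`:

```sh
Rscript inst/exec/mapkcascade robustness --model M2 --scheme K1 \
    --seq USEQ --vary phosphatases --n 500 --seed 1 --out-dir results/
```

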