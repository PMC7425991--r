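# sigmux

Multiplexing capacity of stochastic signalling systems.

Signalling hubs such as NF-κB translate many simultaneous inputs (cytokine
dose and timing, temperature, drugs) into one noisy, oscillatory
transcription-factor response. `sigmux` asks — and quantifies — whether a
downstream observer could tell *which* inputs changed from the stochastic
response alone. It implements:

* **model_core** — stochastic reaction networks (mass-action + Hill rate
  laws, time-gated stimulus dose, system size Ω linking copy numbers and
  concentrations), with built-in NF-κB model variants (`base`, `mNFkB`,
  `m2NFkB`, a downstream `gene_module`, and a `toy` limit-cycle oscillator),
  plus a validated JSON model format;
* **deterministic** — adaptive Dormand–Prince ODE solution of the Ω → ∞
  limit, analytic Jacobians, and peak/trough observation schedules;
* **pclna** — the phase-corrected Linear Noise Approximation: joint Gaussian
  ensembles over scheduled observation times, transversal-section
  projection, and fast trajectory sampling;
* **ssa** — exact Gillespie simulation, a one-way hybrid pcLNA-core /
  SSA-gene simulator, and confidence envelopes;
* **infogeom** — closed-form Gaussian Kullback–Leibler divergences,
  Neyman–Pearson likelihood-ratio tests, the Fisher information matrix in
  log-parameter coordinates, and its factor `s` with `s's = I`;
* **multiplexing** — the QR-based multiplexing calculus: normal components
  `n(i|·)`, the (essentially unique) greedy signal ordering with capacities
  `MX_k = v_k²/2`, threshold subsets, the parameter→signal chain rule, and a
  brute-force KL-minimisation oracle;
* **channels** — dose → nuclear-NF-κB scalar channels with log-normal
  extrinsic cell-to-cell variability and Blahut–Arimoto capacity;
* **fixtures_validation** — a packaged gene-expression decision-table
  worked example and a pcLNA-vs-SSA validation harness.

## The statistic at the core

For signals `S = (S_1, …, S_s)` acting on a stochastic response `R` with
distribution `P_S(R)`, detecting a change in signal `i` against arbitrary
confounding by the others is governed by the scaled minimum divergence

```
D_KL(i, S0) = min_{S'} l(S)^-2 D_KL(P_S || P_S'),   S'_i = S0_i .
```

Locally this equals `||n(i | j ≠ i)||² / 2`, where `n` is the component of
the i-th column of the sensitivity matrix `s` (with `s's = I`, the Fisher
information in log-parameters) orthogonal to the span of the other columns.
Reordering the signals greedily gives nonincreasing residual lengths `v_k`
and the multiplexing capacities `MX(S_i1…S_ik) = v_k²/2`, bounded by the
singular-value products `v_1···v_k ≤ σ_1···σ_k` (equality at `k = s`).
Rapidly decaying spectra ("sloppiness") therefore put a hard ceiling on how
many signals a system can multiplex.

## Worked example

Multiplexing capacities of the base NF-κB model, observed at the first 5
peaks and 4 troughs of nuclear NF-κB under continuous 10 ng/ml TNFα:

```r
library(sigmux)
net   <- build_model("base")
prot  <- stimulus_protocol("continuous", dose = 10, horizon = 600)
traj  <- solve_macroscopic(net, prot)
sched <- observation_schedule(traj, "NFkB_n", q = 9)
round(sched$times, 1)
#> [1]  15.6  69.9 183.0 233.9 312.6 361.8 430.0 478.4 542.0

ps <- parameter_space(net, default_selection(net))
I  <- fim(model_ensemble_fn(net, prot, sched, ps), ps)
s  <- sensitivity_factor(I)
mx_ordering(s)
#> MultiplexingReport (nats)
#>   k signal       v        MX   tie
#> 1 1  TNFKB 866.400 3.753e+05 FALSE
#> 2 2     kp 103.500 5.355e+03 FALSE
#> 3 3    c3a  68.290 2.332e+03 FALSE
#> 4 4    c4a  44.050 9.702e+02 FALSE
#> 5 5   ka1a  43.200 9.332e+02 FALSE
#> 6 6     ki  34.910 6.094e+02 FALSE
#> 7 7    c1a  27.430 3.763e+02 FALSE
#> 8 8   kc1a  20.850 2.174e+02 FALSE
#> 9 9   dose   0.296 4.381e-02 FALSE
```

Read: the total NF-κB abundance dominates every other direction by nearly
an order of magnitude in `v` (the spectrum is sloppy), capacities collapse
by three orders within a few signals, and the TNFα dose — nearly saturated
at 10 ng/ml — is almost undetectable against confounding by the kinetic
parameters. A system described by this model cannot multiplex many signals;
the `mNFkB` variant (an extra regulated NF-κB state driven by an
independent signal `S2`) raises `MX_2` and `MX_3` and promotes `S2` into
the top capacities, which is the paperback argument for post-translational
modification states as multiplexing enablers.

The packaged decision-table worked example (gene codes at 30/130 min):

```r
distinguishable_info(decision_table(), 30)$count        # 5 conditions
distinguishable_info(decision_table(), c(30, 130))$bits # 2.585 bits
```

## Command line

```sh
./exec/sigmux model export --variant m2NFkB -o model.json
./exec/sigmux ode --variant base --protocol continuous --dose 10 -o traj.csv
./exec/sigmux fim --variant base --q 9 -o fim.csv
./exec/sigmux mx --fim fim.csv --threshold 1
./exec/sigmux capacity --variant base --q 5 --doses 8 --cv 0.3 --seed 1
./exec/sigmux validate pclna-vs-ssa --n 500 --seed 1
./exec/sigmux figure2 --times 30,130
```

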