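---
title: "Quantifying signal multiplexing in stochastic oscillatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying signal multiplexing in stochastic oscillatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sigmux)
```

## The question

A signalling hub such as NF-κB receives many simultaneous inputs — cytokine
level and timing, temperature, drugs — and answers with a single, noisy,
oscillatory transcription-factor response that regulates hundreds of genes.
Can a downstream observer, seeing only the stochastic response, tell *which*
inputs changed? We call a system that supports this *multiplexing*, and this
package implements a local information-geometric calculus that quantifies it
for any stochastic reaction network, together with the simulation machinery
(pcLNA, SSA, hybrid) needed to compute the relevant distributions at scale.

## The model class and the pcLNA

A `ReactionNetwork` is a density-dependent Markov jump process: copy numbers
$X$, concentrations $x = X/\Omega$, and copy-number propensities
$a_j(X,t) = \Omega f_j(x,t)$, where each concentration-scale rate $f_j$ is a
product of a rate constant, mass-action powers and Hill terms, optionally
gated by a piecewise-constant stimulus $\mathrm{dose}(t)$. The system size
$\Omega$ (units L/nM) converts between the two scales, and noise scales as
$\Omega^{-1/2}$.

The macroscopic limit solves $\dot x = F(x,t) = \nu f(x,t)$ (Dormand–Prince
5(4), adaptive, restarted at stimulus edges; tolerances $10^{-8}/10^{-10}$
for trajectories, relaxed to $10^{-7}/10^{-10}$ inside the covariance
propagation). The linear noise approximation describes fluctuations
$\xi = \sqrt{\Omega}(x - \bar x)$ as Gaussian with covariance
$\dot V = JV + VJ^\top + \Omega^{-1} D$, $D = \nu\,\mathrm{diag}(f)\nu^\top$,
and cross-time blocks propagated through the fundamental matrix of
$\dot\Phi = J\Phi$.

For oscillatory systems the plain LNA degrades over time: phase diffusion
accumulates variance along the orbit until the Gaussian no longer resembles
the true banana-shaped fixed-time distribution. The *phase-corrected* LNA
exploits the empirical stability of the distribution on *transversal
sections* — hyperplanes crossing the orbit orthogonally to the flow. At each
scheduled observation time the Gaussian is projected onto the section
(removing the flow direction and with it the accumulated phase variance) and
re-anchored before propagation continues. Two conventions were genuinely
open:

* **Resetting rule.** We reset at every scheduled observation time (rather
  than once per period), because the observation times are exactly where the
  distributions are consumed downstream.
* **Section orientation.** Sections are orthogonal to the flow vector at the
  anchor. Isochron-based sections are a known alternative with theoretical
  appeal; they require computing asymptotic phase and are out of scope. This
  choice only matters at second order in the fluctuation size.

Sampling (`pclna_simulate`) draws the section-projected Gaussian at each
phase, then maps the sample forward with $\Phi$ plus fresh process noise.
Negative copy numbers (possible for low-copy coordinates) are truncated at
zero and counted; the count is attached to the returned array so validation
can bound the truncation frequency.

## Fisher information, sensitivity matrix, multiplexing capacities

All sensitivities are computed in scaled coordinates
$\theta_j = \log\tilde\theta_j$, so that steps are relative parameter
changes and parameters of different magnitudes are comparable. The Gaussian
Fisher information at $\theta_0$ is

$$I_{ij} = \partial_i\mu^\top \Sigma^{-1} \partial_j\mu +
\tfrac12\,\mathrm{tr}\!\left(\Sigma^{-1}\partial_i\Sigma\,
\Sigma^{-1}\partial_j\Sigma\right),$$

with derivatives by central differences (default relative step $10^{-3}$,
with an optional step-halving self-check) and an eigenvalue-floored
pseudo-inverse ($10^{-10}\lambda_{\max}$) for near-singular covariances. The
covariance term is included: the information of the full response
distribution, not a mean-only surrogate.

The local divergence for a signal change $\delta S$ is
$D_{KL} = \tfrac12\,\delta S^\top I\,\delta S$ up to third-order terms. A
factor $s$ with $s^\top s = I$ (the *sensitivity matrix*; columns are
principal sensitivity coefficients) generates the multiplexing calculus:

* $n(i\,|\,i_1,\dots,i_k)$ — component of $s_i$ orthogonal to the span of
  the conditioning columns (QR residual);
* per-signal detectability $D_{KL}(i, S_0) = \|n(i\,|\,j\neq i)\|^2/2$;
* the greedy ordering $i_1 = \arg\max\|s_i\|$,
  $i_k = \arg\max \|n(i\,|\,i_1,\dots,i_{k-1})\|$, whose residual lengths
  $v_1 \ge \dots \ge v_s$ give the nested-subset capacities
  $MX_k = v_k^2/2$, with $v_1\cdots v_k \le \sigma_1\cdots\sigma_k$ and
  equality at $k=s$.

Because every one of these quantities depends on $s$ only through the Gram
matrix $s^\top s = I$, the choice of factor is irrelevant; we use the
pivoted Cholesky factor and cross-check against the symmetric square root
in the tests. Capacities default to nats (a `bits` flag converts), since
the defining divergences are log-base agnostic.

A brute-force oracle (`brute_force_oracle`) independently evaluates the
defining scaled minimum divergence by direct numerical minimisation of the
exact Gaussian KL over the confounding hyperplane, probing
$S = S_0 \pm l\,e_i$. The probe is restricted to the two axis directions
because, in the local theory, the minimising probe changes only the $i$-th
component; sampling more directions would only rediscover this. The oracle
exists purely to test the QR formulas and converges to them as $l \to 0$
(the error is the third-order remainder).

### What the response R is

The printed analyses do not pin down the exact observation vector. We
define the response, once, as the **full state at the scheduled times,
expressed in transversal-section coordinates fixed at $\theta_0$**
(dimension $(d-1)q$). Rationale: (i) after phase correction the per-time
covariance is singular in exactly the flow direction, and section
coordinates remove that null space so the Gaussian family stays regular;
(ii) a fixed observation map is required for finite differences in
$\theta$ to be meaningful. An alternative (single observed species at the
scheduled times) is supported via `coords = "state"` and gives the same
qualitative conclusions with less information.

### Identifiability of the selection

`dose` and `ka` enter the model only through the single IKK-activation
propensity, multiplicatively; in log-coordinates their sensitivity columns
are exactly collinear, and a selection containing both has a structurally
zero multiplexing capacity. The default 9-signal selections therefore keep
`dose` (and, in the modified models, `S2`/`p_d1`) and drop the redundant
partner (`ka`, `p_m1`).

## The built-in models

The base model is the classical two-compartment NF-κB oscillator family:
TNFα activates an IKK neutral→active→inactive cycle; active IKK degrades
IκBα (free and in complex), liberating NF-κB to the nucleus; nuclear NF-κB
drives IκBα and A20 transcription (Hill $h = 2$, $K = 65$ nM); IκBα
resequesters NF-κB, A20 shuts IKK down. All concentrations live in one
volume $\Omega$ (nM, minutes). The authoritative supplementary listing of
rate constants was not available when this package was written; constants
are therefore the published values of the reference model family where
known, plus reconstructed values chosen *once* so that the model reproduces
the published qualitative behaviour — sustained ≈106-min nuclear NF-κB
oscillations under continuous TNFα with a dominant first peak, low basal
nuclear NF-κB, TNFα EC50 ≈ 0.1 ng/ml, and nuclear NF-κB copy numbers of a
few thousand ($\Omega = 100$ L/nM). Each constant's provenance is recorded
in the model JSON (`write_model_json`). Consequences of this reconstruction
for specific published numbers are discussed under *Limitations*.

`mNFkB` adds a reversibly modified cytoplasmic NF-κB pool driven by an
independent signal $S_2$ (saturating, $S_2/(S_2+k_{S_2})$), competing with
the unmodified form for the shared free IκBα but otherwise subject to the
same reactions; the reverse rate is $p_{d1}$. `m2NFkB` makes the
modification require both $S_2$ *and* active IKK — AND logic implemented as
a product of saturating terms, the minimal functional form consistent with
joint control. `gene_module` adds EGR1 (activated by nuclear NF-κB,
repressed by nuclear mNF-κB) and COX-2 (the reverse regulation); its rate
constants are fixture values (non-paper), sized for tens of transcripts.
`toy` is a Brusselator at $a=1$, $b=2.5$, close to its Hopf point so the
cycle is near-harmonic and the LNA is accurate at $\Omega = 1000$ — it
validates the machinery, not LNA breakdown.

## Simulation: SSA and the hybrid scheme

`ssa_simulate` is the direct-method Gillespie algorithm with propensity
recomputation per event (networks are small); the piecewise-constant dose
is handled by restarting the exponential clock at window edges, which is
exact for step propensities. Gene expression is far from Gaussian at tens
of copies, so `hybrid_simulate` couples a pcLNA core to an SSA gene module
one way (core → genes): the core path imposed on the genes is the
deterministic solution plus a piecewise-linear interpolation of the sampled
deviation between scheduled phases, refreshed on a 1-min subgrid with
propensities frozen per subinterval. The freezing is an approximation; its
scale is the change of the transcription propensity over one minute, which
is small relative to the gene-module event rate. Gene-to-core feedback is a
non-goal and is rejected.

## Scalar channels

`build_channel` models the dose→response channel: for each dose on a fixed
log-spaced grid (default 8 levels over 0.01–10 ng/ml), the response
distribution of nuclear NF-κB copy numbers at the scheduled phases is a
mixture of pcLNA Gaussians over extrinsic draws of the total NF-κB
abundance and $\Omega$, log-normal with mean 1 and CV 0.3 by default (the
source's exact extrinsic parameters are unavailable; the CV is a documented
placeholder). Mixture densities are evaluated in log space with
log-sum-exp. Capacity is computed by Blahut–Arimoto: exactly on discrete
transition matrices (`ba_discrete`, used for closed-form checks), and by a
Monte-Carlo variant on the Gaussian-mixture channel with fixed response
samples per input and the standard nondecreasing lower-bound trace. The
number of mixture atoms matters: too few atoms make the extrinsic state
effectively observable and inflate capacity; estimates are reported at the
mixture size used and converge from above as it grows.

## What a green test establishes — and what it does not

The synthetic worlds here emulate: sustained stochastic oscillations with
realistic copy numbers, step-like stimulus protocols, cell-to-cell
variability in two global factors, and one-way gene readout. They do not
emulate: receptor-level signal transduction, digital (all-or-none) cell
activation at low TNFα, extrinsic variability in pathway kinetics (e.g.
per-cell EC50), transcriptional bursting, or measurement noise. Green
distributional tests establish that the pcLNA machinery reproduces the
exact SSA law of the *model*; they say nothing about fidelity to cells.

## Numerical choices

Symmetrisation $\Sigma \leftarrow (\Sigma+\Sigma^\top)/2$ after every
covariance operation; eigenvalue floor $10^{-10}\lambda_{\max}$ on all
covariance inversions, with the condition number attached to KL results;
peak detection by derivative sign change with local quadratic refinement
(grid-refinement convergence < 0.1 min is tested); ties in the greedy
ordering broken by index and flagged at $|{\Delta v}| < 10^{-10}$;
negative LNA samples truncated at zero with a logged count; fixed seeds
make every stochastic routine bitwise reproducible.

## Known limitations

* The reconstructed rate constants reproduce the reference model's
  qualitative dynamics, but quantitative published figures tied to the
  exact parameter set do not all transfer. Two matter here. The published
  spectral-gap claim (second sensitivity singular value below 1% of the
  first) measures ≈ 0.12 on the reconstruction (≈ 0.015 if read as
  eigenvalues of the FIM). And the multi-phase dose channel measures
  ≈ 1.9–2.3 bits rather than ≈ 1: with a $q$-dimensional response the two
  extrinsic scale factors can be demixed from the trajectory shape, so the
  capacity is nearly independent of the extrinsic CV; reproducing the
  published one-bit figure presumably requires the unavailable extrinsic
  specification (e.g. per-cell stimulus-sensitivity variation). Both are
  asserted faithfully in the acceptance suite and left failing, with the
  measured values in the failure messages.
* The two-point-schedule comparison (10 min before and at the first peak)
  shows a *larger* relative modified-model gain than the 9-point schedule
  on the reconstruction, opposite to the published direction: with $S_2$
  constitutively on, the modified pool shifts the early response enough
  that two early observations already reveal it.
* LNA truncation error is $O(\Omega^{-1})$ in means; distribution-level
  comparisons at sample sizes around 500 need $\Omega \gtrsim 10^4$ on the
  toy cycle, which is why the acceptance comparison runs the toy at
  $\Omega = 10^4$.
* The hybrid scheme freezes gene propensities on a 1-min subgrid and the
  pcLNA core path is piecewise-linear between phases.
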