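---
title: "Methods: from compression cycles and swelling series to network structure and chi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from compression cycles and swelling series to network structure and chi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelassay)
```

`gelassay` infers polymer-network structure and polymer–solvent
thermodynamics of biopolymer hydrogels from two bulk experiments:
unconfined cyclic compression and gravimetric/pycnometric swelling. This
vignette describes the models, the numerical choices, and — importantly —
what the synthetic-data tests do and do not demonstrate about real data.

## Constitutive models

Both models describe an incompressible, isotropic network whose
deformation enters only through the first invariant
$I_1 = \lambda^2 + 2/\lambda$ (uniaxial). Compression is handled in
stretch space, $\lambda = 1 - \epsilon$; stresses are *nominal*
(force over undeformed area), stored internally with sign (negative in
compression) and presented as magnitudes, matching how compression data
are usually plotted.

**Neo-Hookean.** Gaussian chain statistics give
$\sigma = G(\lambda - \lambda^{-2})$ with $G = \nu k_B T$, $\nu$ the
number density of elastically active strands. Because $\sigma$ is linear
in $G$, `fit_nh()` computes the least-squares minimiser in closed form —
the exact solution of the same objective an iterative solver would
minimise.

**Arruda–Boyce (eight-chain).** Strands on the diagonals of a unit cell
deform by $\lambda_{chain} = \sqrt{I_1/3}$ and carry Langevin (finite
extensibility) statistics:
$$\sigma = G\,\frac{\sqrt{N}}{\lambda_{chain}}
  L^{-1}\!\left(\frac{\lambda_{chain}}{\sqrt{N}}\right)
  (\lambda - \lambda^{-2}), \qquad G = \frac{\nu k_B T}{3},$$
with locking stretch $\lambda_l = \sqrt{N}$. As $N \to \infty$,
$L^{-1}(x) \to 3x$ and the model reduces to $3G(\lambda-\lambda^{-2})$ —
a Neo-Hookean response of modulus $3G$. This Gaussian limit is enforced by
test (0.1% over $\lambda \in [0.8, 1.25]$ at $N = 10^6$) and pins down the
algebraic form of the stress: alternative readings of the eight-chain
nominal stress that do not reduce to the Gaussian limit are rejected.

The inverse Langevin function uses the Petrosyan closed form
$$L^{-1}(y) = 3y + \frac{y^2}{5}\sin\!\left(\frac{7y}{2}\right) +
  \frac{y^3}{1-y}, \qquad 0 \le y < 1 .$$
Rather than trusting the cited error bound, the test suite certifies it
against a bisection oracle on a 1000-point grid over $y \in [0.01, 0.95]$:
the maximum relative error is $1.8\times10^{-3}$, within the
order-$10^{-3}$ bound the approximation is known for.

## Preprocessing and the stability screen

Specimens are tested in repeated loading–unloading cycles. Fits use the
loading arms, resampled by linear interpolation onto 100 evenly spaced
strains over the cycles' common range and averaged point-wise
(`cycle_policy = "average"`; `"first"`/`"last"` select single cycles).
Averaging mirrors the common practice of fitting average stress–strain
responses and reduces effective noise by $\sqrt{n_{cycles}}$.

Before fitting, the loading arm must pass Drucker's first stability
criterion: incremental slopes $\Delta\sigma/\Delta\epsilon \ge 0$. Two
defaults make the screen noise-robust: slopes below 1% of the maximum
observed slope are tolerated, and up to 5% of increments may violate.
One further numerical choice matters: the increments are formed on the
arm resampled to **11 points** (2%-strain steps at the protocol's 20%
range), not on the dense fitting grid. Incremental slopes on a fine grid
measure point noise (slope noise grows as $1/\Delta\epsilon$), and at
instrument-level noise a perfectly stable specimen would trip a
fine-grained screen a few percent of the time; 2%-strain increments
estimate the underlying derivative. A genuinely softening arm still fails
at any resolution, which the pipeline tests exercise with a corrupted
specimen.

## Identifiability of the eight-chain parameters

A point worth making explicit, because it governs what the recovery tests
can promise. Over a compression window of 20% strain the chain stretch
only reaches $\lambda_{chain} \approx 1.023$. For moderate $N$ (say
$N = 4$, i.e. $\lambda_{chain}/\sqrt{N} \approx 0.51$) the Langevin
stiffening factor is then *nearly constant* (~1.21) across the whole
window: $G$ and $N$ trade off almost perfectly, and at 2% stress noise
the pair is practically unidentifiable from one cycle — the fitted $N$
wanders by orders of magnitude while the *product* (the effective
modulus) stays right. Two consequences:

* Fitted Neo-Hookean moduli on stiffening data equal roughly
  $3 G_{AB} \times \langle\text{stiffening}\rangle$, which is why the
  synthetic study's ground-truth ledger records that Neo-Hookean
  projection (computed numerically over the protocol window) as the
  strand density any NH-based analysis will see.
* The Monte-Carlo recovery study is run where the parameters are
  identifiable: a strongly stiffening specimen ($N = 2$, chain stretch
  at 72% of locking by 20% strain) measured with the full five-cycle
  protocol. There, 200 seeded replicates at 2% noise recover $G$ within
  10% and $N$ within 25% in well over 90% of replicates. Noiseless
  self-recovery is exact for both models regardless.

For real gels this means: trust the eight-chain $N$ only if the protocol
visibly enters the stiffening regime; otherwise report the modulus and
treat $N$ as a nuisance parameter.

## Network structure, friction proxy, hysteresis

In the ideal homogeneous cubic-network picture each junction connects two
strands: $c = \nu/2$, $\xi = c^{-1/3}$. Mesh sizes are reported in nm and
densities on the $10^6\,\mu m^{-3}$ ($=10^{24}\,m^{-3}$) scale customary
for these gels, SI internally. The polymer–solvent friction coefficient
is reported only as the proxy $\rho_s \xi^{-2}$ (kg·m⁻⁵): the blob-scale
relation defines $f$ up to a prefactor, and no viscosity calibration is
attempted, so the proxy supports comparisons and trends but not absolute
permeabilities.

Hysteresis $W_{diss}$ is the area between loading and unloading arms over
their common strain interval: both arms are interpolated onto 200 evenly
spaced strains and integrated by the trapezoidal rule. 200 points keep the
quadrature error well below instrument noise (the analytic test case
$\int(\epsilon - \epsilon^2)d\epsilon = 1/6$ is reproduced to $10^{-4}$
relative). Crossing arms yield a signed area and a warning rather than a
silent clamp. No visco-elastic constitutive model is fitted: dissipation
is quantified, not modelled, and the split of $W_{diss}$ into internal vs
thermal parts is not recoverable from the loop area.

## Swelling, kinetics, composition

Swelling uses the two conventional, deliberately asymmetric ratios
$Q_m = 100(m_t - m_0)/m_0$ (zero at $t_0$) and $Q_v = 100\,V_t/V_0$
(100% at $t_0$). The first-order law $Q(t) = Q_{eq}(1 - e^{-t/\tau})$
vanishes at $t = 0$, so on the $Q_v$ scale the *increment* is fitted:
$Q(t) = 100 + (Q_{eq} - 100)(1 - e^{-t/\tau})$, which makes $Q_{eq} = 100$
the no-swelling fixed point and permits de-swelling series
($Q_{eq} < 100$, as observed when ionic cross-linkers in the medium
densify the network). A constant series leaves $\tau$ unidentifiable and
is returned flagged rather than with an arbitrary number.

Composition comes from drying: with hydrogel density $\rho_h$, dry-polymer
density $\rho_p$ and polymer mass fraction $\omega_p$, the mixing rules
$\rho_h = \sum_i \rho_i\phi_i$ and $1/\rho_h = \sum_i \omega_i/\rho_i$
give $\phi_p = \omega_p\rho_h/\rho_p$ and the viscous-phase density
$\rho_s$; both rules hold on the output to $10^{-12}$ by construction.
Molar properties follow as $V_1 = M_m/\rho_s$ and
$n_M = N_A\rho_s/M_m = N_A/V_1$ (for free water,
$n_M \approx 3.337\times10^{22}\,cm^{-3}$; bound water is denser, raising
$n_M$). Saline media are treated as water for $M_m$; the elevated measured
$\rho_s$ then carries the bound-water signal. Degradation is neglected
throughout (polymer content constant), so
$\phi_p = \phi_{p,0}\cdot 100/Q_v$.

## The equilibrium-swelling solver

At swelling equilibrium the mixing and elastic contributions to the
solvent chemical potential balance. With everything expressed in the
dimensionless bracket normalisation,
$$\phi_{p,eq} + \ln(1-\phi_{p,eq}) + \chi\,\phi_{p,eq}^2 \;=\;
  \mu_{el}(\phi_{p,eq}),$$
which is linear in $\chi$, so `chi_from_equilibrium()` is closed-form and
`phi_eq_from_chi()` is a one-dimensional root find (dense sign-change
bracketing on $(10^{-8}, \min(1.5\phi_{p,0}, 1-10^{-8}))$, Brent
refinement, Newton polish; when several roots exist the one nearest
$\phi_{p,0}$ is returned with the multiplicity reported). For
$\phi_{p,eq} < 10^{-4}$ the mixing bracket is evaluated by its series
$-\phi^2/2 - \phi^3/3 - \phi^4/4$ to avoid catastrophic cancellation, and
the solution carries a warning because $\chi$ is then dominated by a tiny
difference of large terms.

Two conventions in $\mu_{el}$ were genuinely open and are fixed as
follows, with reasons:

* **Strand density at equilibrium.** $\nu_0$ is measured per as-prepared
  volume, but solvent exchange happens in the swollen gel, where strands
  have diluted to $\nu_0\,\phi_{p,eq}/\phi_{p,0}$. The solver evaluates
  the elastic potential with that swollen-state density:
  $$\mu_{el} = \frac{\nu_0 (\phi_{p,eq}/\phi_{p,0})\, V_1 \times 10^{-6}}{N_A}
    \left[\left(\frac{\phi_{p,eq}}{\phi_{p,0}}\right)^{1/3}
    - \frac{1}{2}\frac{\phi_{p,eq}}{\phi_{p,0}}\right].$$
* **Sign.** The elastic correction *adds* to the mixing-only
  ($\theta$-balance) value: $\chi = \chi_{mix} + \mu_{el}/\phi_{p,eq}^2$.

The decisive argument for this pair of conventions is empirical: it is the
only combination that reproduces the published interaction parameters of
strongly cross-linked reference formulations within ±0.005 *and* keeps all
eight reference formulations inside the reported near-$\theta$ band
[0.50, 0.56]. The undiluted elastic term at face-value strand densities
would push weakly cross-linked, highly swollen gels to $\chi > 1$ —
irreconcilable with the published values, whose magnitudes show the
elastic term entering at the percent level. The `elastic_fraction`
diagnostic (share of $\chi$ contributed by the elastic correction, 0.6–7%
across the reference set) keeps this visible rather than buried.

Two consequences of the additive convention are worth knowing. First, at
fixed $\chi$ an *increase* in $\nu_0$ lowers $\phi_{p,eq}$ in the forward
model — the elastic correction behaves as an addition to the apparent
interaction parameter, not as an independent restoring pressure, so
"cross-linking restrains swelling" is carried by the measured
$(\phi_{p,eq}, \nu_0)$ pairs rather than by the forward model's
$\nu_0$-derivative. Second, states with $\chi$ very close to 1/2 and
substantial $\nu_0$ admit no equilibrium in the bracket (the balance
cannot close); `phi_eq_from_chi()` then reports the end-point residuals
instead of fabricating a root. Solvent-quality monotonicity is unaffected:
$\partial\phi_{p,eq}/\partial\chi > 0$ (poorer solvent restrains swelling),
and the $\chi \to 1/2^+$ limit of an uncross-linked gel is indefinite
dilution — both are property-tested.

## The synthetic-data generator

The generator emulates the study conditions the analysis assumes:

* **Compression**: 5 cycles at 300 µm/s crosshead speed on a 6 mm
  specimen (strain rate 0.05 s⁻¹) to 20% strain, 80 samples per arm. The
  stress is an eight-chain backbone (Neo-Hookean when $N = \infty$) plus a
  rate-proportional overstress $\pm\eta_{eff}\,\dot\epsilon$ (sign by
  arm) and 2% multiplicative Gaussian noise (load-cell-like). The
  overstress is the *minimal* mechanism producing hysteresis loops with
  analytically known area $2\eta_{eff}\dot\epsilon\,\epsilon_{max}$; it is
  chosen for testability, not physical fidelity — it is not a
  visco-elastic model and produces no rate-dependent loading curvature or
  conditioning.
* **Swelling**: volumes follow first-order kinetics between $V_0$ and the
  equilibrium; mass and density follow from polymer-volume conservation
  and the mixing rule at constant $\rho_s$; mass and volume receive
  independent 0.5% multiplicative noise, reflecting gas-pycnometry-grade
  repeatability (volume determination by gas displacement is an
  order of magnitude more repeatable than a load cell). With 2% volume
  noise, an information (Cramér–Rao) calculation shows $\tau$ could not be
  recovered within 10% from four time points by *any* estimator, i.e. the
  noise level, not the fitter, would be the binding constraint.
* **Study design**: eight scenarios spanning equilibrium swelling from
  2400% down to a de-swelling case (85%), moduli 2.5–6 kPa, and
  per-time-point moduli scaled as $G_t = G\,(Q_v(t)/100)^{-1/3}$ so the
  normalised-modulus scaling exponent is injected and recoverable. Each
  scenario's $\chi_{true}$ is *derived* from its equilibrium state with
  the same conventions the solver uses; the swelling scenarios land in the
  near-$\theta$ band by construction. Every output embeds the seed and
  regeneration is bit-identical (tested).

What passing these tests shows: the estimators are unbiased and correctly
implemented at instrument-realistic noise, the algebra is mutually
consistent (round trips close to $10^{-10}$), and the pipeline propagates
units correctly end to end. What they do not show: robustness to
barreling, specimen–plate friction, conditioning, degradation (all absent
from the generator), or correctness of the idealised network picture
itself (affine, perfect, monodisperse — assumptions the real gels violate
to an unknown degree).

## Problem sizes and defaults

Default analyses in tests and the acceptance script use 200-replicate
Monte-Carlo studies, 100-point fitting grids, 200-point quadrature, and
single-replicate eight-scenario studies at 2 cycles — sizes chosen so the
entire suite runs in well under a minute while keeping binomial noise on
recovery rates (~2% at 200 replicates) far from the tested margins.
Temperature defaults to 293.15 K (testing at 20 °C); $k_B$ and $N_A$ are
CODATA values; the static pre-load that defines specimen contact is
treated as the zero-strain reference with no stress correction.

## Known limitations

* $I_1$-only models: no Mooney–Rivlin/Ogden, no true-stress or
  friction/barreling corrections for unconfined compression.
* Hysteresis is quantified, never modelled; no Prony/creep machinery.
* No degradation or ion-transport kinetics; polymer content is assumed
  constant through swelling.
* The molecular weight between cross-links is deliberately not derived
  from equilibrium swelling (known to over-estimate).
* $N$ from the eight-chain fit is meaningful only when the protocol
  reaches the stiffening regime (see the identifiability section).
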