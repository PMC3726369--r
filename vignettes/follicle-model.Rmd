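---
title: "A spatio-temporal model of hormone signalling in the growing bovine follicle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spatio-temporal model of hormone signalling in the growing bovine follicle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(follicleRD)
```

## The biological problem

During the first wave of bovine folliculogenesis the dominant follicle
grows from about 5 mm to 15–20 mm in five days. Follicle-stimulating
hormone (FSH) and luteinizing hormone (LH) arrive through the blood
vessels of the theca, diffuse inward, and bind G-protein-coupled
receptors whose expression is itself under hormonal control: FSH
receptors concentrate in the granulosa, LH receptors appear first in the
theca and only days later in the granulosa, and the aromatase that
converts thecal androgens into estradiol is induced in the granulosa by
the combined action of gonadotropin, IGF and estrogen signalling.
`follicleRD` implements this regulatory network as an eleven-species
reaction–diffusion system on a uniformly growing 1D cross-section of the
follicle, with every rate constant taken from published measurements
where one exists.

## Model

### Species and reactions

The state comprises the free hormones F (FSH), L (LH), A (androgens) and
E (estradiol); the free receptors Rf, Rl, Re; the bound complexes Cf,
Cl, Ce; and a lumped IGF-receptor-complex variable I that stands in for
active IGF signalling (its binding proteins and proteases are not
resolved). Four reaction classes are used:

* **Blood exchange** in the theca at rate $\Delta = 1\,\mathrm{s^{-1}}$:
  F, L and A are delivered at their serum-set concentrations
  ($\rho_F$, $\rho_L = 0.4\rho_F$, $\rho_A(1+\sigma_G)$) and all four
  soluble species are removed in proportion to their local
  concentration.
* **Mass-action binding**: each hormone binds its receptor at the common
  rate $k_{on}$ and unbinds at a ligand-specific $k_{off}$; the implied
  dissociation constants are 0.5 nM (FSH), 10 nM (LH) and 0.1 nM
  (estradiol).
* **First-order decay**, with separate turnover rates for free and bound
  receptors (internalised gonadotropin receptors do not recycle). The
  follicular fluid contains no cells, so soluble species are *not*
  degraded there — decay terms carry a factor $(1-\Phi)$.
* **Regulated production**. Regulatory influences are Hill functions
  $\sigma_i = c_i^n/(c_i^n + K_i^n)$ of the bound complexes, with
  $n = 2$ throughout; FSH and LH are assumed to trigger the same
  intracellular programme, so regulation depends on
  $\sigma_G = \sigma_F + \sigma_L$. Receptor production follows
  $\rho_{Rf}(\Gamma\vartheta + \sigma_I(1+\sigma_E))$,
  $\rho_{Rl}\,\sigma_I(1+\sigma_E)$ and
  $\rho_{Re}(1+\sigma_E)(1-\sigma_I)$; the IGF complex is produced as
  $\rho_I \sigma_G$; estradiol is produced from androgens by the
  Michaelis–Menten term
  $\rho_E\,\Gamma\,\frac{A}{A+K_M}\,I\,(1+\sigma_E\sigma_G)(1+\sigma_G)$,
  which absorbs the (not explicitly modelled) aromatase.

`reaction_rates()` exposes these terms as a pure function; the tests
verify stoichiometric consistency, quasi-positivity and the closed-form
steady states pointwise.

### Geometry and growth

The cross-section is the stationary coordinate $\xi \in [-1, 1]$, with
physical position $x = \ell(t)\,\xi$ and diameter
$\Lambda(t) = \Lambda(0) + v t$ ($\Lambda(0) = 5$ mm,
$v = 2.3\times10^{-5}\,\mathrm{mm\,s^{-1}}$, i.e. ~10 mm in 5 days).
Uniform dilation turns the growing-domain problem into a fixed-domain
PDE

$$\partial_t c_i + \frac{v}{\Lambda} c_i =
  \frac{D_i}{\ell(t)^2}\,\partial_\xi^2 c_i + R_i(c),$$

with zero-flux boundaries at $\xi = \pm 1$. Compartments are indicator
functions on $\xi$: theca $\Theta$ for $|\xi| \ge \xi_\theta = 0.99$;
in the antrum variants a cellular block $\Gamma$ made of the 12.5 µm
mural granulosa $[-\xi_\theta, \xi_{\phi 1}]$ plus the
cumulus–oocyte complex $[\xi_{\phi 1}, \xi_{\phi 2}]$; and follicular
fluid $\Phi$ filling the remainder. In the two-compartment variant the
whole interior is granulosa.

Two conventions required a decision, and both are exposed as options:

* **Cell-block indicator.** Taken literally, the printed compartment
  formula starts the cellular indicator at $\xi_{\phi 1}$, which would
  assign the mural granulosa to the fluid — contradicting the stated
  restriction of the aromatase to granulosa and cumulus cells and the
  layer arithmetic (granulosa width $0.005 = \xi_{\phi 1}+\xi_\theta$).
  We therefore let $\Gamma$ span the full cell block
  $[-\xi_\theta, \xi_{\phi 2})$, with $\xi_{\phi 1}$ separating the
  granulosa and COC sub-layers for observables. The cell-block end
  defaults to $\xi_{\phi 2} = -0.835$ (fluid filling the interior);
  `as_printed_phi2 = TRUE` restores the uncorrected sign $+0.835$ for
  comparison.
* **Length convention.** The boundary arithmetic (granulosa 12.5 µm at
  $\Lambda = 5$ mm; $\xi_\theta = 1 - 2\times0.1/20$) treats $\Lambda$
  as a diameter spanned by $\xi \in [-1,1]$, so the default scaling uses
  the half-length $\ell = \Lambda/2$ in the diffusion term; the dilution
  rate $v/\Lambda$ equals $\dot\ell/\ell$ either way.
  `length_convention = "as_printed"` uses $\ell = \Lambda$ verbatim
  (gradients twice as wide in physical units).

A `theca_scale` multiplier thickens the theca (1.2 in the sensitivity
variant) by moving $\xi_\theta$ inward; the granulosa and COC widths are
preserved by tying $\xi_{\phi 1}$ and $\xi_{\phi 2}$ to $\xi_\theta$.

### Parameters and units

Concentrations are nanomolar, time is seconds, lengths millimetres.
Membrane receptors react in a volume ~500-fold smaller than the cell, so
the receptor production rates $\rho_{Rf} = \rho_{Rl} = 0.25$ nM/s and
the Hill constants $K_F = 1500$ nM, $K_L = 5$ nM carry that factor
already; the 500 is stored as data (`membrane_factor`), not recomputed.
Unit-conversion helpers (`receptors_per_cell_to_nM()`,
`iu_per_l_to_nM()`, `mass_conc_to_nM()`, `per_cell_rate_to_nM_per_s()`,
`gradient_length()`) reproduce the arithmetic by which the table values
were derived and are tested against the published figures. The derived
production rate of the IGF complex is $\rho_I = 2.8\,K_I\,\delta_I$
(one passage quotes a factor 3; the parameter table's 2.8 is used).

Initial conditions are zero everywhere except
$I(0) = 0.3\,K_I\,\Theta$: the IGF complex is already present in the
theca at antrum formation, which is what lets thecal LH-receptor
expression start immediately while the granulosa curve rises only after
IGF signalling has accumulated there.

## Numerics

* **Mesh**: boundary-fitted, nonuniform; every compartment boundary is a
  node, thin layers (theca, granulosa) get ≥ 10 uniformly spaced nodes,
  wide layers get end-clustered (Chebyshev-extrema) nodes; the default
  antrum mesh has 139 nodes (~1500 unknowns). Boundary nodes belong to
  the compartment on their theca side, removing the Heaviside
  ambiguity at $H(0)$.
* **Spatial operator**: second-order central differences on the
  nonuniform grid; zero-flux ends via the reflected-ghost one-sided
  stencil. With control-volume quadrature weights the discrete operator
  telescopes exactly, so conserved quantities (e.g. $\int F + C_f$ with
  sources off) are preserved to integrator accuracy — this is tested.
* **Time integration**: `deSolve::lsoda` with a banded numeric Jacobian
  (half-bandwidth 11 from the species-fastest ordering), relative
  tolerance $10^{-6}$, absolute tolerance $10^{-8}$ nM. Binding and the
  blood exchange act on the 1 s scale against a $4.3\times10^5$ s
  horizon, so the system is stiff; a default 5-day antrum run takes a
  few seconds.
* **Negative values**: concentrations are clipped to zero only inside
  the reaction evaluation; the stored state is untouched, and the run
  aborts if any state falls below $-100\times$ the absolute tolerance.
* **Well-mixed antrum** (`antrum_mixed`): operator splitting — after
  each 600 s substep the soluble species are replaced by their
  length-weighted fluid mean. The operation is exactly mass-conserving
  and idempotent.
* **Grid and tolerance convergence**: doubling the mesh changes the
  day-5 compartment-averaged observables by < 1%, tightening the
  tolerances tenfold changes them by < 0.1% (both asserted in the
  tests).

## Analytic limit configurations

The test-bed replaces external data with configurations whose solutions
are known exactly: all sources off (identically zero solution), pure
growth ($c(t) = c(0)\Lambda(0)/\Lambda(t)$), diffusion of a uniform
profile (a fixed point), and binding with all decay switched off
(conservation of ligand + complex). These exercise the dilution term,
the diffusion operator, the boundary conditions and the reaction
coupling independently. They emulate no biological variability — passing
them shows the discretisation and integrator are correct, not that the
model matches follicles.

## Robustness analysis

`robustness_bands()` re-runs a scenario with every rate, affinity,
diffusion and production parameter (plus $\vartheta$, $\Delta$,
$\Lambda(0)$ and $v$; 37 fields in all) jointly multiplied by
independent draws from $\mathcal N(1, 0.2)$, redrawn until positive —
i.e. 20% relative Gaussian noise, constant within a run. The Hill
coefficient, the compartment boundaries and the initial-condition
fraction are not perturbed; they are structural, not kinetic. The
default ensemble is 100 runs; the scaled-down test ensemble uses 10.
All draws come from one seeded stream, so a run index always maps to the
same parameter set and the whole ensemble is bit-reproducible. Failed
integrations are excluded and counted; more than 20% failures aborts.

## Behaviour of the calibrated model, and a transport caveat

Under the default configuration the model reproduces the qualitative
spatial programme: FSH and LH form gradients decaying from the theca
into the receptor-expressing cell block (receptor-mediated uptake makes
the effective penetration depth tens of micrometres); thecal LH-receptor
expression rises immediately while the granulosa curve lags by days;
estradiol production peaks in the granulosa nodes adjacent to the theca,
where androgen supply and IGF signalling are strongest; and estrogen
receptors are essentially saturated wherever estradiol exceeds a few
nanomolar.

One quantitative feature of dominant-follicle physiology is **not**
reproduced at physically consistent length scales: in vivo,
follicular-fluid androgen falls (roughly 107 → 33 nM) while estradiol
rises to ~200–250 nM over the five days. In this implementation the
day-5 fluid-averaged estradiol is ≈ 11 nM and fluid androgen creeps
upward instead. The reason is transport: with
$D_S = 10^{-4}\,\mathrm{mm^2\,s^{-1}}$ the diffusion time across the
>10 mm antrum is ~20 days, so the fluid cannot equilibrate with the
12–40 µm granulosa ribbon where estradiol is made, and most of that
estradiol is reclaimed by the adjacent $\Delta = 1\,\mathrm{s^{-1}}$
blood exchange before it escapes inward. Reproducing the measured fluid
levels requires steroid transport to be effectively non-limiting
(so that fluid concentrations ride the theca-exchange balance
$A + E \approx \rho_A(1+\sigma_G)$, as the measurements themselves
suggest). We verified that none of the defensible scalings achieves
this: the alternative `as_printed` length convention is slower still; a
well-stirred antrum drains the fluid estradiol into the theca sink; and
globally faster diffusion destroys the localised receptor patterns. We
have chosen to keep the physically consistent default rather than
rescale the fitted constant $K_I$ (which sets the estradiol production
scale linearly) against this known gap; the corresponding acceptance
checks fail and say so. Physically, bulk mixing of the antral fluid
*without* enhanced transport across the granulosa boundary layer —
i.e. advective stirring confined to the cavity combined with a
granulosa lining the whole antral wall — is the missing ingredient a
future geometry variant would need.

## Known limitations

* 1D cross-section: no spherical focusing, no independently growing
  theca, no cell-based membrane treatment (the 500-fold reaction-volume
  factor is a bulk surrogate).
* No follicle selection, atresia, pituitary feedback or LH pulsatility;
  serum hormone levels are constants.
* IGF binding proteins and proteases are absorbed into the single
  complex variable I; estradiol-independent IGF regulation is ignored.
* The fluid steroid magnitudes are transport-limited as discussed
  above; fluid-compartment predictions should be read qualitatively.
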