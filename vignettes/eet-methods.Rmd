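---
title: "Methods: Förster and generalized Förster energy transfer over pigment networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Förster and generalized Förster energy transfer over pigment networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eetnet)
```

## The model

`eetnet` maps a pigment–protein structural model to excitation energy
transfer (EET) rate matrices. The physical chain is:

1. **Pigments.** Chlorophyll cofactors are extracted from a PDB/mmCIF model.
   Each pigment contributes a center (the Mg atom, or the mean of the four
   chlorin ring nitrogens when Mg is absent), a unit Qy transition axis
   (by convention the NB→ND direction of the chlorin ring), and the
   coordinates of its charge-bearing atoms.

2. **Couplings.** The electronic coupling between pigments $m$ and $n$ is the
   screened transition-charge (TrEsp) Coulomb sum
   $$V_{mn} = f(R)\sum_{l\in m,\; l'\in n} \frac{q_l\, q_{l'}}{|R_{l,l'}|},$$
   with transition charges $q$ in units of $e$, atomic distances in Å, and
   $V$ converted to cm⁻¹ through the Coulomb constant
   $e^2/(4\pi\varepsilon_0\,\text{Å}) \approx 1.1614\times10^5$ cm⁻¹,
   derived once from CODATA 2018 values in a single constants unit
   (`eet_constants()`). The environmental screening factor is piecewise in
   the center–center distance $R$:
   $$f(R) = \begin{cases} 1 & R \le 6.6\ \text{Å} \\
   A e^{-\beta R} + 0.54 & 6.6 < R < 20\ \text{Å} \\
   0.54 & R \ge 20\ \text{Å}.\end{cases}$$

3. **Lineshapes.** Each pigment's absorption is a unit-area Gaussian at its
   site energy $\omega_n$; emission is the same Gaussian displaced by the
   Stokes shift $S$. The donor-emission/acceptor-absorption overlap has the
   Gaussian-product closed form
   $$J_{mn} = \frac{1}{\sqrt{2\pi(\sigma_m^2+\sigma_n^2)}}
   \exp\!\left[-\frac{(\omega_m - S - \omega_n)^2}
   {2(\sigma_m^2+\sigma_n^2)}\right],$$
   which the quadrature path reproduces to better than $10^{-6}$ relative
   (a tested invariant).

4. **Pairwise rates.** The weak-coupling (Förster) rate is
   $$T_{mn} = \frac{2\pi}{\hbar}\,|V_{mn}|^2 \int F_m(\omega) A_n(\omega)\,
   d\omega,$$
   with $2\pi/\hbar$ expressed so that (cm⁻¹)²·(cm⁻¹)⁻¹ yields ps⁻¹
   ($\approx 1.1837$ ps⁻¹ per cm⁻¹). Time constants are $\tau = 1/T$.

5. **Aggregate rates.** Between multi-pigment aggregates (an antenna
   protein's pigment cluster, or the merged reaction-center core) the
   generalized Förster rate sums over exciton states $\alpha$ of the donor
   aggregate $D$ and $\beta$ of the acceptor $A$:
   $$k_{DA} = \frac{2\pi}{\hbar}\sum_{\alpha\in D}\sum_{\beta\in A}
   \frac{e^{-\varepsilon_\alpha/k_BT}}{Z}\,|V_{\alpha\beta}|^2
   \int S_\alpha^D(\omega)\, S_\beta^A(\omega)\, d\omega,$$
   where $\varepsilon$ are eigenvalues of the aggregate Hamiltonian (site
   energies on the diagonal, intra-aggregate couplings off it),
   $Z=\sum_\alpha e^{-\varepsilon_\alpha/k_BT}$, and
   $V_{\alpha\beta}=\sum_{i\in D}\sum_{j\in A} c_{i\alpha}c_{j\beta}V_{ij}$
   is the coefficient-transformed site coupling. Thermal equilibration
   within the donor is assumed instantaneous; no intra-aggregate relaxation
   dynamics are modeled.

6. **Network products.** Time constants are binned into classes
   (default edges 1, 10, 20 ps; pairs slower than the last edge are marked
   OMITTED), antenna domains are grouped as connected components of the
   graph whose edges connect pairs transferring within a reach cutoff
   (default 20 ps, the omission threshold), and transfer routes between two
   domains are enumerated as simple paths and ranked by their bottleneck
   (slowest-step) time constant.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `A`, `beta` | 2.68, 0.27 | –, Å⁻¹ | transition-region constants of $f(R)$; the piecewise branch values (1, 0.54) and cutoffs (6.6, 20 Å) fix the model, while `A`/`beta` are the standard literature exponential fit consistent with those constants. Both are exposed and stamped into output metadata. |
| `fwhm` | 240 | cm⁻¹ | chlorophyll *a* spectral width |
| `stokes` | 160 | cm⁻¹ | chlorophyll *a* Stokes shift |
| site energies | 14900 (Chl *a*), 15750 (Chl *c*) | cm⁻¹ | **illustrative defaults only** — site energies are pocket-specific quantities that must be supplied per type or per pigment (`read_site_energies()`); the shipped values merely place the types in the right spectral region with Chl *c* above Chl *a* |
| `temperature` | 300 | K | Boltzmann weighting of donor exciton states; $k_B = 0.695035$ cm⁻¹ K⁻¹ |
| `target_dipole` | unset | D | optional rescaling of a charge set to an effective in-protein transition dipole |
| bins / cutoff | 1, 10, 20 / 20 | ps | time-constant classes and grouping reach |

## Design choices where the design was open

* **Width parameter ambiguity.** The broadening Gaussians are written with a
  scale parameter $\sigma$ that accompanying text describes as a full width
  at half maximum. These readings differ by the factor
  $2\sqrt{2\ln 2}\approx 2.355$. The default (`sigma_mode = "fwhm"`)
  treats the printed 240 cm⁻¹ as a true FWHM and converts; the literal
  reading (`"sigma"`) is selectable, and the choice is stamped into rate
  metadata. Under the default, the modeled absorption FWHM measured off the
  curve is exactly 240 cm⁻¹ (a tested property).

* **One screening factor per pair.** $f$ is evaluated at the Mg–Mg
  center distance and multiplies the whole TrEsp sum, the form in which the
  screened sum is written; per-atom screening is not modeled. Note the
  piecewise model is discontinuous at its outer cutoff
  ($Ae^{-20\beta}+0.54 \approx 0.552 \ne 0.54$); pairs sitting exactly at
  20 Å take the outer value (both boundaries are inclusive toward the
  constant branches).

* **Qy axis convention.** The NB→ND nitrogen axis, the common convention
  for the chlorin Qy transition; configurable (e.g. NA→NC) since structures
  and charge sets from different sources differ in convention.

* **Exciton lineshapes.** The aggregate-rate integral needs lineshapes for
  exciton states, which the rate model itself does not define. Adopted
  model: a Gaussian at the exciton eigenenergy whose FWHM and Stokes shift
  are the $c_{i\alpha}^2$-weighted mixes of the member pigments' monomer
  parameters (donor emission displaced by the mixed Stokes shift). A
  no-mixing alternative (plain mean of monomer parameters) is selectable
  (`mix_mode = "monomer"`). For single-pigment aggregates both reduce to
  the monomer lineshape, which is what makes the generalized rate collapse
  exactly onto the classical rate — a reduction tested to $10^{-10}$
  relative.

* **Experimental overlap overrides.** A directional table of measured
  overlap values (the Chl *c* → Chl *a* pair is the canonical entry) can
  replace the Gaussian model value per ordered type pair. The override is
  applied in the pairwise Förster path only: exciton states mix pigment
  types, so a type-pair lookup is ill-defined in the aggregate path, which
  always uses the Gaussian exciton-lineshape model.

* **Route score.** Routes are ranked by bottleneck (slowest step) rather
  than summed time, because multi-step pathways are compared by their
  limiting rate; summed-$\tau$ ranking is available behind
  `score = "total"`. Ties break by path length, then lexicographically, so
  rankings are deterministic.

* **Grouping direction.** Group membership uses the better direction of
  each pair ($\min(\tau_{DA}, \tau_{AD})$): transfer maps draw directional
  arrows, but "these two antennae exchange energy" is a symmetric
  statement.

* **Degenerate eigenvalues.** Eigenvectors are accepted as returned by the
  symmetric solver. All reported quantities are invariant to rotations
  within a degenerate subspace because only $|V_{\alpha\beta}|^2$ summed
  over the subspace enters the rate; this is tested on an equilateral
  homotrimer whose lower exciton level is doubly degenerate.

## Numerical choices and degenerate inputs

* Conversion constants are derived once from CODATA 2018 base values and
  versioned; every export embeds the constants version.
* Quadrature for overlap checks uses adaptive integration over the peak
  span ± 8 widths; the closed form is the production path.
* Boltzmann weights are computed after shifting eigenvalues by the lowest
  one, so partition functions never underflow at spectroscopic energies.
* Atom pairs closer than 0.5 Å across two pigments raise a clash error;
  pigment centers closer than 0.1 Å are a degenerate-geometry error.
* Rates below $10^{-6}$ ps⁻¹ (τ beyond a microsecond) are floored to zero
  in sparse exports only; dense matrices in memory are never thresholded.
* Charge atoms missing from a model are an error unless `allow_missing` is
  set, in which case they are dropped *without* charge renormalisation and
  logged — silent renormalisation would change the transition dipole.
* Altloc handling keeps the highest-occupancy alternate; ties break by
  altloc identifier order, so extraction is deterministic.

## What the synthetic generator emulates — and what it does not

`make_grouped_network()` plants clusters of two-point transition dipoles on
a ring of cluster centroids: clusters mimic the pigment complement of
antenna proteins arranged around a core, with intra-cluster spacings in the
~10 Å regime of neighbouring chlorophylls and inter-cluster gaps that
produce group structure. Ground truth records the planted partition, the
planted groups (clusters whose closest-pair dipole-limit time constant is
within a stated reach), and the analytic dipole-limit coupling of every
inter-cluster closest pair. Two-point dipoles make the far-field limit
exact by construction, so TrEsp sums can be validated against the
closed-form point-dipole formula with orientation factor
$\kappa = \hat e_m\!\cdot\!\hat e_n -
3(\hat e_m\!\cdot\!\hat R)(\hat e_n\!\cdot\!\hat R)$.

The generator deliberately does **not** mimic real chlorin geometry
(~70-atom transition-charge distributions), protein-induced site-energy
disorder, vibronic structure, carotenoids, or crystal-contact artifacts.
Passing tests on synthetic networks therefore demonstrate the correctness
of the computational chain — extraction, Coulomb sums, diagonalisation,
thermal weighting, binning, grouping, routing — not the spectroscopic
accuracy of any particular parameter set on a real supercomplex. For real
systems the decisive inputs (quantum-chemistry transition charges and
fitted site energies) must be supplied by the user; the pipeline consumes
them as files and never computes them.

The demonstration scripts under `analysis/` run the chain on a reduced
8-cluster ring (one core, seven antennae, 4 pigments each, adjacent
centroids 24 Å apart, seeded random orientations) sized so the whole
workflow completes in seconds; the test suite uses 2–6 pigment fixtures,
100–1000-draw property sweeps, and ≤ 6-node route graphs for the same
reason.

## Known limitations

* Weak-coupling rate theory throughout: no modified-Redfield or
  non-equilibrium treatments, no master-equation propagation of the
  resulting rate network, and no back-transfer equilibration kinetics.
* Gaussian lineshapes only — no vibronic sidebands, spectral densities, or
  temperature-dependent broadening (temperature enters only the Boltzmann
  weights).
* Carotenoids and other non-chlorophyll cofactors are parsed but never
  enter the EET calculation; quenching channels are out of scope.
* The piecewise screening model is empirical and discontinuous at its
  outer cutoff; results for pairs near 20 Å separation carry that model
  artifact.
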