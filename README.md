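# eetnet — excitation energy transfer networks in pigment–protein complexes

Photosynthetic supercomplexes funnel absorbed light through networks of
chlorophylls: peripheral antenna proteins capture photons and pass the
excitation, pigment by pigment, to the reaction-center core. `eetnet` is an
R package for structural photosynthesis researchers who want to turn a
pigment–protein structural model (mmCIF/PDB) into that transfer network:
inter-pigment rate matrices, antenna-to-core time constants, and the graph
products used to read them (time-constant classes, antenna groups, mediated
transfer routes).

The computational core:

* **TrEsp couplings with environmental screening.**
  V<sub>mn</sub> = f(R) Σ<sub>l∈m,l′∈n</sub> q<sub>l</sub>q<sub>l′</sub>/|R<sub>l,l′</sub>|,
  transition charges in units of *e*, distances in Å, couplings in cm⁻¹;
  f(R) is piecewise: 1 below 6.6 Å, A·exp(−βR) + 0.54 between, 0.54 beyond
  20 Å.
* **Förster rates between all chlorophyll pairs.**
  T<sub>mn</sub> = (2π/ħ)|V<sub>mn</sub>|² ∫F<sub>m</sub>(ω)A<sub>n</sub>(ω)dω
  with unit-area Gaussian lineshapes (absorption at the site energy,
  emission Stokes-shifted below it), reported in ps⁻¹ with time constants
  τ = 1/T.
* **Generalized Förster rates between aggregates.**
  k<sub>DA</sub> = (2π/ħ) Σ<sub>α∈D</sub>Σ<sub>β∈A</sub>
  [exp(−ε<sub>α</sub>/k<sub>B</sub>T)/Z] |V<sub>αβ</sub>|²
  ∫S<sub>α</sub>(ω)S<sub>β</sub>(ω)dω over thermally weighted exciton
  states of each aggregate's Hamiltonian.
* **Network analysis.** Half-open time-constant bins (<1, 1–10, 10–20,
  ≥20 ps omitted), antenna grouping by connected components under a
  transfer-reach cutoff, and simple-path route ranking by bottleneck step.
* **A synthetic generator with planted ground truth** (two-point dipoles in
  clustered networks), so the whole chain is testable without downloading
  any structure.

Transition charges and site energies are *inputs* (TSV tables); the package
never runs quantum chemistry. The methods vignette
(`vignettes/eet-methods.Rmd`) documents the model, its assumptions, and the
design decisions.

## Worked example

A minimal dimer, computed from first principles:

```r
library(eetnet)

# two pigments 20 Å apart, parallel Qy axes perpendicular to the
# separation (orientation factor kappa = 1), 4 D transition dipoles
# carried by two-point charge sets
dimer <- make_dimer(20, "stacked")
cs    <- make_charge_set(4, 1)
V     <- tresp_coupling(dimer$pigments[[1]], dimer$pigments[[2]], cs, cs)
ca    <- lineshape_params(14900, 240, 160)   # site energy, FWHM, Stokes (cm^-1)
J     <- overlap_integral(ca, ca)
T_    <- pairwise_rate(V, J)
c(V_cm1 = V, J_inv_cm1 = J, T_per_ps = T_, tau_ps = 1 / T_)
#>        V_cm1    J_inv_cm1     T_per_ps       tau_ps 
#>  5.426673001  0.001494718  0.052096324 19.195212435
```

Reading: at 20 Å the screening factor is 0.54, giving a 5.43 cm⁻¹ coupling;
the Stokes-shifted self-overlap of the chlorophyll *a* lineshape is
1.49×10⁻³ (cm⁻¹)⁻¹; together they give a transfer time constant of ~19 ps —
slow enough that in a transfer map this pair would sit in the 10–20 ps
class (`classify_edges`).

The `analysis/` scripts run the full pipeline on a synthetic
antenna-ring-plus-core network (8 clusters, 32 pigments; run them in order
from the repository root):

```sh
Rscript analysis/01_build_network.R     # generate + write fixture/tables
Rscript analysis/02_pairwise_rates.R    # TrEsp couplings, pairwise rates
Rscript analysis/03_domain_rates.R      # exciton domains, aggregate rates
Rscript analysis/04_network_products.R  # bins, groups, routes, exports
```

Step 03 prints the antenna → core time constants — the core's two ring
neighbours transfer at 4.4 ps and 5.5 ps while distant antennae are
orders of magnitude slower — and step 04 finds that the farthest antenna
reaches the core fastest by hopping around the ring
(`E -> F -> G -> H -> CORE`, bottleneck 5.5 ps) rather than directly,
the mediated-route pattern these networks are analysed for. Outputs land
under `results/` (pigment table, coupling/rate CSVs, GraphML network,
JSON summaries).

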