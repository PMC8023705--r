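# shieldens

Spatial analysis of NMR shieldings: where in a molecule does the
shielding of a given nucleus come from?

`shieldens` computes **nuclear magnetic shielding densities** — scalar
fields whose volume integral is an element of the shielding tensor
σ<sup>I</sup><sub>αβ</sub> of nucleus *I* — from magnetically induced
current densities via the Biot–Savart relation, and decomposes the
integral into per-atom contributions. It is aimed at computational and
theoretical chemists studying ring currents, aromaticity, and the
spatial origin of NMR chemical shifts.

The pipeline:

1. **Current-density susceptibility tensor (CDT)**
   𝒯<sub>αβ</sub>(**r**) = ∂J<sub>α</sub>(**r**)/∂B<sub>β</sub>, evaluated
   analytically from the density matrix **D** and the magnetically
   perturbed density matrices Im(∂**D**/∂**B**) of a GIAO (London
   orbital) calculation. Any quantum-chemistry engine can supply these
   through a documented adapter contract (`adapt_engine()`); analytic
   ring-current and atomic-vortex models are built in for engine-free
   work. The expression is free of any magnetic gauge origin by
   construction.
2. **Shielding density** for nucleus *I* and component (α, β), in
   atomic units (μ₀/4π → α²):

   ς(**r**) = α² [𝒯<sub>·β</sub>(**r**) × **u**]<sub>α</sub> / |**u**|³,
   **u** = **r** − **R**<sub>I</sub>.

   Positive regions shield the nucleus, negative regions deshield it.
3. **Quadrature** over multicenter molecular grids: Lindh-style
   exponential radial rules, Lebedev-type angular grids, and Becke
   fuzzy-cell partitioning (iteration order k = 3), giving global
   integrals in ppm, per-atom decomposition tables with
   positive/negative splits and percentages, plane maps (CSV), and
   volumetric fields (Gaussian cube).

## Worked example

The Lamb formula σ = (α²/3)⟨1/r⟩ is an exact end-to-end check: a
Gaussian charge density spinning in its Larmor (diamagnetic) vortex must
reproduce it from the kernel, the grids and the unit chain alone.

```r
library(shieldens)

vx    <- make_vortex_provider(vortex_model(exponent = 2, n_electrons = 1))
mol   <- molecule("He", matrix(0, 1, 3))
grids <- build_grids(mol, radial_accuracy = 1e-12, angular_order = 110)
integrate_component(vx, mol, 1, "isotropic", grids)
#> $total
#> [1] 28.32562      # ppm; the closed form gives 28.325622
#> $positive
#> [1] 28.32562
#> $negative
#> [1] 0
```

A benzene-like composite ring-current model (diatropic perimeter loop,
weaker paratropic inner loop, six atomic vortices) decomposed over Becke
atomic domains for a probe proton placed 4.69 bohr from the ring center:

```r
bz   <- benzene_like_composite()
molH <- molecule(c(bz$molecule$element, "H"),
                 rbind(bz$molecule$coords, c(4.69, 0, 0)))
grids <- build_grids(molH, radial_accuracy = 1e-8, angular_order = 110)
lab  <- list(ipso_C = 1L, ortho_C = c(2L, 6L), meta_C = c(3L, 5L),
             para_C = 4L, H = 7L)
decompose_atomic(bz$provider, molH, 7, grids, component = "zz",
                 labeling = lab)
#> Atomic contributions (nucleus 7, component zz)
#> domain          total   positive   negative percentage
#> ipso_C         -24.63       2.47     -27.10    141.74%
#> ortho_C          4.33       6.92      -2.59    -24.92%
#> meta_C           5.08       5.92      -0.84    -29.25%
#> para_C           2.23       2.72      -0.49    -12.86%
#> H               -4.39      11.72     -16.11     25.29%
#> total          -17.37      29.76     -47.13    100.00%
```

Columns are ppm (total = positive + negative exactly) and the percentage
of the grand total; negative percentages mark domains that deshield on
balance. In this *model* the perimeter loop lies inside the probe
proton, so the diatropic current deshields it — exactly the sign rule
the shielding density encodes: what matters is the direction of the
current relative to the studied nucleus, not its tropicity. Plane maps
(`cmd_plane()`, CSV) and volumetric exports (`cmd_cube()`, Gaussian
cube) expose the same fields for visualization.

With an engine-supplied response bundle the same calls run on ab initio
data: `read_bundle("c6h6.json") |> bundle_provider()` in place of the
model provider, and the engine's analytic shieldings (if stored in the
bundle metadata) are compared against the quadrature automatically by
`cmd_atoms()`.

## Command line

```sh
Rscript inst/scripts/shieldens validate --bundle c6h6.json
Rscript inst/scripts/shieldens atoms    --config run.yaml
Rscript inst/scripts/shieldens plane    --config run.yaml --offset 1.0
Rscript inst/scripts/shieldens cube     --config run.yaml --absolute
```

`run.yaml` is a plain hierarchical config (see `?run_config`;
an example is installed at `inst/extdata/example_config.yaml`).

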