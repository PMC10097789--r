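---
title: "Methods: fabric-based finite-element modelling of trabecular bone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fabric-based finite-element modelling of trabecular bone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabrifem)
```

# Overview

`fabrifem` implements a complete desk-scale pipeline for comparing
constitutive models of trabecular bone in linear finite-element (FE)
analyses of proximal-femur-like structures:

1. **Synthetic microstructure** — binary voxel volumes standing in for
   binarized micro-CT scans (`gaussian_field_volume()`,
   `rod_lattice_volume()`).
2. **Fabric estimation** — mean intercept length (MIL) sampling and the
   Harrigan–Mann ellipsoid fit giving a second-order fabric tensor per
   mesh element (`compute_mil()`, `fit_fabric()`, `element_structure()`).
3. **Constitutive mapping** — three material models assigned per element
   (`assign_materials()`).
4. **FE solution** — linear static analysis on C3D4 tetrahedra with
   muscle and joint-reaction loads (`fem_solve()`).
5. **Post-processing** — principal fields, strain energy density, Frost
   mechanostat zones and path profiles (`path_fields()`,
   `frost_classify()`).

Everything runs from synthetic inputs; no external imaging data is
required.

# Units

All lengths are **mm**, forces **N**, stresses and moduli **MPa**
(N/mm²). Voxel sizes and correlation lengths are given in **µm** and the
key names say so (`voxel_size_um`); the conversion to mm happens in one
place. Strains are dimensionless, with **engineering shear**
(γ = 2ε) in Voigt vectors.

# Fabric: MIL and the Harrigan–Mann fit

For a direction ω, the mean intercept length MIL(ω) is the mean distance
between bone/marrow interfaces along parallel test lines. Sampling
directions come from a Fibonacci hemisphere (`fibonacci_hemisphere()`),
and lines are walked through the voxel window counting phase crossings.

The directional distribution is fitted with the Harrigan–Mann ellipsoid

$$\mathrm{MIL}(\omega)^{-2} = \omega^\top H \,\omega,$$

a linear least-squares problem in the six components of the symmetric
positive-definite tensor `H`. The fabric tensor is `M = H^{-1/2}`; its
eigenvalues are normalized to `m₁ ≥ m₂ ≥ m₃` with `Σmᵢ = 3`. The
direction of **largest MIL** (fewest interfaces, longest struts) carries
the **largest mᵢ** and is therefore the stiffest material axis.

Windows containing a single phase (all bone or all marrow) are flagged
*degenerate* and fall back to isotropic material downstream — never to
infinite or zero MIL.

```{r}
A <- diag(c(1, 2, 4)) * 1e-6
dirs <- fibonacci_hemisphere(64)
mil <- apply(dirs, 1, function(w) (t(w) %*% A %*% w)^(-0.5))
fab <- fit_fabric(list(directions = dirs, mil_um = as.numeric(mil),
                       degenerate = FALSE))
fab$m
```

# Constitutive models

The material card (`material_card()`) bundles the tissue-level
constants: `E0 = 22500` MPa, `nu0 = 0.3`, `G0 = 8650` MPa, density
exponent `k = 1.9`, anisotropy exponent `l = 0.99`, thresholds
`rho_lo = 0.1`, `rho_hi = 0.9`, and a soft isotropic tendon/cartilage
material (`E = 5` MPa, `ν = 0.3`).

The Zysset–Curnier orthotropic law maps bone volume fraction ρ (BV/TV)
and fabric eigenvalues mᵢ to engineering constants:

$$E_i = E_0\,\rho^k (m_i^2)^l,\qquad
  \nu_{ij} = \nu_0 (m_i/m_j)^l,\qquad
  G_{ij} = G_0\,\rho^k (m_i m_j)^l.$$

Three models are compared:

* **`anisotropic`** (Model 1): full orthotropic law, stiffness rotated
  into the element's fabric frame.
* **`iso_hetero`** (Model 2): isotropic, `E = E0 ρ^k`, per element.
* **`iso_homo`** (Model 3): isotropic and homogeneous, `E = E0 ρ̄^k`
  with the mean trabecular ρ̄.

Common threshold rules: ρ above `rho_hi` is treated as cortical
(`E = 22500` MPa isotropic); ρ below `rho_lo` is floored at
`E0 · 0.1^1.9 ≈ 280` MPa; degenerate-fabric elements use the isotropic
branch.

Two numerical conventions worth noting:

* **Voigt order** is (11, 22, 33, 23, 31, 12) with engineering shear
  strains. Stiffness rotation uses the 6×6 Bond transformation,
  verified in the tests against a brute-force fourth-order tensor
  rotation.
* **G0 consistency**: the bundled `G0 = 8650` MPa is the printed,
  3-significant-figure value of `E0 / (2(1+ν0)) = 8653.85`. With the
  bundled card, Model 1 at `m = (1,1,1)` is therefore *almost* but not
  exactly Model 2. Exact equivalence (used as a solver verification
  test) requires the consistent override
  `material_card(G0 = 22500 / 2.6)`.

```{r}
ec <- engineering_constants(material_card(), rho = 0.9, m = c(1, 1, 1))
signif(ec$E[1], 4)   # the Model-2 modulus at the cortical threshold
```

The small-exponent approximation `E1/E3 ≈ (m1/m3)^2` (exact exponent
`2l = 1.98`) is reported by `modulus_ratio_report()`:

```{r}
modulus_ratio_report(data.frame(element = 1:3, m1 = c(1.3, 2.1, 2.02),
                                m3 = c(1, 1, 1)))
```

# Finite elements and loads

Meshes are 4-node constant-strain tetrahedra (C3D4). The structured
generators (`box_mesh()`, `femur_like_mesh()`) subdivide hexahedra into
6 Kuhn tetrahedra, guaranteeing positive volumes and conforming faces.
The surrogate femur is a parametric head/neck/shaft solid with the 15
muscle attachment node sets, a distal fixation set, the joint surface
set and a thin tendon/cartilage element layer.

Loads come from the bundled tables: 15 muscle forces (unit direction ×
magnitude) for two configurations, plus a hip joint reaction
(config 1: 1383.005 N, config 2: 773.691 N). The joint reaction is
applied through a **star of rod (truss) elements** from an auxiliary
centre node to the joint-surface nodes, which distributes the load over
the head surface without imposing displacements. The default rod
stiffness is 10³ × the stiffest bone element's axial stiffness
(`E·edge`), placing the rods firmly in the rigid (saturated) regime:
doubling it changes interior displacements by far less than 1%.

The linear system is solved with a Jacobi-scaled sparse Cholesky
factorization followed by iterative refinement. Residuals are evaluated
with a long-double matrix–vector product and the rod contributions in
difference form, `k_c\,n (n^\top (u_c - u_s))`, to avoid catastrophic
cancellation. Relative residuals are typically 10⁻⁹–10⁻¹¹; for the
stiffest anisotropic configuration the very stiff rods impose an
intrinsic floor of about `k_c ε |u| √n / ‖f‖ ≈ 1.4×10⁻⁸`, slightly above
the 10⁻⁸ warning threshold — the solution itself is converged, and the
solver reports the achieved residual.

Problem sizes: the bundled surrogate femur at 2.5 mm edge length has
~8800 elements / ~2000 nodes and the full pipeline (volume → fabric →
solve → post) completes in a few minutes on one CPU.

# Post-processing

Per element (fields are element-wise constant on C3D4, so no nodal
averaging is performed):

* **Major principal stress/strain**: the signed principal value of
  largest absolute magnitude; ties break toward compression.
* **Von Mises stress**.
* **Strain energy density**: apparent `W = σ:ε/2` and the tissue-level
  stimulus `w = W/ρ`.
* **Frost mechanostat zone** of `w`, with boundaries at the bundled SED
  thresholds. Where the source table prints a range, the zone boundary
  is the conservative edge: the MESr upper bound (11.25×10⁻⁵ MPa) must
  be reached to leave disuse and the MESm lower bound (0.01125 MPa) to
  enter modeling. Intervals are left-closed (a value exactly on a
  boundary belongs to the zone above). The fracture threshold
  (1.5 MPa) is stored verbatim; it is not derivable from the strain
  thresholds via `w = Eε²/2`.

`sample_path()` places stations along a polyline and assigns each the
value of its containing element; `femur_paths()` provides surrogate
compressive and tensile trabecular-group paths.

# Synthetic volume generators

* `gaussian_field_volume()` — thresholded anisotropic Gaussian random
  field, correlation lengths per axis, thresholded to an exact target
  BV/TV; seeded and bitwise reproducible.
* `rod_lattice_volume()` — periodic orthogonal strut lattice with
  per-axis strut radii; thicker struts along an axis raise that axis's
  MIL. Used as the analytic ground truth for fabric directions.

These are *statistical stand-ins* for trabecular bone: they reproduce
controllable BV/TV and MIL anisotropy, not biological plate/rod
architecture.

# File formats

* **Meshes**: an Abaqus `.inp` subset (`*NODE`, `*ELEMENT, TYPE=C3D4`,
  `*NSET`, `*ELSET`). Ids on disk are 1-based and may be sparse; in
  memory everything is dense 1-based R indexing. Set names are
  case-preserved.
* **Volumes**: raw `uint8` + JSON sidecar (ZYX order on disk), or TIFF
  stacks via the optional `tiff` package.
* **Results**: legacy ASCII VTK for ParaView, CSVs with unit-annotated
  headers, and a JSON run manifest (seed, versions, timings, mesh hash).
* **Config**: YAML, round-tripping losslessly (`write_config()` /
  `read_config()`).

# End-to-end run

```{r, eval = FALSE}
cfg <- default_config(seed = 1, model = "anisotropic", loads = "config1")
res <- run_pipeline(cfg)
list.files(res$out_dir)
```

The same pipeline is exposed on the command line:

```
Rscript inst/cli/fabrifem.R run config=run.yaml
```

# Limitations

* Linear elasticity, small strains, static loads only; no remodeling
  simulation (density update loops) and no stimulus rate effects.
* The surrogate femur is a parametric solid, not a segmented anatomy;
  paths are parametric stand-ins.
* Grayscale CT ingestion, GUI and Abaqus `.odb` parsing are out of
  scope.
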