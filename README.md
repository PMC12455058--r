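# dtdspec

Nonparametric **frequency-dependent diffusion tensor distributions**
(D(ω)-R₁-R₂ distributions) from multidimensional diffusion–relaxation
MRI, in R.

Tensor-valued diffusion encoding probes both the anisotropy and the
time/frequency-dependence ("restriction") of water diffusion. Every
gradient waveform **g**(t) defines a dephasing vector
**q**(t) = γ∫₀ᵗ**g**(t′)dt′ and a tensor-valued encoding spectrum
**b**(ω) = **q**(ω)**q**(−ω)ᵀ/2π, whose integral is the conventional
b-tensor. `dtdspec` models the signal of a heterogeneous voxel as a sum
of discrete components *i*, each an axisymmetric diffusion tensor
spectrum **D**ᵢ(ω) with Lorentzian transitions between the
low-frequency axial/radial diffusivities (D_A, D_R) and a common
high-frequency isotropic value D₀ (mid-point frequencies Γ_A, Γ_R),
paired with longitudinal and transverse relaxation rates R₁ and R₂:

    S[b(ω), τ_R, τ_E] = Σᵢ wᵢ exp(−∫ b(ω):Dᵢ(ω) dω) [1 − exp(−τ_R R₁ᵢ)] exp(−τ_E R₂ᵢ)

The per-voxel inverse problem — estimating the weights and component
parameters — is solved by Monte Carlo search (proliferation /
mutation / extinction of candidate components with non-negative
least-squares weights, no regularization) with bootstrap replication
for uncertainty, either including the frequency dimension
(9-parameter components) or omitting it (6-parameter, conventional
static analysis). Derived metrics include the projections
D_iso(ω) = (D_A + 2D_R)/3 and D_Δ²(ω) = ((D_A − D_R)/(D_A + 2D_R))²,
bin-resolved signal fractions on the (D_iso, D_Δ²) plane, ensemble
means E[X], spectral-dispersion slopes Δ_ω/2π E[X], and
normalized-difference maps between the two analysis modes.

The package is aimed at researchers developing or validating
multidimensional dMRI acquisitions and inversions: it generates
double-rotation test waveforms (linear/planar/spherical b-tensors with
0–5 oscillations), characterizes acquisition protocols by their
b-weighted centroid-frequency percentiles, synthesizes image-shaped
phantom datasets (Gaussian liquids, lamellar liquid crystal, restricted
diffusion matched to the closed-sphere spectrum) with Gaussian or
Rician noise, and reads/writes NIfTI volumes, TSV protocol/component
tables and YAML/JSON configurations.

## Worked example

A tumor-like voxel (restricted, isotropic diffusion: Lorentzian
dispersion matched to a 7 µm sphere with local diffusivity
1.2·10⁻⁹ m²s⁻¹) is synthesized on the reduced wide-frequency protocol
and inverted with and without frequency-dependence:

```r
library(dtdspec)

prot <- protocol_wide_reduced()          # ~230 acquisitions, 3 shapes
summ <- protocol_summary(prot)
round(summ$percentiles / (2 * pi), 1)
#> omega_10 omega_50 omega_90
#>     17.5    109.0    245.4            # Hz, b-weighted percentiles

tumor <- make_preset("tumor")
set.seed(1)
y <- signal(prot, tumor, mode = "omega_dependent") +
  rnorm(length(prot), 0, 0.01)           # SNR 100

cfg <- inversion_config("omega_dependent", "preclinical",
                        n_proliferation = 8, n_mutation = 8, n_in = 40,
                        seed = 1)
sol <- invert_voxel(prot, y, cfg)
cfg_st <- cfg; cfg_st$mode <- "static"
sol_st <- invert_voxel(prot, y, cfg_st)

ensemble_mean(sol$components, "d_iso", summ$omega_10)  # 8.69e-10 m^2/s
ensemble_mean(sol$components, "d_iso", summ$omega_90)  # 1.10e-09 m^2/s
```

The recovered E[D_iso] rises across the frequency window — the
signature of restriction. Comparing the two analyses:

```text
residual RMS: omega-dependent 0.0091, static 0.0123
static E[D_delta^2] = 0.155 vs omega-dependent 0.070
```

the frequency-dependent inversion fits the dispersive voxel better,
and the static analysis inflates the anisotropy E[D_Δ²] — it can only
explain frequency-dependent attenuation by adding spurious anisotropic
components. For dispersion-free phantoms the two modes agree within
noise (see `tests/testthat/test-acceptance.R`).

A thin command-line pipeline wraps the same functions:

```sh
exec/dtdspec simulate --protocol wide --phantom tumor --snr 100 --out run1
exec/dtdspec compare  --protocol wide --phantom tumor --snr 100 --out run1
```

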