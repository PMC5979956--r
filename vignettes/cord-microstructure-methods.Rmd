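---
title: "Spinal-cord microstructure mapping: models, phantom and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spinal-cord microstructure mapping: models, phantom and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cordgratio` maps the aggregate MR fiber g-ratio — the ratio of inner (axon)
to outer (axon plus myelin) fiber diameter — in the cervical spinal cord, and
compares affected, unaffected and control cord sides in a myelopathy cohort.
Two independent quantitative contrasts feed the g-ratio: a myelin volume
fraction (MVF) from magnetization-transfer saturation (MTsat) imaging, and an
axon volume fraction (AVF) from two-shell NODDI diffusion modelling. Because
no patient data ship with the package, a digital spinal-cord phantom
generates every input the pipeline consumes, with ground truth retained so
that each stage can be validated as an inversion of a known forward model.

## MTsat myelin mapping

Three spoiled gradient-echo (FLASH) volumes are acquired with predominant
PD-, T1- and MT-weighting (PD/MT: TR 24 ms, flip 5 degrees; T1: TR 10 ms,
flip 13 degrees). In the small-angle regime the FLASH steady state is
rational in the acquisition parameters,

$$S = A\,\alpha \frac{R_1 \mathrm{TR}}{R_1 \mathrm{TR} + \alpha^2/2 + \delta},$$

where $\delta$ is the additional per-TR saturation deposited by the MT pulse
($\delta = 0$ for the PD- and T1-weighted volumes). The mapping stage inverts
this algebra exactly: an apparent relaxation rate $R_{1,\mathrm{app}}$ and
amplitude $A_\mathrm{app}$ from the dual-flip pair, then

$$\delta_\mathrm{app} = \left(\frac{A_\mathrm{app}\alpha_\mathrm{MT}}{S_\mathrm{MT}} - 1\right) R_{1,\mathrm{app}} \mathrm{TR}_\mathrm{MT} - \frac{\alpha_\mathrm{MT}^2}{2}.$$

$\delta_\mathrm{app}$ is kept as a dimensionless fraction throughout
(multiply by 100 for the percent units sometimes used in display); the
linear MVF calibration absorbs any such scale, so the choice is purely a
reporting convention. Flip angles enter all interfaces in degrees and are
converted to radians internally — the $\alpha^2/2$ term is only correct in
radians. Voxels where the inversion is undefined (non-positive denominators,
zero MT signal) propagate as `NaN` and are excluded from every ROI mean;
they are never zero-filled.

### B1 correction

Transmit-field inhomogeneity scales every actual flip angle by a factor
$b_1$. The double-angle method estimates it from two fast EPI acquisitions
at 10 and 20 degrees via $\arccos(S_{2\alpha} / 2S_\alpha)$. Because the
double-angle estimator is noise-hungry at small flip angles, the phantom
gives the B1 pair the SNR advantage of its much coarser acquisition voxels
(`b1_map_snr_factor`, default 32), and the pipeline smooths the raw map
with a quadratic polynomial fit over tissue (`estimate_b1(smooth =
"polyfit")`) — B1 fields are smooth by physics, so this is standard
practice.

The measured saturation falls approximately linearly with $b_1$ near
nominal; the empirical correction
$\delta_\mathrm{corr} = \delta_\mathrm{app}(1 - C)/(1 - C\,b_1)$ with
$C = 0.4$ removes it. The phantom is built to be consistent with this
correction: the rational-FLASH inversion biases the recovered saturation by
exactly $1/b_1^2$, and the deposited saturation itself is modelled as
growing with transmit field as $b_1^{4/3}$, so the net measured dependence
is $b_1^{-2/3}$ — slope $-2/3 = -C/(1-C)$ at nominal, which the $C = 0.4$
formula cancels to first order. A noise-free test with a $\pm 10\%$ B1
gradient confirms residual error under 2%. The correction factor itself
grows with $b_1$ (it compensates a falling measurement); its pole at
$b_1 = 1/C$ is flagged invalid.

### MVF calibration

MVF is taken proportional to the corrected saturation, $\mathrm{MVF} = c\,
\delta$. The scalar $c$ is anchored by requiring the mean aggregate g-ratio
over a designated homogeneous white-matter calibration region to equal a
target (default 0.70). The region mean g is strictly decreasing in $c$
wherever $\delta > 0$ and $V_{ic} > 0$, so the root is unique; it is found
by bracketed root finding on $c \in [10^{-3}, 100]$ with tolerance
$10^{-10}$, and an unreachable target errors with the attainable g range
instead of returning a boundary value. The phantom provides the calibration
region as a dedicated tissue block generated alongside the cord (in a real
study this role is played by a separate calibration cohort and the corpus
callosum); each simulated subject is calibrated against its own block.
MVF is clamped to $[0, 1]$ and the clamped fraction is reported as a QC
metric.

## NODDI axon mapping

The diffusion signal is modelled with three compartments:

$$S/S_0 = (1 - V_{iso})\left[V_{ic} A_{ic} + (1 - V_{ic}) A_{ec}\right]
  + V_{iso} e^{-b d_{iso}},$$

a Watson-dispersed stick (intra-neurite), a tortuosity-coupled anisotropic
Gaussian (extra-neurite, $d_\perp = d_\parallel (1 - V_{ic})$, tensor
averaged over the same Watson distribution), and free water. Fixed
diffusivities follow the standard brain parameterization,
$d_\parallel = 1.7\times10^{-3}$, $d_{iso} = 3.0\times10^{-3}$ mm$^2$/s,
exposed in `noddi_options()` for cord-specific overrides. Orientation
dispersion is summarized as $\mathrm{ODI} = (2/\pi)\arctan(1/\kappa)$.

### The dispersed-stick kernel

The Watson-averaged stick attenuation
$A(\kappa, t, c) = E_W[e^{-t(\mathbf{g}\cdot\mathbf{n})^2}]$
(with $t = b d_\parallel$, $c$ the cosine between mean fiber and gradient)
is, by the Funk–Hecke theorem, an even-order Legendre series whose
coefficients factor into a Watson part $G_\ell(\kappa)/G_0(\kappa)$ and a
stick-response part $H_\ell(t)$, both one-dimensional integrals of smooth
integrands. The series truncated at $\ell = 24$ is exact to machine
precision for clinical b-values at any $\kappa$, because the $H_\ell$ of the
smooth kernel decay super-geometrically. The coefficient integrals are
evaluated by fixed 200-point Gauss–Legendre quadrature on the overflow-free
form $e^{\kappa(x^2-1)}$, switching to a Gauss–Laguerre boundary-layer rule
for $\kappa > 500$. Tests verify agreement with brute-force spherical
quadrature to $10^{-4}$ for $\kappa \in \{0, 1, 4, 16, 64\}$ and
convergence to the single-stick law at $\kappa = 10^4$. Inside the fitting
loop the series is evaluated by Horner's scheme in $c^2$ after conversion
to monomial coefficients — identical values, much cheaper per call.

### Fitting

Per voxel the pipeline minimizes the least-squares misfit of the
b0-normalized signal over $(V_{ic}, V_{iso}, \kappa, \mathbf{n})$:

1. direction initialization from the principal eigenvector of a weighted
   log-linear tensor fit (weights proportional to signal); directions are
   reported in the $z \geq 0$ hemisphere (stick models are antipodally
   symmetric);
2. a coarse $8^3$ lattice search over $(V_{ic}, V_{iso}, \mathrm{ODI})$
   with the direction fixed — for fixed $\kappa$ the model is affine in
   $V_{iso}$, so the whole lattice reduces to three quadratic forms;
3. bounded refinement with `nlminb` on transformed parameters (logit for
   the fractions, log for $\kappa$ capped at 128, spherical angles for the
   direction), with an analytic gradient shared between objective and
   gradient calls.

The fit is fully deterministic (no unseeded randomness anywhere) and
recovers noise-free parameters to $\sim 10^{-10}$; the optimizer budget is
capped at 300 evaluations per voxel. Voxels with non-positive mean b0 are
flagged invalid; fitted voxels with $V_{iso} > 0.95$ (pure CSF) are flagged
non-identifiable because $V_{ic}$ then carries no signal. The Rician noise
floor slightly inflates high-b signals and with them $V_{ic}$; no floor
subtraction is applied by default, and the bias is shared across groups so
group contrasts are unaffected.

## g-ratio and QC

$$\mathrm{AVF} = (1 - \mathrm{MVF})(1 - V_{iso})V_{ic}, \qquad
  g = \sqrt{\mathrm{AVF}/(\mathrm{MVF} + \mathrm{AVF})}.$$

Voxels with $\mathrm{MVF} + \mathrm{AVF} = 0$ have no fiber signal and are
`NaN`. Because cord-edge voxels are prone to partial-volume and
registration artifacts (spuriously bright g at the rim), ROI statistics by
default drop the outermost voxel ring of the cord mask. Erosion uses the
in-plane 4-neighbourhood only: slices are 4 mm thick against 1 mm in-plane
resolution and each analysis level is processed per slice.

## Atlas extraction and statistics

Tract summaries are probability-weighted means
$\sum w_i m_i / \sum w_i$ over the analysis-level mask, excluding invalid
voxels, with the summed weight reported as an effective voxel count. The
synthetic atlas provides the six labels analyzed (fasciculus gracilis,
fasciculus cuneatus, lateral corticospinal tract, each left/right) as
annular sectors of the white-matter band with soft (sub-voxel sampled)
edges; it is generated jointly with the phantom on the same grid, standing
in for a perfect template registration. The three tracts are treated as a
flat list — no dorsal-column grouping is modelled, and registration itself
is out of scope.

Group comparison runs a classical one-way ANOVA per tract and metric across
affected / unaffected / control sides, with Scheffé-protected pairwise
p-values ($F_{AB}/(k-1)$ referred to $F(k-1, N-k)$); for two groups the
Scheffé p equals the ANOVA p. Each tract-metric combination is tested
independently at $\alpha = 0.05$ with no multiplicity correction, matching
the usual reporting for this design. Demographics use the Pearson
chi-square (no continuity correction) and the Mann–Whitney U with midrank
ties and tie-corrected normal approximation. Metric–clinical correlations
use Spearman rank correlation — an interpretive choice, since the
myelopathy disability score is ordinal.

## The phantom as study conditions

The phantom is a straight cylindrical cord (craniocaudal fibers) with a
gray-matter core, white-matter annulus, CSF ring and the calibration block,
on an 18 x 18 grid with 1 mm in-plane resolution and 4 mm slices. Healthy
white matter uses MVF 0.32, $V_{ic}$ 0.58, $V_{iso}$ 0.04, $\kappa$ 24,
$R_1$ 1.05 s$^{-1}$; gray matter and CSF differ accordingly. True
saturation is linear in true myelin ($\delta = \mathrm{MVF}/16$, i.e. about
2% in white matter). Noise is Rician on every magnitude volume with
$\sigma$ set as 1/SNR of the white-matter reference signal of each modality
(b = 0 for diffusion, PD-weighted for FLASH), SNR 30 by default. The
default cohort is a realistic clinical case mix for this disease: 20
patients (11 left, 2 right, 7 bilateral affected — 27 affected and 13
unaffected sides; the side counts are configuration, not hard-coded) and 5
controls contributing 10 normal sides. Patients carry a 15% reduction of $V_{ic}$ in
affected-side white matter with myelin unchanged (`mvf_change = 0`);
between-subject biological variability is a 3% coefficient of variation on
the white-matter truths. All randomness derives from one master seed
through an integer-hash splitting scheme (`derive_seed`), so per-subject
streams are independent yet byte-reproducible.

What the phantom does *not* emulate — and what passing tests therefore do
not certify on real data: susceptibility distortion and motion,
segmentation and registration error (labels are perfectly co-registered by
construction), partial volume and CSF pulsation, curved cord geometry,
crossing fibers, and exchange. The phantom's forward models are exactly the
models the pipeline inverts, so end-to-end recovery demonstrates
*inversion consistency and noise behaviour*, not model adequacy for tissue.
An exact-exponential FLASH mode (`flash_model = "exponential"`) exists to
probe the small bias the rational approximation hides.

## Validation problem sizes

The shipped tests validate: machine-exact inversion of the saturation
equations on a parameter grid; the dispersed-stick kernel against
spherical quadrature; noise-free NODDI recovery below $10^{-2}$ on a
parameter lattice and a median $|V_{ic}|$ error of at most 0.05 at SNR 30
over 500 Monte-Carlo voxels; and a 20-replicate cohort study at the default
group structure on single-slice phantoms, which must reproduce the
qualitative disease pattern — significant affected-vs-control AVF deficits
in all three tracts with no MVF differences — in at least 80% of
replicates, with healthy-side g summaries inside the histological
0.6–0.81 band. Single-slice grids keep each replicate's NODDI fit to about
a hundred voxels per subject, which is ample for tract means of three to
nine effective voxels while keeping the replicate study inexpensive.

## Known limitations

* The MVF calibration transfers an external anchor; any error in the
  anchor or in the linearity assumption rescales MVF and AVF jointly.
* $V_{ic}$ at SNR 30 carries a small positive Rician-floor bias; group
  contrasts are unaffected but absolute values are slightly high.
* The double-angle B1 estimator is usable only after smoothing; the
  quadratic polynomial fit assumes a smooth transmit field, which holds by
  construction here and approximately in practice.
* Scheffé protection is conservative; with many tract-metric combinations
  the uncorrected per-combination testing mirrors common practice rather
  than controlling a family-wise rate.
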