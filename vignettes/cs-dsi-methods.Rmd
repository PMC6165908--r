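---
title: "Compressed-sensing DSI: models, solvers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressed-sensing DSI: models, solvers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csdsi)
```

This vignette explains the science implemented by `csdsi`: how q-space
sampling schemes are constructed, how the diffusion propagator is recovered
from undersampled Cartesian q-space data by iterative
shrinkage-thresholding, which quantities are derived from the propagator
and from tensor/kurtosis model fits, and which statistics the package
provides for comparing acquisition protocols. It also records the design
decisions made where the underlying methods leave choices open, and what
the synthetic phantoms do and do not establish about real data.

## The q-space grid and sampling schemes

Diffusion spectrum imaging samples the diffusion signal on a Cartesian
lattice of q-space points truncated to a sphere. `buildGrid(radius, bMax)`
enumerates all integer triples with $|q|^2 \le \mathrm{radius}^2$; the
diffusion weighting at a lattice point follows the quadratic law

$$ b(q) = b_{\max}\,\frac{|q|^2}{\mathrm{radius}^2}, $$

so the strongest weighting sits on the sphere boundary. The standard
radius-5 grid (an $11^3$ lattice) contains 515 points; because the
noise-free diffusion signal is antipodally symmetric, $E(q) = E(-q)$, only
258 of them are informative (257 excluding the origin). The antipodal
representative of each pair is the point whose first nonzero coordinate
(in x, y, z scan order) is positive — a deterministic, orientation-free
convention. With $b_{\max} = 6{,}800$ s/mm² the attainable nonzero
b-values run from 272 s/mm² upward in 22 distinct shells (squared radii
1–25 except 7, 15 and 23, which are not sums of three squares).

```{r grid}
g <- buildGrid(5L, 6800)
g
```

`generateCsScheme()` builds the compressed-sensing acquisition: of the 257
unique samples, $\lceil 257 / \mathrm{accel} \rceil$ are marked measured
(112 at the reference acceleration 2.3). Direction lines are chosen by
greedy farthest-point selection on the sphere — a deterministic proxy for
uniform angular coverage — while the radial position along each line is
drawn uniformly at random under the supplied seed, giving the random
radial coverage that compressed sensing requires. The exact published
selection procedure is not specified in the source design, so this
generator is a reconstruction of its stated properties (uniform angles,
random radii, seeded reproducibility), not a bit-identical copy.

`generateMultishellScheme()` places 30/40/50 directions on shells at
b = 1,000/2,000/3,000 s/mm² (120 DWIs) by minimizing a generalized
electrostatic-repulsion energy over antipodal direction lines,

$$ E = \sum_{i<j} w_{ij}\left(\frac{1}{|u_i-u_j|} +
  \frac{1}{|u_i+u_j|}\right), $$

with $w_{ij} = 1$ within a shell and $0.5$ across shells. The cross-shell
term staggers the shells jointly, in the spirit of incremental multi-shell
designs; the published staggering algorithm is likewise not reproduced
verbatim. Optimization is projected gradient descent with backtracking
from a seeded random start, so the energy trace is non-increasing by
construction. For two directions on one shell the minimizer is a pair of
orthogonal lines, which the test suite verifies against a brute-force
energy scan.

The b = 0 volumes (8 for the CS-DSI protocol, 14 for the 3-shell
protocol) are stored at the front of the gradient table; real scanners
interleave them, but their position carries no information used anywhere
in the package.

## Propagator recovery by ISTA

With measured attenuations $y$ (normalized so that $E(0) = 1$ and
symmetrized over antipodal pairs), the undersampled reconstruction solves

$$ \hat p = \arg\min_p \tfrac12 \lVert R_\Omega \mathcal{F} p - y
  \rVert_2^2 + \lambda \lVert p \rVert_1, $$

where $\mathcal{F}$ is the centred unitary 3-D DFT on the cubic grid and
$R_\Omega$ restricts to the measured locations (each measured point, its
antipodal mirror, and the origin — $2 \times 112 + 1$ cube locations for
the reference scheme). The data term is implemented as the squared
$\ell_2$ norm: this is the form whose gradient step ISTA requires, and the
proximal-gradient iteration

$$ p^{k+1} = \mathrm{soft}_\lambda\!\left(p^k - \mathcal{F}^H R_\Omega^T
  (R_\Omega \mathcal{F} p^k - y)\right) $$

uses unit step size because the restricted unitary DFT has Lipschitz
constant 1. The iterate's real part is taken each step (the symmetrized
data imply a real propagator), and non-negativity is applied as a final
projection only, since the objective itself carries no positivity
constraint.

**Regularization scale and warm start.** The default
$\lambda = 5\times10^{-6}$ applies to attenuations normalized to
$E(0)=1$. At that scale the shrinkage per iteration is tiny relative to
the propagator values, and cold-started ISTA needs on the order of $10^5$
iterations to reach the minimizer. The solver therefore warm-starts with
*threshold continuation*: a geometric schedule of shrinkage thresholds
decreasing from half the zero-filled maximum down to $\lambda$ (20
levels, 300 iterations each), followed by the monotone ISTA phase at the
target $\lambda$ with the stopping rule *relative objective change
< 1e-8* (or 2,000 iterations, flagged if hit). On the radius-5 problem
this recovers noise-free single- and crossing-fiber phantoms with
reconstruction NMSE of order $10^{-4}$–$10^{-2}$ depending on the mask
realization, versus ~0.65 for the zero-filled adjoint baseline.

A caveat worth recording: at this small $\lambda$ the LASSO minimizer is
not always unique. Different exact solvers can return different points of
the solution face while agreeing to machine precision in the objective,
the fitted measurements and the $\ell_1$ norm. The test suite compares
the FFT-based ISTA against an independent dense-matrix proximal-gradient
oracle pointwise where the minimizer is pinned down, and via those
uniquely determined functionals where it is not.

## Propagator-derived quantities

The propagator is stored as a probability mass function over displacement
voxels (non-negative, summing to one). Physical units come from the
narrow-pulse q-space convention $q = \gamma G \delta / 2\pi$: the
q-space pitch is $\Delta q = \sqrt{b_{\max}/\tau}\,/\,(2\pi R)$ with
effective diffusion time $\tau = \Delta - \delta/3$ (0.0429 s for the
CS-DSI timing TE/TR = 101.4/5,300 ms, $\Delta$ = 49.5 ms, $\delta$ =
19.7 ms), and the displacement pitch is $\Delta r = 1/(N \Delta q)$
(7.2 µm at $N = 11$). With $\delta/\Delta \approx 0.4$ the narrow-pulse
approximation is only approximate, which is why all metrics are reported
in grid units alongside nominal millimetres.

* **MSD** $= \sum_r P(r)\,\lVert r\rVert^2$. For free diffusion the
  Einstein relation gives $6 d \tau$; the discrete estimator agrees
  within 5% across $d \in \{0.5, 1, 2, 3\}\times10^{-3}$ mm²/s when the
  propagator is built from signals on the full cube.
* **RTOP** $= P(0)/\Delta r^3$, with its cube root reported alongside;
  the Gaussian closed form $(4\pi d\tau)^{-3/2}$ is matched within 2%
  over the same sweep.
* **dODF** $\Phi(u) = \int_0^{r_{\max}} P(ru)\,r^2\,dr$, evaluated by
  trilinear interpolation at radial step 0.5 grid units with the
  antipodal average enforced — the classical DSI radial projection with
  $r^2$ weighting. The raw integral is kept (no minimum subtraction), so
  the dODF rides on a large isotropic baseline.

Two discretization effects are documented rather than hidden. First,
building a propagator from *sphere-truncated* signals (zeros outside the
truncation sphere) produces Gibbs ringing that inflates MSD at low
diffusivity; the estimators are accurate when the full cube is available
(as with reconstructed or simulated data). Second, trilinear
interpolation on the native $11^3$ grid leaves the dODF of an isotropic
propagator flat only to within ~2%; flatness below $10^{-3}$ is reached
at higher propagator resolution, and a 90° fiber crossing additionally
shows small secondary dODF ridges along the bisectors (amplitude fraction
~0.13). Peak analysis in the tests therefore addresses the dominant
peaks; with the 0.1 relative-fraction rule a crossing voxel can report
spurious low-fraction peaks at native resolution.

Peak extraction finds local maxima on a subdivided-icosahedron
tessellation (default 642 vertices, tests use 2,562 where 5° accuracy is
asserted; vertex quantization is ~4.6° and ~2.3° respectively), accepts
them greedily by amplitude subject to a minimum separation (default 25°),
and discards peaks whose share of the summed peak amplitudes is below the
relative-fraction threshold (default 0.1). That share stands in for the
per-fiber partial volume fraction of fODF-based analyses; the mapping is
a documented operationalization, not an identity.

## Tensor and kurtosis fits

`selectModelSubset()` applies the protocol-specific b-value rules: on the
Cartesian grid the tensor model uses $|q|^2 \le 5$ (28 DWIs, b up to
1,360 s/mm² — the printed range "270–1,300" is treated as approximate and
the count as normative), the kurtosis model b ≤ 3,000 s/mm² (85 DWIs);
on the 3-shell scheme the tensor model uses the inner shell (30 DWIs) and
the kurtosis model all 120.

`fitDti()` is two-pass weighted linear least squares on the log signal
(weights = squared first-pass signal predictions, the standard
heteroscedasticity correction). `fitDki()` fits

$$ \ln S = \ln S_0 - b\,D(g) + \tfrac{b^2}{6}\,\bar D^2\,K(g) $$

linearly in the 6 tensor and 15 kurtosis-tensor parameters, then enforces
$0 \le K(g) \le 3$ and $D(g) \ge 0$ **on the fitted directions** by a
sequential quadratic program (constraint bounds involve $D(g)^2$ and are
rebuilt from the current iterate until stable; `pracma::quadprog` solves
each step). The bound $K_{\max} = 3$ is a common robustness choice — the
constraint set of the published in-house fit is not printed, so the
defaults are this package's own. Between fitted directions the
interpolated $K(g)$ may dip marginally below zero; the contract is
enforced where the data constrain it. MK averages $K(g)$ over a
642-direction set; AK evaluates along the principal eigenvector; RK
averages over a 36-point perpendicular circle. In the small-b limit the
apparent kurtosis of a Gaussian mixture equals
$3\,\mathrm{Var}(D_g)/\mathbb{E}[D_g]^2$, which the tests verify to
$10^{-3}$ against the closed form.

On multi-b mixture voxels the plain tensor fit is biased by the convex
log-signal decay, while the kurtosis fit absorbs the curvature and
returns tensor scalars closer to the Gaussian-part truth — the mechanism
behind protocol differences shrinking under kurtosis fitting, restated as
a testable phantom property. For the same reason the phantom-volume test
asserts exact FA recovery (1e-6) only in single-tensor regions and a
loose bound in the crossing region, where no tensor model is exact.

## Shell assignment

Shell-based preprocessing (eddy-current correction with Gaussian-process
signal models) requires data on b-shells. `assignShells()` merges the
distinct nonzero b-values agglomeratively — closest cluster pair first,
merge allowed only while every member stays within `maxShift` (default
50 s/mm²) of the rounded cluster centre — which respects the hard shift
bound directly and is deterministic, unlike k-means. On the exact
radius-5 grid mapping the 22 distinct b-values are all farther apart
than 50 s/mm², so the assignment is the identity (22 shells, zero
shift). The published protocol reports 20 shells for its acquired data,
presumably reflecting scanner-rounded b-values; the operation supports
both a pure max-shift mode and a target-shell-count mode for that
scenario. Assigned values are an export view only — downstream
computation always keeps the original b-values.

## Comparison and reliability statistics

* `nmse()` — $\lVert \hat s - s\rVert^2 / \lVert s\rVert^2$.
* `mseByBvalue()` — masked per-b-value-bin mean squared difference
  between two volume sets (the distortion-correction quality curve).
* `acc()` — angular cross-correlation of two spherical functions as the
  normalized inner product of real even spherical-harmonic coefficients
  with $l = 0$ excluded; including $l = 0$ would let two isotropic
  functions correlate perfectly. The SH basis is the real orthonormal
  even-order basis (orders 4 or 8).
* `angularPeakDifference()` / `crossingAngleDeviation()` — peaks matched
  by the minimum-total-angle assignment over direction lines
  ($\arccos|u\cdot v|$), computed exactly by enumeration (peak sets have
  at most a few entries); unequal cardinalities are matched on the
  smaller set and flagged.
* `minCrossingAngle()` — lower empirical quantile of per-voxel crossing
  angles at a prevalence level (default 1%).
* `fiberCount()` — minimum over two peak sets of the peaks with relative
  fraction above threshold, capped at 3.
* `icc()` — one-way random-effects ICC(1,1) from the two-measurement
  ANOVA decomposition; `wscv()` — $\sqrt{\overline{d^2/2}}/\bar x
  \times 100$, the paired-difference (Bland–Altman) repeatability form.
  The log-based wsCV variant was not adopted; the paired-difference form
  is the common reading of the repeatability citation.

Monte-Carlo tests generate scan/rescan pairs from known variance
components ($\sigma_b = 0.1$, $\sigma_w = 0.03$, $\mu = 1$; 200 subjects,
50 replicates) and recover $\mathrm{ICC} =
\sigma_b^2/(\sigma_b^2+\sigma_w^2) \approx 0.917$ and
$\mathrm{wsCV} = 3\%$ within three Monte-Carlo standard errors — inside
the ICC > 0.85 / wsCV < 4% band used to call a protocol reliable, showing
that band is reachable under low-noise conditions.

## The phantom generator

`phantomConfig()` describes a voxel as a mixture of Gaussian
compartments: $E(g,b) = \sum_i f_i \exp(-b\,g^\top D_i g)$. Defaults are
standard white-matter values — fiber eigenvalues
$(1.7, 0.3, 0.3)\times10^{-3}$ mm²/s, CSF-like isotropic
$3.0\times10^{-3}$ mm²/s — chosen as field-typical numbers, not fitted
to any dataset. Noise is Rician (magnitude MRI):
$\sqrt{(S+n_1)^2+n_2^2}$ with $n_1, n_2 \sim N(0, \sigma^2)$ and
$\sigma$ defined at $S_0$, so SNR $= S_0/\sigma$. `trtReplicates()` adds
a per-subject multiplicative eigenvalue offset ($1+\delta$,
$\delta\sim N(0,\sigma_b^2)$) and two independent noise realizations per
subject, mirroring a five-subject same-day rescan substudy.

What the phantoms do **not** emulate: spatially varying artifacts (eddy
currents, susceptibility distortion, motion), partial-volume mixing
across voxel faces, non-Gaussian restricted diffusion, T2/TE coupling,
and scanner b-value rounding. Passing tests therefore establish the
correctness of the algorithms on their stated models, and the
reachability of the reported statistical regimes — not in-vivo
performance.

## Problem sizes and runtime choices

The test suite and acceptance script run at desk scale by design: one
voxel per reconstruction (an $11^3$ FFT per ISTA iteration), 20
scheme-seed reconstructions for the CS-vs-zero-fill comparison, 200-voxel
noise ensembles for bias checks, a 10,000-realization average as the
Rician oracle, and $50\times200$ replicates for the reliability
statistics. These sizes give Monte-Carlo standard errors comfortably
below the asserted tolerances while keeping the whole suite in the
low-minute range.

## Known limitations

* The acceleration-2.3 reconstruction quality varies with the random
  radial mask; occasional seeds give NMSE ~$10^{-2}$ rather than
  ~$10^{-4}$ on noise-free phantoms. The median comparison against zero
  filling is robust to this.
* Propagator metrics assume the narrow-pulse q-space interpretation;
  with $\delta = 19.7$ ms the physical-unit MSD/RTOP are nominal.
* The discrete MSD/RTOP estimators here are grid-based; pipelines that
  derive these maps from continuous basis fits (e.g. MAP-type models)
  will not agree numerically, and no such equality is claimed.
* FISTA/ADMM, dictionary sparsity, multi-shell sparse recovery and fODF
  deconvolution are out of scope.
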