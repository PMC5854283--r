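---
title: "Measuring volume-velocity transfer functions by external excitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring volume-velocity transfer functions by external excitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tracttf)
```

## The measurement problem

The acoustics of the vocal tract — and of tube-like resonators generally —
is summarized by the volume-velocity transfer function
$H(\omega) = U_2(\omega)/U_1(\omega)$: the complex ratio of the acoustic
flow through the mouth opening to the flow through the glottis. Its peaks
are the formants; their frequencies, bandwidths and amplitudes carry the
phonetically relevant information. Measuring $H$ directly on a physical
resonator (say, a 3D-printed vocal-tract model) is awkward from the glottal
side, because building a broadband volume-velocity source with a flat,
load-independent response is hard.

`tracttf` implements the alternative: excite the model *externally* with an
ordinary loudspeaker and take two sound-pressure measurements,

1. $P_1$ — at the closed glottal end, with the mouth open,
2. $P_3$ — right in front of the mouth after blocking it with a stiff
   plate,

and form $P_1 / P_3$. The package provides the two-port theory that makes
this ratio *exactly* $H$, the plane-wave and 3D finite-element reference
models used to validate it, a virtual measurement laboratory (exponential
sweep synthesis, deconvolution, noise), and the formant analysis used to
compare all of these.

## The two-port identity

The resonator is a reciprocal acoustic two-port with chain matrix
$M(\omega)$, glottis on port 1 and mouth on port 2, so
$(P_1, U_1)^T = M \,(P_2, U_2)^T$ and $\det M = 1$. The air between the
mouth and the source is another reciprocal two-port $N$; reciprocity and
the requirement that its input impedance seen from the mouth equal the
radiation impedance, $n_{11}/n_{21} = Z_r$, are the *only* constraints
physics places on it. With a source volume velocity $U_s$, the glottal
pressure with the mouth open is an open-circuit pressure of the joint
network $O = M N$, and the blocked-mouth pressure is the open-circuit
pressure of $N$ alone. For unit determinants both collapse to
$-U_s/o_{21}$ and $-U_s/n_{21}$, and the ratio is

$$\frac{P_1}{P_3} = \frac{n_{21}}{o_{21}} = \frac{1}{m_{21} Z_r + m_{22}}
  = H(\omega),$$

the transfer function of the resonator terminated by $Z_r$. Two properties
make this a *measurement principle* rather than a curiosity: the source
spectrum cancels identically, and every detail of the environment beyond
$Z_r$ drops out. `environment_reciprocal()` therefore offers a `"random"`
mode that draws the two free functions of $N$ from a seeded distribution;
`blocked_ratio_transfer()` agreeing with `transfer_direct()` to ~1e-15
over hundreds of random environments is the package's central invariant.
Numerically, the open-circuit pressure returns the cancellation-free
$-U_s/o_{21}$ form whenever the general form agrees with it, and the
blocked ratio uses $n_{21}/o_{21}$, which makes source-invariance exact in
floating point rather than merely close.

### Why the free-field reference fails

Normalizing $P_1$ by the free-field pressure $P_\mathrm{ref}$ (measured
with the model absent) compensates the loudspeaker response but not the
scattering: $P_1/P_\mathrm{ref} = H \cdot U_s/(U_s - n_{11} U_2)$, which
depends on the excitation. Evaluating $U_2$ needs a model of "the
environment with nothing at the mouth". The literal choice — feeding the
free-field monopole pressure back through the two-port equations — yields
a bias of unit magnitude for a pure point-source environment (a point
source scatters nothing), which would contradict the drift such
measurements actually show. `pref_bias()` instead takes $U_2$ as the flow
the free monopole wave carries through the empty mouth-aperture disc,
$U_2 = A_\mathrm{lips} (P_\mathrm{ff}/\rho c)(1 + 1/(jkd))$, giving a bias
magnitude that scales like $|Z_r|/Z_0$ and exhibits the documented upward
spectral drift. This choice is a modeling decision, exposed through the
`u2` override.

## Plane-wave elements

Tube sections use the standard transmission-line form: series impedance
per length $Z' = j\omega\rho/A$, shunt admittance per length
$Y' = j\omega A/(\rho c^2) + \ell_p/Z_\mathrm{wall}$, with
$\Gamma = \sqrt{Z'Y'}$ and $Z_c = \sqrt{Z'/Y'}$ giving the hyperbolic
chain matrix (determinant exactly 1 for any wall impedance). The 3D wall
impedance boundary condition is mapped to the distributed shunt term
$\ell_p/Z_\mathrm{wall}$, with $\ell_p = 2\sqrt{\pi A}$ the perimeter of
the area-equivalent circle — exact for the cylindrical benchmark and the
only geometry an area function supplies. The default
$Z_\mathrm{wall} = 500\rho c$ (specific, 205{,}800 Pa s/m at 20 °C) is the
empirical value appropriate for hard plaster-coated printed models; it is
a constant because a frequency- and position-dependent soft-tissue model
is out of scope. Side cavities (piriform-sinus-like branches) enter as
input-impedance shunts $[[1,0],[1/Z_b,1]]$ with
$Z_b = Z_c \coth(\Gamma L_b)$ for a closed branch; a 20 mm branch places
its quarter-wave zero near $c/(4 L_b) \approx 4.3$ kHz, reproducing the
pole-zero-pair phenomenology without 3D cavity geometry.

## Radiation load

The mouth radiates like a rigid piston of radius
$r = \sqrt{A_\mathrm{lips}/\pi}$ in an infinite baffle:
$Z_r = \rho c [R_1(x) + jX_1(x)]$, $x = 2kr$, with
$R_1 = 1 - 2J_1(x)/x$ and $X_1 = 2\mathbf{H}_1(x)/x$. The Struve function
$\mathbf{H}_1$ is evaluated by its ascending series for $x < 12$ and via
$\mathbf{H}_1 = Y_1 + \tfrac{2}{\pi}\int_0^\infty e^{-xt}\sqrt{1+t^2}\,dt
\cdot x$ (48-node Gauss–Laguerre) above; the split point is where series
cancellation would start costing digits, and both branches agree with
independent quadrature of the trigonometric integral representation to
~1e-13. The naive asymptotic expansion was rejected because it bottoms
out near 1e-8 at moderate arguments. Both the specific (Pa s/m, for the
FEM boundary condition) and acoustic (Pa s/m³, for chain-matrix
termination) conventions are explicit; `as_acoustic()` / `as_specific()`
never convert silently.

## The FEM reference

`solve_helmholtz()` solves $-(\kappa^2 + \nabla^2)P = 0$ with first-order
tetrahedral elements under the time convention $e^{+j\omega t}$:
prescribed normal velocity $V_0$ on the glottis, impedance conditions
$\nabla P\cdot\vec n = -(j\kappa\rho c/Z)P$ on walls ($Z_\mathrm{wall}$)
and lips ($Z_r$, recomputed per frequency). The sign of the weak form and
of the glottal Neumann datum are *pinned by an analytic oracle* — the
rigid closed-closed cylinder's forced solution
$P \propto \cos(k(L-z))/\sin(kL)$ — rather than asserted from notation.
The lips pressure is the area average over the lips facets (more
mesh-robust than a single center point; the difference is far below the
test tolerances for the cylinder). $H_\mathrm{FEM} =
U_\mathrm{lips}/U_\mathrm{glottis}$ with $U_\mathrm{lips} = A_\mathrm{lips}
P_\mathrm{lips}/Z_r$ and $U_\mathrm{glottis} = A_\mathrm{glottis} V_0$;
both areas are the discrete label areas, so the small polygonal deficit of
the meshed circle cancels in the ratio.

Cylinders are meshed by a structured disk triangulation (center plus
concentric rings) extruded into prisms, each split into three tetrahedra
with index-ordered diagonals so neighbouring prisms agree on shared faces.
The resulting layered node ordering keeps the matrix bandwidth small, and
each frequency is solved by a banded complex LU (LAPACK `zgbsv`) — about
0.2 s for the production mesh — with a sparse real-augmented fallback for
externally supplied meshes. The benchmark /Ə/ tube (170 mm × 27.6 mm) at
the default 3 mm edge target yields ≈5,300 nodes and ≈25,600 tetrahedra.

Formants from the FEM use a coarse scan (30 Hz) over 50–3600 Hz followed
by golden-section refinement of each peak and root-bracketed −3 dB
crossings, visiting ~150 frequencies instead of a dense 3 Hz grid — the
peak locations agree with the dense grid, at ~20× less work. These are the
problem sizes used throughout the tests and the acceptance script.

## The virtual measurement laboratory

`farina_sweep()` synthesizes the exponential sweep
$x(t) = \sin(K(e^{t/L}-1))$ (default 100 Hz–10 kHz, 21 s, 48 kHz — the
band and duration of the benchmark measurements; the sample rate covers
the sweep top with margin). `virtual_measurement()` computes $P_1$, $P_3$,
$P_\mathrm{ref}$ on an FFT grid from the chain model with a monopole
environment at 0.25 m, converts them to impulse responses (half-cosine
band-edge tapers below 100 Hz and above 10 kHz, excluded from all scored
bands), convolves with the sweep and adds seeded white Gaussian noise at a
stated in-band SNR — the simplest defensible stand-in for an
anechoic-chamber noise floor. Identical seeds give bit-identical
recordings.

`deconvolve()` applies the amplitude-compensated time-reversed inverse
sweep in its exact frequency-domain form ($\overline{X}/(|X|^2 +
\varepsilon(f))$, with the regularization ramped smoothly outside the
power band). Harmonic-distortion images land at $-L\ln k$ seconds — several
seconds early for the default sweep — and are excluded by the keep-window.
That window is $[-50\ \mathrm{ms}, +500\ \mathrm{ms}]$: the pre-window
must hold the band-limitation pre-ringing of the 100 Hz edge (~20 ms),
which a tighter 1 ms cut would truncate at a cost of >1 dB of in-band
ripple; impulse responses are likewise given a 50 ms bulk delay so the
ringing stays contiguous (pure delays cancel in pressure ratios). What the
simulator deliberately does **not** model: loudspeaker directivity and
nonlinearity, probe-microphone frequency response, room reflections beyond
white noise, and any scattering interaction between source and model —
passing round-trip tests therefore validates the processing chain, not
those hardware effects.

## Spectrum analysis

`find_formants()` picks local maxima of $20\log_{10}|H|$ with a 3 dB
prominence threshold (suppressing ripple) and reports at most four by
default, matching how such tables are conventionally quoted. Peak position
and height are refined by three-point parabolic interpolation; bandwidths
come from −3 dB crossings interpolated linearly in (Hz, dB). When a flank
merges into a neighbouring peak before dropping 3 dB, the bandwidth is the
symmetric reflection of the resolvable flank and the formant is flagged
(`bw_reflected_*`) rather than silently guessed. Amplitudes are absolute
dB of $|H|$ — no per-spectrum renormalization — so the physical limit
$|H| \to 1$ at DC anchors 0 dB. Spectral minima (branch zeros) can be
found by running the same picker on $-|H|$ but are reporting-only. Band
statistics (`rms_spectral_difference()`) interpolate linearly in (Hz, dB),
matching how such plots are read.

The bundled benchmark tables (`benchmark_formants()`) hold published
formant/bandwidth/amplitude rows for four printed resonators (/a/, /u/,
/i/ and the uniform tube) characterized by FEM, by the blocked-pressure
ratio and by free-field normalization; `benchmark_aggregate_deviation()`
pools the 16 per-formant deviations. The bandwidth-extraction scheme
behind the published tables is not documented; this package's −3 dB
convention reproduces the benchmark first-formant bandwidth to within a
few percent, and tolerances on bandwidth comparisons are set accordingly.

## Degenerate inputs and numerical guards

DC is excluded from every grid (several expressions are 0/0 at
$\omega = 0$); low-frequency limits are asserted at 3 Hz. A branch zero or
an undamped pole falling exactly on a grid point raises an error advising
a grid shift. Determinant checks flag non-reciprocal inputs. All identity
tolerances are relative and sized to double precision (1e-10 where pure
algebra is involved); FEM agreement bounds reflect first-order element
dispersion at the stated edge lengths.

## Limitations

Plane-wave chain models are valid below the first transverse duct mode —
about 7.3 kHz for the 27.6 mm benchmark tube — and the FEM reference is
itself limited by the constant wall impedance and the straight-cut lip
termination. The method applies to physical resonator models, not in vivo;
real recordings must be pre-equalized for the probe microphone. Side
branches are impedance shunts, not 3D cavities. End-plate recesses and
microphone ports of physical models are not represented in the 1D
geometry (and lengths are not extended for them by default).

## A worked comparison

```{r example}
library(tracttf)

h_chain <- chain_transfer_function(schwa_tube(), default_grid())
find_formants(h_chain)

mesh <- cylinder_mesh(radius = 0.0138, length = 0.170, target_edge = 3e-3)
ft_fem <- formants_from_solver(fem_solver_function(mesh), f_max = 3600)
glance(compare_formant_tables(find_formants(h_chain), ft_fem))

autoplot(h_chain)
```
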