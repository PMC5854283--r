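# tracttf

Volume-velocity transfer functions of tube-like acoustic resonators —
vocal-tract models in particular — from two external-excitation pressure
measurements, with the plane-wave and 3D finite-element reference models
needed to validate them.

## The problem and the method

The vocal tract transfer function `H(ω) = U2(ω)/U1(ω)` (lip volume
velocity over glottal volume velocity) characterizes formants — the
resonances that define vowels. Driving a physical resonator from the
glottal side requires a broadband constant-volume-velocity source, which
is hard to build. Driving it *externally* with an ordinary loudspeaker is
easy, but the glottal pressure alone only approximates `H`.

Model the resonator as a reciprocal acoustic two-port with chain matrix
`M` (`det M = 1`) and the exterior air as another two-port `N` whose
input impedance from the mouth is the radiation impedance,
`n11/n21 = Zr`. Measure

* `P1` — pressure at the closed glottal end, mouth open,
* `P3` — pressure right in front of the mouth blocked by a stiff plate.

Both are open-circuit pressures (`-Us/o21` and `-Us/n21` with `O = M·N`),
and their ratio is exactly

```
P1/P3 = 1/(m21·Zr + m22) = H(ω)
```

independent of the source spectrum `Us` (it cancels) and of everything
about the environment except `Zr`. `tracttf` implements this identity,
the models on both of its sides, and the analysis around it:

* **two-port algebra** — frequency-gridded 2×2 chain matrices, cascading,
  reciprocity checks (`tm_series()`, `cascade()`,
  `reciprocity_deviation()`);
* **tube elements** — lossless and wall-lossy sections, piecewise area
  functions, closed side branches for piriform-sinus-like spectral zeros
  (`uniform_tube_matrix()`, `area_function()`, `side_branch_matrix()`);
* **radiation** — rigid piston in an infinite baffle,
  `Zr = ρc[R1(x) + jX1(x)]` with Bessel/Struve terms
  (`piston_in_baffle()`, `struve_h1()`);
* **measurement theory** — the identity itself plus the biases of the
  alternatives (`blocked_ratio_transfer()`, `transfer_direct()`,
  `kitamura_prediction()`, `pref_bias()`);
* **Helmholtz FEM** — first-order tetrahedral reference solver with
  impedance boundary conditions on programmatically meshed cylinders or
  external Gmsh v2 meshes (`cylinder_mesh()`, `solve_helmholtz()`,
  `fem_transfer_function()`);
* **sweep lab** — exponential-sweep synthesis, deconvolution, and fully
  virtual `P1/P3/Pref` measurements with seeded noise (`farina_sweep()`,
  `deconvolve()`, `virtual_measurement()`);
* **spectrum analysis** — formant/bandwidth/amplitude extraction and
  comparison statistics against the bundled benchmark tables
  (`find_formants()`, `compare_formant_tables()`,
  `benchmark_formants()`).

## Worked example

The benchmark resonator is a uniform tube of 170 mm length and 27.6 mm
inner diameter (a schwa-like neutral tract, aperture ≈ 5.98 cm²):

```r
library(tracttf)

h <- chain_transfer_function(schwa_tube(), default_grid())
find_formants(h)
#> # A tibble: 4 × 5
#>   formant frequency_hz bandwidth_hz amplitude_db flag
#>     <int>        <dbl>        <dbl>        <dbl> <chr>
#> 1       1         472.         20.0         29.5 ""
#> 2       2        1420.         51.2         21.1 ""
#> 3       3        2378.        103.          14.8 ""
#> 4       4        3346.        165.          10.4 ""
```

Four formants at 472, 1420, 2378 and 3346 Hz: the odd quarter-wave
resonances of a closed-open pipe, lowered from `(2n−1)c/4L` by the
piston end correction, with bandwidths set by the wall impedance
(500·ρc) and radiation loss. The 3D FEM reference on the same geometry
agrees within 0.2 %:

```r
mesh <- cylinder_mesh(radius = 0.0138, length = 0.170, target_edge = 3e-3)
formants_from_solver(fem_solver_function(mesh), f_max = 3600)
#> # A tibble: 4 × 5
#>   formant frequency_hz bandwidth_hz amplitude_db flag
#> 1       1         472.         20.1         29.5 ""
#> 2       2        1421.         51.1         21.2 ""
#> 3       3        2380.        103.          14.8 ""
#> 4       4        3351.        165.          10.5 ""
```

And the measurement identity holds to machine precision for *any*
reciprocal environment:

```r
g  <- default_grid()
m  <- area_function_matrix(schwa_tube(), g)
zr <- as_acoustic(piston_in_baffle(g, effective_radius(pi * 0.0138^2)),
                  pi * 0.0138^2)
n  <- environment_reciprocal(zr, mode = "random", seed = 1)
max(Mod(blocked_ratio_transfer(m, n)$h - transfer_direct(m, zr)$h))
#> [1] ~1e-15
```

A command-line front end with subcommands `simulate-tf`, `fem-tf`,
`virtual-measure`, `deconvolve`, `analyze`, `compare` and `make-fixture`
is installed at `inst/cli/tracttf.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/tracttf.R", package="tracttf"))')" \
    simulate-tf --resonator schwa_tube --out tf.csv
```

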