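# fhnflow

Slow-fast dynamics and waves in FitzHugh–Nagumo-type neuron models.

`fhnflow` is for people studying how complex neuronal oscillations —
bursting, mixed-mode oscillations (MMOs), canards — arise in
FitzHugh–Nagumo (FHN) and FitzHugh–Rinzel (FHR) models, and how they
propagate (or fail to) in excitable tissue.  It implements, end to end:

* the ODE families: the three-variable slow-fast system

  $$\epsilon \dot u = f(u) - v + w + I, \quad \dot v = u - b v - c, \quad
    \dot w = \epsilon(-u - w),$$

  with the soft cubic $f(u) = -u^3/3 + u$, the classic three-timescale
  bursting model, and the planar FHN system — all integrated with a
  fixed-step RK4 core (compiled);
* local stability: fixed points, the Jacobian, the monic characteristic
  polynomial, the Routh–Hurwitz criterion and the cubic discriminant, and
  bisection location of the Hopf drive $I^*$;
* MMO machinery: extrema extraction, S/M/L symbolic sequences with
  run-length motifs (`LLS×4 LM`), the exact focus-frame change of
  variables, the moving-focus approximation, and the small-oscillation
  count $n_o = \frac{1}{2\pi}\int_0^T \beta(t)\,dt$;
* canard classification at the fold: the slow-fast singular subsystems,
  the fold blow-up system $\dot u = -3u^2 - v + w$, $\dot v = u$ with its
  first integral $G(u,v;w) = (-3u^2 - (v-w) + 1/6)e^{6(v-w)}$, and the
  periodic/escape threshold $c^* = w + 1/6$ recovered by bisection;
* a Poincaré return map on $\{u = 0, v < 0\}$ and a two-stage
  periodic-orbit finder;
* a method-of-lines simulator for the non-homogeneous FHN
  reaction-diffusion system (1D/2D, Neumann boundaries), stationary-state
  solvers, and wave diagnostics: frequency filtering, filtering ratio,
  and death-spot location.

Everything is deterministic; results come back as tibbles (or small S3
objects with `tidy()`/`glance()` methods) and plot via `autoplot()`.

## A worked example

Stability of the three-variable system at drive `I = 1.45`:

```r
library(fhnflow)
p <- fhr_params(I = 1.45, b = 0.8, c = 0, eps = 0.1)
spectral_summary(p)
#> <spectral_summary>
#>   fixed point u* = 0.939127 (residual 0.00e+00)
#>   eigenvalues:  0.224688+3.16908i,  0.224688-3.16908i, -0.168976+0.00000i
#>   unstable/stable/center: 2/1/0, complex pair: TRUE
#>   Hurwitz margin a2*a1 - a0 = -4.51451 (stable: FALSE)
```

The fixed point carries an unstable complex pair plus one stable real
eigenvalue — the spectral signature of the MMO regime.  The Hopf
bifurcation where that pair stabilizes:

```r
hopf_locate(p)$I_star
#> [1] 1.500692
```

Simulate past the transient and read off the mixed-mode symbol sequence
(many small oscillations punctuated by a large relaxation excursion):

```r
tr <- integrate_model(p, y0 = c(0.5, 0.5, -0.5), t1 = 400, dt = 1e-3,
                      stride = 20L)
sq <- classify_oscillations(find_extrema(tr[tr$time >= 150, ], "u"))
motif_compress(sq)
#> [1] "SSSLSSSSS×12 S×3 L"
```

Canard classification at the fold — the numerically bisected escape
threshold against its analytic value 1/6:

```r
escape_threshold(w = 0)$c_star
#> [1] 0.1666649
```

The relaxation periodic orbit at zero drive, from the Poincaré map:

```r
glance(find_periodic_orbit(fhr_params(I = 0, eps = 0.01)))
#> # A tibble: 1 × 4
#>   v_star  w_star period residual
#>    <dbl>   <dbl>  <dbl>    <dbl>
#> 1 -0.704 0.00781   2.07 6.77e-15
```

And the three wave regimes of the 1D excitability well, from the preset
sweep (full propagation, an interior death spot, and oscillator death):

```r
run_scenario("quartic1d-deathspot")$regimes
#> [1] "full_propagation" "death_spot"       "stationary"
```

`list_scenarios()` shows all presets (bursting, MMO motifs, eigenvalue
signatures, the 2D filtering ball, ...); each can also be driven from a
shell via the thin wrapper `inst/cli/fhnflow.R`:

```sh
Rscript inst/cli/fhnflow.R run spectral-signature
```

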