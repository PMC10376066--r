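---
title: "Slow-fast analysis of FitzHugh-Nagumo-type models: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slow-fast analysis of FitzHugh-Nagumo-type models: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhnflow)
```

# The model family

The package analyses a family of excitable-membrane models built around a
cubic fast nullcline $f(u)$, in two variants: the *soft* cubic
$f(u) = -u^3/3 + u$ (used throughout the ODE analysis) and the *steep*
cubic $f(u) = -u^3 + 3u$ (used by the reaction-diffusion parameter sets
and the fold computation).  Both have folds at $u = \pm 1$.

The central object is the three-variable slow-fast system

$$\epsilon \dot u = f(u) - v + w + I, \qquad
  \dot v = u - b v - c, \qquad
  \dot w = \epsilon(-u - w),$$

a planar FitzHugh-Nagumo oscillator $(u, v)$ driven by a super-slow
recovery-like variable $w$.  With $b = 0.8$, $c = 0$, $\epsilon = 0.1$ and
the soft cubic, varying the drive $I$ moves the planar subsystem through
attractive-focus, repulsive-focus and relaxation regimes while $w$ drifts,
which is the engine behind its mixed-mode oscillations (MMOs).  The
original bursting model (three timescales: voltage, recovery at rate
$\phi = 0.08$, super-slow drive at rate $\epsilon = 10^{-4}$) and the
planar system with a frozen drive are provided alongside.  The spatial
extension is the non-homogeneous reaction-diffusion system

$$\epsilon u_t = f(u) - v + I(x) + d_u \Delta u, \qquad
  v_t = u - b v - c(x) + d_v \Delta v$$

on an interval or square with no-flux (Neumann) boundaries, where the
excitability profile $c(x)$ makes a central region oscillatory
($|c| < 1$ for the steep cubic at $b = 0$) and the surround excitable.

All quantities are dimensionless and time is the model's own unit
throughout.

Two conventions are settled once, at the constructor level:

* **The printed-versus-classical voltage equation of the bursting
  model.**  `fhr_original_params(literal_eps_on_v = TRUE)` (the default)
  divides the voltage equation by $\epsilon$, exactly as the model is
  written here; `FALSE` gives the classical convention without that
  factor.  The bursting *preset* uses the classical convention, because
  the super-slow variable needs $\sim 10^4$ time units to trace one
  bursting loop while the literal form makes the voltage equation
  $10^4$-fold stiff -- the combination would require on the order of
  $10^9$ fixed steps per run.  The preset records its convention in its
  configuration.
* **The cubic is always explicit.**  Every parameter record carries its
  cubic variant; nothing defaults silently between the two.

# Integration

All trajectories are produced by the classical fixed-step fourth-order
Runge-Kutta scheme (`rk4_solve()` for arbitrary R vector fields, a
compiled core behind `integrate_model()` for the built-in families), with
the final step shortened to land exactly on the requested end time.
Fixed-step RK4 is the package's single time discretization -- also for the
method-of-lines reaction-diffusion runs -- so that ODE and PDE results are
directly comparable (a spatially homogeneous simulation reproduces the
pointwise ODE to round-off, which the tests assert at $10^{-6}$).

* **Step sizes.** The default is $\mathrm{d}t = \epsilon/100$ (e.g.
  $10^{-3}$ at $\epsilon = 0.1$), floored at $10^{-5}$; the classical
  bursting convention uses $10^{-2}$.  These were checked by the order-4
  convergence tests and by step-halving on the analysis runs.
* **Blow-up detection.** A trajectory is truncated and flagged when a
  state component exceeds $10^8$ in magnitude -- far above any bounded
  orbit of these systems and far below overflow.  Escape orbits of the
  fold blow-up system diverge in finite time and rely on this.
* **Extrema.** `find_extrema()` keeps interior strict local extrema,
  prunes adjacent pairs whose swing is below a prominence floor (default
  $10^{-3}$ of the series range; the mixed-mode small oscillations are
  orders of magnitude larger), and refines each survivor with a
  three-point parabola.  Pruning smallest-swing-first keeps the sequence
  strictly alternating.
* **Section crossings.** `section_crossings()` interpolates linearly
  between bracketing samples.  The Poincaré machinery instead refines
  crossings by bisection on the RK4 sub-step, so the crossing inherits
  the solver's accuracy rather than the sampling resolution.

# Stability analysis and the Hopf point

The fixed point of the three-variable system satisfies $v^* = u^*/b$,
$w^* = -u^*$ with $u^*$ the unique root of $f(u) - (1 + 1/b)u + I = 0$
(strictly decreasing map for the soft cubic, since $f' \le 1 < 1 + 1/b$).
The Jacobian is assembled exactly;
the characteristic polynomial is normalized monic,
$\lambda^3 + a_2\lambda^2 + a_1\lambda + a_0$ with $a_0 = b u^{*2} + 1 > 0$,
so that the Routh-Hurwitz criterion applies in its textbook form:
stability $\iff a_2 > 0,\ a_0 > 0,\ a_2 a_1 - a_0 > 0$.  The "Cardan"
quantity reported is the polynomial discriminant, with the convention
*negative $\iff$ one real root plus a complex-conjugate pair*.

Numerical conventions: eigenvalue real parts are compared to zero with
tolerance $10^{-9}$; the Hopf drive $I^*$ is located by bisection on the
real part of the complex pair (falling back to the spectral abscissa at
bracket ends where the spectrum is real) to a default tolerance of
$10^{-10}$ in $I$.  With the reference parameters the package finds

```{r}
hopf_locate(fhr_params(I = 1, b = 0.8, c = 0, eps = 0.1))$I_star
```

inside the theoretical bracket $(1, 2)$.  Along $I \in [1, 2]$ the
discriminant stays negative (the complex pair persists) and the
Routh-Hurwitz margin $a_2 a_1 - a_0$ changes sign exactly at $I^*$; for
$I$ slightly below $I^*$ trajectories started near the fixed point
depart, slightly above they decay, which the tests check by simulation.
For the planar system the Hopf identity $f'(u^*) = b\epsilon$ is used in
the form $u^* = \sqrt{1 - b\epsilon}$ (the square root is forced by
$f'(u) = 1 - u^2$ for the soft cubic).

# Mixed-mode oscillations and their symbolic encoding

An MMO trace is reduced to events by pairing each trough with the
following peak; the peak-to-trough amplitude is the event size.  Events
are labelled relative to the largest event of the window: at least
$\theta_{ML}$ of the maximum is large (L), at least $\theta_{SM}$ medium
(M), below that small (S).  The defaults $(\theta_{SM}, \theta_{ML}) =
(0.3, 0.7)$ reflect the three clearly separated amplitude bands the MMO
regimes produce; they are fractions of the running maximum, so the
labelling is invariant under uniform rescaling of the signal.  They are
tunable and nothing in the analysis depends on their exact values as long
as they fall between the bands.  `motif_compress()` then greedily
collapses the label string into repeated units (most repeats first,
longest unit on ties), e.g. `LLSLLSLLSLLSLM` into `LLS×4 LM`.

No single drive value is asserted for the canard-dominated pattern: the
regime boundaries inside $I \in (1.3, 1.5)$ are delicate, so the
`canard-motif-scan` preset scans the interval and reports the motif per
drive instead.  The tests assert the robust qualitative facts: at
$I = 1.3$ the encoded trace contains repeated `LLS` blocks together with
M events; at $I = 1.45$ many small oscillations alternate with isolated
large ones.

## The moving focus

Freezing $w$, the planar block has a fixed point $(u^*(w), u^*(w)/b)$
which the package continues in $w$ by safeguarded Newton
(`u_star_planar()`).  Writing the system in coordinates centred on that
moving point gives the exact focus-frame system (`transformed_rhs()`)

$$\epsilon \dot u = g(u^*, u) - v - \epsilon^2 k\, s, \qquad
  \dot v = u - bv - \tfrac{\epsilon k}{b} s, \qquad
  \dot w = -\epsilon(w + u^* + u),$$

with $g(u^*, u) = f(u^* + u) - f(u^*)$, $k = 1/(f'(u^*) - 1/b)$ and
$s = u^* + u + w$.  The $\epsilon$-corrections are the chain-rule terms of
the moving frame ($du^*/dw = -k$, $dv^*/dw = -k/b$); with the signs and
the $1/b$ factor as written above the transformation is exact, which the
tests verify by mapping trajectories back onto the original system
($10^{-10}$ sup-norm over five time units).  Dropping the nonlinear and
$O(\epsilon)$ terms of the planar block yields the moving-focus
approximation (`moving_focus_rhs()`)
$\epsilon\dot u = f'(u^*)u - v$, $\dot v = u - bv$, whose $2\times 2$
linearization $A(u^*)$ has eigenvalues $\alpha \pm i\beta$ with
$\alpha = \mathrm{Tr}A/2$ and
$\beta = \tfrac12\sqrt{4\det A - (\mathrm{Tr}A)^2}$ in the complex regime
(the $\tfrac12\sqrt{\cdot}$ form is forced by the standard eigenvalue
formula).  The predicted number of small oscillations over a focus
passage is the integrated rotation rate

$$n_o = \frac{1}{2\pi}\int_0^T \beta(t)\,dt,$$

computed by composite trapezoid quadrature on the sampling grid with
$\beta$ set to zero wherever the discriminant is non-negative (real
eigenvalues -- no rotation).  On a simulated passage the formula agrees
with direct peak counting to within one oscillation, and doubling the
quadrature resolution moves the estimate by less than $10^{-6}$.  The
sign of $\alpha(t)$ partitions the passage into a shrinking and a growing
phase -- the dynamic Hopf signature that the amplitude envelope of the
simulated small oscillations reproduces.

# Slow-fast structure, the fold, and canard classification

The three singular limits -- reduced flow on the critical manifold, fast
layer fibres, and the super-slow flow -- are exposed by
`subsystem_rhs()`, which also flags fold points $f'(u) = 0$ where the
reduced flow is undefined.  For the steep cubic, shifting the origin to
the right fold gives shifts $\tilde v = 1/b$,
$\tilde w = 1/b - 2 - I$ and the unfolding parameter
$\mu = 1 + \tilde w = -1 + 1/b - I$, with the fast equation's local
expansion $-3u^2 - u^3$.

Blowing up the fold requires an anisotropic rescaling.  Writing
$u = \sqrt{\epsilon}\,\bar u$, $v = \epsilon \bar v$,
$w = \epsilon \bar w$ and $\tau = t/\sqrt{\epsilon}$ balances the
quadratic term against the recovery variable and produces, as
$\epsilon \to 0$,

$$\bar u_\tau = -3\bar u^2 - \bar v + \bar w, \qquad
  \bar v_\tau = \bar u, \qquad \bar w_\tau = 0,$$

with $O(\sqrt{\epsilon})$ corrections (an equal $\epsilon$-scaling of all
three states cannot balance the $-3u^2$ and $-v$ terms; the tests verify
the $\sqrt{\epsilon}$ convergence of the rescaled vector field
numerically).  The blow-up system is integrable:

$$G(u, v; w) = \big(-3u^2 - (v - w) + \tfrac16\big)\, e^{6(v - w)}$$

is constant along its flow (conserved to $10^{-6}$ relative drift per
period at $\mathrm{d}t = 10^{-4}$ in the tests -- the conservation is a
property of the exact flow, so the drift measures the integrator).  The
level structure classifies every launch point $(0, c)$: the center
$c = w$ is a fixed point, $0 < G < 1/6$ gives a periodic orbit, $G \le 0$
(i.e. $c \ge w + 1/6$) gives an escape orbit with
$u, v \to -\infty$; the orbit diameter grows without bound as
$c \uparrow w + 1/6$.  `classify_orbit()` implements both the analytic
rule and an integration-based classifier (escape $\iff$ the blow-up
detector trips within a time budget of 500, plenty because escape times
grow only logarithmically near the separatrix), and
`escape_threshold()` bisects the integration-based classifier to recover
the separatrix ordinate numerically -- landing within $10^{-4}$ of the
analytic $w + 1/6$.

# The Poincaré return map and the periodic orbit

On the section $\{u = 0,\ v < 0\}$, departures are taken with
$\dot u > 0$ (the jump off the left branch) and returns matched in the
same direction; the orientation is a package convention, fixed once.  A
return must occur within $50/\epsilon$ time units or the map is flagged
undefined (one relaxation loop is $O(1)$ in the slow time, so the budget
is generous).  The periodic-orbit finder mirrors the two-stage
fixed-point construction: an inner solve for $\varphi(w)$, the fixed
$v$-coordinate at frozen $w$ (fixed-point iteration; the return
$v$-coordinate is nearly independent of $v$ because all loops funnel
through the jump at the left fold, landing at $f(-1) + O(\epsilon)$), then
an outer scalar root of $F_3(0, \varphi(w), w) - w$ (root bracketing to
$10^{-10}$).  The outer map is positive for small $w < 0$ and negative
for small $w > 0$, which guarantees the bracket; the tests verify this
sign structure, a section residual below $10^{-6}$, that the orbit is a
non-constant relaxation loop, that re-integration over five periods stays
within $10^{-3}$ of it, and that its period matches the frozen-$w$ planar
relaxation period within 10%.  No claim is made about the largest drive
at which the orbit persists; the finder is simply exercised at a small
positive drive as a spot check.

# The reaction-diffusion solver and its diagnostics

Space is discretized on a uniform cell-centered grid (an odd point count
puts a cell exactly at the domain center) with the standard second-order
Laplacian and ghost-point reflection at the boundaries, which conserves
the discrete mean of the diffusion operator to round-off.  Time stepping
is the same RK4 scheme, with the explicit-diffusion bound
$\mathrm{d}t \le \epsilon\,\mathrm{d}x^2/(4 n_{dim} d_u)$ (the
$1/\epsilon$ on the fast equation sharpens the usual constraint; a
$d_v$-analogue applies without it) enforced at run time -- a violating
step size is rejected with a message proposing a compliant one.  The
default step adds a reaction-stiffness cap
$2\epsilon/\max|f'|$ over the excitability range, relevant for deep
wells.  The default initial condition is the $b = 0$ stationary formula
with the diffusion term dropped ($u = c(x)$, $v = f(c) + I$):
deterministic, and already an equilibrium wherever the profile is flat.

Stationary solutions (for $d_u > 0$, $d_v = 0$) come in two branches: at
$b = 0$ the solution is explicit ($u = c(x)$ exactly, with $v$ absorbing
the discrete Laplacian), and at $b > 0$ a damped Newton iteration with the
sparse finite-difference Jacobian drives the residual sup-norm below
$10^{-10}$, restarting from several initial guesses if needed.  The
uniqueness probe (same solution from different starts to $10^{-8}$) is
exercised in the regime $\max f' < 1/b$ ($b < 1/3$ for the steep cubic)
where the discretized nonlinearity is monotone; outside it Newton can
stall and discrete solutions need not be unique.

`propagation_diagnostics()` reduces a run to the wave-propagation
picture over the second half of the run (discarding the transient):
per-location counts of peak-to-trough events above an amplitude
threshold (default 1, about half the relaxation amplitude of the steep
cubic), the *death spot* (smallest $|x|$ whose large-event count falls
below half the center count; absent when propagation is full; at the
first off-center cell when nothing oscillates), and the *filtering
ratio* (total event count at the center over the border count).  In 2D
the diagnostics are taken along the horizontal line through the center.

## Geometry of the two spatial scenarios

The domain sizes, grid resolutions, ball radius and run lengths of the
spatial scenarios are package choices (none are forced by the model):

* **2D oscillatory ball** (`ball2d-filtering`): $128 \times 128$ cells on
  a side-100 square, ball radius 8, $c = 0$ inside and $-1.21$ outside,
  $d_u = d_v = 1$, $b = 0$, run length 150.  The qualitative outcome --
  relaxation waves propagating outward at a reduced rate, the center's
  surplus oscillations filtered, border cells showing only large events
  with the diffusive term quiet except around the jumps -- is insensitive
  to the radius across at least 3-12.
* **1D quartic well** (`quartic1d-deathspot`): 81 cells on $(-5, 5)$
  ($\mathrm{d}x = 0.25$, as in the package's wide default grid), well
  depths $p \in \{1, 5, 40\}$, run length 150.  The narrow domain is
  deliberate.  Whether the oscillatory core survives is a linear
  instability question for the operator $f'(c(x)) + d_u\Delta$: its top
  eigenvalue must stay positive, which requires the $f'(c) > 0$ core
  (half-width $\approx \beta/\sqrt{2p}$) to remain wider than roughly the
  fast coupling length $\sim \pi/(2\sqrt{f'(0)/d_u}) \approx 0.9$.  On a
  half-width-50 domain that pushes the stationary (oscillator-death)
  regime beyond $p \sim 10^3$, where the reaction stiffness forces
  $\mathrm{d}t \sim 10^{-8}$; on $(-5, 5)$ the three regimes -- full
  propagation ($p = 1$), wave-death at an interior point ($p = 5$), and
  convergence to the stationary state ($p = 40$) -- all appear within
  seconds of compute.  The death-spot regime also reproduces the
  every-other-wave failure pattern at intermediate depths.

# What the simulations do and do not show

Everything here is a study of the models themselves; the "data" are
simulated trajectories of the stated equations, so passing tests
establish internal consistency (formulas against independent numerical
oracles, approximations against the systems they approximate, PDE
dynamics against its diffusion-less limit) -- not agreement with any
biological recording.  Several constants of the source analysis are not
pinned down numerically anywhere (figure initial conditions, spatial
grids, run lengths, the drive producing one specific canard motif); the
corresponding results are reproduced qualitatively and reported as such
rather than asserted against invented reference numbers.  Known
limitations: no adaptive or implicit stepping (deliberate -- the fixed
grid is part of the method), 3D domains and joint $d_u, d_v > 0$
stationary theory are out of scope, and the symbolic S/M/L thresholds
are descriptive conventions, not detected bifurcation boundaries.
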