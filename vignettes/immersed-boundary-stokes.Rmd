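---
title: "Immersed boundary Stokes flow: model, discretization and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immersed boundary Stokes flow: model, discretization and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibstokes)
```

## The model

`ibstokes` simulates the motion of massless elastic structures — closed
strings (membranes) and open filaments — immersed in a two-dimensional
incompressible fluid at zero Reynolds number. Because inertia is absent, the
fluid has no state of its own: at every instant the velocity field
$(u, v)$ and pressure $p$ are completely determined by the elastic forces
the structures currently exert,

$$\nabla\cdot\mathbf{V} = 0,\qquad
0 = -\partial_x p + \mu\nabla^2 u + f_x,\qquad
0 = -\partial_y p + \mu\nabla^2 v + f_y,$$

on a doubly periodic square box. Taking the divergence of the momentum
balance turns the system into three Poisson problems solved in sequence:
$\nabla^2 p = \nabla\cdot\mathbf{f}$ for pressure, then
$\mu\nabla^2 u = \partial_x p - f_x$ and
$\mu\nabla^2 v = \partial_y p - f_y$ for the velocity components.

A structure is a chain of Lagrangian points $\mathbf{X}_k$ carrying the
elastic energy

$$E[\mathbf{X}] = \frac{c_s}{2}\int\Big(\Big|\frac{\partial\mathbf{X}}
{\partial s}\Big| - 1\Big)^2 ds
 + \frac{c_b}{2}\int\Big|\frac{\partial^2\mathbf{X}}{\partial s^2}\Big|^2 ds,$$

whose variational derivative yields a stretching force
$\partial_s(T\boldsymbol\tau)$ — with the one-sided tension
$T = c_s(|\partial_s\mathbf{X}| - 1)$ active only on taut segments (strings
do not push) — and a bending force $-c_b\,\partial_s^4\mathbf{X}$. Tensions
live on a staggered grid of segment midpoints; bending forces live on
nodes. The structure and the fluid communicate through a regularized delta
kernel: forces are *spread* onto the grid, and grid velocities are
*interpolated* back to the nodes, which then move with the local fluid
velocity (no-slip) by an explicit Euler update
$\mathbf{X}^{n+1}_k = \mathbf{X}^n_k + \Delta t\,\mathbf{U}^n_k$.

## Discretization choices

**Collocated periodic grid.** All fields sample the same $n_x\times n_y$
nodes of a half-open periodic box; node $(0,0)$ sits at $(x_0, y_0)$ and
$x_1$ is identified with $x_0$. Derivatives are second-order central
differences with index wrap.

**The delta kernel.** The 1-d profile is piecewise trigonometric with
support $|r| < 2.5$ cells (wider than the classical 4-point cosine kernel,
which damps grid-scale oscillation), scaled as
$\delta_h(x) = \phi(x/h)/h$ so that spreading and interpolation are
dimensionally consistent and exactly adjoint under the discrete pairing.
Two of its properties were *measured* rather than assumed, and the test
suite pins the measured facts: the partition-of-unity defect is
round-off-level ($2\cdot10^{-16}$, i.e. the grid sums are exact for every
sub-cell shift probed), the profile is nowhere negative, and linear fields
are reproduced exactly.

**Poisson solves.** The periodic 5-point Laplacian is diagonal in the
discrete Fourier basis, so one FFT pair gives the exact direct solution;
a dense pseudo-inverse is the independent oracle in the tests. The operator
is singular — constants span its null space — so every right-hand side is
projected to zero mean (the removed mean is reported; on the velocity
equations it is the net force over the box, which periodicity cannot
balance) and solutions are gauge-fixed to zero mean, which for velocity
removes the free uniform-translation mode.

**Operator compatibility (a deliberate deviation from the "most literal"
scheme).** Assembling $\nabla\cdot\mathbf{f}$ with central differences but
inverting the **5-point** Laplacian for $p$ leaves the discrete velocity
with a divergence of the same order as the velocity itself: measured on the
relaxing-star run, the divergence max-norm was $O(30)$ against
$\max|u| = O(1)$, the membrane lost 17% of its enclosed area by $t = 0.12$,
and node speeds plateaued — the run never reached equilibrium. The package
therefore solves the *pressure* equation with the wide ($2h$) Laplacian,
which is exactly the composition $\nabla_c\cdot\nabla_c$ of the central
operators used everywhere else. With that choice
$\nabla_c\cdot(u,v) \equiv 0$ to round-off (measured $\sim10^{-13}$), and
area drift over a full star run falls to about $-1.6\%$. The wide operator
has four extra null modes, the grid-Nyquist checkerboards; they are
projected out of the right-hand side, which is harmless because the central
gradient annihilates them — they could never influence the velocity. The
velocity Poissons keep the 5-point operator: their right-hand sides are
already consistent and the 5-point inverse introduces no compatibility
error there.

**End conditions for filaments.** Nodes are numbered from the free end
($k=0$) to the clamped end ($k=N$). The free end carries zero curvature and
a third-difference force closure; the clamped end is *pinned* (its position
is reset each step, since without pinning the anchor drifts) and
contributes a prescribed-curvature datum
$(D_{ss}X)_N = [\mathbf{t}_c - (X_N - X_{N-1})/\Delta s]/(\Delta s/2)$
built from a configurable clamp tangent $\mathbf{t}_c$, default $(-1, 0)$.
That default is kept verbatim from the source formulation even though it is
geometrically inconsistent with the packaged quarter-circle arc, which
meets the wall vertically (tangent $(0,-1)$); the inconsistency makes the
clamp closure the dominant force in the filament scenarios (a local force
dipole of magnitude $\sim 800$ against interior bending forces of
$\sim 0.06$). Users studying clamp-driven artifacts should pass
`clamp_tangent = c(0, -1)` to `make_filament_arc()`.

**Rest spacing.** $\Delta s = L_0/N$ for closed chains (unstretched
perimeter $2\pi r_0$ over $N$ nodes) and $\Delta s = L_0/(N-1)$ for open
ones, so that stretch $=1$ is the rest state by construction. The
stretching force at open ends takes the natural one-sided boundary terms of
the variational derivative, preserving a zero force sum on the free chain.

**Stability guards.** The explicit update is protected by a displacement
guard: a step moving any node farther than half a grid cell logs a warning
in the diagnostics; beyond two cells the run aborts. These are engineering
thresholds for a scheme whose stable step scales like $O(h^2)$ against the
strong tension stiffness.

## The packaged scenarios

Three ready-made configurations reproduce the study conditions
(`ib_scenario()`):

* **`star_relaxation`** — a closed string sampled at $N_b = 160$ angles
  from $\rho(\theta) = 0.6 + 0.3\sin 8\theta$, rest radius $0.3$,
  $c_s = 100$, no bending, on a $64\times64$ grid over $(-1,1)^2$ with
  $\mu = 1$. The initial radius extrema are exactly $0.9$ and $0.3$. The
  string is everywhere stretched about twofold, and tension relaxes it to a
  circle whose radius is set by (approximate) area conservation:
  $\sqrt{0.405\pi/\pi} = 0.6364$ from the exact initial-area quadrature.
* **`bending_filament`** — an open quarter-circle arc of radius $0.25$
  ($N_b = 30$, $c_s = 2$, $c_b = 10^{-3}$, $\Delta t = 4\cdot10^{-4}$)
  clamped to the bottom wall of $(-1,1)\times(0,2)$; initially unstretched,
  so only bending forces act at $t=0$.
* **`filament_circle`** — the same filament plus a passive circular string
  ($N_b = 100$, radius $0.3$, center $(0,1)$, $c_s = 0.01$,
  $\Delta t = 5\cdot10^{-4}$). Per-structure coefficients follow the
  narrative source: the circle is a pure string ($c_b = 0$) so its nodes
  rotate freely, even though the associated constants table prints a common
  $c_b$ for both structures. It starts exactly at its equilibrium (the
  one-sided tension of the inscribed polygon is zero), so it exerts no
  force until the filament-driven flow deforms it.

**Time step for the star.** The source only states $\Delta t = O(h^2)$,
started small and later increased. At $\Delta t = h^2$ the very stiff start
(initial node speeds $\approx 122$) would move nodes $\approx 3.8$ cells in
one step — past the abort guard — so the packaged schedule starts at
$h^2/16$, the largest power-of-two fraction keeping the first displacement
under half a cell, and relaxes to $h^2/4$ at $t = 0.05$ once the fast
transient has decayed (stability at $h^2/4$ was verified empirically;
halving both entries changes the converged radii by under $10^{-4}$).

**Equilibrium detection.** Relaxation is judged by the maximum Lagrangian
node speed. Regularized-delta coupling leaks enclosed area slowly (about
$-0.5\%$ per time unit here, a well-known property of immersed-boundary
methods), and that leak sustains a residual drift speed of
$\approx 1.7\cdot10^{-3}$ indefinitely — a run to $t = 12$ (200k steps)
never fell below it, while the radius slowly ratcheted inward past the
physical equilibrium. The packaged threshold is $2\cdot10^{-3}$, just above
the measured floor: it fires at $t \approx 2.9$, where the radii agree with
the area-based prediction to two decimals ($r_{\min} = 0.629$,
$r_{\max} = 0.633$), total area drift is $-1.6\%$, and the converged
pressure jump matches the tension/radius (Young–Laplace) balance to under
$1\%$. The threshold is a plain configuration knob (`tol_speed`).

## What the tests do and do not show

The suite checks, among others: exact spread/interpolate adjointness (the
discrete power identity), Poisson exactness against a dense pseudo-inverse,
translation/rotation equivariance of the elastic forces, the variational
consistency of the stretching force with the discrete energy, zero-force
configurations as exact fixed points, and the full star relaxation with its
area, Laplace-balance and time-step-insensitivity properties. Problem sizes
follow the study conditions ($64\times64$, $N_b \le 160$); the star
equilibrium run and its halved-step twin are the only long computations.

Two qualitative behaviors reported for the filament scenarios are **not**
reproduced by this discretization at the printed parameters, and the
corresponding expectations in the acceptance tests fail by design rather
than being weakened: the filament free end approaches its datum-implied
equilibrium monotonically (no velocity-sign reversal through $t = 4$;
overdamped Stokes elasticity is gradient-flow-like, so monotone approach is
the generic behavior — with the geometrically consistent clamp tangent
$(0,-1)$ a weak reversal does occur), and the passive circle drifts slowly
*downward* (centroid $1.0 \to 0.9857$ by $t = 20$) because the clamp-closure
dipole pushes fluid toward $(+x, -y)$ at the wall, rather than upward. The
narrative source shows large circle deformation within $t = 0.0165$, which
would require effective forces two to three orders of magnitude beyond what
its printed coefficients produce under the dimensionally consistent kernel
scaling; the printed figures and printed parameters appear mutually
inconsistent, and this package follows the parameters.

The synthetic scenarios exercise every code path on the study's own
geometry, but passing them says nothing about, e.g., contact between
structures (not modeled), inertial effects (out of scope), or
non-periodic boundaries (not supported).

## Limitations

* Explicit Euler only; the stable step for stiff tension scales like
  $O(h^2)$, and the package guards rather than adapts.
* Area conservation is approximate; long runs drift at the documented rate,
  and equilibrium detection must sit above the leakage floor.
* Collocated fields: no MAC staggering; incompressibility holds in the
  central-difference sense exactly, but checkerboard pressure modes are
  unobservable and silently projected.
* Fluid-mediated coupling only — structures closer than the kernel width
  interact through smoothed, not resolved, hydrodynamics.
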