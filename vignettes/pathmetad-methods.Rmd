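---
title: "Methods: path collective variables, EDS, and well-tempered metadynamics at desk scale"
author: "pathmetad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: path collective variables, EDS, and well-tempered metadynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmetad)
```

## The problem

Large conformational transitions — a kinase activating, a loop unfolding, a
domain swinging open — are rare events on molecular-dynamics timescales.
`pathmetad` implements a composite enhanced-sampling strategy for such
transitions:

1. **Essential dynamics sampling (EDS)** drags the system from the initial
   to the target state by accepting only moves that reduce the RMSD to the
   target, yielding a rough but connected transition path;
2. **path collective variables** (CVs) `s(R)` and `z(R)` turn that path
   into a one-dimensional progress coordinate plus a distance-from-path
   coordinate;
3. **well-tempered metadynamics (wT-metaD)** biased on `(s, z)` explores
   and flattens the free-energy landscape around — and, crucially, *away
   from* — the input path;
4. the converged bias is inverted into a free-energy surface, a binned
   **minimum free energy path (MFEP)** with per-step barriers is extracted,
   and statistical errors are estimated by constant-final-bias reweighting
   with **block averaging**.

Everything runs at desk scale on toy two-state bead chains and analytic
landscapes with known answers, so every stage is testable without external
data or a cluster.

## Path collective variables

A reference path is an ordered set of `N` frames $X_j$ over a selection of
atoms (typically C$\alpha$). For an instantaneous configuration $X$ with
fitted per-atom mean-squared displacements
$d_j^2 = \lVert X - X_j \rVert^2 / M$ (optimal Kabsch alignment per frame,
$M$ atoms),

$$
s(X) = \frac{\sum_{j=1}^{N} j\, e^{-\lambda d_j^2}}
            {\sum_{j=1}^{N} e^{-\lambda d_j^2}},
\qquad
z(X) = -\frac{1}{\lambda}\,\ln \sum_{j=1}^{N} e^{-\lambda d_j^2},
\qquad
\hat s = \frac{s - 1}{N - 1} \in [0, 1].
$$

Both sums are evaluated with a log-sum-exp shift, so extreme $\lambda d^2$
values cannot overflow. The smoothing parameter is tied to the path spacing
by $\lambda = 2.3 / \overline{d^2_{\mathrm{consec}}}$; for the canonical
$\sim$0.5 Å C$\alpha$ spacing this gives $\lambda \approx 9.2$ Å$^{-2}$,
matching the values reported for kinase activation paths built at
0.44–0.60 Å spacing.

Two conventions deserve emphasis because the literature is not uniform:

* **MSD is per-atom averaged** (Å$^2$), not summed over atoms, so that
  $\lambda$ carries units of Å$^{-2}$ and is independent of the selection
  size. Users comparing against engines that sum over atoms must rescale
  $\lambda$ by $M$.
* **Alignment is per frame**: each $d_j^2$ gets its own optimal
  superposition, which is costlier than a single global fit but makes both
  CVs exactly invariant under rigid-body motion of $X$. At the Kabsch
  optimum the rotation and centroid terms of the gradient vanish, so the
  analytic CV gradients used for biasing reduce to
  $\partial d_j^2 / \partial X = (2/M)(X_c - X_{j,c} R_j)$ in the simulation
  frame — this identity is verified against finite differences in the test
  suite.

Any affine rescaling of the raw $s$ axis is absorbed by the $\hat s$
normalisation, so MFEP results do not depend on the (unobservable) overall
prefactor convention of the progress variable.

### Building the path

`select_frames()` walks the source trajectory greedily: the first frame is
kept, and each later frame is kept when its fitted RMSD from the last kept
frame first enters the spacing band (default 0.44–0.60 Å). Topological
consecutiveness — each kept frame strictly closer to the target than every
frame kept before it — is enforced during the scan, and the path always
terminates at the trajectory frame closest to the target. Because a
discrete trajectory can leave an awkward terminal stretch, frames closer
than the lower band edge to the terminal frame are never kept, and a tail
re-spacing step inserts or drops at most a few frames so the final interval
also lies in the band; a genuine gap (no frame within the band anywhere)
is a hard error that reports the offending indices. `validate_path()`
re-checks both properties and lists violations.

## Essential dynamics sampling

The propagator is Langevin (BAOAB splitting) over a user-supplied force
provider. After each trial step:

* if the fitted RMSD to the target decreased, the step is **accepted**
  unchanged;
* otherwise the displacement component inside the retained
  principal-component subspace is **radially corrected** toward the target
  so the subspace distance does not exceed its previous value, motion in
  the orthogonal complement is kept, and the outward radial component of
  the velocity is removed. If the orthogonal-complement motion alone would
  still increase the RMSD (possible with a truncated subspace), the
  coordinates are held and only the corrected velocities survive, so the
  RMSD trace is monotonically non-increasing by construction.

Several EDS flavours exist and published descriptions rarely state the
exact projection rule; the radial-correction rule here is one consistent
reading that satisfies the observable contract (monotone RMSD decay toward
the target). Likewise "coordinates and velocities were projected" admits
more than one velocity treatment; removing the outward radial component is
the choice that neither injects energy nor kills transverse exploration.

The essential subspace comes from `covariance_modes()`: frames are
least-squares fitted to their running mean (two fit/mean passes), the
$3M \times 3M$ population covariance is diagonalised, eigenvalues are
returned in descending order, and eigenvector signs follow a deterministic
convention (first component of magnitude above $10^{-8}$ positive) so runs
are reproducible across platforms. GROMOS conformational clustering
(`cluster_gromos()`, neighbour counting at a 0.15 nm cutoff with iterative
centroid removal) identifies which trajectory stretch to analyse.

### Propagator defaults

The default EDS parameters (`step_size = 0.004` ps, `friction = 20`
ps$^{-1}$, `mass = 12` amu, 300 K) put the toy dynamics in the overdamped
regime. This matters: the double-basin potential pulls the system back
toward the initial state with a drift velocity proportional to
$F/(m\gamma)$, while the accept/correct ratchet advances by thermal
fluctuation. High friction suppresses the backward drift relative to the
thermal step so the ratchet makes steady progress; with weakly damped
settings the same system needs an order of magnitude more steps. On the
packaged 30-bead fixture at 5 Å initial C$\alpha$ RMSD, EDS reaches below
0.1 Å within $10^4$ steps.

## Well-tempered metadynamics

Gaussians of initial height $w_0$ are deposited every `stride` steps at
the current $(s, z)$, with the well-tempered damping

$$
w = w_0\, e^{-V(s,z)/k_B \Delta T}, \qquad \Delta T = (\gamma - 1)\,T,
$$

where $V$ is the already-deposited Gaussian bias (the static wall does not
temper the heights — it is a restraint, not part of the adaptive bias). A
one-sided harmonic wall $\tfrac12 k_w (z - z_{\max})^2$ confines $z$ from
above; there is no lower wall and no wall on $s$. Defaults follow the
kinase-scale protocol: $w_0 = 0.5$ kJ/mol, stride 500, $\gamma = 30$,
widths $\sigma_s = 2.0$ (raw frame-index units) and $\sigma_z = 0.005$
Å$^2$, $z_{\max} = 3$ Å$^2$, $k_w = 10^4$ kJ mol$^{-1}$ Å$^{-4}$. The
"restraining force of $10^4$" is read as a harmonic force constant on
$(z - z_{\max})$ with $z$ in Å$^2$.

$\sigma_s$ is interpreted in raw frame-index units, not in $\hat s$: a
width of 2.0 on a [0, 1] axis would blanket the entire landscape, whereas
two frames out of $\sim$100 matches the resolved multi-basin profiles the
protocol is known to produce. Widths in $\hat s$ can still be emulated by
rescaling, since the engine treats the numbers opaquely.

Hills are evaluated by direct summation (no grid caching; desk-scale hill
counts make this exact approach affordable) with a cutoff at
$e^{-34} \approx 2\times10^{-15}$, i.e. below double-precision resolution,
so the summed bias agrees with the naive formula to $10^{-12}$ relative.

Two system kinds plug into `run_wt_metad()`: analytic CV-space potentials
(the particle's coordinates are the CVs) and toy molecular systems driven
through the path-CV chain rule
$F_{\mathrm{atoms}} = -\partial V/\partial s\,\nabla_X s
- \partial V/\partial z\,\nabla_X z$. A fixed seed makes the CV log and
hill list bit-identical across runs.

## Free-energy surface, MFEP, and errors

At convergence the well-tempered bias is a scaled mirror of the free
energy, so `fes_from_bias()` evaluates
$F = -\frac{\gamma}{\gamma-1} V_{\mathrm{bias}}$ on a grid (hills only —
the wall is a restraint and is excluded), converts to kcal/mol and shifts
the global minimum to zero.

`extract_mfep()` divides $\hat s \in [0,1]$ into 25 bins of equal width
and takes, within each bin, the grid node of lowest free energy over $z$
(and over the within-bin $\hat s$ nodes). An empty bin is a hard error
asking for a finer grid — silent interpolation could fabricate a barrier.
The profile is referenced to its first local minimum, i.e. the
starting-basin bin, so profiles start near zero like published activation
profiles. `profile_barriers()` locates interior maxima of the 25-point
profile; each ascending segment contributes a step with
`barrier = max - preceding min` and `delta_F = following min - preceding
min`, and the rate-determining step is the largest barrier.

### Reweighting and block averaging

`reweight_series()` assumes the bias was constant in time at its final
value and assigns $w_i \propto e^{+V_{\mathrm{final}}(s_i, z_i)/k_B T}$
(max-shifted before exponentiation, normalised to one). The final bias
here includes the wall, since the wall also deformed the sampled
distribution and is exactly constant in time.

`block_error_scan()` discretises the samples into 25 $\hat s$ bins and,
for each block size $B$ from 10 to 500 in steps of 10, computes the
weighted bin population per contiguous block; the free-energy error per
bin is $k_B T$ times the relative standard error of the block populations,
and the mean over occupied bins is reported. Unoccupied bins are excluded
rather than counted as zero — averaging in structural zeros would
understate the error. The error of a *probability* is propagated into the
free energy as $k_B T\,\sigma_p/p$ (the first-order expansion of
$-k_B T \ln p$); the underlying weighted block standard error is exposed
separately as `block_stderr()`, whose plateau on AR(1) series with known
autocorrelation time reproduces the analytic standard error of the mean
$\sigma\sqrt{(1+\rho)/((1-\rho)n)}$ within 20%.

## The synthetic fixtures and what they do (and do not) show

`make_two_state_system()` builds two conformations of a C$\alpha$ bead
chain — an ideal helix and a smoothly deformed copy at a requested fitted
RMSD (default 5 Å, emulating the several-Å separation between inactive and
active kinase states) — and a double-basin potential: the exponential mix
$V = -\beta^{*-1}\ln(e^{-\beta^* V_A} + e^{-\beta^* V_B})$ of anisotropic
harmonic wells, soft along the inter-state displacement and stiff
(default 5 kJ mol$^{-1}$ Å$^{-2}$ per atom) transverse to it. The
anisotropy mimics a folded protein, which fluctuates far less off its
transition pathway than along it; it also keeps the thermal
distance-from-path scale ($z \sim 3 k_B T / k_{\mathrm{stiff}} \approx
1.5$ Å$^2$) inside the wall at $z_{\max} = 3$ Å$^2$, as in the kinase
protocol. The soft force constant is calibrated by root finding so the
barrier along the inter-state line matches the request (default
5 $k_B T$ — high enough that unbiased crossings are rare on test
timescales, low enough that biased traversal completes in minutes) within
10%; the calibration is recorded in the returned metadata. The mixing
temperature $\beta^*$ is fixed at $1/k_B\,300\,\mathrm{K}$; sharpening it
would narrow the barrier region without changing the calibrated height.

The analytic landscapes carry their own ground truth: the 1D double well
(barrier parameter 12 kJ/mol, tilt 4 kJ/mol) exposes root-polished minima
and barrier top; the curved 2D valley returns its valley curve
$g(\hat s)$ and 1D profile exactly; the designed three-step profile is
built from knots so that the step decomposition is recovered to machine
precision. AR(1) series come with $\tau = -1/\ln\rho$ and the exact
asymptotic standard error.

These fixtures exercise every algorithmic pathway — alignment, selection,
CV evaluation, biasing, inversion, binning, reweighting — under conditions
where the right answer is known. They do **not** emulate rugged all-atom
energy landscapes, solvent friction, or the slow orthogonal degrees of
freedom that make real path-CV studies hard; passing tests certify the
machinery, not the adequacy of any particular CV choice for a real
protein.

## The end-to-end pipeline

`run_activation_pipeline()` chains the whole study design from one
configuration and one seed: fixture → thermal-jitter subspace of the
target state (60 of 90 modes retained, enough to cover all non-rigid
motion of the 30-bead chain) → $10^4$ EDS steps → frame selection at
0.44–0.60 Å (validated for spacing and topology; typically $\sim$125
frames, $\lambda \approx 11$ Å$^{-2}$) → 60 000 wT-metaD steps → FES on a
101 × 61 grid → 25-bin MFEP with step barriers. The desk-scale
metadynamics protocol deviates from the kinase-run defaults in three
places, each a deliberate adaptation to the toy system's statistics:
deposits every 50 steps rather than 500 (the toy diffuses its full $s$
range in minutes, not nanoseconds, and needs bias poured at a matching
rate), $\sigma_z = 0.5$ Å$^2$ rather than 0.005 (the bead chain's thermal
$z$ fluctuations are two orders of magnitude broader than a solvated
kinase's, and hills must be commensurate with the fluctuation they fill),
and moderate friction (10 ps$^{-1}$). With these settings the sampled
$\hat s$ range spans essentially [0, 1], under 1% of samples exceed the
wall, and a repeated run with the same seed is bit-identical. Run lengths
were chosen so the whole chain completes in about a minute on one CPU
while leaving margin across fixture seeds.

## Numerical choices and degenerate inputs

* Kabsch superposition requires at least three non-collinear fit atoms;
  collinearity is detected from the singular values of the centred
  coordinates. The proper-rotation branch (determinant $+1$) is always
  taken.
* Fitted MSDs are computed from the singular values of the 3 × 3
  cross-covariance ($\mathrm{msd} = (|P|^2 + |Q|^2 - 2(\sigma_1 +
  \sigma_2 \pm \sigma_3))/M$), clamped at zero; near-identical
  configurations lose $\sim 10^{-14}$ Å$^2$ to cancellation, so RMSD
  values below $\sim 10^{-6}$ Å are numerically zero.
* Coincident consecutive path frames (zero spacing) are a degenerate-path
  error; `lambda` must be positive.
* Greedy frame-selection ties break toward the first frame entering the
  band.
* Deposits at non-finite CV values and non-finite forces abort with the
  step index rather than propagating NaNs.
* $k_B = 0.0083145$ kJ mol$^{-1}$ K$^{-1}$; coordinates are always Å,
  energies kJ/mol internally with kcal/mol (= kJ/4.184) for reported free
  energies; times ps, masses amu (1 kJ/mol = 100 amu Å$^2$ ps$^{-2}$).

## Known limitations

* The EDS correction rule is one of several consistent readings of the
  published algorithm; others (e.g. full velocity reversal) would satisfy
  the same monotonicity contract but sample differently.
* The MFEP is the per-bin minimum over $z$, not a steepest-descent or
  string-method path; profiles are only as fine as the 25-bin grid.
* Reweighting assumes the final bias was constant throughout — accurate
  late in a well-tempered run, biased early; the block-error scan
  quantifies only statistical, not this systematic, error.
* The hydrogen-bond criterion (0.35 nm, 30°) and Bondi-style radius table
  are fixed conventions; structural observables on real proteins need
  user-supplied element definitions (residue ranges), since none are
  bundled.
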