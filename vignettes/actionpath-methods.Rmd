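---
title: "Minimum-action transition paths on two-well elastic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-action transition paths on two-well elastic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actionpath)
```

## The model

A macromolecule with $N$ coarse-grained sites is described by the position
vector $X \in \mathbb{R}^{3N}$ evolving under overdamped Langevin dynamics
$\gamma \dot X = -\nabla U(X) + B(t)$, with the friction coefficient set to
$\gamma = 1$ by rescaling time. The probability of a path over $[0, F]$ is
$\propto \exp(-\beta S)$ with the Onsager–Machlup action

$$S = \tfrac12 \int_0^F \left( \dot X + \nabla U(X) \right)^2 dt .$$

Given two endpoint conformations $X_A$ and $X_B$, the most probable
(minimum-action) path satisfies the Euler–Lagrange equation
$\ddot X = \nabla\nabla U \,\nabla U$. This package solves that two-point
boundary problem on a deliberately simple energy surface: each endpoint
carries a quadratic well

$$U_A(X) = \tfrac12 (X - X_A)^T H_A (X - X_A),$$

where $H_A$ is the Hessian of an elastic network built on $X_A$ (and likewise
$U_B$, $H_B$ on $X_B$), and the total surface is the lower envelope

$$U = \min(U_A + \Delta E,\; U_B),$$

with $\Delta E$ a free-energy offset between the wells. We write the quadratic
form with the conventional $\tfrac12$ so that $H$ is the true second
derivative of the energy.

Inside one well the Euler–Lagrange equation is linear,
$\ddot X = H_A^2 (X - X_A)$, and the boundary problem $X(0) = X_A$,
$X(t_s) = X_{ts}$ has the closed-form solution

$$X(t) = X_A + f(H_A, t)\, (X_{ts} - X_A), \qquad
  f(x, t) = \frac{\sinh(x t)}{\sinh(x t_s)},$$

applied spectrally. The rigid-body modes of $H$ (eigenvalue 0) propagate as
the limit $f \to t/t_s$: straight-line interpolation of the overall placement.

## Joining the wells: the transition state

The full path runs in well A for $t \in [0, t_A]$ and in well B for
$t \in [t_A, F]$, meeting at the transition state $X_{ts}$ with three
continuity requirements:

* **position** — automatic: both half-paths end at $X_{ts}$;
* **velocity** — the boundary derivative of the sinh propagator gives
  $\dot X = H \coth(H t_s)(X_{ts} - X_{\mathrm{ref}})$, so equality of the
  two one-sided velocities is the linear system
  $(M_A + M_B)\, X_{ts} = M_A X_A + M_B X_B$ with
  $M = H \coth(H t)$, symmetric positive definite (its rigid-mode eigenvalue
  is $1/t > 0$). We solve it by matrix-free conjugate gradients;
* **energy** — $U_A(X_{ts}) + \Delta E = U_B(X_{ts})$, enforced by an outer
  1-D root search on the time split $t_A$ (bisection on
  $[0.02F,\, 0.98F]$, at most 60 iterations).

The solver reports both residuals, the CG iteration count and the outer
trace, so any discrepancy with other implementations of the same model is
visible rather than silent. With identical wells and $\Delta E = 0$ symmetry
forces $t_A = F/2$ and $X_{ts} = (X_A + X_B)/2$; the test suite requires this
to $10^{-10}$.

## Evaluating matrix functions

For systems up to 1000 sites ($3N \le 3000$) the Hessian is diagonalized once,
$H = P D P^T$, and every matrix function is $P f(D) P^T v$. For larger
systems diagonalization is impractical, and $f(H)v$ is evaluated in a Krylov
subspace: an $m$-step Lanczos recursion with full reorthogonalization yields
$H V_m = V_m T_m + \beta_m v_{m+1} e_m^T$ and the approximation
$f(H)v \approx \lVert v\rVert\, V_m f(T_m) e_1$, where the small tridiagonal
$T_m$ is diagonalized directly. The order grows in steps of 10 (up to
$m_{\max} = 100$) until two successive iterates agree to $10^{-8}$; exhaustion
of the Krylov space (Lanczos breakdown) terminates early and is then exact.
Both backends satisfy the same operator contract, and the suite checks they
agree to $10^{-8}$ relative on a 200-atom network.

Numerical safeguards: the sinh ratio is evaluated as
$e^{x(t - t_s)}\operatorname{expm1}(-2xt)/\operatorname{expm1}(-2xt_s)$,
which never overflows and is exact at the $t = 0, t_s$ boundaries;
$x \coth(x t)$ uses a series below $x t < 10^{-6}$. Eigenvalues in
$[-10^{-8}, 0)$ — rounding noise on the rigid kernel — are clamped to zero;
anything more negative aborts, since a reference-state elastic Hessian must
be positive semidefinite.

## The elastic networks

Each well builds its network on its **own** endpoint conformation. Two
geometries are offered:

* **cutoff** — all pairs within $R_c$; defaults 13 Å for one-bead-per-residue
  models and 8 Å for all-atom models, the low-to-middle of the ranges in
  common use (13–15 Å and 7–9 Å);
* **Delaunay** (default) — the edge skeleton of the 3-D Delaunay
  tetrahedralization, parameter-free and robust for dangling or loosely
  connected domains. Degenerate (coplanar) inputs are retried once with a
  $10^{-6}$ Å jitter under a fixed seed. An optional `max_edge` cap exists
  but is off by default to keep the method parameter-free.

The energy is the Tirion form $V = \tfrac{k}{2}\sum (r_{ij} - r^0_{ij})^2$
with one isotropic spring constant per well ($k_1$, $k_2$; defaults
0.1 kcal/mol/Å$^2$). Because every spring is at rest at the reference, the
Hessian there reduces to per-edge rank-1 blocks $k\,\hat u \hat u^T$, stored
sparse. A common alternative calibration is $k = A/\langle B\rangle$ from the
mean crystallographic B-factor, with a warning outside the empirically
expected 0.16 ± 0.09 kcal/mol/Å$^2$; both endpoint $\langle B\rangle$ values
are reported in the run log so the $k_1/k_2$ ratio can be set in a follow-up
run.

As an alternative for proteins, a CA-only Go-like potential preserves local
stereochemistry better over large transitions: harmonic bonds
($K_b = 100\,\varepsilon$/Å$^2$) and angles ($K_a = 20\,\varepsilon$/rad$^2$),
a two-term cosine dihedral ($K_{d1} = \varepsilon$,
$K_{d3} = \varepsilon/2$), and a 12-10 native-contact attraction
$\varepsilon[5(\sigma/r)^{12} - 6(\sigma/r)^{10}]$ over CA pairs within 8 Å
at sequence separation $\ge 4$, with $\varepsilon = 1$ kcal/mol. This is the
classic structure-based parameterization with its customary stiffness ratios;
the published description of the server's Go option names no functional form,
so numeric agreement with it on Go-mode paths is not claimed. Every term is
minimized at the reference, so the Hessian again assembles from rank-1 blocks
$c_q \nabla q\, \nabla q^T$ over the internal coordinates $q$ (curvatures
$2K_b$, $2K_a$, $K_{d1} + 9K_{d3}$, $120\varepsilon/\sigma^2$), and repulsion
between non-native pairs contributes nothing at the reference and is excluded.
The Go Hessian satisfies the same operator contract as the Tirion one and
drives the solver unchanged.

## Matching endpoints with different atom counts

Deposited structure pairs rarely contain identical atom sets. The package
aligns every chain of one endpoint against every chain of the other by global
sequence alignment (match +1, mismatch 0, gap open −10, gap extend −0.5 — a
scoring that strongly prefers the ungapped near-identity alignments this
problem presents), assigns chains one-to-one greedily by descending score
(minimum 10), and keeps aligned residue pairs whose amino acids share a
physico-chemical class — (P,A,G,S,T), (D,N,E,Q), (H,K,R), (F,Y,W),
(V,L,I,C,M) — or whose nucleotides are identical. Atoms with the same name on
both sides of a kept residue pair become the common-atom set. Assignment is
score-driven, never name-driven, so chains that swap identifiers between
depositions still pair correctly. A `bypass` mode pairs atoms by file order
when the inputs are already consistent.

The matched subset of endpoint B is then rigidly superposed onto A by
least squares (SVD with proper-rotation correction) before any path work.
Superposition removes spurious rigid-body motion from the path; this is a
design choice of this implementation — nothing in the model forbids running
on un-superposed frames, but the resulting "transition" would be dominated by
a rigid drift the two wells cannot see.

## Trajectory analytics

Per frame the package reports the two-well energy, RMSD to both endpoints
(without per-frame refitting, which would hide rigid drift; a fitted variant
exists), and the native-contact fractions Q1/Q2: the fraction of the
start (resp. target) network's edges whose frame length is at most
$\lambda\, r^0$, with $\lambda = 1.2$. The contact set and $\lambda$ are
documented knobs — Q is defined only verbally in the literature this model
follows, so absolute Q values are comparable only within one convention.
The discretized Onsager–Machlup action is reported diagnostically
(trapezoidal quadrature, central-difference velocities, gradient from the
active well).

## The synthetic study systems

The generators emulate, at desk scale, the situations the method is built
for, and their defaults are fixed once:

* `make_helix_pair()` — an ideal CA helix hinge-bent by 30° at its midpoint:
  a minimal localized conformational change with shared numbering
  (bypass-compatible).
* `make_dumbbell_pair()` — two rigid 30-residue lobes joined by a 3-residue
  linker, open at 20 Å and closed at 12 Å centre separation, the closed form
  additionally twisted by 50° about the closure axis. Real domain closures
  combine approach with rotation; the rotation is what breaks start-state
  contacts along the path and makes the Q1-vs-Q2 plane informative.
* `make_mutation_pair()` — identical backbones with controlled residue
  substitutions, so the class-matching rule has a closed-form expected
  answer.

What these fixtures do **not** emulate: real side-chain packing, crystal
B-factor structure, heterogeneous spring stiffness, or the
hundreds-of-thousands-of-atoms regime. Passing tests therefore certify the
mathematics (analytic solutions against direct numerical integration of the
boundary problem, Krylov against dense evaluation, continuity contracts,
contact-count combinatorics) and the qualitative physics (asymmetric
$k_1/k_2$ settings bracket the symmetric Q1-vs-Q2 curve and raise the
transition-point energy, as observed for maltodextrin-binding-protein-style
closures), not quantitative agreement with any particular deposited pair.

Problem sizes in the suite were chosen to keep the default run in seconds:
BVP oracles at 5–8 atoms (the finite-difference reference solve with
Richardson extrapolation is the expensive part), backend equivalence at
100–200 atoms, full-pipeline runs at 14–80 residues.

## Parameters at a glance

| parameter | default | units | meaning |
|---|---|---|---|
| `k1`, `k2` | 0.1 | kcal/mol/Å² | Tirion spring constants per well |
| `cutoff` | 13 (CG) / 8 (all-atom) | Å | cutoff-network radius |
| `dE` | 0 | kcal/mol | free-energy offset of well A |
| `total_time` | 1 | — | total path duration F (γ = 1 units) |
| `n_frames` | 50 | — | trajectory frames (endpoints + transition state always included) |
| `q_lambda` | 1.2 | — | contact-present tolerance for Q1/Q2 |
| `go_cutoff` | 8 | Å | Go native-contact cutoff |
| `tol_E` | 1e-4 · max(U_A(X_B), U_B(X_A)) | kcal/mol | energy-continuity tolerance |
| `tol_v` | 1e-4 | relative | velocity-continuity tolerance |
| `m_max` | 100 | — | maximum Lanczos order |

## Known limitations

* The transition state of the min-combined quadratic surface typically has a
  high energy; relaxing the path on a more physical energy is downstream
  work this package does not attempt.
* Exactly two wells; no multi-state surfaces, no stochastic path sampling,
  and the action's probability normalization is never evaluated.
* The Go option covers proteins only; nucleic acids must use the Tirion
  potential.
* Spring constants are isotropic per well; no per-pair or B-factor-refined
  constants.
* Tie-breaking inside the original server's structural aligner cannot be
  reproduced exactly; common-atom counts on deposited pairs may differ by a
  small margin from its output.

## A worked example

```{r example, eval = FALSE}
fx <- make_dumbbell_pair(seed = 1, dir = tempfile())
res <- run_transition_path(map_config(
  fx$A$cif, fx$B$cif, network = "cutoff", n_frames = 41, out_dir = "out"))
res$transition
head(res$stats)
```

The run writes `trajectory.cif` (multi-model mmCIF), `transition_state.cif`,
`frames.tsv`, `match_report.txt` and `run.log` under `out/`.
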