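# actionpath

Non-linear transition paths between two conformations of a macromolecule or
large assembly, generated by **action minimization** on a two-well
coarse-grained energy surface.

Cryo-EM and crystallography increasingly deliver the *endpoints* of functional
motions — open/closed enzymes, ratcheting ribosomes, pH-switched virus
envelopes — but not the transition in between. `actionpath` produces a
physically motivated first guess of that transition for structural biologists
and modellers: a trajectory, a transition-state structure, and per-frame
analytics (energy, RMSD, native-contact fractions Q1/Q2), from nothing more
than two PDB/mmCIF files.

## The model

Under overdamped Langevin dynamics (friction set to 1 by time rescaling), the
most probable path between fixed endpoints minimizes the Onsager–Machlup
action

  S = ½ ∫₀F ( dX/dt + ∇U(X) )² dt,

equivalently solves the Euler–Lagrange equation d²X/dt² = ∇∇U · ∇U. The
energy is the lower envelope of two quadratic wells,

  U = min( U_A + ΔE, U_B ),  U_A(X) = ½ (X − X_A)ᵀ H_A (X − X_A),

where H_A, H_B are elastic-network Hessians built on each endpoint (Tirion
potential V = ½k Σ (r_ij − r⁰_ij)², cutoff- or Delaunay-defined neighbours; or
a CA-only Go-like potential for proteins). Within a well the boundary problem
has the analytic solution X(t) = X_ref + sinh(Ht)/sinh(Ht_s) · (X_ts − X_ref);
the two half-paths are joined at a transition state continuous in position,
velocity (a symmetric-positive-definite linear system solved by matrix-free
conjugate gradients) and energy (1-D root search on the time split). For
large systems all matrix functions are evaluated in a Krylov (Lanczos)
subspace, f(H)v ≈ ‖v‖ V_m f(T_m) e₁, so no diagonalization of the full
Hessian is ever needed.

Endpoints with different atom counts are handled by all-chains-vs-all-chains
global sequence alignment, pairing aligned residues within the same
physico-chemical class — (P,A,G,S,T), (D,N,E,Q), (H,K,R), (F,Y,W),
(V,L,I,C,M) — followed by least-squares superposition of the common atoms.

## Worked example

A two-domain open→closed toy system (63 CA beads, endpoint RMSD 4.68 Å):

```r
library(actionpath)
fx  <- make_dumbbell_pair(seed = 1, dir = tempfile())
res <- run_transition_path(map_config(
  fx$A$cif, fx$B$cif, network = "cutoff", n_frames = 41, out_dir = "out"))
res$transition
#> transition_result: t_A = 0.678594 of F = 1, outer iterations 11
#>   U_A(X_ts)+dE = 94.7503, U_B(X_ts) = 94.7203 kcal/mol
#>   residuals: energy -0.03, velocity 8.96e-13
head(res$stats, 4)
#>   frame  time    energy    rmsd_A   rmsd_B Q1        Q2
#> 1     1 0.000 0.0000000 0.0000000 4.681435  1 0.6622378
#> 2     2 0.025 0.1102509 0.1186978 4.563246  1 0.6643357
#> 3     3 0.050 0.4412246 0.2374063 4.445069  1 0.6657343
#> 4     4 0.075 0.9935861 0.3561364 4.326893  1 0.6664336
```

Reading the numbers: the wells cross at 68% of the total path time after 11
outer iterations; the transition state sits 94.7 kcal/mol above the wells
(min-combined quadratic surfaces give characteristically high barriers — see
the vignette), with energy continuity satisfied to 0.03 kcal/mol and velocity
continuity to ~1e-12. Frame 1 is exactly the start structure (rmsd_A = 0,
Q1 = 1); Q2 grows toward 1 as the target's native contacts form. Five
artifacts are written under `out/`: `trajectory.cif` (one model per frame),
`transition_state.cif`, `frames.tsv`, `match_report.txt`, `run.log`.

A command-line front end with the same options lives at
`inst/cli/actionpath.R`:

```sh
Rscript inst/cli/actionpath.R --start A.cif --end B.cif \
    --network delaunay --k1 0.1 --k2 0.1 --frames 50 --out results/
```

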