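# End-to-end pipeline: read -> filter/coarse-grain -> match -> superpose ->
# build networks -> Hessians -> transition state -> frames -> analytics ->
# artifacts.

#' Configuration for a transition-path run
#'
#' @param start_path,end_path Structure files (PDB or mmCIF) of the two
#'   endpoint conformations.
#' @param cg_mode Coarse graining: `"one_per_residue"` (CA / C3' / C4') or
#'   `"all_atom"`.
#' @param network Network geometry: `"delaunay"` (parameter-free, default) or
#'   `"cutoff"`.
#' @param cutoff Cutoff radius in angstrom; default 13 for one-bead networks,
#'   8 for all-atom.
#' @param potential `"tirion"` (default) or `"go"` (CA-only proteins).
#' @param k1,k2 Tirion spring constants of the start and target wells
#'   (kcal/mol/A^2, default 0.1 each).
#' @param dE Free-energy offset of the start well (kcal/mol, default 0).
#' @param total_time Total path duration F (default 1, dimensionless after
#'   setting the friction coefficient to 1 by time rescaling).
#' @param n_frames Number of trajectory frames (default 50).
#' @param bypass_matching Pair atoms by file order instead of sequence
#'   matching (requires equal atom counts).
#' @param first_model_only Keep only the first model of multi-model inputs.
#' @param backend Matrix-function backend: `"auto"`, `"dense"`, `"krylov"`.
#' @param out_dir Output directory for artifacts.
#' @param max_edge Optional Delaunay edge-length cap in angstrom.
#' @param q_lambda Contact tolerance factor for Q1/Q2 (default 1.2).
#' @param go_cutoff Native-contact cutoff of the Go model (angstrom).
#' @return A `run_config` list.
#' @export
map_config <- function(start_path, end_path,
                       cg_mode = c("one_per_residue", "all_atom"),
                       network = c("delaunay", "cutoff"), cutoff = NULL,
                       potential = c("tirion", "go"), k1 = 0.1, k2 = 0.1,
                       dE = 0, total_time = 1, n_frames = 50,
                       bypass_matching = FALSE, first_model_only = TRUE,
                       backend = "auto", out_dir = ".", max_edge = NULL,
                       q_lambda = 1.2, go_cutoff = 8) {
  cg_mode <- match.arg(cg_mode)
  network <- match.arg(network)
  potential <- match.arg(potential)
  if (k1 <= 0 || k2 <= 0) stop("spring constants k1, k2 must be positive")
  if (total_time <= 0) stop("total_time must be positive")
  if (n_frames < 2) stop("n_frames must be at least 2")
  if (is.null(cutoff))
    cutoff <- if (cg_mode == "one_per_residue") 13 else 8
  structure(list(start_path = start_path, end_path = end_path,
                 cg_mode = cg_mode, network = network, cutoff = cutoff,
                 potential = potential, k1 = k1, k2 = k2, dE = dE,
                 total_time = total_time, n_frames = n_frames,
                 bypass_matching = bypass_matching,
                 first_model_only = first_model_only, backend = backend,
                 out_dir = out_dir, max_edge = max_edge,
                 q_lambda = q_lambda, go_cutoff = go_cutoff),
            class = "run_config")
}

build_well <- function(cfg, xyz, k, atoms_df) {
  if (cfg$potential == "go") {
    s <- new_structure(transform(atoms_df, x = xyz[, 1], y = xyz[, 2],
                                 z = xyz[, 3]))
    top <- build_go_topology(s, contact_cutoff = cfg$go_cutoff)
    H <- go_hessian(top)
    # contacts for Q come from the Go native-contact list
    net <- list(i = top$contacts[, 1], j = top$contacts[, 2], r0 = top$sigma,
                n_edges = nrow(top$contacts))
    list(H = H, net = net, n_edges = nrow(top$contacts), top = top)
  } else {
    net <- if (cfg$network == "delaunay")
      build_delaunay_network(xyz, k = k, max_edge = cfg$max_edge)
    else build_cutoff_network(xyz, cutoff = cfg$cutoff, k = k)
    list(H = assemble_hessian(net), net = net, n_edges = length(net$i))
  }
}

#' Run the full transition-path pipeline
#'
#' Executes every stage of the path generation and writes five artifacts to
#' `config$out_dir`: `trajectory.cif` (multi-model mmCIF), `transition_state.cif`,
#' `frames.tsv` (per-frame analytics), `match_report.txt` and `run.log`.
#'
#' @param config A `run_config` from [map_config()].
#' @return Invisibly, a list with the trajectory, transition result, per-frame
#'   stats, correspondence and artifact paths.
#' @export
run_transition_path <- function(config) {
  cfg <- config
  log <- new_run_log()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  A <- stage("read start structure",
             read_structure(cfg$start_path, cfg$first_model_only))
  B <- stage("read end structure",
             read_structure(cfg$end_path, cfg$first_model_only))
  log_line(log, "read: ", n_atoms(A), " atoms (start), ", n_atoms(B),
           " atoms (end)")
  A <- stage("coarse grain", coarse_grain(A, cfg$cg_mode))
  B <- stage("coarse grain", coarse_grain(B, cfg$cg_mode))
  log_line(log, "coarse-grained (", cfg$cg_mode, "): ", n_atoms(A), " / ",
           n_atoms(B), " atoms")
  log_line(log, "<B> start:  ", fmt_b(mean_bfactor(A)), " A^2")
  log_line(log, "<B> target: ", fmt_b(mean_bfactor(B)), " A^2")

  matching <- NULL
  if (cfg$bypass_matching) {
    corr <- stage("bypass matching", bypass_matching(A, B))
  } else {
    matching <- stage("chain matching", match_chains(A, B))
    corr <- stage("extract common atoms", extract_common_atoms(A, B, matching))
  }
  log_line(log, "n_common: ", corr$n_common)

  XA <- coords(A)[corr$pairs[, "a"], , drop = FALSE]
  XB <- coords(B)[corr$pairs[, "b"], , drop = FALSE]
  fit <- stage("superposition", superpose(XA, XB))
  XB <- sweep(XB %*% t(fit$rotation), 2, fit$translation, "+")
  log_line(log, sprintf("superposition rmsd: %.4f A", fit$rmsd))

  atoms_A <- A$atoms[corr$pairs[, "a"], , drop = FALSE]
  if (cfg$potential == "go" && any(residue_kind(atoms_A$resid) != "protein"))
    stop("stage 'potential': the Go model currently works only for proteins; ",
         "use the Tirion potential for nucleic-acid-containing inputs")
  wellA <- stage("build start network", build_well(cfg, XA, cfg$k1, atoms_A))
  wellB <- stage("build target network", build_well(cfg, XB, cfg$k2, atoms_A))
  log_line(log, "network (", cfg$potential, "/",
           if (cfg$potential == "go") "native contacts" else cfg$network,
           "): ", wellA$n_edges, " / ", wellB$n_edges, " edges")

  vA <- as_vec3(XA); vB <- as_vec3(XB)
  traj <- stage("path solve",
                generate_path(vA, wellA$H, vB, wellB$H,
                              total_time = cfg$total_time, dE = cfg$dE,
                              n_frames = cfg$n_frames, backend = cfg$backend))
  tr <- traj$transition
  log_line(log, sprintf("transition: t_A = %.6g (outer iterations %d, CG iterations %d)",
                        tr$t_A, tr$outer_iterations, tr$cg_iterations))
  log_line(log, sprintf("continuity residuals: energy %.3g, velocity %.3g",
                        tr$energy_gap, tr$velocity_gap))
  log_line(log, sprintf("transition-state energy: U_A+dE = %.6g, U_B = %.6g kcal/mol",
                        tr$U_A, tr$U_B))
  if (!is.null(tr$trace))
    for (q in seq_len(nrow(tr$trace)))
      log_line(log, sprintf("  outer %2d: t_A = %.6g, energy gap = %.4g, cg = %d, vel gap = %.3g",
                            tr$trace$iter[q], tr$trace$t_A[q],
                            tr$trace$energy_gap[q], tr$trace$cg_iterations[q],
                            tr$trace$velocity_gap[q]))

  stats <- stage("analysis",
                 analyze_trajectory(traj, wellA$net, wellB$net,
                                    lambda = cfg$q_lambda))

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  template <- new_structure(atoms_A, source_format = "mmcif")
  paths <- list(
    trajectory = file.path(cfg$out_dir, "trajectory.cif"),
    transition_state = file.path(cfg$out_dir, "transition_state.cif"),
    frames = file.path(cfg$out_dir, "frames.tsv"),
    match_report = file.path(cfg$out_dir, "match_report.txt"),
    log = file.path(cfg$out_dir, "run.log"))
  stage("write artifacts", {
    write_trajectory(traj$frames, template, paths$trajectory)
    ts <- template
    xyz <- as_mat3(tr$X_ts)
    ts$atoms$x <- xyz[, 1]; ts$atoms$y <- xyz[, 2]; ts$atoms$z <- xyz[, 3]
    write_structure(ts, paths$transition_state)
    write_report(stats, paths$frames)
    writeLines(format_match_report(matching, corr, fit), paths$match_report)
    writeLines(log$lines, paths$log)
  })
  invisible(list(trajectory = traj, transition = tr, stats = stats,
                 correspondence = corr, superposition = fit,
                 wells = list(A = wellA, B = wellB), paths = paths,
                 log = log$lines))
}
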