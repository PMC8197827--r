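#' Refinement configuration
#'
#' Controls the restrained steepest-descent minimization and the Langevin
#' sampling stage. Defaults follow the protocol this package implements:
#' 2000 minimization steps, a 2 fs time step, 300 K, harmonic C-alpha
#' restraints of 1000 kJ/(mol nm^2), and frames recorded every 2 ps. The
#' default sampling length of 5000 steps (10 ps, 5 frames) keeps a full
#' decoy-set run at desk scale; set `sample_steps = 50000` for the full
#' 100 ps / 50-frame schedule.
#'
#' @param minimize_steps maximum steepest-descent steps (default 2000).
#' @param initial_step initial trial displacement, Angstrom (default 0.01).
#' @param sample_steps Langevin steps (default 5000).
#' @param dt integration time step, fs (default 2).
#' @param temperature thermostat temperature, K (default 300).
#' @param friction Langevin friction, ps^-1 (default 1).
#' @param frame_interval steps between recorded frames (default 1000,
#'   i.e. 2 ps at dt = 2 fs).
#' @param k_restr positional restraint force constant, kJ/(mol nm^2)
#'   (default 1000; stored internally as kJ/(mol Angstrom^2)).
#' @param k_bond chain-glue bond force constant, kJ/(mol Angstrom^2)
#'   (default 418.4).
#' @param seed integer seed for the thermostat noise.
#' @return an object of class `refine_config`.
#' @export
refine_config <- function(minimize_steps = 2000L, initial_step = 0.01,
                          sample_steps = 5000L, dt = 2.0,
                          temperature = 300.0, friction = 1.0,
                          frame_interval = 1000L, k_restr = 1000.0,
                          k_bond = 418.4, seed = 1L) {
  stopifnot(
    minimize_steps > 0, initial_step > 0, sample_steps > 0, dt > 0,
    temperature >= 0, friction > 0, frame_interval > 0, k_restr >= 0,
    k_bond >= 0
  )
  structure(
    list(
      minimize_steps = as.integer(minimize_steps),
      initial_step = initial_step,
      sample_steps = as.integer(sample_steps), dt = dt,
      temperature = temperature, friction = friction,
      frame_interval = as.integer(frame_interval),
      k_restr = k_restr, k_bond = k_bond, seed = as.integer(seed)
    ),
    class = "refine_config"
  )
}

#' Harmonic positional restraints on C-alpha atoms
#'
#' Builds the restraint specification used during sampling: every C-alpha
#' of both the receptor and the peptide is tethered to a target coordinate
#' (by default its input position) with force constant `k_restr`.
#'
#' @param model a [complex_model()].
#' @param k_restr force constant, kJ/(mol nm^2); converted internally to
#'   kJ/(mol Angstrom^2) (1 kJ/(mol nm^2) = 0.01 kJ/(mol Angstrom^2)).
#' @param target_coords optional matrix of target coordinates for the
#'   restrained atoms (rows aligned with the restrained index set).
#' @return an object of class `restraint_spec`.
#' @export
calpha_restraints <- function(model, k_restr = 1000.0, target_coords = NULL) {
  idx <- which(model$atoms$is_calpha)
  if (is.null(target_coords)) {
    target_coords <- model_coords(model)[idx, , drop = FALSE]
  }
  stopifnot(nrow(target_coords) == length(idx), k_restr >= 0)
  structure(
    list(
      restrained_idx = idx,
      target_coords = target_coords,
      k_restr = k_restr,
      k_internal = k_restr * 0.01
    ),
    class = "restraint_spec"
  )
}

#' Harmonic restraint energy of a configuration
#'
#' `sum over restrained atoms of 0.5 k |x - x0|^2`, in kJ/mol.
#'
#' @param coords n-by-3 coordinate matrix, Angstrom.
#' @param spec a [calpha_restraints()] specification.
#' @return restraint energy, kJ/mol.
#' @export
restraint_energy <- function(coords, spec) {
  d <- coords[spec$restrained_idx, , drop = FALSE] - spec$target_coords
  0.5 * spec$k_internal * sum(d^2)
}

#' Chain-glue topology of a complex model
#'
#' The refinement potential needs a minimal covalent skeleton so chains do
#' not dissolve under thermal noise: harmonic bonds along the backbone
#' (N-CA, CA-C, C-O, CA-CB, and the peptide bond C(i)-N(i+1) within each
#' chain), with any further side-chain atom tied to its nearest atom in
#' the same residue. Bond equilibrium lengths are the input distances.
#' Nonbonded pairs separated by two bonds or fewer are excluded from the
#' potential to avoid clash artifacts between covalently constrained
#' neighbors.
#'
#' @param model a [complex_model()].
#' @return list with `bonds` (m-by-2 atom index matrix), `bond_r0`
#'   (equilibrium lengths, Angstrom) and `exclusions` (p-by-2 matrix of
#'   excluded pairs).
#' @export
build_topology <- function(model) {
  at <- model$atoms
  xyz <- model_coords(model)
  n <- nrow(at)
  keys <- residue_keys(at)
  bonds <- matrix(integer(0), ncol = 2)
  add_bond <- function(i, j) {
    if (length(i) == 1L && length(j) == 1L && !is.na(i) && !is.na(j)) {
      bonds <<- rbind(bonds, c(i, j))
    }
  }
  for (ch in unique(at$chain_id)) {
    rows <- which(at$chain_id == ch)
    res_ids <- unique(keys[rows])
    prev_c <- NA_integer_
    for (rk in res_ids) {
      r <- rows[keys[rows] == rk]
      find <- function(nm) {
        hit <- r[at$name[r] == nm]
        if (length(hit) >= 1L) hit[1L] else NA_integer_
      }
      iN <- find("N"); iCA <- find("CA"); iC <- find("C")
      iO <- find("O"); iCB <- find("CB")
      add_bond(iN, iCA)
      add_bond(iCA, iC)
      add_bond(iC, iO)
      add_bond(iCA, iCB)
      if (!is.na(prev_c)) add_bond(prev_c, iN)
      prev_c <- iC
      bonded <- c(iN, iCA, iC, iO, iCB)
      rest <- setdiff(r, bonded[!is.na(bonded)])
      placed <- bonded[!is.na(bonded)]
      for (i in rest) {
        if (length(placed) == 0L) { placed <- i; next }
        d2 <- colSums((t(xyz[placed, , drop = FALSE]) - xyz[i, ])^2)
        add_bond(placed[which.min(d2)], i)
        placed <- c(placed, i)
      }
    }
  }
  r0 <- sqrt(rowSums((xyz[bonds[, 1L], , drop = FALSE] -
    xyz[bonds[, 2L], , drop = FALSE])^2))
  # exclusions: bond-graph distance <= 2
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1L]; j <- bonds[b, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  excl <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n)) {
    one <- adj[[i]]
    two <- unique(unlist(adj[one]))
    nb <- setdiff(unique(c(one, two)), i)
    nb <- nb[nb > i]
    if (length(nb) > 0L) excl <- rbind(excl, cbind(i, nb))
  }
  list(bonds = bonds, bond_r0 = r0, exclusions = unname(excl))
}

#' Restrained steepest-descent minimization
#'
#' Steepest descent with an adaptive (backtracking) step on the internal
#' refinement potential: all non-excluded nonbonded pairs (Coulomb +
#' Lennard-Jones, intra- and inter-chain), plus the chain-glue bonds of
#' [build_topology()]. C-alpha atoms of both chains are kept exactly at
#' their initial positions (their gradient components are projected out),
#' so the backbone geometry cannot drift during optimization. The energy
#' trace over accepted steps is non-increasing; the run stops after
#' `minimize_steps` accepted steps or when the trial step shrinks below
#' 1e-6 Angstrom.
#'
#' @param model a [complex_model()].
#' @param params a [assign_parameters()] result.
#' @param cfg a [refine_config()].
#' @param energy_cfg an [energy_config()].
#' @param fixed_idx atom indices to keep fixed; defaults to all C-alphas.
#' @param topology optional precomputed [build_topology()] result.
#' @return list with `model` (refined coordinates), `trace` (energies of
#'   accepted steps, kJ/mol), `steps` (accepted step count) and `energy`.
#' @export
minimize_complex <- function(model, params, cfg = refine_config(),
                             energy_cfg = energy_config(),
                             fixed_idx = NULL, topology = NULL) {
  if (is.null(topology)) topology <- build_topology(model)
  if (is.null(fixed_idx)) fixed_idx <- which(model$atoms$is_calpha)
  res <- cpp_minimize(
    model_coords(model), params$charge, params$sigma, params$epsilon,
    topology$bonds, topology$bond_r0, cfg$k_bond, topology$exclusions,
    as.integer(fixed_idx), energy_cfg$cutoff, energy_cfg$dielectric,
    energy_cfg$coulomb_constant, cfg$minimize_steps, cfg$initial_step, 1e-6
  )
  list(
    model = set_model_coords(model, res$coords),
    trace = res$trace, steps = res$steps, energy = res$energy
  )
}

#' Restrained Langevin sampling
#'
#' BAOAB-discretized Langevin dynamics on the internal refinement
#' potential at temperature `cfg$temperature` with friction
#' `cfg$friction`; C-alpha atoms are harmonically restrained (not fixed)
#' per `spec`. Thermal noise comes from a dedicated deterministic stream
#' seeded by `cfg$seed`, so trajectories are exactly reproducible. Frames
#' are recorded every `cfg$frame_interval` steps.
#'
#' @param model a [complex_model()] (ideally pre-minimized; a warning is
#'   emitted when the starting gradient looks unrelaxed).
#' @param params a [assign_parameters()] result.
#' @param spec a [calpha_restraints()] specification; defaults to
#'   restraining the model's C-alphas at their current positions with
#'   `cfg$k_restr`.
#' @param cfg a [refine_config()].
#' @param energy_cfg an [energy_config()].
#' @param topology optional precomputed [build_topology()] result.
#' @param warn_unminimized check the starting configuration (default
#'   `TRUE`).
#' @return an object of class `pepscore_trajectory`: list with `frames`
#'   (list of n-by-3 matrices), `times` (ps), and per-frame `potential`,
#'   `elec`, `vdw`, `restraint` energies (kJ/mol).
#' @export
sample_restrained <- function(model, params, spec = NULL,
                              cfg = refine_config(),
                              energy_cfg = energy_config(),
                              topology = NULL, warn_unminimized = TRUE) {
  if (is.null(topology)) topology <- build_topology(model)
  if (is.null(spec)) spec <- calpha_restraints(model, cfg$k_restr)
  if (warn_unminimized) {
    g <- cpp_potential(
      model_coords(model), params$charge, params$sigma, params$epsilon,
      topology$bonds, topology$bond_r0, cfg$k_bond, topology$exclusions,
      as.integer(spec$restrained_idx), spec$target_coords, spec$k_internal,
      energy_cfg$cutoff, energy_cfg$dielectric, energy_cfg$coulomb_constant,
      TRUE
    )$gradient
    if (max(abs(g)) > 1e3) {
      warning("starting configuration looks unminimized (large forces); consider minimize_complex() first",
        call. = FALSE
      )
    }
  }
  res <- cpp_langevin(
    model_coords(model), params$mass, params$charge, params$sigma,
    params$epsilon, topology$bonds, topology$bond_r0, cfg$k_bond,
    topology$exclusions, as.integer(spec$restrained_idx),
    spec$target_coords, spec$k_internal, energy_cfg$cutoff,
    energy_cfg$dielectric, energy_cfg$coulomb_constant, cfg$dt,
    cfg$temperature, cfg$friction, cfg$sample_steps, cfg$frame_interval,
    as.numeric(cfg$seed)
  )
  structure(res, class = "pepscore_trajectory")
}

#' @export
print.pepscore_trajectory <- function(x, ...) {
  cat(sprintf(
    "pepscore_trajectory: %d frames over %.3g ps\n",
    length(x$frames), if (length(x$times)) max(x$times) else 0
  ))
  invisible(x)
}
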