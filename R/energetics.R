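#' Energy configuration
#'
#' Settings for the nonbonded interaction-energy statistic. The default
#' cutoff of 12 Angstrom (1.2 nm) truncates both the Coulomb and
#' Lennard-Jones sums; pass `cutoff = Inf` to disable truncation. The
#' Coulomb prefactor is the standard electric conversion factor
#' e^2/(4 pi eps0) = 1389.35457644382 kJ mol^-1 Angstrom e^-2 and is not a
#' tunable.
#'
#' @param cutoff pair cutoff distance, Angstrom (default 12).
#' @param dielectric relative permittivity (default 1).
#' @return an object of class `energy_config`.
#' @export
energy_config <- function(cutoff = 12.0, dielectric = 1.0) {
  stopifnot(cutoff > 0, dielectric > 0)
  structure(
    list(
      cutoff = cutoff, dielectric = dielectric,
      coulomb_constant = COULOMB_CONSTANT
    ),
    class = "energy_config"
  )
}

#' Nonbonded energy of one atom pair
#'
#' Coulomb term `k q_i q_j / (eps_r r)` plus 12-6 Lennard-Jones
#' `4 eps_ij ((sigma_ij/r)^12 - (sigma_ij/r)^6)`, both zero beyond the
#' cutoff (plain truncation).
#'
#' @param r interatomic distance, Angstrom (> 0).
#' @param qi,qj partial charges, e.
#' @param sigma_ij combined Lennard-Jones sigma, Angstrom.
#' @param epsilon_ij combined Lennard-Jones epsilon, kJ/mol.
#' @param cfg an [energy_config()].
#' @return list with components `elec`, `vdw`, `total` (kJ/mol).
#' @export
pair_energy <- function(r, qi, qj, sigma_ij, epsilon_ij,
                        cfg = energy_config()) {
  if (r == 0) stop("coincident atoms", call. = FALSE)
  if (r > cfg$cutoff) {
    return(list(elec = 0, vdw = 0, total = 0))
  }
  elec <- cfg$coulomb_constant * qi * qj / (cfg$dielectric * r)
  sr6 <- (sigma_ij / r)^6
  vdw <- 4 * epsilon_ij * (sr6^2 - sr6)
  list(elec = elec, vdw = vdw, total = elec + vdw)
}

#' Receptor-peptide interaction energy of one configuration
#'
#' The scoring statistic: the sum of Coulomb and Lennard-Jones energies
#' over all receptor-peptide atom pairs within the cutoff.
#' Intra-receptor and intra-peptide pairs are excluded by definition;
#' receptor and peptide share no bonds, so every cross pair is a full
#' nonbonded pair (no exclusions, no 1-4 scaling). This is a short-range
#' statistic: no lattice-sum electrostatics are included, so absolute
#' values are not comparable with solvated lattice-sum energies, only the
#' relative ranking is meaningful.
#'
#' @param model a [complex_model()].
#' @param params a [assign_parameters()] result aligned with `model`.
#' @param coords optional n-by-3 coordinate matrix overriding the model's
#'   coordinates (e.g. a trajectory frame).
#' @param cfg an [energy_config()].
#' @return list with components `elec`, `vdw`, `total` (kJ/mol).
#' @export
interaction_energy <- function(model, params, coords = NULL,
                               cfg = energy_config()) {
  if (is.null(coords)) coords <- model_coords(model)
  stopifnot(nrow(coords) == nrow(model$atoms))
  cpp_cross_energy(
    coords, model$receptor_idx, model$peptide_idx,
    params$charge, params$sigma, params$epsilon,
    cfg$cutoff, cfg$dielectric, cfg$coulomb_constant
  )
}

#' Mean interaction energy over a trailing trajectory window
#'
#' Averages per-frame energies over the trailing `ceiling(window_fraction
#' * n)` frames. The default fraction of 0.5 reproduces the
#' last-25-of-50-frames scoring rule (the 50-100 ps half of a 100 ps run
#' recorded every 2 ps).
#'
#' @param energies data frame or list of per-frame energies with components
#'   `elec`, `vdw`, `total`, in frame order.
#' @param window_fraction fraction of trailing frames to average over,
#'   in (0, 1].
#' @param min_frames minimum acceptable number of frames.
#' @return list with components `elec`, `vdw`, `total` (kJ/mol) and
#'   `n_frames` used.
#' @export
window_mean_energy <- function(energies, window_fraction = 0.5,
                               min_frames = 2L) {
  stopifnot(window_fraction > 0, window_fraction <= 1)
  elec <- energies$elec
  vdw <- energies$vdw
  total <- energies$total
  n <- length(total)
  if (n < min_frames) {
    stop(sprintf("insufficient frames: %d < %d", n, min_frames),
      call. = FALSE
    )
  }
  w <- ceiling(window_fraction * n)
  keep <- seq.int(n - w + 1L, n)
  list(
    elec = mean(elec[keep]), vdw = mean(vdw[keep]),
    total = mean(total[keep]), n_frames = w
  )
}
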