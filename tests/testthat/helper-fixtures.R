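# Fixture builders and independent oracles shared across the suite.

# --- PDB text fixtures ------------------------------------------------------

pdb_atom_line <- function(serial, name, res_name, chain, res_seq, x, y, z,
                          alt = " ", insert = " ", element = NULL) {
  if (is.null(element)) element <- substr(name, 1, 1)
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf(
    "ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    serial, nm, alt, res_name, chain, res_seq, insert, x, y, z, 1.0, 0.0,
    element
  )
}

# Two-chain toy: chain A three GLY residues (N, CA, C, O), chain B one ALA.
write_tiny_pdb <- function(path, with_water = FALSE, with_altloc = FALSE) {
  lines <- character(0)
  serial <- 0L
  for (res in 1:3) {
    for (nm in c("N", "CA", "C", "O")) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(
        serial, nm, "GLY", "A", res,
        res * 3.8, 0, c(N = -1.2, CA = 0, C = 1.2, O = 1.8)[[nm]]
      ))
    }
  }
  lines <- c(lines, "TER")
  for (nm in c("N", "CA", "C", "O", "CB")) {
    serial <- serial + 1L
    lines <- c(lines, pdb_atom_line(
      serial, nm, "ALA", "B", 1,
      5, 5, c(N = -1.2, CA = 0, C = 1.2, O = 1.8, CB = 0.5)[[nm]]
    ))
  }
  if (with_altloc) {
    lines <- c(lines, pdb_atom_line(90L, "CB", "ALA", "B", 1, 9, 9, 9,
      alt = "B"))
  }
  if (with_water) {
    lines <- c(
      lines,
      "HETATM   99  O   HOH A 101      20.000  20.000  20.000  1.00  0.00           O"
    )
  }
  writeLines(c(lines, "END"), path)
  path
}

# --- minimal in-memory models ----------------------------------------------

# A bare two-atom complex (one receptor atom, one peptide atom) at distance r.
two_atom_model <- function(r, name = "CA", res_name = "ALA") {
  at <- data.frame(
    serial = 1:2, name = name, element = "C", res_name = res_name,
    res_seq = 1:2, chain_id = c("A", "B"), insert = "",
    x = c(0, r), y = 0, z = 0,
    is_calpha = name == "CA", stringsAsFactors = FALSE
  )
  complex_model(at, 1L, 2L, check = FALSE)
}

uniform_params <- function(n, charge = 0, sigma = 3, epsilon = 0, mass = 12) {
  list(
    charge = rep(charge, n), sigma = rep(sigma, n),
    epsilon = rep(epsilon, n), mass = rep(mass, n)
  )
}

# Random soup of atoms split into receptor/peptide, for energy oracle checks.
random_config <- function(n_rec, n_pep, box = 15) {
  n <- n_rec + n_pep
  at <- data.frame(
    serial = seq_len(n), name = "CA", element = "C", res_name = "ALA",
    res_seq = seq_len(n),
    chain_id = rep(c("A", "B"), c(n_rec, n_pep)), insert = "",
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    is_calpha = TRUE, stringsAsFactors = FALSE
  )
  list(
    model = complex_model(at, seq_len(n_rec), n_rec + seq_len(n_pep),
      check = FALSE),
    params = list(
      charge = runif(n, -0.5, 0.5), sigma = runif(n, 2.5, 3.8),
      epsilon = runif(n, 0, 1), mass = rep(12, n)
    )
  )
}

# --- independent oracles ----------------------------------------------------

# Brute-force all-pairs receptor-peptide energy in plain R (independent of
# the compiled path).
brute_interaction_energy <- function(model, params, cfg = energy_config()) {
  xyz <- model_coords(model)
  elec <- 0
  vdw <- 0
  for (i in model$receptor_idx) {
    for (j in model$peptide_idx) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r > cfg$cutoff) next
      elec <- elec + cfg$coulomb_constant * params$charge[i] *
        params$charge[j] / (cfg$dielectric * r)
      sij <- (params$sigma[i] + params$sigma[j]) / 2
      eij <- sqrt(params$epsilon[i] * params$epsilon[j])
      sr6 <- (sij / r)^6
      vdw <- vdw + 4 * eij * (sr6^2 - sr6)
    }
  }
  list(elec = elec, vdw = vdw, total = elec + vdw)
}

# Exhaustive k-medoids optimum by enumeration (n <= ~15).
exhaustive_kmedoids_cost <- function(dist, k) {
  combos <- utils::combn(nrow(dist), k)
  min(apply(combos, 2, function(med) {
    sum(apply(dist[, med, drop = FALSE], 1, min))
  }))
}

# Random proper rotation matrix.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2
  ), 3, 3, byrow = TRUE)
}

apply_rigid <- function(xyz, R, t) {
  sweep(xyz %*% t(R), 2, t, `+`)
}

# Apply a rigid transform to a whole complex model.
transform_model <- function(m, R, t) {
  set_model_coords(m, apply_rigid(model_coords(m), R, t))
}

# Small template library JSON for validation tests.
write_mini_library <- function(path, gly_atoms = c("N", "CA", "C", "O"),
                               vdw_types = list(
                                 C = list(sigma = 3.4, epsilon = 0.4, mass = 12),
                                 N = list(sigma = 3.2, epsilon = 0.7, mass = 14),
                                 O = list(sigma = 3.0, epsilon = 0.9, mass = 16)
                               ),
                               extra_residues = list(),
                               duplicate_atom = FALSE) {
  type_of <- function(nm) substr(nm, 1, 1)
  tab <- data.frame(
    name = gly_atoms,
    charge = rep(0, length(gly_atoms)),
    vdw_type = vapply(gly_atoms, type_of, ""),
    stringsAsFactors = FALSE
  )
  if (duplicate_atom) tab <- rbind(tab, tab[2, ])
  residues <- c(list(GLY = tab), extra_residues)
  jsonlite::write_json(
    list(vdw_types = vdw_types, residues = residues),
    path,
    auto_unbox = TRUE, digits = NA
  )
  path
}
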