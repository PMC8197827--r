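#' Decoy-set generation parameters
#'
#' Describes a synthetic decoy ensemble emulating coarse-grained docking
#' output: `n_models` decoys split round-robin over `n_replicas`
#' replicas, ligand-RMSD targets drawn from a (truncated-at-zero) normal
#' mixture, and a planted coarse-grained pseudo-energy whose Spearman
#' correlation with RMSD is controlled by `funnel_rho`. The defaults
#' emulate a 1000-model benchmark set with a unimodal RMSD distribution
#' spanning roughly 2-12 Angstrom and a moderate energy funnel.
#'
#' @param n_models number of decoys (default 1000).
#' @param n_replicas number of replicas (default 10; must divide
#'   `n_models`).
#' @param rmsd_mixture list of `c(weight, mean, sd)` components,
#'   Angstrom; weights must sum to 1.
#' @param funnel_rho target Spearman correlation between planted
#'   cg_energy and RMSD, in `[-1, 1]` (default 0.7).
#' @param clash_min_dist minimum receptor-peptide heavy-atom distance,
#'   Angstrom (default 2.5).
#' @param seed integer master seed.
#' @return an object of class `decoy_spec`.
#' @export
decoy_spec <- function(n_models = 1000L, n_replicas = 10L,
                       rmsd_mixture = list(c(1.0, 6.0, 3.0)),
                       funnel_rho = 0.7, clash_min_dist = 2.5, seed = 1L) {
  w <- vapply(rmsd_mixture, `[`, numeric(1), 1L)
  s <- vapply(rmsd_mixture, `[`, numeric(1), 3L)
  stopifnot(
    abs(sum(w) - 1) < 1e-9, all(s > 0),
    n_models %% n_replicas == 0L,
    funnel_rho >= -1, funnel_rho <= 1, clash_min_dist > 0
  )
  structure(
    list(
      n_models = as.integer(n_models), n_replicas = as.integer(n_replicas),
      rmsd_mixture = rmsd_mixture, funnel_rho = funnel_rho,
      clash_min_dist = clash_min_dist, seed = as.integer(seed)
    ),
    class = "decoy_spec"
  )
}

# Ideal-geometry helix CA position (radius 2.3 A, 100 deg per residue,
# 1.5 A rise), optionally reversed along z.
helix_ca <- function(i, phase = 0, origin = c(0, 0, 0), z_dir = 1) {
  ang <- phase + i * 100 * pi / 180
  origin + c(2.3 * cos(ang), 2.3 * sin(ang), z_dir * i * 1.5)
}

# Backbone heavy atoms around a CA trace: N and C sit on the chords to the
# neighboring CAs (virtual neighbors extend the trace at the termini), O on
# C pointing along `out`, CB on CA pointing along `out`.
trace_to_atoms <- function(ca, out_dir, res_names) {
  n_res <- nrow(ca)
  ext <- rbind(2 * ca[1, ] - ca[2, ], ca, 2 * ca[n_res, ] - ca[n_res - 1, ])
  atoms <- list()
  for (i in seq_len(n_res)) {
    prev <- ext[i, ]
    cur <- ca[i, ]
    nxt <- ext[i + 2L, ]
    o <- out_dir[i, ]
    pos <- list(N = cur + 0.38 * (prev - cur) + 0.25 * o)
    pos$CA <- cur
    pos$C <- cur + 0.40 * (nxt - cur) - 0.25 * o
    pos$O <- pos$C + 1.23 * o
    if (res_names[i] != "GLY") pos$CB <- cur + 1.53 * o / sqrt(sum(o^2)) * 1.0
    atoms[[i]] <- pos
  }
  atoms
}

#' Generate a deterministic toy receptor-peptide complex
#'
#' Builds a self-contained benchmark structure compatible with the
#' bundled toyff library: a two-helix receptor bundle (backbone + CB
#' heavy atoms, ideal helical geometry, with the second helix tilted so
#' the binding groove tapers rather than being translationally uniform)
#' and an extended peptide strand docked in the groove. The peptide is
#' first placed at van der Waals contact with both helices, then its
#' rigid-body pose is optimized in the receptor-peptide interaction
#' energy, so the reference pose is a genuine local optimum of the
#' scoring landscape — the property a docking benchmark's native must
#' have. Sequence draws and coordinate jitter are deterministic per seed:
#' different seeds give different complexes with the same fold
#' architecture.
#'
#' @param seed integer seed.
#' @param receptor_len receptor length in residues (default 40, split
#'   over two helices).
#' @param peptide_len peptide length in residues (default 10).
#' @param clash_min_dist minimum receptor-peptide heavy-atom distance,
#'   Angstrom.
#' @return a [complex_model()] (receptor chain "A", peptide chain "B").
#' @export
make_toy_complex <- function(seed = 1L, receptor_len = 40L,
                             peptide_len = 10L, clash_min_dist = 2.5) {
  stopifnot(receptor_len >= 6, peptide_len >= 3)
  # Neutral residues only: even with screened charges, net-charged side
  # chains in a vacuum-with-dielectric potential would dominate the
  # interface electrostatics and drown the shape signal the benchmark is
  # meant to carry.
  res_pool <- c(
    "ALA", "SER", "VAL", "LEU", "THR", "GLN", "PHE", "GLY", "ASN", "ILE"
  )
  m <- with_seed(sub_seed(seed, "toy_complex"), {
    rec_seq <- sample(res_pool, receptor_len, replace = TRUE)
    pep_seq <- sample(res_pool, peptide_len, replace = TRUE)
    l1 <- ceiling(receptor_len / 2)
    l2 <- receptor_len - l1
    phase <- runif(1, 0, 2 * pi)
    tilt <- 0.18 # groove taper: widens with z, so sliding costs energy
    zmid <- (l1 - 1) * 1.5 / 2
    ca1 <- t(vapply(seq_len(l1) - 1L, helix_ca, numeric(3),
      phase = phase, origin = c(0, 0, 0), z_dir = 1))
    ca2 <- t(vapply(seq_len(l2) - 1L, helix_ca, numeric(3),
      phase = phase + pi / 3,
      origin = c(11, 0, (l1 - 1) * 1.5), z_dir = -1))
    ca2[, 1] <- ca2[, 1] + tilt * (ca2[, 3] - zmid)
    # outward radial directions from each (tilted) helix axis
    out1 <- cbind(ca1[, 1], ca1[, 2], 0)
    out1 <- out1 / sqrt(rowSums(out1^2))
    out2 <- cbind(ca2[, 1] - (11 + tilt * (ca2[, 3] - zmid)), ca2[, 2], 0)
    out2 <- out2 / sqrt(rowSums(out2^2))
    # extended peptide strand along the inter-helix groove
    z0 <- zmid - (peptide_len - 1) * 3.5 / 2
    cap <- cbind(
      5.5 + 0.3 * sin(seq_len(peptide_len)),
      5.5,
      z0 + (seq_len(peptide_len) - 1) * 3.5
    )
    outp <- cbind(0, rep(1, peptide_len), 0) # away from the receptor
    rec_atoms <- c(
      trace_to_atoms(ca1, out1, rec_seq[seq_len(l1)]),
      trace_to_atoms(ca2, out2, rec_seq[l1 + seq_len(l2)])
    )
    pep_atoms <- trace_to_atoms(cap, outp, pep_seq)
    flatten <- function(atoms, seqs, chain) {
      rows <- list()
      for (i in seq_along(atoms)) {
        for (nm in names(atoms[[i]])) {
          p <- atoms[[i]][[nm]]
          rows[[length(rows) + 1L]] <- data.frame(
            name = nm, element = substr(nm, 1, 1), res_name = seqs[i],
            res_seq = i, chain_id = chain, insert = "",
            x = p[1], y = p[2], z = p[3],
            stringsAsFactors = FALSE
          )
        }
      }
      do.call(rbind, rows)
    }
    at <- rbind(
      flatten(rec_atoms, rec_seq, "A"),
      flatten(pep_atoms, pep_seq, "B")
    )
    jit <- matrix(rnorm(nrow(at) * 3, sd = 0.05), ncol = 3)
    at$x <- at$x + jit[, 1]
    at$y <- at$y + jit[, 2]
    at$z <- at$z + jit[, 3]
    at$serial <- seq_len(nrow(at))
    at$is_calpha <- at$name == "CA" & at$res_name %in% STANDARD_RESIDUES
    at <- at[, c(
      "serial", "name", "element", "res_name", "res_seq", "chain_id",
      "insert", "x", "y", "z", "is_calpha"
    )]
    rec_idx <- which(at$chain_id == "A")
    pep_idx <- which(at$chain_id == "B")
    mm <- complex_model(at, rec_idx, pep_idx,
      model_id = sprintf("toy_seed%d", seed))
    # pull the strand to van der Waals contact with each helix
    xyz <- model_coords(mm)
    rec_xyz <- xyz[rec_idx, , drop = FALSE]
    h1 <- at$res_seq[rec_idx] <= l1
    min_to <- function(rx, px) {
      sqrt(max(0, min(outer(rowSums(rx^2), rowSums(px^2), `+`) -
        2 * rx %*% t(px))))
    }
    u1 <- c(5.5, 5.5, 0) / sqrt(2 * 5.5^2)
    u2 <- c(-5.5, 5.5, 0) / sqrt(2 * 5.5^2)
    for (it in seq_len(8L)) {
      px <- xyz[pep_idx, , drop = FALSE]
      d1 <- min_to(rec_xyz[h1, , drop = FALSE], px)
      d2 <- min_to(rec_xyz[!h1, , drop = FALSE], px)
      shift <- (3.5 - d1) * u1 + (3.5 - d2) * u2
      xyz[pep_idx, 1L] <- xyz[pep_idx, 1L] + shift[1L]
      xyz[pep_idx, 2L] <- xyz[pep_idx, 2L] + shift[2L]
      if (max(abs(shift)) < 0.05) break
    }
    set_model_coords(mm, xyz)
  })
  m <- optimize_peptide_pose(m)
  if (min_cross_distance(m) < clash_min_dist) {
    stop("toy complex construction violated the clash distance", call. = FALSE)
  }
  m
}

# Rigid-body (6-dof) refinement of the peptide pose in the receptor-peptide
# interaction energy: deterministic pattern search over axis translations
# and rotations about the peptide centroid with step halving.
optimize_peptide_pose <- function(m, params = NULL, max_iter = 60L) {
  if (is.null(params)) params <- assign_parameters(m)
  xyz <- model_coords(m)
  pep <- m$peptide_idx
  e_of <- function(px) {
    x2 <- xyz
    x2[pep, ] <- px
    interaction_energy(m, params, coords = x2)$total
  }
  cur <- xyz[pep, , drop = FALSE]
  e0 <- e_of(cur)
  step_t <- 0.2
  step_r <- 0.05
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (it in seq_len(max_iter)) {
    improved <- FALSE
    for (d in 1:3) {
      for (s in c(-1, 1)) {
        trial <- cur
        trial[, d] <- trial[, d] + s * step_t
        et <- e_of(trial)
        if (et < e0) {
          cur <- trial
          e0 <- et
          improved <- TRUE
        }
      }
    }
    cc <- colMeans(cur)
    for (ax in axes) {
      for (s in c(-1, 1)) {
        R <- rot_about(ax, s * step_r)
        trial <- sweep(sweep(cur, 2L, cc) %*% t(R), 2L, cc, `+`)
        et <- e_of(trial)
        if (et < e0) {
          cur <- trial
          e0 <- et
          improved <- TRUE
        }
      }
    }
    if (!improved) {
      step_t <- step_t / 2
      step_r <- step_r / 2
      if (step_t < 0.01) break
    }
  }
  xyz[pep, ] <- cur
  set_model_coords(m, xyz)
}

# Minimum receptor-peptide heavy-atom distance, Angstrom.
min_cross_distance <- function(m, pep_xyz = NULL) {
  xyz <- model_coords(m)
  rec <- xyz[m$receptor_idx, , drop = FALSE]
  pep <- if (is.null(pep_xyz)) xyz[m$peptide_idx, , drop = FALSE] else pep_xyz
  cross <- outer(rowSums(rec^2), rowSums(pep^2), `+`) -
    2 * rec %*% t(pep)
  sqrt(max(0, min(cross)))
}

# Random unit vector.
runit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Rotation matrix about unit axis u by angle theta (Rodrigues).
rot_about <- function(u, theta) {
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
    byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Generate a synthetic decoy set around a reference complex
#'
#' Each decoy is the reference with its peptide rigidly perturbed: a
#' random rotation about the peptide C-alpha centroid plus a random-
#' direction translation whose magnitude is chosen so the peptide
#' C-alpha RMSD equals a draw from the configured mixture (rotation and
#' translation contributions add in quadrature about the CA centroid, so
#' the target is hit exactly); poses clashing with the receptor (any
#' heavy-atom pair below `clash_min_dist`) are rejected and resampled.
#' A coarse-grained pseudo-energy is planted through a Gaussian copula on
#' the RMSD ranks and rescaled until the realized Spearman correlation is
#' within 0.1 of `funnel_rho`.
#'
#' @param reference a [complex_model()], e.g. [make_toy_complex()].
#' @param spec a [decoy_spec()].
#' @return an object of class `decoy_set`: list with `reference`,
#'   `models` (list of [complex_model()]), `true_rmsd`, `cg_energy`,
#'   `replica_id`, and a `manifest` data frame.
#' @export
generate_decoys <- function(reference, spec = decoy_spec()) {
  xyz <- model_coords(reference)
  pep_idx <- reference$peptide_idx
  pep_xyz <- xyz[pep_idx, , drop = FALSE]
  pep_ca <- xyz[pep_idx[reference$atoms$is_calpha[pep_idx]], , drop = FALSE]
  centroid <- colMeans(pep_ca)
  ca_centered <- sweep(pep_ca, 2L, centroid)
  rgyr <- sqrt(mean(rowSums(ca_centered^2)))
  w <- vapply(spec$rmsd_mixture, `[`, numeric(1), 1L)

  models <- vector("list", spec$n_models)
  true_rmsd <- numeric(spec$n_models)
  with_seed(sub_seed(spec$seed, "poses"), {
    for (i in seq_len(spec$n_models)) {
      comp <- spec$rmsd_mixture[[sample.int(length(w), 1L, prob = w)]]
      target <- -1
      while (target < 0) target <- rnorm(1, comp[2L], comp[3L])
      ok <- FALSE
      for (try in seq_len(1e4)) {
        theta_max <- min(pi, 1.2 * target / max(rgyr, 1e-6))
        R <- rot_about(runit(), runif(1, 0, theta_max))
        rot_rmsd <- sqrt(mean(rowSums((ca_centered %*% t(R) - ca_centered)^2)))
        if (rot_rmsd > target) next
        t_vec <- runit() * sqrt(target^2 - rot_rmsd^2)
        new_pep <- sweep(
          sweep(pep_xyz, 2L, centroid) %*% t(R), 2L,
          centroid + t_vec, `+`
        )
        if (min_cross_distance(reference, new_pep) < spec$clash_min_dist) next
        ok <- TRUE
        break
      }
      if (!ok) {
        stop(sprintf("infeasible spec: no clash-free pose at RMSD %.2f", target),
          call. = FALSE
        )
      }
      m <- reference
      full <- model_coords(m)
      full[pep_idx, ] <- new_pep
      m <- set_model_coords(m, full)
      m$model_id <- sprintf("m%04d", i)
      m$replica_id <- sprintf("rep%d", ((i - 1L) %% spec$n_replicas) + 1L)
      models[[i]] <- m
      new_ca <- new_pep[reference$atoms$is_calpha[pep_idx], , drop = FALSE]
      true_rmsd[i] <- sqrt(mean(rowSums((new_ca - pep_ca)^2)))
    }
  })

  cg_energy <- with_seed(sub_seed(spec$seed, "cg_energy"), {
    n <- spec$n_models
    z <- stats::qnorm((rank(true_rmsd, ties.method = "first") - 0.5) / n)
    rho_p <- 2 * sin(pi * spec$funnel_rho / 6) # copula Pearson for target Spearman
    noise_scale <- sqrt(max(0, 1 - rho_p^2))
    latent <- NULL
    for (try in seq_len(100)) {
      latent <- rho_p * z + noise_scale * rnorm(n)
      realized <- cor(latent, true_rmsd, method = "spearman")
      if (abs(realized - spec$funnel_rho) <= 0.1) break
      # nudge the noise scale toward the target correlation
      noise_scale <- noise_scale * if (abs(realized) > abs(spec$funnel_rho)) 1.15 else 0.85
    }
    -2000 + 150 * latent
  })

  replica_id <- vapply(models, `[[`, "", "replica_id")
  manifest <- data.frame(
    model_id = vapply(models, `[[`, "", "model_id"),
    replica_id = replica_id,
    cg_energy = cg_energy,
    true_rmsd = true_rmsd,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      reference = reference, models = models, true_rmsd = true_rmsd,
      cg_energy = cg_energy, replica_id = replica_id, manifest = manifest,
      spec = spec
    ),
    class = "decoy_set"
  )
}

#' @export
print.decoy_set <- function(x, ...) {
  cat(sprintf(
    "decoy_set: %d models, %d replicas, RMSD %.2f-%.2f A, Spearman(cg_energy, RMSD) = %.2f\n",
    length(x$models), length(unique(x$replica_id)),
    min(x$true_rmsd), max(x$true_rmsd),
    cor(x$cg_energy, x$true_rmsd, method = "spearman")
  ))
  invisible(x)
}

#' Inject Gaussian noise into receptor side-chain atoms
#'
#' Emulates imperfect all-atom reconstruction of a docking model: every
#' receptor atom outside the backbone set (N, CA, C, O, OXT) receives a
#' zero-mean Gaussian displacement with per-coordinate standard deviation
#' `magnitude`. C-alpha and peptide atoms are untouched.
#'
#' @param model a [complex_model()].
#' @param magnitude per-coordinate displacement sd, Angstrom (>= 0).
#' @param seed integer seed.
#' @return the perturbed [complex_model()].
#' @export
perturb_sidechains <- function(model, magnitude, seed = 1L) {
  stopifnot(magnitude >= 0)
  if (magnitude == 0) {
    return(model)
  }
  idx <- model$receptor_idx[!(model$atoms$name[model$receptor_idx] %in%
    BACKBONE_ATOMS)]
  xyz <- model_coords(model)
  with_seed(sub_seed(seed, "sidechain_noise"), {
    xyz[idx, ] <- xyz[idx, , drop = FALSE] +
      matrix(rnorm(length(idx) * 3, sd = magnitude), ncol = 3)
  })
  set_model_coords(model, xyz)
}
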