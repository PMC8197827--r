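#' Path to the bundled "toyff" residue template library
#'
#' `toyff` is a heavy-atom nonbonded parameter library covering the 20
#' standard amino acids, with AMBER-like Lennard-Jones magnitudes (sigma in
#' Angstrom, epsilon in kJ/mol, masses in amu) and condensed-hydrogen
#' partial charges in elementary charge units: polar-hydrogen charges are
#' folded into their heavy atom, and all charges are pre-scaled by
#' 1/sqrt(eps_eff) with an effective dielectric eps_eff = 4, the standard
#' implicit-screening correction for evaluating Coulomb interactions at a
#' solvated protein interface with a vacuum dielectric. It is a compact
#' stand-in for a full force-field topology, meant for relative ranking of
#' docking decoys, not for reproducing any published force field's
#' absolute energies.
#'
#' @return file path of the bundled JSON library.
#' @export
toyff_path <- function() {
  system.file("extdata", "toyff.json", package = "pepscore", mustWork = TRUE)
}

#' Load a residue template parameter library
#'
#' The library file is JSON with two top-level keys: `vdw_types`, mapping a
#' van der Waals type name to `sigma` (Angstrom), `epsilon` (kJ/mol) and
#' `mass` (amu); and `residues`, mapping a 3-letter residue code to a list
#' of atom records `name`, `charge` (e) and `vdw_type`.
#'
#' @param path JSON library file; defaults to the bundled toyff library.
#' @return an object of class `template_library`.
#' @export
load_templates <- function(path = toyff_path()) {
  if (!file.exists(path) || !any(nzchar(trimws(readLines(path, warn = FALSE))))) {
    stop("empty library", call. = FALSE)
  }
  lib <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    error = function(e) {
      stop(sprintf("invalid library JSON: %s", conditionMessage(e)),
        call. = FALSE
      )
    }
  )
  if (is.null(lib$vdw_types) || length(lib$vdw_types) == 0L ||
    is.null(lib$residues) || length(lib$residues) == 0L) {
    stop("empty library", call. = FALSE)
  }
  for (tn in names(lib$vdw_types)) {
    vt <- lib$vdw_types[[tn]]
    if (!(vt$sigma > 0) || vt$epsilon < 0 || !(vt$mass > 0)) {
      stop(sprintf("invalid vdw type '%s'", tn), call. = FALSE)
    }
  }
  for (res in names(lib$residues)) {
    tab <- lib$residues[[res]]
    if (anyDuplicated(tab$name)) {
      stop(sprintf(
        "duplicate template atom '%s' in residue %s",
        tab$name[duplicated(tab$name)][1L], res
      ), call. = FALSE)
    }
    dangling <- setdiff(tab$vdw_type, names(lib$vdw_types))
    if (length(dangling) > 0L) {
      stop(sprintf("unknown vdw type '%s' in residue %s", dangling[1L], res),
        call. = FALSE
      )
    }
    missing_bb <- setdiff(c("N", "CA", "C", "O"), tab$name)
    if (length(missing_bb) > 0L) {
      stop(sprintf(
        "incomplete residue template %s: missing backbone atom(s) %s",
        res, paste(missing_bb, collapse = ", ")
      ), call. = FALSE)
    }
  }
  structure(lib, class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf(
    "template_library: %d residue templates, %d vdW types\n",
    length(x$residues), length(x$vdw_types)
  ))
  invisible(x)
}

#' Assign per-atom nonbonded parameters to a complex model
#'
#' Atoms are matched by (residue name, atom name); the assignment depends
#' only on those labels, never on coordinates. In strict mode an
#' unparameterized atom is an error; otherwise it receives placeholder
#' parameters (charge 0, epsilon 0, sigma 3.0 Angstrom, mass 12 amu) and a
#' warning is emitted once per run.
#'
#' @param model a [complex_model()].
#' @param lib a [load_templates()] library.
#' @param strict error on unparameterized atoms (default `TRUE`).
#' @return an object of class `param_assignment`: list of aligned numeric
#'   vectors `charge`, `sigma`, `epsilon`, `mass`.
#' @export
assign_parameters <- function(model, lib = load_templates(), strict = TRUE) {
  at <- model$atoms
  n <- nrow(at)
  charge <- numeric(n)
  sigma <- rep(3.0, n)
  epsilon <- numeric(n)
  mass <- rep(12.0, n)
  unmatched <- character(0)
  type_tab <- lib$vdw_types
  for (res in unique(at$res_name)) {
    rows <- which(at$res_name == res)
    tmpl <- lib$residues[[res]]
    if (is.null(tmpl)) {
      unmatched <- c(unmatched, paste(res, at$name[rows]))
      next
    }
    j <- match(at$name[rows], tmpl$name)
    bad <- is.na(j)
    if (any(bad)) {
      unmatched <- c(unmatched, paste(res, at$name[rows][bad]))
    }
    ok <- rows[!bad]
    jok <- j[!bad]
    charge[ok] <- tmpl$charge[jok]
    tn <- tmpl$vdw_type[jok]
    sigma[ok] <- vapply(tn, function(t) type_tab[[t]]$sigma, numeric(1))
    epsilon[ok] <- vapply(tn, function(t) type_tab[[t]]$epsilon, numeric(1))
    mass[ok] <- vapply(tn, function(t) type_tab[[t]]$mass, numeric(1))
  }
  if (length(unmatched) > 0L) {
    if (strict) {
      stop(sprintf(
        "unparameterized atom(s): %s",
        paste(unique(unmatched), collapse = "; ")
      ), call. = FALSE)
    }
    warning(sprintf(
      "%d unparameterized atom(s) given placeholder parameters (charge 0, epsilon 0, sigma 3.0)",
      length(unmatched)
    ), call. = FALSE)
  }
  structure(
    list(charge = charge, sigma = sigma, epsilon = epsilon, mass = mass),
    class = "param_assignment"
  )
}

#' Lorentz-Berthelot combination of two Lennard-Jones types
#'
#' Arithmetic mean of sigmas, geometric mean of epsilons (the AMBER
#' convention).
#'
#' @param a,b vdW types: lists (or named vectors) with elements `sigma`
#'   (Angstrom) and `epsilon` (kJ/mol).
#' @return named numeric vector `c(sigma =, epsilon =)`.
#' @export
combine_lj <- function(a, b) {
  c(
    sigma = (a[["sigma"]] + b[["sigma"]]) / 2,
    epsilon = sqrt(a[["epsilon"]] * b[["epsilon"]])
  )
}
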