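#' Construct a protein-peptide complex model
#'
#' A `complex_model` is an all-atom structure partitioned into a receptor
#' atom group and a peptide atom group. The two groups must be disjoint and
#' together cover every atom. Models read from docking decoy sets carry a
#' `model_id` and, when the decoys come from replica simulations, a
#' `replica_id`.
#'
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `res_name`, `res_seq`, `chain_id`, `insert`, `x`, `y`, `z`,
#'   `is_calpha`.
#' @param receptor_idx integer indices (into `atoms`) of receptor atoms.
#' @param peptide_idx integer indices of peptide atoms.
#' @param model_id character model identifier.
#' @param replica_id character replica label, or `""`.
#' @param check if `TRUE`, validate the partition and coordinate finiteness.
#' @return an object of class `complex_model`.
#' @export
complex_model <- function(atoms, receptor_idx, peptide_idx,
                          model_id = "model", replica_id = "",
                          check = TRUE) {
  m <- structure(
    list(
      model_id = as.character(model_id),
      replica_id = as.character(replica_id),
      atoms = atoms,
      receptor_idx = as.integer(receptor_idx),
      peptide_idx = as.integer(peptide_idx)
    ),
    class = "complex_model"
  )
  if (check) validate_complex_model(m)
  m
}

#' Validate a complex model's partition invariants
#'
#' @param m a `complex_model`.
#' @param require_calpha if `TRUE`, additionally require at least one
#'   peptide C-alpha and three receptor C-alphas (needed for
#'   receptor-based superposition).
#' @return `m`, invisibly; errors describe the violated invariant.
#' @export
validate_complex_model <- function(m, require_calpha = FALSE) {
  n <- nrow(m$atoms)
  if (n == 0L) stop("empty model", call. = FALSE)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  if (length(m$receptor_idx) == 0L || length(m$peptide_idx) == 0L) {
    stop("receptor and peptide groups must be nonempty", call. = FALSE)
  }
  if (length(intersect(m$receptor_idx, m$peptide_idx)) > 0L) {
    stop("receptor and peptide groups overlap", call. = FALSE)
  }
  if (!setequal(c(m$receptor_idx, m$peptide_idx), seq_len(n))) {
    stop("receptor and peptide groups must cover all atoms", call. = FALSE)
  }
  if (require_calpha) {
    if (sum(m$atoms$is_calpha[m$peptide_idx]) < 1L) {
      stop("peptide group has no C-alpha atom", call. = FALSE)
    }
    if (sum(m$atoms$is_calpha[m$receptor_idx]) < 3L) {
      stop("receptor group has fewer than 3 C-alpha atoms", call. = FALSE)
    }
  }
  invisible(m)
}

#' @export
print.complex_model <- function(x, ...) {
  cat(sprintf(
    "complex_model '%s'%s: %d atoms (%d receptor, %d peptide), %d residues\n",
    x$model_id,
    if (nzchar(x$replica_id)) sprintf(" [replica %s]", x$replica_id) else "",
    nrow(x$atoms), length(x$receptor_idx), length(x$peptide_idx),
    nrow(unique(x$atoms[, c("chain_id", "res_seq", "insert")]))
  ))
  invisible(x)
}

#' Extract the coordinate matrix of a complex model
#'
#' @param m a `complex_model`.
#' @return numeric n-by-3 matrix of coordinates in Angstrom.
#' @export
model_coords <- function(m) {
  unname(as.matrix(m$atoms[, c("x", "y", "z")]))
}

#' Replace the coordinates of a complex model
#'
#' @param m a `complex_model`.
#' @param xyz numeric n-by-3 matrix, Angstrom.
#' @return the model with updated coordinates.
#' @export
set_model_coords <- function(m, xyz) {
  stopifnot(is.matrix(xyz), nrow(xyz) == nrow(m$atoms), ncol(xyz) == 3L)
  m$atoms$x <- xyz[, 1L]
  m$atoms$y <- xyz[, 2L]
  m$atoms$z <- xyz[, 3L]
  m
}

# Residue identity keys, in atom order. Insertion codes are part of the key.
residue_keys <- function(atoms) {
  paste(atoms$chain_id, atoms$res_seq, atoms$insert, sep = "|")
}

# Normalize a bio3d atom table into the pepscore atom data frame.
# Keeps protein ATOM records only (waters and heteroatoms excluded),
# altloc "A" or blank only.
normalize_atoms <- function(at) {
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  keep <- at$type == "ATOM" &
    !(at$resid %in% c("HOH", "WAT", "DOD")) &
    at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) {
    return(at)
  }
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  missing_elem <- is.na(elem) | !nzchar(trimws(elem))
  elem[missing_elem] <- substr(gsub("[0-9]", "", at$elety[missing_elem]), 1, 1)
  data.frame(
    serial = as.integer(at$eleno),
    name = at$elety,
    element = trimws(elem),
    res_name = at$resid,
    res_seq = as.integer(at$resno),
    chain_id = ifelse(is.na(at$chain), " ", at$chain),
    insert = at$insert,
    x = at$x, y = at$y, z = at$z,
    is_calpha = at$elety == "CA" & at$resid %in% STANDARD_RESIDUES,
    stringsAsFactors = FALSE
  )
}

# Partition a normalized atom table into a complex_model by peptide chain.
partition_atoms <- function(atoms, peptide_chain, model_id, replica_id = "") {
  chains <- unique(atoms$chain_id)
  if (is.null(peptide_chain)) peptide_chain <- chains[length(chains)]
  if (!peptide_chain %in% chains) {
    stop(sprintf("unknown peptide chain '%s'", peptide_chain), call. = FALSE)
  }
  for (ch in chains) {
    sel <- atoms$chain_id == ch
    if (!any(atoms$is_calpha[sel])) {
      stop(sprintf("degenerate chain '%s': no C-alpha atoms", ch),
        call. = FALSE
      )
    }
  }
  pep <- which(atoms$chain_id == peptide_chain)
  rec <- which(atoms$chain_id != peptide_chain)
  complex_model(atoms, rec, pep, model_id = model_id, replica_id = replica_id)
}

#' Read a protein-peptide complex from a PDB file
#'
#' Parses ATOM records (waters, heteroatoms and non-"A" alternate locations
#' are dropped), partitions atoms into receptor and peptide by chain label,
#' and preserves the file's residue numbering and insertion codes. For a
#' multi-model PDB, `model` selects which MODEL block to return; use
#' [read_complex_set()] to load all of them.
#'
#' @param path PDB file path.
#' @param peptide_chain single-character chain label of the peptide; by
#'   default the last chain in the file.
#' @param model MODEL block to read (1-based; ignored for single-model
#'   files).
#' @param model_id identifier for the returned model; defaults to the file
#'   stem (or the MODEL serial for multi-model files).
#' @return a [complex_model()].
#' @export
read_complex <- function(path, peptide_chain = NULL, model = 1L,
                         model_id = NULL) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) {
      stop(sprintf("format error reading '%s': %s", path, conditionMessage(e)),
        call. = FALSE
      )
    }
  )
  atoms <- normalize_atoms(pdb$atom)
  if (nrow(atoms) == 0L) stop("empty model", call. = FALSE)
  n_models <- nrow(pdb$xyz)
  if (n_models > 1L) {
    if (model < 1L || model > n_models) {
      stop(sprintf("model %d not in file (%d models)", model, n_models),
        call. = FALSE
      )
    }
    keep <- which(pdb$atom$type == "ATOM" &
      !(pdb$atom$resid %in% c("HOH", "WAT", "DOD")) &
      (is.na(pdb$atom$alt) | pdb$atom$alt %in% c("", "A")))
    xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)[keep, , drop = FALSE]
    atoms$x <- xyz[, 1L]
    atoms$y <- xyz[, 2L]
    atoms$z <- xyz[, 3L]
    if (is.null(model_id)) model_id <- as.character(model)
  }
  if (is.null(model_id)) {
    model_id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  }
  partition_atoms(atoms, peptide_chain, model_id = model_id)
}

#' Read a decoy set from a directory or a multi-model PDB
#'
#' Directory input yields one model per `*.pdb` file with `model_id` equal
#' to the file stem; a replica label is parsed from a `repN` filename token
#' when present, else taken from the manifest. Multi-model PDB input yields
#' one model per MODEL block with `model_id` equal to the block serial.
#'
#' @param path directory of PDB files, or one multi-model PDB file.
#' @param peptide_chain peptide chain label (see [read_complex()]).
#' @param manifest optional manifest data frame (see [read_manifest()])
#'   supplying `replica_id` per `model_id`.
#' @return a list of [complex_model()] objects.
#' @export
read_complex_set <- function(path, peptide_chain = NULL, manifest = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(pdb|ent)$", full.names = TRUE))
    if (length(files) == 0L) stop("no PDB files in directory", call. = FALSE)
    models <- lapply(files, read_complex, peptide_chain = peptide_chain)
  } else {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
    n_models <- max(1L, nrow(pdb$xyz))
    models <- lapply(seq_len(n_models), function(i) {
      read_complex(path, peptide_chain = peptide_chain, model = i,
        model_id = as.character(i))
    })
  }
  for (i in seq_along(models)) {
    id <- models[[i]]$model_id
    tok <- regmatches(id, regexpr("rep[0-9]+", id))
    if (length(tok) == 1L && nzchar(tok)) {
      models[[i]]$replica_id <- tok
    } else if (!is.null(manifest)) {
      j <- match(id, manifest$model_id)
      if (!is.na(j)) models[[i]]$replica_id <- as.character(manifest$replica_id[j])
    }
  }
  models
}

#' Read a decoy manifest TSV
#'
#' The manifest associates each decoy with its replica and coarse-grained
#' docking energy: tab-separated columns `model_id`, `replica_id`,
#' `cg_energy` (additional columns are preserved).
#'
#' @param path TSV file path.
#' @return a data frame.
#' @export
read_manifest <- function(path) {
  mf <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    colClasses = NA)
  need <- c("model_id", "replica_id", "cg_energy")
  missing <- setdiff(need, names(mf))
  if (length(missing) > 0L) {
    stop(sprintf("manifest lacks column(s): %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  mf$model_id <- as.character(mf$model_id)
  mf$replica_id <- as.character(mf$replica_id)
  mf
}

#' Write a complex model as a PDB file
#'
#' Atom names, chain labels, residue numbers and coordinates round-trip
#' through [read_complex()] to the 3-decimal precision of the fixed-width
#' PDB convention.
#'
#' @param model a [complex_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_complex <- function(model, path) {
  if (is.null(model$atoms) || nrow(model$atoms) == 0L) {
    stop("empty model", call. = FALSE)
  }
  xyz <- model_coords(model)
  if (any(abs(xyz) >= 10000)) {
    stop("coordinate overflow: |coordinate| >= 10000 Angstrom does not fit the PDB field width",
      call. = FALSE
    )
  }
  at <- model$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(xyz)),
    type = rep("ATOM", nrow(at)),
    eleno = at$serial,
    elety = at$name,
    resid = at$res_name,
    chain = at$chain_id,
    resno = at$res_seq,
    insert = ifelse(nzchar(at$insert), at$insert, ""),
    elesy = at$element
  )
  invisible(path)
}

#' Write a trajectory as a multi-model PDB
#'
#' Each frame becomes one MODEL block with the parent model's atom table.
#'
#' @param model the parent [complex_model()].
#' @param trajectory a trajectory as returned by [sample_restrained()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(model, trajectory, path) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (i in seq_along(trajectory$frames)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    write_complex(set_model_coords(model, trajectory$frames[[i]]), tmp)
    lines <- readLines(tmp)
    writeLines(grep("^(ATOM|TER)", lines, value = TRUE), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Replace a decoy's receptor with the reference (crystal) receptor
#'
#' Receptor reconstruction noise in docking decoys perturbs the computed
#' interaction energy; substituting the crystallographic receptor isolates
#' that effect. The returned model's receptor atoms (names and coordinates)
#' are exactly the reference's; the peptide atoms are carried over from the
#' input model unchanged.
#'
#' @param model a decoy [complex_model()].
#' @param reference the reference complex whose receptor is to be used;
#'   its receptor residue sequence must match the model's.
#' @return a [complex_model()] with the substituted receptor.
#' @export
substitute_receptor <- function(model, reference) {
  seq_of <- function(m) {
    at <- m$atoms[m$receptor_idx, , drop = FALSE]
    res <- !duplicated(residue_keys(at))
    at$res_name[res]
  }
  s_model <- seq_of(model)
  s_ref <- seq_of(reference)
  if (length(s_model) != length(s_ref) || any(s_model != s_ref)) {
    first <- if (length(s_model) != length(s_ref)) {
      min(length(s_model), length(s_ref)) + 1L
    } else {
      which(s_model != s_ref)[1L]
    }
    stop(sprintf(
      "receptor mismatch: first differing residue at position %d (%s vs %s)",
      first,
      if (first <= length(s_model)) s_model[first] else "-",
      if (first <= length(s_ref)) s_ref[first] else "-"
    ), call. = FALSE)
  }
  rec <- reference$atoms[reference$receptor_idx, , drop = FALSE]
  pep <- model$atoms[model$peptide_idx, , drop = FALSE]
  atoms <- rbind(rec, pep)
  rownames(atoms) <- NULL
  complex_model(
    atoms,
    receptor_idx = seq_len(nrow(rec)),
    peptide_idx = nrow(rec) + seq_len(nrow(pep)),
    model_id = model$model_id,
    replica_id = model$replica_id
  )
}
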