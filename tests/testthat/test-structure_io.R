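test_that("read_complex partitions atoms by peptide chain and filters waters", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(path, with_water = TRUE, with_altloc = TRUE)
  m <- read_complex(path, peptide_chain = "B")
  expect_s3_class(m, "complex_model")
  expect_equal(nrow(m$atoms), 17L) # water and non-"A" altloc dropped
  expect_setequal(m$atoms$chain_id[m$peptide_idx], "B")
  expect_setequal(m$atoms$chain_id[m$receptor_idx], "A")
  expect_equal(length(m$peptide_idx), 5L)
  expect_false(any(m$atoms$res_name == "HOH"))
  # peptide defaults to the last chain in the file
  m2 <- read_complex(path)
  expect_equal(m2$peptide_idx, m$peptide_idx)
})

test_that("read_complex rejects missing peptide chains and degenerate chains", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(path)
  expect_error(read_complex(path, peptide_chain = "C"), "unknown peptide chain")
  # chain with no C-alpha at all
  lines <- readLines(path)
  lines <- lines[!grepl("^ATOM.* CA  ALA B", lines)]
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path2)
  expect_error(read_complex(path2, peptide_chain = "B"), "degenerate chain")
})

test_that("write_complex/read_complex round-trips the atom table to 3 decimals", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(path)
  m <- read_complex(path, peptide_chain = "B")
  out <- withr::local_tempfile(fileext = ".pdb")
  write_complex(m, out)
  m2 <- read_complex(out, peptide_chain = "B")
  for (col in c("name", "res_name", "res_seq", "chain_id")) {
    expect_equal(m2$atoms[[col]], m$atoms[[col]])
  }
  expect_equal(model_coords(m2), model_coords(m), tolerance = 1e-8)
  # and again: read-write-read is the identity
  out2 <- withr::local_tempfile(fileext = ".pdb")
  write_complex(m2, out2)
  expect_equal(read_complex(out2, "B")$atoms, m2$atoms)
})

test_that("write_complex rejects overflow coordinates and empty models", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(path)
  m <- read_complex(path, peptide_chain = "B")
  big <- set_model_coords(m, model_coords(m) + 10000)
  expect_error(write_complex(big, withr::local_tempfile()), "coordinate overflow")
  m$atoms <- m$atoms[0, ]
  expect_error(write_complex(m, withr::local_tempfile()), "empty model")
})

test_that("substitute_receptor grafts the reference receptor exactly", {
  ref <- make_toy_complex(seed = 1)
  noisy <- perturb_sidechains(ref, 0.4, seed = 9)
  out <- substitute_receptor(noisy, ref)
  expect_equal(
    model_coords(out)[out$receptor_idx, ],
    model_coords(ref)[ref$receptor_idx, ]
  )
  expect_equal(
    model_coords(out)[out$peptide_idx, ],
    model_coords(noisy)[noisy$peptide_idx, ]
  )
  # idempotent, and the identity on an already-clean model
  twice <- substitute_receptor(out, ref)
  expect_equal(twice$atoms, out$atoms)
  same <- substitute_receptor(ref, ref)
  expect_equal(model_coords(same)[same$receptor_idx, ],
    model_coords(ref)[ref$receptor_idx, ])
})

test_that("substitute_receptor rejects mismatched receptor sequences", {
  ref <- make_toy_complex(seed = 1)
  mut <- ref
  first_rec_res <- ref$atoms$res_seq[ref$receptor_idx[1]]
  sel <- mut$atoms$res_seq == first_rec_res & mut$atoms$chain_id == "A"
  mut$atoms$res_name[sel] <- "TRP"
  expect_error(substitute_receptor(mut, ref), "receptor mismatch")
})

test_that("multi-model PDB files and manifests load as decoy sets", {
  toy <- make_toy_complex(seed = 4, receptor_len = 12, peptide_len = 4)
  ds <- generate_decoys(toy, decoy_spec(n_models = 3, n_replicas = 3, seed = 1))
  traj_dir <- withr::local_tempdir()
  traj <- list(frames = lapply(ds$models, model_coords))
  write_trajectory(toy, traj, file.path(traj_dir, "models.pdb"))
  set <- read_complex_set(file.path(traj_dir, "models.pdb"), peptide_chain = "B")
  expect_length(set, 3L)
  expect_equal(
    model_coords(set[[2]]), model_coords(ds$models[[2]]),
    tolerance = 1e-3
  )
  # directory input with manifest-supplied replica labels
  dir <- withr::local_tempdir()
  for (i in seq_along(ds$models)) {
    write_complex(ds$models[[i]], file.path(dir, paste0(ds$models[[i]]$model_id, ".pdb")))
  }
  mpath <- file.path(dir, "manifest.tsv")
  write.table(ds$manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  mf <- read_manifest(mpath)
  set2 <- read_complex_set(dir, peptide_chain = "B", manifest = mf)
  expect_equal(
    vapply(set2, `[[`, "", "replica_id"),
    mf$replica_id[match(vapply(set2, `[[`, "", "model_id"), mf$model_id)]
  )
  expect_error(read_manifest(withr::local_tempfile(lines = "a\tb\n1\t2")),
    "manifest lacks")
})
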