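test_that("rank_by_energy sorts ascending with lexicographic tie-breaks", {
  rec <- data.frame(
    model_id = c("m1", "m2", "m3"),
    mean_energy = c(-5, -10, 0),
    stringsAsFactors = FALSE
  )
  r <- rank_by_energy(rec)
  expect_equal(r$model_id, c("m2", "m1", "m3"))
  expect_equal(r$rank, 1:3)
  # ties broken by model_id
  tie <- data.frame(
    model_id = c("b", "a", "c"), mean_energy = c(1, 1, 1),
    stringsAsFactors = FALSE
  )
  expect_equal(rank_by_energy(tie)$model_id, c("a", "b", "c"))
  # permutation property: every input appears exactly once
  withr::local_seed(1)
  big <- data.frame(
    model_id = sprintf("m%03d", sample(500)),
    mean_energy = rnorm(500), stringsAsFactors = FALSE
  )
  expect_setequal(rank_by_energy(big)$model_id, big$model_id)
  # singletons and NaN handling
  expect_equal(rank_by_energy(rec[1, ])$rank, 1L)
  rec$mean_energy[2] <- NaN
  expect_error(rank_by_energy(rec), "unscored model")
})

test_that("top_n preserves order and saturates", {
  rec <- rank_by_energy(data.frame(
    model_id = sprintf("m%02d", 1:30), mean_energy = rnorm(30),
    stringsAsFactors = FALSE
  ))
  expect_equal(top_n(rec, 10)$model_id, rec$model_id[1:10])
  expect_equal(nrow(top_n(rec, 100)), 30L)
  expect_equal(top_n(rec, 1)$mean_energy, min(rec$mean_energy))
})

test_that("select_low_energy keeps the lowest-energy models per replica", {
  withr::local_seed(2)
  mf <- data.frame(
    model_id = sprintf("m%04d", 1:1500),
    replica_id = rep(sprintf("rep%d", 1:10), each = 150),
    cg_energy = rnorm(1500),
    stringsAsFactors = FALSE
  )
  sel <- select_low_energy(mf, baseline_config(per_replica_keep = 100, n_replicas = 10))
  expect_length(sel, 1000L)
  picked <- mf[mf$model_id %in% sel, ]
  counts <- table(picked$replica_id)
  expect_true(all(counts == 100))
  # within each replica the selected really are the lowest energies
  for (r in c("rep1", "rep7")) {
    sub <- mf[mf$replica_id == r, ]
    expect_setequal(
      picked$model_id[picked$replica_id == r],
      sub$model_id[order(sub$cg_energy)][1:100]
    )
  }
  # no-op selection with one replica keeping everything
  one <- mf[mf$replica_id == "rep1", ]
  expect_setequal(
    select_low_energy(one, baseline_config(per_replica_keep = 150, n_replicas = 1)),
    one$model_id
  )
  # underfilled replica is an error
  short <- mf[-(1:120), ]
  expect_error(
    select_low_energy(short, baseline_config(per_replica_keep = 100, n_replicas = 10)),
    "replica underfilled"
  )
})

test_that("kmedoids handles saturated and single-cluster cases exactly", {
  withr::local_seed(3)
  pts <- matrix(rnorm(16), ncol = 2)
  d <- as.matrix(dist(pts))
  km <- kmedoids(d, k = nrow(d), seed = 1)
  expect_equal(km$cost, 0)
  expect_setequal(km$medoids, seq_len(nrow(d)))
  # k = 1 is the 1-median, by linear scan
  km1 <- kmedoids(d, k = 1, seed = 1)
  expect_equal(km1$cost, min(rowSums(d)))
  expect_equal(unname(km1$medoids), unname(which.min(rowSums(d))))
  expect_error(kmedoids(d + diag(2, nrow(d)), 2), "invalid distance matrix")
  expect_error(kmedoids(matrix(c(0, 1, 2, 0), 2), 1), "invalid distance matrix")
})

test_that("kmedoids separates well-split clouds at the brute-force optimum", {
  withr::local_seed(4)
  for (i in 1:10) {
    cloud1 <- matrix(rnorm(10, sd = 0.3), ncol = 2)
    cloud2 <- matrix(rnorm(10, sd = 0.3), ncol = 2) + 50
    d <- as.matrix(dist(rbind(cloud1, cloud2)))
    km <- kmedoids(d, k = 2, seed = i)
    expect_setequal(
      sort(unique((km$medoids > 5))), c(FALSE, TRUE)
    )
    expect_equal(km$cost, exhaustive_kmedoids_cost(d, 2), tolerance = 1e-12)
    expect_true(all(diff(km$cost_trace) <= 1e-12))
  }
})

test_that("baseline_top_models returns medoids covering planted pose clusters", {
  toy <- make_toy_complex(seed = 9, receptor_len = 16, peptide_len = 4)
  # plant 5 tight, well-separated pose clusters of 6 decoys each
  offsets <- rbind(
    c(0, 0, 0), c(14, 0, 0), c(0, 16, 0), c(0, 0, 18), c(12, 12, 0)
  )
  withr::local_seed(5)
  models <- list()
  labels <- integer(0)
  for (cl in 1:5) {
    for (j in 1:6) {
      xyz <- model_coords(toy)
      xyz[toy$peptide_idx, ] <- sweep(
        xyz[toy$peptide_idx, ], 2,
        offsets[cl, ] + rnorm(3, sd = 0.1), `+`
      )
      m <- set_model_coords(toy, xyz)
      m$model_id <- sprintf("c%d_%d", cl, j)
      m$replica_id <- sprintf("rep%d", j %% 2 + 1)
      models[[length(models) + 1]] <- m
      labels <- c(labels, cl)
    }
  }
  mf <- data.frame(
    model_id = vapply(models, `[[`, "", "model_id"),
    replica_id = vapply(models, `[[`, "", "replica_id"),
    cg_energy = rnorm(30), stringsAsFactors = FALSE
  )
  med <- baseline_top_models(models, mf, toy,
    baseline_config(per_replica_keep = 15, n_replicas = 2, k = 5, seed = 1))
  expect_length(med, 5L)
  med_cluster <- labels[match(med, mf$model_id)]
  expect_setequal(med_cluster, 1:5)
  # saturation: k = pool size returns every model
  all_ids <- baseline_top_models(models, mf, toy,
    baseline_config(per_replica_keep = 15, n_replicas = 2, k = 30, seed = 1))
  expect_setequal(all_ids, mf$model_id)
})
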