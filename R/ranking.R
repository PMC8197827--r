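#' Rank scored models by mean interaction energy
#'
#' Ascending by `mean_energy` (more negative = better), with ties broken
#' by lexicographic `model_id` so the ordering is total and reproducible.
#'
#' @param records data frame with at least `model_id` and `mean_energy`
#'   columns (e.g. the `records` element of a [run_scoring_pipeline()]
#'   result).
#' @return the same data frame sorted, with a `rank` column `1..n`.
#' @export
rank_by_energy <- function(records) {
  stopifnot(nrow(records) > 0)
  if (any(is.na(records$mean_energy) | is.nan(records$mean_energy))) {
    bad <- records$model_id[is.na(records$mean_energy)][1L]
    stop(sprintf("unscored model '%s': NaN energy", bad), call. = FALSE)
  }
  ord <- order(records$mean_energy, records$model_id, method = "radix")
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' First n records of a ranked table
#'
#' @param records a ranked data frame.
#' @param n number of records to keep (order preserved; saturates at the
#'   table length).
#' @return the first `min(n, nrow)` rows.
#' @export
top_n <- function(records, n) {
  stopifnot(n >= 1)
  head(records, n)
}

#' Baseline configuration (per-replica selection + clustering)
#'
#' The clustering-based baseline ranking selects, from each docking
#' replica, the models with the lowest coarse-grained docking energy
#' (100 from each of 10 replicas by default, i.e. a pool of 1000), then
#' clusters the pool and reports the k cluster medoids as the top-scored
#' models (k = 10 or 100).
#'
#' @param per_replica_keep models kept per replica (default 100).
#' @param n_replicas number of replicas (default 10).
#' @param k number of clusters / reported models (10 or 100 typically).
#' @param seed integer seed for the clustering initialization.
#' @return an object of class `baseline_config`.
#' @export
baseline_config <- function(per_replica_keep = 100L, n_replicas = 10L,
                            k = 10L, seed = 1L) {
  stopifnot(per_replica_keep >= 1, n_replicas >= 1, k >= 1)
  structure(
    list(
      per_replica_keep = as.integer(per_replica_keep),
      n_replicas = as.integer(n_replicas),
      k = as.integer(k), seed = as.integer(seed)
    ),
    class = "baseline_config"
  )
}

#' Per-replica low-energy selection
#'
#' From every replica, keep the `per_replica_keep` models with the lowest
#' coarse-grained docking energy (ties broken by `model_id`); the
#' returned pool has `per_replica_keep * n_replicas` members.
#'
#' @param manifest data frame with `model_id`, `replica_id`, `cg_energy`.
#' @param cfg a [baseline_config()].
#' @return character vector of selected `model_id`s.
#' @export
select_low_energy <- function(manifest, cfg = baseline_config()) {
  reps <- sort(unique(manifest$replica_id))
  if (length(reps) != cfg$n_replicas) {
    stop(sprintf(
      "manifest has %d replicas, config expects %d",
      length(reps), cfg$n_replicas
    ), call. = FALSE)
  }
  out <- character(0)
  for (r in reps) {
    sub <- manifest[manifest$replica_id == r, , drop = FALSE]
    if (nrow(sub) < cfg$per_replica_keep) {
      stop(sprintf(
        "replica underfilled: '%s' has %d models, need %d",
        r, nrow(sub), cfg$per_replica_keep
      ), call. = FALSE)
    }
    ord <- order(sub$cg_energy, sub$model_id, method = "radix")
    out <- c(out, sub$model_id[ord][seq_len(cfg$per_replica_keep)])
  }
  out
}

#' k-medoids (PAM) clustering of a distance matrix
#'
#' PAM clustering in two phases: alternation (assign every point to its
#' nearest medoid, then update each medoid to the cluster member
#' minimizing the within-cluster distance sum, until the medoid set is
#' stable), followed by the PAM swap phase (greedily apply the
#' medoid/non-medoid exchange that most lowers the total cost, until no
#' exchange improves it). Initialization is k-medoids++ (greedy seeding
#' with probability proportional to squared distance to the nearest
#' chosen medoid) from an explicit seed, so runs are deterministic. The
#' cost (sum of distances to assigned medoids) is non-increasing across
#' iterations.
#'
#' @param dist symmetric nonnegative n-by-n distance matrix with zero
#'   diagonal.
#' @param k number of medoids (<= n).
#' @param seed integer seed for the initialization.
#' @param max_iter iteration cap (default 100).
#' @return list with `medoids` (indices), `assignment` (length-n medoid
#'   index per point), `cost`, and `cost_trace` (per-iteration costs).
#' @export
kmedoids <- function(dist, k, seed = 1L, max_iter = 100L) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (ncol(dist) != n || any(abs(dist - t(dist)) > 1e-9) ||
    any(diag(dist) != 0) || any(dist < 0)) {
    stop("invalid distance matrix", call. = FALSE)
  }
  stopifnot(k >= 1, k <= n)
  medoids <- with_seed(seed, {
    first <- sample.int(n, 1L)
    chosen <- first
    dmin <- dist[, first]
    while (length(chosen) < k) {
      w <- dmin^2
      nxt <- if (sum(w) == 0) {
        sample(setdiff(seq_len(n), chosen), 1L)
      } else {
        sample.int(n, 1L, prob = w)
      }
      if (!(nxt %in% chosen)) {
        chosen <- c(chosen, nxt)
        dmin <- pmin(dmin, dist[, nxt])
      }
    }
    chosen
  })
  cost_trace <- numeric(0)
  assignment <- integer(n)
  repeat {
    sub <- dist[, medoids, drop = FALSE]
    nearest <- max.col(-sub, ties.method = "first")
    assignment <- medoids[nearest]
    cost <- sum(sub[cbind(seq_len(n), nearest)])
    cost_trace <- c(cost_trace, cost)
    new_medoids <- medoids
    for (c_i in seq_along(medoids)) {
      members <- which(assignment == medoids[c_i])
      sums <- colSums(dist[members, members, drop = FALSE])
      new_medoids[c_i] <- members[which.min(sums)]
    }
    if (setequal(new_medoids, medoids) ||
      length(cost_trace) >= max_iter) {
      medoids <- new_medoids
      break
    }
    medoids <- new_medoids
  }
  # PAM swap phase: greedy medoid/non-medoid exchanges
  cost_of <- function(meds) {
    sum(apply(dist[, meds, drop = FALSE], 1L, min))
  }
  cost <- cost_of(medoids)
  repeat {
    best_gain <- 0
    best_swap <- NULL
    others <- setdiff(seq_len(n), medoids)
    for (mi in seq_along(medoids)) {
      rest <- medoids[-mi]
      dmin_rest <- if (length(rest) > 0L) {
        apply(dist[, rest, drop = FALSE], 1L, min)
      } else {
        rep(Inf, n)
      }
      for (c_new in others) {
        new_cost <- sum(pmin(dmin_rest, dist[, c_new]))
        if (cost - new_cost > best_gain + 1e-12) {
          best_gain <- cost - new_cost
          best_swap <- c(mi, c_new)
        }
      }
    }
    if (is.null(best_swap) || length(cost_trace) >= max_iter + n) break
    medoids[best_swap[1L]] <- best_swap[2L]
    cost <- cost_of(medoids)
    cost_trace <- c(cost_trace, cost)
  }
  # final assignment with the settled medoids
  sub <- dist[, medoids, drop = FALSE]
  nearest <- max.col(-sub, ties.method = "first")
  assignment <- medoids[nearest]
  cost <- sum(sub[cbind(seq_len(n), nearest)])
  cost_trace <- c(cost_trace, cost)
  list(
    medoids = medoids, assignment = assignment, cost = cost,
    cost_trace = cost_trace
  )
}

#' Clustering-baseline top models
#'
#' The baseline ranking pipeline: per-replica low-energy selection, then
#' k-medoids clustering of the selected models in pairwise peptide-RMSD
#' space, returning the k medoid models as the top-scored set. Medoids
#' are ordered by ascending cluster-mean coarse-grained energy.
#'
#' @param models named list (or list with `model_id`s) of
#'   [complex_model()] decoys covering every manifest entry.
#' @param manifest data frame with `model_id`, `replica_id`, `cg_energy`.
#' @param reference reference [complex_model()] for the common receptor
#'   frame of the clustering metric.
#' @param cfg a [baseline_config()].
#' @return character vector of `k` medoid `model_id`s.
#' @export
baseline_top_models <- function(models, manifest, reference,
                                cfg = baseline_config()) {
  ids <- vapply(models, `[[`, "", "model_id")
  selected <- select_low_energy(manifest, cfg)
  missing <- setdiff(selected, ids)
  if (length(missing) > 0L) {
    stop(sprintf("model '%s' in manifest but not in model set", missing[1L]),
      call. = FALSE
    )
  }
  pool <- models[match(selected, ids)]
  d <- pairwise_peptide_rmsd(pool, reference)
  km <- kmedoids(d, k = min(cfg$k, length(pool)), seed = cfg$seed)
  med_ids <- selected[km$medoids]
  cg <- manifest$cg_energy[match(selected, manifest$model_id)]
  cluster_mean_cg <- vapply(km$medoids, function(m) {
    mean(cg[km$assignment == m])
  }, numeric(1))
  med_ids[order(cluster_mean_cg, med_ids, method = "radix")]
}
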