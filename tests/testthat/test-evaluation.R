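test_that("kabsch_superpose recovers rigid transforms exactly", {
  withr::local_seed(1)
  target <- matrix(rnorm(30 * 3, sd = 5), ncol = 3)
  # identity
  sup <- kabsch_superpose(target, target)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-9)
  expect_equal(sup$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(sup$fit_rmsd, 0, tolerance = 1e-9)
  # exact rigid recovery
  for (i in 1:5) {
    R <- random_rotation()
    tr <- rnorm(3, sd = 10)
    mobile <- apply_rigid(target, R, tr)
    sup <- kabsch_superpose(mobile, target)
    expect_lt(sup$fit_rmsd, 1e-6)
    expect_equal(apply_superposition(mobile, sup), target, tolerance = 1e-6)
    expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
    expect_equal(crossprod(sup$rotation), diag(3), tolerance = 1e-9)
  }
})

test_that("fit residual under Gaussian noise matches the least-squares expectation", {
  # E[fit_rmsd] ~ sigma * sqrt(3 (1 - 4/(3n))) for n points with per-axis
  # noise sd sigma (6 rigid dof absorbed); Monte-Carlo average over replicates
  withr::local_seed(2)
  n <- 100
  sigma <- 0.7
  target <- matrix(rnorm(n * 3, sd = 8), ncol = 3)
  got <- mean(vapply(1:20, function(i) {
    mobile <- target + matrix(rnorm(n * 3, sd = sigma), ncol = 3)
    kabsch_superpose(mobile, target)$fit_rmsd
  }, numeric(1)))
  want <- sigma * sqrt(3 * (1 - 4 / (3 * n)))
  expect_equal(got, want, tolerance = 0.15)
})

test_that("kabsch_superpose rejects degenerate inputs", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "degenerate")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
  expect_error(
    kabsch_superpose(matrix(rnorm(12), 4), matrix(rnorm(15), 5)),
    "degenerate"
  )
})

test_that("peptide_rmsd fits on the receptor and measures the peptide", {
  toy <- make_toy_complex(seed = 3)
  expect_equal(peptide_rmsd(toy, toy), 0, tolerance = 1e-9)
  # rigid motion of the whole complex is removed by the fit
  moved <- transform_model(toy, random_rotation(), c(5, -3, 8))
  expect_equal(peptide_rmsd(moved, toy), 0, tolerance = 1e-6)
  # a pure 3 A peptide translation reads out exactly
  xyz <- model_coords(toy)
  xyz[toy$peptide_idx, 1] <- xyz[toy$peptide_idx, 1] + 3
  shifted <- set_model_coords(toy, xyz)
  expect_equal(peptide_rmsd(shifted, toy), 3, tolerance = 1e-9)
  # invariance under a joint rigid transform of the shifted model
  moved2 <- transform_model(shifted, random_rotation(), c(-7, 2, 1))
  expect_equal(peptide_rmsd(moved2, toy), 3, tolerance = 1e-6)
  # all-atom receptor fit agrees for consistent structures
  expect_equal(peptide_rmsd(shifted, toy, fit = "all"), 3, tolerance = 1e-9)
})

test_that("peptide_rmsd rejects broken residue correspondence", {
  toy <- make_toy_complex(seed = 3)
  renum <- toy
  renum$atoms$res_seq[renum$peptide_idx] <-
    renum$atoms$res_seq[renum$peptide_idx] + 100L
  expect_error(peptide_rmsd(renum, toy), "residue mapping error")
})

test_that("best_of_top_n takes the running minimum of ranked RMSDs", {
  rec <- data.frame(peptide_rmsd = c(5.1, 1.9, 3.3, 0.4, 7.7))
  expect_equal(best_of_top_n(rec, 3), 1.9)
  expect_equal(best_of_top_n(rec, 1), 5.1)
  expect_equal(best_of_top_n(rec, 10), 0.4)
  # non-increasing in n
  vals <- vapply(1:5, best_of_top_n, numeric(1), records = rec)
  expect_true(all(diff(vals) <= 0))
  cst <- data.frame(peptide_rmsd = rep(2.2, 4))
  expect_equal(best_of_top_n(cst, 2), 2.2)
})

test_that("bin_win_counts assigns wins to the winner's RMSD bin", {
  r <- bin_win_counts(1.2, 2.0)
  expect_equal(r$bins$wins_a[r$bins$lo == 1.0], 1L)
  expect_equal(sum(r$bins$wins_b), 0L)
  expect_equal(r$ties, 0L)
  # exact ties go to neither
  r2 <- bin_win_counts(2.0, 2.0)
  expect_equal(sum(r2$bins$wins_a) + sum(r2$bins$wins_b), 0L)
  expect_equal(r2$ties, 1L)
  # one win each, hand-countable
  r3 <- bin_win_counts(c(1.2, 3.9), c(2.0, 3.1))
  expect_equal(r3$bins$wins_a[r3$bins$lo == 1.0], 1L)
  expect_equal(r3$bins$wins_b[r3$bins$lo == 3.0], 1L)
  # wins + ties account for every complex
  withr::local_seed(4)
  a <- runif(40, 0, 8)
  b <- runif(40, 0, 8)
  b[1:3] <- a[1:3]
  r4 <- bin_win_counts(a, b)
  expect_equal(sum(r4$bins$wins_a) + sum(r4$bins$wins_b) + r4$ties, 40L)
  expect_error(bin_win_counts(1:3, 1:4), "unpaired")
})

test_that("rmsd_histogram covers [0, max) and conserves counts", {
  h <- rmsd_histogram(c(0.2, 0.3, 2.6), bin_width = 0.5)
  expect_equal(sum(h$count), 3L)
  expect_equal(h$count[1], 2L)
  one <- rmsd_histogram(4.2, 1)
  expect_equal(sum(one$count > 0), 1L)
  withr::local_seed(5)
  u <- runif(2000, 0, 10)
  hu <- rmsd_histogram(u, 1)
  expect_true(all(hu$count > 0))
})
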