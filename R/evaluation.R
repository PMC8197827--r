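#' Kabsch superposition of two point sets
#'
#' Least-squares optimal proper rotation and translation mapping `mobile`
#' onto `target`, via singular value decomposition with the usual
#' reflection correction (sign flip on the smallest singular vector when
#' the optimal orthogonal map would be improper).
#'
#' @param mobile,target n-by-3 matrices of paired coordinates, Angstrom
#'   (n >= 3, non-collinear).
#' @return an object of class `superposition`: `rotation` (3x3, proper
#'   orthogonal), `translation` (length-3), `fit_rmsd` (Angstrom). Apply
#'   with [apply_superposition()]: `x %*% rotation + translation`.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile)
  target <- as.matrix(target)
  if (nrow(mobile) != nrow(target)) {
    stop("degenerate fit: point counts differ", call. = FALSE)
  }
  if (nrow(mobile) < 3L) {
    stop("degenerate fit: fewer than 3 points", call. = FALSE)
  }
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  A <- sweep(mobile, 2L, cm)
  B <- sweep(target, 2L, ct)
  H <- crossprod(A, B)
  s <- svd(H)
  if (s$d[2L] <= 1e-8 * max(s$d[1L], 1e-12)) {
    stop("degenerate fit: collinear points", call. = FALSE)
  }
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v) # mobile-frame -> target-frame
  moved <- A %*% R
  fit_rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  structure(
    list(
      rotation = R,
      translation = as.numeric(ct - cm %*% R),
      fit_rmsd = fit_rmsd
    ),
    class = "superposition"
  )
}

#' Apply a superposition to coordinates
#'
#' @param xyz n-by-3 coordinate matrix.
#' @param sup a [kabsch_superpose()] result.
#' @return transformed n-by-3 matrix.
#' @export
apply_superposition <- function(xyz, sup) {
  sweep(as.matrix(xyz) %*% sup$rotation, 2L, sup$translation, `+`)
}

# Match atoms between model and reference by residue key, restricted to a
# group and (optionally) to C-alphas. Returns aligned index vectors.
match_group <- function(model, reference, group, calpha_only = TRUE) {
  gi <- function(m) if (group == "receptor") m$receptor_idx else m$peptide_idx
  sel <- function(m) {
    idx <- gi(m)
    if (calpha_only) idx <- idx[m$atoms$is_calpha[idx]]
    idx
  }
  im <- sel(model)
  ir <- sel(reference)
  key <- function(m, idx) {
    paste(residue_keys(m$atoms)[idx], m$atoms$name[idx], sep = "|")
  }
  km <- key(model, im)
  kr <- key(reference, ir)
  j <- match(km, kr)
  if (anyNA(j) || length(km) != length(kr)) {
    stop(sprintf("residue mapping error: %s atoms do not correspond", group),
      call. = FALSE
    )
  }
  list(model = im, reference = ir[j])
}

#' Ligand RMSD of a complex model against a reference structure
#'
#' The model is superposed onto the reference using receptor atoms only
#' (C-alphas by default, or all shared receptor atoms with
#' `fit = "all"`), and the root-mean-square deviation is then computed
#' over peptide C-alpha atoms without re-fitting. Atom correspondence is
#' by (chain, residue number, insertion code), as appropriate for decoys
#' of a single complex.
#'
#' @param model a [complex_model()].
#' @param reference the reference (crystal) [complex_model()].
#' @param fit `"calpha"` (default) or `"all"`: receptor atoms used for
#'   the superposition.
#' @return peptide C-alpha RMSD, Angstrom.
#' @export
peptide_rmsd <- function(model, reference, fit = c("calpha", "all")) {
  fit <- match.arg(fit)
  rec <- match_group(model, reference, "receptor", calpha_only = fit == "calpha")
  pep <- match_group(model, reference, "peptide", calpha_only = TRUE)
  xm <- model_coords(model)
  xr <- model_coords(reference)
  sup <- kabsch_superpose(xm[rec$model, , drop = FALSE],
    xr[rec$reference, , drop = FALSE])
  moved <- apply_superposition(xm[pep$model, , drop = FALSE], sup)
  sqrt(mean(rowSums((moved - xr[pep$reference, , drop = FALSE])^2)))
}

#' Pairwise peptide-RMSD distance matrix for a decoy set
#'
#' The structural-clustering metric: every model is superposed onto a
#' common receptor frame (the reference's), and pairwise Euclidean RMSD is
#' computed over the transformed peptide C-alpha coordinates. For decoys
#' sharing one receptor this equals pairwise receptor-fit ligand RMSD.
#'
#' @param models list of [complex_model()] objects.
#' @param reference reference [complex_model()] providing the common
#'   receptor frame.
#' @param fit receptor atoms used for superposition (see
#'   [peptide_rmsd()]).
#' @return symmetric n-by-n matrix of distances, Angstrom, with model ids
#'   as dimnames.
#' @export
pairwise_peptide_rmsd <- function(models, reference, fit = c("calpha", "all")) {
  fit <- match.arg(fit)
  placed <- lapply(models, function(m) {
    rec <- match_group(m, reference, "receptor", calpha_only = fit == "calpha")
    pep <- match_group(m, reference, "peptide", calpha_only = TRUE)
    xm <- model_coords(m)
    sup <- kabsch_superpose(xm[rec$model, , drop = FALSE],
      model_coords(reference)[rec$reference, , drop = FALSE])
    as.vector(t(apply_superposition(xm[pep$model, , drop = FALSE], sup)))
  })
  flat <- do.call(rbind, placed)
  m_ca <- ncol(flat) / 3L
  d <- as.matrix(dist(flat)) / sqrt(m_ca)
  dimnames(d) <- list(
    vapply(models, `[[`, "", "model_id"),
    vapply(models, `[[`, "", "model_id")
  )
  d
}

#' Best (lowest) ligand RMSD among the top-N ranked models
#'
#' The scoring-quality metric: the minimum `peptide_rmsd` among the first
#' `n` records of a ranked score table.
#'
#' @param records a ranked score data frame (see [rank_by_energy()]) with
#'   a `peptide_rmsd` column.
#' @param n number of top-ranked models to consider.
#' @return best RMSD, Angstrom.
#' @export
best_of_top_n <- function(records, n) {
  stopifnot(n >= 1)
  min(head(records$peptide_rmsd, n))
}

#' Per-bin win counts between two scoring methods
#'
#' For each complex, the method with the strictly lower best-RMSD wins;
#' the pair is assigned to the 0.5-Angstrom (by default) half-open bin
#' `[i*w, (i+1)*w)` containing the winning RMSD. Exact ties are counted
#' separately and increment neither method.
#'
#' @param a,b per-complex best RMSD values (Angstrom) for methods A and
#'   B, paired by complex.
#' @param width bin width, Angstrom (default 0.5).
#' @return an object of class `comparison_report`: data frame `bins`
#'   (`lo`, `hi`, `wins_a`, `wins_b`), plus `ties` and `n`.
#' @export
bin_win_counts <- function(a, b, width = 0.5) {
  if (length(a) != length(b)) stop("unpaired comparison", call. = FALSE)
  ties <- sum(a == b)
  win_a <- a < b
  win_b <- b < a
  winner_val <- ifelse(win_a, a, b)
  decided <- win_a | win_b
  hi <- if (any(decided)) max(winner_val[decided]) else 0
  edges <- seq(0, (floor(hi / width) + 1) * width, by = width)
  bin_of <- function(v) findInterval(v, edges, rightmost.closed = FALSE)
  nb <- length(edges) - 1L
  wa <- tabulate(bin_of(winner_val[win_a]), nbins = nb)
  wb <- tabulate(bin_of(winner_val[win_b]), nbins = nb)
  structure(
    list(
      bins = data.frame(
        lo = edges[-length(edges)], hi = edges[-1L],
        wins_a = wa, wins_b = wb
      ),
      ties = ties, n = length(a)
    ),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    "comparison_report: %d complexes, A wins %d, B wins %d, ties %d\n",
    x$n, sum(x$bins$wins_a), sum(x$bins$wins_b), x$ties
  ))
  invisible(x)
}

#' Histogram of ligand RMSD values
#'
#' Counts on a regular `[0, max)` grid; counts sum to the number of
#' values.
#'
#' @param values RMSD values, Angstrom.
#' @param bin_width bin width, Angstrom.
#' @return data frame with `lo`, `hi`, `count`.
#' @export
rmsd_histogram <- function(values, bin_width = 0.5) {
  stopifnot(length(values) > 0, all(values >= 0))
  edges <- seq(0, (floor(max(values) / bin_width) + 1) * bin_width,
    by = bin_width)
  counts <- tabulate(findInterval(values, edges), nbins = length(edges) - 1L)
  data.frame(lo = edges[-length(edges)], hi = edges[-1L], count = counts)
}
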