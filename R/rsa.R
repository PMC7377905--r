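#' Multivoxel pattern array
#'
#' Container for condition-by-run voxel activity estimates: a 3-D array
#' indexed `[run, condition, voxel]` plus a condition-label table carrying
#' the two task factors (coherence level and context).
#'
#' @param patterns Numeric array `n_runs x n_conditions x n_voxels`, finite,
#'   with `>= 2` runs and `>= 2` voxels.
#' @param conditions Tibble/data frame with one row per condition; columns
#'   `coherence_level` and/or `context` label the task factors.
#' @return A list of class `pattern_array`: `patterns`, `conditions`.
#' @export
pattern_array <- function(patterns, conditions) {
  if (!is.array(patterns) || length(dim(patterns)) != 3L) {
    abort("`patterns` must be a 3-D array [run, condition, voxel].")
  }
  if (dim(patterns)[1] < 2L) abort("need >= 2 runs.")
  if (dim(patterns)[3] < 2L) abort("need >= 2 voxels.")
  if (!all(is.finite(patterns))) abort("`patterns` must be finite.")
  conditions <- as_tibble(conditions)
  if (nrow(conditions) != dim(patterns)[2]) {
    abort("`conditions` must have one row per condition.")
  }
  structure(list(patterns = patterns, conditions = conditions),
            class = "pattern_array")
}

#' @export
print.pattern_array <- function(x, ...) {
  d <- dim(x$patterns)
  cat(sprintf("Pattern array: %d runs x %d conditions x %d voxels\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Write/read a pattern array as delimited text
#'
#' Long-format CSV with one row per (run, condition, voxel) cell and the
#' condition labels repeated, so arrays round-trip losslessly through plain
#' text.
#'
#' @param pa A `pattern_array`.
#' @param path CSV file path.
#' @export
write_patterns <- function(pa, path) {
  stopifnot(inherits(pa, "pattern_array"))
  d <- dim(pa$patterns)
  idx <- expand.grid(run = seq_len(d[1]), condition = seq_len(d[2]),
                     voxel = seq_len(d[3]))
  out <- cbind(idx, pa$conditions[idx$condition, , drop = FALSE],
               value = as.vector(pa$patterns))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  d <- utils::read.csv(path)
  nr <- max(d$run); nc <- max(d$condition); nv <- max(d$voxel)
  arr <- array(NA_real_, c(nr, nc, nv))
  arr[cbind(d$run, d$condition, d$voxel)] <- d$value
  lab <- d[d$run == 1 & d$voxel == 1, ]
  lab <- lab[order(lab$condition),
             setdiff(names(lab), c("run", "condition", "voxel", "value")),
             drop = FALSE]
  pattern_array(arr, as_tibble(lab))
}

#' Shrinkage estimate of the voxel noise covariance
#'
#' Multivariate noise normalisation needs an invertible voxel-by-voxel
#' covariance even when voxels outnumber residual observations. The sample
#' covariance is shrunk toward its own diagonal: off-diagonal entries are
#' scaled by `1 - lambda`, with `lambda` chosen analytically
#' (Ledoit-Wolf/Schafer-Strimmer style: the ratio of the summed sampling
#' variances of the off-diagonal entries to their summed squares), or fixed
#' by the caller. The result is symmetric positive definite by construction.
#'
#' @param residuals Numeric matrix, observations x voxels (`>= 2` rows).
#' @param lambda `"auto"` for the analytic shrinkage weight, or a number in
#'   `[0, 1]` (`1` returns exactly the diagonal target).
#' @return Covariance matrix with attribute `"lambda"`.
#' @export
noise_covariance <- function(residuals, lambda = "auto") {
  residuals <- as.matrix(residuals)
  n <- nrow(residuals)
  v <- ncol(residuals)
  if (n < 2L) abort("need more than one residual observation.")
  if (v < 2L) abort("need >= 2 voxels.")
  Xc <- scale(residuals, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / (n - 1)
  if (identical(lambda, "auto")) {
    # sampling variance of each covariance entry from the centred products
    W <- array(0, c(v, v))
    for (i in seq_len(n)) {
      w <- tcrossprod(Xc[i, ])
      W <- W + (w - S * (n - 1) / n)^2
    }
    var_s <- n / ((n - 1)^3) * W
    off <- row(S) != col(S)
    denom <- sum(S[off]^2)
    lambda <- if (denom <= 0) 1 else min(1, max(0, sum(var_s[off]) / denom))
  } else {
    assert_prob(lambda, "lambda")
  }
  Sh <- (1 - lambda) * S + lambda * diag(diag(S), v)
  # guarantee invertibility even for degenerate diagonals
  eps <- 1e-10 * mean(diag(Sh))
  if (!is.finite(eps) || eps <= 0) eps <- 1e-10
  Sh <- Sh + diag(eps, v)
  attr(Sh, "lambda") <- lambda
  Sh
}

# whiten pattern rows so Euclidean distance equals Mahalanobis distance
whiten_rows <- function(X, sigma) {
  if (is.null(sigma)) return(X)
  R <- tryCatch(chol(sigma), error = function(e)
    abort("noise covariance is singular; use shrinkage upstream."))
  t(backsolve(R, t(X), transpose = TRUE))
}

#' Split-data representational dissimilarity matrix
#'
#' For each scan run `i`, entry `(p, q)` is the Mahalanobis distance
#' (Euclidean distance after whitening by the noise covariance) between the
#' pattern of condition `p` in run `i` and the pattern of condition `q`
#' averaged across the remaining runs `j != i`; the run-specific matrices
#' are then averaged. Diagonal entries are cross-run same-condition
#' distances and are therefore not zero in general.
#'
#' @param pa A `pattern_array`.
#' @param noise_cov Voxel covariance from [noise_covariance()], or `NULL`
#'   for the identity (plain cross-validated Euclidean distance).
#' @param squared Return squared distances (default `FALSE`, unsquared).
#' @return A `condition x condition` matrix of class `split_rdm`.
#' @export
sdrdm <- function(pa, noise_cov = NULL, squared = FALSE) {
  stopifnot(inherits(pa, "pattern_array"))
  d <- dim(pa$patterns)
  n_runs <- d[1]; n_cond <- d[2]
  acc <- matrix(0, n_cond, n_cond)
  for (i in seq_len(n_runs)) {
    A <- whiten_rows(matrix(pa$patterns[i, , ], n_cond, d[3]), noise_cov)
    B <- colMeans(pa$patterns[-i, , , drop = FALSE], dims = 1)
    B <- whiten_rows(matrix(B, n_cond, d[3]), noise_cov)
    D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    D2[D2 < 0] <- 0
    acc <- acc + if (squared) D2 else sqrt(D2)
  }
  out <- acc / n_runs
  structure(out, class = c("split_rdm", class(out)),
            conditions = pa$conditions, squared = squared)
}

#' Exemplar discriminability index
#'
#' Mean off-diagonal minus mean diagonal of a run-averaged split-data RDM.
#' A positive EDI indicates that voxel patterns are more stable across runs
#' within conditions than between conditions, i.e. that the region carries
#' information about the conditions; its theoretical expectation under
#' exchangeable condition labels is zero.
#'
#' @param rdm A square `split_rdm` (or plain matrix) with `>= 2` conditions.
#' @return Scalar EDI.
#' @export
edi <- function(rdm) {
  rdm <- unclass(rdm)
  if (!is.matrix(rdm) || nrow(rdm) != ncol(rdm)) abort("`rdm` must be square.")
  if (nrow(rdm) < 2L) abort("EDI needs >= 2 conditions.")
  if (any(!is.finite(rdm))) abort("`rdm` must be finite.")
  off <- row(rdm) != col(rdm)
  mean(rdm[off]) - mean(diag(rdm))
}

#' Collapse a pattern array onto one task factor
#'
#' Averages condition patterns over the other factor within each run,
#' producing the 4-condition array for a sub-space analysis (coherence-only
#' or context-only EDI).
#'
#' @param pa A `pattern_array` whose condition table carries both
#'   `coherence_level` and `context`.
#' @param factor `"coherence"` or `"context"`: the factor to keep.
#' @return A `pattern_array` with one condition per level of the kept
#'   factor.
#' @export
collapse_to_subspace <- function(pa, factor = c("coherence", "context")) {
  stopifnot(inherits(pa, "pattern_array"))
  factor <- match.arg(factor)
  col <- if (factor == "coherence") "coherence_level" else "context"
  if (!all(c("coherence_level", "context") %in% names(pa$conditions))) {
    abort("condition labels must carry both `coherence_level` and `context`.")
  }
  g <- pa$conditions[[col]]
  lev <- sort(unique(g))
  d <- dim(pa$patterns)
  out <- array(NA_real_, c(d[1], length(lev), d[3]))
  for (i in seq_along(lev)) {
    sel <- which(g == lev[i])
    out[, i, ] <- apply(pa$patterns[, sel, , drop = FALSE], c(1, 3), mean)
  }
  lab <- tibble(!!col := lev)
  pattern_array(out, lab)
}

#' EDI in the full task space and both sub-spaces
#'
#' @param pa A 16-condition `pattern_array` (4 coherence x 4 context).
#' @inheritParams sdrdm
#' @return Tibble with columns `space` (`"full"`, `"K"`, `"C"`) and `edi`.
#' @export
edi_by_space <- function(pa, noise_cov = NULL, squared = FALSE) {
  tibble(
    space = c("full", "K", "C"),
    edi = c(
      edi(sdrdm(pa, noise_cov, squared)),
      edi(sdrdm(collapse_to_subspace(pa, "coherence"), noise_cov, squared)),
      edi(sdrdm(collapse_to_subspace(pa, "context"), noise_cov, squared))
    )
  )
}

#' One-tailed signed-rank group test for EDI values
#'
#' Wilcoxon signed-rank test of per-subject EDIs against zero, one-tailed in
#' the positive direction (the EDI cannot be negative in expectation when a
#' region carries condition information). Zeros are dropped and ties
#' mid-ranked; the exact null distribution is used for n <= 25 after
#' zero-dropping (when no ties prevent it), otherwise the normal
#' approximation with continuity correction.
#'
#' @param edis Per-subject EDI values (`>= 5` subjects, not all zero).
#' @return One-row tibble: `n` (non-zero subjects), `statistic` (V),
#'   `p_value`, `exact`.
#' @export
signrank_group_test <- function(edis) {
  if (length(edis) < 5L) abort("need >= 5 subjects.")
  if (any(!is.finite(edis))) abort("EDI values must be finite.")
  nz <- edis[edis != 0]
  if (length(nz) == 0L) abort("all EDI values are zero; test is degenerate.")
  use_exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(
    wilcox.test(nz, mu = 0, alternative = "greater",
                exact = use_exact, correct = TRUE)
  )
  tibble(n = length(nz), statistic = unname(wt$statistic),
         p_value = wt$p.value, exact = use_exact)
}
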