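# Dynamic cross-correlation matrices: covariance of C-alpha displacement
# vectors over an ensemble and its normalized (DCCM) form.

#' Cross-correlation matrix container
#'
#' @param values Symmetric residue-by-residue matrix: raw displacement
#'   covariance `c(i,j) = <dR_i . dR_j>` in nm^2, or its normalized form in
#'   `[-1, 1]`.
#' @param kind `"raw"` or `"normalized"`.
#' @param resseq Author residue numbers used as labels.
#' @return An `xcorr_matrix`.
#' @export
xcorr_matrix <- function(values, kind = c("raw", "normalized"),
                         resseq = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix is not square")
  if (max(abs(values - t(values))) > 1e-10) stop("matrix is not symmetric")
  if (kind == "raw" && any(diag(values) < -1e-12))
    stop("raw covariance has negative diagonal")
  if (is.null(resseq)) resseq <- seq_len(nrow(values))
  dimnames(values) <- list(resseq, resseq)
  structure(list(values = values, kind = kind, resseq = as.integer(resseq)),
            class = "xcorr_matrix")
}

#' @export
print.xcorr_matrix <- function(x, ...) {
  cat("xcorr_matrix (", x$kind, "): ", nrow(x$values), " residues\n", sep = "")
  invisible(x)
}

#' Displacement covariance over an ensemble
#'
#' `c(i,j) = <dR_i(t) . dR_j(t)>`, the mean over frames of the dot product of
#' the two residues' 3-vector displacements from their ensemble means. With
#' `fit = "mean"` (default) frames are superposed onto the mean structure
#' first (fit to frame 1, mean, refit), removing rigid-body tumbling; use
#' `"none"` for generator output that is already aligned. The diagonal equals
#' the squared per-residue RMSF computed with the same alignment.
#'
#' @param traj A C-alpha `md_trajectory` with at least 2 frames.
#' @param fit `"mean"` or `"none"`.
#' @param stride Use every `stride`-th frame (default 1 = all frames).
#' @return An `xcorr_matrix` of kind `"raw"` (nm^2).
#' @export
displacement_covariance <- function(traj, fit = c("mean", "none"), stride = 1L) {
  fit <- match.arg(fit)
  stopifnot(stride >= 1L)
  if (stride > 1L) traj <- slice_frames(traj, seq(1L, n_frames(traj), by = stride))
  if (n_frames(traj) < 2L)
    stop("insufficient frames: covariance needs at least 2")
  al <- .align_to_mean(traj, fit == "mean")
  nfr <- dim(al$coords)[3]
  cv <- 0
  for (ax in 1:3) {
    D <- t(al$coords[, ax, ] - al$mean[, ax])   # frames x residues
    cv <- cv + crossprod(D) / nfr
  }
  xcorr_matrix(cv, "raw", traj$atoms$resseq)
}

#' Normalize a raw covariance to a DCCM
#'
#' Entry-wise `c(i,j) / sqrt(c(i,i) c(j,j))`; the diagonal is exactly 1 and
#' all entries lie in `[-1, 1]` (Cauchy-Schwarz). A residue with zero
#' variance (frozen) gets a zero row/column off-diagonal, with a warning.
#'
#' @param cov An `xcorr_matrix` of kind `"raw"`.
#' @return An `xcorr_matrix` of kind `"normalized"`.
#' @export
normalize_dccm <- function(cov) {
  stopifnot(inherits(cov, "xcorr_matrix"))
  if (cov$kind != "raw") stop("expected a raw covariance matrix")
  d <- diag(cov$values)
  frozen <- d <= 1e-30
  s <- sqrt(ifelse(frozen, 1, d))
  m <- cov$values / outer(s, s)
  if (any(frozen)) {
    warning(sum(frozen), " residue(s) with zero variance; their correlations set to 0")
    m[frozen, ] <- 0; m[, frozen] <- 0
  }
  diag(m) <- 1
  xcorr_matrix(m, "normalized", cov$resseq)
}

#' Compute the DCCM of a trajectory
#'
#' Convenience composition of [displacement_covariance()] and
#' [normalize_dccm()].
#'
#' @inheritParams displacement_covariance
#' @return An `xcorr_matrix` of kind `"normalized"`.
#' @export
dccm_matrix <- function(traj, fit = c("mean", "none"), stride = 1L) {
  normalize_dccm(displacement_covariance(traj, fit, stride))
}

# 2-D prefix sum; S[i+1, j+1] = sum of m[1:i, 1:j]
.prefix2d <- function(m) {
  S <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  S[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  S
}
.block_sum <- function(S, i1, i2, j1, j2)
  S[i2 + 1L, j2 + 1L] - S[i1, j2 + 1L] - S[i2 + 1L, j1] + S[i1, j1]

#' Extract strongly correlated off-diagonal regions
#'
#' Finds maximal contiguous residue-range pairs `(A, B)` with `A` strictly
#' before `B` (disjoint, so the block is off-diagonal) whose mean absolute
#' correlation is at least `threshold` and whose sides are both at least
#' `min_block` residues. A block is maximal if no one-step extension of any
#' side still satisfies the criteria. Exhaustive over all contiguous range
#' pairs via 2-D prefix sums; intended for the moderate matrix sizes of
#' residue-level analysis.
#'
#' @param dccm An `xcorr_matrix` of kind `"normalized"`.
#' @param threshold Mean |correlation| cutoff, in (0, 1].
#' @param min_block Minimum side length in residues (default 3).
#' @return Data frame with author-numbered ranges (`a_from`, `a_to`,
#'   `b_from`, `b_to`), `mean_c` (signed mean correlation), and `sign`,
#'   sorted by decreasing `|mean_c|` with residue-index tie-break.
#' @export
correlated_regions <- function(dccm, threshold = 0.5, min_block = 3L) {
  stopifnot(inherits(dccm, "xcorr_matrix"), dccm$kind == "normalized")
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  n <- nrow(dccm$values)
  Sa <- .prefix2d(abs(dccm$values))
  Sv <- .prefix2d(dccm$values)
  ok <- function(i1, i2, j1, j2) {
    i1 >= 1L && j2 <= n && i2 < j1 &&
      (i2 - i1 + 1L) >= min_block && (j2 - j1 + 1L) >= min_block &&
      .block_sum(Sa, i1, i2, j1, j2) /
        ((i2 - i1 + 1) * (j2 - j1 + 1)) >= threshold
  }
  res <- list()
  for (i1 in seq_len(n)) for (i2 in i1:n) {
    if (i2 - i1 + 1L < min_block) next
    if (i2 + min_block > n) break
    for (j1 in (i2 + 1L):n) for (j2 in j1:n) {
      if (j2 - j1 + 1L < min_block) next
      if (!ok(i1, i2, j1, j2)) next
      maximal <- !ok(i1 - 1L, i2, j1, j2) && !ok(i1, i2 + 1L, j1, j2) &&
                 !ok(i1, i2, j1 - 1L, j2) && !ok(i1, i2, j1, j2 + 1L)
      if (maximal) {
        mc <- .block_sum(Sv, i1, i2, j1, j2) / ((i2 - i1 + 1) * (j2 - j1 + 1))
        res[[length(res) + 1L]] <- c(i1, i2, j1, j2, mc)
      }
    }
  }
  if (length(res) == 0L)
    return(data.frame(a_from = integer(), a_to = integer(), b_from = integer(),
                      b_to = integer(), mean_c = numeric(), sign = integer()))
  m <- do.call(rbind, res)
  out <- data.frame(a_from = dccm$resseq[m[, 1]], a_to = dccm$resseq[m[, 2]],
                    b_from = dccm$resseq[m[, 3]], b_to = dccm$resseq[m[, 4]],
                    mean_c = m[, 5], sign = ifelse(m[, 5] >= 0, 1L, -1L))
  out[order(-abs(out$mean_c), out$a_from, out$b_from), , drop = FALSE]
}
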