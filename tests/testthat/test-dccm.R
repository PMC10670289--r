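test_that("displacement covariance matches closed forms on toys", {
  s <- make_fixture_structure(5, "chain")
  const <- toy_traj(list(s$xyz, s$xyz))
  expect_equal(displacement_covariance(const, fit = "none")$values,
               matrix(0, 5, 5), ignore_attr = TRUE)
  # two atoms moving identically along x: c(1,2) = c(1,1) = d^2
  d <- 0.2
  base <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  up <- base; up[, 1] <- up[, 1] + d
  dn <- base; dn[, 1] <- dn[, 1] - d
  cv <- displacement_covariance(toy_traj(list(up, dn)), fit = "none")
  expect_equal(cv$values[1, 2], d^2, tolerance = 1e-12)
  expect_equal(cv$values[1, 1], d^2, tolerance = 1e-12)
  expect_error(displacement_covariance(toy_traj(list(base))), "insufficient")
})

test_that("covariance equals an independent double-loop implementation", {
  set.seed(31)
  frames <- lapply(1:50, function(f) matrix(rnorm(24, sd = 0.1), 8, 3))
  traj <- toy_traj(frames)
  cv <- displacement_covariance(traj, fit = "none")
  expect_lt(max(abs(cv$values - oracle_covariance(traj$coords))), 1e-12)
  expect_equal(cv$values, t(cv$values))
})

test_that("normalization yields unit diagonal, [-1, 1] entries, and -1 for anti-phase motion", {
  ident <- xcorr_matrix(diag(4), "raw")
  expect_equal(normalize_dccm(ident)$values, diag(4), ignore_attr = TRUE)
  d <- 0.15
  base <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  f1 <- base; f1[1, 1] <- d; f1[2, 1] <- 1 - d
  f2 <- base; f2[1, 1] <- -d; f2[2, 1] <- 1 + d
  nd <- dccm_matrix(toy_traj(list(f1, f2)), fit = "none")
  expect_equal(nd$values[1, 2], -1, tolerance = 1e-12)
  s <- make_fixture_structure(20, "helix")
  traj <- sample_trajectory(gnm_model(s), 200, seed = 12)
  m <- dccm_matrix(traj, fit = "mean")$values
  expect_true(all(m >= -1 - 1e-10 & m <= 1 + 1e-10))
  expect_equal(diag(m), rep(1, 20), ignore_attr = TRUE)
})

test_that("a frozen residue gets zeroed correlations with a warning", {
  set.seed(7)
  frames <- lapply(1:20, function(f) {
    m <- matrix(rnorm(12, sd = 0.05), 4, 3)
    m[2, ] <- c(1, 2, 3)  # residue 2 never moves
    m
  })
  cv <- displacement_covariance(toy_traj(frames), fit = "none")
  expect_warning(nd <- normalize_dccm(cv), "zero variance")
  expect_equal(nd$values[2, -2], rep(0, 3), ignore_attr = TRUE)
  expect_equal(nd$values[2, 2], 1)
})

test_that("the DCCM is invariant to a global rigid motion of all frames", {
  s <- make_fixture_structure(15, "helix")
  traj <- sample_trajectory(gnm_model(s), 80, seed = 9)
  th <- 1.1
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3,
              byrow = TRUE)
  moved <- traj
  for (f in seq_len(n_frames(traj)))
    moved$coords[, , f] <- traj$coords[, , f] %*% t(R) + rep(1, 15) %*% t(c(3, -1, 2))
  expect_equal(dccm_matrix(moved, fit = "mean")$values,
               dccm_matrix(traj, fit = "mean")$values, tolerance = 1e-9)
})

test_that("raw covariance diagonal equals squared RMSF under the same alignment", {
  s <- make_fixture_structure(18, "helix")
  traj <- sample_trajectory(gnm_model(s), 120, seed = 4)
  for (mode in c("mean", "none")) {
    cv <- displacement_covariance(traj, fit = mode)
    p <- rmsf(traj, fit = mode)
    expect_lt(max(abs(diag(cv$values) - p$rmsf^2)), 1e-10)
  }
})

test_that("our DCCM agrees with bio3d's on the same aligned ensemble", {
  s <- make_fixture_structure(15, "helix")
  traj <- sample_trajectory(gnm_model(s), 150, seed = 18)
  ours <- dccm_matrix(traj, fit = "none")$values
  xyz <- t(apply(traj$coords, 3, function(m) as.numeric(t(m))))
  theirs <- suppressWarnings(bio3d::dccm.xyz(xyz))
  expect_equal(unname(ours), unname(theirs[seq_len(15), seq_len(15)]),
               tolerance = 1e-6)
})

test_that("correlated regions recover planted blocks and match brute force", {
  n <- 12
  M <- diag(n)
  M[2:5, 8:11] <- 0.8; M[8:11, 2:5] <- 0.8
  planted <- xcorr_matrix(M, "normalized")
  # threshold chosen so no diluted expansion of the planted block qualifies
  out <- correlated_regions(planted, threshold = 0.75, min_block = 3)
  expect_equal(out$a_from[1], 2); expect_equal(out$a_to[1], 5)
  expect_equal(out$b_from[1], 8); expect_equal(out$b_to[1], 11)
  expect_equal(out$sign[1], 1L)
  expect_equal(nrow(correlated_regions(xcorr_matrix(diag(n), "normalized"),
                                       threshold = 0.3)), 0L)
  expect_error(correlated_regions(planted, threshold = 1.5), "threshold")
  # random symmetric matrix vs exhaustive oracle
  set.seed(77)
  A <- matrix(runif(100, -1, 1), 10); A <- (A + t(A)) / 2; diag(A) <- 1
  rnd <- xcorr_matrix(A, "normalized")
  got <- correlated_regions(rnd, threshold = 0.4, min_block = 2)
  ref <- oracle_regions(A, 0.4, 2)
  expect_equal(nrow(got), if (is.null(ref)) 0L else nrow(ref))
  if (!is.null(ref)) {
    ref <- ref[order(-abs(ref[, 5]), ref[, 1], ref[, 3]), , drop = FALSE]
    expect_equal(unname(as.matrix(got[, 1:4])), unname(ref[, 1:4]))
  }
})
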