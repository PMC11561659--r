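test_that("bval/bvec readers convert units, normalise and auto-orient", {
  bval <- tempfile(fileext = ".bval"); bvec <- tempfile(fileext = ".bvec")
  writeLines("0 800 800", bval)
  writeLines(c("0 1 0", "0 0 1", "0 0 0"), bvec)
  p <- read_bvals_bvecs(bval, bvec)
  expect_equal(p$b, c(0, 0.8, 0.8))
  expect_equal(p$directions[2, ], c(1, 0, 0))
  expect_equal(p$directions[1, ], c(0, 0, 0))

  # a 50 s/mm^2 entry is the 0.05 ms/um^2 shell, distinct from b = 0
  writeLines("0 50 6000", bval)
  writeLines(c("0 1 0", "0 0 0", "0 0 1"), bvec)
  p <- read_bvals_bvecs(bval, bvec)
  expect_equal(p$b, c(0, 0.05, 6))
  sh <- group_shells(p)
  expect_equal(sum(sh$is_b0), 1)
  expect_equal(shell_bvalues(sh), c(0.05, 6))
})

test_that("bvec row-major and column-major files load identically and roundtrip", {
  p0 <- connectome_protocol()
  bval <- tempfile(); bvec <- tempfile()
  write_bvals_bvecs(p0, bval, bvec)
  p1 <- read_bvals_bvecs(bval, bvec)
  expect_equal(p1$b, p0$b, tolerance = 1e-12)
  expect_equal(p1$directions, p0$directions, tolerance = 1e-9)
  # transpose the bvec file (volumes x 3 instead of 3 x volumes)
  m <- as.matrix(utils::read.table(bvec))
  utils::write.table(t(m), bvec, row.names = FALSE, col.names = FALSE)
  p2 <- read_bvals_bvecs(bval, bvec)
  expect_equal(p2$directions, p1$directions, tolerance = 1e-12)
})

test_that("reader errors on malformed gradient tables", {
  bval <- tempfile(); bvec <- tempfile()
  writeLines("0 800 800 800", bval)
  writeLines(c("0 1 0", "0 0 1", "0 0 0"), bvec)
  expect_error(read_bvals_bvecs(bval, bvec), "do not match")
  writeLines("0 800 800", bval)
  writeLines(c("0 1 0", "0 0 0", "0 0 0"), bvec)
  expect_error(read_bvals_bvecs(bval, bvec), "norm 0")
})

test_that("shell grouping matches the 8-shell protocol and is permutation invariant", {
  p <- connectome_protocol()
  sh <- group_shells(p)
  expect_equal(shell_bvalues(sh), connectome_shell_bvalues())
  expect_equal(sum(sh$is_b0), 1)
  expect_equal(sh$n_dir[sh$is_b0], 24)
  expect_equal(sh$n_dir[!sh$is_b0], c(32, 32, 32, 32, 64, 64, 64, 64))
  # shells partition the volumes
  expect_equal(sort(unlist(sh$volumes)), seq_along(p$b))

  perm <- sample(seq_along(p$b))
  p2 <- acquisition_protocol(p$b[perm], p$directions[perm, ])
  sh2 <- group_shells(p2)
  expect_equal(sh2$b, sh$b)
  expect_equal(sh2$n_dir, sh$n_dir)
  # idempotence: regrouping the shell centres yields the same centres
  p3 <- acquisition_protocol(sh$b, matrix(rep(c(1, 0, 0), 9), 9, 3,
                                          byrow = TRUE) *
                               (sh$b > 0))
  expect_equal(group_shells(p3)$b, sh$b)
})

test_that("shell grouping edge cases: all b0, near-merge, chained drift", {
  z <- matrix(0, 3, 3)
  all0 <- acquisition_protocol(c(0, 0, 0), z)
  sh <- group_shells(all0)
  expect_equal(nrow(sh), 1)
  expect_true(sh$is_b0)
  expect_length(shell_bvalues(sh), 0)

  d <- matrix(c(1, 0, 0), 3, 3, byrow = TRUE); d[1, ] <- 0
  near <- acquisition_protocol(c(0, 0.80, 0.81), d)
  expect_equal(length(shell_bvalues(group_shells(near))), 1)

  d4 <- matrix(c(1, 0, 0), 4, 3, byrow = TRUE)
  drift <- acquisition_protocol(c(0.80, 0.84, 0.88, 0.92), d4)
  expect_error(group_shells(drift), "ambiguous")
})

test_that("spherical mean: identity, scale invariance, linearity, stick oracle", {
  p <- connectome_protocol()
  sh <- group_shells(p)
  const <- rep(3.7, length(p$b))
  sm <- compute_spherical_mean(const, p, sh)
  expect_equal(as.vector(sm$values), rep(1, 8), tolerance = 1e-12)
  expect_equal(as.vector(compute_spherical_mean(const * 5, p, sh)$values),
               as.vector(sm$values), tolerance = 1e-12)

  # stick at bD = 2 on 64 directions: closed form sqrt(pi/(4bD)) erf(sqrt(bD))
  dirs <- fibonacci_directions(64)
  b <- c(0, rep(1, 64))
  prot <- acquisition_protocol(b, rbind(c(0, 0, 0), dirs))
  u <- c(0, 0, 1)
  sig <- c(1, stick_directional_signal(1, 2, dirs, u))
  shl <- group_shells(prot)
  v <- compute_spherical_mean(sig, prot, shl)$values[1, 1]
  closed <- sqrt(pi / 8) * (2 * pnorm(sqrt(2) * sqrt(2)) - 1)
  expect_equal(closed, 0.5982, tolerance = 1e-4)
  expect_lt(abs(v - closed) / closed, 0.02)

  # linearity in the signal for a fixed b = 0 reference
  s1 <- runif(length(p$b)); s2 <- runif(length(p$b))
  b0i <- unlist(sh$volumes[sh$is_b0])
  s1[b0i] <- 1; s2[b0i] <- 1
  lhs <- compute_spherical_mean(0.3 * s1 + 0.7 * s2, p, sh)$values
  rhs <- 0.3 * compute_spherical_mean(s1, p, sh)$values +
    0.7 * compute_spherical_mean(s2, p, sh)$values
  expect_equal(lhs, rhs, tolerance = 1e-12)

  # non-positive b = 0 mean flags the record
  badsig <- matrix(const, 2, length(p$b), byrow = TRUE)
  badsig[2, b0i] <- 0
  sm2 <- compute_spherical_mean(badsig, p, sh)
  expect_equal(sm2$valid, c(TRUE, FALSE))
  expect_true(all(is.na(sm2$values[2, ])))
})

test_that("b-gradient conversion matches the scanner limit and inverts", {
  g <- b_to_gradient(6, delta = 8, Delta = 19)
  expect_equal(g, 283.2, tolerance = 1e-3)
  expect_lt(g, 300)
  expect_equal(b_to_gradient(0), 0)
  b <- c(0.05, 1.5, 6)
  expect_equal(gradient_to_b(b_to_gradient(b)), b, tolerance = 1e-10)
  expect_error(b_to_gradient(1, delta = -1), "positive")
})

test_that("NIfTI roundtrip preserves data and dimension mismatches are caught", {
  arr <- array(rnorm(2 * 2 * 2 * 3), c(2, 2, 2, 3))
  nii <- tempfile(fileext = ".nii.gz")
  bval <- tempfile(); bvec <- tempfile()
  writeLines("0 800 800", bval)
  writeLines(c("0 1 0", "0 0 1", "0 0 0"), bvec)
  write_dwi(arr, nii)
  x <- load_dwi(nii, bval, bvec)
  expect_equal(dim(x$data), dim(arr))
  expect_equal(as.vector(x$data), as.vector(arr), tolerance = 1e-6)
  writeLines("0 800", bval)
  writeLines(c("0 1", "0 0", "0 0"), bvec)
  expect_error(load_dwi(nii, bval, bvec), "3 volumes.*2 entries")
})
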