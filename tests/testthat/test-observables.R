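test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  two <- rbind(c(0, 0, 0), c(0.2, 0, 0))
  expect_equal(radius_of_gyration(two), 0.1)
  # mass weighting shifts the com
  expect_equal(radius_of_gyration(two, masses = c(3, 1)),
               sqrt((3 * 0.05^2 + 1 * 0.15^2) / 4))
  # uniform ball: Rg = sqrt(3/5) R
  set.seed(1)
  n <- 1e5
  r <- 2 * (stats::runif(n))^(1/3)
  z <- stats::runif(n, -1, 1); phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  pts <- r * cbind(s * cos(phi), s * sin(phi), z)
  expect_equal(radius_of_gyration(pts), sqrt(3/5) * 2, tolerance = 0.01)
})

test_that("Kabsch RMSD removes rigid motion and keeps real deviations", {
  set.seed(3)
  A <- matrix(stats::rnorm(45), ncol = 3)
  expect_equal(kabsch_rmsd(A, A), 0)
  R <- ffbalance:::.random_rotation()
  B <- sweep(A %*% t(R), 2, c(1, -2, 0.5), "+")
  expect_lt(kabsch_rmsd(B, A), 1e-9)
  # one atom displaced by d among M atoms, alignment disabled: d / sqrt(M)
  C <- A; C[4, ] <- C[4, ] + c(0.3, 0, 0)
  expect_equal(kabsch_rmsd(C, A, superpose = FALSE), 0.3 / sqrt(nrow(A)))
  expect_error(kabsch_superpose(matrix(0, 3, 3), matrix(0, 3, 3)), "degenerate")
})

test_that("RMSF sees only internal motion, not global tumbling", {
  set.seed(8)
  base <- matrix(stats::rnorm(30), ncol = 3)
  frames <- lapply(1:40, function(i) {
    x <- base
    x[1, ] <- x[1, ] + stats::rnorm(3, sd = 0.05)  # one mobile atom
    x %*% t(ffbalance:::.random_rotation())
  })
  traj <- ff_trajectory(frames)
  f <- rmsf(traj)
  expect_equal(which.max(f), 1)
  expect_lt(stats::median(f[-1]), 0.02)
})

test_that("Debye scattering matches its analytic limits", {
  xyz <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  q <- c(0, seq(0.1, 5, by = 0.1))
  curve <- debye_saxs(xyz, q, f = 2)
  expect_equal(curve$I[1], (2 + 2)^2)               # q -> 0: (sum f)^2
  closed <- 2 * 4 * (1 + ifelse(q == 0, 1, sin(q * 0.5) / (q * 0.5)))
  expect_equal(curve$I, closed, tolerance = 1e-9)
  # single atom: f^2 flat
  one <- debye_saxs(matrix(0, 1, 3), q, f = 3)
  expect_equal(one$I, rep(9, length(q)))
  # relabeling symmetry
  set.seed(2)
  pts <- matrix(stats::rnorm(30), ncol = 3)
  c1 <- debye_saxs(pts, q)
  c2 <- debye_saxs(pts[sample(10), ], q)
  expect_equal(c1$I, c2$I, tolerance = 1e-9)
  expect_true(all(c1$I > 0))
})

test_that("Guinier analysis recovers known radii of gyration", {
  # exact Gaussian curve
  q <- seq(0.01, 2, by = 0.01)
  g <- guinier_rg(data.frame(q = q, I = 50 * exp(-q^2 * 1.27^2 / 3)))
  expect_equal(g$rg, 1.27, tolerance = 1e-6)
  expect_equal(g$i0, 50, tolerance = 1e-6)
  # analytic sphere form factor, radius R: Rg within 2% of sqrt(3/5) R
  R <- 2
  qs <- seq(0.02, 1.2, by = 0.02)
  x <- qs * R
  sphere <- data.frame(q = qs, I = (3 * (sin(x) - x * cos(x)) / x^3)^2)
  gs <- guinier_rg(sphere)
  expect_equal(gs$rg, sqrt(3/5) * R, tolerance = 0.02)
  # Debye curve of a rigid two-atom molecule vs geometric Rg
  two <- rbind(c(0, 0, 0), c(0.4, 0, 0))
  rg_geo <- radius_of_gyration(two)
  qg <- seq(0.05, 1.3 / rg_geo, length.out = 40)
  gt <- guinier_rg(debye_saxs(two, qg), qrg_max = 1.0)
  expect_equal(gt$rg, rg_geo, tolerance = 0.05)
  expect_error(guinier_rg(data.frame(q = qs, I = -sphere$I)), "non-positive")
})

test_that("Guinier of a Debye curve agrees with the direct second moment", {
  for (seed in c(3, 7)) {
    fr <- get_frame(gaussian_chain(60, 0.38, seed = seed), 1)
    rg <- radius_of_gyration(fr)
    qs <- seq(0.02, 1.0 / rg, length.out = 50)
    fit <- guinier_rg(debye_saxs(fr, qs), qrg_max = 1.0)
    expect_equal(fit$rg, rg, tolerance = 0.03)
  }
})

test_that("secondary shift differences discriminate helix from coil", {
  rc <- random_coil_shifts("AQGA")
  obs <- rc
  d0 <- secondary_shift_delta(obs, rc)
  expect_equal(d0$delta, rep(0, 4))
  # +2 ppm Ca, -1 ppm Cb => +3 ppm (helical sign)
  obs$ca <- obs$ca + 2
  obs$cb <- obs$cb - 1
  d <- secondary_shift_delta(obs, rc)
  expect_equal(d$delta[!d$gly_ca_only], rep(3, 3))
  # glycine: Ca-only, flagged
  expect_true(d$gly_ca_only[3])
  expect_equal(d$delta[3], 2)
  # order independence
  sh <- obs[c(3, 1, 4, 2), ]
  expect_error(secondary_shift_delta(shift_table(sh$resid[order(sh$resid)],
    sh$resname[order(sh$resid)], sh$ca[order(sh$resid)], sh$cb[order(sh$resid)]),
    rc), NA)
  # residue mismatch is an error naming the row
  rc_bad <- rc; rc_bad$resname[2] <- "ALA"
  expect_error(secondary_shift_delta(obs, rc_bad), "2\\(GLN\\)")
})

test_that("the agreement statistic is the root mean squared deviation", {
  expect_equal(agreement_rmsd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(agreement_rmsd(c(4, 5), c(3, 4)), 1)           # constant offset d
  expect_equal(agreement_rmsd(c(1, 2, 3), c(1, 2, 5)), sqrt(4 / 3))
  expect_error(agreement_rmsd(setNames(1:3, letters[1:3]),
                              setNames(1:3, letters[2:4])), "label")
})

test_that("Kabsch RMSD agrees with an independent superposition engine", {
  set.seed(21)
  A <- matrix(stats::rnorm(60), ncol = 3)
  B <- A + matrix(stats::rnorm(60, sd = 0.05), ncol = 3)
  ours <- kabsch_rmsd(B, A)
  fitted <- suppressWarnings(bio3d::fit.xyz(as.vector(t(A)), as.vector(t(B))))
  theirs <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - A)^2)))
  expect_equal(ours, theirs, tolerance = 1e-9)
})
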