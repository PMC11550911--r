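test_that("centroid size follows its definition and scales linearly", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(square), sqrt(2))
  expect_equal(centroid_size(3 * square), 3 * sqrt(2))
  # brute-force recomputation on a generated template
  lms <- simulate_landmarks(2, 3, 1, 1, seed = 2)$landmarks
  x <- lms$coords[, , 1]
  brute <- sqrt(sum((x[, 1] - mean(x[, 1]))^2 + (x[, 2] - mean(x[, 2]))^2))
  expect_equal(centroid_size(x), brute)
  expect_error(centroid_size(matrix(1, 4, 2)), "degenerate")
})

test_that("GPA removes rotation, translation and scale", {
  lms <- simulate_landmarks(2, 6, 1, 1, seed = 31)$landmarks
  moved <- transform_landmarks(lms)
  a1 <- gpa_align(lms)
  a2 <- gpa_align(moved)
  expect_lt(aligned_rms(a1, a2), 1e-6)
  # two identical shapes, one rotated and translated: Procrustes distance 0
  x <- lms$coords[, , 1]
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  coords <- array(c(x, x %*% R + 5), dim = c(nrow(x), 2, 2))
  pair <- landmark_set(coords)
  ap <- gpa_align(pair)
  expect_lt(sqrt(sum((ap$aligned[, , 1] - ap$aligned[, , 2])^2)), 1e-10)
  # consensus invariants
  expect_lt(max(abs(colMeans(a1$consensus))), 1e-10)
  expect_equal(sqrt(sum(a1$consensus^2)), 1, tolerance = 1e-10)
})

test_that("semilandmark sliding removes tangential-only displacement", {
  base <- simulate_landmarks(2, 10, 0, 0, iso_noise = 0, seed = 7)$landmarks
  coords <- base$coords
  roles <- base$roles
  set.seed(42)
  for (i in seq_len(dim(coords)[3])) {
    for (j in which(roles$role == "sliding")) {
      chord <- coords[roles$after[j], , i] - coords[roles$before[j], , i]
      chord <- chord / sqrt(sum(chord^2))
      coords[j, , i] <- coords[j, , i] + rnorm(1, 0, 0.08) * chord
    }
  }
  shifted <- landmark_set(coords, base$info, roles)
  pvar <- function(a) {
    dev <- sweep(a$aligned, c(1, 2), a$consensus)
    sum(dev^2) / dim(a$aligned)[3]
  }
  off <- pvar(gpa_align(shifted, slide = FALSE))
  on <- pvar(gpa_align(shifted, slide = TRUE))
  expect_lt(on, off)
  expect_lt(on, 0.2 * off)  # tangential noise is almost entirely absorbed
})

test_that("relative warps decompose aligned variation exactly", {
  sim <- simulate_landmarks(4, 12, 2, 1, iso_noise = 1e-4, seed = 13)
  a <- gpa_align(sim$landmarks)
  rw <- relative_warps(a)
  expect_equal(sum(rw$pct_variance), 100, tolerance = 1e-6)
  expect_true(all(diff(rw$pct_variance) <= 1e-12))
  # one planted deformation axis, low jitter: RW1 dominates
  expect_gt(rw$pct_variance[1], 90)
  # orthonormal reconstruction of the aligned deviations
  k <- dim(a$aligned)[1]
  n <- dim(a$aligned)[3]
  flat <- t(vapply(seq_len(n), function(i) as.vector(a$aligned[, , i]),
                   numeric(2 * k)))
  dev <- sweep(flat, 2, as.vector(a$consensus))
  dev <- sweep(dev, 2, rw$center)
  recon <- rw$scores %*% rw$loadings
  expect_lt(max(abs(recon - dev)), 1e-8)
  # sign convention: largest-|loading| entry positive on every axis
  for (j in seq_len(nrow(rw$loadings))) {
    expect_gt(rw$loadings[j, which.max(abs(rw$loadings[j, ]))], 0)
  }
  expect_error(relative_warps(gpa_align(landmark_set(
    sim$landmarks$coords[, , 1:2, drop = FALSE]
  ))), "3 specimens")
})

test_that("pure-noise shapes give a flat relative-warp spectrum", {
  sim <- simulate_landmarks(3, 40, 0, 0, iso_noise = 0.05, seed = 17)
  rw <- relative_warps(gpa_align(sim$landmarks))
  expect_lt(rw$pct_variance[1], 3 * mean(rw$pct_variance))
})

test_that("thin-plate spline interpolates exactly with affine null space", {
  set.seed(5)
  ref <- cbind(runif(10), runif(10))
  # identity
  g0 <- tps_grid(ref, ref)
  expect_lt(max(abs(g0$mapped_landmarks - ref)), 1e-8)
  expect_lt(max(abs(cbind(g0$grid$x_def, g0$grid$y_def) -
                      cbind(g0$grid$x, g0$grid$y))), 1e-8)
  # affine-only deformation has zero bending energy
  A <- matrix(c(1.3, 0.2, -0.1, 0.8), 2, 2)
  ga <- tps_grid(ref, ref %*% A + 1)
  expect_lt(abs(ga$bending_energy), 1e-8)
  # random target: exact interpolation at landmarks, positive bending
  tgt <- ref + matrix(rnorm(20, 0, 0.1), 10, 2)
  gr <- tps_grid(ref, tgt)
  expect_lt(max(abs(gr$mapped_landmarks - tgt)), 1e-8)
  expect_gt(gr$bending_energy, 0)
  expect_error(tps_grid(cbind(1:5, 2 * (1:5)), cbind(1:5, 1:5)), "singular")
})

test_that("repeatability ICC matches its ANOVA expectation", {
  # identical replicates, distinct specimens: perfect repeatability
  r <- matrix(rep(rnorm(10), 3), 10, 3)
  expect_equal(icc_repeatability(r)$icc, 1)
  # pure noise: ICC near zero on average over seeds
  set.seed(99)
  iccs <- replicate(200, icc_repeatability(matrix(rnorm(30), 10, 3))$icc)
  expect_lt(abs(mean(iccs)), 3 * stats::sd(iccs) / sqrt(200))
  # planted specimen variance 9x residual: expectation 9/(9+1) = 0.9
  set.seed(100)
  iccs9 <- replicate(200, {
    spec <- rnorm(10, 0, 3)
    icc_repeatability(matrix(spec, 10, 3) + matrix(rnorm(30), 10, 3))$icc
  })
  expect_lt(abs(mean(iccs9) - 0.9), 3 * stats::sd(iccs9) / sqrt(200) + 0.01)
  expect_error(icc_repeatability(matrix(c(1, NA, 2, 3, 4, 5), 3, 2)),
               "unbalanced")
})

test_that("MANCOVA with one response reproduces the ANCOVA F exactly", {
  set.seed(3)
  n <- 60
  cs <- runif(n, 1, 3)
  grp <- rep(c("a", "b", "c"), each = 20)
  y <- 0.4 * cs + c(a = 0, b = 0.6, c = 1)[grp] + rnorm(n)
  m <- mancova_shape(matrix(y, ncol = 1), cs, grp)
  fit <- anova(lm(y ~ cs + factor(grp)))
  expect_equal(m$statistic, fit[["F value"]][2], tolerance = 1e-8)
  expect_equal(m$p_value, fit[["Pr(>F)"]][2], tolerance = 1e-8)
})

test_that("MANCOVA p-values are uniform under label permutation", {
  set.seed(8)
  n <- 48
  cs <- runif(n, 1, 3)
  scores <- cbind(0.5 * cs + rnorm(n), rnorm(n), rnorm(n))
  grp <- rep(c("a", "b", "c"), each = 16)
  pvals <- replicate(400, {
    mancova_shape(scores, cs, sample(grp))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("MANCOVA detects a planted multivariate group shift", {
  set.seed(12)
  n <- 90
  cs <- runif(n, 1, 3)
  grp <- rep(c("a", "b", "c"), each = 30)
  shift <- c(a = 0, b = 2, c = 4)[grp]
  scores <- cbind(shift + rnorm(n), -shift + rnorm(n), rnorm(n))
  m <- mancova_shape(scores, cs, grp)
  expect_lt(m$p_value, 1e-6)
  expect_error(mancova_shape(scores, cs, rep("a", n)), "2 groups")
})

test_that("Tukey HSD matches the two-sample t-test and letters separate", {
  set.seed(21)
  v <- c(rnorm(15), rnorm(12, 0.8))
  g <- rep(c("x", "y"), c(15, 12))
  tk <- tukey_hsd(v, g)
  tt <- stats::t.test(v ~ g, var.equal = TRUE)
  expect_equal(tk$comparisons$p_adj, tt$p.value, tolerance = 1e-6)

  # all observations one constant: nothing distinguishable, one letter
  tk0 <- tukey_hsd(rep(2, 30), rep(c("a", "b", "c"), 10))
  expect_true(all(tk0$comparisons$p_adj == 1))
  expect_true(all(tk0$letters$letters == "a"))

  # overwhelming separation of the third group
  set.seed(22)
  v3 <- c(rnorm(30), rnorm(30), rnorm(30, 5))
  g3 <- rep(c("g1", "g2", "g3"), each = 30)
  tk3 <- tukey_hsd(v3, g3)
  lt <- setNames(tk3$letters$letters, tk3$letters$group)
  expect_equal(lt[["g1"]], lt[["g2"]])
  expect_false(lt[["g3"]] %in% lt[c("g1", "g2")])
  expect_error(tukey_hsd(c(1, 2, 3), c("a", "a", "b")), "2 observations")
})
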