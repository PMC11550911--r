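test_that("size adjustment removes exactly the linear size association", {
  set.seed(41)
  cs <- runif(100, 1, 4)
  # trait proportional to size collapses to the grand mean
  t2 <- 2 * cs
  expect_equal(size_adjust(t2, cs), rep(mean(t2), 100))
  # planted allometry: adjusted trait uncorrelated with size
  tr <- 0.8 * cs + rnorm(100)
  adj <- size_adjust(tr, cs)
  expect_lt(abs(stats::cor(adj, cs)), 1e-10)
  # independent trait barely moves
  t0 <- rnorm(100)
  expect_lt(max(abs(size_adjust(t0, cs) - t0)),
            abs(stats::coef(lm(t0 ~ cs))[2]) * diff(range(cs)) + 1e-12)
  expect_warning(size_adjust(t0, rep(2, 100)), "constant")
  expect_error(size_adjust(t0, cs[1:10]), "length")
})

test_that("variance components match hand-computed ANOVA values", {
  # two populations of constants: all variance is between
  tr <- c(rep(3, 10), rep(7, 10))
  pop <- rep(c("a", "b"), each = 10)
  vc <- variance_components(tr, pop)
  expect_equal(vc$sigma2_W, 0)
  expect_equal(vc$sigma2_B, (3 - 7)^2 / 2)  # = n * (a-b)^2/2 / n0, n0 = n
  # balanced planted recovery
  set.seed(42)
  est <- replicate(100, {
    mu <- rnorm(5, 0, sqrt(2))
    v <- variance_components(rep(mu, each = 30) + rnorm(150), rep(1:5, each = 30))
    c(v$sigma2_B, v$sigma2_W)
  })
  expect_lt(abs(mean(est[1, ]) - 2), 3 * stats::sd(est[1, ]) / 10)
  expect_lt(abs(mean(est[2, ]) - 1), 3 * stats::sd(est[2, ]) / 10)
  # identical distributions: sigma2_B below the null 95th percentile
  set.seed(43)
  null_b <- replicate(200, {
    variance_components(rnorm(100), rep(1:5, each = 20))$sigma2_B
  })
  v0 <- variance_components(rnorm(100), rep(1:5, each = 20))
  expect_lte(v0$sigma2_B, stats::quantile(null_b, 0.99))
  expect_error(variance_components(1:5, c(1, 1, 1, 1, 2)), "size 1")
})

test_that("the P_ST formula obeys its closed forms and limits", {
  expect_equal(pst(2, 1, 1), 0.5)
  expect_equal(pst(1, 1, 0.5), 0.2)
  expect_equal(pst(0, 1, c(0, 0.5, 1, 2)), rep(0, 4))
  expect_equal(pst(3, 0, c(0.1, 1, 2)), rep(1, 3))
  expect_equal(pst(3, 0, 0), 0)
  # strictly increasing in phi when both components positive
  curve <- pst(2, 1, seq(0, 2, 0.1))
  expect_true(all(diff(curve) > 0))
  expect_error(pst(0, 0, 1), "undefined")
  expect_error(pst(1, 1, -1), "phi")
})

test_that("trace is monotone with seeded deterministic bands", {
  set.seed(44)
  tr <- rep(rnorm(6, 0, 1), each = 20) + rnorm(120)
  pop <- rep(sprintf("p%d", 1:6), each = 20)
  t1 <- trace_pst(tr, pop, n_boot = 200, fst_global = 0.1, seed = 10)
  expect_true(all(diff(t1$trace$pst) >= 0))
  expect_true(all(diff(t1$trace$ci_lower) >= -1e-12))
  expect_true(all(t1$trace$ci_lower <= t1$trace$ci_upper + 1e-12))
  expect_true(all(t1$trace$pst >= 0 & t1$trace$pst <= 1))
  expect_equal(t1$trace$pst[1], 0)
  t2 <- trace_pst(tr, pop, n_boot = 200, fst_global = 0.1, seed = 10)
  expect_identical(t1$trace, t2$trace)
  expect_warning(trace_pst(tr, pop, n_boot = 50, seed = 1), "n_boot")
})

test_that("robustness flag separates strong divergence from the boundary", {
  pops <- rep(sprintf("p%02d", 1:12), each = 15)
  strong <- boundary <- logical(15)
  for (s in 1:15) {
    set.seed(900 + s)
    mu <- rnorm(12); mu <- (mu - mean(mu)) / sqrt(sum((mu - mean(mu))^2) / 11)
    # planted P_ST(1) = 0.5: sigma2_B = 2, sigma2_W = 1
    tr_s <- rep(mu * sqrt(2), each = 15) + rnorm(180)
    strong[s] <- trace_pst(tr_s, pops, n_boot = 200, fst_global = 0.118,
                           seed = s)$robust_flag
    # planted P_ST(1) = fst: sigma2_B = 2 * 0.118 / (1 - 0.118)
    tr_b <- rep(mu * sqrt(2 * 0.118 / (1 - 0.118)), each = 15) + rnorm(180)
    boundary[s] <- trace_pst(tr_b, pops, n_boot = 200, fst_global = 0.118,
                             seed = s)$robust_flag
  }
  expect_gte(mean(strong), 0.9)
  expect_lte(mean(boundary), 0.1)
})

test_that("bootstrap bands tighten as samples grow", {
  widths <- vapply(c(10, 30, 100), function(n) {
    set.seed(45)
    mu <- rnorm(6); mu <- (mu - mean(mu)) / sqrt(sum((mu - mean(mu))^2) / 5)
    tr <- rep(mu * sqrt(2), each = n) + rnorm(6 * n)
    t1 <- trace_pst(tr, rep(1:6, each = n), n_boot = 300, seed = 11)
    unname(t1$ci_1[2] - t1$ci_1[1])
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("pairwise P_ST reflects planted structure and symmetry", {
  set.seed(46)
  tr <- rnorm(120)
  pop <- rep(sprintf("p%d", 1:4), each = 30)
  # identical populations: all entries near zero (sigma2_B truncates at 0)
  p0 <- pairwise_pst(tr, pop)
  expect_equal(p0, t(p0))
  expect_true(all(diag(p0) == 0))
  expect_lt(max(p0), 0.2)
  # one population shifted by 10 SD dominates its row
  tr_shift <- tr + ifelse(pop == "p3", 10, 0)
  p1 <- pairwise_pst(tr_shift, pop)
  off <- p1["p3", setdiff(colnames(p1), "p3")]
  expect_true(all(off > 0.9))
  # invariant to input ordering
  idx <- sample(length(tr))
  p2 <- pairwise_pst(tr_shift[idx], pop[idx])
  expect_equal(p1, p2[rownames(p1), colnames(p1)])
})

test_that("P_ST-F_ST comparison delegates to a two-sided Mantel test", {
  set.seed(47)
  m <- as.matrix(dist(matrix(runif(24), 8)))
  dimnames(m) <- list(sprintf("p%d", 1:8), sprintf("p%d", 1:8))
  cmp <- compare_pst_fst(m, m, n_perm = 199, seed = 3)
  expect_equal(cmp$r, 1)
  expect_equal(cmp$alternative, "two.sided")
  m2 <- m; dimnames(m2) <- list(sprintf("q%d", 1:8), sprintf("q%d", 1:8))
  expect_error(compare_pst_fst(m, m2), "labels")
})

test_that("the landmark-to-P_ST pipeline recovers the planted index", {
  # frozen oracle from 40 end-to-end generator replicates at 12 x 15,
  # sigma2_B = 2, sigma2_W = 1: P_ST-hat mean 0.4655, SD 0.0432
  sim <- simulate_landmarks(12, 15, 2, 1, seed = 501)
  rw <- relative_warps(gpa_align(sim$landmarks, slide = TRUE))
  adj <- size_adjust(rw$scores[, 1], rw$centroid_size)
  vc <- variance_components(adj, rw$info$population)
  p_hat <- pst(vc$sigma2_B, vc$sigma2_W, 1)
  expect_lt(abs(p_hat - 0.4655), 4 * 0.0432)
})
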