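test_that("SNP filter retains exactly the enumerated survivor set", {
  s <- simulate_genotypes(3, 20, 10, 0.1, seed = 8)
  d <- degrade_genotypes(s$genotypes, locus_dropout = 0.2, ind_dropout = 0,
                         n_monomorphic = 1, n_multi_per_tag = 1,
                         n_low_maf = 2, seed = 9)
  fl <- filter_snps(d$genotypes)
  # enumerate survivors by applying each rule to the planted design:
  # degraded loci fall to the rule that degraded them, the extra tag SNP
  # loses one-per-tag (lower call rate than its host), clean loci survive
  planted_loci <- d$planted$item[d$planted$kind != "low_call_rate_individual"]
  expected <- setdiff(colnames(d$genotypes$genotypes), planted_loci)
  # a clean locus can still be legitimately monomorphic/low-MAF by chance;
  # remove any such from the expectation using the raw per-locus stats
  ls <- locus_stats(d$genotypes)
  chance <- ls$locus_id[ls$monomorphic |
                          (!is.na(ls$maf) & ls$maf < 0.05)]
  expected <- setdiff(expected, chance)
  expect_setequal(colnames(fl$genotypes$genotypes), expected)
  # every removed item appears under exactly one rule
  expect_equal(anyDuplicated(fl$report$item), 0)
  removed <- setdiff(colnames(d$genotypes$genotypes),
                     colnames(fl$genotypes$genotypes))
  expect_setequal(fl$report$item[fl$report$type == "locus"], removed)
  # planted degradations are caught by their intended rule
  rep_by_item <- setNames(fl$report$rule, fl$report$item)
  low_call <- d$planted$item[d$planted$kind == "low_call_rate_locus"]
  expect_true(all(rep_by_item[low_call] == "locus_call_rate"))
  mono <- d$planted$item[d$planted$kind == "monomorphic"]
  expect_true(all(rep_by_item[mono] == "monomorphic"))
  multi <- d$planted$item[d$planted$kind == "multi_per_tag"]
  expect_true(all(rep_by_item[multi] == "one_per_tag"))
})

test_that("zero thresholds leave a clean matrix untouched", {
  s <- simulate_genotypes(3, 30, 50, 0.1, seed = 12)
  ls <- locus_stats(s$genotypes)
  # the fixture must already pass every rule for identity to be expected
  expect_false(any(ls$monomorphic))
  fl <- filter_snps(s$genotypes, locus_call_min = 0, ind_call_min = 0,
                    maf_min = 0, one_per_tag = FALSE)
  expect_identical(fl$genotypes$genotypes, s$genotypes$genotypes)
  expect_equal(nrow(fl$report), 0)
})

test_that("an all-missing locus is removed and reported by call rate", {
  s <- simulate_genotypes(2, 10, 5, 0.1, seed = 3)
  gt <- s$genotypes$genotypes
  gt[, 3] <- NA_integer_
  fl <- filter_snps(genotype_matrix(gt, s$genotypes$locus_meta))
  expect_false(colnames(gt)[3] %in% colnames(fl$genotypes$genotypes))
  expect_equal(fl$report$rule[fl$report$item == colnames(gt)[3]],
               "locus_call_rate")
})

test_that("diversity statistics match their definitions and recover F_IS", {
  # fixed population: He = Ho = 0, F_IS undefined
  gt <- cbind(matrix(0L, 10, 3), matrix(2L, 10, 2))
  rownames(gt) <- sprintf("i%02d", 1:10)
  colnames(gt) <- sprintf("l%02d", 1:5)
  pm <- tibble::tibble(individual = rownames(gt), population = "p1")
  div <- diversity(genotype_matrix(gt), pm)
  expect_equal(div$he, 0)
  expect_equal(div$ho, 0)
  expect_true(is.na(div$fis))

  # Hardy-Weinberg generator: mean F_IS within 3 SE of 0
  s <- simulate_genotypes(4, 25, 800, 0.05, seed = 41)
  div_hw <- diversity(s$genotypes, s$popmap)
  se <- stats::sd(div_hw$fis) / sqrt(nrow(div_hw)) + 0.01
  expect_lt(abs(mean(div_hw$fis)), 3 * se)

  # planted heterozygote deficit of 0.1 recovers
  si <- simulate_genotypes(4, 30, 1500, 0.05, seed = 42, f_within = 0.1)
  div_f <- diversity(si$genotypes, si$popmap)
  expect_lt(abs(mean(div_f$fis) - 0.1), 0.03)
})

test_that("Weir-Cockerham theta matches limits and an independent oracle", {
  fx <- fixed_difference_genotypes()
  f <- wc_fst(fx$g, fx$pm)
  expect_equal(f$theta, 1)
  expect_true(all(abs(f$components$b) < 1e-12))
  expect_true(all(abs(f$components$c) < 1e-12))

  # one population split under two labels: theta within 3 bootstrap SE of 0
  s <- simulate_genotypes(2, 40, 400, 0, seed = 51)
  f0 <- bootstrap_fst_ci(wc_fst(s$genotypes, s$popmap), n_boot = 300,
                         seed = 4)
  expect_lt(abs(f0$theta), 3 * stats::sd(f0$boot_theta))

  # independent nested-ANOVA-on-alleles oracle on unbalanced missing data
  s2 <- simulate_genotypes(3, 12, 40, 0.15, seed = 52)
  gt <- s2$genotypes$genotypes
  set.seed(6)
  gt[sample(length(gt), 30)] <- NA_integer_
  pop <- s2$popmap$population
  ours <- wc_fst(genotype_matrix(gt), s2$popmap)$theta
  expect_equal(ours, naive_wc_theta(gt, pop), tolerance = 1e-10)

  # allele-label swap invariance, locus by locus
  gt_swap <- gt
  swap <- seq(1, ncol(gt), by = 2)
  gt_swap[, swap] <- 2L - gt_swap[, swap]
  expect_equal(wc_fst(genotype_matrix(gt_swap), s2$popmap)$theta, ours,
               tolerance = 1e-12)

  expect_error(wc_fst(fx$g, dplyr::mutate(fx$pm, population = "one")),
               "2 populations")
})

test_that("pairwise theta is symmetric with the expected structure", {
  s <- simulate_genotypes(4, 12, 200, 0.15, seed = 53)
  f <- wc_fst(s$genotypes, s$popmap, pairwise = TRUE)
  expect_equal(f$pairwise, t(f$pairwise))
  expect_true(all(diag(f$pairwise) == 0))
  expect_equal(dim(f$pairwise), c(4, 4))
})

test_that("bootstrap interval behaves at the extremes and is seeded", {
  fx <- fixed_difference_genotypes()
  f <- bootstrap_fst_ci(wc_fst(fx$g, fx$pm), n_boot = 200, seed = 9)
  expect_equal(unname(f$ci), c(1, 1))
  s <- simulate_genotypes(3, 15, 300, 0.1, seed = 55)
  b1 <- bootstrap_fst_ci(wc_fst(s$genotypes, s$popmap), n_boot = 200,
                         seed = 7)
  b2 <- bootstrap_fst_ci(wc_fst(s$genotypes, s$popmap), n_boot = 200,
                         seed = 7)
  expect_identical(b1$ci, b2$ci)
  expect_warning(
    bootstrap_fst_ci(wc_fst(
      fixed_difference_genotypes(n_loci = 10)$g,
      fixed_difference_genotypes(n_loci = 10)$pm
    ), n_boot = 50, seed = 1),
    "20 informative loci"
  )
})

test_that("null bootstrap intervals cover zero at the nominal rate", {
  covered <- vapply(1:30, function(s) {
    sim <- simulate_genotypes(4, 10, 200, 0, seed = 600 + s)
    f <- bootstrap_fst_ci(wc_fst(sim$genotypes, sim$popmap), n_boot = 200,
                          seed = s)
    f$ci[1] <= 0 && f$ci[2] >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("Mantel statistic and permutation p behave as specified", {
  set.seed(31)
  x <- matrix(runif(36), 6); d1 <- as.matrix(dist(x))
  r_same <- mantel(d1, d1, n_perm = 199, seed = 1)
  expect_equal(r_same$r, 1)
  expect_equal(r_same$p_value, 1 / 200)
  # perfectly anticorrelated off-diagonal structure
  d2 <- max(d1) + 1 - d1
  diag(d2) <- 0
  expect_equal(mantel(d1, d2, n_perm = 99, seed = 1)$r, -1)
  expect_error(mantel(d1, d1[1:5, 1:5]), "dimension")
  expect_error(mantel(d1, d1 + 1), "symmetric")
})

test_that("Mantel r agrees with an independent implementation", {
  set.seed(32)
  d1 <- as.matrix(dist(matrix(runif(30), 10)))
  d2 <- as.matrix(dist(matrix(runif(30), 10)))
  ours <- mantel(d1, d2, n_perm = 99, seed = 1)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("Mantel p-values are uniform under independence", {
  set.seed(77)
  pvals <- replicate(120, {
    d1 <- as.matrix(dist(matrix(runif(24), 8)))
    d2 <- as.matrix(dist(matrix(runif(24), 8)))
    mantel(d1, d2, n_perm = 99, seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("diversity contrast ranks a planted low-diversity population last", {
  # identical He vectors: nothing to detect
  he0 <- tibble::tibble(
    locus_id = rep(sprintf("l%d", 1:50), 3),
    population = rep(c("a", "b", "c"), each = 50),
    he = rep(runif(50, 0.1, 0.4), 3)
  )
  dc0 <- diversity_contrast(he0)
  expect_gt(dc0$kruskal$p_value, 0.99)
  expect_true(all(dc0$dunn$p_adj > 0.99))

  # population with stronger drift (higher F) has lower He
  s_lo <- simulate_genotypes(2, 20, 400, 0.45, seed = 81)
  s_hi <- simulate_genotypes(3, 20, 400, 0.02, seed = 82)
  gt <- rbind(s_lo$genotypes$genotypes[1:20, ],
              s_hi$genotypes$genotypes)
  rownames(gt) <- sprintf("i%03d", seq_len(nrow(gt)))
  pm <- tibble::tibble(
    individual = rownames(gt),
    population = rep(c("drifted", "p1", "p2", "p3"), each = 20)
  )
  he <- he_by_locus(genotype_matrix(gt), pm)
  dc <- diversity_contrast(he)
  worst <- dc$dunn[which.min(dc$dunn$p_adj), ]
  expect_true("drifted" %in% c(worst$pop1, worst$pop2))
})

test_that("cluster assignments are invariant to individual ordering", {
  s <- simulate_genotypes(3, 20, 300, 0.3, seed = 91)
  d1 <- dapc_cluster(s$genotypes, k_max = 5, seed = 5)
  perm <- sample(nrow(s$genotypes$genotypes))
  g2 <- genotype_matrix(s$genotypes$genotypes[perm, ],
                        s$genotypes$locus_meta)
  d2 <- dapc_cluster(g2, k_max = 5, seed = 5)
  expect_equal(d1$best_k, d2$best_k)
  m <- dplyr::inner_join(d1$assignments, d2$assignments, by = "individual")
  # same partition up to label permutation
  expect_equal(length(unique(paste(m$cluster.x, m$cluster.y))),
               d1$best_k)
  expect_error(dapc_cluster(s$genotypes, k_max = 60), "k_max")
})

test_that("diversity-distance regression guards and recovers a gradient", {
  set.seed(14)
  div <- tibble::tibble(
    population = sprintf("p%d", 1:8),
    he = 0.25 - 0.01 * (1:8) + rnorm(8, 0, 0.002)
  )
  pm <- tibble::tibble(
    population = sprintf("p%d", 1:8),
    individual = sprintf("i%d", 1:8),
    lat = -20 - (1:8) * 0.9, lon = rep(146, 8)
  )
  reg <- he_distance_regression(div, pm, origin = c(146, -19.25))
  expect_lt(reg$p_value, 0.05)
  expect_lt(reg$slope, 0)
  # constant diversity: flat line, p = 1
  div0 <- dplyr::mutate(div, he = 0.2)
  reg0 <- he_distance_regression(div0, pm, origin = c(146, -19.25))
  expect_equal(reg0$slope, 0)
  expect_equal(reg0$p_value, 1)
  # two populations leave no residual degrees of freedom
  expect_error(
    he_distance_regression(div[1:2, ], pm[1:2, ], origin = c(146, -19.25)),
    "3 populations"
  )
  expect_error(
    he_distance_regression(div, dplyr::mutate(pm, lat = NA_real_),
                           origin = c(146, -19.25)),
    "missing coordinates"
  )
})
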