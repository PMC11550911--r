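# Shared fixtures and independent oracles used across the test files.

# Two populations fixed for alternate alleles: theta must be exactly 1.
fixed_difference_genotypes <- function(n_per_pop = 10, n_loci = 50) {
  gt <- rbind(
    matrix(0L, n_per_pop, n_loci),
    matrix(2L, n_per_pop, n_loci)
  )
  rownames(gt) <- sprintf("i%03d", seq_len(2 * n_per_pop))
  colnames(gt) <- sprintf("l%03d", seq_len(n_loci))
  list(
    g = genotype_matrix(gt),
    pm = tibble::tibble(
      individual = rownames(gt),
      population = rep(c("popA", "popB"), each = n_per_pop)
    )
  )
}

# Independent Weir-Cockerham theta oracle via the nested ANOVA-on-alleles
# route: each diploid is expanded to two allele values and theta is built
# from the among-population / among-individual / within-individual mean
# squares. A different computational path from the package's moment
# estimator on per-population frequencies.
naive_wc_theta <- function(gt, pop) {
  num <- 0
  den <- 0
  for (j in seq_len(ncol(gt))) {
    keep <- !is.na(gt[, j])
    if (sum(keep) < 2) next
    g <- gt[keep, j]
    p <- pop[keep]
    if (length(unique(p)) < 2) next
    # allele table: one row per allele copy
    alleles <- c(ifelse(g >= 1, 1, 0), ifelse(g == 2, 1, 0))
    ind <- factor(rep(seq_along(g), 2), levels = seq_along(g))
    popa <- factor(rep(p, 2))
    ni <- table(factor(p, levels = levels(popa)))
    r <- length(ni)
    N <- sum(ni)
    nc <- (N - sum(ni^2) / N) / (r - 1)
    ybar <- mean(alleles)
    pop_means <- tapply(alleles, popa, mean)     # level order, matches ni
    ind_means <- tapply(alleles, ind, mean)      # 1..N order
    ms_p <- sum(2 * as.numeric(ni) * (pop_means - ybar)^2) / (r - 1)
    # among individuals within populations
    ss_i <- sum(2 * (ind_means - pop_means[factor(p)])^2)
    ms_i <- ss_i / (N - r)
    ss_g <- sum((alleles - ind_means[ind])^2)
    ms_g <- ss_g / N
    a <- (ms_p - ms_i) / (2 * nc)
    b <- (ms_i - ms_g) / 2
    cc <- ms_g
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Brute-force percent p-distance with pairwise deletion, character by
# character (independent of the package's vectorised resolution masking).
brute_pdist <- function(s1, s2) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  100 * sum(a[ok] != b[ok]) / sum(ok)
}

# Small aligned-sequence fixture with known differences.
seq_pair_with_diffs <- function(len = 612, n_diff = 6) {
  base <- paste(rep(c("A", "C", "G", "T"), length.out = len), collapse = "")
  s2 <- strsplit(base, "")[[1]]
  s2[seq_len(n_diff)] <- ifelse(s2[seq_len(n_diff)] == "A", "G", "A")
  c(one = base, two = paste(s2, collapse = ""))
}

# Deterministic rotation/translation/scale of every configuration.
transform_landmarks <- function(lms, angle = pi / 3, scale = 2.5,
                                shift = c(10, -4)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  coords <- lms$coords
  for (i in seq_len(dim(coords)[3])) {
    coords[, , i] <- scale * coords[, , i] %*% R +
      matrix(shift, nrow(coords), 2, byrow = TRUE)
  }
  landmark_set(coords, lms$info, lms$roles)
}
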