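# SNP quality control, diversity, Weir-Cockerham F_ST, isolation by
# distance, diversity contrasts, and BIC-selected clustering.

#' Filter a SNP matrix
#'
#' Applies, in order: locus call-rate filter, individual call-rate filter,
#' recomputation of locus statistics on the retained individuals, minor
#' allele frequency filter, monomorphic-locus removal, and one SNP per
#' sequence tag (keeping the highest call rate, ties broken by lowest
#' position). The removal report assigns every removed item to exactly one
#' rule (the first that removed it).
#'
#' @param g a [genotype_matrix()].
#' @param locus_call_min minimum locus call rate (default 0.95).
#' @param ind_call_min minimum individual call rate (default 0.85).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param one_per_tag keep a single SNP per tag ID (default TRUE).
#' @return List of class `snp_filter`: `genotypes` (filtered
#'   [genotype_matrix()]) and `report` (tibble: item, type, rule).
#' @export
filter_snps <- function(g, locus_call_min = 0.95, ind_call_min = 0.85,
                        maf_min = 0.05, one_per_tag = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  check_number(locus_call_min, "locus_call_min", 0, 1)
  check_number(ind_call_min, "ind_call_min", 0, 1)
  check_number(maf_min, "maf_min", 0, 0.5)
  report <- tibble(item = character(), type = character(), rule = character())
  log_rm <- function(items, type, rule) {
    if (length(items)) {
      report <<- bind_rows(report, tibble(item = items, type = type,
                                          rule = rule))
    }
  }
  cur <- g
  # 1. locus call rate
  ls <- locus_stats(cur)
  drop <- ls$locus_id[ls$call_rate < locus_call_min]
  log_rm(drop, "locus", "locus_call_rate")
  cur <- subset_genotypes(cur, loci = setdiff(ls$locus_id, drop))
  # 2. individual call rate
  is <- individual_stats(cur)
  drop_i <- is$individual[is$call_rate < ind_call_min]
  log_rm(drop_i, "individual", "individual_call_rate")
  cur <- subset_genotypes(cur, individuals = setdiff(is$individual, drop_i))
  if (nrow(cur$genotypes) == 0) {
    warn("all individuals removed by call-rate filtering")
    return(structure(list(genotypes = cur, report = report),
                     class = "snp_filter"))
  }
  # 3. recompute locus stats, then MAF filter
  ls <- locus_stats(cur)
  drop <- ls$locus_id[!is.na(ls$maf) & ls$maf < maf_min & !ls$monomorphic]
  log_rm(drop, "locus", "maf")
  cur <- subset_genotypes(cur, loci = setdiff(ls$locus_id, drop))
  # 4. monomorphic removal (also catches all-missing loci left over)
  ls <- locus_stats(cur)
  drop <- ls$locus_id[ls$monomorphic | ls$call_rate == 0]
  log_rm(drop, "locus", "monomorphic")
  cur <- subset_genotypes(cur, loci = setdiff(ls$locus_id, drop))
  # 5. one SNP per tag
  if (one_per_tag && ncol(cur$genotypes) > 0) {
    ls <- locus_stats(cur)
    keep <- ls %>%
      arrange(.data$tag_id, dplyr::desc(.data$call_rate), .data$position) %>%
      group_by(.data$tag_id) %>%
      dplyr::slice(1) %>%
      ungroup() %>%
      pull("locus_id")
    drop <- setdiff(ls$locus_id, keep)
    log_rm(drop, "locus", "one_per_tag")
    cur <- subset_genotypes(cur, loci = intersect(ls$locus_id, keep))
  }
  if (ncol(cur$genotypes) == 0) warn("no loci retained by filtering")
  structure(list(genotypes = cur, report = report), class = "snp_filter")
}

#' @export
print.snp_filter <- function(x, ...) {
  cat(sprintf("<snp_filter> retained %d individuals x %d loci; removed:\n",
              nrow(x$genotypes$genotypes), ncol(x$genotypes$genotypes)))
  if (nrow(x$report)) print(dplyr::count(x$report, .data$rule))
  invisible(x)
}

#' @export
tidy.snp_filter <- function(x, ...) x$report

# per population per locus allele frequency, het proportion and sample size
pop_locus_stats <- function(gt, pop) {
  upop <- unique(pop)
  L <- ncol(gt)
  res <- list()
  for (p in upop) {
    sub <- gt[pop == p, , drop = FALSE]
    n_called <- colSums(!is.na(sub))
    phat <- colSums(sub, na.rm = TRUE) / (2 * pmax(n_called, 1L))
    phat[n_called == 0] <- NA_real_
    het <- colSums(sub == 1L, na.rm = TRUE) / pmax(n_called, 1L)
    het[n_called == 0] <- NA_real_
    res[[p]] <- list(n = n_called, p = phat, h = het)
  }
  res
}

#' Within-population diversity
#'
#' Observed heterozygosity (Ho), Nei's unbiased expected heterozygosity
#' (He = 2pq * 2n/(2n-1)) and the inbreeding coefficient
#' F_IS = 1 - mean(Ho)/mean(He), per population, with standard errors over
#' loci.
#'
#' @param g a filtered [genotype_matrix()].
#' @param pm population map (see [as_popmap()]).
#' @return Tibble of class `diversity_table`: population, n, he, he_se, ho,
#'   ho_se, fis.
#' @export
diversity <- function(g, pm) {
  stopifnot(inherits(g, "genotype_matrix"))
  pm <- as_popmap(pm, rownames(g$genotypes))
  gt <- g$genotypes
  pop <- pm$population[match(rownames(gt), pm$individual)]
  st <- pop_locus_stats(gt, pop)
  rows <- lapply(names(st), function(p) {
    s <- st[[p]]
    ok <- !is.na(s$p) & s$n >= 2
    if (!any(ok)) {
      warn(sprintf("population %s has < 2 called individuals at all loci", p))
      return(NULL)
    }
    he <- 2 * s$p[ok] * (1 - s$p[ok]) * (2 * s$n[ok]) / (2 * s$n[ok] - 1)
    ho <- s$h[ok]
    mean_he <- mean(he)
    fis <- if (mean_he > 0) 1 - mean(ho) / mean_he else NA_real_
    tibble(
      population = p,
      n = max(s$n),
      he = mean_he, he_se = sd(he) / sqrt(length(he)),
      ho = mean(ho), ho_se = sd(ho) / sqrt(length(ho)),
      fis = fis
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("diversity_table", class(out))
  out
}

#' Per-locus expected heterozygosity by population
#'
#' He per locus per population (Nei's unbiased), as input for
#' [diversity_contrast()].
#'
#' @inheritParams diversity
#' @return Tibble: locus_id, population, he.
#' @export
he_by_locus <- function(g, pm) {
  stopifnot(inherits(g, "genotype_matrix"))
  pm <- as_popmap(pm, rownames(g$genotypes))
  gt <- g$genotypes
  pop <- pm$population[match(rownames(gt), pm$individual)]
  st <- pop_locus_stats(gt, pop)
  bind_rows(lapply(names(st), function(p) {
    s <- st[[p]]
    he <- ifelse(!is.na(s$p) & s$n >= 2,
                 2 * s$p * (1 - s$p) * (2 * s$n) / (2 * s$n - 1), NA_real_)
    tibble(locus_id = colnames(gt), population = p, he = he)
  }))
}

# Weir & Cockerham (1984) per-locus variance components for one biallelic
# locus: a (among populations), b (among individuals within), c (within
# individuals), from per-population n, allele frequency and het proportion.
wc_components <- function(n, p, h) {
  ok <- !is.na(p) & n >= 1
  n <- n[ok]; p <- p[ok]; h <- h[ok]
  r <- length(n)
  if (r < 2 || sum(n) == 0) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  if (nbar <= 1 || nc <= 0) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Weir-Cockerham F_ST
#'
#' Per-locus variance components a (among populations), b (among individuals
#' within populations) and c (within individuals) of Weir & Cockerham's 1984
#' theta, with unequal sample sizes and per-locus exclusion of missing
#' genotypes. The global estimate is the ratio of sums over informative
#' loci: theta = sum(a) / sum(a + b + c). Pairwise mode computes theta for
#' every population pair.
#'
#' @param g a filtered [genotype_matrix()].
#' @param pm population map.
#' @param pops optional character vector of exactly two populations to
#'   restrict to (pairwise mode for one pair).
#' @param pairwise compute the full pairwise theta matrix too.
#' @return Object of class `fst_result`: `components` (tibble: locus_id, a,
#'   b, c, fst), `theta` (global), `pairwise` (matrix or NULL), `n_loci_used`.
#' @export
wc_fst <- function(g, pm, pops = NULL, pairwise = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  pm <- as_popmap(pm, rownames(g$genotypes))
  gt <- g$genotypes
  pop <- pm$population[match(rownames(gt), pm$individual)]
  if (!is.null(pops)) {
    stopifnot(length(pops) >= 2)
    keep <- pop %in% pops
    gt <- gt[keep, , drop = FALSE]
    pop <- pop[keep]
  }
  if (length(unique(pop)) < 2) abort("need >= 2 populations")
  core <- wc_theta_core(gt, pop)
  pw <- NULL
  if (pairwise) {
    upop <- sort(unique(pop))
    pw <- matrix(0, length(upop), length(upop),
                 dimnames = list(upop, upop))
    for (i in seq_along(upop)) {
      for (j in seq_along(upop)) {
        if (j <= i) next
        keep <- pop %in% upop[c(i, j)]
        sub <- wc_theta_core(gt[keep, , drop = FALSE], pop[keep])
        pw[i, j] <- pw[j, i] <- sub$theta
      }
    }
  }
  structure(
    list(components = core$components, theta = core$theta, pairwise = pw,
         n_loci_used = core$n_loci_used, n_pops = length(unique(pop)),
         ci = NULL),
    class = "fst_result"
  )
}

wc_theta_core <- function(gt, pop) {
  st <- pop_locus_stats(gt, pop)
  L <- ncol(gt)
  nmat <- do.call(cbind, lapply(st, `[[`, "n"))
  pmat <- do.call(cbind, lapply(st, `[[`, "p"))
  hmat <- do.call(cbind, lapply(st, `[[`, "h"))
  comp <- t(vapply(seq_len(L), function(j) {
    wc_components(nmat[j, ], pmat[j, ], hmat[j, ])
  }, numeric(3)))
  tot <- rowSums(comp)
  informative <- !is.na(tot) & tot != 0
  theta <- if (any(informative)) {
    sum(comp[informative, 1]) / sum(tot[informative])
  } else {
    NA_real_
  }
  list(
    components = tibble(
      locus_id = colnames(gt),
      a = comp[, 1], b = comp[, 2], c = comp[, 3],
      fst = ifelse(informative, comp[, 1] / tot, NA_real_)
    ),
    theta = theta,
    n_loci_used = sum(informative)
  )
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result> global theta = %.4f over %d informative loci\n",
              x$theta, x$n_loci_used))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% bootstrap CI [%.4f, %.4f]\n", x$ci[1], x$ci[2]))
  }
  invisible(x)
}

#' @export
tidy.fst_result <- function(x, ...) x$components

#' @export
glance.fst_result <- function(x, ...) {
  tibble(
    theta = x$theta, n_loci_used = x$n_loci_used, n_pops = x$n_pops,
    ci_lower = if (is.null(x$ci)) NA_real_ else x$ci[1],
    ci_upper = if (is.null(x$ci)) NA_real_ else x$ci[2]
  )
}

#' Bootstrap confidence interval for theta
#'
#' Resamples loci with replacement and recomputes the ratio-of-sums theta;
#' percentile interval. Theta is deemed significantly positive when the
#' interval excludes zero.
#'
#' @param r an `fst_result`.
#' @param n_boot bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return The `fst_result` with `ci` (named vector lower/upper),
#'   `boot_theta` and `significant` filled in.
#' @export
bootstrap_fst_ci <- function(r, n_boot = 1000, level = 0.95, seed = 1L) {
  stopifnot(inherits(r, "fst_result"))
  comp <- r$components %>% filter(!is.na(.data$fst))
  L <- nrow(comp)
  if (L < 20) warn("fewer than 20 informative loci: interval is unstable")
  tot <- comp$a + comp$b + comp$c
  with_local_seed(seed, {
    bt <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(L, L, replace = TRUE)
      sum(comp$a[idx]) / sum(tot[idx])
    }, numeric(1))
    alpha <- (1 - level) / 2
    ci <- unname(quantile(bt, c(alpha, 1 - alpha), na.rm = TRUE))
    r$ci <- c(lower = ci[1], upper = ci[2])
    r$boot_theta <- bt
    r$significant <- ci[1] > 0
    r
  })
}

#' Mantel test
#'
#' Pearson correlation between the lower triangles of two distance matrices;
#' significance by joint row/column permutation. One-sided
#' (`alternative = "greater"`, the isolation-by-distance convention) or
#' two-sided. p = (1 + #{permuted statistic at least as extreme}) /
#' (n_perm + 1).
#'
#' @param d1,d2 symmetric matrices with zero diagonals, same dimension.
#' @param n_perm permutations (default 9999).
#' @param alternative "greater" (default) or "two.sided".
#' @param seed integer seed.
#' @return Tibble of class `mantel_test`: `r`, `p_value`, `n_perm`,
#'   `alternative`.
#' @export
mantel <- function(d1, d2, n_perm = 9999, alternative = c("greater", "two.sided"),
                   seed = 1L) {
  alternative <- match.arg(alternative)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2))) abort("dimension mismatch")
  if (!is_symmetric_zero_diag(d1) || !is_symmetric_zero_diag(d2)) {
    abort("inputs must be symmetric with zero diagonals")
  }
  v1 <- lower_vec(d1)
  v2 <- lower_vec(d2)
  if (sd(v1) == 0 || sd(v2) == 0) {
    warn("a distance matrix has zero variance: Mantel r is undefined")
    out <- tibble(r = NA_real_, p_value = NA_real_, n_perm = n_perm,
                  alternative = alternative)
    class(out) <- c("mantel_test", class(out))
    return(out)
  }
  r_obs <- cor(v1, v2)
  n <- nrow(d1)
  with_local_seed(seed, {
    r_perm <- vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n)
      # the observed ordering already contributes the +1; drawing it again
      # would double-count it
      while (all(idx == seq_len(n))) idx <- sample.int(n)
      cor(v1, lower_vec(d2[idx, idx]))
    }, numeric(1))
    hits <- if (alternative == "greater") {
      sum(r_perm >= r_obs)
    } else {
      sum(abs(r_perm) >= abs(r_obs))
    }
    out <- tibble(r = r_obs, p_value = (1 + hits) / (n_perm + 1),
                  n_perm = n_perm, alternative = alternative)
    class(out) <- c("mantel_test", class(out))
    out
  })
}

#' Kruskal-Wallis + Dunn pairwise contrasts of per-locus diversity
#'
#' Kruskal-Wallis test (midranks, tie-corrected) on per-locus expected
#' heterozygosity across populations, followed by Dunn's z for every
#' population pair with Benjamini-Hochberg adjustment.
#'
#' @param he_long tibble from [he_by_locus()] (columns population, he).
#' @return List of class `diversity_contrast`: `kruskal` (tibble: statistic,
#'   df, p_value) and `dunn` (tibble: pop1, pop2, z, p_value, p_adj).
#' @export
diversity_contrast <- function(he_long) {
  he_long <- he_long %>% filter(!is.na(.data$he))
  pops <- unique(he_long$population)
  if (length(pops) < 2) abort("need >= 2 populations")
  kw <- kruskal.test(he_long$he, factor(he_long$population))
  x <- he_long$he
  g <- factor(he_long$population)
  N <- length(x)
  rk <- rank(x)
  tie_tab <- table(rk)
  tie_corr <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  mean_rk <- tapply(rk, g, mean)
  n_g <- tapply(rk, g, length)
  pairs <- utils::combn(levels(g), 2)
  z <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    p1 <- pairs[1, j]; p2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 -
                  sum(tie_tab^3 - tie_tab) / (12 * (N - 1))) *
                 (1 / n_g[p1] + 1 / n_g[p2]))
    z[j] <- (mean_rk[p1] - mean_rk[p2]) / se
  }
  p <- 2 * pnorm(-abs(z))
  dunn <- tibble(
    pop1 = pairs[1, ], pop2 = pairs[2, ],
    z = z, p_value = p, p_adj = p.adjust(p, method = "BH")
  )
  structure(
    list(
      kruskal = tibble(statistic = unname(kw$statistic),
                       df = unname(kw$parameter),
                       p_value = kw$p.value, tie_correction = tie_corr),
      dunn = dunn
    ),
    class = "diversity_contrast"
  )
}

#' @export
tidy.diversity_contrast <- function(x, ...) x$dunn

#' @export
glance.diversity_contrast <- function(x, ...) x$kruskal

#' BIC-selected k-means clustering with discriminant axes
#'
#' Genotypes are mean-imputed, centred and scaled; k-means is run on the
#' leading principal components for k = 1..k_max (25 seeded restarts each);
#' BIC(k) = n log(WSS/n) + k log(n); the best k minimizes BIC. Linear
#' discriminant axes are computed on the retained PCs for the chosen
#' clustering.
#'
#' @param g a filtered [genotype_matrix()].
#' @param k_max maximum number of clusters tried (default 10).
#' @param n_pcs principal components to retain (default 40, capped at
#'   n_individuals - 1 and at the matrix rank).
#' @param seed integer seed.
#' @return Object of class `dapc_clusters`: `bic` (tibble: k, bic),
#'   `best_k`, `assignments` (tibble: individual, cluster), `scores`
#'   (discriminant scores, NULL when best_k = 1), `n_pcs`.
#' @export
dapc_cluster <- function(g, k_max = 10, n_pcs = 40, seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"))
  gt <- g$genotypes
  n <- nrow(gt)
  if (k_max >= n) abort("k_max must be smaller than the number of individuals")
  # mean imputation, centring, unit scaling of non-constant loci
  m <- apply(gt, 2, function(v) {
    mu <- mean(v, na.rm = TRUE)
    v[is.na(v)] <- mu
    v
  })
  sds <- apply(m, 2, sd)
  m <- m[, sds > 0, drop = FALSE]
  m <- scale(m)
  pc <- prcomp(m, center = FALSE, scale. = FALSE)
  n_pcs <- min(n_pcs, n - 1, sum(pc$sdev > 1e-10))
  X <- pc$x[, seq_len(n_pcs), drop = FALSE]
  with_local_seed(seed, {
    fits <- lapply(seq_len(k_max), function(k) {
      if (k == 1) {
        wss <- sum(scale(X, scale = FALSE)^2)
        list(cluster = rep(1L, n), wss = wss)
      } else {
        km <- kmeans(X, centers = k, nstart = 25, iter.max = 100)
        list(cluster = km$cluster, wss = km$tot.withinss)
      }
    })
    bic <- vapply(seq_len(k_max), function(k) {
      n * log(fits[[k]]$wss / n) + k * log(n)
    }, numeric(1))
    best_k <- which.min(bic)
    cl <- fits[[best_k]]$cluster
    scores <- NULL
    if (best_k > 1) {
      ld <- MASS::lda(X, grouping = factor(cl))
      scores <- as.matrix(X %*% ld$scaling)
      rownames(scores) <- rownames(gt)
    }
    structure(
      list(
        bic = tibble(k = seq_len(k_max), bic = bic),
        best_k = best_k,
        assignments = tibble(individual = rownames(gt),
                             cluster = unname(cl)),
        scores = scores, n_pcs = n_pcs
      ),
      class = "dapc_clusters"
    )
  })
}

#' @export
print.dapc_clusters <- function(x, ...) {
  cat(sprintf("<dapc_clusters> best k = %d (BIC), %d PCs retained\n",
              x$best_k, x$n_pcs))
  invisible(x)
}

#' @export
tidy.dapc_clusters <- function(x, ...) x$assignments

#' @export
glance.dapc_clusters <- function(x, ...) {
  tibble(best_k = x$best_k, n_pcs = x$n_pcs,
         bic_min = min(x$bic$bic))
}

#' Great-circle distance matrix between populations
#'
#' Haversine distances in kilometres between population coordinates.
#'
#' @param pm population map with `population`, `lat`, `lon`.
#' @return Symmetric matrix (km) over the unique populations.
#' @export
population_distances <- function(pm) {
  pm <- as_tibble(pm)
  stopifnot(all(c("population", "lat", "lon") %in% names(pm)))
  sites <- distinct(pm, .data$population, .data$lat, .data$lon)
  if (anyNA(sites$lat) || anyNA(sites$lon)) {
    bad <- sites$population[is.na(sites$lat) | is.na(sites$lon)]
    abort(paste("missing coordinates for:", paste(bad, collapse = ", ")))
  }
  n <- nrow(sites)
  d <- matrix(0, n, n, dimnames = list(sites$population, sites$population))
  for (i in seq_len(n)) {
    d[i, ] <- geosphere::distHaversine(
      c(sites$lon[i], sites$lat[i]),
      cbind(sites$lon, sites$lat)
    ) / 1000
  }
  (d + t(d)) / 2
}

#' Regression of diversity on distance from an origin
#'
#' Ordinary least squares of population expected heterozygosity on the
#' great-circle distance (km) to an origin site (e.g. the first release
#' site), with the F-test of the slope.
#'
#' @param div a `diversity_table` from [diversity()].
#' @param pm population map with coordinates.
#' @param origin numeric `c(lon, lat)` of the origin.
#' @return Tibble: slope, intercept, statistic (F), df1, df2, p_value, r_squared.
#' @export
he_distance_regression <- function(div, pm, origin) {
  stopifnot(length(origin) == 2)
  pm <- as_tibble(pm)
  sites <- distinct(pm, .data$population, .data$lat, .data$lon)
  dat <- left_join(div, sites, by = "population")
  if (anyNA(dat$lat) || anyNA(dat$lon)) {
    bad <- dat$population[is.na(dat$lat) | is.na(dat$lon)]
    abort(paste("missing coordinates for:", paste(bad, collapse = ", ")))
  }
  if (nrow(dat) < 3) {
    abort("need >= 3 populations for a slope F-test (df2 would be 0)")
  }
  dat$dist_km <- geosphere::distHaversine(
    origin, cbind(dat$lon, dat$lat)
  ) / 1000
  if (sd(dat$he) == 0) {
    # constant diversity: zero slope, nothing to test
    return(tibble(slope = 0, intercept = dat$he[1], statistic = 0,
                  df1 = 1L, df2 = nrow(dat) - 2L, p_value = 1,
                  r_squared = 0))
  }
  fit <- lm(he ~ dist_km, data = dat)
  an <- anova(fit)
  tibble(
    slope = coef(fit)[["dist_km"]],
    intercept = coef(fit)[["(Intercept)"]],
    statistic = an$`F value`[1],
    df1 = an$Df[1], df2 = an$Df[2],
    p_value = an$`Pr(>F)`[1],
    r_squared = summary(fit)$r.squared
  )
}
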