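# P_ST: phenotypic analogue of Q_ST from wild-population trait variances,
# swept over the c/h^2 ratio and compared against neutral F_ST.

#' Size-adjust a trait
#'
#' Removes the linear association of a trait with centroid size: ordinary
#' least squares of trait on CS across all specimens, adjusted value =
#' residual + grand mean. The adjusted trait has zero sample correlation
#' with CS.
#'
#' @param trait numeric per-specimen values.
#' @param cs positive centroid sizes, same length.
#' @return Numeric vector of adjusted values.
#' @export
size_adjust <- function(trait, cs) {
  if (length(trait) != length(cs)) abort("length mismatch")
  if (any(cs <= 0)) abort("centroid sizes must be positive")
  if (sd(cs) == 0) {
    warn("constant centroid size: returning trait unchanged")
    return(trait)
  }
  fit <- lm(trait ~ cs)
  unname(resid(fit) + mean(trait))
}

#' One-way random-effects variance components
#'
#' Between- and within-population variance of a trait from the one-way
#' ANOVA mean squares: sigma2_W = MS_within and
#' sigma2_B = max(0, (MS_between - MS_within) / n0) with
#' n0 = (N - sum(n_i^2)/N) / (k - 1) for unbalanced designs.
#'
#' @param trait numeric values (already size-adjusted if appropriate).
#' @param population population label per value; >= 2 populations with >= 2
#'   values each.
#' @return Named list: sigma2_B, sigma2_W, n0, ms_between, ms_within.
#' @export
variance_components <- function(trait, population) {
  population <- factor(population)
  if (nlevels(population) < 2) abort("need >= 2 populations")
  tab <- table(population)
  if (any(tab < 2)) {
    abort(paste("populations of size 1:",
                paste(names(tab)[tab < 2], collapse = ", ")))
  }
  N <- length(trait)
  k <- nlevels(population)
  grand <- mean(trait)
  means <- tapply(trait, population, mean)
  n_i <- as.numeric(tab)
  ss_b <- sum(n_i * (means - grand)^2)
  ss_w <- sum((trait - means[population])^2)
  ms_b <- ss_b / (k - 1)
  ms_w <- ss_w / (N - k)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  list(
    sigma2_B = max(0, (ms_b - ms_w) / n0),
    sigma2_W = ms_w,
    n0 = n0, ms_between = ms_b, ms_within = ms_w
  )
}

#' The P_ST index
#'
#' P_ST(phi) = phi * sigma2_B / (phi * sigma2_B + 2 * sigma2_W), with
#' phi = c / h^2 (c the fraction of between-population variance that is
#' additive-genetic, h^2 the narrow-sense heritability; only the ratio
#' enters). At phi = 1 this is sigma2_B / (sigma2_B + 2 sigma2_W), the
#' conventional "robust" case.
#'
#' @param sigma2_B,sigma2_W non-negative variances, not both zero.
#' @param phi c/h^2 ratio(s), >= 0; vectorized.
#' @return P_ST value(s) in [0, 1].
#' @export
pst <- function(sigma2_B, sigma2_W, phi = 1) {
  check_number(sigma2_B, "sigma2_B", 0)
  check_number(sigma2_W, "sigma2_W", 0)
  if (sigma2_B == 0 && sigma2_W == 0) {
    abort("both variance components are zero: P_ST undefined")
  }
  if (any(phi < 0)) abort("phi must be >= 0")
  num <- phi * sigma2_B
  den <- num + 2 * sigma2_W
  out <- ifelse(den == 0, ifelse(num > 0, 1, NaN), num / den)
  # sigma2_W = 0, sigma2_B > 0: P_ST = 1 for phi > 0, 0 at phi = 0
  out[phi == 0] <- 0
  out
}

#' P_ST trace over the c/h^2 ratio with bootstrap bands
#'
#' Computes the P_ST curve of a trait over a grid of phi = c/h^2 values,
#' with percentile bootstrap confidence bands obtained by resampling
#' individuals within populations and recomputing the variance components.
#' The robustness flag follows the usual decision rule for comparing trait
#' divergence with neutral differentiation: it is TRUE when the lower
#' confidence bound already exceeds the neutral F_ST at some phi below 1
#' (and stays above it up to phi = 1, which is automatic because every
#' bootstrap curve is non-decreasing in phi).
#'
#' @param trait per-specimen trait values (size-adjusted upstream if needed).
#' @param population population label per specimen.
#' @param phi_grid grid of c/h^2 values (default seq(0, 2, 0.01)).
#' @param n_boot bootstrap replicates (default 1000; < 100 warns).
#' @param fst_global neutral global F_ST in [0, 1] used by the robustness
#'   rule (optional; NA disables the flag).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @param trait_name label carried into the output.
#' @return Object of class `pst_trace`: `trace` (tibble: phi, pst, ci_lower,
#'   ci_upper), `sigma2_B`, `sigma2_W`, `pst_1` (point estimate at phi = 1),
#'   `ci_1` (CI at phi = 1), `robust_flag`, `fst_global`, `trait`.
#' @export
trace_pst <- function(trait, population, phi_grid = seq(0, 2, by = 0.01),
                      n_boot = 1000, fst_global = NA_real_, level = 0.95,
                      seed = 1L, trait_name = "trait") {
  if (n_boot < 100) warn("n_boot < 100: confidence bands will be unstable")
  if (!is.na(fst_global)) check_number(fst_global, "fst_global", 0, 1)
  population <- factor(population)
  vc <- variance_components(trait, population)
  curve <- pst(vc$sigma2_B, vc$sigma2_W, phi_grid)
  idx_by_pop <- split(seq_along(trait), population)
  with_local_seed(seed, {
    boot_vc <- matrix(NA_real_, n_boot, 2)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(idx_by_pop, function(ii) {
        sample(ii, length(ii), replace = TRUE)
      }), use.names = FALSE)
      v <- variance_components(trait[idx], population[idx])
      boot_vc[b, ] <- c(v$sigma2_B, v$sigma2_W)
    }
    alpha <- (1 - level) / 2
    # each bootstrap curve is the P_ST formula at the replicate's variance
    # components; percentile bands per grid point
    bands <- vapply(phi_grid, function(ph) {
      num <- ph * boot_vc[, 1]
      den <- num + 2 * boot_vc[, 2]
      v <- ifelse(den == 0, ifelse(num > 0, 1, NA_real_), num / den)
      if (ph == 0) v <- rep(0, length(v))
      quantile(v, c(alpha, 1 - alpha), na.rm = TRUE)
    }, numeric(2))
    trace <- tibble(
      phi = phi_grid, pst = curve,
      ci_lower = bands[1, ], ci_upper = bands[2, ]
    )
    robust <- NA
    if (!is.na(fst_global)) {
      below1 <- which(phi_grid > 0 & phi_grid < 1)
      robust <- length(below1) > 0 &&
        any(trace$ci_lower[below1] > fst_global)
    }
    at1 <- which.min(abs(phi_grid - 1))
    structure(
      list(
        trace = trace,
        sigma2_B = vc$sigma2_B, sigma2_W = vc$sigma2_W,
        pst_1 = curve[at1],
        ci_1 = c(lower = trace$ci_lower[at1], upper = trace$ci_upper[at1]),
        robust_flag = robust, fst_global = fst_global,
        trait = trait_name, n_boot = n_boot, level = level
      ),
      class = "pst_trace"
    )
  })
}

#' @export
print.pst_trace <- function(x, ...) {
  cat(sprintf(
    "<pst_trace> %s: P_ST(1) = %.3f [%.3f, %.3f]; sigma2_B = %.3g, sigma2_W = %.3g\n",
    x$trait, x$pst_1, x$ci_1[1], x$ci_1[2], x$sigma2_B, x$sigma2_W
  ))
  if (!is.na(x$fst_global)) {
    cat(sprintf("  vs F_ST = %.3f: robust divergence = %s\n",
                x$fst_global, x$robust_flag))
  }
  invisible(x)
}

#' @export
tidy.pst_trace <- function(x, ...) x$trace

#' @export
glance.pst_trace <- function(x, ...) {
  tibble(
    trait = x$trait, sigma2_B = x$sigma2_B, sigma2_W = x$sigma2_W,
    pst_1 = x$pst_1, ci_lower_1 = x$ci_1[1], ci_upper_1 = x$ci_1[2],
    fst_global = x$fst_global, robust_flag = x$robust_flag
  )
}

#' Pairwise P_ST matrix
#'
#' P_ST at a given phi from the two-population ANOVA for every population
#' pair. Pairs with zero total variance give missing entries.
#'
#' @param trait per-specimen trait values.
#' @param population population labels.
#' @param phi c/h^2 ratio (default 1).
#' @return Symmetric matrix with zero diagonal; NA for undefined pairs.
#' @export
pairwise_pst <- function(trait, population, phi = 1) {
  population <- factor(population)
  upop <- levels(population)
  m <- matrix(0, length(upop), length(upop), dimnames = list(upop, upop))
  for (i in seq_along(upop)) {
    for (j in seq_along(upop)) {
      if (j <= i) next
      sel <- population %in% upop[c(i, j)]
      vc <- variance_components(trait[sel], droplevels(population[sel]))
      v <- if (vc$sigma2_B == 0 && vc$sigma2_W == 0) {
        NA_real_
      } else {
        pst(vc$sigma2_B, vc$sigma2_W, phi)
      }
      m[i, j] <- m[j, i] <- v
    }
  }
  m
}

#' Mantel comparison of pairwise P_ST and F_ST
#'
#' Two-sided Mantel test between matched pairwise P_ST and F_ST matrices
#' (two-sided because both positive and negative correlations are
#' interpretable).
#'
#' @param pst_matrix,fst_matrix symmetric matrices over the same populations
#'   (matched dimnames).
#' @param n_perm permutations (default 9999).
#' @param seed integer seed.
#' @return A `mantel_test` tibble (see [mantel()]).
#' @export
compare_pst_fst <- function(pst_matrix, fst_matrix, n_perm = 9999, seed = 1L) {
  if (!identical(dimnames(pst_matrix)[[1]], dimnames(fst_matrix)[[1]])) {
    abort("population labels of the two matrices do not match")
  }
  mantel(pst_matrix, fst_matrix, n_perm = n_perm,
         alternative = "two.sided", seed = seed)
}
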