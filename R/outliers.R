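# F_ST-outlier screening: a trimmed-likelihood chi-square scan on
# Weir-Cockerham per-locus F_ST, a PCA-Mahalanobis scan on genotype/PC
# regression z-scores, and the consensus neutral-set construction.

#' Trimmed chi-square F_ST outlier scan
#'
#' Per-locus Weir-Cockerham F_ST values are modelled as
#' F_ST * df / Fbar ~ chi^2_df for neutral loci. The neutral mean Fbar and
#' effective degrees of freedom df are inferred by maximum likelihood on the
#' two-sided-trimmed set (truncated chi-square likelihood, so the trimming
#' itself is accounted for). Loci with expected heterozygosity below
#' `he_min` are excluded from the fit (their F_ST is noisy) but still
#' receive p-values. Right-tail p-values are Benjamini-Hochberg adjusted;
#' loci with q <= `q_thresh` are flagged.
#'
#' @param g a filtered [genotype_matrix()].
#' @param pm population map.
#' @param trim fraction trimmed from each tail before fitting (default 0.05).
#' @param he_min minimum overall expected heterozygosity for a locus to
#'   enter the fit (default 0.1).
#' @param q_thresh flagging threshold on the q-value (default 0.05).
#' @return Tibble of class `outlier_report` (attribute `method`):
#'   locus_id, statistic (F_ST), p_value, q_value, flagged; attributes
#'   `fbar` and `df` carry the fit.
#' @export
trimmed_chisq_outliers <- function(g, pm, trim = 0.05, he_min = 0.1,
                                   q_thresh = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  check_number(trim, "trim", 0, 0.4)
  fst <- wc_fst(g, pm)
  comp <- fst$components
  gt <- g$genotypes
  n_called <- colSums(!is.na(gt))
  p <- colSums(gt, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  he_all <- 2 * p * (1 - p)
  usable <- !is.na(comp$fst)
  fit_set <- usable & he_all >= he_min & comp$fst > 0
  x <- comp$fst[fit_set]
  if (length(x) < 20) abort("too few usable loci to fit the neutral model")
  qs <- quantile(x, c(trim, 1 - trim))
  core <- x[x >= qs[1] & x <= qs[2]]
  # ML under F * df / Fbar ~ chi^2_df truncated to the trimmed window
  nll <- function(par) {
    fbar <- exp(par[1]); df <- exp(par[2])
    z <- core * df / fbar
    lo <- qs[1] * df / fbar; hi <- qs[2] * df / fbar
    # a degenerate trim window (all values tied) reduces to untruncated ML
    denom <- if (hi > lo) pchisq(hi, df) - pchisq(lo, df) else 1
    if (!is.finite(denom) || denom <= 0) return(1e10)
    -sum(stats::dchisq(z, df, log = TRUE) + log(df / fbar)) +
      length(core) * log(denom)
  }
  ini <- c(log(mean(core)), log(max(2, fst$n_pops - 1)))
  opt <- optim(ini, nll, method = "Nelder-Mead",
               control = list(maxit = 2000))
  fbar <- exp(opt$par[1]); df <- exp(opt$par[2])
  if (!is.finite(df) || df <= 0) {
    abort("neutral-model fit failed (non-positive effective df)")
  }
  pval <- rep(NA_real_, nrow(comp))
  pval[usable] <- pchisq(comp$fst[usable] * df / fbar, df, lower.tail = FALSE)
  qval <- rep(NA_real_, length(pval))
  qval[!is.na(pval)] <- p.adjust(pval[!is.na(pval)], method = "BH")
  out <- tibble(
    locus_id = comp$locus_id,
    statistic = comp$fst,
    p_value = pval,
    q_value = qval,
    flagged = !is.na(qval) & qval <= q_thresh & he_all >= he_min
  )
  attr(out, "method") <- "trimmed_chisq"
  attr(out, "fbar") <- fbar
  attr(out, "df") <- df
  class(out) <- c("outlier_report", class(out))
  out
}

#' PCA-Mahalanobis outlier scan
#'
#' Genotypes are centred and scaled by sqrt(2 p (1 - p)); each locus is
#' regressed on the first K principal components of the individuals; the
#' per-locus vector of regression z-scores is scored by Mahalanobis distance
#' (covariance estimated on the bulk of loci: the 5th-95th distance
#' percentile band, iterated twice). Distances are divided by the genomic
#' inflation factor (median distance over the chi-square median) and
#' converted to chi-square_K p-values with Benjamini-Hochberg adjustment.
#'
#' @param g a filtered [genotype_matrix()].
#' @param K number of principal components (default 2).
#' @param q_thresh flagging threshold (default 0.05).
#' @return `outlier_report` tibble (method "pca_mahalanobis"); attribute
#'   `gif` carries the genomic inflation factor, `pc_scores` the individual
#'   PC coordinates.
#' @export
pca_mahalanobis_outliers <- function(g, K = 2, q_thresh = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  gt <- g$genotypes
  n <- nrow(gt); L <- ncol(gt)
  check_number(K, "K", 1, min(n, L) - 1, integer = TRUE)
  n_called <- colSums(!is.na(gt))
  p <- colSums(gt, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  sdv <- sqrt(2 * p * (1 - p))
  ok <- sdv > 0 & n_called > 0
  Gs <- gt[, ok, drop = FALSE]
  ps <- p[ok]; sds <- sdv[ok]
  Gs <- sweep(Gs, 2, 2 * ps)
  Gs <- sweep(Gs, 2, sds, "/")
  Gs[is.na(Gs)] <- 0
  sv <- svd(Gs, nu = K, nv = 0)
  U <- sv$u[, seq_len(K), drop = FALSE]  # orthonormal individual scores
  # z-scores of per-locus regressions on the K orthonormal PCs
  B <- crossprod(U, Gs)                   # K x L coefficient matrix
  fitted_ss <- colSums(B^2)
  total_ss <- colSums(Gs^2)
  df_res <- n - K - 1
  s2 <- pmax(total_ss - fitted_ss, 0) / df_res
  Z <- t(B) / sqrt(pmax(s2, .Machine$double.eps))  # L x K
  # robust-ish covariance: bulk loci between 5th and 95th distance
  # percentiles, iterated twice
  use <- rep(TRUE, nrow(Z))
  for (it in 1:2) {
    Sig <- stats::cov(Z[use, , drop = FALSE])
    Sig_inv <- tryCatch(solve(Sig), error = function(e) {
      abort("singular z-score covariance: try a smaller K")
    })
    d2 <- rowSums((Z %*% Sig_inv) * Z)
    qs <- quantile(d2, c(0.05, 0.95))
    use <- d2 >= qs[1] & d2 <= qs[2]
  }
  gif <- median(d2) / qchisq(0.5, K)
  d2_adj <- d2 / gif
  pval_ok <- pchisq(d2_adj, K, lower.tail = FALSE)
  pval <- rep(NA_real_, L)
  pval[ok] <- pval_ok
  qval <- rep(NA_real_, L)
  qval[!is.na(pval)] <- p.adjust(pval[!is.na(pval)], method = "BH")
  stat <- rep(NA_real_, L)
  stat[ok] <- d2_adj
  out <- tibble(
    locus_id = colnames(gt),
    statistic = stat,
    p_value = pval,
    q_value = qval,
    flagged = !is.na(qval) & qval <= q_thresh
  )
  attr(out, "method") <- "pca_mahalanobis"
  attr(out, "gif") <- gif
  attr(out, "pc_scores") <- U * rep(sv$d[seq_len(K)], each = n)
  class(out) <- c("outlier_report", class(out))
  out
}

#' Consensus outlier set and neutral loci
#'
#' A locus is a consensus outlier when flagged by at least `min_methods`
#' of the supplied per-method reports; the neutral set is the complement.
#'
#' @param reports list of `outlier_report` tibbles over identical locus sets.
#' @param min_methods minimum number of methods that must flag a locus
#'   (default 2).
#' @return List of class `outlier_consensus`: `per_locus` (tibble: locus_id,
#'   n_flagged, consensus_flagged), `neutral_set` (locus ids), `outliers`.
#' @export
outlier_consensus <- function(reports, min_methods = 2) {
  stopifnot(is.list(reports), length(reports) >= 2)
  ids <- lapply(reports, function(r) r$locus_id)
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]]))) {
    abort("reports cover different locus sets")
  }
  flags <- vapply(reports, function(r) r$flagged, logical(length(ids[[1]])))
  n_flagged <- rowSums(flags)
  consensus <- n_flagged >= min_methods
  structure(
    list(
      per_locus = tibble(locus_id = ids[[1]], n_flagged = n_flagged,
                         consensus_flagged = consensus),
      neutral_set = ids[[1]][!consensus],
      outliers = ids[[1]][consensus],
      min_methods = min_methods,
      methods = vapply(reports, function(r) {
        m <- attr(r, "method"); if (is.null(m)) "unknown" else m
      }, "")
    ),
    class = "outlier_consensus"
  )
}

#' @export
print.outlier_consensus <- function(x, ...) {
  cat(sprintf(
    "<outlier_consensus> %d outliers (flagged by >= %d of %d methods), %d neutral\n",
    length(x$outliers), x$min_methods, length(x$methods),
    length(x$neutral_set)
  ))
  invisible(x)
}

#' @export
tidy.outlier_consensus <- function(x, ...) x$per_locus
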