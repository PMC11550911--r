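# Landmark-based shape analysis: centroid size, generalized Procrustes
# alignment with sliding semilandmarks, relative warps, thin-plate splines,
# repeatability, and size-controlled group tests.

#' Centroid size of a configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid -- the standard geometric-morphometric size measure. It is
#' homogeneous of degree one: scaling the configuration by s scales CS by s.
#'
#' @param coords numeric k x 2 matrix (k >= 3).
#' @return Positive scalar.
#' @export
centroid_size <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, nrow(coords) >= 3)
  cen <- colMeans(coords)
  cs <- sqrt(sum((coords[, 1] - cen[1])^2 + (coords[, 2] - cen[2])^2))
  if (cs <= .Machine$double.eps) {
    abort("degenerate configuration: all landmarks coincide (zero size)")
  }
  cs
}

# rotate X (k x 2, centered) onto target C by the proper orthogonal
# Procrustes rotation (reflections excluded)
rotate_onto <- function(X, C) {
  s <- svd(crossprod(X, C))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, 2] <- -u[, 2]
    R <- u %*% t(s$v)
  }
  X %*% R
}

# bending-energy matrix of a reference configuration: the top-left k x k
# block of the inverse TPS system matrix
bending_energy_matrix <- function(C) {
  k <- nrow(C)
  r2 <- as.matrix(dist(C))^2
  K <- ifelse(r2 == 0, 0, r2 * log(r2))
  P <- cbind(1, C)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  Li <- tryCatch(solve(L), error = function(e) {
    abort("singular TPS system (collinear landmarks?)")
  })
  Li[seq_len(k), seq_len(k), drop = FALSE]
}

# slide semilandmarks of one aligned configuration along chord tangents to
# minimize bending energy against the consensus
slide_one <- function(X, consensus, roles, B) {
  sliders <- which(roles$role == "sliding")
  if (!length(sliders)) return(X)
  m <- length(sliders)
  k <- nrow(X)
  U <- matrix(0, k, 2)
  for (j in sliders) {
    chord <- X[roles$after[j], ] - X[roles$before[j], ]
    len <- sqrt(sum(chord^2))
    if (len < .Machine$double.eps) next
    U[j, ] <- chord / len
  }
  Sx <- matrix(0, k, m)
  Sy <- matrix(0, k, m)
  for (jj in seq_len(m)) {
    Sx[sliders[jj], jj] <- U[sliders[jj], 1]
    Sy[sliders[jj], jj] <- U[sliders[jj], 2]
  }
  d <- X - consensus
  M <- crossprod(Sx, B %*% Sx) + crossprod(Sy, B %*% Sy)
  rhs <- -(crossprod(Sx, B %*% d[, 1]) + crossprod(Sy, B %*% d[, 2]))
  t_par <- tryCatch(solve(M + diag(1e-12, m), rhs),
                    error = function(e) matrix(0, m, 1))
  X[sliders, 1] <- X[sliders, 1] + U[sliders, 1] * t_par
  X[sliders, 2] <- X[sliders, 2] + U[sliders, 2] * t_par
  X
}

#' Generalized Procrustes alignment
#'
#' Full Procrustes superimposition: every configuration is centred, scaled
#' to unit centroid size, and rotated (proper rotations only) onto the
#' running consensus; the consensus is iterated to convergence. With
#' `slide = TRUE`, semilandmarks then slide along their chord tangents to
#' minimize the thin-plate-spline bending energy against the consensus,
#' alternating with re-superimposition for `slide_rounds` rounds.
#'
#' @param lms a [landmark_set()] with at least two configurations.
#' @param slide slide semilandmarks (requires sliding roles in `lms`).
#' @param max_iter maximum consensus iterations (default 100).
#' @param tol consensus convergence tolerance (root-mean-square change,
#'   default 1e-10).
#' @param slide_rounds sliding/re-superimposition rounds (default 5).
#' @return Object of class `aligned_shapes`: `consensus` (k x 2, centroid at
#'   origin, unit centroid size), `aligned` (k x 2 x n Procrustes
#'   coordinates), `centroid_size` (per specimen, input units), plus the
#'   specimen `info` and landmark `roles` carried through.
#' @export
gpa_align <- function(lms, slide = FALSE, max_iter = 100, tol = 1e-10,
                      slide_rounds = 5) {
  stopifnot(inherits(lms, "landmark_set"))
  coords <- lms$coords
  n <- dim(coords)[3]
  k <- dim(coords)[1]
  if (n < 2) abort("need at least 2 configurations")
  if (slide && !any(lms$roles$role == "sliding")) {
    abort("slide = TRUE but no sliding landmarks defined")
  }
  cs <- numeric(n)
  X <- array(0, dim = dim(coords), dimnames = dimnames(coords))
  for (i in seq_len(n)) {
    xi <- coords[, , i]
    cen <- colMeans(xi)
    xi <- sweep(xi, 2, cen)
    cs[i] <- sqrt(sum(xi^2))
    if (cs[i] <= .Machine$double.eps) abort("zero-size configuration")
    X[, , i] <- xi / cs[i]
  }

  superimpose <- function(X) {
    consensus <- X[, , 1]
    for (iter in seq_len(max_iter)) {
      for (i in seq_len(n)) X[, , i] <- rotate_onto(X[, , i], consensus)
      new_cons <- apply(X, c(1, 2), mean)
      new_cons <- sweep(new_cons, 2, colMeans(new_cons))
      new_cons <- new_cons / sqrt(sum(new_cons^2))
      delta <- sqrt(mean((new_cons - consensus)^2))
      consensus <- new_cons
      if (delta < tol) break
    }
    if (delta >= tol) {
      warn(sprintf("GPA did not converge in %d iterations (delta = %.2e)",
                   max_iter, delta))
    }
    list(X = X, consensus = consensus)
  }

  fit <- superimpose(X)
  if (slide) {
    for (round in seq_len(slide_rounds)) {
      B <- bending_energy_matrix(fit$consensus)
      for (i in seq_len(n)) {
        xi <- slide_one(fit$X[, , i], fit$consensus, lms$roles, B)
        cen <- colMeans(xi)
        xi <- sweep(xi, 2, cen)
        fit$X[, , i] <- xi / sqrt(sum(xi^2))
      }
      fit <- superimpose(fit$X)
    }
  }
  structure(
    list(consensus = fit$consensus, aligned = fit$X,
         centroid_size = setNames(cs, dimnames(coords)[[3]]),
         info = lms$info, roles = lms$roles),
    class = "aligned_shapes"
  )
}

#' @export
print.aligned_shapes <- function(x, ...) {
  d <- dim(x$aligned)
  cat(sprintf("<aligned_shapes> %d specimens, %d landmarks; consensus CS = %.6f\n",
              d[3], d[1], sqrt(sum(x$consensus^2))))
  invisible(x)
}

# Procrustes variance: mean squared deviation of aligned coords from consensus
procrustes_variance <- function(a) {
  stopifnot(inherits(a, "aligned_shapes"))
  n <- dim(a$aligned)[3]
  dev <- sweep(a$aligned, c(1, 2), a$consensus)
  sum(dev^2) / n
}

#' Root-mean-square difference between two aligned sets
#'
#' Aligned coordinate systems from two GPA runs differ by an arbitrary
#' rotation of the consensus; the RMS is computed after rotating the first
#' set's consensus (and all its configurations) onto the second's.
#'
#' @param a,b `aligned_shapes` objects over the same specimens/landmarks.
#' @return RMS coordinate difference (scalar).
#' @export
aligned_rms <- function(a, b) {
  stopifnot(inherits(a, "aligned_shapes"), inherits(b, "aligned_shapes"),
            identical(dim(a$aligned), dim(b$aligned)))
  s <- svd(crossprod(a$consensus, b$consensus))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, 2] <- -u[, 2]
    R <- u %*% t(s$v)
  }
  n <- dim(a$aligned)[3]
  dif <- vapply(seq_len(n), function(i) {
    mean((a$aligned[, , i] %*% R - b$aligned[, , i])^2)
  }, numeric(1))
  sqrt(mean(dif))
}

#' Relative warps (principal components of shape)
#'
#' Principal-component decomposition of the Procrustes-aligned coordinate
#' deviations from the consensus (alpha = 0: uniform and non-uniform
#' components weighted equally). Axis signs are fixed so each axis's
#' largest-magnitude loading is positive.
#'
#' @param a an `aligned_shapes` object with >= 3 specimens.
#' @return Object of class `relative_warps`: `scores` (specimens x axes),
#'   `pct_variance`, `loadings` (axes x 2k), `consensus`, `centroid_size`,
#'   `info`.
#' @export
relative_warps <- function(a) {
  stopifnot(inherits(a, "aligned_shapes"))
  n <- dim(a$aligned)[3]
  if (n < 3) abort("need at least 3 specimens for relative warps")
  k <- dim(a$aligned)[1]
  flat <- t(vapply(seq_len(n), function(i) as.vector(a$aligned[, , i]),
                   numeric(2 * k)))
  rownames(flat) <- dimnames(a$aligned)[[3]]
  dev <- sweep(flat, 2, as.vector(a$consensus))
  pc <- prcomp(dev, center = TRUE, scale. = FALSE)
  keep <- which(pc$sdev > 1e-12 * pc$sdev[1])
  scores <- pc$x[, keep, drop = FALSE]
  load <- t(pc$rotation[, keep, drop = FALSE])
  # sign convention: largest |loading| positive per axis
  for (j in seq_len(nrow(load))) {
    if (load[j, which.max(abs(load[j, ]))] < 0) {
      load[j, ] <- -load[j, ]
      scores[, j] <- -scores[, j]
    }
  }
  v <- pc$sdev[keep]^2
  colnames(scores) <- rownames(load) <- sprintf("RW%d", seq_along(keep))
  structure(
    list(scores = scores, pct_variance = 100 * v / sum(v),
         loadings = load, center = pc$center,
         consensus = a$consensus,
         centroid_size = a$centroid_size, info = a$info),
    class = "relative_warps"
  )
}

#' @export
tidy.relative_warps <- function(x, ...) {
  as_tibble(x$scores, rownames = "specimen_id") %>%
    left_join(x$info, by = "specimen_id") %>%
    mutate(centroid_size = unname(x$centroid_size))
}

#' @export
glance.relative_warps <- function(x, ...) {
  tibble(
    n_axes = ncol(x$scores),
    pct_rw1 = x$pct_variance[1],
    pct_first3 = sum(x$pct_variance[seq_len(min(3, length(x$pct_variance)))])
  )
}

#' Thin-plate spline deformation grid
#'
#' Fits the interpolating thin-plate spline (kernel U(r) = r^2 log r^2) from
#' `reference` to `target` and evaluates it on a rectangular grid spanning
#' the reference (with a margin). The affine part lies in the null space of
#' the bending energy, so affine-only deformations have zero bending energy.
#'
#' @param reference,target k x 2 landmark configurations.
#' @param n_grid grid resolution per axis (default 24).
#' @param margin fractional margin around the reference range (default 0.1).
#' @return Object of class `tps_grid`: `grid` (tibble: x, y, x_def, y_def),
#'   `mapped_landmarks` (k x 2, the spline evaluated at the reference
#'   landmarks), `bending_energy` (scalar, summed over x and y).
#' @export
tps_grid <- function(reference, target, n_grid = 24, margin = 0.1) {
  reference <- as.matrix(reference); target <- as.matrix(target)
  stopifnot(nrow(reference) == nrow(target), ncol(reference) == 2,
            ncol(target) == 2)
  k <- nrow(reference)
  r2 <- as.matrix(dist(reference))^2
  K <- ifelse(r2 == 0, 0, r2 * log(r2))
  P <- cbind(1, reference)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(target, matrix(0, 3, 2))
  coefs <- tryCatch(solve(L, rhs), error = function(e) {
    abort("singular TPS system (collinear landmarks?)")
  })
  W <- coefs[seq_len(k), , drop = FALSE]
  A <- coefs[(k + 1):(k + 3), , drop = FALSE]
  be <- sum(diag(t(W) %*% K %*% W))
  eval_tps <- function(pts) {
    d2 <- outer(rowSums(pts^2), rowSums(reference^2), "+") -
      2 * pts %*% t(reference)
    d2[d2 < 0] <- 0
    Ug <- ifelse(d2 == 0, 0, d2 * log(d2))
    cbind(1, pts) %*% A + Ug %*% W
  }
  rx <- range(reference[, 1]); ry <- range(reference[, 2])
  mx <- margin * diff(rx); my <- margin * diff(ry)
  gx <- seq(rx[1] - mx, rx[2] + mx, length.out = n_grid)
  gy <- seq(ry[1] - my, ry[2] + my, length.out = n_grid)
  pts <- as.matrix(expand.grid(x = gx, y = gy))
  def <- eval_tps(pts)
  structure(
    list(
      grid = tibble(x = pts[, 1], y = pts[, 2],
                    x_def = def[, 1], y_def = def[, 2]),
      mapped_landmarks = eval_tps(reference),
      bending_energy = be
    ),
    class = "tps_grid"
  )
}

#' Repeatability by intraclass correlation
#'
#' Two-way mixed-effects consistency ICC (single measurement) from the
#' ANOVA mean squares of a balanced specimens x sessions design:
#' ICC = (MS_specimen - MS_error) / (MS_specimen + (k - 1) MS_error),
#' with MS_error the residual after removing the session effect.
#'
#' @param replicates numeric matrix, specimens x replicate sessions
#'   (balanced; >= 2 of each).
#' @return Tibble: `icc`, `ms_specimen`, `ms_session`, `ms_error`,
#'   `f_statistic`, `df1`, `df2`, `p_value`.
#' @export
icc_repeatability <- function(replicates) {
  replicates <- as.matrix(replicates)
  if (anyNA(replicates)) abort("unbalanced input: missing replicate values")
  ns <- nrow(replicates); kr <- ncol(replicates)
  if (ns < 2 || kr < 2) abort("need >= 2 specimens and >= 2 replicates each")
  grand <- mean(replicates)
  row_m <- rowMeans(replicates)
  col_m <- colMeans(replicates)
  ss_spec <- kr * sum((row_m - grand)^2)
  ss_sess <- ns * sum((col_m - grand)^2)
  ss_tot <- sum((replicates - grand)^2)
  ss_err <- ss_tot - ss_spec - ss_sess
  ms_spec <- ss_spec / (ns - 1)
  ms_sess <- ss_sess / (kr - 1)
  ms_err <- ss_err / ((ns - 1) * (kr - 1))
  icc <- (ms_spec - ms_err) / (ms_spec + (kr - 1) * ms_err)
  f <- ms_spec / ms_err
  df1 <- ns - 1; df2 <- (ns - 1) * (kr - 1)
  tibble(
    icc = icc, ms_specimen = ms_spec, ms_session = ms_sess,
    ms_error = ms_err, f_statistic = f, df1 = df1, df2 = df2,
    p_value = pf(f, df1, df2, lower.tail = FALSE)
  )
}

#' MANCOVA of shape scores controlling for centroid size
#'
#' Multivariate linear model of the first m relative-warp axes on centroid
#' size plus a grouping factor; reports Pillai's trace and its standard F
#' approximation for the group term, adjusted for centroid size (sequential
#' sums of squares with size entered first, equivalent to Type II for this
#' two-term design).
#'
#' @param scores numeric matrix (specimens x m axes) or vector (m = 1).
#' @param cs centroid sizes.
#' @param group factor/character group labels (>= 2 levels).
#' @return Tibble: `term`, `pillai`, `statistic` (approximate F), `df1`,
#'   `df2`, `p_value`.
#' @export
mancova_shape <- function(scores, cs, group) {
  scores <- as.matrix(scores)
  group <- factor(group)
  n <- nrow(scores)
  m <- ncol(scores)
  if (nlevels(group) < 2) abort("need >= 2 groups")
  if (n != length(cs) || n != length(group)) abort("length mismatch")
  if (n <= m + nlevels(group)) abort("too few specimens for the design")
  full <- lm(scores ~ cs + group)
  red <- lm(scores ~ cs)
  if (any(is.na(coef(full)))) abort("rank-deficient design")
  E <- crossprod(resid(full))
  H <- crossprod(resid(red)) - E
  df_h <- nlevels(group) - 1
  df_e <- n - nlevels(group) - 1  # cs consumes 1 df beyond the intercept
  ev <- Re(eigen(H %*% solve(H + E), only.values = TRUE)$values)
  pillai <- sum(pmax(pmin(ev, 1), 0)[seq_len(min(m, df_h))])
  s <- min(m, df_h)
  m1 <- (abs(m - df_h) - 1) / 2
  n1 <- (df_e - m - 1) / 2
  df1 <- s * (2 * m1 + s + 1)
  df2 <- s * (2 * n1 + s + 1)
  f <- (df2 / df1) * pillai / (s - pillai)
  tibble(
    term = "group", pillai = pillai, statistic = f,
    df1 = df1, df2 = df2,
    p_value = pf(f, df1, df2, lower.tail = FALSE),
    ss_type = "sequential, size first"
  )
}

#' Tukey HSD pairwise comparisons with compact letter display
#'
#' Tukey-Kramer studentized-range comparisons of group means (unequal group
#' sizes supported), plus letter groups computed by the insert-and-absorb
#' algorithm: groups sharing a letter are not significantly different.
#'
#' @param values numeric response per specimen.
#' @param group group labels (every group needs >= 2 observations).
#' @param alpha significance level for the letter display (default 0.05).
#' @return List of class `tukey_letters`: `comparisons` (tibble: contrast,
#'   estimate, conf_low, conf_high, p_adj) and `letters` (tibble: group,
#'   letters).
#' @export
tukey_hsd <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  if (any(table(group) < 2)) abort("every group needs >= 2 observations")
  if (sd(values) == 0) {
    # degenerate: no variation anywhere, nothing distinguishable
    pairs <- utils::combn(levels(group), 2)
    return(structure(list(
      comparisons = tibble(
        contrast = paste(pairs[2, ], pairs[1, ], sep = "-"),
        estimate = 0, conf_low = 0, conf_high = 0, p_adj = 1
      ),
      letters = tibble(group = levels(group), letters = "a")
    ), class = "tukey_letters"))
  }
  fit <- aov(values ~ group)
  tk <- stats::TukeyHSD(fit, "group")$group
  comparisons <- tibble(
    contrast = rownames(tk),
    estimate = tk[, "diff"],
    conf_low = tk[, "lwr"],
    conf_high = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  lv <- levels(group)
  sig <- matrix(FALSE, length(lv), length(lv), dimnames = list(lv, lv))
  for (r in seq_len(nrow(comparisons))) {
    pair <- strsplit(comparisons$contrast[r], "-", fixed = TRUE)[[1]]
    if (comparisons$p_adj[r] <= alpha) {
      sig[pair[1], pair[2]] <- sig[pair[2], pair[1]] <- TRUE
    }
  }
  letters_df <- compact_letters(sig)
  structure(list(comparisons = comparisons, letters = letters_df),
            class = "tukey_letters")
}

# insert-and-absorb compact letter display from a logical "significantly
# different" matrix
compact_letters <- function(sig) {
  lv <- rownames(sig)
  cols <- list(rep(TRUE, length(lv)))  # start: everyone in one letter column
  for (i in seq_along(lv)) {
    for (j in seq_along(lv)) {
      if (j <= i || !sig[i, j]) next
      # any column containing both i and j must be split
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[i] && col[j]) {
          c1 <- col; c1[j] <- FALSE
          c2 <- col; c2[i] <- FALSE
          cols[[ci]] <- c1
          cols[[length(cols) + 1]] <- c2
        }
      }
      # absorb: drop columns that are subsets of another
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a != b && keep[a] && keep[b] &&
              all(cols[[a]] <= cols[[b]]) && any(cols[[b]] & !cols[[a]])) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- cols[keep]
      # dedupe
      cols <- cols[!duplicated(vapply(cols, paste, "", collapse = ""))]
    }
  }
  lab <- vapply(seq_along(lv), function(i) {
    paste0(letters[which(vapply(cols, function(c) c[i], logical(1)))],
           collapse = "")
  }, "")
  tibble(group = lv, letters = lab)
}

#' @export
tidy.tukey_letters <- function(x, ...) x$comparisons
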