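# Synthetic-data generators with known ground truth. Every downstream stage
# has a parameter-recovery test built on these.

#' Ground truth of a simulation
#'
#' @param fst_true divergence parameter of the genotype generator, in [0, 1).
#' @param sigma2_B_true,sigma2_W_true between-/within-population trait
#'   variances of the landmark generator.
#' @param n_segsites_true planted number of segregating sites.
#' @param seed RNG seed used.
#' @return Object of class `sim_truth` (a named list).
#' @export
sim_truth <- function(fst_true = NA_real_, sigma2_B_true = NA_real_,
                      sigma2_W_true = NA_real_, n_segsites_true = NA_integer_,
                      seed = NA_integer_) {
  if (!is.na(fst_true)) check_number(fst_true, "fst_true", 0, 1 - 1e-12)
  if (!is.na(sigma2_B_true)) check_number(sigma2_B_true, "sigma2_B_true", 0)
  if (!is.na(sigma2_W_true)) check_number(sigma2_W_true, "sigma2_W_true", 0)
  structure(
    list(fst_true = fst_true, sigma2_B_true = sigma2_B_true,
         sigma2_W_true = sigma2_W_true,
         n_segsites_true = n_segsites_true, seed = seed),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>\n")
  for (nm in names(x)) cat(sprintf("  %s = %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' Ancestral allele frequencies are drawn Uniform(0.05, 0.95) per locus;
#' population frequencies are Beta(p(1-F)/F, (1-p)(1-F)/F) around the
#' ancestral p (collapsing to p exactly when F = 0); genotypes are
#' Binomial(2, freq). The divergence parameter F is on the F_ST scale, so
#' the Weir-Cockerham estimator applied to the output should recover it.
#'
#' @param n_pops number of populations (>= 2).
#' @param n_per_pop individuals per population.
#' @param n_loci number of biallelic loci.
#' @param fst_true divergence parameter in [0, 1).
#' @param seed integer seed; identical seeds give identical output.
#' @param f_within optional within-population inbreeding coefficient: when
#'   positive, genotypes are drawn with a heterozygote deficit of this size
#'   (used for F_IS recovery tests). Default 0 (Hardy-Weinberg).
#' @param region assignment of populations to region labels; defaults to a
#'   round-robin over tropical/subtropical/arid.
#' @return A list of class `sim_genotypes`: `genotypes` (a
#'   [genotype_matrix()]), `popmap` (tibble: individual, population, region,
#'   lat, lon) and `truth` (a [sim_truth()]).
#' @export
simulate_genotypes <- function(n_pops, n_per_pop, n_loci, fst_true,
                               seed = 1L, f_within = 0, region = NULL) {
  check_number(n_pops, "n_pops", 2, integer = TRUE)
  check_number(n_per_pop, "n_per_pop", 1, integer = TRUE)
  check_number(n_loci, "n_loci", 1, integer = TRUE)
  check_number(fst_true, "fst_true", 0, 1 - 1e-12)
  check_number(f_within, "f_within", 0, 1)
  pops <- sprintf("pop%02d", seq_len(n_pops))
  if (is.null(region)) {
    region <- rep(c("tropical", "subtropical", "arid"), length.out = n_pops)
  }
  n_ind <- n_pops * n_per_pop
  with_local_seed(seed, {
    p_anc <- runif(n_loci, 0.05, 0.95)
    # population x locus allele frequencies
    if (fst_true > 0) {
      a <- p_anc * (1 - fst_true) / fst_true
      b <- (1 - p_anc) * (1 - fst_true) / fst_true
      freq <- matrix(rbeta(n_pops * n_loci, rep(a, each = n_pops),
                           rep(b, each = n_pops)),
                     nrow = n_pops, ncol = n_loci)
    } else {
      freq <- matrix(rep(p_anc, each = n_pops), nrow = n_pops)
    }
    gt <- matrix(NA_integer_, nrow = n_ind, ncol = n_loci)
    for (i in seq_len(n_pops)) {
      rows <- ((i - 1) * n_per_pop + 1):(i * n_per_pop)
      q <- freq[i, ]
      if (f_within > 0) {
        # genotype frequencies with inbreeding: draw allele pairs that are
        # identical by descent with probability f_within
        ibd <- matrix(runif(n_per_pop * n_loci) < f_within,
                      nrow = n_per_pop)
        a1 <- matrix(runif(n_per_pop * n_loci) < rep(q, each = n_per_pop),
                     nrow = n_per_pop)
        a2 <- matrix(runif(n_per_pop * n_loci) < rep(q, each = n_per_pop),
                     nrow = n_per_pop)
        a2[ibd] <- a1[ibd]
        gt[rows, ] <- a1 + a2
      } else {
        gt[rows, ] <- matrix(
          rbinom(n_per_pop * n_loci, 2L, rep(q, each = n_per_pop)),
          nrow = n_per_pop
        )
      }
    }
    rownames(gt) <- sprintf("%s_i%03d", rep(pops, each = n_per_pop),
                            rep(seq_len(n_per_pop), n_pops))
    colnames(gt) <- sprintf("loc_%05d", seq_len(n_loci))
    # population coordinates: jittered grid so IBD machinery has something
    lat <- -12 - 2 * seq_len(n_pops) + runif(n_pops, -0.5, 0.5)
    lon <- 130 + 1.5 * seq_len(n_pops) + runif(n_pops, -0.5, 0.5)
    popmap <- tibble(
      individual = rownames(gt),
      population = rep(pops, each = n_per_pop),
      region = rep(region, each = n_per_pop),
      lat = rep(lat, each = n_per_pop),
      lon = rep(lon, each = n_per_pop)
    )
    structure(
      list(
        genotypes = genotype_matrix(gt),
        popmap = popmap,
        truth = sim_truth(fst_true = fst_true, seed = seed)
      ),
      class = "sim_genotypes"
    )
  })
}

#' Plant strongly divergent loci into a simulated dataset
#'
#' Replaces `n_outliers` randomly chosen loci with loci re-simulated under a
#' higher divergence parameter, for outlier-scan power tests.
#'
#' @param sim a `sim_genotypes` object.
#' @param n_outliers number of loci to replace.
#' @param fst_outlier divergence parameter for the planted loci.
#' @param seed integer seed.
#' @return The modified `sim_genotypes`, with `planted_outliers` (locus ids)
#'   added to the list.
#' @export
plant_outlier_loci <- function(sim, n_outliers, fst_outlier, seed = 1L) {
  stopifnot(inherits(sim, "sim_genotypes"))
  gt <- sim$genotypes$genotypes
  check_number(n_outliers, "n_outliers", 1, ncol(gt), integer = TRUE)
  check_number(fst_outlier, "fst_outlier", 0, 1 - 1e-12)
  pops <- sim$popmap$population
  upops <- unique(pops)
  with_local_seed(seed, {
    target <- sort(sample(ncol(gt), n_outliers))
    for (j in target) {
      p_anc <- runif(1, 0.2, 0.8)
      a <- p_anc * (1 - fst_outlier) / fst_outlier
      b <- (1 - p_anc) * (1 - fst_outlier) / fst_outlier
      q <- rbeta(length(upops), a, b)
      for (i in seq_along(upops)) {
        rows <- which(pops == upops[i])
        gt[rows, j] <- rbinom(length(rows), 2L, q[i])
      }
    }
    sim$genotypes <- genotype_matrix(gt, sim$genotypes$locus_meta)
    sim$planted_outliers <- colnames(gt)[target]
    sim
  })
}

#' Degrade a clean genotype matrix for filter testing
#'
#' Injects missingness to push chosen loci below a 95% call rate and chosen
#' individuals below 85%, appends monomorphic loci and extra SNPs sharing an
#' existing tag ID, and optionally forces loci to low minor allele frequency.
#' Returns the planted removal lists so the SNP filter can be checked against
#' an enumerated survivor set.
#'
#' @param g a [genotype_matrix()].
#' @param locus_dropout proportion of loci to degrade below the locus
#'   call-rate threshold.
#' @param ind_dropout proportion of individuals to degrade below the
#'   individual call-rate threshold.
#' @param n_monomorphic number of monomorphic loci to append.
#' @param n_multi_per_tag number of extra SNPs appended onto existing tags.
#' @param n_low_maf number of loci forced to minor allele frequency below
#'   0.05 (near-fixed).
#' @param seed integer seed.
#' @return List of class `degraded_genotypes`: `genotypes`, and `planted`
#'   (tibble: item, kind).
#' @export
degrade_genotypes <- function(g, locus_dropout = 0, ind_dropout = 0,
                              n_monomorphic = 0, n_multi_per_tag = 0,
                              n_low_maf = 0, seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"))
  check_number(locus_dropout, "locus_dropout", 0, 1)
  check_number(ind_dropout, "ind_dropout", 0, 1)
  gt <- g$genotypes
  n <- nrow(gt); L <- ncol(gt)
  n_loc_drop <- round(locus_dropout * L)
  n_ind_drop <- round(ind_dropout * n)
  if (n_monomorphic < 0 || n_multi_per_tag < 0 || n_low_maf < 0) {
    abort("plant counts must be non-negative")
  }
  if (n_loc_drop + n_low_maf > L || n_multi_per_tag > L) {
    abort("requested plants exceed matrix size")
  }
  planted <- tibble(item = character(), kind = character())
  with_local_seed(seed, {
    loc_pool <- sample(L, n_loc_drop + n_low_maf)
    drop_loc <- sort(head(loc_pool, n_loc_drop))
    lowmaf_loc <- sort(utils::tail(loc_pool, n_low_maf))
    # missing calls: >5% of individuals missing at the chosen loci
    n_miss <- ceiling(0.06 * n) + 1L
    for (j in drop_loc) {
      gt[sample(n, min(n_miss, n)), j] <- NA_integer_
    }
    if (n_loc_drop) {
      planted <- bind_rows(planted, tibble(
        item = colnames(gt)[drop_loc], kind = "low_call_rate_locus"
      ))
    }
    # low-MAF loci: make all but one called genotype the major homozygote
    for (j in lowmaf_loc) {
      gt[, j] <- 0L
      gt[sample(n, 1L), j] <- 1L
    }
    if (n_low_maf) {
      planted <- bind_rows(planted, tibble(
        item = colnames(gt)[lowmaf_loc], kind = "low_maf_locus"
      ))
    }
    drop_ind <- sort(sample(n, n_ind_drop))
    ncol_miss <- ceiling(0.16 * ncol(gt)) + 1L
    for (i in drop_ind) {
      gt[i, sample(ncol(gt), min(ncol_miss, ncol(gt)))] <- NA_integer_
    }
    if (n_ind_drop) {
      planted <- bind_rows(planted, tibble(
        item = rownames(gt)[drop_ind], kind = "low_call_rate_individual"
      ))
    }
    meta <- g$locus_meta
    if (n_monomorphic > 0) {
      mono <- matrix(0L, nrow = n, ncol = n_monomorphic)
      cn <- sprintf("mono_%03d", seq_len(n_monomorphic))
      colnames(mono) <- cn
      gt <- cbind(gt, mono)
      meta <- bind_rows(meta, tibble(locus_id = cn, tag_id = cn,
                                     position = 1L))
      planted <- bind_rows(planted, tibble(item = cn, kind = "monomorphic"))
    }
    if (n_multi_per_tag > 0) {
      host <- sample(seq_len(L), n_multi_per_tag)
      extra <- matrix(NA_integer_, nrow = n, ncol = n_multi_per_tag)
      cn <- sprintf("multi_%03d", seq_len(n_multi_per_tag))
      for (m in seq_len(n_multi_per_tag)) {
        # a second SNP on the host tag, with a slightly lower call rate so
        # the one-per-tag rule keeps the host
        v <- rbinom(n, 2L, 0.5)
        v[sample(n, max(1L, ceiling(0.02 * n)))] <- NA_integer_
        extra[, m] <- v
      }
      colnames(extra) <- cn
      gt <- cbind(gt, extra)
      meta <- bind_rows(meta, tibble(
        locus_id = cn,
        tag_id = g$locus_meta$tag_id[host],
        position = 2L
      ))
      planted <- bind_rows(planted, tibble(item = cn, kind = "multi_per_tag"))
    }
    structure(
      list(genotypes = genotype_matrix(gt, meta), planted = planted),
      class = "degraded_genotypes"
    )
  })
}

# Deterministic 22-point foretibia-like template: 12 fixed landmarks on a
# tapering outline plus 10 sliding semilandmarks along the toothed edge.
landmark_template <- function() {
  t_fix <- seq(0, 2 * pi, length.out = 13)[-13]
  fixed <- cbind(cos(t_fix) * c(rep(1, 6), rep(0.6, 6)),
                 sin(t_fix) * c(rep(0.8, 6), rep(1.1, 6)))
  s <- seq(0.15, 0.85, length.out = 10)
  slide <- cbind(2 + 0.5 * s, -0.5 + 2 * s + 0.15 * sin(6 * s))
  coords <- rbind(fixed, slide)
  roles <- tibble(
    landmark = 1:22,
    role = c(rep("fixed", 12), rep("sliding", 10)),
    before = c(rep(NA_integer_, 12), c(12L, 13:21)),
    after = c(rep(NA_integer_, 12), c(14:22, 1L))
  )
  list(coords = coords, roles = roles)
}

# A fixed unit direction in the template's shape space along which the
# between/within-population deformation acts. Deterministic and RNG-free so
# user seeds are untouched, and projected into the tangent space at the
# template: orthogonal to translation (column centring), to scaling (the
# centred template itself) and to rotation (the 90-degree-rotated template),
# so the planted signal is neither removed by Procrustes superimposition nor
# correlated with centroid size.
deformation_direction <- function(template, roles = NULL) {
  k <- nrow(template)
  i <- seq_len(k)
  d <- cbind(sin(1.7 * i) + 0.3 * cos(0.9 * i),
             cos(2.3 * i) - 0.2 * sin(1.1 * i))
  X0 <- scale(template, scale = FALSE)
  u_scale <- X0 / sqrt(sum(X0^2))
  rot <- cbind(-X0[, 2], X0[, 1])
  u_rot <- rot / sqrt(sum(rot^2))
  # the position of a semilandmark along its curve is arbitrary (that is why
  # it slides), so a meaningful planted signal must be normal to the slider
  # chords; otherwise bending-energy sliding would rightly remove part of it
  for (pass in 1:2) {
    if (!is.null(roles)) {
      for (j in which(roles$role == "sliding")) {
        chord <- template[roles$after[j], ] - template[roles$before[j], ]
        chord <- chord / sqrt(sum(chord^2))
        d[j, ] <- d[j, ] - sum(d[j, ] * chord) * chord
      }
    }
    d <- d - matrix(colMeans(d), k, 2, byrow = TRUE)
    d <- d - sum(d * u_scale) * u_scale
    d <- d - sum(d * u_rot) * u_rot
  }
  d <- d - matrix(colMeans(d), k, 2, byrow = TRUE)
  d / sqrt(sum(d^2))
}

#' Simulate landmark configurations with known shape variance
#'
#' A deterministic 22-point template (12 fixed landmarks, 10 sliding
#' semilandmarks) is deformed along a single fixed unit direction in shape
#' space. Population offsets on that axis are N(0, sigma2_B); individual
#' offsets N(0, sigma2_W); optional isotropic jitter is added to every
#' landmark. When `nuisance = TRUE` each configuration is additionally
#' rotated by U(0, 2*pi), translated, and scaled log-normally, which
#' generalized Procrustes alignment must remove. The true P_ST of the
#' deformation trait at c/h^2 = 1 is sigma2_B / (sigma2_B + 2 * sigma2_W).
#'
#' @param n_pops,n_per_pop population count and size.
#' @param sigma2_B,sigma2_W between-/within-population variances of the
#'   deformation score (shape-space units squared).
#' @param iso_noise isotropic landmark jitter SD, in template length units
#'   (default 1% of the template centroid size).
#' @param nuisance add random rotation/translation/scale per specimen.
#' @param seed integer seed.
#' @return List of class `sim_landmarks`: `landmarks` (a [landmark_set()]),
#'   `popmap`, `truth`, and `scores_true` (the planted deformation scores).
#' @export
simulate_landmarks <- function(n_pops, n_per_pop, sigma2_B, sigma2_W,
                               iso_noise = NULL, nuisance = FALSE, seed = 1L) {
  check_number(n_pops, "n_pops", 1, integer = TRUE)
  check_number(n_per_pop, "n_per_pop", 1, integer = TRUE)
  check_number(sigma2_B, "sigma2_B", 0)
  check_number(sigma2_W, "sigma2_W", 0)
  tmpl <- landmark_template()
  k <- nrow(tmpl$coords)
  cs0 <- sqrt(sum(scale(tmpl$coords, scale = FALSE)^2))
  if (is.null(iso_noise)) iso_noise <- 0.01 * cs0
  dirn <- deformation_direction(tmpl$coords, tmpl$roles)
  n <- n_pops * n_per_pop
  pops <- sprintf("pop%02d", seq_len(n_pops))
  with_local_seed(seed, {
    # population effects: normal draws standardised so their realised
    # (k - 1)-divisor variance equals sigma2_B exactly. The generated
    # dataset then carries the declared between-population variance as an
    # exact property, making P_ST recovery well-defined per dataset rather
    # than up to the sampling noise of a handful of population draws.
    if (n_pops > 1 && sigma2_B > 0) {
      mu_pop <- rnorm(n_pops)
      mu_pop <- mu_pop - mean(mu_pop)
      mu_pop <- mu_pop * sqrt(sigma2_B) / sqrt(sum(mu_pop^2) / (n_pops - 1))
    } else {
      mu_pop <- rep(0, n_pops)
    }
    score <- rep(mu_pop, each = n_per_pop) + rnorm(n, 0, sqrt(sigma2_W))
    coords <- array(0, dim = c(k, 2, n))
    # deformation scale: one score unit moves the shape by 5% of centroid
    # size along the planted axis, large against the default 1% jitter yet
    # small enough that Procrustes projection stays effectively linear
    eps <- 0.05 * cs0
    jitter <- array(rnorm(k * 2 * n, 0, iso_noise), dim = c(k, 2, n))
    for (i in seq_len(n)) {
      coords[, , i] <- tmpl$coords + eps * score[i] * dirn + jitter[, , i]
    }
    # nuisance transforms are drawn after all shape randomness so that runs
    # with nuisance on/off share identical underlying shapes at equal seeds
    if (nuisance) {
      for (i in seq_len(n)) {
        th <- runif(1, 0, 2 * pi)
        R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
        s <- rlnorm(1, 0, 0.3)
        tr <- runif(2, -5, 5)
        coords[, , i] <- s * coords[, , i] %*% R +
          matrix(tr, k, 2, byrow = TRUE)
      }
    }
    ids <- sprintf("%s_s%03d", rep(pops, each = n_per_pop),
                   rep(seq_len(n_per_pop), n_pops))
    dimnames(coords) <- list(NULL, c("x", "y"), ids)
    info <- tibble(
      specimen_id = ids,
      population = rep(pops, each = n_per_pop),
      region = rep(rep(c("tropical", "subtropical", "arid"),
                       length.out = n_pops), each = n_per_pop),
      sex = "female"
    )
    structure(
      list(
        landmarks = landmark_set(coords, info, tmpl$roles),
        popmap = distinct(select(info, individual = "specimen_id",
                                 population = "population",
                                 region = "region")),
        truth = sim_truth(sigma2_B_true = sigma2_B,
                          sigma2_W_true = sigma2_W, seed = seed),
        scores_true = score
      ),
      class = "sim_landmarks"
    )
  })
}

#' Simulate an aligned haplotype sample
#'
#' Builds a random reference sequence, plants mutations at exactly
#' `n_segsites` distinct positions distributed over the unique haplotypes,
#' then replicates haplotypes according to `dup_profile` to produce the
#' full sample.
#'
#' @param n_seqs total number of sequences to emit.
#' @param length_bp alignment length.
#' @param n_segsites exact number of segregating (polymorphic) sites.
#' @param dup_profile integer vector of per-haplotype frequencies summing to
#'   `n_seqs`; its length is the number of unique haplotypes. Default: one
#'   haplotype per sequence (all ones).
#' @param seed integer seed.
#' @return List of class `sim_haplotypes`: `sequences` (named character
#'   vector of aligned sequences), `haplotype_of` (index of the unique
#'   haplotype each sequence copies) and `truth`.
#' @export
simulate_haplotypes <- function(n_seqs, length_bp, n_segsites,
                                dup_profile = NULL, seed = 1L) {
  check_number(n_seqs, "n_seqs", 1, integer = TRUE)
  check_number(length_bp, "length_bp", 1, integer = TRUE)
  check_number(n_segsites, "n_segsites", 0, length_bp, integer = TRUE)
  if (is.null(dup_profile)) dup_profile <- rep(1L, n_seqs)
  if (sum(dup_profile) != n_seqs || any(dup_profile < 1)) {
    abort("dup_profile must be positive integers summing to n_seqs")
  }
  n_hap <- length(dup_profile)
  if (n_segsites > 0 && n_hap < 2) {
    abort("cannot plant segregating sites with fewer than 2 unique haplotypes")
  }
  bases <- c("A", "C", "G", "T")
  with_local_seed(seed, {
    ref <- sample(bases, length_bp, replace = TRUE)
    haps <- matrix(rep(ref, n_hap), nrow = n_hap, byrow = TRUE)
    if (n_segsites > 0) {
      sites <- sample(length_bp, n_segsites)
      for (s in sites) {
        # mutate a random non-empty proper subset of haplotypes at this site
        n_mut <- sample(n_hap - 1L, 1L)
        who <- sample(n_hap, n_mut)
        alt <- sample(setdiff(bases, ref[s]), 1L)
        haps[who, s] <- alt
      }
    }
    hap_seq <- apply(haps, 1, paste0, collapse = "")
    # the random site subsets can collide; re-draw states at already
    # segregating sites (keeps the site count exact) until haplotypes are
    # pairwise distinct, where the planted design allows it
    tries <- 0L
    while (anyDuplicated(hap_seq) && n_segsites >= 1L && tries < 200L) {
      d <- which(duplicated(hap_seq))[1]
      s <- sample(sites, 1L)
      haps[d, s] <- sample(setdiff(bases, haps[d, s]), 1L)
      # never let the redraw collapse the site to a single state
      if (length(unique(haps[, s])) < 2L) {
        haps[d, s] <- sample(setdiff(bases, haps[1, s]), 1L)
      }
      hap_seq <- apply(haps, 1, paste0, collapse = "")
      tries <- tries + 1L
    }
    idx <- rep(seq_len(n_hap), times = dup_profile)
    seqs <- hap_seq[idx]
    names(seqs) <- sprintf("seq_%03d", seq_len(n_seqs))
    structure(
      list(sequences = seqs, haplotype_of = idx,
           truth = sim_truth(n_segsites_true = as.integer(n_segsites),
                             seed = seed)),
      class = "sim_haplotypes"
    )
  })
}
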