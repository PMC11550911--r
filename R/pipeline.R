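# End-to-end orchestration: a strict flat configuration, a synthetic-bundle
# writer, and the staged pipeline with per-stage derived seeds and a
# content-hash manifest.

default_config <- function() {
  list(
    # input paths (NULL = stage disabled or simulated in place)
    tps_path = NULL, sliders_path = NULL,
    genotype_path = NULL, genotype_format = "csv",
    popmap_path = NULL, fasta_path = NULL,
    out_dir = NULL,
    master_seed = 1L,
    # morphometry
    morpho_slide = TRUE, morpho_n_axes = 3,
    # SNP filters
    filter_locus_call_min = 0.95, filter_ind_call_min = 0.85,
    filter_maf_min = 0.05, filter_one_per_tag = TRUE,
    # outlier scan
    # outlier_K = NULL: use one less than the number of populations
    outlier_trim = 0.05, outlier_he_min = 0.1, outlier_q_thresh = 0.05,
    outlier_K = NULL, outlier_min_methods = 2,
    # popgen
    fst_n_boot = 1000, mantel_n_perm = 999,
    dapc_k_max = 10, dapc_n_pcs = 40,
    origin_lonlat = NULL,
    # pst
    pst_phi_max = 2, pst_phi_step = 0.01, pst_n_boot = 1000
  )
}

#' Build a pipeline configuration
#'
#' Flat key=value configuration with strict validation: unknown keys are
#' rejected so threshold typos fail loudly. Every stochastic stage derives
#' its own seed deterministically from `master_seed` plus the stage name.
#'
#' @param ... configuration overrides (see Details in the package vignette);
#'   keys not in the default set are an error.
#' @return Named list of class `run_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- default_config()
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) {
    abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  cfg[names(ov)] <- ov
  structure(cfg, class = "run_config")
}

#' Write a complete synthetic input bundle
#'
#' Generates genotypes, landmarks (one TPS file plus sliders sidecar) and a
#' haplotype FASTA with known ground truth, and writes them with a truth
#' sidecar in the interchange formats the pipeline reads.
#'
#' @param dir output directory (created if needed).
#' @param n_pops,n_per_pop,n_loci,fst_true genotype generator settings
#'   (defaults mirror the study scale: 12 populations x 15 individuals x
#'   2000 loci at F_ST 0.118).
#' @param sigma2_B,sigma2_W landmark generator variances (default 2 and 1,
#'   giving a true P_ST(1) of 0.5).
#' @param n_seqs,length_bp,n_segsites,n_haplotypes haplotype generator
#'   settings (defaults: 60 sequences of 612 bp, 42 segregating sites, 15
#'   unique haplotypes).
#' @param seed master seed.
#' @return Invisibly, a named list of written paths.
#' @export
simulate_bundle <- function(dir, n_pops = 12, n_per_pop = 15, n_loci = 2000,
                            fst_true = 0.118, sigma2_B = 2, sigma2_W = 1,
                            n_seqs = 60, length_bp = 612, n_segsites = 42,
                            n_haplotypes = 15, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gsim <- simulate_genotypes(n_pops, n_per_pop, n_loci, fst_true,
                             seed = derive_seed(seed, "genotypes"))
  lsim <- simulate_landmarks(n_pops, n_per_pop, sigma2_B, sigma2_W,
                             nuisance = TRUE,
                             seed = derive_seed(seed, "landmarks"))
  # duplicate profile: n_haplotypes unique sequences over n_seqs total
  base_n <- n_seqs %/% n_haplotypes
  prof <- rep(base_n, n_haplotypes)
  extra <- n_seqs - sum(prof)
  if (extra > 0) prof[seq_len(extra)] <- prof[seq_len(extra)] + 1L
  hsim <- simulate_haplotypes(n_seqs, length_bp, n_segsites,
                              dup_profile = prof,
                              seed = derive_seed(seed, "haplotypes"))
  paths <- list(
    genotypes = file.path(dir, "genotypes.csv"),
    popmap = file.path(dir, "popmap.tsv"),
    tps = file.path(dir, "landmarks.tps"),
    sliders = file.path(dir, "sliders.txt"),
    fasta = file.path(dir, "haplotypes.fasta"),
    truth = file.path(dir, "truth.txt")
  )
  write_genotypes(gsim$genotypes, paths$genotypes)
  # one popmap covers genotyped individuals and landmarked specimens
  pm_geno <- mutate(gsim$popmap, sex = NA_character_)
  pm_lms <- lsim$landmarks$info %>%
    rename(individual = "specimen_id") %>%
    mutate(lat = NA_real_, lon = NA_real_) %>%
    select("individual", "population", "region", "lat", "lon", "sex")
  write_popmap(bind_rows(pm_geno, pm_lms), paths$popmap)
  write_tps(lsim$landmarks, paths$tps)
  write_sliders(lsim$landmarks$roles, paths$sliders)
  write_fasta(hsim$sequences, paths$fasta)
  truth <- sim_truth(
    fst_true = fst_true, sigma2_B_true = sigma2_B, sigma2_W_true = sigma2_W,
    n_segsites_true = as.integer(n_segsites), seed = as.integer(seed)
  )
  write_truth(truth, paths$truth)
  invisible(paths)
}

write_stage_csv <- function(df, out_dir, name) {
  p <- file.path(out_dir, name)
  write.csv(df, p, row.names = FALSE)
  p
}

#' Run the full analysis pipeline
#'
#' Executes the staged analysis on the configured inputs: morphometrics
#' (GPA, relative warps) -> SNP filtering -> outlier scan -> neutral set ->
#' diversity / F_ST / isolation by distance / clustering -> P_ST traces and
#' P_ST-F_ST comparison -> mtDNA summaries. Result tables are written as
#' CSV under `cfg$out_dir` together with a manifest (file, md5) and a
#' key=value summary. A stage failure halts the run, preserving the outputs
#' of completed stages and a status file naming the failed stage.
#'
#' @param cfg a [pipeline_config()] with input paths and `out_dir` set.
#' @return Invisibly, a list with the per-stage results and the summary.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$out_dir)) abort("config needs out_dir")
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  status_path <- file.path(out_dir, "status.txt")
  summary <- list()
  results <- list()
  files <- character()
  stage <- function(name, f) {
    res <- tryCatch(f(), error = function(e) {
      writeLines(c(sprintf("failed_stage=%s", name),
                   sprintf("error=%s", conditionMessage(e))), status_path)
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    res
  }

  # --- morphometrics ---------------------------------------------------
  if (!is.null(cfg$tps_path)) {
    results$morpho <- stage("morpho", function() {
      sliders <- if (!is.null(cfg$sliders_path)) {
        read_sliders(cfg$sliders_path)
      } else {
        NULL
      }
      info <- NULL
      if (!is.null(cfg$popmap_path)) {
        pm <- read_popmap(cfg$popmap_path)
        info <- pm %>% rename(specimen_id = "individual")
      }
      lms <- read_tps(cfg$tps_path, sliders = sliders, info = info)
      sexes <- if ("sex" %in% names(lms$info) && !anyNA(lms$info$sex)) {
        split(seq_len(nrow(lms$info)), lms$info$sex)
      } else {
        list(all = seq_len(nrow(lms$info)))
      }
      per_sex <- lapply(names(sexes), function(sx) {
        idx <- sexes[[sx]]
        sub <- landmark_set(lms$coords[, , idx, drop = FALSE],
                            lms$info[idx, ], lms$roles)
        a <- gpa_align(sub, slide = isTRUE(cfg$morpho_slide) &&
                         any(lms$roles$role == "sliding"))
        rw <- relative_warps(a)
        files <<- c(files, write_stage_csv(
          tidy(rw), out_dir, sprintf("rw_scores_%s.csv", sx)
        ))
        rw
      })
      names(per_sex) <- names(sexes)
      per_sex
    })
    first_rw <- results$morpho[[1]]
    summary$rw1_pct_variance <- first_rw$pct_variance[1]
  }

  # --- SNP filtering and outlier scan ----------------------------------
  neutral <- NULL
  if (!is.null(cfg$genotype_path)) {
    results$filter <- stage("filter", function() {
      g <- read_genotypes(cfg$genotype_path, cfg$genotype_format)
      fl <- filter_snps(g, cfg$filter_locus_call_min, cfg$filter_ind_call_min,
                        cfg$filter_maf_min, cfg$filter_one_per_tag)
      files <<- c(files, write_stage_csv(fl$report, out_dir,
                                         "filter_report.csv"))
      fl
    })
    g <- results$filter$genotypes
    pm <- read_popmap(cfg$popmap_path)
    summary$n_loci_filtered <- ncol(g$genotypes)
    summary$n_individuals <- nrow(g$genotypes)

    results$outliers <- stage("outliers", function() {
      r1 <- trimmed_chisq_outliers(g, pm, trim = cfg$outlier_trim,
                                   he_min = cfg$outlier_he_min,
                                   q_thresh = cfg$outlier_q_thresh)
      K <- cfg$outlier_K
      if (is.null(K)) {
        K <- max(1L, length(unique(
          pm$population[pm$individual %in% rownames(g$genotypes)]
        )) - 1L)
      }
      r2 <- pca_mahalanobis_outliers(g, K = K,
                                     q_thresh = cfg$outlier_q_thresh)
      cons <- outlier_consensus(list(r1, r2),
                                min_methods = cfg$outlier_min_methods)
      per_locus <- bind_rows(
        mutate(as_tibble(r1), method = "trimmed_chisq"),
        mutate(as_tibble(r2), method = "pca_mahalanobis")
      )
      files <<- c(files, write_stage_csv(per_locus, out_dir,
                                         "outlier_scan.csv"))
      writeLines(cons$neutral_set, file.path(out_dir, "neutral_loci.txt"))
      files <<- c(files, file.path(out_dir, "neutral_loci.txt"))
      cons
    })
    neutral <- results$outliers$neutral_set
    summary$n_outliers <- length(results$outliers$outliers)
    summary$n_neutral <- length(neutral)

    results$popgen <- stage("popgen", function() {
      gn <- subset_genotypes(g, loci = neutral)
      # the popmap may also carry landmarked specimens; popgen uses only
      # the genotyped individuals
      pm_g <- filter(pm, .data$individual %in% rownames(gn$genotypes))
      div <- diversity(gn, pm_g)
      files <<- c(files, write_stage_csv(div, out_dir, "diversity.csv"))
      contrast <- diversity_contrast(he_by_locus(gn, pm_g))
      fst <- wc_fst(gn, pm_g, pairwise = TRUE)
      fst <- bootstrap_fst_ci(fst, n_boot = cfg$fst_n_boot,
                              seed = derive_seed(cfg$master_seed, "fst_boot"))
      files <<- c(files, write_stage_csv(
        as_tibble(fst$pairwise, rownames = "population"),
        out_dir, "fst_pairwise.csv"
      ))
      ibd <- NULL
      if (all(c("lat", "lon") %in% names(pm_g)) && !anyNA(pm_g$lat)) {
        dgeo <- population_distances(pm_g)
        dgeo_log <- log(dgeo + diag(nrow(dgeo)))  # log km, zero diagonal kept
        diag(dgeo_log) <- 0
        ord <- rownames(fst$pairwise)
        ibd <- mantel(fst$pairwise, dgeo_log[ord, ord],
                      n_perm = cfg$mantel_n_perm,
                      seed = derive_seed(cfg$master_seed, "ibd"))
      }
      cl <- dapc_cluster(gn, k_max = cfg$dapc_k_max, n_pcs = cfg$dapc_n_pcs,
                         seed = derive_seed(cfg$master_seed, "dapc"))
      files <<- c(files, write_stage_csv(cl$bic, out_dir, "dapc_bic.csv"))
      reg <- NULL
      if (!is.null(cfg$origin_lonlat)) {
        reg <- he_distance_regression(div, pm_g, cfg$origin_lonlat)
      }
      list(diversity = div, contrast = contrast, fst = fst, ibd = ibd,
           clusters = cl, he_regression = reg)
    })
    summary$theta_global <- results$popgen$fst$theta
    summary$theta_ci_lower <- unname(results$popgen$fst$ci[1])
    summary$theta_ci_upper <- unname(results$popgen$fst$ci[2])
    summary$dapc_best_k <- results$popgen$clusters$best_k
    if (!is.null(results$popgen$ibd)) {
      summary$ibd_mantel_r <- results$popgen$ibd$r
      summary$ibd_mantel_p <- results$popgen$ibd$p_value
    }
  }

  # --- P_ST ------------------------------------------------------------
  if (!is.null(results$morpho) && !is.null(results$popgen)) {
    results$pst <- stage("pst", function() {
      fst <- results$popgen$fst
      phi_grid <- seq(0, cfg$pst_phi_max, by = cfg$pst_phi_step)
      out <- list()
      for (sx in names(results$morpho)) {
        rw <- results$morpho[[sx]]
        pops <- rw$info$population
        n_axes <- min(cfg$morpho_n_axes, ncol(rw$scores))
        for (ax in seq_len(n_axes)) {
          adj <- size_adjust(rw$scores[, ax], rw$centroid_size)
          tr <- trace_pst(
            adj, pops, phi_grid = phi_grid, n_boot = cfg$pst_n_boot,
            fst_global = fst$theta,
            seed = derive_seed(cfg$master_seed, paste0("pst_", sx, ax)),
            trait_name = sprintf("%s_RW%d", sx, ax)
          )
          files <<- c(files, write_stage_csv(
            tidy(tr), out_dir, sprintf("pst_trace_%s_RW%d.csv", sx, ax)
          ))
          pw <- pairwise_pst(adj, pops)
          cmp_pops <- intersect(rownames(pw), rownames(fst$pairwise))
          cmp <- compare_pst_fst(
            pw[cmp_pops, cmp_pops], fst$pairwise[cmp_pops, cmp_pops],
            n_perm = cfg$mantel_n_perm,
            seed = derive_seed(cfg$master_seed, paste0("cmp_", sx, ax))
          )
          out[[sprintf("%s_RW%d", sx, ax)]] <-
            list(trace = tr, pairwise = pw, comparison = cmp)
        }
      }
      cmp_tab <- bind_rows(lapply(names(out), function(nm) {
        tibble(trait = nm, mantel_r = out[[nm]]$comparison$r,
               mantel_p = out[[nm]]$comparison$p_value,
               pst_1 = out[[nm]]$trace$pst_1,
               robust_flag = out[[nm]]$trace$robust_flag)
      }))
      files <<- c(files, write_stage_csv(cmp_tab, out_dir,
                                         "pst_fst_comparison.csv"))
      out
    })
    for (nm in names(results$pst)) {
      summary[[paste0("pst1_", nm)]] <- results$pst[[nm]]$trace$pst_1
      summary[[paste0("robust_", nm)]] <- results$pst[[nm]]$trace$robust_flag
    }
  }

  # --- mtDNA -----------------------------------------------------------
  if (!is.null(cfg$fasta_path)) {
    results$mtdna <- stage("mtdna", function() {
      seqs <- read_fasta(cfg$fasta_path)
      haps <- collapse_haplotypes(seqs)
      dm <- pdistance_matrix(seqs)
      files <<- c(files, write_stage_csv(
        as_tibble(haps$distance_matrix, rownames = "haplotype"),
        out_dir, "haplotype_distances.csv"
      ))
      net <- mst_network(haps)
      files <<- c(files, write_stage_csv(tidy(net), out_dir,
                                         "haplotype_network.csv"))
      tr <- NULL
      if (nrow(haps$haplotypes) >= 3) {
        tr <- nj_tree(haps$distance_matrix)
        ape::write.tree(tr, file.path(out_dir, "nj_tree.nwk"))
        files <<- c(files, file.path(out_dir, "nj_tree.nwk"))
      }
      list(haplotypes = haps, distances = dm, network = net, tree = tr)
    })
    summary$n_haplotypes <- nrow(results$mtdna$haplotypes$haplotypes)
    summary$n_segregating_sites <-
      segregating_sites(read_fasta(cfg$fasta_path))
    summary$max_p_distance <- max(results$mtdna$distances, na.rm = TRUE)
  }

  # --- manifest and summary -------------------------------------------
  summary_path <- file.path(out_dir, "summary.txt")
  writeLines(sprintf("%s=%s", names(summary),
                     vapply(summary, format, "", digits = 15)), summary_path)
  files <- c(files, summary_path)
  manifest <- tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  manifest <- bind_rows(manifest, tibble(
    file = "_params",
    md5 = unname(tools::md5sum(write_config_snapshot(cfg, out_dir)))
  ))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  writeLines("status=ok", status_path)
  invisible(list(results = results, summary = summary, manifest = manifest))
}

write_config_snapshot <- function(cfg, out_dir) {
  p <- file.path(out_dir, "config_used.txt")
  vals <- vapply(cfg, function(v) {
    if (is.null(v)) "NULL" else paste(format(v), collapse = ",")
  }, "")
  writeLines(sprintf("%s=%s", names(cfg), vals), p)
  p
}
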