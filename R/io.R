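# Readers and writers for the plain-text interchange formats: TPS landmark
# files (with an NTS-style sliders sidecar), genotype CSV, minimal VCF (GT
# only), popmap TSV, FASTA, and the simulation truth sidecar.

#' Read a TPS landmark file
#'
#' Parses LM=, ID=, IMAGE= and SCALE= records. When SCALE is present the
#' coordinates are multiplied by it. Sliding-semilandmark roles can be
#' attached from a sliders sidecar (see [read_sliders()]).
#'
#' @param path TPS file.
#' @param sliders optional tibble of (before, landmark, after) index triplets.
#' @param info optional specimen info tibble joined by `specimen_id`.
#' @return A [landmark_set()].
#' @export
read_tps <- function(path, sliders = NULL, info = NULL) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  lines <- readLines(path)
  specs <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^LM=", ln, ignore.case = TRUE)) {
      abort(sprintf("parse error at line %d: expected LM= record, got '%s'",
                    i, ln))
    }
    k <- as.integer(sub("^LM=", "", ln, ignore.case = TRUE))
    if (is.na(k) || k < 1) abort(sprintf("bad LM count at line %d", i))
    if (i + k > length(lines)) {
      abort(sprintf("line %d: LM=%d but file ends early", i, k))
    }
    xy <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      parts <- strsplit(trimws(lines[i + j]), "\\s+")[[1]]
      if (length(parts) < 2 || anyNA(suppressWarnings(as.numeric(parts[1:2])))) {
        abort(sprintf("line %d: expected 2 coordinates, got '%s'",
                      i + j, lines[i + j]))
      }
      xy[j, ] <- as.numeric(parts[1:2])
    }
    i <- i + k + 1L
    id <- NA_character_; image <- NA_character_; scale <- NA_real_
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (grepl("^ID=", ln, ignore.case = TRUE)) {
        id <- sub("^ID=", "", ln, ignore.case = TRUE)
      } else if (grepl("^IMAGE=", ln, ignore.case = TRUE)) {
        image <- sub("^IMAGE=", "", ln, ignore.case = TRUE)
      } else if (grepl("^SCALE=", ln, ignore.case = TRUE)) {
        scale <- as.numeric(sub("^SCALE=", "", ln, ignore.case = TRUE))
      } else if (ln == "") {
      } else {
        break
      }
      i <- i + 1L
    }
    if (!is.na(scale)) xy <- xy * scale
    specs[[length(specs) + 1L]] <- list(
      coords = xy,
      id = if (!is.na(id)) id else if (!is.na(image)) image else
        sprintf("spec_%03d", length(specs) + 1L)
    )
  }
  if (!length(specs)) abort("no configurations found")
  ks <- vapply(specs, function(s) nrow(s$coords), integer(1))
  if (length(unique(ks)) != 1) abort("configurations have differing LM counts")
  k <- ks[1]
  coords <- array(0, dim = c(k, 2, length(specs)),
                  dimnames = list(NULL, c("x", "y"),
                                  vapply(specs, `[[`, "", "id")))
  for (s in seq_along(specs)) coords[, , s] <- specs[[s]]$coords
  roles <- NULL
  if (!is.null(sliders)) {
    roles <- tibble(landmark = seq_len(k), role = "fixed",
                    before = NA_integer_, after = NA_integer_)
    roles$role[sliders$landmark] <- "sliding"
    roles$before[sliders$landmark] <- as.integer(sliders$before)
    roles$after[sliders$landmark] <- as.integer(sliders$after)
  }
  spec_info <- tibble(specimen_id = dimnames(coords)[[3]])
  if (!is.null(info)) spec_info <- left_join(spec_info, info, by = "specimen_id")
  landmark_set(coords, spec_info, roles)
}

#' Write a TPS landmark file
#'
#' @param lms a [landmark_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tps <- function(lms, path) {
  stopifnot(inherits(lms, "landmark_set"))
  k <- dim(lms$coords)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(dim(lms$coords)[3])) {
    writeLines(sprintf("LM=%d", k), con)
    writeLines(sprintf("%.10g %.10g", lms$coords[, 1, i],
                       lms$coords[, 2, i]), con)
    writeLines(sprintf("ID=%s", dimnames(lms$coords)[[3]][i]), con)
  }
  invisible(path)
}

#' Read a sliders sidecar file
#'
#' NTS-style triplets: three whitespace-separated integer columns
#' (predecessor, sliding landmark, successor), one row per semilandmark.
#' Lines starting with '#' are ignored.
#'
#' @param path sliders file.
#' @return Tibble: before, landmark, after.
#' @export
read_sliders <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  tab <- read.table(path, comment.char = "#",
                    col.names = c("before", "landmark", "after"))
  as_tibble(tab)
}

#' Write a sliders sidecar from landmark roles
#'
#' @param roles roles tibble of a [landmark_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sliders <- function(roles, path) {
  sl <- roles[roles$role == "sliding", ]
  writeLines(sprintf("%d %d %d", sl$before, sl$landmark, sl$after), path)
  invisible(path)
}

#' Read genotypes from CSV or VCF
#'
#' CSV dialect: one row per locus with columns `locus_id`, `tag_id`,
#' `position`, then one column per individual holding 0/1/2 or empty/NA.
#' VCF: biallelic SNPs only; the GT subfield is parsed to minor-allele
#' counts; "./." becomes missing; multi-allelic records are skipped with a
#' warning.
#'
#' @param path input file.
#' @param format "csv" or "vcf".
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("csv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste("no such file:", path))
  if (format == "csv") {
    tab <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    need <- c("locus_id", "tag_id", "position")
    missing_cols <- setdiff(need, names(tab))
    if (length(missing_cols)) {
      abort(paste("genotype CSV lacks required column(s):",
                  paste(missing_cols, collapse = ", ")))
    }
    ind_cols <- setdiff(names(tab), need)
    if (!length(ind_cols)) abort("genotype CSV has no individual columns")
    gt <- t(as.matrix(tab[, ind_cols, drop = FALSE]))
    mode(gt) <- "integer"
    colnames(gt) <- tab$locus_id
    rownames(gt) <- ind_cols
    bad <- which(!is.na(gt) & !(gt %in% 0:2), arr.ind = TRUE)
    if (nrow(bad)) {
      abort(sprintf(
        "invalid genotype value at individual '%s', locus '%s': %s",
        rownames(gt)[bad[1, 1]], colnames(gt)[bad[1, 2]],
        gt[bad[1, 1], bad[1, 2]]
      ))
    }
    genotype_matrix(gt, tibble(locus_id = tab$locus_id, tag_id = tab$tag_id,
                               position = tab$position))
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    biallelic <- vcfR::is.biallelic(v)
    n_skip <- sum(!biallelic)
    if (n_skip > 0) {
      warn(sprintf("skipped %d multi-allelic record(s)", n_skip))
      v <- v[biallelic, ]
    }
    gt_raw <- vcfR::extract.gt(v, element = "GT")
    counts <- matrix(NA_integer_, nrow = nrow(gt_raw), ncol = ncol(gt_raw),
                     dimnames = dimnames(gt_raw))
    clean <- gsub("\\|", "/", gt_raw)
    counts[clean == "0/0"] <- 0L
    counts[clean %in% c("0/1", "1/0")] <- 1L
    counts[clean == "1/1"] <- 2L
    gt <- t(counts)
    ids <- vcfR::getID(v)
    chrom <- vcfR::getCHROM(v)
    pos <- vcfR::getPOS(v)
    locus_id <- ifelse(is.na(ids) | ids == ".",
                       paste0(chrom, "_", pos), ids)
    colnames(gt) <- locus_id
    genotype_matrix(gt, tibble(locus_id = locus_id, tag_id = chrom,
                               position = pos))
  }
}

#' Write genotypes as CSV
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  tab <- cbind(
    as.data.frame(g$locus_meta[, c("locus_id", "tag_id", "position")]),
    as.data.frame(t(g$genotypes))
  )
  write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a popmap TSV
#'
#' Tab-separated with header: individual, population, and optionally
#' region, lat, lon.
#'
#' @param path popmap file.
#' @return Popmap tibble.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  as_popmap(as_tibble(read.table(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)))
}

#' Write a popmap TSV
#' @param pm popmap tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(pm, path) {
  utils::write.table(pm, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read aligned sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  dna <- ape::read.FASTA(path)
  toupper(vapply(as.character(dna), paste0, "", collapse = ""))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  invisible(path)
}

#' Write a simulation truth sidecar
#'
#' Plain key=value text with every [sim_truth()] field.
#'
#' @param truth a `sim_truth`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  writeLines(sprintf("%s=%s", names(truth),
                     vapply(truth, format, "", digits = 15)), path)
  invisible(path)
}

#' Read a simulation truth sidecar
#' @param path truth file.
#' @return A `sim_truth`.
#' @export
read_truth <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- setNames(vapply(kv, `[[`, "", 2), vapply(kv, `[[`, "", 1))
  sim_truth(
    fst_true = as.numeric(vals[["fst_true"]]),
    sigma2_B_true = as.numeric(vals[["sigma2_B_true"]]),
    sigma2_W_true = as.numeric(vals[["sigma2_W_true"]]),
    n_segsites_true = as.integer(vals[["n_segsites_true"]]),
    seed = as.integer(vals[["seed"]])
  )
}
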