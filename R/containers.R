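#' Construct a genotype matrix container
#'
#' Biallelic SNP genotypes coded as minor-allele counts 0/1/2 with `NA` for
#' missing calls, plus per-locus metadata. Rows are individuals, columns loci.
#'
#' @param genotypes integer matrix, individuals x loci, values in
#'   \{0, 1, 2, NA\}; must carry row and column names.
#' @param locus_meta tibble with one row per locus: `locus_id`, `tag_id`
#'   (sequence-tag identifier shared by SNPs on the same fragment) and
#'   `position` (SNP position within the tag). Defaults to one tag per locus.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, locus_meta = NULL) {
  if (!is.matrix(genotypes)) abort("`genotypes` must be a matrix")
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% 0:2)) {
    bad <- which(!is.na(genotypes) & !(genotypes %in% 0:2), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "genotypes must be 0/1/2/NA; offending cell individual '%s', locus '%s'",
      rownames(genotypes)[bad[1]], colnames(genotypes)[bad[2]]
    ))
  }
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- sprintf("ind_%03d", seq_len(nrow(genotypes)))
  }
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- sprintf("loc_%05d", seq_len(ncol(genotypes)))
  }
  if (is.null(locus_meta)) {
    locus_meta <- tibble(
      locus_id = colnames(genotypes),
      tag_id = colnames(genotypes),
      position = 1L
    )
  }
  stopifnot(all(c("locus_id", "tag_id", "position") %in% names(locus_meta)))
  cn <- colnames(genotypes)
  if (is.null(cn)) cn <- character(0)  # zero-locus matrices drop dimnames
  if (!identical(as.character(locus_meta$locus_id), cn)) {
    abort("locus_meta$locus_id must match colnames(genotypes) in order")
  }
  if (any(!nzchar(locus_meta$tag_id))) abort("tag_id must be non-empty")
  structure(
    list(genotypes = genotypes, locus_meta = as_tibble(locus_meta)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  g <- x$genotypes
  cat(sprintf(
    "<genotype_matrix> %d individuals x %d loci (%.1f%% missing)\n",
    nrow(g), ncol(g), 100 * mean(is.na(g))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Per-locus summary statistics
#'
#' Call rate, minor allele frequency (computed over called genotypes) and
#' monomorphism flag per locus, joined to the tag metadata.
#'
#' @param g a [genotype_matrix()].
#' @return Tibble with one row per locus: `locus_id`, `tag_id`, `position`,
#'   `call_rate`, `maf`, `monomorphic`.
#' @export
locus_stats <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  gt <- g$genotypes
  n_called <- colSums(!is.na(gt))
  call_rate <- n_called / nrow(gt)
  p <- colSums(gt, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  p[n_called == 0] <- NA_real_
  maf <- pmin(p, 1 - p)
  mono <- vapply(seq_len(ncol(gt)), function(j) {
    v <- gt[, j]
    length(unique(v[!is.na(v)])) <= 1L
  }, logical(1))
  g$locus_meta %>%
    mutate(call_rate = unname(call_rate), maf = unname(maf),
           monomorphic = mono)
}

#' Per-individual call rates
#'
#' @param g a [genotype_matrix()].
#' @return Tibble: `individual`, `call_rate`.
#' @export
individual_stats <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  gt <- g$genotypes
  cr <- if (ncol(gt) == 0) rep(0, nrow(gt)) else rowMeans(!is.na(gt))
  tibble(
    individual = rownames(gt),
    call_rate = cr
  )
}

#' @export
tidy.genotype_matrix <- function(x, ...) {
  gt <- x$genotypes
  as_tibble(gt, rownames = "individual") %>%
    tidyr::pivot_longer(-"individual", names_to = "locus_id",
                        values_to = "genotype")
}

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param g a [genotype_matrix()].
#' @param individuals row selector (names or indices); NULL keeps all.
#' @param loci column selector (locus ids or indices); NULL keeps all.
#' @return A [genotype_matrix()] with metadata subset in step.
#' @export
subset_genotypes <- function(g, individuals = NULL, loci = NULL) {
  gt <- g$genotypes
  if (!is.null(individuals)) gt <- gt[individuals, , drop = FALSE]
  meta <- g$locus_meta
  if (!is.null(loci)) {
    gt <- gt[, loci, drop = FALSE]
    meta <- meta[match(colnames(gt), meta$locus_id), ]
  }
  genotype_matrix(gt, meta)
}

#' Construct a landmark set
#'
#' A collection of 2-D landmark configurations sharing a common landmark
#' scheme, with fixed/sliding roles for semilandmark handling.
#'
#' @param coords numeric array k x 2 x n (landmarks, xy, specimens) with
#'   specimen names on the third dimension.
#' @param info tibble with one row per specimen: `specimen_id` plus optional
#'   `population`, `region`, `sex`.
#' @param roles tibble with one row per landmark: `landmark` (index), `role`
#'   ("fixed" or "sliding"), and for sliders the neighbour indices `before`,
#'   `after` defining the chord tangent. Defaults to all-fixed.
#' @return Object of class `landmark_set`.
#' @export
landmark_set <- function(coords, info = NULL, roles = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 2L)
  k <- dim(coords)[1]
  n <- dim(coords)[3]
  if (is.null(dimnames(coords)[[3]])) {
    dimnames(coords)[[3]] <- sprintf("spec_%03d", seq_len(n))
  }
  if (is.null(info)) {
    info <- tibble(specimen_id = dimnames(coords)[[3]])
  }
  stopifnot("specimen_id" %in% names(info), nrow(info) == n)
  if (is.null(roles)) {
    roles <- tibble(landmark = seq_len(k), role = "fixed",
                    before = NA_integer_, after = NA_integer_)
  }
  stopifnot(nrow(roles) == k, all(roles$role %in% c("fixed", "sliding")))
  sl <- roles$role == "sliding"
  if (any(sl)) {
    ok <- !is.na(roles$before[sl]) & !is.na(roles$after[sl]) &
      roles$before[sl] >= 1 & roles$after[sl] <= k
    if (!all(ok)) abort("sliding landmarks need valid before/after indices")
  }
  for (i in seq_len(n)) {
    if (anyDuplicated(round(coords[, , i], 12))) {
      abort(sprintf("coincident landmarks in specimen %s",
                    dimnames(coords)[[3]][i]))
    }
  }
  structure(list(coords = coords, info = as_tibble(info),
                 roles = as_tibble(roles)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<landmark_set> %d specimens, %d landmarks (%d sliding)\n",
              d[3], d[1], sum(x$roles$role == "sliding")))
  invisible(x)
}

#' @export
tidy.landmark_set <- function(x, ...) {
  d <- dim(x$coords)
  out <- tibble(
    specimen_id = rep(dimnames(x$coords)[[3]], each = d[1]),
    landmark = rep(seq_len(d[1]), times = d[3]),
    x = as.vector(x$coords[, 1, ]),
    y = as.vector(x$coords[, 2, ])
  )
  left_join(out, x$info, by = "specimen_id")
}

#' Validate a population map
#'
#' @param pm tibble/data.frame with columns `individual`, `population` and
#'   optionally `region`, `lat`, `lon`.
#' @param individuals optional character vector that must all be mapped.
#' @return The popmap as a tibble (invisibly validated).
#' @export
as_popmap <- function(pm, individuals = NULL) {
  pm <- as_tibble(pm)
  stopifnot(all(c("individual", "population") %in% names(pm)))
  if (!is.null(individuals)) {
    missing_ind <- setdiff(individuals, pm$individual)
    if (length(missing_ind)) {
      abort(sprintf("popmap is missing %d individuals (e.g. %s)",
                    length(missing_ind), missing_ind[1]))
    }
  }
  pm
}
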