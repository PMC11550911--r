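# Mitochondrial COI summaries: p-distances, haplotype collapse, segregating
# sites, neighbor-joining tree, and minimum-spanning haplotype network.

seqs_to_char_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) abort("sequences must be aligned (equal length)")
  m <- t(vapply(strsplit(toupper(seqs), ""), identity,
                character(lens[1])))
  rownames(m) <- names(seqs)
  m
}

RESOLVED_BASES <- c("A", "C", "G", "T")

#' Pairwise uncorrected p-distance matrix
#'
#' Percent sequence divergence with pairwise deletion: positions where
#' either sequence carries N or a gap are excluded from that comparison.
#' No substitution-model correction is applied.
#'
#' @param seqs named character vector of aligned sequences (A/C/G/T/N/-).
#' @return Symmetric matrix of percent distances; NA where no comparable
#'   positions remain.
#' @export
pdistance_matrix <- function(seqs) {
  m <- seqs_to_char_matrix(seqs)
  n <- nrow(m)
  res <- ok <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  resolved <- matrix(m %in% RESOLVED_BASES, nrow = n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      comp <- resolved[i, ] & resolved[j, ]
      nc <- sum(comp)
      if (nc == 0) {
        res[i, j] <- res[j, i] <- NA_real_
      } else {
        d <- sum(m[i, comp] != m[j, comp]) / nc
        res[i, j] <- res[j, i] <- 100 * d
      }
    }
  }
  res
}

#' Collapse sequences into haplotypes
#'
#' Exact string-equality collapse: sequences differing only at N/gap
#' positions are kept distinct. Haplotype IDs are assigned by first
#' occurrence.
#'
#' @param seqs named character vector of aligned sequences.
#' @param labels optional per-sequence grouping (e.g. population) recorded
#'   in the haplotype composition.
#' @return Object of class `haplotype_set`: `haplotypes` (tibble:
#'   haplotype_id, sequence, frequency), `membership` (tibble: sequence_id,
#'   haplotype_id, label), `distance_matrix` (percent p-distances between
#'   unique haplotypes).
#' @export
collapse_haplotypes <- function(seqs, labels = NULL) {
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq_%03d", seq_along(seqs))
  if (is.null(labels)) labels <- rep(NA_character_, length(seqs))
  seqs_up <- toupper(seqs)
  uniq <- unique(seqs_up)
  hap_id <- sprintf("H%02d", seq_along(uniq))
  idx <- match(seqs_up, uniq)
  haps <- setNames(uniq, hap_id)
  structure(
    list(
      haplotypes = tibble(
        haplotype_id = hap_id,
        sequence = uniq,
        frequency = as.integer(table(factor(idx, levels = seq_along(uniq))))
      ),
      membership = tibble(
        sequence_id = names(seqs),
        haplotype_id = hap_id[idx],
        label = labels
      ),
      distance_matrix = pdistance_matrix(haps)
    ),
    class = "haplotype_set"
  )
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotypes from %d sequences\n",
              nrow(x$haplotypes), nrow(x$membership)))
  invisible(x)
}

#' @export
tidy.haplotype_set <- function(x, ...) {
  x$membership %>%
    dplyr::count(.data$haplotype_id, .data$label, name = "n") %>%
    left_join(select(x$haplotypes, "haplotype_id", "frequency"),
              by = "haplotype_id")
}

#' Count segregating sites
#'
#' Number of alignment columns with at least two distinct resolved
#' (non-N, non-gap) nucleotide states.
#'
#' @param seqs named character vector of aligned sequences.
#' @return Integer count.
#' @export
segregating_sites <- function(seqs) {
  m <- seqs_to_char_matrix(seqs)
  sum(apply(m, 2, function(col) {
    length(unique(col[col %in% RESOLVED_BASES])) >= 2
  }))
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix (via ape). Negative
#' branch lengths are clamped to zero with the deficit transferred to the
#' sibling branch so that path lengths are approximately preserved.
#' Optionally rooted on an outgroup.
#'
#' @param d symmetric distance matrix with taxon dimnames (>= 3 taxa, no
#'   NA entries).
#' @param outgroup optional taxon label to root on.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(d, outgroup = NULL) {
  d <- as.matrix(d)
  if (anyNA(d)) abort("distance matrix contains NA entries")
  if (nrow(d) < 3) abort("need >= 3 taxa")
  tr <- ape::nj(as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent & seq_along(tr$edge.length) != e)
    tr$edge.length[e] <- 0
    if (length(sibs)) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + deficit
    }
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label) abort("outgroup not among taxa")
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  tr
}

# absolute-count Hamming distances between haplotype sequences (positions
# with unresolved states in either sequence are skipped)
hamming_matrix <- function(seqs) {
  m <- seqs_to_char_matrix(seqs)
  n <- nrow(m)
  res <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  resolved <- matrix(m %in% RESOLVED_BASES, nrow = n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      comp <- resolved[i, ] & resolved[j, ]
      res[i, j] <- res[j, i] <- sum(m[i, comp] != m[j, comp])
    }
  }
  res
}

#' Minimum-spanning haplotype network
#'
#' Kruskal minimum spanning tree on absolute-count mutational (Hamming)
#' distances between haplotypes. Non-tree edges whose weight ties the
#' maximum edge weight on the tree path between their endpoints are
#' reported as co-minimal alternative connections.
#'
#' @param h a `haplotype_set` from [collapse_haplotypes()].
#' @return Object of class `haplotype_network`: `edges` (tibble: from, to,
#'   steps), `alternatives` (same columns), `distances` (the Hamming
#'   matrix).
#' @export
mst_network <- function(h) {
  stopifnot(inherits(h, "haplotype_set"))
  seqs <- setNames(h$haplotypes$sequence, h$haplotypes$haplotype_id)
  if (length(seqs) < 2) abort("need >= 2 haplotypes")
  dm <- hamming_matrix(seqs)
  g <- igraph::graph_from_adjacency_matrix(dm, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  el <- igraph::as_edgelist(mst)
  edges <- tibble(
    from = el[, 1], to = el[, 2],
    steps = igraph::E(mst)$weight
  )
  # alternatives: non-tree edges tying the cycle maximum
  all_el <- igraph::as_edgelist(g)
  all_w <- igraph::E(g)$weight
  in_tree <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  alts <- list()
  for (e in seq_len(nrow(all_el))) {
    key <- paste(pmin(all_el[e, 1], all_el[e, 2]),
                 pmax(all_el[e, 1], all_el[e, 2]))
    if (key %in% in_tree) next
    path <- igraph::shortest_paths(mst, from = all_el[e, 1],
                                   to = all_el[e, 2], output = "epath")
    pw <- igraph::E(mst)$weight[as.integer(path$epath[[1]])]
    if (length(pw) && all_w[e] <= max(pw)) {
      alts[[length(alts) + 1]] <- tibble(
        from = all_el[e, 1], to = all_el[e, 2], steps = all_w[e]
      )
    }
  }
  structure(
    list(
      edges = edges,
      alternatives = if (length(alts)) bind_rows(alts) else
        tibble(from = character(), to = character(), steps = numeric()),
      distances = dm
    ),
    class = "haplotype_network"
  )
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype_network> %d tree edges, %d alternatives\n",
              nrow(x$edges), nrow(x$alternatives)))
  invisible(x)
}

#' @export
tidy.haplotype_network <- function(x, ...) {
  bind_rows(
    mutate(x$edges, type = "tree"),
    mutate(x$alternatives, type = "alternative")
  )
}
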