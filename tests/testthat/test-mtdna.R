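test_that("p-distances follow the fragment arithmetic and an oracle", {
  pr <- seq_pair_with_diffs(612, 6)
  d <- pdistance_matrix(pr)
  expect_equal(d["one", "two"], 100 * 6 / 612, tolerance = 1e-12)
  expect_equal(d["one", "one"], 0)
  # N and gap positions drop out pairwise
  s <- c(a = "ACGTACGT", b = "ACGTNCGA", c = "AC-TACGA")
  dm <- pdistance_matrix(s)
  expect_equal(dm["a", "b"], 100 * 1 / 7)
  expect_equal(dm["a", "c"], 100 * 1 / 7)
  # brute-force per-pair oracle on simulated divergence
  h <- simulate_haplotypes(8, 300, 25, seed = 61)
  dm2 <- pdistance_matrix(h$sequences)
  for (i in 1:7) {
    for (j in (i + 1):8) {
      expect_equal(dm2[i, j],
                   brute_pdist(h$sequences[i], h$sequences[j]))
    }
  }
  # agreement with the established raw-distance implementation
  dna <- ape::as.DNAbin(strsplit(h$sequences, ""))
  d_ape <- as.matrix(ape::dist.dna(dna, model = "raw",
                                   pairwise.deletion = TRUE)) * 100
  expect_equal(unname(dm2), unname(d_ape), tolerance = 1e-12)
  expect_error(pdistance_matrix(c("ACGT", "ACG")), "aligned")
})

test_that("haplotype collapse is strict and order-stable", {
  h <- simulate_haplotypes(60, 612, 42, dup_profile = rep(4L, 15), seed = 62)
  hs <- collapse_haplotypes(h$sequences)
  expect_equal(nrow(hs$haplotypes), 15)
  expect_equal(sum(hs$haplotypes$frequency), 60)
  # sequences differing only at N are NOT merged
  sn <- c(x = "ACGT", y = "ACGN")
  expect_equal(nrow(collapse_haplotypes(sn)$haplotypes), 2)
  # all identical
  expect_equal(nrow(collapse_haplotypes(c(a = "AAAA", b = "AAAA"))$haplotypes), 1)
  # permuting input order: same haplotype set, ids by first occurrence
  perm <- rev(seq_along(h$sequences))
  hs2 <- collapse_haplotypes(h$sequences[perm])
  expect_setequal(hs2$haplotypes$sequence, hs$haplotypes$sequence)
  expect_equal(hs2$haplotypes$sequence[1], unname(h$sequences[perm][1]))
  # max pairwise distance invariant under deduplication
  expect_equal(max(pdistance_matrix(h$sequences)),
               max(hs$distance_matrix))
})

test_that("segregating sites count resolved polymorphic columns", {
  expect_equal(segregating_sites(c("AAA", "AAT", "AAA")), 1)
  # a column with only N against one resolved state is not polymorphic
  expect_equal(segregating_sites(c("NA-", "AAT", "AAA")), 1)
  h <- simulate_haplotypes(20, 400, 42, dup_profile = rep(2L, 10), seed = 63)
  expect_equal(segregating_sites(h$sequences), 42)
})

test_that("neighbor joining recovers additive trees exactly", {
  # 4 taxa from a known tree: ((a:1,b:2):1.5,c:3,d:1)
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- 3; d["a", "c"] <- 5.5; d["a", "d"] <- 3.5
  d["b", "c"] <- 6.5; d["b", "d"] <- 4.5; d["c", "d"] <- 4
  d <- d + t(d)
  tr <- nj_tree(d)
  expect_equal(unname(stats::cophenetic(tr)[rownames(d), colnames(d)]),
               unname(d), tolerance = 1e-12)
  expect_true(all(tr$edge.length >= 0))
  # 3 taxa: closed-form three-point branch lengths
  d3 <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  d3["x", "y"] <- 5; d3["x", "z"] <- 7; d3["y", "z"] <- 8
  d3 <- d3 + t(d3)
  t3 <- nj_tree(d3)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[["x"]], (5 + 7 - 8) / 2)
  expect_equal(bl[["y"]], (5 + 8 - 7) / 2)
  expect_equal(bl[["z"]], (7 + 8 - 5) / 2)
  expect_error(nj_tree(d3[1:2, 1:2]), "3 taxa")
  dna <- d; dna[1, 2] <- dna[2, 1] <- NA
  expect_error(nj_tree(dna), "NA")
})

test_that("two distance-separated clades come out monophyletic", {
  # within-clade < 3%, between-clade > 11%, the scale separating
  # intraspecific from interspecific divergence
  taxa <- c("a1", "a2", "a3", "b1", "b2", "b3")
  d <- matrix(11.5, 6, 6, dimnames = list(taxa, taxa))
  d[1:3, 1:3] <- 1.5
  d[4:6, 4:6] <- 2.5
  diag(d) <- 0
  d <- (d + t(d)) / 2
  tr <- ape::root(nj_tree(d), outgroup = "b1", resolve.root = TRUE)
  expect_true(ape::is.monophyletic(tr, c("a1", "a2", "a3")))
})

test_that("the minimum-spanning network has the planted topology", {
  # three haplotypes in a line: A-1-B-1-C with d(A,C) = 2
  s <- c(A = "AAAA", B = "AAAT", C = "AATT")
  hs <- collapse_haplotypes(s)
  net <- mst_network(hs)
  edges <- paste(pmin(net$edges$from, net$edges$to),
                 pmax(net$edges$from, net$edges$to))
  expect_equal(nrow(net$edges), 2)
  expect_true(all(net$edges$steps == 1))
  expect_equal(nrow(net$alternatives), 0)
  # star genealogy: hub has maximal degree
  hub <- "AAAAAAAA"
  tips <- vapply(1:5, function(i) {
    x <- strsplit(hub, "")[[1]]
    x[i] <- "T"
    paste(x, collapse = "")
  }, "")
  star <- collapse_haplotypes(setNames(c(hub, tips), paste0("s", 0:5)))
  net_star <- mst_network(star)
  deg <- table(c(net_star$edges$from, net_star$edges$to))
  hub_id <- star$membership$haplotype_id[1]
  expect_equal(names(which.max(deg)), hub_id)
  # spanning-tree property
  h <- simulate_haplotypes(30, 200, 25, dup_profile = rep(3L, 10), seed = 64)
  net_h <- mst_network(collapse_haplotypes(h$sequences))
  expect_equal(nrow(net_h$edges), 10 - 1)
})
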