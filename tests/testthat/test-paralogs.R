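test_that("percent identity follows the unit-score global-alignment definition", {
  s <- "ACDEFGHIKL"
  expect_equal(pairwise_identity(s, s), 100)
  expect_equal(pairwise_identity(s, "ACDEFGHIKV"), 90)
  # one match over two alignment columns, whichever end gaps
  expect_equal(pairwise_identity("A", "AA"), 50)
  expect_equal(pairwise_identity("AA", "A"), 50)
  expect_error(pairwise_identity("", "AA"), "nonempty")
  # symmetry on arbitrary pairs
  set.seed(4)
  for (i in 1:5) {
    a <- paste(sample(c("A", "C", "D", "E"), 30, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "D", "E"), 25, TRUE), collapse = "")
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("identity matrices are symmetric with a 100 diagonal", {
  sim <- simulate_panel(3, 1, 2, p_dup = 1, dup_copies = 2, seed = 13)
  seqs <- dplyr::filter(sim$hits, gene == "G0001")
  v <- setNames(seqs$sequence, paste(seqs$species, seqs$paralog_index, sep = "|"))
  m <- identity_matrix(v)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(100, length(v)))
  expect_true(all(m >= 0 & m <= 100))
})

test_that("duplication detection flags genes with a duplicated Neoave median", {
  hits <- dplyr::bind_rows(
    tidyr::expand_grid(species = paste0("n", 1:4), clade = "neoaves",
                       gene = "dup", paralog_index = 1:2),
    tidyr::expand_grid(species = paste0("n", 1:4), clade = "neoaves",
                       gene = "single", paralog_index = 1L)
  ) |> dplyr::mutate(hit_length = 100L)
  out <- detect_duplications(hits)
  expect_true(out$duplicated_in_neoaves[out$gene == "dup"])
  expect_equal(out$median_neoave_paralogs[out$gene == "dup"], 2)
  expect_false(out$duplicated_in_neoaves[out$gene == "single"])
  expect_equal(nrow(detect_duplications(hits[0, ])), 0)
})

test_that("simulated duplications are recovered exactly at p_dup = 1", {
  sim <- simulate_panel(5, 2, 3, p_dup = 1, dup_copies = 3, seed = 17)
  out <- detect_duplications(sim$hits)
  expect_true(all(out$duplicated_in_neoaves))
  expect_equal(out$median_neoave_paralogs, rep(3, 3))
})

test_that("three-sequence phylogram reproduces the hand-computed NJ lengths", {
  # gap-free sequences of length 100 with d(A,B) = 2, d(A,C) = d(B,C) = 8:
  # NJ splits the external branches as 1, 1, 7
  base <- strsplit(paste(rep("ACDEFGHIKL", 10), collapse = ""), "")[[1]]
  b <- base; b[1:2] <- "W"
  c_ <- base; c_[1] <- "W"; c_[11:17] <- "Y"
  seqs <- c(A = paste(base, collapse = ""), B = paste(b, collapse = ""),
            C = paste(c_, collapse = ""))
  pc <- build_phylogram(seqs)
  expect_setequal(pc$tree$tip.label, c("A", "B", "C"))
  lens <- setNames(pc$tree$edge.length[match(1:3, pc$tree$edge[, 2])],
                   pc$tree$tip.label)
  expect_equal(unname(lens[c("A", "B", "C")]), c(1, 1, 7))
})

test_that("identical sequences cluster together away from a divergent one", {
  base <- paste(rep("ACDEFGHIKL", 5), collapse = "")
  far <- paste(rep("YWYWYWYWYW", 5), collapse = "")
  seqs <- c(id1 = base, id2 = base, id3 = far)
  pc <- build_phylogram(seqs, cluster_cutoff = 80)
  expect_equal(pc$clusters[["id1"]], pc$clusters[["id2"]])
  expect_false(pc$clusters[["id3"]] == pc$clusters[["id1"]])
  expect_equal(glance(pc)$n_clusters, 2L)
  expect_error(build_phylogram(seqs[1:2]), "at least 3")
})

test_that("NJ equals brute-force minimum evolution on additive matrices (<= 5 taxa)", {
  set.seed(99)
  for (ntax in c(4, 5)) {
    for (rep in 1:5) {
      true_tree <- ape::rtree(ntax, tip.label = paste0("t", seq_len(ntax)))
      true_tree$edge.length <- sample(1:6, nrow(true_tree$edge), replace = TRUE)
      seqs <- seqs_from_tree(true_tree)
      pc <- build_phylogram(seqs)
      dm <- as.dist(100 - pc$identity)
      best <- brute_force_me(dm)
      expect_equal(phangorn::RF.dist(ape::unroot(pc$tree), ape::unroot(best)), 0)
      expect_equal(phangorn::RF.dist(ape::unroot(pc$tree), ape::unroot(true_tree)), 0)
    }
  }
})

test_that("phylogram output is deterministic, complete and non-negative", {
  sim <- simulate_panel(4, 2, 1, p_dup = 1, dup_copies = 2,
                        paralog_identity = 70, seed = 23)
  seqs <- dplyr::filter(sim$hits, gene == "G0001")
  v <- setNames(seqs$sequence, paste(seqs$species, seqs$paralog_index, sep = "|"))
  pc1 <- build_phylogram(v)
  pc2 <- build_phylogram(rev(v))  # input order must not matter
  expect_equal(ape::write.tree(pc1$tree), ape::write.tree(pc2$tree))
  expect_setequal(pc1$tree$tip.label, names(v))
  expect_true(all(pc1$tree$edge.length >= 0))
})

test_that("max_sequences truncates deterministically after alphabetical ordering", {
  seqs <- setNames(rep(paste(rep("ACDEFGHIKL", 3), collapse = ""), 6),
                   c("d", "b", "f", "a", "c", "e"))
  pc <- build_phylogram(seqs, max_sequences = 4)
  expect_setequal(rownames(pc$identity), c("a", "b", "c", "d"))
  expect_error(build_phylogram(seqs, max_sequences = 2), "max_sequences")
})

test_that("simulated two-paralog families recover cluster structure and identity", {
  sim <- simulate_panel(8, 2, 1, p_dup = 1, dup_copies = 2,
                        paralog_identity = 70, species_divergence = 0.02,
                        seed = 29)
  seqs <- dplyr::filter(sim$hits, gene == "G0001", clade == "neoaves")
  v <- setNames(seqs$sequence, paste(seqs$species, seqs$paralog_index, sep = "|"))
  pc <- build_phylogram(v, cluster_cutoff = 80)
  expect_equal(glance(pc)$n_clusters, 2L)
  # all members of a cluster share the paralog index
  idx <- sub(".*\\|", "", names(pc$clusters))
  expect_true(all(tapply(idx, pc$clusters, function(x) length(unique(x))) == 1))
  # within-cluster identity ~= 100 (1 - species_divergence)^2
  expect_lt(abs(pc$within_identity - 100 * 0.98^2), 3)
})
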