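seq_panel <- function(...) {
  seqs <- c(...)
  tibble::tibble(id = names(seqs), sequence = unname(seqs))
}

test_that("p-distance excludes missing sites pairwise", {
  dm <- p_distance_matrix(seq_panel(a = "AAAA", b = "AAAA"), min_sites = 1)
  expect_equal(dm$d["a", "b"], 0)
  dm <- p_distance_matrix(seq_panel(a = "AAAA", b = "AAAT"), min_sites = 1)
  expect_equal(dm$d["a", "b"], 0.25)
  dm <- p_distance_matrix(seq_panel(a = "AANA", b = "AATA"), min_sites = 1)
  expect_equal(dm$d["a", "b"], 0)
  expect_equal(dm$n_comparable["a", "b"], 3)
  expect_error(
    p_distance_matrix(seq_panel(x = "NNNN", y = "AAAA"), min_sites = 1),
    "'x' / 'y'"
  )
})

test_that("p-distance is symmetric and invariant to accession order", {
  panel <- random_panel(3, 8, 60, p_missing = 0.1)
  dm <- p_distance_matrix(panel, min_sites = 10)
  expect_equal(dm$d, t(dm$d))
  expect_true(all(diag(dm$d) == 0))
  perm <- panel[sample(nrow(panel)), ]
  dm2 <- p_distance_matrix(perm, min_sites = 10)
  expect_equal(dm2$d[dm$labels, dm$labels], dm$d)
})

test_that("allele-aware distances score het vs constituent hom as half", {
  dm <- p_distance_matrix(seq_panel(a = "AR", b = "AA"), min_sites = 1,
                          allele_aware = TRUE)
  expect_equal(dm$d["a", "b"], 0.25)   # (0 + 0.5) / 2
  dm <- p_distance_matrix(seq_panel(a = "R", b = "Y"), min_sites = 1,
                          allele_aware = TRUE)
  expect_equal(dm$d["a", "b"], 1)      # A/G vs C/T share nothing
  dm <- p_distance_matrix(seq_panel(a = "R", b = "S"), min_sites = 1,
                          allele_aware = TRUE)
  expect_equal(dm$d["a", "b"], 0.5)    # share G
})

test_that("three-taxon NJ reproduces the closed-form limb lengths", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(D)
  limb <- setNames(tree$edge.length[match(seq_len(3), tree$edge[, 2])],
                   tree$tip.label)
  expect_equal(limb[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
})

test_that("the first NJ join matches an explicit Q-matrix minimum", {
  withr::with_seed(11, {
    base <- ape::rtree(4, rooted = FALSE)
    D <- ape::cophenetic.phylo(base)
  })
  n <- 4
  R <- rowSums(D)
  Q <- (n - 2) * D - outer(R, R, "+")
  diag(Q) <- Inf
  expected_pair <- sort(rownames(D)[which(Q == min(Q),
                                          arr.ind = TRUE)[1, ]])
  tree <- nj_tree(D)
  # the Q-minimal pair must form a cherry in the NJ tree
  tips <- match(expected_pair, tree$tip.label)
  parents <- tree$edge[match(tips, tree$edge[, 2]), 1]
  expect_equal(parents[1], parents[2])
})

test_that("NJ recovers random additive trees exactly", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      ntaxa <- sample(5:8, 1)
      gen <- ape::unroot(ape::rtree(ntaxa))
      D <- ape::cophenetic.phylo(gen)
      rec <- suppressMessages(nj_tree(D))
      expect_equal(phangorn::RF.dist(gen, rec), 0)
      expect_equal(
        ape::cophenetic.phylo(rec)[rownames(D), colnames(D)], D,
        tolerance = 1e-12
      )
    }
  })
})

test_that("NJ is invariant to taxon input order", {
  withr::with_seed(33, {
    gen <- ape::unroot(ape::rtree(7))
    D <- ape::cophenetic.phylo(gen)
    perm <- sample(nrow(D))
    t1 <- nj_tree(D)
    t2 <- nj_tree(D[perm, perm])
  })
  expect_equal(phangorn::RF.dist(t1, t2), 0)
})

test_that("Newick round trips preserve topology, lengths and supports", {
  withr::with_seed(44, {
    tree <- ape::rtree(8)
  })
  tree$node.label <- as.character(seq_len(tree$Nnode) * 10)
  text <- write_newick(tree)
  back <- read_newick(text)
  expect_equal(phangorn::RF.dist(ape::unroot(tree), ape::unroot(back)), 0)
  expect_equal(sort(back$edge.length), sort(tree$edge.length),
               tolerance = 1e-5)
  expect_equal(sort(back$node.label), sort(tree$node.label))

  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  expect_equal(write_newick(read_newick(path)), text)
})

test_that("malformed Newick is rejected with a character position", {
  expect_error(read_newick("((A:1,B:1):1,C:1;"), "unclosed")
  expect_error(read_newick("(A:1,B:1)):1;"), "character 10")
})

test_that("bootstrap saturates for an identical pair and is seeded", {
  m <- rbind(
    dup1 = rep(c("A", "C"), 30),
    dup2 = rep(c("A", "C"), 30),
    far1 = rep(c("G", "T"), 30),
    far2 = rep(c("T", "G"), 30)
  )
  panel <- panel_from_matrix(m)
  tree <- bootstrap_support(panel, replicates = 50, seed = 5,
                            min_sites = 10)
  sup <- tree$node.label[!is.na(tree$node.label)]
  expect_true(any(sup == 100))   # the dup1/dup2 bipartition

  again <- bootstrap_support(panel, replicates = 50, seed = 5,
                             min_sites = 10)
  expect_identical(write_newick(tree), write_newick(again))

  one <- bootstrap_support(panel, replicates = 1, seed = 3,
                           min_sites = 10)
  sup1 <- one$node.label[!is.na(one$node.label)]
  expect_true(all(sup1 %in% c(0, 100)))
})

test_that("different bootstrap seeds agree within sampling error", {
  sim <- simulate_panel(8, n_accessions = 10, n_loci = 200,
                        n_duplicate_pairs = 1)
  t1 <- bootstrap_support(sim$panel, replicates = 200, seed = 1,
                          min_sites = 20)
  t2 <- bootstrap_support(sim$panel, replicates = 200, seed = 2,
                          min_sites = 20)
  s1 <- t1$node.label[!is.na(t1$node.label)]
  s2 <- t2$node.label[!is.na(t2$node.label)]
  # same tree, same splits; supports are binomial percentages over 200
  expect_equal(length(s1), length(s2))
  expect_true(all(abs(s1 - s2) <= 15))
})
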