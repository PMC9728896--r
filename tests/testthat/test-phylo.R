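# path-length (patristic) distances of the generating tree are what NJ must
# reproduce on additive input
additive_4taxon <- function() {
  # tree: A-u:1, B-u:2, u-v:1, C-v:3, D-v:4
  m <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m
}

test_that("p_distance matches brute-force allele pairing", {
  gm <- random_dosage_matrix(2, 2)
  gm$dosages[, 1] <- c(0L, 2L)
  gm$dosages[, 2] <- c(2L, 0L)
  d <- p_distance(gm)
  expect_equal(unname(d[1, 2]), 1.0)
  expect_equal(diag(d), setNames(c(0, 0), gm$samples))

  set.seed(12)
  for (rep in 1:10) {
    gm2 <- random_dosage_matrix(30, 6, miss = 0.2)
    d2 <- p_distance(gm2)
    expect_true(isSymmetric(d2))
    for (a in 1:5) for (b in (a + 1):6) {
      expect_equal(d2[a, b],
                   oracle_p_distance(gm2$dosages[, a], gm2$dosages[, b]),
                   tolerance = 1e-12)
    }
  }
  # identical samples have distance zero (identity of indiscernibles)
  gm3 <- random_dosage_matrix(10, 2)
  gm3$dosages[, 2] <- gm3$dosages[, 1]
  expect_equal(unname(p_distance(gm3)[1, 2]), 0)
})

test_that("NJ recovers the worked 4-taxon additive tree exactly", {
  tr <- neighbor_joining(additive_4taxon())
  expect_s3_class(tr, "phylo")
  # topology AB|CD
  ab <- ape::getMRCA(ape::root(tr, "D", resolve.root = TRUE), c("A", "B"))
  expect_false(is.na(ab))
  # patristic distances reproduce the additive matrix exactly
  got <- cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(got, additive_4taxon(), tolerance = 1e-9)
  # pendant branch lengths are those of the generating tree
  pend <- setNames(tr$edge.length[tr$edge[, 2] <= 4],
                   tr$tip.label[tr$edge[tr$edge[, 2] <= 4, 2]])
  expect_equal(pend[LETTERS[1:4]], c(A = 1, B = 2, C = 3, D = 4),
               tolerance = 1e-9)
})

test_that("NJ recovers a 5-taxon additive tree and matches ape::nj", {
  # caterpillar: ((A:1,B:2):1,(C:1.5,(D:0.7,E:1.1):0.9):0.6)
  txt <- "((A:1,B:2):1,(C:1.5,(D:0.7,E:1.1):0.9):0.6);"
  ref <- ape::read.tree(text = txt)
  dm <- cophenetic(ref)
  tr <- neighbor_joining(dm)
  expect_equal(cophenetic(tr)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-9)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
               ignore_attr = TRUE)

  # against ape's NJ on random (noisy, non-additive) matrices: same topology
  set.seed(13)
  for (rep in 1:5) {
    n <- 8
    pts <- matrix(runif(n * 3), n)
    dm2 <- as.matrix(dist(pts))
    rownames(dm2) <- colnames(dm2) <- paste0("t", 1:n)
    t1 <- neighbor_joining(dm2)
    t2 <- ape::nj(dm2)
    expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(t1$edge.length), sort(pmax(t2$edge.length, 0)),
                 tolerance = 1e-8)
  }
})

test_that("3 taxa give the closed-form star and degenerate ties are stable", {
  dm <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(dm)
  pend <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(pend[c("a", "b", "c")], c(a = 0.5, b = 1.5, c = 2.5))

  eq <- matrix(1, 5, 5) - diag(5)
  rownames(eq) <- colnames(eq) <- paste0("t", 1:5)
  t1 <- neighbor_joining(eq)
  t2 <- neighbor_joining(eq)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  expect_error(neighbor_joining(dm[1:2, 1:2]), "at least 3")
  dm_na <- dm; dm_na[1, 2] <- dm_na[2, 1] <- NA
  expect_error(neighbor_joining(dm_na), "undefined")
})

test_that("NJ is invariant to label permutation up to relabeling", {
  dm <- additive_4taxon()
  perm <- c("C", "A", "D", "B")
  t1 <- neighbor_joining(dm)
  t2 <- neighbor_joining(dm[perm, perm])
  expect_equal(cophenetic(t2)[LETTERS[1:4], LETTERS[1:4]],
               cophenetic(t1)[LETTERS[1:4], LETTERS[1:4]],
               tolerance = 1e-12)
})

test_that("negative branch lengths are clamped and flagged", {
  dm <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 0.1, 9, 10, 0.1, 0),
               4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(dm)
  expect_true(all(tr$edge.length >= 0))
  expect_true(attr(tr, "clamped_edges") >= 0)
})

test_that("outgroup rooting halves the pendant edge and is idempotent", {
  tr <- neighbor_joining(additive_4taxon())
  r1 <- root_with_outgroup(tr, "D")
  # D's pendant edge was 4; root splits it into 2 + 2
  root_node <- ape::Ntip(r1) + 1L
  re <- which(r1$edge[, 1] == root_node)
  expect_equal(length(re), 2)
  expect_equal(sort(r1$edge.length[re]), c(2, 2))
  # clade (A,B) with C as its sister is preserved
  expect_true(ape::is.monophyletic(r1, c("A", "B")))
  expect_true(ape::is.monophyletic(r1, c("A", "B", "C")))
  # leaf-to-leaf path lengths unchanged
  expect_equal(cophenetic(r1)[LETTERS[1:4], LETTERS[1:4]],
               additive_4taxon(), tolerance = 1e-9)
  # idempotence
  r2 <- root_with_outgroup(r1, "D")
  expect_identical(ape::write.tree(r2), ape::write.tree(r1))
  expect_error(root_with_outgroup(tr, "Q"), "not a tip")
})
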