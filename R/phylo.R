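#' Pairwise p-distance matrix from diploid genotypes
#'
#' For unphased diploids the p-distance between samples a and b is the
#' allele-difference fraction `sum(|dosage_a - dosage_b|) /
#' (2 * n_shared)`, taken over sites where both calls are present.  This is
#' phase-free and reduces to the standard p-distance for haploid (0/2)
#' data.  Pairs with no shared called site are `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @return symmetric numeric matrix with zero diagonal, labelled by sample.
#' @export
p_distance <- function(gm) {
  X <- gm$dosages
  n <- ncol(X)
  if (n < 2) stop("need at least two samples")
  M <- !is.na(X)
  D <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  for (a in seq_len(n - 1)) {
    rest <- (a + 1):n
    diffs <- abs(X[, rest, drop = FALSE] - X[, a])   # NA where either missing
    shared <- colSums(M[, rest, drop = FALSE] & M[, a])
    tot <- colSums(diffs, na.rm = TRUE)
    d <- ifelse(shared > 0, tot / (2 * shared), NA_real_)
    D[a, rest] <- d
    D[rest, a] <- d
  }
  D
}

#' Neighbour-joining tree (Saitou-Nei, Studier-Keppler update)
#'
#' Classic agglomerative NJ with the Q criterion and O(n^3) row-sum
#' updates; exact on additive matrices (recovers topology and branch
#' lengths of the generating tree).  Ties in Q are broken by the smallest
#' (i, j) index pair, so output is deterministic.  Negative branch lengths
#' are clamped to zero; the number of clamped edges is recorded in the
#' `clamped_edges` attribute.
#'
#' @param dm symmetric distance matrix with labels (e.g. [p_distance()]
#'   output); all entries must be defined.
#' @return an unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("need at least 3 taxa")
  if (anyNA(dm)) stop("distance matrix contains undefined entries")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix not symmetric")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  clamped <- 0L
  fmt <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; x <- 0 }
    sprintf("%.12g", x)
  }
  nwk <- labels          # growing newick fragment per active cluster
  D <- dm
  repeat {
    r <- nrow(D)
    if (r == 3) break
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    # smallest Q; ties -> smallest (i, j) with i < j
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    bi <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(bi), nwk[j], fmt(bj))
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    D <- D2
    nwk <- c(nwk[keep], new_nwk)
  }
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(l1), nwk[2], fmt(l2),
                 nwk[3], fmt(l3))
  tree <- ape::read.tree(text = txt)
  attr(tree, "clamped_edges") <- clamped
  tree
}

#' Root a tree on an outgroup's pendant edge
#'
#' Places the root at the midpoint of the outgroup's pendant edge, so the
#' outgroup and the ingroup clade each receive half of the original edge
#' length.  Leaf-to-leaf path lengths are unchanged and re-rooting on the
#' same outgroup is idempotent.
#'
#' @param tree a `phylo` tree.
#' @param outgroup a tip label present in the tree.
#' @return a rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    stop("outgroup '", outgroup, "' is not a tip of the tree")
  }
  rooted <- ape::root(ape::unroot(tree), outgroup = outgroup,
                      resolve.root = TRUE)
  root_node <- ape::Ntip(rooted) + 1L
  re <- which(rooted$edge[, 1] == root_node)
  if (length(re) == 2) {
    tot <- sum(rooted$edge.length[re])
    rooted$edge.length[re] <- tot / 2
  }
  rooted
}

#' Write a distance matrix as square TSV
#'
#' @param dm symmetric labelled matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  utils::write.table(data.frame(sample = rownames(dm), dm,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
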