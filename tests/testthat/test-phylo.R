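test_that("supermatrix concatenation tracks widths and partitions", {
  blocks <- list(
    ND2 = c(a = "ATGATGATG", b = "ATGATGATG", c = "ATGATGATG"),
    COI = c(a = "CCCCCCCCCCCC", b = "CCCCCCCCCCCC", c = "CCCCCCCCCCCC"),
    CytB = c(a = "GGGGGG", b = "GGGGGG", c = "GGGGGG"))
  sm <- build_supermatrix(blocks)
  expect_equal(nchar(sm$sequences[[1]]), 27L)
  expect_equal(sm$partitions$start, c(1L, 10L, 22L))
  expect_equal(sm$partitions$end, c(9L, 21L, 27L))
  expect_equal(sm$partitions$gene, c("ND2", "COI", "CytB"))  # canonical order

  bad <- blocks; bad$COI <- bad$COI[c("a", "b")]
  expect_error(build_supermatrix(bad), "COI.*c|c.*COI")
  # complete deletion is the identity on gap-free input
  sm2 <- build_supermatrix(blocks, drop_gapped = TRUE)
  expect_equal(sm2$sequences, sm$sequences)
  expect_equal(sm2$partitions, sm$partitions)
  # gapped columns dropped, partitions still tile
  gappy <- blocks
  gappy$ND2["b"] <- "ATG-TGATG"
  sm3 <- build_supermatrix(gappy, drop_gapped = TRUE)
  expect_equal(nchar(sm3$sequences[[1]]), 26L)
  expect_equal(sm3$partitions$end[nrow(sm3$partitions)], 26L)
})

test_that("supermatrix export formats are readable", {
  blocks <- list(ND2 = c(a = "ATGAAA", b = "ATGTTT", c = "ATGCCC"))
  sm <- build_supermatrix(blocks)
  phy <- file.path(tempdir(), "sm.phy")
  nex <- file.path(tempdir(), "sm.nex")
  write_phylip(sm, phy)
  expect_match(readLines(phy)[1], "3 6")
  write_nexus(sm, nex)
  expect_true(any(grepl("CHARSET ND2 = 1-6", readLines(nex))))
})

test_that("K2P distance matches the closed form and the reference oracle", {
  expect_equal(k2p_distance("ACGTACGT", "ACGTACGT"), 0)
  one_ts <- paste0(strrep("A", 99), "G")
  expect_equal(k2p_distance(strrep("A", 100), one_ts), -0.5 * log(0.98))
  expect_warning(d <- k2p_distance(strrep("A", 10), strrep("G", 10)),
                 "saturated")
  expect_equal(d, Inf)
  expect_error(k2p_distance("AC", "ACG"), "aligned")
  set.seed(101)
  for (i in 1:5) {
    a <- random_dna(500)
    # moderately diverged partner: ~10% of sites substituted
    ch <- strsplit(a, "")[[1]]
    hit <- runif(500) < 0.1
    ch[hit] <- vapply(ch[hit], function(x) {
      sample(setdiff(c("A", "C", "G", "T"), x), 1)
    }, character(1))
    b <- paste(ch, collapse = "")
    expect_equal(k2p_distance(a, b), k2p_distance(b, a))
    ora <- as.matrix(ape::dist.dna(ape::as.DNAbin(strsplit(c(x = a, y = b),
                                                           "")),
                                   model = "K80"))["x", "y"]
    expect_equal(k2p_distance(a, b), unname(ora), tolerance = 1e-12)
  }
})

test_that("NJ resolves 3 taxa by the three-point formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  expect_equal(ape::Ntip(tr), 3L)
  bl <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("NJ recovers additive topologies (brute-force oracle, n <= 6)", {
  set.seed(7)
  for (n in 4:6) {
    for (rep in 1:3) {
      true_tree <- ape::rtree(n, rooted = FALSE)
      true_tree$edge.length <- runif(nrow(true_tree$edge), 0.05, 0.5)
      D <- cophenetic(true_tree)
      # oracle: enumerate all unrooted topologies, least-squares fit each,
      # pick the (unique, for additive D) topology with zero residual
      cand <- phangorn::allTrees(n, rooted = FALSE,
                                 tip.label = rownames(D))
      res <- vapply(cand, function(ct) {
        ft <- phangorn::nnls.tree(as.dist(D), ct, method = "unrooted")
        sum((cophenetic(ft)[rownames(D), colnames(D)] - D)^2)
      }, numeric(1))
      oracle_best <- cand[[which.min(res)]]
      expect_equal(rf_distance(oracle_best, true_tree), 0L)
      expect_equal(rf_distance(nj_tree(D), true_tree), 0L)
    }
  }
  expect_error(nj_tree(matrix(c(0, Inf, Inf, 0), 2,
                              dimnames = list(c("a", "b"), c("a", "b")))),
               "at least 3|non-finite")
})

# independent bipartition oracle for RF: enumerate the non-trivial splits of
# each tree as sorted leaf subsets and take the symmetric difference
.rf_oracle <- function(t1, t2) {
  splits <- function(tr) {
    tr <- ape::unroot(tr)
    tips <- sort(tr$tip.label)
    out <- character(0)
    for (node in setdiff(unique(tr$edge[, 2]), seq_along(tr$tip.label))) {
      clade <- ape::extract.clade(tr, node)$tip.label
      side <- sort(clade)
      other <- sort(setdiff(tips, side))
      if (length(side) < 2 || length(other) < 2) next
      key <- min(paste(side, collapse = ","), paste(other, collapse = ","))
      out <- c(out, key)
    }
    unique(out)
  }
  s1 <- splits(t1); s2 <- splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

test_that("RF distance agrees with a bipartition-enumeration oracle", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  expect_equal(.rf_oracle(t1, t2), 2L)
  expect_error(rf_distance(t1, ape::read.tree(text = "((a,b),(c,e));")),
               "leaf sets")
  set.seed(55)
  for (i in 1:5) {
    n <- sample(5:8, 1)
    x <- ape::rtree(n); y <- ape::rtree(n)
    y$tip.label <- x$tip.label
    expect_equal(rf_distance(x, y), .rf_oracle(x, y))
    expect_equal(rf_distance(x, y), rf_distance(y, x))
  }
})
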