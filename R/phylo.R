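# Supermatrix plumbing and a lightweight distance phylogeny:
# Kimura 2-parameter distances, canonical neighbor-joining, and
# Robinson-Foulds topology comparison. This is a desk-scale, falsifiable
# stand-in for full ML/BI inference, not a replacement for it.

#' Canonical PCG concatenation order
#'
#' Genome order of the 13 PCGs from trnM in the conserved lepidopteran
#' arrangement.
#' @export
pcg_concat_order <- function() {
  c("ND2", "COI", "COII", "ATP8", "ATP6", "COIII", "ND3", "ND5", "ND4",
    "ND4L", "ND6", "CytB", "ND1")
}

#' Concatenate aligned gene blocks into a supermatrix
#'
#' Each block is an alignment of the same taxon set for one gene; blocks are
#' concatenated in the canonical genome order (genes outside it are appended
#' alphabetically). Optionally drops every column containing a gap in any
#' taxon — a transparent complete-deletion stand-in for alignment trimming.
#'
#' @param blocks named list: gene -> named character vector of equal-length
#'   aligned sequences, one per taxon.
#' @param drop_gapped drop columns containing `-` or `?` in any row.
#' @return object of class `supermatrix`: list with `taxa`, `sequences`
#'   (named character vector), `partitions` (data.frame gene/start/end;
#'   recorded before any column dropping when `drop_gapped = FALSE` only).
#' @export
build_supermatrix <- function(blocks, drop_gapped = FALSE) {
  if (length(blocks) == 0L) stop("no gene blocks")
  canon <- pcg_concat_order()
  ord <- c(intersect(canon, names(blocks)),
           sort(setdiff(names(blocks), canon)))
  taxa <- sort(names(blocks[[1]]))
  for (g in ord) {
    b <- blocks[[g]]
    if (is.null(names(b)) || !setequal(names(b), taxa) ||
        length(b) != length(taxa))
      stop("taxon set mismatch in gene ", g, ": missing ",
           paste(setdiff(taxa, names(b)), collapse = ", "))
    if (length(unique(nchar(b))) != 1L)
      stop("unequal row lengths in gene ", g)
  }
  widths <- unname(vapply(ord, function(g) nchar(blocks[[g]][[1]]),
                          integer(1)))
  ends <- cumsum(widths)
  partitions <- data.frame(gene = ord, start = ends - widths + 1L, end = ends,
                           stringsAsFactors = FALSE)
  seqs <- vapply(taxa, function(tx) {
    paste(vapply(ord, function(g) toupper(blocks[[g]][[tx]]), character(1)),
          collapse = "")
  }, character(1))
  if (drop_gapped) {
    mat <- do.call(rbind, strsplit(seqs, ""))
    keep <- colSums(mat == "-" | mat == "?") == 0L
    seqs <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
    names(seqs) <- taxa
    # remap partitions onto the surviving columns so they still tile
    colgene <- rep(partitions$gene, widths)[keep]
    if (length(colgene)) {
      r <- rle(colgene)
      ends2 <- cumsum(r$lengths)
      partitions <- data.frame(gene = r$values,
                               start = ends2 - r$lengths + 1L, end = ends2,
                               stringsAsFactors = FALSE)
    } else {
      partitions <- partitions[0, , drop = FALSE]
    }
  }
  structure(list(taxa = taxa, sequences = seqs, partitions = partitions),
            class = "supermatrix")
}

#' Write a supermatrix in relaxed PHYLIP format
#' @param sm supermatrix.
#' @param path output path.
#' @export
write_phylip <- function(sm, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf(" %d %d", length(sm$taxa), nchar(sm$sequences[[1]])), con)
  writeLines(sprintf("%s  %s", sm$taxa, sm$sequences), con)
  invisible(path)
}

#' Write a supermatrix as NEXUS with a partition block
#' @param sm supermatrix.
#' @param path output path.
#' @export
write_nexus <- function(sm, path) {
  con <- file(path, "w"); on.exit(close(con))
  nchar_tot <- nchar(sm$sequences[[1]])
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                       length(sm$taxa), nchar_tot),
               "  FORMAT DATATYPE=DNA MISSING=? GAP=-;", "  MATRIX"), con)
  writeLines(sprintf("    %s  %s", sm$taxa, sm$sequences), con)
  writeLines(c("  ;", "END;"), con)
  if (!is.null(sm$partitions)) {
    writeLines("BEGIN SETS;", con)
    writeLines(sprintf("  CHARSET %s = %d-%d;", sm$partitions$gene,
                       sm$partitions$start, sm$partitions$end), con)
    writeLines("END;", con)
  }
  invisible(path)
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with P and Q the transition
#' and transversion proportions over sites where both sequences carry an
#' unambiguous base. Saturated pairs (log argument <= 0) return Inf with a
#' warning.
#'
#' @param seq_a,seq_b equal-length aligned DNA strings.
#' @return non-negative distance (substitutions/site), possibly Inf.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must be aligned")
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no pairwise-complete sites")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  diff <- a != b
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ts <- diff & (purine[a] == purine[b])     # A<->G, C<->T
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    warning("K2P distance saturated; returning Inf")
    return(Inf)
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K2P distance matrix
#' @param seqs named character vector of aligned sequences.
#' @return symmetric matrix with zero diagonal, dimnames = taxa.
#' @export
k2p_matrix <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- k2p_distance(seqs[[i]], seqs[[j]])
  }
  d
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei neighbor joining with deterministic tie-breaking
#' (the lowest current row/column index pair wins) and negative branch
#' lengths clamped to zero with a warning.
#'
#' @param dist symmetric numeric matrix with taxon dimnames, or a `dist`.
#' @return unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  if (is.null(rownames(dist))) stop("distance matrix needs taxon names")
  if (!all(is.finite(dist))) stop("non-finite distances")
  if (max(abs(dist - t(dist))) > 1e-9) stop("distance matrix not symmetric")
  n <- nrow(dist)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(dist)
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0) clamped <<- TRUE
    max(x, 0)
  }
  nodes <- labels  # newick fragment per active cluster
  D <- dist
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(D)
    q <- (m - 2) * D - outer(r, r, "+")
    diag(q) <- Inf
    # lowest (i, j) with i < j among the minima
    idx <- which(q == min(q), arr.ind = TRUE)
    idx <- t(apply(idx, 1, sort))
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    merged <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], bl(li), nodes[j], bl(lj))
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    nodes <- c(nodes[keep], merged)
  }
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- D[1, 2] - l1
  l3 <- D[1, 3] - l1
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nodes[1], bl(l1), nodes[2], bl(l2), nodes[3], bl(l3))
  if (clamped) warning("negative branch length(s) clamped to 0")
  ape::read.tree(text = nwk)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the non-trivial bipartition sets (both trees are
#' unrooted first).
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) stop("leaf sets differ")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}
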