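# Base composition, A+T / G+C content and strand-skew statistics.
#
# Skews follow the standard strand-asymmetry definitions
#   AT-skew = (A - T) / (A + T),  GC-skew = (G - C) / (G + C),
# computed on the stored (majority, J) strand unless stated otherwise.
# Ambiguity codes and N are excluded from skew denominators and reported
# in n_other.

.count_bases <- function(seq) {
  if (is.null(seq) || !nzchar(seq)) stop("empty input")
  tab <- table(strsplit(toupper(seq), "")[[1]])
  cnt <- function(b) if (b %in% names(tab)) as.integer(tab[[b]]) else 0L
  n <- c(A = cnt("A"), T = cnt("T"), G = cnt("G"), C = cnt("C"))
  c(n, other = nchar(seq) - sum(n))
}

#' Strand skew of two base counts
#'
#' `skew(n_A, n_T)` is the AT-skew, `skew(n_G, n_C)` the GC-skew.
#'
#' @param x_count,y_count non-negative integer counts.
#' @return `(x - y) / (x + y)`, or NA when `x + y == 0`.
#' @export
skew <- function(x_count, y_count) {
  if (any(c(x_count, y_count) < 0)) stop("negative counts")
  tot <- x_count + y_count
  ifelse(tot == 0, NA_real_, (x_count - y_count) / tot)
}

#' Base composition and skew statistics
#'
#' Accepts either a DNA string or explicit base counts (as printed in
#' composition tables). Percentages are of the total length including
#' ambiguous bases; skews use unambiguous bases only.
#'
#' @param seq DNA string (ignored when counts are given).
#' @param counts optional named vector/list with elements A, T, G, C and
#'   optionally other.
#' @return object of class `composition_stats`: a list with the raw counts
#'   (`n_A` ...), per-base percentages, `at_content`, `gc_content`,
#'   `at_skew`, `gc_skew` and `length`.
#' @export
base_composition <- function(seq = NULL, counts = NULL) {
  if (is.null(counts)) {
    n <- .count_bases(seq)
  } else {
    counts <- as.list(counts)
    n <- c(A = as.numeric(counts$A), T = as.numeric(counts$T),
           G = as.numeric(counts$G), C = as.numeric(counts$C),
           other = if (is.null(counts$other)) 0 else as.numeric(counts$other))
    if (anyNA(n) || any(n < 0)) stop("counts must be non-negative A,T,G,C")
    if (sum(n) == 0) stop("empty input")
  }
  len <- sum(n)
  pct <- 100 * n / len
  structure(list(
    n_A = unname(n["A"]), n_T = unname(n["T"]),
    n_G = unname(n["G"]), n_C = unname(n["C"]),
    n_other = unname(n["other"]), length = unname(len),
    pct_A = unname(pct["A"]), pct_T = unname(pct["T"]),
    pct_G = unname(pct["G"]), pct_C = unname(pct["C"]),
    at_content = unname(pct["A"] + pct["T"]),
    gc_content = unname(pct["G"] + pct["C"]),
    at_skew = skew(n[["A"]], n[["T"]]),
    gc_skew = skew(n[["G"]], n[["C"]])), class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf(
    "<composition_stats> %d bp | A %.2f%% T %.2f%% G %.2f%% C %.2f%% | A+T %.2f%% | AT-skew %.4f GC-skew %.4f\n",
    x$length, x$pct_A, x$pct_T, x$pct_G, x$pct_C, x$at_content,
    x$at_skew, x$gc_skew))
  invisible(x)
}

#' Composition of an annotated region
#'
#' @param genome annotated genome with sequence.
#' @param region a gene symbol, a one-row feature slice, or `c(start, end)`.
#' @param strand strand on which to compute ("J" default: as stored; "N"
#'   reverse-complements first, flipping skew signs).
#' @return `composition_stats` for the region.
#' @export
region_composition <- function(genome, region, strand = "J") {
  if (is.character(region) || is.data.frame(region)) {
    seq <- feature_sequence(genome, region)
    # feature_sequence already honors the gene's own strand; optional extra flip
    if (normalize_strand(strand) == "N") seq <- reverse_complement(seq)
  } else {
    seq <- extract_region(genome, region[1], region[2], strand)
  }
  base_composition(seq)
}

#' Pooled A+T content at codon positions 1-3
#'
#' Pools codons across a set of coding sequences taken in reading
#' orientation (reverse-complement N-strand genes first); any incomplete
#' trailing codon is excluded.
#'
#' @param cds_set character vector of CDS sequences 5'->3'.
#' @return numeric vector `c(at_pos1, at_pos2, at_pos3)` in percent.
#' @export
codon_position_composition <- function(cds_set) {
  cds_set <- cds_set[nzchar(cds_set)]
  if (length(cds_set) == 0L) stop("empty CDS set")
  at <- integer(3); tot <- integer(3)
  for (s in cds_set) {
    s <- toupper(s)
    ncod <- nchar(s) %/% 3L
    if (ncod == 0L) next
    ch <- strsplit(substr(s, 1L, 3L * ncod), "")[[1]]
    pos <- rep_len(1:3, length(ch))
    for (p in 1:3) {
      b <- ch[pos == p]
      at[p] <- at[p] + sum(b %in% c("A", "T"))
      tot[p] <- tot[p] + length(b)
    }
  }
  if (any(tot == 0L)) stop("no complete codons in CDS set")
  stats::setNames(100 * at / tot, c("at_pos1", "at_pos2", "at_pos3"))
}
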