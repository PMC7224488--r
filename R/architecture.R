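# Gene-junction accounting, gene-order comparison, and control-region
# motif scanning.
#
# Junction accounting is linear from the first annotated feature: with
# 1-based inclusive coordinates the gap at a junction is
#   gap = downstream$start - upstream$end - 1
# (positive = intergenic spacer, negative = overlap, 0 = abutting). The
# wrap-around junction of the circle (last feature -> first) is reported
# separately and excluded from linear summaries, matching how published
# organization tables account for their junctions.

#' Per-junction gap/overlap report
#'
#' @param genome an annotated genome (sequence not required).
#' @return data.frame with one row per consecutive feature pair: columns
#'   `upstream`, `downstream`, `gap` and, when carried by the annotation,
#'   `printed_gap` (the downstream feature's published value). The
#'   wrap-around junction is attached as attribute `"wraparound"` (NULL for
#'   linear molecules).
#' @export
adjacency_report <- function(genome) {
  f <- genome$features
  if (nrow(f) < 2L) stop("need at least 2 features")
  if (is.unsorted(f$start)) {
    warning("features not sorted by start; sorting")
    f <- f[order(f$start, f$end), , drop = FALSE]
  }
  up <- f[-nrow(f), , drop = FALSE]
  dn <- f[-1L, , drop = FALSE]
  lab <- function(x) ifelse(x$copy_index > 1L,
                            paste0(x$gene, ".", x$copy_index), x$gene)
  out <- data.frame(upstream = lab(up), downstream = lab(dn),
                    gap = dn$start - up$end - 1L, stringsAsFactors = FALSE)
  if ("printed_gap" %in% names(f)) out$printed_gap <- dn$printed_gap
  if (genome$circular) {
    last <- f[nrow(f), , drop = FALSE]
    first <- f[1L, , drop = FALSE]
    wrap <- data.frame(upstream = lab(last), downstream = lab(first),
                       gap = (genome$length - last$end) + (first$start - 1L),
                       stringsAsFactors = FALSE)
    attr(out, "wraparound") <- wrap
  }
  out
}

#' Summarize junction gaps into overlap/spacer/abutting tallies
#'
#' Overlap totals are magnitudes (a "-8" junction contributes 8 bp).
#' With `source = "printed"` only records carrying a printed value are
#' classified — the accounting of the published column.
#'
#' @param records data.frame from [adjacency_report()].
#' @param source `"computed"` (gap from coordinates) or `"printed"`.
#' @param allow_empty return an all-zero summary instead of erroring on an
#'   empty record set.
#' @return object of class `adjacency_summary`: list with `n_overlaps`,
#'   `total_overlap_bp`, `max_overlap_bp`, `n_spacers`, `total_spacer_bp`,
#'   `max_spacer_bp`, `n_abutting`, `n_junctions`, and `top_spacers` (ranked
#'   data.frame of spacer junctions; ties broken by genome position).
#' @export
summarize_adjacencies <- function(records, source = c("computed", "printed"),
                                  allow_empty = FALSE) {
  source <- match.arg(source)
  if (source == "printed") {
    if (!"printed_gap" %in% names(records))
      stop("no printed_gap column in records")
    records <- records[!is.na(records$printed_gap), , drop = FALSE]
    g <- records$printed_gap
  } else {
    g <- records$gap
  }
  if (length(g) == 0L && !allow_empty) stop("no junction records")
  ov <- g < 0L; sp <- g > 0L
  spacers <- records[sp, , drop = FALSE]
  spacers$size <- g[sp]
  spacers <- spacers[order(-spacers$size, seq_len(nrow(spacers))),
                     c("upstream", "downstream", "size")]
  rownames(spacers) <- NULL
  structure(list(
    n_overlaps = sum(ov), total_overlap_bp = sum(-g[ov]),
    max_overlap_bp = if (any(ov)) max(-g[ov]) else 0L,
    n_spacers = sum(sp), total_spacer_bp = sum(g[sp]),
    max_spacer_bp = if (any(sp)) max(g[sp]) else 0L,
    n_abutting = sum(g == 0L), n_junctions = length(g),
    top_spacers = spacers), class = "adjacency_summary")
}

#' @export
print.adjacency_summary <- function(x, ...) {
  cat(sprintf(
    "<adjacency_summary> %d junctions: %d overlaps (%d bp, max %d) | %d spacers (%d bp, max %d) | %d abutting\n",
    x$n_junctions, x$n_overlaps, x$total_overlap_bp, x$max_overlap_bp,
    x$n_spacers, x$total_spacer_bp, x$max_spacer_bp, x$n_abutting))
  invisible(x)
}

#' Cross-validate computed junction gaps against a published column
#'
#' @param records data.frame from [adjacency_report()] carrying `printed_gap`.
#' @return data.frame of junctions whose computed gap disagrees with the
#'   printed value (printed-NA junctions are skipped).
#' @export
cross_validate_gaps <- function(records) {
  if (!"printed_gap" %in% names(records))
    stop("no printed_gap column in records")
  keep <- !is.na(records$printed_gap) & records$printed_gap != records$gap
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- gene order ------------------------------------------------------------

#' Signed gene order of a genome
#'
#' The ordered list of (gene, strand) around the circle, rotated to start at
#' trnM when present (insect mitogenomes conventionally start there);
#' duplicated genes are retained with their copy index.
#'
#' @param genome annotated genome.
#' @return object of class `gene_order`: data.frame with columns `gene`,
#'   `strand`, `copy_index`.
#' @export
gene_order <- function(genome) {
  f <- genome$features[order(genome$features$start, genome$features$end),
                       c("gene", "strand", "copy_index")]
  i <- which(f$gene == "trnM")
  if (length(i) == 0L) {
    warning("trnM absent; order left unrotated")
  } else if (i[1] > 1L) {
    n <- nrow(f)
    f <- f[c(i[1]:n, 1:(i[1] - 1L)), , drop = FALSE]
  }
  rownames(f) <- NULL
  structure(f, class = c("gene_order", "data.frame"))
}

# circular adjacency signatures over a signed order; strand is part of the
# signature so an inversion between the same neighbors changes it
.adjacency_set <- function(ord) {
  n <- nrow(ord)
  sig <- character(0)
  for (k in seq_len(n)) {
    a <- ord[k, ]; b <- ord[if (k == n) 1L else k + 1L, ]
    x <- paste0(a$gene, ":", a$strand)
    y <- paste0(b$gene, ":", b$strand)
    # orientation-agnostic: reading the circle backwards flips both strands
    xr <- paste0(b$gene, ":", ifelse(b$strand == "J", "N", "J"))
    yr <- paste0(a$gene, ":", ifelse(a$strand == "J", "N", "J"))
    sig <- c(sig, min(paste(x, y), paste(xr, yr)))
  }
  sig
}

#' Compare two gene orders
#'
#' Duplicate-aware: genes duplicated or missing on either side are reported
#' as such and removed before adjacency comparison, so a duplication is not
#' double-counted as breakpoints. Breakpoints are adjacencies (with strand
#' signature) present in one order but not the other.
#'
#' @param a,b `gene_order` objects (or annotated genomes).
#' @return object of class `order_comparison`: list with `identical`,
#'   `shared_adjacencies`, `breakpoints`, `duplicated_in_a`,
#'   `duplicated_in_b`, `missing_in_a`, `missing_in_b`.
#' @export
compare_orders <- function(a, b) {
  if (inherits(a, "annotated_genome")) a <- gene_order(a)
  if (inherits(b, "annotated_genome")) b <- gene_order(b)
  dup_a <- unique(a$gene[duplicated(a$gene)])
  dup_b <- unique(b$gene[duplicated(b$gene)])
  miss_a <- setdiff(unique(b$gene), unique(a$gene))
  miss_b <- setdiff(unique(a$gene), unique(b$gene))
  shared <- setdiff(intersect(unique(a$gene), unique(b$gene)),
                    union(dup_a, dup_b))
  ra <- a[a$gene %in% shared, , drop = FALSE]
  rb <- b[b$gene %in% shared, , drop = FALSE]
  sa <- .adjacency_set(ra)
  sb <- .adjacency_set(rb)
  brk <- length(setdiff(sa, sb))
  ident <- nrow(a) == nrow(b) &&
    identical(paste(a$gene, a$strand), paste(b$gene, b$strand))
  structure(list(identical = ident,
                 shared_adjacencies = length(intersect(sa, sb)),
                 breakpoints = brk,
                 duplicated_in_a = dup_a, duplicated_in_b = dup_b,
                 missing_in_a = miss_a, missing_in_b = miss_b),
            class = "order_comparison")
}

#' @export
print.order_comparison <- function(x, ...) {
  cat(sprintf(
    "<order_comparison> identical: %s | shared adjacencies: %d | breakpoints: %d\n",
    x$identical, x$shared_adjacencies, x$breakpoints))
  if (length(x$duplicated_in_a))
    cat("  duplicated in a:", paste(x$duplicated_in_a, collapse = ", "), "\n")
  if (length(x$duplicated_in_b))
    cat("  duplicated in b:", paste(x$duplicated_in_b, collapse = ", "), "\n")
  if (length(x$missing_in_a))
    cat("  missing in a:", paste(x$missing_in_a, collapse = ", "), "\n")
  if (length(x$missing_in_b))
    cat("  missing in b:", paste(x$missing_in_b, collapse = ", "), "\n")
  invisible(x)
}

# ---- control-region motif scanning ----------------------------------------

#' Scan a control-region sequence for conserved motifs, poly-T runs and
#' tandem repeats
#'
#' Reports exact motif matches, maximal poly-T runs of at least
#' `min_polyT` bp, and maximal tandem arrays of the given repeat units with
#' at least `min_repeat_copies` complete copies — the structural features of
#' the lepidopteran A+T-rich region (the ATAGA motif adjoining a long poly-T
#' stretch near the origin of replication, and microsatellite-like AT/AAT
#' repeats).
#'
#' @param seq control-region DNA string.
#' @param motif motif to match exactly (default "ATAGA").
#' @param min_polyT minimum poly-T run length reported (default 10).
#' @param min_repeat_copies minimum tandem copies reported (default 3).
#' @param repeat_units character vector of repeat units (default AT, AAT).
#' @param offset genome coordinate of the region's first base minus 1; added
#'   to all reported coordinates (default 0 = region-relative).
#' @return object of class `motif_report`: list of data.frames `motif_hits`
#'   (motif, start, end), `polyT_runs` (start, length), `tandem_repeats`
#'   (unit, copies, start, end).
#' @export
scan_control_region <- function(seq, motif = "ATAGA", min_polyT = 10L,
                                min_repeat_copies = 3L,
                                repeat_units = c("AT", "AAT"), offset = 0L) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty sequence")

  hit <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  motif_hits <- if (hit[1] == -1L) {
    data.frame(motif = character(0), start = integer(0), end = integer(0))
  } else {
    data.frame(motif = motif, start = as.integer(hit) + offset,
               end = as.integer(hit) + nchar(motif) - 1L + offset,
               stringsAsFactors = FALSE)
  }

  r <- rle(strsplit(seq, "")[[1]])
  ends <- cumsum(r$lengths)
  keep <- r$values == "T" & r$lengths >= min_polyT
  polyT_runs <- data.frame(start = (ends - r$lengths + 1L)[keep] + offset,
                           length = r$lengths[keep])

  reps <- lapply(repeat_units, function(u) {
    m <- gregexpr(sprintf("(?:%s){%d,}", u, min_repeat_copies), seq,
                  perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    len <- attr(m, "match.length")
    copies <- len %/% nchar(u)
    data.frame(unit = u, copies = copies,
               start = as.integer(m) + offset,
               end = as.integer(m) + copies * nchar(u) - 1L + offset,
               stringsAsFactors = FALSE)
  })
  tandem <- do.call(rbind, reps)
  if (is.null(tandem))
    tandem <- data.frame(unit = character(0), copies = integer(0),
                         start = integer(0), end = integer(0))
  structure(list(motif_hits = motif_hits, polyT_runs = polyT_runs,
                 tandem_repeats = tandem), class = "motif_report")
}
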