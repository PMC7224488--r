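# Annotated-genome container and readers/writers for the formats the
# pipeline touches. Coordinates are 1-based fully inclusive throughout;
# no feature may span the circular origin.

#' Construct a gene feature table
#'
#' Builds and validates the feature `data.frame` carried by an
#' [annotated_genome()]: columns `gene` (canonical symbol), `ftype`,
#' `strand` ("J"/"N"), `start`, `end` (1-based inclusive), `copy_index`
#' (distinguishes duplicated genes), and optionally `printed_gap` (a
#' gap/overlap value carried from a published table).
#'
#' @param gene,strand,start,end vectors of equal length.
#' @param ftype feature types; inferred from the vocabulary when NULL.
#' @param copy_index integer copy numbers, default 1.
#' @param printed_gap optional integer gaps as printed in a source table.
#' @param permissive passed to [normalize_gene_symbol()].
#' @return data.frame of validated features, sorted by start (ties by end).
#' @export
gene_features <- function(gene, strand, start, end, ftype = NULL,
                          copy_index = NULL, printed_gap = NULL,
                          permissive = FALSE) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (anyNA(start) || anyNA(end) ||
      any(start != floor(start)) || any(end != floor(end)))
    stop("non-integer coordinates")
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L)) stop("coordinates must be >= 1")
  if (any(start > end))
    stop("start > end for feature(s): ",
         paste(gene[start > end], collapse = ", "))
  gene <- normalize_gene_symbol(gene, permissive = permissive)
  known <- gene %in% all_gene_symbols()
  ft <- gene_ftype(gene)
  if (!is.null(ftype)) {
    ft[!known] <- as.character(ftype)[!known]  # keep caller's type for aliens
    mismatch <- known & !is.na(ftype) & as.character(ftype) != ft
    if (any(mismatch))
      warning("declared type overridden by vocabulary for: ",
              paste(unique(gene[mismatch]), collapse = ", "))
  }
  if (anyNA(ft)) stop("cannot infer feature type for: ",
                      paste(unique(gene[is.na(ft)]), collapse = ", "))
  if (is.null(copy_index)) copy_index <- rep(1L, length(gene))
  fts <- data.frame(gene = gene, ftype = ft,
                    strand = normalize_strand(strand),
                    start = start, end = end,
                    copy_index = as.integer(copy_index),
                    stringsAsFactors = FALSE)
  if (!is.null(printed_gap)) fts$printed_gap <- as.integer(printed_gap)
  if (anyDuplicated(fts[, c("gene", "copy_index")]))
    stop("duplicate (gene, copy_index) pair(s)")
  fts[order(fts$start, fts$end), , drop = FALSE]
}

#' Construct an annotated mitogenome
#'
#' The unit flowing through every analysis stage: an ordered feature table on
#' a (by default circular) molecule, with or without the nucleotide sequence.
#'
#' @param genome_id short identifier.
#' @param features data.frame as returned by [gene_features()].
#' @param sequence IUPAC DNA string, or NULL for annotation-only genomes.
#' @param length genome length in bp; inferred from the sequence, else from
#'   `max(end)`, when NULL.
#' @param taxon optional taxon name.
#' @param circular logical flag.
#' @return object of class `annotated_genome`.
#' @export
annotated_genome <- function(genome_id, features, sequence = NULL,
                             length = NULL, taxon = NA_character_,
                             circular = TRUE) {
  if (!is.null(sequence)) {
    sequence <- toupper(chartr("u", "t", as.character(sequence)))
    sequence <- chartr("U", "T", sequence)
    if (!grepl("^[ACGTRYSWKMBDHVN]*$", sequence))
      stop("sequence contains non-IUPAC characters")
    seq_len <- nchar(sequence)
    if (!is.null(length) && length != seq_len)
      stop("declared length ", length, " != sequence length ", seq_len)
    length <- seq_len
  }
  if (is.null(length)) length <- max(features$end)
  if (max(features$end) > length)
    stop("feature end ", max(features$end), " exceeds genome length ", length)
  structure(list(genome_id = as.character(genome_id),
                 taxon = as.character(taxon),
                 sequence = sequence, length = as.integer(length),
                 circular = isTRUE(circular), features = features),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s%s: %d bp (%s), %d features, sequence %s\n",
              x$genome_id,
              if (is.na(x$taxon)) "" else paste0(" [", x$taxon, "]"),
              x$length, if (x$circular) "circular" else "linear",
              nrow(x$features),
              if (is.null(x$sequence)) "absent" else "present"))
  invisible(x)
}

#' Read a TSV gene table into annotated genomes
#'
#' Expected columns: `genome_id`, `gene`, `type`, `strand`, `start`, `end`,
#' optionally `copy_index` and `printed_gap` (the parenthesized gap/overlap
#' values of published organization tables). Lines starting with `#` are
#' comments. Strand accepts J/N, F/R and +/-.
#'
#' @param path file path.
#' @param permissive keep unknown gene names (warning) instead of erroring.
#' @return named list of [annotated_genome()] (features only, no sequence).
#' @export
read_gene_table <- function(path, permissive = FALSE) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("genome_id", "gene", "type", "strand", "start", "end")
  if (!all(need %in% names(tab)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  lapply(split(tab, factor(tab$genome_id, unique(tab$genome_id))), function(g) {
    annotated_genome(
      genome_id = g$genome_id[1],
      features = gene_features(
        gene = g$gene, strand = g$strand, start = g$start, end = g$end,
        ftype = g$type,
        copy_index = if ("copy_index" %in% names(g)) g$copy_index else NULL,
        printed_gap = if ("printed_gap" %in% names(g)) g$printed_gap else NULL,
        permissive = permissive))
  })
}

#' Write annotated genomes back to a TSV gene table
#'
#' Inverse of [read_gene_table()]: write-then-read reproduces the genomes
#' field for field.
#'
#' @param genomes a single genome or list of them.
#' @param path output file path.
#' @export
write_gene_table <- function(genomes, path) {
  if (inherits(genomes, "annotated_genome")) genomes <- list(genomes)
  rows <- do.call(rbind, lapply(genomes, function(g) {
    f <- g$features
    out <- data.frame(genome_id = g$genome_id, gene = f$gene, type = f$ftype,
                      strand = f$strand, start = f$start, end = f$end,
                      copy_index = f$copy_index, stringsAsFactors = FALSE)
    out$printed_gap <- if ("printed_gap" %in% names(f)) f$printed_gap else NA
    out
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a FASTA file
#' @param path file path.
#' @return named character vector of upper-case DNA sequences (U mapped to T).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no records in ", path)
  seqs <- toupper(as.character(ss))
  seqs <- chartr("U", "T", seqs)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = width)
  invisible(path)
}

#' Reverse-complement a DNA string
#'
#' IUPAC-aware; an involution that preserves length.
#' @param seq character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Extract a region of a genome sequence
#'
#' @param genome an [annotated_genome()] with sequence, or a bare DNA string.
#' @param start,end 1-based inclusive coordinates (no origin wrap-around).
#' @param strand "J" returns the stored strand; "N" reverse-complements.
#' @return DNA string of length `end - start + 1`.
#' @export
extract_region <- function(genome, start, end, strand = "J") {
  seq <- if (inherits(genome, "annotated_genome")) genome$sequence else genome
  if (is.null(seq)) stop("sequence absent")
  if (start < 1L || end > nchar(seq) || start > end)
    stop("coordinates out of range: ", start, "..", end,
         " on sequence of length ", nchar(seq))
  out <- substr(seq, start, end)
  if (normalize_strand(strand) == "N") out <- reverse_complement(out)
  out
}

#' Extract the sequence of an annotated feature in reading orientation
#' @param genome annotated genome with sequence.
#' @param feature one-row slice of `genome$features`, or a gene symbol.
#' @return DNA string 5'->3' in the gene's reading direction.
#' @export
feature_sequence <- function(genome, feature) {
  if (is.character(feature)) {
    hit <- genome$features[genome$features$gene == feature, , drop = FALSE]
    if (nrow(hit) == 0L) stop("gene not annotated: ", feature)
    if (nrow(hit) > 1L) warning("gene ", feature, " duplicated; using copy 1")
    feature <- hit[1, , drop = FALSE]
  }
  extract_region(genome, feature$start, feature$end, feature$strand)
}

# ---- GenBank flat file -----------------------------------------------------

.parse_gb_location <- function(loc) {
  strand <- "J"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    # no origin-spanning features supported: collapse to the covering span
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(loc, ",")[[1]]
    nums <- as.integer(unlist(regmatches(parts, gregexpr("[0-9]+", parts))))
    return(list(start = min(nums), end = max(nums), strand = strand))
  }
  nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
  list(start = min(nums), end = max(nums), strand = strand)
}

#' Read a GenBank flat file into an annotated genome
#'
#' Minimal reader for single-record mitogenome flat files: parses LOCUS,
#' ORIGIN sequence, and CDS / tRNA / rRNA / misc_feature / D-loop features,
#' mapping their `/gene` or `/product` qualifiers onto the canonical
#' vocabulary. `complement(a..b)` locations become strand N. Unresolvable
#' names are kept with a warning.
#'
#' @param path file path.
#' @return an [annotated_genome()] with sequence.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("no records in ", path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("not a GenBank flat file: no LOCUS line")
  genome_id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
  circular <- grepl("circular", locus[1], ignore.case = TRUE)
  def <- grep("^DEFINITION", lines, value = TRUE)
  taxon <- if (length(def)) {
    trimws(sub("mitochondrion.*$", "",
               sub("^DEFINITION\\s+", "", def[1])))
  } else NA_character_

  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) == 0L) stop("no ORIGIN section")
  oend <- grep("^//", lines)
  oend <- if (length(oend)) oend[oend > ostart[1]][1] else length(lines) + 1L
  seqlines <- lines[(ostart[1] + 1L):(oend - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))

  fstart <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fstart)) {
    block <- lines[(fstart[1] + 1L):(ostart[1] - 1L)]
    keep <- c("CDS", "tRNA", "rRNA", "misc_feature", "D-loop")
    type_map <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                  misc_feature = "control_region", `D-loop` = "control_region")
    idx <- grep("^\\s{5}\\S", block)
    for (k in seq_along(idx)) {
      hdr <- block[idx[k]]
      key <- sub("^\\s+", "", substr(hdr, 1, 20))
      key <- trimws(key)
      if (!key %in% keep) next
      to <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
      body <- block[idx[k]:to]
      loc <- trimws(substr(hdr, 22, nchar(hdr)))
      q <- paste(body[-1], collapse = " ")
      get_q <- function(name) {
        m <- regmatches(q, regexpr(sprintf('/%s="[^"]*"', name), q))
        if (length(m)) sub(sprintf('^/%s="(.*)"$', name), "\\1", m) else NA
      }
      raw <- get_q("gene")
      if (is.na(raw)) raw <- get_q("product")
      if (is.na(raw)) raw <- key
      pl <- .parse_gb_location(loc)
      feats[[length(feats) + 1L]] <- data.frame(
        gene = raw, type = type_map[[key]], strand = pl$strand,
        start = pl$start, end = pl$end, stringsAsFactors = FALSE)
    }
  }
  if (length(feats) == 0L) stop("no usable features in ", path)
  tab <- do.call(rbind, feats)
  canon <- suppressWarnings(normalize_gene_symbol(tab$gene, permissive = TRUE))
  unknown <- !(canon %in% all_gene_symbols())
  if (any(unknown))
    warning("unresolved gene name(s) kept: ",
            paste(unique(tab$gene[unknown]), collapse = ", "))
  # disambiguate duplicated symbols by copy_index in file order
  ci <- stats::ave(seq_along(canon), canon, FUN = seq_along)
  fts <- gene_features(gene = canon, strand = tab$strand, start = tab$start,
                       end = tab$end, ftype = tab$type, copy_index = ci,
                       permissive = TRUE)
  annotated_genome(genome_id, fts, sequence = sequence, taxon = taxon,
                   circular = circular)
}

# ---- JSON dump -------------------------------------------------------------

#' Serialize an annotated genome to JSON
#' @param genome annotated genome.
#' @param path output path; when NULL the JSON string is returned.
#' @export
genome_to_json <- function(genome, path = NULL) {
  obj <- unclass(genome)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                         digits = NA)
    invisible(path)
  }
}

#' Deserialize an annotated genome from JSON
#' @param path file path or JSON string.
#' @export
genome_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  annotated_genome(obj$genome_id,
                   gene_features(gene = obj$features$gene,
                                 strand = obj$features$strand,
                                 start = obj$features$start,
                                 end = obj$features$end,
                                 ftype = obj$features$ftype,
                                 copy_index = obj$features$copy_index,
                                 printed_gap = obj$features$printed_gap),
                   sequence = obj$sequence, length = obj$length,
                   taxon = obj$taxon, circular = obj$circular)
}
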