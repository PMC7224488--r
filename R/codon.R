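# Codon-level analyses under the invertebrate mitochondrial genetic code
# (NCBI translation table 5: AGA/AGG = Ser, ATA = Met, TGA = Trp; stops are
# TAA and TAG only, leaving 62 sense codons).

#' Invertebrate mitochondrial genetic code
#'
#' @return named character vector mapping the 64 DNA codons to one-letter
#'   amino acids, stops as `"*"` (NCBI table 5, via Biostrings).
#' @export
invertebrate_mito_code <- function() Biostrings::getGeneticCode("5")

sense_codons <- function() {
  code <- invertebrate_mito_code()
  names(code)[code != "*"]
}

.aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val")

# reporting sub-labels used in mitogenome RSCU tables:
# Leu2 = TTR (UUR), Leu1 = CTN, Ser2 = TCN (UCN), Ser1 = AGN
.family_label <- function(codon) {
  aa <- invertebrate_mito_code()[codon]
  lab <- unname(.aa3[aa])
  lab[aa == "L"] <- ifelse(substr(codon[aa == "L"], 1, 1) == "T",
                           "Leu2", "Leu1")
  lab[aa == "S"] <- ifelse(substr(codon[aa == "S"], 1, 2) == "AG",
                           "Ser1", "Ser2")
  lab
}

.split_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# classify the 3' terminus of a CDS: complete TAA/TAG stop, incomplete
# single-T or TA stop (completed by polyadenylation), or nonstandard
.classify_stop <- function(cds) {
  len <- nchar(cds)
  rem <- len %% 3L
  if (rem == 1L) {
    tail1 <- substr(cds, len, len)
    list(stop = tail1, incomplete = TRUE, nonstandard = !identical(tail1, "T"))
  } else if (rem == 2L) {
    tail2 <- substr(cds, len - 1L, len)
    list(stop = tail2, incomplete = TRUE, nonstandard = !identical(tail2, "TA"))
  } else {
    last <- substr(cds, len - 2L, len)
    list(stop = last, incomplete = FALSE,
         nonstandard = !last %in% c("TAA", "TAG"))
  }
}

#' Extract a coding sequence as a codon record
#'
#' Takes the annotated boundaries as given (no ORF re-scanning): the region
#' is extracted in reading orientation (N-strand genes reverse-complemented),
#' the first triplet is the start codon, and the terminus is classified as a
#' complete (TAA/TAG), incomplete (trailing T or TA with length mod 3 of 1
#' or 2), or nonstandard stop. Sense codons exclude the stop.
#'
#' @param genome annotated genome with sequence.
#' @param feature a gene symbol or one-row feature slice; must be a PCG.
#' @return object of class `codon_record`: list with `gene`, `start_codon`,
#'   `stop_codon`, `incomplete_stop`, `nonstandard_stop`, `codons`, `cds`.
#' @export
extract_cds <- function(genome, feature) {
  if (is.character(feature)) {
    hit <- genome$features[genome$features$gene == feature, , drop = FALSE]
    if (nrow(hit) == 0L) stop("gene not annotated: ", feature)
    feature <- hit[1, , drop = FALSE]
  }
  if (!identical(feature$ftype, "PCG"))
    stop(feature$gene, " is not a protein-coding gene")
  cds <- feature_sequence(genome, feature)
  codon_record(feature$gene, cds)
}

#' Build a codon record from a raw CDS string
#' @param gene gene symbol.
#' @param cds CDS 5'->3' in reading orientation.
#' @export
codon_record <- function(gene, cds) {
  cds <- toupper(cds)
  if (nchar(cds) < 6L) stop("CDS shorter than 6 nt for ", gene)
  st <- .classify_stop(cds)
  body_len <- nchar(cds) - nchar(st$stop)
  structure(list(gene = gene,
                 start_codon = substr(cds, 1L, 3L),
                 stop_codon = st$stop,
                 incomplete_stop = st$incomplete,
                 nonstandard_stop = st$nonstandard,
                 codons = .split_codons(substr(cds, 1L, body_len)),
                 cds = cds), class = "codon_record")
}

#' Start/stop codon table across genomes
#'
#' One row per PCG, one column per genome, cells formatted `"START/STOP"`
#' (e.g. `"ATT/TAA"`, `"CGA/T"`), the layout of published start/stop tables.
#' A missing gene leaves an NA cell.
#'
#' @param genomes list of annotated genomes with sequence.
#' @param genes PCG order for the rows; defaults to genome order.
#' @return data.frame with rownames = genes.
#' @export
start_stop_table <- function(genomes,
                             genes = c("ND2", "COI", "COII", "ATP8", "ATP6",
                                       "COIII", "ND3", "ND5", "ND4", "ND4L",
                                       "ND6", "CytB", "ND1")) {
  cols <- lapply(genomes, function(g) {
    vapply(genes, function(gene) {
      if (!gene %in% g$features$gene) return(NA_character_)
      r <- extract_cds(g, gene)
      paste0(r$start_codon, "/", r$stop_codon)
    }, character(1))
  })
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  out <- as.data.frame(cols, col.names = ids, check.names = FALSE)
  rownames(out) <- genes
  out
}

#' Pool codon counts over codon records
#'
#' Codons containing N or other ambiguity codes are excluded from the counts
#' and tallied in `n_ambiguous`; stop codons are never counted.
#'
#' @param records a `codon_record` or list of them.
#' @return object of class `codon_usage`: list with `counts` (named integer
#'   vector over the 62 sense codons), `total_codons`, `n_ambiguous`.
#' @export
count_codons <- function(records) {
  if (inherits(records, "codon_record")) records <- list(records)
  if (length(records) == 0L) stop("no codon records")
  all_cod <- unlist(lapply(records, function(r) r$codons))
  ok <- grepl("^[ACGT]{3}$", all_cod)
  counts <- stats::setNames(integer(length(sense_codons())), sense_codons())
  tab <- table(all_cod[ok])
  counts[names(tab)] <- as.integer(tab)
  structure(list(counts = counts, total_codons = sum(counts),
                 n_ambiguous = sum(!ok)), class = "codon_usage")
}

#' Amino-acid usage frequencies
#'
#' Percent of total sense codons per amino acid under translation table 5.
#' Leucine and serine are reported both pooled and split into the
#' conventional sub-families (Leu1 = CUN, Leu2 = UUR; Ser1 = AGN, Ser2 = UCN).
#'
#' @param usage a `codon_usage`.
#' @return list with `pooled` (named percent vector, 3-letter codes) and
#'   `split` (Leu1/Leu2/Ser1/Ser2 percents).
#' @export
amino_acid_frequencies <- function(usage) {
  if (usage$total_codons == 0L) stop("empty usage table")
  code <- invertebrate_mito_code()
  aa <- code[names(usage$counts)]
  pooled <- tapply(usage$counts, unname(.aa3[aa]), sum)
  pooled <- 100 * pooled / usage$total_codons
  lab <- .family_label(names(usage$counts))
  sub <- lab %in% c("Leu1", "Leu2", "Ser1", "Ser2")
  split <- tapply(usage$counts[sub], lab[sub], sum)
  split <- 100 * split / usage$total_codons
  list(pooled = pooled[order(-pooled)], split = split)
}

#' Relative synonymous codon usage
#'
#' Sharp & Li convention: `RSCU(c) = count(c) / mean(count over c's
#' synonymous family)`, families being the full synonymous sets of
#' translation table 5 (6 leucine codons, 8 serine codons). For an observed
#' family the RSCU values sum to the family degeneracy by construction;
#' codons of families with zero total get NA.
#'
#' @param usage a `codon_usage`.
#' @return data.frame with columns `amino_acid` (reporting label, Leu1/Leu2
#'   and Ser1/Ser2 retained), `family` (pooled 3-letter code), `codon` (DNA),
#'   `codon_rna`, `count`, `rscu`, sorted by family then codon.
#' @export
rscu <- function(usage) {
  counts <- usage$counts
  codons <- names(counts)
  code <- invertebrate_mito_code()
  fam <- unname(.aa3[code[codons]])
  fam_mean <- tapply(counts, fam, mean)
  vals <- as.numeric(counts) / as.numeric(fam_mean[fam])
  vals[fam_mean[fam] == 0] <- NA_real_
  out <- data.frame(amino_acid = .family_label(codons), family = fam,
                    codon = codons, codon_rna = chartr("T", "U", codons),
                    count = as.integer(counts), rscu = vals,
                    stringsAsFactors = FALSE)
  out <- out[order(out$family, out$codon), , drop = FALSE]
  rownames(out) <- NULL
  out
}
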