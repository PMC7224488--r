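# Controlled vocabulary for mitochondrial gene symbols and strand codes.

#' Canonical mitochondrial gene symbols
#'
#' The 37 genes of the typical insect mitogenome plus the control region:
#' 13 protein-coding genes (PCGs), 22 tRNAs (with the two leucine and two
#' serine isoacceptors distinguished as trnL1/trnL2 and trnS1/trnS2), the
#' large and small rRNAs, and the A+T-rich control region.
#'
#' @return Named list with elements `pcg`, `trna`, `rrna`, `control_region`,
#'   each a character vector of canonical symbols.
#' @export
mito_vocabulary <- function() {
  list(
    pcg = c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
            "COI", "COII", "COIII", "ATP6", "ATP8", "CytB"),
    trna = c("trnA", "trnR", "trnN", "trnD", "trnC", "trnQ", "trnE", "trnG",
             "trnH", "trnI", "trnL1", "trnL2", "trnK", "trnM", "trnF",
             "trnP", "trnS1", "trnS2", "trnT", "trnW", "trnY", "trnV"),
    rrna = c("rrnL", "rrnS"),
    control_region = "control_region"
  )
}

all_gene_symbols <- function() unlist(mito_vocabulary(), use.names = FALSE)

#' Feature type of a canonical gene symbol
#' @param gene character vector of canonical symbols.
#' @return character vector in {PCG, tRNA, rRNA, control_region}.
#' @export
gene_ftype <- function(gene) {
  v <- mito_vocabulary()
  out <- rep(NA_character_, length(gene))
  out[gene %in% v$pcg] <- "PCG"
  out[gene %in% v$trna] <- "tRNA"
  out[gene %in% v$rrna] <- "rRNA"
  out[gene %in% v$control_region] <- "control_region"
  out
}

# collapse a raw gene name to a lookup key: case-folded alphanumerics only
.name_key <- function(x) toupper(gsub("[^A-Za-z0-9]", "", x))

.synonym_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "gene_synonyms.tsv", package = "mitoarch")
      tab <- utils::read.delim(path, comment.char = "#",
                               stringsAsFactors = FALSE)
      cache <<- stats::setNames(tab$canonical, .name_key(tab$alias))
    }
    cache
  }
})

#' Normalize a gene name to the canonical vocabulary
#'
#' Resolves the heterogeneous gene names found in GenBank records and
#' published tables ("COX1", "CYTB", "l-rRNA", "tRNA-Leu(CUN)", "D-loop", ...)
#' against the canonical symbols. The alias map ships as an editable TSV
#' (`inst/extdata/gene_synonyms.tsv`). Already-canonical symbols pass through.
#'
#' @param x character vector of raw gene names.
#' @param permissive if TRUE, unresolvable names are returned unchanged with a
#'   warning instead of an error.
#' @return character vector of canonical symbols.
#' @export
normalize_gene_symbol <- function(x, permissive = FALSE) {
  canon <- all_gene_symbols()
  map <- .synonym_table()
  key <- .name_key(x)
  canon_key <- stats::setNames(canon, .name_key(canon))
  out <- ifelse(key %in% names(canon_key), canon_key[key],
                ifelse(key %in% names(map), map[key], NA_character_))
  bad <- is.na(out)
  if (any(bad)) {
    if (permissive) {
      warning("unresolved gene name(s) kept verbatim: ",
              paste(unique(x[bad]), collapse = ", "))
      out[bad] <- x[bad]
    } else {
      stop("unknown gene symbol(s): ", paste(unique(x[bad]), collapse = ", "))
    }
  }
  unname(out)
}

#' Normalize a strand code
#'
#' The package uses the J/N vocabulary (majority and minority coding strand).
#' `F`, `+`, `1` are accepted as J; `R`, `-`, `-1` as N.
#' @param x character vector of strand codes.
#' @return character vector of "J"/"N".
#' @export
normalize_strand <- function(x) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  out[x %in% c("J", "F", "+", "1")] <- "J"
  out[x %in% c("N", "R", "-", "-1")] <- "N"
  if (anyNA(out)) stop("unknown strand code(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}
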