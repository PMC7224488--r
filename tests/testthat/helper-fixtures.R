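# Shared fixtures: bundled organization tables and a tiny toy genome with
# sequence, built in code.

dh_genome <- function() {
  read_gene_table(mito_example("dendrolimus_houi_genes.tsv"))[["DH"]]
}

ku_genome <- function() {
  read_gene_table(mito_example("kunugia_undans_genes.tsv"))[["KU"]]
}

# 3-feature toy genome: a J-strand PCG, an N-strand PCG (same CDS), a tRNA.
# CDS = ATG AAA CCC TAA (12 nt).
toy_genome <- function() {
  cds <- "ATGAAACCCTAA"
  trna <- "GCTAGCTAGCTAGCTAGCTA"            # 20 nt
  seqn <- paste0(cds, "TT", reverse_complement(cds), "G", trna)
  fts <- gene_features(gene = c("ND2", "ND3", "trnM"),
                       strand = c("J", "N", "J"),
                       start = c(1, 15, 28), end = c(12, 26, 47))
  annotated_genome("TOY", fts, sequence = seqn, circular = FALSE)
}

random_dna <- function(n, at = 0.6) {
  p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
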