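test_that("translation table 5 is the single source of truth", {
  code <- invertebrate_mito_code()
  expect_equal(unname(code[c("AGA", "AGG", "TGA", "ATA")]),
               c("S", "S", "W", "M"))
  expect_equal(sum(code == "*"), 2L)          # TAA, TAG only
  expect_equal(length(sense_codons()), 62L)
})

test_that("codon records classify complete, incomplete and nonstandard stops", {
  r <- codon_record("ND2", "ATGAAATAA")
  expect_equal(r$start_codon, "ATG")
  expect_equal(r$stop_codon, "TAA")
  expect_false(r$incomplete_stop)
  expect_equal(r$codons, c("ATG", "AAA"))

  r1 <- codon_record("COI", paste0("CGAAAACCC", "T"))   # 3n + 1, trailing T
  expect_true(r1$incomplete_stop)
  expect_equal(r1$stop_codon, "T")
  expect_false(r1$nonstandard_stop)

  r2 <- codon_record("COII", paste0("ATGAAA", "TA"))    # 3n + 2, trailing TA
  expect_true(r2$incomplete_stop)
  expect_equal(r2$stop_codon, "TA")

  r3 <- codon_record("ND1", "ATGAAACCC")                # no stop at all
  expect_true(r3$nonstandard_stop)
  expect_false(r3$incomplete_stop)
  expect_error(codon_record("ND1", "ATG"), "shorter")
})

test_that("extract_cds honors strand: J and N annotations of one CDS agree", {
  g <- toy_genome()
  rj <- extract_cds(g, "ND2")
  rn <- extract_cds(g, "ND3")
  expect_equal(rj$cds, rn$cds)
  expect_equal(rj$start_codon, "ATG")
  expect_equal(rj$stop_codon, "TAA")
  expect_equal(rj$codons, rn$codons)
  expect_error(extract_cds(g, "trnM"), "not a protein-coding")
})

test_that("codon counting pools records, excludes stops and ambiguity", {
  r1 <- codon_record("a", "ATGAAATAA")
  r2 <- codon_record("b", "ATGTTTTAA")
  u12 <- count_codons(list(r1, r2))
  u21 <- count_codons(list(r2, r1))
  expect_equal(u12$counts, u21$counts)        # order-independent pooling
  expect_equal(u12$total_codons,
               count_codons(r1)$total_codons + count_codons(r2)$total_codons)
  expect_equal(u12$counts[["ATG"]], 2L)
  expect_true(all(!c("TAA", "TAG") %in% names(u12$counts)))
  rn <- codon_record("c", "ATGANATAA")
  un <- count_codons(rn)
  expect_equal(un$n_ambiguous, 1L)
  expect_equal(un$total_codons, 1L)
})

test_that("amino-acid frequencies sum to 100 and split Leu/Ser families", {
  u <- count_codons(codon_record("x", "ATGATGATGATGTAA"))
  fr <- amino_acid_frequencies(u)
  expect_equal(unname(fr$pooled["Met"]), 100)
  set.seed(5)
  fake <- count_codons(codon_record("y", paste0(
    paste(sample(sense_codons(), 300, replace = TRUE), collapse = ""), "TAA")))
  fr2 <- amino_acid_frequencies(fake)
  expect_lt(abs(sum(fr2$pooled) - 100), 0.05)
  expect_equal(unname(fr2$pooled["Leu"]),
               unname(fr2$split["Leu1"] + fr2$split["Leu2"]))
  expect_equal(unname(fr2$pooled["Ser"]),
               unname(fr2$split["Ser1"] + fr2$split["Ser2"]))
})

test_that("RSCU follows the synonymous-family mean convention", {
  # uniform usage: every codon at its family mean
  u <- count_codons(codon_record("u", paste0(
    paste(rep(sense_codons(), 2), collapse = ""), "TAA")))
  r <- rscu(u)
  expect_true(all(abs(r$rscu - 1) < 1e-12))
  # Phe family 3:1
  u2 <- count_codons(codon_record("p", "TTTTTTTTTTTCTAA"))
  r2 <- rscu(u2)
  expect_equal(r2$rscu[r2$codon == "TTT"], 1.5)
  expect_equal(r2$rscu[r2$codon == "TTC"], 0.5)
  # unobserved family -> NA; observed family with unobserved codon -> 0
  expect_true(is.na(r2$rscu[r2$codon == "GGG"]))
  u3 <- count_codons(codon_record("q", "TTTTTTTAA"))
  r3 <- rscu(u3)
  expect_equal(r3$rscu[r3$codon == "TTC"], 0)
})

test_that("RSCU family sums equal degeneracy on arbitrary usage tables", {
  set.seed(91)
  code <- invertebrate_mito_code()
  for (i in 1:15) {
    n <- sample(c(50, 500, 5000), 1)
    cods <- sample(sense_codons(), n, replace = TRUE,
                   prob = runif(62, 0.1, 5))
    u <- count_codons(codon_record("z", paste0(paste(cods, collapse = ""),
                                               "TAA")))
    r <- rscu(u)
    fam_sum <- tapply(r$rscu, r$family, sum)
    fam_deg <- tapply(r$rscu, r$family, length)
    observed <- names(fam_sum)[!is.na(fam_sum)]
    expect_equal(as.vector(fam_sum[observed]),
                 as.numeric(fam_deg[observed]))
  }
})

test_that("start/stop table formats cells as START/STOP", {
  spec <- sim_spec()
  plan <- spec$gene_plan
  plan$start[!is.na(plan$start)] <- "ATG"
  plan$stop[!is.na(plan$stop)] <- "TAA"
  is_pcg <- !is.na(plan$start)
  # make lengths stop-consistent (all complete stops)
  plan$length[is_pcg] <- plan$length[is_pcg] + (3 - plan$length[is_pcg] %% 3) %% 3
  plan$gap[plan$gap < 0] <- 2   # no overlaps: planted codons must survive
  g <- generate_mitogenome(sim_spec(gene_plan = plan), seed = 2,
                           genome_id = "ALLATG")
  tab <- start_stop_table(list(g))
  expect_equal(dim(tab), c(13L, 1L))
  expect_true(all(tab[["ALLATG"]] == "ATG/TAA"))
})

test_that("codon bookkeeping conserves annotated PCG lengths", {
  g <- generate_mitogenome(seed = 31)
  pcgs <- g$features[g$features$ftype == "PCG", ]
  recs <- lapply(seq_len(nrow(pcgs)), function(i) extract_cds(g, pcgs[i, ]))
  tot <- sum(vapply(recs, function(r) {
    3L * length(r$codons) + nchar(r$stop_codon)
  }, integer(1)))
  expect_equal(tot, sum(pcgs$end - pcgs$start + 1L))
})
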