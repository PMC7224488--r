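test_that("generation is deterministic given spec and seed", {
  a <- generate_mitogenome(seed = 4)
  b <- generate_mitogenome(seed = 4)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$features, b$features)
  expect_false(identical(generate_mitogenome(seed = 5)$sequence, a$sequence))
})

test_that("an all-abutting junction plan tiles the genome exactly", {
  plan <- sim_spec()$gene_plan
  plan$gap[-1] <- 0L
  g <- generate_mitogenome(sim_spec(gene_plan = plan), seed = 9)
  adj <- adjacency_report(g)
  expect_true(all(adj$gap == 0L))
  expect_equal(sum(g$features$end - g$features$start + 1L), g$length)
})

test_that("infeasible plans are rejected", {
  plan <- sim_spec()$gene_plan
  plan$gap[plan$gene == "trnI"] <- -200L  # deeper than either neighbor
  expect_error(sim_spec(gene_plan = plan), "infeasible")
  plan2 <- sim_spec()$gene_plan
  plan2$stop[plan2$gene == "ND2"] <- "T"  # length mod 3 no longer matches
  expect_error(sim_spec(gene_plan = plan2), "inconsistent")
})

test_that("realized A+T tracks the target and tightens with length", {
  devs <- sapply(1:3, function(s) {
    g <- generate_mitogenome(seed = s)
    abs(base_composition(g$sequence)$at_content / 100 - 0.80)
  })
  expect_true(all(devs < 0.01))
  # short genome (tRNAs only, ~1.4 kb): deviations spread visibly wider
  plan <- sim_spec()$gene_plan
  short <- plan[gene_ftype(plan$gene) == "tRNA", ]
  short$gap[1] <- NA; short$gap[-1] <- 0L
  devs_short <- sapply(1:6, function(s) {
    g <- generate_mitogenome(sim_spec(gene_plan = short), seed = s)
    abs(base_composition(g$sequence)$at_content / 100 - 0.80)
  })
  expect_lt(mean(devs), mean(devs_short))
})

test_that("planned codons survive on overlap-free plans", {
  plan <- sim_spec()$gene_plan
  plan$gap[which(plan$gap < 0)] <- 3L
  g <- generate_mitogenome(sim_spec(gene_plan = plan), seed = 21)
  truth <- attr(g, "truth")
  expect_equal(truth$codons$planned_start, truth$codons$realized_start)
  expect_equal(truth$codons$planned_stop, truth$codons$realized_stop)
  for (i in seq_len(nrow(truth$codons))) {
    rec <- extract_cds(g, truth$codons$gene[i])
    expect_equal(rec$start_codon, truth$codons$planned_start[i])
    expect_equal(rec$stop_codon, truth$codons$planned_stop[i])
    expect_equal(rec$incomplete_stop, nchar(rec$stop_codon) < 3L)
  }
})

test_that("the duplicate-trnR variant is detected as a duplication", {
  ku_like <- generate_mitogenome(sim_spec(variant = "duplicate_trnR"),
                                 seed = 3, genome_id = "KUSIM")
  std <- generate_mitogenome(seed = 3)
  cmp <- compare_orders(ku_like, std)
  expect_equal(cmp$duplicated_in_a, "trnR")
  expect_equal(cmp$breakpoints, 0L)
})

test_that("evolution along a tree is seeded and degenerate-safe", {
  tre <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  root <- strrep("ACGT", 25)
  tips <- evolve_sequences(tre, root_seq = root, seed = 1)
  expect_true(all(tips == root))           # zero branch lengths: no change
  tre2 <- ape::read.tree(text = "((a:0.1,b:0.1):0.05,(c:0.1,d:0.1):0.05);")
  x <- evolve_sequences(tre2, root_length = 500, seed = 8)
  y <- evolve_sequences(tre2, root_length = 500, seed = 8)
  expect_identical(x, y)
  expect_false(identical(x, evolve_sequences(tre2, root_length = 500,
                                             seed = 9)))
})

test_that("K2P estimates from simulation are consistent with the truth", {
  d_true <- 0.1
  tre <- ape::read.tree(text = sprintf("(a:%f,b:%f);", d_true / 2, d_true / 2))
  aln <- evolve_sequences(tre, root_length = 100000, model = "k2p",
                          kappa = 2, seed = 12)
  d_hat <- k2p_distance(aln[["a"]], aln[["b"]])
  # Kimura's large-sample variance of the K2P estimator
  ch <- cbind(strsplit(aln[["a"]], "")[[1]], strsplit(aln[["b"]], "")[[1]])
  diffs <- ch[, 1] != ch[, 2]
  ts <- diffs & (ch[, 1] %in% c("A", "G")) == (ch[, 2] %in% c("A", "G"))
  P <- mean(ts); Q <- mean(diffs & !ts); n <- nrow(ch)
  c1 <- 1 / (1 - 2 * P - Q); c2 <- 1 / (1 - 2 * Q); c3 <- (c1 + c2) / 2
  se <- sqrt((c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / n)
  expect_lt(abs(d_hat - d_true), 3 * se)

  # with transitions and transversions forced equal (kappa = 1) the K2P
  # estimate agrees with the Jukes-Cantor estimate within Monte-Carlo error
  aln2 <- evolve_sequences(tre, root_length = 100000, model = "k2p",
                           kappa = 1, seed = 13)
  d_k2p <- k2p_distance(aln2[["a"]], aln2[["b"]])
  p_diff <- mean(strsplit(aln2[["a"]], "")[[1]] !=
                 strsplit(aln2[["b"]], "")[[1]])
  d_jc <- -0.75 * log(1 - 4 * p_diff / 3)
  expect_lt(abs(d_k2p - d_jc), 0.003)
})

test_that("generator truth is recovered exactly by the analysis modules", {
  g <- generate_mitogenome(seed = 17)
  truth <- attr(g, "truth")
  # junctions: computed == planted
  adj <- adjacency_report(g)
  expect_identical(adj$gap, adj$printed_gap)
  # codons: pipeline recovers the realized start/stop of every PCG
  for (i in seq_len(nrow(truth$codons))) {
    rec <- extract_cds(g, truth$codons$gene[i])
    expect_equal(rec$start_codon, truth$codons$realized_start[i])
    expect_equal(rec$stop_codon, truth$codons$realized_stop[i])
  }
  # control region: motif, poly-T and tandem repeats at the planted spans
  crf <- g$features[g$features$ftype == "control_region", ]
  rep <- scan_control_region(extract_region(g, crf$start, crf$end, "J"),
                             offset = crf$start - 1L)
  expect_equal(rep$motif_hits$start, truth$cr$motif$start)
  expect_equal(rep$polyT_runs$start, truth$cr$polyT$start)
  expect_equal(rep$polyT_runs$length, truth$cr$polyT$length)
  got <- rep$tandem_repeats[order(rep$tandem_repeats$start), ]
  want <- truth$cr$repeats[order(truth$cr$repeats$start), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})
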