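# Synthetic annotated mitogenomes and tree-evolved sequence sets.
#
# The generator emits a circular 37-gene genome in the conserved
# lepidopteran arrangement (starting at trnM) with a planned junction
# profile (overlaps/spacers), AT-biased composition, per-gene start/stop
# codons including incomplete single-T / TA stops, and a control region
# carrying an ATAGA motif, a long poly-T stretch and microsatellite-like
# tandem repeats — so every analysis stage can be tested against known
# truth without downloads.

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.default_gene_plan <- function() {
  # gene, strand, length, gap to the PREVIOUS gene (NA for the first),
  # start/stop codons for PCGs. Lengths and junctions follow the compact
  # lepidopteran layout: ~15.4 kb total, 8 overlapping junctions, a 60 bp
  # spacer ahead of COI; stop lengths are consistent with gene lengths
  # (length mod 3 = 1 for single-T stops).
  plan <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene strand length gap start stop
trnM J 67 NA NA NA
trnI J 64 1 NA NA
trnQ N 69 -3 NA NA
ND2 J 1035 31 ATA TAA
trnW J 70 -2 NA NA
trnC N 67 -8 NA NA
trnY N 71 1 NA NA
COI J 1504 60 CGA T
trnL2 J 67 -5 NA NA
COII J 685 0 ATA T
trnK J 71 1 NA NA
trnD J 67 1 NA NA
ATP8 J 162 0 ATT TAA
ATP6 J 675 -4 ATG TAA
COIII J 789 16 ATG TAA
trnG J 66 2 NA NA
ND3 J 354 0 ATT TAG
trnA J 68 -2 NA NA
trnR J 65 9 NA NA
trnN J 67 4 NA NA
trnS1 J 66 20 NA NA
trnE J 69 0 NA NA
trnF N 67 8 NA NA
ND5 N 1686 4 ATA TAA
trnH N 64 57 NA NA
ND4 N 1336 1 ATG T
ND4L N 267 31 ATG TAA
trnT J 65 31 NA NA
trnP N 65 0 NA NA
ND6 J 522 17 ATA TAA
CytB J 1146 8 ATG TAA
trnS2 J 66 3 NA NA
ND1 N 930 -1 ATG TAA
trnL1 N 68 25 NA NA
rrnL N 1365 40 NA NA
trnV N 68 -1 NA NA
rrnS N 776 0 NA NA
control_region J 319 0 NA NA
")
  plan
}

.default_cr_plan <- function() {
  list(motif = "ATAGA", polyT_len = 14L,
       repeats = data.frame(unit = c("AT", "AAT", "AAT", "AT"),
                            copies = c(6L, 4L, 4L, 5L),
                            stringsAsFactors = FALSE))
}

#' Specification for a synthetic mitogenome
#'
#' Defaults describe a typical compact lepidopteran mitogenome: the 37-gene
#' arrangement from trnM with the conserved strand pattern, ~15.4 kb, A+T
#' target 0.80, planned overlaps/spacers at every junction, ATN/CGA starts,
#' complete and incomplete (T / TA) stops, and a control region with an
#' ATAGA motif, a 14 bp poly-T stretch, and AT/AAT tandem repeats.
#'
#' @param gene_plan data.frame with columns gene, strand, length, gap (to
#'   the previous gene; NA for the first), start, stop (PCGs only).
#' @param at_content_target target A+T fraction in (0, 1).
#' @param codon_bias named numeric weights over sense codons for PCG bodies;
#'   NULL = independent-base weights at the A+T target.
#' @param cr_plan control-region recipe: list(motif, polyT_len, repeats).
#' @param variant "standard" or "duplicate_trnR" (inserts a second trnR
#'   copy, the arrangement peculiarity known from *Kunugia undans*).
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(gene_plan = .default_gene_plan(),
                     at_content_target = 0.80,
                     codon_bias = NULL,
                     cr_plan = .default_cr_plan(),
                     variant = c("standard", "duplicate_trnR")) {
  variant <- match.arg(variant)
  if (variant == "duplicate_trnR") {
    i <- which(gene_plan$gene == "trnR")[1]
    extra <- data.frame(gene = "trnR", strand = "J", length = 67L, gap = 27L,
                        start = NA, stop = NA, stringsAsFactors = FALSE)
    gene_plan <- rbind(gene_plan[1:i, ], extra,
                       gene_plan[(i + 1):nrow(gene_plan), ])
  }
  stopifnot(all(gene_plan$length > 0),
            at_content_target > 0, at_content_target < 1)
  is_pcg <- gene_ftype(gene_plan$gene) == "PCG"
  bad <- is_pcg & (gene_plan$length - 3L - nchar(gene_plan$stop)) %% 3L != 0L
  if (any(bad, na.rm = TRUE))
    stop("PCG length inconsistent with whole-codon body plus stop: ",
         paste(gene_plan$gene[which(bad)], collapse = ", "))
  # an overlap may not swallow either neighbor
  g <- gene_plan$gap[-1]
  if (any(-g >= pmin(gene_plan$length[-1],
                     gene_plan$length[-nrow(gene_plan)]), na.rm = TRUE))
    stop("infeasible junction plan: overlap exceeds a neighbor's length")
  structure(list(gene_plan = gene_plan,
                 at_content_target = at_content_target,
                 codon_bias = codon_bias, cr_plan = cr_plan,
                 variant = variant), class = "sim_spec")
}

.base_probs <- function(at) {
  c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
}

.sample_bases <- function(n, at) {
  p <- .base_probs(at)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.default_codon_bias <- function(at) {
  cods <- sense_codons()
  chars <- strsplit(cods, "")
  at_frac <- vapply(chars, function(cc) sum(cc %in% c("A", "T")) / 3,
                    numeric(1))
  weights <- function(atp) {
    p <- .base_probs(atp)
    w <- vapply(chars, function(cc) prod(p[cc]), numeric(1))
    w / sum(w)
  }
  # dropping the AT-rich stop codons (TAA/TAG) from the pool depresses the
  # realized A+T below an independent-base target; tilt the per-base
  # probability so the sense-codon mixture hits the target exactly
  atp <- stats::uniroot(function(x) sum(weights(x) * at_frac) - at,
                        c(max(at - 0.15, 0.02), min(at + 0.15, 0.98)))$root
  stats::setNames(weights(atp), cods)
}

# mutate CR filler so no spurious motif / poly-T run / tandem array appears
# outside the planted spans (planted spans are protected)
.scrub_cr <- function(chars, protected, plan, min_polyT = 10L,
                      min_copies = 3L) {
  seqstr <- function() paste(chars, collapse = "")
  units <- unique(plan$repeats$unit)
  for (pass in 1:50) {
    dirty <- FALSE
    rep_hit <- scan_control_region(seqstr(), motif = plan$motif,
                                   min_polyT = min_polyT,
                                   min_repeat_copies = min_copies,
                                   repeat_units = units)
    spans <- rbind(
      if (nrow(rep_hit$motif_hits))
        cbind(rep_hit$motif_hits$start, rep_hit$motif_hits$end),
      if (nrow(rep_hit$polyT_runs))
        cbind(rep_hit$polyT_runs$start,
              rep_hit$polyT_runs$start + rep_hit$polyT_runs$length - 1L),
      if (nrow(rep_hit$tandem_repeats))
        cbind(rep_hit$tandem_repeats$start, rep_hit$tandem_repeats$end))
    if (!is.null(spans)) {
      for (k in seq_len(nrow(spans))) {
        span <- spans[k, 1]:spans[k, 2]
        if (all(span %in% protected)) next
        fix <- setdiff(span, protected)
        mid <- fix[ceiling(length(fix) / 2)]
        chars[mid] <- if (chars[mid] == "C") "G" else "C"
        dirty <- TRUE
      }
    }
    if (!dirty) break
  }
  chars
}

.build_cr <- function(len, at, plan) {
  motif_ch <- strsplit(plan$motif, "")[[1]]
  polyT_ch <- rep("T", plan$polyT_len)
  rep_seqs <- lapply(seq_len(nrow(plan$repeats)), function(i) {
    strsplit(strrep(plan$repeats$unit[i], plan$repeats$copies[i]), "")[[1]]
  })
  # planted blocks with single-base C guards so arrays/runs stay maximal
  blocks <- c(list(c(motif_ch, polyT_ch, "C")),
              lapply(rep_seqs, function(x) c("C", x, "C")))
  need <- sum(lengths(blocks))
  if (need + length(blocks) > len)
    stop("control region too short for its motif plan")
  filler_total <- len - need
  cuts <- sort(sample.int(filler_total, length(blocks)))
  seg_len <- diff(c(0L, cuts, filler_total))
  chars <- character(0)
  truth <- list()
  pos <- 0L
  protected <- integer(0)
  add <- function(x) { chars <<- c(chars, x); pos <<- pos + length(x) }
  add(strsplit(.sample_bases(seg_len[1], at), "")[[1]])
  for (i in seq_along(blocks)) {
    if (i == 1L) {
      truth$motif <- data.frame(motif = plan$motif, start = pos + 1L,
                                end = pos + length(motif_ch))
      truth$polyT <- data.frame(start = pos + length(motif_ch) + 1L,
                                length = plan$polyT_len)
      protected <- c(protected,
                     (pos + 1L):(pos + length(motif_ch) + plan$polyT_len))
    } else {
      u <- plan$repeats$unit[i - 1L]; cp <- plan$repeats$copies[i - 1L]
      truth$repeats <- rbind(truth$repeats,
        data.frame(unit = u, copies = cp, start = pos + 2L,
                   end = pos + 1L + cp * nchar(u), stringsAsFactors = FALSE))
      protected <- c(protected, (pos + 2L):(pos + 1L + cp * nchar(u)))
    }
    add(blocks[[i]])
    if (seg_len[i + 1L] > 0L)
      add(strsplit(.sample_bases(seg_len[i + 1L], at), "")[[1]])
  }
  chars <- .scrub_cr(chars, protected, plan)
  list(seq = paste(chars, collapse = ""), truth = truth)
}

#' Generate a synthetic annotated mitogenome
#'
#' Realizes a [sim_spec()] exactly: the annotation reproduces the planned
#' gene order and junction profile, PCG bodies are drawn from the codon
#' bias, non-coding filler is i.i.d. at the A+T target, and the control
#' region carries its planted motif structure. In overlapped bases the
#' downstream gene's sequence takes precedence, so an upstream PCG's planted
#' stop can be rewritten by its neighbor (as in real compact mitogenomes);
#' the truth metadata records both the planned and the realized codons.
#'
#' @param spec a [sim_spec()].
#' @param seed integer seed; same spec + seed gives a byte-identical genome.
#' @param genome_id identifier for the genome.
#' @return [annotated_genome()] with sequence and attribute `"truth"`: list
#'   with `features` (planned coordinates and gaps), `codons` (planned and
#'   realized start/stop per PCG), `cr` (motif/poly-T/repeat coordinates,
#'   genome-relative), `at_content_target`, `seed`.
#' @export
generate_mitogenome <- function(spec = sim_spec(), seed = 1L,
                                genome_id = "SIM") {
  with_seed(seed, {
    plan <- spec$gene_plan
    at <- spec$at_content_target
    n <- nrow(plan)
    start <- integer(n); end <- integer(n)
    start[1] <- 1L
    end[1] <- plan$length[1]
    for (i in 2:n) {
      start[i] <- end[i - 1L] + plan$gap[i] + 1L
      end[i] <- start[i] + plan$length[i] - 1L
    }
    glen <- end[n]
    if (any(start < 1L)) stop("infeasible junction plan: negative coordinate")
    bias <- spec$codon_bias
    if (is.null(bias)) bias <- .default_codon_bias(at)

    chars <- strsplit(.sample_bases(glen, at), "")[[1]]
    cr_truth <- NULL
    ftype <- gene_ftype(plan$gene)
    for (i in seq_len(n)) {
      L <- plan$length[i]
      if (ftype[i] == "PCG") {
        nbody <- (L - 3L - nchar(plan$stop[i])) %/% 3L
        body <- sample(names(bias), nbody, replace = TRUE, prob = bias)
        reading <- paste0(plan$start[i], paste(body, collapse = ""),
                          plan$stop[i])
      } else if (ftype[i] == "control_region") {
        built <- .build_cr(L, at, spec$cr_plan)
        reading <- built$seq
        cr_truth <- built$truth
        cr_truth$motif$start <- cr_truth$motif$start + start[i] - 1L
        cr_truth$motif$end <- cr_truth$motif$end + start[i] - 1L
        cr_truth$polyT$start <- cr_truth$polyT$start + start[i] - 1L
        cr_truth$repeats$start <- cr_truth$repeats$start + start[i] - 1L
        cr_truth$repeats$end <- cr_truth$repeats$end + start[i] - 1L
      } else {
        reading <- .sample_bases(L, at)
      }
      placed <- if (plan$strand[i] == "N") reverse_complement(reading)
                else reading
      chars[start[i]:end[i]] <- strsplit(placed, "")[[1]]
    }
    sequence <- paste(chars, collapse = "")

    ci <- stats::ave(seq_len(n), plan$gene, FUN = seq_along)
    fts <- gene_features(gene = plan$gene, strand = plan$strand,
                         start = start, end = end, copy_index = ci,
                         printed_gap = plan$gap)
    g <- annotated_genome(genome_id, fts, sequence = sequence,
                          circular = TRUE)

    pcg <- which(ftype == "PCG")
    realized <- lapply(pcg, function(i) {
      rec <- codon_record(plan$gene[i],
                          extract_region(g, start[i], end[i], plan$strand[i]))
      data.frame(gene = plan$gene[i],
                 planned_start = plan$start[i], planned_stop = plan$stop[i],
                 realized_start = rec$start_codon,
                 realized_stop = rec$stop_codon,
                 incomplete_stop = rec$incomplete_stop,
                 stringsAsFactors = FALSE)
    })
    attr(g, "truth") <- list(features = cbind(fts),
                             codons = do.call(rbind, realized),
                             cr = cr_truth,
                             at_content_target = at, seed = seed)
    g
  })
}

# ---- sequence evolution along a tree --------------------------------------

.BASES <- c("A", "C", "G", "T")
.TS_PARTNER <- c(A = "G", C = "T", G = "A", T = "C")
.TV1 <- c(A = "C", C = "A", G = "C", T = "A")
.TV2 <- c(A = "T", C = "G", G = "T", T = "G")

# one branch of per-site substitution; x is a character vector of bases
.evolve_branch <- function(x, d, model, kappa, freqs) {
  if (d <= 0) return(x)
  n <- length(x)
  if (model == "k2p") {
    bt <- d / (kappa + 2)          # beta * t
    at <- kappa * bt               # alpha * t
    pTs <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
    pTv <- 0.5 - 0.5 * exp(-4 * bt)    # split equally over the two targets
    u <- stats::runif(n)
    out <- x
    sel <- u < pTs
    out[sel] <- .TS_PARTNER[x[sel]]
    sel2 <- !sel & u < pTs + pTv / 2
    out[sel2] <- .TV1[x[sel2]]
    sel3 <- !sel & !sel2 & u < pTs + pTv
    out[sel3] <- .TV2[x[sel3]]
    out
  } else {                         # jc with arbitrary base frequencies (F81)
    mu <- 1 / (1 - sum(freqs^2))
    p_same <- exp(-mu * d)
    hit <- stats::runif(n) >= p_same
    out <- x
    out[hit] <- sample(.BASES, sum(hit), replace = TRUE, prob = freqs)
    out
  }
}

#' Evolve sequences along a phylogeny
#'
#' Simulates independent per-site substitution along each branch under K2P
#' (uniform base frequencies, transition/transversion ratio `kappa`) or an
#' equal-rates model with arbitrary base frequencies ("jc"; with AT-biased
#' frequencies this mimics mitochondrial composition). Branch lengths are in
#' expected substitutions per site.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param root_seq root DNA string; when NULL a root of `root_length` bases
#'   is drawn from the model's equilibrium frequencies.
#' @param root_length root sequence length when `root_seq` is NULL.
#' @param model "k2p" or "jc".
#' @param kappa transition/transversion rate ratio (k2p).
#' @param base_freqs equilibrium base frequencies A,C,G,T (jc).
#' @param seed integer seed.
#' @return named character vector of tip sequences.
#' @export
evolve_sequences <- function(tree, root_seq = NULL, root_length = 1000L,
                             model = c("k2p", "jc"), kappa = 2,
                             base_freqs = c(A = 0.4, C = 0.1, G = 0.1,
                                            T = 0.4),
                             seed = 1L) {
  model <- match.arg(model)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  base_freqs <- base_freqs / sum(base_freqs)
  with_seed(seed, {
    if (is.null(root_seq)) {
      p <- if (model == "k2p") rep(0.25, 4) else base_freqs
      root <- sample(.BASES, root_length, replace = TRUE, prob = p)
    } else {
      root <- strsplit(toupper(root_seq), "")[[1]]
      if (!all(root %in% .BASES)) stop("root_seq must be unambiguous ACGT")
    }
    ntip <- length(tree$tip.label)
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[ntip + 1L]] <- root
    tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
    for (k in seq_len(nrow(tree$edge))) {
      par <- tree$edge[k, 1]; child <- tree$edge[k, 2]
      seqs[[child]] <- .evolve_branch(seqs[[par]], tree$edge.length[k],
                                      model, kappa, base_freqs)
    }
    out <- vapply(seqs[seq_len(ntip)], paste, character(1), collapse = "")
    stats::setNames(out, tree$tip.label)
  })
}
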