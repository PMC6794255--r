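## Synthetic-data module: labelled mitogenomes, divergent references and
## RNA-Seq read sets with the statistical structure of real insect
## transcriptomes (polycistronic baseline coverage, strong per-gene
## expression differences, mature tRNA depletion by library size
## selection, nuclear transcripts with one NUMT carrier, contaminants).

# canonical insect-like gene order: 13 PCGs, 22 tRNAs, 2 rRNAs, control region
.GENE_ORDER <- data.frame(
  gene_id = c("trnI", "trnQ", "trnM", "nad2", "trnW", "trnC", "trnY", "cox1",
              "trnL2", "cox2", "trnK", "trnD", "atp8", "atp6", "cox3", "trnG",
              "nad3", "trnA", "trnR", "trnN", "trnS1", "trnE", "trnF", "nad5",
              "trnH", "nad4", "nad4l", "trnT", "trnP", "nad6", "cob", "trnS2",
              "nad1", "trnL1", "rrnL", "trnV", "rrnS", "CR"),
  type = c("tRNA", "tRNA", "tRNA", "PCG", "tRNA", "tRNA", "tRNA", "PCG",
           "tRNA", "PCG", "tRNA", "tRNA", "PCG", "PCG", "PCG", "tRNA",
           "PCG", "tRNA", "tRNA", "tRNA", "tRNA", "tRNA", "tRNA", "PCG",
           "tRNA", "PCG", "PCG", "tRNA", "tRNA", "PCG", "PCG", "tRNA",
           "PCG", "tRNA", "rRNA", "tRNA", "rRNA", "control_region"),
  strand = c("+", "-", "+", "+", "+", "-", "-", "+",
             "+", "+", "+", "+", "+", "+", "+", "+",
             "+", "+", "+", "+", "+", "+", "-", "-",
             "-", "-", "-", "+", "-", "+", "+", "+",
             "-", "-", "-", "-", "-", "+"),
  stringsAsFactors = FALSE)

.PCG_LEN <- c(nad2 = 1020, cox1 = 1536, cox2 = 684, atp8 = 159, atp6 = 675,
              cox3 = 786, nad3 = 354, nad5 = 1716, nad4 = 1341, nad4l = 291,
              nad6 = 522, cob = 1137, nad1 = 942)
.RRNA_LEN <- c(rrnL = 1280, rrnS = 780)

# stylized per-base expression levels (relative units); high cox/cob/rRNA,
# low atp8/nad4l, per published mito expression profiles in shape only.
# All PCG/rRNA levels sit far above the polycistronic floor, as in real
# libraries where the mature/precursor gap spans orders of magnitude.
.EXPR_DEFAULT <- c(nad2 = 18, cox1 = 60, cox2 = 40, atp8 = 15, atp6 = 25,
                   cox3 = 40, nad3 = 15, nad5 = 18, nad4 = 18, nad4l = 15,
                   nad6 = 15, cob = 40, nad1 = 18, rrnL = 80, rrnS = 80)

.MITO_START_CODONS <- c("ATG", "ATA", "ATT", "ATC", "GTG", "TTG")
.MITO_STOP_CODONS <- c("TAA", "TAG")

#' Simulation configuration
#'
#' Defaults describe a desk-scale analogue of a real single-end 51 nt
#' termite RNA-Seq library: a 16 kb circular mitogenome, ~12 percent of
#' reads of mitochondrial origin, a polycistronic per-base coverage floor
#' plus strongly heterogeneous mature-transcript expression, 95 percent of
#' mature tRNA reads lost to size selection, a near-silent control region,
#' 1 percent substitution error and a labelled nuclear/contaminant
#' background including one NUMT-bearing transcript.
#'
#' @param seed integer RNG seed; all draws derive named substreams from it.
#' @param genome_length mitogenome length in bp.
#' @param read_length read length in nt.
#' @param paired simulate paired-end fragments (FR, insert ~ N(250, 25)).
#' @param n_reads total number of reads (pairs count as two).
#' @param mito_fraction,nuclear_fraction,contaminant_fraction class mix;
#'   fractions must sum to at most 1, any remainder is nuclear.
#' @param per_gene_expression named per-base expression levels for mature
#'   transcripts; NULL for the stylized default profile.
#' @param polycistron_baseline per-base expression of the unprocessed
#'   full-molecule polycistron (same units).
#' @param trna_mature_depletion fraction of mature tRNA reads removed by
#'   size selection.
#' @param control_region_expression per-base expression of the control
#'   region (near zero by default).
#' @param error_rate per-base substitution probability.
#' @param reference_divergence divergence used when deriving a reference.
#' @param cr_repeat_unit,cr_repeat_copies control-region tandem repeat
#'   geometry.  The default 2 x 20 bp stays below the k-mer collapse
#'   limit of the assembler; larger arrays are collapsed and persist as
#'   gaps, as in real data.
#' @param fragment_mean,fragment_sd paired-end fragment length model.
#' @param n_nuclear_tx number of simulated nuclear transcripts.
#' @param contaminant_genome_length length of the contaminant genome.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome_length = 16000L, read_length = 51L,
                       paired = FALSE, n_reads = 64000L,
                       mito_fraction = 0.12, nuclear_fraction = NULL,
                       contaminant_fraction = 0.02,
                       per_gene_expression = NULL,
                       polycistron_baseline = 1.5,
                       trna_mature_depletion = 0.95,
                       control_region_expression = 0.05,
                       error_rate = 0.01, reference_divergence = 0.02,
                       cr_repeat_unit = 20L, cr_repeat_copies = 2L,
                       fragment_mean = 250, fragment_sd = 25,
                       n_nuclear_tx = 40L,
                       contaminant_genome_length = 50000L) {
  if (is.null(nuclear_fraction))
    nuclear_fraction <- 1 - mito_fraction - contaminant_fraction
  tot <- mito_fraction + nuclear_fraction + contaminant_fraction
  if (tot > 1 + 1e-9) stop("class fractions sum to more than 1")
  nuclear_fraction <- nuclear_fraction + (1 - tot)
  stopifnot(error_rate >= 0, error_rate < 0.1,
            trna_mature_depletion >= 0, trna_mature_depletion <= 1,
            polycistron_baseline >= 0, n_reads >= 0)
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              read_length = as.integer(read_length), paired = isTRUE(paired),
              n_reads = as.integer(n_reads), mito_fraction = mito_fraction,
              nuclear_fraction = nuclear_fraction,
              contaminant_fraction = contaminant_fraction,
              per_gene_expression = per_gene_expression,
              polycistron_baseline = polycistron_baseline,
              trna_mature_depletion = trna_mature_depletion,
              control_region_expression = control_region_expression,
              error_rate = error_rate,
              reference_divergence = reference_divergence,
              cr_repeat_unit = as.integer(cr_repeat_unit),
              cr_repeat_copies = as.integer(cr_repeat_copies),
              fragment_mean = fragment_mean, fragment_sd = fragment_sd,
              n_nuclear_tx = as.integer(n_nuclear_tx),
              contaminant_genome_length = as.integer(contaminant_genome_length))
  class(cfg) <- "sim_config"
  cfg
}

random_orf <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  codons <- setdiff(codons, .MITO_STOP_CODONS)
  ncod <- len / 3 - 2
  paste0("ATG", paste(sample(codons, ncod, replace = TRUE), collapse = ""), "TAA")
}

#' Simulate a circular mitogenome with annotation
#'
#' Builds a 16 kb-class circular genome in a fixed insect-like gene order:
#' 13 protein-coding genes as clean open reading frames in the
#' invertebrate mitochondrial code, 22 tRNA placeholders of 60-75 bp, two
#' rRNAs and one control region carrying a tandem repeat.  Deterministic
#' given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `record` (a one-row [seq_set()]) and
#'   `annotation` (a [annotation()]).
#' @export
make_mitogenome <- function(cfg = sim_config()) {
  set.seed(derive_seed(cfg$seed, "genome"))
  tab <- .GENE_ORDER
  lens <- integer(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    g <- tab$gene_id[i]
    lens[i] <- switch(tab$type[i],
                      PCG = .PCG_LEN[[g]],
                      rRNA = .RRNA_LEN[[g]],
                      tRNA = sample(60:75, 1),
                      control_region = 0L)
  }
  cr_len <- cfg$genome_length - sum(lens)
  rep_span <- cfg$cr_repeat_unit * cfg$cr_repeat_copies
  if (cr_len < rep_span + 40)
    stop("gene lengths exceed genome_length")
  lens[tab$type == "control_region"] <- cr_len
  blocks <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    g <- tab$gene_id[i]
    blk <- switch(tab$type[i],
                  PCG = random_orf(lens[i]),
                  rRNA = random_dna(lens[i]),
                  tRNA = random_dna(lens[i]),
                  control_region = {
                    unit <- random_dna(cfg$cr_repeat_unit)
                    pre <- random_dna(20)
                    rest <- random_dna(cr_len - rep_span - 20)
                    paste0(pre, strrep(unit, cfg$cr_repeat_copies), rest)
                  })
    if (tab$strand[i] == "-") blk <- revcomp(blk)
    blocks[i] <- blk
  }
  genome <- paste(blocks, collapse = "")
  ends <- cumsum(lens)
  starts <- ends - lens
  ann <- annotation(
    data.frame(gene_id = tab$gene_id, type = tab$type, start = starts,
               end = ends, strand = tab$strand, wrap = FALSE),
    seq_length = cfg$genome_length, circular = TRUE)
  list(record = seq_set("mito_truth", genome, "simulated circular mitogenome"),
       annotation = ann)
}

#' Derive a divergent reference by random substitution
#'
#' Substitutions are placed at uniformly chosen distinct sites (each
#' mutated to one of the three alternative bases), so realized divergence
#' equals the request up to rounding.  Emulates a congeneric (low
#' divergence) or intra-familial (higher divergence) reference.
#'
#' @param genome sequence string or one-row [seq_set()].
#' @param divergence requested proportion of substituted sites, in [0, 0.3].
#' @param seed RNG seed.
#' @return sequence string of the mutated reference.
#' @export
mutate_reference <- function(genome, divergence, seed = 1L) {
  if (is.data.frame(genome)) genome <- genome$seq[1]
  stopifnot(divergence >= 0, divergence <= 0.3)
  set.seed(derive_seed(seed, "mutate"))
  L <- nchar(genome)
  nsub <- round(divergence * L)
  if (nsub == 0) return(genome)
  sites <- sample.int(L, nsub)
  chars <- strsplit(genome, "")[[1]]
  alt <- c("A", "C", "G", "T")
  for (i in sites) chars[i] <- sample(setdiff(alt, chars[i]), 1)
  paste(chars, collapse = "")
}

#' Rearrange gene blocks of an annotated genome
#'
#' Permutes (and optionally strand-flips) the annotated blocks into a new
#' circular sequence.  The multiset of per-gene sequences is preserved.
#'
#' @param genome sequence string or one-row [seq_set()].
#' @param ann the genome's [annotation()]; features must tile the genome.
#' @param permutation_seed RNG seed for the permutation and flips.
#' @param permutation explicit block order (indices into the feature
#'   table), or NULL to sample one.
#' @param flip explicit logical vector of strand flips (aligned with the
#'   feature table), or NULL to sample; explicit permutations default to
#'   no flips.
#' @param flip_prob probability of strand-flipping each block when sampled.
#' @return list with `seq` (rearranged genome) and `annotation`.
#' @export
rearrange_reference <- function(genome, ann, permutation_seed = 1L,
                                permutation = NULL, flip = NULL,
                                flip_prob = 0.3) {
  if (is.data.frame(genome)) genome <- genome$seq[1]
  f <- ann$features
  lens <- feature_lengths(ann)
  if (sum(lens) != ann$seq_length)
    stop("annotation must tile the genome to rearrange it")
  set.seed(derive_seed(permutation_seed, "rearrange"))
  n <- nrow(f)
  explicit <- !is.null(permutation)
  if (!explicit) permutation <- sample.int(n)
  flips <- flip %||% (if (explicit) logical(n) else runif(n) < flip_prob)
  blocks <- character(n)
  for (i in seq_len(n))
    blocks[i] <- circ_substr(genome, f$start[i], lens[i])
  newblocks <- blocks[permutation]
  newstrand <- f$strand[permutation]
  flip <- flips[permutation]
  newblocks[flip] <- revcomp(newblocks[flip])
  newstrand[flip] <- ifelse(newstrand[flip] == "+", "-", "+")
  newlens <- lens[permutation]
  ends <- cumsum(newlens)
  starts <- ends - newlens
  newf <- data.frame(gene_id = f$gene_id[permutation], type = f$type[permutation],
                     start = starts, end = ends, strand = newstrand,
                     wrap = FALSE)
  list(seq = paste(newblocks, collapse = ""),
       annotation = annotation(newf, ann$seq_length, circular = TRUE))
}

# per-source sampling weights for mitochondrial reads: mature transcripts
# weighted by per-base expression x length (tRNAs depleted), plus the
# full-molecule polycistron
.mito_source_weights <- function(ann, cfg) {
  f <- ann$features
  lens <- feature_lengths(ann)
  e <- numeric(nrow(f))
  prof <- cfg$per_gene_expression %||% .EXPR_DEFAULT
  level <- function(g, d) if (g %in% names(prof)) prof[[g]] else d
  for (i in seq_len(nrow(f))) {
    g <- f$gene_id[i]
    e[i] <- switch(f$type[i],
                   PCG = , rRNA = level(g, 10),
                   tRNA = level(g, 8) * (1 - cfg$trna_mature_depletion),
                   control_region = cfg$control_region_expression)
  }
  w <- e * lens
  # mature transcripts shorter than a read cannot be sampled
  w[lens < cfg$read_length] <- 0
  c(setNames(w, f$gene_id), polycistron = cfg$polycistron_baseline * ann$seq_length)
}

.inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    ch <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(ch), n_err[i])
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate a labelled RNA-Seq read set
#'
#' Mitochondrial reads are drawn either from the unprocessed polycistron
#' (uniform around the circle) or from mature per-gene transcripts
#' weighted by expression, with mature tRNA draws thinned by size
#' selection; nuclear reads come from simulated transcripts, one of which
#' carries a 200-500 bp NUMT insert at 2-10 percent divergence;
#' contaminant reads come from an unrelated random genome.  Every read is
#' labelled with its origin.  Deterministic given `cfg$seed`.
#'
#' @param truth output of [make_mitogenome()].
#' @param cfg a [sim_config()].
#' @return list with `reads` (a [read_set()] with truth columns),
#'   `nuclear_db` and `contaminant_db` ([seq_set()]s usable as leakage
#'   databases) and `numt` (insert bookkeeping).
#' @export
simulate_reads <- function(truth, cfg = sim_config()) {
  if (cfg$n_reads <= 0) stop("n_reads must be positive")
  genome <- truth$record$seq[1]
  ann <- truth$annotation
  G <- nchar(genome)
  rl <- cfg$read_length

  # --- background references (own substreams) ---
  set.seed(derive_seed(cfg$seed, "nuclear"))
  ntx <- max(1L, cfg$n_nuclear_tx)
  tx_len <- sample(500:3000, ntx, replace = TRUE)
  tx_seq <- vapply(tx_len, random_dna, character(1))
  numt_len <- sample(200:500, 1)
  # the insert is drawn from within a protein-coding gene: NUMT-carrying
  # reads then inflate the (already high-coverage) PCG they mimic rather
  # than masquerading as tRNA expression, keeping per-gene coverage
  # readouts identifiable
  fpcg <- ann$features[ann$features$type == "PCG", ]
  fpcg <- fpcg[(fpcg$end - fpcg$start) >= numt_len + 2L, ]
  host <- fpcg[sample.int(nrow(fpcg), 1, prob = fpcg$end - fpcg$start), ]
  numt_start <- host$start + sample.int(host$end - host$start - numt_len, 1)
  numt_div <- runif(1, 0.02, 0.10)
  numt_seq <- mutate_reference(circ_substr(genome, numt_start, numt_len),
                               numt_div, seed = derive_seed(cfg$seed, "numt"))
  ins_at <- sample.int(max(1L, tx_len[1] - 1L), 1)
  tx_seq[1] <- paste0(substr(tx_seq[1], 1, ins_at), numt_seq,
                      substr(tx_seq[1], ins_at + 1, tx_len[1]))
  tx_len[1] <- nchar(tx_seq[1])
  tx_w <- rexp(ntx) * tx_len
  # the NUMT carrier is a lowly-expressed transcript: with a handful of
  # simulated transcripts standing in for a whole transcriptome, a
  # random (often high) weight would give the NUMT near-mitochondrial
  # coverage and shred the assembly graph - a regime the underlying
  # observations (complete assemblies despite nuclear leakage) exclude
  tx_w[1] <- 0.05 * mean(tx_w[-1]) * tx_len[1] / mean(tx_len[-1])
  tx_w[tx_len < rl] <- 0
  nuclear_db <- seq_set(sprintf("nuc_tx%03d", seq_len(ntx)), tx_seq)

  set.seed(derive_seed(cfg$seed, "contaminant"))
  cont_seq <- random_dna(cfg$contaminant_genome_length)
  contaminant_db <- seq_set("contaminant_genome", cont_seq)

  # --- class counts (exact partition) ---
  n <- cfg$n_reads
  n_mito <- round(n * cfg$mito_fraction)
  n_cont <- round(n * cfg$contaminant_fraction)
  n_nuc <- n - n_mito - n_cont

  set.seed(derive_seed(cfg$seed, "reads"))
  w <- .mito_source_weights(ann, cfg)
  if (sum(w) <= 0) stop("all mitochondrial source weights are zero")
  src_names <- names(w)
  pick <- if (n_mito > 0)
    sample(seq_along(w), n_mito, replace = TRUE, prob = w) else integer(0)

  f <- ann$features
  lens <- feature_lengths(ann)
  mito_start <- integer(n_mito)
  mito_strand <- character(n_mito)
  mito_src <- src_names[pick]
  poly <- pick == length(w)
  npoly <- sum(poly)
  if (npoly > 0) {
    mito_start[poly] <- sample.int(G, npoly, replace = TRUE) - 1L
    mito_strand[poly] <- sample(c("+", "-"), npoly, replace = TRUE)
  }
  for (i in which(!poly)) {
    fi <- pick[i]
    tlen <- lens[fi]
    s <- sample.int(tlen - rl + 1L, 1) - 1L  # position on the mature transcript
    if (f$strand[fi] == "+") {
      mito_start[i] <- (f$start[fi] + s) %% G
    } else {
      end_g <- if (f$wrap[fi]) f$end[fi] + G else f$end[fi]
      mito_start[i] <- (end_g - s - rl) %% G
    }
    mito_strand[i] <- sample(c("+", "-"), 1)  # unstranded library
  }
  mito_seq <- circ_substr_vec(genome, mito_start, rl)
  flip <- mito_strand == "-"
  mito_seq[flip] <- revcomp(mito_seq[flip])

  nuc_pick <- if (n_nuc > 0)
    sample(seq_len(ntx), n_nuc, replace = TRUE, prob = tx_w) else integer(0)
  nuc_start <- vapply(nuc_pick, function(t)
    sample.int(tx_len[t] - rl + 1L, 1) - 1L, integer(1))
  nuc_strand <- sample(c("+", "-"), n_nuc, replace = TRUE)
  nuc_seq <- if (n_nuc > 0)
    substring(tx_seq[nuc_pick], nuc_start + 1L, nuc_start + rl) else character(0)
  nuc_seq[nuc_strand == "-"] <- revcomp(nuc_seq[nuc_strand == "-"])

  cont_start <- if (n_cont > 0)
    sample.int(cfg$contaminant_genome_length - rl + 1L, n_cont,
               replace = TRUE) - 1L else integer(0)
  cont_strand <- sample(c("+", "-"), n_cont, replace = TRUE)
  cont_seq_reads <- if (n_cont > 0)
    substring(cont_seq, cont_start + 1L, cont_start + rl) else character(0)
  cont_seq_reads[cont_strand == "-"] <- revcomp(cont_seq_reads[cont_strand == "-"])

  seqs <- c(mito_seq, nuc_seq, cont_seq_reads)
  seqs <- .inject_errors(seqs, cfg$error_rate)
  quals <- strrep(intToUtf8(33 + sample(33:40, n, replace = TRUE),
                            multiple = TRUE), rl)
  labels <- c(rep("mito", n_mito), rep("nuclear", n_nuc),
              rep("contaminant", n_cont))
  srcs <- c(mito_src,
            if (n_nuc > 0) sprintf("nuc_tx%03d", nuc_pick) else character(0),
            rep("contaminant_genome", n_cont))
  starts <- c(mito_start, nuc_start, cont_start)
  strands <- c(mito_strand, nuc_strand, cont_strand)

  reads <- read_set(id = sprintf("sim%06d", seq_len(n)), seq = seqs,
                    qual = quals, mate = 0L, label = labels, src = srcs,
                    src_start = as.integer(starts),
                    src_end = as.integer(starts + rl),
                    src_strand = strands)
  if (cfg$paired) reads <- .pair_reads(reads, genome, cfg)
  list(reads = reads, nuclear_db = nuclear_db,
       contaminant_db = contaminant_db,
       numt = list(transcript = "nuc_tx001", start = ins_at,
                   length = numt_len, divergence = numt_div,
                   mito_start = numt_start))
}

# Turn every consecutive pair of single-end draws into an FR pair by
# re-reading a fragment around the first mate's origin.  Mates keep the
# same truth label; fragments too long for their source fall back to the
# polycistron.  Used only when cfg$paired is TRUE.
.pair_reads <- function(reads, genome, cfg) {
  n <- nrow(reads) - nrow(reads) %% 2L
  reads <- reads[seq_len(n)]
  rl <- cfg$read_length
  G <- nchar(genome)
  half <- n %/% 2L
  frag <- pmax(rl + 10L, round(rnorm(half, cfg$fragment_mean, cfg$fragment_sd)))
  first <- reads[seq_len(half)]
  r2seq <- character(half)
  for (i in seq_len(half)) {
    if (first$label[i] == "mito") {
      fseq <- circ_substr(genome, first$src_start[i], frag[i])
      if (first$src_strand[i] == "-") fseq <- revcomp(fseq)
    } else {
      # non-mito mates re-read the same source window; approximate by
      # reusing the mate-1 sequence context
      fseq <- paste0(first$seq[i], random_dna(frag[i] - rl))
    }
    r2seq[i] <- revcomp(substr(fseq, frag[i] - rl + 1L, frag[i]))
  }
  r2 <- first
  r2 <- data.table::copy(first)
  r2[, `:=`(seq = r2seq, mate = 2L)]
  first <- data.table::copy(first)
  first[, mate := 1L]
  out <- rbind(first, r2)
  out[, id := rep(sprintf("pair%06d", seq_len(half)), 2L)]
  data.table::setattr(out, "class", class(reads))
  out
}
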