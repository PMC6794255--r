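test_that("make_mitogenome is reproducible and structurally correct", {
  cfg <- sim_config(seed = 1)
  g1 <- make_mitogenome(cfg)
  g2 <- make_mitogenome(cfg)
  expect_identical(g1$record$seq, g2$record$seq)
  expect_equal(nchar(g1$record$seq), cfg$genome_length)

  f <- g1$annotation$features
  expect_equal(sum(f$type == "PCG"), 13L)
  expect_equal(sum(f$type == "tRNA"), 22L)
  expect_equal(sum(f$type == "rRNA"), 2L)
  expect_equal(sum(f$type == "control_region"), 1L)

  # features tile the genome without overlap
  expect_equal(f$start[-1], f$end[-nrow(f)])
  expect_equal(f$start[1], 0)
  expect_equal(f$end[nrow(f)], cfg$genome_length)

  # every PCG translates without internal stops and with a start codon
  orfs <- check_orfs(g1$record$seq, g1$annotation)
  expect_true(attr(orfs, "ok"))
  expect_true(all(orfs$has_start))
  expect_true(all(orfs$terminal_stop))

  # oversized gene set is rejected
  expect_error(make_mitogenome(sim_config(genome_length = 12000)),
               "exceed")
})

test_that("mutate_reference realizes the requested divergence", {
  cfg <- sim_config(seed = 1)
  g <- make_mitogenome(cfg)$record$seq
  expect_identical(mutate_reference(g, 0, seed = 3), g)
  expect_identical(mutate_reference(g, 0.05, seed = 3),
                   mutate_reference(g, 0.05, seed = 3))
  for (seed in 1:5) {
    m <- mutate_reference(g, 0.02, seed = seed)
    d <- sum(utf8ToInt(g) != utf8ToInt(m)) / nchar(g)
    expect_gte(d, 0.018)
    expect_lte(d, 0.022)
  }
})

test_that("rearrange_reference permutes blocks content-preservingly", {
  cfg <- sim_config(seed = 2)
  tr <- make_mitogenome(cfg)
  n <- nrow(tr$annotation$features)

  ident <- rearrange_reference(tr$record, tr$annotation,
                               permutation = seq_len(n))
  expect_identical(ident$seq, tr$record$seq)

  re <- rearrange_reference(tr$record, tr$annotation, permutation_seed = 9)
  expect_equal(nchar(re$seq), nchar(tr$record$seq))
  s1 <- sort(feature_seqs(tr$record$seq, tr$annotation))
  s2 <- sort(feature_seqs(re$seq, re$annotation))
  expect_identical(s2, s1)  # same multiset of oriented gene sequences
  expect_false(identical(re$annotation$features$gene_id,
                         tr$annotation$features$gene_id))

  # explicit reversal of one block reverse-complements it in place
  flip <- rep(FALSE, n); flip[4] <- TRUE
  rev1 <- rearrange_reference(tr$record, tr$annotation,
                              permutation = seq_len(n), flip = flip)
  f <- tr$annotation$features
  blk <- substr(tr$record$seq, f$start[4] + 1, f$end[4])
  blk_new <- substr(rev1$seq, f$start[4] + 1, f$end[4])
  expect_identical(blk_new, revcomp(blk))
  expect_equal(rev1$annotation$features$strand[4],
               ifelse(f$strand[4] == "+", "-", "+"))
})

test_that("simulate_reads labels every read and conserves class counts", {
  w <- fx_default_world()
  reads <- w$sim$reads
  expect_equal(nrow(reads), w$cfg$n_reads)
  tab <- table(reads$label)
  expect_equal(sum(tab), w$cfg$n_reads)
  expect_equal(unname(tab["mito"]), round(w$cfg$n_reads * w$cfg$mito_fraction))
  expect_equal(unname(tab["contaminant"]),
               round(w$cfg$n_reads * w$cfg$contaminant_fraction))
  expect_true(all(nchar(reads$seq) == w$cfg$read_length))
  expect_true(all(nchar(reads$qual) == w$cfg$read_length))

  # mito-only configuration gives only mito labels
  p <- fx_perfect_world()
  expect_true(all(p$sim$reads$label == "mito"))

  expect_error(simulate_reads(w$truth, sim_config(n_reads = 0)), "positive")
})

test_that("mito read truth intervals match the genome", {
  w <- fx_perfect_world()
  reads <- w$sim$reads
  g <- w$truth$record$seq
  idx <- sample(nrow(reads), 200)
  for (i in idx) {
    src <- mitobait:::circ_substr(g, reads$src_start[i],
                                  reads$src_end[i] - reads$src_start[i])
    if (reads$src_strand[i] == "-") src <- revcomp(src)
    expect_identical(reads$seq[i], src)  # error-free world
  }
})

test_that("expression weighting puts mature-PCG coverage above depleted tRNAs", {
  # expectation n*L_read*w/L_gene vs empirical mean, loose 3-sigma band
  w <- fx_default_world()
  reads <- w$sim$reads[w$sim$reads$label == "mito"]
  f <- w$truth$annotation$features
  counts <- table(factor(reads$src, levels = c(f$gene_id, "polycistron")))
  lens <- feature_lengths(w$truth$annotation)
  names(lens) <- f$gene_id
  pcg_cov <- counts[f$gene_id[f$type == "PCG"]] * w$cfg$read_length /
    lens[f$gene_id[f$type == "PCG"]]
  trna_cov <- counts[f$gene_id[f$type == "tRNA"]] * w$cfg$read_length /
    lens[f$gene_id[f$type == "tRNA"]]
  expect_gt(min(pcg_cov), max(trna_cov))
})

test_that("simulation output is byte-identical for a fixed seed", {
  cfg <- sim_config(seed = 6, n_reads = 2000)
  tr <- make_mitogenome(cfg)
  f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
  write_fastq(simulate_reads(tr, cfg)$reads, f1)
  write_fastq(simulate_reads(tr, cfg)$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("paired-end mode emits synchronized FR mates", {
  cfg <- sim_config(seed = 8, n_reads = 400, paired = TRUE, read_length = 100,
                    mito_fraction = 1, nuclear_fraction = 0,
                    contaminant_fraction = 0, error_rate = 0)
  tr <- make_mitogenome(cfg)
  reads <- simulate_reads(tr, cfg)$reads
  expect_equal(sort(unique(reads$mate)), c(1L, 2L))
  expect_equal(sum(reads$mate == 1), sum(reads$mate == 2))
  expect_true(all(nchar(reads$seq) == 100))
  # a mate-2 read maps to the genome on the opposite strand of its mate-1
  g <- tr$record$seq
  ext <- paste0(g, substr(g, 1, 500))
  r2 <- reads[reads$mate == 2][1:20]
  hitcount <- vapply(seq_len(nrow(r2)), function(i)
    grepl(r2$seq[i], ext, fixed = TRUE) ||
      grepl(revcomp(r2$seq[i]), ext, fixed = TRUE), logical(1))
  expect_true(all(hitcount))
})
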