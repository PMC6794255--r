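test_that("error-free tiled reads reassemble the source exactly", {
  src <- random_reads(1, 2000, seed = 21)
  reads <- tile_reads(src, depth = 30, seed = 22)
  ct <- assemble(reads)
  expect_equal(nrow(ct), 1L)
  expect_true(ct$seq == src || ct$seq == revcomp(src))
  expect_false(ct$circular)

  # two sources sharing no k-mer give exactly two contigs
  src2 <- random_reads(1, 1500, seed = 23)
  ct2 <- assemble(c(tile_reads(src, depth = 25, seed = 24),
                    tile_reads(src2, depth = 25, seed = 25)))
  expect_equal(nrow(ct2), 2L)
  got <- sort(ct2$seq)
  want <- sort(c(min(src, revcomp(src)), min(src2, revcomp(src2))))
  expect_identical(got, want)
})

test_that("1x coverage is erased by the k-mer count floor", {
  src <- random_reads(1, 1000, seed = 26)
  starts <- seq(1, 950, by = 51)
  reads <- substring(src, starts, starts + 50)
  ct <- assemble(reads, assembly_params(min_kmer_count = 2))
  expect_equal(nrow(ct), 0L)
})

test_that("reads shorter than dbg_k warn and yield an empty assembly", {
  expect_warning(ct <- assemble(random_reads(10, 20, seed = 27)), "shorter")
  expect_equal(nrow(ct), 0L)
})

test_that("assembly is deterministic byte-for-byte", {
  w <- fx_perfect_world()
  reads <- w$sim$reads[1:4000]
  c1 <- assemble(reads)
  c2 <- assemble(reads)
  expect_identical(c1$seq, c2$seq)
  expect_identical(c1$mean_kmer_coverage, c2$mean_kmer_coverage)
})

test_that("no chimeras: contigs from a mixed library match one source each", {
  cfg <- sim_config(seed = 9, n_reads = 12000, mito_fraction = 0.5,
                    contaminant_fraction = 0.3, polycistron_baseline = 50)
  tr <- make_mitogenome(cfg)
  sim <- simulate_reads(tr, cfg)
  ct <- assemble(sim$reads)
  expect_gt(nrow(ct), 0)
  sources <- list(mito = tr$record$seq,
                  contaminant = sim$contaminant_db$seq,
                  nuclear = sim$nuclear_db$seq)
  for (i in seq_len(nrow(ct))) {
    best <- vapply(sources, function(ss) {
      idx <- build_index(seq_set(paste0("s", seq_along(ss)), ss), 11)
      h <- align_local(ct$seq[i], idx, align_params(k = 11))
      if (nrow(h) == 0) 0 else
        max((h$qend - h$qstart) * h$identity) / ct$length[i]
    }, numeric(1))
    # end-to-end match to exactly one source class at >= 1 - 2*error_rate
    expect_gte(max(best), 1 - 2 * cfg$error_rate - 0.02)
  }
})

test_that("bubbles collapse to the higher-coverage branch", {
  src <- random_reads(1, 1200, seed = 31)
  # variant allele at one site, at 1/5 the coverage of the major allele
  var <- src
  substr(var, 600, 600) <- if (substr(src, 600, 600) == "A") "C" else "A"
  reads <- c(tile_reads(src, depth = 40, seed = 32),
             tile_reads(var, depth = 8, seed = 33))
  ct <- assemble(reads)
  expect_equal(nrow(ct), 1L)
  expect_true(ct$seq == src || ct$seq == revcomp(src))
})

test_that("supporting read sets track contig membership", {
  srcA <- random_reads(1, 1200, seed = 34)
  srcB <- random_reads(1, 1200, seed = 35)
  rsA <- tile_reads(srcA, depth = 20, seed = 36)
  rsB <- tile_reads(srcB, depth = 20, seed = 37)
  rs <- read_set(c(sprintf("A%03d", seq_along(rsA)),
                   sprintf("B%03d", seq_along(rsB))),
                 c(rsA, rsB),
                 strrep("I", 51))
  ct <- assemble(rs)
  expect_equal(nrow(ct), 2L)
  for (i in 1:2) {
    ids <- ct$supporting[[i]]
    cls <- substr(ids, 1, 1)
    expect_equal(length(unique(cls)), 1L)  # no cross-source support
  }
})

test_that("contig_stats computes standard summaries", {
  expect_equal(contig_stats(data.frame(length = integer(0))),
               list(n = 0L, mean_len = 0, total_len = 0L, N50 = 0L))
  st <- contig_stats(data.frame(length = c(150L, 300L)))
  expect_equal(st$mean_len, 225)
  expect_equal(st$N50, 300L)
  expect_equal(contig_stats(data.frame(length = 777L))$N50, 777L)
})
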