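test_that("depth increments follow best alignments and conserve bases", {
  ref <- random_reads(1, 2000, seed = 101)
  one <- read_set("r1", substr(ref, 11, 61), strrep("I", 51))
  prof <- coverage_profile(one, list(sequence = ref, circular = FALSE))
  expect_equal(sum(prof$depth), 51L)
  expect_equal(which(prof$depth == 1L), 11:61)

  reads <- read_set(sprintf("r%03d", 1:100),
                    tile_reads(ref, depth = 2.5, seed = 102)[1:100],
                    strrep("I", 51))
  prof2 <- coverage_profile(reads, list(sequence = ref, circular = FALSE))
  expect_equal(sum(prof2$depth), 100L * 51L)  # exact conservation
})

test_that("circular wrap folds depth across the origin", {
  w <- fx_perfect_world()
  g <- w$truth$record$seq
  # a read spanning the linearization origin
  jread <- read_set("j", mitobait:::circ_substr(g, 15980, 51), strrep("I", 51))
  prof <- coverage_profile(jread, list(sequence = g, circular = TRUE))
  expect_equal(sum(prof$depth), 51L)
  expect_true(all(prof$depth[c(1:31, 15981:16000)] == 1L))
})

test_that("per_gene_coverage aggregates features, wrap included", {
  depth <- rep(10L, 1000)
  prof <- structure(list(depth = depth, length = 1000L, circular = TRUE,
                         cap_for_plots = 5000L), class = "coverage_profile")
  ann <- annotation(data.frame(gene_id = c("g1", "g2", "w"),
                               type = c("PCG", "tRNA", "control_region"),
                               start = c(0, 500, 950), end = c(300, 560, 30),
                               strand = "+", wrap = c(FALSE, FALSE, TRUE)),
                    1000, circular = TRUE)
  pg <- per_gene_coverage(prof, ann)
  expect_true(all(pg$mean_depth == 10))
  expect_true(all(pg$fraction_below == 0))
  expect_equal(pg$length[pg$gene_id == "w"], 80L)

  # half at 2, half at 6 -> mean 4, fraction_below(4) = 0.5
  prof$depth[1:150] <- 2L
  prof$depth[151:300] <- 6L
  pg2 <- per_gene_coverage(prof, ann)
  expect_equal(pg2$mean_depth[pg2$gene_id == "g1"], 4)
  expect_equal(pg2$fraction_below[pg2$gene_id == "g1"], 0.5)

  # all-low tRNA
  prof$depth[501:560] <- 3L
  pg3 <- per_gene_coverage(prof, ann)
  expect_equal(pg3$fraction_below[pg3$gene_id == "g2"], 1)

  bad <- annotation(data.frame(gene_id = "x", type = "PCG", start = 0,
                               end = 10, strand = "+"), 2000)
  expect_error(per_gene_coverage(prof, bad), "length")
})

test_that("low_coverage_regions reports filtered maximal runs", {
  prof <- structure(list(depth = rep(10L, 500), length = 500L,
                         circular = FALSE, cap_for_plots = 5000L),
                    class = "coverage_profile")
  expect_equal(nrow(low_coverage_regions(prof)), 0L)

  prof$depth[101:130] <- 3L
  iv <- low_coverage_regions(prof, threshold = 4, min_run = 10)
  expect_equal(iv$start, 100L)
  expect_equal(iv$end, 130L)

  # two sub-min_run dips are filtered out
  prof$depth[101:130] <- 10L
  prof$depth[201:205] <- 0L
  prof$depth[301:308] <- 0L
  expect_equal(nrow(low_coverage_regions(prof, min_run = 10)), 0L)

  # intervals are disjoint, sorted, each >= min_run
  set.seed(103)
  prof$depth <- sample(0:8, 500, replace = TRUE)
  iv2 <- low_coverage_regions(prof, threshold = 4, min_run = 5)
  if (nrow(iv2) > 1) {
    expect_true(all(diff(iv2$start) > 0))
    expect_true(all(iv2$start[-1] >= iv2$end[-nrow(iv2)]))
  }
  expect_true(all(iv2$end - iv2$start >= 5))
})

test_that("BED round-trip preserves intervals and BEDGraph caps for display", {
  iv <- data.frame(start = c(10L, 200L), end = c(50L, 260L))
  bed <- tempfile(fileext = ".bed")
  write_bed(iv, bed)
  expect_equal(read_bed(bed), iv)

  prof <- structure(list(depth = c(rep(6000L, 5), rep(2L, 5)), length = 10L,
                         circular = FALSE, cap_for_plots = 5000L),
                    class = "coverage_profile")
  bg <- tempfile(fileext = ".bedgraph")
  write_bedgraph(prof, bg)
  vals <- as.integer(vapply(strsplit(readLines(bg), "\t"), `[`, "", 4))
  expect_equal(max(vals), 5000L)   # display capped
  expect_equal(max(prof$depth), 6000L)  # stored depths untouched
})
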