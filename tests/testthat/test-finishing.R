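test_that("exact guide fragments scaffold back to the guide", {
  w <- fx_default_world()
  g <- w$truth$record$seq
  # exact fragments with 150 bp overlaps covering the whole guide
  frs <- c(substr(g, 1, 4100), substr(g, 3951, 8100),
           substr(g, 7951, 12100), substr(g, 11951, 16000))
  contigs <- mitobait:::contig_set(sprintf("c%d", 1:4), frs,
                                   mean_kmer_coverage = 10)
  sc <- scaffold_contigs(contigs, seq_set("guide", g))
  expect_equal(nrow(sc$gaps), 0L)
  expect_identical(sc$merged_sequence, g)

  # a reverse-complemented contig places on the minus strand, same merge
  contigs_rc <- data.table::copy(contigs)
  contigs_rc[2, seq := revcomp(seq)]
  sc2 <- scaffold_contigs(contigs_rc, seq_set("guide", g))
  expect_equal(sc2$placed$strand[sc2$placed$contig_id == "c2"], "-")
  expect_identical(sc2$merged_sequence, sc$merged_sequence)
})

test_that("uncovered guide intervals are reported as gaps exactly", {
  w <- fx_default_world()
  g <- w$truth$record$seq
  c1 <- substr(g, 1, 5000)          # [0, 5000)
  c2 <- substr(g, 5071, 16000)      # [5070, 16000)
  contigs <- mitobait:::contig_set(c("a", "b"), c(c1, c2),
                                   mean_kmer_coverage = 10)
  sc <- scaffold_contigs(contigs, seq_set("guide", g))
  expect_equal(sc$gaps, data.frame(start = 5000L, end = 5070L),
               ignore_attr = TRUE)
  # gap accounting: placed coverage + gaps = guide length
  placed_cov <- 16000L - sum(sc$gaps$end - sc$gaps$start)
  expect_equal(placed_cov + sum(sc$gaps$end - sc$gaps$start), 16000L)
  expect_match(sc$merged_sequence, "N{70}")
})

test_that("contigs failing identity/coverage validation go to leftover", {
  w <- fx_default_world()
  g <- w$truth$record$seq
  good <- substr(g, 1001, 3000)
  junk <- random_reads(1, 2000, seed = 51)
  contigs <- mitobait:::contig_set(c("good", "junk"), c(good, junk),
                                   mean_kmer_coverage = 10)
  sc <- scaffold_contigs(contigs, seq_set("guide", g))
  expect_identical(sc$leftover, "junk")
  expect_identical(sc$placed$contig_id, "good")
  expect_error(
    scaffold_contigs(mitobait:::contig_set("j", junk, mean_kmer_coverage = 1),
                     seq_set("guide", g)),
    "no mitochondrial contigs")
})

test_that("fill_gaps closes a covered gap and leaves silent gaps open", {
  cfg <- sim_config(seed = 7)
  truth <- make_mitogenome(cfg)
  g <- truth$record$seq
  f <- truth$annotation$features
  trna <- f[f$type == "tRNA", ][5, ]
  c1 <- substr(g, 1001, trna$start)
  c2 <- substr(g, trna$end + 1, 15000)
  contigs <- mitobait:::contig_set(c("c1", "c2"), c(c1, c2),
                                   mean_kmer_coverage = 10)
  guide <- seq_set("guide", g)
  sc <- scaffold_contigs(contigs, guide)

  # polycistronic reads at ~3x close the gap with the truth sequence
  cfgp <- sim_config(seed = 7, mito_fraction = 1, nuclear_fraction = 0,
                     contaminant_fraction = 0, n_reads = round(6 * 16000 / 51),
                     polycistron_baseline = 1000, error_rate = 0)
  sim <- simulate_reads(truth, cfgp)
  sc2 <- fill_gaps(sc, sim$reads, guide)
  expect_false(any((sc2$gaps$start < trna$end) & (sc2$gaps$end > trna$start)))
  patch <- substr(sc2$merged_sequence, trna$start - 1000 + 1, trna$end - 1000)
  expect_identical(patch, substr(g, trna$start + 1, trna$end))

  # with no reads over the gap, the Ns persist
  sc3 <- fill_gaps(sc, sim$reads[0], guide)
  expect_match(sc3$merged_sequence, "N")

  # an already complete scaffold passes through unchanged
  whole <- mitobait:::contig_set("w", g, mean_kmer_coverage = 10)
  scw <- scaffold_contigs(whole, guide)
  expect_identical(fill_gaps(scw, sim$reads, guide)$merged_sequence,
                   scw$merged_sequence)
})

test_that("circularize trims terminal redundancy and rotates to the anchor", {
  w <- fx_default_world()
  g <- w$truth$record$seq
  # molecule = rotation of G plus 80 bp terminal duplication
  rot <- paste0(substr(g, 4001, 16000), substr(g, 1, 4000))
  s <- paste0(rot, substr(rot, 1, 80))
  sc <- list(merged_sequence = s, guide_length = 16000, merged_offset = 0)
  class(sc) <- "scaffold"
  mito <- circularize(sc, guide = g, guide_ann = w$truth$annotation)
  expect_true(mito$circular)
  expect_equal(nchar(mito$sequence), nchar(g))
  # rotation anchor = first annotated gene => sequence equals the truth
  expect_equal(mito$rotation_anchor, w$truth$annotation$features$gene_id[1])
  expect_identical(mito$sequence, g)

  # no terminal overlap -> linear with warning
  sc2 <- list(merged_sequence = substr(g, 1, 12000), guide_length = 16000,
              merged_offset = 0)
  class(sc2) <- "scaffold"
  expect_warning(lin <- circularize(sc2), "linear")
  expect_false(lin$circular)
})

test_that("annotation transfer projects features through the alignment", {
  w <- fx_default_world()
  g <- w$truth$record$seq
  ann <- w$truth$annotation

  # identity projection
  mito <- list(sequence = g, circular = TRUE)
  t1 <- transfer_annotation(mito, ann, g)
  expect_true(all(t1$features$found))
  expect_equal(t1$features$start, ann$features$start)
  expect_equal(t1$features$end, ann$features$end)
  expect_equal(t1$features$strand, ann$features$strand)

  # ten random substitutions inside one PCG leave coordinates unchanged
  f <- ann$features
  pcg <- f[f$gene_id == "cox1", ]
  set.seed(61)
  chars <- strsplit(g, "")[[1]]
  for (pos in sample(pcg$start:(pcg$end - 1), 10) + 1)
    chars[pos] <- setdiff(c("A", "C", "G", "T"), chars[pos])[1]
  g10 <- paste(chars, collapse = "")
  t2 <- transfer_annotation(list(sequence = g10, circular = TRUE), ann, g)
  expect_equal(t2$features$start, ann$features$start)
  expect_equal(t2$features$end, ann$features$end)

  # rearranged target: features found in the target's order
  re <- rearrange_reference(w$truth$record, ann, permutation_seed = 71)
  t3 <- transfer_annotation(list(sequence = re$seq, circular = TRUE), ann, g)
  expect_true(all(t3$features$found))
  got <- t3$features[order(t3$features$start), ]
  expect_equal(got$start, re$annotation$features$start)
  expect_equal(got$gene_id, re$annotation$features$gene_id)
})

test_that("check_orfs flags injected internal stops", {
  w <- fx_default_world()
  g <- w$truth$record$seq
  ann <- w$truth$annotation
  clean <- check_orfs(g, ann)
  expect_true(attr(clean, "ok"))
  expect_equal(nrow(clean), 13L)

  # inject a TAA mid-cox1 (plus strand) in frame
  f <- ann$features[ann$features$gene_id == "cox1", ]
  pos <- f$start + 301  # codon-aligned offset (0-based 300)
  broken <- paste0(substr(g, 1, pos - 1), "TAA", substr(g, pos + 3, nchar(g)))
  rep <- check_orfs(broken, ann)
  expect_false(attr(rep, "ok"))
  expect_gte(rep$internal_stop_count[rep$gene_id == "cox1"], 1L)

  empty <- annotation(data.frame(gene_id = character(0), type = character(0),
                                 start = integer(0), end = integer(0),
                                 strand = character(0)), nchar(g))
  expect_equal(nrow(check_orfs(g, empty)), 0L)
})

test_that("select_guide picks the closest candidate", {
  w <- fx_default_world()
  g <- w$truth$record
  near <- mutate_reference(g, 0.02, seed = 81)
  far <- mutate_reference(g, 0.25, seed = 82)
  contigs <- mitobait:::contig_set("c", substr(g$seq, 2001, 10000),
                                   mean_kmer_coverage = 10)
  pick <- select_guide(contigs, seq_set(c("far", "near"), c(far, near)))
  expect_equal(pick, "near")
})
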