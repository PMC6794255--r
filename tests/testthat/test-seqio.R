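test_that("read_fastq parses records, handles gzip, and names bad records", {
  fq <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
  rs <- read_fastq(fq)
  expect_equal(rs$id, "r1")
  expect_equal(nchar(rs$seq), 4L)
  expect_equal(utf8ToInt(rs$qual) - 33L, rep(40L, 4))

  # empty file -> empty stream
  empty <- tempfile(fileext = ".fq")
  file.create(empty)
  expect_equal(nrow(read_fastq(empty)), 0L)

  # truncated record -> error naming the record
  bad <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+"), bad)
  expect_error(read_fastq(bad), "record 1")

  # gzip round trip
  rs2 <- read_set(c("a", "b"), c("ACGTN", "GGGTT"), c("IIIII", "BBBBB"))
  gz <- tempfile(fileext = ".fq.gz")
  write_fastq(rs2, gz)
  back <- read_fastq(gz)
  expect_equal(back$seq, rs2$seq)
  expect_equal(back$qual, rs2$qual)
})

test_that("paired FASTQ files must be synchronized", {
  f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
  writeLines(c("@p1/1", "ACGT", "+", "IIII"), f1)
  writeLines(c("@p1/2", "TTTT", "+", "IIII"), f2)
  rs <- read_fastq(f1, f2)
  expect_equal(rs$mate, c(1L, 2L))
  writeLines(c("@p9/2", "TTTT", "+", "IIII"), f2)
  expect_error(read_fastq(f1, f2), "desynchronized")
})

test_that("quality_trim follows leading/trailing/sliding-window semantics", {
  p <- trim_params()  # LEADING 3, TRAILING 3, window 25:33, min_len auto

  # 51 nt all Q40: untouched (min_len auto = 45)
  r <- read_set("a", strrep("A", 51), phred_str(40, 51))
  expect_equal(quality_trim(r, p)$seq, strrep("A", 51))

  # 51 nt all Q30: first window mean 30 < 33 -> cut at 0 -> DISCARD
  r <- read_set("b", strrep("A", 51), phred_str(30, 51))
  out <- quality_trim(r, p)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_discarded"), 1L)

  # leading base Q2 removed by LEADING:3
  r <- read_set("c", strrep("A", 51), paste0(intToUtf8(33 + 2), phred_str(40, 50)))
  expect_equal(nchar(quality_trim(r, trim_params(min_len = 45))$seq), 50L)

  # min_len default flips to 90 for long reads
  r <- read_set("d", strrep("A", 80), phred_str(40, 80))
  expect_equal(nrow(quality_trim(r, p)), 0L)  # 80 < 90
  r <- read_set("e", strrep("A", 150), phred_str(40, 150))
  expect_equal(nrow(quality_trim(r, p)), 1L)
})

test_that("quality_trim is idempotent and never lengthens reads", {
  set.seed(42)
  n <- 60
  len <- 51L
  quals <- vapply(seq_len(n), function(i)
    intToUtf8(33 + sample(0:40, len, replace = TRUE)), character(1))
  rs <- read_set(sprintf("r%02d", seq_len(n)), random_reads(n, len), quals)
  p <- trim_params(min_len = 20)
  t1 <- quality_trim(rs, p)
  t2 <- quality_trim(t1, p)
  expect_equal(t1$seq, t2$seq)
  expect_true(all(nchar(t1$seq) <= len))
  # DISCARD iff post-trim length < min_len (no survivor below min_len)
  expect_true(all(nchar(t1$seq) >= 20))
})

test_that("FASTA writing round-trips through reading", {
  rec <- seq_set("x", "ACGT")
  fa <- tempfile(fileext = ".fa")
  write_fasta(rec, fa, wrap = 60)
  expect_equal(readLines(fa), c(">x", "ACGT"))
  set.seed(7)
  recs <- seq_set(sprintf("s%02d", 1:20),
                  vapply(sample(30:300, 20, TRUE), function(L)
                    paste(sample(c("A", "C", "G", "T", "N"), L, TRUE),
                          collapse = ""), character(1)))
  write_fasta(recs, fa)
  back <- read_fasta(fa)
  expect_equal(back$id, recs$id)
  expect_equal(back$seq, recs$seq)
})

test_that("GFF3 converts 1-based inclusive disk to 0-based half-open memory", {
  ann <- annotation(data.frame(gene_id = "g", type = "PCG", start = 0, end = 3,
                               strand = "+"), 100, circular = FALSE)
  gff <- tempfile(fileext = ".gff3")
  write_gff3(ann, gff)
  line <- grep("\tPCG\t", readLines(gff), value = TRUE)
  expect_match(line, "\t1\t3\t")  # disk start=1, end=3
  back <- read_gff3(gff, circular = FALSE)
  expect_equal(back$features$start, 0)
  expect_equal(back$features$end, 3)
})

test_that("GFF3 round-trips randomized annotations and wrap features", {
  set.seed(11)
  for (rep in 1:3) {
    n <- sample(3:8, 1)
    starts <- sort(sample(0:900, n))
    ends <- starts + sample(10:60, n, TRUE)
    f <- data.frame(gene_id = sprintf("g%02d", seq_len(n)),
                    type = sample(c("PCG", "tRNA", "rRNA"), n, TRUE),
                    start = starts, end = pmin(ends, 1000),
                    strand = sample(c("+", "-"), n, TRUE), wrap = FALSE)
    f <- rbind(f, data.frame(gene_id = "wrapf", type = "control_region",
                             start = 980, end = 5, strand = "+", wrap = TRUE))
    ann <- annotation(f, 1000, circular = TRUE)
    gff <- tempfile(fileext = ".gff3")
    write_gff3(ann, gff)
    back <- read_gff3(gff)
    o1 <- ann$features[order(ann$features$gene_id), ]
    o2 <- back$features[order(back$features$gene_id), ]
    rownames(o1) <- rownames(o2) <- NULL
    expect_equal(o2, o1)
    expect_true(back$features$wrap[back$features$gene_id == "wrapf"])
  }
})

test_that("malformed annotations are rejected", {
  expect_error(annotation(data.frame(gene_id = "g", type = "PCG", start = 5,
                                     end = 3, strand = "+"), 100),
               "out of bounds")
  expect_error(annotation(data.frame(gene_id = c("g", "g"), type = "PCG",
                                     start = c(0, 10), end = c(5, 20),
                                     strand = "+"), 100), "unique")
})
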