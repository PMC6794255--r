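#' Assembly parameters
#'
#' Single-k De Bruijn assembly over canonical k-mers with a k-mer count
#' floor in lieu of read normalization, simple bubble popping, and a
#' minimum emitted contig length.
#'
#' @param dbg_k odd k-mer size, 15-31, smaller than the read length.
#' @param min_contig_len shortest contig reported (bp).
#' @param min_kmer_count k-mers seen fewer times are dropped (error floor).
#' @param bubble_identity branch identity at or above which a simple
#'   bubble is popped in favour of the higher-coverage branch.
#' @return an `assembly_params` list.
#' @export
assembly_params <- function(dbg_k = 25L, min_contig_len = 150L,
                            min_kmer_count = 2L, bubble_identity = 0.95) {
  stopifnot(dbg_k %% 2 == 1, dbg_k >= 15, dbg_k <= 31,
            min_contig_len >= dbg_k, min_kmer_count >= 1,
            bubble_identity >= 0, bubble_identity <= 1)
  structure(list(dbg_k = as.integer(dbg_k),
                 min_contig_len = as.integer(min_contig_len),
                 min_kmer_count = as.integer(min_kmer_count),
                 bubble_identity = bubble_identity),
            class = "assembly_params")
}

#' Construct a contig set
#' @keywords internal
contig_set <- function(id, seq, iteration_born = NA_integer_,
                       mean_kmer_coverage = NA_real_, circular = FALSE,
                       supporting = NULL) {
  ct <- data.table::data.table(
    id = as.character(id), seq = toupper(as.character(seq)),
    length = nchar(seq), iteration_born = as.integer(iteration_born),
    mean_kmer_coverage = as.numeric(mean_kmer_coverage),
    circular = as.logical(circular),
    supporting = supporting %||% replicate(length(id), character(0),
                                           simplify = FALSE))
  data.table::setattr(ct, "class", c("contig_set", class(ct)))
  ct
}

#' De novo assembly of a read set
#'
#' Builds a De Bruijn graph on canonical `dbg_k`-mers with count at least
#' `min_kmer_count`, clips short tips, pops near-identical simple bubbles
#' (keeping the higher-coverage branch), and emits maximal unbranched
#' paths of at least `min_contig_len` bp.  Output ordering (length
#' descending, then sequence) and orientation (lexicographic minimum of
#' contig/reverse complement) are deterministic.  A contig whose De
#' Bruijn path closes on itself is emitted with deliberate terminal
#' redundancy so circularity is detectable downstream.
#'
#' @param reads a [read_set()] or character vector of sequences.
#' @param p an [assembly_params()].
#' @param iteration iteration index recorded in the contigs' provenance.
#' @return a `contig_set`: id, seq, length, iteration_born,
#'   mean_kmer_coverage, circular, supporting (read ids whose k-mers
#'   majority-vote for the contig).
#' @export
assemble <- function(reads, p = assembly_params(), iteration = NA_integer_) {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  ids <- if (is.data.frame(reads)) reads$id else as.character(seq_along(seqs))
  if (length(seqs) == 0) stop("no reads to assemble")
  res <- cpp_assemble(seqs, p$dbg_k, p$min_kmer_count, p$min_contig_len,
                      p$bubble_identity)
  n <- length(res$seq)
  if (n == 0)
    return(contig_set(character(0), character(0)))
  cid <- sprintf("it%s_c%03d",
                 ifelse(is.na(iteration), "X", as.character(iteration)),
                 seq_len(n))
  assign <- cpp_assign_reads(res$seq, seqs, p$dbg_k)
  supporting <- lapply(seq_len(n), function(i) ids[which(assign == i)])
  contig_set(cid, res$seq, iteration_born = iteration,
             mean_kmer_coverage = res$mean_cov, circular = res$circular,
             supporting = supporting)
}

#' Summary statistics of a contig set
#'
#' @param contigs a contig set (or anything with a `length` column).
#' @return list with `n`, `mean_len`, `total_len` and `N50` (conventional
#'   definition: length of the shortest contig in the minimal set covering
#'   half the total assembly span).
#' @export
contig_stats <- function(contigs) {
  lens <- if (is.data.frame(contigs)) contigs$length else as.integer(contigs)
  if (length(lens) == 0)
    return(list(n = 0L, mean_len = 0, total_len = 0L, N50 = 0L))
  lens <- sort(lens, decreasing = TRUE)
  csum <- cumsum(as.numeric(lens))
  n50 <- lens[which(csum >= sum(lens) / 2)[1]]
  list(n = length(lens), mean_len = mean(lens), total_len = sum(lens),
       N50 = n50)
}
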