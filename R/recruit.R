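#' Alignment parameters for read recruitment
#'
#' Short seeds (default k = 10) with a one-mismatch seed neighbourhood and
#' a local alignment score threshold `min_score(L) = a + b * ln(L)` mirror
#' a very-sensitive local mapper; scoring uses the conventional local
#' match/mismatch/gap values for this setting.
#'
#' @param k seed length (exact k-mer seeds; Hamming-1 neighbours are only
#'   generated for k of at most 12).
#' @param seed_mismatches mismatches tolerated in a seed (0 or 1).
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @param min_score_a,min_score_b intercept and log-length slope of the
#'   reporting threshold.
#' @return an `align_params` list.
#' @export
align_params <- function(k = 10L, seed_mismatches = 1L, match = 2,
                         mismatch = -3, gap_open = -5, gap_extend = -2,
                         min_score_a = 20, min_score_b = 8) {
  stopifnot(k >= 2, seed_mismatches %in% c(0L, 1L), match > 0,
            mismatch < 0, gap_open <= 0, gap_extend <= 0)
  structure(list(k = as.integer(k), seed_mismatches = as.integer(seed_mismatches),
                 match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_score_a = min_score_a,
                 min_score_b = min_score_b),
            class = "align_params")
}

#' Minimum reported local alignment score for a read of length L
#' @param L read length.
#' @param p an [align_params()].
#' @return numeric threshold.
#' @export
min_score <- function(L, p = align_params()) {
  p$min_score_a + p$min_score_b * log(L)
}

#' Build a seed index over a reference set
#'
#' Indexes every k-mer position of the forward strand of each reference;
#' queries are aligned in both orientations against it (one documented
#' convention rather than double indexing).
#'
#' @param references a [seq_set()], a named character vector, or anything
#'   with `id` and `seq` columns.
#' @param k seed length.
#' @return a `seed_index` handle.
#' @export
build_index <- function(references, k = 10L) {
  if (is.character(references))
    references <- seq_set(names(references) %||%
                            paste0("ref", seq_along(references)), references)
  if (nrow(references) == 0) stop("reference set is empty")
  ptr <- cpp_index_build(references$id, references$seq, as.integer(k))
  structure(list(ptr = ptr, ids = references$id, k = as.integer(k)),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat(sprintf("seed_index: k=%d, %d reference(s), %.0f k-mers / %.0f positions\n",
              info$k, info$n_refs, info$n_kmers, info$n_positions))
  invisible(x)
}

.hits_to_dt <- function(df, index, read_ids = NULL) {
  dt <- data.table::as.data.table(df)
  dt[, reference_id := index$ids[ref]]
  if (!is.null(read_ids)) dt[, read_id := read_ids[read]]
  dt[]
}

#' Locally align one read against a seed index
#'
#' Seeds are the read's exact k-mers (plus all Hamming-1 neighbours when
#' `seed_mismatches = 1` and no exact seed produced a passing hit); each
#' candidate diagonal is scored by gapless local extension with a banded
#' Smith-Waterman fallback near the threshold.  Hits below
#' `min_score(L)` are dropped; survivors are sorted by score then
#' (reference_id, position).
#'
#' @param read sequence string or one-row [read_set()].
#' @param index a [build_index()] handle.
#' @param p an [align_params()].
#' @return data.table of hits: reference_id, strand, read/reference
#'   intervals (0-based half-open), score, identity.
#' @export
align_local <- function(read, index, p = align_params()) {
  if (is.data.frame(read)) read <- read$seq[1]
  if (nchar(read) < index$k) stop("read shorter than seed length")
  df <- cpp_align_local(index$ptr, read, unclass(p))
  .hits_to_dt(df, index)
}

#' Recruit reads against a reference set
#'
#' A read is recruited iff it has at least one passing local alignment;
#' paired mates are recruited independently.  Deterministic.
#'
#' @param reads a [read_set()].
#' @param references a [seq_set()] or an existing [build_index()].
#' @param p an [align_params()].
#' @return list with `recruited` (character vector of read ids, set
#'   semantics) and `hits` (best hit per recruited read).
#' @export
recruit_reads <- function(reads, references, p = align_params()) {
  index <- if (inherits(references, "seed_index")) references
           else build_index(references, p$k)
  if (nrow(reads) == 0)
    return(list(recruited = character(0),
                hits = .hits_to_dt(cpp_recruit_batch(index$ptr, character(0),
                                                     unclass(p)),
                                   index, character(0))))
  df <- cpp_recruit_batch(index$ptr, reads$seq, unclass(p))
  hits <- .hits_to_dt(df, index, reads$id)
  list(recruited = unique(hits$read_id), hits = hits)
}
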