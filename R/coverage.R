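## Coverage profiling: per-position depth over the final mitogenome,
## per-gene summaries, and low-coverage interval flagging.

#' Per-position coverage of a mitogenome
#'
#' Maps every read and lets its single best alignment increment depth
#' over the aligned reference interval (ties broken as in recruitment);
#' circular molecules are handled by aligning against an origin-extended
#' copy and folding the depth back.  Total depth equals total aligned
#' bases, exactly.
#'
#' @param reads the full trimmed [read_set()].
#' @param mito a mitogenome (from [circularize()]) or sequence string.
#' @param p an [align_params()].
#' @param cap_for_plots depth cap applied by [write_bedgraph()] for
#'   display only; stored depths are never capped.
#' @return a `coverage_profile`: integer `depth` (length = genome
#'   length), `length`, `circular`, `cap_for_plots`.
#' @export
coverage_profile <- function(reads, mito, p = align_params(),
                             cap_for_plots = 5000L) {
  s <- if (is.list(mito) && !is.null(mito$sequence)) mito$sequence else
    (if (is.data.frame(mito)) mito$seq[1] else mito)
  circular <- if (is.list(mito) && !is.null(mito$circular)) mito$circular else TRUE
  L <- nchar(s)
  ext <- if (circular && nrow(reads) > 0)
    max(0L, min(L, max(nchar(reads$seq)) - 1L)) else 0L
  idx <- build_index(seq_set("mito", paste0(s, substr(s, 1L, ext))), p$k)
  hits <- recruit_reads(reads, idx, p)$hits
  n <- L + ext
  delta <- integer(n + 1L)
  if (nrow(hits) > 0) {
    st <- hits$rstart + 1L
    en <- hits$rend + 1L
    for (i in seq_along(st)) {
      delta[st[i]] <- delta[st[i]] + 1L
      delta[en[i]] <- delta[en[i]] - 1L
    }
  }
  depth <- cumsum(delta[seq_len(n)])
  if (ext > 0) {
    depth[seq_len(ext)] <- depth[seq_len(ext)] + depth[L + seq_len(ext)]
    depth <- depth[seq_len(L)]
  }
  structure(list(depth = as.integer(depth), length = L, circular = circular,
                 cap_for_plots = cap_for_plots),
            class = "coverage_profile")
}

#' Per-gene coverage summaries
#'
#' Aggregates a coverage profile over annotated features (wrap-around
#' features are aggregated across the origin) and reports, per gene, the
#' mean and minimum depth and the fraction of positions below
#' `low_threshold`.
#'
#' @param profile a [coverage_profile()].
#' @param ann a [annotation()] covering the profile length.
#' @param low_threshold depth below which a position counts as low.
#' @return data.frame: gene_id, type, length, mean_depth, min_depth,
#'   fraction_below.
#' @export
per_gene_coverage <- function(profile, ann, low_threshold = 4) {
  if (ann$seq_length != profile$length)
    stop("annotation length does not match profile length")
  f <- ann$features
  lens <- feature_lengths(ann)
  rows <- lapply(seq_len(nrow(f)), function(i) {
    if (is.na(f$start[i]))
      return(data.frame(gene_id = f$gene_id[i], type = f$type[i],
                        length = NA_integer_, mean_depth = NA_real_,
                        min_depth = NA_real_, fraction_below = NA_real_))
    idx <- (f$start[i] + seq_len(lens[i]) - 1L) %% profile$length + 1L
    if (any(idx > profile$length)) stop("feature outside profile")
    d <- profile$depth[idx]
    data.frame(gene_id = f$gene_id[i], type = f$type[i], length = lens[i],
               mean_depth = mean(d), min_depth = min(d),
               fraction_below = mean(d < low_threshold))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Low-coverage intervals
#'
#' Maximal runs of positions with depth below `threshold`, at least
#' `min_run` long, as 0-based half-open intervals (disjoint and sorted).
#'
#' @param profile a [coverage_profile()].
#' @param threshold depth threshold.
#' @param min_run minimum run length reported.
#' @return data.frame with columns start, end.
#' @export
low_coverage_regions <- function(profile, threshold = 4, min_run = 10L) {
  iv <- .runs_false(profile$depth >= threshold)
  iv[iv$end - iv$start >= min_run, , drop = FALSE]
}

#' Write a coverage profile as BEDGraph
#'
#' @param profile a [coverage_profile()].
#' @param path output file.
#' @param name chromosome name in column 1.
#' @param cap optional depth cap for display (default the profile's
#'   `cap_for_plots`); pass `Inf` to disable.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path, name = "mito", cap = NULL) {
  cap <- cap %||% profile$cap_for_plots
  d <- pmin(profile$depth, cap)
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  writeLines(sprintf("%s\t%d\t%d\t%d", name, starts, ends, r$values), path)
  invisible(path)
}

#' Write intervals as BED
#'
#' @param intervals data.frame with 0-based half-open start/end columns.
#' @param path output file.
#' @param name chromosome name.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, name = "mito") {
  writeLines(sprintf("%s\t%d\t%d", name, as.integer(intervals$start),
                     as.integer(intervals$end)), path)
  invisible(path)
}

#' Read a BED file written by [write_bed()]
#'
#' @param path BED file.
#' @return data.frame with columns start, end.
#' @export
read_bed <- function(path) {
  ln <- readLines(path)
  if (length(ln) == 0) return(data.frame(start = integer(0), end = integer(0)))
  parts <- do.call(rbind, strsplit(ln, "\t"))
  data.frame(start = as.integer(parts[, 2]), end = as.integer(parts[, 3]))
}
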