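## Post-iteration finishing: validate, order, orient and merge final
## contigs against the closest non-conspecific guide reference, fill gaps
## from raw reads, circularize, transfer annotations, check ORFs.

.SCAFFOLD_ALIGN_K <- 11L

.guide_seq <- function(guide) if (is.data.frame(guide)) guide$seq[1] else guide
.guide_id <- function(guide)
  if (is.data.frame(guide)) guide$id[1] else "guide"

# best placement of an arbitrary-length query on a reference index
.best_hit <- function(qseq, index, p) {
  hits <- align_local(qseq, index, p)
  if (nrow(hits) == 0) NULL else hits[1]
}

#' Pick the guide reference closest to an assembly
#'
#' Automates "closest non-conspecific reference" selection: the candidate
#' with the highest summed best-hit alignment score over all contigs.
#'
#' @param contigs a contig set.
#' @param candidates a [seq_set()] of candidate references.
#' @param p an [align_params()] (seed length is overridden).
#' @return the id of the best candidate.
#' @export
select_guide <- function(contigs, candidates, p = align_params()) {
  p$k <- .SCAFFOLD_ALIGN_K
  scores <- setNames(numeric(nrow(candidates)), candidates$id)
  for (i in seq_len(nrow(candidates))) {
    idx <- build_index(candidates[i], p$k)
    for (s in contigs$seq) {
      h <- .best_hit(s, idx, p)
      if (!is.null(h)) scores[i] <- scores[i] + h$score
    }
  }
  names(which.max(scores))
}

#' Order, orient and merge contigs along a guide reference
#'
#' Each contig is locally aligned to the guide; contigs whose best hit has
#' identity below `min_identity` or covers less than `min_coverage` of the
#' contig are excluded (kept in `$leftover` for leakage triage).  Passing
#' contigs are placed by guide position (the guide is treated as
#' circular, so placements may overhang its end), near-identical overlaps
#' (identity at least `merge_identity`) are merged by per-column majority
#' with ties going to the higher-coverage contig, and conflicting
#' placements are resolved in favour of the higher alignment score.
#' Unplaced guide intervals become `N` runs in the merged sequence and
#' are reported as gaps.
#'
#' @param contigs a contig set from [run_iterations()].
#' @param guide a one-row [seq_set()] (or string) guide mitogenome.
#' @param p an [align_params()]; the seed length is fixed at 11 here.
#' @param min_identity,min_coverage contig validation thresholds.
#' @param merge_identity overlap identity at or above which two placed
#'   contigs are merged rather than treated as conflicting.
#' @return a `scaffold`: guide id/length, `placed` table, `gaps` table
#'   (0-based half-open guide intervals), `merged_sequence` (gap runs as
#'   N), `merged_offset` (guide coordinate of the merged sequence's first
#'   base) and `leftover` contig ids.
#' @export
scaffold_contigs <- function(contigs, guide, p = align_params(),
                             min_identity = 0.70, min_coverage = 0.30,
                             merge_identity = 0.98) {
  gseq <- .guide_seq(guide)
  L <- nchar(gseq)
  p$k <- .SCAFFOLD_ALIGN_K
  index <- build_index(seq_set(.guide_id(guide), gseq), p$k)

  placed <- list()
  leftover <- character(0)
  for (i in seq_len(nrow(contigs))) {
    len <- contigs$length[i]
    h <- .best_hit(contigs$seq[i], index, p)
    ok <- !is.null(h) && h$identity >= min_identity &&
      (h$qend - h$qstart) / len >= min_coverage
    if (!ok) { leftover <- c(leftover, contigs$id[i]); next }
    if (h$strand == "+") {
      oseq <- contigs$seq[i]
      qs <- h$qstart
    } else {
      oseq <- revcomp(contigs$seq[i])
      qs <- len - h$qend
    }
    start <- (h$rstart - qs) %% L
    placed[[length(placed) + 1L]] <- list(
      contig_id = contigs$id[i], strand = h$strand, oseq = oseq,
      gstart = start, gend = start + len, cstart = h$qstart, cend = h$qend,
      score = h$score, identity = h$identity,
      mean_cov = contigs$mean_kmer_coverage[i])
  }
  if (length(placed) == 0) stop("no mitochondrial contigs pass validation")
  ord <- order(vapply(placed, `[[`, numeric(1), "gstart"),
               -vapply(placed, `[[`, numeric(1), "score"))
  placed <- placed[ord]

  # resolve conflicting overlaps (identity below merge_identity) in favour
  # of the higher alignment score
  accepted <- list()
  for (pc in placed) {
    while (length(accepted) > 0) {
      last <- accepted[[length(accepted)]]
      ov <- last$gend - pc$gstart
      if (ov <= 0) break
      na <- min(ov, nchar(last$oseq), nchar(pc$oseq))
      a <- substr(last$oseq, nchar(last$oseq) - na + 1L, nchar(last$oseq))
      b <- substr(pc$oseq, 1L, na)
      if (string_identity(a, b) >= merge_identity) break
      if (pc$score > last$score) {
        leftover <- c(leftover, last$contig_id)
        accepted[[length(accepted)]] <- NULL
      } else {
        leftover <- c(leftover, pc$contig_id)
        pc <- NULL
        break
      }
    }
    if (!is.null(pc)) accepted[[length(accepted) + 1L]] <- pc
  }

  # build the merged sequence with majority consensus in overlaps
  merged <- ""
  merged_offset <- accepted[[1]]$gstart
  cur_end <- merged_offset
  prev_cov <- -Inf
  for (pc in accepted) {
    if (pc$gend <= cur_end) next  # contained in previous placement
    if (pc$gstart >= cur_end) {
      merged <- paste0(merged, strrep("N", pc$gstart - cur_end), pc$oseq)
    } else {
      ov <- cur_end - pc$gstart
      a <- substr(merged, nchar(merged) - ov + 1L, nchar(merged))
      b <- substr(pc$oseq, 1L, ov)
      cons <- if (pc$mean_cov > prev_cov) b else a
      merged <- paste0(substr(merged, 1L, nchar(merged) - ov), cons,
                       substr(pc$oseq, ov + 1L, nchar(pc$oseq)))
    }
    cur_end <- pc$gend
    prev_cov <- pc$mean_cov
  }

  covered <- logical(L)
  for (pc in accepted) {
    idx <- (pc$gstart:(pc$gend - 1L)) %% L
    covered[idx + 1L] <- TRUE
  }
  gaps <- .runs_false(covered)

  placed_df <- data.frame(
    contig_id = vapply(accepted, `[[`, character(1), "contig_id"),
    strand = vapply(accepted, `[[`, character(1), "strand"),
    gstart = vapply(accepted, `[[`, numeric(1), "gstart"),
    gend = vapply(accepted, `[[`, numeric(1), "gend"),
    cstart = vapply(accepted, `[[`, numeric(1), "cstart"),
    cend = vapply(accepted, `[[`, numeric(1), "cend"),
    score = vapply(accepted, `[[`, numeric(1), "score"),
    identity = vapply(accepted, `[[`, numeric(1), "identity"))
  structure(list(guide_id = .guide_id(guide), guide_length = L,
                 placed = placed_df, gaps = gaps,
                 merged_sequence = merged, merged_offset = merged_offset,
                 leftover = leftover),
            class = "scaffold")
}

# maximal runs of FALSE as a 0-based half-open interval table
.runs_false <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[!r$values], end = ends[!r$values])
}

#' Fill scaffold gaps from the raw read set
#'
#' For each `N` run in the merged sequence, reads aligning to the
#' homologous guide window (gap plus `flank` bp on each side, relaxed
#' score threshold) are collected and laid out by their guide-projected
#' positions into an overlap-consensus patch: adjacent reads must overlap
#' by at least `min_overlap` bp at `overlap_identity` or better, and the
#' per-column majority consensus must bridge both gap flanks at
#' `bridge_identity` over `bridge_len` bp.  Gaps whose patch fails any of
#' this remain as `N` (low-expression regions such as the control region
#' may legitimately stay open).
#'
#' @param scaffold a [scaffold_contigs()] result.
#' @param reads the full trimmed [read_set()].
#' @param guide the guide used for scaffolding.
#' @param p an [align_params()]; default relaxes the score intercept to 15.
#' @param flank guide flank width around each gap.
#' @param min_overlap,overlap_identity adjacent-read chaining rule.
#' @param bridge_len,bridge_identity patch-to-scaffold acceptance rule.
#' @return the updated scaffold.
#' @export
fill_gaps <- function(scaffold, reads, guide,
                      p = align_params(min_score_a = 15), flank = 100L,
                      min_overlap = 20L, overlap_identity = 0.95,
                      bridge_len = 20L, bridge_identity = 0.98) {
  gseq <- .guide_seq(guide)
  L <- scaffold$guide_length
  merged <- scaffold$merged_sequence
  nruns <- gregexpr("N+", merged)[[1]]
  if (nruns[1] == -1) return(scaffold)
  starts <- as.integer(nruns) - 1L
  lens <- attr(nruns, "match.length")
  for (gi in seq_along(starts)) {
    ms <- starts[gi]
    glen <- lens[gi]
    gs <- (scaffold$merged_offset + ms) %% L
    region <- circ_substr(gseq, gs - flank, glen + 2L * flank)
    W <- nchar(region)
    idx <- build_index(seq_set("gap_region", region), p$k)
    hits <- recruit_reads(reads, idx, p)$hits
    if (nrow(hits) == 0) next
    rs <- reads[match(hits$read_id, reads$id)]
    oseq <- ifelse(hits$strand == "+", rs$seq, revcomp(rs$seq))
    oqs <- ifelse(hits$strand == "+", hits$qstart, nchar(rs$seq) - hits$qend)
    pos <- hits$rstart - oqs
    ok <- pos > -nchar(oseq) & pos < W
    oseq <- oseq[ok]; pos <- pos[ok]
    if (length(oseq) == 0) next
    o <- order(pos, oseq)
    oseq <- oseq[o]; pos <- pos[o]
    # per-column base counts
    counts <- matrix(0L, 5L, W, dimnames = list(c("A", "C", "G", "T", "N"), NULL))
    for (i in seq_along(oseq)) {
      ch <- strsplit(oseq[i], "")[[1]]
      cols <- pos[i] + seq_along(ch)
      keep <- cols >= 1 & cols <= W
      ch <- ch[keep]; cols <- cols[keep]
      ch[!ch %in% rownames(counts)] <- "N"
      for (j in seq_along(ch))
        counts[ch[j], cols[j]] <- counts[ch[j], cols[j]] + 1L
    }
    depth <- colSums(counts)
    cons <- rownames(counts)[apply(counts, 2, which.max)]
    # chaining: breaks where adjacent reads fail the overlap rule
    breaks <- rep(FALSE, W)
    if (length(oseq) > 1) {
      for (i in seq_len(length(oseq) - 1L)) {
        ov <- pos[i] + nchar(oseq[i]) - pos[i + 1L]
        bad <- ov < min_overlap ||
          string_identity(substr(oseq[i], nchar(oseq[i]) - ov + 1L,
                                 nchar(oseq[i])),
                          substr(oseq[i + 1L], 1L, ov)) < overlap_identity
        if (bad && pos[i + 1L] >= 1 && pos[i + 1L] <= W)
          breaks[pos[i + 1L]] <- TRUE
      }
    }
    gap_cols <- (flank + 1L):(flank + glen)
    span_cols <- (flank + 1L - bridge_len):(flank + glen + bridge_len)
    span_cols <- span_cols[span_cols >= 1 & span_cols <= W]
    if (any(depth[span_cols] == 0) || any(breaks[span_cols])) next
    # bridge check against the contig-derived flanks
    left_m <- substr(merged, ms - bridge_len + 1L, ms)
    right_m <- substr(merged, ms + glen + 1L, ms + glen + bridge_len)
    left_p <- paste(cons[(flank - bridge_len + 1L):flank], collapse = "")
    right_p <- paste(cons[(flank + glen + 1L):(flank + glen + bridge_len)],
                     collapse = "")
    if (nchar(left_m) < bridge_len || nchar(right_m) < bridge_len) next
    if (string_identity(left_m, left_p) < bridge_identity ||
        string_identity(right_m, right_p) < bridge_identity) next
    patch <- paste(cons[gap_cols], collapse = "")
    merged <- paste0(substr(merged, 1L, ms), patch,
                     substr(merged, ms + glen + 1L, nchar(merged)))
  }
  scaffold$merged_sequence <- merged
  # recompute gaps from the remaining N runs
  covered <- rep(TRUE, L)
  nr <- gregexpr("N+", merged)[[1]]
  if (nr[1] != -1) {
    st <- as.integer(nr) - 1L
    le <- attr(nr, "match.length")
    for (i in seq_along(st)) {
      idx <- ((scaffold$merged_offset + st[i]) %% L + seq_len(le[i]) - 1L) %% L
      covered[idx + 1L] <- FALSE
    }
  }
  # guide positions never covered by any placement stay gaps too
  span <- nchar(merged)
  placed_idx <- (scaffold$merged_offset + seq_len(min(span, L)) - 1L) %% L
  uncovered <- setdiff(0:(L - 1L), placed_idx)
  covered[uncovered + 1L] <- FALSE
  scaffold$gaps <- .runs_false(covered)
  scaffold
}

#' Circularize a finished scaffold
#'
#' Detects a terminal self-overlap of at least `min_overlap` bp at
#' `min_identity` or better, trims one copy and marks the molecule
#' circular, then rotates it so the anchor gene (default: the guide's
#' first annotated gene) starts at position 0 on the plus strand.  With
#' no terminal overlap the molecule is returned linear with a warning.
#'
#' @param scaffold a [scaffold_contigs()] (optionally gap-filled) result.
#' @param guide,guide_ann guide sequence and [annotation()] (used for the
#'   rotation anchor; omit to skip rotation).
#' @param anchor anchor gene id; default the guide's first feature.
#' @param min_overlap,min_identity terminal overlap detection rule.
#' @param max_overlap largest terminal overlap searched for.
#' @return a `mitogenome`: sequence, circular flag, `annotation` (NULL
#'   until [transfer_annotation()]) and `rotation_anchor`.
#' @export
circularize <- function(scaffold, guide = NULL, guide_ann = NULL,
                        anchor = NULL, min_overlap = 50L,
                        min_identity = 0.99, max_overlap = 3000L) {
  s <- scaffold$merged_sequence
  len <- nchar(s)
  if (substr(s, 1, 1) == "N" || substr(s, len, len) == "N")
    stop("merged sequence must be gap-free at its ends to circularize")
  best_ov <- 0L
  tailw <- min(max_overlap, len - min_overlap)
  tail_s <- substr(s, len - tailw + 1L, len)
  for (probe_off in c(0L, 30L, 60L)) {
    probe <- substr(s, probe_off + 1L, probe_off + 30L)
    if (nchar(probe) < 30L) next
    m <- gregexpr(probe, tail_s, fixed = TRUE)[[1]]
    if (m[1] == -1) next
    for (q in as.integer(m)) {
      gp <- len - tailw + q - 1L          # 0-based match start in s
      ov <- len - gp + probe_off
      if (ov < min_overlap || ov >= len) next
      if (string_identity(substr(s, 1L, ov), substr(s, len - ov + 1L, len)) >=
          min_identity)
        best_ov <- max(best_ov, ov)
    }
  }
  circular <- best_ov >= min_overlap
  if (circular) {
    s <- substr(s, 1L, len - best_ov)
  } else {
    warning("no terminal overlap found; returning a linear molecule")
  }
  anchor_id <- anchor %||%
    (if (!is.null(guide_ann)) guide_ann$features$gene_id[1] else NA_character_)
  if (circular && !is.null(guide) && !is.null(guide_ann) &&
      !is.na(anchor_id)) {
    aseq <- feature_seqs(.guide_seq(guide), guide_ann)[[anchor_id]]
    for (attempt in 1:2) {
      ext <- paste0(s, substr(s, 1L, min(nchar(s), nchar(aseq) + 50L)))
      idx <- build_index(seq_set("m", ext), .SCAFFOLD_ALIGN_K)
      h <- .best_hit(aseq, idx, align_params(k = .SCAFFOLD_ALIGN_K))
      if (is.null(h)) break
      if (h$strand == "-" && attempt == 1L) { s <- revcomp(s); next }
      pos <- (h$rstart - h$qstart) %% nchar(s)
      if (pos > 0)
        s <- paste0(substr(s, pos + 1L, nchar(s)), substr(s, 1L, pos))
      break
    }
  }
  structure(list(sequence = s, circular = circular, annotation = NULL,
                 rotation_anchor = anchor_id),
            class = "mitogenome")
}

#' Transfer a guide annotation onto a finished mitogenome
#'
#' Each guide feature is located independently on the target by local
#' alignment of its (genome-forward) sequence; boundaries are projected
#' through the gapless alignment, and protein-coding genes are snapped to
#' the nearest in-frame start/stop within `snap` bp.  Features that
#' cannot be located are reported with `found = FALSE`.
#'
#' @param mito a [circularize()] result (or list with `sequence`,
#'   `circular`).
#' @param guide_ann the guide's [annotation()].
#' @param guide_seq the guide sequence (string or one-row [seq_set()]).
#' @param snap snapping window for PCG boundaries (bp; frame-preserving
#'   shifts only).
#' @return a [annotation()] for the target, with a `found` column, in
#'   target coordinate order.
#' @export
transfer_annotation <- function(mito, guide_ann, guide_seq, snap = 6L) {
  s <- mito$sequence
  L <- nchar(s)
  gseq <- .guide_seq(guide_seq)
  ext <- if (isTRUE(mito$circular))
    paste0(s, substr(s, 1L, min(L, 2500L))) else s
  idx <- build_index(seq_set("target", ext), .SCAFFOLD_ALIGN_K)
  p <- align_params(k = .SCAFFOLD_ALIGN_K)
  f <- guide_ann$features
  lens <- feature_lengths(guide_ann)
  out <- vector("list", nrow(f))
  for (i in seq_len(nrow(f))) {
    fseq <- circ_substr(gseq, f$start[i], lens[i])  # genome-forward
    h <- .best_hit(fseq, idx, p)
    if (is.null(h)) {
      out[[i]] <- data.frame(gene_id = f$gene_id[i], type = f$type[i],
                             start = NA_integer_, end = NA_integer_,
                             strand = f$strand[i], wrap = FALSE, found = FALSE)
      next
    }
    if (h$strand == "+") {
      ms <- h$rstart - h$qstart
      me <- ms + lens[i]
      strand_m <- f$strand[i]
    } else {
      me <- h$rend + h$qstart
      ms <- me - lens[i]
      strand_m <- if (f$strand[i] == "+") "-" else "+"
    }
    if (f$type[i] == "PCG" && snap > 0) {
      shifts <- c(0L, -3L, 3L, -6L, 6L)
      shifts <- shifts[abs(shifts) <= snap]
      for (sh in shifts) {
        cs <- ms + sh; ce <- me + sh
        fs <- circ_substr(s, cs %% L, lens[i])
        if (strand_m == "-") fs <- revcomp(fs)
        first <- substr(fs, 1, 3)
        last <- substr(fs, nchar(fs) - 2, nchar(fs))
        if (first %in% .MITO_START_CODONS && last %in% .MITO_STOP_CODONS) {
          ms <- cs; me <- ce
          break
        }
      }
    }
    if (isTRUE(mito$circular)) {
      msL <- ms %% L
      meL <- ((me - 1L) %% L) + 1L
    } else {
      # linear target: truncate projections at the molecule ends
      msL <- max(0L, ms)
      meL <- min(L, me)
      if (meL <= msL) {
        out[[i]] <- data.frame(gene_id = f$gene_id[i], type = f$type[i],
                               start = NA_integer_, end = NA_integer_,
                               strand = strand_m, wrap = FALSE, found = FALSE)
        next
      }
    }
    wrap <- isTRUE(mito$circular) && (msL >= meL)
    out[[i]] <- data.frame(gene_id = f$gene_id[i], type = f$type[i],
                           start = as.integer(msL), end = as.integer(meL),
                           strand = strand_m, wrap = wrap, found = TRUE)
  }
  ftab <- do.call(rbind, out)
  ftab <- ftab[order(is.na(ftab$start), ftab$start, ftab$gene_id), ,
               drop = FALSE]
  rownames(ftab) <- NULL
  located <- ftab[!is.na(ftab$start), , drop = FALSE]
  ann <- annotation(located, seq_length = L,
                    circular = isTRUE(mito$circular))
  ann$features <- ftab
  ann
}

#' Check open reading frames of annotated protein-coding genes
#'
#' Translates every located PCG with the invertebrate mitochondrial code
#' and reports start-codon presence, internal stop count, terminal stop
#' and frame integrity.  The result carries `attr(, "ok")`, TRUE iff no
#' gene has an internal stop.
#'
#' @param mito a mitogenome (or list with `sequence`).
#' @param ann a [annotation()] for the same sequence.
#' @param genetic_code NCBI translation table id (default "5",
#'   invertebrate mitochondrial).
#' @return data.frame: gene_id, has_start, internal_stop_count,
#'   terminal_stop, frame_intact.
#' @export
check_orfs <- function(mito, ann, genetic_code = "5") {
  s <- if (is.list(mito) && !is.null(mito$sequence)) mito$sequence else mito
  f <- ann$features
  pcg <- which(f$type == "PCG" & !is.na(f$start))
  if (length(pcg) == 0) {
    out <- data.frame(gene_id = character(0), has_start = logical(0),
                      internal_stop_count = integer(0),
                      terminal_stop = logical(0), frame_intact = logical(0))
    attr(out, "ok") <- TRUE
    return(out)
  }
  code <- Biostrings::getGeneticCode(genetic_code)
  sub_ann <- ann
  sub_ann$features <- f[pcg, , drop = FALSE]
  seqs <- feature_seqs(s, sub_ann)
  rows <- lapply(seq_along(seqs), function(i) {
    fs <- seqs[[i]]
    n <- nchar(fs)
    frame_ok <- n %% 3 == 0
    usable <- substr(fs, 1, n - n %% 3)
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(usable), genetic.code = code,
      if.fuzzy.codon = "X"))
    naa <- nchar(aa)
    internal <- if (naa > 1)
      lengths(regmatches(substr(aa, 1, naa - 1L),
                         gregexpr("\\*", substr(aa, 1, naa - 1L)))) else 0L
    data.frame(gene_id = names(seqs)[i],
               has_start = substr(fs, 1, 3) %in% .MITO_START_CODONS,
               internal_stop_count = as.integer(internal),
               terminal_stop = substr(aa, naa, naa) == "*",
               frame_intact = frame_ok)
  })
  out <- do.call(rbind, rows)
  attr(out, "ok") <- all(out$internal_stop_count == 0L)
  out
}
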