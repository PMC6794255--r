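## Leakage triage: classify end-of-run contigs into target mitochondrial,
## contaminant and nuclear leakage, with count (percentage) summaries.

#' Classify contigs against target / contaminant / nuclear databases
#'
#' A contig gets a passing hit against a database when its best local
#' alignment reaches `min_identity` and covers at least `min_coverage` of
#' the contig.  Precedence is target > contaminant > nuclear (the
#' two-step triage order: first split off non-target organisms, then
#' separate host-nuclear matches); anything without a passing hit is
#' unassigned.  Databases are local FASTA-style sequence sets.
#'
#' @param contigs a contig set (or [seq_set()]).
#' @param target_ref the reconstructed (or reference) mitogenome(s).
#' @param contaminant_db,nuclear_db optional [seq_set()] databases.
#' @param min_identity,min_coverage passing-hit thresholds.
#' @param p an [align_params()]; seed length fixed at 11.
#' @return a `leakage_report`: `per_contig` table (contig_id, class,
#'   best_hit_db, identity, coverage_of_contig), `summary` counts, `total`.
#' @export
classify_contigs <- function(contigs, target_ref, contaminant_db = NULL,
                             nuclear_db = NULL, min_identity = 0.80,
                             min_coverage = 0.30, p = align_params()) {
  p$k <- .SCAFFOLD_ALIGN_K
  dbs <- list(target = target_ref, contaminant = contaminant_db,
              nuclear = nuclear_db)
  dbs <- dbs[!vapply(dbs, is.null, logical(1))]
  idxs <- lapply(dbs, function(db) {
    db <- if (is.character(db)) seq_set("db", db) else db
    build_index(db, p$k)
  })
  n <- nrow(contigs)
  cls <- rep("unassigned", n)
  bdb <- rep(NA_character_, n)
  bid <- rep(NA_real_, n)
  bcov <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    len <- nchar(contigs$seq[i])
    for (db in names(idxs)) {  # precedence = list order
      h <- .best_hit(contigs$seq[i], idxs[[db]], p)
      if (is.null(h)) next
      cov <- (h$qend - h$qstart) / len
      if (h$identity >= min_identity && cov >= min_coverage) {
        cls[i] <- db
        bdb[i] <- db
        bid[i] <- h$identity
        bcov[i] <- cov
        break
      }
    }
  }
  per_contig <- data.frame(contig_id = contigs$id, class = cls,
                           best_hit_db = bdb, identity = bid,
                           coverage_of_contig = bcov)
  counts <- c(target = sum(cls == "target"),
              contaminant = sum(cls == "contaminant"),
              nuclear = sum(cls == "nuclear"),
              unassigned = sum(cls == "unassigned"))
  structure(list(per_contig = per_contig, summary = counts, total = n),
            class = "leakage_report")
}

#' Format a count with its percentage of a total
#'
#' Renders "count (pct%)" with a thousands separator; percentages use one
#' decimal, or two when below 1 percent.
#'
#' @param count,total non-negative integers.
#' @return character scalar.
#' @export
format_count_pct <- function(count, total) {
  pct <- if (total > 0) 100 * count / total else 0
  fmt <- if (pct < 1) "%.2f%%" else "%.1f%%"
  sprintf("%s (%s)", formatC(count, big.mark = ",", format = "d"),
          sprintf(fmt, pct))
}

#' Summarize a leakage report as display rows
#'
#' One row per class in the order Total, target, contaminant, nuclear
#' (plus unassigned when present), each cell formatted as
#' "count (pct%)".
#'
#' @param report a [classify_contigs()] result, or a named count vector
#'   with entries target/contaminant/nuclear (and optionally unassigned).
#' @return data.frame with columns `class` and `cell`.
#' @export
summarize_leakage <- function(report) {
  counts <- if (inherits(report, "leakage_report")) report$summary
            else unlist(report)
  total <- sum(counts)
  rows <- data.frame(class = "Total",
                     cell = formatC(total, big.mark = ",", format = "d"))
  for (cl in c("target", "contaminant", "nuclear", "unassigned")) {
    if (cl == "unassigned" && (is.na(counts[cl]) || counts[cl] == 0)) next
    cnt <- if (is.na(counts[cl])) 0L else counts[cl]
    rows <- rbind(rows, data.frame(class = cl,
                                   cell = format_count_pct(cnt, total)))
  }
  rownames(rows) <- NULL
  rows
}

#' Majority-origin truth class of each contig
#'
#' For labelled synthetic data: a contig's truth class is the majority
#' label among its supporting reads (ties and unsupported contigs give
#' NA).  Used to score classification accuracy.
#'
#' @param contigs a contig set with a `supporting` list-column.
#' @param reads the labelled [read_set()] the contigs were assembled from.
#' @return character vector of truth classes, aligned with `contigs`.
#' @export
contig_truth_class <- function(contigs, reads) {
  lab <- setNames(reads$label, reads$id)
  vapply(contigs$supporting, function(ids) {
    if (length(ids) == 0) return(NA_character_)
    tb <- sort(table(lab[ids]), decreasing = TRUE)
    if (length(tb) == 0) return(NA_character_)
    names(tb)[1]
  }, character(1))
}
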