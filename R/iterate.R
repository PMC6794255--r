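#' Iteration loop parameters
#'
#' The loop stops after `max_iterations` rounds, or earlier once the
#' recruited fraction has plateaued: the last `plateau_patience`
#' consecutive increments are each below `plateau_rel_tol` (a fraction of
#' the total read count).  Early stopping can be disabled to reproduce a
#' fixed-iteration protocol.
#'
#' @param max_iterations iteration cap (default 10).
#' @param plateau_rel_tol plateau tolerance on the recruited fraction.
#' @param plateau_patience number of consecutive small increments required.
#' @param early_stop stop at the plateau (TRUE) or always run
#'   `max_iterations` rounds (FALSE).
#' @return a `loop_params` list.
#' @export
loop_params <- function(max_iterations = 10L, plateau_rel_tol = 0.001,
                        plateau_patience = 2L, early_stop = TRUE) {
  stopifnot(max_iterations >= 1, plateau_rel_tol >= 0, plateau_patience >= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 plateau_rel_tol = plateau_rel_tol,
                 plateau_patience = as.integer(plateau_patience),
                 early_stop = isTRUE(early_stop)),
            class = "loop_params")
}

#' Has recruitment plateaued?
#'
#' TRUE iff the last `plateau_patience` consecutive increments of
#' `recruited_fraction` are each below `plateau_rel_tol`.
#'
#' @param stats data.frame of per-iteration statistics (needs
#'   `recruited_fraction`).
#' @param loop_p a [loop_params()].
#' @return logical.
#' @export
detect_plateau <- function(stats, loop_p = loop_params()) {
  fr <- stats$recruited_fraction
  if (length(fr) < loop_p$plateau_patience + 1L) return(FALSE)
  d <- abs(diff(fr))
  all(tail(d, loop_p$plateau_patience) < loop_p$plateau_rel_tol)
}

#' Run the iterative baiting loop
#'
#' Iteration 1 recruits the full read set against `initial_refs`
#' (which must already exclude conspecific genomes - caller contract);
#' every later iteration recruits the full read set against the contigs
#' of the previous round, which fully replace the reference set.  Each
#' round logs recruited counts and contig summaries; the loop stops at a
#' plateau or at `max_iterations`.
#'
#' @param reads a quality-trimmed [read_set()].
#' @param initial_refs a [seq_set()] of non-conspecific reference
#'   mitogenomes.
#' @param align_p an [align_params()].
#' @param asm_p an [assembly_params()].
#' @param loop_p a [loop_params()].
#' @param outdir optional directory: per-iteration `contigs_<i>.fa` and a
#'   progressively rewritten `stats.tsv` make interrupted runs
#'   inspectable.
#' @param verbose log one line per iteration.
#' @return list with `contigs` (final round's contig set), `stats`
#'   (one row per iteration: iteration, recruited_reads,
#'   recruited_fraction, n_contigs, mean_contig_len) and `converged`
#'   (TRUE iff a plateau was reached).
#' @export
run_iterations <- function(reads, initial_refs, align_p = align_params(),
                           asm_p = assembly_params(),
                           loop_p = loop_params(), outdir = NULL,
                           verbose = FALSE) {
  total <- nrow(reads)
  refs <- initial_refs
  stats <- data.frame(iteration = integer(0), recruited_reads = integer(0),
                      recruited_fraction = numeric(0), n_contigs = integer(0),
                      mean_contig_len = numeric(0))
  contigs <- contig_set(character(0), character(0))
  converged <- FALSE
  for (it in seq_len(loop_p$max_iterations)) {
    t0 <- Sys.time()
    rec <- recruit_reads(reads, refs, align_p)
    sel <- reads[reads$id %in% rec$recruited]
    if (nrow(sel) == 0) {
      if (it == 1L) {
        message("no reads recruited at iteration 1; check the reference set")
        stats[1, ] <- list(1L, 0L, 0, 0L, 0)
        return(list(contigs = contigs, stats = stats, converged = FALSE))
      }
      break
    }
    contigs <- assemble(sel, asm_p, iteration = it)
    cs <- contig_stats(contigs)
    stats[it, ] <- list(it, nrow(sel), nrow(sel) / total, cs$n, cs$mean_len)
    if (verbose)
      message(sprintf(
        "iteration %d: %d/%d reads (%.2f%%), %d contigs, mean %.0f bp [%.1fs]",
        it, nrow(sel), total, 100 * nrow(sel) / total, cs$n, cs$mean_len,
        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_fasta(contigs, file.path(outdir, sprintf("contigs_%d.fa", it)))
      utils::write.table(stats, file.path(outdir, "stats.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (cs$n == 0) break
    if (loop_p$early_stop && detect_plateau(stats, loop_p)) {
      converged <- TRUE
      break
    }
    refs <- seq_set(contigs$id, contigs$seq)
  }
  list(contigs = contigs, stats = stats, converged = converged)
}
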