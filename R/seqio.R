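#' Construct a read set
#'
#' A read set is a `data.table` with one row per read: `id`, `seq`, `qual`
#' (Sanger Phred+33 string, same length as `seq`), `mate` (0 = unpaired,
#' 1/2 = mate in a pair) and optional truth columns (`label` in
#' mito/nuclear/contaminant, `src`, `src_start`, `src_end`, `src_strand`)
#' carried by simulated data.
#'
#' @param id,seq,qual character vectors of equal length.
#' @param mate integer vector (0, 1 or 2).
#' @param label,src,src_start,src_end,src_strand optional truth columns.
#' @return a `read_set` (also a `data.table`).
#' @export
read_set <- function(id, seq, qual, mate = 0L, label = NA_character_,
                     src = NA_character_, src_start = NA_integer_,
                     src_end = NA_integer_, src_strand = NA_character_) {
  if (any(nchar(seq) != nchar(qual)))
    stop("sequence and quality lengths differ")
  if (any(!nzchar(id))) stop("read ids must be non-empty")
  rs <- data.table::data.table(
    id = as.character(id), seq = toupper(as.character(seq)),
    qual = as.character(qual), mate = as.integer(mate),
    label = label, src = src, src_start = src_start, src_end = src_end,
    src_strand = src_strand)
  data.table::setattr(rs, "class", c("read_set", class(rs)))
  rs
}

#' Read a FASTQ file
#'
#' Gzip input is handled transparently.  For paired data pass the two
#' synchronized files; mates must share an id stem (trailing `/1`, `/2` or
#' a space-separated tag are stripped).
#'
#' @param path FASTQ file (optionally .gz).
#' @param path2 optional mate file for paired-end data.
#' @return a [read_set()].
#' @export
read_fastq <- function(path, path2 = NULL) {
  parse_one <- function(p, mate) {
    if (!file.exists(p)) stop("no such file: ", p)
    ln <- readLines(p)
    if (length(ln) == 0)
      return(read_set(character(), character(), character())[0])
    if (length(ln) %% 4 != 0)
      stop(sprintf("malformed FASTQ '%s': truncated record %d",
                   p, length(ln) %/% 4 + 1))
    hd <- ln[seq(1, length(ln), by = 4)]
    sq <- ln[seq(2, length(ln), by = 4)]
    pl <- ln[seq(3, length(ln), by = 4)]
    ql <- ln[seq(4, length(ln), by = 4)]
    bad <- which(substr(hd, 1, 1) != "@" | substr(pl, 1, 1) != "+" |
                   nchar(sq) != nchar(ql))
    if (length(bad))
      stop(sprintf("malformed FASTQ '%s': record %d", p, bad[1]))
    id <- sub("\\s.*$", "", sub("^@", "", hd))
    read_set(id = id, seq = sq, qual = ql, mate = mate)
  }
  if (is.null(path2)) return(parse_one(path, 0L))
  r1 <- parse_one(path, 1L)
  r2 <- parse_one(path2, 2L)
  stem <- function(x) sub("/[12]$", "", x)
  if (nrow(r1) != nrow(r2) || !all(stem(r1$id) == stem(r2$id)))
    stop("desynchronized mate files: ", path, " / ", path2)
  out <- rbind(r1, r2)
  data.table::setattr(out, "class", class(r1))
  out
}

#' Write a read set as FASTQ
#'
#' @param reads a [read_set()].
#' @param path output file; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  suffix <- ifelse(reads$mate > 0L, paste0("/", reads$mate), "")
  txt <- paste0("@", reads$id, suffix, "\n", reads$seq, "\n+\n", reads$qual)
  writeLines(txt, con)
  invisible(path)
}

#' Quality-trimming parameters
#'
#' Mirrors sliding-window read trimming as used for Illumina RNA-Seq
#' libraries: leading/trailing low-quality bases are removed, then the read
#' is cut at the first 5'->3' window whose mean quality falls below
#' `window_q`; reads shorter than `min_len` after trimming are discarded.
#' `min_len = NULL` selects 45 for reads of 60 nt or less and 90 otherwise
#' (the two common parameter sets for ~50 nt and ~100-150 nt designs).
#'
#' @param leading_q,trailing_q minimum quality to keep a leading/trailing base.
#' @param window_len,window_q sliding window length and mean-quality floor.
#' @param min_len minimum post-trim length, or NULL for length-dependent default.
#' @return a `trim_params` list.
#' @export
trim_params <- function(leading_q = 3, trailing_q = 3, window_len = 25,
                        window_q = 33, min_len = NULL) {
  stopifnot(leading_q >= 0, trailing_q >= 0, window_len >= 0, window_q >= 0,
            is.null(min_len) || min_len > 0)
  structure(list(leading_q = leading_q, trailing_q = trailing_q,
                 window_len = window_len, window_q = window_q,
                 min_len = min_len),
            class = "trim_params")
}

#' Quality-trim a read set
#'
#' Discarded reads (shorter than `min_len` after trimming) are dropped;
#' their count is available as `attr(, "n_discarded")`.  Trimming is
#' idempotent and never lengthens a read.
#'
#' @param reads a [read_set()].
#' @param p a [trim_params()].
#' @return the trimmed `read_set`.
#' @export
quality_trim <- function(reads, p = trim_params()) {
  if (nrow(reads) == 0) {
    attr(reads, "n_discarded") <- 0L
    return(reads)
  }
  iv <- cpp_quality_trim(reads$qual, p$leading_q, p$trailing_q,
                         p$window_len, p$window_q)
  newlen <- iv[, 2] - iv[, 1]
  minlen <- if (is.null(p$min_len)) ifelse(nchar(reads$seq) <= 60, 45L, 90L)
            else rep.int(as.integer(p$min_len), nrow(reads))
  keep <- newlen >= minlen
  out <- reads[keep]
  s <- iv[keep, 1, drop = TRUE] + 1L
  e <- iv[keep, 2, drop = TRUE]
  out[, `:=`(seq = substring(seq, s, e), qual = substring(qual, s, e))]
  data.table::setattr(out, "class", class(reads))
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Construct a sequence record set
#'
#' @param id,seq,desc character vectors (`desc` optional).
#' @return a `seq_set` data.table with columns id, seq, desc.
#' @export
seq_set <- function(id, seq, desc = "") {
  seq <- toupper(as.character(seq))
  if (any(nchar(seq) == 0)) stop("empty sequence")
  if (any(grepl("[^ACGTN]", seq))) stop("sequence outside alphabet {A,C,G,T,N}")
  ss <- data.table::data.table(id = as.character(id), seq = seq,
                               desc = rep_len(as.character(desc), length(id)))
  data.table::setattr(ss, "class", c("seq_set", class(ss)))
  ss
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return a [seq_set()].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- names(x)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  seq_set(id = id, seq = as.character(x), desc = desc)
}

#' Write sequences as FASTA
#'
#' @param records a [seq_set()] (or anything with `id` and `seq` columns).
#' @param path output file.
#' @param wrap line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 70L) {
  x <- Biostrings::DNAStringSet(setNames(records$seq, records$id))
  if (!is.null(records$desc) && any(nzchar(records$desc)))
    names(x) <- ifelse(nzchar(records$desc),
                       paste(records$id, records$desc), records$id)
  Biostrings::writeXStringSet(x, path, width = max(1L, as.integer(wrap)))
  invisible(path)
}

#' Construct an annotation
#'
#' Coordinates are 0-based half-open on a declared sequence length.  A
#' feature wrapping the origin of a circular sequence is stored with
#' `wrap = TRUE` and `end` giving the post-origin endpoint (so `end <
#' start`); all other features satisfy `0 <= start < end <= seq_length`.
#'
#' @param features data.frame with columns gene_id, type (PCG, tRNA, rRNA
#'   or control_region), start, end, strand (+/-), and optionally wrap.
#' @param seq_length declared sequence length.
#' @param circular whether the sequence is circular.
#' @return a `mito_annotation` object.
#' @export
annotation <- function(features, seq_length, circular = TRUE) {
  f <- as.data.frame(features, stringsAsFactors = FALSE)
  if (is.null(f$wrap)) f$wrap <- rep(FALSE, nrow(f))
  stopifnot(all(c("gene_id", "type", "start", "end", "strand") %in% names(f)))
  if (anyDuplicated(f$gene_id)) stop("feature ids must be unique")
  if (!all(f$type %in% c("PCG", "tRNA", "rRNA", "control_region")))
    stop("unknown feature type")
  bad <- !f$wrap & !(f$start >= 0 & f$start < f$end & f$end <= seq_length)
  if (any(bad)) stop("feature coordinates out of bounds: ",
                     paste(f$gene_id[bad], collapse = ", "))
  if (any(f$wrap) && !circular) stop("wrap features require a circular sequence")
  structure(list(features = f, seq_length = as.integer(seq_length),
                 circular = isTRUE(circular)),
            class = "mito_annotation")
}

#' Feature length, wrap-aware
#' @param ann a [annotation()].
#' @return integer vector of feature lengths.
#' @export
feature_lengths <- function(ann) {
  f <- ann$features
  ifelse(f$wrap, ann$seq_length - f$start + f$end, f$end - f$start)
}

#' Extract oriented feature sequences
#'
#' Returns each feature's sequence on its coding strand (reverse
#' complemented for `-` features), following wrap-around features across
#' the origin of circular sequences.
#'
#' @param seq sequence string the annotation refers to.
#' @param ann a [annotation()].
#' @return named character vector of feature sequences.
#' @export
feature_seqs <- function(seq, ann) {
  f <- ann$features
  lens <- feature_lengths(ann)
  out <- character(nrow(f))
  for (i in seq_len(nrow(f))) {
    s <- circ_substr(seq, f$start[i], lens[i])
    out[i] <- if (f$strand[i] == "-") revcomp(s) else s
  }
  setNames(out, f$gene_id)
}

#' Read a GFF3 annotation
#'
#' GFF3 is 1-based inclusive on disk; in memory coordinates are 0-based
#' half-open.  A wrap-around feature is encoded on disk as two lines
#' sharing an `ID` (one ending at the sequence end, one starting at 1) and
#' is read back as a single feature with `wrap = TRUE`.
#'
#' @param path GFF3 file.
#' @param seq_length declared sequence length; taken from the
#'   `##sequence-region` directive when NULL.
#' @param circular whether the annotated sequence is circular.
#' @return a [annotation()].
#' @export
read_gff3 <- function(path, seq_length = NULL, circular = TRUE) {
  if (is.null(seq_length)) {
    hdr <- grep("^##sequence-region", readLines(path), value = TRUE)
    if (length(hdr))
      seq_length <- as.integer(strsplit(hdr[1], "\\s+")[[1]][4])
    else stop("seq_length not given and no ##sequence-region directive")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  if (any(df$end < df$start)) stop("GFF3 feature with end < start")
  ids <- if (!is.null(df$ID)) as.character(df$ID) else as.character(df$Name)
  type <- as.character(df$type)
  rows <- split(seq_len(nrow(df)), ids)
  feats <- lapply(names(rows), function(idv) {
    ix <- rows[[idv]]
    if (length(ix) == 1L) {
      data.frame(gene_id = idv, type = type[ix],
                 start = df$start[ix] - 1L, end = df$end[ix],
                 strand = as.character(df$strand[ix]), wrap = FALSE)
    } else if (length(ix) == 2L) {
      # wrap-around: the piece touching the sequence end holds the start
      a <- ix[which(df$end[ix] == seq_length)]
      b <- ix[which(df$start[ix] == 1L)]
      if (length(a) != 1L || length(b) != 1L)
        stop("two-line feature '", idv, "' does not wrap the origin")
      data.frame(gene_id = idv, type = type[a],
                 start = df$start[a] - 1L, end = df$end[b],
                 strand = as.character(df$strand[a]), wrap = TRUE)
    } else stop("feature '", idv, "' has more than two GFF lines")
  })
  f <- do.call(rbind, feats)
  f <- f[order(f$start, f$gene_id), , drop = FALSE]
  rownames(f) <- NULL
  annotation(f, seq_length = seq_length, circular = circular)
}

#' Write an annotation as GFF3
#'
#' @param ann a [annotation()].
#' @param path output file.
#' @param seqid sequence name used in column 1.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path, seqid = "mito") {
  f <- ann$features
  rows <- list()
  for (i in seq_len(nrow(f))) {
    if (!f$wrap[i]) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = f$start[i] + 1L, end = f$end[i], strand = f$strand[i],
        type = f$type[i], ID = f$gene_id[i])
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        start = f$start[i] + 1L, end = ann$seq_length, strand = f$strand[i],
        type = f$type[i], ID = f$gene_id[i])
      rows[[length(rows) + 1L]] <- data.frame(
        start = 1L, end = f$end[i], strand = f$strand[i],
        type = f$type[i], ID = f$gene_id[i])
    }
  }
  d <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = d$start, end = d$end),
    strand = d$strand, type = d$type, ID = d$ID)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", seqid, ann$seq_length))
  writeLines(lines, path)
  rtracklayer::export(gr, path, format = "gff3", append = TRUE)
  invisible(path)
}
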