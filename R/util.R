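#' Reverse complement
#'
#' @param x character vector of DNA sequences over {A,C,G,T,N}.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  cpp_revcomp(as.character(x))
}

#' Derive a named RNG substream seed
#'
#' All stochastic stages draw from substreams derived from one base seed so
#' that, e.g., the genome draw is unaffected by how many reads are later
#' simulated.  Kept below 2^31 - 1.
#'
#' @param seed integer base seed.
#' @param what substream name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, what) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(what)) * seq_along(utf8ToInt(as.character(what))))
  as.integer((as.numeric(seed) %% 97651L * 7919 + h * 104729 + 13) %% 2147483647)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Extract a substring of a circular sequence
#'
#' @param seq sequence string.
#' @param start 0-based start.
#' @param len substring length (may wrap past the end).
#' @return character substring.
#' @keywords internal
circ_substr <- function(seq, start, len) {
  L <- nchar(seq)
  start <- start %% L
  if (start + len <= L) return(substr(seq, start + 1, start + len))
  paste0(substr(seq, start + 1, L), circ_substr(seq, 0, len - (L - start)))
}

# vectorized circular substring (all same length)
circ_substr_vec <- function(seq, starts, len) {
  L <- nchar(seq)
  ext <- paste0(seq, substr(seq, 1, min(len, L)))
  starts <- starts %% L
  substring(ext, starts + 1, starts + len)
}

#' Identity between equal-length aligned strings
#' @keywords internal
string_identity <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0)
  av <- utf8ToInt(substr(a, 1, n))
  bv <- utf8ToInt(substr(b, 1, n))
  sum(av == bv) / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
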