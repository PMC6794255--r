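# Shared fixtures, built in code and cached per test run.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# small labelled default-world library (defaults scaled to one seed)
fx_default_world <- function(seed = 1) {
  fixture(paste0("default_", seed), function() {
    cfg <- sim_config(seed = seed)
    truth <- make_mitogenome(cfg)
    sim <- simulate_reads(truth, cfg)
    list(cfg = cfg, truth = truth, sim = sim)
  })
}

# mito-only, error-free, polycistron-dominated 30x world ("perfect data")
fx_perfect_world <- function(seed = 1) {
  fixture(paste0("perfect_", seed), function() {
    cfg <- sim_config(seed = seed, mito_fraction = 1, nuclear_fraction = 0,
                      contaminant_fraction = 0,
                      n_reads = round(30 * 16000 / 51), error_rate = 0,
                      polycistron_baseline = 1000)
    truth <- make_mitogenome(cfg)
    sim <- simulate_reads(truth, cfg)
    list(cfg = cfg, truth = truth, sim = sim)
  })
}

random_reads <- function(n, len, seed = 99) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# tile an interval of a sequence with error-free reads at a given depth
tile_reads <- function(seq, len = 51L, depth = 30, seed = 1) {
  set.seed(seed)
  L <- nchar(seq)
  n <- ceiling(depth * L / len)
  # terminal k-mers must clear the assembler's count floor, so the two
  # boundary reads are included twice
  starts <- c(0L, 0L, L - len, L - len,
              sample.int(L - len + 1L, n, replace = TRUE) - 1L)
  substring(seq, starts + 1L, starts + len)
}

# are two gene orders equal as circular sequences (up to rotation and,
# optionally, reversal)?
cyclic_order_equal <- function(a, b, allow_reversal = TRUE) {
  if (length(a) != length(b)) return(FALSE)
  da <- paste(c(a, a), collapse = "|")
  if (grepl(paste(b, collapse = "|"), da, fixed = TRUE)) return(TRUE)
  allow_reversal && grepl(paste(rev(b), collapse = "|"), da, fixed = TRUE)
}

phred_str <- function(q, n) strrep(intToUtf8(33 + q), n)
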