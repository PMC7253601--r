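# Independent oracles and small fixtures used across the suite.

# Naive position-by-position degenerate scanner, written independently of
# the package implementation (per-window character loop, own IUPAC and
# complement tables). Returns a data.frame(start, strand, mismatches) in
# 0-based coordinates.
naive_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), K = c("G", "T"), M = c("A", "C"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

naive_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTRYKMBVDH", "TGCAYRMKVBHD", s), "")[[1]]),
        collapse = "")
}

naive_scan_strand <- function(chars, iupac, max_mismatch, strand) {
  sets <- naive_iupac[strsplit(iupac, "")[[1]]]
  L <- length(sets)
  n <- length(chars)
  out <- list()
  if (n >= L) {
    for (i in seq_len(n - L + 1L)) {
      mm <- 0L
      for (j in seq_len(L)) {
        if (!chars[i + j - 1L] %in% sets[[j]]) mm <- mm + 1L
      }
      if (mm <= max_mismatch) {
        out[[length(out) + 1L]] <-
          data.frame(start = i - 1L, strand = strand, mismatches = mm)
      }
    }
  }
  do.call(rbind, c(out, list(data.frame(start = integer(0),
                                        strand = character(0),
                                        mismatches = integer(0)))))
}

naive_scan <- function(seq, iupac, max_mismatch = 0L) {
  chars <- strsplit(seq, "")[[1]]
  rbind(
    naive_scan_strand(chars, iupac, max_mismatch, "+"),
    naive_scan_strand(chars, naive_revcomp(iupac), max_mismatch, "-")
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_iupac <- function(n) {
  paste(sample(names(naive_iupac), n, replace = TRUE,
               prob = c(rep(4, 4), rep(2, 6), rep(1, 4), 2)),
        collapse = "")
}

# A noiseless model and a coarser schedule for fast simulations.
noiseless <- function() noise_model(0, 0, 0)
quick_schedule <- function(dt = 0.5) phase_schedule(dt = dt)

# Sorted (start, strand, mismatches) for comparing hit tables.
hit_key <- function(df) {
  df <- df[order(df$start, df$strand, df$mismatches), , drop = FALSE]
  paste(df$start, df$strand, df$mismatches, sep = ":", collapse = ";")
}
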