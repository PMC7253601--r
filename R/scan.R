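# Both-strand degenerate-motif scanning and per-promoter operator reports.

# Mismatch counts of a compiled pattern against every window of an
# integer-encoded sequence (1..4 for ACGT). Vectorised over windows.
window_mismatches <- function(idx, pattern) {
  L <- length(pattern)
  n <- length(idx)
  nw <- n - L + 1L
  if (nw < 1L) return(integer(0))
  allowed <- vapply(pattern$sets, function(set) {
    c("A", "C", "G", "T") %in% set
  }, logical(4)) # 4 x L
  mm <- integer(nw)
  for (j in seq_len(L)) {
    mm <- mm + !allowed[cbind(idx[j:(j + nw - 1L)], j)]
  }
  mm
}

encode_dna <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  if (anyNA(idx)) {
    stop(sprintf(
      "sequence contains non-ACGT character '%s' at position %d",
      chars[which(is.na(idx))[1]], which(is.na(idx))[1]
    ), call. = FALSE)
  }
  idx
}

#' Scan a DNA sequence for a degenerate operator motif
#'
#' Slides the pattern over every window of the subject on the requested
#' strand(s) and reports windows whose number of positions outside the
#' pattern's allowed sets is at most `max_mismatch`. Reverse-strand matches
#' are found by scanning with the reverse-complemented pattern, so all
#' coordinates are forward-strand, 0-based, half-open. Overlapping hits are
#' all reported; a window matching on both strands yields two hits.
#'
#' @param seq A single DNA string (A/C/G/T only; ambiguity codes in the
#'   subject are rejected).
#' @param pattern IUPAC string, preset name or `degenerate_pattern`.
#' @param max_mismatch Maximum mismatching positions per window
#'   (default 0).
#' @param strands `"both"` (default), `"forward"` or `"reverse"`.
#' @return A tibble with columns `start`, `end` (0-based, half-open),
#'   `strand` (`"+"`/`"-"`), `matched` (forward-strand subsequence) and
#'   `mismatches`, sorted by `start` then strand.
#' @export
#' @examples
#' scan_operators("GTGTAATTGACAAATGTAGATTTTGGA", "FAMILY_16")
scan_operators <- function(seq, pattern, max_mismatch = 0L,
                           strands = c("both", "forward", "reverse")) {
  strands <- match.arg(strands)
  stopifnot(is.character(seq), length(seq) == 1L)
  stopifnot(is.numeric(max_mismatch), max_mismatch >= 0)
  pattern <- compile_pattern(pattern)
  L <- length(pattern)
  seq <- toupper(seq)
  idx <- encode_dna(seq)

  hits <- list()
  if (strands %in% c("both", "forward")) {
    mm <- window_mismatches(idx, pattern)
    at <- which(mm <= max_mismatch)
    if (length(at) > 0L) {
      hits$fwd <- tibble::tibble(
        start = at - 1L, end = at - 1L + L, strand = "+",
        matched = substring(seq, at, at + L - 1L),
        mismatches = mm[at]
      )
    }
  }
  if (strands %in% c("both", "reverse")) {
    mm <- window_mismatches(idx, reverse_complement(pattern))
    at <- which(mm <= max_mismatch)
    if (length(at) > 0L) {
      hits$rev <- tibble::tibble(
        start = at - 1L, end = at - 1L + L, strand = "-",
        matched = substring(seq, at, at + L - 1L),
        mismatches = mm[at]
      )
    }
  }
  out <- if (length(hits) == 0L) {
    tibble::tibble(
      start = integer(0), end = integer(0), strand = character(0),
      matched = character(0), mismatches = integer(0)
    )
  } else {
    do.call(rbind, unname(hits))
  }
  out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
}

# Collapse overlapping windows to the leftmost hit: two overlapping windows
# are one physical site. Among hits at equal start, the fewest mismatches
# (then "+" strand) is kept.
collapse_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order(hits$start, hits$mismatches,
                     match(hits$strand, c("+", "-"))), , drop = FALSE]
  keep <- logical(nrow(hits))
  last_end <- -1L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- hits$end[i]
    }
  }
  hits[keep, , drop = FALSE]
}

#' Count operator occurrences in one promoter
#'
#' Scans the promoter on both strands, collapses overlapping windows to the
#' leftmost hit (one physical site), and summarises the result as the
#' operator count class used for panel classification: 0, 1 or 2 (where 2
#' means two or more). Inter-operator spacings are end-to-start gaps (bases
#' between the exclusive end of one collapsed hit and the start of the
#' next); `start_to_start = TRUE` reports start-to-start distances instead.
#'
#' @param promoter A `promoter_record` (see [generate_promoter()]), or a
#'   plain DNA string, or a list with elements `id` and `sequence`.
#' @param pattern IUPAC string, preset name or `degenerate_pattern`.
#' @param max_mismatch Maximum mismatches per window (default 0).
#' @param start_to_start Report start-to-start spacings instead of the
#'   default end-to-start gaps.
#' @return An object of class `operator_report`: list with `id`, `hits`
#'   (all hits), `sites` (collapsed hits with a `palindromic` flag),
#'   `count_class`, `spacings`.
#' @export
count_operators <- function(promoter, pattern, max_mismatch = 0L,
                            start_to_start = FALSE) {
  if (is.character(promoter) && length(promoter) == 1L) {
    promoter <- list(id = "seq", sequence = promoter)
  }
  stopifnot(!is.null(promoter$sequence))
  id <- if (is.null(promoter$id)) "seq" else promoter$id
  hits <- scan_operators(promoter$sequence, pattern, max_mismatch)
  sites <- collapse_hits(hits)
  sites$palindromic <- if (nrow(sites) > 0L) {
    is_palindromic(sites$matched)
  } else {
    logical(0)
  }
  spacings <- if (nrow(sites) >= 2L) {
    if (start_to_start) {
      diff(sites$start)
    } else {
      sites$start[-1L] - sites$end[-nrow(sites)]
    }
  } else {
    integer(0)
  }
  structure(
    list(
      id = id, hits = hits, sites = sites,
      count_class = min(nrow(sites), 2L),
      spacings = as.integer(spacings)
    ),
    class = "operator_report"
  )
}

#' @export
print.operator_report <- function(x, ...) {
  cat(sprintf(
    "<operator_report> %s: %d site(s) (class %d)%s\n",
    x$id, nrow(x$sites), x$count_class,
    if (length(x$spacings)) {
      sprintf(", spacing %s", paste(x$spacings, collapse = ","))
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Pooled inter-operator spacing distribution
#'
#' Pools the spacings of a list of [count_operators()] reports into a
#' histogram and reports its mode (ties broken toward the smaller gap).
#'
#' @param reports List of `operator_report` objects (or a single one).
#' @return An object of class `spacing_distribution`: list with `histogram`
#'   (named integer vector, gap -> count), `mode` (integer, `NA` when
#'   `n == 0`) and `n`.
#' @export
spacing_distribution <- function(reports) {
  if (inherits(reports, "operator_report")) reports <- list(reports)
  gaps <- unlist(lapply(reports, function(r) r$spacings), use.names = FALSE)
  if (length(gaps) == 0L) {
    return(structure(
      list(histogram = integer(0), mode = NA_integer_, n = 0L),
      class = "spacing_distribution"
    ))
  }
  tab <- table(gaps)
  counts <- as.integer(tab)
  vals <- as.integer(names(tab))
  mode <- min(vals[counts == max(counts)])
  structure(
    list(histogram = setNames(counts, vals), mode = mode,
         n = length(gaps)),
    class = "spacing_distribution"
  )
}

#' @export
print.spacing_distribution <- function(x, ...) {
  cat(sprintf("<spacing_distribution> n = %d, mode = %s\n", x$n,
              ifelse(is.na(x$mode), "NA", x$mode)))
  if (x$n > 0) print(x$histogram)
  invisible(x)
}

#' Classify a promoter panel by operator count
#'
#' Runs [count_operators()] over a panel and aggregates counts per class
#' (none / one / two-or-more), the pooled spacing distribution, and a
#' per-promoter table. Rows are ordered by promoter id.
#'
#' @param promoters List of `promoter_record`s (or id-named character
#'   vector of sequences).
#' @param pattern IUPAC string, preset name or `degenerate_pattern`.
#' @param max_mismatch Maximum mismatches per window (default 0).
#' @return List with `per_promoter` (tibble: id, n_hits, count_class,
#'   starts, strands, mismatches, spacings, palindromic), `class_counts`
#'   (named integer vector for classes "0", "1", "2") and `spacing`
#'   (a `spacing_distribution`).
#' @export
classify_panel <- function(promoters, pattern, max_mismatch = 0L) {
  if (is.character(promoters)) {
    ids <- names(promoters)
    if (is.null(ids)) ids <- sprintf("seq%03d", seq_along(promoters))
    promoters <- Map(function(id, s) list(id = id, sequence = s),
                     ids, promoters)
  }
  reports <- lapply(promoters, count_operators, pattern = pattern,
                    max_mismatch = max_mismatch)
  ids <- vapply(reports, function(r) r$id, character(1))
  reports <- reports[order(ids)]
  per <- do.call(rbind, lapply(reports, function(r) {
    tibble::tibble(
      id = r$id,
      n_hits = nrow(r$sites),
      count_class = r$count_class,
      starts = paste(r$sites$start, collapse = ","),
      strands = paste(r$sites$strand, collapse = ","),
      mismatches = paste(r$sites$mismatches, collapse = ","),
      spacings = paste(r$spacings, collapse = ","),
      palindromic = paste(substr(as.character(r$sites$palindromic), 1, 1),
                          collapse = ",")
    )
  }))
  if (is.null(per)) {
    per <- tibble::tibble(
      id = character(0), n_hits = integer(0), count_class = integer(0),
      starts = character(0), strands = character(0),
      mismatches = character(0), spacings = character(0),
      palindromic = character(0)
    )
  }
  cls <- factor(per$count_class, levels = 0:2)
  list(
    per_promoter = per,
    class_counts = setNames(as.integer(table(cls)), c("0", "1", "2")),
    spacing = spacing_distribution(reports)
  )
}
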