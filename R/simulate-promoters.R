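# Synthetic promoter panels with planted operator instances.

#' Discrete triangular gap sampler
#'
#' Sampler for inter-operator gaps: a discrete triangular distribution on
#' `min..max` peaked at `mode`, emulating the observed spacing of paired
#' operators (most 24-39 bases apart, mode 26). Weights rise linearly from
#' `min` to `mode` and fall linearly from `mode` to `max`, with weight 1 at
#' the mode on both arms.
#'
#' @param min,mode,max Integer support and peak (default 24, 26, 39).
#' @return A function `f(n, seed = NULL)` drawing `n` gaps; its `weights`
#'   attribute holds the normalised probabilities.
#' @export
triangular_gap_sampler <- function(min = 24L, mode = 26L, max = 39L) {
  stopifnot(min <= mode, mode <= max)
  g <- seq.int(min, max)
  w <- ifelse(g <= mode,
              (g - min + 1) / (mode - min + 1),
              (max - g + 1) / (max - mode + 1))
  w <- w / sum(w)
  f <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    sample(g, n, replace = TRUE, prob = w)
  }
  attr(f, "weights") <- setNames(w, g)
  f
}

# Scan both strands and check the hits are exactly the planted ones: the
# set of distinct hit starts equals the planted starts, and each planted
# strand is present at its start.
matches_ground_truth <- function(sequence, pattern, truth) {
  hits <- scan_operators(sequence, pattern, max_mismatch = 0L)
  if (!setequal(unique(hits$start), truth$start)) return(FALSE)
  for (i in seq_len(nrow(truth))) {
    at <- hits$strand[hits$start == truth$start[i]]
    if (!truth$strand[i] %in% at) return(FALSE)
  }
  TRUE
}

#' Generate a promoter with a known number of planted operators
#'
#' Builds a random-background sequence (uniform A/C/G/T) of length
#' `length` carrying exactly `n_operators` concrete instances drawn from
#' `pattern` (reverse-complemented when planted on the minus strand), with
#' an end-to-start gap of `gap` bases between the two instances when
#' `n_operators = 2`. The whole record is rejection-sampled until a
#' both-strand zero-mismatch scan recovers exactly the planted sites — so
#' the ground truth is exact by construction, with no spurious matches.
#'
#' @param length Sequence length (default 100, an upstream promoter
#'   region).
#' @param n_operators 0, 1 or 2 planted instances.
#' @param gap End-to-start gap in bases between two planted operators;
#'   either an integer or a sampler function `f(n)` (see
#'   [triangular_gap_sampler()], the default when `NULL` and
#'   `n_operators = 2`).
#' @param strand_choice `"random"` (default), `"+"` or `"-"`, applied
#'   independently per instance.
#' @param pattern IUPAC string, preset name or `degenerate_pattern`
#'   (default `FAMILY_16`).
#' @param seed Integer seed.
#' @param id Promoter identifier.
#' @param max_attempts Rejection-sampling cap (default 10000) before
#'   erroring.
#' @return A `promoter_record`: list with `id`, `sequence`,
#'   `ground_truth` (tibble: start, strand, instance; 0-based starts),
#'   `gap` and `seed`.
#' @export
generate_promoter <- function(length = 100L, n_operators = 1L, gap = NULL,
                              strand_choice = c("random", "+", "-"),
                              pattern = "FAMILY_16", seed = 1L,
                              id = "promoter", max_attempts = 10000L) {
  strand_choice <- match.arg(strand_choice)
  stopifnot(n_operators %in% 0:2)
  pattern <- compile_pattern(pattern)
  L <- length(pattern)
  set.seed(as.integer(seed %% .Machine$integer.max))

  gap_val <- NA_integer_
  if (n_operators == 2L) {
    if (is.null(gap)) gap <- triangular_gap_sampler()
    gap_val <- if (is.function(gap)) as.integer(gap(1L)) else as.integer(gap)
    if (gap_val < 0L) stop("gap must be >= 0", call. = FALSE)
  }
  span <- n_operators * L + ifelse(n_operators == 2L, gap_val, 0L)
  if (span > length) {
    stop(sprintf(
      "infeasible geometry: %d operator(s) of %d nt with gap %s exceed length %d",
      n_operators, L, ifelse(is.na(gap_val), "0", gap_val), length
    ), call. = FALSE)
  }

  bases <- c("A", "C", "G", "T")
  for (attempt in seq_len(max_attempts)) {
    chars <- sample(bases, length, replace = TRUE)
    truth <- tibble::tibble(start = integer(0), strand = character(0),
                            instance = character(0))
    if (n_operators > 0L) {
      offset <- sample.int(length - span + 1L, 1L) - 1L
      starts <- if (n_operators == 2L) {
        c(offset, offset + L + gap_val)
      } else {
        offset
      }
      for (s in starts) {
        strand <- switch(strand_choice,
                         random = sample(c("+", "-"), 1L),
                         strand_choice)
        inst <- sample_from_pattern(pattern)
        planted <- if (strand == "+") inst else reverse_complement(inst)
        chars[(s + 1L):(s + L)] <- strsplit(planted, "", fixed = TRUE)[[1]]
        truth <- rbind(truth, tibble::tibble(
          start = as.integer(s), strand = strand, instance = inst
        ))
      }
    }
    sequence <- paste(chars, collapse = "")
    if (matches_ground_truth(sequence, pattern, truth)) {
      return(structure(
        list(id = id, sequence = sequence, ground_truth = truth,
             gap = gap_val, seed = seed),
        class = "promoter_record"
      ))
    }
  }
  stop(sprintf("no spurious-match-free record found in %d attempts",
               max_attempts), call. = FALSE)
}

#' @export
print.promoter_record <- function(x, ...) {
  cat(sprintf(
    "<promoter_record> %s [%d nt], %d planted operator(s)%s\n",
    x$id, nchar(x$sequence), nrow(x$ground_truth),
    if (!is.na(x$gap)) sprintf(", gap %d", x$gap) else ""
  ))
  invisible(x)
}

#' Generate a promoter panel with a fixed class composition
#'
#' A panel of [generate_promoter()] records: `composition` gives the number
#' of promoters carrying two, one and zero operators (the default 67/14/7
#' mirrors the observed homolog panel of 88 upstream regions). Gaps of
#' two-operator records are drawn from `gap_sampler`.
#'
#' @param composition Named counts for classes `"2"`, `"1"`, `"0"`.
#' @param gap_sampler Function `f(n)` drawing gaps (default
#'   [triangular_gap_sampler()]).
#' @param pattern IUPAC string, preset name or `degenerate_pattern`.
#' @param length Promoter length (default 100).
#' @param seed Integer master seed; per-record sub-seeds are derived
#'   deterministically.
#' @return List of `promoter_record`s (ids `P001`, `P002`, ...; class-2
#'   records first, then class-1, then class-0).
#' @export
generate_panel <- function(composition = c("2" = 67L, "1" = 14L, "0" = 7L),
                           gap_sampler = triangular_gap_sampler(),
                           pattern = "FAMILY_16", length = 100L,
                           seed = 1L) {
  stopifnot(all(names(composition) %in% c("0", "1", "2")),
            all(composition >= 0))
  pattern <- compile_pattern(pattern)
  classes <- rep(
    as.integer(names(composition)),
    times = as.integer(composition)
  )
  lapply(seq_along(classes), function(i) {
    sub_seed <- (as.numeric(seed) * 10007 + i * 104729) %%
      .Machine$integer.max
    generate_promoter(
      length = length, n_operators = classes[i],
      gap = if (classes[i] == 2L) gap_sampler else NULL,
      pattern = pattern, seed = sub_seed,
      id = sprintf("P%03d", i)
    )
  })
}
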