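# IUPAC degenerate patterns: compilation, complementation, palindromy.
#
# Coordinates everywhere in this package are 0-based, half-open, on the
# forward strand.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), K = c("G", "T"), M = c("A", "C"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", K = "M", M = "K", S = "S", W = "W",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Named consensus operator presets
#'
#' The operator consensus strings for the CopR-CopY copper-operon repressor
#' family that this package ships as named presets:
#'
#' * `OLD_CORE` (`KACANNTGTA`): the historical 10-base "cop box" core,
#'   necessary but not sufficient for repressor binding.
#' * `MINIMAL_16` (`ATTGACAAATGTAGAT`): the concrete 16-base minimal
#'   operator sufficient for pneumococcal CopY binding.
#' * `PNEUMO_16` (`RNYKACAAATGTMRNY`): the degenerate 16-base pneumococcal
#'   operator consensus.
#' * `INTERMEDIATE_16` (`RNYKACANNTGTARNY`): the purine-N-pyrimidine
#'   flanked consensus proposed from the homolog alignment.
#' * `FAMILY_16` (`RNYKACANNYGTMRNY`): the family-wide consensus covering
#'   cross-species binding.
#'
#' @return Named character vector of IUPAC strings.
#' @export
#' @examples
#' operator_presets()["FAMILY_16"]
operator_presets <- function() {
  c(
    OLD_CORE        = "KACANNTGTA",
    MINIMAL_16      = "ATTGACAAATGTAGAT",
    PNEUMO_16       = "RNYKACAAATGTMRNY",
    INTERMEDIATE_16 = "RNYKACANNTGTARNY",
    FAMILY_16       = "RNYKACANNYGTMRNY"
  )
}

#' Compile a degenerate IUPAC motif
#'
#' Turns an IUPAC nucleotide string (or the name of a shipped preset, see
#' [operator_presets()]) into a compiled pattern: a list of per-position
#' allowed base sets used by [scan_operators()] and the synthetic-promoter
#' generators. Case-insensitive.
#'
#' @param iupac IUPAC DNA string (alphabet `ACGTRYKMSWBDHVN`) or a preset
#'   name such as `"FAMILY_16"`.
#' @return An object of class `degenerate_pattern` with fields `iupac`,
#'   `sets` (list of character vectors) and `name` (preset name or `NA`).
#' @export
#' @examples
#' p <- compile_pattern("KACANNTGTA")
#' p$sets[[1]] # G or T
compile_pattern <- function(iupac) {
  if (inherits(iupac, "degenerate_pattern")) {
    return(iupac)
  }
  stopifnot(is.character(iupac), length(iupac) == 1L)
  name <- NA_character_
  presets <- operator_presets()
  if (iupac %in% names(presets)) {
    name <- iupac
    iupac <- presets[[iupac]]
  }
  iupac <- toupper(iupac)
  if (nchar(iupac) < 1L) {
    stop("pattern must contain at least one symbol", call. = FALSE)
  }
  chars <- strsplit(iupac, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad) > 0L) {
    stop(sprintf(
      "invalid IUPAC symbol '%s' at position %d", chars[bad[1]], bad[1]
    ), call. = FALSE)
  }
  structure(
    list(iupac = iupac, sets = IUPAC_SETS[chars], name = name),
    class = "degenerate_pattern"
  )
}

#' @export
length.degenerate_pattern <- function(x) nchar(x$iupac)

#' @export
print.degenerate_pattern <- function(x, ...) {
  nm <- if (is.na(x$name)) "" else sprintf(" (%s)", x$name)
  cat(sprintf("<degenerate_pattern%s> %s [%d nt]\n", nm, x$iupac, length(x)))
  invisible(x)
}

#' Reverse complement of a DNA sequence or degenerate pattern
#'
#' Degenerate symbols complement as R-Y, K-M, B-V, D-H; S, W and N are
#' self-complementary. An involution: applying it twice returns the input.
#'
#' @param x A character vector of DNA/IUPAC strings, or a
#'   `degenerate_pattern`.
#' @return Same kind as the input.
#' @export
#' @examples
#' reverse_complement("TACA") # "TGTA"
reverse_complement <- function(x) {
  if (inherits(x, "degenerate_pattern")) {
    return(compile_pattern(reverse_complement(x$iupac)))
  }
  stopifnot(is.character(x))
  vapply(x, function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    comp <- IUPAC_COMPLEMENT[chars]
    if (anyNA(comp)) {
      stop("sequence contains non-IUPAC characters", call. = FALSE)
    }
    paste(rev(comp), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Is a DNA site palindromic?
#'
#' A DNA palindrome equals its own reverse complement (so only even-length
#' sites can be palindromic).
#'
#' @param site Character vector of ACGT strings.
#' @return Logical vector.
#' @export
#' @examples
#' is_palindromic("TACATATGTA") # TRUE
is_palindromic <- function(site) {
  stopifnot(is.character(site))
  site <- toupper(site)
  ok <- grepl("^[ACGT]*$", site)
  if (!all(ok)) stop("site must contain only A, C, G, T", call. = FALSE)
  vapply(site, function(s) {
    nchar(s) > 0L && s == reverse_complement(s)
  }, logical(1), USE.NAMES = FALSE)
}

#' Draw one concrete instance from a degenerate pattern
#'
#' Samples, independently and uniformly at each position, one base from the
#' pattern's allowed set. Any draw matches the pattern with zero mismatches
#' by construction.
#'
#' @param pattern IUPAC string, preset name or `degenerate_pattern`.
#' @param seed Optional integer seed for reproducibility.
#' @return A single ACGT string of the pattern's length.
#' @export
sample_from_pattern <- function(pattern, seed = NULL) {
  pattern <- compile_pattern(pattern)
  if (!is.null(seed)) set.seed(seed)
  paste(
    vapply(pattern$sets, function(set) set[sample.int(length(set), 1L)],
           character(1)),
    collapse = ""
  )
}
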