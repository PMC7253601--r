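# Readers and writers: long-format sensorgram CSV, promoter FASTA with a
# ground-truth sidecar TSV, and report TSVs. Every delimited output starts
# with '#' header comments carrying the tool version, a config hash and the
# seed, so a run can be traced from its files.

output_header <- function(seed = NULL, config = NULL) {
  c(
    sprintf("# coperator v%s", as.character(packageVersion("coperator"))),
    sprintf("# config_hash: %s",
            rlang::hash(if (is.null(config)) list() else config)),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else format(seed))
  )
}

write_commented_table <- function(x, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, config), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read sensorgrams as long-format CSV
#'
#' Columns: `sensor_id`, `conc_nM`, `phase`, `t_s`, `response`. Header
#' comment lines (starting `#`) carry the package version, config hash and
#' seed. Numeric values round-trip to at least 12 significant digits.
#'
#' @param set A `sensorgram_set` tibble.
#' @param path Output/input file path.
#' @param seed,config Optional provenance recorded in the header.
#' @return `write_sensorgrams` returns `path` invisibly;
#'   `read_sensorgrams` returns the sensorgram tibble (with
#'   `is_reference` recomputed from `conc_nM`).
#' @export
write_sensorgrams <- function(set, path, seed = NULL, config = NULL) {
  out <- set[, c("sensor_id", "conc_nM", "phase", "t_s", "response")]
  writeLines(output_header(seed, config), path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_sensorgrams
#' @export
read_sensorgrams <- function(path) {
  out <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      sensor_id = readr::col_character(),
      conc_nM = readr::col_double(),
      phase = readr::col_character(),
      t_s = readr::col_double(),
      response = readr::col_double()
    )
  )
  if (nrow(out) == 0L) stop("no sensorgram rows in ", path, call. = FALSE)
  out$is_reference <- out$conc_nM == 0
  out[, c("sensor_id", "conc_nM", "is_reference", "phase", "t_s",
          "response")]
}

#' Write / read a promoter panel as FASTA (+ ground-truth TSV)
#'
#' Sequences go to a standard multi-record FASTA (wrapped lines and mixed
#' case are accepted on reading); the planted ground truth goes to a
#' sidecar TSV with columns `id`, `n_operators`, `positions` (0-based,
#' comma-separated), `strands` and `gap`.
#'
#' @param panel List of `promoter_record`s.
#' @param path FASTA path.
#' @param truth_path Optional sidecar TSV path.
#' @param seed,config Optional provenance for the sidecar header.
#' @return `write_promoter_fasta` returns `path` invisibly;
#'   `read_promoter_fasta` returns a tibble `id`, `sequence` (upper-case).
#' @export
write_promoter_fasta <- function(panel, path, truth_path = NULL,
                                 seed = NULL, config = NULL) {
  seqs <- Biostrings::DNAStringSet(
    setNames(
      vapply(panel, function(p) p$sequence, character(1)),
      vapply(panel, function(p) p$id, character(1))
    )
  )
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  if (!is.null(truth_path)) {
    truth <- do.call(rbind, lapply(panel, function(p) {
      tibble::tibble(
        id = p$id,
        n_operators = nrow(p$ground_truth),
        positions = paste(p$ground_truth$start, collapse = ","),
        strands = paste(p$ground_truth$strand, collapse = ","),
        gap = ifelse(is.na(p$gap), "", as.character(p$gap))
      )
    }))
    write_commented_table(truth, truth_path, seed = seed, config = config)
  }
  invisible(path)
}

#' @rdname write_promoter_fasta
#' @export
read_promoter_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tibble::tibble(
    id = names(seqs),
    sequence = unname(toupper(as.character(seqs)))
  )
}
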