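# Printed reference sequences shipped as in-code fixtures.

#' Tested candidate operator 27-mers with their binding outcome
#'
#' The 18 double-stranded 27-base fragments assayed for CopR/CopY binding:
#' candidate sites upstream of copper-regulated genes in Lactococcus lactis
#' and Streptococcus pneumoniae, plus the pneumococcal proximal and distal
#' cop-operon operators. `binding` records the experimental outcome
#' (`"Yes"`/`"No"`). Scanning these fragments with the `FAMILY_16`
#' consensus separates the two outcomes perfectly.
#'
#' @return Tibble with columns `organism`, `gene`, `sequence`, `binding`.
#' @export
#' @examples
#' sum(candidate_operator_sites()$binding == "Yes") # 9
candidate_operator_sites <- function() {
  tibble::tribble(
    ~organism, ~gene, ~sequence, ~binding,
    "Lactococcus lactis", "ytjD1", "AAATAGTTTACAAGTGTAAATTTATTT", "Yes",
    "Lactococcus lactis", "ydiD", "AAAATGTTTACATGTGTAAATTTTCAC", "Yes",
    "Lactococcus lactis", "copR", "TTAGTGTTTACACGTGTAAACTTATCT", "Yes",
    "Lactococcus lactis", "copB", "TGATAGTTTACAATTGTAAACTATATA", "Yes",
    "Lactococcus lactis", "yahC", "TTTTCGTTTACAATTGTAAACATAGAA", "Yes",
    "Lactococcus lactis", "lctO", "CTATCATCTACAGATGTAAACTTTATA", "Yes",
    "Lactococcus lactis", "ytjD2", "GATAAGATTACATATGTAAACAATAAA", "Yes",
    "Lactococcus lactis", "yfhF", "TAAGTATATACATCTGTAAAACTGAAA", "No",
    "Lactococcus lactis", "yxdE", "TTTGCTATTACACTTGTATCACATAAA", "No",
    "Streptococcus pneumoniae", "Sp_0090_1", "TGATTTAGGACATTTGTTTGATAGTGG", "No",
    "Streptococcus pneumoniae", "Sp_0090_2", "GAGTATACTAATAATGTAATCGTTATC", "No",
    "Streptococcus pneumoniae", "Sp_0045", "GGTGAACTAACAGATGTTTACGAAATT", "No",
    "Streptococcus pneumoniae", "Sp_0530", "ATTTGAGGAACAAATGTACGTTTATAA", "No",
    "Streptococcus pneumoniae", "Sp_1433", "GTAATTATAACAGATGTATAATAGAAA", "No",
    "Streptococcus pneumoniae", "Sp_1863", "ATGAATAAAACAATTGTAACACTCATC", "No",
    "Streptococcus pneumoniae", "Sp_2073", "AAGGCGGAAACATGTGTCAATGACTTG", "No",
    "Streptococcus pneumoniae", "CopY_proximal", "GTGTAATTGACAAATGTAGATTTTGGA", "Yes",
    "Streptococcus pneumoniae", "CopY_distal", "CTATAATTGACAAATGTAGATTTTAAG", "Yes"
  )
}

#' The 61-base pneumococcal cop-operon promoter fragment
#'
#' The double-stranded fragment used in gel-shift binding assays; it
#' carries both the distal and the proximal operator, 24 bases apart
#' (end-to-start), so a `FAMILY_16` scan finds two sites at 0-based starts
#' 2 and 42.
#'
#' @return A single 61-nt character string.
#' @export
cop_promoter_61mer <- function() {
  "TAATTGACAAATGTAGATTTTAAGAGTATACTGATGAGTGTAATTGACAAATGTAGATTTT"
}
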