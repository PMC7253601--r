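test_that("scan_operators finds the printed operator sites", {
  proximal <- "GTGTAATTGACAAATGTAGATTTTGGA"
  hits <- scan_operators(proximal, "FAMILY_16", strands = "forward")
  expect_identical(hits$start, 5L)
  expect_identical(hits$end, 21L)
  expect_identical(hits$matched, "ATTGACAAATGTAGAT")

  expect_identical(nrow(scan_operators("TAAGTATATACATCTGTAAAACTGAAA",
                                       "FAMILY_16")), 0L)

  # shorter than the pattern
  expect_identical(nrow(scan_operators("ACGT", "FAMILY_16")), 0L)

  # one base variation from the 10-base core
  hits <- scan_operators("TGATTTAGGACATTTGTTTGATAGTGG", "OLD_CORE",
                         max_mismatch = 1)
  expect_true(any(hits$start == 8L & hits$strand == "+" &
                    hits$mismatches == 1L))
  expect_identical(substr("TGATTTAGGACATTTGTTTGATAGTGG", 9, 18),
                   "GACATTTGTT")
})

test_that("subject sequences must be pure ACGT", {
  expect_error(scan_operators("ACGTNACGT", "OLD_CORE"), "non-ACGT")
  expect_error(scan_operators("ACGT-ACGT", "OLD_CORE"), "position 5")
})

test_that("scan_operators equals the naive oracle on random cases", {
  set.seed(11)
  for (i in 1:200) {
    s <- random_dna(sample(10:200, 1))
    p <- random_iupac(sample(3:20, 1))
    mm <- sample(0:2, 1)
    got <- scan_operators(s, p, max_mismatch = mm)
    want <- naive_scan(s, p, max_mismatch = mm)
    expect_identical(hit_key(got), hit_key(want))
  }
})

test_that("strand symmetry identities hold", {
  set.seed(23)
  for (i in 1:40) {
    s <- random_dna(sample(30:120, 1))
    p <- random_iupac(sample(4:12, 1))
    both <- scan_operators(s, p)
    fwd <- scan_operators(s, p, strands = "forward")
    rev <- scan_operators(s, p, strands = "reverse")

    # both = forward scan with pattern + forward scan with rc(pattern)
    rc_fwd <- scan_operators(s, reverse_complement(compile_pattern(p)),
                             strands = "forward")
    expect_identical(sort(rev$start), sort(rc_fwd$start))
    expect_identical(nrow(both), nrow(fwd) + nrow(rev))

    # scanning the reverse complement mirrors coordinates: start -> L - end
    L <- nchar(s)
    mirrored <- scan_operators(reverse_complement(s), p)
    expect_identical(sort(L - both$end), sort(mirrored$start))
  }
})

test_that("hits at a lower mismatch allowance are a subset of higher", {
  set.seed(31)
  for (i in 1:25) {
    s <- random_dna(120)
    p <- random_iupac(8)
    for (k in 0:1) {
      lo <- scan_operators(s, p, max_mismatch = k)
      hi <- scan_operators(s, p, max_mismatch = k + 1)
      key <- function(d) paste(d$start, d$strand)
      expect_true(all(key(lo) %in% key(hi)))
    }
  }
})

test_that("scan_operators agrees with Biostrings on degenerate matching", {
  set.seed(47)
  for (i in 1:20) {
    s <- random_dna(150)
    p <- random_iupac(10)
    mm <- sample(0:2, 1)
    got <- scan_operators(s, p, max_mismatch = mm, strands = "forward")
    ref <- Biostrings::matchPattern(
      p, Biostrings::DNAString(s),
      max.mismatch = mm, fixed = "subject"
    )
    # keep only alignments fully inside the subject (matchPattern also
    # reports windows hanging off the edges at max.mismatch > 0)
    starts <- BiocGenerics::start(ref) - 1L
    ends <- BiocGenerics::end(ref)
    inside <- starts >= 0L & ends <= nchar(s)
    expect_identical(sort(got$start), sort(starts[inside]))
  }
})

test_that("count_operators summarises the two-operator cop fragment", {
  rep61 <- count_operators(cop_promoter_61mer(), "FAMILY_16")
  expect_identical(rep61$count_class, 2L)
  expect_identical(sort(rep61$sites$start), c(2L, 42L))
  expect_identical(rep61$spacings, 24L)

  # start-to-start option differs by the pattern length
  s2s <- count_operators(cop_promoter_61mer(), "FAMILY_16",
                         start_to_start = TRUE)
  expect_identical(s2s$spacings, 40L)

  none <- count_operators("GGGGGGGGGGGGGGGGGGGGGGGG", "FAMILY_16")
  expect_identical(none$count_class, 0L)
  expect_length(none$spacings, 0L)

  single <- generate_promoter(n_operators = 1, seed = 5, id = "one")
  rep1 <- count_operators(single, "FAMILY_16")
  expect_identical(rep1$count_class, 1L)
  expect_length(rep1$spacings, 0L)
})

test_that("overlapping windows collapse to one physical site", {
  # "AA" matches AAAA at starts 0,1,2 (+); collapsed to starts 0 and 2
  rep <- count_operators("AAAAG", "AA")
  expect_identical(nrow(rep$hits), 3L)
  expect_identical(rep$sites$start, c(0L, 2L))
  expect_identical(rep$count_class, 2L)
  expect_identical(rep$spacings, 0L)
})

test_that("spacing_distribution pools gaps and reports the modal gap", {
  mk <- function(sp) structure(list(spacings = sp), class = "operator_report")
  d <- spacing_distribution(list(mk(c(26L, 26L)), mk(30L)))
  expect_identical(d$mode, 26L)
  expect_identical(d$n, 3L)
  expect_identical(sum(d$histogram), 3L)

  empty <- spacing_distribution(list(mk(integer(0))))
  expect_identical(empty$n, 0L)
  expect_true(is.na(empty$mode))

  # ties break toward the smaller gap
  tie <- spacing_distribution(list(mk(c(24L, 31L))))
  expect_identical(tie$mode, 24L)
})

test_that("classify_panel separates binders from non-binders in the printed sites", {
  t2 <- candidate_operator_sites()
  res <- classify_panel(setNames(t2$sequence, t2$gene), "FAMILY_16")
  expect_identical(nrow(res$per_promoter), 18L)
  per <- res$per_promoter
  has_hit <- setNames(per$n_hits >= 1L, per$id)
  expect_identical(unname(has_hit[t2$gene]), t2$binding == "Yes")
  expect_identical(sum(has_hit), 9L)

  empty <- classify_panel(character(0), "FAMILY_16")
  expect_identical(nrow(empty$per_promoter), 0L)
  expect_identical(unname(empty$class_counts), c(0L, 0L, 0L))
})
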