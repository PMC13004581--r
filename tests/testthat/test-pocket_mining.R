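spec_qrqy <- function(id = "ref") pocket_spec(id, c(1, 2, 3, 4), c("Q", "R", "Q", "Y"))

test_that("reference positions map through gaps to the right columns", {
  aln <- aa_alignment(c("ref", "m1"), c("QRQY", "QAQY"))
  sp <- spec_qrqy()
  expect_identical(map_reference_positions(aln, pocket_spec("ref", c(1, 3), c("Q", "Q"))),
                   c(1L, 3L))

  aln2 <- aa_alignment(c("ref", "m1"), c("A-CD", "ABCD"))
  expect_identical(map_reference_positions(aln2, pocket_spec("ref", 2, "C")), 3L)

  expect_error(map_reference_positions(aln2, pocket_spec("ref", 9, "C")),
               "position 9")
  expect_error(map_reference_positions(aln2, pocket_spec("nope", 1, "A")),
               "nope")
})

test_that("mapped columns agree with a brute-force ungap walk", {
  for (s in 1:25) {
    set.seed(s)
    chars <- sample(c("A", "C", "G", "-"), 40, replace = TRUE,
                    prob = c(0.3, 0.3, 0.2, 0.2))
    if (sum(chars != "-") < 5) chars[1:5] <- "A"
    ref <- paste(chars, collapse = "")
    n_ungapped <- sum(chars != "-")
    positions <- sort(sample(n_ungapped, 3))
    # brute force: walk the aligned string counting non-gaps
    expected <- integer(3)
    for (k in seq_along(positions)) {
      cnt <- 0L
      for (col in seq_along(chars)) {
        if (chars[col] != "-") cnt <- cnt + 1L
        if (cnt == positions[k]) { expected[k] <- col; break }
      }
    }
    aln <- aa_alignment("ref", ref)
    sp <- pocket_spec("ref", positions, rep("A", 3))
    expect_identical(map_reference_positions(aln, sp), expected)
  }
})

test_that("pocket table counts exact matches, with gaps never matching", {
  aln <- aa_alignment(c("ref", "same", "gaps", "two"),
                      c("QRQY", "QRQY", "----", "QR-F"))
  tab <- extract_pocket_table(aln, spec_qrqy())
  expect_equal(tab$n_matches, c(4L, 4L, 0L, 2L))
  # ambiguity codes never match
  aln2 <- aa_alignment(c("ref", "amb"), c("QRQY", "XBZQ"))
  expect_equal(extract_pocket_table(aln2, spec_qrqy())$n_matches[2], 0L)
})

test_that("pocket table is invariant to all-gap columns outside pocket columns", {
  aln <- aa_alignment(c("ref", "m1", "m2"), c("QRQYA", "QAQFD", "FRQYC"))
  tab <- extract_pocket_table(aln, spec_qrqy())
  # insert an all-gap column between pocket columns 2 and 3
  pad <- function(s) paste0(substr(s, 1, 2), "-", substr(s, 3, 5))
  aln_pad <- aa_alignment(aln$member_id, vapply(aln$aligned_seq, pad, ""))
  tab_pad <- extract_pocket_table(aln_pad, spec_qrqy())
  expect_equal(tab$n_matches, tab_pad$n_matches)
  expect_equal(tab$pos_3, tab_pad$pos_3)
})

test_that("filter_members is monotone and respects the threshold", {
  sp <- pocket_spec("ref", c(10, 20, 30, 40), c("Q", "R", "Q", "Y"))
  aln <- gen_alignment(20, sp,
                       match_counts = c(rep(3, 5), rep(1, 15)),
                       seed = 42)
  tab <- extract_pocket_table(aln, sp)
  expect_error(filter_members(tab, -1), "non-negative")
  expect_identical(filter_members(tab, 0), tab$member_id)
  expect_length(filter_members(tab, 5), 0)
  got <- filter_members(tab, 2)
  expect_setequal(got, c("ref", attr(aln, "truth")$member_ids[1:5]))
  # monotone subset chain
  prev <- filter_members(tab, 0)
  for (k in 1:4) {
    cur <- filter_members(tab, k)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("residue distribution tallies codes and gaps over all members", {
  aln <- aa_alignment(c("ref", paste0("m", 1:5)),
                      c("QRQY", "QRQY", "QRQF", "QRQF", "FRQY", "-RQY"))
  tab <- extract_pocket_table(aln, spec_qrqy())
  d1 <- residue_distribution(tab, 1)
  expect_equal(sum(d1), 6)
  expect_equal(unname(d1["Q"]), 4)
  expect_equal(unname(d1["F"]), 1)
  expect_equal(unname(d1["-"]), 1)
  d2 <- residue_distribution(tab, 2)
  expect_equal(unname(d2["R"]), 6)
  expect_error(residue_distribution(tab, 5), "out of range")
})

test_that("hydrophobic candidate screen selects exactly the planted member", {
  sp <- pocket_spec("ref", c(69, 96, 183, 203), c("Q", "R", "Q", "Y"))
  flags <- rep(FALSE, 50); flags[17] <- TRUE
  aln <- gen_alignment(50, sp, match_counts = rep(2, 50),
                       candidate_flags = flags,
                       candidate_positions = c(69, 203), seed = 9,
                       ref_length = 210)
  tab <- extract_pocket_table(aln, sp)
  cand <- rank_hydrophobic_candidates(tab, c(69, 203))
  expect_equal(cand$member_id, "member_017")
  expect_true(all(c(cand$pos_69, cand$pos_203) %in% HYDROPHOBIC_SET))
  expect_error(rank_hydrophobic_candidates(tab, c(69, 203),
                                           hydrophobic_set = character()),
               "non-empty")
  # a polar residue at either position excludes the member
  aln2 <- aa_alignment(c("ref", "mF", "mQ"), c("QRQY", "FRQV", "QRQV"))
  tab2 <- extract_pocket_table(aln2, spec_qrqy())
  cand2 <- rank_hydrophobic_candidates(tab2, c(1, 4))
  expect_equal(cand2$member_id, "mF")
})

test_that("mining round-trips planted match counts over many seeds", {
  sp <- pocket_spec("ref", c(5, 12, 19, 26), c("Q", "R", "Q", "Y"))
  for (s in 1:100) {
    aln <- gen_alignment(12, sp, seed = s, ref_length = 30)
    tab <- extract_pocket_table(aln, sp)
    expect_equal(tab$n_matches[-1], attr(aln, "truth")$match_counts,
                 info = paste("seed", s))
    expect_equal(tab$n_matches[1], 4L)
  }
})

test_that("alignments read back identically from FASTA and Stockholm", {
  sp <- spec_qrqy()
  aln <- gen_alignment(6, sp, seed = 3, ref_length = 12, gap_rate = 0.2)
  fa <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", aln$member_id, "\n", aln$aligned_seq), fa)
  rt <- read_alignment(fa)
  expect_equal(rt$member_id, aln$member_id)
  expect_equal(rt$aligned_seq, aln$aligned_seq)
  sto <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               sprintf("%-12s %s", aln$member_id,
                       gsub("-", ".", aln$aligned_seq)),
               "//"), sto)
  rt2 <- read_alignment(sto)
  expect_equal(rt2$aligned_seq, aln$aligned_seq)  # '.' normalized to '-'
})
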