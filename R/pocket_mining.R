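# Mining a fluorescent-protein family alignment for members whose residues at
# reference-defined anion-binding-pocket positions match a reference pattern.
# This reproduces the screen that surfaced cgreGFP: align the family, map the
# pocket positions of an anion-sensitive reference (YFP-H148Q's Q69, R96,
# Q183, Y203) onto alignment columns, count matches per member, and flag
# members with informative divergence (e.g. hydrophobic residues where the
# reference coordinates anions).

AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
AMBIGUOUS_CODES <- c("X", "B", "Z")

#' Construct a multiple alignment
#'
#' @param member_id character vector of unique member identifiers.
#' @param aligned_seq character vector of aligned sequences (uppercase
#'   one-letter amino-acid codes plus `-`); `.` is normalized to `-` and
#'   lowercase letters are uppercased.
#' @return object of class `"aa_alignment"`: a list with `member_id` and
#'   `aligned_seq`.
#' @export
aa_alignment <- function(member_id, aligned_seq) {
  member_id <- as.character(member_id)
  aligned_seq <- toupper(gsub(".", "-", as.character(aligned_seq), fixed = TRUE))
  if (anyDuplicated(member_id)) stop("member ids must be unique")
  if (length(member_id) != length(aligned_seq))
    stop("member_id and aligned_seq lengths differ")
  if (length(aligned_seq)) {
    w <- unique(nchar(aligned_seq))
    if (length(w) > 1L) stop("aligned sequences must all have the same length")
    if (w < 1L) stop("aligned sequences must be non-empty")
    bad <- grepl(paste0("[^", paste(AA_CODES, collapse = ""), "XBZ-]"),
                 aligned_seq)
    if (any(bad))
      stop("invalid characters in aligned sequence of member ",
           member_id[which(bad)[1L]])
  }
  structure(list(member_id = member_id, aligned_seq = aligned_seq),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("<aa_alignment> ", length(x$member_id), " members, width ",
      if (length(x$aligned_seq)) nchar(x$aligned_seq[1L]) else 0, "\n",
      sep = "")
  invisible(x)
}

#' Read an alignment from aligned FASTA or Stockholm
#'
#' @param path path to the alignment file.
#' @param format `"auto"` (sniff the first non-blank line), `"fasta"` or
#'   `"stockholm"`.
#' @return an [aa_alignment()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    aa_alignment(names(ss), as.character(ss))
  } else {
    msa <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
    seqs <- as.character(msa)
    aa_alignment(names(seqs), seqs)
  }
}

#' Define the reference binding-pocket pattern
#'
#' @param reference_id member id of the reference protein in the alignment.
#' @param positions 1-based ungapped residue indices in the reference
#'   sequence (strictly increasing), e.g. `c(69, 96, 183, 203)`.
#' @param expected_residues one-letter codes expected at those positions,
#'   e.g. `c("Q", "R", "Q", "Y")`.
#' @param min_matches minimum number of exact matches for a member to pass
#'   the filter (default 2).
#' @return object of class `"pocket_spec"`.
#' @export
pocket_spec <- function(reference_id, positions, expected_residues,
                        min_matches = 2L) {
  positions <- as.integer(positions)
  expected_residues <- toupper(as.character(expected_residues))
  if (length(positions) != length(expected_residues))
    stop("positions and expected_residues must align")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  if (min_matches < 0) stop("min_matches must be non-negative")
  structure(list(reference_id = as.character(reference_id),
                 positions = positions,
                 expected_residues = expected_residues,
                 min_matches = as.integer(min_matches)),
            class = "pocket_spec")
}

#' Map reference residue positions to alignment columns
#'
#' Walks the reference's aligned sequence counting non-gap characters to
#' locate the alignment column of each 1-based ungapped position.
#'
#' @param aln an [aa_alignment()].
#' @param spec a [pocket_spec()].
#' @return integer vector of 1-based alignment column indices, one per
#'   pocket position.
#' @export
map_reference_positions <- function(aln, spec) {
  i <- match(spec$reference_id, aln$member_id)
  if (is.na(i)) stop("reference id not in alignment: ", spec$reference_id)
  chars <- strsplit(aln$aligned_seq[i], "")[[1L]]
  nongap <- cumsum(chars != "-")
  cols <- match(spec$positions, nongap)
  if (anyNA(cols)) {
    bad <- spec$positions[which(is.na(cols))[1L]]
    stop("position ", bad, " exceeds the reference's ungapped length (",
         max(nongap), ")")
  }
  cols
}

#' Extract per-member pocket residues and match counts
#'
#' One row per alignment member, with the residue observed at each pocket
#' column and the number of exact matches to the expected pattern. A gap
#' never matches; ambiguity codes (X/B/Z) never match.
#'
#' @param aln an [aa_alignment()].
#' @param spec a [pocket_spec()].
#' @return a `data.frame` of class `"pocket_table"` with columns
#'   `member_id`, one `pos_<k>` column per pocket position, and `n_matches`.
#' @export
extract_pocket_table <- function(aln, spec) {
  cols <- map_reference_positions(aln, spec)
  n <- length(aln$member_id)
  res <- matrix("-", nrow = n, ncol = length(cols))
  for (j in seq_along(cols))
    res[, j] <- toupper(substr(aln$aligned_seq, cols[j], cols[j]))
  matches <- sweep(res, 2L, spec$expected_residues, "==")
  matches[res == "-" | res %in% AMBIGUOUS_CODES] <- FALSE
  out <- data.frame(member_id = aln$member_id, stringsAsFactors = FALSE)
  for (j in seq_along(cols)) out[[paste0("pos_", spec$positions[j])]] <- res[, j]
  out$n_matches <- as.integer(rowSums(matches))
  attr(out, "positions") <- spec$positions
  attr(out, "expected_residues") <- spec$expected_residues
  attr(out, "columns") <- cols
  class(out) <- c("pocket_table", "data.frame")
  out
}

#' Filter members by minimum pocket-match count
#'
#' @param table a [extract_pocket_table()] result.
#' @param min_matches non-negative integer threshold.
#' @return character vector of member ids with `n_matches >= min_matches`,
#'   in input order.
#' @export
filter_members <- function(table, min_matches) {
  if (min_matches < 0) stop("min_matches must be non-negative")
  table$member_id[table$n_matches >= min_matches]
}

#' Residue distribution at one pocket position
#'
#' @param table a [extract_pocket_table()] result.
#' @param position_index 1-based index into the pocket positions (not the
#'   reference numbering).
#' @return named integer vector of counts per one-letter code, gaps tallied
#'   under `"-"`; counts sum to the number of members.
#' @export
residue_distribution <- function(table, position_index) {
  positions <- attr(table, "positions")
  if (position_index < 1L || position_index > length(positions))
    stop("position_index out of range 1..", length(positions))
  col <- table[[paste0("pos_", positions[position_index])]]
  tab <- table(factor(col, levels = unique(col)))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Default hydrophobic residue set
#'
#' Standard nonpolar side chains used when screening pocket positions for
#' hydrophobic substitutions.
#' @export
HYDROPHOBIC_SET <- c("A", "V", "L", "I", "M", "F", "W")

#' Rank members with hydrophobic residues at candidate pocket positions
#'
#' Selects the members whose residues at all `candidate_positions` fall in
#' `hydrophobic_set` — the screen that flagged F69/V203 members as putative
#' anion sensors.
#'
#' @param table a [extract_pocket_table()] result.
#' @param candidate_positions subset of the table's pocket positions
#'   (reference numbering), e.g. `c(69, 203)`.
#' @param hydrophobic_set allowed one-letter codes (default
#'   [HYDROPHOBIC_SET]).
#' @return `data.frame` with `member_id` and the residues at the candidate
#'   positions, one row per selected member, in input order.
#' @export
rank_hydrophobic_candidates <- function(table, candidate_positions,
                                        hydrophobic_set = HYDROPHOBIC_SET) {
  if (!length(hydrophobic_set)) stop("hydrophobic_set must be non-empty")
  positions <- attr(table, "positions")
  if (!all(candidate_positions %in% positions))
    stop("candidate_positions must be a subset of the pocket positions")
  cols <- paste0("pos_", candidate_positions)
  keep <- rep(TRUE, nrow(table))
  for (cn in cols) keep <- keep & table[[cn]] %in% toupper(hydrophobic_set)
  out <- table[keep, c("member_id", cols), drop = FALSE]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Write a pocket-mining TSV report
#'
#' @param table a [extract_pocket_table()] result.
#' @param path output TSV path.
#' @param min_matches threshold used for the `passes_filter` column.
#' @param candidate_positions optional positions for the `candidate` flag
#'   (hydrophobic at all of them).
#' @param hydrophobic_set allowed codes for the candidate flag.
#' @return `path`, invisibly.
#' @export
write_pocket_report <- function(table, path,
                                min_matches = 2L,
                                candidate_positions = NULL,
                                hydrophobic_set = HYDROPHOBIC_SET) {
  df <- as.data.frame(table)
  df$passes_filter <- table$n_matches >= min_matches
  if (!is.null(candidate_positions)) {
    cand <- rank_hydrophobic_candidates(table, candidate_positions,
                                        hydrophobic_set)
    df$candidate <- df$member_id %in% cand$member_id
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
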