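#!/usr/bin/env Rscript
# Stage 1 — binding-pocket mining.
#
# Emulates the family-wide screen that surfaced cgreGFP: an 806-member
# synthetic GFP-family alignment is generated with 71 members planted to
# carry at least two of the four reference pocket residues (Q69, R96, Q183,
# Y203 in the anion-sensitive reference), and one member planted with
# hydrophobic residues (F/V-type) at positions 69 and 203 — the profile that
# flagged cgreGFP. The mining operations must read all of it back.

suppressPackageStartupMessages(library(anionsense))
dir.create("results", showWarnings = FALSE)
seed <- 20190201  # the alignment snapshot is frozen; one seed, never tuned

spec <- pocket_spec("YFP_H148Q_ref", positions = c(69, 96, 183, 203),
                    expected_residues = c("Q", "R", "Q", "Y"),
                    min_matches = 2)

n_members <- 806
n_pass <- 71
set.seed(seed)
match_counts <- sample(c(sample(rep(2:4, length.out = n_pass)),
                         sample(0:1, n_members - n_pass, replace = TRUE)))
candidate_flags <- rep(FALSE, n_members)
candidate_flags[which(match_counts == 2)[1]] <- TRUE  # the cgreGFP-like member

aln <- gen_alignment(n_members, spec, match_counts = match_counts,
                     candidate_flags = candidate_flags,
                     candidate_positions = c(69, 203),
                     ref_length = 230, seed = seed)

tab <- extract_pocket_table(aln, spec)
passing <- setdiff(filter_members(tab, spec$min_matches), spec$reference_id)
cat(sprintf("Screened %d members; %d carry >= %d pocket matches.\n",
            n_members, length(passing), spec$min_matches))

for (i in seq_along(spec$positions)) {
  d <- residue_distribution(tab, i)
  top3 <- sort(d, decreasing = TRUE)[1:3]
  cat(sprintf("  position %d: %s\n", spec$positions[i],
              paste(names(top3), top3, sep = "=", collapse = ", ")))
}

cand <- rank_hydrophobic_candidates(tab, c(69, 203))
cand <- cand[cand$member_id != spec$reference_id, ]
cat(sprintf("Hydrophobic 69/203 candidates: %s (residues %s/%s)\n",
            paste(cand$member_id, collapse = ", "),
            cand$pos_69, cand$pos_203))

write_pocket_report(tab, "results/pocket_report.tsv",
                    min_matches = spec$min_matches,
                    candidate_positions = c(69, 203))
jsonlite::write_json(list(
  n_members = n_members, n_passing = length(passing),
  min_matches = spec$min_matches,
  candidates = cand$member_id,
  positions = spec$positions, expected = spec$expected_residues
), "results/pocket_summary.json", auto_unbox = TRUE, pretty = TRUE)
cat("Wrote results/pocket_report.tsv and results/pocket_summary.json\n")
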