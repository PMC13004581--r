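# Synthetic-data generators with planted ground truth for every pipeline
# input: family alignments with planted pocket matches, trajectories with a
# scripted anion entry path and structured hydration shell, constant-pH state
# series with planted pKa and binding coupling, and titration / pH-response
# curves built from presets encoding the measured constants of cgreGFP.
#
# Every generator takes a mandatory seed and leaves the session RNG state
# untouched; the planted truth rides along as attr(x, "truth").

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Anion presets encoding the measured cgreGFP constants
#'
#' Dissociation constants (mM), ionic radii (Angstrom) and first-shell water
#' hints for the anions characterized with cgreGFP: chloride Kd 25.2,
#' bromide 15.1, iodide 5.3, nitrate 10.7 mM; gluconate does not bind and
#' serves as the negative control. Chloride and bromide carry at least four
#' first-shell waters; nitrate about two.
#'
#' @return `data.frame` with `name`, `Kd`, `ionic_radius`,
#'   `shell_count_hint`, `binds`.
#' @export
anion_presets <- function() {
  data.frame(
    name = c("chloride", "bromide", "iodide", "nitrate", "gluconate"),
    Kd = c(25.2, 15.1, 5.3, 10.7, NA_real_),
    ionic_radius = c(1.81, 1.96, 2.20, 2.64, NA_real_),
    shell_count_hint = c(4L, 4L, 4L, 2L, NA_integer_),
    binds = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Chromophore pKa presets
#'
#' Measured 50%-retention pKa values: wild type 4.9 (apo) shifting to 5.2
#' with 100 mM chloride; the H149A gate-post mutant 3.6 (apo) shifting to
#' 4.0.
#'
#' @return named numeric vector.
#' @export
pka_presets <- function() {
  c(apo = 4.9, chloride_bound = 5.2, H149A_apo = 3.6, H149A_chloride = 4.0)
}

# ---- Alignment generator ----------------------------------------------------

#' Generate a family alignment with planted pocket-match counts
#'
#' Builds a gap-free reference realizing the pocket pattern, then one member
#' per planted match count: exactly `match_counts[i]` of the pocket positions
#' carry the expected residue; the rest are resampled to differ. Members
#' flagged in `candidate_flags` carry residues from `hydrophobic_set` at
#' `candidate_positions` (without disturbing their planted match count when
#' the candidate positions are non-matching there). Gaps are sprinkled at
#' non-pocket columns at rate `gap_rate`, and `n_insert` insert columns
#' (gap in the reference) are added at random positions.
#'
#' @param n_members number of non-reference members.
#' @param spec a [pocket_spec()]; its `reference_id` names the reference row.
#' @param match_counts integer vector (length `n_members`) of planted exact
#'   match counts, each at most `length(spec$positions)`. Default: random.
#' @param candidate_flags logical vector (length `n_members`); default all
#'   FALSE.
#' @param candidate_positions positions receiving hydrophobic residues for
#'   flagged members (default the first and last pocket position).
#' @param hydrophobic_set residues used for candidates (default
#'   [HYDROPHOBIC_SET]).
#' @param ref_length ungapped reference length (default 60; must cover
#'   `max(spec$positions)`).
#' @param gap_rate per-cell gap probability at non-pocket columns (default
#'   0.05).
#' @param n_insert number of reference-gap insert columns (default 4).
#' @param seed RNG seed (mandatory).
#' @return an [aa_alignment()] with `attr(, "truth")`: list with
#'   `match_counts`, `candidate_flags`, `member_ids`, `seed`.
#' @export
gen_alignment <- function(n_members, spec, match_counts = NULL,
                          candidate_flags = NULL,
                          candidate_positions = NULL,
                          hydrophobic_set = HYDROPHOBIC_SET,
                          ref_length = NULL, gap_rate = 0.05,
                          n_insert = 4L, seed) {
  k <- length(spec$positions)
  if (is.null(ref_length)) ref_length <- max(60L, max(spec$positions) + 5L)
  if (max(spec$positions) > ref_length)
    stop("ref_length must cover the largest pocket position")
  if (is.null(candidate_positions))
    candidate_positions <- spec$positions[c(1L, k)]
  with_seed(seed, {
    if (is.null(match_counts))
      match_counts <- sample(0:k, n_members, replace = TRUE)
    if (any(match_counts > k)) stop("infeasible plant: match count exceeds positions")
    if (is.null(candidate_flags)) candidate_flags <- rep(FALSE, n_members)
    non_expected <- function(exp_res, n) {
      pool <- setdiff(AA_CODES, c(exp_res, toupper(hydrophobic_set)))
      sample(pool, n, replace = TRUE)
    }
    ref <- sample(AA_CODES, ref_length, replace = TRUE)
    ref[spec$positions] <- spec$expected_residues
    cand_idx <- match(candidate_positions, spec$positions)
    member_ids <- sprintf("member_%03d", seq_len(n_members))
    seqs <- matrix("", nrow = n_members + 1L, ncol = ref_length)
    seqs[1L, ] <- ref
    for (i in seq_len(n_members)) {
      s <- sample(AA_CODES, ref_length, replace = TRUE)
      if (candidate_flags[i]) {
        # candidate positions carry hydrophobic residues, so they cannot be
        # planted as matches (the expected pocket residues are polar)
        avail <- setdiff(seq_len(k), cand_idx)
        if (match_counts[i] > length(avail))
          stop("infeasible plant: candidate member ", i,
               " cannot match at candidate positions")
        which_match <- avail[sample.int(length(avail), match_counts[i])]
      } else {
        which_match <- sample.int(k, match_counts[i])
      }
      for (j in seq_len(k)) {
        pos <- spec$positions[j]
        if (j %in% which_match) s[pos] <- spec$expected_residues[j]
        else s[pos] <- non_expected(spec$expected_residues[j], 1L)
      }
      if (candidate_flags[i]) {
        for (j in cand_idx) {
          if (!(j %in% which_match))
            s[spec$positions[j]] <- sample(toupper(hydrophobic_set), 1L)
        }
      }
      # per-cell gaps at non-pocket columns only (pocket plants stay intact)
      gap_cols <- setdiff(seq_len(ref_length), spec$positions)
      gapped <- gap_cols[stats::runif(length(gap_cols)) < gap_rate]
      s[gapped] <- "-"
      seqs[i + 1L, ] <- s
    }
    # insert columns where the reference is gapped
    if (n_insert > 0L) {
      at <- sort(sample.int(ref_length + 1L, n_insert, replace = TRUE))
      width <- ref_length + n_insert
      full <- matrix("-", nrow = n_members + 1L, ncol = width)
      src <- seq_len(ref_length)
      dest <- src + vapply(src, function(p) sum(at <= p), integer(1))
      full[, dest] <- seqs
      ins_cols <- setdiff(seq_len(width), dest)
      for (ic in ins_cols) {
        fill <- stats::runif(n_members) < 0.5
        full[c(FALSE, fill), ic] <- sample(AA_CODES, sum(fill), replace = TRUE)
      }
      seqs <- full
    }
    aln <- aa_alignment(c(spec$reference_id, member_ids),
                        apply(seqs, 1L, paste, collapse = ""))
    attr(aln, "truth") <- list(match_counts = match_counts,
                               candidate_flags = candidate_flags,
                               member_ids = member_ids, seed = seed)
    aln
  })
}

# ---- Trajectory generator ---------------------------------------------------

# Coarse pseudo-barrel scaffold: CA-only wall residues on a cylinder, a
# planar 5-atom chromophore at the center, seven single-atom cavity residues
# on a sphere around the cavity point, a two-residue gate on the wall, one
# anion, k shell waters and a parked slab of bulk waters.
build_scaffold <- function(box, k_waters, n_bulk, cavity_offset = c(0, 0, -5),
                           cavity_radius = 3.0) {
  c0 <- box / 2
  p_cav <- c0 + cavity_offset
  ring <- function(n, radius, z) {
    th <- 2 * pi * (seq_len(n) - 1L) / n
    cbind(c0[1L] + radius * cos(th), c0[2L] + radius * sin(th), z)
  }
  wall <- rbind(ring(12L, 12, c0[3L] - 6), ring(12L, 12, c0[3L] + 6))
  th <- 2 * pi * (0:4) / 5
  cro <- cbind(c0[1L] + 1.2 * cos(th), c0[2L] + 1.2 * sin(th), c0[3L])
  pts <- sphere_points(7L)
  cav <- sweep(pts * cavity_radius, 2L, p_cav, "+")
  # the gate sits on the entry portal, between the cavity and the wall, so
  # it is the nearest wall-side pair to a cavity-bound anion
  gate <- rbind(p_cav + c(6, 2, 0), p_cav + c(6, -2, 0))
  shell_dirs <- sphere_points(max(k_waters, 1L))
  atoms <- list(
    wall = wall, cro = cro, cav = cav, gate = gate,
    anion = matrix(c0 + c(25, 0, 0), nrow = 1L),
    shell = matrix(0, nrow = k_waters, ncol = 3L),
    bulk = cbind(stats::runif(n_bulk, 2, 12), stats::runif(n_bulk, 2, box[2L] - 2),
                 stats::runif(n_bulk, 2, box[3L] - 2))
  )
  cav_names <- c("LEU", "TYR", "SER", "ARG", "PHE", "LYS", "HIS")
  top <- topology(
    serial = seq_len(24L + 5L + 7L + 2L + 1L + k_waters + n_bulk),
    atom_name = c(rep("CA", 24L), paste0("C", 1:5), rep("X", 7L),
                  c("CZ", "OG"), "CL",
                  rep("O", k_waters + n_bulk)),
    element = c(rep("C", 24L), rep("C", 5L), rep("O", 7L), c("C", "O"), "Cl",
                rep("O", k_waters + n_bulk)),
    residue_name = c(rep("BAR", 24L), rep("CRO", 5L), cav_names,
                     c("PHE", "SER"), "CLA",
                     rep("HOH", k_waters + n_bulk)),
    residue_id = c(1:24, rep(100L, 5L), 101:107, 108:109, 200L,
                   300L + seq_len(k_waters + n_bulk) - 1L)
  )
  list(top = top, atoms = atoms, c0 = c0, p_cav = p_cav,
       shell_dirs = shell_dirs,
       idx = list(wall = 1:24, cro = 25:29, cav = 30:36, gate = 37:38,
                  anion = 39L, shell = 39L + seq_len(k_waters),
                  bulk = 39L + k_waters + seq_len(n_bulk)),
       cavity_residues = 101:107, gate_pair = c(108L, 109L),
       anion_residue = 200L)
}

#' Generate a trajectory with a scripted anion entry and hydration shell
#'
#' A coarse pseudo-barrel (CA-only wall, planar chromophore, seven cavity
#' residues, a two-residue gate) hosts a single anion that approaches from
#' bulk along the gate axis and drops into the binding cavity at
#' `entry_frame`, staying bound for `persistence` frames. While bound,
#' exactly `k_waters` waters sit on a first shell of radius `r0` around the
#' anion; a slab of bulk waters stays far from the path. Small Gaussian
#' jitter (`jitter_sd`) is added to all coordinates.
#'
#' @param n_frames number of frames (default 200).
#' @param entry_frame 0-based frame at which the anion crosses into the
#'   cavity (default 60; must be >= 1 and < `n_frames` unless
#'   `anion_script = "bulk_only"`).
#' @param persistence bound frames after entry (default: to the last frame).
#' @param k_waters first-shell water count (default 4, the halide shell).
#' @param r0 shell radius in Angstrom (default 3.2).
#' @param box orthorhombic box lengths (default `c(60, 60, 60)`).
#' @param jitter_sd coordinate noise SD in Angstrom (default 0.1).
#' @param n_bulk parked bulk waters (default 20).
#' @param anion_script `"entry"` (default) or `"bulk_only"` (the anion never
#'   approaches; zero bound frames).
#' @param seed RNG seed (mandatory).
#' @return a [trajectory()] with `attr(, "truth")`: list with
#'   `entry_frame`, `bound` (logical per frame), `k_waters`, `r0`,
#'   `cavity_residues`, `gate_pair`, `anion_residue`, `seed`.
#' @export
gen_trajectory <- function(n_frames = 200L, entry_frame = 60L,
                           persistence = NULL, k_waters = 4L, r0 = 3.2,
                           box = c(60, 60, 60), jitter_sd = 0.1,
                           n_bulk = 20L, anion_script = c("entry", "bulk_only"),
                           seed) {
  anion_script <- match.arg(anion_script)
  if (anion_script == "entry" &&
      (entry_frame < 1L || entry_frame >= n_frames))
    stop("entry_frame must lie in [1, n_frames)")
  if (is.null(persistence)) persistence <- n_frames - entry_frame
  if (r0 >= 8) stop("shell radius must sit inside the barrel (r0 < 8)")
  with_seed(seed, {
    sc <- build_scaffold(box, k_waters, n_bulk)
    fixed <- rbind(sc$atoms$wall, sc$atoms$cro, sc$atoms$cav, sc$atoms$gate)
    n_at <- nrow(sc$top)
    coords <- array(NA_real_, dim = c(n_at, 3L, n_frames))
    bound <- rep(FALSE, n_frames)
    if (anion_script == "entry")
      bound[(entry_frame + 1L):min(n_frames, entry_frame + persistence)] <- TRUE
    park <- cbind(stats::runif(k_waters, 2, 12),
                  stats::runif(k_waters, 2, box[2L] - 2),
                  stats::runif(k_waters, 2, box[3L] - 2))
    for (f in seq_len(n_frames)) {
      f0 <- f - 1L  # 0-based
      if (anion_script == "bulk_only") {
        d <- 20 + 5 * sin(2 * pi * f0 / max(n_frames - 1L, 1L))
        anion <- sc$c0 + c(d, 0, 0)
      } else if (!bound[f]) {
        if (f0 < entry_frame) {
          # linear approach from 25 A to 10 A from the chromophore center
          d <- 25 - 15 * f0 / max(entry_frame - 1L, 1L)
        } else {
          d <- 20  # escaped back to bulk after the residence segment
        }
        anion <- sc$c0 + c(d, 0, 0)
      } else {
        anion <- sc$p_cav
      }
      shell <- if (bound[f])
        sweep(sc$shell_dirs[seq_len(k_waters), , drop = FALSE] * r0, 2L,
              anion, "+")
      else park
      xyz <- rbind(fixed, matrix(anion, nrow = 1L), shell, sc$atoms$bulk)
      coords[, , f] <- xyz + matrix(stats::rnorm(n_at * 3L, sd = jitter_sd),
                                    n_at, 3L)
    }
    traj <- trajectory(sc$top, coords, box = box)
    attr(traj, "truth") <- list(
      entry_frame = if (anion_script == "entry") entry_frame else NA_integer_,
      bound = bound, k_waters = k_waters, r0 = r0,
      cavity_residues = sc$cavity_residues, gate_pair = sc$gate_pair,
      anion_residue = sc$anion_residue, chromophore_residue = 100L,
      seed = seed)
    traj
  })
}

# ---- Solvation box generator ------------------------------------------------

#' Generate a solvation test box (uniform gas or planted shell)
#'
#' One center particle sits at the box center; targets are either uniform
#' i.i.d. positions per frame (`mode = "uniform"`, the ideal-gas RDF test
#' bed) or `k` targets fixed on a sphere of radius `r0` around the center
#' (re-oriented each frame) plus a uniform background
#' (`mode = "planted_shell"`).
#'
#' @param n_targets number of target atoms (total, including shell atoms).
#' @param mode `"uniform"` or `"planted_shell"`.
#' @param r0 shell radius (Angstrom), planted mode only.
#' @param k shell atom count, planted mode only.
#' @param box box lengths (default `c(30, 30, 30)`).
#' @param n_frames frames (default 20).
#' @param seed RNG seed (mandatory).
#' @return a [trajectory()]; the center is residue `CLA` id 1, targets are
#'   `HOH` oxygens. `attr(, "truth")` carries `mode`, `r0`, `k`, `seed`.
#' @export
gen_solvation_box <- function(n_targets, mode = c("uniform", "planted_shell"),
                              r0 = NULL, k = NULL, box = c(30, 30, 30),
                              n_frames = 20L, seed) {
  mode <- match.arg(mode)
  if (mode == "planted_shell") {
    if (is.null(r0) || is.null(k)) stop("planted_shell needs r0 and k")
    if (r0 >= min(box) / 2) stop("r0 must be below half the box")
    if (k > n_targets) stop("k cannot exceed n_targets")
  }
  with_seed(seed, {
    c0 <- box / 2
    n_at <- 1L + n_targets
    top <- topology(
      serial = seq_len(n_at),
      atom_name = c("CL", rep("O", n_targets)),
      element = c("Cl", rep("O", n_targets)),
      residue_name = c("CLA", rep("HOH", n_targets)),
      residue_id = seq_len(n_at)
    )
    coords <- array(NA_real_, dim = c(n_at, 3L, n_frames))
    for (f in seq_len(n_frames)) {
      bg_n <- if (mode == "uniform") n_targets else n_targets - k
      bg <- cbind(stats::runif(bg_n, 0, box[1L]), stats::runif(bg_n, 0, box[2L]),
                  stats::runif(bg_n, 0, box[3L]))
      if (mode == "planted_shell") {
        u <- matrix(stats::rnorm(3L * k), k, 3L)
        u <- u / sqrt(rowSums(u^2))
        shell <- sweep(u * r0, 2L, c0, "+")
        tgt <- rbind(shell, bg)
      } else tgt <- bg
      coords[, , f] <- rbind(matrix(c0, nrow = 1L), tgt)
    }
    traj <- trajectory(top, coords, box = box)
    attr(traj, "truth") <- list(mode = mode, r0 = r0, k = k, seed = seed)
    traj
  })
}

# ---- Constant-pH state generator --------------------------------------------

#' Generate constant-pH titration-state records with planted pKa
#'
#' Each residue is protonated per frame with the Henderson-Hasselbalch
#' probability `1 / (1 + 10^(pH - pKa))`; on bound frames (when `occupancy`
#' is supplied) a residue listed in `coupling` uses its coupled protonation
#' probability instead. With `n_prot_states = 2` a protonated frame is
#' assigned one of two tautomer state indices (1 or 2) uniformly, emulating
#' the two carboxylate oxygens of a glutamate.
#'
#' @param n_frames frames (0-based frame ids `0..n_frames-1`).
#' @param residues `data.frame` with `residue_id`, `residue_name`, `pKa`.
#' @param pH simulation pH.
#' @param coupling optional named numeric vector: bound-state protonated
#'   probability by residue id (names).
#' @param occupancy optional [occupancy_series()] (or logical vector) with
#'   one flag per frame; required when `coupling` is given.
#' @param n_prot_states 1 or 2 protonated tautomer states (default 1).
#' @param seed RNG seed (mandatory).
#' @return a [titration_states()] table with `attr(, "truth")`: list with
#'   `residues`, `pH`, `coupling`, `bound`, `seed`.
#' @export
gen_cphmd_states <- function(n_frames, residues, pH, coupling = NULL,
                             occupancy = NULL, n_prot_states = 1L, seed) {
  if (!is.null(coupling)) {
    if (is.null(occupancy)) stop("coupling requires an occupancy series")
    if (any(coupling < 0 | coupling > 1)) stop("coupling probabilities must be in [0,1]")
  }
  bound <- if (is.null(occupancy)) rep(FALSE, n_frames)
           else if (is.logical(occupancy)) occupancy else occupancy$bound
  if (length(bound) != n_frames)
    stop("occupancy length does not match n_frames")
  with_seed(seed, {
    recs <- lapply(seq_len(nrow(residues)), function(i) {
      p_hh <- 1 / (1 + 10^(pH - residues$pKa[i]))
      p <- rep(p_hh, n_frames)
      cid <- as.character(residues$residue_id[i])
      if (!is.null(coupling) && cid %in% names(coupling))
        p[bound] <- coupling[[cid]]
      prot <- stats::runif(n_frames) < p
      state <- integer(n_frames)
      if (n_prot_states >= 2L) {
        state[prot] <- sample(1:2, sum(prot), replace = TRUE)
      } else state[prot] <- 1L
      data.frame(frame = 0:(n_frames - 1L),
                 residue_id = residues$residue_id[i],
                 residue_name = residues$residue_name[i],
                 state_index = state, is_protonated = prot, pH = pH)
    })
    out <- titration_states(do.call(rbind, recs))
    attr(out, "truth") <- list(residues = residues, pH = pH,
                               coupling = coupling, bound = bound,
                               seed = seed)
    out
  })
}

# ---- Spectroscopy generators ------------------------------------------------

DEFAULT_CONCENTRATIONS <- c(0, 1, 2.5, 5, 10, 25, 50, 100)

#' Generate a synthetic anion titration curve
#'
#' Emission intensities follow the one-site isotherm
#' `Fobs = [X](Fmax - Fmin)/(Kd + [X]) + Fmin` with additive i.i.d. Gaussian
#' noise. Named presets take `Kd` from [anion_presets()]; the non-binding
#' gluconate preset yields a flat curve at `Fmin`.
#'
#' @param anion preset name (`"chloride"`, `"bromide"`, `"iodide"`,
#'   `"nitrate"`, `"gluconate"`) or `NULL` to use `Kd` directly.
#' @param Kd,Fmin,Fmax isotherm parameters; `Kd` is ignored when a binding
#'   preset is named. Defaults `Fmin = 1.0`, `Fmax = 0.2` (turn-off
#'   response).
#' @param concentrations mM grid including 0 (default
#'   `c(0, 1, 2.5, 5, 10, 25, 50, 100)`).
#' @param noise_sd additive Gaussian noise SD (default 0).
#' @param n_replicates technical replicates per concentration (default 1).
#' @param seed RNG seed (mandatory).
#' @return a [titration_curve()] with `attr(, "truth")`: list with `Kd`,
#'   `Fmin`, `Fmax`, `binds`, `noise_sd`, `seed`.
#' @export
gen_titration <- function(anion = NULL, Kd = NULL, Fmin = 1.0, Fmax = 0.2,
                          concentrations = DEFAULT_CONCENTRATIONS,
                          noise_sd = 0, n_replicates = 1L, seed) {
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  binds <- TRUE
  if (!is.null(anion)) {
    presets <- anion_presets()
    row <- presets[presets$name == anion, ]
    if (!nrow(row)) stop("unknown anion preset: ", anion)
    binds <- row$binds
    if (binds) Kd <- row$Kd
  }
  if (binds && (is.null(Kd) || Kd <= 0)) stop("Kd must be positive")
  with_seed(seed, {
    mu <- if (binds) binding_isotherm(concentrations, Kd, Fmin, Fmax)
          else rep(Fmin, length(concentrations))
    noise <- matrix(stats::rnorm(length(mu) * n_replicates, sd = noise_sd),
                    length(mu), n_replicates)
    curve <- titration_curve(if (is.null(anion)) "custom" else anion,
                             concentrations, mu + noise)
    attr(curve, "truth") <- list(Kd = if (binds) Kd else NA_real_,
                                 Fmin = Fmin, Fmax = Fmax, binds = binds,
                                 noise_sd = noise_sd, seed = seed)
    curve
  })
}

#' Generate a Henderson-Hasselbalch pH-response curve
#'
#' Raw emission is proportional to the deprotonated (fluorescent phenolate)
#' fraction `1 / (1 + 10^(pKa - pH))`, plus additive Gaussian noise, then
#' normalized to the series min/max by [ph_response_curve()].
#'
#' @param pKa planted chromophore pKa (see [pka_presets()]).
#' @param pH_grid strictly increasing pH values (default
#'   `seq(3.5, 8, 0.25)`).
#' @param noise_sd additive noise SD on the raw emission (default 0).
#' @param seed RNG seed (mandatory).
#' @return a [ph_response_curve()] with `attr(, "truth")`: list with `pKa`,
#'   `noise_sd`, `seed`.
#' @export
gen_ph_curve <- function(pKa, pH_grid = seq(3.5, 8, 0.25), noise_sd = 0,
                         seed) {
  with_seed(seed, {
    f <- 1 / (1 + 10^(pKa - pH_grid))
    em <- f + stats::rnorm(length(f), sd = noise_sd)
    curve <- ph_response_curve(pH_grid, em)
    attr(curve, "truth") <- list(pKa = pKa, noise_sd = noise_sd, seed = seed)
    curve
  })
}

# ---- Ion counts -------------------------------------------------------------

AVOGADRO <- 6.02214076e23

#' Ion counts for a neutral box at a target ionic strength
#'
#' The anion concentration follows from the ionic strength
#' `I = 1/2 sum c_i z_i^2` of the charge-balanced salt pair (for a
#' monovalent pair, `c = I`); `n_anion = round(c V N_A)` and the cation
#' count is chosen to neutralize the total charge including the protein.
#'
#' @param target_ionic_strength ionic strength in mol/L.
#' @param box_volume box volume in Angstrom^3.
#' @param protein_charge net protein charge (integer, in e).
#' @param anion_charge anion charge (default -1).
#' @param cation_charge cation charge (default +1).
#' @return named integer vector `c(n_anion, n_cation)`.
#' @export
ion_counts_for_box <- function(target_ionic_strength, box_volume,
                               protein_charge, anion_charge = -1L,
                               cation_charge = 1L) {
  if (anion_charge == 0 || cation_charge == 0) stop("ion charges must be nonzero")
  if (box_volume <= 0) stop("box volume must be positive")
  za <- abs(anion_charge); zc <- abs(cation_charge)
  c_anion <- 2 * target_ionic_strength / (za * (za + zc))
  n_anion <- round(c_anion * box_volume * 1e-27 * AVOGADRO)
  total <- -(protein_charge + n_anion * anion_charge)
  if (total %% cation_charge != 0 || total / cation_charge < 0)
    stop("neutrality unreachable with integer cation counts")
  c(n_anion = as.integer(n_anion),
    n_cation = as.integer(total / cation_charge))
}
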