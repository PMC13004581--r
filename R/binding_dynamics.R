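# Anion-centric trajectory analytics: residue contact fingerprints, binding
# cavity occupancy and residence segments, entry-event detection through the
# beta-barrel gate, RMSD/RMSF, hydrogen-bond occupancies, Shrake-Rupley SASA
# and chromophore planarity.

#' Default van der Waals radii by element (Angstrom)
#'
#' Used by [sasa()]. Halide radii follow the ionic radii of the anions
#' analyzed (Cl 1.81, Br 1.96, I 2.20 A).
#' @export
DEFAULT_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2,
                   Cl = 1.81, Br = 1.96, I = 2.20)

#' Per-frame anion-protein contact fingerprint
#'
#' For each frame, the set of residue ids whose minimum heavy-atom distance
#' (minimum image when a box is present) from any anion atom is at most
#' `cutoff`.
#'
#' @param traj a [trajectory()].
#' @param anion_selection selection expression or atom indices for the anion
#'   (must resolve to at least one atom).
#' @param protein_selection selection expression or atom indices for the
#'   protein atoms considered (default `"heavy"` restricted happens via the
#'   expression; pass e.g. `"heavy and not resname CLA HOH"`).
#' @param cutoff contact distance in Angstrom (default 4.0).
#' @return object of class `"contact_fingerprint"`: list with `cutoff` and
#'   `residues`, a list of sorted integer residue-id vectors, one per frame.
#' @export
contact_fingerprint <- function(traj, anion_selection, protein_selection,
                                cutoff = 4.0) {
  if (cutoff <= 0) stop("cutoff must be positive")
  ai <- resolve_selection(traj, anion_selection)
  pi_ <- resolve_selection(traj, protein_selection)
  if (!length(ai)) stop("empty anion selection")
  rid <- traj$topology$residue_id[pi_]
  nf <- n_frames(traj)
  residues <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    d <- pair_distances(xyz[ai, , drop = FALSE], xyz[pi_, , drop = FALSE],
                        frame_box(traj, f))
    dmin <- apply(d, 2L, min)
    hit <- tapply(dmin, rid, min) <= cutoff
    residues[[f]] <- sort(as.integer(names(hit))[hit])
  }
  structure(list(cutoff = cutoff, residues = residues, n_frames = nf),
            class = "contact_fingerprint")
}

merge_bound_runs <- function(bound, gap_tolerance) {
  n <- length(bound)
  idx <- which(bound)
  if (!length(idx)) return(matrix(integer(), ncol = 2L,
                                  dimnames = list(NULL, c("start", "end"))))
  r <- rle(bound)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- cbind(starts[r$values], ends[r$values])  # 1-based inclusive
  merged <- segs[1L, , drop = FALSE]
  if (nrow(segs) > 1L) {
    for (i in 2L:nrow(segs)) {
      gap <- segs[i, 1L] - merged[nrow(merged), 2L] - 1L
      if (gap <= gap_tolerance) merged[nrow(merged), 2L] <- segs[i, 2L]
      else merged <- rbind(merged, segs[i, ])
    }
  }
  out <- cbind(start = merged[, 1L] - 1L, end = merged[, 2L])  # 0-based half-open
  out
}

#' Cavity occupancy and residence segments
#'
#' A frame is bound when the contact fingerprint intersects the cavity
#' residue set in at least `min_residues` residues; bound runs separated by
#' at most `gap_tolerance` unbound frames are merged into one residence
#' segment (recrossing-noise suppression).
#'
#' @param fingerprint a [contact_fingerprint()].
#' @param cavity_residues non-empty integer vector of cavity residue ids
#'   (e.g. the seven-residue cavity L66, Y64, S67, R97, F101, K168, H182).
#' @param min_residues simultaneous-contact threshold (default 3).
#' @param gap_tolerance frames of allowed gap when merging (default 2).
#' @return object of class `"occupancy_series"`: list with `bound` (raw
#'   per-frame logical), `segments` (0-based half-open `[start, end)`
#'   matrix after gap merging) and the parameters used.
#' @export
cavity_occupancy <- function(fingerprint, cavity_residues, min_residues = 3L,
                             gap_tolerance = 2L) {
  if (!length(cavity_residues)) stop("cavity_residues must be non-empty")
  if (min_residues > length(cavity_residues))
    stop("min_residues exceeds the number of cavity residues")
  bound <- vapply(fingerprint$residues,
                  function(r) sum(r %in% cavity_residues) >= min_residues,
                  logical(1))
  segments <- merge_bound_runs(bound, gap_tolerance)
  structure(list(bound = bound, segments = segments,
                 parameters = list(cutoff = fingerprint$cutoff,
                                   min_residues = as.integer(min_residues),
                                   gap_tolerance = as.integer(gap_tolerance))),
            class = "occupancy_series")
}

#' Construct an occupancy series from a per-frame bound flag
#'
#' Convenience constructor used when occupancy comes from a source other
#' than a contact fingerprint (e.g. planted truth).
#'
#' @param bound logical vector, one element per frame.
#' @param gap_tolerance frames of allowed gap when merging (default 0).
#' @return an `"occupancy_series"`.
#' @export
occupancy_series <- function(bound, gap_tolerance = 0L) {
  structure(list(bound = as.logical(bound),
                 segments = merge_bound_runs(as.logical(bound), gap_tolerance),
                 parameters = list(gap_tolerance = as.integer(gap_tolerance))),
            class = "occupancy_series")
}

#' Detect anion entry events into the barrel interior
#'
#' "Inside the barrel" is operationalized as anion centroid distance to the
#' interior-center centroid (typically the chromophore) below `r_inside`,
#' with hysteresis: an entry requires an earlier frame farther than
#' `r_bulk` since the last event. An event is reported at the first frame
#' of each maximal inside-run lasting at least `min_persistence` frames.
#'
#' @param traj a [trajectory()].
#' @param anion_selection selection for the anion atoms.
#' @param interior_center_selection selection for the interior reference
#'   atoms; their centroid defines the barrel center.
#' @param r_inside inside threshold in Angstrom (default 8).
#' @param r_bulk bulk (re-arm) threshold in Angstrom (default 15).
#' @param min_persistence minimum inside-run length in frames (default 10).
#' @param gate_candidates optional list of length-2 residue-id vectors; the
#'   reported gate is the pair with the smallest summed minimum heavy-atom
#'   distance to the anion at the event frame.
#' @return `data.frame` with columns `frame` (0-based), `persistence`,
#'   `gate_res1`, `gate_res2` (NA when no candidates given).
#' @export
detect_entry_events <- function(traj, anion_selection,
                                interior_center_selection,
                                r_inside = 8, r_bulk = 15,
                                min_persistence = 10L,
                                gate_candidates = NULL) {
  if (r_inside >= r_bulk) stop("r_inside must be smaller than r_bulk")
  ai <- resolve_selection(traj, anion_selection)
  ci <- resolve_selection(traj, interior_center_selection)
  if (!length(ai)) stop("empty anion selection")
  if (!length(ci)) stop("empty interior center selection")
  nf <- n_frames(traj)
  d <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    a <- colMeans(xyz[ai, , drop = FALSE])
    ctr <- colMeans(xyz[ci, , drop = FALSE])
    d[f] <- sqrt(sum(min_image(a - ctr, frame_box(traj, f))^2))
  }
  inside <- d < r_inside
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  events <- list()
  armed_after <- 0L  # need a frame > r_bulk at index > armed_after
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] < min_persistence) next
    s <- starts[i]
    if (s == 1L || s <= armed_after + 1L) next  # no prior bulk frame
    prior <- d[seq.int(armed_after + 1L, s - 1L)]
    if (!any(prior > r_bulk)) next
    events[[length(events) + 1L]] <- list(frame = s - 1L,  # 0-based
                                          persistence = r$lengths[i])
    armed_after <- ends[i]
  }
  out <- data.frame(frame = integer(), persistence = integer(),
                    gate_res1 = integer(), gate_res2 = integer())
  if (!length(events)) return(out)
  out <- data.frame(
    frame = vapply(events, `[[`, integer(1), "frame"),
    persistence = vapply(events, `[[`, integer(1), "persistence"),
    gate_res1 = NA_integer_, gate_res2 = NA_integer_
  )
  if (!is.null(gate_candidates) && length(gate_candidates)) {
    heavy <- which(traj$topology$element != "H")
    rid <- traj$topology$residue_id
    for (e in seq_len(nrow(out))) {
      xyz <- frame_coords(traj, out$frame[e] + 1L)
      box <- frame_box(traj, out$frame[e] + 1L)
      axyz <- xyz[ai, , drop = FALSE]
      score <- vapply(gate_candidates, function(pr) {
        sum(vapply(pr, function(r1) {
          sel <- heavy[rid[heavy] == r1]
          if (!length(sel)) return(Inf)
          min(pair_distances(axyz, xyz[sel, , drop = FALSE], box))
        }, numeric(1)))
      }, numeric(1))
      best <- gate_candidates[[which.min(score)]]
      out$gate_res1[e] <- best[1L]
      out$gate_res2[e] <- best[2L]
    }
  }
  out
}

# ---- Superposition, RMSD, RMSF ----------------------------------------------

# Kabsch: proper rotation M (det +1) such that P %*% M best matches Q for
# centered row-vector coordinate sets P, Q.
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Root-mean-square deviation between two frames
#'
#' With `superpose = TRUE` (default), the minimal RMSD over rigid rotations
#' and translations is returned (optimal superposition with a proper
#' rotation enforced); otherwise the raw coordinate RMSD.
#'
#' @param frame_a,frame_b `n x 3` coordinate matrices.
#' @param selection optional integer indices applied to both frames.
#' @param superpose logical (default TRUE).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(frame_a, frame_b, selection = NULL, superpose = TRUE) {
  if (!is.null(selection)) {
    frame_a <- frame_a[selection, , drop = FALSE]
    frame_b <- frame_b[selection, , drop = FALSE]
  }
  if (nrow(frame_a) != nrow(frame_b))
    stop("selections have different cardinality")
  if (superpose) {
    if (nrow(frame_a) < 3L) stop("superposition needs at least 3 atoms")
    A <- scale(frame_a, scale = FALSE)
    B <- scale(frame_b, scale = FALSE)
    A <- A %*% kabsch_rotation(A, B)
    sqrt(mean(rowSums((A - B)^2)))
  } else {
    sqrt(mean(rowSums((frame_a - frame_b)^2)))
  }
}

#' Per-atom root-mean-square fluctuation
#'
#' Every frame is first superposed onto frame 1 over the selection; RMSF of
#' atom i is the root-mean-square distance from its time-averaged position.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param selection selection expression or atom indices.
#' @param superpose superpose each frame onto frame 1 before measuring
#'   fluctuations (default TRUE); with FALSE, raw coordinates are used,
#'   which isolates a single atom's motion exactly.
#' @return numeric vector of per-atom RMSF (Angstrom), one per selected atom.
#' @export
rmsf <- function(traj, selection, superpose = TRUE) {
  sel <- resolve_selection(traj, selection)
  nf <- n_frames(traj)
  if (nf < 2L) stop("RMSF needs at least 2 frames")
  ref <- frame_coords(traj, 1L)[sel, , drop = FALSE]
  ref_c <- scale(ref, scale = FALSE)
  stack <- array(NA_real_, dim = c(length(sel), 3L, nf))
  for (f in seq_len(nf)) {
    X <- frame_coords(traj, f)[sel, , drop = FALSE]
    if (superpose) {
      Xc <- scale(X, scale = FALSE)
      stack[, , f] <- Xc %*% kabsch_rotation(Xc, ref_c)
    } else {
      stack[, , f] <- X
    }
  }
  xbar <- apply(stack, c(1L, 2L), mean)
  dev2 <- sapply(seq_len(nf), function(f) rowSums((stack[, , f] - xbar)^2))
  sqrt(rowMeans(dev2))
}

# ---- Hydrogen bonds ----------------------------------------------------------

#' Hydrogen-bond occupancies
#'
#' A donor-acceptor pair is bonded in a frame when the heavy-donor to
#' acceptor distance is at most `d_cut` and the D-H...A angle (at the
#' hydrogen) is at least `angle_cut` degrees. Occupancy is the fraction of
#' frames bonded. Donor pairs whose hydrogen lies farther than 1.5 A from
#' the heavy donor in frame 1 are implausible and skipped with a warning.
#'
#' @param traj a [trajectory()].
#' @param donors two-column matrix or data.frame of atom indices
#'   `(D_heavy, H)`.
#' @param acceptors integer vector of acceptor heavy-atom indices.
#' @param d_cut distance criterion in Angstrom (default 3.5).
#' @param angle_cut angle criterion in degrees (default 120).
#' @return `data.frame` with `donor`, `hydrogen`, `acceptor`, `occupancy`.
#' @export
hydrogen_bonds <- function(traj, donors, acceptors, d_cut = 3.5,
                           angle_cut = 120) {
  donors <- as.matrix(donors)
  if (ncol(donors) != 2L) stop("donors must have two columns (D_heavy, H)")
  xyz1 <- frame_coords(traj, 1L)
  box1 <- frame_box(traj, 1L)
  dh <- sqrt(rowSums(min_image(xyz1[donors[, 1L], , drop = FALSE] -
                               xyz1[donors[, 2L], , drop = FALSE], box1)^2))
  if (any(dh > 1.5)) {
    warning(sum(dh > 1.5), " donor pair(s) with H farther than 1.5 A from ",
            "the heavy donor; skipped")
    donors <- donors[dh <= 1.5, , drop = FALSE]
  }
  nf <- n_frames(traj)
  grid <- expand.grid(di = seq_len(nrow(donors)), a = acceptors)
  present <- matrix(FALSE, nrow(grid), nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    box <- frame_box(traj, f)
    D <- xyz[donors[grid$di, 1L], , drop = FALSE]
    H <- xyz[donors[grid$di, 2L], , drop = FALSE]
    A <- xyz[grid$a, , drop = FALSE]
    dDA <- sqrt(rowSums(min_image(D - A, box)^2))
    hd <- min_image(D - H, box)
    ha <- min_image(A - H, box)
    cosang <- rowSums(hd * ha) /
      (sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    present[, f] <- dDA <= d_cut & ang >= angle_cut
  }
  data.frame(donor = donors[grid$di, 1L], hydrogen = donors[grid$di, 2L],
             acceptor = grid$a, occupancy = rowMeans(present))
}

# ---- SASA --------------------------------------------------------------------

# Quasi-uniform points on the unit sphere (golden-spiral construction).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each atom, quasi-uniform test points are placed on a sphere of radius
#' `r_i + probe`; a point is accessible when it lies outside every other
#' atom's expanded sphere. The atom's SASA is the accessible fraction of
#' `4 * pi * (r_i + probe)^2`.
#'
#' @param frame `n x 3` coordinate matrix (a single frame).
#' @param elements character vector of element symbols, one per atom.
#' @param radii_map named radii (Angstrom) by element (default
#'   [DEFAULT_RADII]).
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points test points per atom (default 960).
#' @return numeric vector of per-atom areas in Angstrom^2.
#' @export
sasa <- function(frame, elements, radii_map = DEFAULT_RADII, probe = 1.4,
                 n_points = 960L) {
  elements <- normalize_element(elements)
  missing <- setdiff(unique(elements), names(radii_map))
  if (length(missing))
    stop("no radius for element(s): ", paste(missing, collapse = ", "))
  r <- unname(radii_map[elements]) + probe
  n <- nrow(frame)
  pts <- sphere_points(n_points)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    test <- sweep(pts * r[i], 2L, frame[i, ], "+")
    # neighbor prefilter: atoms whose expanded sphere can reach atom i's shell
    dd <- sqrt(colSums((t(frame) - frame[i, ])^2))
    nb <- which(dd < r[i] + r & seq_len(n) != i)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- rowSums(sweep(test, 2L, frame[j, ], "-")^2)
      acc <- acc & d2 > r[j]^2
      if (!any(acc)) break
    }
    areas[i] <- 4 * pi * r[i]^2 * mean(acc)
  }
  areas
}

# ---- Chromophore planarity ---------------------------------------------------

#' Per-frame deviation of a ring from planarity
#'
#' RMS distance of the selected atoms from their least-squares plane,
#' computed per frame by singular value decomposition of the centered
#' coordinates. Invariant under rigid motion of the frame.
#'
#' @param traj a [trajectory()].
#' @param ring_selection selection resolving to at least 4 atoms (e.g. the
#'   chromophore phenol ring).
#' @return numeric vector, one RMS-out-of-plane value (Angstrom) per frame.
#' @export
chromophore_planarity <- function(traj, ring_selection) {
  sel <- resolve_selection(traj, ring_selection)
  if (length(sel) < 4L) stop("planarity needs at least 4 atoms")
  vapply(seq_len(n_frames(traj)), function(f) {
    X <- scale(frame_coords(traj, f)[sel, , drop = FALSE], scale = FALSE)
    s <- svd(X)
    s$d[3L] / sqrt(nrow(X))
  }, numeric(1))
}
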