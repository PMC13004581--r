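# Radial distribution functions around anions, first-solvation-shell
# boundaries and coordination (shell-water) counts. RDF normalization uses
# the full box volume (no protein-excluded-volume correction) with exact
# spherical shell volumes.

#' Radial distribution function g(r)
#'
#' Histogram of minimum-image center-target distances, normalized per bin by
#' `n_frames * N_center * rho * V_shell` with exact shell volumes
#' `(4/3) pi (r2^3 - r1^3)` and `rho` the frame-averaged target number
#' density `N_target / V_box`.
#'
#' @param traj a [trajectory()] with a box in every frame.
#' @param center_selection selection for the center atoms (e.g. the anion;
#'   for nitrate, its nitrogen).
#' @param target_selection selection for the target atoms (e.g. water
#'   oxygens). Atoms present in both selections are removed from the target.
#' @param dr bin width in Angstrom (default 0.1).
#' @param r_max maximum radius; must not exceed half the smallest box length.
#' @param frame_mask optional logical vector restricting the frames used
#'   (default all frames).
#' @return object of class `"rdf_profile"`: list with `bin_centers`, `g`,
#'   `counts`, `dr`, `r_max`, `n_frames`, `n_center`, `rho`.
#' @export
rdf <- function(traj, center_selection, target_selection, dr = 0.1, r_max,
                frame_mask = NULL) {
  if (is.null(traj$box)) stop("RDF requires a box in every frame")
  ci <- resolve_selection(traj, center_selection)
  ti <- resolve_selection(traj, target_selection)
  ti <- setdiff(ti, ci)
  if (!length(ci) || !length(ti)) stop("empty selection")
  frames <- seq_len(n_frames(traj))
  if (!is.null(frame_mask)) frames <- frames[frame_mask]
  if (r_max > min(traj$box[frames, ]) / 2)
    stop("r_max exceeds half the smallest box length")
  nb <- ceiling(r_max / dr)
  counts <- numeric(nb)
  rho_f <- numeric(length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    xyz <- frame_coords(traj, f)
    box <- frame_box(traj, f)
    d <- pair_distances(xyz[ci, , drop = FALSE], xyz[ti, , drop = FALSE], box)
    d <- d[d < r_max]
    if (length(d)) {
      h <- tabulate(pmin(nb, floor(d / dr) + 1L), nbins = nb)
      counts <- counts + h
    }
    rho_f[k] <- length(ti) / prod(box)
  }
  rho <- mean(rho_f)
  edges <- dr * (0:nb)
  v_shell <- 4 / 3 * pi * (edges[-1L]^3 - edges[-(nb + 1L)]^3)
  g <- counts / (length(frames) * length(ci) * rho * v_shell)
  structure(list(bin_centers = edges[-(nb + 1L)] + dr / 2, g = g,
                 counts = counts, dr = dr, r_max = r_max,
                 n_frames = length(frames), n_center = length(ci),
                 rho = rho),
            class = "rdf_profile")
}

# 3-bin moving average; edge bins average over the available window.
smooth3 <- function(g) {
  n <- length(g)
  vapply(seq_len(n), function(i)
    mean(g[max(1L, i - 1L):min(n, i + 1L)]), numeric(1))
}

#' First solvation shell boundary from an RDF profile
#'
#' The profile is smoothed with a 3-bin moving average; `r_peak` is the
#' center of the first local maximum with smoothed g > 1 (ties broken toward
#' smaller r) and `r_min` the center of the first local minimum after the
#' peak (the end of the profile counts as a minimum when g is still
#' decreasing there).
#'
#' @param profile an [rdf()] result.
#' @return named numeric vector `c(r_peak, r_min)` in Angstrom.
#' @export
first_shell_boundary <- function(profile) {
  gs <- smooth3(profile$g)
  n <- length(gs)
  if (n < 3L || all(gs <= 1)) stop("flat profile: no solvation shell peak")
  peak <- NA_integer_
  for (i in seq_len(n)) {
    left_ok <- i == 1L || gs[i] > gs[i - 1L]
    right_ok <- i == n || gs[i] >= gs[i + 1L]
    if (left_ok && right_ok && gs[i] > 1) { peak <- i; break }
  }
  if (is.na(peak)) stop("flat profile: no solvation shell peak")
  rmin <- NA_integer_
  if (peak < n) {
    for (i in (peak + 1L):n) {
      left_ok <- gs[i] < gs[i - 1L]
      right_ok <- i == n || gs[i] <= gs[i + 1L]
      if (left_ok && right_ok) { rmin <- i; break }
    }
  }
  if (is.na(rmin)) stop("no local minimum after the first peak")
  c(r_peak = profile$bin_centers[peak], r_min = profile$bin_centers[rmin])
}

#' Coordination count within a cutoff
#'
#' Number of target atoms within `r_cut` (minimum image) of any center atom,
#' per frame, plus the mean over frames.
#'
#' @param traj a [trajectory()].
#' @param center_selection,target_selection selections; overlapping atoms
#'   are removed from the target.
#' @param r_cut cutoff in Angstrom (> 0).
#' @return list with `per_frame` (integer vector) and `mean`.
#' @export
coordination_count <- function(traj, center_selection, target_selection,
                               r_cut) {
  if (r_cut <= 0) stop("r_cut must be positive")
  ci <- resolve_selection(traj, center_selection)
  ti <- resolve_selection(traj, target_selection)
  ti <- setdiff(ti, ci)
  if (!length(ci) || !length(ti)) stop("empty selection")
  nf <- n_frames(traj)
  per_frame <- integer(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    d <- pair_distances(xyz[ci, , drop = FALSE], xyz[ti, , drop = FALSE],
                        frame_box(traj, f))
    per_frame[f] <- sum(apply(d, 2L, min) <= r_cut)
  }
  list(per_frame = per_frame, mean = mean(per_frame))
}

#' Write an RDF profile as TSV (r, g, cumulative n(r))
#'
#' @param profile an [rdf()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rdf <- function(profile, path) {
  n_r <- cumsum(profile$counts) / (profile$n_frames * profile$n_center)
  utils::write.table(
    data.frame(r = profile$bin_centers, g = profile$g, n = n_r),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
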