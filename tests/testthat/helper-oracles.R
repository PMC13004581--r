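# Independent brute-force oracles used to cross-check the package's
# vectorized implementations. These deliberately use naive per-pair loops
# and share no code with the implementation.

min_image_scalar <- function(d, L) {
  w <- d - L * round(d / L)
  if (abs(w + L / 2) < 1e-12) w <- L / 2
  w
}

brute_distance <- function(p, q, box = NULL) {
  d <- p - q
  if (!is.null(box)) for (k in 1:3) d[k] <- min_image_scalar(d[k], box[k])
  sqrt(sum(d^2))
}

# residue ids within cutoff of any anion atom, one frame
brute_contacts <- function(xyz, anion_idx, prot_idx, resid, cutoff, box) {
  hits <- integer()
  for (j in prot_idx) {
    dmin <- Inf
    for (i in anion_idx)
      dmin <- min(dmin, brute_distance(xyz[i, ], xyz[j, ], box))
    if (dmin <= cutoff) hits <- c(hits, resid[j])
  }
  sort(unique(hits))
}

brute_rdf_counts <- function(traj, ci, ti, dr, r_max) {
  nb <- ceiling(r_max / dr)
  counts <- numeric(nb)
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    box <- traj$box[f, ]
    for (i in ci) for (j in ti) {
      d <- brute_distance(xyz[i, ], xyz[j, ], box)
      if (d < r_max) {
        b <- floor(d / dr) + 1
        counts[b] <- counts[b] + 1
      }
    }
  }
  counts
}

brute_coordination <- function(traj, ci, ti, r_cut) {
  vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    box <- if (is.null(traj$box)) NULL else traj$box[f, ]
    sum(vapply(ti, function(j) {
      any(vapply(ci, function(i)
        brute_distance(xyz[i, ], xyz[j, ], box) <= r_cut, logical(1)))
    }, logical(1)))
  }, numeric(1))
}

brute_hbond_occupancy <- function(traj, d_idx, h_idx, a_idx, d_cut, angle_cut) {
  pres <- logical(n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    box <- if (is.null(traj$box)) NULL else traj$box[f, ]
    dDA <- brute_distance(xyz[d_idx, ], xyz[a_idx, ], box)
    v1 <- xyz[d_idx, ] - xyz[h_idx, ]
    v2 <- xyz[a_idx, ] - xyz[h_idx, ]
    if (!is.null(box)) for (k in 1:3) {
      v1[k] <- min_image_scalar(v1[k], box[k])
      v2[k] <- min_image_scalar(v2[k], box[k])
    }
    ang <- acos(max(-1, min(1, sum(v1 * v2) /
                              sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    pres[f] <- dDA <= d_cut && ang >= angle_cut
  }
  mean(pres)
}

# RMSF by the plain formula after naive superposition onto frame 1
brute_rmsf <- function(traj, sel) {
  nf <- n_frames(traj)
  ref <- frame_coords(traj, 1)[sel, , drop = FALSE]
  refc <- sweep(ref, 2, colMeans(ref))
  aligned <- vector("list", nf)
  for (f in seq_len(nf)) {
    X <- frame_coords(traj, f)[sel, , drop = FALSE]
    Xc <- sweep(X, 2, colMeans(X))
    H <- t(Xc) %*% refc
    s <- svd(H)
    d <- sign(det(s$u %*% t(s$v)))
    aligned[[f]] <- Xc %*% (s$u %*% diag(c(1, 1, d)) %*% t(s$v))
  }
  xbar <- Reduce(`+`, aligned) / nf
  sqrt(Reduce(`+`, lapply(aligned, function(X) rowSums((X - xbar)^2))) / nf)
}

# random small trajectory with a box, for oracle tests
random_traj <- function(n_atoms, n_frames, box = c(20, 20, 20),
                        elements = NULL) {
  if (is.null(elements))
    elements <- sample(c("C", "N", "O", "H"), n_atoms, replace = TRUE)
  top <- topology(seq_len(n_atoms), rep("X", n_atoms), elements,
                  rep("RES", n_atoms),
                  residue_id = sort(sample(1:max(2, n_atoms %/% 3), n_atoms,
                                           replace = TRUE)))
  span <- if (is.null(box)) 20 else box[1]
  coords <- array(stats::runif(n_atoms * 3 * n_frames, 0, span),
                  dim = c(n_atoms, 3, n_frames))
  trajectory(top, coords, box = box)
}
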