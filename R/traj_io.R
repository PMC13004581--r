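# ---- Topology and Trajectory data model -------------------------------------

#' Construct a topology table
#'
#' A topology lists every atom of the system with its serial number, atom
#' name, element, residue name, residue id and chain. It is the metadata
#' companion of a [trajectory()]'s coordinate frames.
#'
#' @param serial integer vector of unique, increasing 1-based atom serials.
#' @param atom_name character vector of atom names (e.g. `"CA"`, `"O"`).
#' @param element character vector of element symbols; normalized to
#'   canonical case (`"CL"` becomes `"Cl"`).
#' @param residue_name character vector of 3-letter residue names.
#' @param residue_id integer vector of 1-based residue ids (need not be
#'   contiguous).
#' @param chain character vector of chain identifiers (default `"A"`).
#' @return a `data.frame` of class `"topology"`.
#' @export
topology <- function(serial, atom_name, element, residue_name, residue_id,
                     chain = "A") {
  n <- length(serial)
  serial <- as.integer(serial)
  if (anyDuplicated(serial)) stop("atom serials must be unique")
  if (is.unsorted(serial, strictly = TRUE)) stop("atom serials must be increasing")
  top <- data.frame(
    serial = serial,
    atom_name = as.character(atom_name),
    element = normalize_element(element),
    residue_name = as.character(residue_name),
    residue_id = as.integer(residue_id),
    chain = rep_len(as.character(chain), n),
    stringsAsFactors = FALSE
  )
  class(top) <- c("topology", "data.frame")
  top
}

#' Normalize element symbols to canonical case
#'
#' @param element character vector (`"CL"`, `"cl"`, `"Cl"` all map to `"Cl"`).
#' @return character vector with first letter upper, remainder lower.
#' @export
normalize_element <- function(element) {
  e <- trimws(as.character(element))
  out <- tolower(e)
  substr(out, 1, 1) <- toupper(substr(out, 1, 1))
  out
}

#' Construct a trajectory
#'
#' Frames of Cartesian coordinates (in Angstrom) over a fixed topology, with
#' an optional orthorhombic box per frame. All distance computations in the
#' package apply the minimum-image convention when a box is present.
#'
#' @param topology a [topology()].
#' @param coords a `n_atoms x 3 x n_frames` numeric array, a single
#'   `n_atoms x 3` matrix (one frame), or a list of such matrices.
#' @param box `NULL`, a length-3 vector `(Lx, Ly, Lz)` applied to every
#'   frame, or an `n_frames x 3` matrix of box lengths in Angstrom.
#' @return an object of class `"trajectory"`.
#' @export
trajectory <- function(topology, coords, box = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  if (is.list(coords)) {
    nf <- length(coords)
    coords <- array(unlist(coords, use.names = FALSE),
                    dim = c(nrow(coords[[1L]]), 3L, nf))
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2L] == 3L)
  n_atoms <- dim(coords)[1L]
  n_frames <- dim(coords)[3L]
  if (n_frames < 1L) stop("a trajectory needs at least one frame")
  if (n_atoms != nrow(topology))
    stop("coordinate rows (", n_atoms, ") do not match topology atoms (",
         nrow(topology), ")")
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = n_frames, ncol = 3L,
                                         byrow = TRUE)
    if (nrow(box) != n_frames) stop("box rows must equal n_frames")
    if (any(box <= 0)) stop("box lengths must be positive")
  }
  structure(list(topology = topology, coords = coords, box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", n_atoms(x), " atoms, ", n_frames(x), " frames, ",
      if (is.null(x$box)) "no box" else "orthorhombic box", "\n", sep = "")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj a [trajectory()].
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3L]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1L]

#' Extract one frame's coordinates
#' @param traj a [trajectory()].
#' @param i 1-based frame index.
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(traj, i) traj$coords[, , i, drop = FALSE][, , 1L]

frame_box <- function(traj, i) if (is.null(traj$box)) NULL else traj$box[i, ]

# ---- PDB reading and writing ------------------------------------------------

parse_pdb_atom <- function(line, lineno) {
  xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                       substr(line, 39, 46),
                                       substr(line, 47, 54))))
  serial <- suppressWarnings(as.integer(substr(line, 7, 11)))
  resid <- suppressWarnings(as.integer(substr(line, 23, 26)))
  if (anyNA(xyz) || is.na(serial) || is.na(resid))
    stop("unparseable ATOM/HETATM record at line ", lineno, ": ", line)
  elem <- trimws(substr(line, 77, 78))
  name <- trimws(substr(line, 13, 16))
  if (elem == "") elem <- substr(gsub("[^A-Za-z]", "", name), 1, 1)
  list(serial = serial, atom_name = name,
       residue_name = trimws(substr(line, 18, 20)),
       chain = trimws(substr(line, 22, 22)),
       residue_id = resid, xyz = xyz, element = elem)
}

#' Read a PDB structure or multi-model PDB trajectory
#'
#' `MODEL`/`ENDMDL` blocks become frames sharing one topology; a `CRYST1`
#' record populates the orthorhombic box. A file without `MODEL` records
#' yields a single-frame trajectory. Coordinates are preserved to the PDB's
#' 3-decimal precision.
#'
#' @param path path to a PDB file.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  box <- NULL
  cr <- grep("^CRYST1", lines)
  if (length(cr)) {
    l <- lines[cr[1L]]
    box <- suppressWarnings(as.numeric(c(substr(l, 7, 15), substr(l, 16, 24),
                                         substr(l, 25, 33))))
    if (anyNA(box)) stop("unparseable CRYST1 record at line ", cr[1L])
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  frames <- list()
  if (length(model_starts) == 0L) {
    idx <- which(is_atom)
    if (!length(idx)) stop("no ATOM/HETATM records in ", path)
    frames[[1L]] <- list(idx = idx, label = 1L)
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) < length(model_starts))
      model_ends <- c(model_ends, length(lines))
    for (m in seq_along(model_starts)) {
      lo <- model_starts[m]
      hi <- model_ends[m]
      idx <- which(is_atom & seq_along(lines) >= lo & seq_along(lines) <= hi)
      lab <- suppressWarnings(as.integer(trimws(substr(lines[lo], 7, 14))))
      frames[[m]] <- list(idx = idx, label = if (is.na(lab)) m else lab)
    }
  }
  first <- lapply(frames[[1L]]$idx, function(i) parse_pdb_atom(lines[i], i))
  n <- length(first)
  top <- topology(
    serial = vapply(first, `[[`, integer(1), "serial"),
    atom_name = vapply(first, `[[`, character(1), "atom_name"),
    element = vapply(first, `[[`, character(1), "element"),
    residue_name = vapply(first, `[[`, character(1), "residue_name"),
    residue_id = vapply(first, `[[`, integer(1), "residue_id"),
    chain = vapply(first, `[[`, character(1), "chain")
  )
  coords <- array(NA_real_, dim = c(n, 3L, length(frames)))
  coords[, , 1L] <- t(vapply(first, `[[`, numeric(3), "xyz"))
  if (length(frames) > 1L) {
    for (m in 2L:length(frames)) {
      idx <- frames[[m]]$idx
      if (length(idx) != n)
        stop("MODEL ", frames[[m]]$label, " has ", length(idx),
             " atoms; expected ", n)
      parsed <- lapply(idx, function(i) parse_pdb_atom(lines[i], i))
      coords[, , m] <- t(vapply(parsed, `[[`, numeric(3), "xyz"))
    }
  }
  trajectory(top, coords,
             box = if (is.null(box)) NULL else
               matrix(box, nrow = length(frames), ncol = 3L, byrow = TRUE))
}

#' @rdname read_trajectory
#' @export
read_structure <- function(path) read_trajectory(path)

#' Write a trajectory as (multi-model) PDB
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(traj$box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       traj$box[1L, 1L], traj$box[1L, 2L], traj$box[1L, 3L],
                       90, 90, 90), con)
  nf <- n_frames(traj)
  for (m in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- frame_coords(traj, m)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      top$serial, formatC(top$atom_name, width = -4),
      top$residue_name, top$chain, top$residue_id,
      xyz[, 1L], xyz[, 2L], xyz[, 3L], toupper(top$element)), con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- Atom selection ---------------------------------------------------------

BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Select atoms by a simple expression language
#'
#' Supported primaries: `backbone` (atom names N, CA, C, O), `heavy`
#' (element not H), `all`, `resname X [Y ...]`, `name X [Y ...]`,
#' `element X [Y ...]`, `resid 5 7 9:12`. Combine with `and`, `or`, `not`
#' and parentheses; `and` binds tighter than `or`.
#'
#' @param top a [topology()] or a [trajectory()] (its topology is used).
#' @param expression selection string, e.g. `"backbone and heavy"`.
#' @return increasing integer vector of atom indices (1-based rows of the
#'   topology); may be empty.
#' @export
select_atoms <- function(top, expression) {
  if (inherits(top, "trajectory")) top <- top$topology
  toks <- strsplit(trimws(gsub("([()])", " \\1 ", expression)), "\\s+")[[1L]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("empty selection expression")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  keywords <- c("and", "or", "not", "(", ")", "backbone", "heavy", "all",
                "resname", "name", "element", "resid")
  parse_values <- function() {
    vals <- character()
    while (!is.na(peek()) && !(peek() %in% keywords)) vals <- c(vals, take())
    if (!length(vals)) stop("selection keyword needs at least one value")
    vals
  }
  parse_primary <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of selection expression")
    switch(t,
      "(" = {
        r <- parse_or()
        if (!identical(take(), ")")) stop("unbalanced parenthesis in selection")
        r
      },
      "not" = !parse_primary(),
      "backbone" = top$atom_name %in% BACKBONE_NAMES,
      "heavy" = top$element != "H",
      "all" = rep(TRUE, nrow(top)),
      "resname" = toupper(top$residue_name) %in% toupper(parse_values()),
      "name" = toupper(top$atom_name) %in% toupper(parse_values()),
      "element" = top$element %in% normalize_element(parse_values()),
      "resid" = {
        vals <- parse_values()
        ids <- integer()
        for (v in vals) {
          if (grepl("^-?[0-9]+[:-][0-9]+$", v)) {
            ab <- as.integer(strsplit(v, "[:-]")[[1L]])
            ids <- c(ids, ab[1L]:ab[2L])
          } else {
            iv <- suppressWarnings(as.integer(v))
            if (is.na(iv)) stop("bad resid value in selection: ", v)
            ids <- c(ids, iv)
          }
        }
        top$residue_id %in% ids
      },
      stop("syntax error in selection expression near '", t, "'")
    )
  }
  parse_and <- function() {
    r <- parse_primary()
    while (identical(peek(), "and")) { take(); r <- r & parse_primary() }
    r
  }
  parse_or <- function() {
    r <- parse_and()
    while (identical(peek(), "or")) { take(); r <- r | parse_and() }
    r
  }
  res <- parse_or()
  if (!is.na(peek())) stop("syntax error in selection expression near '",
                           peek(), "'")
  which(res)
}

resolve_selection <- function(traj, selection) {
  if (is.character(selection)) select_atoms(traj$topology, selection)
  else as.integer(selection)
}

# ---- Minimum image and distances --------------------------------------------

#' Minimum-image displacement
#'
#' Wraps each displacement component into `(-L/2, L/2]` for an orthorhombic
#' box of lengths `box`. With `box = NULL` the displacement is returned
#' unchanged (plain Euclidean geometry).
#'
#' @param d numeric vector or `n x 3` matrix of displacement components.
#' @param box length-3 box vector, or `NULL`.
#' @return wrapped displacement of the same shape.
#' @export
min_image <- function(d, box = NULL) {
  if (is.null(box)) return(d)
  if (is.matrix(d)) {
    for (k in 1:3) {
      d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
      at_edge <- d[, k] <= -box[k] / 2 + 1e-12 & d[, k] >= -box[k] / 2 - 1e-12
      d[at_edge, k] <- box[k] / 2
    }
  } else {
    d <- d - box * round(d / box)
    at_edge <- abs(d + box / 2) < 1e-12
    d[at_edge] <- box[at_edge] / 2
  }
  d
}

# All pairwise minimum-image distances between row sets xa (na x 3) and
# xb (nb x 3): returns na x nb matrix.
pair_distances <- function(xa, xb, box = NULL) {
  na_ <- nrow(xa); nb_ <- nrow(xb)
  d2 <- matrix(0, na_, nb_)
  for (k in 1:3) {
    dk <- outer(xa[, k], xb[, k], "-")
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

# ---- Titration-state records ------------------------------------------------

TITRATION_COLS <- c("frame", "residue_id", "residue_name", "state_index",
                    "is_protonated", "pH")

#' Read a constant-pH titration-state table
#'
#' The carrier is a TSV with header columns `frame` (0-based),
#' `residue_id`, `residue_name`, `state_index`, `is_protonated`
#' (TRUE/FALSE or 0/1) and `pH`. At most one record per
#' `(frame, residue_id)` pair is allowed.
#'
#' @param path path to the TSV file.
#' @return a `data.frame` of class `"titration_states"`.
#' @export
read_titration_states <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(TITRATION_COLS, names(df))
  if (length(missing))
    stop("titration-state table is missing column(s): ",
         paste(missing, collapse = ", "))
  df <- df[TITRATION_COLS]
  fr <- suppressWarnings(as.integer(df$frame))
  if (anyNA(fr)) stop("non-integer frame value in titration-state table")
  df$frame <- fr
  df$residue_id <- as.integer(df$residue_id)
  df$state_index <- as.integer(df$state_index)
  if (any(df$state_index < 0)) stop("state_index must be >= 0")
  df$is_protonated <- as.logical(df$is_protonated)
  df$pH <- as.numeric(df$pH)
  titration_states(df)
}

#' Validate and class a titration-state data frame
#' @param df data frame with the columns of [read_titration_states()].
#' @return the validated `data.frame`, classed `"titration_states"`.
#' @export
titration_states <- function(df) {
  key <- paste(df$frame, df$residue_id)
  if (anyDuplicated(key))
    stop("duplicate (frame, residue_id) record: ",
         key[anyDuplicated(key)])
  class(df) <- c("titration_states", "data.frame")
  df
}

#' Write a titration-state table as TSV
#' @param states a `titration_states` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_titration_states <- function(states, path) {
  utils::write.table(as.data.frame(states)[TITRATION_COLS], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
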