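# Constant-pH analytics: per-residue protonation fractions and state
# occupancies, transition counts, binding-coupled protonation shifts, and a
# Henderson-Hasselbalch pKa fit over deprotonated fractions by pH.

#' Per-residue protonation summary
#'
#' Fractions are computed over the frames actually recorded for each residue
#' (missing frames are excluded, not imputed). Transitions are counted on
#' `state_index` changes between consecutive recorded frames, so tautomer
#' flips of a carboxylate count even when `is_protonated` does not change.
#'
#' @param series a [titration_states()] table.
#' @return object of class `"protonation_summary"`: a `data.frame` with
#'   `residue_id`, `residue_name`, `n_frames`, `fraction_protonated`,
#'   `n_transitions`; per-residue state occupancies (fractions per
#'   `state_index`, summing to 1) are in `attr(, "state_occupancies")`.
#' @export
protonation_fractions <- function(series) {
  if (!nrow(series)) stop("empty titration-state series")
  sp <- split(seq_len(nrow(series)), series$residue_id)
  rows <- lapply(sp, function(idx) {
    s <- series[idx[order(series$frame[idx])], ]
    data.frame(residue_id = s$residue_id[1L],
               residue_name = s$residue_name[1L],
               n_frames = nrow(s),
               fraction_protonated = mean(s$is_protonated),
               n_transitions = sum(diff(s$state_index) != 0L))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  occ <- lapply(sp, function(idx) {
    tab <- table(series$state_index[idx])
    v <- as.numeric(tab) / length(idx)
    names(v) <- names(tab)
    v
  })
  names(occ) <- vapply(sp, function(idx) as.character(series$residue_id[idx[1L]]),
                       character(1))
  attr(out, "state_occupancies") <- occ
  class(out) <- c("protonation_summary", "data.frame")
  out
}

#' Protonation fraction conditioned on anion binding
#'
#' Splits a residue's recorded frames by the bound flag of an occupancy
#' series (frame f of the series corresponds to `occupancy$bound[f + 1]`)
#' and reports the protonated fraction under each condition. A condition
#' with no frames yields `NA` (undefined), not 0.
#'
#' @param series a [titration_states()] table.
#' @param occupancy an [occupancy_series()] or [cavity_occupancy()] result
#'   whose `bound` vector covers every frame referenced by the series.
#' @param residue_id the residue to condition.
#' @return list with `fraction_bound`, `fraction_unbound`,
#'   `n_bound_frames`, `n_unbound_frames`.
#' @export
binding_coupled_fractions <- function(series, occupancy, residue_id) {
  s <- series[series$residue_id == residue_id, ]
  if (!nrow(s)) stop("residue ", residue_id, " absent from the series")
  if (any(s$frame + 1L > length(occupancy$bound)))
    stop("series references frames beyond the occupancy series")
  b <- occupancy$bound[s$frame + 1L]
  list(
    fraction_bound = if (any(b)) mean(s$is_protonated[b]) else NA_real_,
    fraction_unbound = if (any(!b)) mean(s$is_protonated[!b]) else NA_real_,
    n_bound_frames = sum(b),
    n_unbound_frames = sum(!b)
  )
}

#' Fit a Henderson-Hasselbalch titration curve for pKa
#'
#' Least-squares fit of `f = 1 / (1 + 10^(pKa - pH))` to deprotonated
#' fractions observed at several pH values.
#'
#' @param fractions_by_pH `data.frame` (or list) with numeric `pH` and
#'   `fraction_deprotonated` entries; at least 3 distinct pH values.
#' @return list with `pKa`, `residual_norm` and the fitted values.
#' @export
fit_titration_pka <- function(fractions_by_pH) {
  df <- as.data.frame(fractions_by_pH)
  if (!all(c("pH", "fraction_deprotonated") %in% names(df)))
    stop("need columns pH and fraction_deprotonated")
  if (length(unique(df$pH)) < 3L) stop("need at least 3 distinct pH values")
  if (diff(range(df$fraction_deprotonated)) < 1e-12)
    stop("degenerate curve: all fractions equal")
  start <- df$pH[which.min(abs(df$fraction_deprotonated - 0.5))]
  fit <- minpack.lm::nlsLM(
    fraction_deprotonated ~ 1 / (1 + 10^(pKa - pH)),
    data = df, start = list(pKa = start),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  list(pKa = unname(stats::coef(fit)["pKa"]),
       residual_norm = sqrt(sum(stats::resid(fit)^2)),
       fitted = stats::fitted(fit))
}

#' Write a protonation summary as TSV
#'
#' @param summary a [protonation_fractions()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protonation_summary <- function(summary, path) {
  utils::write.table(as.data.frame(summary), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
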