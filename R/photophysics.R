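# Spectroscopy models: one-site binding isotherm (Kd), the 50%-retention
# chromophore pKa estimator, fold change, extinction coefficients and
# relative quantum yield. The binding model is
#   Fobs([X]) = [X] (Fmax - Fmin) / (Kd + [X]) + Fmin
# with Fmin the emission at 0 mM anion and Fmax the saturation asymptote;
# for a turn-off sensor Fmax < Fmin.

#' Construct a titration curve
#'
#' @param anion label, e.g. `"chloride"`.
#' @param concentrations anion concentrations in mM (must include 0; at
#'   least 4 distinct values are needed for fitting).
#' @param intensities matrix of emission intensities, one row per
#'   concentration, one column per technical replicate (a vector is treated
#'   as a single replicate).
#' @return object of class `"titration_curve"`.
#' @export
titration_curve <- function(anion, concentrations, intensities) {
  concentrations <- as.numeric(concentrations)
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  if (!any(concentrations == 0)) stop("concentrations must include 0")
  if (is.null(dim(intensities))) intensities <- matrix(intensities, ncol = 1L)
  if (nrow(intensities) != length(concentrations))
    stop("one intensity row per concentration required")
  if (any(intensities <= 0)) stop("intensities must be positive")
  structure(list(anion = anion, concentrations = concentrations,
                 intensities = intensities),
            class = "titration_curve")
}

#' One-site binding isotherm evaluated at given concentrations
#'
#' @param conc concentrations in mM.
#' @param Kd dissociation constant in mM.
#' @param Fmin intensity at 0 mM; `Fmax` the saturation asymptote.
#' @param Fmax see `Fmin`.
#' @return predicted intensities.
#' @export
binding_isotherm <- function(conc, Kd, Fmin, Fmax) {
  conc * (Fmax - Fmin) / (Kd + conc) + Fmin
}

#' Fit the one-site binding isotherm to a titration curve
#'
#' Replicates are averaged per concentration before fitting (per-replicate
#' pooled fitting is available with `average_replicates = FALSE`). The fit
#' is nonlinear least squares with `Kd` constrained positive, initialized at
#' `Fmin = F(0)`, `Fmax = F(max conc)` and `Kd` at the concentration nearest
#' the half-change. Standard errors come from the Jacobian at the optimum.
#'
#' @param curve a [titration_curve()].
#' @param average_replicates average replicates before fitting (default
#'   TRUE).
#' @param noise_floor minimum signal change treated as a saturable response;
#'   default: 3x the pooled replicate standard deviation (or a 1e-6
#'   relative floor with a single replicate). A flat curve (the gluconate
#'   case) errors with "no saturable response".
#' @return object of class `"binding_fit"`: list with `Kd`, `Fmin`, `Fmax`,
#'   `se` (named vector), `residual_norm`, `fitted`, `data`.
#' @export
fit_binding_isotherm <- function(curve, average_replicates = TRUE,
                                 noise_floor = NULL) {
  if (length(unique(curve$concentrations)) < 4L)
    stop("need at least 4 distinct concentrations")
  Fbar <- rowMeans(curve$intensities)
  if (is.null(noise_floor)) {
    if (ncol(curve$intensities) > 1L) {
      noise_floor <- 3 * sqrt(mean(apply(curve$intensities, 1L,
                                         stats::var)))
    } else {
      noise_floor <- 1e-6 * mean(Fbar)
    }
  }
  o <- order(curve$concentrations)
  conc_s <- curve$concentrations[o]
  F_s <- Fbar[o]
  f0 <- F_s[1L]
  finf <- F_s[length(F_s)]
  if (abs(finf - f0) < noise_floor)
    stop("no saturable response: signal change below the noise floor")
  half <- (f0 + finf) / 2
  kd0 <- conc_s[conc_s > 0][which.min(abs(F_s[conc_s > 0] - half))]
  if (average_replicates) {
    df <- data.frame(conc = conc_s, Fobs = F_s)
  } else {
    df <- data.frame(conc = rep(curve$concentrations,
                                ncol(curve$intensities)),
                     Fobs = as.vector(curve$intensities))
  }
  fit <- minpack.lm::nlsLM(
    Fobs ~ conc * (Fmax - Fmin) / (Kd + conc) + Fmin,
    data = df, start = list(Kd = kd0, Fmin = f0, Fmax = finf),
    lower = c(Kd = 1e-9, Fmin = -Inf, Fmax = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3L))
  structure(list(Kd = unname(cf["Kd"]), Fmin = unname(cf["Fmin"]),
                 Fmax = unname(cf["Fmax"]),
                 se = c(Kd = unname(se[1L]), Fmin = unname(se[2L]),
                        Fmax = unname(se[3L])),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 fitted = stats::fitted(fit), data = df,
                 anion = curve$anion),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit%s> Kd = %.3g mM (SE %.2g), Fmin = %.4g, Fmax = %.4g\n",
              if (is.null(x$anion)) "" else paste0(" ", x$anion),
              x$Kd, x$se["Kd"], x$Fmin, x$Fmax))
  invisible(x)
}

#' Construct a pH-response curve
#'
#' @param pH strictly increasing pH values.
#' @param emission raw emission intensities at each pH; normalized to the
#'   series min/max internally.
#' @return object of class `"ph_response_curve"`: data.frame with `pH`,
#'   `emission`, `normalized`.
#' @export
ph_response_curve <- function(pH, emission) {
  pH <- as.numeric(pH)
  if (is.unsorted(pH, strictly = TRUE)) stop("pH values must be strictly increasing")
  rng <- range(emission)
  if (diff(rng) < .Machine$double.eps)
    stop("flat emission series cannot be normalized")
  df <- data.frame(pH = pH, emission = as.numeric(emission),
                   normalized = (emission - rng[1L]) / diff(rng))
  class(df) <- c("ph_response_curve", "data.frame")
  df
}

#' Estimate the chromophore pKa as the 50%-signal-retention point
#'
#' Scanning from high pH toward low pH, the first adjacent pH pair whose
#' normalized emissions bracket 0.5 is linearly interpolated to the pH at
#' normalized emission 0.5. Multiple crossings trigger a warning (the first
#' from high pH is reported); no crossing is an error.
#'
#' @param curve a [ph_response_curve()], or a data.frame with `pH` and
#'   `normalized` columns.
#' @return pKa estimate (pH units).
#' @export
estimate_pka_50pct <- function(curve) {
  pH <- curve$pH
  y <- curve$normalized
  if (is.null(y)) stop("curve must carry a 'normalized' column")
  o <- order(pH, decreasing = TRUE)
  pH <- pH[o]; y <- y[o]
  z <- y - 0.5
  cross_ph <- numeric()
  for (i in seq_along(z)) {
    if (z[i] == 0 && (i == 1L || z[i - 1L] != 0)) {
      cross_ph <- c(cross_ph, pH[i])  # grid point exactly at 0.5
    } else if (i < length(z) && z[i] * z[i + 1L] < 0) {
      cross_ph <- c(cross_ph,
                    pH[i] + (0.5 - y[i]) * (pH[i + 1L] - pH[i]) /
                      (y[i + 1L] - y[i]))
    }
  }
  if (!length(cross_ph))
    stop("normalized emission never crosses 0.5: no pKa estimate")
  if (length(cross_ph) > 1L)
    warning("multiple 0.5 crossings; reporting the first from high pH")
  cross_ph[1L]
}

#' Emission fold change
#'
#' @param F_i emission intensity in the absence of anion (must be > 0).
#' @param F_f emission intensity in the presence of anion.
#' @return `F_f / F_i`.
#' @export
fold_change <- function(F_i, F_f) {
  if (any(F_i <= 0)) stop("F_i must be positive")
  F_f / F_i
}

#' Molar extinction coefficient at 280 nm from sequence
#'
#' `5500 * nTrp + 1490 * nTyr + 125 * nCystine`, with the cystine term zero
#' by default (reduced cysteines); with `oxidized = TRUE` cystines are
#' counted as `floor(nCys / 2)` pairs.
#'
#' @param sequence one-letter amino-acid string.
#' @param oxidized count cystine pairs (default FALSE).
#' @return epsilon_280 in 1/(M cm).
#' @export
extinction_from_sequence <- function(sequence, oxidized = FALSE) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  bad <- setdiff(unique(chars), AA_CODES)
  if (length(bad))
    stop("invalid amino-acid code(s): ", paste(bad, collapse = ", "))
  nW <- sum(chars == "W"); nY <- sum(chars == "Y"); nC <- sum(chars == "C")
  5500 * nW + 1490 * nY + if (oxidized) 125 * (nC %/% 2L) else 0
}

#' Extinction coefficient at another wavelength by absorbance ratio
#'
#' Same cuvette, path length and concentration: `e_lambda = e280 * A_lambda
#' / A280`.
#'
#' @param e280 extinction coefficient at 280 nm.
#' @param A280 absorbance at 280 nm (> 0).
#' @param A_lambda absorbance at the target wavelength.
#' @return extinction coefficient at the target wavelength.
#' @export
extinction_at_wavelength <- function(e280, A280, A_lambda) {
  if (A280 <= 0) stop("A280 must be positive")
  e280 * A_lambda / A280
}

#' Relative quantum yield versus a reference fluorophore
#'
#' `Phi = Phi_ref * (slope_sample / slope_ref) * (n_sample^2 / n_ref^2)`,
#' where the slopes are from linear regressions of integrated emission on
#' absorbance.
#'
#' @param slope_sample,slope_reference positive regression slopes.
#' @param phi_reference quantum yield of the reference (e.g. fluorescein).
#' @param n_sample,n_reference solvent refractive indices (default 1.333,
#'   aqueous buffer).
#' @return quantum yield estimate.
#' @export
relative_quantum_yield <- function(slope_sample, slope_reference,
                                   phi_reference,
                                   n_sample = 1.333, n_reference = 1.333) {
  if (slope_sample <= 0 || slope_reference <= 0)
    stop("slopes must be positive")
  phi_reference * (slope_sample / slope_reference) *
    (n_sample^2 / n_reference^2)
}

#' Combine batch estimates with propagated standard deviation
#'
#' Mean of the values with `sqrt(sum(sd_i^2)) / n` as the propagated SD, as
#' used when averaging protein-batch measurements.
#'
#' @param values numeric vector of estimates.
#' @param sds their standard deviations (same length, all >= 0).
#' @return named numeric vector `c(mean, sd)`.
#' @export
combine_batches <- function(values, sds) {
  if (!length(values)) stop("need at least one estimate")
  if (length(values) != length(sds)) stop("values and sds lengths differ")
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  c(mean = mean(values), sd = sqrt(sum(sds^2)) / length(values))
}
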