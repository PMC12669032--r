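# Community composition and bioaccumulation arithmetic: relative/absolute
# abundance, monoculture-vs-community susceptibility ratios, calibration-curve
# quantification and depletion statistics.

#' Relative abundance of community members
#'
#' @param counts named numeric vector of per-species read counts.
#' @return named proportions summing to 1.
#' @export
relativeAbundance <- function(counts) {
  .stopIfNot(all(counts >= 0), "counts must be nonnegative")
  tot <- sum(counts)
  .stopIfNot(tot > 0, "all-zero count vector")
  counts / tot
}

#' Absolute abundance proxy
#'
#' Relative abundance scaled by the culture's optical density (total
#' biomass proxy), so species abundances are comparable across samples with
#' different overall growth.
#'
#' @param counts named numeric vector of per-species read counts.
#' @param od culture optical density, > 0.
#' @return named abundance proxies.
#' @export
absoluteAbundance <- function(counts, od) {
  .stopIfNot(is.finite(od) && od > 0, "od must be > 0")
  relativeAbundance(counts) * od
}

#' Per-species treatment/control abundance ratios
#'
#' For every species, the mean absolute-abundance proxy across treated
#' replicates divided by the mean across control replicates. Species with a
#' zero control mean are returned as NA (flagged) rather than infinite.
#'
#' @param treated list of named count vectors (one per replicate).
#' @param control list of named count vectors (one per replicate).
#' @param od_treated,od_control per-replicate optical densities.
#' @return named numeric vector of ratios over the union of species.
#' @export
treatmentRatio <- function(treated, control, od_treated, od_control) {
  .stopIfNot(length(treated) >= 1L && length(control) >= 1L,
             "need >= 1 replicate per arm")
  .stopIfNot(length(treated) == length(od_treated) &&
               length(control) == length(od_control),
             "one OD per replicate")
  species <- unique(c(unlist(lapply(treated, names)),
                      unlist(lapply(control, names))))
  armMean <- function(reps, ods) {
    prox <- vapply(seq_along(reps), function(i) {
      a <- absoluteAbundance(reps[[i]], ods[i])
      unname(a[species])
    }, numeric(length(species)))
    rowMeans(matrix(prox, nrow = length(species)), na.rm = TRUE)
  }
  mt <- armMean(treated, od_treated)
  mc <- armMean(control, od_control)
  out <- ifelse(is.finite(mc) & mc > 0, mt / mc, NA_real_)
  setNames(out, species)
}

#' Calibration-curve quantification
#'
#' Fits an ordinary least-squares line through signal/concentration
#' standards and inverts it to quantify sample signals. Samples outside the
#' standards' signal range are flagged as extrapolated.
#'
#' @param std_conc standard concentrations (>= 3, spanning the samples).
#' @param std_signal measured standard signals.
#' @param sample_signal signals to quantify.
#' @return list with \code{concentration}, \code{extrapolated} (logical),
#'   \code{slope}, \code{intercept}.
#' @export
linearQuantify <- function(std_conc, std_signal, sample_signal) {
  .stopIfNot(length(std_conc) >= 3L && length(std_signal) == length(std_conc),
             "need >= 3 standards")
  fit <- lm(std_signal ~ std_conc)
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  .stopIfNot(is.finite(slope) && slope != 0, "zero calibration slope")
  conc <- (sample_signal - intercept) / slope
  rng <- range(std_signal)
  list(concentration = conc,
       extrapolated = sample_signal < rng[1L] | sample_signal > rng[2L],
       slope = slope, intercept = intercept)
}

#' Supernatant depletion (bioaccumulation) statistics
#'
#' Percent depletion of a compound in culture supernatant relative to whole
#' culture, \code{100 * (1 - mean(supernatant) / mean(whole))}, with a
#' two-sided Welch t-test on the replicate concentrations. Depletion
#' indicates cell-associated sequestration of the compound.
#'
#' @param whole whole-culture concentrations (>= 2 replicates).
#' @param supernatant supernatant concentrations (>= 2 replicates).
#' @return list with \code{percent_depletion} and \code{p}.
#' @examples
#' depletionStats(c(20, 20), c(7.2, 7.2))$percent_depletion  # 64
#' @export
depletionStats <- function(whole, supernatant) {
  .stopIfNot(length(whole) >= 2L && length(supernatant) >= 2L,
             "need >= 2 replicates per fraction")
  mw <- mean(whole)
  .stopIfNot(mw != 0, "whole-culture mean concentration is zero")
  p <- if (sd(whole) == 0 && sd(supernatant) == 0) {
    if (mw == mean(supernatant)) 1 else 0
  } else {
    t.test(whole, supernatant, var.equal = FALSE)$p.value
  }
  list(percent_depletion = 100 * (1 - mean(supernatant) / mw), p = p)
}
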