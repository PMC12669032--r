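# Plate normalization, z-score hit calling with the two-of-three replicate
# concordance rule, MIC determination and screen summaries.

#' Normalize plate AUCs by the vehicle-control median
#'
#' Divides every well's raw AUC by the median raw AUC of the plate's vehicle
#' (solvent-only) control wells, so the control median maps to 1.
#'
#' @param plateAucs named numeric vector of raw AUCs (names are wells).
#' @param map the plate's \linkS4class{PlateMap}.
#' @return named numeric vector of normalized AUCs.
#' @export
normalizeDmso <- function(plateAucs, map) {
  w <- wells(map)
  ctrl <- rownames(w)[w$role == "vehicle_control"]
  ctrl <- intersect(ctrl, names(plateAucs))
  .stopIfNot(length(ctrl) >= 3L,
             "plate ", plateId(map), ": need >= 3 vehicle_control wells with AUCs")
  m <- median(plateAucs[ctrl])
  if (!is.finite(m) || m <= 0) {
    stop("plate ", plateId(map), " rejected: control median AUC <= 0",
         call. = FALSE)
  }
  plateAucs / m
}

#' Row/column-median (edge-effect) plate normalization
#'
#' Multiplicative two-way correction for plate edge effects:
#' \code{norm(r, c) = raw(r, c) * plate_median / (row_median(r) *
#' col_median(c))}, with medians computed over assay wells only
#' (\code{exclude} removes dye-footprint and empty wells). A uniform plate
#' maps to 1 everywhere; wells in a row or column whose median is zero are
#' returned as \code{NA} rather than infinite.
#'
#' @param plateAucs named numeric vector of raw AUCs (names are wells of a
#'   full-plate grid).
#' @param exclude well names excluded from the medians (and returned as NA).
#' @return named numeric vector of normalized AUCs on the fraction-of-plate
#'   scale.
#' @export
normalizeEdge <- function(plateAucs, exclude = character()) {
  wellsv <- normalizeWell(names(plateAucs))
  names(plateAucs) <- wellsv
  exclude <- if (length(exclude)) normalizeWell(exclude) else character()
  keep <- !(wellsv %in% exclude)
  rows <- .wellRow(wellsv)
  cols <- .wellCol(wellsv)
  .stopIfNot(length(unique(rows[keep])) >= 2L && length(unique(cols[keep])) >= 2L,
             "edge correction needs a grid with >= 2 rows and columns")
  rmed <- tapply(plateAucs[keep], rows[keep], median)
  cmed <- tapply(plateAucs[keep], cols[keep], median)
  pmed <- median(plateAucs[keep])
  denom <- as.vector(rmed[rows]) * as.vector(cmed[as.character(cols)])
  out <- setNames(as.vector(plateAucs) * pmed / denom, wellsv)
  out[!keep | !is.finite(denom) | denom == 0] <- NA_real_
  out
}

#' z-score and inhibition p-value against plate controls
#'
#' Standard score of a well's AUC against the plate's vehicle-control
#' distribution: \code{z = (value - median(controls)) / sd(controls)},
#' converted to a one-sided lower-tail normal p-value (growth inhibition
#' direction) by default.
#'
#' @param values numeric vector of (raw) AUCs to score.
#' @param controls numeric vector of control AUCs (>= 3 values).
#' @param alternative \code{"less"} (inhibition only, default) or
#'   \code{"two.sided"}.
#' @param robust use MAD instead of the sample standard deviation.
#' @return list with numeric vectors \code{z} and \code{p}.
#' @export
zscorePvalue <- function(values, controls, alternative = c("less", "two.sided"),
                         robust = FALSE) {
  alternative <- match.arg(alternative)
  .stopIfNot(length(controls) >= 3L, "need >= 3 control values")
  s <- if (robust) stats::mad(controls) else sd(controls)
  if (!is.finite(s) || s <= 0) {
    stop("control spread is zero; cannot compute z-scores", call. = FALSE)
  }
  z <- (values - median(controls)) / s
  p <- if (alternative == "less") pnorm(z) else 2 * pnorm(-abs(z))
  list(z = z, p = p)
}

#' Benjamini-Hochberg adjustment with an explicit test count
#'
#' Step-up false-discovery-rate adjustment where the denominator is the full
#' number of tests \code{m} (e.g. the compound library size), which may exceed
#' the number of p-values passed in.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param m total number of tests; defaults to \code{length(p)}.
#' @return adjusted p-values, order-preserving, in [0, 1].
#' @export
bhAdjust <- function(p, m = length(p)) {
  .stopIfNot(m >= length(p), "m must be >= length(p)")
  .stopIfNot(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH", n = m)
}

#' Per-replicate inhibition significance
#'
#' A replicate is significant for growth inhibition when its FDR-adjusted
#' p-value is below \code{alpha} and the normalized AUC shows more than a
#' 20 percent growth reduction (\code{norm_auc < 0.8}). Normalized AUCs are
#' clamped at zero before comparison.
#'
#' @param p_adj adjusted p-values.
#' @param norm_auc normalized AUCs (fraction of control).
#' @param alpha significance level, default 0.05.
#' @param max_norm_auc effect-size cutoff, default 0.8.
#' @return logical vector of replicate-level hit flags.
#' @export
callReplicateHit <- function(p_adj, norm_auc, alpha = 0.05,
                             max_norm_auc = 0.8) {
  pmax(norm_auc, 0) < max_norm_auc & p_adj < alpha
}

#' Aggregate replicate flags into a compound x strain HitMatrix
#'
#' A compound significantly inhibits a strain when at least
#' \code{min_reps} of its replicates are individually significant.
#'
#' @param replicateStats data.frame with columns \code{compound_id},
#'   \code{strain_id}, \code{replicate}, \code{sig} (logical) and
#'   \code{norm_auc}.
#' @param min_reps replicate-concordance threshold, default 2 (of 3).
#' @return a \linkS4class{HitMatrix}; pairs with zero replicates are NA.
#' @export
callCompoundHits <- function(replicateStats, min_reps = 2L) {
  rs <- replicateStats
  need <- c("compound_id", "strain_id", "replicate", "sig", "norm_auc")
  .stopIfNot(all(need %in% colnames(rs)),
             "replicateStats needs columns: ", paste(need, collapse = ", "))
  compounds <- sort(unique(rs$compound_id))
  strains <- sort(unique(rs$strain_id))
  ci <- match(rs$compound_id, compounds)
  si <- match(rs$strain_id, strains)
  idx <- (si - 1L) * length(compounds) + ci
  dims <- c(length(compounds), length(strains))
  nsig <- matrix(0L, dims[1L], dims[2L], dimnames = list(compounds, strains))
  nrep <- nsig
  msum <- matrix(0, dims[1L], dims[2L], dimnames = list(compounds, strains))
  tab_sig <- tapply(rs$sig, idx, sum)
  tab_n <- tapply(rs$sig, idx, length)
  tab_mean <- tapply(pmax(rs$norm_auc, 0), idx, mean)
  at <- as.integer(names(tab_sig))
  nsig[at] <- as.integer(tab_sig)
  nrep[at] <- as.integer(tab_n)
  msum[] <- NA_real_
  msum[at] <- tab_mean
  if (any(nrep > 0L & nrep < 3L)) {
    warning("some compound-strain pairs have fewer than 3 replicates")
  }
  hit <- nsig >= min_reps
  hit[nrep == 0L] <- NA
  HitMatrix(hit, nsig, msum)
}

#' Summarize a hit matrix
#'
#' Counts total inhibitory interactions, compounds with any activity,
#' broad-spectrum compounds (hits in more than a third of the species
#' tested), and compounds with strong activity (at least one hit with a mean
#' normalized AUC below 0.1, i.e. >90 percent growth reduction).
#'
#' @param hits a \linkS4class{HitMatrix}.
#' @param n_species number of species tested; defaults to the number of
#'   strain columns.
#' @return list with \code{n_interactions}, \code{n_active_compounds},
#'   \code{n_broad_compounds}, \code{n_strong_compounds}.
#' @export
summarizeHits <- function(hits, n_species = ncol(isHit(hits))) {
  h <- isHit(hits)
  h[is.na(h)] <- FALSE
  per_compound <- rowSums(h)
  strong <- rowSums(h & meanNormAuc(hits) < 0.1, na.rm = TRUE)
  list(n_interactions = sum(h),
       n_active_compounds = sum(per_compound >= 1L),
       n_broad_compounds = sum(per_compound > n_species / 3),
       n_strong_compounds = sum(strong >= 1L))
}

#' Determine the minimum inhibitory concentration
#'
#' The MIC is the lowest tested concentration at which the growth metric
#' (normalized AUC, or blanked 24-h OD for isolates) falls strictly below
#' the threshold (default 0.1, i.e. >90 percent inhibition). No monotonicity
#' repair is applied. If no concentration qualifies the result is censored
#' above the highest tested dose.
#'
#' @param concentrations tested concentrations, micromolar.
#' @param values growth metric at each concentration.
#' @param threshold inhibition cutoff, default 0.1.
#' @return list with \code{mic} (numeric, NA when censored),
#'   \code{censored} (logical) and \code{label} (e.g. \code{">20"}).
#' @examples
#' determineMic(c(2.5, 5, 10, 20), c(0.9, 0.4, 0.05, 0.02))  # MIC 10
#' @export
determineMic <- function(concentrations, values, threshold = 0.1) {
  .stopIfNot(length(concentrations) >= 2L, "need >= 2 tested concentrations")
  .stopIfNot(length(values) == length(concentrations),
             "values and concentrations must align")
  o <- order(concentrations)
  concentrations <- concentrations[o]
  values <- values[o]
  below <- which(values < threshold)
  if (length(below) == 0L) {
    list(mic = NA_real_, censored = TRUE,
         label = paste0(">", format(max(concentrations), trim = TRUE)))
  } else {
    mic <- concentrations[below[1L]]
    list(mic = mic, censored = FALSE, label = format(mic, trim = TRUE))
  }
}

#' Concordance between main-screen hits and a validation dose series
#'
#' A main-screen hit is confirmed when its validation dose series shows a
#' significant inhibition (\code{norm_auc < 0.8} and \code{p_adj < alpha}) at
#' any tested concentration at or below the main-screen dose. Pairs absent
#' from the validation set are excluded from the denominator.
#'
#' @param hits main-screen \linkS4class{HitMatrix}.
#' @param validation data.frame with columns \code{compound_id},
#'   \code{strain_id}, \code{concentration}, \code{norm_auc}, \code{p_adj}.
#' @param main_dose the main-screen test concentration (default 20).
#' @param alpha significance level, default 0.05.
#' @return list with \code{n_confirmed}, \code{n_tested}, \code{fraction}
#'   (NA when no overlap).
#' @export
validationConcordance <- function(hits, validation, main_dose = 20,
                                  alpha = 0.05) {
  h <- isHit(hits)
  hit_pairs <- which(!is.na(h) & h, arr.ind = TRUE)
  if (nrow(hit_pairs) == 0L) {
    return(list(n_confirmed = 0L, n_tested = 0L, fraction = NA_real_))
  }
  keys_main <- paste(rownames(h)[hit_pairs[, 1L]],
                     colnames(h)[hit_pairs[, 2L]], sep = "\r")
  v <- validation[validation$concentration <= main_dose, , drop = FALSE]
  keys_val <- paste(validation$compound_id, validation$strain_id, sep = "\r")
  tested <- keys_main[keys_main %in% keys_val]
  conf_keys <- unique(paste(v$compound_id, v$strain_id, sep = "\r")[
    pmax(v$norm_auc, 0) < 0.8 & v$p_adj < alpha])
  n_conf <- sum(tested %in% conf_keys)
  n_test <- length(tested)
  list(n_confirmed = n_conf, n_tested = n_test,
       fraction = if (n_test > 0L) n_conf / n_test else NA_real_)
}

#' Full monoculture hit-calling pipeline
#'
#' Runs the complete per-replicate analysis: per-curve baseline correction
#' and trapezoidal AUC, plate normalization (vehicle-control median by
#' default, row/column-median edge correction optionally), raw-AUC z-scores
#' against the plate's vehicle controls, one-sided normal p-values, BH
#' adjustment across the compound library within each strain-replicate, the
#' >20 percent effect-size filter, and the two-of-three replicate-concordance
#' rule.
#'
#' @param curves a \linkS4class{GrowthCurveSet} covering all plates and
#'   replicates (one strain per plate).
#' @param maps named list of \linkS4class{PlateMap}s keyed by plate id.
#' @param m number of compounds tested, the BH denominator; defaults to the
#'   number of distinct treatment compounds observed.
#' @param normalization \code{"dmso"} or \code{"edge"}.
#' @param alpha,max_norm_auc replicate-significance thresholds.
#' @return list with \code{replicateStats} (per compound-strain-replicate
#'   data.frame) and \code{hits} (a \linkS4class{HitMatrix}).
#' @export
screenCallHits <- function(curves, maps, m = NULL,
                           normalization = c("dmso", "edge"),
                           alpha = 0.05, max_norm_auc = 0.8) {
  normalization <- match.arg(normalization)
  cd <- as.data.frame(curveData(curves))
  raw_auc <- aucTrapezoid(baselineCorrect(curves))
  grp <- interaction(cd$plate_id, cd$replicate, drop = TRUE)
  recs <- vector("list", nlevels(grp))
  for (g in seq_len(nlevels(grp))) {
    sel <- which(grp == levels(grp)[g])
    pid <- cd$plate_id[sel[1L]]
    map <- maps[[pid]]
    .stopIfNot(!is.null(map), "no plate map for plate ", pid)
    w <- wells(map)
    aucs <- setNames(raw_auc[sel], cd$well[sel])
    roles <- setNames(w$role, rownames(w))[names(aucs)]
    ctrl_wells <- names(aucs)[roles == "vehicle_control"]
    excl <- names(aucs)[roles %in% c("dye_footprint", "empty")]
    norm <- switch(normalization,
      dmso = normalizeDmso(aucs, map),
      edge = normalizeEdge(aucs, exclude = excl))
    zp <- zscorePvalue(aucs, aucs[ctrl_wells])
    treat <- names(aucs)[roles == "treatment"]
    recs[[g]] <- data.frame(
      plate_id = pid,
      strain_id = cd$strain_id[sel[1L]],
      replicate = cd$replicate[sel[1L]],
      well = treat,
      compound_id = setNames(w$content_id, rownames(w))[treat],
      raw_auc = unname(aucs[treat]),
      norm_auc = unname(norm[treat]),
      z = unname(zp$z[treat]),
      p = unname(zp$p[treat]))
  }
  stats <- do.call(rbind, recs)
  if (is.null(m)) m <- length(unique(stats$compound_id))
  stats$p_adj <- NA_real_
  for (key in unique(paste(stats$strain_id, stats$replicate))) {
    sel <- paste(stats$strain_id, stats$replicate) == key
    stats$p_adj[sel] <- bhAdjust(stats$p[sel], m = max(m, sum(sel)))
  }
  stats$sig <- callReplicateHit(stats$p_adj, stats$norm_auc,
                                alpha = alpha, max_norm_auc = max_norm_auc)
  list(replicateStats = stats, hits = callCompoundHits(stats))
}
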