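# Conditional-growth analysis of arrayed loss-of-function libraries:
# plate-median-relative AUC ratios (rAUC), treatment/control ratios (nrAUC)
# and Welch tests with BH correction.

#' Plate-median-relative AUC (rAUC)
#'
#' Divides each mutant's AUC by the median AUC of all mutants on the plate,
#' assuming a neutral phenotype for most mutants; the output median is
#' exactly 1 and the result is invariant to rescaling the plate.
#'
#' @param plateAucs named numeric vector of per-mutant AUCs (empty-well
#'   controls already excluded).
#' @param min_mutants minimum mutants per plate, default 10.
#' @return named numeric vector of rAUC values.
#' @export
computeRauc <- function(plateAucs, min_mutants = 10L) {
  .stopIfNot(length(plateAucs) >= min_mutants,
             "need >= ", min_mutants, " mutant wells on the plate")
  m <- median(plateAucs)
  if (!is.finite(m) || m <= 0) {
    stop("plate rejected: median mutant AUC <= 0", call. = FALSE)
  }
  plateAucs / m
}

#' Treatment/control growth ratio (nrAUC)
#'
#' The mean rAUC of a mutant under a chemical divided by its mean rAUC under
#' the vehicle control; technical replicates should be averaged before
#' forming the arms.
#'
#' @param treat rAUC values under the chemical.
#' @param control rAUC values under the vehicle control.
#' @return single nrAUC value; \code{NaN} with a warning when the control
#'   mean is zero.
#' @export
computeNrauc <- function(treat, control) {
  .stopIfNot(length(treat) >= 1L && length(control) >= 1L,
             "need >= 1 value per arm")
  mc <- mean(control)
  if (mc == 0) {
    warning("control mean rAUC is zero; nrAUC undefined")
    return(NaN)
  }
  mean(treat) / mc
}

#' Test mutants for condition-dependent growth
#'
#' Per mutant and condition, a two-sided Welch unequal-variance t-test of
#' treated versus vehicle-control rAUC replicates; BH correction across
#' mutants within a condition. Hits follow the rule raw \code{p < alpha} and
#' a >20 percent growth change (\code{|nrAUC - 1| > effect}); the adjusted
#' p-value is reported alongside. Mutants that fail growth in vehicle
#' control (mean control rAUC below \code{control_floor}) are excluded.
#' Identical degenerate arms (zero variance, equal means) yield p = 1.
#'
#' @param records data.frame with columns \code{mutant_id},
#'   \code{condition}, \code{arm} (\code{"treatment"} or \code{"control"})
#'   and \code{rAUC}, one row per biological replicate.
#' @param alpha raw-p significance level, default 0.05.
#' @param effect minimum absolute growth change, default 0.2.
#' @param control_floor vehicle-control viability floor on mean rAUC,
#'   default 0.1.
#' @return data.frame of \code{mutant_id}, \code{condition}, \code{nrAUC},
#'   \code{p}, \code{p_adj}, \code{is_hit}.
#' @export
testConditionalEffects <- function(records, alpha = 0.05, effect = 0.2,
                                   control_floor = 0.1) {
  need <- c("mutant_id", "condition", "arm", "rAUC")
  .stopIfNot(all(need %in% colnames(records)),
             "records needs columns: ", paste(need, collapse = ", "))
  .stopIfNot(all(records$arm %in% c("treatment", "control")),
             "arm must be 'treatment' or 'control'")
  out <- list()
  for (cond in unique(records$condition)) {
    rc <- records[records$condition == cond, , drop = FALSE]
    res <- lapply(split(rc, rc$mutant_id), function(d) {
      tr <- d$rAUC[d$arm == "treatment"]
      ct <- d$rAUC[d$arm == "control"]
      if (length(tr) < 2L || length(ct) < 2L) {
        return(NULL)
      }
      if (mean(ct) < control_floor) return(NULL)  # failed growth in vehicle
      p <- if (sd(tr) == 0 && sd(ct) == 0) {
        if (mean(tr) == mean(ct)) 1 else 0
      } else {
        t.test(tr, ct, var.equal = FALSE)$p.value
      }
      data.frame(mutant_id = d$mutant_id[1L], condition = cond,
                 nrAUC = computeNrauc(tr, ct), p = p)
    })
    res <- do.call(rbind, res)
    if (is.null(res)) next
    res$p_adj <- bhAdjust(res$p)
    res$is_hit <- res$p < alpha & abs(res$nrAUC - 1) > effect
    out[[cond]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Full arrayed-library analysis
#'
#' Computes per-plate rAUC values (each combination of condition, arm,
#' biological replicate and technical replicate is one plate), averages
#' technical replicates within each biological replicate, and runs
#' \code{\link{testConditionalEffects}} on the biological-replicate arms.
#'
#' @param records data.frame with columns \code{mutant_id},
#'   \code{condition}, \code{arm}, \code{replicate}, \code{tech_replicate}
#'   and \code{auc}.
#' @param ... passed to \code{\link{testConditionalEffects}}.
#' @return data.frame of conditional effects (see
#'   \code{\link{testConditionalEffects}}).
#' @export
arrayedScreenAnalysis <- function(records, ...) {
  need <- c("mutant_id", "condition", "arm", "replicate", "tech_replicate",
            "auc")
  .stopIfNot(all(need %in% colnames(records)),
             "records needs columns: ", paste(need, collapse = ", "))
  plate <- interaction(records$condition, records$arm, records$replicate,
                       records$tech_replicate, drop = TRUE)
  records$rAUC <- NA_real_
  for (pl in levels(plate)) {
    sel <- plate == pl
    records$rAUC[sel] <- computeRauc(setNames(records$auc[sel],
                                              records$mutant_id[sel]))
  }
  key <- interaction(records$mutant_id, records$condition, records$arm,
                     records$replicate, drop = TRUE)
  agg <- tapply(records$rAUC, key, mean)
  first <- !duplicated(key)
  avg <- data.frame(mutant_id = records$mutant_id[first],
                    condition = records$condition[first],
                    arm = records$arm[first],
                    replicate = records$replicate[first],
                    rAUC = unname(agg[as.character(key[first])]))
  testConditionalEffects(avg, ...)
}
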