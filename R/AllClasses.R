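#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

# ---------------------------------------------------------------------------
# PlateMap
# ---------------------------------------------------------------------------

#' PlateMap: well layout of a screening plate
#'
#' Maps well coordinates to their content (compound or control), tested
#' concentration and role. Every plate must declare at least one vehicle
#' (solvent-only) control well, which anchors all plate normalization.
#'
#' @slot plateId single plate identifier.
#' @slot wells a \link[S4Vectors]{DataFrame} with one row per well (rownames
#'   are zero-padded well coordinates) and columns \code{content_id},
#'   \code{concentration} (micromolar, nonnegative) and \code{role} (one of
#'   treatment, vehicle_control, dye_footprint, empty, media_control).
#'
#' @aliases PlateMap
#' @exportClass PlateMap
setClass("PlateMap",
  representation(plateId = "character", wells = "DataFrame"))

setValidity("PlateMap", function(object) {
  w <- object@wells
  msg <- character()
  if (length(object@plateId) != 1L || is.na(object@plateId))
    msg <- c(msg, "plateId must be a single non-NA string")
  need <- c("content_id", "concentration", "role")
  if (!all(need %in% colnames(w)))
    msg <- c(msg, paste("wells must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(rownames(w)))
      msg <- c(msg, "well coordinates must be unique")
    if (!all(w$role %in% .VALID_ROLES))
      msg <- c(msg, paste("unknown role token(s):",
                          paste(unique(setdiff(w$role, .VALID_ROLES)), collapse = ", ")))
    if (!all(is.finite(w$concentration)) || any(w$concentration < 0))
      msg <- c(msg, "concentrations must be finite and >= 0")
    if (sum(w$role == "vehicle_control") < 1L)
      msg <- c(msg, "plate must declare at least one vehicle_control well")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PlateMap
#'
#' @param plateId plate identifier.
#' @param well character vector of well coordinates.
#' @param content_id compound/control identifier per well.
#' @param concentration concentration in micromolar per well.
#' @param role well role; see \linkS4class{PlateMap}.
#' @return a \linkS4class{PlateMap}.
#' @examples
#' PlateMap("P1", c("A1", "A2"), c("cmpd1", "DMSO"), c(20, 0),
#'          c("treatment", "vehicle_control"))
#' @export
PlateMap <- function(plateId, well, content_id, concentration, role) {
  well <- normalizeWell(well)
  w <- DataFrame(content_id = as.character(content_id),
                 concentration = as.numeric(concentration),
                 role = as.character(role),
                 row.names = well)
  new("PlateMap", plateId = as.character(plateId), wells = w)
}

#' @describeIn PlateMap plate identifier accessor.
#' @param object a \code{PlateMap}.
#' @export
setGeneric("plateId", function(object) standardGeneric("plateId"))

#' @rdname PlateMap-class
#' @aliases plateId,PlateMap-method
setMethod("plateId", "PlateMap", function(object) object@plateId)

#' Wells accessor
#' @param object a \linkS4class{PlateMap}.
#' @return the wells \code{DataFrame}.
#' @export
setGeneric("wells", function(object) standardGeneric("wells"))

#' @rdname wells
#' @aliases wells,PlateMap-method
setMethod("wells", "PlateMap", function(object) object@wells)

setMethod("show", "PlateMap", function(object) {
  w <- object@wells
  cat("PlateMap '", object@plateId, "' with ", nrow(w), " wells\n", sep = "")
  tab <- table(w$role)
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# GrowthCurveSet
# ---------------------------------------------------------------------------

#' GrowthCurveSet: OD600 time series on a shared time grid
#'
#' Holds one growth curve per row of the \code{od} matrix, sampled at a common
#' strictly increasing time grid (hours). Per-curve metadata (plate, well,
#' strain, replicate, and optionally compound, concentration and role) live in
#' \code{curveData}.
#'
#' @slot times numeric vector of time points in hours, strictly increasing.
#' @slot od numeric matrix, curves x time points, finite OD600 readings.
#' @slot curveData \link[S4Vectors]{DataFrame} of per-curve metadata with at
#'   least columns \code{plate_id}, \code{well}, \code{strain_id},
#'   \code{replicate}.
#'
#' @aliases GrowthCurveSet
#' @exportClass GrowthCurveSet
setClass("GrowthCurveSet",
  representation(times = "numeric", od = "matrix", curveData = "DataFrame"))

setValidity("GrowthCurveSet", function(object) {
  msg <- character()
  t <- object@times
  if (length(t) < 2L || any(diff(t) <= 0) || !all(is.finite(t)))
    msg <- c(msg, "times must be >= 2 finite, strictly increasing values")
  if (ncol(object@od) != length(t))
    msg <- c(msg, "ncol(od) must equal length(times)")
  if (!all(is.finite(object@od)))
    msg <- c(msg, "od values must be finite")
  if (nrow(object@curveData) != nrow(object@od))
    msg <- c(msg, "curveData must have one row per curve")
  need <- c("plate_id", "well", "strain_id", "replicate")
  if (!all(need %in% colnames(object@curveData)))
    msg <- c(msg, paste("curveData must have columns:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a GrowthCurveSet
#'
#' @param times shared time grid in hours.
#' @param od curves x times matrix of OD600 values.
#' @param curveData per-curve metadata (coercible to DataFrame) with columns
#'   \code{plate_id}, \code{well}, \code{strain_id}, \code{replicate}.
#' @return a \linkS4class{GrowthCurveSet}.
#' @export
GrowthCurveSet <- function(times, od, curveData) {
  od <- as.matrix(od)
  cd <- as(curveData, "DataFrame")
  if ("well" %in% colnames(cd)) cd$well <- normalizeWell(cd$well)
  new("GrowthCurveSet", times = as.numeric(times), od = od, curveData = cd)
}

#' Time grid accessor
#' @param object a \linkS4class{GrowthCurveSet}.
#' @return numeric vector of hours.
#' @export
setGeneric("curveTimes", function(object) standardGeneric("curveTimes"))

#' @rdname curveTimes
#' @aliases curveTimes,GrowthCurveSet-method
setMethod("curveTimes", "GrowthCurveSet", function(object) object@times)

#' OD matrix accessor
#' @param object a \linkS4class{GrowthCurveSet}.
#' @return the curves x times OD600 matrix.
#' @export
setGeneric("odMatrix", function(object) standardGeneric("odMatrix"))

#' @rdname odMatrix
#' @aliases odMatrix,GrowthCurveSet-method
setMethod("odMatrix", "GrowthCurveSet", function(object) object@od)

#' Per-curve metadata accessor
#' @param object a \linkS4class{GrowthCurveSet}.
#' @return a \code{DataFrame} of per-curve metadata.
#' @export
setGeneric("curveData", function(object) standardGeneric("curveData"))

#' @rdname curveData
#' @aliases curveData,GrowthCurveSet-method
setMethod("curveData", "GrowthCurveSet", function(object) object@curveData)

setMethod("length", "GrowthCurveSet", function(x) nrow(x@od))

setMethod("show", "GrowthCurveSet", function(object) {
  cat("GrowthCurveSet:", nrow(object@od), "curves x",
      length(object@times), "time points (",
      min(object@times), "-", max(object@times), "h )\n")
  cat("  plates:", length(unique(object@curveData$plate_id)),
      " strains:", length(unique(object@curveData$strain_id)), "\n")
})

#' @rdname GrowthCurveSet
#' @param x a \code{GrowthCurveSet}.
#' @param i curve (row) index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "GrowthCurveSet", function(x, i, j, ..., drop = FALSE) {
  new("GrowthCurveSet", times = x@times,
      od = x@od[i, , drop = FALSE],
      curveData = x@curveData[i, , drop = FALSE])
})

# ---------------------------------------------------------------------------
# HitMatrix
# ---------------------------------------------------------------------------

#' HitMatrix: compound x strain inhibition calls
#'
#' The central output of the monoculture screen: for every compound-strain
#' pair, whether the pair is an inhibition hit (significant in at least two of
#' three replicates), how many replicates were individually significant, and
#' the mean normalized AUC (growth relative to vehicle control).
#'
#' @slot isHit logical compound x strain matrix.
#' @slot nSigReps integer matrix of per-pair significant replicate counts.
#' @slot meanNormAuc numeric matrix of mean normalized AUC per pair.
#'
#' @aliases HitMatrix
#' @exportClass HitMatrix
setClass("HitMatrix",
  representation(isHit = "matrix", nSigReps = "matrix", meanNormAuc = "matrix"))

setValidity("HitMatrix", function(object) {
  msg <- character()
  d <- dim(object@isHit)
  if (!identical(d, dim(object@nSigReps)) || !identical(d, dim(object@meanNormAuc)))
    msg <- c(msg, "all three matrices must share dimensions")
  if (!is.logical(object@isHit)) msg <- c(msg, "isHit must be logical")
  ok <- !is.na(object@isHit) & object@isHit
  if (any(object@nSigReps[ok] < 2L, na.rm = TRUE))
    msg <- c(msg, "is_hit implies >= 2 significant replicates")
  if (any(object@meanNormAuc < 0, na.rm = TRUE))
    msg <- c(msg, "meanNormAuc must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a HitMatrix
#' @param isHit logical compound x strain matrix.
#' @param nSigReps integer matrix of significant replicate counts.
#' @param meanNormAuc numeric matrix of mean normalized AUCs.
#' @return a \linkS4class{HitMatrix}.
#' @export
HitMatrix <- function(isHit, nSigReps, meanNormAuc) {
  storage.mode(nSigReps) <- "integer"
  new("HitMatrix", isHit = isHit, nSigReps = nSigReps, meanNormAuc = meanNormAuc)
}

#' Hit indicator accessor
#' @param object a \linkS4class{HitMatrix}.
#' @return logical compound x strain matrix.
#' @export
setGeneric("isHit", function(object) standardGeneric("isHit"))

#' @rdname isHit
#' @aliases isHit,HitMatrix-method
setMethod("isHit", "HitMatrix", function(object) object@isHit)

#' Significant-replicate count accessor
#' @param object a \linkS4class{HitMatrix}.
#' @export
setGeneric("nSigReps", function(object) standardGeneric("nSigReps"))

#' @rdname nSigReps
#' @aliases nSigReps,HitMatrix-method
setMethod("nSigReps", "HitMatrix", function(object) object@nSigReps)

#' Mean normalized AUC accessor
#' @param object a \linkS4class{HitMatrix}.
#' @export
setGeneric("meanNormAuc", function(object) standardGeneric("meanNormAuc"))

#' @rdname meanNormAuc
#' @aliases meanNormAuc,HitMatrix-method
setMethod("meanNormAuc", "HitMatrix", function(object) object@meanNormAuc)

setMethod("show", "HitMatrix", function(object) {
  cat("HitMatrix:", nrow(object@isHit), "compounds x", ncol(object@isHit),
      "strains;", sum(object@isHit, na.rm = TRUE), "hits\n")
})

# ---------------------------------------------------------------------------
# FingerprintSet
# ---------------------------------------------------------------------------

#' FingerprintSet: binary molecular fingerprints as bit sets
#'
#' Stores, per compound, the sorted indices of the set bits of a fixed-length
#' binary fingerprint (e.g. a circular/ECFP fingerprint). All similarity math
#' in the package operates on these bit sets, so it is independent of the
#' chemistry software used to derive them.
#'
#' @slot bits named list of sorted integer vectors (0-based bit indices).
#' @slot nbits fingerprint length.
#'
#' @aliases FingerprintSet
#' @exportClass FingerprintSet
setClass("FingerprintSet",
  representation(bits = "list", nbits = "integer"))

setValidity("FingerprintSet", function(object) {
  msg <- character()
  if (length(object@nbits) != 1L || object@nbits < 1L)
    msg <- c(msg, "nbits must be a single positive integer")
  if (is.null(names(object@bits)) || anyDuplicated(names(object@bits)))
    msg <- c(msg, "bits must be a uniquely named list")
  ok <- vapply(object@bits, function(b) {
    is.integer(b) && !anyDuplicated(b) && !is.unsorted(b) &&
      (length(b) == 0L || (b[1L] >= 0L && b[length(b)] < object@nbits))
  }, logical(1))
  if (!all(ok))
    msg <- c(msg, "each bit set must be sorted, duplicate-free and within [0, nbits)")
  if (length(msg)) msg else TRUE
})

#' Construct a FingerprintSet
#' @param bits named list of integer vectors of set-bit indices (0-based).
#' @param nbits fingerprint length in bits.
#' @return a \linkS4class{FingerprintSet}.
#' @examples
#' FingerprintSet(list(a = c(1L, 5L), b = c(5L, 9L)), nbits = 16L)
#' @export
FingerprintSet <- function(bits, nbits) {
  bits <- lapply(bits, function(b) sort(unique(as.integer(b))))
  new("FingerprintSet", bits = bits, nbits = as.integer(nbits))
}

#' Bit-set accessor
#' @param object a \linkS4class{FingerprintSet}.
#' @return named list of integer vectors.
#' @export
setGeneric("fpBits", function(object) standardGeneric("fpBits"))

#' @rdname fpBits
#' @aliases fpBits,FingerprintSet-method
setMethod("fpBits", "FingerprintSet", function(object) object@bits)

setMethod("length", "FingerprintSet", function(x) length(x@bits))

setMethod("names", "FingerprintSet", function(x) names(x@bits))

setMethod("show", "FingerprintSet", function(object) {
  cat("FingerprintSet:", length(object@bits), "compounds,",
      object@nbits, "bits; mean density",
      signif(mean(lengths(object@bits)) / object@nbits, 3), "\n")
})

# ---------------------------------------------------------------------------
# ToxDataset
# ---------------------------------------------------------------------------

#' ToxDataset: molecular features plus per-species inhibition labels
#'
#' Pairs a compound x feature numeric matrix (molecular descriptors and,
#' optionally, learned embedding columns) with one binary inhibition label
#' vector per modelled species, for species-specific antibacterial-activity
#' classification.
#'
#' @slot features numeric compound x feature matrix, no missing values.
#' @slot labels integer (0/1) compound x species matrix, aligned by rowname.
#'
#' @aliases ToxDataset
#' @exportClass ToxDataset
setClass("ToxDataset",
  representation(features = "matrix", labels = "matrix"))

setValidity("ToxDataset", function(object) {
  msg <- character()
  if (!all(is.finite(object@features)))
    msg <- c(msg, "features must be finite (no missing values after assembly)")
  if (nrow(object@features) != nrow(object@labels))
    msg <- c(msg, "features and labels must cover the same compounds")
  if (!identical(rownames(object@features), rownames(object@labels)))
    msg <- c(msg, "features and labels rownames must align")
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be binary 0/1")
  if (length(msg)) msg else TRUE
})

#' Construct a ToxDataset
#' @param features numeric compound x feature matrix with rownames.
#' @param labels binary compound x species matrix with matching rownames.
#' @return a \linkS4class{ToxDataset}.
#' @export
ToxDataset <- function(features, labels) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  new("ToxDataset", features = as.matrix(features), labels = labels)
}

#' Feature matrix accessor
#' @param object a \linkS4class{ToxDataset}.
#' @export
setGeneric("toxFeatures", function(object) standardGeneric("toxFeatures"))

#' @rdname toxFeatures
#' @aliases toxFeatures,ToxDataset-method
setMethod("toxFeatures", "ToxDataset", function(object) object@features)

#' Label matrix accessor
#' @param object a \linkS4class{ToxDataset}.
#' @export
setGeneric("toxLabels", function(object) standardGeneric("toxLabels"))

#' @rdname toxLabels
#' @aliases toxLabels,ToxDataset-method
setMethod("toxLabels", "ToxDataset", function(object) object@labels)

setMethod("show", "ToxDataset", function(object) {
  cat("ToxDataset:", nrow(object@features), "compounds x",
      ncol(object@features), "features;", ncol(object@labels), "species\n")
  prev <- colMeans(object@labels)
  cat("  label prevalence:", paste(signif(prev, 2), collapse = ", "), "\n")
})
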