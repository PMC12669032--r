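#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats median sd pnorm p.adjust t.test fisher.test ks.test
#'   rnorm rlnorm runif rnbinom rgamma rmultinom rbinom quantile setNames
#'   coef predict lm
#' @importFrom utils combn head
NULL

.VALID_ROLES <- c("treatment", "vehicle_control", "dye_footprint", "empty",
                  "media_control")

#' Normalize well coordinates to zero-padded form
#'
#' Converts well labels such as \code{"A1"} into the canonical zero-padded
#' form \code{"A01"} used throughout the package, so wells sort stably.
#'
#' @param x character vector of well labels (row letter(s) followed by a
#'   column number).
#' @return character vector of normalized labels.
#' @examples
#' normalizeWell(c("A1", "H12", "b9"))
#' @export
normalizeWell <- function(x) {
  x <- toupper(trimws(as.character(x)))
  m <- regexec("^([A-Z]+)([0-9]+)$", x)
  parts <- regmatches(x, m)
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop("malformed well coordinate(s): ", paste(x[bad], collapse = ", "))
  }
  row <- vapply(parts, `[`, character(1), 2L)
  col <- as.integer(vapply(parts, `[`, character(1), 3L))
  if (any(col < 1L)) stop("well column numbers must be >= 1")
  sprintf("%s%02d", row, col)
}

.wellRow <- function(x) sub("[0-9]+$", "", x)
.wellCol <- function(x) as.integer(sub("^[A-Z]+", "", x))

# median of finite values, NA if none
.medianFinite <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  median(x)
}

.stopIfNot <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)
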