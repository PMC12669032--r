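# Tabular readers/writers. UTF-8, tab-separated by default with comma
# auto-detect; header row mandatory; malformed numeric fields are rejected
# with the offending row number rather than coerced.

.detectSep <- function(path) {
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  if (length(first) == 0L) stop("empty file: ", path)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0L) "\t" else ","
}

.readTable <- function(path, sep = NULL) {
  .stopIfNot(file.exists(path), "file not found: ", path)
  if (is.null(sep)) sep <- .detectSep(path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", fileEncoding = "UTF-8",
                    colClasses = "character")
}

# strict numeric parser: errors with 1-based data row numbers on failure
.parseNumStrict <- function(x, what, rows = seq_along(x)) {
  y <- suppressWarnings(as.numeric(x))
  bad <- !is.finite(y)
  if (any(bad)) {
    stop("non-numeric ", what, " at row(s): ",
         paste(head(rows[bad], 5L), collapse = ", "), call. = FALSE)
  }
  y
}

#' Read plate-reader OD600 time series
#'
#' Reads a long (\code{plate_id, well, strain_id, replicate, time, od}) or
#' wide (metadata columns followed by one numeric column per time point)
#' tabular export into a \linkS4class{GrowthCurveSet}. Times are hours; a
#' \code{time_unit} column (\code{hours}/\code{minutes}/\code{seconds}) is
#' honoured when present in long files. All curves in one file must share the
#' same time grid.
#'
#' @param path file path (TSV by default, comma auto-detected).
#' @param dialect \code{"auto"}, \code{"long"} or \code{"wide"}.
#' @return a \linkS4class{GrowthCurveSet}.
#' @export
readPlateTimeseries <- function(path, dialect = c("auto", "long", "wide")) {
  dialect <- match.arg(dialect)
  tab <- .readTable(path)
  if (dialect == "auto") {
    dialect <- if (all(c("time", "od") %in% colnames(tab))) "long" else "wide"
  }
  meta_cols <- c("plate_id", "well", "strain_id", "replicate")
  .stopIfNot(all(meta_cols %in% colnames(tab)),
             "time-series file must have columns: ",
             paste(meta_cols, collapse = ", "))
  if (dialect == "long") {
    .stopIfNot(all(c("time", "od") %in% colnames(tab)),
               "long dialect needs 'time' and 'od' columns")
    rows <- seq_len(nrow(tab))
    time <- .parseNumStrict(tab$time, "time", rows)
    if ("time_unit" %in% colnames(tab)) {
      fac <- c(hours = 1, minutes = 1 / 60, seconds = 1 / 3600)
      u <- tab$time_unit
      .stopIfNot(all(u %in% names(fac)), "unknown time unit(s): ",
                 paste(unique(setdiff(u, names(fac))), collapse = ", "))
      time <- time * fac[u]
    }
    od <- .parseNumStrict(tab$od, "OD", rows)
    well <- normalizeWell(tab$well)
    key <- paste(tab$plate_id, well, tab$replicate, sep = "\r")
    dup <- duplicated(cbind(key, time))
    if (any(dup)) {
      stop("duplicate (plate, well, time) row(s): ",
           paste(head(rows[dup], 5L), collapse = ", "), call. = FALSE)
    }
    o <- order(key, time)
    key_o <- key[o]
    curves <- split(seq_along(key_o), factor(key_o, levels = unique(key_o)))
    times0 <- time[o][curves[[1L]]]
    .stopIfNot(all(diff(times0) > 0), "times not strictly increasing ",
               "after sort; duplicate or invalid time values")
    odm <- matrix(NA_real_, nrow = length(curves), ncol = length(times0))
    for (i in seq_along(curves)) {
      idx <- curves[[i]]
      ti <- time[o][idx]
      .stopIfNot(isTRUE(all.equal(ti, times0)),
                 "all curves must share the same time grid")
      odm[i, ] <- od[o][idx]
    }
    first <- vapply(curves, `[`, integer(1), 1L)
    cd <- DataFrame(plate_id = tab$plate_id[o][first],
                    well = well[o][first],
                    strain_id = tab$strain_id[o][first],
                    replicate = as.integer(tab$replicate[o][first]))
    extra <- intersect(c("compound_id", "concentration", "role"), colnames(tab))
    for (cc in extra) {
      v <- tab[[cc]][o][first]
      cd[[cc]] <- if (cc == "concentration") as.numeric(v) else v
    }
    GrowthCurveSet(times0, odm, cd)
  } else {
    tcols <- setdiff(colnames(tab),
                     c(meta_cols, "compound_id", "concentration", "role"))
    times <- suppressWarnings(as.numeric(sub("^[tT]", "", tcols)))
    .stopIfNot(all(is.finite(times)), "wide dialect: time columns must be ",
               "numeric (optionally prefixed 't')")
    o <- order(times)
    odm <- matrix(NA_real_, nrow = nrow(tab), ncol = length(tcols))
    for (j in seq_along(tcols)) {
      odm[, j] <- .parseNumStrict(tab[[tcols[j]]], paste0("OD (", tcols[j], ")"),
                                  seq_len(nrow(tab)))
    }
    key <- paste(tab$plate_id, normalizeWell(tab$well), tab$replicate)
    if (anyDuplicated(key)) {
      stop("duplicate (plate, well, replicate) row(s): ",
           paste(head(which(duplicated(key)), 5L), collapse = ", "),
           call. = FALSE)
    }
    cd <- DataFrame(plate_id = tab$plate_id, well = normalizeWell(tab$well),
                    strain_id = tab$strain_id,
                    replicate = as.integer(tab$replicate))
    extra <- intersect(c("compound_id", "concentration", "role"), colnames(tab))
    for (cc in extra) {
      v <- tab[[cc]]
      cd[[cc]] <- if (cc == "concentration") as.numeric(v) else v
    }
    GrowthCurveSet(times[o], odm[, o, drop = FALSE], cd)
  }
}

#' Write plate-reader time series
#'
#' Inverse of \code{\link{readPlateTimeseries}}; writes a long or wide
#' tab-separated file that round-trips through the reader.
#'
#' @param curves a \linkS4class{GrowthCurveSet}.
#' @param path output path.
#' @param dialect \code{"long"} or \code{"wide"}.
#' @return \code{path}, invisibly.
#' @export
writePlateTimeseries <- function(curves, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  cd <- as.data.frame(curveData(curves))
  od <- odMatrix(curves)
  times <- curveTimes(curves)
  if (dialect == "long") {
    n <- nrow(od)
    k <- length(times)
    out <- cd[rep(seq_len(n), each = k), , drop = FALSE]
    out$time <- rep(times, n)
    out$od <- as.vector(t(od))
  } else {
    out <- cd
    tm <- as.data.frame(od)
    colnames(tm) <- paste0("t", times)
    out <- cbind(out, tm)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a plate map
#'
#' Reads a tabular plate layout with mandatory header columns \code{well},
#' \code{content}, \code{concentration} and \code{role} (an optional
#' \code{plate_id} column names the plate). Rejects unknown role tokens,
#' duplicate wells and plates without vehicle-control wells.
#'
#' @param path file path.
#' @return a \linkS4class{PlateMap}.
#' @export
readPlateMap <- function(path) {
  tab <- .readTable(path)
  need <- c("well", "content", "concentration", "role")
  .stopIfNot(all(need %in% colnames(tab)),
             "plate map must declare columns: ", paste(need, collapse = ", "))
  conc <- .parseNumStrict(tab$concentration, "concentration")
  pid <- if ("plate_id" %in% colnames(tab)) unique(tab$plate_id) else "plate1"
  .stopIfNot(length(pid) == 1L, "one plate map file per plate")
  PlateMap(pid, tab$well, tab$content, conc, tab$role)
}

#' Write a plate map
#'
#' @param map a \linkS4class{PlateMap}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePlateMap <- function(map, path) {
  w <- as.data.frame(wells(map))
  out <- data.frame(plate_id = plateId(map), well = rownames(w),
                    content = w$content_id, concentration = w$concentration,
                    role = w$role)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a variableStep wiggle track of insertion counts
#'
#' Writes per-position insertion read counts as a 1-based variableStep wiggle
#' track (the input convention of transposon-fitness tools).
#'
#' @param siteCounts named numeric vector, names are 1-based positions.
#' @param chrom chromosome/contig name for the track header.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeWig <- function(siteCounts, chrom, path) {
  pos <- as.numeric(names(siteCounts))
  .stopIfNot(length(siteCounts) == 0L ||
               (all(is.finite(pos)) && all(pos >= 1) && all(pos == round(pos))),
             "wiggle positions must be positive 1-based integers")
  .stopIfNot(all(siteCounts >= 0), "wiggle counts must be nonnegative")
  o <- order(pos)
  lines <- c(sprintf("variableStep chrom=%s", chrom),
             if (length(siteCounts)) {
               sprintf("%d %s", as.integer(pos[o]),
                       format(unname(siteCounts[o]), trim = TRUE,
                              scientific = FALSE))
             })
  writeLines(lines, path)
  invisible(path)
}

#' Read a variableStep wiggle track
#'
#' @param path wiggle file written by \code{\link{writeWig}}.
#' @return list with \code{chrom} and \code{counts} (named numeric vector,
#'   names are positions).
#' @export
readWig <- function(path) {
  lines <- readLines(path)
  .stopIfNot(length(lines) >= 1L && grepl("^variableStep chrom=", lines[1L]),
             "not a variableStep wiggle file")
  chrom <- sub("^variableStep chrom=", "", lines[1L])
  body <- lines[-1L][nzchar(lines[-1L])]
  if (length(body) == 0L) return(list(chrom = chrom, counts = setNames(numeric(0), character(0))))
  parts <- strsplit(body, "[ \t]+")
  pos <- vapply(parts, `[`, character(1), 1L)
  val <- .parseNumStrict(vapply(parts, `[`, character(1), 2L), "wiggle count")
  list(chrom = chrom, counts = setNames(val, pos))
}
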