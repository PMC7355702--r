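#' Construct a single-sample GC-MS scan run
#'
#' A `sample_run` bundles the raw scan registers of one chromatographic
#' acquisition: (retention time, m/z, intensity) triples in scan order,
#' together with the sample identifier and an optional binary class label
#' (1 = treated, 0 = non-treated, `NA` = unknown).
#'
#' @param sample_id Non-empty character scalar.
#' @param time Retention times in minutes (>= 0).
#' @param mz Mass-to-charge values in amu (> 0).
#' @param intensity Non-negative intensities (arbitrary counts).
#' @param label Optional class label: 0, 1 or `NA`.
#' @return An object of class `sample_run`: a list with elements
#'   `sample_id`, `label` and `records` (a data frame with columns
#'   `time`, `mz`, `intensity`).
#' @export
sample_run <- function(sample_id, time, mz, intensity, label = NA_integer_) {
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id))
    stop("'sample_id' must be a non-empty character scalar")
  n <- length(time)
  if (n == 0L) stop("a sample_run must contain at least one scan register")
  if (length(mz) != n || length(intensity) != n)
    stop("'time', 'mz' and 'intensity' must have equal length")
  if (any(!is.finite(time)) || any(time < 0)) stop("retention times must be finite and >= 0")
  if (any(!is.finite(mz)) || any(mz <= 0)) stop("m/z values must be finite and > 0")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and >= 0")
  if (!is.na(label) && !label %in% c(0, 1)) stop("'label' must be 0, 1 or NA")
  structure(
    list(sample_id = sample_id,
         label = if (is.na(label)) NA_integer_ else as.integer(label),
         records = data.frame(time = as.numeric(time), mz = as.numeric(mz),
                              intensity = as.numeric(intensity))),
    class = "sample_run")
}

#' @export
print.sample_run <- function(x, ...) {
  cat(sprintf("<sample_run> '%s'  %d registers, RT %.3f-%.3f min, label: %s\n",
              x$sample_id, nrow(x$records), min(x$records$time),
              max(x$records$time),
              if (is.na(x$label)) "unknown" else x$label))
  invisible(x)
}

#' Read MS1 scans from an mzML file
#'
#' Reads all MS1-level spectra through `mzR` and flattens them into one
#' scan register per (scan, peak) pair. Retention times are converted to
#' minutes. Scan order is preserved.
#'
#' @param path Path to an mzML file.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @param label Optional binary class label.
#' @return A [sample_run].
#' @export
read_mzml <- function(path, sample_id = NULL, label = NA_integer_) {
  if (!file.exists(path)) stop("mzML file not found: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  ms <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("failed to parse mzML file '", path,
                                          "': ", conditionMessage(e)))
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::header(ms)
  ms1 <- which(hdr$msLevel == 1L)
  if (length(ms1) == 0L) stop("no MS1 scans in mzML file: ", path)
  pieces <- vector("list", length(ms1))
  for (i in seq_along(ms1)) {
    pk <- tryCatch(mzR::peaks(ms, ms1[i]),
                   error = function(e) stop("failed to read scan ", ms1[i],
                                            " of '", path, "': ",
                                            conditionMessage(e)))
    if (is.null(dim(pk)) || nrow(pk) == 0L) next
    pieces[[i]] <- data.frame(time = hdr$retentionTime[ms1[i]] / 60,
                              mz = pk[, 1L], intensity = pk[, 2L])
  }
  rec <- do.call(rbind, pieces)
  if (is.null(rec) || nrow(rec) == 0L) stop("mzML file contains no peaks: ", path)
  sample_run(sample_id, rec$time, rec$mz, rec$intensity, label = label)
}

#' Write a sample run to mzML
#'
#' Registers sharing a retention time are grouped into one spectrum.
#' Times are written in seconds (the mzML convention).
#'
#' @param run A [sample_run].
#' @param path Output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "sample_run"))
  rec <- run$records
  times <- sort(unique(rec$time))
  idx <- match(rec$time, times)
  pk <- lapply(seq_along(times), function(i) {
    r <- rec[idx == i, , drop = FALSE]
    r <- r[order(r$mz), , drop = FALSE]
    cbind(mz = r$mz, intensity = r$intensity)
  })
  ns <- length(times)
  hdr <- data.frame(
    seqNum = seq_len(ns), acquisitionNum = seq_len(ns), msLevel = 1L,
    polarity = 1L, peaksCount = vapply(pk, nrow, 0L),
    totIonCurrent = vapply(pk, function(p) sum(p[, 2L]), 0),
    retentionTime = times * 60,
    basePeakMZ = vapply(pk, function(p) p[which.max(p[, 2L]), 1L], 0),
    basePeakIntensity = vapply(pk, function(p) max(p[, 2L]), 0),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(pk, function(p) min(p[, 1L]), 0),
    highMZ = vapply(pk, function(p) max(p[, 1L]), 0),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(ns)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_)
  mzR::writeMSData(pk, path, header = hdr)
  invisible(path)
}

.sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file (no header): ", path)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a long-format scan table
#'
#' Reads a delimited text table with header columns `sample_id`,
#' `time_min`, `mz`, `intensity` (comma- or tab-delimited, auto-sniffed)
#' and groups rows by sample into [sample_run] objects.
#'
#' @param path Path to the table.
#' @param sep Field separator; `NULL` (default) sniffs the header line.
#' @return A named list of [sample_run] objects, in order of first
#'   appearance of each `sample_id`.
#' @export
read_long_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- .sniff_sep(path)
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  need <- c("sample_id", "time_min", "mz", "intensity")
  miss <- setdiff(need, trimws(header))
  if (length(miss))
    stop("missing column(s) in '", path, "': ", paste(miss, collapse = ", "))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(list())
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at line ",
           bad[1L] + 1L, " of ", path)
    v
  }
  tm <- num("time_min"); mz <- num("mz"); it <- num("intensity")
  neg <- which(it < 0)
  if (length(neg))
    stop("negative intensity at line ", neg[1L] + 1L, " of ", path)
  ids <- df$sample_id
  out <- lapply(unique(ids), function(id) {
    i <- which(ids == id)
    sample_run(id, tm[i], mz[i], it[i])
  })
  names(out) <- unique(ids)
  out
}

#' Write sample runs as a long-format scan table
#'
#' @param runs A [sample_run] or list of them.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_long_table <- function(runs, path, sep = ",") {
  if (inherits(runs, "sample_run")) runs <- list(runs)
  df <- do.call(rbind, lapply(runs, function(r)
    data.frame(sample_id = r$sample_id, time_min = r$records$time,
               mz = r$records$mz, intensity = r$records$intensity)))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample-labels table
#'
#' Two-column delimited text (`sample_id`, `label`) with labels 0/1.
#'
#' @param path Path to the labels file.
#' @return Named integer vector of labels, named by sample id.
#' @export
read_labels <- function(path) {
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(df)))
    stop("labels file must have columns sample_id, label: ", path)
  if (!all(df$label %in% c(0, 1)))
    stop("labels must be 0 or 1: ", path)
  stats::setNames(as.integer(df$label), df$sample_id)
}

#' Apply a labels table to a list of runs
#'
#' @param runs List of [sample_run] objects.
#' @param labels Named 0/1 vector as returned by [read_labels()].
#' @return The runs, with `label` fields filled in.
#' @export
apply_labels <- function(runs, labels) {
  lapply(runs, function(r) {
    if (r$sample_id %in% names(labels)) r$label <- labels[[r$sample_id]]
    r
  })
}

#' Extracted-ion chromatogram summed over an ion set
#'
#' For each scan time, sums the intensities whose m/z falls within the
#' half-open window `[ion - tolerance, ion + tolerance)` of any listed
#' ion. The half-open convention makes double counting at window
#' boundaries impossible, so the trace is additive over disjoint ion
#' sets.
#'
#' @param run A [sample_run].
#' @param ions Integer ion masses (amu); must be non-empty.
#' @param tolerance Window half-width in amu (>= 0); default 0.25.
#' @return Data frame with columns `time` (strictly increasing, one row
#'   per scan time present in the run) and `intensity`.
#' @export
extract_xic <- function(run, ions, tolerance = 0.25) {
  stopifnot(inherits(run, "sample_run"))
  if (length(ions) == 0L) stop("'ions' must contain at least one ion mass")
  if (!is.numeric(tolerance) || tolerance < 0) stop("'tolerance' must be >= 0")
  rec <- run$records
  hit <- rep(FALSE, nrow(rec))
  for (ion in ions)
    hit <- hit | (rec$mz >= ion - tolerance & rec$mz < ion + tolerance)
  times <- sort(unique(rec$time))
  val <- numeric(length(times))
  if (any(hit)) {
    s <- rowsum(rec$intensity[hit], match(rec$time[hit], times))
    val[as.integer(rownames(s))] <- s[, 1L]
  }
  data.frame(time = times, intensity = val)
}

#' Write an extracted-ion chromatogram as two-column text
#'
#' @param xic Data frame from [extract_xic()].
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_xic <- function(xic, path, sep = ",") {
  utils::write.table(data.frame(time_min = xic$time, intensity = xic$intensity),
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
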