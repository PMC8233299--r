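.FORMAT_EXT <- "\\.(nii|nii\\.gz|txt|csv|tsv)$"

.detect_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti4d"
  else if (grepl("\\.(txt|csv|tsv)$", path, ignore.case = TRUE)) "delimited_text"
  else .n3l_stop(sprintf("cannot infer format of '%s'", path),
                 "n3lband_io_error")
}

.read_delim_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  toks <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1L]]
  header <- any(is.na(suppressWarnings(as.numeric(toks))))
  as.matrix(utils::read.table(path, header = header, sep = sep))
}

#' Read a time-series container
#'
#' Reads either a 4D NIfTI volume (time along the 4th dimension; voxels are
#' flattened to rows with the x index fastest, so a write restores the
#' original order exactly) or a delimited text matrix (rows = timepoints,
#' columns = units). The repetition time is taken from, in order of
#' precedence: the explicit `trSeconds` argument, then the NIfTI header.
#' Text files carry no timing metadata, so `trSeconds` is required for them.
#'
#' @param path input file.
#' @param format "auto" (by extension), "nifti4d" or "delimited_text".
#' @param trSeconds repetition time override in seconds.
#' @param unitKind unit kind for the result; defaults to "voxel" for NIfTI
#'   and "parcel" for text.
#' @return a \linkS4class{TimeSeriesMatrix}; NIfTI inputs carry their header
#'   and spatial dimensions as attributes so \code{\link{writeDecoded}} can
#'   restore them.
#' @export
readTimeSeries <- function(path, format = c("auto", "nifti4d",
                                            "delimited_text"),
                           trSeconds = NULL, unitKind = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    .n3l_stop(sprintf("no such file: '%s'", path), "n3lband_io_error")
  if (format == "auto") format <- .detect_format(path)
  if (format == "nifti4d") {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 4L)
      .n3l_stop(sprintf("'%s' is not a 4D volume", path), "n3lband_io_error")
    hdrTr <- RNifti::pixdim(img)[4L]
    tr <- trSeconds
    if (is.null(tr)) {
      if (!is.finite(hdrTr) || hdrTr <= 0)
        .n3l_stop("NIfTI header carries no usable TR; supply trSeconds",
                  "n3lband_data_error")
      tr <- hdrTr
    } else if (is.finite(hdrTr) && hdrTr > 0 &&
               abs(hdrTr - tr) > 1e-6 * max(tr, hdrTr)) {
      warning(sprintf("header TR %g s conflicts with supplied %g s; using %g",
                      hdrTr, tr, tr))
    }
    spec <- samplingSpec(trSeconds = tr, nSamples = d[4L])
    vals <- matrix(as.vector(img), nrow = prod(d[1:3]), ncol = d[4L])
    ts <- timeSeriesMatrix(vals, spec,
                           unitKind = if (is.null(unitKind)) "voxel" else unitKind)
    attr(ts, "niftiHeader") <- RNifti::niftiHeader(img)
    attr(ts, "spatialDim") <- d[1:3]
    ts
  } else {
    if (is.null(trSeconds))
      .n3l_stop("delimited text carries no TR; supply trSeconds",
                "n3lband_data_error")
    m <- .read_delim_matrix(path)             # timepoints x units
    spec <- samplingSpec(trSeconds = trSeconds, nSamples = nrow(m))
    timeSeriesMatrix(t(m), spec,
                     unitKind = if (is.null(unitKind)) "parcel" else unitKind)
  }
}

#' Write a decoded series to per-band files plus a boundary CSV
#'
#' One output file per band, named `<stem>_<bandname>.<ext>`, in the same
#' container format as the input (NIfTI with the source header and affine
#' restored, or delimited text with rows = timepoints), plus
#' `<stem>_boundaries.csv` with the band boundary table.
#'
#' @param decoded a \linkS4class{DecodedSeries}.
#' @param outDir output directory (created if absent).
#' @param stem file name stem.
#' @param reference the \linkS4class{TimeSeriesMatrix} the decomposition was
#'   computed from; required to restore NIfTI geometry. If it carries no
#'   NIfTI header, text output is written.
#' @return character vector of paths written, invisibly.
#' @export
writeDecoded <- function(decoded, outDir, stem, reference = NULL) {
  stopifnot(is(decoded, "DecodedSeries"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hdr <- if (!is.null(reference)) attr(reference, "niftiHeader") else NULL
  sdim <- if (!is.null(reference)) attr(reference, "spatialDim") else NULL
  paths <- character(0)
  for (nm in names(decoded@components)) {
    comp <- decoded@components[[nm]]
    if (!is.null(hdr)) {
      p <- file.path(outDir, sprintf("%s_%s.nii.gz", stem, nm))
      arr <- array(comp, dim = c(sdim, ncol(comp)))
      RNifti::writeNifti(RNifti::asNifti(arr, reference = hdr), p)
    } else {
      p <- file.path(outDir, sprintf("%s_%s.txt", stem, nm))
      utils::write.table(t(comp), p, row.names = FALSE, col.names = FALSE)
    }
    paths <- c(paths, p)
  }
  csv <- file.path(outDir, sprintf("%s_boundaries.csv", stem))
  writeBoundariesCsv(decoded@bandSet, csv)
  invisible(c(paths, csv))
}

#' Discover subject data in a CCS-style work directory
#'
#' A CCS-style tree holds one directory per subject under the work
#' directory, with the data file inside the subject directory or a data
#' subdirectory. One manifest entry is produced per subject (the
#' lexicographically first matching file); subjects without a matching,
#' readable file are skipped with a warning. Ordering is lexicographic in
#' subject id.
#'
#' @param workDir the work directory.
#' @param filePattern regular expression the data file must match
#'   (default: NIfTI or delimited-text extensions).
#' @return a data.frame manifest with columns subject_id, path, format.
#' @export
scanCcsTree <- function(workDir, filePattern = .FORMAT_EXT) {
  if (!dir.exists(workDir))
    .n3l_stop(sprintf("no such directory: '%s'", workDir), "n3lband_io_error")
  subjects <- sort(list.dirs(workDir, recursive = FALSE, full.names = FALSE))
  rows <- list()
  for (s in subjects) {
    f <- sort(list.files(file.path(workDir, s), pattern = filePattern,
                         recursive = TRUE, full.names = TRUE))
    f <- f[file.access(f, 4L) == 0L]
    if (length(f) == 0L) {
      warning(sprintf("subject '%s': no readable data file; skipped", s))
      next
    }
    rows[[s]] <- data.frame(subject_id = s, path = f[1L],
                            format = .detect_format(f[1L]),
                            tr_seconds = NA_real_, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    warning("empty tree: no subjects with data found")
    return(data.frame(subject_id = character(0), path = character(0),
                      format = character(0), tr_seconds = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Discover functional runs in a BIDS-style directory
#'
#' Scans `sub-*/[ses-*/]func` for bold runs (`*_bold.nii[.gz]` or delimited
#' text), keys entries by the sub-/ses-/task- entities, and reads the
#' repetition time from the JSON sidecar when present. Entries without a
#' sidecar get `tr_seconds = NA`; decoding such an entry requires an
#' explicit TR.
#'
#' @param root BIDS root directory.
#' @return a data.frame manifest with columns subject_id, session, task,
#'   path, format, tr_seconds.
#' @export
scanBidsTree <- function(root) {
  if (!dir.exists(root))
    .n3l_stop(sprintf("no such directory: '%s'", root), "n3lband_io_error")
  subs <- sort(list.files(root, pattern = "^sub-"))
  subs <- subs[dir.exists(file.path(root, subs))]
  bad <- sort(setdiff(list.dirs(root, recursive = FALSE, full.names = FALSE),
                      c(subs, c("derivatives", "code", "sourcedata"))))
  for (b in bad) warning(sprintf("non-BIDS directory '%s' skipped", b))
  rows <- list()
  for (s in subs) {
    sesDirs <- sort(list.files(file.path(root, s), pattern = "^ses-"))
    sesDirs <- sesDirs[dir.exists(file.path(root, s, sesDirs))]
    funcDirs <- if (length(sesDirs) > 0L)
      file.path(root, s, sesDirs, "func") else file.path(root, s, "func")
    for (fd in funcDirs[dir.exists(funcDirs)]) {
      runs <- sort(list.files(fd, pattern = "_bold\\.(nii(\\.gz)?|tsv|txt|csv)$",
                              full.names = TRUE))
      for (r in runs) {
        base <- sub("\\.(nii(\\.gz)?|tsv|txt|csv)$", "", basename(r))
        ent <- function(key) {
          m <- regmatches(base, regexpr(sprintf("%s-[A-Za-z0-9]+", key), base))
          if (length(m) == 0L) NA_character_ else sub(sprintf("^%s-", key), "", m)
        }
        sidecar <- file.path(fd, paste0(base, ".json"))
        tr <- NA_real_
        if (file.exists(sidecar)) {
          meta <- jsonlite::read_json(sidecar)
          if (!is.null(meta$RepetitionTime)) tr <- as.numeric(meta$RepetitionTime)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = ent("sub"), session = ent("ses"), task = ent("task"),
          path = r, format = .detect_format(r), tr_seconds = tr,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    warning("no BIDS functional runs found")
    return(data.frame(subject_id = character(0), session = character(0),
                      task = character(0), path = character(0),
                      format = character(0), tr_seconds = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a six-parameter motion log
#'
#' Whitespace- or comma-delimited text, one row per timepoint, six columns:
#' three translations (mm) then three rotations (degrees). The zeroed
#' timepoint defaults to the first row where all six parameters are exactly
#' zero (the calibration reset), or 1 if none is.
#'
#' @param path text file.
#' @param spec a \linkS4class{SamplingSpec} (its sample count must match the
#'   row count) or NULL with `fsHz` given.
#' @param fsHz sampling rate, used if `spec` is NULL.
#' @param zeroIndex explicit zeroed-sample index (1-based), or NULL to detect.
#' @return a \linkS4class{MotionTrace}.
#' @export
readMotionLog <- function(path, spec = NULL, fsHz = NULL, zeroIndex = NULL) {
  m <- .read_delim_matrix(path)
  if (ncol(m) != 6L)
    .n3l_stop(sprintf("motion log '%s' has %d columns, expected 6",
                      path, ncol(m)), "n3lband_data_error")
  if (is.null(spec)) {
    if (is.null(fsHz))
      .n3l_stop("supply spec or fsHz for the motion log", "n3lband_data_error")
    spec <- samplingSpec(fsHz = fsHz, nSamples = nrow(m))
  }
  if (nSamples(spec) != nrow(m))
    .n3l_stop("motion log length does not match the sampling spec",
              "n3lband_data_error")
  if (is.null(zeroIndex)) {
    z <- which(rowSums(abs(m)) == 0)
    zeroIndex <- if (length(z) > 0L) z[1L] else 1L
  }
  motionTrace(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE], spec,
              zeroIndex = zeroIndex)
}
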