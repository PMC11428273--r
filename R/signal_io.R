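#' ROI time-series container
#'
#' Bundles one subject's region-averaged BOLD signals as a regions x
#' timepoints matrix together with region labels and the sampling interval
#' (TR, seconds). This is the unit every other stage of the pipeline
#' consumes: rows are atlas regions, columns are scan volumes.
#'
#' @param subject_id character scalar identifying the subject.
#' @param data numeric matrix, regions x timepoints; all entries finite.
#' @param region_labels character vector of unique region names, one per row.
#' @param tr_seconds positive sampling interval in seconds (repetition time).
#' @return An object of class `roi_series`.
#' @examples
#' x <- roi_series("s1", matrix(rnorm(20), 2, 10), c("PCC", "mPFC"), 0.72)
#' dim(x$data)
#' @export
roi_series <- function(subject_id, data, region_labels, tr_seconds) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  obj <- structure(
    list(subject_id = as.character(subject_id),
         region_labels = as.character(region_labels),
         data = data,
         tr_seconds = as.numeric(tr_seconds)),
    class = "roi_series")
  validate_roi_series(obj)
}

validate_roi_series <- function(x) {
  stopifnot(inherits(x, "roi_series"))
  if (length(x$subject_id) != 1L || !nzchar(x$subject_id))
    stop("subject_id must be a non-empty string")
  if (length(x$tr_seconds) != 1L || !is.finite(x$tr_seconds) || x$tr_seconds <= 0)
    stop("tr_seconds must be a positive number")
  if (length(x$region_labels) == 0L)
    stop("region_labels must be non-empty")
  if (anyDuplicated(x$region_labels))
    stop("region_labels must be unique; duplicated: ",
         paste(unique(x$region_labels[duplicated(x$region_labels)]), collapse = ", "))
  if (nrow(x$data) != length(x$region_labels))
    stop("data has ", nrow(x$data), " rows but ", length(x$region_labels),
         " region labels")
  if (ncol(x$data) < 2L)
    stop("need at least 2 timepoints, got ", ncol(x$data))
  if (!all(is.finite(x$data))) {
    bad <- which(!is.finite(x$data), arr.ind = TRUE)[1L, ]
    stop("non-finite value in data at region ", bad[1L], " (",
         x$region_labels[bad[1L]], "), timepoint ", bad[2L])
  }
  x
}

#' @export
print.roi_series <- function(x, ...) {
  cat(sprintf("<roi_series> subject '%s': %d regions x %d timepoints, TR = %g s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Cohort of ROI time series
#'
#' A cohort is an ordered list of [roi_series()] objects sharing the same
#' region set (labels and order) and the same TR, so that decomposition,
#' model fitting and reliability analyses can be run subject-wise and
#' aggregated edge-wise.
#'
#' @param subjects list of `roi_series` objects.
#' @return An object of class `roi_cohort`.
#' @export
roi_cohort <- function(subjects) {
  if (!length(subjects)) stop("cohort must contain at least one subject")
  if (!all(vapply(subjects, inherits, logical(1), "roi_series")))
    stop("all cohort members must be roi_series objects")
  ref <- subjects[[1L]]
  for (s in subjects) {
    if (!identical(s$region_labels, ref$region_labels))
      stop("subject '", s$subject_id, "' has different region labels than '",
           ref$subject_id, "'")
    if (!identical(s$tr_seconds, ref$tr_seconds))
      stop("subject '", s$subject_id, "' has different tr_seconds than '",
           ref$subject_id, "'")
  }
  ids <- vapply(subjects, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) stop("duplicate subject ids in cohort")
  structure(list(subjects = subjects), class = "roi_cohort")
}

#' @export
print.roi_cohort <- function(x, ...) {
  cat(sprintf("<roi_cohort> %d subjects, %d regions, TR = %g s\n",
              length(x$subjects), nrow(x$subjects[[1L]]$data),
              x$subjects[[1L]]$tr_seconds))
  invisible(x)
}

#' Read a ROI time-series table
#'
#' Reads a delimited table whose first column holds region labels and whose
#' remaining columns are numeric timepoints (one column per TR). A header
#' row is detected automatically and skipped. The delimiter is inferred from
#' the file extension (`.csv` = comma, otherwise tab).
#'
#' @param path file path.
#' @param tr_seconds sampling interval in seconds, carried as metadata.
#' @param subject_id optional subject id; defaults to the file base name.
#' @return A validated [roi_series()].
#' @export
read_roi_table <- function(path, tr_seconds, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = FALSE, quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 3L) stop("table must have a label column plus >= 2 timepoints")
  # header row: every data cell in row 1 must parse as numeric, else drop it
  first_vals <- suppressWarnings(as.numeric(unlist(raw[1L, -1L])))
  if (anyNA(first_vals)) raw <- raw[-1L, , drop = FALSE]
  if (!nrow(raw)) stop("no data rows in ", path)
  labels <- as.character(raw[[1L]])
  mat <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L)
  for (j in seq_len(ncol(raw) - 1L)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) & !(trimws(raw[[j + 1L]]) %in% c("NA", "NaN")))
    if (length(bad))
      stop("malformed numeric cell at row ", bad[1L], ", column ", j + 1L,
           " ('", raw[[j + 1L]][bad[1L]], "') in ", path)
    mat[, j] <- v
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  roi_series(subject_id, mat, labels, tr_seconds)
}

#' Write a ROI time-series table
#'
#' Inverse of [read_roi_table()]: writes labels in the first column and the
#' series in full double precision so a read/write round trip reproduces the
#' object to within float-formatting tolerance.
#'
#' @param series a [roi_series()].
#' @param path output file path (`.csv` = comma-separated, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_roi_table <- function(series, path) {
  validate_roi_series(series)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  num <- format(series$data, digits = 17, trim = TRUE, scientific = TRUE)
  out <- cbind(series$region_labels, matrix(num, nrow(series$data)))
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Write a cohort as a directory of tables plus a manifest
#'
#' The container is a directory holding one TSV per subject and a
#' `manifest.json` recording subject order, file names, region labels and
#' TR, so a cohort round-trips without loss.
#'
#' @param cohort a [roi_cohort()].
#' @param dir output directory (created if needed).
#' @param force overwrite an existing manifest.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, force = FALSE) {
  stopifnot(inherits(cohort, "roi_cohort"))
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path) && !force)
    stop("manifest already exists in ", dir, " (use force = TRUE to overwrite)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    files[i] <- paste0(gsub("[^A-Za-z0-9._-]", "_", s$subject_id), ".tsv")
    write_roi_table(s, file.path(dir, files[i]))
  }
  manifest <- list(
    container = "boldcast-cohort",
    tr_seconds = cohort$subjects[[1L]]$tr_seconds,
    region_labels = cohort$subjects[[1L]]$region_labels,
    subjects = data.frame(
      subject_id = vapply(cohort$subjects, `[[`, character(1), "subject_id"),
      file = files, stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort container directory
#'
#' @param dir directory written by [write_cohort()].
#' @return A [roi_cohort()].
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  subs <- lapply(seq_len(nrow(manifest$subjects)), function(i) {
    read_roi_table(file.path(dir, manifest$subjects$file[i]),
                   tr_seconds = manifest$tr_seconds,
                   subject_id = manifest$subjects$subject_id[i])
  })
  roi_cohort(subs)
}
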