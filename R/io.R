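#' Read an EEG recording from disk
#'
#' Two formats are supported: EDF, and tab/whitespace-delimited numeric text
#' with a header row of channel labels and one column per channel. For text
#' input the sampling rate is not stored in the file and must be supplied.
#' Channel labels are normalized to canonical 10-20 spelling.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"edf"` or `"text"`.
#' @param fs sampling rate in Hz; required for text input, ignored for EDF.
#' @param subject_id optional subject identifier.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "text"),
                           fs = NULL, subject_id = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "text"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edf") {
    rec <- read_edf(path, subject_id = subject_id)
  } else {
    if (is.null(fs)) stop("sampling rate required for delimited text input")
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE)
    if (ncol(tab) < 1L || nrow(tab) < 1L) stop("unreadable delimited file")
    m <- t(as.matrix(tab))
    if (!is.numeric(m)) stop("non-numeric sample values")
    rec <- eeg_recording(m, fs = fs,
                         channel_labels = normalize_channel_labels(colnames(tab)),
                         subject_id = if (is.null(subject_id)) "" else subject_id)
  }
  rec
}

#' Write a recording as delimited text
#'
#' One column per channel, header row of labels, tab separated, full double
#' precision. The sampling rate is not stored; keep it in the metadata.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @export
write_recording_text <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rec$channel_labels, collapse = "\t"), con)
  m <- t(rec$samples)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a feature table
#'
#' A feature table is a data frame with a `subject_id` column followed by one
#' numeric column per feature; feature names follow the package conventions
#' `rp.<band>.<scope>`, `fiwbic.<bandA>_<bandB>.<scope>`,
#' `coh.<band>.<chA>-<chB>` / `coh.<band>.global` and
#' `ent.<estimator>.<scope>`. Provenance (config hash, package version) is
#' kept in attributes and survives the TSV round trip.
#'
#' @param subject_id character vector of subject ids.
#' @param values numeric matrix, subjects x features, with column names.
#' @param provenance optional named character vector.
#' @return A `feature_table` (data frame subclass).
#' @export
feature_table <- function(subject_id, values, provenance = character()) {
  values <- as.matrix(values)
  if (length(subject_id) != nrow(values) && nrow(values) > 0)
    stop("one row of values per subject required")
  if (is.null(colnames(values)) && ncol(values) > 0)
    stop("feature names required")
  if (anyDuplicated(colnames(values))) stop("duplicate feature names")
  df <- data.frame(subject_id = as.character(subject_id),
                   stringsAsFactors = FALSE)
  if (ncol(values) > 0) df <- cbind(df, as.data.frame(values))
  rownames(df) <- NULL
  attr(df, "provenance") <- provenance
  class(df) <- c("feature_table", "data.frame")
  df
}

#' @export
feature_names <- function(ft) setdiff(colnames(ft), "subject_id")

#' Write a feature table as TSV
#'
#' Values are serialized with 17 significant digits so the read/write round
#' trip is exact in double precision; missing values become `NA`. Provenance
#' attributes are stored in `#!` comment lines before the header.
#'
#' @param ft a [feature_table()].
#' @param path output path.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  con <- file(path, "w")
  on.exit(close(con))
  prov <- attr(ft, "provenance")
  if (length(prov))
    writeLines(sprintf("#! %s=%s", names(prov), unname(prov)), con)
  fn <- feature_names(ft)
  writeLines(paste(c("subject_id", fn), collapse = "\t"), con)
  if (nrow(ft) > 0) {
    vals <- as.matrix(ft[, fn, drop = FALSE])
    txt <- matrix(sprintf("%.17g", vals), nrow = nrow(vals))
    txt[is.na(vals)] <- "NA"
    writeLines(paste(ft$subject_id,
                     apply(txt, 1, paste, collapse = "\t"),
                     sep = if (length(fn)) "\t" else ""), con)
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path TSV path.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  provlines <- grep("^#! ", lines, value = TRUE)
  prov <- character()
  if (length(provlines)) {
    kv <- sub("^#! ", "", provlines)
    eq <- regexpr("=", kv, fixed = TRUE)
    prov <- structure(substring(kv, eq + 1L), names = substring(kv, 1L, eq - 1L))
  }
  body <- lines[!startsWith(lines, "#! ")]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  fn <- header[-1]
  if (length(body) > 1L) {
    cells <- strsplit(body[-1], "\t", fixed = TRUE)
    ids <- vapply(cells, `[`, character(1), 1L)
    vals <- t(vapply(cells, function(r)
      suppressWarnings(as.numeric(r[-1])), numeric(length(fn))))
    if (length(fn) == 1L) vals <- matrix(vals, ncol = 1L)
    colnames(vals) <- fn
  } else {
    ids <- character(0)
    vals <- matrix(numeric(0), 0, length(fn), dimnames = list(NULL, fn))
  }
  feature_table(ids, vals, provenance = prov)
}

#' Write / read the subject metadata table
#'
#' Columns: `subject_id`, `group` (`WS` or `control`), `structural_flag`,
#' `genetic_flag` (0/1).
#'
#' @param meta data frame with the four columns.
#' @param path TSV path.
#' @export
write_subject_meta <- function(meta, path) {
  need <- c("subject_id", "group", "structural_flag", "genetic_flag")
  stopifnot(all(need %in% colnames(meta)))
  utils::write.table(meta[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_meta
#' @export
read_subject_meta <- function(path) {
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!all(meta$group %in% c("WS", "control")))
    stop("group must be 'WS' or 'control'")
  if (anyNA(meta$structural_flag) || anyNA(meta$genetic_flag))
    stop("etiology flags must be non-missing")
  meta
}
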