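#' Read a spectrum from a two-column text file
#'
#' Accepts whitespace- or comma-separated (wavenumber, intensity) pairs, with
#' up to 5 non-numeric header lines which are skipped. A descending axis is
#' re-sorted ascending with a warning.
#'
#' @param path File path.
#' @param meta Optional named list of metadata to attach.
#' @return A [raman_spectrum()].
#' @export
read_spectrum <- function(path, meta = list()) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parse_row <- function(l) {
    parts <- strsplit(trimws(l), "[,;[:space:]]+")[[1]]
    suppressWarnings(as.numeric(parts))
  }
  rows <- lapply(lines, parse_row)
  numeric_row <- vapply(rows, function(r) length(r) >= 2 && !anyNA(r[1:2]), TRUE)
  first <- which(numeric_row)[1]
  if (is.na(first)) stop("no numeric (wavenumber, intensity) rows in ", path)
  if (first > 6) stop("more than 5 non-numeric header lines in ", path)
  if (!all(numeric_row[first:length(rows)])) {
    stop("non-numeric or ragged rows after data start in ", path)
  }
  ncols <- vapply(rows[first:length(rows)], length, 1L)
  if (length(unique(ncols)) != 1) stop("ragged rows in ", path)
  m <- do.call(rbind, rows[first:length(rows)])
  w <- m[, 1]; y <- m[, 2]
  if (anyNA(w) || anyNA(y)) stop("NaN/NA values in ", path)
  if (all(diff(w) < 0)) {
    warning("descending wavenumber axis in ", path, "; re-sorting ascending")
    o <- order(w); w <- w[o]; y <- y[o]
  }
  raman_spectrum(w, y, meta = meta)
}

#' Write a spectrum as two-column text
#'
#' Full-precision (17 significant digits) so that write/read round-trips are
#' lossless.
#'
#' @param s A [raman_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "raman_spectrum"))
  txt <- sprintf("%.17g %.17g", s$wavenumber, s$intensity)
  writeLines(txt, path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with columns `file`, `subject`, `cohort` and
#' optionally `site`, `accumulation`, `true_ratio`. Paths are resolved
#' relative to the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @param check_files Verify that every referenced spectrum file exists.
#' @return Data frame with an absolute `file` column.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "subject", "cohort")
  missing <- setdiff(need, names(man))
  if (length(missing)) {
    stop("manifest lacks required column(s): ", paste(missing, collapse = ", "))
  }
  man$file <- file.path(dirname(path), man$file)
  if (check_files) {
    absent <- man$file[!file.exists(man$file)]
    if (length(absent)) stop("manifest references missing files: ",
                             paste(utils::head(absent, 3), collapse = ", "))
  }
  if (all(c("site", "accumulation") %in% names(man))) {
    key <- paste(man$subject, man$site, man$accumulation)
    if (anyDuplicated(key)) {
      stop("(subject, site, accumulation) must be unique in a manifest")
    }
  }
  man
}

#' Load the spectra listed in a manifest into a set
#'
#' @param manifest Data frame from [read_manifest()].
#' @return A [spectrum_set()] whose metadata are the manifest columns.
#' @export
load_manifest_spectra <- function(manifest) {
  spectra <- lapply(seq_len(nrow(manifest)), function(i) {
    read_spectrum(manifest$file[i],
                  meta = as.list(manifest[i, setdiff(names(manifest), "file"),
                                          drop = FALSE]))
  })
  bind_spectra(spectra)
}

#' Write a spectrum set to a directory plus manifest
#'
#' One two-column text file per spectrum and a `manifest.csv` tying files to
#' subject, cohort, site, accumulation and (for synthetic data) true ratio.
#'
#' @param set A [spectrum_set()].
#' @param dir Output directory, created if needed.
#' @return Path of the written manifest, invisibly.
#' @export
write_spectrum_set <- function(set, dir) {
  stopifnot(inherits(set, "spectrum_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(set$intensity)
  files <- sprintf("spectrum_%04d.txt", seq_len(n))
  for (i in seq_len(n)) write_spectrum(set_spectrum(set, i), file.path(dir, files[i]))
  man <- cbind(data.frame(file = files, stringsAsFactors = FALSE), set$meta)
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  invisible(man_path)
}
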