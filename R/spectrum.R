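#' Construct an FTIR transmission spectrum
#'
#' A spectrum is a pair of equal-length numeric vectors (wavenumber in
#' 1/cm, absorbance) plus optional sample metadata. Wavenumbers may be
#' supplied in either direction but are stored descending (4000 -> 400),
#' the usual infrared presentation.
#'
#' @param wavenumber numeric vector of wavenumbers (1/cm), strictly
#'   monotonic in either direction, length >= 2, all finite.
#' @param absorbance numeric vector of absorbance values, same length.
#' @param meta optional sample key as returned by
#'   [parse_library_filename()], i.e. a list with elements `species`,
#'   `replicate`, `grinding`.
#' @param source free-text provenance (file name, generator call, ...).
#' @return An object of class `ftir_spectrum`: a list with elements
#'   `wavenumber` (descending), `absorbance`, `meta`, `source`.
#' @examples
#' s <- ftir_spectrum(c(1034, 1030), c(1.0, 0.98))
#' s$wavenumber
#' @export
ftir_spectrum <- function(wavenumber, absorbance, meta = NULL, source = "") {
  wavenumber <- as.numeric(wavenumber)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumber) != length(absorbance))
    stop("wavenumber and absorbance must have the same length")
  if (length(wavenumber) < 2)
    stop("a spectrum needs at least 2 points")
  if (!all(is.finite(wavenumber)) || !all(is.finite(absorbance)))
    stop("all spectral values must be finite")
  d <- diff(wavenumber)
  if (all(d > 0)) {
    wavenumber <- rev(wavenumber)
    absorbance <- rev(absorbance)
  } else if (!all(d < 0)) {
    stop("wavenumbers must be strictly monotonic")
  }
  structure(list(wavenumber = wavenumber, absorbance = absorbance,
                 meta = meta, source = source),
            class = "ftir_spectrum")
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf("FTIR spectrum: %d points, %.0f-%.0f 1/cm\n",
              length(x$wavenumber), max(x$wavenumber), min(x$wavenumber)))
  if (!is.null(x$meta))
    cat(sprintf("  sample: %s, curve %d, grinding %d\n",
                x$meta$species, x$meta$replicate, x$meta$grinding))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' @export
range.ftir_spectrum <- function(..., na.rm = FALSE) {
  range(..1$wavenumber)
}

.is_numeric_token <- function(x) {
  suppressWarnings(!is.na(as.numeric(x)))
}

#' Read a two-column spectrum from CSV
#'
#' Reads (wavenumber, absorbance) rows. The field delimiter is
#' auto-detected among comma, semicolon and tab unless forced; when the
#' delimiter is a semicolon, a decimal comma is tolerated (European
#' instrument exports). Leading non-numeric header rows are skipped.
#'
#' @param file path to a CSV file, a connection, or a character vector of
#'   lines (`text` input).
#' @param sep field delimiter; `NULL` (default) auto-detects among
#'   `","`, `";"`, `"\t"`.
#' @param meta,source passed to [ftir_spectrum()]; `source` defaults to
#'   the file path.
#' @return An [ftir_spectrum()].
#' @seealso [write_spectrum_csv()]
#' @export
read_spectrum_csv <- function(file, sep = NULL, meta = NULL, source = NULL) {
  if (is.character(file) && length(file) == 1 && !file.exists(file) &&
      grepl("[\n,;\t]", file)) {
    lines <- strsplit(file, "\n", fixed = TRUE)[[1]]
    if (is.null(source)) source <- "text"
  } else if (is.character(file) && length(file) > 1) {
    lines <- file
    if (is.null(source)) source <- "text"
  } else {
    lines <- readLines(file, warn = FALSE)
    if (is.null(source) && is.character(file)) source <- file
    if (is.null(source)) source <- "connection"
  }
  lines_trim <- trimws(lines)
  keep <- nzchar(lines_trim)
  if (!any(keep)) stop("empty input: no rows to parse")

  # detect delimiter from the first line holding two numeric fields
  detect <- function(line) {
    for (cand in c("\t", ";", ",")) {
      f <- strsplit(line, cand, fixed = TRUE)[[1]]
      f <- trimws(f)
      if (length(f) >= 2) {
        if (cand == ";") f <- gsub(",", ".", f, fixed = TRUE)
        if (all(.is_numeric_token(f[1:2]))) return(cand)
      }
    }
    NA_character_
  }
  if (is.null(sep)) {
    for (ln in lines_trim[keep]) {
      sep <- detect(ln)
      if (!is.na(sep)) break
    }
    if (is.null(sep) || is.na(sep))
      stop("could not detect a delimiter with two numeric columns")
  }

  w <- numeric(0); a <- numeric(0)
  data_started <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines_trim[i]
    if (!nzchar(ln)) next
    f <- trimws(strsplit(ln, sep, fixed = TRUE)[[1]])
    if (sep == ";") f <- gsub(",", ".", f, fixed = TRUE)
    vals <- if (length(f) >= 2) suppressWarnings(as.numeric(f[1:2])) else c(NA, NA)
    if (any(is.na(vals))) {
      if (!data_started) next  # header row(s)
      stop(sprintf("parse error at line %d: %s", i, lines[i]))
    }
    data_started <- TRUE
    w <- c(w, vals[1]); a <- c(a, vals[2])
  }
  if (length(w) < 2) stop("fewer than 2 data points in input")
  ftir_spectrum(w, a, meta = meta, source = source)
}

#' Write a spectrum as two-column CSV
#'
#' Writes wavenumber-descending rows at full double precision so that
#' write/read round-trips are exact. Metadata is not embedded; the file
#' name carries the sample key by convention.
#'
#' @param s an [ftir_spectrum()].
#' @param file path or connection; a character vector of lines is
#'   returned invisibly either way.
#' @param header write a `wavenumber,absorbance` header row (default TRUE).
#' @export
write_spectrum_csv <- function(s, file, header = TRUE) {
  stopifnot(inherits(s, "ftir_spectrum"))
  rows <- sprintf("%.17g,%.17g", s$wavenumber, s$absorbance)
  if (header) rows <- c("wavenumber,absorbance", rows)
  writeLines(rows, file)
  invisible(rows)
}

#' Parse a deposited-library file name into a sample key
#'
#' The reference library names spectra `<Species><curve>_<grinding>`,
#' e.g. `"Giraffe2_03"` for the third grinding of the second giraffe
#' grinding curve. Any file extension is stripped first.
#'
#' @param name file name or path.
#' @return A list (class `sample_key`) with `species` (character),
#'   `replicate` (integer, the grinding-curve number) and `grinding`
#'   (integer, position within the curve).
#' @examples
#' parse_library_filename("Giraffe2_03.csv")
#' @export
parse_library_filename <- function(name) {
  base <- tools::file_path_sans_ext(basename(name))
  m <- regmatches(base, regexec("^([A-Za-z]+?)([0-9]+)_([0-9]+)$", base))[[1]]
  if (length(m) != 4)
    stop(sprintf("file name %s does not follow <Species><curve>_<grinding>",
                 sQuote(base)))
  key <- list(species = m[2],
              replicate = as.integer(m[3]),
              grinding = as.integer(m[4]))
  if (key$replicate < 1 || key$grinding < 1)
    stop("replicate and grinding indices must be >= 1")
  class(key) <- "sample_key"
  key
}

#' @export
format.sample_key <- function(x, ...) {
  sprintf("%s%d_%02d", x$species, x$replicate, x$grinding)
}

#' @export
print.sample_key <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Load a folder of library spectra
#'
#' Reads every CSV in a folder whose name parses as a sample key, the
#' layout of the deposited reference archive. Files that do not match the
#' naming convention or fail to parse are skipped and listed in the
#' manifest rather than aborting the load.
#'
#' @param path directory holding spectra.
#' @param pattern file-name filter, default `"\\.csv$"` (case-insensitive).
#' @return A list with
#'   \describe{
#'     \item{spectra}{named list of [ftir_spectrum()], keyed
#'       `Species<curve>_<grinding>`;}
#'     \item{index}{data frame (file, species, replicate, grinding);}
#'     \item{skipped}{data frame (file, reason) of files not loaded.}
#'   }
#' @export
load_library_folder <- function(path, pattern = "\\.csv$") {
  if (!dir.exists(path)) stop("directory does not exist: ", path)
  files <- list.files(path, pattern = pattern, ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0) stop("no spectra matching ", pattern, " in ", path)
  spectra <- list()
  src_of <- character(0)
  idx <- list(); skipped <- list()
  for (f in files) {
    key <- tryCatch(parse_library_filename(f), error = function(e) e)
    if (inherits(key, "error")) {
      skipped[[length(skipped) + 1]] <-
        data.frame(file = basename(f), reason = "name does not parse")
      next
    }
    id <- format(key)
    if (!is.null(spectra[[id]]))
      stop(sprintf("duplicate sample key %s from files %s and %s",
                   id, src_of[[id]], basename(f)))
    s <- tryCatch(read_spectrum_csv(f, meta = key), error = function(e) e)
    if (inherits(s, "error")) {
      skipped[[length(skipped) + 1]] <-
        data.frame(file = basename(f), reason = conditionMessage(s))
      next
    }
    spectra[[id]] <- s
    src_of[id] <- basename(f)
    idx[[length(idx) + 1]] <-
      data.frame(file = basename(f), species = key$species,
                 replicate = key$replicate, grinding = key$grinding)
  }
  index <- if (length(idx)) do.call(rbind, idx) else
    data.frame(file = character(0), species = character(0),
               replicate = integer(0), grinding = integer(0))
  skip <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(file = character(0), reason = character(0))
  list(spectra = spectra, index = index, skipped = skip)
}
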