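# JCAMP-DX interchange support. Read path covers XYPOINTS=(XY..XY) and
# XYDATA=(X++(Y..Y)) with AFFN ordinates or ASDF compression (SQZ, DIF,
# DUP). Write path emits uncompressed AFFN XYPOINTS at full precision.

# ASDF pseudo-digit tables
.sqz_chars <- c("@", LETTERS[1:9], letters[1:9])
.sqz_vals  <- c(0, 1:9, -(1:9))
.dif_chars <- c("%", LETTERS[10:18], letters[10:18])
.dif_vals  <- c(0, 1:9, -(1:9))
.dup_chars <- c(LETTERS[19:26], "s")
.dup_vals  <- 1:9

.jcamp_tokens <- function(line) {
  # split a data line into AFFN numbers and ASDF tokens
  pat <- "[+-]?[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?|[@A-Za-z%][0-9]*\\.?[0-9]*"
  regmatches(line, gregexpr(pat, line))[[1]]
}

.decode_asdf_line <- function(tokens, last_y, in_dif) {
  # returns list(y = ordinates, last_mode = "dif"/"sqz", check_first = bool)
  y <- numeric(0)
  mode <- "sqz"
  last_diff <- NA_real_
  for (tk in tokens) {
    c1 <- substr(tk, 1, 1)
    rest <- substr(tk, 2, nchar(tk))
    if (c1 %in% .dup_chars) {
      n <- .dup_vals[match(c1, .dup_chars)]
      if (nchar(rest))
        n <- as.numeric(paste0(n, rest))
      if (n < 2) next
      if (mode == "dif") {
        for (i in seq_len(n - 1)) {
          last_y <- last_y + last_diff
          y <- c(y, last_y)
        }
      } else {
        y <- c(y, rep(last_y, n - 1))
      }
    } else if (c1 %in% .dif_chars) {
      d <- .dif_vals[match(c1, .dif_chars)]
      val <- if (nchar(rest)) sign(d + 0.5) * as.numeric(paste0(abs(d), rest)) else d
      if (c1 == "%" && nchar(rest)) val <- as.numeric(rest)
      last_diff <- val
      last_y <- last_y + val
      y <- c(y, last_y)
      mode <- "dif"
    } else if (c1 %in% .sqz_chars) {
      v <- .sqz_vals[match(c1, .sqz_chars)]
      val <- if (nchar(rest)) {
        sgn <- if (v < 0) -1 else 1
        sgn * as.numeric(paste0(abs(v), rest))
      } else v
      if (c1 == "@" && nchar(rest)) val <- as.numeric(rest)
      last_y <- val
      y <- c(y, val)
      mode <- "sqz"
    } else {
      # plain AFFN ordinate
      last_y <- as.numeric(tk)
      y <- c(y, last_y)
      mode <- "sqz"
    }
  }
  list(y = y, mode = mode, last_y = last_y)
}

#' Read a JCAMP-DX spectrum
#'
#' Supports `XYPOINTS=(XY..XY)` pair tables and `XYDATA=(X++(Y..Y))`
#' tables in AFFN or ASDF-compressed (SQZ/DIF/DUP) form, honouring
#' `XFACTOR`, `YFACTOR`, `FIRSTX`, `LASTX` and `NPOINTS`. The result
#' follows the same invariants as the CSV reader.
#'
#' @param file path, connection, or character vector of lines.
#' @param meta,source as in [read_spectrum_csv()].
#' @return An [ftir_spectrum()].
#' @export
read_jcamp <- function(file, meta = NULL, source = NULL) {
  if (is.character(file) && length(file) > 1) {
    lines <- file
    if (is.null(source)) source <- "text"
  } else if (is.character(file) && length(file) == 1 && !file.exists(file) &&
             grepl("##", file, fixed = TRUE)) {
    lines <- strsplit(file, "\n", fixed = TRUE)[[1]]
    if (is.null(source)) source <- "text"
  } else {
    lines <- readLines(file, warn = FALSE)
    if (is.null(source)) source <- if (is.character(file)) file else "connection"
  }
  lines <- sub("\\$\\$.*$", "", lines)  # strip comments

  # gather label records
  is_ldr <- grepl("^\\s*##", lines)
  if (!any(is_ldr)) stop("not a JCAMP-DX stream: no ## labels found")
  starts <- which(is_ldr)
  ldr <- list()
  for (k in seq_along(starts)) {
    i <- starts[k]
    j <- if (k < length(starts)) starts[k + 1] - 1 else length(lines)
    m <- regmatches(lines[i], regexec("^\\s*##([^=]*)=(.*)$", lines[i]))[[1]]
    if (length(m) != 3) next
    label <- toupper(gsub("[ _/-]", "", m[2]))
    ldr[[label]] <- list(value = trimws(m[3]),
                         body = if (j > i) lines[(i + 1):j] else character(0))
  }
  num <- function(label, default = NULL) {
    if (!is.null(ldr[[label]])) return(as.numeric(ldr[[label]]$value))
    if (is.null(default)) stop("JCAMP record missing required ##", label)
    default
  }

  if (!is.null(ldr$XYPOINTS)) {
    body <- ldr$XYPOINTS$body
    xf <- num("XFACTOR", 1); yf <- num("YFACTOR", 1)
    toks <- unlist(lapply(body, function(l)
      regmatches(l, gregexpr("[+-]?[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?", l))[[1]]))
    vals <- as.numeric(toks)
    if (length(vals) < 4 || length(vals) %% 2 != 0)
      stop("XYPOINTS table malformed")
    w <- vals[seq(1, length(vals), by = 2)] * xf
    a <- vals[seq(2, length(vals), by = 2)] * yf
    return(ftir_spectrum(w, a, meta = meta, source = source))
  }

  if (is.null(ldr$XYDATA))
    stop("JCAMP stream has neither ##XYDATA nor ##XYPOINTS")
  firstx <- num("FIRSTX"); lastx <- num("LASTX"); npts <- num("NPOINTS")
  yf <- num("YFACTOR", 1)
  body <- ldr$XYDATA$body
  y <- numeric(0)
  prev_dif <- FALSE
  last_y <- NA_real_
  for (ln in body) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    toks <- .jcamp_tokens(ln)
    if (length(toks) < 2) next
    dec <- .decode_asdf_line(toks[-1], last_y, prev_dif)
    ys <- dec$y
    if (prev_dif && length(ys)) {
      # first ordinate of a line following DIF mode is an X-sequence check
      if (abs(ys[1] - y[length(y)]) > max(1e-6, 1e-9 * abs(ys[1])))
        stop("JCAMP DIF checkpoint mismatch")
      ys <- ys[-1]
    }
    y <- c(y, ys)
    last_y <- if (length(y)) y[length(y)] else NA_real_
    prev_dif <- dec$mode == "dif"
  }
  if (length(y) != npts)
    stop(sprintf("JCAMP NPOINTS=%d but %d ordinates decoded", npts, length(y)))
  w <- seq(firstx, lastx, length.out = npts)
  ftir_spectrum(w, y * yf, meta = meta, source = source)
}

#' Write a spectrum as JCAMP-DX
#'
#' Emits an uncompressed AFFN `XYPOINTS=(XY..XY)` table at full double
#' precision, so CSV and JCAMP encodings of the same spectrum yield
#' identical band metrics downstream.
#'
#' @param s an [ftir_spectrum()].
#' @param file path or connection.
#' @param title value for the `##TITLE` record.
#' @export
write_jcamp <- function(s, file, title = "enamel spectrum") {
  stopifnot(inherits(s, "ftir_spectrum"))
  hdr <- c(sprintf("##TITLE=%s", title),
           "##JCAMP-DX=4.24",
           "##DATA TYPE=INFRARED SPECTRUM",
           "##XUNITS=1/CM",
           "##YUNITS=ABSORBANCE",
           sprintf("##NPOINTS=%d", length(s$wavenumber)),
           sprintf("##FIRSTX=%.17g", s$wavenumber[1]),
           sprintf("##LASTX=%.17g", s$wavenumber[length(s$wavenumber)]),
           "##XFACTOR=1", "##YFACTOR=1",
           "##XYPOINTS=(XY..XY)")
  rows <- sprintf("%.17g, %.17g", s$wavenumber, s$absorbance)
  writeLines(c(hdr, rows, "##END="), file)
  invisible(NULL)
}
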