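# Independent oracles and fixture builders used across the suite.

# analytic sum of Gaussian bands, optionally on a drifting background
gauss_sum <- function(w, centers, amps, sigmas, drift = function(w) 0) {
  y <- drift(w)
  for (i in seq_along(centers))
    y <- y + amps[i] * exp(-(w - centers[i])^2 / (2 * sigmas[i]^2))
  y
}

# a 4 1/cm acquisition grid aligned so that 1034 (and 604/565 via the
# shared 2 mod 4 phase... 604 %% 4 == 0, grid holds multiples of 2) is
# sampled exactly: 2002, 1998, ..., 398
aligned_grid <- function(hi = 2002, lo = 398, step = 4) seq(hi, lo, by = -step)

# Dense-grid brute-force FWHM: evaluates the analytic model on a 0.01
# 1/cm grid, corrects against the straight line through the anchors, and
# takes nearest-sample half-height crossings (no interpolation) -- an
# independent path from the package's scan-and-interpolate.
oracle_fwhm <- function(f, window = c(1100, 950), baseline = c(2000, 400),
                        step = 0.01) {
  w <- seq(baseline[1], baseline[2], by = -step)
  y <- f(w)
  bl <- y[1] + (y[length(y)] - y[1]) * (w - w[1]) / (w[length(w)] - w[1])
  y <- y - bl
  win <- which(w <= window[1] & w >= window[2])
  ipk <- win[which.max(y[win])]
  half <- y[ipk] / 2
  i_left <- max(which(y[1:ipk] < half))            # higher wavenumber side
  i_right <- ipk - 1 + min(which(y[ipk:length(y)] < half))
  list(fwhm = w[i_left] - w[i_right], peak = w[ipk], height = y[ipk])
}

# Dense-grid brute-force IRSF on the nu4 region.
oracle_irsf <- function(f, window_a = c(615, 595), window_b = c(580, 550),
                        baseline = c(820, 400), step = 0.01) {
  w <- seq(baseline[1], baseline[2], by = -step)
  y <- f(w)
  bl <- y[1] + (y[length(y)] - y[1]) * (w - w[1]) / (w[length(w)] - w[1])
  y <- y - bl
  pk <- function(win) {
    idx <- which(w <= win[1] & w >= win[2])
    idx[which.max(y[idx])]
  }
  ia <- pk(window_a); ib <- pk(window_b)
  mid <- which(w < w[ia] & w > w[ib])
  iv <- mid[which.min(y[mid])]
  list(irsf = (y[ia] + y[ib]) / y[iv],
       heights = c(y[ia], y[ib], y[iv]))
}

# --- JCAMP fixture encoders (independent of the package's writer) ----

# plain AFFN (X++(Y..Y)) encoding, integer-scaled ordinates
jcamp_xydata_affn <- function(s, yfactor = 1e-08, perline = 6) {
  yi <- round(s$absorbance / yfactor)
  n <- length(yi)
  lines <- c(sprintf("##TITLE=fixture"), "##JCAMP-DX=4.24",
             "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
             sprintf("##FIRSTX=%.10g", s$wavenumber[1]),
             sprintf("##LASTX=%.10g", s$wavenumber[n]),
             sprintf("##NPOINTS=%d", n),
             sprintf("##YFACTOR=%.17g", yfactor),
             "##XFACTOR=1",
             "##XYDATA=(X++(Y..Y))")
  i <- 1
  while (i <= n) {
    j <- min(i + perline - 1, n)
    lines <- c(lines, paste(c(sprintf("%.10g", s$wavenumber[i]),
                              sprintf("%d", yi[i:j])), collapse = " "))
    i <- j + 1
  }
  c(lines, "##END=")
}

.sqz_encode <- function(n) {
  digs <- as.character(abs(n))
  first <- as.integer(substr(digs, 1, 1))
  head <- if (n < 0) letters[first] else c("@", LETTERS[1:9])[first + 1]
  paste0(head, substr(digs, 2, nchar(digs)))
}
.dif_encode <- function(n) {
  digs <- as.character(abs(n))
  first <- as.integer(substr(digs, 1, 1))
  head <- if (n < 0) letters[9 + first] else c("%", LETTERS[10:18])[first + 1]
  paste0(head, substr(digs, 2, nchar(digs)))
}
.dup_encode <- function(n) {
  digs <- as.character(n)
  first <- as.integer(substr(digs, 1, 1))
  paste0(c(LETTERS[19:26], "s")[first], substr(digs, 2, nchar(digs)))
}

# DIFDUP-compressed encoding: first ordinate of each line in SQZ form
# (the DIF-mode line check), successive ordinates as differences, runs
# of equal differences collapsed with DUP counts (count = total
# occurrences of the token).
jcamp_xydata_difdup <- function(s, yfactor = 1e-08, perline = 10) {
  yi <- round(s$absorbance / yfactor)
  n <- length(yi)
  hdr <- c("##TITLE=fixture difdup", "##JCAMP-DX=4.24",
           "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
           sprintf("##FIRSTX=%.10g", s$wavenumber[1]),
           sprintf("##LASTX=%.10g", s$wavenumber[n]),
           sprintf("##NPOINTS=%d", n),
           sprintf("##YFACTOR=%.17g", yfactor),
           "##XFACTOR=1",
           "##XYDATA=(X++(Y..Y))")
  body <- character(0)
  i <- 1
  first_line <- TRUE
  while (i <= n) {
    j <- min(i + perline - 1, n)
    # line covers ordinates i..j; start index for the check token
    start <- if (first_line) i else i - 1
    toks <- .sqz_encode(yi[start])
    difs <- diff(yi[start:j])
    k <- 1
    while (k <= length(difs)) {
      run <- 1
      while (k + run <= length(difs) && difs[k + run] == difs[k]) run <- run + 1
      toks <- c(toks, .dif_encode(difs[k]))
      if (run > 1) toks <- c(toks, .dup_encode(run))
      k <- k + run
    }
    body <- c(body, paste0(sprintf("%.10g", s$wavenumber[start]),
                           paste(toks, collapse = "")))
    first_line <- FALSE
    i <- j + 1
  }
  c(hdr, body, "##END=")
}

# a small but spectroscopically complete synthetic folder
make_mini_library <- function(dir, species = c("Giraffe", "Impala"),
                              crystallinity = c(0.85, 0.95),
                              n_replicates = 2, n_grindings = 3, seed = 11) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_synthetic_library(dir, seed = seed, species = species,
                          crystallinity = crystallinity,
                          n_replicates = n_replicates,
                          n_grindings = n_grindings)
}
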