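# Synthetic enamel-like FTIR spectra with controllable atomic order and
# grinding-dependent particle-size broadening, so the whole pipeline is
# testable without the deposited archive.
#
# Model: a sum of Gaussian bands (nu3 main + shoulder, nu4 doublet,
# carbonate nu2/nu3, broad structural OH) convolved with a Gaussian
# particle-size kernel of width k (analytically: variances add and band
# area is conserved), plus a scattering baseline that shrinks as k does,
# plus white noise. Atomic order is expressed as a latent straight line
# in the (IRSF, FWHM) plane: higher crystallinity lowers the line at
# matched IRSF. For each grinding level the generator SOLVES the kernel
# width (against the target IRSF) and the nu3 width scale (against the
# line's FWHM at that IRSF) so that, noise-free, the measured statistics
# of the emitted 4 1/cm spectrum sit exactly on the latent line: points
# are collinear by construction and grinding moves them along the curve,
# while crystallinity moves the curve itself.

.default_band_set <- function() {
  data.frame(
    band   = c("v3_main", "v3_shoulder", "v4_604", "v4_565",
               "co3_1455", "co3_1415", "co3_872", "oh_broad"),
    center = c(1034, 1096, 604, 565, 1455, 1415, 872, 3400),
    amplitude = c(1.00, 0.35, 0.50, 0.45, 0.16, 0.18, 0.06, 0.12),
    sigma  = c(24, 22, 10, 11, 20, 20, 9, 180),
    group  = c("v3", "v3", "v4", "v4", "co3", "co3", "co3", "oh"),
    stringsAsFactors = FALSE)
}

#' Parameters for the synthetic enamel-spectrum generator
#'
#' @param crystallinity atomic-order parameter in (0, 1]; higher order
#'   lowers the sample's FWHM-vs-IRSF line: the FWHM anchor is
#'   `fwhm_anchor / crystallinity`.
#' @param band_set data frame (band, center, amplitude, sigma, group) of
#'   Gaussian components; default models nu3 (1034 main + 1096
#'   shoulder), the nu4 doublet (604, 565), carbonate (1455, 1415, 872)
#'   and broad OH (~3400).
#' @param irsf_targets increasing IRSF reached at grinding levels
#'   1..n (default c(2.7, 3.4, 4.1)); grinding reduces particle size,
#'   sharpening the nu4 doublet.
#' @param fwhm_anchor,fwhm_slope,irsf_anchor the latent line: at
#'   `crystallinity = 1`, FWHM equals `fwhm_anchor` (1/cm) at
#'   `IRSF = irsf_anchor` and changes by `fwhm_slope` (1/cm per IRSF
#'   unit, negative) along the curve.
#' @param grinding_kernel_widths optional decreasing vector of Gaussian
#'   particle-size kernel widths (1/cm) per grinding level. When given,
#'   the generator runs in forward mode (no calibration) and the latent
#'   line is only approximate; default `NULL` solves the widths from
#'   `irsf_targets`.
#' @param baseline_drift `c(slope, curvature)` of the scattering
#'   baseline `drift(w) = scale * (slope*(w-400) + curvature*(w-400)^2)`,
#'   where `scale` shrinks with the kernel width (coarser particles
#'   scatter more).
#' @param noise_sd white-noise standard deviation, absorbance units.
#' @param replicate_jitter_sd per-replicate vertical jitter of the
#'   latent line, 1/cm of FWHM (a fresh aliquot ground by the same
#'   operator).
#' @param irsf_jitter_sd per-grinding jitter of the IRSF target
#'   (grinding vigour is subjective); moves the point along the line,
#'   not off it.
#' @param seed integer master seed; all randomness is derived from it.
#' @return list of class `synth_params`.
#' @export
synth_params <- function(crystallinity = 0.9,
                         band_set = .default_band_set(),
                         irsf_targets = c(2.7, 3.4, 4.1),
                         fwhm_anchor = 52, fwhm_slope = -7,
                         irsf_anchor = 3.4,
                         grinding_kernel_widths = NULL,
                         baseline_drift = c(slope = 5e-05, curvature = 5e-09),
                         noise_sd = 0.002,
                         replicate_jitter_sd = 0.4,
                         irsf_jitter_sd = 0.05,
                         seed = 1L) {
  if (crystallinity <= 0 || crystallinity > 1)
    stop("crystallinity must be in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.unsorted(irsf_targets, strictly = TRUE))
    stop("irsf_targets must be strictly increasing")
  if (!is.null(grinding_kernel_widths) &&
      is.unsorted(rev(grinding_kernel_widths), strictly = TRUE))
    stop("grinding_kernel_widths must be strictly decreasing")
  structure(list(crystallinity = crystallinity, band_set = band_set,
                 irsf_targets = irsf_targets,
                 fwhm_anchor = fwhm_anchor, fwhm_slope = fwhm_slope,
                 irsf_anchor = irsf_anchor,
                 grinding_kernel_widths = grinding_kernel_widths,
                 baseline_drift = baseline_drift,
                 noise_sd = noise_sd,
                 replicate_jitter_sd = replicate_jitter_sd,
                 irsf_jitter_sd = irsf_jitter_sd,
                 seed = as.integer(seed)),
            class = "synth_params")
}

# run expr with a private RNG stream, restoring the caller's state
.with_stream <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.stream_seed <- function(seed, replicate, g = 0L) {
  (abs(seed) * 48271 + replicate * 7919 + g * 131 + 17) %% 2147483629L
}

#' Default spectral grid of the generator
#' @param hi,lo,step grid bounds and spacing in 1/cm.
#' @return descending wavenumber vector (default 4000 -> 400 at 4 1/cm).
#' @export
synth_grid <- function(hi = 4000, lo = 400, step = 4) {
  if (hi <= lo || step <= 0) stop("invalid grid specification")
  seq(hi, lo, by = -step)
}

# noise-free spectrum values on a grid for kernel width k and nu3 width
# scale v3_scale
.synth_clean <- function(p, k, v3_scale, grid) {
  bs <- p$band_set
  sig <- bs$sigma
  sig[bs$group == "v3"] <- sig[bs$group == "v3"] * v3_scale
  sig_eff <- sqrt(sig^2 + k^2)
  amp_eff <- bs$amplitude * sig / sig_eff   # area-conserving convolution
  A <- exp(-outer(grid, bs$center, "-")^2 /
             rep(2 * sig_eff^2, each = length(grid))) %*% amp_eff
  x <- grid - 400
  drift <- (k / 10) * (p$baseline_drift[[1]] * x + p$baseline_drift[[2]] * x^2)
  as.vector(A) + drift
}

.measure <- function(p, k, v3_scale, grid) {
  s <- ftir_spectrum(grid, .synth_clean(p, k, v3_scale, grid))
  list(spectrum = s,
       irsf = compute_irsf_v4(s)$irsf,
       fwhm = compute_fwhm_v3(s)$fwhm)
}

# solve kernel width so the measured IRSF hits target (IRSF decreases
# monotonically with k: coarser particles blur the nu4 valley). The
# upper bound stays below the width at which the default doublet merges.
.solve_kernel <- function(p, irsf_target, grid) {
  f <- function(k) compute_irsf_v4(
    ftir_spectrum(grid, .synth_clean(p, k, 1, grid)))$irsf - irsf_target
  r <- tryCatch(stats::uniroot(f, lower = 0.3, upper = 14, tol = 1e-08),
                error = function(e)
                  stop("cannot reach IRSF target ", signif(irsf_target, 4),
                       " with this band set: ", conditionMessage(e),
                       call. = FALSE))
  r$root
}

# solve the nu3 width scale so the measured FWHM hits target
.solve_v3_scale <- function(p, k, fwhm_target, grid) {
  f <- function(sc) compute_fwhm_v3(
    ftir_spectrum(grid, .synth_clean(p, k, sc, grid)))$fwhm - fwhm_target
  stats::uniroot(f, lower = 0.25, upper = 3.5, tol = 1e-09)$root
}

#' Synthesise one enamel-like spectrum
#'
#' @param p a [synth_params()] object.
#' @param g grinding level (1 = coarsest).
#' @param replicate replicate-curve index (drives the per-replicate
#'   jitter stream).
#' @param grid wavenumber grid, default [synth_grid()].
#' @param species label written into the sample key.
#' @return An [ftir_spectrum()] with attribute `truth`: a list with the
#'   solved kernel width `k`, `v3_scale`, and the noise-free measured
#'   `irsf` and `fwhm` targets.
#' @examples
#' s <- synth_spectrum(synth_params(seed = 7), g = 2)
#' compute_band_metrics(s)
#' @export
synth_spectrum <- function(p, g, replicate = 1L, grid = synth_grid(),
                           species = "Synthetic") {
  series <- synth_grinding_series(p, n_grindings = max(g, length(p$irsf_targets)),
                                  replicate = replicate, grid = grid,
                                  species = species)
  series[[g]]
}

#' Synthesise a grinding series (one grinding curve)
#'
#' One spectrum per grinding level, sharing the replicate's latent line
#' jitter; successive levels have strictly decreasing particle-size
#' kernel widths, so noise-free FWHM decreases and IRSF increases with
#' grinding.
#'
#' @inheritParams synth_spectrum
#' @param n_grindings number of grinding levels (>= 2; default 3, the
#'   standard design).
#' @return list of [ftir_spectrum()] with sample keys
#'   `(species, replicate, 1..n)` and per-spectrum `truth` attributes;
#'   the list carries attribute `truth` collecting the targets.
#' @export
synth_grinding_series <- function(p, n_grindings = 3, replicate = 1L,
                                  grid = synth_grid(), species = "Synthetic") {
  stopifnot(inherits(p, "synth_params"))
  if (n_grindings < 2) stop("n_grindings must be >= 2")
  targets <- p$irsf_targets
  if (length(targets) != n_grindings)
    targets <- seq(min(targets), max(targets), length.out = n_grindings)

  jit <- .with_stream(.stream_seed(p$seed, replicate), {
    list(line = stats::rnorm(1, 0, p$replicate_jitter_sd),
         irsf = stats::rnorm(n_grindings, 0, p$irsf_jitter_sd))
  })
  anchor_fwhm <- p$fwhm_anchor / p$crystallinity + jit$line

  out <- vector("list", n_grindings)
  truth <- vector("list", n_grindings)
  forward <- !is.null(p$grinding_kernel_widths)
  if (forward && length(p$grinding_kernel_widths) < n_grindings)
    stop("grinding_kernel_widths shorter than n_grindings")
  for (g in seq_len(n_grindings)) {
    if (forward) {
      k <- p$grinding_kernel_widths[g]
      sc <- 1 / p$crystallinity
      m <- .measure(p, k, sc, grid)
      t_irsf <- m$irsf; t_fwhm <- m$fwhm
    } else {
      t_irsf <- targets[g] + jit$irsf[g]
      t_fwhm <- anchor_fwhm + p$fwhm_slope * (t_irsf - p$irsf_anchor)
      # solvers only need the region their statistic reads; the
      # sub-grids share the emitted grid's points, so the calibrated
      # metrics are identical to full-grid evaluation
      g_irsf <- grid[grid <= 910]
      g_fwhm <- grid[grid <= 2150]
      k <- .solve_kernel(p, t_irsf, g_irsf)
      sc <- .solve_v3_scale(p, k, t_fwhm, g_fwhm)
    }
    clean <- .synth_clean(p, k, sc, grid)
    noise <- if (p$noise_sd > 0)
      .with_stream(.stream_seed(p$seed, replicate, g),
                   stats::rnorm(length(grid), 0, p$noise_sd))
    else 0
    key <- structure(list(species = species, replicate = as.integer(replicate),
                          grinding = as.integer(g)), class = "sample_key")
    s <- ftir_spectrum(grid, clean + noise, meta = key,
                       source = sprintf("synth(seed=%d)", p$seed))
    attr(s, "truth") <- list(k = k, v3_scale = sc,
                             irsf = t_irsf, fwhm = t_fwhm)
    out[[g]] <- s
    truth[[g]] <- data.frame(replicate = replicate, grinding = g,
                             kernel_width = k, irsf = t_irsf, fwhm = t_fwhm)
  }
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

#' Crystallinity shift producing a target vertical offset
#'
#' Inverts the latent-line anchor `fwhm_anchor / crystallinity`: returns
#' the shift to add to `p$crystallinity` so the shifted sample's line
#' sits `offset` 1/cm above (positive) or below (negative, more ordered)
#' the unshifted one at matched IRSF.
#'
#' @param p a [synth_params()] object.
#' @param offset desired vertical offset in 1/cm of FWHM.
#' @export
shift_for_offset <- function(p, offset) {
  c_new <- p$fwhm_anchor / (p$fwhm_anchor / p$crystallinity + offset)
  if (c_new <= 0 || c_new > 1)
    stop(sprintf("offset %g 1/cm needs crystallinity %.3f outside (0, 1]",
                 offset, c_new))
  c_new - p$crystallinity
}

#' Synthesise a reference set plus fossil test samples
#'
#' Emulates a screening study: `n_reference_replicates` grinding curves
#' from the reference parameters, and one test grinding curve per fossil
#' with its crystallinity shifted. The truth table records each fossil's
#' injected vertical offset (exact, by the latent-line construction) and
#' the label the generator's own thresholding rule implies: offsets
#' within `2 * max(replicate_jitter_sd, 0.5)` 1/cm count as overlapping.
#'
#' @param ref_p [synth_params()] for the reference species.
#' @param n_reference_replicates number of reference grinding curves
#'   (default 5, the standard design).
#' @param fossils data frame with columns `id` and `shift`
#'   (crystallinity shift, positive = more ordered), or a bare numeric
#'   vector of shifts.
#' @param grid wavenumber grid.
#' @return list (class `synthetic_assemblage`): `reference` (list of
#'   grinding series), `fossils` (named list of series), `truth` (data
#'   frame id, crystallinity, injected_offset, label), `params`.
#' @export
synth_assemblage <- function(ref_p, n_reference_replicates = 5, fossils,
                             grid = synth_grid()) {
  if (is.numeric(fossils))
    fossils <- data.frame(id = sprintf("Fossil%02d", seq_along(fossils)),
                          shift = fossils)
  if (nrow(fossils) < 1) stop("at least one fossil specification is required")
  reference <- lapply(seq_len(n_reference_replicates), function(r)
    synth_grinding_series(ref_p, replicate = r, grid = grid,
                          species = "Reference"))
  fossil_series <- list(); truth <- list()
  for (i in seq_len(nrow(fossils))) {
    c_new <- ref_p$crystallinity + fossils$shift[i]
    if (c_new <= 0 || c_new > 1)
      stop("fossil ", fossils$id[i], ": shifted crystallinity outside (0, 1]")
    fp <- ref_p
    fp$crystallinity <- c_new
    fp$seed <- .stream_seed(ref_p$seed, 1000L + i)
    fossil_series[[fossils$id[i]]] <-
      synth_grinding_series(fp, replicate = 1L, grid = grid,
                            species = fossils$id[i])
    off <- ref_p$fwhm_anchor / c_new - ref_p$fwhm_anchor / ref_p$crystallinity
    tol <- 2 * max(ref_p$replicate_jitter_sd, 0.5)
    truth[[i]] <- data.frame(
      id = fossils$id[i], crystallinity = c_new, injected_offset = off,
      label = if (abs(off) <= tol) "overlapping"
              else if (off < 0) "offset_ordered" else "offset_disordered")
  }
  structure(list(reference = reference, fossils = fossil_series,
                 truth = do.call(rbind, truth), params = ref_p),
            class = "synthetic_assemblage")
}

#' Write a full synthetic spectral library to disk
#'
#' Emulates the deposited archive layout: one file per spectrum named
#' `<Label><curve>_<0g>` for every registry species, replicate curve and
#' grinding level, plus a `truth.csv` sidecar of generator targets. Per
#' species, crystallinity is spread over a plausible range so the curves
#' fan out as real inter-species differences do.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @param species character vector of species labels; default the 15
#'   registry labels.
#' @param crystallinity per-species values; default evenly spread over
#'   0.78-0.98.
#' @param n_replicates,n_grindings design, default 5 x 3.
#' @param formats any of `"csv"`, `"jdx"`; both mirror the deposited
#'   two-format layout.
#' @param ... overrides passed to [synth_params()].
#' @return invisibly, a list with the file manifest and the truth table.
#' @export
write_synthetic_library <- function(dir, seed = 1L,
                                    species = species_registry()$label,
                                    crystallinity = NULL,
                                    n_replicates = 5, n_grindings = 3,
                                    formats = "csv", ...) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  formats <- match.arg(formats, c("csv", "jdx"), several.ok = TRUE)
  if (is.null(crystallinity))
    crystallinity <- seq(0.78, 0.98, length.out = length(species))
  if (length(crystallinity) != length(species))
    stop("crystallinity must match species length")
  manifest <- list(); truth <- list()
  for (i in seq_along(species)) {
    p <- synth_params(crystallinity = crystallinity[i],
                      seed = .stream_seed(seed, i), ...)
    for (r in seq_len(n_replicates)) {
      series <- synth_grinding_series(p, n_grindings = n_grindings,
                                      replicate = r, species = species[i])
      tr <- attr(series, "truth")
      tr$species <- species[i]
      truth[[length(truth) + 1]] <- tr
      for (g in seq_len(n_grindings)) {
        base <- sprintf("%s%d_%02d", species[i], r, g)
        if ("csv" %in% formats) {
          f <- file.path(dir, paste0(base, ".csv"))
          write_spectrum_csv(series[[g]], f)
          manifest[[length(manifest) + 1]] <- f
        }
        if ("jdx" %in% formats) {
          f <- file.path(dir, paste0(base, ".jdx"))
          write_jcamp(series[[g]], f, title = base)
          manifest[[length(manifest) + 1]] <- f
        }
      }
    }
  }
  truth <- do.call(rbind, truth)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(list(files = unlist(manifest), truth = truth))
}
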