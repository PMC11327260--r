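# Species registry of the African ungulate reference collection and
# construction of per-species reference curves from a spectra folder.

.registry_path <- function() {
  system.file("extdata", "species_registry.csv", package = "grindcurve",
              mustWork = TRUE)
}

#' Registry of the bundled reference species
#'
#' The 15 African ungulate species of the reference collection (museum
#' specimens from the National Museum Bloemfontein), with taxonomy,
#' specimen id, tooth position and locality, plus the file-name label
#' used in the spectral library (`"Giraffe"`, `"PlainsZebra"`, ...).
#'
#' @return data frame with columns label, common_name, binomial,
#'   subfamily, family, specimen_id, tooth_position, locality.
#' @examples
#' nrow(species_registry())   # 15
#' @export
species_registry <- function() {
  utils::read.csv(.registry_path(), stringsAsFactors = FALSE)
}

#' Look up one registry entry
#'
#' Matches case-insensitively against binomial, common name or file-name
#' label.
#'
#' @param name species name in any of the three forms.
#' @return one-row data frame, or `NULL` when not found.
#' @examples
#' species_lookup("Giraffa camelopardalis")$family
#' @export
species_lookup <- function(name) {
  reg <- species_registry()
  key <- tolower(trimws(name))
  hit <- tolower(reg$binomial) == key | tolower(reg$common_name) == key |
    tolower(reg$label) == key
  if (!any(hit)) return(NULL)
  reg[which(hit)[1], , drop = FALSE]
}

#' Build a reference library from a folder of spectra
#'
#' Loads every library-named CSV, computes both crystallinity statistics
#' per spectrum, fits a grinding curve per (species, replicate), and
#' pools replicates into one reference curve per species. Species whose
#' files fail the metrics entirely are excluded with a warning; per-file
#' failures are kept in the metrics table's `qc` column.
#'
#' @param folder directory loadable by [load_library_folder()].
#' @param ... metric parameter overrides for [compute_band_metrics()].
#' @return A list (class `reference_library`): `registry`, `references`
#'   (named list of [pool_reference()] results keyed by species label),
#'   `curves` (named list of per-replicate [fit_grinding_curve()]
#'   results), `metrics` (per-spectrum table), `r2_table` (per-species
#'   pooled and replicate r2), `skipped`, `provenance`.
#' @export
build_reference_library <- function(folder, ...) {
  lib <- load_library_folder(folder)
  metrics <- metrics_table(lib$spectra, ...)
  ok <- metrics$qc == "ok"
  if (!any(ok)) stop("no spectrum in ", folder, " yielded both statistics")
  references <- list(); curves <- list(); r2_rows <- list()
  for (sp in unique(metrics$species[ok])) {
    sp_rows <- metrics[ok & metrics$species == sp, , drop = FALSE]
    sp_curves <- list()
    for (r in sort(unique(sp_rows$replicate))) {
      pts <- sp_rows[sp_rows$replicate == r,
                     c("irsf", "fwhm_v3", "grinding"), drop = FALSE]
      names(pts) <- c("irsf", "fwhm", "grinding")
      if (nrow(pts) < 2) next
      cu <- tryCatch(
        fit_grinding_curve(pts, key = list(species = sp, replicate = r)),
        error = function(e) NULL)
      if (!is.null(cu)) {
        sp_curves[[length(sp_curves) + 1]] <- cu
        curves[[sprintf("%s%d", sp, r)]] <- cu
      }
    }
    if (length(sp_curves) == 0) {
      warning("species ", sp, " has no complete grinding curve; excluded")
      next
    }
    ref <- pool_reference(sp_curves, species = sp)
    references[[sp]] <- ref
    r2_rows[[length(r2_rows) + 1]] <- data.frame(
      species = sp,
      binomial = { e <- species_lookup(sp); if (is.null(e)) NA_character_ else e$binomial },
      r2_pooled = ref$r2,
      r2_replicate_min = min(ref$replicate_r2),
      r2_replicate_max = max(ref$replicate_r2),
      n_replicates = ref$n_replicates)
  }
  structure(list(registry = species_registry(),
                 references = references,
                 curves = curves,
                 metrics = metrics,
                 r2_table = do.call(rbind, r2_rows),
                 skipped = lib$skipped,
                 provenance = list(folder = folder,
                                   n_loaded = length(lib$spectra))),
            class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf("reference library: %d species, %d replicate curves, %d spectra\n",
              length(x$references), length(x$curves), nrow(x$metrics)))
  invisible(x)
}

#' Export reference curves as a CSV table
#'
#' Writes one row per species at full double precision, so a library can
#' be reloaded for screening without the raw spectra.
#'
#' @param lib a `reference_library` or a named list of
#'   [pool_reference()] results.
#' @param file path or connection.
#' @return the lines written, invisibly.
#' @seealso [read_reference_table()]
#' @export
export_reference_table <- function(lib, file) {
  refs <- if (inherits(lib, "reference_library")) lib$references else lib
  hdr <- paste("species,slope,intercept,r2,replicate_spread",
               "irsf_lo,irsf_hi,n_replicates,n_points", sep = ",")
  rows <- vapply(refs, function(r)
    sprintf("%s,%.17g,%.17g,%.17g,%.17g,%.17g,%.17g,%d,%d",
            r$species, r$slope, r$intercept, r$r2, r$replicate_spread,
            r$irsf_range[1], r$irsf_range[2], r$n_replicates, r$n_points),
    "")
  writeLines(c(hdr, rows), file)
  invisible(c(hdr, rows))
}

#' Reload reference curves from an exported table
#'
#' @param file path to a CSV written by [export_reference_table()]
#'   (leading `#` provenance lines are ignored).
#' @return named list of `reference_curve` objects.
#' @export
read_reference_table <- function(file) {
  tab <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("species", "slope", "intercept", "r2", "replicate_spread",
            "irsf_lo", "irsf_hi", "n_replicates", "n_points")
  if (!all(need %in% names(tab)))
    stop("reference table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  refs <- lapply(seq_len(nrow(tab)), function(i) {
    structure(list(species = tab$species[i],
                   slope = tab$slope[i], intercept = tab$intercept[i],
                   r2 = tab$r2[i], replicate_spread = tab$replicate_spread[i],
                   irsf_range = c(tab$irsf_lo[i], tab$irsf_hi[i]),
                   n_replicates = tab$n_replicates[i],
                   n_points = tab$n_points[i],
                   replicate_r2 = NA_real_, flag = "imported"),
              class = "reference_curve")
  })
  names(refs) <- tab$species
  refs
}
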