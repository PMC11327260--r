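# Grinding curves: repeated grindings of one enamel sample traced in the
# (IRSF, FWHM) plane. Particle-size reduction moves the point along a
# line; the line's position indexes atomic order. Convention throughout:
# IRSF on the x axis (predictor), FWHM on the y axis (response), so
# curve offsets are vertical and in 1/cm.

#' Fit a grinding curve by ordinary least squares
#'
#' @param points either a data frame with columns `irsf`, `fwhm` and
#'   optionally `grinding`, or a list of [compute_band_metrics()]
#'   results for the successive grindings of one sample.
#' @param key optional sample key attached to the curve.
#' @return A list (class `grinding_curve`): `points` (ordered by
#'   grinding index when known), `slope` (1/cm per IRSF unit),
#'   `intercept` (1/cm), `r2` (squared Pearson correlation, invariant to
#'   which statistic is called predictor), `n_points`, and `flag`
#'   (`"standard"` for >= 3 points, `"minimal"` for 2).
#' @examples
#' fit_grinding_curve(data.frame(irsf = c(2.5, 3.0, 3.5),
#'                               fwhm = c(60, 50, 40)))
#' @export
fit_grinding_curve <- function(points, key = NULL) {
  if (is.list(points) && !is.data.frame(points) &&
      all(vapply(points, inherits, TRUE, "band_metrics"))) {
    if (is.null(key) && !is.null(points[[1]]$key)) key <- points[[1]]$key
    points <- data.frame(
      irsf = vapply(points, function(m) m$irsf$irsf, 0),
      fwhm = vapply(points, function(m) m$fwhm$fwhm, 0),
      grinding = vapply(points, function(m)
        if (is.null(m$key)) NA_integer_ else m$key$grinding, 0L))
    if (all(is.na(points$grinding))) points$grinding <- NULL
  }
  if (!is.data.frame(points) || !all(c("irsf", "fwhm") %in% names(points)))
    stop("points must carry irsf and fwhm columns")
  if (nrow(points) < 2) stop("a grinding curve needs at least 2 points")
  if (!is.null(points$grinding) && !all(is.na(points$grinding))) {
    if (anyDuplicated(points$grinding))
      stop("duplicate grinding index in curve points")
    points <- points[order(points$grinding), , drop = FALSE]
  }
  if (max(points$irsf) - min(points$irsf) < 1e-12)
    stop("all IRSF values identical: vertical line cannot be fitted")
  fit <- stats::lm(fwhm ~ irsf, data = points)
  co <- stats::coef(fit)
  r2 <- if (stats::sd(points$fwhm) < 1e-15) 1.0 else
    stats::cor(points$irsf, points$fwhm)^2
  structure(list(points = points,
                 slope = unname(co[2]), intercept = unname(co[1]),
                 r2 = r2, n_points = nrow(points),
                 flag = if (nrow(points) >= 3) "standard" else "minimal",
                 key = key),
            class = "grinding_curve")
}

#' @export
print.grinding_curve <- function(x, ...) {
  cat(sprintf("grinding curve (%d points, %s): FWHM = %.3f %+.3f*IRSF, r2 = %.4f\n",
              x$n_points, x$flag, x$intercept, x$slope, x$r2))
  invisible(x)
}

#' Pool replicate grinding curves into a species reference
#'
#' Fits one least-squares line through the union of all replicate points
#' and summarises between-replicate dispersion as the standard deviation,
#' over replicates, of each replicate's mean vertical residual from the
#' pooled line.
#'
#' @param curves list of [fit_grinding_curve()] results for one species.
#' @param species species label or registry binomial for the reference.
#' @return A list (class `reference_curve`): `species`, `slope`,
#'   `intercept`, `r2` (pooled), `replicate_spread` (1/cm; 0 with a
#'   `"single_replicate"` flag when only one curve is given),
#'   `irsf_range`, `n_replicates`, `n_points`, `replicate_r2`.
#' @export
pool_reference <- function(curves, species = NULL) {
  if (inherits(curves, "grinding_curve")) curves <- list(curves)
  if (length(curves) < 1) stop("at least one grinding curve is required")
  labs <- unlist(lapply(curves, function(cu)
    if (!is.null(cu$key)) cu$key$species else NULL))
  if (length(unique(labs)) > 1)
    stop("mixed species in replicate curves: ", paste(unique(labs), collapse = ", "))
  if (is.null(species)) species <- if (length(labs)) labs[1] else NA_character_
  pts <- do.call(rbind, lapply(seq_along(curves), function(i)
    cbind(curves[[i]]$points[c("irsf", "fwhm")], replicate = i)))
  fit <- stats::lm(fwhm ~ irsf, data = pts)
  co <- stats::coef(fit)
  resid_mean <- tapply(pts$fwhm - (co[1] + co[2] * pts$irsf), pts$replicate, mean)
  spread <- if (length(curves) > 1) stats::sd(resid_mean) else 0
  structure(list(species = species,
                 slope = unname(co[2]), intercept = unname(co[1]),
                 r2 = stats::cor(pts$irsf, pts$fwhm)^2,
                 replicate_spread = spread,
                 irsf_range = range(pts$irsf),
                 n_replicates = length(curves),
                 n_points = nrow(pts),
                 replicate_r2 = vapply(curves, function(cu) cu$r2, 0),
                 flag = if (length(curves) == 1) "single_replicate" else "ok"),
            class = "reference_curve")
}

#' @export
print.reference_curve <- function(x, ...) {
  cat(sprintf(paste0("reference curve [%s]: FWHM = %.3f %+.3f*IRSF, r2 = %.4f, ",
                     "spread = %.3f 1/cm (%d replicates, IRSF %.2f-%.2f)\n"),
              x$species, x$intercept, x$slope, x$r2, x$replicate_spread,
              x$n_replicates, x$irsf_range[1], x$irsf_range[2]))
  invisible(x)
}

#' Predict reference FWHM at given IRSF values
#' @param object a `reference_curve`.
#' @param irsf numeric IRSF values.
#' @param ... ignored.
#' @export
predict.reference_curve <- function(object, irsf, ...) {
  object$intercept + object$slope * irsf
}

#' Assess the offset of a test grinding curve from a reference
#'
#' The signed offset is the mean, over test points whose IRSF falls
#' inside the reference IRSF range, of test FWHM minus the reference
#' prediction at the same IRSF. The score divides it by the reference's
#' replicate spread (floored to guard near-identical replicates).
#' Negative scores (lower FWHM at matched IRSF) indicate increased
#' atomic order, i.e. recrystallisation; extrapolation beyond the
#' reference IRSF range is refused (`insufficient_overlap`) because the
#' grinding-curve premise holds only over the sampled particle sizes.
#'
#' @param test a [fit_grinding_curve()] result.
#' @param ref a [pool_reference()] result.
#' @param threshold score magnitude separating `overlapping` from
#'   `offset_*` labels (default 2.0, roughly a two-sigma rule).
#' @param min_overlap_fraction minimum fraction of the reference IRSF
#'   range the test curve must overlap (default 0.25).
#' @param spread_floor lower bound on the spread used in the score
#'   denominator, in 1/cm (default 0.5).
#' @return A list (class `offset_assessment`): `mean_offset` (1/cm),
#'   `score`, `overlap_range`, `n_overlap`, `label` in
#'   `overlapping`, `offset_ordered`, `offset_disordered`,
#'   `insufficient_overlap`.
#' @export
assess_offset <- function(test, ref, threshold = 2.0,
                          min_overlap_fraction = 0.25, spread_floor = 0.5) {
  stopifnot(inherits(test, "grinding_curve"), inherits(ref, "reference_curve"))
  rlo <- ref$irsf_range[1]; rhi <- ref$irsf_range[2]
  inside <- test$points$irsf >= rlo & test$points$irsf <= rhi
  olo <- max(min(test$points$irsf), rlo)
  ohi <- min(max(test$points$irsf), rhi)
  overlap_len <- max(0, ohi - olo)
  out <- list(mean_offset = NA_real_, score = NA_real_,
              overlap_range = c(olo, ohi), n_overlap = sum(inside),
              label = "insufficient_overlap",
              threshold = threshold, spread_used = NA_real_)
  if (!any(inside) ||
      overlap_len < min_overlap_fraction * (rhi - rlo)) {
    return(structure(out, class = "offset_assessment"))
  }
  pred <- ref$intercept + ref$slope * test$points$irsf[inside]
  mean_offset <- mean(test$points$fwhm[inside] - pred)
  spread <- max(ref$replicate_spread, spread_floor)
  score <- mean_offset / spread
  label <- if (abs(score) <= threshold) "overlapping"
           else if (score < 0) "offset_ordered" else "offset_disordered"
  out$mean_offset <- mean_offset
  out$score <- score
  out$label <- label
  out$spread_used <- spread
  structure(out, class = "offset_assessment")
}

#' @export
print.offset_assessment <- function(x, ...) {
  if (x$label == "insufficient_overlap")
    cat("offset assessment: insufficient IRSF overlap with reference\n")
  else
    cat(sprintf("offset assessment: %+.2f 1/cm (score %+.2f) -> %s\n",
                x$mean_offset, x$score, x$label))
  invisible(x)
}

#' Screen an assemblage of test curves against a reference
#'
#' Assesses each test curve with [assess_offset()] and ranks samples by
#' absolute score, best preserved first; samples labelled `overlapping`
#' are recommended for dating. Samples without sufficient IRSF overlap
#' sort last.
#'
#' @param tests named list of [fit_grinding_curve()] results.
#' @param ref a [pool_reference()] result.
#' @param ... passed to [assess_offset()].
#' @return data frame (class `screening_report`) with one row per
#'   sample: sample, n_points, mean_offset, score, label, overlap_lo,
#'   overlap_hi, recommended; ordered by |score| ascending, ties broken
#'   by sample id.
#' @export
screen_assemblage <- function(tests, ref, ...) {
  if (length(tests) < 1) stop("at least one test curve is required")
  ids <- names(tests)
  if (is.null(ids)) ids <- sprintf("sample%02d", seq_along(tests))
  rows <- lapply(seq_along(tests), function(i) {
    a <- assess_offset(tests[[i]], ref, ...)
    data.frame(sample = ids[i], n_points = tests[[i]]$n_points,
               mean_offset = a$mean_offset, score = a$score,
               label = a$label,
               overlap_lo = a$overlap_range[1], overlap_hi = a$overlap_range[2],
               recommended = identical(a$label, "overlapping"))
  })
  rep <- do.call(rbind, rows)
  ord <- order(is.na(rep$score), abs(rep$score), rep$sample)
  rep <- rep[ord, , drop = FALSE]
  rownames(rep) <- NULL
  class(rep) <- c("screening_report", "data.frame")
  rep
}
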