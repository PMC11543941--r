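# Volumetric biomarker quantification and ETDRS central subfield thickness.

#' Volume-scan acquisition geometry
#'
#' @param n_bscans Number of B-scans in the volume.
#' @param axial_um_per_px,lateral_um_per_px In-plane physical scale.
#' @param bscan_spacing_um Distance between consecutive B-scans.
#' @param fovea_center `c(bscan index, column)` of the foveal centre;
#'   `NULL` defaults to the geometric centre of the volume.
#' @return An object of class `volume_geometry`.
#' @export
volume_geometry <- function(n_bscans, axial_um_per_px, lateral_um_per_px,
                            bscan_spacing_um, fovea_center = NULL) {
  .check(n_bscans >= 1, "n_bscans must be >= 1")
  .check(axial_um_per_px > 0 && lateral_um_per_px > 0 && bscan_spacing_um > 0,
         "all physical spacings must be positive")
  structure(list(n_bscans = as.integer(n_bscans),
                 axial_um_per_px = axial_um_per_px,
                 lateral_um_per_px = lateral_um_per_px,
                 bscan_spacing_um = bscan_spacing_um,
                 fovea_center = fovea_center),
            class = "volume_geometry")
}

#' Per-class biomarker volumes of a segmented volume scan
#'
#' Volume of a class = its voxel count x the voxel volume
#' (axial x lateral x B-scan spacing). Volumes are computed in cubic
#' micrometres and reported in the requested unit. Conservation holds
#' exactly: foreground volumes plus background volume equal the voxel
#' volume times the total voxel count.
#'
#' @param masks List of `label_mask` (or code matrices), one per B-scan.
#' @param geom A `volume_geometry` with `n_bscans == length(masks)`.
#' @param scheme An `oct_scheme`.
#' @param units `"mm3"` (default) or `"um3"`.
#' @return An object of class `biomarker_volumes`: `volumes` (named, per
#'   foreground class), `background`, `total`, `units`, `voxel_um3`.
#' @export
mask_volumes <- function(masks, geom, scheme = oct_class_scheme(),
                         units = c("mm3", "um3")) {
  units <- match.arg(units)
  stopifnot(inherits(geom, "volume_geometry"))
  .check(length(masks) == geom$n_bscans,
         "mask count (%d) does not match geometry n_bscans (%d)",
         length(masks), geom$n_bscans)
  codes <- .mask_codes_list(masks)
  K <- length(scheme$labels)
  counts <- numeric(K)
  for (m in codes) counts <- counts + tabulate(as.integer(m) + 1L, nbins = K)
  voxel <- geom$axial_um_per_px * geom$lateral_um_per_px * geom$bscan_spacing_um
  scale <- if (units == "mm3") 1e-9 else 1
  vols <- counts * voxel * scale
  structure(list(volumes = stats::setNames(vols[-1], scheme$classes),
                 background = vols[1], total = sum(vols),
                 units = units, voxel_um3 = voxel),
            class = "biomarker_volumes")
}

#' @export
print.biomarker_volumes <- function(x, ...) {
  cat("biomarker volumes (", x$units, "):\n", sep = "")
  print(round(x$volumes, 6))
  invisible(x)
}

#' ETDRS central subfield thickness (C0)
#'
#' Mean retinal thickness over all A-scan columns whose en-face position
#' lies within the 1 mm-diameter central ETDRS disc around the foveal
#' centre. Column thickness = (pixels belonging to the retina classes) x
#' axial scale. Columns with zero retinal pixels are excluded with a
#' warning.
#'
#' @param masks List of `label_mask` (or code matrices), one per B-scan.
#' @param geom A `volume_geometry`; `fovea_center` defaults to the volume
#'   centre.
#' @param scheme An `oct_scheme`.
#' @param retina_classes Classes counted as retina, inner surface to outer
#'   RPE (default NR, IRF, SRF, SHRM, RPE - the ILM-to-Bruch's convention).
#' @param radius_um Disc radius (default 500, i.e. the 1 mm C0 subfield).
#' @return Central subfield thickness in micrometres.
#' @export
central_thickness_c0 <- function(masks, geom, scheme = oct_class_scheme(),
                                 retina_classes = c("NR", "IRF", "SRF", "SHRM", "RPE"),
                                 radius_um = 500) {
  stopifnot(inherits(geom, "volume_geometry"))
  .check(length(retina_classes) >= 1, "retina_classes must be non-empty")
  .check(length(masks) == geom$n_bscans, "mask count does not match geometry")
  codes <- .mask_codes_list(masks)
  w <- ncol(codes[[1]])
  fc <- geom$fovea_center
  if (is.null(fc)) fc <- c((geom$n_bscans + 1) / 2, (w + 1) / 2)
  rc <- class_code(scheme, retina_classes)
  th <- c(); excluded <- 0L
  for (b in seq_along(codes)) {
    dy <- (b - fc[1]) * geom$bscan_spacing_um
    if (abs(dy) > radius_um) next
    dx_max2 <- radius_um^2 - dy^2
    cols <- which(((seq_len(w) - fc[2]) * geom$lateral_um_per_px)^2 <= dx_max2)
    if (!length(cols)) next
    cnt <- colSums(matrix(codes[[b]][, cols] %in% rc, nrow(codes[[b]])))
    zero <- cnt == 0
    excluded <- excluded + sum(zero)
    th <- c(th, cnt[!zero] * geom$axial_um_per_px)
  }
  .check(length(th) + excluded > 0, "central disc lies entirely outside the scanned field")
  .check(length(th) > 0, "no column with retinal pixels within the central disc")
  if (excluded > 0)
    warning(sprintf("%d column(s) with zero retinal pixels excluded from C0", excluded))
  mean(th)
}

#' Interpolate dated visits to the months 0/3/12 measurement points
#'
#' Month 0 is anchored at the first injection. For each target month the
#' visit nearest in time within the tolerance window is assigned (ties go
#' to the earlier visit); eyes missing any window are flagged incomplete
#' rather than erroring.
#'
#' @param visits A `data.frame` with columns `eye_id` and either `date`
#'   (Date) or `day` (numeric); additional columns travel along.
#' @param anchor Per-eye month-0 anchor (first injection): a named vector
#'   (`eye_id` -> day), or `NULL` meaning day/date values are already
#'   relative to the first injection (day 0).
#' @param windows_days Tolerance half-windows for months 0, 3 and 12
#'   (default +/-45, +/-45, +/-90 days).
#' @return A `data.frame` with one row per eye x target month: `eye_id`,
#'   `month`, `visit_row` (row index into `visits`, `NA` if unmatched),
#'   `day_offset`, `incomplete` (eye-level flag).
#' @export
interpolate_timepoints <- function(visits, anchor = NULL,
                                   windows_days = c(45, 45, 90)) {
  .check(is.data.frame(visits) && nrow(visits) >= 1, "need at least one visit")
  .check("eye_id" %in% names(visits), "visits must have an eye_id column")
  day <- if ("day" %in% names(visits)) as.numeric(visits$day)
         else if ("date" %in% names(visits)) as.numeric(visits$date)
         else stop("visits must have a 'day' or 'date' column", call. = FALSE)
  targets <- c(0, 3, 12) * 365.25 / 12
  months <- c(0L, 3L, 12L)
  out <- list()
  for (eye in unique(visits$eye_id)) {
    rows <- which(visits$eye_id == eye)
    a <- if (is.null(anchor)) 0 else anchor[[as.character(eye)]]
    d <- day[rows] - a
    assigned <- rep(NA_integer_, 3)
    offs <- rep(NA_real_, 3)
    for (k in 1:3) {
      dist <- abs(d - targets[k])
      ok <- dist <= windows_days[k]
      if (any(ok)) {
        best <- min(dist[ok])
        cand <- which(ok & dist == best)
        pick <- cand[which.min(d[cand])]  # tie: earlier visit
        assigned[k] <- rows[pick]
        offs[k] <- d[pick] - targets[k]
      }
    }
    out[[length(out) + 1]] <- data.frame(
      eye_id = eye, month = months, visit_row = assigned, day_offset = offs,
      incomplete = anyNA(assigned), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
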