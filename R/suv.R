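# ---------------------------------------------------------------------------
# VOI-based SUV quantification on 3-D uptake volumes.
#
# Geometry convention: physical coordinates place the origin at the center of
# voxel (1,1,1); axes are ordered (x, y, z) with the given spacing, so voxel
# (i,j,k) has center ((i-1)*sx, (j-1)*sy, (k-1)*sz) mm. Voxel membership in a
# spherical VOI is decided by center-in-sphere, without partial-volume
# weighting. NIfTI affines vary between tools; this package's own convention
# is applied to any volume it reads.
# ---------------------------------------------------------------------------

F18_HALF_LIFE_MIN <- 109.77

#' Construct a 3-D uptake volume
#'
#' @param values Numeric 3-D array of nonnegative voxel values.
#' @param spacing_mm Positive length-3 numeric: voxel spacing (x, y, z) in mm.
#'   Defaults to the 1.5 x 1.5 x 5.0 mm grid of the reference protocol.
#' @param units `"kBq_per_ml"` (activity concentration) or `"suv"`.
#' @return An `uptake_volume` object.
#' @export
uptake_volume <- function(values, spacing_mm = c(1.5, 1.5, 5.0),
                          units = c("kBq_per_ml", "suv")) {
  units <- match.arg(units)
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3-D array", call. = FALSE)
  if (any(dim(values) < 1L)) stop("each axis must have >= 1 voxel", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be three strictly positive numbers", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("voxel values must be finite and nonnegative", call. = FALSE)
  structure(list(values = values, spacing_mm = spacing_mm, units = units),
            class = "uptake_volume")
}

#' @export
print.uptake_volume <- function(x, ...) {
  cat(sprintf("Uptake volume %s [%s], spacing %.2f x %.2f x %.2f mm, max %.3g\n",
              paste(dim(x$values), collapse = " x "), x$units,
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              max(x$values)))
  invisible(x)
}

#' Spherical volume of interest
#'
#' @param center_mm Length-3 numeric: sphere center in the volume's physical
#'   coordinates (mm).
#' @param diameter_mm Positive sphere diameter in mm (e.g. 50 for the liver
#'   reference VOI, 20 for the brainstem).
#' @return A `sphere_voi` object.
#' @export
sphere_voi <- function(center_mm, diameter_mm) {
  center_mm <- as.numeric(center_mm)
  if (length(center_mm) != 3L || any(!is.finite(center_mm)))
    stop("center_mm must be three finite numbers", call. = FALSE)
  if (!is.finite(diameter_mm) || diameter_mm <= 0)
    stop("diameter_mm must be > 0", call. = FALSE)
  structure(list(center_mm = center_mm, diameter_mm = diameter_mm),
            class = "sphere_voi")
}

#' Acquisition context for SUV normalisation
#'
#' @param injected_activity_mbq Injected tracer activity in MBq at injection
#'   time.
#' @param body_weight_kg Patient body weight in kg.
#' @param minutes_injection_to_scan Uptake time in minutes; the injected
#'   activity is decay-corrected over this interval.
#' @param half_life_min Tracer half-life in minutes; default 109.77 (F-18).
#' @return A `scan_context` object.
#' @export
scan_context <- function(injected_activity_mbq, body_weight_kg,
                         minutes_injection_to_scan,
                         half_life_min = F18_HALF_LIFE_MIN) {
  vals <- c(injected_activity_mbq, body_weight_kg, half_life_min)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("activity, weight and half-life must be strictly positive", call. = FALSE)
  if (!is.finite(minutes_injection_to_scan) || minutes_injection_to_scan < 0)
    stop("minutes_injection_to_scan must be >= 0", call. = FALSE)
  structure(list(injected_activity_mbq = injected_activity_mbq,
                 body_weight_kg = body_weight_kg,
                 minutes_injection_to_scan = minutes_injection_to_scan,
                 half_life_min = half_life_min),
            class = "scan_context")
}

#' Convert an activity-concentration volume to SUV
#'
#' Body-weight SUV under the 1 g/mL tissue-density convention:
#' `SUV = C * w * 1000 / (A * 1000 * 2^(-t / T_half))`, with `C` in kBq/mL,
#' body weight `w` in kg and injected activity `A` in MBq decay-corrected
#' over the uptake time `t`.
#'
#' @param volume An [uptake_volume()] with units `kBq_per_ml`.
#' @param ctx A [scan_context()].
#' @return An [uptake_volume()] with units `suv`.
#' @export
suv_normalize <- function(volume, ctx) {
  stopifnot(inherits(volume, "uptake_volume"), inherits(ctx, "scan_context"))
  if (volume$units != "kBq_per_ml")
    stop("suv_normalize expects a volume in kBq_per_ml, got ", volume$units,
         call. = FALSE)
  decayed_kbq <- ctx$injected_activity_mbq * 1000 *
    2^(-ctx$minutes_injection_to_scan / ctx$half_life_min)
  factor <- ctx$body_weight_kg * 1000 / decayed_kbq
  uptake_volume(volume$values * factor, volume$spacing_mm, units = "suv")
}

# centers of all voxels along one axis, in mm
axis_centers <- function(n, spacing) (seq_len(n) - 1) * spacing

#' Voxels inside a spherical VOI
#'
#' Selects exactly the voxels whose geometric centers lie within
#' `diameter_mm / 2` of the VOI center (Euclidean distance in mm).
#'
#' @param volume An [uptake_volume()].
#' @param voi A [sphere_voi()].
#' @return Integer matrix with one row per voxel and columns `i`, `j`, `k`
#'   (1-based array indices).
#' @export
voi_voxels <- function(volume, voi) {
  stopifnot(inherits(volume, "uptake_volume"), inherits(voi, "sphere_voi"))
  dm <- dim(volume$values)
  sp <- volume$spacing_mm
  r2 <- (voi$diameter_mm / 2)^2
  dx2 <- (axis_centers(dm[1], sp[1]) - voi$center_mm[1])^2
  dy2 <- (axis_centers(dm[2], sp[2]) - voi$center_mm[2])^2
  dz2 <- (axis_centers(dm[3], sp[3]) - voi$center_mm[3])^2
  # voxels can only qualify where each axis contribution is within r2
  ii <- which(dx2 <= r2); jj <- which(dy2 <= r2); kk <- which(dz2 <= r2)
  if (length(ii) && length(jj) && length(kk)) {
    grid <- expand.grid(i = ii, j = jj, k = kk, KEEP.OUT.ATTRS = FALSE)
    inside <- dx2[grid$i] + dy2[grid$j] + dz2[grid$k] <= r2
    grid <- grid[inside, , drop = FALSE]
  } else {
    grid <- data.frame(i = integer(0), j = integer(0), k = integer(0))
  }
  if (nrow(grid) == 0L)
    stop(sprintf(paste0("VOI (center %.1f/%.1f/%.1f mm, diameter %.1f mm) ",
                        "contains no voxel center"),
                 voi$center_mm[1], voi$center_mm[2], voi$center_mm[3],
                 voi$diameter_mm), call. = FALSE)
  m <- as.matrix(grid)
  m <- m[order(m[, "k"], m[, "j"], m[, "i"]), , drop = FALSE]
  rownames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

voi_values <- function(volume, voi) volume$values[voi_voxels(volume, voi)]

#' SUVmax, SUVmean and SUVpeak within a VOI
#'
#' `suv_max` and `suv_mean` are the maximum and arithmetic mean voxel value
#' in the VOI. `suv_peak` follows the EANM-style definition: the maximum,
#' over candidate positions at voxel centers inside the VOI, of the mean
#' value within a 1.0 mL sphere (diameter ~12.4 mm) centered there; the
#' averaging sphere may extend beyond the VOI but is clipped at the volume
#' boundary.
#'
#' @param volume An [uptake_volume()].
#' @param voi A [sphere_voi()].
#' @return A single numeric value.
#' @export
suv_max <- function(volume, voi) max(voi_values(volume, voi))

#' @rdname suv_max
#' @export
suv_mean <- function(volume, voi) mean(voi_values(volume, voi))

PEAK_SPHERE_VOLUME_ML <- 1.0

peak_sphere_radius_mm <- function(volume_ml = PEAK_SPHERE_VOLUME_ML) {
  (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
}

#' @rdname suv_max
#' @export
suv_peak <- function(volume, voi) {
  centers <- voi_voxels(volume, voi)
  dm <- dim(volume$values)
  sp <- volume$spacing_mm
  r <- peak_sphere_radius_mm()
  # index-space offsets of voxels within the averaging sphere of a center
  reach <- pmax(0L, floor(r / sp))
  off <- expand.grid(di = -reach[1]:reach[1], dj = -reach[2]:reach[2],
                     dk = -reach[3]:reach[3], KEEP.OUT.ATTRS = FALSE)
  keep <- (off$di * sp[1])^2 + (off$dj * sp[2])^2 + (off$dk * sp[3])^2 <= r^2
  off <- off[keep, , drop = FALSE]
  best <- -Inf
  for (c_idx in seq_len(nrow(centers))) {
    i <- centers[c_idx, 1] + off$di
    j <- centers[c_idx, 2] + off$dj
    k <- centers[c_idx, 3] + off$dk
    inb <- i >= 1L & i <= dm[1] & j >= 1L & j <= dm[2] & k >= 1L & k <= dm[3]
    vals <- volume$values[cbind(i[inb], j[inb], k[inb])]
    best <- max(best, mean(vals))
  }
  best
}

#' Synthesise a phantom uptake volume
#'
#' Paints spherical lesions of given values onto a uniform background,
#' optionally perturbed by multiplicative log-normal noise; used as a
#' programmatic fixture for the quantification routines.
#'
#' @param dims Length-3 integer grid dimensions.
#' @param spacing_mm Voxel spacing (x, y, z) in mm.
#' @param background Background voxel value.
#' @param lesions List of `list(voi = sphere_voi(...), value = <numeric>)`;
#'   each lesion sphere must lie inside the grid.
#' @param noise_sd Standard deviation of the log-normal multiplicative noise
#'   (0 disables noise).
#' @param seed Optional integer seed making the noise reproducible.
#' @return An [uptake_volume()] in SUV units.
#' @export
make_phantom <- function(dims, spacing_mm = c(1.5, 1.5, 5.0), background = 1,
                         lesions = list(), noise_sd = 0, seed = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  extent <- (dims - 1) * spacing_mm
  vals <- array(background, dim = dims)
  vol <- uptake_volume(vals, spacing_mm, units = "suv")
  for (les in lesions) {
    voi <- les$voi
    lo <- voi$center_mm - voi$diameter_mm / 2
    hi <- voi$center_mm + voi$diameter_mm / 2
    if (any(lo < -spacing_mm / 2) || any(hi > extent + spacing_mm / 2))
      stop("lesion sphere extends outside the grid", call. = FALSE)
    idx <- voi_voxels(vol, voi)
    vol$values[idx] <- les$value
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    vol$values <- vol$values * exp(stats::rnorm(length(vol$values), 0, noise_sd))
  }
  vol
}

# ---------------------------------------------------------------------------
# Volume / VOI I/O
# ---------------------------------------------------------------------------

#' Read and write uptake volumes as NIfTI-1
#'
#' Voxel values are taken verbatim; the voxel spacing comes from the NIfTI
#' pixdim and the value units from the `units` argument (NIfTI carries no
#' activity-unit metadata this package trusts).
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param units Units of the stored voxel values.
#' @return `read_uptake_volume`: an [uptake_volume()].
#' @export
read_uptake_volume <- function(path, units = c("kBq_per_ml", "suv")) {
  units <- match.arg(units)
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L) stop("expected a 3-D NIfTI volume", call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  uptake_volume(vals, spacing, units = units)
}

#' @rdname read_uptake_volume
#' @param volume An [uptake_volume()] to write.
#' @export
write_uptake_volume <- function(volume, path) {
  stopifnot(inherits(volume, "uptake_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read spherical VOI definitions from a JSON sidecar
#'
#' The sidecar is a JSON array of objects with fields `name`, `center_mm`
#' (length-3) and `diameter_mm`.
#'
#' @param path JSON file path.
#' @return Named list of [sphere_voi()] objects.
#' @export
read_vois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  vois <- lapply(raw, function(v) sphere_voi(unlist(v$center_mm), v$diameter_mm))
  names(vois) <- vapply(raw, function(v) as.character(v$name), character(1))
  vois
}
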