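#' 3-D image volume
#'
#' A plain numeric 3-D array carrying voxel spacing (mm), world origin (mm)
#' and a unit label. World coordinates follow the half-voxel convention:
#' the centre of 0-based voxel `i` sits at `origin + (i + 0.5) * spacing`.
#'
#' @param data numeric 3-D array.
#' @param spacing voxel spacing in mm, length 3.
#' @param origin world position of the corner of voxel (0,0,0) in mm;
#'   defaults to centring the grid on the world origin.
#' @param units unit label, e.g. `"Bq"`, `"counts"`, `"MBq.h"`, `"mGy"`.
#' @return An `image_volume` object.
#' @export
image_volume <- function(data, spacing, origin = NULL, units = "arb") {
  data <- unclass(data)
  if (length(dim(data)) != 3L) stop("image_volume requires a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("bad voxel spacing")
  if (is.null(origin)) origin <- -spacing * dim(data) / 2
  structure(data, spacing = spacing, origin = as.numeric(origin),
            units = units, class = c("image_volume", "array"))
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_volume> %d x %d x %d voxels @ %s mm [%s]\n",
              d[1], d[2], d[3],
              paste(signif(attr(x, "spacing"), 4), collapse = " x "),
              attr(x, "units")))
  cat(sprintf("  range [%.4g, %.4g], sum %.6g\n",
              min(x), max(x), sum(x)))
  invisible(x)
}

#' Rewrap an array with the geometry of a template volume
#' @param data array with the template's dimensions.
#' @param template an `image_volume`.
#' @param units optional new unit label.
#' @export
vol_like <- function(data, template, units = NULL) {
  image_volume(data, attr(template, "spacing"), attr(template, "origin"),
               units %||% attr(template, "units"))
}

#' @export
#' @rdname image_volume
vox_spacing <- function(x) attr(x, "spacing")

#' Voxel volume in mL
#' @param x an `image_volume`.
#' @export
voxel_volume_ml <- function(x) prod(attr(x, "spacing")) / 1000

#' World coordinates (mm) of voxel centres along each axis
#' @param x an `image_volume`.
#' @return list of three numeric vectors.
#' @export
voxel_centres <- function(x) {
  sp <- attr(x, "spacing"); or <- attr(x, "origin"); d <- dim(x)
  lapply(1:3, function(a) or[a] + (seq_len(d[a]) - 0.5) * sp[a])
}

#' 2-D planar image
#'
#' A numeric matrix with pixel spacing (mm) and a unit label; axis 1 is the
#' transaxial (left-right) direction, axis 2 the axial (head-foot) direction.
#'
#' @param data numeric matrix.
#' @param spacing pixel spacing in mm (length 1 or 2).
#' @param units unit label.
#' @param time_h optional acquisition time post-injection in hours.
#' @export
planar_image <- function(data, spacing, units = "counts", time_h = NA_real_) {
  data <- unclass(as.matrix(data))
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  structure(data, spacing = spacing, units = units, time_h = time_h,
            class = c("planar_image", "matrix"))
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("<planar_image> %d x %d px @ %s mm [%s] t=%.3g h, sum %.6g\n",
              nrow(x), ncol(x), paste(signif(attr(x, "spacing"), 4),
                                      collapse = " x "),
              attr(x, "units"), attr(x, "time_h"), sum(x)))
  invisible(x)
}

#' Bilinear resampling of a planar image to a new pixel spacing
#'
#' Used to bring the planar matrix dialects (2.21 mm vs 2.88 mm pixels) to a
#' common grid before ROI propagation. Intensities are treated as per-pixel
#' counts, so total counts are rescaled by the pixel-area ratio.
#'
#' @param img a `planar_image`.
#' @param new_spacing target pixel spacing in mm (length 1 or 2).
#' @export
resample_planar <- function(img, new_spacing) {
  new_spacing <- as.numeric(new_spacing)
  if (length(new_spacing) == 1L) new_spacing <- rep(new_spacing, 2L)
  sp <- attr(img, "spacing")
  if (isTRUE(all.equal(sp, new_spacing))) return(img)
  extent <- dim(img) * sp
  nd <- pmax(1L, as.integer(round(extent / new_spacing)))
  # sample centre of each new pixel in old pixel index space
  cx <- ((seq_len(nd[1]) - 0.5) * new_spacing[1]) / sp[1] + 0.5
  cy <- ((seq_len(nd[2]) - 0.5) * new_spacing[2]) / sp[2] + 0.5
  out <- bilinear_sample(unclass(img), cx, cy)
  out <- out * prod(new_spacing) / prod(sp)  # preserve counts per area
  planar_image(out, new_spacing, attr(img, "units"), attr(img, "time_h"))
}

# bilinear interpolation of matrix m at grid outer(xs, ys)
bilinear_sample <- function(m, xs, ys) {
  nx <- nrow(m); ny <- ncol(m)
  x0 <- pmin(pmax(floor(xs), 1L), nx - 1L); fx <- pmin(pmax(xs - x0, 0), 1)
  y0 <- pmin(pmax(floor(ys), 1L), ny - 1L); fy <- pmin(pmax(ys - y0, 0), 1)
  m00 <- m[x0, y0, drop = FALSE]; m10 <- m[x0 + 1L, y0, drop = FALSE]
  m01 <- m[x0, y0 + 1L, drop = FALSE]; m11 <- m[x0 + 1L, y0 + 1L, drop = FALSE]
  wfx <- matrix(fx, length(xs), length(ys))
  wfy <- matrix(fy, length(xs), length(ys), byrow = TRUE)
  m00 * (1 - wfx) * (1 - wfy) + m10 * wfx * (1 - wfy) +
    m01 * (1 - wfx) * wfy + m11 * wfx * wfy
}

#' Write / read image volumes as NIfTI with a JSON sidecar
#'
#' The sidecar records origin and units, which plain NIfTI headers do not
#' carry in the package's convention.
#'
#' @param x an `image_volume` (or `planar_image` for the 2-D variants).
#' @param path output path, conventionally ending in `.nii.gz`.
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(array(as.numeric(x), dim = dim(x)))
  RNifti::pixdim(img) <- attr(x, "spacing")
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(origin = attr(x, "origin"),
                            spacing = attr(x, "spacing"),
                            units = attr(x, "units")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
  else list()
  sp <- meta$spacing %||% RNifti::pixdim(img)
  image_volume(as.array(img), sp, meta$origin, meta$units %||% "arb")
}
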