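#' Axis-aligned region of interest
#'
#' A `region_box` is the reference space for one brain region: an axis-aligned
#' box in micrometers with `x`, `y` in the section plane and `z` along the
#' cutting axis. The z extent must be an integer multiple of the section
#' thickness so that sections partition the region exactly.
#'
#' @param name Region label. Conventional labels are `"M1"`, `"S1BF"`,
#'   `"Cg"`, `"DG"`, `"CA1"` and `"NbM"`, but any string is accepted.
#' @param extent Numeric length-3 vector `c(x, y, z)` of box edge lengths
#'   in micrometers; all must be positive.
#' @param section_thickness Cut section thickness in micrometers used to
#'   validate the z extent (default 40).
#'
#' @return An object of class `region_box` with fields `name`, `extent`
#'   (named numeric) and `volume` (um^3). The box spans `[0, extent]` on
#'   each axis.
#' @export
#' @examples
#' roi <- region_box("DG", c(200, 200, 80))
#' roi$volume
region_box <- function(name, extent, section_thickness = 40) {
  if (!is.character(name) || length(name) != 1L)
    stop("`name` must be a single string", call. = FALSE)
  extent <- as.numeric(extent)
  if (length(extent) != 3L || anyNA(extent) || any(extent <= 0))
    stop("`extent` must be three positive lengths (um)", call. = FALSE)
  stopifnot_scalar(section_thickness, "section_thickness", positive = TRUE)
  k <- extent[3] / section_thickness
  if (abs(k - round(k)) > 1e-9)
    stop("z extent must be an integer multiple of section thickness",
         call. = FALSE)
  structure(
    list(name = name,
         extent = c(x = extent[1], y = extent[2], z = extent[3]),
         volume = prod(extent)),
    class = "region_box")
}

#' @export
print.region_box <- function(x, ...) {
  cat(sprintf("<region_box> %s: %g x %g x %g um (V = %g um^3)\n",
              x$name, x$extent[1], x$extent[2], x$extent[3], x$volume))
  invisible(x)
}
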