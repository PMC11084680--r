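#' Assemble a synthetic scene
#'
#' Bundles a region box with its fiber field, plaque set and neuron
#' population, plus generation metadata. All coordinates are micrometers,
#' right-handed, z along the cutting axis.
#'
#' @param roi A [region_box()].
#' @param fibers Optional `fiber_field`.
#' @param plaques Optional `plaque_set`.
#' @param neurons Optional `neuron_set`.
#' @param meta Named list of metadata (seed, preset name, ...); `units`
#'   is always recorded as `"micrometer"`.
#' @return A `scene` object.
#' @export
scene <- function(roi, fibers = NULL, plaques = NULL, neurons = NULL,
                  meta = list()) {
  stopifnot(inherits(roi, "region_box"))
  meta$units <- "micrometer"
  structure(list(roi = roi, fibers = fibers, plaques = plaques,
                 neurons = neurons, meta = meta),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %s", x$roi$name))
  if (!is.null(x$fibers))
    cat(sprintf(", L = %.0f um fibers", x$fibers$true_total_length))
  if (!is.null(x$plaques))
    cat(sprintf(", %d plaques", nrow(x$plaques$plaques)))
  if (!is.null(x$neurons))
    cat(sprintf(", %d neurons", x$neurons$true_count))
  cat("\n")
  invisible(x)
}

#' Write a scene to a JSON file
#'
#' Numbers are written at full double precision so a write/read round trip
#' reproduces the geometry exactly.
#'
#' @param x A [scene()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(x, path) {
  stopifnot(inherits(x, "scene"))
  truth <- list()
  obj <- list(
    roi = list(name = x$roi$name, extent = unname(x$roi$extent)),
    meta = x$meta)
  if (!is.null(x$fibers)) {
    obj$fibers <- lapply(x$fibers$polylines, function(m) unname(m))
    obj$orientation <- x$fibers$orientation
    truth$total_length <- x$fibers$true_total_length
    if (!is.null(x$fibers$true_length_by_zone))
      truth$length_by_zone <- as.list(x$fibers$true_length_by_zone)
  }
  if (!is.null(x$plaques)) {
    pm <- x$plaques$plaques
    obj$plaques <- lapply(seq_len(nrow(pm)), function(i) as.numeric(pm[i, ]))
    truth$burden <- x$plaques$burden
  }
  if (!is.null(x$neurons)) {
    cm <- as.matrix(x$neurons$cells[, c("x", "y", "z", "a", "b", "c")])
    obj$neurons <- lapply(seq_len(nrow(cm)), function(i) as.numeric(cm[i, ]))
    truth$neuron_count <- x$neurons$true_count
  }
  obj$truth <- truth
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a scene from a JSON file
#'
#' @param path File written by [write_scene()].
#' @return A [scene()].
#' @export
read_scene <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi <- region_box(obj$roi$name, as.numeric(obj$roi$extent))
  fibers <- NULL
  if (!is.null(obj$fibers)) {
    polylines <- if (is.list(obj$fibers)) {
      lapply(obj$fibers, function(m) matrix(unlist(m), ncol = 3,
                                            byrow = !is.matrix(m)))
    } else list()
    polylines <- lapply(polylines, unname)
    orientation <- normalize_orientation(obj$orientation)
    zl <- NULL
    if (!is.null(obj$truth$length_by_zone))
      zl <- unlist(obj$truth$length_by_zone)
    fibers <- new_fiber_field(polylines, orientation, roi, zl)
  }
  as_row_matrix <- function(x, ncol) {
    if (is.matrix(x)) return(unname(x))
    matrix(unlist(lapply(x, as.numeric)), ncol = ncol, byrow = TRUE)
  }
  plaques <- NULL
  if (!is.null(obj$plaques) && length(obj$plaques))
    plaques <- new_plaque_set(as_row_matrix(obj$plaques, 4), roi)
  neurons <- NULL
  if (!is.null(obj$neurons)) {
    cm <- as.data.frame(as_row_matrix(obj$neurons, 6))
    names(cm) <- c("x", "y", "z", "a", "b", "c")
    neurons <- new_neuron_set(cm, roi)
  }
  meta <- obj$meta
  s <- scene(roi, fibers = fibers, plaques = plaques, neurons = neurons,
             meta = if (is.null(meta)) list() else meta)
  s
}
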