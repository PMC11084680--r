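#' Proximity classification rule
#'
#' Probes are classed by the signed distance `d*` of the probe center from
#' the nearest plaque edge: `d* <= 0` is `within`, `0 < d* <= threshold_d`
#' is `near`, `d* > threshold_d` is `distant`. The default threshold is
#' 20 um. In `in_plane_2d` mode (default) the distance is measured in the
#' section plane against the plaque's circular profile at the section's cut
#' mid-plane, mirroring classification on a 2D micrograph; `full_3d` uses
#' the Euclidean distance to the plaque sphere surface.
#'
#' @param threshold_d Near/distant threshold, um (> 0; default 20).
#' @param mode `"in_plane_2d"` or `"full_3d"`.
#' @return A `proximity_rule` object.
#' @export
proximity_rule <- function(threshold_d = 20,
                           mode = c("in_plane_2d", "full_3d")) {
  stopifnot_scalar(threshold_d, "threshold_d", positive = TRUE)
  structure(list(threshold_d = threshold_d, mode = match.arg(mode)),
            class = "proximity_rule")
}

# signed distance of probe centers from the nearest plaque edge under a rule;
# Inf when no plaque qualifies
probe_plaque_distance <- function(probes, plaques, rule, section_set) {
  pm <- if (inherits(plaques, "plaque_set")) plaques$plaques else plaques
  n <- nrow(probes)
  if (is.null(pm) || nrow(pm) == 0L) return(rep(Inf, n))
  if (rule$mode == "full_3d") {
    pts <- cbind(probes$x, probes$y, probes$z_world)
    return(plaque_edge_distance(pts, pm))
  }
  # in-plane: plaque profile circle at the probe's section cut mid-plane
  t <- section_set$section_thickness
  z_mid <- vapply(probes$section, function(i)
    section_set$sections[[i]]$z0 + t / 2, 0)
  d <- rep(Inf, n)
  for (i in seq_len(nrow(pm))) {
    dz <- pm[i, 3] - z_mid
    hit <- abs(dz) < pm[i, 4]
    if (!any(hit)) next
    r_prof <- sqrt(pm[i, 4]^2 - dz[hit]^2)
    di <- sqrt((probes$x[hit] - pm[i, 1])^2 +
                 (probes$y[hit] - pm[i, 2])^2) - r_prof
    d[hit] <- pmin(d[hit], di)
  }
  d
}

#' Classify probes as within / near / distant from plaques
#'
#' Applies the center-based rule of [proximity_rule()] to every probe. A
#' probe partially overlapping a plaque but with its center outside is
#' near or distant by the center rule, never within. With an empty plaque
#' set every probe is distant.
#'
#' @param probes A `sphere_probe_frame`.
#' @param plaques A `plaque_set` (or 4-column plaque matrix).
#' @param rule A [proximity_rule()].
#' @param section_set The `section_set` the probes live in (needed for
#'   `in_plane_2d` mode to locate section mid-planes).
#' @return The probe frame with `proximity` set to
#'   `"within"`, `"near"` or `"distant"`, and the signed edge distance in
#'   column `d_star`.
#' @export
classify_probes <- function(probes, plaques, rule = proximity_rule(),
                            section_set = NULL) {
  stopifnot(inherits(rule, "proximity_rule"))
  if (rule$mode == "in_plane_2d" && is.null(section_set))
    stop("`section_set` is required for in_plane_2d classification",
         call. = FALSE)
  d <- probe_plaque_distance(probes, plaques, rule, section_set)
  probes$d_star <- d
  probes$proximity <- ifelse(d <= 0, "within",
                             ifelse(d <= rule$threshold_d, "near", "distant"))
  probes
}

#' Stratified crossings-per-probe density
#'
#' Mean crossings per probe computed separately for the near and distant
#' strata; `within` probes are excluded from both. An empty stratum yields
#' `NA` (flagged by `n = 0`), never zero.
#'
#' @param probes A classified `sphere_probe_frame` with `Q` filled.
#' @return A `stratified_density`: per-class mean Q, per-class probe
#'   counts (including `within`), and total probes.
#' @export
stratified_density <- function(probes) {
  if (any(probes$proximity == "unset"))
    stop("probes are unclassified; run classify_probes() first", call. = FALSE)
  if (anyNA(probes$Q))
    stop("probes have uncounted Q; run probe_crossings() first", call. = FALSE)
  n_within <- sum(probes$proximity == "within")
  if (n_within == nrow(probes))
    stop("all probes fall within plaques; near/distant strata are empty",
         call. = FALSE)
  cls <- c("near", "distant")
  means <- vapply(cls, function(k) {
    q <- probes$Q[probes$proximity == k]
    if (length(q) == 0L) NA_real_ else mean(q)
  }, 0)
  ns <- vapply(cls, function(k) sum(probes$proximity == k), 0L)
  structure(
    list(mean_Q = means,
         n_probes = c(ns, within = n_within),
         n_total = nrow(probes),
         relative_to_reference = NULL),
    class = "stratified_density")
}

#' @export
print.stratified_density <- function(x, ...) {
  cat(sprintf(
    "<stratified_density> near %.3g (n=%d) / distant %.3g (n=%d), %d within excluded\n",
    x$mean_Q[["near"]], x$n_probes[["near"]],
    x$mean_Q[["distant"]], x$n_probes[["distant"]], x$n_probes[["within"]]))
  if (!is.null(x$relative_to_reference))
    cat(sprintf("  relative to reference: near %.1f%% / distant %.1f%%\n",
                x$relative_to_reference[["near"]],
                x$relative_to_reference[["distant"]]))
  invisible(x)
}

#' Express stratified densities relative to a reference group
#'
#' Rescales each stratum mean to percent of a reference mean
#' crossings-per-probe — conventionally the age- and region-matched
#' non-transgenic (nTg) group mean.
#'
#' @param strat A [stratified_density()] result.
#' @param reference_mean_Q Reference mean crossings per probe (> 0).
#' @return The `stratified_density` with `relative_to_reference` filled
#'   (percent).
#' @export
relative_density <- function(strat, reference_mean_Q) {
  stopifnot(inherits(strat, "stratified_density"))
  if (!is.finite(reference_mean_Q) || reference_mean_Q <= 0)
    stop("`reference_mean_Q` must be > 0", call. = FALSE)
  strat$relative_to_reference <- 100 * strat$mean_Q / reference_mean_Q
  strat
}
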