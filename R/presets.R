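#' Load the scenario preset table
#'
#' Reads the versioned `presets.yaml` shipped with the package (or a
#' user-supplied file of the same schema) and merges each preset with the
#' shared defaults.
#'
#' @param path Optional path to a presets YAML file; defaults to the
#'   file shipped in `inst/extdata`.
#' @return Named list of preset parameter lists; the schema version is in
#'   the `"schema_version"` attribute.
#' @export
load_presets <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "presets.yaml", package = "stereosim")
  cfg <- yaml::read_yaml(path)
  defaults <- cfg$defaults %||% list()
  presets <- lapply(cfg$presets, function(p) utils::modifyList(defaults, p))
  attr(presets, "schema_version") <- cfg$schema_version %||% NA
  presets
}

#' Fetch one preset by name
#'
#' @param name Preset name.
#' @param path Optional presets file (see [load_presets()]).
#' @return Parameter list.
#' @export
get_preset <- function(name, path = NULL) {
  presets <- load_presets(path)
  if (!name %in% names(presets))
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  p <- presets[[name]]
  p$name <- name
  p
}

#' Simulate one subject of an afferent-density scenario
#'
#' Runs the full single-subject pipeline: scene generation (fibers +
#' plaques), plaque-local depletion, sectioning, spherical-probe placement,
#' crossing counts and proximity classification. The non-transgenic control
#' genotype (`"nTg"`) carries no plaques and full survival.
#'
#' @param preset Preset parameter list (see [get_preset()]) or preset name.
#' @param seed Subject-level master seed; stage seeds are derived with
#'   [child_seeds()].
#' @param genotype `"APP/PS1"` (pathology as parameterized) or `"nTg"`
#'   (no plaques, survival 1).
#' @return List: classified `probes`, `strat` ([stratified_density()];
#'   `NULL` for plaque-free subjects), `field` (post-depletion), `plaques`,
#'   `section_set`, `truth` (imposed parameters and zone lengths).
#' @export
simulate_afferent_subject <- function(preset, seed, genotype = "APP/PS1") {
  p <- if (is.character(preset)) get_preset(preset) else preset
  if (genotype == "nTg") {
    p$plaque_count <- 0
    p$survival_near <- 1
    p$survival_distant <- 1
  }
  seeds <- child_seeds(seed, 5)
  roi <- region_box(p$region, as.numeric(p$roi),
                    section_thickness = p$section_thickness)
  field <- generate_fiber_field(roi, p$target_Lv,
                                orientation = p$orientation,
                                seed = seeds[1])
  plq <- generate_plaques(roi, p$plaque_count,
                          radius = as.numeric(p$plaque_radius),
                          min_edge_separation = p$min_edge_separation,
                          seed = seeds[2])
  dep <- apply_depletion(field, plq, threshold_d = p$threshold_d,
                         survival_near = p$survival_near,
                         survival_distant = p$survival_distant,
                         seed = seeds[3])
  ss <- slice_sections(dep, section_thickness = p$section_thickness,
                       sampling_interval = p$sampling_interval,
                       mounted_thickness = p$mounted_thickness,
                       phase_seed = seeds[4])
  probes <- place_probes(ss, roi, n_locations = p$n_probes,
                         probe_radius = p$probe_radius,
                         guard_z = p$guard_z, seed = seeds[5])
  probes <- probe_crossings(probes, ss)
  rule <- proximity_rule(p$threshold_d, p$proximity_mode)
  probes <- classify_probes(probes, plq, rule, ss)
  strat <- if (any(probes$proximity != "within") &&
               nrow(plq$plaques) > 0) stratified_density(probes) else NULL
  list(probes = probes,
       strat = strat,
       field = dep,
       plaques = plq,
       section_set = ss,
       truth = list(
         survival_near = p$survival_near,
         survival_distant = p$survival_distant,
         threshold_d = p$threshold_d,
         target_Lv = p$target_Lv,
         length_by_zone = dep$true_length_by_zone,
         predepletion_length_by_zone =
           attr(dep, "predepletion_length_by_zone")))
}

#' Simulate one subject of a neuron-counting scenario
#'
#' Generates the control population, optionally thins it, slices sections
#' at the design's interval and runs the optical fractionator.
#'
#' @param preset Preset list or name (a `kind: neuron` preset).
#' @param seed Subject-level master seed.
#' @param genotype `"APP/PS1"` (thinned by `loss_fraction`) or `"nTg"`.
#' @return List: `neurons`, `sum_Qminus`, `estimate`
#'   ([fractionator_estimate()]), `design`, `truth`.
#' @export
simulate_neuron_subject <- function(preset, seed, genotype = "APP/PS1") {
  p <- if (is.character(preset)) get_preset(preset) else preset
  loss <- if (genotype == "nTg") 0 else p$loss_fraction
  seeds <- child_seeds(seed, 4)
  roi <- region_box(p$region, as.numeric(p$roi),
                    section_thickness = p$section_thickness)
  cells <- generate_neurons(roi, p$n_true, seed = seeds[1])
  if (loss > 0) cells <- thin_neurons(cells, loss, seed = seeds[2])
  design <- fractionator_design(section_interval = p$section_interval,
                                mounted_thickness = p$mounted_thickness)
  ss <- slice_sections(generate_fiber_field(roi, 0, seed = 1),
                       section_thickness = p$section_thickness,
                       sampling_interval = p$section_interval,
                       mounted_thickness = p$mounted_thickness,
                       phase_seed = seeds[3])
  q <- count_in_frames(cells, design, ss, seed = seeds[4])
  list(neurons = cells,
       sum_Qminus = as.integer(q),
       estimate = fractionator_estimate(q, design),
       design = design,
       truth = list(n_true = cells$true_count, loss_fraction = loss))
}

#' Near-vs-distant percent reduction recovered from one scenario run
#'
#' Simulates a group of subjects under an afferent preset, pools the
#' classified probes, and reports the percent reduction of near-plaque
#' relative to distant fiber density,
#' `100 * (1 - mean(Q near) / mean(Q distant))`.
#'
#' @param preset Preset list or name.
#' @param seed Master seed for the group (per-subject seeds derived).
#' @param n_subjects Number of subjects (defaults to the preset's value).
#' @return List: `reduction_pct`, pooled `near_mean`, `distant_mean`,
#'   per-class probe counts.
#' @export
near_distant_reduction <- function(preset, seed, n_subjects = NULL) {
  p <- if (is.character(preset)) get_preset(preset) else preset
  n_subjects <- n_subjects %||% p$n_subjects
  seeds <- child_seeds(seed, n_subjects)
  probes <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    r <- simulate_afferent_subject(p, seeds[i])
    cbind(subject = i, r$probes)
  }))
  near <- probes$Q[probes$proximity == "near"]
  distant <- probes$Q[probes$proximity == "distant"]
  if (!length(near) || !length(distant))
    stop("empty near or distant stratum in pooled probes", call. = FALSE)
  list(reduction_pct = 100 * (1 - mean(near) / mean(distant)),
       near_mean = mean(near),
       distant_mean = mean(distant),
       n = c(near = length(near), distant = length(distant),
             within = sum(probes$proximity == "within")))
}

#' Percent neuron loss recovered by the optical fractionator
#'
#' Simulates a control and a thinned group under a neuron preset and
#' reports `100 * (1 - mean(N_hat thinned) / mean(N_hat control))`.
#'
#' @inheritParams near_distant_reduction
#' @return List: `loss_pct`, group mean estimates.
#' @export
fractionator_loss <- function(preset, seed, n_subjects = NULL) {
  p <- if (is.character(preset)) get_preset(preset) else preset
  n_subjects <- n_subjects %||% p$n_subjects
  seeds <- child_seeds(seed, 2 * n_subjects)
  n_ctrl <- vapply(seq_len(n_subjects), function(i)
    simulate_neuron_subject(p, seeds[i], "nTg")$estimate$N_hat, 0)
  n_tg <- vapply(seq_len(n_subjects), function(i)
    simulate_neuron_subject(p, seeds[n_subjects + i], "APP/PS1")$estimate$N_hat, 0)
  list(loss_pct = 100 * (1 - mean(n_tg) / mean(n_ctrl)),
       mean_control = mean(n_ctrl),
       mean_thinned = mean(n_tg))
}

#' Build a tidy density table from an afferent preset
#'
#' Simulates both genotype groups and returns one `density_table` row per
#' subject x proximity class (plus `"overall"`), with the mean crossings
#' per probe as the density value. Control subjects have no plaques, so
#' only their `"overall"` row is produced.
#'
#' @param preset Preset list or name (kind `afferent`).
#' @param seed Master seed.
#' @param genotypes Genotype groups to simulate.
#' @return A [density_table()].
#' @export
simulate_density_table <- function(preset, seed,
                                   genotypes = c("nTg", "APP/PS1")) {
  p <- if (is.character(preset)) get_preset(preset) else preset
  gseeds <- child_seeds(seed, length(genotypes))
  rows <- list()
  for (gi in seq_along(genotypes)) {
    g <- genotypes[gi]
    sseeds <- child_seeds(gseeds[gi], p$n_subjects)
    for (i in seq_len(p$n_subjects)) {
      r <- simulate_afferent_subject(p, sseeds[i], g)
      id <- sprintf("%s-%02d", gsub("[^A-Za-z0-9]", "", g), i)
      q <- r$probes$Q[r$probes$proximity != "within"]
      rows[[length(rows) + 1L]] <-
        data.frame(subject = id, genotype = g, age = p$age,
                   region = p$region, class = "overall", value = mean(q))
      if (!is.null(r$strat)) {
        for (k in c("near", "distant")) {
          if (r$strat$n_probes[[k]] > 0)
            rows[[length(rows) + 1L]] <-
              data.frame(subject = id, genotype = g, age = p$age,
                         region = p$region, class = k,
                         value = r$strat$mean_Q[[k]])
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  density_table(out$subject, out$genotype, out$age, out$region,
                out$value, out$class)
}
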