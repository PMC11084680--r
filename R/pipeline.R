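# 32-bit FNV-1a over a string, implemented with 16-bit limbs so the
# multiplication stays inside double precision
fnv1a_hash <- function(s) {
  h <- 2166136261
  m <- 16777619
  for (x in utf8ToInt(enc2utf8(s))) {
    h <- bitwXor(as.integer(h %% 2^31), x) + (h %/% 2^31) * 2^31
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- ((h1 * m) %% 65536) * 65536 + h0 * m
    h <- h %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run configuration for the end-to-end pipeline
#'
#' @param preset Preset name (see [load_presets()]).
#' @param seed Master seed; per-stage and per-subject seeds are derived
#'   from it with [child_seeds()].
#' @param out_dir Output directory (created if absent).
#' @param threshold_d Optional override of the preset's near/distant
#'   threshold, um.
#' @param n_probes Optional override of probes per subject.
#' @param proximity_mode Optional override (`"in_plane_2d"` / `"full_3d"`).
#' @param save_scenes Write per-subject scene JSON files (default FALSE;
#'   scene files are large).
#' @return A `run_config` list.
#' @export
run_config <- function(preset, seed, out_dir,
                       threshold_d = NULL, n_probes = NULL,
                       proximity_mode = NULL, save_scenes = FALSE) {
  cfg <- list(preset = preset, seed = as.integer(seed), out_dir = out_dir,
              threshold_d = threshold_d, n_probes = n_probes,
              proximity_mode = proximity_mode, save_scenes = save_scenes)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full simulation-to-statistics pipeline
#'
#' Simulates both genotype groups under the configured preset, writes the
#' probe records, stratified densities, density estimates and the
#' statistics report as CSV, and a reproducibility block (config YAML +
#' hash). Running the same config and seed twice produces byte-identical
#' outputs.
#'
#' @param config A [run_config()] (or a list with the same fields).
#' @return Invisibly, a list with the output paths and the in-memory
#'   results (`probes`, `table`, `summary`, `anova`, `posthoc`).
#' @export
run_pipeline <- function(config) {
  p <- get_preset(config$preset)
  if (!is.null(config$threshold_d)) p$threshold_d <- config$threshold_d
  if (!is.null(config$n_probes)) p$n_probes <- config$n_probes
  if (!is.null(config$proximity_mode)) p$proximity_mode <- config$proximity_mode
  if (identical(p$kind, "neuron"))
    return(run_neuron_pipeline(config, p))
  if (identical(p$kind, "afferent_panel"))
    stop("panel presets: run each region's preset separately", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_yaml <- yaml::as.yaml(config[setdiff(names(config), "out_dir")])
  hash <- fnv1a_hash(cfg_yaml)

  genotypes <- c("nTg", "APP/PS1")
  gseeds <- child_seeds(config$seed, length(genotypes))
  all_probes <- list(); strat_rows <- list(); est_rows <- list()
  for (gi in seq_along(genotypes)) {
    g <- genotypes[gi]
    sseeds <- child_seeds(gseeds[gi], p$n_subjects)
    for (i in seq_len(p$n_subjects)) {
      r <- simulate_afferent_subject(p, sseeds[i], g)
      id <- sprintf("%s-%02d", gsub("[^A-Za-z0-9]", "", g), i)
      pr <- r$probes
      all_probes[[length(all_probes) + 1L]] <- data.frame(
        subject = id, genotype = g, region = p$region,
        section = pr$section, x = pr$x, y = pr$y, z = pr$z_mounted,
        radius = pr$radius, Q = pr$Q, proximity_class = pr$proximity)
      est <- estimate_length_density(pr)
      est_rows[[length(est_rows) + 1L]] <- data.frame(
        subject = id, genotype = g, region = p$region,
        Lv_hat = est$Lv_hat, sum_Q = est$sum_Q, n_probes = est$n_probes,
        L_hat = estimate_total_length(est, region_box(
          p$region, as.numeric(p$roi), p$section_thickness), r$section_set))
      if (!is.null(r$strat)) {
        for (k in c("near", "distant"))
          strat_rows[[length(strat_rows) + 1L]] <- data.frame(
            subject = id, genotype = g, region = p$region, class = k,
            n_probes = r$strat$n_probes[[k]],
            mean_Q = r$strat$mean_Q[[k]])
      }
    }
  }
  probes_df <- do.call(rbind, all_probes)
  est_df <- do.call(rbind, est_rows)
  strat_df <- if (length(strat_rows)) do.call(rbind, strat_rows) else NULL

  tab <- simulate_density_table(p, config$seed, genotypes)
  summ <- summarize_groups(tab)
  overall <- tab[tab$class == "overall", ]
  aov_tab <- anova_table(overall, "genotype")
  ph <- posthoc_pairwise(overall, "genotype", method = "tukey")

  paths <- c(probes = "probes.csv", estimates = "estimates.csv",
             stratified = "stratified.csv", density = "density_table.csv",
             summary = "summary.csv", anova = "anova.csv",
             posthoc = "posthoc.csv", config = "config.yaml",
             log = "run.log")
  paths <- vapply(paths, function(f) file.path(config$out_dir, f), "")
  wcsv <- function(d, f) if (!is.null(d)) {
    d$config_hash <- hash
    utils::write.csv(d, f, row.names = FALSE)
  }
  wcsv(probes_df, paths[["probes"]])
  wcsv(est_df, paths[["estimates"]])
  wcsv(strat_df, paths[["stratified"]])
  wcsv(as.data.frame(tab), paths[["density"]])
  wcsv(summ, paths[["summary"]])
  wcsv(aov_tab, paths[["anova"]])
  wcsv(ph, paths[["posthoc"]])
  writeLines(c(sprintf("config_hash: %s", hash), cfg_yaml),
             paths[["config"]])
  writeLines(sprintf(
    "stereosim run: preset=%s seed=%d hash=%s probes=%d subjects=%d",
    config$preset, config$seed, hash, nrow(probes_df),
    p$n_subjects * length(genotypes)), paths[["log"]])
  invisible(list(paths = paths, probes = probes_df, estimates = est_df,
                 stratified = strat_df, table = tab, summary = summ,
                 anova = aov_tab, posthoc = ph, config_hash = hash))
}

run_neuron_pipeline <- function(config, p) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_yaml <- yaml::as.yaml(config[setdiff(names(config), "out_dir")])
  hash <- fnv1a_hash(cfg_yaml)
  genotypes <- c("nTg", "APP/PS1")
  gseeds <- child_seeds(config$seed, 2)
  rows <- list()
  for (gi in seq_along(genotypes)) {
    sseeds <- child_seeds(gseeds[gi], p$n_subjects)
    for (i in seq_len(p$n_subjects)) {
      r <- simulate_neuron_subject(p, sseeds[i], genotypes[gi])
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("%s-%02d",
                          gsub("[^A-Za-z0-9]", "", genotypes[gi]), i),
        genotype = genotypes[gi], region = p$region,
        sum_Qminus = r$sum_Qminus, N_hat = r$estimate$N_hat,
        ssf = r$estimate$ssf, asf = r$estimate$asf, hsf = r$estimate$hsf)
    }
  }
  est_df <- do.call(rbind, rows)
  tab <- density_table(est_df$subject, est_df$genotype, p$age, p$region,
                       est_df$N_hat, "overall")
  aov_tab <- anova_table(tab, "genotype")
  est_path <- file.path(config$out_dir, "estimates.csv")
  est_df$config_hash <- hash
  utils::write.csv(est_df, est_path, row.names = FALSE)
  aov_path <- file.path(config$out_dir, "anova.csv")
  aov_tab$config_hash <- hash
  utils::write.csv(aov_tab, aov_path, row.names = FALSE)
  writeLines(c(sprintf("config_hash: %s", hash), cfg_yaml),
             file.path(config$out_dir, "config.yaml"))
  invisible(list(paths = c(estimates = est_path, anova = aov_path),
                 estimates = est_df, table = tab, anova = aov_tab,
                 config_hash = hash))
}
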