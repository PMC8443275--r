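#' Default pipeline configuration
#'
#' Central run configuration for [run_pipeline()]. Defaults follow the
#' assay parameters where these are standard: 15-pixel dilate/erode mask
#' radius, 2.5 um probe radius (5 um bead), Poisson ratio 0.5, 500 um
#' confrontation gap.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param ... Named overrides of any default entry.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    density_variant = "inverse_of_sum",
    bin_width_um = 50,
    mask_radius_px = 15L,
    hertz = list(R_um = 2.5, nu = 0.5, fit_fraction = 0.5),
    field = list(width_um = 1000, height_um = 1000, pixel_size_um = 0.5),
    pattern = list(n_winner = 300L, n_loser = 300L,
                   gap_width_um = 500, apoptosis_base_rate = 0.05,
                   apoptosis_amplitude = 0.4,
                   apoptosis_decay_length_um = 100),
    growth = list(rate_winner = 1.1, rate_loser = 0.9,
                  plating_density = 4.4e4, mix_fraction_winner = 0.5,
                  coupling = 3e-6, days = 3L),
    qpcr = list(ddcq_example = -1))
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = c("run_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' Entries present in the file override the defaults of
#' [default_config()]; everything else keeps its default.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  modify <- function(base, new) {
    for (nm in names(new))
      base[[nm]] <- if (is.list(new[[nm]]) && is.list(base[[nm]]))
        modify(base[[nm]], new[[nm]]) else new[[nm]]
    base
  }
  structure(modify(unclass(cfg), user), class = c("run_config", "list"))
}

#' Run the quantification pipeline on synthetic data
#'
#' Binds the stages into one deterministic, seeded run: generates the
#' synthetic inputs and executes the requested analysis, writing CSV
#' artifacts plus a machine-readable JSON report per stage into
#' `out_dir`. Commands: `simulate` (write the synthetic inputs),
#' `density`, `profile`, `ncratio`, `hertz`, `compete`, `qpcr`, `all`.
#'
#' @param command One of the stage names above.
#' @param config A `run_config` (see [default_config()]), or a YAML path.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of stage reports (also written as
#'   `report_<command>.json`).
#' @export
run_pipeline <- function(command = "all", config = default_config(),
                         out_dir = tempfile("cellcompr_run_")) {
  cmds <- c("simulate", "density", "profile", "ncratio", "hertz",
            "compete", "qpcr", "all")
  if (!is.character(command) || length(command) != 1 ||
      !command %in% cmds)
    stopf("unknown command '%s'; expected one of: %s",
          paste(command, collapse = ","), paste(cmds, collapse = ", "))
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  todo <- if (command == "all")
    c("simulate", "density", "profile", "ncratio", "hertz", "compete",
      "qpcr") else command
  reports <- list()
  for (cmd in todo)
    reports[[cmd]] <- switch(cmd,
      simulate = stage_simulate(config, out_dir),
      density = stage_density(config, out_dir),
      profile = stage_profile(config, out_dir),
      ncratio = stage_ncratio(config, out_dir),
      hertz = stage_hertz(config, out_dir),
      compete = stage_compete(config, out_dir),
      qpcr = stage_qpcr(config, out_dir))
  report <- c(list(config = unclass(config)), reports)
  jsonlite::write_json(report,
                       file.path(out_dir, paste0("report_", command,
                                                 ".json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "columns")
  invisible(reports)
}

#' @noRd
cfg_field <- function(config, offset = 0L) {
  field_spec(config$field$width_um, config$field$height_um,
             config$field$pixel_size_um, seed = config$seed + offset)
}

#' @noRd
stage_simulate <- function(config, out_dir) {
  pp <- make_point_pattern(
    cfg_field(config),
    pattern_params(config$pattern$n_winner, config$pattern$n_loser,
                   "corralled"))
  write_point_pattern(pp, file.path(out_dir, "pattern_corralled.csv"))
  counts <- simulate_growth(do.call(growth_params, config$growth))
  write_counts(counts, file.path(out_dir, "competition_counts.csv"))
  list(n_cells = nrow(pp$points), n_count_rows = nrow(counts))
}

#' @noRd
stage_density <- function(config, out_dir) {
  field <- cfg_field(config)
  corr <- make_point_pattern(
    field, pattern_params(config$pattern$n_winner, config$pattern$n_loser,
                          "corralled"))
  unif <- make_point_pattern(
    field_spec(field$width, field$height, field$pixel_size,
               seed = field$seed + 1L),
    pattern_params(config$pattern$n_winner, config$pattern$n_loser,
                   "uniform"))
  dc <- pattern_density(corr, variant = config$density_variant)
  du <- pattern_density(unif, variant = config$density_variant)
  write_density(dc, file.path(out_dir, "density_corralled.csv"))
  write_density(du, file.path(out_dir, "density_uniform.csv"))
  keep <- function(d) d$rho[!d$hull_flag & d$subline == "loser" &
                             !is.na(d$rho)]
  ks <- compare_density(keep(dc), keep(du))
  list(variant = config$density_variant,
       mean_rho_loser_corralled = mean(keep(dc)),
       mean_rho_loser_uniform = mean(keep(du)),
       ks_D = ks$D, ks_p = ks$p)
}

#' @noRd
stage_profile <- function(config, out_dir) {
  field <- field_spec(4000, 2000, config$field$pixel_size_um,
                      seed = config$seed + 2L)
  pp <- make_point_pattern(
    field,
    pattern_params(2000, 2000, "confrontation", gap_width = 1,
                   apoptosis_base_rate = config$pattern$apoptosis_base_rate,
                   apoptosis_amplitude = config$pattern$apoptosis_amplitude,
                   apoptosis_decay_length =
                     config$pattern$apoptosis_decay_length_um))
  d <- assign_border_distance(pp, border = "estimate")
  prof <- profile_caspase(pp, d, bin_width = config$bin_width_um)
  write_border_profile(prof, file.path(out_dir, "border_profile.csv"))
  fit <- fit_caspase_decay(d, pp$points$caspase_pos)
  list(border_estimate_um = attr(d, "border_x"),
       border_truth_um = pp$border_x,
       fitted_decay_length_um = fit$decay_length,
       true_decay_length_um = config$pattern$apoptosis_decay_length_um)
}

#' @noRd
stage_ncratio <- function(config, out_dir) {
  field <- field_spec(200, 200, config$field$pixel_size_um,
                      seed = config$seed + 3L)
  centers <- place_nuclei(field, n = 12, min_dist = 40, margin = 20)
  truth <- image_truth(centers, nuclear_radius = 8, nc_partition = 2,
                       noise_sd = 0)
  img <- render_image(truth, field)
  write_cell_image(img, file.path(out_dir, "synthetic_image.tiff"))
  res <- quantify_nc(img, radius_px = config$mask_radius_px)
  write.csv(res, file.path(out_dir, "nc_ratios.csv"), row.names = FALSE)
  ok <- !res$empty_inner & !res$zero_cytoplasm & !res$edge_cell
  list(n_cells = nrow(res),
       median_nc_ratio = median(res$nc_ratio[ok], na.rm = TRUE),
       true_nc_partition = 2)
}

#' @noRd
stage_hertz <- function(config, out_dir) {
  truth <- hertz_truth(E_true = 1000, R = config$hertz$R_um,
                       nu = config$hertz$nu, noise_sd = 0.028)
  curves <- lapply(seq_len(20), function(i)
    make_force_curve(truth, seed = config$seed + 100L + i))
  fits <- lapply(curves, fit_hertz,
                 fit_fraction = config$hertz$fit_fraction)
  write_force_curve(curves[[1]], file.path(out_dir, "force_curve_01.csv"))
  df <- data.frame(
    curve_id = seq_along(fits),
    cell_id = rep(seq_len(5), each = 4),
    experiment_id = 1L,
    E_Pa = vapply(fits, function(f) f$E_Pa, numeric(1)),
    contact_point_um = vapply(fits, function(f) f$contact_point_um,
                              numeric(1)),
    rss = vapply(fits, function(f) f$rss, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)))
  write.csv(df, file.path(out_dir, "hertz_fits.csv"), row.names = FALSE)
  sm <- summarize_cells(df)
  list(median_E_Pa = median(df$E_Pa[df$converged]),
       experiment_mean_E_Pa = sm$experiments$E_Pa[1], true_E_Pa = 1000)
}

#' @noRd
stage_compete <- function(config, out_dir) {
  counts <- simulate_growth(do.call(growth_params, config$growth))
  gc <- growth_curves(counts)
  rs <- competition_ratio(counts)
  write.csv(rs, file.path(out_dir, "competition_ratios.csv"),
            row.names = FALSE)
  end <- max(counts$day)
  sep_l <- counts$count[counts$day == end & counts$condition == "separate" &
                          counts$subline == "loser"]
  co_l <- counts$count[counts$day == end & counts$condition == "coculture" &
                         counts$subline == "loser"]
  list(doubling_time_winner_sep =
         gc$rates$doubling_time[gc$rates$condition == "separate" &
                                  gc$rates$subline == "winner"],
       loser_suppression = 1 - co_l /
         (sep_l * (1 - config$growth$mix_fraction_winner)),
       final_ratio_coculture = rs$ratio[rs$condition == "coculture" &
                                          rs$day == end])
}

#' @noRd
stage_qpcr <- function(config, out_dir) {
  dd <- config$qpcr$ddcq_example
  res <- copy_number_2ddcq(
    target_sample = rep(25 + dd, 3), ref_sample = rep(25, 3),
    target_cal = rep(25, 3), ref_cal = rep(25, 3))
  jsonlite::write_json(res, file.path(out_dir, "qpcr.json"),
                       auto_unbox = TRUE, digits = NA)
  list(ddCq = res$ddCq, RQ = res$RQ,
       copy_number_estimate = res$copy_number_estimate)
}
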