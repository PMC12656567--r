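#' @title Pipeline configuration and orchestration
#' @description One declarative YAML (or list) configuration drives the
#'   full analysis: simulate the two acquisition years, preprocess, build
#'   the endmember library, unmix, map trends, summarize abundances,
#'   validate against reference points at both thresholds, and run the
#'   change tests. Every written artifact is listed, with a content hash,
#'   in a JSON manifest so any stage can be re-run in isolation.
#' @name pipeline
NULL

default_config <- function() {
  list(
    seed = 1L,
    years = c(2018L, 2022L),
    scene = list(
      rows = 100L, cols = 100L, n_bands = 426L,
      noise_sd = 0.005, smoothness_px = 0.5,
      concentration = c(0.12, 0.15, 0.10),
      concentration_year2 = c(0.08, 0.15, 0.14),
      corrupted_band_ranges = water_band_ranges(),
      n_bad_pixels = 25L),
    preprocess = list(
      sentinel = -9999, min_valid = 0,
      band_exclusions = water_band_ranges()),
    endmembers = list(source = "roi", purity = 0.8),
    unmix = list(mode = "fcls"),
    trend = list(breaks = default_trend_breaks()),
    summarize = list(n_bins = 10L, abundance_breaks = c(0.3, 0.6)),
    validate = list(taus = c(0.5, 0.75), n_per_class = 50L, purity = 0.75),
    stats = list(source = "scene"))
}

merge_config <- function(defaults, user, path = "", strict = TRUE) {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      if (strict) stop("unknown config key: ", full)
      next
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full,
                                      strict)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

config_check <- function(cond, key, msg) {
  if (!cond) stop("config `", key, "`: ", msg)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, rejects unknown
#' keys in strict mode, and checks every stage's preconditions, reporting
#' violations with their key path.
#'
#' @param config path to a YAML file, or a named list.
#' @param strict error on unknown keys.
#' @return A fully resolved config list of class `run_config`.
#' @export
validate_config <- function(config = list(), strict = TRUE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  cfg <- merge_config(default_config(), config, strict = strict)
  config_check(length(cfg$years) == 2 && cfg$years[2] > cfg$years[1],
               "years", "must be two increasing calendar years")
  config_check(cfg$scene$rows >= 1 && cfg$scene$cols >= 1, "scene.rows",
               "scene dimensions must be >= 1")
  config_check(cfg$scene$noise_sd >= 0, "scene.noise_sd", "must be >= 0")
  config_check(all(cfg$scene$concentration > 0), "scene.concentration",
               "must be positive")
  config_check(all(unlist(cfg$preprocess$band_exclusions) >= 1),
               "preprocess.band_exclusions", "indices are 1-based")
  config_check(cfg$unmix$mode %in% UNMIX_MODES, "unmix.mode",
               paste("must be one of", paste(UNMIX_MODES, collapse = ", ")))
  config_check(all(cfg$validate$taus > 0 & cfg$validate$taus < 1),
               "validate.taus", "must lie in (0, 1)")
  config_check(cfg$validate$purity > 0 && cfg$validate$purity <= 1,
               "validate.purity", "must lie in (0, 1]")
  config_check(!is.unsorted(cfg$trend$breaks, strictly = TRUE),
               "trend.breaks", "must be strictly increasing")
  config_check(cfg$summarize$n_bins >= 1, "summarize.n_bins",
               "must be >= 1")
  config_check(cfg$endmembers$source %in% c("roi", "truth"),
               "endmembers.source", "must be 'roi' or 'truth'")
  if (!identical(cfg$stats$source, "scene"))
    config_check(file.exists(cfg$stats$source), "stats.source",
                 "must be 'scene' or an existing CSV path")
  class(cfg) <- c("run_config", "list")
  cfg
}

# endmember library from high-purity truth pixels (emulating ROI
# delineation over visually pure patches)
library_from_purity_masks <- function(cube, truth, purity) {
  fs <- truth$fractions
  d <- dim(fs$fractions)
  K <- d[3]
  spectra <- matrix(NA_real_, K, dim(cube$reflectance)[3])
  band_sd <- spectra
  prov <- data.frame(class = fs$class_names, roi_ids = "purity-mask",
                     n_pixels = NA_integer_, stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    mask <- fs$fractions[, , k] >= purity
    if (!any(mask & cube$pixel_valid))
      stop("label '", fs$class_names[k],
           "' has zero valid pixels at ROI purity ", purity)
    ms <- extract_mean_spectrum(cube, mask)
    spectra[k, ] <- ms$spectrum
    band_sd[k, ] <- ms$sd
    prov$n_pixels[k] <- ms$n_pixels
  }
  endmember_library(spectra, fs$class_names, cube$wavelengths_nm,
                    band_valid = cube$band_valid, provenance = prov,
                    band_sd = band_sd)
}

pipeline_file <- function(files, path, stage) {
  rbind(files, data.frame(path = path, stage = stage,
                          stringsAsFactors = FALSE))
}

#' Run the full two-year analysis pipeline
#'
#' Executes simulate, preprocess, endmembers, unmix (both years), trend,
#' summarize, validate and stats in dependency order, writing all artifacts
#' under `out_dir` and a `manifest.json` listing every file with its MD5
#' content hash. Deterministic for a fixed config and seed.
#'
#' @param config a `run_config` from [validate_config()] (or anything it
#'   accepts).
#' @param out_dir output directory (created if absent).
#' @param seed optional seed overriding the config's.
#' @param verbose log stage progress to stderr.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL,
                         verbose = FALSE) {
  cfg <- if (inherits(config, "run_config")) config
         else validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[grassunmix] ", ...)
  files <- data.frame(path = character(), stage = character(),
                      stringsAsFactors = FALSE)
  log <- list()
  sc <- cfg$scene
  years <- cfg$years
  conc <- list(sc$concentration,
               sc$concentration_year2 %||% sc$concentration)

  # simulate + preprocess + unmix per year -------------------------------
  stacks <- list()
  truths <- list()
  hists <- list()
  lib <- NULL
  for (i in 1:2) {
    yr <- years[i]
    say("simulate ", yr)
    scn <- simulate_scene(sc$rows, sc$cols, sc$n_bands,
                          concentration = conc[[i]],
                          smoothness_px = sc$smoothness_px,
                          noise_sd = sc$noise_sd,
                          corrupted_band_ranges = sc$corrupted_band_ranges,
                          n_bad_pixels = sc$n_bad_pixels,
                          seed = cfg$seed + (i - 1L) * 1000L)
    cube <- exclude_bands(scn$cube, cfg$preprocess$band_exclusions)
    cube <- mask_invalid(cube, sentinel = cfg$preprocess$sentinel,
                         min_valid = cfg$preprocess$min_valid)
    log[[paste0("preprocess_", yr)]] <-
      list(n_masked = attr(cube, "n_newly_masked"),
           n_bands_valid = attr(cube, "n_bands_valid"))
    truths[[i]] <- scn$truth
    if (i == 2) {
      say("endmembers from year ", yr)
      lib <- if (cfg$endmembers$source == "roi")
        library_from_purity_masks(cube, scn$truth, cfg$endmembers$purity)
      else {
        tl <- scn$truth$library
        tl$band_valid <- cube$band_valid
        tl
      }
    }
    stacks[[i]] <- cube
  }
  for (i in 1:2) {
    yr <- years[i]
    say("unmix ", yr)
    st <- unmix_cube(stacks[[i]], lib, mode = cfg$unmix$mode)
    log[[paste0("unmix_", yr)]] <-
      list(mean_rmse = attr(st, "mean_rmse"),
           constraint_violations = attr(st, "constraint_violations"))
    fp <- file.path(out_dir, sprintf("fractions_%d.tif", yr))
    write_fraction_maps(st, fp)
    files <- pipeline_file(files, c(fp, tiff_sidecar(fp)), "unmix")
    stacks[[i]] <- st
    hists[[i]] <- stack_histograms(st, cfg$summarize$n_bins)
  }
  classes <- lib$class_names

  # trend ----------------------------------------------------------------
  say("trend")
  trend_rows <- list()
  for (cl in classes) {
    tr <- slope_map(stacks[[1]], stacks[[2]], years[1], years[2],
                    class_name = cl)
    tc <- classify_trend(tr, breaks = cfg$trend$breaks)
    ts <- trend_summary(tr)
    trend_rows[[cl]] <- data.frame(
      class = cl, mean_slope = ts$mean, sd_slope = ts$sd, n = ts$n,
      t(tc$counts), stringsAsFactors = FALSE, check.names = FALSE)
  }
  trend_csv <- file.path(out_dir, "trend_summary.csv")
  utils::write.csv(do.call(rbind, trend_rows), trend_csv,
                   row.names = FALSE)
  files <- pipeline_file(files, trend_csv, "trend")

  # summarize: bin counts + areas ----------------------------------------
  say("summarize")
  edges <- hists[[1]][[1]]$bin_edges
  bins_df <- data.frame(bin_lo = head(edges, -1), bin_hi = tail(edges, -1))
  area_rows <- list()
  for (i in 1:2) for (cl in classes) {
    bins_df[[paste0(cl, "_", years[i])]] <- hists[[i]][[cl]]$counts
    area_rows[[paste(cl, years[i])]] <- data.frame(
      class = cl, year = years[i],
      area_ha = weighted_area_ha(fraction_map(stacks[[i]], cl),
                                 stacks[[i]]$pixel_size_m^2),
      stringsAsFactors = FALSE)
  }
  bins_csv <- file.path(out_dir, "abundance_bin_counts.csv")
  utils::write.csv(bins_df, bins_csv, row.names = FALSE)
  area_csv <- file.path(out_dir, "area_estimates.csv")
  utils::write.csv(do.call(rbind, area_rows), area_csv, row.names = FALSE)
  files <- pipeline_file(files, c(bins_csv, area_csv), "summarize")

  # validate: reference points + confusion matrices ----------------------
  say("validate")
  pts <- sample_reference_points(truths[[2]], cfg$validate$n_per_class,
                                 purity = cfg$validate$purity,
                                 seed = cfg$seed + 7L)
  pts_csv <- file.path(out_dir, "reference_points.csv")
  write_points(pts, pts_csv)
  files <- pipeline_file(files, pts_csv, "validate")
  acc_log <- list()
  for (tau in cfg$validate$taus) {
    acc <- assess_accuracy(stacks[[2]], pts, tau = tau)
    cmat <- acc$confusion$counts
    out <- data.frame(reference = rownames(cmat), cmat,
                      users_accuracy = acc$metrics$users,
                      producers_accuracy = acc$metrics$producers,
                      check.names = FALSE)
    cm_csv <- file.path(out_dir,
                        sprintf("confusion_tau%02d.csv", round(tau * 100)))
    utils::write.csv(out, cm_csv, row.names = FALSE)
    files <- pipeline_file(files, cm_csv, "validate")
    acc_log[[sprintf("tau_%g", tau)]] <-
      list(overall = acc$metrics$overall,
           n_unclassified = acc$confusion$n_unclassified)
  }
  log$accuracy <- acc_log

  # stats ----------------------------------------------------------------
  say("stats")
  stats_input <- if (identical(cfg$stats$source, "scene")) bins_df
                 else utils::read.csv(cfg$stats$source)
  stats_df <- change_test_table(stats_input)
  stats_csv <- file.path(out_dir, "change_tests.csv")
  utils::write.csv(stats_df, stats_csv, row.names = FALSE)
  files <- pipeline_file(files, stats_csv, "stats")

  # library + manifest ----------------------------------------------------
  lib_csv <- file.path(out_dir, "endmember_library.csv")
  write_library(lib, lib_csv)
  files <- pipeline_file(files, lib_csv, "endmembers")
  files$md5 <- unname(tools::md5sum(files$path))
  manifest <- list(seed = cfg$seed, years = years, classes = classes,
                   stages = log,
                   files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  say("done: ", nrow(files), " artifacts")
  invisible(manifest)
}
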