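# Reproducible study runs: configuration schema and staged pipeline.

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults. Unknown keys
#' in a user configuration are rejected by [load_config()]; values given
#' override these defaults.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    pixel_size_um = 2,
    fluence_ratio = 1.0,
    noise_sd = 0,
    noise_floor = 0.05,
    prf = 2000,
    w = 3,
    n_repeats = 100L,
    so2_threshold = 0.75,
    segmentation = list(hi_frac = 0.5, lo_frac = 0.25, min_length = 10L),
    oxymap = list(ksv = 1.0, gray_bounds = c(1, 3), red_floor = NULL,
                  backgrounds = c(0.05, 0.05), noise_sd = 0),
    wound = list(r0_mm = 2, per_day_shrink = 0.05,
                 days = c(0, 3, 6, 10, 14), pixel_size_mm = 0.02),
    pk = list(ka = 0.4205, ke = 0.0439, scale = 52.31,
              times = c(0, 1, 2, 4, 6, 9, 12, 18, 24, 36, 48, 72, 96, 120,
                        144), noise_sd = 0),
    study = list(groups = c("treated", "vehicle"), n_per_group = 4L)
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a JSON configuration file, checks every key (recursively) against
#' [default_config()] — unknown keys raise a schema error naming the key —
#' and merges the values over the defaults.
#'
#' @param path JSON file, or a named list already in memory.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list()
  else if (is.character(path)) {
    if (!file.exists(path)) stop("missing config file: ", path,
                                 call. = FALSE)
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else path
  merge_config(default_config(), cfg, prefix = "")
}

merge_config <- function(defaults, given, prefix) {
  if (length(given) == 0) return(defaults)
  if (is.null(names(given)) || any(names(given) == ""))
    stop("config entries must be named (at '", prefix, "')", call. = FALSE)
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    stop("unknown config key: ", paste0(prefix, unknown[1]), call. = FALSE)
  for (k in names(given)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], as.list(given[[k]]),
                                    paste0(prefix, k, "."))
    } else {
      defaults[[k]] <- given[[k]]
    }
  }
  defaults
}

#' Run the analysis pipeline
#'
#' Executes one stage (or `"all"`) of the phantom demo study on disk. Every
#' output file carries a JSON provenance sidecar with the full configuration,
#' its hash and the seed; rerunning a stage with identical configuration and
#' seed reproduces the numeric outputs bit-for-bit.
#'
#' Stages: `simulate` (phantom ground truth + all raw inputs), `pam`
#' (structure/sO2/flow maps from the simulated scan), `vessels`
#' (segmentation, per-vessel metrics, OEF and MRO2), `oxymap` (ratiometric
#' oxygen map and wound-bed mean gray), `wound` (closure time course), `pk`
#' (Cmax/Tmax/AUC), `stats` (two-way ANOVA + Tukey report on a metric
#' table), `all` (everything in order).
#'
#' @param subcommand one of simulate, pam, vessels, oxymap, wound, pk,
#'   stats, all.
#' @param config configuration list from [load_config()] (or a path).
#' @param out_dir output directory (created if needed).
#' @param seed optional override of `config$seed`.
#' @return named list of the artifact paths written, invisibly.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "pam", "vessels",
                                        "oxymap", "wound", "pk", "stats"),
                         config = default_config(), out_dir, seed = NULL) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- load_config(config)
  config <- merge_config(default_config(), config, "")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (subcommand == "all")
    c("simulate", "pam", "vessels", "oxymap", "wound", "pk", "stats")
  else subcommand
  out <- list()
  for (st in stages) out[[st]] <- switch(
    st,
    simulate = stage_simulate(config, out_dir),
    pam = stage_pam(config, out_dir),
    vessels = stage_vessels(config, out_dir),
    oxymap = stage_oxymap(config, out_dir),
    wound = stage_wound(config, out_dir),
    pk = stage_pk(config, out_dir),
    stats = stage_stats(config, out_dir)
  )
  invisible(out)
}

# Demo phantom: an arterial/venous pair plus a slow capillary, spanning the
# sO2 and speed ranges of interest.
demo_phantom <- function(config) {
  px <- config$pixel_size_um
  n <- 128L
  ext <- n * px
  make_vessel_phantom(
    vessels = list(
      vessel(rbind(c(0.1 * ext, 0.3 * ext), c(0.9 * ext, 0.3 * ext)),
             diameter_um = 24, so2 = 0.95, speed_mm_s = 2,
             class = "arterial"),
      vessel(rbind(c(0.1 * ext, 0.7 * ext), c(0.9 * ext, 0.7 * ext)),
             diameter_um = 30, so2 = 0.65, speed_mm_s = 1.2,
             class = "venous"),
      vessel(rbind(c(0.5 * ext, 0.1 * ext), c(0.5 * ext, 0.9 * ext)),
             diameter_um = 12, so2 = 0.8, speed_mm_s = 0.5,
             class = "capillary")
    ),
    dim = c(n, n), pixel_size_um = px, seed = config$seed
  )
}

stage_simulate <- function(config, out_dir) {
  phantom <- demo_phantom(config)
  scan <- simulate_pam_scan(phantom, fluence_ratio = config$fluence_ratio,
                            noise_sd = config$noise_sd, seed = config$seed,
                            prf = config$prf, w = config$w,
                            n_repeats = config$n_repeats)
  paths <- character()
  truth_csv <- file.path(out_dir, "truth_vessels.csv")
  utils::write.csv(phantom_truth_table(phantom), truth_csv,
                   row.names = FALSE)
  paths <- c(paths, truth_csv)
  for (wl in scan$wavelengths) {
    p <- file.path(out_dir, sprintf("amp_%d.tif", wl))
    write_image_tiff(scan$amp[[as.character(wl)]], p,
                     meta = list(wavelength_nm = wl,
                                 pixel_size_um = config$pixel_size_um))
    paths <- c(paths, p)
  }
  for (fs in scan$flow_stacks) {
    p <- file.path(out_dir, sprintf("flow_stack_%02d.tif", fs$vessel_id))
    write_image_tiff(fs$stack, p, meta = list(prf = scan$prf, w = scan$w))
    pm <- file.path(out_dir, sprintf("flow_mask_%02d.tif", fs$vessel_id))
    write_image_tiff(fs$mask, pm)
    paths <- c(paths, p, pm)
  }
  # ratiometric oxygen phantom: radial pO2 gradient over the wound bed
  d <- c(96L, 96L)
  ctr <- pixel_centers(d, 1)
  rr <- sqrt(outer((ctr$y - d[1] / 2)^2, (ctr$x - d[2] / 2)^2, "+"))
  po2 <- clamp(rr / (d[1] / 2), 0, 1)
  pair <- simulate_ratiometric_images(po2, ksv = config$oxymap$ksv,
                                      backgrounds = config$oxymap$backgrounds,
                                      noise_sd = config$oxymap$noise_sd,
                                      seed = config$seed)
  for (nm in c("blue", "red", "blue_bg", "red_bg")) {
    p <- file.path(out_dir, paste0(nm, ".tif"))
    write_image_tiff(pair[[nm]], p)
    paths <- c(paths, p)
  }
  roi <- rr <= d[1] / 3
  roi_p <- file.path(out_dir, "roi.tif")
  write_image_tiff(roi, roi_p)
  paths <- c(paths, roi_p)
  masks <- simulate_wound_series(config$wound$r0_mm,
                                 config$wound$per_day_shrink,
                                 config$wound$days,
                                 config$wound$pixel_size_mm)
  for (d_ in names(masks)) {
    p <- file.path(out_dir, sprintf("wound_day%s.tif", d_))
    write_image_tiff(masks[[d_]], p,
                     meta = list(day = as.numeric(d_),
                                 pixel_size_mm = config$wound$pixel_size_mm))
    paths <- c(paths, p)
  }
  pk <- simulate_pk_profile(config$pk$ka, config$pk$ke, config$pk$scale,
                            config$pk$times, config$pk$noise_sd,
                            seed = config$seed)
  pk_csv <- file.path(out_dir, "pk.csv")
  utils::write.csv(as.data.frame(pk), pk_csv, row.names = FALSE)
  paths <- c(paths, pk_csv)
  write_provenance(file.path(out_dir, "simulate.provenance.json"),
                   config, config$seed)
  paths
}

stage_pam <- function(config, out_dir) {
  amp532 <- read_image_tiff(file.path(out_dir, "amp_532.tif"))
  amp559 <- read_image_tiff(file.path(out_dir, "amp_559.tif"))
  struct <- pmax(apply(amp532, c(1, 2), max), 0)
  so2 <- unmix_so2(apply(amp532, c(1, 2), mean),
                   apply(amp559, c(1, 2), mean),
                   fluence_ratio = config$fluence_ratio,
                   noise_floor = config$noise_floor)
  p_struct <- file.path(out_dir, "structure.tif")
  write_image_tiff(struct, p_struct,
                   meta = list(pixel_size_um = config$pixel_size_um))
  so2_store <- so2$so2; so2_store[!so2$valid] <- 0
  p_so2 <- file.path(out_dir, "so2.tif")
  write_image_tiff(so2_store, p_so2,
                   meta = list(noise_floor = config$noise_floor,
                               fluence_ratio = config$fluence_ratio))
  p_valid <- file.path(out_dir, "so2_valid.tif")
  write_image_tiff(so2$valid, p_valid)
  stack_files <- sort(list.files(out_dir, "^flow_stack_[0-9]+\\.tif$",
                                 full.names = TRUE))
  speeds <- do.call(rbind, lapply(stack_files, function(f) {
    est <- flow_speed(read_image_tiff(f), prf = config$prf, w = config$w)
    data.frame(stack = basename(f), speed_mm_s = est$speed_mm_s,
               quality = est$quality, degenerate = est$degenerate)
  }))
  p_flow <- file.path(out_dir, "flow_speeds.csv")
  utils::write.csv(speeds, p_flow, row.names = FALSE)
  write_provenance(file.path(out_dir, "pam.provenance.json"), config,
                   config$seed,
                   inputs = c("amp_532.tif", "amp_559.tif",
                              basename(stack_files)))
  c(p_struct, p_so2, p_valid, p_flow)
}

stage_vessels <- function(config, out_dir) {
  struct <- read_image_tiff(file.path(out_dir, "structure.tif"))
  so2_m <- read_image_tiff(file.path(out_dir, "so2.tif"))
  valid <- read_image_tiff(file.path(out_dir, "so2_valid.tif")) > 0.5
  so2_m[!valid] <- NA
  seg <- segment_vessels(struct,
                         hi_frac = config$segmentation$hi_frac,
                         lo_frac = config$segmentation$lo_frac,
                         min_length = config$segmentation$min_length)
  speeds <- utils::read.csv(file.path(out_dir, "flow_speeds.csv"))
  speed_map <- matrix(NA_real_, nrow(struct), ncol(struct))
  for (i in seq_len(nrow(speeds))) {
    mfile <- file.path(out_dir, sub("flow_stack", "flow_mask",
                                    speeds$stack[i]))
    mk <- read_image_tiff(mfile) > 0.5
    speed_map[mk] <- speeds$speed_mm_s[i]
  }
  tab <- vessel_metrics(seg, so2 = so2_m, flow = speed_map,
                        pixel_size_um = config$pixel_size_um)
  tab <- classify_av(tab, so2_threshold = config$so2_threshold)
  p_tab <- file.path(out_dir, "vessels.csv")
  write_vessel_table(tab, p_tab)
  p_lab <- file.path(out_dir, "vessel_labels.tif")
  write_image_tiff(seg$labels, p_lab)
  summ <- tryCatch({
    oef <- compute_oef(tab)
    oef <- compute_mro2(tab, oef)
    list(sao2 = oef$sao2, svo2 = oef$svo2, oef = oef$oef, mro2 = oef$mro2,
         inverted = oef$inverted)
  }, error = function(e) list(error = conditionMessage(e)))
  p_sum <- file.path(out_dir, "oxygen_summary.json")
  jsonlite::write_json(summ, p_sum, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write_provenance(file.path(out_dir, "vessels.provenance.json"), config,
                   config$seed,
                   inputs = c("structure.tif", "so2.tif", "flow_speeds.csv"))
  c(p_tab, p_lab, p_sum)
}

stage_oxymap <- function(config, out_dir) {
  pair <- list(blue = read_image_tiff(file.path(out_dir, "blue.tif")),
               red = read_image_tiff(file.path(out_dir, "red.tif")),
               blue_bg = read_image_tiff(file.path(out_dir, "blue_bg.tif")),
               red_bg = read_image_tiff(file.path(out_dir, "red_bg.tif")))
  corr <- subtract_background(pair)
  floor <- config$oxymap$red_floor %||% default_red_floor(pair$red_bg)
  if (floor <= 0) floor <- 0.05 * max(corr$red)
  ri <- ratio_map(corr$blue, corr$red, red_floor = floor,
                  gray_bounds = config$oxymap$gray_bounds)
  roi <- read_image_tiff(file.path(out_dir, "roi.tif")) > 0.5
  mg <- mean_gray(ri, roi)
  p_gray <- file.path(out_dir, "oxygen_gray.tif")
  gray_store <- ri$gray; gray_store[!ri$valid] <- 0
  write_image_tiff(gray_store, p_gray,
                   meta = list(gray_bounds = ri$bounds, red_floor = floor))
  p_mg <- file.path(out_dir, "mean_gray.json")
  jsonlite::write_json(list(mean_gray = mg, red_floor = floor,
                            gray_bounds = ri$bounds),
                       p_mg, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(file.path(out_dir, "oxymap.provenance.json"), config,
                   config$seed,
                   inputs = c("blue.tif", "red.tif", "blue_bg.tif",
                              "red_bg.tif", "roi.tif"))
  c(p_gray, p_mg)
}

stage_wound <- function(config, out_dir) {
  files <- list.files(out_dir, "^wound_day[0-9.]+\\.tif$")
  days <- as.numeric(sub("^wound_day([0-9.]+)\\.tif$", "\\1", files))
  ord <- order(days)
  masks <- lapply(files[ord], function(f)
    read_image_tiff(file.path(out_dir, f)) > 0.5)
  names(masks) <- days[ord]
  series <- closure_series(masks, config$wound$pixel_size_mm)
  p <- file.path(out_dir, "closure.csv")
  utils::write.csv(series, p, row.names = FALSE)
  write_provenance(file.path(out_dir, "wound.provenance.json"), config,
                   config$seed, inputs = files[ord])
  p
}

stage_pk <- function(config, out_dir) {
  pk <- utils::read.csv(file.path(out_dir, "pk.csv"))
  summ <- pk_summary(pk)
  p <- file.path(out_dir, "pk_summary.json")
  jsonlite::write_json(as.list(summ), p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write_provenance(file.path(out_dir, "pk.provenance.json"), config,
                   config$seed, inputs = "pk.csv")
  p
}

# Metric table for the statistics stage: use metrics.csv if the user placed
# one in out_dir; otherwise build a demo table of per-replicate day-6 wound
# closure where treated wounds shrink faster than vehicle wounds.
stage_stats <- function(config, out_dir) {
  mfile <- file.path(out_dir, "metrics.csv")
  metrics <- if (file.exists(mfile)) utils::read.csv(mfile)
  else local_seed(config$seed + 1L, {
    grp <- config$study$groups
    n <- config$study$n_per_group
    shrink <- c(config$wound$per_day_shrink,
                0.5 * config$wound$per_day_shrink)[seq_along(grp)]
    do.call(rbind, lapply(seq_along(grp), function(g) {
      do.call(rbind, lapply(seq_len(n), function(r) {
        s <- max(shrink[g] + stats::rnorm(1, sd = 0.005), 0)
        days <- setdiff(config$wound$days, 0)
        data.frame(value = 100 * (1 - s)^(2 * days), group = grp[g],
                   time = days, replicate = r, stringsAsFactors = FALSE)
      }))
    }))
  })
  gc_res <- group_compare(metrics)
  p_json <- file.path(out_dir, "stats.json")
  jsonlite::write_json(list(contrasts = gc_res$contrasts,
                            alpha_tiers = gc_res$alpha_tiers),
                       p_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  p_txt <- file.path(out_dir, "stats.txt")
  con <- file(p_txt, "w")
  sink(con); print(gc_res); sink()
  close(con)
  write_provenance(file.path(out_dir, "stats.provenance.json"), config,
                   config$seed,
                   inputs = if (file.exists(mfile)) "metrics.csv"
                            else character())
  c(p_json, p_txt)
}
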