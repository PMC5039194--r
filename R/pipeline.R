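#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()].
#' The default input source is the built-in simulator; point
#' `images_dir`/`traces_dir` at files to process platform exports
#' instead (images named `tray<t>_day<d>.png`, traces
#' `trace_<plant_id>_day<d>.csv` with columns `time_s`, `signal`,
#' `event`).
#'
#' @param n_accessions,n_treatments,n_replicates,days Design shape
#'   (simulator input).
#' @param style A [tray_style()].
#' @param params An [effect_params()].
#' @param chlf_kind `"quenching"` or `"light_curve"`.
#' @param intervals Growth intervals (`NULL` = choose from day range).
#' @param palette_k Number of hues.
#' @param exg_threshold,min_green,min_object_px,closing_radius
#'   Segmentation settings.
#' @param calib_cap Calibration pixel cap per image.
#' @param seed Global seed; all stage seeds derive from it.
#' @param images_dir,traces_dir Optional input directories of platform
#'   files (disables the simulator for that stage).
#' @param out_dir Optional output directory; when set, the merged trait
#'   table and per-stage CSVs are written there.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_accessions = 2, n_treatments = 2,
                            n_replicates = 3, days = 0:7,
                            style = tray_style(), params = effect_params(),
                            chlf_kind = c("light_curve", "quenching"),
                            intervals = NULL, palette_k = 9,
                            exg_threshold = 25, min_green = 50,
                            min_object_px = 20, closing_radius = 2,
                            calib_cap = 2000, seed = 1,
                            images_dir = NULL, traces_dir = NULL,
                            out_dir = NULL) {
  chlf_kind <- match.arg(chlf_kind)
  stopifnot(inherits(style, "tray_style"), inherits(params, "effect_params"))
  if (!is.null(intervals)) check_intervals(intervals)
  for (d in c(images_dir, traces_dir)) {
    if (!is.null(d) && !dir.exists(d)) abort("input directory not found: ", d)
  }
  cfg <- list(n_accessions = n_accessions, n_treatments = n_treatments,
              n_replicates = n_replicates, days = days, style = style,
              params = params, chlf_kind = chlf_kind, intervals = intervals,
              palette_k = palette_k, exg_threshold = exg_threshold,
              min_green = min_green, min_object_px = min_object_px,
              closing_radius = closing_radius, calib_cap = calib_cap,
              seed = as.integer(seed), images_dir = images_dir,
              traces_dir = traces_dir, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- unclass(config)
  plain$style <- unclass(plain$style)
  plain$style$leaf_palette <- as.vector(t(plain$style$leaf_palette))
  plain$params <- unclass(plain$params)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sty <- y$style
  sty$leaf_palette <- matrix(unlist(sty$leaf_palette), ncol = 3, byrow = TRUE)
  style <- do.call(tray_style, sty[intersect(names(sty),
                                             names(formals(tray_style)))])
  params <- do.call(effect_params, y$params[intersect(names(y$params),
                                            names(formals(effect_params)))])
  keep <- intersect(names(y), names(formals(pipeline_config)))
  args <- y[setdiff(keep, c("style", "params"))]
  args$intervals <- if (!is.null(y$intervals)) lapply(y$intervals, unlist)
  do.call(pipeline_config, c(args, list(style = style, params = params)))
}

#' Run the full phenotyping pipeline
#'
#' Executes the stage sequence segmentation -> morphometrics -> colour
#' segmentation -> chlorophyll fluorescence -> growth/SIIT ->
#' statistics on a simulated (default) or file-based experiment, and
#' merges everything into one long-format trait table
#' (`plant_id`, `accession`, `treatment`, `day`, `state`, `trait`,
#' `value`).  Tray images are processed one at a time so memory stays
#' flat; all randomness derives from `config$seed`, making re-runs
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class `pipeline_result`: `traits` (merged long
#'   tibble), `areas`, `morpho`, `hue`, `chlf`, `growth`, `siit`,
#'   `palette`, `cluster_report` (or `NULL` when not estimable),
#'   `design`, `log` (per-stage counts).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  seed <- config$seed
  log <- list()

  design <- generate_design(config$n_accessions, config$n_treatments,
                            config$n_replicates, days = config$days,
                            seed = seed)
  days <- design_days(design)
  sim <- simulate_experiment_tables(design, config$params,
                                    intervals = config$intervals, seed = seed)
  layout <- tray_layout(attr(design, "layout")[["rows"]],
                        attr(design, "layout")[["cols"]])
  trays <- sort(unique(design$tray))

  tray_image <- function(tr, d) {
    if (!is.null(config$images_dir)) {
      f <- file.path(config$images_dir, sprintf("tray%d_day%d.png", tr, d))
      if (!file.exists(f)) abort("tray image not found: ", f)
      return(read_tray_png(f))
    }
    targets <- sim$areas$area_px[sim$areas$day == d]
    names(targets) <- sim$areas$plant_id[sim$areas$day == d]
    render_tray_image(design, tr, d, config$style, targets, seed = seed)$image
  }

  # --- segmentation + morphometrics + colour labels, streaming by tray ---
  say("segmenting ", length(trays), " tray(s) x ", length(days), " day(s)")
  pot_rows <- list()
  calib <- list()
  calib_days <- unique(days[round(c(1, (length(days) + 1) / 2,
                                    length(days)))])
  for (d in days) {
    for (tr in trays) {
      img <- tray_image(tr, d)
      pots <- segment_tray(img, layout, config$exg_threshold,
                           config$min_green, config$min_object_px,
                           config$closing_radius)
      pots <- dplyr::inner_join(
        pots, design[design$tray == tr,
                     c("plant_id", "accession", "treatment", "tray_row",
                       "tray_col")],
        by = c("tray_row", "tray_col"))
      pots$day <- d
      if (d %in% calib_days) {
        nonempty <- pots$area_px > 0
        if (any(nonempty)) {
          calib[[length(calib) + 1]] <- collect_calibration_pixels(
            pots$crop[nonempty], pots$veg_mask[nonempty],
            strata = sprintf("day%d", d),
            cap_per_image = config$calib_cap, seed = seed + d)
        }
      }
      pot_rows[[length(pot_rows) + 1]] <- pots
    }
  }
  pots <- dplyr::bind_rows(pot_rows)
  log$segmented <- nrow(pots)

  say("morphometrics")
  morpho <- morphometrics_table(
    dplyr::select(pots, "plant_id", "accession", "treatment", "day", "mask"))

  say("building hue palette (k = ", config$palette_k, ")")
  calib_px <- dplyr::bind_rows(calib)
  palette <- build_hue_palette(calib_px, k = config$palette_k,
                               seed = seed + 101L)
  hue <- purrr::pmap(
    dplyr::select(pots, "plant_id", "accession", "treatment", "day",
                  "crop", "veg_mask"),
    function(plant_id, accession, treatment, day, crop, veg_mask) {
      lab <- segment_colors(crop, veg_mask, palette)
      ab <- hue_abundance(lab, k = config$palette_k)
      dplyr::mutate(ab, plant_id = plant_id, accession = accession,
                    treatment = treatment, day = day, .before = 1)
    }) |> dplyr::bind_rows()
  log$hue_plants <- length(unique(hue$plant_id))

  # --- chlorophyll fluorescence ---
  say("chlorophyll fluorescence (", config$chlf_kind, ")")
  protocol <- chlf_protocol(config$chlf_kind)
  chlf_rows <- list()
  truth_by_plant <- setNames(sim$plant_truth$chlf, sim$plant_truth$plant_id)
  for (i in seq_len(nrow(design))) {
    pid <- design$plant_id[i]
    for (d in days) {
      trace <- NULL
      if (!is.null(config$traces_dir)) {
        f <- file.path(config$traces_dir,
                       sprintf("trace_%s_day%d.csv", pid, d))
        if (file.exists(f)) {
          trace <- readr::read_csv(f, show_col_types = FALSE)
          trace$event[is.na(trace$event)] <- ""
        }
      } else {
        trace <- simulate_chlf_trace(truth_by_plant[[pid]], protocol,
                                     noise_sd = config$params$chlf_noise_sd,
                                     seed = seed + 977L * i + d)
      }
      row <- if (is.null(trace)) {
        tibble(state = NA_character_, trait = "FvFm", value = NA_real_,
               missing_trace = TRUE)
      } else {
        lv <- extract_levels(trace, protocol)
        dplyr::mutate(derive_parameters(lv), missing_trace = FALSE)
      }
      chlf_rows[[length(chlf_rows) + 1]] <-
        dplyr::mutate(row, plant_id = pid, day = d, .before = 1)
    }
  }
  chlf <- dplyr::bind_rows(chlf_rows) |>
    dplyr::left_join(design[, c("plant_id", "accession", "treatment")],
                     by = "plant_id")
  log$chlf_missing <- sum(chlf$missing_trace[chlf$trait == "FvFm"])

  # --- growth & SIIT on measured areas ---
  say("growth rates and SIIT")
  areas_measured <- morpho |>
    dplyr::select("plant_id", "accession", "treatment", "day", "area_px")
  growth <- fit_growth_rates(areas_measured, intervals = sim$intervals)
  siit_tbl <- if (any(growth$treatment != "control")) siit(growth) else NULL

  # --- merge into the long trait table ---
  trait_long <- dplyr::bind_rows(
    morpho |>
      tidyr::pivot_longer(dplyr::all_of(c("area_px", "perimeter_px",
                                          "roundness", "compactness", "rms",
                                          "eccentricity", "slenderness")),
                          names_to = "trait", values_to = "value") |>
      dplyr::mutate(state = NA_character_) |>
      dplyr::select("plant_id", "accession", "treatment", "day", "state",
                    "trait", "value"),
    hue |>
      dplyr::mutate(trait = sprintf("hue_%d", .data$hue),
                    state = NA_character_) |>
      dplyr::select("plant_id", "accession", "treatment", "day", "state",
                    "trait", value = "fraction"),
    chlf |>
      dplyr::select("plant_id", "accession", "treatment", "day", "state",
                    "trait", "value")
  )

  # --- accession-level clustering (needs >= 2 accessions, both arms) ---
  report <- NULL
  if (length(unique(design$accession)) >= 2 && !is.null(siit_tbl)) {
    report <- tryCatch(
      early_late_cluster_report(
        chlf, siit_tbl, day = max(days),
        state = if (config$chlf_kind == "quenching") "Lss" else "L4",
        k_rows = min(3, length(unique(design$accession)))),
      error = function(e) {
        say("cluster report skipped: ", conditionMessage(e)); NULL
      })
  }

  out <- structure(
    list(traits = trait_long, areas = areas_measured, morpho = morpho,
         hue = hue, chlf = chlf, growth = growth, siit = siit_tbl,
         palette = palette, cluster_report = report, design = design,
         config = config, log = log),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(out, config$out_dir)
  out
}

#' Write pipeline outputs as CSV/YAML files
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    readr::write_csv(x, file.path(dir, name))
  }
  wr(result$traits, "traits.csv")
  wr(result$areas, "areas.csv")
  wr(result$growth, "growth.csv")
  if (!is.null(result$siit)) wr(result$siit, "siit.csv")
  pal <- as.data.frame(result$palette$centroids)
  pal$hue <- seq_len(nrow(pal))
  wr(pal[, c("hue", "R", "G", "B")], "palette.csv")
  yaml::write_yaml(list(seed = result$config$seed,
                        chlf_kind = result$config$chlf_kind,
                        log = result$log),
                   file.path(dir, "run_manifest.yaml"))
  invisible(dir)
}

#' Read / write a tray image as PNG
#'
#' Images are handled as height x width x 3 arrays on the 0-255 scale.
#'
#' @param path PNG file path.
#' @param image H x W x 3 array (0-255) for writing.
#' @return `read_tray_png()` returns the array; `write_tray_png()`
#'   returns `path` invisibly.
#' @export
read_tray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  a[, , 1:3, drop = FALSE] * 255
}

#' @rdname read_tray_png
#' @export
write_tray_png <- function(image, path) {
  img <- image / 255
  img[img < 0] <- 0
  img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  plants:", nrow(x$design), " days:",
      length(unique(x$traits$day)), "\n")
  cat("  trait rows:", nrow(x$traits), "\n")
  cat("  stages:", paste(names(x$log), unlist(x$log), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}
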