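# Configuration parsing, result serialization, run manifests, and the
# ASCII geometry dump. Config files are YAML; all CSV output is comma
# separated, dot decimal, header row, UTF-8 (see inst/FORMATS.md).

#' Read a scenario configuration file
#'
#' YAML blocks: \code{scenario} (type "treatment" or "pdd", target P1..P5,
#' field_cm), \code{beam} (mode, energy_mev or spectrum_file with
#' energy/probability columns, half_angle_deg), \code{run} (n_histories,
#' n_batches, seed, workers, cutoff_mev, analog, target_rel_error).
#' Omitted run parameters take the \code{run_config} defaults; the
#' geometry defaults are the standard room/phantom/head parameters.
#'
#' @param path Config file path.
#' @return list(scenario, config, raw).
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  sc <- cfg$scenario
  if (is.null(sc$type)) stop("config error: scenario.type missing")
  src <- NULL
  if (!is.null(cfg$beam)) {
    spec <- NULL
    if (!is.null(cfg$beam$spectrum_file)) {
      st <- utils::read.csv(cfg$beam$spectrum_file)
      spec <- spectrum_table(energies = st[[1]], probs = st[[2]])
    } else if (!is.null(cfg$beam$energy_mev)) {
      spec <- spectrum_line(cfg$beam$energy_mev)
    }
    if (identical(cfg$beam$mode, "monoenergetic-point")) {
      if (is.null(spec)) stop("config error: point mode needs energy_mev")
      src <- beam_source("monoenergetic-point",
                         position = if (!is.null(cfg$beam$position))
                           as.numeric(cfg$beam$position) else c(0, 0, 100),
                         spectrum = spec)
    } else if (!is.null(spec) || !is.null(cfg$beam$half_angle_deg)) {
      field <- if (!is.null(sc$field_cm)) sc$field_cm else 10
      half <- if (!is.null(cfg$beam$half_angle_deg)) cfg$beam$half_angle_deg
              else atan((field / 2) / SOURCE_TO_ISOCENTER_CM) * 180 / pi
      src <- beam_source("spectrum-beam", position = c(0, 0, 100),
                         axis = c(0, 0, -1), half_angle_deg = half,
                         spectrum = if (is.null(spec))
                           default_6mv_spectrum() else spec)
    }
  }
  scenario <- switch(sc$type,
    treatment = build_treatment_scenario(
      target = if (is.null(sc$target)) "P4" else sc$target,
      field_cm = if (is.null(sc$field_cm)) 10 else sc$field_cm,
      source = src),
    pdd = build_water_phantom_benchmark(
      depth_cm = if (is.null(sc$depth_cm)) 30 else sc$depth_cm,
      bin_cm = if (is.null(sc$bin_cm)) 0.5 else sc$bin_cm,
      field_cm = if (is.null(sc$field_cm)) 10 else sc$field_cm,
      source = src),
    stop("config error: unknown scenario.type '", sc$type, "'"))
  rn <- cfg$run
  if (is.null(rn$n_histories) || rn$n_histories <= 0)
    stop("config error: run.n_histories must be a positive integer")
  config <- run_config(
    n_histories = rn$n_histories,
    n_batches = if (is.null(rn$n_batches)) 20L else rn$n_batches,
    seed = if (is.null(rn$seed)) 1L else rn$seed,
    cutoff_mev = if (is.null(rn$cutoff_mev)) 0.01 else rn$cutoff_mev,
    analog = isTRUE(rn$analog),
    workers = if (is.null(rn$workers)) 1L else rn$workers,
    target_rel_error = rn$target_rel_error)
  list(scenario = scenario, config = config, raw = cfg)
}

#' Write the per-organ dose table
#' @param tally A \code{tally_result}. @param path Output CSV.
#' @export
write_dose_csv <- function(tally, path) {
  d <- tally$doses
  out <- data.frame(cell = d$cell, organ = d$organ,
                    dose_mev_g_per_photon = d$dose_mev_g,
                    dose_agy_per_photon = d$dose_agy,
                    rel_error = d$rel_error)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a conversion table
#' @param table A \code{conversion_table}. @param path CSV path.
#' @param seed Provenance seed recorded in the file.
#' @export
write_conversion_csv <- function(table, path, seed = NA) {
  out <- as.data.frame(table)
  out$target <- attr(table, "target")
  out$seed <- seed
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_conversion_csv
#' @export
read_conversion_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- conversion_table(d$position[1],
                          stats::setNames(d$F, d$organ),
                          target = d$target[1],
                          rel_error = stats::setNames(d$rel_error, d$organ))
  attr(tab, "seed") <- d$seed[1]
  tab
}

#' Plain-text dose summary (targeted-tissue table layout)
#'
#' @param doses Named list position -> \code{dose_result}; each entry's
#'   target organ dose is printed (aGy/photon, 3 s.f.).
#' @param targets Named character vector position -> target organ.
#' @return Character vector of report lines.
#' @export
dose_table_text <- function(doses, targets) {
  pos <- names(doses)
  lines <- c("Absorbed doses in targeted tissues per irradiation position",
             paste0("position\ttarget\tdose_aGy_per_photon"))
  for (p in pos) {
    tgt <- targets[[p]]
    lines <- c(lines, sprintf("%s\t%s\t%s", p, tgt,
                              signif(doses[[p]]$doses[[tgt]], 3)))
  }
  lines
}

#' Write a run manifest
#'
#' JSON snapshot written before the run and finalized after: config,
#' package version, seed, timestamps, scenario checksum (stable for
#' identical configs), and the output file list.
#'
#' @param path Manifest path.
#' @param config A \code{run_config}.
#' @param scenario A \code{scenario}.
#' @param outputs Character vector of output files (finalization).
#' @param manifest An existing manifest to finalize.
#' @return The manifest list, invisibly (written to \code{path}).
#' @export
write_manifest <- function(path, config, scenario, outputs = NULL,
                           manifest = NULL) {
  if (is.null(manifest)) {
    tmp <- tempfile()
    writeLines(c(scenario$label,
                 vapply(scenario$model$surfaces, function(s)
                   paste(signif(s$coefficients, 12), collapse = ","), "")),
               tmp)
    manifest <- list(
      label = scenario$label,
      code_version = as.character(utils::packageVersion("photondose")),
      seed = config$seed,
      n_histories = config$n_histories,
      scenario_checksum = unname(tools::md5sum(tmp)),
      started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      finished = NULL, outputs = NULL)
    unlink(tmp)
  }
  if (!is.null(outputs)) {
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    manifest$outputs <- outputs
  }
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' ASCII cross-section through a geometry model
#'
#' Renders a character map of cell indices on a plane slice (mirrors a
#' 2-D geometry plot); useful for eyeballing the assembled room.
#'
#' @param model A \code{geometry_model}.
#' @param plane "x", "y" or "z" (the fixed axis).
#' @param at Plane coordinate (cm).
#' @param extent list(lo, hi) length-2 in the remaining axes (defaults to
#'   the bounding box).
#' @param n Characters per row.
#' @return Character vector of map lines plus a legend.
#' @export
dump_geometry <- function(model, plane = "y", at = 0, extent = NULL,
                          n = 72) {
  ia <- match(plane, c("x", "y", "z"))
  oth <- setdiff(1:3, ia)
  if (is.null(extent))
    extent <- list(lo = model$bounding_box$lo[oth],
                   hi = model$bounding_box$hi[oth])
  a <- seq(extent$lo[1], extent$hi[1], length.out = n)
  b <- seq(extent$lo[2], extent$hi[2], length.out = max(12, n %/% 3))
  glyphs <- c(".", letters, LETTERS, 0:9, "#", "@", "%", "&", "*", "+")
  pts <- matrix(0, n, 3)
  lines <- character(length(b))
  for (j in seq_along(b)) {
    pts[, ia] <- at
    pts[, oth[1]] <- a
    pts[, oth[2]] <- b[length(b) - j + 1]
    idx <- match(locate_point(pts, model), names(model$cells))
    lines[j] <- paste(glyphs[pmin(idx, length(glyphs))], collapse = "")
  }
  legend <- sprintf("%s = %s", glyphs[pmin(seq_along(model$cells),
                                           length(glyphs))],
                    names(model$cells))
  c(lines, "", legend)
}
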