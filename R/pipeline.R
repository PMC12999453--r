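#' Configuration for an end-to-end analysis run
#'
#' @param input The volume source: a [phantom_spec()], a
#'   [disc_phantom_spec()], or a list
#'   `list(path =, spacing_um =, axis_map =, legend =)` pointing at a
#'   TIFF stack.
#' @param label For labeled inputs: the label value to analyze (its
#'   voxels become the binary mask).  Ignored for phantoms, whose own
#'   mask is analyzed.
#' @param window A [window_spec()].
#' @param n_directions Direction count for MIL sampling.
#' @param line_spacing_vox Test-line spacing in voxels.
#' @param n_bins Bins per plane histogram.
#' @param regions Optional length-2 vector naming the regions to
#'   contrast (resolved against the phantom/label legend), e.g.
#'   `c("rim", "center")`.
#' @param morphometry Include the morphometry stage (thickness is the
#'   costly part).
#' @param out_dir Output directory (created if missing).
#' @param seed Seed applied to every stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(input, label = NULL, window = window_spec(),
                       n_directions = 128L, line_spacing_vox = 2,
                       n_bins = 18L, regions = NULL, morphometry = TRUE,
                       out_dir, seed = 0L) {
  if (missing(out_dir)) stop("out_dir is required", call. = FALSE)
  if (!(inherits(input, "phantom_spec") ||
        inherits(input, "disc_phantom_spec") ||
        (is.list(input) && !is.null(input$path))))
    stop("input must be a phantom spec or list(path=, spacing_um=, ...)",
         call. = FALSE)
  structure(list(input = input, label = label, window = window,
                 n_directions = as.integer(n_directions),
                 line_spacing_vox = line_spacing_vox,
                 n_bins = as.integer(n_bins), regions = regions,
                 morphometry = isTRUE(morphometry),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

.config_echo <- function(config) {
  ech <- unclass(config)
  ech$window <- unclass(ech$window)
  ech$input <- c(list(class = class(config$input)[1]),
                 lapply(unclass(config$input), function(v)
                   if (is.matrix(v)) NULL else v))
  ech
}

.write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, null = "null")
}

#' Run the full analysis pipeline
#'
#' Executes ingest (phantom generation or stack reading), orientation
#' field mapping, directional statistics (axis summary; sagittal,
#' frontal and transverse rose histograms carrying both the frequency
#' and sum-magnitude weightings; anisotropy summaries overall and per
#' dominant axis; optional region contrast), and morphometry, writing
#' every artifact plus a manifest into `out_dir`.  The run is wholly
#' deterministic given the seed: repeating it yields byte-identical
#' outputs.
#'
#' Outputs: `field.csv`, `axis_summary.json`,
#' `anisotropy_summary.json`, `rose_<plane>.csv` (x3),
#' `histograms.json`, optionally `region_contrast.json` and
#' `morphometry.json`, and `manifest.json` (config echo, package
#' version, per-stage counts, md5 checksum of every output).
#'
#' A failing stage aborts with the stage name after writing a partial
#' manifest of the outputs completed so far.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  counts <- list()
  manifest_path <- file.path(config$out_dir, "manifest.json")

  fail <- function(stage, e) {
    partial <- list(status = "failed", failed_stage = stage,
                    error = conditionMessage(e),
                    config = .config_echo(config),
                    version = as.character(utils::packageVersion("fibrefab")),
                    counts = counts,
                    outputs = as.list(tools::md5sum(outputs)))
    .write_json_out(partial, manifest_path)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) fail(stage, e))
  }
  emit <- function(name, writer) {
    p <- file.path(config$out_dir, name)
    writer(p)
    outputs <<- c(outputs, p)
    p
  }

  # -- ingest ---------------------------------------------------------
  vol <- run_stage("ingest", {
    inp <- config$input
    if (inherits(inp, "phantom_spec")) {
      inp$seed <- config$seed
      generate_phantom(do.call(phantom_spec, unclass(inp)))
    } else if (inherits(inp, "disc_phantom_spec")) {
      inp$seed <- config$seed
      make_disc_phantom(do.call(disc_phantom_spec, unclass(inp)))
    } else {
      v <- read_volume_stack(inp$path, spacing_um = inp$spacing_um,
                             axis_map = inp$axis_map, legend = inp$legend)
      if (inherits(v, "label_map")) {
        if (is.null(config$label))
          stop("labeled input needs config$label")
        if (!any(v$labels == config$label))
          stop("tissue label ", config$label, " is absent from the input")
        structure(list(mask = v$labels == config$label, labels = v$labels,
                       legend = v$legend, spacing_um = v$spacing_um,
                       axis_map = v$axis_map,
                       truth = list(kind = "real", seed = config$seed)),
                  class = "phantom_volume")
      } else {
        structure(list(mask = v$data != 0, labels = NULL,
                       spacing_um = v$spacing_um, axis_map = v$axis_map,
                       truth = list(kind = "real", seed = config$seed)),
                  class = "phantom_volume")
      }
    }
  })

  # -- orientation field ----------------------------------------------
  dirs <- sample_directions(config$n_directions)
  field <- run_stage("orientation_field", {
    map_orientation_field(vol, window = config$window, directions = dirs,
                          line_spacing_vox = config$line_spacing_vox)
  })
  counts$windows <- attr(field, "counts")
  counts$vectors <- nrow(field)
  emit("field.csv", function(p) export_field_csv(field, p))

  # -- directional statistics -----------------------------------------
  run_stage("directional_stats", {
    if (nrow(field) == 0)
      stop("orientation field is empty; no statistics to compute")
    axs <- dominant_axis_fractions(field)
    emit("axis_summary.json", function(p)
      .write_json_out(list(counts = as.list(axs$counts),
                           fractions = as.list(axs$fractions),
                           total = axs$total), p))
    hists <- lapply(.planes, function(pl)
      rose_histogram(field, pl, config$n_bins))
    names(hists) <- .planes
    for (pl in .planes)
      emit(paste0("rose_", pl, ".csv"), function(p)
        write_histogram_csv(hists[[pl]], p))
    emit("histograms.json", function(p)
      .write_json_out(lapply(hists, function(h)
        list(plane = h$plane, excluded = h$excluded, total = h$total,
             counts = h$counts, sum_magnitude_um = h$sum_magnitude_um)), p))
    overall <- summarize_anisotropy(field)
    per_axis <- summarize_anisotropy(field, by = "axis")
    emit("anisotropy_summary.json", function(p)
      .write_json_out(list(overall = unclass(overall),
                           per_axis = lapply(per_axis, unclass)), p))
    if (!is.null(config$regions)) {
      if (is.null(vol$labels))
        stop("region contrast requested but the input has no labels")
      regs <- window_region_labels(field, vol$labels, vol$mask)
      legend <- vol$legend
      name_of <- function(r) {
        if (!is.null(legend) && r %in% legend)
          as.integer(names(legend)[match(r, legend)]) else r
      }
      rc <- region_contrast(field, regs, name_of(config$regions[1]),
                            name_of(config$regions[2]))
      emit("region_contrast.json", function(p)
        .write_json_out(list(
          region_a = config$regions[1], region_b = config$regions[2],
          summaries = lapply(rc$summaries, unclass),
          difference_of_means = rc$difference_of_means), p))
    }
  })

  # -- morphometry ----------------------------------------------------
  if (config$morphometry) {
    run_stage("morphometry", {
      mrep <- tissue_metrics(vol$mask, spacing_um = vol$spacing_um,
                             axis_map = vol$axis_map,
                             directions = dirs,
                             line_spacing_vox = config$line_spacing_vox)
      emit("morphometry.json", function(p)
        .write_json_out(list(
          volume_mm3 = mrep$volume_mm3, voxel_count = mrep$voxel_count,
          extent_mm = as.list(mrep$extent_mm),
          thickness_um = mrep$thickness_um,
          global_anisotropy = mrep$global_anisotropy,
          eigenvalues_um = mrep$global_fabric$eigenvalues_um), p))
    })
  }

  manifest <- list(status = "ok", config = .config_echo(config),
                   version = as.character(utils::packageVersion("fibrefab")),
                   counts = counts,
                   outputs = as.list(tools::md5sum(outputs)))
  .write_json_out(manifest, manifest_path)
  invisible(manifest)
}
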