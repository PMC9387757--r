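#' Default pipeline configuration
#'
#' Per-stage parameter blocks mirroring each module's defaults. Unknown keys
#' in a supplied configuration are rejected; the fully materialized
#' configuration is recorded in the output manifest for reproducibility.
#'
#' @return Nested list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1L,
    paths = list(ct = NULL, mr = NULL, template = NULL, seg = NULL,
                 lut = NULL, electrodes = NULL, surface = NULL,
                 initial = NULL, out_dir = NULL),
    register = list(bins = 32L, pyramid_factors = c(4L, 2L, 1L),
                    stages = c("translation", "rigid", "affine"),
                    max_eval = 300L),
    snap = list(radius = 5, intensity_floor = 0.25, max_region_radius = 5),
    project = list(channels = NULL),
    label = list(radius = 2),
    warp = list(level_iters = c(30L, 30L, 25L), field_sigma = 2,
                pyramid_factors = c(4L, 2L, 1L))
  )
}

# Merge user config over defaults, rejecting unknown keys at any depth.
merge_config <- function(user, defaults, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    ielec_stop("validation", "unknown config key(s): %s",
               paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(user[[k]], defaults[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Run the full localization pipeline on disk inputs
#'
#' Stages, in order: CT-to-MR affine registration, snap-to-center contact
#' refinement on the CT, ECoG projection onto the leptomeningeal surface
#' (if a surface is supplied), anatomical labeling (if a segmentation is
#' supplied), and subject-to-template SDR warping (if a template is
#' supplied). Writes `registration.json`, `snapped.tsv`, `projected.tsv`,
#' `labels.tsv`, `template_space.tsv`, `manifest.json` and `pipeline.log`
#' into the output directory. Electrode seed coordinates are interpreted in
#' the MR subject frame.
#'
#' @param config Nested list (see [pipeline_defaults()]) or path to a JSON
#'   file with the same structure.
#' @return Invisibly, a list with the output directory, the final montage
#'   and the per-stage timings.
#' @export
run_pipeline <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- merge_config(config, pipeline_defaults())
  pt <- cfg$paths
  for (key in c("ct", "mr", "electrodes", "out_dir"))
    if (is.null(pt[[key]]))
      ielec_stop("validation", "config paths.%s is required", key)
  for (key in c("ct", "mr", "electrodes", "template", "seg", "lut", "surface",
                "initial"))
    if (!is.null(pt[[key]]) && !file.exists(pt[[key]]))
      ielec_stop("io", "input file for paths.%s not found: %s", key, pt[[key]])
  dir.create(pt$out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(pt$out_dir, "pipeline.log")
  cat("", file = logfile)
  note <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
    message(msg)
  }
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      note("stage %s FAILED: %s", name, conditionMessage(e))
      ielec_stop("stage", "pipeline stage %s failed: %s", name,
                 conditionMessage(e))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    note("stage %s done in %.1f s", name, timings[[name]])
    out
  }

  set.seed(as.integer(cfg$seed))
  ct <- read_volume(pt$ct, "ct")
  mr <- read_volume(pt$mr, "mr_subject")
  seeds <- read_electrodes_tsv(pt$electrodes, frame = "mr_subject")

  reg <- stage("register", {
    init <- if (!is.null(pt$initial)) read_transform(pt$initial) else NULL
    compute_affine_registration(ct, mr, initial = init,
                                stages = cfg$register$stages,
                                pyramid_factors = cfg$register$pyramid_factors,
                                bins = cfg$register$bins,
                                max_eval = cfg$register$max_eval)
  })
  write_transform(reg$affine, file.path(pt$out_dir, "registration.json"))

  snapped <- stage("snap", {
    m <- seeds
    pos <- montage_positions(seeds)
    ct_seeds <- matrix(apply_affine(invert(reg$affine), pos), ncol = 3)
    for (i in seq_len(nrow(pos))) {
      s <- snap_to_center(ct, ct_seeds[i, ], radius = cfg$snap$radius,
                          intensity_floor = cfg$snap$intensity_floor,
                          max_region_radius = cfg$snap$max_region_radius)
      m <- mark_contact(m, rownames(pos)[i],
                        apply_affine(reg$affine, s$center))
    }
    m
  })
  write_electrodes_tsv(snapped, file.path(pt$out_dir, "snapped.tsv"))

  final <- snapped
  if (!is.null(pt$surface)) {
    final <- stage("project", {
      surf <- read_off(pt$surface, frame = "mr_subject")
      chans <- cfg$project$channels
      if (is.null(chans)) chans <- snapped$contacts$name
      project_sensors_onto_brain(snapped, surf, channels = chans)
    })
    write_electrodes_tsv(final, file.path(pt$out_dir, "projected.tsv"))
  }

  if (!is.null(pt$seg)) {
    labs <- stage("label", {
      seg <- read_volume(pt$seg, "mr_subject", kind = "label")
      lut <- if (!is.null(pt$lut)) read_lut(pt$lut) else phantom_lut()
      labels_at_positions(seg, lut, montage_positions(final),
                          radius = cfg$label$radius)
    })
    write_labels_tsv(final$contacts$name[final$contacts$status == "located"],
                     labs, file.path(pt$out_dir, "labels.tsv"))
  }

  if (!is.null(pt$template)) {
    stage("warp", {
      tmpl <- read_volume(pt$template, "mr_template")
      field <- compute_sdr_registration(
        mr, tmpl,
        pre_affine = affine_transform(diag(4), "mr_subject", "mr_template"),
        level_iters = cfg$warp$level_iters,
        field_sigma = cfg$warp$field_sigma,
        pyramid_factors = cfg$warp$pyramid_factors)
      pos <- montage_positions(final)
      warped <- matrix(apply_point_registration(pos, field, "forward"),
                       ncol = 3)
      mt <- montage(rownames(pos), warped, frame = "mr_template")
      write_electrodes_tsv(mt, file.path(pt$out_dir, "template_space.tsv"))
    })
  }

  outputs <- setdiff(list.files(pt$out_dir),
                     c("manifest.json", "pipeline.log"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("ielec")),
    config = cfg,
    timings_s = timings,
    outputs = lapply(setNames(outputs, outputs), function(f)
      list(md5 = unname(tools::md5sum(file.path(pt$out_dir, f))))))
  jsonlite::write_json(manifest, file.path(pt$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(out_dir = pt$out_dir, montage = final, timings = timings))
}
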