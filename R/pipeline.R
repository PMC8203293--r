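#' Default end-to-end study configuration
#'
#' Two-arm synthetic study (untreated control versus a collagen-crosslinking
#' inhibitor arm) with per-stage generator parameters chosen to match the
#' regimes reported for desmoplastic tumor models: control tumors stiffer
#' with more >40 kPa patches, wide (about 7.4 um mean) and straight collagen
#' fibers, slower T cells; treated tumors softer, with narrower (about
#' 6.7 um) and wavier fibers and faster T cells.
#'
#' @param seed Integer study seed; every stage derives substreams from it.
#' @param output_dir Optional directory for per-stage artifacts; `NULL` keeps
#'   everything in memory.
#' @param n_subjects Subjects per arm.
#' @return A named list understood by [run_pipeline()].
#' @export
default_study_config <- function(seed = 1, output_dir = NULL, n_subjects = 5) {
  list(
    seed = seed,
    output_dir = output_dir,
    stages = c("simulate", "quantify", "correlate"),
    threshold_kPa = 40,
    recording_min = 20,
    cut_depth_um = 15,
    min_fraction = 0.1,
    groups = list(
      control = list(
        n_subjects = n_subjects,
        stiffness = list(background_mean_kPa = 16, background_sd_kPa = 4,
                         n_patches = 6, patch_kPa = 60, patch_radius_px = 6),
        fibers = list(n_fibers = 4, width_um_range = c(5.4, 9.4),
                      length_um_range = c(50, 110), waviness_amplitude_um = 1,
                      image_size_px = 288),
        tracks = list(n_tracks = 30, speed_um_per_min = 2.5,
                      turning_sd_deg = 70),
        afm = list(E_Pa = 4000, n_curves = 16, noise_relative = 0.05)
      ),
      BAPN = list(
        n_subjects = n_subjects,
        stiffness = list(background_mean_kPa = 9, background_sd_kPa = 3,
                         n_patches = 1, patch_kPa = 60, patch_radius_px = 6),
        fibers = list(n_fibers = 4, width_um_range = c(4.7, 8.7),
                      length_um_range = c(50, 110), waviness_amplitude_um = 3,
                      image_size_px = 288),
        tracks = list(n_tracks = 30, speed_um_per_min = 3.6,
                      turning_sd_deg = 70),
        afm = list(E_Pa = 2200, n_curves = 16, noise_relative = 0.05)
      )
    )
  )
}

empty_study_table <- function() {
  tibble(subject_id = character(), group = character(),
         mean_stiffness_kPa = double(), stiff_fraction = double(),
         mean_fiber_width_um = double(), mean_curvature_ratio = double(),
         mean_E_Pa = double(), mean_speed_um_per_min = double(),
         mean_displacement_um = double(), mean_straightness = double())
}

validate_config <- function(config) {
  known <- c("seed", "output_dir", "stages", "threshold_kPa", "recording_min",
             "cut_depth_um", "min_fraction", "groups")
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    abort(paste("Unknown config keys (typo?):", toString(extra)))
  }
  if (is.null(config$seed)) abort("Config must set `seed`.")
  bad <- setdiff(config$stages, c("simulate", "quantify", "correlate"))
  if (length(bad)) abort(paste("Unknown stage(s):", toString(bad)))
  if (!length(config$groups)) abort("Config needs at least one group.")
  invisible(config)
}

#' Run the end-to-end synthetic study pipeline
#'
#' Executes the requested stages in order: `simulate` generates, per subject,
#' a stiffness map, an SHG fiber image, a batch of AFM force curves, and a
#' set of T-cell tracks with the group's parameters; `quantify` runs every
#' quantification module (ROI summary, fiber tracing, Hertzian fits, track
#' filtering plus motility statistics) and aggregates one row of scalars per
#' subject into the study table; `correlate` fits motility against stiffness
#' per group. A stage failure aborts with the failing stage named (and leaves
#' a `FAILED` marker in `output_dir`, retaining partial outputs).
#'
#' Reruns with the same config and seed are deterministic: the study table is
#' identical.
#'
#' @param config Configuration list, see [default_study_config()]. Unknown
#'   keys are rejected.
#' @return A `mechanoscape_run` list: `study_table` (tibble, one row per
#'   subject; empty if `quantify` not run), `fits` (per-group
#'   [stiffness_motility_fit()] results or `NULL`), `artifacts` (per-subject
#'   simulated objects), `manifest` (seed, stages, parameters, and file
#'   digests when `output_dir` is set).
#' @export
run_pipeline <- function(config = default_study_config()) {
  validate_config(config)
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  run_stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      if (!is.null(out_dir)) {
        writeLines(c(name, conditionMessage(e)), file.path(out_dir, "FAILED"))
      }
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  artifacts <- list()
  study <- empty_study_table()
  fits <- NULL

  if ("simulate" %in% config$stages) {
    artifacts <- run_stage("simulate", {
      subj_counter <- 0L
      res <- list()
      for (gname in names(config$groups)) {
        grp <- config$groups[[gname]]
        for (j in seq_len(grp$n_subjects)) {
          subj_counter <- subj_counter + 1L
          sid <- sprintf("%s-%02d", gname, j)
          sseed <- substream_seed(config$seed, subj_counter)
          sw <- do.call(gen_stiffness_map, c(grp$stiffness, list(seed = sseed)))
          fib <- do.call(gen_fiber_image, c(grp$fibers, list(seed = sseed)))
          trk <- do.call(gen_tracks,
                         c(grp$tracks,
                           list(duration_min = config$recording_min,
                                seed = sseed)))
          afm_par <- grp$afm
          curves <- lapply(seq_len(afm_par$n_curves), function(k) {
            gen_force_curve(afm_par$E_Pa,
                            noise_relative = afm_par$noise_relative,
                            seed = substream_seed(sseed, k))
          })
          res[[sid]] <- list(subject_id = sid, group = gname,
                             stiffness = sw, fibers = fib, tracks = trk,
                             afm_curves = curves)
        }
      }
      res
    })
    if (!is.null(out_dir)) {
      run_stage("simulate", {
        for (sid in names(artifacts)) {
          a <- artifacts[[sid]]
          write_stiffness_map(a$stiffness$map,
                              file.path(out_dir, paste0(sid, "_stiffness.tif")))
          utils::write.csv(a$tracks, file.path(out_dir, paste0(sid, "_tracks.csv")),
                           row.names = FALSE)
          truth <- list(stiff_fraction = a$stiffness$stiff_fraction_truth,
                        fiber_width_um = a$fibers$truth$width_um,
                        fiber_length_um = a$fibers$truth$length_um,
                        afm_E_Pa = attr(a$afm_curves[[1]], "true_E_Pa"),
                        track_speed_um_per_min = attr(a$tracks, "speed_um_per_min"))
          jsonlite::write_json(truth,
                               file.path(out_dir, paste0(sid, "_ground_truth.json")),
                               auto_unbox = TRUE, digits = NA)
        }
      })
    }
  }

  if ("quantify" %in% config$stages) {
    study <- run_stage("quantify", {
      if (!length(artifacts)) abort("Nothing to quantify: run `simulate` first.")
      rows <- lapply(artifacts, function(a) {
        sw <- compute_roi_summary(a$stiffness$map, config$threshold_kPa)
        traced <- trace_fibers(a$fibers$image,
                               source_id = a$subject_id)
        arch <- if (nrow(traced) > 0L) architecture_summary(traced) else
          tibble(mean_width_um = NA_real_, mean_curvature_ratio = NA_real_)
        kept <- a$tracks |>
          depth_filter(config$cut_depth_um) |>
          duration_filter(config$recording_min * 60, config$min_fraction)
        mot <- motility_summary(kept)
        es <- vapply(a$afm_curves, fit_young_modulus, numeric(1))
        tibble(
          subject_id = a$subject_id,
          group = a$group,
          mean_stiffness_kPa = sw$mean_kPa,
          stiff_fraction = sw$stiff_fraction,
          mean_fiber_width_um = arch$mean_width_um,
          mean_curvature_ratio = arch$mean_curvature_ratio,
          mean_E_Pa = summarize_moduli(tibble(E_Pa = es))$summary$mean_Pa,
          mean_speed_um_per_min = mean(mot$speed_um_per_min),
          mean_displacement_um = mean(mot$displacement_um),
          mean_straightness = mean(mot$straightness)
        )
      })
      list_rbind(unname(rows))
    })
    if (!is.null(out_dir)) {
      utils::write.csv(study, file.path(out_dir, "study_table.csv"),
                       row.names = FALSE)
    }
  }

  if ("correlate" %in% config$stages && nrow(study) > 0L) {
    fits <- run_stage("correlate", {
      list(
        speed = stiffness_motility_fit(study, "mean_speed_um_per_min"),
        displacement = stiffness_motility_fit(study, "mean_displacement_um")
      )
    })
  }

  manifest <- list(seed = config$seed, stages = config$stages,
                   groups = lapply(config$groups, function(g) g["n_subjects"]),
                   n_subjects = nrow(study))
  if (!is.null(out_dir)) {
    files <- list.files(out_dir, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    manifest$digests <- as.list(tools::md5sum(files))
    names(manifest$digests) <- basename(files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(study_table = study, fits = fits, artifacts = artifacts,
                 manifest = manifest),
            class = "mechanoscape_run")
}

#' @export
print.mechanoscape_run <- function(x, ...) {
  cat(sprintf("<mechanoscape_run> seed %s; %d subject(s)\n",
              format(x$manifest$seed), nrow(x$study_table)))
  if (nrow(x$study_table)) print(x$study_table)
  invisible(x)
}
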