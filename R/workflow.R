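# End-to-end orchestration: simulate/load -> register -> preprocess ->
# detect/link/correct -> select -> estimate (-> qc across runs). Stage
# outputs are written to a run directory as CSV/JSON/TIFF; a rerun with
# `resume = TRUE` reloads cached stage outputs instead of recomputing, and
# never changes the result relative to a cold run because all randomness
# flows from the config seeds.

#' Default workflow configuration
#'
#' Builds the nested run configuration. A serialized config (plus its
#' seeds) fully determines a run's outputs. Configs round-trip through
#' YAML via [read_run_config()] / [write_run_config()].
#'
#' @param seed master seed; per-stage seeds derive from it.
#' @param out_dir run directory for stage outputs.
#' @param mode `"intra"` or `"inter"` assembly measurement; selects the
#'   recommended linking separation (2 px intra, 3 px inter).
#' @param ... named overrides of nested sections, e.g.
#'   `estimation = list(n_boot = 50)`.
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("f2f_run_"),
                       mode = c("intra", "inter"), ...) {
  mode <- match.arg(mode)
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    optical = list(pixel_size_nm = 64.5, diffraction_limit_px = 5.5,
                   image_shape = c(256L, 256L)),
    simulate = list(
      beads = list(n_fov = 20, beads_per_fov = c(25, 75),
                   scale = 1.002, translation_px = c(1.0, 0.6),
                   loc_noise_nm = 0.2),
      cells = list(n_fov = 9, n_cells = 9, pairs_per_cell = 2,
                   true_sep_nm = 20, loc_noise_nm = 7)),
    registration = list(match_tol_px = 3, tre_gate_nm = 1,
                        enforce_tre_gate = FALSE),
    preprocess = list(rolling_ball_radius_px = 70, median_diameter_px = 11),
    detection = list(diameter_px = 11, percentile = 99.5, min_mass = 1000,
                     max_sep_px = if (mode == "intra") 2 else 3),
    selection = list(max_closest_neighbour_px = 10, max_contour_dist_px = 13,
                     density_cutoff = 0.5, r2_threshold = 0.35,
                     segmentation = "threshold"),
    estimation = list(n_boot = 100, trim_grid = seq(0, 0.30, by = 0.025)))
  overrides <- list(...)
  for (nm in names(overrides)) {
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], overrides[[nm]])
  }
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- run_config()
  for (nm in intersect(names(cfg), names(base))) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]])) {
      base[[nm]] <- utils::modifyList(base[[nm]], cfg[[nm]])
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  base
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

wf_log <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
}

# Deterministic CSV writing for byte-identical reruns.
write_stage_csv <- function(x, path) {
  utils::write.csv(format(x, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full distance-measurement workflow
#'
#' Executes the stages in the fixed order simulate -> register ->
#' preprocess -> detect/link/correct -> select -> estimate, writing each
#' stage's tables to the run directory. Any stage error aborts with the
#' stage name. When `config$registration$enforce_tre_gate` is set, a
#' validation TRE at or above `tre_gate_nm` halts the run at registration;
#' otherwise a warning is raised.
#'
#' @param config a [run_config()].
#' @param resume reuse cached stage outputs present in the run directory.
#' @param verbose log stage progress to stderr.
#' @return a list of class `f2f_run`: `fit` (the [estimate_distance()]
#'   result), `registration`, `pairs` (annotated pair table), `config`,
#'   `out_dir`.
#' @export
run_workflow <- function(config = run_config(), resume = TRUE,
                         verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  opt <- config$optical
  cfg <- optical_config(pixel_size_nm = opt$pixel_size_nm,
                        diffraction_limit_px = opt$diffraction_limit_px,
                        image_shape = opt$image_shape)

  ## -- registration ------------------------------------------------------
  map_path <- file.path(out, "registration_map.json")
  rep_path <- file.path(out, "registration_report.csv")
  sim_b <- config$simulate$beads
  distortion <- affine_map(diag(2) * sim_b$scale, sim_b$translation_px)
  if (resume && file.exists(map_path) && file.exists(rep_path)) {
    wf_log(verbose, "registration: cached map reused")
    map <- read_affine(map_path)
    report <- as.list(utils::read.csv(rep_path))
  } else {
    wf_log(verbose, "registration: simulating %d bead FOVs", sim_b$n_fov)
    beads <- make_bead_dataset(cfg, n_fov = sim_b$n_fov,
                               beads_per_fov = sim_b$beads_per_fov,
                               distortion = distortion,
                               loc_noise_nm = sim_b$loc_noise_nm,
                               seed = child_seed(config$seed, 1))
    reg <- tryCatch(
      register_beads(beads, cfg,
                     match_tol_px = config$registration$match_tol_px),
      error = function(e) stop("stage 'register' failed: ",
                               conditionMessage(e), call. = FALSE))
    map <- reg$map
    report <- reg$report
    write_affine(map, map_path)
    write_stage_csv(data.frame(tre_nm = report$tre_nm,
                               pre_tre_nm = report$pre_tre_nm,
                               mean_dev_y_nm = report$mean_dev_y_nm,
                               mean_dev_x_nm = report$mean_dev_x_nm,
                               n_validation_beads =
                                 report$n_validation_beads),
                    rep_path)
    wf_log(verbose, "registration: TRE %.3f nm on %d beads",
           report$tre_nm, report$n_validation_beads)
  }
  if (report$tre_nm >= config$registration$tre_gate_nm) {
    msg <- sprintf("registration TRE %.3f nm >= gate %.3f nm",
                   as.numeric(report$tre_nm),
                   config$registration$tre_gate_nm)
    if (isTRUE(config$registration$enforce_tre_gate)) {
      stop("stage 'register' halted: ", msg, call. = FALSE)
    }
    warning(msg, call. = FALSE)
  }

  ## -- cells: simulate, preprocess, detect, link, correct ----------------
  pairs_path <- file.path(out, "pairs.csv")
  spots1_path <- file.path(out, "spots_ch1.csv")
  spots2_path <- file.path(out, "spots_ch2.csv")
  sel_path <- file.path(out, "pairs_selected.csv")
  det <- config$detection
  sel_cfg <- config$selection
  pre <- preprocess_config(cfg,
                           config$preprocess$rolling_ball_radius_px,
                           config$preprocess$median_diameter_px)
  sim_c <- config$simulate$cells

  if (resume && file.exists(sel_path)) {
    wf_log(verbose, "detect/select: cached pair table reused")
    pairs <- utils::read.csv(sel_path)
  } else {
    all_pairs <- vector("list", sim_c$n_fov)
    all_s1 <- vector("list", sim_c$n_fov)
    all_s2 <- vector("list", sim_c$n_fov)
    for (f in seq_len(sim_c$n_fov)) {
      fov <- make_pict_fov(cfg, n_cells = sim_c$n_cells,
                           pairs_per_cell = sim_c$pairs_per_cell,
                           true_sep_nm = sim_c$true_sep_nm,
                           loc_noise_nm = sim_c$loc_noise_nm,
                           distortion = distortion,
                           seed = child_seed(config$seed, 100 + f))
      p1 <- preprocess_image(fov$ch1, pre)
      p2 <- preprocess_image(fov$ch2, pre)
      s1 <- detect_spots(p1, det$diameter_px, det$min_mass, det$percentile)
      s2 <- detect_spots(p2, det$diameter_px, det$min_mass, det$percentile)
      pr <- link_pairs(s1, s2, det$max_sep_px)
      pr <- correct_chromatic(pr, map, cfg$pixel_size_nm)
      pr <- isolation_filter(pr, s1, s2, sel_cfg$max_closest_neighbour_px)
      # segment the cytoplasmic (prey) channel: diffuse GFP outlines the
      # cell; the anchor channel's membrane rim would bias the contour
      mask <- if (identical(sel_cfg$segmentation, "truth")) fov$mask else
        segment_cells(fov$ch2, "threshold")
      pr <- contour_filter(pr, mask, sel_cfg$max_contour_dist_px)
      pr <- gaussian_fit_filter(pr, p1, p2, sel_cfg$r2_threshold,
                                det$diameter_px)
      if (nrow(pr)) pr <- cbind(fov = f, pr)
      all_pairs[[f]] <- if (nrow(pr)) pr else NULL
      all_s1[[f]] <- if (nrow(s1)) cbind(fov = f, s1) else NULL
      all_s2[[f]] <- if (nrow(s2)) cbind(fov = f, s2) else NULL
    }
    pairs <- do.call(rbind, all_pairs)
    if (is.null(pairs) || nrow(pairs) == 0L) {
      stop("stage 'detect' failed: no spot pairs found", call. = FALSE)
    }
    wf_log(verbose, "detect: %d linked pairs across %d FOVs", nrow(pairs),
           sim_c$n_fov)
    # density filter runs on the pooled population (it needs the full
    # feature cloud); it is stage 3 of the cascade, before the Gaussian
    # R2 flag is consulted, so reorder the flag columns accordingly
    pg <- pairs$pass_gauss
    pairs$pass_gauss <- NULL
    pairs <- density_filter(pairs, sel_cfg$density_cutoff)
    pairs$pass_gauss <- ifelse(pairs_active(pairs), pg, NA)
    write_stage_csv(do.call(rbind, all_s1), spots1_path)
    write_stage_csv(do.call(rbind, all_s2), spots2_path)
    write_stage_csv(pairs, pairs_path)
    write_stage_csv(selected_pairs(pairs), sel_path)
  }

  ## -- estimate ----------------------------------------------------------
  est <- config$estimation
  fit <- tryCatch(
    estimate_distance(pairs, trim_grid = est$trim_grid,
                      n_boot = est$n_boot,
                      seed = child_seed(config$seed, 2)),
    error = function(e) stop("stage 'estimate' failed: ",
                             conditionMessage(e), call. = FALSE))
  jsonlite::write_json(
    list(mu_nm = fit$mu, sigma_nm = fit$sigma, mu_se = fit$mu_se,
         sigma_se = fit$sigma_se, n_total = fit$n_total,
         n_used = fit$n_used, loglik = fit$loglik,
         trim_fraction = fit$trim, flags = as.list(fit$flags)),
    file.path(out, "fit.json"), digits = NA, auto_unbox = TRUE)
  write_stage_csv(data.frame(distance_nm = fit$kept),
                  file.path(out, "distances_kept.csv"))
  wf_log(verbose, "estimate: mu %.2f nm (sigma %.2f), %d/%d pairs",
         fit$mu, fit$sigma, fit$n_used, fit$n_total)
  structure(list(fit = fit, map = map, report = report, pairs = pairs,
                 config = config, out_dir = out),
            class = "f2f_run")
}

#' @export
print.f2f_run <- function(x, ...) {
  cat("PICT distance-measurement run:", x$out_dir, "\n")
  print(x$fit)
  invisible(x)
}
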