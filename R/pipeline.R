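#' Pipeline configuration
#'
#' Bundles every stage's options plus a single global seed that fans out
#' deterministically to the stage seeds, and a dataset kind that fixes the
#' baseline source: liquid-culture-style data are baselined on the
#' no-inducer control condition at each timepoint, leaf-style data on the
#' time-zero population of the same condition.
#'
#' @param dataset_kind `"synthetic"`, `"in_vitro"` or `"in_planta"`.
#' @param design for synthetic data: tibble with one row per
#'   condition x timepoint x replicate, columns `condition`, `timepoint`,
#'   `replicate`, `p_high`, `n_images`.
#' @param images for image-file input: tibble with `image_id`,
#'   `phase_path`, `fluor_path`, `condition`, `timepoint`, `replicate`.
#' @param pixel_size micrometres per pixel; required when `images` is used.
#' @param sim a [simulation_config()] template (p_high is overridden per
#'   design row).
#' @param seg a [segmentation_config()].
#' @param clf a [classifier_spec()].
#' @param n_training_particles size of the labelled synthetic feature table
#'   the classifier is trained on.
#' @param baseline_control condition label of the no-inducer control
#'   (in-vitro-style baselining).
#' @param q top-quantile fraction for the subpopulation analysis (0.01 for
#'   in-vitro-style data, 0.10 for in-planta-style).
#' @param min_cells replicate-exclusion minimum (default 20).
#' @param seed global integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(dataset_kind = c("synthetic", "in_vitro", "in_planta"),
                            design = NULL, images = NULL, pixel_size = NULL,
                            sim = simulation_config(),
                            seg = segmentation_config(),
                            clf = classifier_spec(),
                            n_training_particles = 600L,
                            baseline_control = "control",
                            q = 0.01, min_cells = 20L, seed = 1L) {
  dataset_kind <- match.arg(dataset_kind)
  if (dataset_kind == "synthetic") {
    if (is.null(design)) stopf("synthetic pipelines need a `design` table")
    need <- c("condition", "timepoint", "replicate", "p_high", "n_images")
    miss <- setdiff(need, names(design))
    if (length(miss)) stopf("design lacks column(s): %s", paste(miss, collapse = ", "))
  } else {
    if (is.null(images)) stopf("image pipelines need an `images` table")
    if (is.null(pixel_size))
      stopf("`pixel_size` is required for TIFF input: the particle area filter is physical")
    assert_number(pixel_size, "pixel_size", lo = 1e-9)
  }
  structure(list(dataset_kind = dataset_kind, design = design, images = images,
                 pixel_size = pixel_size, sim = sim, seg = seg, clf = clf,
                 n_training_particles = as.integer(n_training_particles),
                 baseline_control = baseline_control, q = q,
                 min_cells = as.integer(min_cells), seed = as.integer(seed)),
            class = "pipeline_config")
}

# Relative fluorescence with the baseline source implied by dataset kind:
# control condition per timepoint (in vitro) or time zero per condition
# (in planta / synthetic treated as in vitro when a control condition is
# present in the data, time-zero otherwise).
compute_relative <- function(pop, config) {
  has_control <- config$baseline_control %in% pop$condition
  out <- list(); baselines <- list()
  if (has_control) {
    for (tp in sort(unique(pop$timepoint))) {
      ctrl <- pop[pop$condition == config$baseline_control & pop$timepoint == tp, ]
      if (nrow(ctrl) == 0L)
        stopf("no control population for timepoint %s", tp)
      bl <- fit_baseline(ctrl$value,
                         source = sprintf("%s at timepoint %s",
                                          config$baseline_control, tp))
      chunk <- pop[pop$timepoint == tp, ]
      out[[length(out) + 1L]] <- relative_fluorescence(chunk, bl)
      baselines[[as.character(tp)]] <- bl
    }
  } else {
    t0 <- min(pop$timepoint)
    for (cond in unique(pop$condition)) {
      ctrl <- pop[pop$condition == cond & pop$timepoint == t0, ]
      if (nrow(ctrl) == 0L) stopf("no time-zero population for condition %s", cond)
      bl <- fit_baseline(ctrl$value, source = sprintf("%s at time zero", cond))
      chunk <- pop[pop$condition == cond, ]
      out[[length(out) + 1L]] <- relative_fluorescence(chunk, bl)
      baselines[[cond]] <- bl
    }
  }
  list(pop = dplyr::bind_rows(out), baselines = baselines)
}

#' Run the full quantification pipeline
#'
#' Executes simulate (for synthetic configs) -> segment -> classify
#' (train on the labelled synthetic feature table, then apply) ->
#' background estimation and correction -> population statistics, writing
#' every intermediate table plus a manifest into `out_dir`. A rerun with
#' the same config and seed reproduces the output tables exactly.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created; existing files are overwritten).
#' @return invisibly, a list with the main results: `particles`,
#'   `population`, `summary`, `subpopulation`, `classifier_report`,
#'   `baselines`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warn_log <- character(0)
  note <- function(w) warn_log <<- c(warn_log, w)

  # --- stage 1: obtain micrographs ------------------------------------
  mgs <- list(); gts <- list()
  if (config$dataset_kind == "synthetic") {
    base <- stage_seed(config$seed, "simulate")
    d <- config$design
    img_n <- 0L
    for (i in seq_len(nrow(d))) {
      for (j in seq_len(d$n_images[i])) {
        img_n <- img_n + 1L
        sim <- config$sim
        sim$p_high <- d$p_high[i]
        sim$seed <- as.integer((base + 97L * img_n) %% .Machine$integer.max)
        id <- sprintf("%s_t%s_%s_i%d", d$condition[i], d$timepoint[i],
                      d$replicate[i], j)
        res <- simulate_micrograph(sim, image_id = id,
                                   condition = d$condition[i],
                                   replicate = d$replicate[i])
        res$ground_truth$image_id <- id
        res$ground_truth$timepoint <- d$timepoint[i]
        mgs[[id]] <- res$micrograph
        gts[[id]] <- res$ground_truth
        write_micrograph(res$micrograph, file.path(out_dir, "images"))
      }
    }
    gt <- dplyr::bind_rows(gts)
    utils::write.csv(gt, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
    tp_of <- stats::setNames(rep(d$timepoint, d$n_images),
                             unlist(mapply(function(i) sprintf(
                               "%s_t%s_%s_i%d", d$condition[i], d$timepoint[i],
                               d$replicate[i], seq_len(d$n_images[i])),
                               seq_len(nrow(d)), SIMPLIFY = FALSE)))
  } else {
    im <- config$images
    for (i in seq_len(nrow(im))) {
      mgs[[im$image_id[i]]] <- read_micrograph(
        im$phase_path[i], im$fluor_path[i], config$pixel_size,
        image_id = im$image_id[i], condition = im$condition[i],
        replicate = im$replicate[i])
    }
    tp_of <- stats::setNames(im$timepoint, im$image_id)
  }

  # --- stage 2: segmentation ------------------------------------------
  particles <- dplyr::bind_rows(lapply(mgs, detect_particles, config = config$seg))
  if (nrow(particles) == 0L) stopf("segmentation produced no particles")
  particles$timepoint <- unname(tp_of[particles$image_id])
  write_particles(particles, file.path(out_dir, "particles.csv"))

  # --- stage 3: classification ----------------------------------------
  sim_train <- config$sim
  sim_train$seed <- as.integer(stage_seed(config$seed, "split"))
  train_tab <- simulate_feature_table(sim_train, config$n_training_particles)
  fitted <- train_and_tune(train_tab, config$clf)
  jsonlite::write_json(list(
    model_family = fitted$report$model_family,
    best_hyperparameters = fitted$report$best_hyperparameters,
    cv_roc_auc = fitted$report$cv_roc_auc,
    metrics = as.list(fitted$report$metrics),
    feature_importances = as.list(fitted$report$feature_importances)),
    file.path(out_dir, "classifier_report.json"), auto_unbox = TRUE, digits = NA)
  particles <- apply_model(fitted$model, particles)
  write_particles(particles, file.path(out_dir, "particles_classified.csv"))
  cells <- particles[particles$label == "cell", ]
  if (nrow(cells) == 0L) stopf("classification retained no cells")

  # --- stage 4: background --------------------------------------------
  bg_seed <- stage_seed(config$seed, "background")
  estimates <- lapply(seq_along(mgs), function(i) {
    mg <- mgs[[i]]
    bm <- background_mask(mg$phase, target = config$seg$bg_target,
                          dark_foreground = TRUE)
    withCallingHandlers(
      estimate_background(mg$fluor, bm, n_squares = config$seg$n_bg_squares,
                          square_size = config$seg$bg_square_size,
                          seed = as.integer((bg_seed + i) %% .Machine$integer.max),
                          image_id = mg$image_id),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
  })
  write_background_estimates(estimates, file.path(out_dir, "background.csv"))
  pop <- correct_fluorescence(cells, estimates)
  write_population(pop, file.path(out_dir, "population.csv"))

  # --- stage 5: population statistics ---------------------------------
  pop <- withCallingHandlers(
    exclude_small_replicates(pop, config$min_cells),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
  rel <- compute_relative(pop, config)
  summ <- summarize_population(rel$pop)
  utils::write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
  treat <- rel$pop[rel$pop$condition != config$baseline_control, ]
  subpop <- NULL
  if (nrow(treat) > 0) {
    subpop <- withCallingHandlers(
      top_quantile_foldchange(treat, config$q),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    utils::write.csv(subpop$replicate_foldchanges,
                     file.path(out_dir, "subpopulation.csv"), row.names = FALSE)
  }

  writeLines(warn_log, file.path(out_dir, "warnings.txt"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("popfluor")),
    r_version = as.character(getRversion()),
    seed = config$seed, dataset_kind = config$dataset_kind,
    q = config$q, min_cells = config$min_cells,
    k_sd = config$seg$k_sd,
    area_filter = c(config$seg$area_min, config$seg$area_max),
    morphology = config$seg$morphology_sequence,
    classifier = config$clf$model_family,
    baselines = lapply(rel$baselines, function(b)
      list(source = b$source, q75 = b$q75, iqr = b$iqr,
           threshold_I = b$threshold_I)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(particles = particles, population = pop, summary = summ,
                 subpopulation = subpop, classifier_report = fitted$report,
                 baselines = rel$baselines, out_dir = out_dir))
}

fixture_presets <- function() c("tiny", "invitro_like", "inplanta_like")

#' Generate a named fixture data set
#'
#' Writes synthetic TIFF micrographs, the ground-truth table, and a
#' sidecar of expected population statistics computed directly from the
#' ground truth. Presets: `"tiny"` (2 conditions x 2 replicates, small
#' fields, for quick checks), `"invitro_like"` (3 biological replicates x
#' 3 timepoints of an induced condition plus a no-inducer control at each
#' timepoint), `"inplanta_like"` (8 replicates x 3 timepoints, time-zero
#' baseline).
#'
#' @param preset one of `"tiny"`, `"invitro_like"`, `"inplanta_like"`.
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return invisibly, the design tibble used.
#' @export
make_fixtures <- function(preset, seed = 1L, out_dir) {
  if (!preset %in% fixture_presets())
    stopf("unknown preset '%s'; available: %s", preset,
          paste(fixture_presets(), collapse = ", "))
  design <- switch(preset,
    tiny = tidyr::expand_grid(condition = c("control", "treatment"),
                              timepoint = 1, replicate = c("r1", "r2")) |>
      dplyr::mutate(p_high = ifelse(.data$condition == "control", 0.01, 0.2),
                    n_images = 1L),
    invitro_like = tidyr::expand_grid(condition = c("control", "diesel"),
                                      timepoint = c(1, 6, 28),
                                      replicate = c("r1", "r2", "r3")) |>
      dplyr::mutate(p_high = ifelse(.data$condition == "control", 0.01, 0.15),
                    n_images = 2L),
    inplanta_like = tidyr::expand_grid(condition = "leaf",
                                       timepoint = c(0, 2, 7),
                                       replicate = paste0("r", 1:8)) |>
      dplyr::mutate(p_high = c(`0` = 0.02, `2` = 0.15, `7` = 0.25)[
        as.character(.data$timepoint)], n_images = 1L))
  sim <- if (preset == "tiny") {
    simulation_config(image_shape = c(256L, 256L), n_cells = 12L, n_debris = 4L)
  } else simulation_config()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- stage_seed(seed, "fixtures")
  gts <- list()
  for (i in seq_len(nrow(design))) {
    for (j in seq_len(design$n_images[i])) {
      s <- sim
      s$p_high <- design$p_high[i]
      s$seed <- as.integer((base + 31L * i + j) %% .Machine$integer.max)
      id <- sprintf("%s_t%s_%s_i%d", design$condition[i], design$timepoint[i],
                    design$replicate[i], j)
      res <- simulate_micrograph(s, image_id = id,
                                 condition = design$condition[i],
                                 replicate = design$replicate[i])
      res$ground_truth$image_id <- id
      res$ground_truth$timepoint <- design$timepoint[i]
      gts[[id]] <- res$ground_truth
      write_micrograph(res$micrograph, file.path(out_dir, "images"))
    }
  }
  gt <- dplyr::bind_rows(gts)
  utils::write.csv(gt, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  # expected statistics computed from ground truth (true cell fluorescence)
  cells <- gt[gt$is_cell, ]
  expected <- cells |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     mean_true_fluor = mean(.data$true_fluorescence),
                     frac_high = mean(.data$expression_class == "high"),
                     .groups = "drop")
  utils::write.csv(expected, file.path(out_dir, "expected_statistics.csv"),
                   row.names = FALSE)
  utils::write.csv(design, file.path(out_dir, "design.csv"), row.names = FALSE)
  invisible(design)
}
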