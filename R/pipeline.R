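#' Build a run configuration
#'
#' Every parameter defaults to the reference setting where one exists:
#' word widths m = 5 (contour waveform) and m = 8 (gray spiral), alpha grid
#' 0.1-0.9 in steps of 0.1, ten normal model sperms for dARD, five
#' representative training sperms per class for the SVM, C-SVC defaults
#' (cost 1, eps 0.001, gamma = 1/k), K-NN with k = 10 and normal cut 3,
#' ovality band (1.2, 1.8), automatic background-mode threshold.
#'
#' @param ... overrides of individual defaults (unknown keys are rejected).
#' @return a validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    simulate = list(n_normal = 80, n_abnormal = 80),
    input = NULL, labels_csv = NULL, roi = NULL,
    threshold = "auto", min_area = 60, tail_width = 4, margin = 2,
    waveform_method = "centroid",
    m_contour = 5, m_gray = 8,
    n_models = 10, n_train_per_class = 5,
    alpha_grid = seq(0.1, 0.9, by = 0.1),
    svm = list(cost = 1, gamma = NULL, eps = 0.001),
    knn_k = 10, knn_normal_cut = 3,
    ovality_band = c(1.2, 1.8),
    classifiers = c("dard", "gray", "joint", "svm", "knn", "ellipse"),
    scene = list(),
    seed = 1, out_dir = NULL
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' Fills defaults for missing keys, rejects unknown keys and out-of-range
#' values, and returns the effective configuration.
#'
#' @param cfg a (partial) configuration list.
#' @return the validated `run_config`.
#' @export
validate_config <- function(cfg) {
  defaults <- list(
    simulate = list(n_normal = 80, n_abnormal = 80),
    input = NULL, labels_csv = NULL, roi = NULL,
    threshold = "auto", min_area = 60, tail_width = 4, margin = 2,
    waveform_method = "centroid",
    m_contour = 5, m_gray = 8,
    n_models = 10, n_train_per_class = 5,
    alpha_grid = seq(0.1, 0.9, by = 0.1),
    svm = list(cost = 1, gamma = NULL, eps = 0.001),
    knn_k = 10, knn_normal_cut = 3,
    ovality_band = c(1.2, 1.8),
    classifiers = c("dard", "gray", "joint", "svm", "knn", "ellipse"),
    scene = list(),
    seed = 1, out_dir = NULL
  )
  bad <- setdiff(names(cfg), names(defaults))
  if (length(bad)) stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  full <- defaults
  full[names(cfg)] <- cfg
  with(full, {
    if (any(alpha_grid < 0 | alpha_grid > 1)) stopf("alpha_grid values must lie in [0, 1]")
    if (!waveform_method %in% c("centroid", "symmetry")) {
      stopf("waveform_method must be 'centroid' or 'symmetry'")
    }
    if (!is_count(m_contour) || !is_count(m_gray)) stopf("m values must be integers")
    if (length(ovality_band) != 2L || ovality_band[1] >= ovality_band[2]) {
      stopf("ovality_band must be an increasing pair")
    }
    if (!all(classifiers %in% c("dard", "gray", "joint", "svm", "knn", "ellipse"))) {
      stopf("unknown classifier requested")
    }
  })
  structure(full, class = "run_config")
}

#' Load a run configuration from a JSON file
#'
#' Missing keys take their defaults; unknown keys are rejected. An empty
#' file (or `{}`) yields the full default configuration.
#'
#' @param path JSON file path.
#' @return a validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' does not exist", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  cfg <- if (!nzchar(trimws(txt))) list() else
    tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
             error = function(e) stopf("malformed config '%s': %s", path,
                                       conditionMessage(e)))
  validate_config(cfg)
}

#' Segment every sperm in a micrograph into head crops
#'
#' Thresholds the image, extracts 8-connected components above the minimum
#' area, removes tails and returns one [crop_head()] crop per sperm, with
#' origins in source-image coordinates.
#'
#' @param image a `gray_image`.
#' @param roi optional ROI box list (see [threshold_segment()]).
#' @param threshold intensity cut, `"auto"` or `"otsu"`.
#' @param min_area minimum component area in pixels.
#' @param tail_width tail-removal disc radius (see [remove_tail()]).
#' @param margin crop margin in pixels.
#' @return list of `sperm_crop`s whose `mask` is the head-only mask.
#' @export
segment_micrograph <- function(image, roi = NULL, threshold = "auto",
                               min_area = 60, tail_width = 4, margin = 2) {
  image <- as_gray_image(image)
  fg <- threshold_segment(image, roi = roi, threshold = threshold)
  comps <- extract_components(fg, min_area = min_area)
  crops <- list()
  for (comp in comps) {
    head_sub <- tryCatch(remove_tail(comp$mask, width_threshold = tail_width),
                         error = function(e) NULL)
    if (is.null(head_sub)) next                 # speck thinner than a head
    b <- comp$bbox
    sub_img <- image[b[1]:b[3], b[2]:b[4], drop = FALSE]
    crop <- crop_head(sub_img, head_sub, margin = margin)
    crop$origin <- crop$origin + c(b[1], b[2]) - 1L
    crops[[length(crops) + 1L]] <- crop
  }
  crops
}

# Majority ground-truth sperm id under a crop's mask (0 if none).
match_crop_to_scene <- function(crop, label_image) {
  h <- nrow(crop$mask); w <- ncol(crop$mask)
  rows <- crop$origin[1]:(crop$origin[1] + h - 1L)
  cols <- crop$origin[2]:(crop$origin[2] + w - 1L)
  ids <- label_image[rows, cols][crop$mask]
  ids <- ids[ids > 0L]
  if (!length(ids)) return(0L)
  tab <- tabulate(ids)
  which.max(tab)
}

# Leave-one-out K-NN accuracy over a set of crops (common frame built once).
knn_loo_accuracy <- function(crops, labels, k = 10, normal_cut = NULL) {
  if (is.null(normal_cut)) normal_cut <- if (k == 10) 3 else floor(k / 2)
  imgs <- lapply(crops, `[[`, "image")
  h <- round(stats::median(vapply(imgs, nrow, 0L)))
  w <- round(stats::median(vapply(imgs, ncol, 0L)))
  frame <- vapply(imgs, function(im) as.numeric(resample_image(im, h, w)),
                  numeric(h * w))
  n <- length(crops)
  pred <- character(n)
  for (i in seq_len(n)) {
    d <- colSums(abs(frame - frame[, i]))[-i]
    nb <- order(d, seq_len(n - 1L))[seq_len(k)]
    votes <- sum(labels[-i][nb] == "normal")
    pred[i] <- if (votes > normal_cut) "normal" else "abnormal"
  }
  evaluate(pred, labels)
}

#' Run the full classification pipeline
#'
#' Executes segment -> contour -> waveform -> rank -> gray -> classify on
#' either a synthetic scene (`config$simulate`) or an input image, and
#' returns a report holding every requested classifier's accuracy together
#' with the effective configuration. With `config$out_dir` set, crops,
#' waveforms, profiles, features and the report are written to disk.
#'
#' @param config a `run_config` (see [run_config()]).
#' @return a `pipeline_report` list.
#' @export
run_pipeline <- function(config = run_config()) {
  config <- validate_config(config)
  t0 <- Sys.time()

  if (!is.null(config$input)) {
    image <- read_gray_image(config$input)
    truth <- NULL
    if (!is.null(config$labels_csv)) {
      lab_df <- utils::read.csv(config$labels_csv)
      truth <- normalize_labels(lab_df$label)
    }
    scene <- NULL
  } else {
    scene <- generate_scene(config$simulate$n_normal, config$simulate$n_abnormal,
                            seed = config$seed,
                            config = do.call(scene_config, config$scene))
    image <- scene$image
    truth <- NULL                                # matched per crop below
  }

  roi <- if (is.null(config$roi)) NULL else
    lapply(seq_len(nrow(config$roi)), function(i) config$roi[i, ])
  crops <- segment_micrograph(image, roi = roi, threshold = config$threshold,
                              min_area = config$min_area,
                              tail_width = config$tail_width,
                              margin = config$margin)
  if (!length(crops)) stopf("segmentation produced no sperms")

  labels <- if (!is.null(scene)) {
    ids <- vapply(crops, match_crop_to_scene, 0L,
                  label_image = scene$head_label_image)
    keep <- ids > 0L
    crops <- crops[keep]
    scene$labels[ids[keep]]
  } else if (!is.null(truth)) {
    if (length(truth) != length(crops)) {
      stopf("labels_csv has %d labels but %d sperms were segmented",
            length(truth), length(crops))
    }
    truth
  } else NULL

  n <- length(crops)
  waveforms <- vector("list", n)
  contour_profiles <- vector("list", n)
  gray_profiles <- vector("list", n)
  stats_list <- vector("list", n)
  for (i in seq_len(n)) {
    ctr <- trace_contour(crops[[i]]$mask)
    wv <- if (config$waveform_method == "centroid") distance_waveform(ctr)
          else symmetry_waveform(ctr)
    waveforms[[i]] <- wv
    contour_profiles[[i]] <- word_histogram(rank_binarize(wv), config$m_contour)
    gray_profiles[[i]] <- word_histogram(
      rank_binarize(spiral_gray_sequence(crops[[i]])), config$m_gray)
    stats_list[[i]] <- gray_stats(crops[[i]])
  }
  ps <- vapply(stats_list, `[[`, 0, "P")

  report <- list(n_sperms = n, config_echo = unclass(config), results = list())
  class(report) <- "pipeline_report"

  dards <- NULL
  if (!is.null(labels)) {
    normal_idx <- which(labels == "normal")
    if (length(normal_idx) < config$n_models) {
      stopf("need at least %d normal sperms for the dARD model set",
            config$n_models)
    }
    models <- select_representatives(contour_profiles[normal_idx],
                                     config$n_models, class = "normal")
    dards <- vapply(contour_profiles, average_rank_difference, 0,
                    models = models)
    report$model_indices <- normal_idx[models$indices]
  }

  want <- function(x) x %in% config$classifiers
  if (!is.null(labels)) {
    if (want("dard")) {
      fit <- find_dividing_line(dards, labels)
      report$results$dard <- list(dl = fit$dl, accuracy = fit$accuracy)
    }
    if (want("gray")) {
      fit <- find_dividing_line(ps, labels)
      report$results$gray <- list(dl = fit$dl, accuracy = fit$accuracy)
    }
    if (want("joint")) {
      sweep_tab <- alpha_sweep(dards, ps, labels, config$alpha_grid)
      best <- attr(sweep_tab, "best")
      report$results$joint <- list(sweep = sweep_tab,
                                   alpha = sweep_tab$alpha[best],
                                   dl = sweep_tab$dl[best],
                                   accuracy = sweep_tab$accuracy[best])
    }
    if (want("svm")) {
      feats <- build_fused_features(gray_profiles, dards)
      svm_cfg <- svm_config(cost = config$svm$cost, gamma = config$svm$gamma,
                            eps = config$svm$eps)
      rep_svm <- svm_train_test(feats, labels, gray_profiles = gray_profiles,
                                n_train_per_class = config$n_train_per_class,
                                config = svm_cfg)
      report$results$svm <- list(accuracy = rep_svm$accuracy,
                                 n_test = rep_svm$n_total,
                                 train_indices = rep_svm$train_indices)
      report$fused_features <- feats
      report$gray_profiles <- gray_profiles
    }
    if (want("knn")) {
      rep_knn <- knn_loo_accuracy(crops, labels, k = config$knn_k,
                                  normal_cut = config$knn_normal_cut)
      report$results$knn <- list(accuracy = rep_knn$accuracy)
    }
    if (want("ellipse")) {
      pred <- vapply(crops, function(cr)
        ellipse_classify(cr$mask, band = config$ovality_band)$label, "")
      rep_ell <- evaluate(pred, labels)
      report$results$ellipse <- list(accuracy = rep_ell$accuracy)
    }
  }

  report$labels <- labels
  report$dards <- dards
  report$darkness <- ps
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  if (!is.null(config$out_dir)) {
    write_pipeline_artifacts(config$out_dir, crops, labels, waveforms,
                             contour_profiles, gray_profiles, stats_list,
                             dards, report)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d sperms\n", x$n_sperms))
  for (nm in names(x$results)) {
    cat(sprintf("  %-8s accuracy %.4f\n", nm, x$results[[nm]]$accuracy))
  }
  invisible(x)
}

write_pipeline_artifacts <- function(dir, crops, labels, waveforms,
                                     contour_profiles, gray_profiles,
                                     stats_list, dards, report) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  crop_dir <- file.path(dir, "crops")
  dir.create(crop_dir, showWarnings = FALSE)
  n <- length(crops)
  for (i in seq_len(n)) {
    write_pgm(crops[[i]]$image, file.path(crop_dir, sprintf("crop_%03d.pgm", i)))
    write_pgm(matrix(ifelse(crops[[i]]$mask, 255L, 0L), nrow(crops[[i]]$mask)),
              file.path(crop_dir, sprintf("mask_%03d.pgm", i)))
  }
  utils::write.csv(data.frame(
    sperm_id = seq_len(n),
    origin_row = vapply(crops, function(x) x$origin[1], 0L),
    origin_col = vapply(crops, function(x) x$origin[2], 0L),
    label = if (is.null(labels)) NA_character_ else labels,
    dard = if (is.null(dards)) NA_real_ else dards,
    darkness = vapply(stats_list, `[[`, 0, "P")
  ), file.path(dir, "sperms.csv"), row.names = FALSE)
  write_waveforms(waveforms, file.path(dir, "waveforms.csv"))
  prof_df <- do.call(rbind, lapply(seq_len(n), function(i)
    cbind(sperm_id = i, profile_table(contour_profiles[[i]]))))
  utils::write.csv(prof_df, file.path(dir, "contour_profiles.csv"),
                   row.names = FALSE)
  out <- report
  out$results <- lapply(out$results, function(r) {
    if (!is.null(r$sweep)) r$sweep <- as.list(r$sweep)
    r
  })
  jsonlite::write_json(out[c("n_sperms", "results", "config_echo")],
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
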