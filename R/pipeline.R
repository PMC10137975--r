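default_config <- function() {
  list(
    seed = 0L,
    split = list(ratio = 0.5, stratified = TRUE),
    enhance = list(low_pct = 0, high_pct = 100),
    diffusion = list(kappa = 0.1, dt = 0.25, max_iters = 50L, tol = 0.02,
                     form = "exponential"),
    features = list(levels = 8L),
    svm = list(cost = 1, gamma = NULL),
    segment = list(enabled = TRUE, se_radius = 2L, connectivity = 8L,
                   head_floor = 0.05, head_erode = 3L, z_guard = 2.5),
    quality = list(enabled = TRUE)
  )
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
      merge_config(base[[k]], user[[k]]) else user[[k]]
  }
  base
}

load_directory_input <- function(input) {
  lab <- utils::read.csv(input$labels, stringsAsFactors = FALSE)
  if (!all(c("file", "label") %in% names(lab)))
    stop("label CSV must have columns `file` and `label`", call. = FALSE)
  target <- if (!is.null(input$target_size)) as.integer(input$target_size)
  images <- lapply(file.path(input$dir, lab$file), load_image,
                   target_size = target)
  list(images = images, masks = NULL, labels = as.integer(lab$label),
       ids = lab$file, specs = NULL)
}

stratified_split <- function(labels, ratio, seed) {
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_train <- max(1L, round(ratio * length(idx)))
    train_idx <- c(train_idx, sample(idx, n_train))
  }
  sort(train_idx)
}

#' Run the full tumor-recognition pipeline from a configuration
#'
#' Executes the three phases — denoising preprocessing (contrast stretch
#' plus anisotropic diffusion), feature extraction, and Gaussian-kernel
#' SVM classification — together with optional per-image quality metrics
#' and tumor localization, and returns a machine-readable run report.
#'
#' The configuration is a named list (or a path to a YAML file with the
#' same structure). The only required key is `input`, which either holds
#' a `phantom` block (`n_abnormal`, `n_normal`, optional [phantom_spec()]
#' fields, e.g. `size`, `noise_sigma`) or a `dir` + `labels` pair naming
#' an image directory and a CSV with `file,label` columns. All other
#' sections (`seed`, `split`, `enhance`, `diffusion`, `features`, `svm`,
#' `segment`, `quality`) are optional overrides of the package defaults.
#'
#' @param config named list or path to a YAML config file.
#' @return an object of class `pipeline_report`: nested list with the
#'   resolved parameters, seeds, per-image quality tibble (phantom input
#'   only), segmentation summary, confusion matrix and accuracy. The
#'   `timestamp` field is the only non-deterministic entry.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("`config` must be a list or YAML path", call. = FALSE)
  missing_keys <- setdiff("input", names(config))
  if (length(missing_keys) > 0L)
    stop("missing config keys: ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  cfg <- merge_config(default_config(), config[setdiff(names(config), "input")])
  input <- config$input
  seed <- as.integer(cfg$seed)

  message("[input] loading images")
  is_phantom <- !is.null(input$phantom)
  if (is_phantom) {
    pb <- input$phantom
    spec_fields <- intersect(names(pb), names(formals(phantom_spec)))
    base_spec <- do.call(phantom_spec, pb[spec_fields])
    data <- generate_dataset(pb$n_abnormal, pb$n_normal,
                             base_spec = base_spec, seed = seed)
    clean_specs <- lapply(data$specs, function(s) { s$noise_sigma <- 0; s })
  } else if (!is.null(input$dir)) {
    data <- load_directory_input(input)
  } else {
    stop("config input must contain a `phantom` block or a `dir` + `labels` pair",
         call. = FALSE)
  }
  n_img <- length(data$images)

  message("[enhance] contrast stretching ", n_img, " images")
  enhanced <- lapply(data$images, contrast_stretch,
                     low_pct = cfg$enhance$low_pct,
                     high_pct = cfg$enhance$high_pct)

  message("[diffusion] anisotropic filtering")
  dpar <- diffusion_params(kappa = cfg$diffusion$kappa, dt = cfg$diffusion$dt,
                           max_iters = cfg$diffusion$max_iters,
                           tol = cfg$diffusion$tol, form = cfg$diffusion$form)
  diffused <- lapply(enhanced, anisotropic_filter, params = dpar)
  filtered <- lapply(diffused, `[[`, "image")
  n_iters <- vapply(diffused, `[[`, integer(1), "n_iters")

  quality_tbl <- NULL
  if (isTRUE(cfg$quality$enabled) && is_phantom) {
    message("[quality] scoring denoising against clean renderings")
    # the clean reference is replayed through the same stretch mapping as
    # its noisy counterpart so all comparisons share one intensity scale
    quality_tbl <- do.call(rbind, lapply(seq_len(n_img), function(i) {
      clean <- generate_phantom(clean_specs[[i]])$image
      ab <- attr(enhanced[[i]], "range")
      clean <- if (ab[2] > ab[1])
        clip01((clean - ab[1]) / (ab[2] - ab[1])) else clean
      noisy <- enhanced[[i]]
      tibble::tibble(
        id = data$ids[i],
        mse_noisy = mse(noisy, clean),
        mse_filtered = mse(filtered[[i]], clean),
        ssim_noisy = ssim(noisy, clean),
        ssim_filtered = ssim(filtered[[i]], clean),
        psnr_noisy = psnr(noisy, clean),
        psnr_filtered = psnr(filtered[[i]], clean))
    }))
  }

  segment_summary <- NULL
  if (isTRUE(cfg$segment$enabled) && is_phantom) {
    message("[segment] localizing tumors on abnormal images")
    scfg <- segment_config(se_radius = cfg$segment$se_radius,
                           connectivity = cfg$segment$connectivity,
                           head_floor = cfg$segment$head_floor,
                           head_erode = cfg$segment$head_erode,
                           z_guard = cfg$segment$z_guard)
    ab <- which(data$labels == 1L)
    dices <- vapply(ab, function(i) {
      res <- localize_tumor(filtered[[i]], data$images[[i]], scfg)
      dice(res$mask, data$masks[[i]])
    }, numeric(1))
    segment_summary <- list(n_images = length(ab),
                            mean_dice = mean(dices),
                            min_dice = min(dices))
  }

  message("[features] extracting ", n_img, " feature vectors")
  fcfg <- glcm_config(levels = cfg$features$levels)
  feats <- feature_table(filtered, fcfg)

  message("[classify] training and evaluating the SVM")
  train_idx <- stratified_split(data$labels, cfg$split$ratio, seed)
  test_idx <- setdiff(seq_len(n_img), train_idx)
  clf <- train_svm(feats[train_idx, ], data$labels[train_idx],
                   cost = cfg$svm$cost, gamma = cfg$svm$gamma, seed = seed)
  cm <- evaluate_classifier(clf, feats[test_idx, ], data$labels[test_idx])

  structure(list(
    version = "1.0",
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = cfg,
    seed = seed,
    n_images = n_img,
    n_train = length(train_idx),
    n_test = length(test_idx),
    diffusion_iters = list(mean = mean(n_iters), max = max(n_iters)),
    quality = quality_tbl,
    segmentation = segment_summary,
    confusion = cm,
    accuracy = accuracy(cm)),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d images (%d train / %d test), accuracy %.3f\n",
              x$n_images, x$n_train, x$n_test, x$accuracy))
  print(unclass(x$confusion))
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' @param report a [run_pipeline()] report.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$confusion <- list(layout = "rows truth, cols predicted; abnormal first",
                        counts = unclass(out$confusion))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows", force = TRUE)
  invisible(path)
}
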