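#' Pipeline configuration
#'
#' All tunables of the segmentation/separation/feature pipeline with
#' their defaults. Values stated by the underlying method (mean-shift
#' bandwidth `h = 25`, 21-term Fibonacci erosion schedule) are the
#' defaults; everything else is exposed here.
#'
#' @param bandwidth Mean-shift kernel radius in a*/b* units.
#' @param min_region_area Minimum segmented region area (px).
#' @param schedule_terms Erosion schedule length.
#' @param min_object_area Minimum object area counted during erosion.
#' @param gvf_mu,gvf_iter,gvf_sigma GVF diffusion weight, iterations,
#'   and edge-map Gaussian scale.
#' @param snake_alpha,snake_beta,snake_gamma,snake_kappa,snake_iter,snake_points
#'   Active-contour tension, rigidity, step, external force weight,
#'   iterations and contour points.
#' @param glcm_levels,glcm_distance Co-occurrence quantization.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(bandwidth = 25, min_region_area = 150L,
                            schedule_terms = 21L, min_object_area = 8L,
                            gvf_mu = 0.2, gvf_iter = 200L, gvf_sigma = 1.5,
                            snake_alpha = 0.1, snake_beta = 0.05,
                            snake_gamma = 1, snake_kappa = 2,
                            snake_iter = 200L, snake_points = 64L,
                            glcm_levels = 32L, glcm_distance = 1L) {
  cfg <- as.list(environment())
  num <- unlist(cfg[c("bandwidth", "min_region_area", "schedule_terms",
                      "gvf_iter", "gvf_sigma", "snake_iter", "snake_points",
                      "glcm_levels", "glcm_distance")])
  if (any(num <= 0)) stop("pipeline parameters must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Segment, case-classify, separate and describe one image
#'
#' Runs the full single-image pipeline: CIELAB conversion, mean-shift
#' plus Otsu segmentation of the pollen region, the Fibonacci erosion
#' schedule on each region to decide Case I (isolated) versus Case II
#' (overlapping), seed recovery and GVF-snake separation for Case II,
#' and the 33-feature descriptor of every resulting grain.
#'
#' @param image An `rgb_image` or a path readable by [read_image()].
#' @param config A [pipeline_config()].
#' @return A list: `grain_masks` (list of logical masks), `features`
#'   (matrix, one row per grain), `regions` (per-region log: case,
#'   erosion counts, number of grains), `n_modes`.
#' @export
process_image <- function(image, config = pipeline_config()) {
  if (is.character(image)) image <- read_image(image)
  lab <- rgb_to_lab(image)
  modes <- mean_shift_modes(lab, bandwidth = config$bandwidth)
  schedule <- fibonacci_schedule(config$schedule_terms)
  mask <- tryCatch(binarize_pollen(lab, modes), error = function(e) NULL)
  if (is.null(mask)) {
    return(list(grain_masks = list(), features = NULL, regions = list(),
                n_modes = nrow(modes$modes)))
  }
  regions <- extract_regions(mask, config$min_region_area)
  grain_masks <- list()
  region_log <- list()
  for (ri in seq_along(regions)) {
    region <- regions[[ri]]$mask
    profile <- erosion_profile(region, schedule, config$min_object_area)
    case <- classify_case(profile)
    # a transient count increase is also overlap evidence: erosion can
    # split objects but never merge them, so a later decrease only means
    # a near-twin fragment died first at the deepest scheduled radius
    if (max(profile$counts) > profile$initial_count) case <- "CASE_II"
    masks_r <- list(region)
    if (case == "CASE_II") {
      seeds <- extract_seeds(region, profile, schedule, config$min_object_area)
      if (length(seeds) >= 2) {
        field <- gvf_field(region, config$gvf_mu, config$gvf_iter, config$gvf_sigma)
        contours <- lapply(seeds, function(s) {
          tryCatch(
            evolve_snake(s, field, config$snake_alpha, config$snake_beta,
                         config$snake_gamma, config$snake_kappa,
                         config$snake_iter, config$snake_points),
            error = function(e) { # collapsed snake: fall back to the seed outline
              structure(resample_closed(trace_boundary(s), config$snake_points),
                        class = "snake_contour")
            })
        })
        masks_r <- separate_region(region, contours)
      } else {
        case <- "CASE_I" # count change not confirmed by seeds; keep region whole
      }
    }
    grain_masks <- c(grain_masks, masks_r)
    region_log[[ri]] <- list(case = case, counts = profile$counts,
                             radii = profile$radii, n_grains = length(masks_r),
                             area = regions[[ri]]$area)
  }
  features <- NULL
  if (length(grain_masks)) {
    features <- do.call(rbind, lapply(grain_masks, function(m)
      feature_vector(m, lab, config$glcm_levels, config$glcm_distance)))
    colnames(features) <- feature_names()
  }
  list(grain_masks = grain_masks, features = features, regions = region_log,
       n_modes = nrow(modes$modes))
}

#' Run the pipeline over a batch of images
#'
#' Per-image failures are caught and logged; the run fails only if all
#' images fail.
#'
#' @param images List of paths or `rgb_image`s (nonempty).
#' @param config A [pipeline_config()].
#' @return A list: `reports` (per image), `features` (row-bound
#'   feature table with an `image` id column attribute), `errors`.
#' @export
run_pipeline <- function(images, config = pipeline_config()) {
  if (length(images) == 0) stop("no input images")
  reports <- vector("list", length(images))
  errors <- list()
  for (i in seq_along(images)) {
    reports[[i]] <- tryCatch(process_image(images[[i]], config),
                             error = function(e) {
                               errors[[length(errors) + 1L]] <<- conditionMessage(e)
                               NULL
                             })
  }
  if (all(vapply(reports, is.null, TRUE)))
    stop("all images failed: ", paste(unlist(errors), collapse = "; "))
  feats <- do.call(rbind, lapply(seq_along(reports), function(i) {
    f <- reports[[i]]$features
    if (is.null(f)) NULL else cbind(image = i, f)
  }))
  list(reports = reports, features = feats, errors = errors)
}

#' Bundled 12-class confusion-matrix benchmark
#'
#' Nine published confusion matrices (three classifier families —
#' multilayer perceptron, random tree forest, Bayes net — under 10-,
#' 5- and 2-fold cross validation) for a 618-grain, 12-species
#' airborne-pollen benchmark, shipped as plain-text fixtures for the
#' metrics engine. Note that the matrices filed under "mlp" and "rtf"
#' carry each other's summary statistics in the original source (the
#' two 2-fold matrices are printed identical); the metrics tests
#' encode the observed correspondence.
#'
#' @param technique One of `"mlp"`, `"rtf"`, `"bn"` (caption labels).
#' @param folds One of 10, 5, 2.
#' @return A `confusion_matrix` (12 x 12).
#' @export
benchmark_confusion <- function(technique = c("mlp", "rtf", "bn"),
                                folds = c(10, 5, 2)) {
  technique <- match.arg(technique)
  folds <- match.arg(as.character(folds[1]), c("10", "5", "2"))
  path <- system.file("extdata", "confusion",
                      sprintf("%s_%sfold.csv", technique, folds),
                      package = "pollensep", mustWork = TRUE)
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  confusion_matrix(m)
}
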