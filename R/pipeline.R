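#' Run the full structural/mechanical analysis for one sample
#'
#' Executes the per-sample pipeline: read (or accept) the collagen and
#' elastin stacks, clip the field of view, estimate voxelwise 3D
#' orientation, summarize it (3DOI, main angles), fit the two-family von
#' Mises mixture to the aggregate angle histogram, measure fiber density,
#' and extract the mechanical characteristics from the tensile log. A
#' failure in one stage is recorded and the remaining stages proceed; the
#' affected columns are missing-coded (`NA`).
#'
#' @param entry A list describing one sample:
#'   \describe{
#'     \item{sample_id}{Identifier (required).}
#'     \item{collagen, elastin}{Either an [image_stack()], a TIFF path, or
#'       `NULL` to skip that channel.}
#'     \item{tensile}{Either a data frame with columns `displacement_mm` and
#'       `force_N`, a CSV path with those columns, or `NULL`.}
#'     \item{age, thickness_collagen, thickness_elastin}{Optional metadata
#'       carried into the feature row (fiber thickness is measured manually
#'       upstream and enters only as a column).}
#'     \item{stepwise}{`TRUE` if the tensile log is a stepwise-loading
#'       record (upper envelope applied). Default `FALSE`.}
#'   }
#' @param config An [acquisition_config()].
#' @param geometry A [sample_geometry()].
#' @param window_size Orientation window (default 11).
#' @param threshold_factor Intensity threshold factor (default 0.45).
#' @param clip If `TRUE` (default) apply [clip_fov()] to stacks read from
#'   disk or passed in at the raw field of view; stacks smaller than the
#'   clipped extent are used as-is.
#' @return A list: `features` (one-row data frame in the cohort schema),
#'   `details` (per-channel summaries, fits, mask, mechanics), `errors`
#'   (named character vector of stage failures).
#' @export
run_sample <- function(entry, config = acquisition_config(),
                       geometry = sample_geometry(),
                       window_size = 11L, threshold_factor = 0.45,
                       clip = TRUE) {
  stopifnot(is.list(entry), !is.null(entry$sample_id))
  errors <- character(0)
  details <- list()
  feat <- data.frame(
    sample_id = entry$sample_id,
    age = if (is.null(entry$age)) NA_real_ else entry$age,
    E1 = NA_real_, E2 = NA_real_, sigma_max = NA_real_,
    eps_max = NA_real_, eps_mid = NA_real_,
    D_CO = NA_real_,
    T_CO = if (is.null(entry$thickness_collagen)) NA_real_
           else entry$thickness_collagen,
    OI3D_CO = NA_real_, main_theta_CO = NA_real_,
    D_EL = NA_real_,
    T_EL = if (is.null(entry$thickness_elastin)) NA_real_
           else entry$thickness_elastin,
    OI3D_EL = NA_real_, main_theta_EL = NA_real_,
    stringsAsFactors = FALSE)

  for (ch in c("collagen", "elastin")) {
    src <- entry[[ch]]
    if (is.null(src)) next
    suffix <- if (ch == "collagen") "CO" else "EL"
    res <- tryCatch({
      stack <- if (inherits(src, "image_stack")) src
               else read_stack(src, channel = ch, config = config,
                               sample_id = entry$sample_id)
      px <- round(config$fov_clipped_um / config$lateral_res_um)
      if (clip && all(dim(stack$voxels)[2:3] >= px))
        stack <- clip_fov(stack, config)
      mask <- binary_mask(stack, factor = threshold_factor)
      field <- estimate_orientation(stack, window_size = window_size,
                                    intensity_threshold_factor =
                                      threshold_factor)
      summ <- directional_summary(field)
      hist <- layer_histograms(field)
      fit <- vm_fit(hist)
      list(stack_dim = dim(stack$voxels), mask = mask, summary = summ,
           histogram = hist, vm = fit,
           density = fiber_density(mask))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[ch] <- conditionMessage(res)
      next
    }
    details[[ch]] <- res
    feat[[paste0("D_", suffix)]] <- res$density
    feat[[paste0("OI3D_", suffix)]] <- res$summary$oi3d
    feat[[paste0("main_theta_", suffix)]] <- res$summary$main_theta_folded
  }

  if (!is.null(entry$tensile)) {
    res <- tryCatch({
      log <- if (is.data.frame(entry$tensile)) entry$tensile
             else utils::read.csv(entry$tensile)
      curve <- build_curve(log$displacement_mm, log$force_N,
                           geometry = geometry)
      extract_characteristics(curve,
                              envelope = isTRUE(entry$stepwise))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors["mechanics"] <- conditionMessage(res)
    } else {
      details$mechanics <- res
      feat$E1 <- res$E1
      feat$E2 <- res$E2
      feat$sigma_max <- res$sigma_max
      feat$eps_max <- res$eps_max
      feat$eps_mid <- res$eps_mid
    }
  }
  list(features = feat, details = details, errors = errors)
}

#' Run the cohort-level analysis
#'
#' Applies [run_sample()] to every entry, assembles the feature table,
#' drops incomplete rows, screens all feature pairs with the
#' distance-correlation permutation test, and (when per-region 3DOI values
#' are supplied) compares the orientation index across stress regions by
#' ANOVA + Tukey HSD.
#'
#' @param entries List of sample entries (see [run_sample()]), or a
#'   ready-made feature data frame in the cohort schema.
#' @param features Feature columns for the dependency screen; defaults to
#'   every numeric column.
#' @param n_resamples Permutations per pair (default 2000).
#' @param alpha Significance level (default 0.05).
#' @param seed Seed for the permutation streams.
#' @param region_oi Optional named list (`toe`, `heel`, `linear`) of 3DOI
#'   vectors for [region_comparison()].
#' @param ... Passed to [run_sample()].
#' @return A list: `features` (full table), `complete` (complete-case
#'   table), `n_complete`, `dependencies` (pairwise screen, `NULL` when
#'   fewer than 4 complete rows, with a message), `region_anova`,
#'   `manifest` (seed, parameters, package version).
#' @export
run_cohort <- function(entries, features = NULL, n_resamples = 2000,
                       alpha = 0.05, seed = 1L, region_oi = NULL, ...) {
  if (is.data.frame(entries)) {
    tab <- entries
    per_sample <- NULL
  } else {
    per_sample <- lapply(entries, run_sample, ...)
    tab <- do.call(rbind, lapply(per_sample, `[[`, "features"))
  }
  if (is.null(features))
    features <- names(tab)[vapply(tab, is.numeric, logical(1))]
  complete <- tryCatch(complete_cases(tab, features),
                       error = function(e) tab[0, , drop = FALSE])
  deps <- NULL
  dep_message <- NULL
  if (nrow(complete) >= 4L) {
    deps <- pairwise_dependencies(complete, features = features,
                                  alpha = alpha, n_resamples = n_resamples,
                                  seed = seed)
  } else {
    dep_message <- sprintf(
      "dependency screen skipped: %d complete rows (< 4)", nrow(complete))
  }
  region <- if (!is.null(region_oi)) region_comparison(region_oi) else NULL
  list(features = tab, complete = complete, n_complete = nrow(complete),
       dependencies = deps, dependency_message = dep_message,
       region_anova = region, per_sample = per_sample,
       manifest = list(seed = seed, n_resamples = n_resamples,
                       alpha = alpha, features = features,
                       package_version =
                         as.character(utils::packageVersion("dermafiber"))))
}
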