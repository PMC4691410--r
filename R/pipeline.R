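#' Configure the end-to-end analysis pipeline
#'
#' Bundles every tunable of the simulate / extract / fit / couple /
#' contrast stages into one validated list.
#'
#' @param seed Integer seed for all stochastic stages.
#' @param cohort A [cohort_spec()].
#' @param trajectories,couplings Generator specs; see [trajectory_specs()]
#'   and [coupling_specs()].
#' @param phantom Optional [phantom_spec()]; when supplied the extraction
#'   stage runs on a generated phantom.
#' @param fwhm_mm,blur_plane,binarize_threshold Adjacent-WM mask settings,
#'   see [blur_parcel_2d()] and [extract_regional_measures()].
#' @param tie_threshold BIC tie band, see [select_growth_model()].
#' @param alpha,family_size Holm correction settings, see
#'   [coupling_analysis()].
#' @param ti_ms Inversion time for the contrast stage, ms.
#' @param contrast_residualize Age-residualize the contrast correlation
#'   (default TRUE).
#' @param contrast_mode \code{"difference"} or \code{"michelson"}.
#' @return A list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(seed = 1,
                            cohort = cohort_spec(),
                            trajectories = trajectory_specs(),
                            couplings = coupling_specs(),
                            phantom = phantom_spec(),
                            fwhm_mm = 4, blur_plane = "axial",
                            binarize_threshold = NULL,
                            tie_threshold = 2,
                            alpha = 0.05, family_size = NULL,
                            ti_ms = 950,
                            contrast_residualize = TRUE,
                            contrast_mode = "difference") {
  stopifnot(alpha > 0, alpha < 1, fwhm_mm > 0, ti_ms > 0, tie_threshold >= 0)
  structure(list(seed = as.integer(seed), cohort = cohort,
                 trajectories = trajectories, couplings = couplings,
                 phantom = phantom, fwhm_mm = fwhm_mm,
                 blur_plane = blur_plane,
                 binarize_threshold = binarize_threshold,
                 tie_threshold = tie_threshold, alpha = alpha,
                 family_size = family_size, ti_ms = ti_ms,
                 contrast_residualize = contrast_residualize,
                 contrast_mode = contrast_mode),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config, file = f)
  unname(tools::md5sum(f))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation, optional phantom generation and
#' regional extraction, per-region growth-model fitting with BIC selection,
#' age-residualized coupling analysis, and the ideal T1 contrast analysis.
#' When \code{out_dir} is given, each stage's table is written as TSV with
#' the configuration hash and seed stamped on every row, so re-running the
#' same configuration reproduces the files byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for TSV tables.
#' @param stages Character subset of
#'   \code{c("simulate", "extract", "fit", "couple", "contrast")}; stages
#'   depending on a skipped earlier stage require \code{data}.
#' @param data Optional pre-existing scan table (columns as produced by
#'   [simulate_cohort()]); when supplied the simulate stage is skipped.
#' @return Invisibly, a list of class \code{"pipeline_result"} with
#'   elements \code{cohort}, \code{extraction} (or NULL),
#'   \code{coefficients} (per region/hemisphere/measure logarithmic slope
#'   and intercept), \code{bic} (per-form BIC and selected model),
#'   \code{coupling}, \code{contrast}, \code{config_hash}.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         stages = c("simulate", "extract", "fit", "couple",
                                    "contrast"),
                         data = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  hash <- config_hash(config)
  res <- list(config_hash = hash)

  if ("simulate" %in% stages && is.null(data)) {
    data <- run_stage("simulate", simulate_cohort(
      config$cohort, config$trajectories, config$couplings,
      seed = config$seed))
  }
  res$cohort <- data

  if ("extract" %in% stages && !is.null(config$phantom)) {
    res$extraction <- run_stage("extract", {
      ph <- simulate_phantom(config$phantom, seed = config$seed)
      extract_regional_measures(ph, fwhm_mm = config$fwhm_mm,
                                plane = config$blur_plane,
                                binarize_threshold = config$binarize_threshold)
    })
  }

  if ("fit" %in% stages) {
    if (is.null(data)) stop("stage 'fit' needs a scan table")
    res[c("coefficients", "bic")] <- run_stage("fit", {
      units <- unique(data[c("region", "hemisphere")])
      coefs <- list(); bics <- list()
      for (u in seq_len(nrow(units))) {
        sub <- data[data$region == units$region[u] &
                      data$hemisphere == units$hemisphere[u], ]
        for (m in intersect(measure_names, names(sub))) {
          sel <- fit_growth_models(sub$age_days, sub[[m]],
                                   config$tie_threshold)
          lf <- coef(sel$fits$logarithmic)
          coefs[[length(coefs) + 1L]] <- data.frame(
            region = units$region[u], hemisphere = units$hemisphere[u],
            measure = m, slope = lf[["slope"]],
            intercept = lf[["intercept"]],
            n = sel$fits$logarithmic$n_obs, stringsAsFactors = FALSE)
          bics[[length(bics) + 1L]] <- data.frame(
            region = units$region[u], hemisphere = units$hemisphere[u],
            measure = m, bic_logarithmic = sel$bic[["logarithmic"]],
            bic_quadratic = sel$bic[["quadratic"]],
            bic_linear = sel$bic[["linear"]], best = sel$best,
            ties = paste(sel$ties, collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
      list(coefficients = do.call(rbind, coefs), bic = do.call(rbind, bics))
    })
  }

  if ("couple" %in% stages) {
    if (is.null(data)) stop("stage 'couple' needs a scan table")
    res$coupling <- run_stage("couple", coupling_analysis(
      data, alpha = config$alpha, family_size = config$family_size))
  }

  if ("contrast" %in% stages) {
    if (is.null(data)) stop("stage 'contrast' needs a scan table")
    res$contrast <- run_stage("contrast", contrast_coupling(
      data, ti_ms = config$ti_ms, mode = config$contrast_mode,
      residualize = config$contrast_residualize, alpha = config$alpha,
      family_size = config$family_size))
  }

  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_tables(res, out_dir, config$seed)
  invisible(res)
}

write_pipeline_tables <- function(res, out_dir, seed) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tabs <- c(cohort = "cohort", extraction = "extraction",
            coefficients = "trajectory_coefficients", bic = "bic_selection",
            coupling = "coupling", contrast = "contrast")
  for (nm in names(tabs)) {
    tab <- res[[nm]]
    if (is.null(tab)) next
    tab$config_hash <- res$config_hash
    tab$seed <- seed
    utils::write.table(format(tab, digits = 10, trim = TRUE, scientific = NA),
                       file.path(out_dir, paste0(tabs[[nm]], ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result (config ", substr(x$config_hash, 1, 8), "...)\n",
      sep = "")
  if (!is.null(x$cohort))
    cat(sprintf("  cohort: %d rows (%d scans x %d region-hemispheres)\n",
                nrow(x$cohort), length(unique(x$cohort$scan_id)),
                nrow(unique(x$cohort[c("region", "hemisphere")]))))
  if (!is.null(x$extraction))
    cat(sprintf("  extraction: %d parcels\n", nrow(x$extraction)))
  if (!is.null(x$bic))
    cat(sprintf("  fits: logarithmic selected in %d/%d series\n",
                sum(x$bic$best == "logarithmic"), nrow(x$bic)))
  if (!is.null(x$coupling)) {
    cat("  coupling: "); print(x$coupling)
  }
  if (!is.null(x$contrast))
    cat(sprintf("  contrast: %d/%d regions significant\n",
                sum(x$contrast$significant, na.rm = TRUE),
                nrow(x$contrast)))
  invisible(x)
}
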