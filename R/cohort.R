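#' Describe a longitudinal scan cohort
#'
#' Captures the sampling structure of a mixed cross-sectional/longitudinal
#' pediatric imaging cohort: number of children, how many return for a
#' second and a third scan, the age window, and the typical gap between
#' repeat scans. Defaults reproduce a 134-child / 177-scan cohort aged
#' 363-2198 days (corrected to a 40-week gestation) with 36 children
#' scanned twice and 7 scanned three times, roughly one year apart.
#'
#' @param n_children Number of children.
#' @param n_repeat2 Children scanned at least twice (includes the
#'   three-scan children).
#' @param n_repeat3 Children scanned three times (a subset of
#'   \code{n_repeat2}).
#' @param age_range_days Length-2 numeric, minimum and maximum age in days.
#' @param mean_repeat_gap_days Mean gap between repeat scans, days.
#' @param gap_sd_days Gaussian jitter (SD) of the repeat gap, days.
#' @param age_distribution Baseline age sampling: \code{"uniform"} over the
#'   age range, or \code{"truncnorm"} (normal truncated to the range).
#' @param age_mean,age_sd Mean and SD (days) of the untruncated normal when
#'   \code{age_distribution = "truncnorm"}.
#' @return An object of class \code{"cohort_spec"}.
#' @export
#' @examples
#' spec <- cohort_spec()
#' n_scans(spec)   # 177
cohort_spec <- function(n_children = 134, n_repeat2 = 36, n_repeat3 = 7,
                        age_range_days = c(363, 2198),
                        mean_repeat_gap_days = 365, gap_sd_days = 60,
                        age_distribution = c("uniform", "truncnorm"),
                        age_mean = 1044, age_sd = 523) {
  age_distribution <- match.arg(age_distribution)
  stopifnot(n_children >= 1, n_repeat2 >= 0, n_repeat3 >= 0,
            length(age_range_days) == 2, gap_sd_days >= 0,
            mean_repeat_gap_days > 0, age_sd > 0)
  if (n_repeat3 > n_repeat2)
    stop("n_repeat3 (scanned three times) must be a subset of n_repeat2 ",
         "(scanned at least twice)")
  if (n_repeat2 > n_children)
    stop("n_repeat2 must not exceed n_children")
  if (age_range_days[1] >= age_range_days[2])
    stop("age_range_days must be increasing")
  if (age_range_days[1] <= 0)
    stop("ages must be positive")
  structure(list(n_children = as.integer(n_children),
                 n_repeat2 = as.integer(n_repeat2),
                 n_repeat3 = as.integer(n_repeat3),
                 age_range_days = as.numeric(age_range_days),
                 mean_repeat_gap_days = mean_repeat_gap_days,
                 gap_sd_days = gap_sd_days,
                 age_distribution = age_distribution,
                 age_mean = age_mean, age_sd = age_sd),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param spec A \code{cohort_spec}.
#' @export
n_scans <- function(spec) {
  # one scan each + one extra per at-least-twice child + one more per thrice
  spec$n_children + spec$n_repeat2 + spec$n_repeat3
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort: %d children, %d scans (%d x2, %d x3), ages %g-%g days (%s)\n",
              x$n_children, n_scans(x), x$n_repeat2, x$n_repeat3,
              x$age_range_days[1], x$age_range_days[2], x$age_distribution))
  invisible(x)
}

#' Draw scan ages for a cohort
#'
#' Samples one baseline age per child and adds jittered gaps for repeat
#' scans. Baseline ages of children with k scans are drawn from the
#' configured distribution restricted to
#' \code{[min, max - (k-1) * mean_repeat_gap_days]} so that the expected
#' repeat schedule fits the age window; follow-up ages are
#' \code{previous + N(mean_gap, gap_sd)} truncated to the window.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer; when given, \code{set.seed(seed)} is called
#'   first so the table is reproducible.
#' @return A data frame with columns \code{child_id}, \code{scan_id},
#'   \code{age_days}, one row per scan.
#' @export
#' @examples
#' ages <- simulate_ages(cohort_spec(), seed = 1)
#' nrow(ages)  # 177
simulate_ages <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  lo <- spec$age_range_days[1]
  hi <- spec$age_range_days[2]
  scans_per_child <- rep(c(3L, 2L, 1L),
                         c(spec$n_repeat3, spec$n_repeat2 - spec$n_repeat3,
                           spec$n_children - spec$n_repeat2))
  out <- vector("list", spec$n_children)
  for (i in seq_len(spec$n_children)) {
    k <- scans_per_child[i]
    base_hi <- hi - (k - 1L) * spec$mean_repeat_gap_days
    if (base_hi <= lo)
      stop("infeasible repeat structure: ", k, " scans with mean gap ",
           spec$mean_repeat_gap_days, " days cannot fit in the age range")
    age <- draw_baseline_age(spec, lo, base_hi)
    ages <- age
    for (j in seq_len(k - 1L)) {
      gap <- max(stats::rnorm(1, spec$mean_repeat_gap_days, spec$gap_sd_days), 30)
      age <- min(age + gap, hi)
      ages <- c(ages, age)
    }
    out[[i]] <- data.frame(child_id = sprintf("child%03d", i),
                           scan_id = sprintf("child%03d_s%d", i, seq_len(k)),
                           age_days = ages, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

draw_baseline_age <- function(spec, lo, hi) {
  if (spec$age_distribution == "uniform")
    return(stats::runif(1, lo, hi))
  # truncated normal by inversion
  plo <- stats::pnorm(lo, spec$age_mean, spec$age_sd)
  phi <- stats::pnorm(hi, spec$age_mean, spec$age_sd)
  stats::qnorm(stats::runif(1, plo, phi), spec$age_mean, spec$age_sd)
}

#' Per-region trajectory specifications for the generator
#'
#' One row per (region, hemisphere, measure) giving the logarithmic model
#' \eqn{y = a \ln(\mathrm{age}) + b} and the residual SD used to generate
#' that measure. Slopes and intercepts default to the reference table
#' [ref_trajectories()]; right-hemisphere rows mirror the left-hemisphere
#' coefficients, which are the only printed reference values.
#'
#' @param regions Character vector of region identifiers.
#' @param hemispheres Character vector, subset of \code{c("left","right")}.
#' @param residual_sd Named numeric of per-measure residual SDs, units of
#'   each measure (mm for thickness, MWF fraction otherwise).
#' @param table Coefficient table in the format of [ref_trajectories()].
#' @return Data frame with columns \code{region}, \code{hemisphere},
#'   \code{measure}, \code{slope}, \code{intercept}, \code{residual_sd}.
#' @export
trajectory_specs <- function(regions = dk_regions(),
                             hemispheres = c("left", "right"),
                             residual_sd = c(thickness_mm = 0.1,
                                             cortical_mwf = 0.01,
                                             adjacent_mwf = 0.01),
                             table = ref_trajectories()) {
  stopifnot(all(hemispheres %in% c("left", "right")),
            all(measure_names %in% names(residual_sd)),
            all(residual_sd >= 0))
  tab <- table[match(regions, table$region), ]
  if (anyNA(tab$region))
    stop("unknown region(s): ",
         paste(regions[is.na(tab$region)], collapse = ", "))
  slope_col <- c(thickness_mm = "thickness_slope",
                 cortical_mwf = "cortical_mwf_slope",
                 adjacent_mwf = "adjacent_mwf_slope")
  int_col <- c(thickness_mm = "thickness_intercept",
               cortical_mwf = "cortical_mwf_intercept",
               adjacent_mwf = "adjacent_mwf_intercept")
  grid <- expand.grid(measure = measure_names, region = regions,
                      hemisphere = hemispheres,
                      stringsAsFactors = FALSE)
  i <- match(grid$region, tab$region)
  data.frame(region = grid$region, hemisphere = grid$hemisphere,
             measure = grid$measure,
             slope = as.numeric(mapply(function(r, m) tab[r, slope_col[m]],
                                       i, grid$measure)),
             intercept = as.numeric(mapply(function(r, m) tab[r, int_col[m]],
                                           i, grid$measure)),
             residual_sd = as.numeric(residual_sd[grid$measure]),
             stringsAsFactors = FALSE)
}

#' Per-region residual coupling specifications for the generator
#'
#' One row per (region, hemisphere) giving the three pairwise correlations
#' of the zero-mean trivariate residual vector (thickness, cortical MWF,
#' adjacent MWF). Defaults come from the reference coupling table
#' [ref_couplings()] (right hemisphere mirrors left). Pass scalar \code{r_*}
#' values to impose a common structure, e.g. all zero for a null generator.
#'
#' @param regions,hemispheres As in [trajectory_specs()].
#' @param r_thickness_adjacent,r_thickness_cortical,r_cortical_adjacent
#'   Optional scalars overriding the reference correlations for every region.
#' @return Data frame with columns \code{region}, \code{hemisphere},
#'   \code{r_thickness_adjacent}, \code{r_thickness_cortical},
#'   \code{r_cortical_adjacent}.
#' @export
coupling_specs <- function(regions = dk_regions(),
                           hemispheres = c("left", "right"),
                           r_thickness_adjacent = NULL,
                           r_thickness_cortical = NULL,
                           r_cortical_adjacent = NULL) {
  ref <- ref_couplings()
  i <- match(regions, ref$region)
  if (anyNA(i))
    stop("unknown region(s): ", paste(regions[is.na(i)], collapse = ", "))
  grid <- expand.grid(region = regions, hemisphere = hemispheres,
                      stringsAsFactors = FALSE)
  j <- match(grid$region, ref$region)
  pick <- function(override, col)
    if (is.null(override)) ref[j, col] else rep(override, nrow(grid))
  data.frame(region = grid$region, hemisphere = grid$hemisphere,
             r_thickness_adjacent = pick(r_thickness_adjacent, "r_thickness_adjacent"),
             r_thickness_cortical = pick(r_thickness_cortical, "r_thickness_cortical"),
             r_cortical_adjacent = pick(r_cortical_adjacent, "r_cortical_adjacent"),
             stringsAsFactors = FALSE)
}

coupling_matrix <- function(row) {
  cm <- diag(3)
  dimnames(cm) <- list(measure_names, measure_names)
  cm[1, 3] <- cm[3, 1] <- row$r_thickness_adjacent
  cm[1, 2] <- cm[2, 1] <- row$r_thickness_cortical
  cm[2, 3] <- cm[3, 2] <- row$r_cortical_adjacent
  cm
}

#' Simulate a regional scan table
#'
#' Generates a full scan-by-region measurement table: ages via
#' [simulate_ages()], then for every scan and (region, hemisphere) a
#' trivariate residual draw from a zero-mean normal with the region's
#' correlation matrix and the per-measure SDs, added to the logarithmic age
#' trend \eqn{a \ln(\mathrm{age}) + b}. Regional T1 values (ms) are
#' generated as configurable flat or slowly log-varying series with
#' Gaussian noise, independent of the MWF residuals.
#'
#' @param spec A [cohort_spec()].
#' @param trajectories Output of [trajectory_specs()] (or same format).
#' @param couplings Output of [coupling_specs()]; every (region, hemisphere)
#'   present in \code{trajectories} must appear here.
#' @param seed Optional integer seed governing all randomness in the call.
#' @param t1_gm_ms,t1_wm_ms Mean cortical and adjacent-WM T1, ms.
#' @param t1_log_slope_ms Change of T1 per ln(day) (same for both tissues;
#'   negative values emulate slow developmental T1 shortening). Default 0.
#' @param t1_sd_ms Gaussian noise SD on regional T1, ms.
#' @param child_intercept_sd Optional named numeric (same names as
#'   \code{residual_sd} in [trajectory_specs()]) of child-level random
#'   intercept SDs shared across a child's repeat scans; default all zero,
#'   i.e. scans are exchangeable.
#' @param clip_mwf Clip generated MWF values into [0, 1] (default TRUE).
#' @return Data frame with one row per scan x region x hemisphere and
#'   columns \code{child_id}, \code{scan_id}, \code{age_days}, \code{region},
#'   \code{hemisphere}, \code{thickness_mm}, \code{cortical_mwf},
#'   \code{adjacent_mwf}, \code{cortical_t1_ms}, \code{adjacent_t1_ms}.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(), seed = 1,
#'                           trajectories = trajectory_specs(regions = "cuneus",
#'                                                           hemispheres = "left"),
#'                           couplings = coupling_specs(regions = "cuneus",
#'                                                      hemispheres = "left"))
#' head(cohort)
simulate_cohort <- function(spec = cohort_spec(),
                            trajectories = trajectory_specs(),
                            couplings = coupling_specs(),
                            seed = NULL,
                            t1_gm_ms = 1400, t1_wm_ms = 900,
                            t1_log_slope_ms = 0, t1_sd_ms = 25,
                            child_intercept_sd = NULL,
                            clip_mwf = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  ages <- simulate_ages(spec, seed = NULL)
  n <- nrow(ages)
  units <- unique(trajectories[c("region", "hemisphere")])
  key <- function(d) paste(d$region, d$hemisphere)
  ck <- key(couplings)
  out <- vector("list", nrow(units))
  for (u in seq_len(nrow(units))) {
    reg <- units$region[u]; hemi <- units$hemisphere[u]
    tr <- trajectories[trajectories$region == reg &
                         trajectories$hemisphere == hemi, ]
    tr <- tr[match(measure_names, tr$measure), ]
    if (anyNA(tr$slope))
      stop("incomplete trajectory spec for ", reg, " (", hemi, ")")
    ci <- match(paste(reg, hemi), ck)
    if (is.na(ci))
      stop("no coupling spec for ", reg, " (", hemi, ")")
    cm <- coupling_matrix(couplings[ci, ])
    ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("correlation matrix for region '", reg,
           "' is not positive semi-definite")
    sds <- tr$residual_sd
    sigma <- diag(sds, 3) %*% cm %*% diag(sds, 3)
    res <- MASS::mvrnorm(n, mu = c(0, 0, 0), Sigma = sigma)
    if (!is.null(child_intercept_sd)) {
      b <- sapply(measure_names, function(m)
        stats::rnorm(spec$n_children, 0, child_intercept_sd[[m]]))
      res <- res + b[match(ages$child_id, unique(ages$child_id)), , drop = FALSE]
    }
    lage <- log(ages$age_days)
    vals <- sapply(1:3, function(j) tr$slope[j] * lage + tr$intercept[j]) + res
    colnames(vals) <- measure_names
    if (clip_mwf) {
      vals[, "cortical_mwf"] <- pmin(pmax(vals[, "cortical_mwf"], 0), 1)
      vals[, "adjacent_mwf"] <- pmin(pmax(vals[, "adjacent_mwf"], 0), 1)
    }
    out[[u]] <- data.frame(ages, region = reg, hemisphere = hemi,
                           thickness_mm = vals[, "thickness_mm"],
                           cortical_mwf = vals[, "cortical_mwf"],
                           adjacent_mwf = vals[, "adjacent_mwf"],
                           cortical_t1_ms = t1_gm_ms + t1_log_slope_ms * lage +
                             stats::rnorm(n, 0, t1_sd_ms),
                           adjacent_t1_ms = t1_wm_ms + t1_log_slope_ms * lage +
                             stats::rnorm(n, 0, t1_sd_ms),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
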