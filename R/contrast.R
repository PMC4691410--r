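#' Ideal inversion-recovery T1-weighted signal
#'
#' The proton-density-free inversion-recovery signal
#' \eqn{S = 1 - 2 e^{-TI/T_1}} at inversion time \code{ti_ms}. The default
#' TI of 950 ms matches a typical pediatric MP-RAGE protocol. The signal is
#' strictly decreasing in T1 and bounded in (-1, 1).
#'
#' @param t1_ms Longitudinal relaxation time(s), ms (positive).
#' @param ti_ms Inversion time, ms (positive, default 950).
#' @return Signal value(s) in (-1, 1).
#' @export
#' @examples
#' ideal_signal(950)          # 1 - 2/e
#' ideal_signal(950 / log(2)) # 0 (null point)
ideal_signal <- function(t1_ms, ti_ms = 950) {
  if (any(t1_ms <= 0)) stop("t1 must be positive")
  if (any(ti_ms <= 0)) stop("ti must be positive")
  1 - 2 * exp(-ti_ms / t1_ms)
}

#' Gray vs adjacent-white-matter ideal T1 contrast
#'
#' Signed difference of ideal T1-weighted signals,
#' \eqn{S_{WM} - S_{GM}}; positive when WM relaxes faster than GM
#' (\eqn{T_{1,WM} < T_{1,GM}}), i.e. the usual bright-WM appearance. A
#' Michelson-style normalized alternative
#' \eqn{(S_{WM}-S_{GM})/(|S_{WM}|+|S_{GM}|)} is available.
#'
#' @param t1_gm_ms,t1_wm_ms Regional T1 of gray matter and adjacent white
#'   matter, ms.
#' @param ti_ms Inversion time, ms (default 950).
#' @param mode \code{"difference"} (default) or \code{"michelson"}.
#' @return Contrast value(s).
#' @export
#' @examples
#' t1_contrast(t1_gm_ms = 1400, t1_wm_ms = 900)   # ~0.319
t1_contrast <- function(t1_gm_ms, t1_wm_ms, ti_ms = 950,
                        mode = c("difference", "michelson")) {
  mode <- match.arg(mode)
  s_gm <- ideal_signal(t1_gm_ms, ti_ms)
  s_wm <- ideal_signal(t1_wm_ms, ti_ms)
  if (mode == "difference") s_wm - s_gm
  else (s_wm - s_gm) / (abs(s_wm) + abs(s_gm))
}

#' Per-scan contrast records
#'
#' Appends the ideal GM signal, ideal adjacent-WM signal and their contrast
#' to a scan table carrying regional T1 columns.
#'
#' @param data Scan table with columns \code{cortical_t1_ms} and
#'   \code{adjacent_t1_ms}.
#' @inheritParams t1_contrast
#' @return \code{data} with added columns \code{s_gm}, \code{s_wm},
#'   \code{contrast}.
#' @export
contrast_table <- function(data, ti_ms = 950,
                           mode = c("difference", "michelson")) {
  mode <- match.arg(mode)
  stopifnot(all(c("cortical_t1_ms", "adjacent_t1_ms") %in% names(data)))
  data$s_gm <- ideal_signal(data$cortical_t1_ms, ti_ms)
  data$s_wm <- ideal_signal(data$adjacent_t1_ms, ti_ms)
  data$contrast <- if (mode == "difference") data$s_wm - data$s_gm
  else (data$s_wm - data$s_gm) / (abs(data$s_wm) + abs(data$s_gm))
  data
}

#' Correlate ideal T1 contrast with cortical thickness across regions
#'
#' Computes the per-scan gray/adjacent-WM ideal T1 contrast and its Pearson
#' correlation with cortical thickness within each (region, hemisphere),
#' with two-sided p-values and Holm-Bonferroni family-wise flags (family =
#' regional tests within a hemisphere, as in [coupling_analysis()]). By
#' default both series are age-residualized with the logarithmic trend
#' first; set \code{residualize = FALSE} to correlate raw values.
#'
#' @param data Scan table with columns \code{age_days}, \code{region},
#'   \code{hemisphere}, \code{thickness_mm}, \code{cortical_t1_ms},
#'   \code{adjacent_t1_ms}.
#' @inheritParams t1_contrast
#' @param residualize Age-residualize contrast and thickness before
#'   correlating (default TRUE).
#' @param alpha,family_size As in [coupling_analysis()].
#' @return Data frame of class \code{"coupling_results"} with pair
#'   \code{"contrast_thickness"}; regions with degenerate (e.g. constant)
#'   contrast are reported with \code{NA} and a warning.
#' @export
contrast_coupling <- function(data, ti_ms = 950,
                              mode = c("difference", "michelson"),
                              residualize = TRUE, alpha = 0.05,
                              family_size = NULL) {
  mode <- match.arg(mode)
  need <- c("age_days", "region", "hemisphere", "thickness_mm",
            "cortical_t1_ms", "adjacent_t1_ms")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  data <- contrast_table(data, ti_ms, mode)
  units <- unique(data[c("region", "hemisphere")])
  rows <- vector("list", nrow(units))
  for (u in seq_len(nrow(units))) {
    sub <- data[data$region == units$region[u] &
                  data$hemisphere == units$hemisphere[u], ]
    n <- nrow(sub)
    rp <- tryCatch({
      x <- sub$contrast
      y <- sub$thickness_mm
      if (residualize) {
        x <- trend_residuals(sub$age_days, x)
        y <- trend_residuals(sub$age_days, y)
      } else if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        stop("zero variance in measure")
      }
      r <- pearson_r(x, y)
      c(r = r, p = pearson_p(r, n))
    }, error = function(e) e)
    if (inherits(rp, "error")) {
      warning("region ", units$region[u], " (", units$hemisphere[u],
              "): ", conditionMessage(rp))
      rp <- c(r = NA_real_, p = NA_real_)
    }
    rows[[u]] <- data.frame(region = units$region[u],
                            hemisphere = units$hemisphere[u],
                            pair = "contrast_thickness",
                            r = rp[["r"]], p = rp[["p"]], n = n,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$significant <- FALSE
  out$alpha <- alpha
  out$family_size <- NA_integer_
  for (h in unique(out$hemisphere)) {
    sel <- out$hemisphere == h & !is.na(out$p)
    m <- if (is.null(family_size)) sum(out$hemisphere == h) else family_size
    out$significant[sel] <- holm_reject(out$p[sel], alpha, m)
    out$family_size[out$hemisphere == h] <- m
  }
  rownames(out) <- NULL
  class(out) <- c("coupling_results", "data.frame")
  out
}
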