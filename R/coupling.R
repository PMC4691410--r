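#' Pearson correlation of two residual series
#'
#' Standard product-moment correlation; errors on zero variance rather
#' than returning \code{NA}, because a zero-variance residual series
#' signals an upstream problem (constant measure).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Scalar correlation in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input series")
  stats::cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact null transform \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} with a
#' Student-t reference on \eqn{n-2} degrees of freedom. Taking (r, n)
#' rather than raw data allows published correlation tables to be
#' re-assessed directly.
#'
#' @param r Pearson correlation(s), in [-1, 1].
#' @param n Number of paired observations (>= 3).
#' @return Two-sided p-value(s); \eqn{|r| = 1} returns 0.
#' @export
#' @examples
#' pearson_p(-0.374, 177)   # ~3e-07
pearson_p <- function(r, n) {
  stopifnot(all(abs(r) <= 1), all(n >= 3))
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  t <- abs(r[ok]) * sqrt(n - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
  p
}

#' Holm-Bonferroni step-down rejections
#'
#' Orders the p-values ascending and rejects while
#' \eqn{p_{(k)} < \alpha/(m-k+1)}, stopping at the first failure; flags are
#' returned in the input order. Implemented through
#' \code{\link[stats]{p.adjust}(method = "holm")}, whose adjusted values
#' reproduce the step-down rule exactly; \code{family_size} may exceed the
#' number of supplied p-values (e.g. a fixed family of 33 regional tests of
#' which some regions were skipped).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param alpha Family-wise error level (default 0.05).
#' @param family_size Number of tests in the family, \code{m >= length(p)}
#'   (default \code{length(p)}).
#' @return Logical vector of rejection flags, same order as \code{p}.
#' @export
#' @examples
#' holm_reject(c(0.001, 0.01, 0.02, 0.5))   # TRUE TRUE TRUE FALSE
holm_reject <- function(p, alpha = 0.05, family_size = length(p)) {
  if (length(p) == 0) return(logical(0))
  stopifnot(all(p >= 0 & p <= 1), alpha > 0, alpha < 1,
            family_size >= length(p))
  stats::p.adjust(p, method = "holm", n = family_size) < alpha
}

#' Age-residualized coupling analysis across regions
#'
#' For every (region, hemisphere) in a scan table, removes the logarithmic
#' age trend from cortical thickness, cortical MWF and adjacent white-matter
#' MWF, and computes the Pearson correlation, two-sided p-value and
#' Holm-Bonferroni family-wise significance flag for the three measure
#' pairs: thickness vs adjacent MWF (does adjacent myelination drive
#' apparent cortical growth?), thickness vs cortical MWF, and cortical vs
#' adjacent MWF. The correction family is, per hemisphere and measure pair,
#' the set of regional tests (m = number of regions by default, e.g. 33 for
#' a full parcellation; override via \code{family_size} to pool hemispheres).
#'
#' @param data Scan table as produced by [simulate_cohort()]: columns
#'   \code{age_days}, \code{region}, \code{hemisphere},
#'   \code{thickness_mm}, \code{cortical_mwf}, \code{adjacent_mwf}.
#' @param alpha Family-wise error level (default 0.05).
#' @param family_size Tests per family; default the number of analyzed
#'   regions within each (hemisphere, pair) family.
#' @param model_form Trend removed before correlating (default
#'   \code{"logarithmic"}).
#' @return Data frame of class \code{"coupling_results"}: one row per
#'   region x hemisphere x pair with columns \code{region},
#'   \code{hemisphere}, \code{pair}, \code{r}, \code{p}, \code{n},
#'   \code{significant}, \code{alpha}, \code{family_size}. Regions with a
#'   missing or degenerate measure are skipped with a warning.
#' @export
coupling_analysis <- function(data, alpha = 0.05, family_size = NULL,
                              model_form = "logarithmic") {
  need <- c("age_days", "region", "hemisphere", measure_names)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  units <- unique(data[c("region", "hemisphere")])
  rows <- vector("list", nrow(units))
  for (u in seq_len(nrow(units))) {
    sub <- data[data$region == units$region[u] &
                  data$hemisphere == units$hemisphere[u], ]
    res <- tryCatch(
      lapply(measure_names, function(m) {
        if (anyNA(sub[[m]])) stop("missing values in ", m)
        trend_residuals(sub$age_days, sub[[m]], model_form)
      }),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping region ", units$region[u], " (",
              units$hemisphere[u], "): ", conditionMessage(res))
      next
    }
    names(res) <- measure_names
    n <- nrow(sub)
    pr <- lapply(pair_names, function(pn) {
      ij <- pair_index[[pn]]
      r <- tryCatch(pearson_r(res[[ij[1]]], res[[ij[2]]]),
                    error = function(e) e)
      if (inherits(r, "error")) return(r)
      c(r = r, p = pearson_p(r, n))
    })
    bad <- vapply(pr, inherits, TRUE, "error")
    if (any(bad)) {
      warning("skipping region ", units$region[u], " (",
              units$hemisphere[u], "): ", conditionMessage(pr[bad][[1]]))
      next
    }
    rows[[u]] <- data.frame(region = units$region[u],
                            hemisphere = units$hemisphere[u],
                            pair = pair_names,
                            r = vapply(pr, `[[`, 0, "r"),
                            p = vapply(pr, `[[`, 0, "p"),
                            n = n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no analyzable regions in input")
  out$significant <- FALSE
  out$alpha <- alpha
  out$family_size <- NA_integer_
  for (h in unique(out$hemisphere)) {
    for (pn in pair_names) {
      sel <- out$hemisphere == h & out$pair == pn
      m <- if (is.null(family_size)) sum(sel) else family_size
      out$significant[sel] <- holm_reject(out$p[sel], alpha, m)
      out$family_size[sel] <- m
    }
  }
  rownames(out) <- NULL
  class(out) <- c("coupling_results", "data.frame")
  out
}

# Residualize with degeneracy detection: a measure that is constant, or so
# perfectly age-determined that its residuals are numerical dust, carries no
# coupling information and must be surfaced, not silently correlated.
trend_residuals <- function(age_days, values, form = "logarithmic") {
  s_raw <- stats::sd(values)
  if (s_raw == 0) stop("zero variance in measure")
  r <- age_residuals(age_days, values, form)
  if (stats::sd(r) < 1e-10 * s_raw)
    stop("zero variance in age-residualized measure")
  r
}

#' @export
print.coupling_results <- function(x, ...) {
  cat(sprintf("Coupling analysis: %d regions x %d pair(s), n = %d scans\n",
              length(unique(x$region)), length(unique(x$pair)),
              max(x$n)))
  for (pn in unique(x$pair)) {
    sel <- x$pair == pn
    cat(sprintf("  %-20s %2d/%2d significant (alpha %.2f, Holm m = %d), r in [%.3f, %.3f]\n",
                pn, sum(x$significant[sel]), sum(sel), x$alpha[1],
                x$family_size[which(sel)[1]],
                min(x$r[sel]), max(x$r[sel])))
  }
  invisible(x)
}
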