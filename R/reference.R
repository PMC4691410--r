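#' Reference regional growth coefficients
#'
#' Logarithmic growth-curve coefficients for 33 left-hemisphere
#' Desikan-Killiany cortical regions in children aged roughly 1-6 years
#' (ages in days corrected to a 40-week gestation). For each region and each
#' of the three measures -- cortical thickness (mm), adjacent white-matter
#' MWF, and cortical MWF -- the table gives the slope \eqn{a} and intercept
#' \eqn{b} of the model \eqn{y = a \ln(\mathrm{age\ days}) + b}. These
#' coefficients parameterize the default synthetic cohort generator.
#'
#' @return A data frame with columns \code{region},
#'   \code{thickness_slope}, \code{thickness_intercept},
#'   \code{adjacent_mwf_slope}, \code{adjacent_mwf_intercept},
#'   \code{cortical_mwf_slope}, \code{cortical_mwf_intercept}.
#' @seealso [ref_couplings()], [ref_thickness_bic()]
#' @export
#' @examples
#' head(ref_trajectories())
ref_trajectories <- function() {
  read_ref("dk_left_growth_coefficients.tsv")
}

#' Reference residual correlation structure
#'
#' Age-residualized Pearson correlations (with two-sided p-values at
#' n = 177 pooled scans, and family-wise significance flags after
#' Holm-Bonferroni correction over 33 regions) between the three measure
#' pairs, for 33 left-hemisphere Desikan-Killiany regions. Used as the
#' default residual coupling structure of the synthetic cohort generator
#' and as worked-example input for the p-value machinery.
#'
#' @return A data frame with one row per region and columns
#'   \code{r_*}, \code{p_*}, \code{sig_*} for the pairs
#'   \code{thickness_adjacent}, \code{thickness_cortical},
#'   \code{cortical_adjacent}.
#' @export
ref_couplings <- function() {
  read_ref("dk_left_residual_correlations.tsv")
}

#' Reference BIC table for cortical thickness growth models
#'
#' Bayesian Information Criterion values for logarithmic, quadratic and
#' linear models of left-hemisphere cortical thickness against age, with
#' flags marking the model form(s) reported as best-describing each region.
#'
#' @return A data frame with columns \code{region}, \code{bic_logarithmic},
#'   \code{bic_quadratic}, \code{bic_linear} and the corresponding
#'   \code{flag_*} logicals.
#' @export
ref_thickness_bic <- function() {
  read_ref("dk_left_thickness_bic.tsv")
}

#' Desikan-Killiany region names used by the reference tables
#'
#' @return Character vector of the 33 bilateral cortical region identifiers
#'   (snake_case).
#' @export
dk_regions <- function() {
  ref_trajectories()$region
}

read_ref <- function(file) {
  path <- system.file("extdata", file, package = "mwfcoupling", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Assemble the reference 3x3 residual correlation matrix of one region
#'
#' Correlation matrix over (thickness, cortical MWF, adjacent WM MWF)
#' residuals, filled from [ref_couplings()].
#'
#' @param region Region identifier, see [dk_regions()].
#' @return A 3x3 correlation matrix with dimnames
#'   \code{c("thickness_mm", "cortical_mwf", "adjacent_mwf")}.
#' @export
ref_corr_matrix <- function(region) {
  tab <- ref_couplings()
  row <- tab[tab$region == region, ]
  if (nrow(row) != 1L)
    stop("unknown region: ", region)
  cm <- diag(3)
  dimnames(cm) <- list(measure_names, measure_names)
  cm["thickness_mm", "adjacent_mwf"] <- cm["adjacent_mwf", "thickness_mm"] <-
    row$r_thickness_adjacent
  cm["thickness_mm", "cortical_mwf"] <- cm["cortical_mwf", "thickness_mm"] <-
    row$r_thickness_cortical
  cm["cortical_mwf", "adjacent_mwf"] <- cm["adjacent_mwf", "cortical_mwf"] <-
    row$r_cortical_adjacent
  cm
}
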