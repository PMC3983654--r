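#' Per-sample mutation-burden table of a cohort bundle
#'
#' One row per sample: substitution, indel and copy-number event counts
#' (each called amplified or deleted segment is one event), the engineered
#' driver count, and age.
#'
#' @param bundle a [generate_cohort()] bundle (or equivalent list with
#'   `sample_sheet`, `mutations`, `segments`)
#' @return tibble keyed by `sample_id`
#' @export
build_burden_table <- function(bundle) {
  sheet <- bundle$sample_sheet
  mut <- bundle$mutations
  seg <- call_cna(bundle$segments, sheet)
  count_of <- function(ids) {
    as.integer(table(factor(ids, levels = sheet$sample_id)))
  }
  tibble(
    sample_id = sheet$sample_id,
    substitution_count = count_of(mut$sample_id[mut$class == "SNV"]),
    indel_count = count_of(mut$sample_id[mut$class != "SNV"]),
    cna_event_count = count_of(seg$sample_id[seg$call != "none"]),
    driver_count = count_drivers(sheet),
    age = sheet$age
  )
}

#' Pearson correlation between two burden-table columns
#'
#' Rows with missing values in either column are excluded listwise.
#'
#' @param burden_table a [build_burden_table()] tibble
#' @param x,y column names
#' @return list with `r`, `p_value`, `n`; `NULL` entries with a warning
#'   when fewer than 3 complete pairs remain or either variable is constant
#' @export
correlate <- function(burden_table, x, y) {
  xv <- burden_table[[x]]
  yv <- burden_table[[y]]
  ok <- complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) {
    warning("fewer than 3 complete pairs")
    return(list(r = NA_real_, p_value = NA_real_, n = length(xv)))
  }
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = length(xv)))
  }
  ct <- cor.test(xv, yv, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(xv))
}

#' Count GLM of a mutation burden on covariates
#'
#' Poisson log-link GLM fitted by iteratively reweighted least squares
#' (`glm`), with an automatic quasi-Poisson refit when the Pearson
#' dispersion exceeds `dispersion_cutoff` (overdispersed counts then keep
#' the same coefficients but get wider Wald intervals).
#'
#' @param burden_table a [build_burden_table()] tibble
#' @param response count column name
#' @param covariates character vector of covariate column names
#' @param dispersion_cutoff Pearson-dispersion threshold for the
#'   quasi-Poisson fallback (default 2)
#' @return list with `coefficients` tibble (term, estimate, se, p_value),
#'   `family`, `dispersion`, and the underlying `fit`
#' @export
burden_glm <- function(burden_table, response, covariates,
                       dispersion_cutoff = 2) {
  dat <- burden_table[, c(response, covariates)]
  dat <- dat[complete.cases(dat), ]
  for (cv in covariates) {
    if (stats::sd(dat[[cv]]) == 0) {
      stop("constant covariate: ", cv, " (design not full rank)")
    }
  }
  form <- stats::as.formula(
    paste(response, "~", paste(covariates, collapse = " + "))
  )
  fit <- glm(form, family = poisson(), data = dat)
  if (!fit$converged) stop("GLM did not converge")
  qr_rank <- fit$rank
  if (qr_rank < length(covariates) + 1) {
    stop("singular design matrix")
  }
  disp <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  family <- "poisson"
  if (disp > dispersion_cutoff) {
    fit <- glm(form, family = quasipoisson(), data = dat)
    family <- "quasipoisson"
  }
  sm <- summary(fit)$coefficients
  list(
    coefficients = tibble(
      term = rownames(sm),
      estimate = sm[, 1],
      se = sm[, 2],
      p_value = sm[, 4]
    ),
    family = family,
    dispersion = disp,
    fit = fit
  )
}
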