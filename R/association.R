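#' Covariate-adjusted single-variant logistic association
#'
#' Additive-coded (0/1/2) logistic regression of case status on risk-allele
#' count, fit by maximum likelihood (iteratively reweighted least squares
#' via `stats::glm`), with Wald standard errors from the observed
#' information. Subjects missing the dose, status, or any covariate are
#' excluded and counted. Perfect separation is flagged rather than
#' returned as a silently divergent estimate.
#'
#' @param status 0/1 (or logical) case indicator.
#' @param dose Risk-allele count per subject (NA = missing).
#' @param covariates Optional numeric matrix/data.frame of covariates
#'   (e.g. principal components, local-ancestry dosages).
#' @return one-row data.frame: `beta`, `se`, `or_`, `ci_lo`, `ci_hi`, `p`
#'   (Wald two-sided), `n_cases`, `n_controls`, `freq_cases`,
#'   `freq_controls`, `covariate_names`, `n_excluded`, `separation`.
#' @export
logistic_fit <- function(status, dose, covariates = NULL) {
  status <- as.integer(status)
  stopifnot(all(status %in% c(0L, 1L, NA)))
  n <- length(status)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    }
  }
  keep <- !is.na(status) & !is.na(dose)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  n_excluded <- sum(!keep)
  status <- status[keep]; dose <- dose[keep]
  X <- if (is.null(covariates)) NULL else covariates[keep, , drop = FALSE]

  if (sum(status == 1) < 1 || sum(status == 0) < 1) {
    stop("need at least one case and one control after exclusions")
  }
  design <- cbind(dose = dose, X)
  sds <- apply(design, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant design column(s): ",
         paste(colnames(design)[sds == 0], collapse = ", "))
  }
  full <- cbind(`(Intercept)` = 1, design)
  qr_d <- qr(full)
  if (qr_d$rank < ncol(full)) {
    dropped <- colnames(full)[qr_d$pivot[(qr_d$rank + 1):ncol(full)]]
    stop("singular design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }

  df <- data.frame(status = status, design)
  fit <- withCallingHandlers(
    stats::glm(status ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) invokeRestart("muffleWarning")
  )
  co <- summary(fit)$coefficients
  beta <- co["dose", "Estimate"]
  se <- co["dose", "Std. Error"]
  separation <- !fit$converged || abs(beta) > 15 ||
    any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
  p <- 2 * stats::pnorm(-abs(beta / se))

  data.frame(
    beta = beta, se = se, or_ = exp(beta),
    ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se),
    p = p,
    n_cases = sum(status == 1), n_controls = sum(status == 0),
    freq_cases = mean(dose[status == 1]) / 2,
    freq_controls = mean(dose[status == 0]) / 2,
    covariate_names = paste(colnames(X), collapse = ","),
    n_excluded = n_excluded, separation = separation,
    stringsAsFactors = FALSE
  )
}

#' Association across a range of ANC case thresholds
#'
#' Refits the single-variant model while the case definition moves along an
#' ANC threshold grid. Controls are always subjects with ANC above the
#' neutropenia threshold. Modes:
#' \describe{
#'   \item{cumulative}{cases are all subjects with `ANC <= T`.}
#'   \item{exclude_agranulocytosis}{cases are
#'     `agran_threshold < ANC <= T`; agranulocytosis subjects are dropped
#'     from the fit entirely (isolates the non-severe signal).}
#'   \item{exclude_neutropenia_band}{cases are `ANC <= T`; subjects with
#'     `T < ANC <= neut_threshold` are dropped entirely, never used as
#'     controls.}
#' }
#' Thresholds producing zero cases are skipped with a message, not an
#' error.
#'
#' @param anc ANC per subject (NA excluded from every fit).
#' @param dose Risk-allele count per subject.
#' @param covariates Optional covariate matrix.
#' @param thresholds ANC grid, default `seq(500, 1500, by = 100)`.
#' @param mode Exclusion mode (see above).
#' @param neut_threshold,agran_threshold Case-definition thresholds.
#' @return list of class `sweep_result`: `fits` (data.frame, one row per
#'   fitted threshold with the [logistic_fit()] columns plus `threshold`
#'   and `mode`), `skipped` (thresholds without cases), `trend`
#'   (slope/intercept of the weighted OR-on-threshold line, NA when fewer
#'   than two fits).
#' @export
anc_threshold_sweep <- function(anc, dose, covariates = NULL,
                                thresholds = seq(500, 1500, by = 100),
                                mode = c("exclude_agranulocytosis",
                                         "exclude_neutropenia_band",
                                         "cumulative"),
                                neut_threshold = 1500, agran_threshold = 500) {
  mode <- match.arg(mode)
  stopifnot(!is.unsorted(thresholds, strictly = TRUE))
  fits <- list()
  skipped <- numeric(0)
  for (T in thresholds) {
    is_control <- !is.na(anc) & anc > neut_threshold
    if (mode == "cumulative") {
      is_case <- !is.na(anc) & anc <= T
      drop <- rep(FALSE, length(anc))
    } else if (mode == "exclude_agranulocytosis") {
      is_case <- !is.na(anc) & anc > agran_threshold & anc <= T
      drop <- !is.na(anc) & anc <= agran_threshold
    } else {
      is_case <- !is.na(anc) & anc <= T
      drop <- !is.na(anc) & anc > T & anc <= neut_threshold
    }
    use <- (is_case | is_control) & !drop & !is.na(anc)
    if (sum(is_case & use) == 0) {
      message("threshold ", T, " (", mode, "): no cases; fit skipped")
      skipped <- c(skipped, T)
      next
    }
    st <- ifelse(is_case, 1L, 0L)
    res <- logistic_fit(st[use], dose[use],
                        if (is.null(covariates)) NULL
                        else covariates[use, , drop = FALSE])
    res$threshold <- T
    res$mode <- mode
    fits[[as.character(T)]] <- res
  }
  fits <- if (length(fits)) do.call(rbind, c(fits, make.row.names = FALSE))
          else NULL
  trend <- if (!is.null(fits) && nrow(fits) >= 2) {
    wls_trend(fits$threshold, fits$or_, fits$or_ * fits$se)
  } else {
    list(slope = NA_real_, intercept = NA_real_, slope_se = NA_real_)
  }
  structure(list(fits = fits, skipped = skipped, trend = trend),
            class = "sweep_result")
}

#' Weighted least-squares trend of odds ratio on ANC threshold
#'
#' Fits `or = intercept + slope * threshold` minimising
#' `sum(w * residual^2)` with weights `w = 1/se`, the reciprocal of each
#' estimate's standard error (delta-method SE of the OR,
#' `SE(OR) = OR * SE(beta)`, when the points come from logistic fits).
#'
#' @param threshold,or_ Point coordinates.
#' @param se_or Standard error of each OR; must be positive.
#' @return list: `slope`, `intercept`, `slope_se`, `intercept_se`.
#' @export
wls_trend <- function(threshold, or_, se_or) {
  stopifnot(length(threshold) == length(or_),
            length(or_) == length(se_or))
  if (length(threshold) < 2) stop("need at least two points")
  if (any(se_or <= 0)) stop("standard errors must be positive")
  if (length(unique(threshold)) == 1) stop("thresholds are all equal")
  fit <- stats::lm(or_ ~ threshold, weights = 1 / se_or)
  co <- summary(fit)$coefficients
  list(slope = co["threshold", "Estimate"],
       intercept = co["(Intercept)", "Estimate"],
       slope_se = co["threshold", "Std. Error"],
       intercept_se = co["(Intercept)", "Std. Error"])
}
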