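#' Classify subjects into high/low pharmacogenetic risk
#'
#' `genotype_only`: high risk iff the subject carries at least one risk
#' allele. `genotype_plus_lae` additionally promotes non-carriers whose
#' windowed AFR dosage strictly exceeds their EAS dosage; an exact tie
#' stays low risk. Subjects with a missing hard call are returned `NA`
#' (to be excluded with a logged count by callers).
#'
#' @param hard_call Risk-allele count (NA = missing).
#' @param afr,eas Windowed local-ancestry dosage means (required for
#'   `genotype_plus_lae`).
#' @param rule `"genotype_only"` or `"genotype_plus_lae"`.
#' @return factor with levels `low_risk`, `high_risk` (NA for missing
#'   calls).
#' @export
classify_risk <- function(hard_call, afr = NULL, eas = NULL,
                          rule = c("genotype_only", "genotype_plus_lae")) {
  rule <- match.arg(rule)
  high <- hard_call >= 1
  if (rule == "genotype_plus_lae") {
    if (is.null(afr) || is.null(eas)) {
      stop("genotype_plus_lae requires afr and eas window dosages")
    }
    high <- high | (hard_call == 0 & afr > eas)
  }
  factor(ifelse(high, "high_risk", "low_risk"),
         levels = c("low_risk", "high_risk"))
}

#' Confusion matrix of a risk classification
#'
#' Positives are cases under the chosen definition: `neutropenia` counts
#' both case classes; `agranulocytosis` counts only the severe class, and
#' subjects in the neutropenia-only band are excluded from the tally (the
#' control set is the same for both definitions). Subjects with missing
#' prediction or phenotype are excluded and counted.
#'
#' @param prediction factor from [classify_risk()].
#' @param phenotype factor from [define_phenotype()].
#' @param case_definition `"neutropenia"` or `"agranulocytosis"`.
#' @return list of class `confusion_matrix`: `tp`, `fp`, `fn`, `tn`,
#'   `n_excluded`.
#' @export
confusion_matrix <- function(prediction, phenotype,
                             case_definition = c("neutropenia",
                                                 "agranulocytosis")) {
  case_definition <- match.arg(case_definition)
  stopifnot(length(prediction) == length(phenotype))
  is_case <- if (case_definition == "neutropenia") {
    is_neutropenia(phenotype)
  } else {
    phenotype == "agranulocytosis"
  }
  in_scope <- !is.na(prediction) & !is.na(phenotype) &
    (phenotype == "control" | is_case)
  pred_high <- prediction[in_scope] == "high_risk"
  cs <- is_case[in_scope]
  structure(
    list(tp = sum(pred_high & cs), fp = sum(pred_high & !cs),
         fn = sum(!pred_high & cs), tn = sum(!pred_high & !cs),
         n_excluded = sum(!in_scope)),
    class = "confusion_matrix"
  )
}

#' Prevalence-recalibrated predictive test characteristics
#'
#' Applies Bayes' rule to sample sensitivity and specificity at an
#' externally assumed population risk `p` rather than the sample case
#' fraction:
#' `ppv_adj = s*p / (s*p + (1-spec)(1-p))`,
#' `npv_adj = spec*(1-p) / (spec*(1-p) + (1-s)*p)`.
#' The risk in the high-risk group equals the adjusted PPV, the risk in the
#' low-risk group equals one minus the adjusted NPV, and the relative risk
#' is the assumed risk divided by the risk in the high-risk group.
#' Sensitivity and specificity should be supplied unrounded.
#'
#' @param sens,spec Sensitivity and specificity in (0, 1].
#' @param p Assumed population risk in (0, 1).
#' @return data.frame: `sensitivity`, `specificity`, `prevalence`,
#'   `ppv_adj`, `npv_adj`, `risk_high`, `risk_low`, `rr`.
#' @export
recalibrate <- function(sens, spec, p) {
  if (p <= 0 || p >= 1) stop("assumed risk p must lie in (0, 1)")
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1)
  ppv <- sens * p / (sens * p + (1 - spec) * (1 - p))
  npv <- spec * (1 - p) / (spec * (1 - p) + (1 - sens) * p)
  data.frame(
    sensitivity = sens, specificity = spec, prevalence = p,
    ppv_adj = ppv, npv_adj = npv,
    risk_high = ppv, risk_low = 1 - npv, rr = p / ppv
  )
}

#' Minimum sensitivity for an acceptable residual risk
#'
#' Solves for the sensitivity at which the risk of the adverse event among
#' test-negative individuals falls to `acceptable_risk`, given population
#' risk `p`. Under the default perfect-specificity convention the solution
#' is closed-form:
#' `s = 1 - acceptable_risk * (1 - p) / (p * (1 - acceptable_risk))`.
#' A general specificity can be supplied, in which case the same algebra
#' applies with `spec` scaling the true-negative mass.
#'
#' @param acceptable_risk Tolerable residual risk among test-negatives.
#' @param p Population risk; must exceed `acceptable_risk`.
#' @param spec Assumed specificity (default 1).
#' @return Minimum sensitivity in \code{[0, 1]}; 0 with a warning when the
#'   acceptable risk already meets or exceeds the population risk.
#' @export
required_sensitivity <- function(acceptable_risk, p, spec = 1) {
  stopifnot(acceptable_risk > 0, p < 1, spec > 0, spec <= 1)
  if (acceptable_risk >= p) {
    warning("acceptable risk >= population risk; any test suffices")
    return(0)
  }
  1 - acceptable_risk * spec * (1 - p) / (p * (1 - acceptable_risk))
}

#' Full predictive-characteristics report
#'
#' One column per classifier rule and case definition: confusion counts,
#' sensitivity, specificity and the prevalence-recalibrated metrics at the
#' configured assumed risks. Subjects with missing hard calls are excluded
#' with a logged count.
#'
#' @param hard_call Risk-allele counts (NA = missing).
#' @param afr,eas Windowed local-ancestry dosage means.
#' @param phenotype factor from [define_phenotype()].
#' @param rules Classifier rules to evaluate.
#' @param case_definitions Case definitions to evaluate.
#' @param prevalences Named assumed risks, default
#'   `c(neutropenia = 0.038, agranulocytosis = 0.009)`.
#' @return data.frame, one row per rule x case definition, with columns
#'   `rule`, `case_definition`, `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `risk_high`, `risk_low`, `ppv_adj`, `npv_adj`, `rr`,
#'   `n_excluded_missing_call`.
#' @export
characteristics_table <- function(hard_call, afr, eas, phenotype,
                                  rules = c("genotype_only",
                                            "genotype_plus_lae"),
                                  case_definitions = c("neutropenia",
                                                       "agranulocytosis"),
                                  prevalences = c(neutropenia = 0.038,
                                                  agranulocytosis = 0.009)) {
  n_missing <- sum(is.na(hard_call))
  if (n_missing > 0) {
    message(n_missing, " subject(s) with missing hard calls excluded from ",
            "predictive characteristics")
  }
  rows <- list()
  for (rule in rules) {
    pred <- classify_risk(hard_call, afr, eas, rule)
    for (cd in case_definitions) {
      cm <- confusion_matrix(pred, phenotype, cd)
      sens <- cm$tp / (cm$tp + cm$fn)
      spec <- cm$tn / (cm$tn + cm$fp)
      rc <- recalibrate(sens, spec, prevalences[[cd]])
      rows[[paste(rule, cd)]] <- data.frame(
        rule = rule, case_definition = cd,
        tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
        sensitivity = sens, specificity = spec,
        risk_high = rc$risk_high, risk_low = rc$risk_low,
        ppv_adj = rc$ppv_adj, npv_adj = rc$npv_adj, rr = rc$rr,
        n_excluded_missing_call = n_missing,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
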