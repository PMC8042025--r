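#' Simulation parameters for a synthetic admixed cohort
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults describe a
#' predominantly European clozapine-treated cohort with three-way
#' (AFR/EAS/EUR) admixture across a 10 Mb MHC-like region, a risk allele at
#' roughly 2% frequency on a predominantly East-Asian haplotype background,
#' and a liability model in which the allele raises neutropenia risk and, in
#' non-carriers, a relative excess of African over East Asian local ancestry
#' does the same.
#'
#' @param n_subjects Number of diploid subjects.
#' @param region_start,region_end Region bounds in base pairs (1-based,
#'   closed). Default 25-35 Mb, an extended-MHC-sized window.
#' @param n_markers Number of evenly spaced backbone markers across the
#'   region at which local-ancestry dosages are reported. Five extra markers
#'   at `focal_pos + c(-1000, -500, 0, 500, 1000)` are always added so the
#'   1 kb averaging window around the focal variant is populated.
#' @param focal_pos Position of the focal risk variant (must lie inside the
#'   region).
#' @param pops Labels of the K ancestral populations.
#' @param global_props_alpha Dirichlet concentration (one value per
#'   population) for per-subject global ancestry proportions. The default
#'   `c(0.75, 0.75, 13.5)` gives mean fractions (0.05, 0.05, 0.90), so most
#'   subjects pass an 80% European-ancestry filter while a minority are
#'   admixed.
#' @param switch_rate Intensity of the ancestry switch process, expected
#'   switch points per megabase per haplotype. Stands in for mixture
#'   generations times recombination rate; tract lengths are exponential
#'   with mean `1/switch_rate` Mb.
#' @param p_risk_by_ancestry Named per-population probability that a
#'   haplotype whose local ancestry at `focal_pos` is that population
#'   carries the risk allele. The default `(AFR 0.01, EAS 0.15, EUR 0.01)`
#'   yields an overall risk-allele frequency near 2% in a European-dominant
#'   cohort with the allele enriched on East-Asian local haplotypes.
#' @param beta0 Baseline log-odds of neutropenia. Default `qlogis(0.038)`,
#'   the reported 3.8% incidence of clozapine-induced neutropenia.
#' @param beta_G Log odds ratio per risk-allele copy (additive). Default
#'   `log(6.2)`.
#' @param beta_LA Log odds ratio per unit of the windowed AFR-vs-EAS normed
#'   dosage difference, active in non-carriers only. Default `log(3)`.
#' @param anc_params List controlling the ANC draw:
#'   `control_meanlog`/`control_sdlog` for the log-normal control
#'   distribution (truncated above the neutropenia threshold);
#'   `p_agran` baseline probability that a case falls in the
#'   agranulocytosis band (ANC below 500), default 0.34 (60 of 178 cases);
#'   `agran_shift` additive log-odds shift of that probability per
#'   risk-allele copy, default 1.0, so carrier cases skew severe;
#'   `p_clinical` probability a case is recorded by clinical judgement
#'   (ANC missing, flag set), default 22/178; `p_clinical_agran`
#'   probability such a case carries an agranulocytosis annotation,
#'   default 3/22; `p_control_anc_missing` probability a control's ANC is
#'   unrecorded, default 0.05 (register-recruited controls).
#' @param dosage_noise_sd Standard deviation of the noise added to emitted
#'   local-ancestry dosages to emulate estimated (rather than true)
#'   dosages; noisy values are clipped to `[0, 2]` and renormalised to sum
#'   to 2. Set 0 to emit true integer dosages.
#' @param call_miscall_rate Probability that an emitted genotype-probability
#'   triplet is blurred away from a point mass on the true genotype.
#' @param neut_threshold,agran_threshold ANC case thresholds (cells/mm^3).
#' @param seed Integer RNG seed; all draws come from one stream seeded here.
#'
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_subjects = 1000L,
                       region_start = 25e6, region_end = 35e6,
                       n_markers = 101L,
                       focal_pos = 32629000,
                       pops = c("afr", "eas", "eur"),
                       global_props_alpha = c(0.75, 0.75, 13.5),
                       switch_rate = 3,
                       p_risk_by_ancestry = c(afr = 0.01, eas = 0.15, eur = 0.01),
                       beta0 = stats::qlogis(0.038),
                       beta_G = log(6.2),
                       beta_LA = log(3),
                       anc_params = list(),
                       dosage_noise_sd = 0.05,
                       call_miscall_rate = 0,
                       neut_threshold = 1500,
                       agran_threshold = 500,
                       seed = 1L) {
  anc_defaults <- list(
    control_meanlog = log(4000), control_sdlog = 0.3,
    p_agran = 60 / 178, agran_shift = 1.0,
    p_clinical = 22 / 178, p_clinical_agran = 3 / 22,
    p_control_anc_missing = 0.05
  )
  stopifnot(is.list(anc_params))
  unknown <- setdiff(names(anc_params), names(anc_defaults))
  if (length(unknown)) {
    stop("unknown anc_params field(s): ", paste(unknown, collapse = ", "))
  }
  anc_params <- utils::modifyList(anc_defaults, anc_params)

  p <- list(
    n_subjects = as.integer(n_subjects),
    region_start = region_start, region_end = region_end,
    n_markers = as.integer(n_markers), focal_pos = focal_pos,
    pops = pops, K = length(pops),
    global_props_alpha = global_props_alpha,
    switch_rate = switch_rate,
    p_risk_by_ancestry = p_risk_by_ancestry,
    beta0 = beta0, beta_G = beta_G, beta_LA = beta_LA,
    anc_params = anc_params,
    dosage_noise_sd = dosage_noise_sd,
    call_miscall_rate = call_miscall_rate,
    neut_threshold = neut_threshold, agran_threshold = agran_threshold,
    seed = as.integer(seed)
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  if (!is.finite(p$region_start) || !is.finite(p$region_end) ||
      p$region_end <= p$region_start) {
    stop("invalid region bounds: region_end must exceed region_start")
  }
  if (p$focal_pos < p$region_start || p$focal_pos > p$region_end) {
    stop("focal_pos must lie inside [region_start, region_end]")
  }
  if (p$n_subjects < 1L) stop("n_subjects must be at least 1")
  if (p$n_markers < 2L) stop("n_markers must be at least 2")
  if (p$switch_rate <= 0) stop("switch_rate must be positive")
  if (length(p$global_props_alpha) != p$K ||
      any(p$global_props_alpha <= 0)) {
    stop("global_props_alpha must be ", p$K, " positive values")
  }
  if (length(p$p_risk_by_ancestry) != p$K ||
      any(p$p_risk_by_ancestry < 0) || any(p$p_risk_by_ancestry > 1)) {
    stop("p_risk_by_ancestry must be ", p$K, " probabilities in [0, 1]")
  }
  if (!is.null(names(p$p_risk_by_ancestry)) &&
      !identical(sort(names(p$p_risk_by_ancestry)), sort(p$pops))) {
    stop("names of p_risk_by_ancestry must match pops")
  }
  if (p$agran_threshold >= p$neut_threshold || p$agran_threshold <= 0) {
    stop("need 0 < agran_threshold < neut_threshold")
  }
  invisible(p)
}

#' Marker map implied by simulation parameters
#'
#' Evenly spaced backbone markers plus a guaranteed cluster of five markers
#' spanning `focal_pos` +/- 1 kb, so the focal averaging window is never
#' empty.
#'
#' @param params A `sim_params` object.
#' @return data.frame with columns `marker_id`, `pos` (sorted, unique).
#' @export
marker_map <- function(params) {
  backbone <- round(seq(params$region_start, params$region_end,
                        length.out = params$n_markers))
  cluster <- params$focal_pos + c(-1000, -500, 0, 500, 1000)
  cluster <- cluster[cluster >= params$region_start &
                     cluster <= params$region_end]
  pos <- sort(unique(c(backbone, cluster)))
  data.frame(
    marker_id = ifelse(pos == params$focal_pos, "rs_focal",
                       paste0("m", seq_along(pos))),
    pos = pos,
    stringsAsFactors = FALSE
  )
}
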