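#' Run the full case-control analysis pipeline
#'
#' Orchestrates every stage on the three input files: genotype
#' hard-calling and variant QC, ANC-based phenotype definition, ancestry
#' grouping and carrier cross-tabulation, local-ancestry window
#' summarisation with permutation group comparisons (restricted, like all
#' downstream stages, to the European-ancestry stratum), covariate-adjusted
#' logistic association for neutropenia and agranulocytosis under the
#' global-ancestry (PC1-PC7) and global-plus-local-ancestry covariate
#' models, ANC-threshold sweeps with a weighted OR trend line, and the
#' predictive-characteristics report. All randomness (the permutation
#' nulls) derives from `seed`, and a config echo is written beside the
#' results, so a run is reproducible from its output directory alone.
#'
#' @param vcf_path,pheno_path,la_path The three input files.
#' @param out_dir Output directory for the report bundle.
#' @param call_threshold Posterior-probability threshold for hard calls.
#' @param window_bp Averaging half-window around the focal variant (bp).
#' @param neut_threshold,agran_threshold ANC case thresholds.
#' @param n_perm Permutations per group comparison.
#' @param prevalences Assumed population risks for the predictive report.
#' @param sweep_modes Exclusion modes to run in the threshold sweep.
#' @param seed Integer seed for the permutation nulls.
#' @return Invisibly, a list with every intermediate table (`qc`,
#'   `carriers`, `table1`, `table2`, `sweeps`, `table3`, `summary`) and the
#'   paths written.
#' @export
run_analyze <- function(vcf_path, pheno_path, la_path, out_dir,
                        call_threshold = 0.7, window_bp = 1000,
                        neut_threshold = 1500, agran_threshold = 500,
                        n_perm = 10000,
                        prevalences = c(neutropenia = 0.038,
                                        agranulocytosis = 0.009),
                        sweep_modes = c("exclude_agranulocytosis",
                                        "exclude_neutropenia_band"),
                        seed = 1L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  inputs <- read_cohort(vcf_path, pheno_path, la_path,
                        call_threshold = call_threshold)
  gt <- inputs$genotypes
  ph <- inputs$phenotypes
  ph <- ph[match(gt$subject_id, ph$subject_id), ]
  focal_pos <- gt$pos[1]

  phenotype <- define_phenotype(ph$anc, ph$clinical_case,
                                neut_threshold, agran_threshold)
  group <- classify_ancestry_group(ph$frac_afr, ph$frac_eas, ph$frac_eur)
  qc <- variant_qc(gt$hard_call, phenotype, variant_id = gt$variant_id[1])
  carriers <- carrier_table(gt$hard_call, phenotype, group)

  win <- window_mean(inputs$la, focal_pos, window_bp)
  win <- win[match(gt$subject_id, win$subject_id), ]

  n_case_total <- sum(is_neutropenia(phenotype), na.rm = TRUE)
  if (n_case_total == 0) stop("no cases in the cohort; nothing to analyse")

  eur <- !is.na(group) & group == "EUR" & !is.na(phenotype)
  message(sum(eur), " subjects in the European-ancestry stratum (of ",
          nrow(ph), ")")

  # ---- local-ancestry group comparisons (Table-1-shaped) ----------------
  table1 <- local_ancestry_report(win, gt$hard_call, phenotype, eur,
                                  n_perm = n_perm, seed = seed)

  # ---- association (Table-2-shaped) -------------------------------------
  pcs <- as.matrix(ph[, paste0("pc", 1:7)])
  la_cov <- cbind(la_afr = win$afr, la_eas = win$eas)
  table2 <- association_report(phenotype, gt$hard_call, pcs, la_cov, eur)

  # ---- ANC-threshold sweeps ---------------------------------------------
  sweeps <- list()
  for (m in sweep_modes) {
    sw <- anc_threshold_sweep(
      ph$anc[eur], gt$hard_call[eur],
      cbind(pcs, la_cov)[eur, , drop = FALSE],
      mode = m, neut_threshold = neut_threshold,
      agran_threshold = agran_threshold
    )
    sweeps[[m]] <- sw
  }

  # ---- predictive characteristics (Table-3-shaped) ----------------------
  table3 <- suppressMessages(characteristics_table(
    gt$hard_call[eur], win$afr[eur], win$eas[eur], phenotype[eur],
    prevalences = prevalences
  ))

  summary_list <- list(
    n_subjects = nrow(ph),
    n_eur = sum(eur),
    n_cases_neutropenia = sum(is_neutropenia(phenotype[eur])),
    n_cases_agranulocytosis = sum(phenotype[eur] == "agranulocytosis"),
    n_controls = sum(phenotype[eur] == "control"),
    n_missing_calls = sum(is.na(gt$hard_call)),
    n_unclassifiable = sum(is.na(phenotype)),
    qc_pass = qc$pass,
    required_sensitivity_agran = required_sensitivity(
      0.0013, prevalences[["agranulocytosis"]])
  )

  config <- list(
    vcf = vcf_path, phenotypes = pheno_path, local_ancestry = la_path,
    call_threshold = call_threshold, window_bp = window_bp,
    neut_threshold = neut_threshold, agran_threshold = agran_threshold,
    n_perm = n_perm, prevalences = as.list(prevalences),
    sweep_modes = sweep_modes, seed = seed, focal_pos = focal_pos
  )

  paths <- write_report_bundle(out_dir, qc, carriers, table1, table2,
                               sweeps, table3, summary_list, config)
  invisible(list(qc = qc, carriers = carriers, table1 = table1,
                 table2 = table2, sweeps = sweeps, table3 = table3,
                 summary = summary_list, paths = paths))
}

#' Stratified local-ancestry group comparisons with permutation p-values
#'
#' Two comparisons within the analysis stratum — risk-allele carriers vs
#' non-carriers, and non-carrier neutropenia cases vs controls — each over
#' six measures: the three per-population window means and the three
#' pairwise per-subject normed differences. Every measure gets a
#' two-sided permutation p-value whose seed derives from `seed`.
#'
#' @param win Window means from [window_mean()], one row per subject.
#' @param hard_call Risk-allele counts aligned with `win`.
#' @param phenotype factor from [define_phenotype()].
#' @param in_stratum logical; subjects eligible for the comparisons.
#' @param n_perm Permutations per measure.
#' @param seed Base seed for the permutation nulls.
#' @return data.frame with one row per comparison x measure.
#' @export
local_ancestry_report <- function(win, hard_call, phenotype, in_stratum,
                                  n_perm = 10000, seed = 1L) {
  comparisons <- list(
    carrier_vs_noncarrier = list(
      use = in_stratum & !is.na(hard_call),
      label = function(i) ifelse(hard_call[i] >= 1, "risk_carrier",
                                 "non_carrier"),
      ref = "risk_carrier"
    ),
    noncarrier_case_vs_control = list(
      use = in_stratum & !is.na(hard_call) & hard_call == 0 &
        !is.na(phenotype),
      label = function(i) ifelse(is_neutropenia(phenotype[i]), "case",
                                 "control"),
      ref = "case"
    )
  )
  pops <- c("afr", "eas", "eur")
  out <- list()
  ci <- 0L
  for (cmp_name in names(comparisons)) {
    ci <- ci + 1L
    cmp <- comparisons[[cmp_name]]
    idx <- which(cmp$use)
    lab <- cmp$label(idx)
    if (length(unique(lab)) < 2) {
      message("comparison ", cmp_name, " has an empty group; skipped")
      next
    }
    gs <- group_summary(win[idx, ], lab, pops)
    groups <- sub("^mean_", "", names(gs)[2:3])
    names(gs)[2:3] <- c("mean_group1", "mean_group2")
    gs$group1 <- groups[1]
    gs$group2 <- groups[2]
    measures <- list(
      afr = win$afr[idx], eas = win$eas[idx], eur = win$eur[idx],
      pair_afr_eas = normed_difference(win$afr[idx], win$eas[idx]),
      pair_afr_eur = normed_difference(win$afr[idx], win$eur[idx]),
      pair_eas_eur = normed_difference(win$eas[idx], win$eur[idx])
    )
    for (mi in seq_along(measures)) {
      v <- measures[[mi]]
      keep <- is.finite(v)
      pt <- permutation_test(v[keep], lab[keep], n_perm = n_perm,
                             seed = seed + 1000L * ci + mi)
      row <- gs[gs$measure == names(measures)[mi], ]
      out[[paste(cmp_name, names(measures)[mi])]] <- data.frame(
        comparison = cmp_name, row,
        p_point = pt$p_point, p_report = pt$p_report,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Single-variant association under both covariate models
#'
#' Fits the neutropenia and agranulocytosis case definitions under the
#' global-ancestry model (PC1-PC7) and the global-plus-local-ancestry
#' model (PC1-PC7 plus windowed AFR and EAS dosages as additive linear
#' covariates).
#'
#' @param phenotype factor from [define_phenotype()].
#' @param hard_call Risk-allele counts.
#' @param pcs Matrix of principal-component covariates.
#' @param la_cov Two-column matrix of windowed AFR/EAS dosage means.
#' @param in_stratum logical; subjects eligible for the fits.
#' @return data.frame, one row per phenotype x model, with the
#'   [logistic_fit()] columns.
#' @export
association_report <- function(phenotype, hard_call, pcs, la_cov,
                               in_stratum) {
  out <- list()
  for (def in c("neutropenia", "agranulocytosis")) {
    is_case <- if (def == "neutropenia") is_neutropenia(phenotype)
               else phenotype == "agranulocytosis"
    use <- in_stratum & (phenotype == "control" | is_case) &
      !is.na(phenotype)
    st <- ifelse(is_case[use], 1L, 0L)
    for (model in c("global", "global_local")) {
      covs <- if (model == "global") pcs[use, , drop = FALSE]
              else cbind(pcs, la_cov)[use, , drop = FALSE]
      fit <- logistic_fit(st, hard_call[use], covs)
      fit$phenotype <- def
      fit$model <- model
      out[[paste(def, model)]] <- fit
    }
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[, c("phenotype", "model",
          setdiff(names(res), c("phenotype", "model")))]
}

write_report_bundle <- function(out_dir, qc, carriers, table1, table2,
                                sweeps, table3, summary_list, config) {
  p <- function(f) file.path(out_dir, f)
  paths <- c(
    qc = p("variant_qc.tsv"), carriers = p("carrier_table.tsv"),
    table1 = p("table1_local_ancestry.tsv"),
    table2 = p("table2_association.tsv"),
    table3 = p("table3_prediction.tsv"),
    summary = p("summary.json"), config = p("config.json")
  )
  fwrite(as.data.table(qc), paths[["qc"]], sep = "\t", quote = FALSE)
  fwrite(as.data.table(carriers$counts), paths[["carriers"]], sep = "\t",
         quote = FALSE, na = "NA")
  fwrite(as.data.table(table1), paths[["table1"]], sep = "\t", quote = FALSE)
  fwrite(as.data.table(table2), paths[["table2"]], sep = "\t", quote = FALSE)
  fwrite(as.data.table(table3), paths[["table3"]], sep = "\t", quote = FALSE)
  for (m in names(sweeps)) {
    f <- p(paste0("sweep_", m, ".tsv"))
    if (!is.null(sweeps[[m]]$fits)) {
      fwrite(as.data.table(sweeps[[m]]$fits), f, sep = "\t", quote = FALSE)
      paths[paste0("sweep_", m)] <- f
    }
  }
  jsonlite::write_json(summary_list, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(config, paths[["config"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
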