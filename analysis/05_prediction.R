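#!/usr/bin/env Rscript
# Stage 5: predictive utility of the variant, alone and with local
# ancestry.
#
# Classifies European-ancestry subjects as high/low risk by carrier
# status (and, in the extended rule, by AFR-over-EAS window dosage excess
# among non-carriers), tallies confusion matrices for neutropenia and
# agranulocytosis, and recalibrates the predictive values to assumed
# population risks of 3.8% (neutropenia) and 0.9% (agranulocytosis).
# Also reports the sensitivity a test must reach before blood monitoring
# could be relaxed at an acceptable residual risk of 0.13%. Writes
# results/table3_prediction.tsv and results/prediction_summary.json.

suppressPackageStartupMessages({
  library(clozanc)
  library(data.table)
})

inp <- read_cohort("results/cohort/genotypes.vcf",
                   "results/cohort/phenotypes.tsv",
                   "results/cohort/local_ancestry.tsv")
ph <- inp$phenotypes
gt <- inp$genotypes
phenotype <- define_phenotype(ph$anc, ph$clinical_case)
group <- classify_ancestry_group(ph$frac_afr, ph$frac_eas, ph$frac_eur)
win <- window_mean(inp$la, gt$pos[1], 1000)
win <- win[match(gt$subject_id, win$subject_id), ]
eur <- !is.na(group) & group == "EUR" & !is.na(phenotype)

tab3 <- characteristics_table(gt$hard_call[eur], win$afr[eur],
                              win$eas[eur], phenotype[eur])
fwrite(as.data.table(tab3), "results/table3_prediction.tsv", sep = "\t",
       quote = FALSE)
cat("predictive characteristics, European stratum:\n")
print(tab3[, c("rule", "case_definition", "tp", "fp", "fn", "tn",
               "sensitivity", "specificity", "risk_high", "risk_low")],
      digits = 3)

req <- required_sensitivity(acceptable_risk = 0.0013, p = 0.009)
cat("\nsensitivity required to relax monitoring at 0.13% residual risk",
    "(0.9% population risk):", paste0(signif(100 * req, 3), "%"), "\n")

jsonlite::write_json(
  list(table = tab3, required_sensitivity_pct = 100 * req),
  "results/prediction_summary.json", auto_unbox = TRUE, digits = NA,
  dataframe = "rows", pretty = TRUE)
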