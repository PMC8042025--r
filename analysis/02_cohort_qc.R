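#!/usr/bin/env Rscript
# Stage 2: read the cohort back, hard-call genotypes, apply variant QC and
# tabulate risk-allele carriers by ancestry group and phenotype class.
#
# Expects results/cohort/ from 01_simulate_cohort.R; writes
# results/variant_qc.tsv and results/carrier_table.tsv.

suppressPackageStartupMessages({
  library(clozanc)
  library(data.table)
})

inp <- read_cohort("results/cohort/genotypes.vcf",
                   "results/cohort/phenotypes.tsv",
                   "results/cohort/local_ancestry.tsv")
ph <- inp$phenotypes
phenotype <- define_phenotype(ph$anc, ph$clinical_case)
group <- classify_ancestry_group(ph$frac_afr, ph$frac_eas, ph$frac_eur)

qc <- variant_qc(inp$genotypes$hard_call, phenotype,
                 variant_id = inp$genotypes$variant_id[1])
fwrite(as.data.table(qc), "results/variant_qc.tsv", sep = "\t", quote = FALSE)
cat("variant QC: call rate", round(qc$call_rate, 4),
    "| MAF", round(qc$maf, 4),
    "| HWE p", signif(qc$hwe_p, 3),
    "|", if (qc$pass) "PASS" else paste("FAIL:", qc$fails), "\n")

ct <- carrier_table(inp$genotypes$hard_call, phenotype, group)
fwrite(as.data.table(ct$counts), "results/carrier_table.tsv", sep = "\t",
       quote = FALSE, na = "NA")
cat("ancestry groups:", paste(names(table(group)), table(group),
                              collapse = ", "), "\n")
cat("carriers:", ct$totals$carriers, "of", ct$totals$n_called,
    "called subjects (", round(100 * ct$totals$carrier_prop, 1), "% )\n")
cat("unclassifiable subjects (no ANC, no clinical flag):",
    sum(is.na(phenotype)), "\n")
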