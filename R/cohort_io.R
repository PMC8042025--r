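#' Hard-call a genotype from posterior probabilities
#'
#' Best-guess calling: the argmax genotype is kept when its posterior
#' probability reaches the confidence threshold, otherwise the call is set
#' missing. The comparison is inclusive (a maximum posterior exactly at the
#' threshold keeps the call); ties for the maximum go missing.
#'
#' @param gp Numeric length-3 vector of genotype probabilities for 0, 1, 2
#'   risk-allele copies. Must be nonnegative and sum to 1 within 1e-4.
#' @param threshold Minimum posterior probability to keep a call (default
#'   0.7).
#' @return Integer risk-allele count in `{0, 1, 2}` or `NA_integer_`.
#' @export
best_guess <- function(gp, threshold = 0.7) {
  if (length(gp) != 3 || anyNA(gp) || any(gp < 0)) {
    stop("gp must be three nonnegative probabilities")
  }
  if (abs(sum(gp) - 1) > 1e-4) {
    stop("gp must sum to 1 (got ", format(sum(gp)), ")")
  }
  best_guess_vec(gp[1], gp[2], gp[3], threshold)
}

# vectorised core shared with the simulator / VCF reader
best_guess_vec <- function(gp0, gp1, gp2, threshold = 0.7) {
  m <- pmax(gp0, gp1, gp2)
  call <- max.col(cbind(gp0, gp1, gp2), ties.method = "first") - 1L
  tie <- (gp0 == m) + (gp1 == m) + (gp2 == m) > 1L
  out <- ifelse(m >= threshold & !tie, call, NA_integer_)
  as.integer(out)
}

#' Classify a subject's phenotype from ANC and clinical flag
#'
#' ANC at or below the agranulocytosis threshold gives `agranulocytosis`;
#' above it but at or below the neutropenia threshold gives
#' `neutropenia_only`; above the neutropenia threshold gives `control`
#' (boundaries inclusive). Subjects without a recorded ANC are classified by
#' the clinical-judgement flag: `"1"` gives `neutropenia_only`, `"agran"`
#' gives `agranulocytosis`, `"0"` is unclassifiable and returned `NA` with a
#' warning (never silently dropped).
#'
#' @param anc Numeric ANC in cells/mm^3 (NA allowed).
#' @param clinical_flag Character flag per subject: "0", "1" or "agran".
#' @param neut_threshold,agran_threshold Case thresholds, default 1500/500.
#' @return factor with levels `control`, `neutropenia_only`,
#'   `agranulocytosis` (NA = unclassifiable).
#' @export
define_phenotype <- function(anc, clinical_flag = "0",
                             neut_threshold = 1500, agran_threshold = 500) {
  stopifnot(agran_threshold > 0, agran_threshold < neut_threshold)
  n <- max(length(anc), length(clinical_flag))
  anc <- rep_len(anc, n)
  clinical_flag <- rep_len(as.character(clinical_flag), n)
  if (!all(clinical_flag %in% c("0", "1", "agran"))) {
    stop("clinical_flag values must be one of '0', '1', 'agran'")
  }
  out <- rep(NA_character_, n)
  has <- !is.na(anc)
  out[has & anc <= agran_threshold] <- "agranulocytosis"
  out[has & anc > agran_threshold & anc <= neut_threshold] <- "neutropenia_only"
  out[has & anc > neut_threshold] <- "control"
  out[!has & clinical_flag == "1"] <- "neutropenia_only"
  out[!has & clinical_flag == "agran"] <- "agranulocytosis"
  n_bad <- sum(!has & clinical_flag == "0")
  if (n_bad > 0) {
    warning(n_bad, " subject(s) without ANC or clinical flag are unclassifiable")
  }
  factor(out, levels = c("control", "neutropenia_only", "agranulocytosis"))
}

#' Is a phenotype class a neutropenia case?
#'
#' Agranulocytosis implies neutropenia, so both case classes count.
#' @param phenotype factor from [define_phenotype()].
#' @return logical (NA for unclassifiable).
#' @export
is_neutropenia <- function(phenotype) {
  out <- phenotype %in% c("neutropenia_only", "agranulocytosis")
  out[is.na(phenotype)] <- NA
  out
}

#' Assign subjects to broad ancestry groups
#'
#' A subject is `EUR` (`AFR`) when the European (African) global ancestry
#' fraction is at least the threshold; anyone else is `admixed`.
#'
#' @param frac_afr,frac_eas,frac_eur Global ancestry fractions per subject;
#'   each row must lie on the simplex within 1e-6.
#' @param threshold Fraction cutoff, default 0.8.
#' @return factor with levels `EUR`, `AFR`, `admixed`.
#' @export
classify_ancestry_group <- function(frac_afr, frac_eas, frac_eur,
                                    threshold = 0.8) {
  s <- frac_afr + frac_eas + frac_eur
  if (any(abs(s - 1) > 1e-6, na.rm = TRUE)) {
    stop("ancestry fractions must sum to 1")
  }
  out <- rep("admixed", length(s))
  out[frac_eur >= threshold] <- "EUR"
  out[frac_afr >= threshold] <- "AFR"
  out[is.na(s)] <- NA
  factor(out, levels = c("EUR", "AFR", "admixed"))
}

#' Hardy-Weinberg exact test on genotype counts
#'
#' Standard two-sided exact test: the p-value is the total probability,
#' under the conditional distribution of heterozygote counts given the
#' allele counts, of all heterozygote configurations no more probable than
#' the observed one. No mid-p correction.
#'
#' @param n_aa,n_ab,n_bb Genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop("no genotypes")
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(het = h | allele counts) up to a shared constant
  logp <- vapply(hets, function(h) {
    haa <- (n_a - h) / 2
    hbb <- (n_b - h) / 2
    if (n_a < n_b) { tmp <- haa; haa <- hbb; hbb <- tmp }
    h * log(2) - lfactorial(h) - lfactorial(haa) - lfactorial(hbb)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[hets == n_ab]
  min(1, sum(p[p <= obs + 1e-12]))
}

#' Single-variant QC: missingness, MAF, Hardy-Weinberg
#'
#' Mirrors standard post-imputation filters: fail when the missing-call
#' fraction exceeds `geno`, the minor-allele frequency falls below `maf`,
#' or the HWE exact-test p-value falls below `hwe`. HWE is evaluated in
#' controls when phenotype classes are supplied, otherwise in everyone.
#'
#' @param hard_call Integer vector of risk-allele counts (NA = missing).
#' @param phenotype Optional factor from [define_phenotype()]; controls are
#'   used for the HWE test.
#' @param geno,maf,hwe Filter thresholds, defaults 0.1 / 0.01 / 1e-5.
#' @param variant_id Label carried into the report.
#' @return one-row data.frame: `variant_id`, `call_rate`, `maf`, `hwe_p`,
#'   `pass`, plus the failing filters in `fails` (comma-separated, "" if
#'   passing).
#' @export
variant_qc <- function(hard_call, phenotype = NULL,
                       geno = 0.1, maf = 0.01, hwe = 1e-5,
                       variant_id = "variant") {
  if (length(hard_call) == 0) stop("no genotype calls")
  ok <- !is.na(hard_call)
  if (!any(ok)) stop("zero non-missing calls")
  stopifnot(all(hard_call[ok] %in% 0:2))
  call_rate <- mean(ok)
  af <- mean(hard_call[ok]) / 2
  maf_obs <- min(af, 1 - af)

  hwe_set <- hard_call
  if (!is.null(phenotype)) {
    hwe_set <- hard_call[!is.na(phenotype) & phenotype == "control"]
  }
  hwe_set <- hwe_set[!is.na(hwe_set)]
  hwe_p <- if (length(hwe_set)) {
    hwe_exact_test(sum(hwe_set == 0), sum(hwe_set == 1), sum(hwe_set == 2))
  } else NA_real_
  fails <- c(
    if (1 - call_rate > geno) "geno",
    if (maf_obs < maf) "maf",
    if (!is.na(hwe_p) && hwe_p < hwe) "hwe"
  )
  data.frame(
    variant_id = variant_id, call_rate = call_rate, maf = maf_obs,
    hwe_p = hwe_p, pass = length(fails) == 0,
    fails = paste(fails, collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Count non-missing calls of a given genotype class
#'
#' @param hard_call Integer risk-allele counts (NA = missing).
#' @param genotype_class Count to tally (0, 1 or 2).
#' @return integer count.
#' @export
genotype_class_count <- function(hard_call, genotype_class) {
  sum(hard_call == genotype_class, na.rm = TRUE)
}

#' Cross-tabulate risk-allele carriers by ancestry group and phenotype
#'
#' @param hard_call Integer risk-allele counts, aligned with the other
#'   arguments by position.
#' @param phenotype factor from [define_phenotype()].
#' @param ancestry_group factor from [classify_ancestry_group()].
#' @return list with `counts` (data.frame: group, phenotype, carriers,
#'   non_carriers, missing, allele_freq) and `totals` (overall carriers,
#'   called subjects, carrier proportion).
#' @export
carrier_table <- function(hard_call, phenotype, ancestry_group) {
  n <- length(hard_call)
  if (length(phenotype) != n || length(ancestry_group) != n) {
    stop("hard_call, phenotype and ancestry_group must align")
  }
  dt <- data.table(g = hard_call, ph = phenotype, grp = ancestry_group)
  counts <- dt[, .(
    carriers = sum(g >= 1, na.rm = TRUE),
    non_carriers = sum(g == 0, na.rm = TRUE),
    missing = sum(is.na(g)),
    allele_freq = {
      called <- g[!is.na(g)]
      if (length(called)) mean(called) / 2 else NA_real_
    }
  ), by = .(group = grp, phenotype = ph)]
  setorder(counts, group, phenotype)
  called <- dt[!is.na(g)]
  totals <- data.frame(
    carriers = called[, sum(g >= 1)],
    n_called = nrow(called),
    carrier_prop = called[, mean(g >= 1)]
  )
  list(counts = as.data.frame(counts), totals = totals)
}

# ---- file I/O ------------------------------------------------------------

#' Write a one-site VCF 4.2 with GT and GP fields
#'
#' @param genotypes data.frame with `subject_id`, `gp0`, `gp1`, `gp2`,
#'   `hard_call` (NA allowed) as produced by [assign_focal_genotypes()].
#' @param pos Variant position.
#' @param path Output file.
#' @param chrom,id,ref,alt Site fields; the risk allele is ALT.
#' @return invisibly, `path`.
#' @export
write_focal_vcf <- function(genotypes, pos, path, chrom = "6",
                            id = "rs_focal", ref = "C", alt = "G") {
  g <- as.data.frame(genotypes)
  gt <- c("0/0", "0/1", "1/1")[g$hard_call + 1L]
  gt[is.na(gt)] <- "./."
  gp <- sprintf("%.4f,%.4f,%.4f", g$gp0, g$gp1, g$gp2)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=GP,Number=G,Type=Float,Description=",
           "\"Genotype posterior probabilities for 0/0, 0/1, 1/1\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$subject_id), collapse = "\t")
  )
  row <- paste(c(chrom, format(pos, scientific = FALSE), id, ref, alt, ".",
                 "PASS", ".", "GT:GP", paste(gt, gp, sep = ":")),
               collapse = "\t")
  writeLines(c(header, row), path)
  invisible(path)
}

#' Read focal-variant genotypes from a VCF
#'
#' Reads a biallelic single-site VCF. When a GP field is present, hard
#' calls are re-derived by [best_guess()] at `call_threshold`; otherwise the
#' GT field is used directly. Allele counts are always reported for the
#' risk allele (ALT by default).
#'
#' @param path VCF file.
#' @param call_threshold Posterior threshold for hard-calling.
#' @param risk_allele `"ALT"` or `"REF"`.
#' @return data.frame: `subject_id`, `variant_id`, `gp0..gp2` (NA when GP
#'   absent), `hard_call`, `risk_allele`.
#' @export
read_genotypes <- function(path, call_threshold = 0.7, risk_allele = "ALT") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) != 1) stop("expected a single-site VCF, got ", nrow(v@fix))
  risk_allele <- match.arg(risk_allele, c("ALT", "REF"))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  ids <- colnames(gt_raw)
  alt_count <- function(x) {
    if (is.na(x) || grepl("\\.", x)) return(NA_integer_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]))
  }
  from_gt <- vapply(gt_raw[1, ], alt_count, integer(1))

  gp_raw <- tryCatch(vcfR::extract.gt(v, element = "GP"), error = function(e) NULL)
  if (!is.null(gp_raw) && !all(is.na(gp_raw))) {
    gp <- do.call(rbind, lapply(strsplit(gp_raw[1, ], ","), as.numeric))
    hard <- best_guess_vec(gp[, 1], gp[, 2], gp[, 3], call_threshold)
  } else {
    gp <- matrix(NA_real_, length(ids), 3)
    hard <- from_gt
  }
  if (risk_allele == "REF") {
    hard <- 2L - hard
    gp <- gp[, 3:1, drop = FALSE]
  }
  allele <- if (risk_allele == "ALT") v@fix[1, "ALT"] else v@fix[1, "REF"]
  data.frame(
    subject_id = ids, variant_id = unname(v@fix[1, "ID"]),
    pos = as.numeric(v@fix[1, "POS"]),
    gp0 = gp[, 1], gp1 = gp[, 2], gp2 = gp[, 3],
    hard_call = hard, risk_allele = unname(allele),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Read the phenotype/covariate table
#'
#' Tab-separated with header: `subject_id`, `anc`, `clinical_case`
#' (0/1/agran), `sex`, `age`, `pc1`..`pc7`, `frac_afr`, `frac_eas`,
#' `frac_eur`, `site`; missing values as "NA". Validates ancestry fractions
#' and ANC sign.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  ph <- as.data.frame(fread(path, sep = "\t", na.strings = "NA",
                            colClasses = list(character = "clinical_case")))
  required <- c("subject_id", "anc", "clinical_case", "frac_afr",
                "frac_eas", "frac_eur")
  missing_cols <- setdiff(required, names(ph))
  if (length(missing_cols)) {
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(ph$subject_id)) stop("duplicate subject ids")
  if (any(ph$anc < 0, na.rm = TRUE)) stop("negative ANC values")
  s <- ph$frac_afr + ph$frac_eas + ph$frac_eur
  if (any(abs(s - 1) > 1e-6, na.rm = TRUE)) {
    stop("ancestry fractions must sum to 1")
  }
  ph
}

#' Read the long-format local-ancestry dosage table
#'
#' Columns: `subject_id`, `marker_id`, `pos`, `dos_afr`, `dos_eas`,
#' `dos_eur`; dosages in `[0, 2]`, summing to 2 per marker within a
#' tolerance (estimated dosages are noisy).
#'
#' @param path TSV file.
#' @param sum_tol Allowed deviation of the per-marker dosage sum from 2.
#' @return data.table keyed by subject and position.
#' @export
read_local_ancestry <- function(path, sum_tol = 1e-3) {
  la <- fread(path, sep = "\t", na.strings = "NA")
  need <- c("subject_id", "marker_id", "pos", "dos_afr", "dos_eas", "dos_eur")
  if (!all(need %in% names(la))) {
    stop("local-ancestry table lacks column(s): ",
         paste(setdiff(need, names(la)), collapse = ", "))
  }
  d <- as.matrix(la[, .(dos_afr, dos_eas, dos_eur)])
  if (any(d < 0) || any(d > 2)) stop("dosages must lie in [0, 2]")
  if (any(abs(rowSums(d) - 2) > sum_tol)) {
    stop("per-marker dosages must sum to 2 within ", sum_tol)
  }
  setorder(la, subject_id, pos)
  la[]
}

#' Read and cross-validate the three cohort input files
#'
#' @param vcf_path,pheno_path,la_path Input files.
#' @param call_threshold Posterior threshold for hard-calling.
#' @return list: `genotypes`, `phenotypes`, `la`; errors if subject ids
#'   disagree across files.
#' @export
read_cohort <- function(vcf_path, pheno_path, la_path, call_threshold = 0.7) {
  gt <- read_genotypes(vcf_path, call_threshold = call_threshold)
  ph <- read_phenotypes(pheno_path)
  la <- read_local_ancestry(la_path)
  if (!setequal(gt$subject_id, ph$subject_id) ||
      !setequal(ph$subject_id, unique(la$subject_id))) {
    stop("subject ids disagree across the three input files")
  }
  list(genotypes = gt, phenotypes = ph, la = la)
}
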