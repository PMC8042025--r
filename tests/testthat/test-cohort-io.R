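test_that("best-guess calling keeps confident argmax calls and drops the rest", {
  expect_identical(best_guess(c(1, 0, 0)), 0L)
  expect_identical(best_guess(c(0.1, 0.2, 0.7)), 2L)  # inclusive at threshold
  expect_identical(best_guess(c(0.5, 0.4, 0.1)), NA_integer_)
  expect_identical(best_guess(c(0.4, 0.4, 0.2), threshold = 0.3),
                   NA_integer_)  # exact tie goes missing
  expect_error(best_guess(c(0.5, 0.5)), "three")
  expect_error(best_guess(c(0.9, 0.3, 0.1)), "sum to 1")
})

test_that("best-guess is invariant to renormalised re-encoding of the simplex", {
  set.seed(4)
  for (i in 1:50) {
    gp <- stats::rgamma(3, 1)
    gp <- gp / sum(gp)
    jitter <- gp * (1 + 5e-5)
    expect_identical(best_guess(gp), best_guess(jitter / sum(jitter)))
  }
})

test_that("phenotype classes follow the inclusive ANC thresholds", {
  expect_equal(as.character(define_phenotype(400)), "agranulocytosis")
  expect_equal(as.character(define_phenotype(500)), "agranulocytosis")
  expect_equal(as.character(define_phenotype(501)), "neutropenia_only")
  expect_equal(as.character(define_phenotype(1500)), "neutropenia_only")
  expect_equal(as.character(define_phenotype(2000)), "control")

  # clinical-judgement cases bypass ANC; annotation picks the stratum
  expect_equal(as.character(define_phenotype(NA, "1")), "neutropenia_only")
  expect_equal(as.character(define_phenotype(NA, "agran")), "agranulocytosis")
  expect_warning(ph <- define_phenotype(NA, "0"), "unclassifiable")
  expect_true(is.na(ph))
})

test_that("every classifiable subject lands in exactly one class and severity nests", {
  set.seed(8)
  anc <- c(stats::runif(200, 1, 5000), NA, NA)
  flag <- c(rep("0", 200), "1", "agran")
  ph <- define_phenotype(anc, flag)
  expect_false(anyNA(ph))
  expect_true(all(ph[!is.na(anc) & anc <= 500] == "agranulocytosis"))
  agran <- which(ph == "agranulocytosis")
  expect_true(all(is_neutropenia(ph)[agran]))
})

test_that("ancestry grouping applies the 80% fraction rule", {
  expect_equal(as.character(classify_ancestry_group(0.05, 0.05, 0.90)), "EUR")
  expect_equal(as.character(classify_ancestry_group(0.85, 0.10, 0.05)), "AFR")
  expect_equal(as.character(classify_ancestry_group(0.40, 0.30, 0.30)),
               "admixed")
  expect_equal(as.character(classify_ancestry_group(0.80, 0.15, 0.05)), "AFR")
  expect_error(classify_ancestry_group(0.5, 0.2, 0.2), "sum to 1")
})

test_that("HWE exact test matches the enumeration oracle", {
  cases <- list(c(25, 50, 25), c(998, 0, 2), c(80, 15, 5), c(50, 10, 40),
                c(90, 9, 1), c(3, 5, 2))
  for (cc in cases) {
    expect_equal(hwe_exact_test(cc[1], cc[2], cc[3]),
                 hwe_oracle(cc[1], cc[2], cc[3]), tolerance = 1e-10,
                 info = paste(cc, collapse = "/"))
  }
  set.seed(12)
  for (i in 1:40) {
    n <- sample(10:200, 1)
    g <- as.vector(stats::rmultinom(1, n, prob = c(0.5, 0.35, 0.15)))
    expect_equal(hwe_exact_test(g[1], g[2], g[3]),
                 hwe_oracle(g[1], g[2], g[3]), tolerance = 1e-10)
  }
})

test_that("variant QC applies the missingness, MAF and HWE filters", {
  # balanced common variant in equilibrium: passes everything
  g <- rep(c(0L, 1L, 2L), c(25, 50, 25))
  r <- variant_qc(g)
  expect_true(r$pass)
  expect_equal(r$maf, 0.5)
  expect_gte(r$hwe_p, 0.9)

  # 20% missing fails the geno filter
  g2 <- c(rep(c(0L, 1L), c(70, 10)), rep(NA_integer_, 20))
  r2 <- variant_qc(g2)
  expect_false(r2$pass)
  expect_match(r2$fails, "geno")

  # gross heterozygote deficit fails HWE below 1e-5
  g3 <- rep(c(0L, 1L, 2L), c(998, 0, 2))
  r3 <- variant_qc(g3)
  expect_false(r3$pass)
  expect_match(r3$fails, "hwe")
  expect_lt(r3$hwe_p, 1e-5)

  # rare variant fails MAF
  r4 <- variant_qc(rep(c(0L, 1L), c(999, 1)))
  expect_match(r4$fails, "maf")
  expect_error(variant_qc(rep(NA_integer_, 5)), "non-missing")
})

test_that("genotype class counts ignore missing calls", {
  expect_equal(genotype_class_count(rep(NA_integer_, 4), 2), 0)
  expect_equal(genotype_class_count(c(0L, 1L, 2L, 2L, NA), 2), 2)
  co <- small_cohort(n = 200, seed = 13,
                     p_risk_by_ancestry = c(afr = 0.2, eas = 0.2, eur = 0.2))
  expect_equal(genotype_class_count(co$genotypes$hard_call, 2),
               sum(co$truth$g_true == 2))
})

test_that("carrier table tallies strata and reproduces the carrier proportion", {
  # no carriers anywhere
  ph <- define_phenotype(c(2000, 2000, 400))
  grp <- classify_ancestry_group(c(0, 0.9, 0.3), c(0.05, 0.05, 0.3),
                                 c(0.95, 0.05, 0.4))
  ct <- carrier_table(c(0L, 0L, 0L), ph, grp)
  expect_true(all(ct$counts$carriers == 0))
  expect_equal(ct$totals$carrier_prop, 0)

  # planted strata: 2 EUR-case carriers, 1 AFR-control carrier, 1 missing
  hard <- c(1L, 2L, 1L, 0L, NA)
  ph2 <- define_phenotype(c(400, 1200, 2000, 2000, 2000))
  grp2 <- factor(c("EUR", "EUR", "AFR", "EUR", "admixed"),
                 levels = c("EUR", "AFR", "admixed"))
  ct2 <- carrier_table(hard, ph2, grp2)
  cdf <- ct2$counts
  expect_equal(cdf$carriers[cdf$group == "EUR" &
                            cdf$phenotype == "agranulocytosis"], 1)
  expect_equal(cdf$carriers[cdf$group == "AFR" & cdf$phenotype == "control"], 1)
  expect_equal(cdf$missing[cdf$group == "admixed" &
                           cdf$phenotype == "control"], 1)

  # 68 carriers among 1566 called subjects -> 4.3%
  hard3 <- rep(c(1L, 0L), c(68, 1498))
  ph3 <- define_phenotype(rep(2000, 1566))
  grp3 <- factor(rep("EUR", 1566), levels = c("EUR", "AFR", "admixed"))
  ct3 <- carrier_table(hard3, ph3, grp3)
  expect_equal(ct3$totals$n_called, 1566)
  expect_equal(round(100 * ct3$totals$carrier_prop, 1), 4.3)
})

test_that("the one-site VCF round-trips calls, probabilities and missingness", {
  g <- data.frame(
    subject_id = sprintf("P%02d", 1:5),
    gp0 = c(1, 0, 0, 0.5, 0.2), gp1 = c(0, 1, 0.15, 0.4, 0.5),
    gp2 = c(0, 0, 0.85, 0.1, 0.3),
    hard_call = c(0L, 1L, 2L, NA, NA)
  )
  f <- file.path(tempdir(), "roundtrip.vcf")
  write_focal_vcf(g, 32629000, f)
  back <- read_genotypes(f)
  expect_equal(back$subject_id, g$subject_id)
  expect_equal(back$hard_call, g$hard_call)
  expect_equal(back$gp1, g$gp1, tolerance = 1e-4)
  expect_equal(back$pos[1], 32629000)
  expect_equal(back$risk_allele[1], "G")

  # risk allele on the REF side flips the counts
  ref <- read_genotypes(f, risk_allele = "REF")
  expect_equal(ref$hard_call, 2L - g$hard_call)
  expect_equal(ref$risk_allele[1], "C")
})

test_that("cohort readers validate structure and cross-file consistency", {
  co <- small_cohort(n = 40, seed = 19)
  d <- file.path(tempdir(), "io_validate")
  paths <- emit_cohort(co, d)
  inp <- read_cohort(paths[["vcf"]], paths[["pheno"]], paths[["la"]])
  expect_setequal(inp$genotypes$subject_id, inp$phenotypes$subject_id)

  # corrupt the phenotype table: drop a subject
  ph <- data.table::fread(paths[["pheno"]])
  data.table::fwrite(ph[-1], file.path(d, "bad.tsv"), sep = "\t", na = "NA",
                     quote = FALSE)
  expect_error(read_cohort(paths[["vcf"]], file.path(d, "bad.tsv"),
                           paths[["la"]]), "disagree")

  # dosages violating the simplex tolerance are rejected
  la <- data.table::fread(paths[["la"]])
  la$dos_afr[1] <- la$dos_afr[1] + 0.5
  data.table::fwrite(la, file.path(d, "bad_la.tsv"), sep = "\t", na = "NA",
                     quote = FALSE)
  expect_error(read_local_ancestry(file.path(d, "bad_la.tsv")), "sum to 2")
})
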