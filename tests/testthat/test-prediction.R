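test_that("risk classification follows the carrier and ancestry rules", {
  # any carrier is high risk under either rule
  expect_equal(as.character(classify_risk(1, 0.2, 0.8, "genotype_only")),
               "high_risk")
  expect_equal(as.character(classify_risk(1, 0.2, 0.8, "genotype_plus_lae")),
               "high_risk")
  # non-carrier with AFR excess is promoted only under the extended rule
  expect_equal(as.character(classify_risk(0, 0.6, 0.4, "genotype_only")),
               "low_risk")
  expect_equal(as.character(classify_risk(0, 0.6, 0.4, "genotype_plus_lae")),
               "high_risk")
  # an exact AFR/EAS tie stays low risk
  expect_equal(as.character(classify_risk(0, 0.5, 0.5, "genotype_plus_lae")),
               "low_risk")
  expect_true(is.na(classify_risk(NA, 0.5, 0.5, "genotype_only")))
  expect_error(classify_risk(0, rule = "genotype_plus_lae"), "requires")
})

test_that("confusion matrices tally the chosen case definition", {
  ph <- define_phenotype(c(400, 1200, 2000, 2000, 450, 3000))
  pred <- factor(c("high_risk", "low_risk", "low_risk", "high_risk",
                   "low_risk", "low_risk"),
                 levels = c("low_risk", "high_risk"))
  cm_n <- confusion_matrix(pred, ph, "neutropenia")
  expect_equal(unlist(cm_n[c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 1, fn = 2, tn = 2))
  # agranulocytosis: the neutropenia-only subject leaves the tally,
  # controls stay
  cm_a <- confusion_matrix(pred, ph, "agranulocytosis")
  expect_equal(unlist(cm_a[c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 1, fn = 1, tn = 2))
  expect_equal(cm_a$n_excluded, 1)

  # all predicted low: no positives at all
  all_low <- factor(rep("low_risk", 6), levels = c("low_risk", "high_risk"))
  cm0 <- confusion_matrix(all_low, ph, "neutropenia")
  expect_equal(cm0$tp + cm0$fp, 0)
})

test_that("prevalence recalibration reproduces the published predictive metrics", {
  # genotype-only neutropenia column
  rc <- recalibrate(15 / 133, 838 / 868, 0.038)
  expect_equal(round(rc$risk_high, 4), 0.1142)
  expect_equal(round(rc$risk_low, 4), 0.0350)
  expect_equal(round(rc$rr, 4), 0.3328)
  expect_equal(round(rc$ppv_adj, 4), 0.1142)
  expect_equal(round(rc$npv_adj, 4), 0.9650)

  # perfect specificity forces PPV to 1
  expect_equal(recalibrate(0.3, 1, 0.01)$ppv_adj, 1)

  # at the sample case fraction the adjusted PPV equals the raw PPV
  rc2 <- recalibrate(15 / 133, 838 / 868, 133 / 1001)
  expect_equal(rc2$ppv_adj, 15 / 45, tolerance = 1e-12)

  expect_error(recalibrate(0.5, 0.9, 0), "\\(0, 1\\)")
})

test_that("recalibration identities hold over random confusion matrices", {
  set.seed(101)
  for (i in 1:100) {
    m <- sample(5:200, 4, replace = TRUE)  # tp, fp, fn, tn
    sens <- m[1] / (m[1] + m[3])
    spec <- m[4] / (m[4] + m[2])
    frac <- (m[1] + m[3]) / sum(m)
    rc <- recalibrate(sens, spec, frac)
    expect_equal(rc$ppv_adj, m[1] / (m[1] + m[2]), tolerance = 1e-12)
    expect_equal(rc$npv_adj, m[4] / (m[4] + m[3]), tolerance = 1e-12)
    # informative tests widen the risk spread around the prevalence
    if (sens + spec > 1) {
      p <- 0.02
      rc2 <- recalibrate(sens, spec, p)
      expect_gt(rc2$risk_high, p)
      expect_lt(rc2$risk_low, p)
    }
  }
})

test_that("the required-sensitivity bound matches its closed form and inverts risk_low", {
  expect_equal(round(100 * required_sensitivity(0.0013, 0.009), 1), 85.7)

  # round-trip: recalibrate at spec = 1 returns the acceptable risk
  for (r in c(0.0005, 0.0013, 0.004)) {
    s <- required_sensitivity(r, 0.009)
    expect_equal(recalibrate(s, 1, 0.009)$risk_low, r, tolerance = 1e-12)
  }

  # numeric root-finder oracle at acceptable_risk = p / 2
  p <- 0.009
  s_closed <- required_sensitivity(p / 2, p)
  s_root <- stats::uniroot(function(s) recalibrate(s, 1, p)$risk_low - p / 2,
                           c(1e-6, 1 - 1e-6), tol = 1e-12)$root
  expect_equal(s_closed, s_root, tolerance = 1e-9)

  # limits: tiny acceptable risk needs near-perfect sensitivity
  expect_gt(required_sensitivity(1e-8, 0.009), 0.999)
  expect_warning(s0 <- required_sensitivity(0.02, 0.009), "suffices")
  expect_equal(s0, 0)

  # general-specificity inversion agrees with a root-finder too
  s_gen <- required_sensitivity(0.0013, 0.009, spec = 0.95)
  s_gen_root <- stats::uniroot(
    function(s) recalibrate(s, 0.95, 0.009)$risk_low - 0.0013,
    c(1e-6, 1 - 1e-6), tol = 1e-12)$root
  expect_equal(s_gen, s_gen_root, tolerance = 1e-9)
})

test_that("the characteristics table reproduces the published columns at 4 dp", {
  # build subjects matching the printed confusion counts, genotype rule
  ph <- define_phenotype(c(rep(400, 54), rep(1000, 79), rep(2000, 868)))
  hard <- integer(1001)
  afr <- eas <- numeric(1001)
  # 15 carrier cases (9 with agranulocytosis), 30 carrier controls
  hard[c(1:9, 55:60)] <- 1L
  hard[134 + (1:30)] <- 1L
  tab <- suppressMessages(characteristics_table(hard, afr, eas, ph))
  gn <- tab[tab$rule == "genotype_only" &
            tab$case_definition == "neutropenia", ]
  expect_equal(unlist(gn[c("tp", "fp", "fn", "tn")], use.names = FALSE),
               c(15, 30, 118, 838))
  expect_equal(round(gn$sensitivity, 4), 0.1128)
  expect_equal(round(gn$specificity, 4), 0.9654)
  expect_equal(round(gn$risk_high, 4), 0.1142)
  expect_equal(round(gn$risk_low, 4), 0.0350)
  expect_equal(round(gn$rr, 4), 0.3328)

  ga <- tab[tab$rule == "genotype_only" &
            tab$case_definition == "agranulocytosis", ]
  expect_equal(unlist(ga[c("tp", "fp", "fn", "tn")], use.names = FALSE),
               c(9, 30, 45, 838))
  expect_equal(round(ga$sensitivity, 4), 0.1667)
  expect_equal(round(ga$risk_high, 4), 0.0420)
  expect_equal(round(ga$npv_adj, 4), 0.9922)
  expect_equal(round(ga$rr, 4), 0.2145)
})

test_that("a perfect classifier yields degenerate characteristics", {
  ph <- define_phenotype(c(rep(300, 10), rep(3000, 40)))
  hard <- rep(c(1L, 0L), c(10, 40))
  tab <- suppressMessages(
    characteristics_table(hard, numeric(50), numeric(50), ph,
                          rules = "genotype_only",
                          case_definitions = "agranulocytosis"))
  expect_equal(tab$sensitivity, 1)
  expect_equal(tab$specificity, 1)
  expect_equal(tab$risk_low, 0)
})

test_that("widening the rule never loses sensitivity nor gains specificity", {
  set.seed(202)
  for (i in 1:20) {
    n <- 300
    hard <- sample(0:2, n, replace = TRUE, prob = c(0.9, 0.08, 0.02))
    afr <- stats::runif(n, 0, 1.5)
    eas <- stats::runif(n, 0, 1.5)
    ph <- define_phenotype(sample(c(300, 1000, 3000), n, replace = TRUE,
                                  prob = c(0.05, 0.1, 0.85)))
    if (!any(is_neutropenia(ph)) || !any(ph == "control")) next
    tab <- suppressMessages(characteristics_table(
      hard, afr, eas, ph, case_definitions = "neutropenia"))
    g <- tab[tab$rule == "genotype_only", ]
    l <- tab[tab$rule == "genotype_plus_lae", ]
    expect_gte(l$sensitivity, g$sensitivity)
    expect_lte(l$specificity, g$specificity)
  }
})
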