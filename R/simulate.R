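#' @import data.table
NULL

# Dirichlet draw, one row per subject, columns in params$pops order.
rdirichlet_rows <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate ancestry tract mosaics for a cohort
#'
#' Each haplotype is tiled by ancestry tracts from a homogeneous
#' (memoryless) switch process: switch points arrive as a Poisson process
#' with intensity `switch_rate` per Mb, and the ancestral population of each
#' tract is drawn independently from the subject's global ancestry
#' proportions. Consecutive tracts may therefore share a label; switch
#' points are process events, not guaranteed label changes.
#'
#' Uses the current RNG stream: call `set.seed()` first (or use
#' [simulate_cohort()], which seeds once and draws in a documented order).
#'
#' @param params A [sim_params()] object.
#' @param global_props Optional `n_subjects x K` matrix of per-subject
#'   global ancestry proportions (rows on the simplex). Drawn from
#'   `Dirichlet(global_props_alpha)` when `NULL`.
#' @return A `data.table` of class `tract_set` with columns `subject_id`,
#'   `hap` (1/2), `start`, `end` (1-based closed, tiling the region), `pop`;
#'   attribute `global_props` carries the proportions used.
#' @export
simulate_tracts <- function(params, global_props = NULL) {
  validate_sim_params(params)
  n <- params$n_subjects
  K <- params$K
  if (is.null(global_props)) {
    global_props <- rdirichlet_rows(n, params$global_props_alpha)
  }
  stopifnot(nrow(global_props) == n, ncol(global_props) == K)
  if (any(abs(rowSums(global_props) - 1) > 1e-9)) {
    stop("global_props rows must sum to 1")
  }

  H <- 2L * n
  L_bp <- params$region_end - params$region_start
  lambda <- params$switch_rate * L_bp / 1e6
  n_sw <- stats::rpois(H, lambda)
  total <- sum(n_sw)
  hap_of_sw <- rep.int(seq_len(H), n_sw)
  sw_pos <- round(stats::runif(total, params$region_start, params$region_end))
  # keep breakpoints strictly inside the region; duplicates collapse
  keep <- sw_pos > params$region_start & sw_pos < params$region_end
  sw <- data.table(hid = hap_of_sw[keep], bp = sw_pos[keep])
  sw <- unique(sw)
  setorder(sw, hid, bp)

  n_tr <- rep.int(1L, H)
  if (nrow(sw)) {
    tab <- sw[, .N, by = hid]
    n_tr[tab$hid] <- tab$N + 1L
  }
  hid <- rep.int(seq_len(H), n_tr)
  # per-haplotype tract bounds from the ordered breakpoints
  starts <- ends <- numeric(length(hid))
  first <- cumsum(n_tr) - n_tr + 1L
  starts[first] <- params$region_start
  ends[cumsum(n_tr)] <- params$region_end
  if (nrow(sw)) {
    brk_idx <- setdiff(seq_along(hid), first)       # rows whose start is a break+1
    starts[brk_idx] <- sw$bp + 1
    ends[setdiff(seq_along(hid), cumsum(n_tr))] <- sw$bp
  }

  subj <- (hid + 1L) %/% 2L
  # tract labels: iid from the subject's global proportions
  cum <- global_props %*% upper.tri(diag(K), diag = TRUE)
  u <- stats::runif(length(hid))
  lab <- rep.int(1L, length(hid))
  for (k in seq_len(K - 1L)) lab <- lab + (u > cum[subj, k])

  tr <- data.table(
    subject_id = sprintf("S%04d", subj),
    hap = ((hid - 1L) %% 2L) + 1L,
    start = starts, end = ends,
    pop = params$pops[lab]
  )
  setattr(tr, "global_props", global_props)
  setattr(tr, "class", c("tract_set", class(tr)))
  tr[]
}

#' Local-ancestry dosage at given positions
#'
#' Counts, per subject and position, how many of the two haplotypes derive
#' from each ancestral population (integer dosages summing to 2).
#'
#' @param tracts A `tract_set` from [simulate_tracts()].
#' @param positions Base-pair positions inside the simulated region.
#' @param pops Population labels, fixing column order.
#' @return `data.table` with `subject_id`, `pos`, and one `dos_<pop>`
#'   column per population.
#' @export
local_dosage <- function(tracts, positions, pops = c("afr", "eas", "eur")) {
  stopifnot(length(positions) >= 1)
  tr <- as.data.table(tracts)[, .(subject_id, hap, start = as.numeric(start),
                                  end = as.numeric(end), pop)]
  tr[, hid := rleid(subject_id, hap)]
  setkey(tr, hid, start)
  # tracts tile each haplotype, so the covering tract is the last one
  # starting at or before the query position: a rolling join per haplotype
  q <- CJ(hid = unique(tr$hid), start = as.numeric(positions))
  q[, pos := start]
  hits <- tr[q, roll = TRUE]
  if (anyNA(hits$pop) || any(hits$end < hits$pos)) {
    stop("positions must lie inside the tract region")
  }
  out <- dcast(hits, subject_id + pos ~ factor(pop, levels = pops),
               fun.aggregate = length, value.var = "hap",
               drop = c(TRUE, FALSE))
  setnames(out, as.character(pops), paste0("dos_", pops))
  setorder(out, subject_id, pos)
  out[]
}

# population of each haplotype at one position
hap_pop_at <- function(tracts, pos) {
  tr <- as.data.table(tracts)
  hit <- tr[start <= pos & end >= pos]
  setorder(hit, subject_id, hap)
  hit[, .(subject_id, hap, pop)]
}

#' Assign focal-variant genotypes given local ancestry
#'
#' Each haplotype carries the risk allele with the probability configured
#' for its ancestral population at the focal position, coupling the allele
#' to (by default) an East-Asian haplotype background. Genotype
#' probabilities are emitted as a point mass on the true genotype unless a
#' miscall rate is set, in which case a fraction of triplets is blurred
#' toward the simplex interior (so some hard calls fall below the
#' confidence threshold and go missing).
#'
#' @param tracts A `tract_set`.
#' @param params A [sim_params()] object.
#' @return `data.table` with `subject_id`, `variant_id`, `g_true`,
#'   `gp0`, `gp1`, `gp2`, `hard_call`, `risk_allele`.
#' @export
assign_focal_genotypes <- function(tracts, params) {
  if (params$focal_pos < params$region_start ||
      params$focal_pos > params$region_end) {
    stop("focal_pos outside simulated region")
  }
  hp <- hap_pop_at(tracts, params$focal_pos)
  pr <- params$p_risk_by_ancestry
  if (is.null(names(pr))) names(pr) <- params$pops
  hp[, carries := stats::runif(.N) < pr[pop]]
  g <- hp[, .(g_true = sum(carries)), by = subject_id]

  n <- nrow(g)
  gp <- matrix(0, n, 3)
  gp[cbind(seq_len(n), g$g_true + 1L)] <- 1
  if (params$call_miscall_rate > 0) {
    blur <- stats::runif(n) < params$call_miscall_rate
    if (any(blur)) {
      noise <- rdirichlet_rows(sum(blur), c(1, 1, 1))
      gp[blur, ] <- (gp[blur, , drop = FALSE] + noise) / 2
    }
  }
  out <- data.table(
    subject_id = g$subject_id, variant_id = "rs_focal",
    g_true = g$g_true,
    gp0 = gp[, 1], gp1 = gp[, 2], gp2 = gp[, 3],
    risk_allele = "G"
  )
  out[, hard_call := best_guess_vec(gp0, gp1, gp2)]
  out[]
}

#' Simulate phenotype (case status) and absolute neutrophil counts
#'
#' Case status follows a logistic liability model:
#' `logit p = beta0 + beta_G * G + beta_LA * nd * [G == 0]`, where `nd` is
#' the AFR-vs-EAS normed difference of true local-ancestry dosages averaged
#' over the 1 kb window around the focal variant. ANC is then drawn
#' conditional on status: controls from a log-normal truncated above the
#' neutropenia threshold; cases from a two-band mixture (agranulocytosis
#' band, uniform on (0, agran_threshold]; neutropenia band, uniform on
#' (agran_threshold, neut_threshold]), with the agranulocytosis weight
#' shifted on the log-odds scale per risk-allele copy so carrier cases skew
#' severe. A configurable fraction of cases is recorded by clinical
#' judgement (ANC missing, flag set); a fraction of controls has ANC
#' unrecorded.
#'
#' @param genotypes Output of [assign_focal_genotypes()].
#' @param tracts A `tract_set`.
#' @param params A [sim_params()] object.
#' @return list with `subjects` (phenotype/covariate table in the emitted
#'   TSV layout) and `truth` (`subject_id`, `case`, `g_true`, `normdiff`).
#' @export
simulate_phenotype_anc <- function(genotypes, tracts, params) {
  win_pos <- params$focal_pos + c(-1000, -500, 0, 500, 1000)
  win_pos <- win_pos[win_pos >= params$region_start &
                     win_pos <= params$region_end]
  dos <- local_dosage(tracts, win_pos, params$pops)
  win <- dos[, .(afr = mean(dos_afr), eas = mean(dos_eas)), by = subject_id]
  win[, nd := fifelse(afr + eas > 0, (afr - eas) / (afr + eas), 0)]

  gt <- as.data.table(genotypes)[win, on = "subject_id"]
  stopifnot(!anyNA(gt$g_true))
  eta <- params$beta0 + params$beta_G * gt$g_true +
    params$beta_LA * gt$nd * (gt$g_true == 0)
  case <- stats::runif(nrow(gt)) < stats::plogis(eta)

  ap <- params$anc_params
  n <- nrow(gt)
  anc <- numeric(n)
  # controls: truncated log-normal above the neutropenia threshold
  ctl <- which(!case)
  todo <- ctl
  while (length(todo)) {
    draw <- stats::rlnorm(length(todo), ap$control_meanlog, ap$control_sdlog)
    anc[todo] <- draw
    todo <- todo[draw <= params$neut_threshold]
  }
  # cases: severity band then uniform within band
  cs <- which(case)
  w_agran <- stats::plogis(stats::qlogis(ap$p_agran) +
                           ap$agran_shift * gt$g_true[cs])
  in_agran <- stats::runif(length(cs)) < w_agran
  anc[cs[in_agran]] <- stats::runif(sum(in_agran), 0, params$agran_threshold)
  anc[cs[!in_agran]] <- stats::runif(sum(!in_agran), params$agran_threshold,
                                     params$neut_threshold)
  anc <- round(anc)
  anc[anc == 0] <- 1

  clinical <- rep("0", n)
  cl_case <- cs[stats::runif(length(cs)) < ap$p_clinical]
  if (length(cl_case)) {
    anc[cl_case] <- NA_real_
    is_agran <- stats::runif(length(cl_case)) < ap$p_clinical_agran
    clinical[cl_case] <- ifelse(is_agran, "agran", "1")
  }
  ctl_missing <- ctl[stats::runif(length(ctl)) < ap$p_control_anc_missing]
  anc[ctl_missing] <- NA_real_

  gp <- attr(tracts, "global_props")
  props <- as.data.table(gp)
  setnames(props, paste0("frac_", params$pops))
  # PCs loosely track global ancestry (PC1 ~ AFR, PC2 ~ EAS), as in a
  # supervised-admixture + EIGENSTRAT workflow
  pc1 <- as.vector(scale(gp[, 1])) + stats::rnorm(n, sd = 0.5)
  pc2 <- as.vector(scale(gp[, 2])) + stats::rnorm(n, sd = 0.5)
  other <- matrix(stats::rnorm(n * 5), n)

  subjects <- data.table(
    subject_id = gt$subject_id,
    anc = anc,
    clinical_case = clinical,
    sex = sample(1:2, n, replace = TRUE),
    age = pmin(pmax(round(stats::rnorm(n, 40, 12)), 18), 90),
    pc1 = pc1, pc2 = pc2,
    pc3 = other[, 1], pc4 = other[, 2], pc5 = other[, 3],
    pc6 = other[, 4], pc7 = other[, 5]
  )
  subjects <- cbind(subjects, props)
  subjects[, site := sample(paste0("site_", LETTERS[1:3]), n, replace = TRUE)]

  truth <- data.table(subject_id = gt$subject_id, case = case,
                      g_true = gt$g_true, normdiff = gt$nd)
  list(subjects = subjects[], truth = truth[])
}

#' Simulate a complete synthetic cohort
#'
#' Seeds the RNG once from `params$seed` and draws, in order: global
#' ancestry proportions, ancestry tracts, focal genotypes, case status and
#' ANC (with covariates), then measurement noise on the emitted
#' local-ancestry dosages. Emitted dosages are true integer dosages plus
#' Gaussian noise, clipped to `[0, 2]` and renormalised to sum to 2,
#' emulating HMM-estimated dosages.
#'
#' @param params A [sim_params()] object.
#' @return list of class `synthetic_cohort`: `params`, `markers`, `tracts`,
#'   `genotypes`, `subjects`, `truth`, `la` (emitted long-format dosage
#'   table).
#' @export
simulate_cohort <- function(params) {
  validate_sim_params(params)
  set.seed(params$seed)
  tracts <- simulate_tracts(params)
  genotypes <- assign_focal_genotypes(tracts, params)
  ph <- simulate_phenotype_anc(genotypes, tracts, params)

  mk <- marker_map(params)
  dos <- local_dosage(tracts, mk$pos, params$pops)
  dos <- merge(dos, as.data.table(mk), by = "pos")
  dcols <- paste0("dos_", params$pops)
  if (params$dosage_noise_sd > 0) {
    m <- as.matrix(dos[, ..dcols])
    m <- pmin(pmax(m + stats::rnorm(length(m), sd = params$dosage_noise_sd), 0), 2)
    m <- 2 * m / rowSums(m)
    for (j in seq_along(dcols)) set(dos, j = dcols[j], value = round(m[, j], 6))
  }
  la <- dos[, c("subject_id", "marker_id", "pos", dcols), with = FALSE]
  setorder(la, subject_id, pos)

  structure(
    list(params = params, markers = mk, tracts = tracts,
         genotypes = genotypes, subjects = ph$subjects, truth = ph$truth,
         la = la),
    class = "synthetic_cohort"
  )
}

#' Write a synthetic cohort to disk
#'
#' Emits the three pipeline input files — a one-site VCF 4.2 (GT and GP),
#' the phenotype/covariate TSV and the long-format local-ancestry TSV — plus
#' a JSON sidecar with the generating parameters and per-subject truth for
#' recovery tests. Output is byte-stable for a fixed-seed cohort.
#'
#' @param cohort A `synthetic_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of file paths.
#' @export
emit_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             pheno = file.path(out_dir, "phenotypes.tsv"),
             la = file.path(out_dir, "local_ancestry.tsv"),
             sidecar = file.path(out_dir, "truth.json"))

  write_focal_vcf(cohort$genotypes, cohort$params$focal_pos, paths[["vcf"]])

  ph <- copy(cohort$subjects)
  num <- c("pc1", "pc2", "pc3", "pc4", "pc5", "pc6", "pc7",
           "frac_afr", "frac_eas")
  for (j in num) set(ph, j = j, value = round(ph[[j]], 6))
  # last fraction as the complement so rows stay on the simplex after
  # 6-dp rounding
  set(ph, j = "frac_eur", value = round(1 - ph$frac_afr - ph$frac_eas, 6))
  fwrite(ph, paths[["pheno"]], sep = "\t", na = "NA", quote = FALSE)
  fwrite(cohort$la, paths[["la"]], sep = "\t", na = "NA", quote = FALSE)

  sidecar <- list(
    params = unclass(cohort$params),
    truth = cohort$truth
  )
  jsonlite::write_json(sidecar, paths[["sidecar"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
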