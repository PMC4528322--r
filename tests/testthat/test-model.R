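test_that("the design codes parent, lineage and their product per family", {
  # AE maternal cell with count 63: y = log2(64) = 6, P = L = +1/2, PL = +1/4
  rec <- count_fixture(n_snps = 1, reps_per_family = 1,
                       counts = c(63L, 20L, 63L, 20L))
  d <- build_design(rec)
  ae_m <- d[d$family == "AE" & d$P == 0.5, ]
  expect_equal(ae_m$y, 6)
  expect_equal(ae_m$L, 0.5)
  expect_equal(ae_m$PL, 0.25)
  # EA maternal: European mother, so L = -1/2 and PL = -1/4
  ea_m <- d[d$family == "EA" & d$P == 0.5, ]
  expect_equal(ea_m$L, -0.5)
  expect_equal(ea_m$PL, -0.25)
})

test_that("a 2-family, 2-replicate, 2-SNP design has 16 rows and PL is the family indicator", {
  rec <- count_fixture(n_snps = 2, reps_per_family = 2)
  d <- build_design(rec)
  expect_equal(nrow(d), 16L)
  expect_equal(d$PL, d$P * d$L)
  expect_true(all(d$PL[d$family == "AE"] == 0.25))
  expect_true(all(d$PL[d$family == "EA"] == -0.25))
  expect_equal(dplyr::n_distinct(d$cell_id), 8L)
})

test_that("noiseless designs recover the generating coefficients exactly", {
  rec <- count_fixture(n_snps = 2, reps_per_family = 2)
  d <- build_design(rec)
  beta <- c(intercept = 1, P = 1, L = 0.4, PL = -0.2)
  d$y <- beta["intercept"] + beta["P"] * d$P + beta["L"] * d$L + beta["PL"] * d$PL
  fit <- fit_transcript(d)
  co <- tidy(fit)
  expect_equal(co$estimate[co$term == "(Intercept)"], 1, tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "P"], 1, tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "L"], 0.4, tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "PL"], -0.2, tolerance = 1e-8)
  g <- glance(fit)
  expect_equal(g$sigma2_snp + g$sigma2_rep + g$sigma2_cell, 0)
  expect_lt(g$sigma2_resid, 1e-16)
  expect_true(g$degenerate)
  # zero-SE conventions: nonzero coefficients get p = 0, flagged fit
  expect_equal(co$p_value[co$term == "P"], 0)
})

test_that("a constant response gives zero slopes, zero variances, p = 1", {
  rec <- count_fixture(n_snps = 2, reps_per_family = 2, counts = rep(31L, 16))
  fit <- fit_transcript(build_design(rec))
  co <- tidy(fit)
  expect_equal(co$estimate[co$term %in% c("P", "L", "PL")], rep(0, 3))
  expect_equal(co$p_value[co$term %in% c("P", "L", "PL")], rep(1, 3))
  expect_equal(unname(fit$varcomp[c("sigma2_snp", "sigma2_rep", "sigma2_cell")]),
               rep(0, 3))
})

test_that("Wald term tests match the chi-square(1) tail oracle and zero-SE conventions", {
  expect_equal(wald_p(0, 1), 1)
  # the 97.5% normal quantile gives p ~ 0.05
  z <- 1.959964
  expect_equal(wald_p(z, 1),
               pchisq(z^2, df = 1, lower.tail = FALSE))
  expect_equal(wald_p(z, 1), 0.05, tolerance = 1e-6)
  expect_equal(wald_p(3, 0), 0)   # infinite statistic by convention
  expect_equal(wald_p(0, 0), 1)
})

test_that("Benjamini-Hochberg q-values match hand and independent step-up computations", {
  fits <- tibble::tibble(
    transcript_id = paste0("t", 1:4), sample_group = "brains",
    p_P = c(0.01, 0.02, 0.03, 0.04), p_L = 1, p_PL = NA_real_)
  q <- adjust_fdr(fits)
  expect_equal(q$q_P, rep(0.04, 4))
  expect_equal(adjust_fdr(fits[1, ])$q_P, 0.01)

  single <- tibble::tibble(transcript_id = "t", sample_group = "larvae",
                           p_P = 0.049, p_L = 1, p_PL = 1)
  expect_equal(adjust_fdr(single)$q_P, 0.049)
  expect_equal(adjust_fdr(tibble::tibble(
    transcript_id = paste0("t", 1:3), sample_group = "adults",
    p_P = c(1, 1, 1), p_L = 1, p_PL = 1))$q_P, rep(1, 3))

  set.seed(31)
  p <- runif(200)
  rand <- tibble::tibble(transcript_id = paste0("t", 1:200),
                         sample_group = "brains", p_P = p, p_L = p, p_PL = p)
  expect_equal(adjust_fdr(rand)$q_P, bh_stepup(p))
  # q-values never fall below their p-values
  expect_true(all(adjust_fdr(rand)$q_P >= p))
})

test_that("single-family transcripts fall back to a parent-only fit with NA lineage terms", {
  rec <- count_fixture(n_snps = 2, reps_per_family = 2)
  rec <- rec[rec$family == "AE", ]
  rec$count <- c(40L, 9L, 45L, 11L, 38L, 10L, 42L, 12L)
  expect_warning(d <- build_design(rec), "single")
  fit <- suppressWarnings(fit_transcript(d))
  co <- tidy(fit)
  expect_true(fit$single_family)
  expect_gt(co$estimate[co$term == "P"], 1)
  expect_true(is.na(co$estimate[co$term == "L"]))
  expect_true(is.na(co$p_value[co$term == "PL"]))
})

test_that("degenerate inputs are refused with informative errors", {
  rec <- count_fixture(n_snps = 1, reps_per_family = 1, counts = rep(0L, 4))
  expect_error(fit_transcript(build_design(rec)), "zero")
  one_parent <- count_fixture(n_snps = 2, reps_per_family = 2)
  one_parent <- one_parent[one_parent$parent == "maternal", ]
  expect_error(fit_transcript(build_design(one_parent)), "maternal and paternal")
})

test_that("null transcripts produce approximately uniform parent p-values", {
  # Monte-Carlo calibration at the individual-brains design (3 + 3 libraries)
  cfg <- sim_config(n_transcripts = 200,
                    replicates = list(brains = c(AE = 3, EA = 3)), seed = 77)
  sim <- simulate_dataset(cfg)
  fits <- fit_psge(filter_counts(sim$counts))
  expect_equal(nrow(fits), 200L)
  rate <- mean(fits$p_P < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.08)
})

test_that("fit_psge returns one row per transcript-group with q-values attached", {
  sim <- simulate_dataset(sim_config(
    n_transcripts = 8, class_proportions = c(null = 0.5, maternal = 0.5),
    seed = 12))
  fits <- adjust_fdr(fit_psge(filter_counts(sim$counts)))
  expect_equal(nrow(fits), 8L * 3L)  # three sample groups
  expect_true(all(c("q_P", "q_L", "q_PL") %in% names(fits)))
  expect_true(all(fits$p_P >= 0 & fits$p_P <= 1, na.rm = TRUE))
  expect_true(all(fits$sigma2_resid >= 0))
  # strong maternal transcripts show large positive parent effects
  truth <- sim$truth
  strong <- fits$transcript_id %in% truth$transcript_id[truth$class == "maternal"]
  expect_gt(min(fits$estimate_P[strong]), 0.5)
})
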