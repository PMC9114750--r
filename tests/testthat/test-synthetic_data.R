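test_that("simulated studies satisfy roster invariants and size bounds", {
  d <- simulate_meta_dataset(sim_config(k = 40, true_log_or = 0.2,
                                        tau2 = 0.05, n_range = c(60, 300),
                                        seed = 801))
  expect_equal(nrow(d), 40)
  expect_silent(validate_studies(d))
  expect_true(all(has_genotype_counts(d)))
  expect_true(all(d$n_case >= 60 & d$n_case <= 300))
  expect_true(all(d$n_control >= 60 & d$n_control <= 300))
  truth <- attr(d, "truth")
  expect_equal(truth$study_id, d$study_id)
  expect_true(all(truth$q_control >= 0.25 & truth$q_control <= 0.70))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(k = 12, true_log_or = -0.1, tau2 = 0.02, seed = 802)
  d1 <- simulate_meta_dataset(cfg)
  d2 <- simulate_meta_dataset(cfg)
  expect_identical(d1, d2)
  expect_equal(nrow(simulate_meta_dataset(sim_config(k = 0, seed = 1))), 0)
})

test_that("null effect gives identical case and control genotype laws", {
  # theta = 0, f = 0: both arms draw from the same multinomial; empirical
  # genotype frequencies agree within Monte-Carlo error at large n
  cfg <- sim_config(k = 1, true_log_or = 0, n_range = c(200000, 200000),
                    allele_freq_range = c(0.4, 0.4), seed = 803)
  d <- simulate_meta_dataset(cfg)
  case_p <- as.numeric(d[1, c("case_AA", "case_AG", "case_GG")]) / d$n_case
  ctrl_p <- as.numeric(d[1, c("ctrl_AA", "ctrl_AG", "ctrl_GG")]) / d$n_control
  hw <- c(0.36, 0.48, 0.16)
  expect_equal(case_p, hw, tolerance = 0.01)
  expect_equal(ctrl_p, hw, tolerance = 0.01)
})

test_that("exponential tilting matches the closed-form case distribution", {
  # q = 0.5, theta = ln 2: case probabilities prop. to (0.25, 0.5*2, 0.25*4),
  # i.e. (1/9, 4/9, 4/9) after renormalization
  cfg <- sim_config(k = 1, true_log_or = log(2),
                    n_range = c(300000, 300000),
                    allele_freq_range = c(0.5, 0.5), seed = 804)
  d <- simulate_meta_dataset(cfg)
  case_p <- as.numeric(d[1, c("case_AA", "case_AG", "case_GG")]) / d$n_case
  expect_equal(case_p, c(1, 4, 4) / 9, tolerance = 0.01)
  # and the allelic estimand equals the generating log odds ratio
  eff <- study_effects(d, "allelic")
  expect_equal(eff$log_or, log(2), tolerance = 0.05)
})

test_that("inbreeding produces the expected heterozygote deficit", {
  f <- 0.15; q <- 0.3
  cfg <- sim_config(k = 1, true_log_or = 0, inbreeding_f = f,
                    n_range = c(300000, 300000),
                    allele_freq_range = c(q, q), seed = 805)
  d <- simulate_meta_dataset(cfg)
  het <- d$ctrl_AG / d$n_control
  expect_equal(2 * q * (1 - q) - het, f * 2 * q * (1 - q), tolerance = 0.05)
  # and the HWE screen detects the departure at this n
  expect_lt(d$hwe_p, 0.05)
})

test_that("HWE rejection is calibrated at alpha under exact equilibrium", {
  set.seed(806)
  reps <- 2000
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    q <- runif(1, 0.2, 0.8)
    counts <- as.vector(rmultinom(1, 500, c((1 - q)^2, 2 * q * (1 - q), q^2)))
    rej[r] <- hwe_chisq(counts)$p < 0.05
  }
  expect_gt(mean(rej), 0.025)
  expect_lt(mean(rej), 0.075)
})

test_that("the pipeline recovers the generating effect across conditions", {
  # smaller-scale version of the recovery grid: the chosen-model pooled
  # estimate is unbiased for the generating log odds ratio
  set.seed(807)
  for (theta in c(log(0.85), 0, log(1.5))) {
    for (tau2 in c(0, 0.05)) {
      reps <- 40
      est <- numeric(reps)
      for (r in seq_len(reps)) {
        d <- simulate_meta_dataset(sim_config(k = 25, true_log_or = theta,
                                              tau2 = tau2,
                                              n_range = c(100, 1000)))
        eff <- study_effects(d, "allelic")
        est[r] <- pool_effects(eff, fixed_estimator = "IV")$log_or
      }
      mc_se <- sd(est) / sqrt(reps)
      expect_lt(abs(mean(est) - theta), 4 * mc_se + 0.01)
    }
  }
})

test_that("selection bias filtering behaves at its extremes", {
  d <- simulate_meta_dataset(sim_config(k = 30, true_log_or = 0, seed = 808))
  cfg0 <- sim_config(k = 30, selection_prob = 0)
  expect_identical(apply_selection_bias(d, cfg0), d)
  cfg1 <- sim_config(k = 30, selection_prob = 1)
  kept <- apply_selection_bias(d, cfg1)
  eff <- study_effects(d, "allelic")
  p <- 2 * pnorm(-abs(eff$log_or) / sqrt(eff$var))
  expect_setequal(kept$study_id, d$study_id[p < 0.05])
  expect_equal(attr(kept, "truth")$study_id, kept$study_id)
})

test_that("simulated datasets round-trip through the TSV dialect", {
  d <- simulate_meta_dataset(sim_config(k = 8, true_log_or = 0.3, seed = 809))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_simulated(d, tmp)
  back <- read_study_table(tmp)
  expect_equal(back$study_id, d$study_id)
  expect_equal(back$case_AA, d$case_AA)
  expect_equal(back$ctrl_GG, d$ctrl_GG)
  expect_equal(back$hwe_p, d$hwe_p, tolerance = 1e-12)
  truth <- utils::read.delim(paste0(tmp, ".truth.tsv"))
  expect_equal(nrow(truth), 8)
})
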