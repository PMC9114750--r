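test_that("inverse-variance pooling matches hand arithmetic", {
  one <- iv_fixed(data.frame(study_id = "a", log_or = log(2), var = 0.25))
  expect_equal(one$log_or, log(2))
  expect_equal(one$se, 0.5)
  expect_equal(one$q, 0)
  expect_equal(one$p_q, 1)

  two <- iv_fixed(data.frame(study_id = c("a", "b"), log_or = c(0, 0.2),
                             var = c(0.04, 0.01)))
  expect_equal(two$log_or, 0.16)
  expect_equal(two$se, 1 / sqrt(125))
  expect_equal(two$q, 0.8)
  expect_equal(two$i2, 0)
  expect_equal(two$z, 0.16 * sqrt(125))
  expect_equal(two$p, 2 * pnorm(-0.16 * sqrt(125)))

  # n identical studies: same estimate, se shrinks by 1/sqrt(n)
  rep5 <- data.frame(study_id = letters[1:5], log_or = 0.3, var = 0.09)
  expect_equal(iv_fixed(rep5)$log_or, 0.3)
  expect_equal(iv_fixed(rep5)$se, 0.3 / sqrt(5))
  expect_error(iv_fixed(rep5[0, ]), "studies")
})

test_that("Mantel-Haenszel pooling is exact for shared stratum ORs", {
  expect_equal(mh_fixed(list(ct(10, 10, 5, 15), ct(20, 20, 10, 30)))$or, 3)
  # single stratum = crude OR
  expect_equal(mh_fixed(list(ct(12, 8, 6, 14)))$or, (12 * 14) / (8 * 6))
  # any strata sharing OR r pool to exactly r
  set.seed(404)
  for (i in 1:20) {
    r <- exp(rnorm(1, 0, 0.5))
    tabs <- lapply(1:4, function(j) {
      b <- runif(1, 5, 50); cc <- runif(1, 5, 50); d <- runif(1, 5, 50)
      ct(r * b * cc / d, b, cc, d)
    })
    expect_equal(mh_fixed(tabs)$or, r)
  }
})

test_that("Mantel-Haenszel log-OR variance matches the metafor oracle", {
  skip_if_not_installed("metafor")
  set.seed(405)
  ai <- c(10, 25, 40, 8); bi <- c(20, 15, 30, 22)
  ci <- c(12, 20, 22, 9); di <- c(18, 20, 40, 21)
  tabs <- lapply(1:4, function(i) ct(ai[i], bi[i], ci[i], di[i]))
  got <- mh_fixed(tabs)
  oracle <- metafor::rma.mh(ai = ai, bi = bi, ci = ci, di = di,
                            measure = "OR", correct = FALSE)
  expect_equal(got$log_or, as.numeric(oracle$beta), tolerance = 1e-12)
  expect_equal(got$se, oracle$se, tolerance = 1e-12)
})

test_that("Cochran's Q and I2 follow their definitions", {
  q1 <- cochran_q(data.frame(log_or = c(0, 1), var = c(0.1, 0.1)), 0.5)
  expect_equal(q1$q, 5)
  expect_equal(q1$p_q, pchisq(5, 1, lower.tail = FALSE))
  expect_equal(q1$i2, (5 - 1) / 5 * 100)

  same <- cochran_q(data.frame(log_or = rep(0.4, 4), var = 1:4 / 10), 0.4)
  expect_equal(same$q, 0)
  expect_equal(same$i2, 0)

  low <- cochran_q(data.frame(log_or = c(0, 0.2), var = c(0.04, 0.01)), 0.16)
  expect_equal(low$q, 0.8)
  expect_equal(low$i2, 0)
})

test_that("DerSimonian-Laird pooling recovers the moment estimator", {
  d <- dl_random(data.frame(study_id = c("a", "b"), log_or = c(0, 1),
                            var = c(0.1, 0.1)))
  expect_equal(d$tau2, 0.4)
  expect_equal(d$log_or, 0.5)
  expect_equal(d$se, 0.5)

  # collapse to fixed when Q <= k - 1
  eff <- data.frame(study_id = c("a", "b"), log_or = c(0, 0.2),
                    var = c(0.04, 0.01))
  f <- iv_fixed(eff); r <- dl_random(eff)
  expect_equal(r$tau2, 0)
  for (field in c("log_or", "se", "or", "ci_low", "ci_high", "z", "p", "q"))
    expect_identical(r[[field]], f[[field]])

  expect_equal(dl_random(data.frame(study_id = 1:3, log_or = 0.2,
                                    var = 0.05))$tau2, 0)
  expect_error(dl_random(eff[1, ]), "2 studies")
})

test_that("pooling is permutation-invariant, sign-equivariant, and random se dominates", {
  set.seed(505)
  for (i in 1:25) {
    eff <- make_effects(sample(3:12, 1))
    f <- iv_fixed(eff); r <- dl_random(eff)
    perm <- eff[sample(nrow(eff)), ]
    expect_equal(iv_fixed(perm)$log_or, f$log_or)
    expect_equal(dl_random(perm)[c("log_or", "se", "tau2")],
                 r[c("log_or", "se", "tau2")])
    expect_gte(r$se, f$se)
    neg <- eff; neg$log_or <- -neg$log_or
    fn <- iv_fixed(neg)
    expect_equal(fn$log_or, -f$log_or)
    expect_equal(fn$z, -f$z)
    expect_equal(fn$ci_low, 1 / f$ci_high)
    expect_equal(fn$ci_high, 1 / f$ci_low)
    expect_equal(fn$q, f$q)
  }
})

test_that("fixed and random pooling agree with metafor on random data", {
  skip_if_not_installed("metafor")
  set.seed(506)
  for (i in 1:20) {
    eff <- make_effects(sample(2:10, 1), sd = runif(1, 0.1, 0.8))
    f <- iv_fixed(eff); r <- dl_random(eff)
    mf <- metafor::rma(yi = eff$log_or, vi = eff$var, method = "FE")
    mr <- metafor::rma(yi = eff$log_or, vi = eff$var, method = "DL")
    expect_equal(f$log_or, as.numeric(mf$beta), tolerance = 1e-12)
    expect_equal(f$se, mf$se, tolerance = 1e-12)
    expect_equal(r$log_or, as.numeric(mr$beta), tolerance = 1e-12)
    expect_equal(r$tau2, mr$tau2, tolerance = 1e-12)
    expect_equal(r$q, mr$QE, tolerance = 1e-12)
  }
})

test_that("the model-selection rule is strict at the threshold", {
  expect_equal(select_model(0.371), "fixed")
  expect_equal(select_model(0.05), "random")
  expect_equal(select_model(1.0), "fixed")
  expect_equal(select_model(0.04), "random")
  expect_equal(select_model(0.06, alpha_het = 0.1), "random")
})

test_that("the Z-test matches the normal quantile identities", {
  expect_equal(z_test(0, 1), list(z = 0, p = 1))
  expect_equal(z_test(qnorm(0.975) * 0.3, 0.3)$p, 0.05)
  zt <- z_test(0.16, 1 / sqrt(125))
  expect_equal(zt$z, 0.16 * sqrt(125))
  expect_equal(round(zt$p, 4), 0.0736)
  expect_error(z_test(0.1, 0), "se")
})

test_that("pool_effects applies the heterogeneity-driven selection rule", {
  hom <- data.frame(study_id = c("a", "b"), log_or = c(0, 0.2),
                    var = c(0.04, 0.01))
  het <- data.frame(study_id = c("a", "b"), log_or = c(0, 1),
                    var = c(0.1, 0.1))
  expect_equal(pool_effects(hom, fixed_estimator = "IV")$method, "fixed_IV")
  expect_equal(pool_effects(het, fixed_estimator = "IV")$method, "random_DL")
  tabs <- list(ct(10, 10, 5, 15), ct(20, 20, 10, 30))
  eff <- do.call(rbind, lapply(seq_along(tabs), function(i)
    as.data.frame(unclass(study_odds_ratio(tabs[[i]],
                                           study_id = as.character(i))))))
  got <- pool_effects(eff, tables = tabs)
  expect_equal(got$method, "fixed_MH")
  expect_equal(got$or, 3)
  expect_error(pool_effects(eff, fixed_estimator = "MH"), "tables")
})
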