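test_that("SD/LD classification uses a closed lower segment at 13.5 h", {
  expect_equal(classify_sd_ld(c(12.4, 13.5, 14.5)), c("SD", "SD", "LD"))
  expect_equal(classify_sd_ld(12, threshold = 11), "LD")
  expect_error(classify_sd_ld(25), "0, 24")
})

test_that("latent adjustment subtracts control deviations per environment", {
  met <- data.frame(
    genotype_id = c("ctrl", "ctrl", "g1", "g1"),
    env_id = c("e1", "e2", "e1", "e2"),
    tt_em_ant = c(800, 840, 900, 1000))
  controls <- data.frame(set_id = "s1", genotype_id = "ctrl")
  adj <- latent_adjust(met, controls)
  # control means 800/840, overall 820 -> deviations -20/+20
  expect_equal(adj$deviations$deviation_cd, c(-20, 20))
  expect_equal(adj$met$tt_em_ant[adj$met$genotype_id == "g1"], c(920, 980))
  # controls are pinned at the overall mean
  expect_equal(adj$met$tt_em_ant[adj$met$genotype_id == "ctrl"], c(820, 820))
  # deviations sum to zero across the set's environments
  expect_equal(sum(adj$deviations$deviation_cd), 0)

  # identical controls across environments: adjustment is the identity
  met2 <- met
  met2$tt_em_ant[met2$genotype_id == "ctrl"] <- 810
  adj2 <- latent_adjust(met2, controls)
  expect_equal(adj2$met$tt_em_ant[adj2$met$genotype_id == "g1"],
               c(900, 1000))

  expect_error(
    latent_adjust(rbind(met, data.frame(genotype_id = "g1", env_id = "e3",
                                        tt_em_ant = 950)), controls),
    "e3")
})

test_that("noise-free controls invert injected environment offsets exactly", {
  set.seed(21)
  n_env <- 12
  lambda <- rnorm(n_env, 0, 40)
  lambda <- lambda - mean(lambda)
  envs <- sprintf("e%02d", seq_len(n_env))
  truth_target <- 850 + 55 * pmax(0, runif(n_env, 12, 16) - 13)
  met <- rbind(
    data.frame(genotype_id = "c1", env_id = envs, tt_em_ant = 700 + lambda),
    data.frame(genotype_id = "c2", env_id = envs, tt_em_ant = 760 + lambda),
    data.frame(genotype_id = "g1", env_id = envs,
               tt_em_ant = truth_target + lambda))
  controls <- data.frame(set_id = "s1", genotype_id = c("c1", "c2"))
  adj <- latent_adjust(met, controls)
  expect_equal(adj$met$tt_em_ant[adj$met$genotype_id == "g1"], truth_target,
               tolerance = 1e-12)
  expect_equal(adj$deviations$deviation_cd,
               lambda[match(adj$deviations$env_id, envs)], tolerance = 1e-12)
})

test_that("multiple control sets adjust their mapped environments independently", {
  met <- data.frame(
    genotype_id = c("c1", "c1", "c2", "c2", "g", "g", "g", "g"),
    env_id = c("e1", "e2", "e3", "e4", "e1", "e2", "e3", "e4"),
    tt_em_ant = c(700, 720, 600, 640, 900, 910, 920, 930))
  controls <- data.frame(set_id = c("s1", "s2"),
                         genotype_id = c("c1", "c2"))
  env_map <- data.frame(env_id = c("e1", "e2", "e3", "e4"),
                        set_id = c("s1", "s1", "s2", "s2"))
  adj <- latent_adjust(met, controls, env_map)
  expect_equal(adj$met$tt_em_ant[adj$met$genotype_id == "g"],
               c(900 + 10, 910 - 10, 920 + 20, 930 - 20))
  dev <- adj$deviations
  expect_equal(sum(dev$deviation_cd[dev$set_id == "s1"]), 0)
  expect_equal(sum(dev$deviation_cd[dev$set_id == "s2"]), 0)
  expect_error(latent_adjust(met, controls), "env_map")
})

test_that("noiseless bilinear data are recovered exactly by the hinge fit", {
  dls <- c(11.5, 12, 12.5, 13, 13.5, 14, 15, 16)
  tt <- 800 + 50 * pmax(0, dls - 13)
  # a perfect fit makes the conditional-OLS summary grumble; that is fine
  fit <- suppressWarnings(fit_hinge(dls, tt))
  expect_equal(fit$intercept, 800, tolerance = 1e-8)
  expect_equal(fit$threshold, 13, tolerance = 1e-8)
  expect_equal(fit$slope, 50, tolerance = 1e-8)
  expect_equal(fit$rmse, 0, tolerance = 1e-6)
  expect_equal(fit$n_obs, 8L)
  expect_equal(fit$method, "hinge")
})

test_that("degenerate and insufficient hinge inputs raise targeted errors", {
  dls <- c(11.5, 12, 12.5, 13, 13.5, 14, 15, 16)
  expect_error(fit_hinge(dls, rep(900, 8)), "degenerate")
  expect_error(fit_hinge(dls[1:5], rnorm(5, 900, 10)), "use ld_sd")
  expect_error(fit_hinge(rep(13, 8), rnorm(8, 900, 10)), "spread")
  # downward response is fitted but flagged
  tt_neg <- 900 - 40 * pmax(0, dls - 13) + c(0.3, -0.2, 0.1, 0, 0.2, -0.1, 0.3, -0.3)
  expect_warning(fit <- fit_hinge(dls, tt_neg), "negative")
  expect_lt(fit$slope, 0)
  expect_match(fit$flags, "negative_slope")
})

test_that("hinge profile search matches the dense-grid oracle on noisy data", {
  set.seed(31)
  for (i in 1:12) {
    n <- sample(20:45, 1)
    dls <- runif(n, 11.5, 17)
    tt <- 820 + runif(1, 30, 80) * pmax(0, dls - runif(1, 12.5, 14.5)) +
      rnorm(n, 0, 20)
    fit <- fit_hinge(dls, tt)
    oracle <- hinge_grid_oracle(dls, tt, step = 0.01)
    expect_lte(fit$rmse^2 * n, oracle$rss * (1 + 1e-8))
    if (abs(fit$threshold - oracle$e) < 0.011) {
      expect_equal(fit$intercept, oracle$alpha, tolerance = 0.05)
      expect_equal(fit$slope, oracle$beta, tolerance = 0.05)
    } else {
      # near-tied local optima: the fit must be strictly better
      expect_lt(fit$rmse^2 * n, oracle$rss)
    }
  }
})

test_that("the hinge fit never does worse than the best straight line", {
  set.seed(37)
  for (i in 1:10) {
    n <- 30
    dls <- runif(n, 11.5, 17)
    # half the cases have no threshold structure at all
    tt <- if (i %% 2) 850 + 20 * dls + rnorm(n, 0, 15) else
      850 + 60 * pmax(0, dls - 13.5) + rnorm(n, 0, 15)
    fit <- suppressWarnings(fit_hinge(dls, tt))
    line_rss <- sum(resid(lm(tt ~ dls))^2)
    expect_lte(fit$rmse^2 * n, line_rss * (1 + 1e-8))
  }
})

test_that("bootstrap threshold uncertainty is reported and reproducible", {
  set.seed(41)
  dls <- runif(40, 11.5, 17)
  tt <- 850 + 60 * pmax(0, dls - 13) + rnorm(40, 0, 20)
  f1 <- fit_hinge(dls, tt, boot_B = 150, boot_seed = 99)
  f2 <- fit_hinge(dls, tt, boot_B = 150, boot_seed = 99)
  expect_identical(f1$se_threshold, f2$se_threshold)
  expect_true(is.finite(f1$se_threshold) && f1$se_threshold > 0)
  expect_true(is.finite(f1$se_intercept) && is.finite(f1$se_slope))
  f0 <- fit_hinge(dls, tt)
  expect_true(is.na(f0$se_threshold))
})

test_that("LD-SD fit equals the two-level difference-of-means identity", {
  fit <- fit_ld_sd(dls = c(12.0, 12.2, 15.4, 15.6),
                   tt = c(800, 820, 900, 940))
  expect_equal(fit$intercept, 810)
  expect_equal(fit$slope, 110 / 3.4)
  expect_true(is.na(fit$threshold))

  # equal class means give zero sensitivity
  f0 <- fit_ld_sd(dls = c(12, 12.4, 15, 15.8), tt = c(850, 860, 855, 855))
  expect_equal(f0$slope, 0, tolerance = 1e-12)

  expect_error(fit_ld_sd(dls = c(12, 12.2, 12.4, 12.6), tt = rnorm(4, 850)),
               "each daylength class")
})

test_that("imbalanced LD-SD counts still reduce to the group-mean formula", {
  set.seed(43)
  dls <- c(runif(3, 11.8, 12.6), runif(13, 14.6, 16.5))
  tt <- c(rnorm(3, 840, 15), rnorm(13, 950, 25))
  fit <- fit_ld_sd(dls, tt)
  cls <- classify_sd_ld(dls)
  d_dls <- mean(dls[cls == "LD"]) - mean(dls[cls == "SD"])
  d_tt <- mean(tt[cls == "LD"]) - mean(tt[cls == "SD"])
  expect_equal(fit$slope, d_tt / d_dls, tolerance = 1e-10)
  expect_equal(fit$intercept, mean(tt[cls == "SD"]), tolerance = 1e-10)
})

test_that("LD-SD sensitivity is biased by the SD-mean vs true-threshold gap", {
  # Short days are physiologically non-inductive: SD observations sit at
  # the flowering time per se, while long-day delay accrues from the true
  # critical photoperiod upward. The two-level fit anchors its slope at the
  # SD daylength mean instead of the threshold, so the delay is divided by
  # the wrong daylength contrast.
  dls <- c(11.8, 12.0, 12.5, 12.7, 14.6, 15.0, 15.5, 16.0)
  cls <- classify_sd_ld(dls)
  beta_true <- 50
  sd_mean <- mean(dls[cls == "SD"])   # 12.25 h
  norm_frame <- function(e_true) {
    ifelse(cls == "LD", 850 + beta_true * (dls - e_true), 850)
  }
  # threshold below the SD mean: delay divided by a too-small contrast
  expect_gt(fit_ld_sd(dls, norm_frame(11.9))$slope, beta_true)
  # threshold above the SD mean: part of the contrast is photoperiod-blind
  expect_lt(fit_ld_sd(dls, norm_frame(14.0))$slope, beta_true)
  # under a pure hinge response the two-level slope never exceeds the true
  # slope (the recoded means lie on the convex hinge)
  tt_hinge <- 850 + beta_true * pmax(0, dls - 12.4)
  expect_lte(fit_ld_sd(dls, tt_hinge)$slope, beta_true + 1e-9)
})

test_that("panel fitting separates groups and records per-genotype failures", {
  set.seed(47)
  n_env <- 24
  dls_env <- c(runif(8, 11.8, 12.8), runif(16, 13.6, 16.5))
  envs <- sprintf("e%02d", seq_len(n_env))
  panel <- data.frame(
    genotype_id = sprintf("g%02d", 1:10),
    alpha = c(rnorm(5, 800, 15), rnorm(5, 900, 15)),
    beta = c(rep(0, 5), rnorm(5, 60, 5)),
    e = 13.2)
  met <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    g <- panel[i, ]
    data.frame(genotype_id = g$genotype_id, env_id = envs, dls = dls_env,
               tt_em_ant = g$alpha + g$beta * pmax(0, dls_env - g$e) +
                 rnorm(n_env, 0, 10))
  }))
  res <- fit_panel(met, method = "ld_sd")
  expect_equal(nrow(res$fits), 10)
  expect_null(res$failures)
  insens <- res$fits$slope[res$fits$genotype_id %in% panel$genotype_id[1:5]]
  sens <- res$fits$slope[res$fits$genotype_id %in% panel$genotype_id[6:10]]
  expect_lt(max(abs(insens)), 10)
  expect_gt(min(sens), 30)
  expect_equal(mean(res$fits$intercept[1:5]), 800, tolerance = 0.03)

  # a genotype observed in only a handful of long-day environments cannot
  # support a hinge fit
  met_ld <- met[met$dls > 13.5 & met$genotype_id == "g06", ][1:6, ]
  res2 <- fit_panel(rbind(met[met$genotype_id == "g07", ], met_ld),
                    method = "hinge")
  expect_equal(res2$failures$genotype_id, "g06")
  expect_match(res2$failures$message, "use ld_sd")

  # single genotype panel gives a single-row table
  res1 <- fit_panel(met[met$genotype_id == "g06", ], method = "hinge")
  expect_equal(nrow(res1$fits), 1)
})
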