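# The linear model layer: conversion, fitting, statistics, leave-one-out
# and external evaluation, against closed forms and hand arithmetic.

test_that("Ki converts to dG on the molar standard state at 298 K", {
  expect_equal(ki_to_dg(1.0), 0)
  expect_equal(ki_to_dg(10^-8.27), -11.27, tolerance = 0.01)
  expect_equal(ki_to_dg(10^-10), -13.63, tolerance = 0.01)
  expect_error(ki_to_dg(0), "positive")
  expect_error(ki_to_dg(-1), "positive")
  # explicit constant: RT ln Ki
  expect_equal(ki_to_dg(exp(1), temperature = 500), 1.9872e-3 * 500)
})

test_that("noiseless linear tables are interpolated exactly", {
  truth <- c(alpha = 0.2, beta = -0.03, gamma = -0.05, delta = -3.0)
  tab <- gen_energy_table(table_spec(alpha = truth["alpha"],
                                     beta = truth["beta"],
                                     gamma = truth["gamma"],
                                     delta = truth["delta"],
                                     noise_sd = 0, n = 25, seed = 42))
  m <- fit_liece(tab, "full_int")
  expect_equal(m$coefficients, truth, tolerance = 1e-8)
  expect_equal(m$fit$r2, 1, tolerance = 1e-10)
  expect_equal(m$fit$rmse, 0, tolerance = 1e-6)
})

test_that("model variants expose the right coefficients", {
  tab <- gen_energy_table(table_spec(n = 30, seed = 2))
  m_fi <- fit_liece(tab, "full_int")
  m_fn <- fit_liece(tab, "full_noint")
  m_vi <- fit_liece(tab, "vdwonly_int")
  m_vn <- fit_liece(tab, "vdwonly_noint")
  expect_setequal(names(m_fi$coefficients),
                  c("alpha", "beta", "gamma", "delta"))
  expect_setequal(names(m_fn$coefficients), c("alpha", "beta", "gamma"))
  expect_setequal(names(m_vi$coefficients), c("alpha", "delta"))
  expect_equal(names(m_vn$coefficients), "alpha")
  # guards
  expect_error(fit_liece(tab[1:3, ], "full_int"), "at least")
  collinear <- tab
  collinear$dE_coul <- 2 * collinear$dE_vdw
  expect_error(fit_liece(collinear, "full_int"), "collinear")
})

test_that("fit statistics match hand arithmetic", {
  st <- fit_statistics(c(-10, -9, -7), c(-10, -9, -8))
  expect_equal(st$rmse, sqrt(1 / 3))
  expect_equal(st$r2, 0.5)
  perfect <- fit_statistics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  # predicting the mean gives r2 = 0 by definition
  obs <- c(-9, -8, -10, -7)
  st0 <- fit_statistics(rep(mean(obs), 4), obs)
  expect_equal(st0$r2, 0)
  expect_warning(fit_statistics(c(1, 2), c(5, 5)), "zero-variance")
})

test_that("predictions are the explicit linear combination", {
  tab <- gen_energy_table(table_spec(n = 20, seed = 3))
  m <- fit_liece(tab, "full_int")
  cf <- m$coefficients
  terms <- c(dE_vdw = -37.2, dE_coul = -9.1, dG_solv = 14.6)
  expect_equal(predict_dg(m, terms),
               cf["alpha"] * terms["dE_vdw"] + cf["beta"] * terms["dE_coul"] +
               cf["gamma"] * terms["dG_solv"] + cf["delta"],
               ignore_attr = TRUE)
  expect_equal(predict_dg(m, c(dE_vdw = 0, dE_coul = 0, dG_solv = 0)),
               unname(cf["delta"]))
  m0 <- fit_liece(tab, "full_noint")
  expect_equal(predict_dg(m0, c(dE_vdw = 0, dE_coul = 0, dG_solv = 0)), 0)
})

test_that("OLS fits are at the optimum: coefficient nudges never reduce SSE", {
  tab <- gen_energy_table(table_spec(n = 40, seed = 8, noise_sd = 0.5))
  for (variant in c("full_int", "full_noint", "vdwonly_noint")) {
    m <- fit_liece(tab, variant)
    sse <- function(cf) {
      mm <- m; mm$coefficients <- cf
      sum((predict_dg(mm, tab) - tab$dg_exp)^2)
    }
    base <- sse(m$coefficients)
    for (k in seq_along(m$coefficients)) for (dd in c(-1e-3, 1e-3)) {
      cf <- m$coefficients
      cf[k] <- cf[k] + dd
      expect_gte(sse(cf), base)
    }
  }
})

test_that("leave-one-out is exact on noiseless data and guards its df", {
  tab <- gen_energy_table(table_spec(noise_sd = 0, n = 15, seed = 4))
  loo <- loo_cv(tab, "full_int")
  expect_true(all(loo$coef_std < 1e-10))
  expect_lt(abs(loo$mean_ddg), 1e-10)
  expect_equal(nrow(loo$per_fold), 15)
  # n = p + 1 would interpolate exactly in every fold: refused
  expect_error(loo_cv(tab[1:5, ], "full_int"), "at least")
})

test_that("a duplicated ligand leaves its fold's coefficients unchanged", {
  tab <- gen_energy_table(table_spec(n = 12, seed = 6, noise_sd = 0.5))
  dup <- rbind(tab, tab[3, ])
  m_all <- fit_liece(tab, "full_int")
  loo <- loo_cv(dup, "full_int")
  # the fold dropping one copy of ligand 3 refits on data equivalent to
  # the original table plus nothing new
  fold <- which(loo$per_fold$left_out == tab$ligand_id[3])[1]
  expect_equal(unlist(loo$per_fold[fold, names(m_all$coefficients)]),
               m_all$coefficients, tolerance = 1e-4)
})

test_that("both ddG conventions and both std normalizations are available", {
  tab <- gen_energy_table(table_spec(n = 12, seed = 9, noise_sd = 0.8))
  l1 <- loo_cv(tab, "full_int", ddg_mode = "left_out")
  l2 <- loo_cv(tab, "full_int", ddg_mode = "all")
  expect_false(isTRUE(all.equal(l1$mean_ddg, l2$mean_ddg)))
  lp <- loo_cv(tab, "full_int", coef_norm = "population")
  ls <- loo_cv(tab, "full_int", coef_norm = "sample")
  expect_true(all(ls$coef_std >= lp$coef_std))
  expect_equal(ls$coef_std / lp$coef_std,
               rep(sqrt(12 / 11), 4), ignore_attr = TRUE)
})

test_that("external evaluation matches in-sample statistics on identical rows", {
  tab <- gen_energy_table(table_spec(n = 20, seed = 10, noise_sd = 0.5))
  m <- fit_liece(tab, "full_int")
  ext <- evaluate_external(m, tab)
  expect_equal(ext$r2, m$fit$r2)
  expect_equal(ext$rmse, m$fit$rmse)
  expect_error(evaluate_external(m, tab[0, ]), "empty")
  # an all-zero no-intercept model predicts 0: rmse = sqrt(mean(obs^2))
  m0 <- fit_liece(tab, "full_noint")
  m0$coefficients[] <- 0
  expect_equal(evaluate_external(m0, tab)$rmse, sqrt(mean(tab$dg_exp^2)))
})

test_that("bulk refits cover every group-variant combination", {
  t1 <- gen_energy_table(table_spec(n = 15, seed = 1,
                                    dataset_label = "setA"))
  t2 <- gen_energy_table(table_spec(n = 12, seed = 2,
                                    dataset_label = "setB",
                                    docking_program = "other"))
  res <- fit_liece_models(rbind(t1, t2))
  expect_equal(nrow(res), 8)  # 2 groups x 4 variants
  expect_true(all(res$rmse >= 0))
  expect_true(all(res$r2 <= 1))
  models <- attr(res, "models")
  expect_length(models, 8)
  one <- models[["setA|simulated|toy|full_int"]]
  expect_s3_class(one, "liece_model")
  expect_equal(one$n_train, 15)
})
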