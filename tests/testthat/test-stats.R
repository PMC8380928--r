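test_that("the coded design is centered, product-structured, 12 terms wide", {
  tab <- simulate_mmn_table(n_per_domain = 2, noise = study_noise(0, 0, 0, 0),
                            seed = 1)
  d <- build_design(tab)
  for (col in c("domain_c", "dimension_c", "deviant_c", "lat_right",
                "lat_mid", "ant_frontal", "ant_parietal"))
    expect_equal(sum(d[[col]]), 0, info = col)
  X <- model.matrix(rovingmmn:::mmn_fixed_formula()[-2], data = d)
  expect_equal(ncol(X), 12)
  expect_equal(unname(X[, "deviant_c:dimension_c:domain_c"]),
               unname(d$deviant_c * d$dimension_c * d$domain_c))
  bad <- tab; bad$domain[1] <- "music"
  expect_error(build_design(bad), "unknown factor level")
})

test_that("true_fixed_effects maps the default generator to Table-2-style
           coefficients with the expected signs", {
  truth <- true_fixed_effects()
  expect_equal(length(truth), 12)
  expect_lt(truth[["(Intercept)"]], 0)              # overall MMN
  expect_lt(truth[["ant_frontal"]], 0)              # frontal > central
  expect_gt(truth[["ant_parietal"]], 0)             # parietal < central
  expect_equal(truth[["ant_frontal"]], -46)
  expect_equal(truth[["ant_parietal"]], 31)
  expect_equal(truth[["lat_right"]], 8)
  expect_equal(truth[["lat_mid"]], -20)
  # only the speech-spectral cell is asymmetric, so the three-way term is
  # exactly the (non-prominent - prominent) gap there
  cm <- default_cell_means()
  gap <- cm$mean[cm$domain == "speech" & cm$dimension == "spectral" &
                 cm$deviant == "non-prominent"] -
         cm$mean[cm$domain == "speech" & cm$dimension == "spectral" &
                 cm$deviant == "prominent"]
  expect_equal(truth[["deviant_c:dimension_c:domain_c"]], -gap)
})

test_that("zero-noise data are recovered exactly and the balanced
           random-intercept fit matches the OLS oracle", {
  tab <- simulate_mmn_table(n_per_domain = 3, noise = study_noise(0, 0, 0, 0),
                            seed = 2)
  truth <- true_fixed_effects()
  # lm warns that a perfect fit makes its summary unreliable -- expected here
  fit_ols <- suppressWarnings(fit_mmn_model(tab, method = "ols"))
  expect_equal(setNames(fit_ols$coefficients$estimate,
                        fit_ols$coefficients$term)[names(truth)],
               truth, tolerance = 1e-9)
  cm <- estimate_cell_means(fit_ols)
  gen <- default_cell_means()
  key <- paste(gen$domain, gen$dimension, gen$deviant)
  expect_equal(cm$estimate[match(key, paste(cm$domain, cm$dimension,
                                            cm$deviant))],
               gen$mean, tolerance = 1e-9)
  # with noise, random-intercept LMM fixed effects equal OLS on the
  # balanced design to high precision
  tabn <- simulate_mmn_table(n_per_domain = 4,
                             noise = study_noise(30, 0, 0, 50), seed = 3)
  f_lmm <- fit_mmn_model(tabn, method = "lmm_intercept",
                         df_method = "residual")
  f_ols <- fit_mmn_model(tabn, method = "ols")
  expect_equal(f_lmm$coefficients$estimate, f_ols$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("cell-mean confidence intervals bracket the estimate and shrink
           roughly as 1/sqrt(participants)", {
  w8 <- w32 <- numeric(3)
  for (r in 1:3) {
    t8 <- simulate_mmn_table(n_per_domain = 8, seed = 100 + r)
    t32 <- simulate_mmn_table(n_per_domain = 32, seed = 200 + r)
    w8[r] <- mean(with(estimate_cell_means(
      fit_mmn_model(t8, df_method = "residual")), hi - lo))
    w32[r] <- mean(with(estimate_cell_means(
      fit_mmn_model(t32, df_method = "residual")), hi - lo))
  }
  cm <- estimate_cell_means(fit_mmn_model(t32, df_method = "residual"))
  expect_true(all(cm$lo < cm$estimate & cm$estimate < cm$hi))
  expect_equal(mean(w8) / mean(w32), 2, tolerance = 0.35)
})

test_that("the asymmetry flag fires only in the generated asymmetric cell", {
  off_target <- matrix(NA, 3, 3)
  for (r in 1:3) {
    tab <- simulate_mmn_table(seed = 300 + r)
    fl <- asymmetry_flags(estimate_cell_means(
      fit_mmn_model(tab, df_method = "residual")))
    target <- fl$domain == "speech" & fl$dimension == "spectral"
    expect_true(fl$asymmetric[target])
    expect_gt(fl$difference[target], 0)
    off_target[r, ] <- fl$asymmetric[!target]
  }
  # the three symmetric cells stay quiet in the clear majority of runs
  expect_lt(mean(off_target), 0.35)
})

test_that("singular and undersized fits are reported, not hidden", {
  tab <- simulate_mmn_table(n_per_domain = 1)
  expect_error(fit_mmn_model(tab[tab$participant == "sub-01", ]),
               "2 participants")
  tab4 <- simulate_mmn_table(n_per_domain = 2,
                             noise = study_noise(0, 0, 0, 20), seed = 4)
  fit <- fit_mmn_model(tab4, df_method = "residual")
  expect_true(is.logical(fit$singular))
})
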