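test_that("fit_dissociation recovers the decay rate", {
  params <- kinetic_params(1e6, 0.01, 1)
  tr <- simulate_sensorgram(params, 500, noise = noiseless(),
                            load_level = 0)
  fit <- fit_dissociation(tr)
  expect_true(fit$converged)
  expect_equal(fit$rate, 0.01, tolerance = 1e-4)

  # constant segment: no decay
  flat <- tr
  flat$response <- 0.7
  ffit <- fit_dissociation(flat)
  expect_true(ffit$converged)
  expect_lte(ffit$rate, 1e-6)
  expect_lt(abs(ffit$A), 1e-9)

  # 1% noise: mean recovery over 10 seeds within 5%
  est <- vapply(1:10, function(s) {
    noisy <- simulate_sensorgram(params, 500,
                                 noise = noise_model(0.01, 0, 0),
                                 seed = s, load_level = 0)
    fit_dissociation(noisy)$rate
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.01) / 0.01, 0.05)
})

test_that("fit_association recovers k_obs and flags empty references", {
  params <- kinetic_params(1e6, 0.0281, 1)
  tr <- simulate_sensorgram(params, 1000, noise = noiseless(),
                            load_level = 0)
  fit <- fit_association(tr)
  expect_equal(fit$rate, 1.0281, tolerance = 1e-4)

  ref <- simulate_sensorgram(params, 0, noise = noise_model(0.005, 0, 0),
                             seed = 2, load_level = 0)
  rfit <- fit_association(ref)
  expect_true(!rfit$converged || abs(rfit$A) < 0.05)

  # k_obs differences follow the affine law
  tr2 <- simulate_sensorgram(params, 500, noise = noiseless(),
                             load_level = 0)
  dk <- fit$rate - fit_association(tr2)$rate
  expect_equal(dk, 1e6 * 500e-9, tolerance = 1e-3)
})

test_that("rate-constant arithmetic matches the pseudo-first-order relations", {
  expect_equal(derive_ka(1.0281, 0.0281, 1e-6), 1e6, tolerance = 1e-12)
  expect_equal(derive_ka(0.5281, 0.0281, 5e-7), 1e6, tolerance = 1e-12)
  expect_warning(ka0 <- derive_ka(0.01, 0.01, 1e-6), "no detectable")
  expect_identical(ka0, 0)
  expect_error(derive_ka(0.005, 0.01, 1e-6), "unphysical")
  expect_error(derive_ka(1, 0.01, 0), "conc")

  expect_equal(derive_equilibrium_kd(1e6, 0.0281) * 1e9, 28.1,
               tolerance = 1e-9)
  expect_equal(derive_equilibrium_kd(2e6, 0.0281) * 1e9, 14.05,
               tolerance = 1e-9)
  expect_warning(kd0 <- derive_equilibrium_kd(1e6, 0), "no measurable")
  expect_identical(kd0, 0)
  expect_error(derive_equilibrium_kd(0, 0.01), "k_a")
})

test_that("the global 1:1 fit recovers rates exactly on noiseless data", {
  params <- kinetic_params(1e6, 0.0281, 1)
  set <- simulate_set(params, noise = noiseless(), seed = 1)
  fit <- global_fit_1to1(set)
  expect_true(fit$converged)
  expect_equal(fit$Kd_nM, 28.1, tolerance = 1e-3)
  expect_equal(fit$k_a, 1e6, tolerance = 1e-3)
  expect_equal(fit$k_d, 0.0281, tolerance = 1e-3)
  expect_gt(fit$R2, 0.999999)
  # K_d = k_d / k_a exactly on every emitted result
  expect_identical(fit$K_d, fit$k_d / fit$k_a)
  expect_identical(fit$n_sensors, 6L)

  refs <- set[set$conc_nM == 0, ]
  expect_error(global_fit_1to1(refs), "positive concentrations")
  one <- set[set$conc_nM %in% c(0, 500), ]
  expect_error(global_fit_1to1(one), "2 distinct")
})

test_that("global fit and the two-stage route agree on noiseless data", {
  params <- kinetic_params(3e5, 0.02, 0.9)
  set <- simulate_set(params, noise = noiseless(), seed = 2)
  g <- global_fit_1to1(set)
  s <- two_stage_fit(set)
  expect_lt(abs(g$Kd_nM - s$Kd_nM) / s$Kd_nM, 0.01)
  expect_equal(s$Kd_nM, params$K_d * 1e9, tolerance = 1e-3)
})

test_that("association plateau is nondecreasing in concentration", {
  params <- kinetic_params(1e6, 0.0281, 1)
  set <- simulate_set(params, noise = noiseless(), seed = 1)
  plateaus <- vapply(split(set, set$sensor_id), function(tr) {
    max(tr$response[tr$phase == "association"])
  }, numeric(1))
  concs <- vapply(split(set, set$sensor_id), function(tr) tr$conc_nM[1],
                  numeric(1))
  ord <- order(concs)
  expect_true(all(diff(plateaus[ord]) >= -1e-12))
})

test_that("recovered K_d is stable across noise seeds (1% noise)", {
  params <- kinetic_params(0.01 / 28.1e-9, 0.01, 1) # K_d = 28.1 nM
  est <- vapply(1:10, function(s) {
    set <- simulate_set(params, noise = noise_model(0.01, 0.02, 0),
                        seed = s)
    global_fit_1to1(preprocess_set(set))$Kd_nM
  }, numeric(1))
  expect_lt(sd(est) / 28.1, 0.10)
  expect_lt(abs(mean(est) - 28.1) / 28.1, 0.10)
})

test_that("binding calls follow the affinity categories", {
  params <- kinetic_params(0.01 / 28.1e-9, 0.01, 1)
  set <- simulate_set(params, noise = noiseless(), seed = 1)
  fit <- global_fit_1to1(set)
  expect_identical(classify_binding(fit), "strong")
  expect_identical(binding_symbol(classify_binding(fit)), "++")

  mk <- function(kd_M, converged = TRUE) {
    structure(list(K_d = kd_M, converged = converged), class = "bli_fit")
  }
  expect_identical(classify_binding(mk(164e-9)), "strong")
  expect_identical(classify_binding(mk(1e-6)), "weak")
  expect_identical(classify_binding(mk(3e-6)), "weak") # inclusive bound
  expect_identical(classify_binding(mk(5e-6)), "none")
  expect_identical(classify_binding(mk(28e-9, converged = FALSE)), "none")
  expect_identical(binding_symbol(c("none", "weak", "strong")),
                   c("-", "+", "++"))
})
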