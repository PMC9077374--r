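test_that("BD pair survival matches the Smoluchowski closed form", {
  set.seed(21)
  r0 <- 2; R <- 1; D <- 0.01
  times <- c(25, 100, 400, 1600)
  bd <- bd_pair_survival(r0, R, D, times,
                         bd_params(dt = 0.15, t_end = 1600, n_rep = 4000))
  S_exact <- 1 - (R / r0) * irtrad:::erfc_((r0 - R) / sqrt(4 * D * times))
  expect_true(all(abs(bd$S - S_exact) < 3 * bd$se))
  # long-time capture tends to R/r0
  expect_lt(abs((1 - bd$S[4]) - (R / r0) *
                  irtrad:::erfc_((r0 - R) / sqrt(4 * D * 1600))), 3 * bd$se[4])
  # no sink: survival stays 1
  bd0 <- bd_pair_survival(r0, 0, D, c(50, 100),
                          bd_params(dt = 0.2, t_end = 100, n_rep = 200))
  expect_true(all(bd0$S == 1))
  # the timestep guard fires on coarse steps
  expect_error(bd_pair_survival(r0, R, D, times,
                                bd_params(dt = 50, t_end = 1600, n_rep = 10)),
               "timestep")
})

test_that("halving the BD timestep moves estimates less than the noise band", {
  set.seed(22)
  r0 <- 1.6; R <- 1; D <- 0.01
  times <- c(50, 200, 800)
  a <- bd_pair_survival(r0, R, D, times,
                        bd_params(dt = 0.16, t_end = 800, n_rep = 3000))
  b <- bd_pair_survival(r0, R, D, times,
                        bd_params(dt = 0.08, t_end = 800, n_rep = 3000))
  expect_true(all(abs(a$S - b$S) < 3 * sqrt(a$se^2 + b$se^2)))
})

test_that("volume-reactivity BD reproduces the Collins-Kimball capture", {
  set.seed(23)
  R <- 1; D <- 0.01; r0 <- 2
  k_diff <- 4 * pi * D * R / irtrad:::K_M1S1_TO_NM3PS
  k_obs <- k_diff / 2            # half the diffusion limit
  q <- bd_tune_q(k_obs, R, D)
  # tuning identity: Doi steady-state rate equals k_obs within 5%
  x <- R * sqrt(q / D)
  expect_equal(k_diff * (1 - tanh(x) / x), k_obs, tolerance = 1e-10)
  # ultimate capture probability (R/r0) * k_obs/k_diff
  times <- c(100, 400, 2000)
  bd <- bd_pair_survival(r0, R, D, times,
                         bd_params(dt = 0.1, t_end = 2000, n_rep = 4000), q = q)
  v <- D / R  # vR/(D+vR) = 1/2 matches k_obs/k_diff = 1/2
  ck <- irtrad:::ck_reaction_prob(times, r0, R, v, D)
  expect_true(all(abs((1 - bd$S) - ck) < 3 * bd$se + 0.01))
  # capture approaches the ultimate probability (R/r0) k_obs/k_diff from below
  expect_true(all(diff(1 - bd$S) >= 0))
  expect_lt(1 - bd$S[3], (R / r0) * k_obs / k_diff + 3 * bd$se[3] + 0.01)
})

test_that("BD cluster reduces to the pair law for a two-particle system", {
  set.seed(24)
  net <- pair_network(R_nm = 0.5)
  compiled <- compile_engine(net, azide = 0, o2 = 0, t_end = 800)
  r0 <- 1.2
  cfg <- list(particles = data.frame(species = c("A", "B"),
                                     x = c(0, r0), y = 0, z = 0),
              energy = 100)
  times <- c(50, 200, 800)
  out <- bd_cluster(cfg, compiled, times, bd_params(dt = 0.05, t_end = 800,
                                                    n_rep = 3000))
  D <- diffusion_nm2ps(4.9e-5 + 7.0e-5)
  w <- (0.5 / r0) * irtrad:::erfc_((r0 - 0.5) / sqrt(4 * D * times))
  expect_true(all(abs(out$events - w) < 3 * out$se + 0.01))
  # single particle, no channels: nothing reacts
  one <- list(particles = data.frame(species = "A", x = 0, y = 0, z = 0),
              energy = 1)
  out1 <- bd_cluster(one, compiled, c(10, 100), bd_params(dt = 0.05,
                                                          t_end = 100,
                                                          n_rep = 50))
  expect_true(all(out1$events == 0))
})
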