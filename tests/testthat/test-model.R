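test_that("assembly_rate is the linear speed law V = k_tilde * G_T", {
  p <- turnover_params(l_max = 100, k_tilde = 0.01)
  expect_equal(assembly_rate(100, p), 1.0)   # V0 at full pool
  expect_equal(assembly_rate(0, p), 0)
  expect_equal(assembly_rate(30, p), 0.3)
  expect_error(assembly_rate(-1, p), "nonnegative")
})

test_that("assembly closed form matches its formula and limits", {
  cf0 <- assembly_closed_form(0, V0 = 1, l_max = 120, sigma = 1)
  expect_equal(cf0$l_um, 0)
  expect_equal(cf0$l_tilde_um, 0)
  # frozen value: 60 * (1 - exp(-1)) evaluated independently
  cf <- assembly_closed_form(60, V0 = 1, l_max = 120, sigma = 1)
  expect_equal(cf$l_um, 37.92724, tolerance = 1e-6)
  expect_equal(cf$l_tilde_um, cf$l_um)
  # sigma = 1 saturates at half the pool
  cf_inf <- assembly_closed_form(1e7, V0 = 1, l_max = 120, sigma = 1)
  expect_equal(cf_inf$l_um, 60)
  expect_error(assembly_closed_form(-1, 1, 100, 0), "nonnegative")
})

test_that("saturation timescale is l_max / ((1+sigma) V0)", {
  expect_equal(saturation_timescale(100, 1, sigma = 1), 50)
  expect_equal(saturation_timescale(100, 1, sigma = 0), 100)
  expect_equal(saturation_timescale(110, 1.08, sigma = 1), 110 / 2.16)
  expect_error(saturation_timescale(100, 0), "V0")
})

test_that("simulate: zero rates give a constant trajectory", {
  p <- turnover_params(l_max = 50, k_tilde = 0)
  init <- pool_state(l = 10, G_D = 15, G_T = 25, l_max = 50)
  tr <- simulate_turnover(p, init, t_grid = seq(0, 500, by = 50))
  expect_true(all(abs(sweep(tr$states, 2, unclass(init))) < 1e-12))
})

test_that("simulate converges to the analytic steady state", {
  p <- comet_preset("disassembly_deduced") # l* = 20 um at l_max = 60
  tr <- simulate_turnover(p, t_grid = c(0, 1500, 3000))
  ss <- steady_state(p)
  expect_equal(ss$l_star, 20)
  final <- tr$states[3, ]
  expect_rel_equal(final[["l"]], ss$l_star, 1e-3)
  expect_rel_equal(final[["G_T"]], ss$G_T_star, 1e-3)
  expect_rel_equal(final[["G_D"]], ss$G_D_star, 1e-3)
})

test_that("analytic and RK45 routes agree with the eigen oracle", {
  p <- turnover_params(l_max = 60, k_tilde = 0.01, gamma = 0.037,
                       k_DT = 0.11, psi = 0.0013)
  tg <- seq(0, 1200, by = 40)
  x0 <- c(0, 0, 0, 60, 0)
  ora <- oracle_solve(0.01, 0.037, 0.11, 0.0013, 0, x0, tg)
  tr_a <- simulate_turnover(p, t_grid = tg)
  tr_n <- simulate_turnover(p, t_grid = tg, method = "rk45")
  expect_true(max(abs(tr_a$states - ora)) < 1e-8)
  expect_true(max(abs(tr_n$states - ora)) < 1e-6)
})

test_that("aging decay law: active pool is l_max * exp(-psi t)", {
  p <- turnover_params(l_max = 60, k_tilde = 0.01, gamma = 0.02,
                       k_DT = 0.02, psi = 0.001)
  tg <- seq(0, 1000, by = 100)
  tr <- simulate_turnover(p, t_grid = tg)
  active <- rowSums(tr$states[, c("l", "G_D", "G_T")])
  expect_rel_equal(active, 60 * exp(-0.001 * tg), 1e-6)
  expect_rel_equal(active[length(tg)], 60 * exp(-1), 1e-9)
})

test_that("conservation holds over random parameter draws (20 h)", {
  set.seed(401)
  for (i in 1:25) {
    p <- turnover_params(l_max = stats::runif(1, 40, 150),
                         k_tilde = 10^stats::runif(1, -3, -1),
                         gamma = 10^stats::runif(1, -3, 0),
                         k_DT = 10^stats::runif(1, -3, 0),
                         psi = 10^stats::runif(1, -4, -2))
    tr <- simulate_turnover(p, t_grid = seq(0, 1200, by = 60))
    expect_lt(conservation_residual(tr), 1e-6 * p$l_max)
    expect_true(all(tr$velocities >= 0))
  }
})

test_that("simulate rejects invalid inputs", {
  p <- comet_preset("disassembly")
  expect_error(simulate_turnover(p, pool_state(G_T = 50), seq(0, 10, 1)),
               "sums to")
  expect_error(simulate_turnover(p, t_grid = c(0, 5, 5)), "increasing")
  expect_error(simulate_turnover(p, t_grid = c(1, 5, 10)), "start at 0")
  bad <- turnover_params(l_max = 60, k_tilde = 0.01, gamma = 0.02,
                         k_DT = 0.02, sigma = 1)
  expect_error(simulate_turnover(bad, t_grid = c(0, 10)), "assembly mode")
})

test_that("steady state matches the deduced-fraction worked case", {
  p <- comet_preset("disassembly_deduced")
  ss <- steady_state(p)
  expect_equal(ss$alpha, 1 / 3)
  expect_equal(ss$beta, 2 / 3)
  # one-third tail, one-half ATP-G, one-sixth ADP-G
  expect_equal(ss$l_star / p$l_max, 1 / 3)
  expect_equal(ss$G_T_star / p$l_max, 1 / 2)
  expect_equal(ss$G_D_star / p$l_max, 1 / 6)
  expect_equal(ss$l_star + ss$G_T_star + ss$G_D_star, p$l_max)
  # recycling-deduction worked case, evaluated by hand
  pr <- comet_preset("recycling_deduced")
  sr <- steady_state(pr)
  expect_equal(sr$alpha, 0.05)
  expect_equal(sr$beta, 1 / 6)
  expect_equal(sr$l_star, (1 / 6) * 60 / (1 + 0.05 + 1 / 6))
  expect_equal(sr$l_star, 8.22, tolerance = 1e-3)
})

test_that("steady state flux balance and error modes", {
  ss <- steady_state(comet_preset("recycling_deduced"))
  fx <- flux_triplet(pool_state(l = ss$l_star, G_D = ss$G_D_star,
                                G_T = ss$G_T_star),
                     comet_preset("recycling_deduced"))
  expect_lt(max(abs(fx - fx[1])) / fx[1], 1e-9)
  expect_error(steady_state(comet_preset("disassembly")), "aging")
  expect_error(steady_state(turnover_params(gamma = 0, k_DT = 0.1)),
               "gamma > 0")
  # instantaneous-recycling limit: alpha -> 0, G_D -> 0
  p_fast <- turnover_params(l_max = 60, k_tilde = 0.01, gamma = 0.015,
                            k_DT = 1e6)
  expect_lt(steady_state(p_fast)$G_D_star, 1e-6)
})

test_that("steady state is monotone in the rates", {
  base <- list(l_max = 60, k_tilde = 0.01, gamma = 0.015, k_DT = 0.03)
  l_star <- function(gamma = base$gamma, k_tilde = base$k_tilde,
                     k_DT = base$k_DT)
    steady_state(turnover_params(l_max = 60, k_tilde = k_tilde,
                                 gamma = gamma, k_DT = k_DT))$l_star
  v_star <- function(k_DT)
    steady_state(turnover_params(l_max = 60, k_tilde = 0.01, gamma = 0.015,
                                 k_DT = k_DT))$V_star
  gammas <- c(0.005, 0.01, 0.02, 0.05, 0.2)
  expect_true(all(diff(vapply(gammas, function(g) l_star(gamma = g),
                              numeric(1))) < 0))
  kts <- c(0.002, 0.005, 0.01, 0.02, 0.05)
  expect_true(all(diff(vapply(kts, function(k) l_star(k_tilde = k),
                              numeric(1))) > 0))
  kdts <- c(0.005, 0.02, 0.08, 0.3)
  expect_true(all(diff(vapply(kdts, v_star, numeric(1))) > 0))
})

test_that("flux triplet tracks dl/dt away from steady state", {
  p <- comet_preset("disassembly")
  tg <- seq(0, 200, by = 1)
  tr <- simulate_turnover(p, t_grid = tg)
  fx <- flux_triplet(pool_state(l = tr$states[50, "l"],
                                G_D = tr$states[50, "G_D"],
                                G_T = tr$states[50, "G_T"]), p)
  expect_gt(max(abs(fx - fx[1])), 1e-4) # transient: fluxes unequal
  # finite-difference check of dl/dt = assembly - disassembly - psi l
  dldt_fd <- (tr$states[51, "l"] - tr$states[49, "l"]) / 2
  dldt_model <- fx[["assembly"]] - fx[["disassembly"]] -
    p$psi * tr$states[50, "l"]
  expect_equal(dldt_fd, dldt_model, tolerance = 1e-3) # O(dt^2) at dt = 1
  expect_equal(unname(flux_triplet(pool_state(), p)), c(0, 0, 0))
})

test_that("numerical integration reproduces the assembly closed form", {
  p <- comet_preset("assembly") # sigma = 1, l_max = 120
  tg <- seq(0, 1200, by = 10)   # 20 h
  tr <- simulate_turnover(p, t_grid = tg, method = "rk45")
  l_ref <- oracle_assembly_l(tg, V0 = p$k_tilde * p$l_max, p$l_max, p$sigma)
  expect_lt(max(abs(tr$states[, "l"] - l_ref)), 1e-4)
  expect_equal(tr$states[, "l_tilde"], tr$states[, "l"],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("trajectory data frame carries unit-tagged columns", {
  tr <- simulate_turnover(comet_preset("recycling"),
                          t_grid = seq(0, 100, by = 10))
  df <- as.data.frame(tr)
  expect_named(df, c("time_min", "l_um", "l_tilde_um", "GD_um", "GT_um",
                     "aged_um", "V_um_per_min"))
  expect_equal(df$V_um_per_min, 0.01 * df$GT_um)
})
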