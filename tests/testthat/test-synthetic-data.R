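test_that("simulated tables are deterministic under a fixed seed", {
  cfg <- simulation_config(n_proteins = 30, noise_cv = 0.3, seed = 11)
  tr <- dilution_only_truths(30, seed = 12)
  expect_identical(simulate_labeling_experiment(cfg, tr),
                   simulate_labeling_experiment(cfg, tr))
  s <- growth_sim_spec(mu = 0.5, noise_cv = 0.05)
  expect_identical(simulate_growth_curve(s, seed = 3),
                   simulate_growth_curve(s, seed = 3))
})

test_that("pre-noise relative abundances are conserved within each sample", {
  cfg <- simulation_config(n_proteins = 50, noise_cv = 0,
                           detection_limit = 0, seed = 5)
  set.seed(99)
  tr <- protein_truth(sprintf("P%02d", 1:50), a0 = rlnorm(50),
                      a1 = rlnorm(50), k_deg = c(rep(0, 45), rep(0.5, 5)))
  tab <- simulate_labeling_experiment(cfg, tr)
  sums <- tapply(tab$intensity_L + ifelse(is.na(tab$intensity_H), 0,
                                          tab$intensity_H),
                 tab$sample, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("noiseless H/L ratios follow the closed form (a1/a0)(e^{mu t}-1)", {
  mu <- log(2) / 1.6  # doubling time 1.6 h -> H/L = 1 at 96 min
  cfg <- simulation_config(n_proteins = 3, mu_post = mu,
                           sampling_times = c(24, 48, 96, 120),
                           noise_cv = 0, detection_limit = 0, seed = 1)
  tr <- protein_truth(c("A", "B", "C"), a0 = c(1, 2, 4),
                      a1 = c(1, 4, 2))  # fold changes 1, 2, 0.5
  tab <- simulate_labeling_experiment(cfg, tr)
  post <- tab[tab$time_min > 0, ]
  expected <- hl_closed_form(post$time_min, mu,
                             a1_over_a0 = tr$a1[match(post$protein_id,
                                                      tr$protein_id)] /
                               tr$a0[match(post$protein_id, tr$protein_id)])
  expect_equal(post$ratio_HL, expected, tolerance = 1e-9)
  expect_equal(post$ratio_HL[post$protein_id == "A" & post$time_min == 96], 1,
               tolerance = 1e-9)
})

test_that("t0 replicates carry no heavy label and censoring produces NA", {
  cfg <- simulation_config(n_proteins = 4, noise_cv = 0, seed = 2,
                           detection_limit = 1e-3)
  tr <- protein_truth(c("a", "b", "c", "d"), a0 = c(10, 10, 10, 1e-3))
  tab <- simulate_labeling_experiment(cfg, tr)
  t0 <- tab[tab$time_min == 0, ]
  expect_equal(nrow(t0), 4 * 2)
  expect_true(all(is.na(t0$intensity_H)))
  expect_true(all(is.na(t0$ratio_HL)))
  # protein d sits at ~3e-5 relative abundance, below the 1e-3 floor
  expect_true(all(is.na(tab$intensity_L[tab$protein_id == "d"])))
})

test_that("instant production stagnation yields no heavy signal", {
  cfg <- simulation_config(n_proteins = 2, noise_cv = 0,
                           detection_limit = 0, seed = 3)
  tr <- protein_truth(c("s", "n"), a0 = c(1, 1),
                      stagnation_time = c(0, Inf))
  tab <- simulate_labeling_experiment(cfg, tr)
  post <- tab[tab$time_min > 0, ]
  expect_true(all(post$intensity_H[post$protein_id == "s"] == 0))
  expect_true(all(post$intensity_H[post$protein_id == "n"] > 0))
})

test_that("active degradation steepens the light log-slope to -(mu+k_deg)", {
  # bulk of dilution-only proteins with a1 = a0 keeps the sample total
  # constant, so relative light abundance of the degraded protein decays
  # exactly at mu + k_deg
  mu <- 0.433
  cfg <- simulation_config(n_proteins = 100, mu_post = mu, noise_cv = 0,
                           detection_limit = 0, seed = 4)
  set.seed(7)
  tr <- protein_truth(sprintf("P%03d", 1:100), a0 = rlnorm(100))
  tr$k_deg[1] <- 2 * mu
  tab <- simulate_labeling_experiment(cfg, tr)
  sub <- tab[tab$protein_id == "P001", ]
  f <- fit_log_linear(sub$time_min, sub$intensity_L)
  expect_equal(f$slope, -3 * mu * log10(exp(1)), tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
})

test_that("larger expression fold change moves the H/L crossing earlier", {
  mu <- 0.433
  ratios <- c(0.5, 1, 2, 4, 8)
  cfg <- simulation_config(n_proteins = 5, mu_post = mu, noise_cv = 0,
                           detection_limit = 0, seed = 6)
  tr <- protein_truth(paste0("r", seq_along(ratios)), a0 = 1, a1 = ratios)
  tab <- simulate_labeling_experiment(cfg, tr)
  crossing <- sapply(paste0("r", seq_along(ratios)), function(id) {
    sub <- tab[tab$protein_id == id & tab$time_min > 0, ]
    as.numeric(replacement_time(gate_quality(
      fit_log_linear(sub$time_min, sub$ratio_HL))))
  })
  expect_true(all(diff(crossing) < 0))
})

test_that("invalid configurations and truths are rejected", {
  expect_error(simulation_config(mu_post = -1), "mu_post")
  expect_error(simulation_config(sampling_times = c(30, 15)), "increasing")
  expect_error(protein_truth(character(0), a0 = 1), "at least one")
  expect_error(protein_truth("p", a0 = -1), "a0")
  cfg <- simulation_config(n_proteins = 2, seed = 1)
  expect_error(simulate_labeling_experiment(cfg, protein_truth("p", 1)),
               "one row per protein")
})

test_that("growth curves show lag, exponential and plateau phases", {
  s <- growth_sim_spec(lag_minutes = 60, mu = 0.64, od_start = 0.05,
                       od_plateau = 1.0, noise_cv = 0)
  crv <- simulate_growth_curve(s)
  expect_true(all(crv$od600[crv$time_min <= 60] == 0.05))
  expect_equal(max(crv$od600), 1.0)
  mid <- crv[crv$time_min > 60 & crv$od600 < 1, ]
  f <- ols_oracle(mid$time_min / 60, log(mid$od600))
  expect_equal(f$slope, 0.64, tolerance = 1e-9)
  flat <- simulate_growth_curve(growth_sim_spec(mu = 0, noise_cv = 0,
                                                total_minutes = 180))
  expect_true(all(flat$od600 == 0.05))
})

test_that("NMR tables sum to one before noise and seed reproducibly", {
  spec <- nmr_sim_spec(c("glc", "gal"), lactate = c(0.30, 0.15),
                       acetate = c(0.01, 0.05), ornithine = c(0.02, 0.06),
                       od600 = c(0.5, 0.4), n_replicates = 3, noise_cv = 0,
                       seed = 9)
  tab <- simulate_nmr_tables(spec)
  expect_equal(nrow(tab), 6)
  expect_true(all(abs(rowSums(tab[, c("lactate", "acetate", "ornithine",
                                      "other")]) - 1) < 1e-9))
  spec_noisy <- nmr_sim_spec("x", lactate = 0.2, acetate = 0.1,
                             noise_cv = 0.1, seed = 4)
  expect_identical(simulate_nmr_tables(spec_noisy),
                   simulate_nmr_tables(spec_noisy))
  expect_error(nmr_sim_spec("x", lactate = 0.5, acetate = 0.3, other = 0.5),
               "sum to 1")
})

test_that("MaxQuant-flavored export carries one column triple per sample", {
  cfg <- simulation_config(n_proteins = 3, noise_cv = 0, seed = 8)
  tab <- simulate_labeling_experiment(cfg, dilution_only_truths(3, seed = 8))
  wide <- export_maxquant_layout(tab)
  expect_equal(nrow(wide), 3)
  expect_true(all(c("iBAQ L t015", "iBAQ H t015", "Ratio H/L t015",
                    "iBAQ L t0_r1") %in% names(wide)))
  path <- withr::local_tempfile(fileext = ".tsv")
  export_maxquant_layout(tab, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(nrow(back), 3)
})
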