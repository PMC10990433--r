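# Synthetic-data engine: map layout, BC1F4 pedigree genetics, EC series,
# and the phenotype generative model.

test_that("simulated map has the requested layout and is deterministic", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 100,
                    n_markers_per_chr = 11)
  map <- simulate_map(cfg)
  expect_equal(map$pos, seq(0, 100, by = 10))

  cfg2 <- sim_config(n_chromosomes = 2, n_markers_per_chr = 5)
  map2 <- simulate_map(cfg2)
  expect_equal(nrow(map2), 10L)
  expect_equal(sort(unique(map2$chr)), c(1L, 2L))
  expect_false(anyDuplicated(map2$marker) > 0)
  for (ch in 1:2) {
    expect_true(all(diff(map2$pos[map2$chr == ch]) > 0))
  }

  set.seed(99); m_a <- simulate_map(cfg2, spacing = "uniform")
  set.seed(99); m_b <- simulate_map(cfg2, spacing = "uniform")
  expect_identical(m_a, m_b)

  expect_error(sim_config(n_markers_per_chr = 0))
})

test_that("BC1F4 progeny match pedigree expectations", {
  map <- do.call(rbind, lapply(1:5, function(ch)
    data.frame(marker = sprintf("c%dm%02d", ch, 1:11), chr = ch,
               pos = seq(0, 100, by = 10))))
  d <- simulate_cross(2000, map, n_selfing = 3, seed = 5)
  expect_true(all(d %in% 0:2))
  # BC1 puts the donor allele at frequency 1/4; selfing preserves it
  expect_lt(abs(mean(d) / 2 - 0.25), 0.01)
  # heterozygosity 0.5 at BC1, halved by each of 3 selfing meioses
  expect_lt(abs(mean(d == 1) - 0.0625), 0.01)
  expect_error(simulate_cross(0, map))
  # determinism under a fixed seed
  expect_identical(simulate_cross(50, map, seed = 3),
                   simulate_cross(50, map, seed = 3))
})

test_that("gametic recombination follows the Haldane map function", {
  r_true <- haldane_r(10)
  expect_equal(r_true, (1 - exp(-0.2)) / 2)
  set.seed(11)
  n <- 40000
  g <- mppqtlx:::.meiosis(matrix(0, n, 2), matrix(1, n, 2), r_true)
  r_obs <- mean(g[, 1] != g[, 2])
  se <- sqrt(r_true * (1 - r_true) / n)
  expect_lt(abs(r_obs - r_true), 3 * se)
})

test_that("EC series honour offsets, constancy and the seed", {
  cfg <- sim_config(n_environments = 4)
  ec <- simulate_ec(cfg, seed = 2)
  ph <- ec[ec$ec == "photoperiod", ]
  m <- tapply(ph$value, ph$environment, mean)
  expect_true(all(diff(m[sprintf("env%d", 1:4)]) > 0))
  expect_equal(length(unique(ph$day)), cfg$n_days)

  ecc <- simulate_ec(cfg, constant = TRUE)
  v <- ecc[ecc$ec == "tmax" & ecc$environment == "env2", "value"]
  expect_equal(length(unique(v)), 1L)

  expect_identical(simulate_ec(cfg, seed = 4), simulate_ec(cfg, seed = 4))
})

test_that("noise-free phenotypes equal the stated generative sum", {
  cfg <- noiseless_config()
  sim <- simulate_bcnam(cfg)
  # dosage-2 minus dosage-0 genotypes differ by exactly 2*(alpha + S*EC_j)
  dos <- sim$dosage_true[, "c1m11"]
  cr1 <- sim$crosses$genotype[sim$crosses$donor == "D1"]
  ec <- sim$ec_values$photoperiod
  tb <- sim$true_blues
  for (j in c("env1", "env4")) {
    v <- tb$value[tb$environment == j]
    names(v) <- tb$genotype[tb$environment == j]
    g2 <- intersect(cr1, names(dos)[dos == 2])
    g0 <- intersect(cr1, names(dos)[dos == 0])
    expect_equal(unname(v[g2[1]] - v[g0[1]]),
                 2 * (1.0 + 3 * ec[[j]]), tolerance = 1e-12)
  }
  # plot values reproduce the deterministic part bit-for-bit
  pl <- merge(sim$phenotypes, tb, by = c("genotype", "environment"))
  expect_equal(pl$value.x, pl$value.y, tolerance = 1e-12)
})

test_that("all-zero effects leave only the environment means", {
  cfg <- sim_config(qtl = list(), vcov = matrix(0, 4, 4), error_sd = 0,
                    block_sd = 0, seed = 3,
                    crosses = data.frame(cross = "cr1", recurrent = "R1",
                                         donor = "D1", n_progeny = 40L))
  sim <- simulate_bcnam(cfg)
  m <- tapply(sim$true_blues$value, sim$true_blues$environment, mean)
  expect_equal(as.numeric(m[sprintf("env%d", 1:4)]), cfg$env_effects,
               tolerance = 1e-12)
})

test_that("GxE draws follow the configured unstructured covariance", {
  cfg <- sim_config(
    crosses = data.frame(cross = "cr1", recurrent = "R1", donor = "D1",
                         n_progeny = 10000L),
    n_environments = 3, qtl = list(), vcov = diag(3), error_sd = 0,
    block_sd = 0, seed = 8)
  sim <- simulate_bcnam(cfg)
  tb <- sim$true_blues[sim$true_blues$cross != "check", ]
  Y <- matrix(tb$value, ncol = 3)
  emp <- stats::cov(Y)
  expect_lt(max(abs(emp - diag(3))), 0.03)
})

test_that("the full experiment is reproducible from its seed", {
  a <- simulate_bcnam(small_sim_config(n_progeny = 30L, seed = 17))
  b <- simulate_bcnam(small_sim_config(n_progeny = 30L, seed = 17))
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$ec_daily, b$ec_daily)
})

test_that("phenotype simulation rejects QTL positions off the map", {
  cfg <- small_sim_config(n_progeny = 20L,
                          qtl = list(qtl_spec(1, 33.33,
                                              alpha = c(D1 = 1))))
  expect_error(simulate_bcnam(cfg), "no marker")
})
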