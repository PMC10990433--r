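# Main/QEI decomposition, EC sensitivity, grouping and projection.

test_that("model 3 rejects a single environment and decomposes effects", {
  sim <- simulate_bcnam(small_sim_config(n_progeny = 150L, seed = 41))
  dos <- dosage_from_sim(sim)
  blues <- fit_env_blues(sim$phenotypes)
  one_env <- blues[blues$environment == "env1", ]
  expect_error(fit_model3(one_env, dos, "c1m11"), ">= 2 environments")

  m3 <- fit_model3(blues, dos, "c1m11")
  tab <- m3$table
  expect_equal(sort(tab$parent), c("D1", "D2"))
  # D1 carries the photoperiod sensitivity: classified QEI
  expect_equal(tab$class[tab$parent == "D1"], "QEI")
  # alpha estimates near truth (centered EC -> alpha is the mean effect)
  expect_lt(abs(tab$alpha[tab$parent == "D1"] - 1.0),
            4 * tab$se_alpha[tab$parent == "D1"])
  expect_lt(abs(tab$alpha[tab$parent == "D2"] - (-0.8)),
            4 * tab$se_alpha[tab$parent == "D2"])
  # beta_pj sums to zero over environments within parent
  b <- m3$beta_env
  s <- tapply(b$beta, b$parent, sum)
  expect_lt(max(abs(s)), 1e-8)
})

test_that("model-3 fitted env effects match the model-2 parameterization", {
  # alpha_p + beta_pj is a reparameterization of the per-environment
  # allelic effects beta_pj of the detection model
  sim <- simulate_bcnam(small_sim_config(n_progeny = 120L, seed = 42))
  dos <- dosage_from_sim(sim)
  blues <- fit_env_blues(sim$phenotypes)
  m3 <- fit_model3(blues, dos, "c1m11")
  st <- mppqtlx:::.make_stack(blues)
  Xb <- mppqtlx:::.base_design(st)
  bd <- build_design_matrix(dos, "c1m11")
  Q <- mppqtlx:::.expand_env(st, bd)
  m2 <- mppqtlx:::.reml_fit_stack(st, cbind(Xb, Q))
  for (p in c("D1", "D2")) {
    eff2 <- m2$beta[sprintf("%s@env%d", p, 1:4)]
    a <- m3$table$alpha[m3$table$parent == p]
    bj <- m3$beta_env$beta[m3$beta_env$parent == p]
    expect_equal(unname(a + bj), unname(eff2), tolerance = 1e-4)
  }
})

test_that("model 4 recovers a simulated EC sensitivity", {
  sim <- simulate_bcnam(small_sim_config(n_progeny = 300L, seed = 43))
  dos <- dosage_from_sim(sim)
  blues <- fit_env_blues(sim$phenotypes)
  qei <- data.frame(qtl = "c1m11", parent = "D1")
  ecv <- list(photoperiod = sim$ec_values$photoperiod)
  s4 <- fit_model4(blues, dos, "c1m11", qei, ecv)
  expect_equal(nrow(s4), 1L)
  expect_lt(abs(s4$sensitivity - 3), 4 * s4$se)
  expect_lt(s4$p_value, 0.05)
  # a constant EC is skipped with a message
  flat <- list(flat = stats::setNames(rep(1, 4), sprintf("env%d", 1:4)))
  expect_message(s4b <- fit_model4(blues, dos, "c1m11", qei, flat),
                 "constant")
  expect_equal(nrow(s4b), 0L)
})

test_that("EC rescaling leaves p-values and projections unchanged", {
  sim <- simulate_bcnam(small_sim_config(n_progeny = 200L, seed = 44))
  dos <- dosage_from_sim(sim)
  blues <- fit_env_blues(sim$phenotypes)
  qei <- data.frame(qtl = "c1m11", parent = "D1")
  ecv <- sim$ec_values$photoperiod + 12.4
  a <- fit_model4(blues, dos, "c1m11", qei, list(photoperiod = ecv))
  scl <- 3.7
  b <- fit_model4(blues, dos, "c1m11", qei,
                  list(photoperiod = 10 + scl * ecv))
  expect_equal(a$p_value, b$p_value, tolerance = 1e-8)
  expect_equal(b$sensitivity, a$sensitivity / scl, tolerance = 1e-6)
  grid <- data.frame(point = 1:6, photoperiod = seq(12, 13, length.out = 6))
  grid_b <- grid
  grid_b$photoperiod <- 10 + scl * grid$photoperiod
  pa <- project_effects(a, grid)
  pb <- project_effects(b, grid_b)
  expect_equal(pa$qeff, pb$qeff, tolerance = 1e-8)
})

test_that("classification summarises allele proportions", {
  tab <- data.frame(qtl = "q1", parent = c("A", "B", "C"),
                    p_alpha = c(0.001, 0.5, 0.01),
                    p_qei = c(0.02, 0.9, 0.4))
  eff <- structure(list(table = tab), class = "allelic_effects")
  sens <- data.frame(qtl = "q1", parent = c("A", "A"),
                     ec = c("e1", "e2"), p_value = c(0.01, 0.3))
  cl <- classify_alleles(eff, sens)
  expect_equal(cl$n_alleles, 3L)
  expect_equal(cl$prop_significant, 2 / 3)
  expect_equal(cl$prop_qei, 1 / 3)
  expect_equal(cl$prop_ec_interacting, 1 / 3)
  empty <- classify_alleles(structure(list(table = NULL),
                                      class = "allelic_effects"))
  expect_equal(empty$n_alleles, 0L)
})

test_that("unique-QTL grouping follows the iterative agglomeration rule", {
  q1 <- data.frame(chr = 1, pos = c(12, 18, 40))
  g1 <- group_unique_qtl(q1, max_span = 10)
  expect_equal(nrow(g1), 2L)
  expect_equal(g1$pos_min, c(12, 40))
  expect_equal(g1$span, c(6, 0))

  q2 <- data.frame(chr = 1, pos = c(0, 8, 16))
  g2 <- group_unique_qtl(q2, max_span = 10)
  expect_equal(nrow(g2), 2L)
  expect_equal(g2$members[1], "0;8")   # leftmost pair merged first
  expect_equal(g2$pos_max[2], 16)

  g3 <- group_unique_qtl(data.frame(chr = 2, pos = 33), max_span = 10)
  expect_equal(nrow(g3), 1L)
  expect_equal(g3$n_members, 1L)

  # invariance to input order; spans never exceed the cap
  set.seed(45)
  q4 <- data.frame(chr = rep(1:2, each = 6),
                   pos = c(0, 3, 9, 30, 33, 60, 5, 6, 7, 50, 58, 59))
  g4a <- group_unique_qtl(q4, max_span = 10)
  g4b <- group_unique_qtl(q4[sample(nrow(q4)), ], max_span = 10)
  expect_equal(g4a, g4b)
  expect_true(all(g4a$span <= 10))
})

test_that("projection is affine in the EC and matches fitted env effects", {
  sens <- data.frame(qtl = "q1", parent = "D1", ec = "photoperiod",
                     alpha = 2, sensitivity = 3, ec_center = 0,
                     p_value = 0.01)
  grid <- data.frame(point = 1, photoperiod = 0.5)
  expect_equal(project_effects(sens, grid)$qeff, 3.5)
  grid60 <- data.frame(point = 1:60, lat = 12.5, lon = -5,
                       photoperiod = seq(11.8, 13.2, length.out = 60))
  p60 <- project_effects(sens, grid60)
  expect_equal(nrow(p60), 60L)
  # affine: two points determine the whole surface
  slope <- (p60$qeff[60] - p60$qeff[1]) /
    (grid60$photoperiod[60] - grid60$photoperiod[1])
  expect_equal(slope, 3)
  expect_error(project_effects(sens, data.frame(point = 1, tmax = 30)),
               "lacks a column")

  # consistency identity: projecting at a fitted environment's EC value
  # reproduces that environment's allelic effect alpha + S * (EC - mean)
  sim <- simulate_bcnam(small_sim_config(n_progeny = 150L, seed = 46))
  dos <- dosage_from_sim(sim)
  blues <- fit_env_blues(sim$phenotypes)
  qei <- data.frame(qtl = "c1m11", parent = "D1")
  ecv <- sim$ec_values$photoperiod + 12.4
  s4 <- fit_model4(blues, dos, "c1m11", qei, list(photoperiod = ecv))
  gridE <- data.frame(point = 1:4, photoperiod = unname(ecv))
  pE <- project_effects(s4, gridE)
  fit <- attr(s4, "fits")$photoperiod
  a <- fit$beta[["q:c1m11.D1.a"]]
  S <- fit$beta[["q:c1m11.D1.S"]]
  expect_equal(pE$qeff, as.numeric(a + S * (ecv - mean(ecv))),
               tolerance = 1e-10)
})
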