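# REML with unstructured environment covariance, Wald tests, the
# fixed-Sigma GLS scan statistic, Li-Ji Meff and thresholds.

test_that("REML matches the closed-form sample covariance on balanced data", {
  Sig <- matrix(c(2, 0.8, 0.5,
                  0.8, 1.5, 0.3,
                  0.5, 0.3, 1.0), 3)
  blues <- mvn_blues(n = 20, Sigma = Sig, seed = 3)
  fit <- reml_fit(blues, env_design(blues))
  Y <- matrix(blues$value, 20)
  oracle <- stats::cov(Y)            # REML of mean + unstructured Sigma
  expect_lt(max(abs(fit$Sigma - oracle)), 1e-6)
  expect_equal(unname(fit$beta), unname(colMeans(Y)), tolerance = 1e-8)
})

test_that("a four-environment fit carries 10 covariance parameters", {
  blues <- mvn_blues(n = 15, Sigma = diag(4), seed = 4)
  fit <- reml_fit(blues, env_design(blues))
  expect_equal(fit$n_vcov_params, 10)
  expect_equal(dim(fit$Sigma), c(4L, 4L))
  # PSD by construction
  expect_gte(min(eigen(fit$Sigma, symmetric = TRUE,
                       only.values = TRUE)$values), 0)
})

test_that("one environment degenerates to the OLS residual variance", {
  set.seed(7)
  n <- 30
  blues <- data.frame(genotype = sprintf("g%02d", 1:n),
                      environment = "e1", value = stats::rnorm(n, 5, 2))
  X <- matrix(1, n, 1, dimnames = list(NULL, "mu"))
  fit <- reml_fit(blues, X)
  expect_equal(dim(fit$Sigma), c(1L, 1L))
  expect_equal(fit$Sigma[1, 1], stats::var(blues$value),
               tolerance = 1e-6)   # REML denominator n - 1
})

test_that("incomplete genotypes use their observed-environment submatrix", {
  Sig <- matrix(c(1.5, 0.6, 0.6, 1.0), 2)
  blues <- mvn_blues(n = 60, Sigma = Sig, seed = 9)
  drop <- sample(which(blues$environment == "e2"), 10)
  blues <- blues[-drop, ]
  fit <- reml_fit(blues, env_design(blues))
  expect_equal(dim(fit$Sigma), c(2L, 2L))
  expect_lt(max(abs(fit$Sigma - Sig)), 0.6)   # sanity at this n
  expect_equal(fit$convergence, 0)
})

test_that("Wald test follows the 1-df algebra and handles zero estimates", {
  V <- diag(c(0.04, 0.09, 0.25))
  dimnames(V) <- list(c("a", "b", "c"), c("a", "b", "c"))
  fit <- structure(list(beta = c(a = 0.6, b = 0, c = 1.2), vcov_beta = V),
                   class = "mpp_fit")
  w <- wald_test(fit, "a")
  expect_equal(w$statistic, 0.6^2 / 0.04)
  expect_equal(w$df, 1L)
  expect_equal(w$p_value, stats::pchisq(9, 1, lower.tail = FALSE))
  w0 <- wald_test(fit, "b")
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
  w2 <- wald_test(fit, c("a", "c"))
  expect_equal(w2$df, 2L)
  expect_equal(w2$statistic, 9 + 1.2^2 / 0.25)
})

test_that("a singular coefficient covariance falls back to rank df", {
  V <- matrix(1, 2, 2)
  dimnames(V) <- list(c("a", "b"), c("a", "b"))
  fit <- structure(list(beta = c(a = 1, b = 1), vcov_beta = V),
                   class = "mpp_fit")
  expect_warning(w <- wald_test(fit, c("a", "b")), "singular")
  expect_equal(w$df, 1L)
})

test_that("Wald p-values are calibrated under the null", {
  set.seed(13)
  n_rep <- 400
  n <- 150
  p <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    blues <- mvn_blues(n = n, Sigma = 0.5 * diag(3) + 0.5,
                       seed = 1000 + r)
    X <- env_design(blues)
    x <- stats::rbinom(n, 2, 0.25)        # a marker with no effect
    Q <- matrix(0, nrow(blues), 3)
    ei <- as.integer(factor(blues$environment))
    for (j in 1:3) Q[, j] <- x[match(blues$genotype,
                                     unique(blues$genotype))] * (ei == j)
    fit <- reml_fit(blues, cbind(X, Q))
    w <- wald_test(fit, ncol(X) + 1:3)
    p[r] <- w$p_value
  }
  rej <- mean(p < 0.05)
  # generous binomial band around the nominal 0.05 at 400 replicates
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.085)
})

test_that("fixed-Sigma GLS equals the exact Wald when Sigma is the joint fit's", {
  sim <- simulate_bcnam(small_sim_config(n_progeny = 60L, n_env = 3,
                                         seed = 22, vcov = diag(3)))
  dos <- dosage_from_sim(sim)
  blues <- fit_env_blues(sim$phenotypes)
  st <- mppqtlx:::.make_stack(blues)
  Xb <- mppqtlx:::.base_design(st)
  bd <- build_design_matrix(dos, "c1m11", min_seg = 5)
  Q <- mppqtlx:::.expand_env(st, bd)
  joint <- mppqtlx:::.reml_fit_stack(st, cbind(Xb, Q))
  w_exact <- wald_test(joint, colnames(Q))
  ctx <- gls_context(blues, Xb, joint$Sigma)
  w_gls <- gls_scan_stat(ctx, Q)
  expect_lt(abs(w_exact$statistic - w_gls$statistic) /
              w_exact$statistic, 1e-8)
  expect_equal(w_exact$df, w_gls$df)
})

test_that("GLS with identity Sigma collapses to the OLS statistic", {
  set.seed(15)
  n <- 50
  blues <- mvn_blues(n = n, Sigma = diag(3), seed = 15)
  X <- env_design(blues)
  x <- stats::rnorm(n)
  Q <- matrix(x[match(blues$genotype, unique(blues$genotype))], ncol = 1)
  ctx <- gls_context(blues, X, diag(3))
  w <- gls_scan_stat(ctx, Q)
  # OLS with unit error variance: stat = ||P_{Q|X} y||^2
  qx <- qr(X)
  yr <- qr.resid(qx, blues$value)
  Qr <- qr.resid(qx, Q)
  stat_ols <- sum(Qr * yr)^2 / sum(Qr^2)
  expect_equal(w$statistic, stat_ols, tolerance = 1e-10)
})

test_that("Meff matches eigenvalue oracles and is invariant to coding", {
  set.seed(23)
  # independent markers -> Meff = M
  S <- matrix(stats::rnorm(500 * 6), 500)
  expect_equal(meff_li_ji(S), 6, tolerance = 0.15)
  # perfectly correlated markers -> Meff = 1
  base <- stats::rnorm(200)
  S1 <- cbind(base, 2 * base, -base + 0 * base)
  expect_equal(meff_li_ji(S1), 1)
  # AR(1) rho = 0.5, M = 5: direct eigen evaluation as oracle
  rho <- 0.5
  C <- rho^abs(outer(1:5, 1:5, "-"))
  lam <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  oracle <- sum((lam >= 1) + (lam - floor(lam)))
  L <- chol(C)
  S2 <- matrix(stats::rnorm(200000 * 5), ncol = 5) %*% L
  expect_equal(meff_li_ji(S2), oracle, tolerance = 0.02)
  # invariance to marker order and affine rescaling
  S3 <- S2[, c(3, 1, 5, 2, 4)]
  expect_equal(meff_li_ji(S3), meff_li_ji(S2), tolerance = 1e-10)
  S4 <- sweep(sweep(S2, 2, c(1, 2, 3, 4, 5), "*"), 2, 7, "+")
  expect_equal(meff_li_ji(S4), meff_li_ji(S2), tolerance = 1e-10)
})

test_that("Meff sums over chromosomes and drops constant markers", {
  set.seed(29)
  S <- matrix(stats::rnorm(300 * 4), 300)
  colnames(S) <- c("m1", "m2", "m3", "m4")
  map <- data.frame(marker = colnames(S), chr = c(1, 1, 2, 2),
                    pos = c(0, 10, 0, 10))
  whole <- meff_li_ji(S, map)
  expect_equal(whole, meff_li_ji(S[, 1:2]) + meff_li_ji(S[, 3:4]),
               tolerance = 1e-10)
  S[, 2] <- 5
  expect_message(m <- meff_li_ji(S, map), "constant")
  expect_equal(m, 1 + meff_li_ji(S[, 3:4]), tolerance = 1e-10)
})

test_that("the genome-wide threshold follows 1-(1-alpha)^(1/Meff)", {
  expect_equal(significance_threshold(0.05, 1)$p_threshold, 0.05)
  expect_equal(significance_threshold(0.05, 100)$p_threshold,
               1 - 0.95^(1 / 100), tolerance = 1e-12)
  th <- vapply(c(1, 2, 5, 20, 100, 1000),
               function(m) significance_threshold(0.05, m)$p_threshold,
               numeric(1))
  expect_true(all(diff(th) < 0))
  expect_true(all(th > 0 & th <= 0.05 + 1e-12))
})
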