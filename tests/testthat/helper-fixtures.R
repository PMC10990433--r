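# Shared fixture builders: small simulated experiments and hand-built
# tables used across the module tests.

# Two-cross, two-chromosome BCNAM at desk scale; one photoperiod-sensitive
# QTL unless overridden.
small_sim_config <- function(n_progeny = 150L, n_env = 4, seed = 1L,
                             qtl = NULL, vcov = NULL, ...) {
  if (is.null(qtl)) {
    qtl <- list(qtl_spec(1, 50, alpha = c(D1 = 1.0, D2 = -0.8),
                         sensitivity = c(D1 = 3), ec = "photoperiod"))
  }
  if (is.null(vcov)) vcov <- 0.5 * diag(n_env) + 0.5
  sim_config(
    crosses = data.frame(cross = c("cr1", "cr2"), recurrent = "R1",
                         donor = c("D1", "D2"),
                         n_progeny = rep(as.integer(n_progeny), 2)),
    n_environments = n_env, qtl = qtl, vcov = vcov, seed = seed, ...)
}

# A deterministic noise-free configuration: no GxE, no plot error, no
# block effects.
noiseless_config <- function(...) {
  small_sim_config(vcov = matrix(0, 4, 4), error_sd = 0, block_sd = 0, ...)
}

# Balanced complete multivariate-normal BLUE table with known Sigma and
# environment means; the closed-form REML oracle applies to it.
mvn_blues <- function(n = 20, Sigma = diag(3), mu = NULL, seed = 1) {
  set.seed(seed)
  J <- nrow(Sigma)
  if (is.null(mu)) mu <- seq(10, by = 2, length.out = J)
  Y <- matrix(stats::rnorm(n * J), n) %*% chol(Sigma) +
    matrix(mu, n, J, byrow = TRUE)
  data.frame(genotype = rep(sprintf("g%03d", seq_len(n)), J),
             environment = rep(sprintf("e%d", seq_len(J)), each = n),
             value = as.vector(Y))
}

# Environment-mean design for a BLUE table.
env_design <- function(blues) {
  env <- factor(blues$environment)
  X <- stats::model.matrix(~ 0 + env)
  colnames(X) <- levels(env)
  X
}

# Hand-built three-peak scan profile on one chromosome (positions in cM).
toy_profile <- function() {
  p <- rep(0.5, 21)
  pos <- seq(0, 100, by = 5)
  p[pos == 10] <- 1e-8
  p[pos == 25] <- 1e-6
  p[pos == 60] <- 1e-4
  structure(data.frame(marker = sprintf("m%02d", seq_along(pos)),
                       chr = 1L, pos = pos, n_alleles = 2L,
                       wald = -log(p), df = 8L, p = p,
                       neg_log10_p = -log10(p), df_alleles = 2L,
                       p_alleles = p, scannable = TRUE,
                       cofactors_active = "",
                       stringsAsFactors = FALSE),
            class = c("scan_profile", "data.frame"))
}
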