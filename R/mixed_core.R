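# Multi-environment mixed models on genotype BLUEs with an unstructured
# environment (co)variance for the combined GxE + error term. Genotypes are
# independent blocks; each genotype's covariance is the submatrix of Sigma
# for its observed environments. Sigma is parameterized by its log-Cholesky
# factor so every iterate is positive definite.

# ---- stacked data -----------------------------------------------------------

# Internal canonical representation of a BLUE table: numeric response plus
# integer genotype/environment indices and the observation pattern grouping.
.make_stack <- function(blues, trait = NULL) {
  if (!is.null(trait) && "trait" %in% names(blues)) {
    blues <- blues[blues$trait == trait, ]
  }
  blues <- blues[!is.na(blues$value), ]
  env <- factor(blues$environment)
  geno <- factor(blues$genotype)
  if (anyDuplicated(paste(geno, env))) {
    stop("more than one BLUE per (genotype, environment)")
  }
  list(y = as.numeric(blues$value), env = env, geno = geno,
       cross = if ("cross" %in% names(blues)) factor(blues$cross) else NULL,
       envs = levels(env), genos = levels(geno),
       data = blues)
}

# Group genotypes by their set of observed environments. Returns, per
# pattern: the environment indices (sorted) and an m x n matrix of
# observation row indices (column = genotype, rows in environment order).
.stack_patterns <- function(stack) {
  ei <- as.integer(stack$env)
  gi <- as.integer(stack$geno)
  o <- order(gi, ei)
  sp <- split(o, gi[o])
  key <- vapply(sp, function(ix) paste(ei[ix], collapse = ","),
                character(1))
  pats <- list()
  for (k in unique(key)) {
    cols <- sp[key == k]
    pats[[k]] <- list(envs = ei[cols[[1]]],
                      idx = matrix(unlist(cols), nrow = length(cols[[1]])))
  }
  pats
}

# Whitening machinery for a fixed Sigma: returns a function mapping any
# observation-aligned matrix to its whitened version, plus log|V|.
.whitener <- function(patterns, Sigma) {
  n_obs <- sum(vapply(patterns, function(p) length(p$idx), numeric(1)))
  Us <- list(); logdet <- 0
  for (k in seq_along(patterns)) {
    p <- patterns[[k]]
    S <- Sigma[p$envs, p$envs, drop = FALSE]
    R <- chol(S)
    logdet <- logdet + ncol(p$idx) * 2 * sum(log(diag(R)))
    Us[[k]] <- forwardsolve(t(R), diag(nrow(S)))
  }
  apply_w <- function(M) {
    M <- as.matrix(M)
    out <- matrix(0, n_obs, ncol(M))
    for (k in seq_along(patterns)) {
      p <- patterns[[k]]
      iv <- as.vector(p$idx)
      m <- nrow(p$idx)
      A <- M[iv, , drop = FALSE]
      B <- Us[[k]] %*% matrix(A, m, length(iv) / m * ncol(M))
      out[iv, ] <- matrix(B, length(iv), ncol(M))
    }
    out
  }
  list(apply = apply_w, logdetV = logdet)
}

# log-Cholesky <-> matrix
.theta_to_sigma <- function(theta, J) {
  L <- matrix(0, J, J)
  L[lower.tri(L, diag = TRUE)] <- theta
  diag(L) <- exp(diag(L))
  tcrossprod(L)
}
.sigma_to_theta <- function(Sigma) {
  L <- t(chol(Sigma))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

# Moment starting value: per-environment OLS residuals arranged as a
# genotype x environment matrix, sample covariance over genotypes (pairwise
# complete), ridged to positive definiteness.
.sigma_start <- function(stack, X) {
  r <- stats::residuals(stats::lm.fit(X, stack$y))
  J <- length(stack$envs)
  Rm <- matrix(NA_real_, length(stack$genos), J)
  Rm[cbind(as.integer(stack$geno), as.integer(stack$env))] <- r
  S <- stats::cov(Rm, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 * max(abs(ev), 1)) {
    S <- S + diag(max(1e-6, 1e-4 * mean(diag(S))), J)
  }
  S
}

#' REML fit of the unstructured multi-environment model
#'
#' Estimates the fixed effects of a user-supplied design matrix by
#' generalized least squares under an unstructured environment covariance
#' Sigma for the combined GxE + error deviations of genotype means, with
#' Sigma maximizing the restricted likelihood. Genotypes are independent;
#' an incomplete genotype contributes the Sigma submatrix of its observed
#' environments. Sigma is optimized on the log-Cholesky scale (every
#' iterate positive definite) with a quasi-Newton method.
#'
#' @param blues A `blue_table` (or any data frame with `genotype`,
#'   `environment`, `value`).
#' @param X Fixed-effect design matrix, rows aligned with `blues` rows
#'   (after dropping missing values); aliased columns are dropped in
#'   first-come order.
#' @param trait Optional trait filter.
#' @param init Optional starting Sigma; default is a moment estimator.
#' @param maxit,reltol Optimizer control (quasi-Newton BFGS).
#' @return Object of class `mpp_fit`: `beta`, `vcov_beta`, `Sigma`,
#'   `loglik` (restricted, up to a constant), `n_vcov_params`,
#'   `convergence`, `kept` (retained design columns), plus the internal
#'   stack for downstream tests.
#' @export
reml_fit <- function(blues, X, trait = NULL, init = NULL,
                     maxit = 200, reltol = 1e-10) {
  stack <- .make_stack(blues, trait)
  X <- as.matrix(X)
  if (nrow(X) != length(stack$y)) {
    stop("design matrix rows (", nrow(X), ") do not match the ",
         length(stack$y), " usable BLUEs")
  }
  .reml_fit_stack(stack, X, init = init, maxit = maxit, reltol = reltol)
}

.reml_fit_stack <- function(stack, X, init = NULL, maxit = 200,
                            reltol = 1e-10) {
  J <- length(stack$envs)
  keep <- .drop_aliased(X)
  Xk <- X[, keep, drop = FALSE]
  patterns <- .stack_patterns(stack)
  y <- stack$y
  p <- ncol(Xk)
  crit <- function(theta) {
    Sigma <- .theta_to_sigma(theta, J)
    w <- tryCatch(.whitener(patterns, Sigma), error = function(e) NULL)
    if (is.null(w)) return(1e10)
    yt <- w$apply(matrix(y, ncol = 1))
    Xt <- w$apply(Xk)
    C <- crossprod(Xt)
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Xty <- crossprod(Xt, yt)
    b <- backsolve(ch, backsolve(ch, Xty, transpose = TRUE))
    quad <- sum(yt^2) - sum(Xty * b)
    if (!is.finite(quad) || quad < 0) return(1e10)
    0.5 * (w$logdetV + 2 * sum(log(diag(ch))) + quad)
  }
  S0 <- if (is.null(init)) .sigma_start(stack, Xk) else as.matrix(init)
  theta0 <- .sigma_to_theta(S0)
  opt <- stats::optim(theta0, crit, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  if (opt$convergence != 0) {
    warning("REML optimizer did not report convergence (code ",
            opt$convergence, "); returning last iterate", call. = FALSE)
  }
  Sigma <- .theta_to_sigma(opt$par, J)
  dimnames(Sigma) <- list(stack$envs, stack$envs)
  w <- .whitener(patterns, Sigma)
  yt <- w$apply(matrix(y, ncol = 1))
  Xt <- w$apply(Xk)
  C <- crossprod(Xt)
  ch <- chol(C)
  Xty <- crossprod(Xt, yt)
  beta <- drop(backsolve(ch, backsolve(ch, Xty, transpose = TRUE)))
  names(beta) <- colnames(Xk)
  vcov_beta <- chol2inv(ch)
  dimnames(vcov_beta) <- list(colnames(Xk), colnames(Xk))
  structure(list(
    beta = beta, vcov_beta = vcov_beta, Sigma = Sigma,
    loglik = -opt$value, n_vcov_params = J * (J + 1) / 2,
    convergence = opt$convergence, counts = opt$counts,
    kept = keep, dropped = colnames(X)[setdiff(seq_len(ncol(X)), keep)],
    stack = stack, X = Xk), class = "mpp_fit")
}

#' @export
print.mpp_fit <- function(x, ...) {
  cat(sprintf(
    "REML fit: %d obs, %d environments, %d fixed effects, %d VCOV parameters\n",
    length(x$stack$y), length(x$stack$envs), length(x$beta),
    x$n_vcov_params))
  cat(sprintf("  restricted log-likelihood (up to const): %.4f\n", x$loglik))
  invisible(x)
}

#' Wald test on a subset of fixed effects
#'
#' Quadratic-form chi-square test `b' V(b)^-1 b` on the named (or indexed)
#' coefficients of a fitted model, with degrees of freedom equal to the
#' number of estimable parameters in the subset.
#'
#' @param fit An `mpp_fit`.
#' @param coefficients Character names or integer indices of the tested
#'   coefficient block.
#' @return A `wald_result`: `statistic`, `df`, `p_value`, `neg_log10_p`.
#' @export
wald_test <- function(fit, coefficients) {
  stopifnot(inherits(fit, "mpp_fit"))
  idx <- if (is.character(coefficients)) {
    match(coefficients, names(fit$beta))
  } else {
    as.integer(coefficients)
  }
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    stop("no estimable coefficient in the requested subset")
  }
  .wald_quad(fit$beta[idx], fit$vcov_beta[idx, idx, drop = FALSE])
}

# ---- fixed-Sigma GLS scan machinery ----------------------------------------

#' Build a fixed-Sigma GLS context for genome scans
#'
#' Whitens the response and the null (cofactor-only) design once under a
#' Sigma estimated on the null model, so each scan position only requires
#' residualizing and testing its QTL incidence columns. This is the
#' approximate scan statistic: Sigma is not re-estimated per position.
#'
#' @param blues A `blue_table`.
#' @param X_null Null-model design matrix (environment, cross-within-
#'   environment, cofactor terms).
#' @param Sigma Unstructured covariance from the null-model REML fit.
#' @param trait Optional trait filter.
#' @return Object of class `gls_context`.
#' @export
gls_context <- function(blues, X_null, Sigma, trait = NULL) {
  stack <- .make_stack(blues, trait)
  .gls_context_stack(stack, X_null, Sigma)
}

.gls_context_stack <- function(stack, X_null, Sigma) {
  if (!is.null(dimnames(Sigma)) &&
      all(stack$envs %in% rownames(Sigma))) {
    Sigma <- Sigma[stack$envs, stack$envs, drop = FALSE]
  }
  patterns <- .stack_patterns(stack)
  w <- .whitener(patterns, Sigma)
  keep <- .drop_aliased(X_null)
  Xt <- w$apply(X_null[, keep, drop = FALSE])
  yt <- drop(w$apply(matrix(stack$y, ncol = 1)))
  q0 <- qr(Xt)
  structure(list(stack = stack, Sigma = Sigma, whiten = w$apply,
                 qr0 = q0, yt = yt, y_res = qr.resid(q0, yt),
                 n_null = ncol(Xt)),
            class = "gls_context")
}

#' Approximate GLS Wald statistic at one position
#'
#' Tests the QTL incidence block `Q` (already expanded to its per-
#' environment columns) added to the null design, holding Sigma fixed at
#' the null-model estimate. With Sigma equal to the joint-fit estimate this
#' reproduces the exact Wald statistic; the approximation's only error
#' source is the re-use of the null Sigma across positions.
#'
#' @param ctx A [gls_context()].
#' @param Q Observation-aligned matrix of QTL columns.
#' @param df_alleles Optional alternative degrees of freedom (number of
#'   parental alleles) for the secondary p-value convention.
#' @return A `wald_result`, with `estimate`, `vcov` and (when
#'   `df_alleles` is given) `p_alleles` attached.
#' @export
gls_scan_stat <- function(ctx, Q, df_alleles = NULL) {
  stopifnot(inherits(ctx, "gls_context"))
  Qt <- ctx$whiten(as.matrix(Q))
  Qr <- qr.resid(ctx$qr0, Qt)
  G <- crossprod(Qr)
  z <- crossprod(Qr, ctx$yt)
  res <- tryCatch({
    ch <- chol(G)
    u <- backsolve(ch, z, transpose = TRUE)
    gamma <- backsolve(ch, u)
    list(stat = sum(u^2), df = ncol(Qr), gamma = drop(gamma),
         vc = chol2inv(ch))
  }, error = function(e) NULL)
  if (is.null(res)) {
    ev <- eigen(G, symmetric = TRUE)
    tol <- max(ev$values, 0) * nrow(G) * .Machine$double.eps
    pos <- ev$values > max(tol, 1e-12)
    if (!any(pos)) return(NULL)
    Vp <- ev$vectors[, pos, drop = FALSE]
    u <- drop(crossprod(Vp, z)) / sqrt(ev$values[pos])
    res <- list(stat = sum(u^2), df = sum(pos),
                gamma = drop(Vp %*% (crossprod(Vp, z) / ev$values[pos])),
                vc = Vp %*% (t(Vp) / ev$values[pos]))
  }
  p <- stats::pchisq(res$stat, res$df, lower.tail = FALSE)
  out <- structure(
    list(statistic = res$stat, df = res$df, p_value = p,
         neg_log10_p = -log10(max(p, .Machine$double.xmin))),
    class = "wald_result")
  attr(out, "estimate") <- res$gamma
  attr(out, "vcov") <- res$vc
  if (!is.null(df_alleles)) {
    attr(out, "df_alleles") <- df_alleles
    attr(out, "p_alleles") <- stats::pchisq(res$stat, df_alleles,
                                            lower.tail = FALSE)
  }
  out
}

# ---- multiple testing -------------------------------------------------------

#' Effective number of independent tests (Li-Ji)
#'
#' Computes, per chromosome, the eigenvalues of the marker correlation
#' matrix and sums `f(lambda) = 1(lambda >= 1) + (lambda - floor(lambda))`;
#' chromosome contributions are added (linkage does not extend across
#' chromosomes). Constant markers are removed first. Chromosomes are thinned
#' to at most `max_markers` evenly spaced markers before the eigen
#' decomposition.
#'
#' @param scores Matrix individuals x markers (any numeric coding; the
#'   result is invariant to affine rescaling and marker order).
#' @param map Optional genetic map restricting/grouping the columns by
#'   chromosome; without it, all markers form one block.
#' @param max_markers Per-chromosome thinning cap (default 2000).
#' @return Effective number of tests, `1 <= Meff <= M`.
#' @export
meff_li_ji <- function(scores, map = NULL, max_markers = 2000) {
  scores <- as.matrix(scores)
  blocks <- if (is.null(map)) {
    list(seq_len(ncol(scores)))
  } else {
    mk <- intersect(map$marker, colnames(scores))
    split(match(mk, colnames(scores)), map$chr[match(mk, map$marker)])
  }
  meff <- 0
  for (idx in blocks) {
    if (length(idx) > max_markers) {
      idx <- idx[unique(round(seq(1, length(idx),
                                  length.out = max_markers)))]
    }
    S <- scores[, idx, drop = FALSE]
    sds <- apply(S, 2, stats::sd, na.rm = TRUE)
    if (any(sds == 0 | is.na(sds))) {
      message(sum(sds == 0 | is.na(sds)),
              " constant marker(s) removed before Meff computation")
      S <- S[, sds > 0 & !is.na(sds), drop = FALSE]
    }
    m <- ncol(S)
    if (m == 0L) next
    if (m == 1L) { meff <- meff + 1; next }
    C <- stats::cor(S, use = "pairwise.complete.obs")
    C[is.na(C)] <- 0; diag(C) <- 1
    lam <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    lam <- pmax(lam, 0)
    # snap to integers: floor() is discontinuous there and numerical
    # eigenvalues of exactly-singular correlation matrices sit at 3 - eps
    snap <- abs(lam - round(lam)) < 1e-8
    lam[snap] <- round(lam[snap])
    meff <- meff + min(max(sum((lam >= 1) + (lam - floor(lam))), 1), m)
  }
  if (meff < 1) stop("need at least 2 markers with variance")
  meff
}

#' Genome-wide significance threshold from Meff
#'
#' Per-test p-value threshold `1 - (1 - alpha)^(1/Meff)` controlling the
#' family-wise error at `alpha` over Meff effectively independent tests.
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param meff Effective number of tests (>= 1).
#' @return List with `p_threshold` and `neg_log10_p`.
#' @export
significance_threshold <- function(alpha = 0.05, meff) {
  stopifnot(alpha > 0, alpha < 1, meff >= 1)
  p <- 1 - (1 - alpha)^(1 / meff)
  list(p_threshold = p, neg_log10_p = -log10(p))
}
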