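#' Within-environment BLUEs of genotype means
#'
#' Fits, separately for each environment, an ordinary least-squares model
#' with fixed genotype effects and fixed block (within replicate) effects
#' under sum-to-zero block contrasts, so each genotype BLUE is its adjusted
#' mean at the average block. Replicated entries (checks) carry the block
#' information in unreplicated augmented layouts. Genotypes sitting only in
#' blocks whose effect is inestimable get a missing BLUE.
#'
#' @param plots Data frame with columns `genotype`, `environment`, `value`
#'   and optionally `replicate`, `block`, `trait`, `cross`.
#' @param trait Optional trait to filter on when a `trait` column is present.
#' @return Data frame of class `blue_table`: `genotype`, `cross` (if
#'   available), `environment`, `trait`, `value` (the BLUE), `se`.
#' @export
fit_env_blues <- function(plots, trait = NULL) {
  if (!is.null(trait) && "trait" %in% names(plots)) {
    plots <- plots[plots$trait == trait, ]
  }
  plots <- plots[!is.na(plots$value), ]
  out <- lapply(split(plots, plots$environment), .blues_one_env)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("blue_table", "data.frame")
  res
}

.blues_one_env <- function(d) {
  if (length(unique(d$genotype)) < 2L) {
    stop("need at least 2 genotypes with data in environment ",
         d$environment[1])
  }
  g <- factor(d$genotype)
  blk <- if (all(c("replicate", "block") %in% names(d))) {
    interaction(d$replicate, d$block, drop = TRUE)
  } else if ("block" %in% names(d)) {
    factor(d$block)
  } else {
    factor(rep(1, nrow(d)))
  }
  if (nlevels(blk) > 1L) {
    B <- stats::model.matrix(~blk, contrasts.arg = list(blk = "contr.sum"))
    B <- B[, -1, drop = FALSE]
    fit <- stats::lm(d$value ~ 0 + g + B)
  } else {
    fit <- stats::lm(d$value ~ 0 + g)
  }
  cf <- stats::coef(fit)
  gi <- grep("^g", names(cf))
  blue <- cf[gi]
  names(blue) <- sub("^g", "", names(blue))
  se <- rep(NA_real_, length(blue))
  ok <- !is.na(blue)
  vc <- diag(stats::vcov(fit))
  se[ok] <- sqrt(vc[match(names(cf)[gi][ok], names(vc))])
  # genotypes confined to blocks with inestimable (aliased) effects are not
  # block-adjustable: their BLUE is reported missing
  if (nlevels(blk) > 1L && anyNA(cf)) {
    bad_b <- which(is.na(cf[grep("^B", names(cf))]))
    if (length(bad_b)) {
      bad_lv <- levels(blk)[bad_b + 1L]
      confined <- tapply(as.character(blk), d$genotype,
                         function(b) all(b %in% bad_lv))
      blue[names(which(confined))] <- NA
    }
  }
  lev <- names(blue)
  res <- data.frame(genotype = lev,
                    environment = d$environment[1],
                    trait = if ("trait" %in% names(d)) d$trait[1] else "trait",
                    value = as.numeric(blue), se = se,
                    stringsAsFactors = FALSE)
  if ("cross" %in% names(d)) {
    res$cross <- d$cross[match(lev, d$genotype)]
    res <- res[, c("genotype", "cross", "environment", "trait",
                   "value", "se")]
  }
  res
}

#' Cross-specific variance components from plot data
#'
#' Fits, per cross, the multi-environment plot model with fixed environment
#' (and block within environment) effects and random genotype, random
#' genotype-by-environment and residual terms by REML, yielding
#' cross-specific variances (sigma^2_G, sigma^2_GE, sigma^2_e). A replicate
#' random term is added when the layout is replicated. With no
#' within-environment replication the GxE and plot-error terms are
#' confounded at the plot level; the GxE term is then dropped and its
#' variance reported as 0 with a warning (the compound ends up in
#' sigma^2_e).
#'
#' @param plots Plot-level data frame (`genotype`, `cross`, `environment`,
#'   `replicate`, `block`, `value`).
#' @param trait Optional trait filter.
#' @return Data frame of class `variance_components`: one row per cross with
#'   `sigma2_G`, `sigma2_GE`, `sigma2_e`, `n_env`, `n_rep`, `h2`.
#' @export
estimate_variance_components <- function(plots, trait = NULL) {
  if (!is.null(trait) && "trait" %in% names(plots)) {
    plots <- plots[plots$trait == trait, ]
  }
  plots <- plots[!is.na(plots$value), ]
  if (length(unique(plots$environment)) < 2L) {
    stop("variance-component estimation needs >= 2 environments")
  }
  groups <- split(plots, plots$cross)
  small <- vapply(groups, function(d) length(unique(d$genotype)) < 2L,
                  logical(1))
  if (any(small)) {
    message("skipping group(s) with < 2 genotypes: ",
            paste(names(groups)[small], collapse = ", "))
    groups <- groups[!small]
  }
  if (length(groups) == 0L) stop("each cross needs >= 2 genotypes")
  out <- lapply(groups, .vc_one_cross)
  res <- do.call(rbind, out)
  res$cross <- names(out)
  res <- res[, c("cross", "sigma2_G", "sigma2_GE", "sigma2_e",
                 "n_env", "n_rep", "h2")]
  rownames(res) <- NULL
  class(res) <- c("variance_components", "data.frame")
  res
}

.vc_one_cross <- function(d) {
  if (length(unique(d$genotype)) < 2L) {
    stop("each cross needs >= 2 genotypes")
  }
  d$genotype <- factor(d$genotype)
  d$environment <- factor(d$environment)
  n_env <- nlevels(d$environment)
  n_rep <- if ("replicate" %in% names(d))
    max(table(d$genotype, d$environment)) else 1L
  replicated <- n_rep > 1L
  terms <- c("(1 | genotype)")
  if (replicated) terms <- c(terms, "(1 | genotype:environment)")
  if (replicated && "replicate" %in% names(d) &&
      length(unique(d$replicate)) > 1L) {
    d$rep_env <- interaction(d$environment, d$replicate, drop = TRUE)
    terms <- c(terms, "(1 | rep_env)")
  }
  if ("block" %in% names(d) && length(unique(d$block)) > 1L) {
    d$blk_env <- interaction(d$environment,
                             if ("replicate" %in% names(d)) d$replicate else 1,
                             d$block, drop = TRUE)
    terms <- c(terms, "(1 | blk_env)")
  }
  form <- stats::as.formula(paste("value ~ 0 + environment +",
                                  paste(terms, collapse = " + ")))
  fit <- suppressMessages(lme4::lmer(form, data = d, REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(term) {
    i <- which(vc$grp == term)
    if (length(i)) vc$vcov[i[1]] else 0
  }
  s2g <- getv("genotype")
  s2ge <- if (replicated) getv("genotype:environment") else 0
  s2e <- getv("Residual")
  if (!replicated) {
    warning("no within-environment replication: sigma2_GE confounded with ",
            "sigma2_e; reporting it as 0", call. = FALSE)
  }
  data.frame(sigma2_G = s2g, sigma2_GE = s2ge, sigma2_e = s2e,
             n_env = n_env, n_rep = n_rep,
             h2 = heritability(s2g, s2ge, s2e, n_env, n_rep))
}

#' Broad-sense heritability on an entry-mean basis
#'
#' `h2 = s2_G / (s2_G + s2_GE / n_env + s2_e / (n_env * n_rep))`.
#'
#' @param sigma2_G,sigma2_GE,sigma2_e Variance components (>= 0).
#' @param n_env Number of environments (>= 1).
#' @param n_rep Number of replicates per environment (>= 1).
#' @return Heritability in [0, 1]; `NA` with a warning when all components
#'   are zero.
#' @export
heritability <- function(sigma2_G, sigma2_GE, sigma2_e, n_env, n_rep) {
  stopifnot(n_env >= 1, n_rep >= 1)
  if (any(c(sigma2_G, sigma2_GE, sigma2_e) < 0)) {
    stop("variance components must be non-negative")
  }
  den <- sigma2_G + sigma2_GE / n_env + sigma2_e / (n_env * n_rep)
  if (den == 0) {
    warning("all variance components are zero: heritability undefined",
            call. = FALSE)
    return(NA_real_)
  }
  sigma2_G / den
}

#' Pearson correlations between trait BLUEs
#'
#' @param blues A `blue_table` with several traits.
#' @return Correlation matrix of per-genotype mean BLUEs across traits.
#' @export
blue_trait_cor <- function(blues) {
  wide <- tapply(blues$value, list(blues$genotype, blues$trait), mean,
                 na.rm = TRUE)
  stats::cor(wide, use = "pairwise.complete.obs")
}
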