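#' Specify a simulated QTL
#'
#' Defines one ground-truth QTL for the BCNAM simulator: its map location,
#' the main allelic effect of each donor parent relative to the recurrent
#' parent, an optional sensitivity of each donor allele to an environmental
#' covariate (EC), and optional residual environment-specific deviations.
#'
#' @param chr Chromosome index.
#' @param pos Position in cM; must coincide with a simulated marker.
#' @param alpha Named numeric, main effect per donor parent (trait units per
#'   donor allele). Donors absent from the vector get effect 0.
#' @param sensitivity Named numeric, EC sensitivity per donor parent (trait
#'   units per EC unit); `NULL` for a constitutive QTL.
#' @param ec Name of the daily EC the sensitivity acts on.
#' @param beta Optional matrix (donors x environments) of residual
#'   environment-specific deviations added on top of the EC response.
#' @return An object of class `qtl_spec`.
#' @export
qtl_spec <- function(chr, pos, alpha, sensitivity = NULL, ec = NA_character_,
                     beta = NULL) {
  stopifnot(length(chr) == 1L, length(pos) == 1L, pos >= 0)
  if (is.null(names(alpha)) || any(names(alpha) == "")) {
    stop("'alpha' must be a named vector (names = donor parent ids)")
  }
  if (!is.null(sensitivity) &&
      (is.null(names(sensitivity)) || any(names(sensitivity) == ""))) {
    stop("'sensitivity' must be a named vector")
  }
  if (!is.null(sensitivity) && is.na(ec)) {
    stop("an EC name is required when a sensitivity is specified")
  }
  structure(list(chr = chr, pos = pos, alpha = alpha,
                 sensitivity = sensitivity, ec = ec, beta = beta),
            class = "qtl_spec")
}

#' Simulation configuration for a multireference BCNAM design
#'
#' Bundles every parameter of the synthetic-data engine: genome layout,
#' cross design (several recurrent parents, each crossed to its own donors),
#' number of environments, daily EC series, ground-truth QTL architecture,
#' the unstructured environment covariance of the combined GxE + error term
#' on genotype means, and plot-level design parameters.
#'
#' The defaults emulate a backcross nested association mapping population of
#' BC1F4 lines (one backcross to the recurrent parent followed by three
#' selfing generations) evaluated in four environments, the scale at which
#' the field's multi-environment trials are typically analyzed.
#'
#' @param n_chromosomes,chromosome_length,n_markers_per_chr Genome layout;
#'   markers are evenly spaced from 0 to `chromosome_length` cM by default.
#' @param crosses Data frame with columns `cross`, `recurrent`, `donor`,
#'   `n_progeny`.
#' @param n_environments Number of environments (>= 2 for GxE structure).
#' @param n_days Length of the daily EC series per environment.
#' @param qtl List of [qtl_spec()] objects (may be empty for null data).
#' @param vcov Unstructured covariance (environments x environments) of the
#'   combined GxE + error deviation of genotype means; scalar is expanded to
#'   `diag(scalar, n_environments)`.
#' @param env_effects Environment means; default `seq` centered on 0.
#' @param error_sd Plot-level iid error standard deviation.
#' @param block_sd Standard deviation of iid block effects.
#' @param n_blocks Blocks per replicate within environment.
#' @param n_rep Replicates per environment (1 = unreplicated augmented-like
#'   layout with the recurrent parents as replicated checks).
#' @param n_selfing Selfing generations after the backcross (3 gives BC1F4).
#' @param ec_profiles Data frame describing the daily EC generator; see
#'   [simulate_ec()].
#' @param ec_phase_days Seasonal phase shift between consecutive
#'   environments (days), emulating staggered sowing dates; makes
#'   between-environment EC contrasts window-dependent.
#' @param ec_window `c(start, size)` window (days) used to turn daily series
#'   into the per-environment EC value that drives QTL sensitivities.
#' @param center_ec Center the driving EC at its across-environment mean, so
#'   a QTL main effect is the effect in the average environment.
#' @param prop_uninformative Fraction of markers at which the two parents of
#'   a cross share the same score (uninformative for dosage inference).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2,
                       chromosome_length = 100,
                       n_markers_per_chr = 21,
                       crosses = data.frame(
                         cross = c("cr1", "cr2"),
                         recurrent = c("R1", "R1"),
                         donor = c("D1", "D2"),
                         n_progeny = c(150L, 150L)),
                       n_environments = 4,
                       n_days = 120,
                       qtl = list(),
                       vcov = 1,
                       env_effects = NULL,
                       error_sd = 0.5,
                       block_sd = 0.5,
                       n_blocks = 4,
                       n_rep = 1,
                       n_selfing = 3,
                       ec_profiles = default_ec_profiles(),
                       ec_phase_days = 21,
                       ec_window = c(30, 40),
                       center_ec = TRUE,
                       prop_uninformative = 0,
                       seed = 1L) {
  stopifnot(n_chromosomes >= 1, chromosome_length > 0, n_markers_per_chr >= 1,
            n_environments >= 1, n_days >= 1, n_selfing >= 0,
            all(crosses$n_progeny >= 1), n_rep >= 1, n_blocks >= 1,
            prop_uninformative >= 0, prop_uninformative < 1)
  if (length(vcov) == 1L) vcov <- diag(vcov, n_environments)
  vcov <- as.matrix(vcov)
  if (!isTRUE(all.equal(vcov, t(vcov))) ||
      nrow(vcov) != n_environments) {
    stop("'vcov' must be a symmetric n_environments x n_environments matrix")
  }
  if (min(eigen(vcov, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("'vcov' must be positive semi-definite")
  }
  if (is.null(env_effects)) {
    env_effects <- seq_len(n_environments) - (n_environments + 1) / 2
  }
  for (q in qtl) {
    if (!inherits(q, "qtl_spec")) stop("'qtl' must be a list of qtl_spec")
    if (q$pos > chromosome_length) stop("QTL position outside chromosome")
  }
  structure(list(
    n_chromosomes = n_chromosomes, chromosome_length = chromosome_length,
    n_markers_per_chr = n_markers_per_chr, crosses = crosses,
    n_environments = n_environments, n_days = n_days, qtl = qtl,
    vcov = vcov, env_effects = env_effects, error_sd = error_sd,
    block_sd = block_sd, n_blocks = n_blocks, n_rep = n_rep,
    n_selfing = n_selfing, ec_profiles = ec_profiles,
    ec_phase_days = ec_phase_days,
    ec_window = ec_window, center_ec = center_ec,
    prop_uninformative = prop_uninformative, seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a genetic map
#'
#' @param config A [sim_config()].
#' @param spacing `"even"` (default) or `"uniform"` for uniform-random marker
#'   positions.
#' @return Data frame with columns `marker`, `chr`, `pos` (cM), sorted by
#'   chromosome and position.
#' @export
simulate_map <- function(config, spacing = c("even", "uniform")) {
  spacing <- match.arg(spacing)
  if (config$n_markers_per_chr < 1) stop("need at least one marker")
  maps <- lapply(seq_len(config$n_chromosomes), function(ch) {
    m <- config$n_markers_per_chr
    if (spacing == "even") {
      pos <- if (m == 1L) config$chromosome_length / 2 else
        seq(0, config$chromosome_length, length.out = m)
    } else {
      pos <- sort(stats::runif(m, 0, config$chromosome_length))
    }
    data.frame(marker = sprintf("c%dm%02d", ch, seq_len(m)),
               chr = ch, pos = pos, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, maps)
  rownames(out) <- NULL
  out
}

#' Haldane map function
#'
#' Recombination fraction per meiosis for a map distance in cM, assuming no
#' crossover interference: `r = (1 - exp(-2d/100)) / 2`.
#'
#' @param d_cm Map distance in centimorgans.
#' @return Recombination fraction in [0, 0.5).
#' @export
haldane_r <- function(d_cm) (1 - exp(-2 * d_cm / 100)) / 2

# One meiosis for n individuals over one chromosome.
# h1, h2: n x M haplotype matrices; r: length M-1 recombination fractions.
.meiosis <- function(h1, h2, r) {
  n <- nrow(h1); m <- ncol(h1)
  start <- stats::rbinom(n, 1, 0.5)
  if (m == 1L) {
    src <- matrix(start, n, 1)
  } else {
    co <- matrix(stats::rbinom(n * (m - 1L), 1, rep(r, each = n)), n, m - 1L)
    tri <- upper.tri(matrix(0, m - 1L, m - 1L), diag = TRUE)
    cum <- co %*% tri
    src <- (start + cbind(0, cum)) %% 2
  }
  h1 * (src == 0) + h2 * (src == 1)
}

#' Simulate one backcross-derived inbred cross
#'
#' Produces BC1F(1 + n_selfing) progeny of a (recurrent x donor) F1
#' backcrossed once to the recurrent parent and then selfed, with meiosis
#' under the Haldane map function (no interference). Scores count donor
#' alleles, so the pedigree expectation is a donor allele frequency of 1/4
#' and, after three selfing generations, a heterozygosity of 1/16.
#'
#' @param n_progeny Number of progeny (>= 1).
#' @param map Genetic map data frame (`marker`, `chr`, `pos`).
#' @param n_selfing Number of selfing generations after the BC1 (default 3).
#' @param seed Optional integer seed.
#' @return Integer matrix `n_progeny` x markers of donor-allele counts
#'   (0/1/2), columns named by marker.
#' @export
simulate_cross <- function(n_progeny, map, n_selfing = 3, seed = NULL) {
  if (n_progeny < 1) stop("'n_progeny' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(0L, n_progeny, nrow(map),
                dimnames = list(NULL, map$marker))
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    m <- length(idx)
    r <- if (m > 1L) haldane_r(diff(map$pos[idx])) else numeric(0)
    # F1 haplotypes: recurrent (0) and donor (1)
    f1_a <- matrix(0, n_progeny, m)
    f1_b <- matrix(1, n_progeny, m)
    # BC1: one gamete from the F1, one recurrent chromosome
    h1 <- .meiosis(f1_a, f1_b, r)
    h2 <- matrix(0, n_progeny, m)
    for (g in seq_len(n_selfing)) {
      n1 <- .meiosis(h1, h2, r)
      n2 <- .meiosis(h1, h2, r)
      h1 <- n1; h2 <- n2
    }
    out[, idx] <- h1 + h2
  }
  storage.mode(out) <- "integer"
  out
}

#' Default daily EC generator profiles
#'
#' One row per EC: a baseline level, a per-environment step (environment `j`
#' gets `base + (j-1) * env_step`), a seasonal sine amplitude over the
#' series, a daily noise standard deviation, and whether the EC is
#' cumulative (aggregated by sum downstream) or intensive (mean). Values are
#' loosely calibrated to a Sudano-Sahelian growing season: day lengths near
#' 12-13 h, maximum temperatures in the mid-30s (deg C), and intermittent
#' rain.
#'
#' @return Data frame with columns `ec`, `base`, `env_step`, `seasonal_amp`,
#'   `daily_sd`, `cumulative`.
#' @export
default_ec_profiles <- function() {
  data.frame(
    ec = c("photoperiod", "tmax", "tmin", "vpd", "humidity", "rain"),
    base = c(12.2, 34, 22, 1.8, 65, 4),
    env_step = c(0.2, 1.0, 0.6, 0.15, -4, -1),
    seasonal_amp = c(0.4, 2, 1.5, 0.3, 6, 2),
    daily_sd = c(0.02, 1.2, 1.0, 0.15, 4, 3),
    cumulative = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' Simulate daily environmental covariate series
#'
#' @param config A [sim_config()]; uses `n_environments`, `n_days` and
#'   `ec_profiles`.
#' @param seed Optional integer seed.
#' @param constant If `TRUE`, suppress seasonal trend and daily noise so each
#'   (environment, EC) series is constant.
#' @return Data frame `environment`, `day`, `ec`, `value` with contiguous
#'   1-based day indices per (environment, EC).
#' @export
simulate_ec <- function(config, seed = NULL, constant = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  pr <- config$ec_profiles
  days <- seq_len(config$n_days)
  out <- vector("list", config$n_environments * nrow(pr))
  k <- 0L
  for (j in seq_len(config$n_environments)) {
    for (i in seq_len(nrow(pr))) {
      mu <- pr$base[i] + (j - 1) * pr$env_step[i]
      # environments are shifted in the season (staggered sowing dates), so
      # between-environment EC contrasts vary along the crop cycle
      shift <- (j - 1) * config$ec_phase_days
      v <- if (constant) rep(mu, length(days)) else
        mu + pr$seasonal_amp[i] * sin(2 * pi * (days + shift) / 120) +
          stats::rnorm(length(days), 0, pr$daily_sd[i])
      if (pr$ec[i] == "rain") v <- pmax(v, 0)
      k <- k + 1L
      out[[k]] <- data.frame(environment = sprintf("env%d", j), day = days,
                             ec = pr$ec[i], value = v,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# True per-environment EC values driving QTL sensitivities: window mean of
# the daily series, optionally centered across environments.
.ec_driver <- function(ec_daily, ec_name, window, center) {
  sub <- ec_daily[ec_daily$ec == ec_name &
                    ec_daily$day >= window[1] &
                    ec_daily$day <= window[1] + window[2] - 1, ]
  if (nrow(sub) == 0L) stop("EC window outside the simulated series")
  v <- tapply(sub$value, sub$environment, mean)
  v <- v[order(names(v))]
  if (center) v <- v - mean(v)
  v
}

#' Simulate phenotypes from dosages and ground-truth QTL effects
#'
#' Generates genotype-by-environment means as
#' `g_ij = E_j + C_cj + sum_q x_iq * (alpha_p + S_p * EC_j + beta_pj) + GE_ij`
#' with the GE vectors drawn from a zero-mean multivariate normal with the
#' configured unstructured covariance, then expands them to plot records by
#' adding block effects and iid plot error.
#'
#' @param config A [sim_config()].
#' @param design Data frame `genotype`, `cross`, `recurrent`, `donor`.
#' @param dosage Matrix genotypes x markers of donor-allele counts.
#' @param map Genetic map (QTL positions must match markers).
#' @param ec_values Named list: for each EC used by a QTL, a named numeric of
#'   per-environment driving values.
#' @param seed Optional integer seed.
#' @return List with `plots` (plot-level records: genotype, cross,
#'   environment, replicate, block, trait, value), `true_blues` (the
#'   noise-free-at-plot-level genotype x environment means, long format) and
#'   `truth` (per-QTL realized allelic effects per environment).
#' @export
simulate_phenotypes <- function(config, design, dosage, map, ec_values,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(design)
  J <- config$n_environments
  envs <- sprintf("env%d", seq_len(J))
  g <- matrix(rep(config$env_effects, each = n), n, J,
              dimnames = list(design$genotype, envs))
  # within-environment cross effects: fixed, reproducible from the config
  cross_ids <- sort(unique(design$cross))
  cross_eff <- outer(seq_along(cross_ids) - mean(seq_along(cross_ids)),
                     rep(0.25, J))
  dimnames(cross_eff) <- list(cross_ids, envs)
  g <- g + cross_eff[design$cross, , drop = FALSE]
  truth <- list()
  for (k in seq_along(config$qtl)) {
    q <- config$qtl[[k]]
    mi <- .find_marker(map, chr = q$chr, pos = q$pos)
    x <- dosage[, mi]
    eff <- matrix(0, n, J)
    qeff_env <- matrix(0, length(unique(design$donor)), J,
                       dimnames = list(sort(unique(design$donor)), envs))
    for (p in sort(unique(design$donor))) {
      a <- if (p %in% names(q$alpha)) q$alpha[[p]] else 0
      s <- if (!is.null(q$sensitivity) && p %in% names(q$sensitivity))
        q$sensitivity[[p]] else 0
      b <- if (!is.null(q$beta) && p %in% rownames(q$beta))
        q$beta[p, ] else rep(0, J)
      ecj <- if (s != 0) ec_values[[q$ec]][envs] else rep(0, J)
      per_env <- a + s * ecj + b
      qeff_env[p, ] <- per_env
      rows <- design$donor == p
      eff[rows, ] <- eff[rows, ] + outer(x[rows], per_env)
    }
    g <- g + eff
    truth[[k]] <- list(chr = q$chr, pos = q$pos, ec = q$ec,
                       alpha = q$alpha, sensitivity = q$sensitivity,
                       effect_by_env = qeff_env)
  }
  # combined GxE + error deviation on genotype means, unstructured covariance
  if (any(config$vcov != 0)) {
    L <- chol(config$vcov + diag(1e-12, J))
    ge <- matrix(stats::rnorm(n * J), n, J) %*% L
    g <- g + ge
  }
  # replicated checks: the recurrent parents, planted in every block; their
  # genotype-by-environment mean is the environment mean plus their own GxE
  # deviation (no donor introgression)
  checks <- sort(unique(design$recurrent))
  gc <- matrix(rep(config$env_effects, each = length(checks)),
               length(checks), J, dimnames = list(checks, envs))
  if (any(config$vcov != 0)) {
    Lc <- chol(config$vcov + diag(1e-12, J))
    gc <- gc + matrix(stats::rnorm(length(checks) * J),
                      length(checks), J) %*% Lc
  }
  true_blues <- data.frame(
    genotype = c(rep(design$genotype, J), rep(checks, J)),
    cross = c(rep(design$cross, J), rep("check", length(checks) * J)),
    environment = c(rep(envs, each = n), rep(envs, each = length(checks))),
    trait = "trait1",
    value = c(as.vector(g), as.vector(gc)),
    stringsAsFactors = FALSE)
  # plot expansion: replicates x blocks, block effects iid normal; every
  # block carries one plot of each check (augmented layout)
  plots <- vector("list", J * config$n_rep)
  k <- 0L
  for (j in seq_len(J)) {
    for (r in seq_len(config$n_rep)) {
      blk <- 1L + (seq_len(n) - 1L) %% config$n_blocks
      beff <- stats::rnorm(config$n_blocks, 0, config$block_sd)
      chk_blk <- rep(seq_len(config$n_blocks), each = length(checks))
      chk_id <- rep(checks, config$n_blocks)
      k <- k + 1L
      plots[[k]] <- data.frame(
        genotype = c(design$genotype, chk_id),
        cross = c(design$cross, rep("check", length(chk_id))),
        environment = envs[j], replicate = r,
        block = c(blk, chk_blk),
        trait = "trait1",
        value = c(g[, j] + beff[blk] +
                    stats::rnorm(n, 0, config$error_sd),
                  gc[chk_id, j] + beff[chk_blk] +
                    stats::rnorm(length(chk_id), 0, config$error_sd)),
        stringsAsFactors = FALSE)
    }
  }
  list(plots = do.call(rbind, plots), true_blues = true_blues, truth = truth)
}

#' Simulate a complete multireference BCNAM experiment
#'
#' End-to-end synthetic-data engine: genetic map, parental marker scores,
#' BC1F4 progeny per cross, daily EC series, and phenotypes generated from
#' the configured ground-truth QTL architecture under an unstructured GxE
#' covariance. All randomness is driven by `config$seed`, so the same
#' configuration reproduces identical output.
#'
#' @param config A [sim_config()].
#' @return An object of class `bcnam_sim`: list with `map`, `genotypes`
#'   (progeny and parent scores, 0/1/2 counts of an arbitrary reference
#'   allele), `crosses` (genotype-level design table), `dosage_true` (true
#'   donor-allele counts), `ec_daily`, `ec_values` (per-EC driving values per
#'   environment), `phenotypes` (plot records), `true_blues`, `truth`, and
#'   the `config`.
#' @export
simulate_bcnam <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  map <- simulate_map(config)
  M <- nrow(map)
  cr <- config$crosses
  parents <- sort(unique(c(cr$recurrent, cr$donor)))
  # reference-allele scores of the (fully homozygous) parents; donor and
  # recurrent of a cross differ at informative markers
  par_scores <- matrix(0L, length(parents), M,
                       dimnames = list(parents, map$marker))
  for (p in parents) {
    par_scores[p, ] <- 2L * stats::rbinom(M, 1, 0.5)
  }
  # force informativeness except at a configured uninformative fraction
  uninf <- matrix(FALSE, nrow(cr), M)
  for (i in seq_len(nrow(cr))) {
    uninf[i, ] <- stats::runif(M) < config$prop_uninformative
    d <- cr$donor[i]; r <- cr$recurrent[i]
    same <- par_scores[d, ] == par_scores[r, ]
    flip <- same & !uninf[i, ]
    par_scores[d, flip] <- 2L - par_scores[r, flip]
    par_scores[d, uninf[i, ]] <- par_scores[r, uninf[i, ]]
  }
  design <- list(); dosage <- list(); scores <- list()
  for (i in seq_len(nrow(cr))) {
    n <- cr$n_progeny[i]
    dos <- simulate_cross(n, map, n_selfing = config$n_selfing)
    ids <- sprintf("%s_%03d", cr$cross[i], seq_len(n))
    rownames(dos) <- ids
    rs <- par_scores[cr$recurrent[i], ]
    ds <- par_scores[cr$donor[i], ]
    # progeny reference-allele score from donor dosage and parent scores
    sc <- sweep(dos, 2L, (ds - rs) / 2, `*`)
    sc <- sweep(sc, 2L, rs, `+`)
    storage.mode(sc) <- "integer"
    design[[i]] <- data.frame(genotype = ids, cross = cr$cross[i],
                              recurrent = cr$recurrent[i],
                              donor = cr$donor[i], stringsAsFactors = FALSE)
    dosage[[i]] <- dos
    scores[[i]] <- sc
  }
  design <- do.call(rbind, design)
  dosage <- do.call(rbind, dosage)
  scores <- rbind(do.call(rbind, scores), par_scores)
  ec_daily <- simulate_ec(config)
  ec_values <- list()
  for (q in config$qtl) {
    if (!is.na(q$ec) && is.null(ec_values[[q$ec]])) {
      ec_values[[q$ec]] <- .ec_driver(ec_daily, q$ec, config$ec_window,
                                      config$center_ec)
    }
  }
  ph <- simulate_phenotypes(config, design, dosage, map, ec_values)
  structure(list(map = map, genotypes = scores, crosses = design,
                 dosage_true = dosage, ec_daily = ec_daily,
                 ec_values = ec_values, phenotypes = ph$plots,
                 true_blues = ph$true_blues, truth = ph$truth,
                 config = config),
            class = "bcnam_sim")
}

#' @export
print.bcnam_sim <- function(x, ...) {
  cat("Simulated BCNAM experiment\n")
  cat(sprintf("  %d genotypes, %d crosses, %d markers on %d chromosome(s)\n",
              nrow(x$crosses), length(unique(x$crosses$cross)),
              nrow(x$map), x$config$n_chromosomes))
  cat(sprintf("  %d environments, %d ground-truth QTL\n",
              x$config$n_environments, length(x$config$qtl)))
  invisible(x)
}
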