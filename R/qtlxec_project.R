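# Post-detection characterization: decomposition of parental QTL effects
# into main and QTL-by-environment components (exact REML), factorial
# regression of QEI on environmental covariates, unique-QTL grouping across
# subpopulations, and projection of allelic effects onto environment grids.

# Sum-to-zero environment contrasts: J x (J-1); beta_pj = H %*% b sums to
# zero over environments, so alpha_p is the across-environment mean effect.
.env_contrasts <- function(J) {
  H <- stats::contr.sum(J)
  rownames(H) <- NULL
  H
}

# Assemble the model-3 / model-4 design blocks for one QTL.
# type: "main_qei" (alpha + beta columns), "main_only" (alpha), or
# "main_ec" (alpha + EC-slope column).
.qtl_term <- function(stack, bd, marker, type_by_parent, ecc = NULL) {
  gi <- match(as.character(stack$geno), bd$genotype)
  Xg <- bd$X[gi, , drop = FALSE]
  Xg[is.na(gi), ] <- 0
  J <- length(stack$envs)
  H <- .env_contrasts(J)
  ei <- as.integer(stack$env)
  cols <- list(); info <- list()
  for (p in colnames(bd$X)) {
    x <- Xg[, p]
    a <- matrix(x, ncol = 1,
                dimnames = list(NULL, sprintf("q:%s.%s.a", marker, p)))
    cols[[length(cols) + 1L]] <- a
    type <- type_by_parent[[p]]
    if (type == "main_qei") {
      B <- x * H[ei, , drop = FALSE]
      colnames(B) <- sprintf("q:%s.%s.b%d", marker, p,
                             seq_len(ncol(B)))
      cols[[length(cols) + 1L]] <- B
    } else if (type == "main_ec") {
      S <- matrix(x * ecc[ei], ncol = 1,
                  dimnames = list(NULL, sprintf("q:%s.%s.S", marker, p)))
      cols[[length(cols) + 1L]] <- S
    }
    info[[p]] <- type
  }
  out <- do.call(cbind, cols)
  attr(out, "exclude") <- which(!bd$keep[gi] & !is.na(gi))
  out
}

.subset_stack <- function(stack, keep) {
  s <- list(y = stack$y[keep], env = droplevels(stack$env[keep]),
            geno = droplevels(stack$geno[keep]),
            cross = if (is.null(stack$cross)) NULL else
              droplevels(stack$cross[keep]))
  s$envs <- levels(s$env); s$genos <- levels(s$geno)
  s
}

#' Decompose parental QTL effects into main and QEI components
#'
#' Exact REML fit of the multi-QTL model with, for every QTL and donor
#' parent, a main allelic effect (alpha_p) and environment-specific
#' deviations (beta_pj) constrained to sum to zero over environments, under
#' the unstructured environment covariance. Each parental allele gets a
#' 1-df Wald test of alpha_p and a (Nenv - 1)-df Wald test of its QEI
#' block, and is classified as `nonsignificant`, `main-only` (alpha
#' significant, QEI not) or `QEI` at the `alpha_level` rule.
#'
#' @param blues A `blue_table`.
#' @param dosage A `parental_dosage`.
#' @param markers QTL marker ids (all fitted jointly).
#' @param trait,subpopulation,min_seg As in [sim_scan()].
#' @param alpha_level Significance level of the classification (default
#'   0.05).
#' @return Object of class `allelic_effects`: list with `table` (per QTL x
#'   parent: alpha, se, p_alpha, wald_qei, p_qei, class), `beta_env`
#'   (environment-specific deviations, long), and the underlying `fit`.
#'   A single observed environment is an error: the QEI decomposition
#'   needs at least two.
#' @export
fit_model3 <- function(blues, dosage, markers, trait = NULL,
                       subpopulation = NULL, min_seg = 10,
                       alpha_level = 0.05) {
  stack <- .make_stack(blues, trait)
  J <- length(stack$envs)
  if (J < 2L) {
    stop("QEI decomposition needs >= 2 environments; got ", J)
  }
  if (length(markers) == 0L) stop("no QTL to fit")
  Xb <- .base_design(stack)
  blocks <- list(); bds <- list(); excl <- integer(0)
  for (m in markers) {
    bd <- build_design_matrix(dosage, marker = m,
                              subpopulation = subpopulation,
                              min_seg = min_seg)
    if (!bd$scannable) {
      warning("QTL ", m, " has no segregating parental column; skipped",
              call. = FALSE)
      next
    }
    types <- stats::setNames(as.list(rep("main_qei", ncol(bd$X))),
                             colnames(bd$X))
    Q <- .qtl_term(stack, bd, m, types)
    excl <- union(excl, attr(Q, "exclude"))
    blocks[[m]] <- Q
    bds[[m]] <- bd
  }
  keep <- setdiff(seq_along(stack$y), excl)
  s <- if (length(excl)) .subset_stack(stack, keep) else stack
  X <- do.call(cbind, c(list(Xb), unname(blocks)))[keep, , drop = FALSE]
  fit <- .reml_fit_stack(s, X)
  H <- .env_contrasts(J)
  rows <- list(); benv <- list()
  for (m in names(bds)) {
    for (p in colnames(bds[[m]]$X)) {
      a_name <- sprintf("q:%s.%s.a", m, p)
      b_names <- sprintf("q:%s.%s.b%d", m, p, seq_len(J - 1))
      b_names <- intersect(b_names, names(fit$beta))
      w_a <- if (a_name %in% names(fit$beta))
        wald_test(fit, a_name) else NULL
      w_b <- if (length(b_names)) wald_test(fit, b_names) else NULL
      p_a <- if (is.null(w_a)) NA_real_ else w_a$p_value
      p_b <- if (is.null(w_b)) NA_real_ else w_b$p_value
      cls <- if (!is.na(p_b) && p_b < alpha_level) "QEI"
      else if (!is.na(p_a) && p_a < alpha_level) "main-only"
      else "nonsignificant"
      rows[[length(rows) + 1L]] <- data.frame(
        qtl = m, parent = p,
        alpha = if (is.null(w_a)) NA_real_ else fit$beta[[a_name]],
        se_alpha = if (is.null(w_a)) NA_real_ else
          sqrt(fit$vcov_beta[a_name, a_name]),
        p_alpha = p_a,
        wald_qei = if (is.null(w_b)) NA_real_ else w_b$statistic,
        df_qei = if (is.null(w_b)) NA_integer_ else w_b$df,
        p_qei = p_b, class = cls, stringsAsFactors = FALSE)
      if (length(b_names) == J - 1L) {
        bj <- drop(H %*% fit$beta[b_names])
        benv[[length(benv) + 1L]] <- data.frame(
          qtl = m, parent = p, environment = s$envs,
          beta = bj, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(table = do.call(rbind, rows),
                 beta_env = if (length(benv)) do.call(rbind, benv) else NULL,
                 fit = fit, markers = names(bds),
                 alpha_level = alpha_level),
            class = "allelic_effects")
}

#' @export
print.allelic_effects <- function(x, ...) {
  cat("Parental allelic effects (main + QEI decomposition)\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' EC sensitivity of QEI parental alleles (factorial regression)
#'
#' For the parental alleles with a significant QEI, replaces the
#' environment-specific deviations beta_pj by a linear response
#' `EC_j * S_p` to one environmental covariate at a time (the EC is
#' centered at its across-environment mean, so alpha_p stays the
#' mean-environment effect); non-QEI parents keep their main + QEI terms.
#' Each candidate EC of the selection is fitted in turn by exact REML and
#' S_p is tested with a 1-df Wald test. The lack-of-fit of the EC
#' regression is absorbed by the unstructured GxE term. An EC with no
#' variation across the observed environments is skipped with a message.
#'
#' @param blues,dosage,markers,trait,subpopulation,min_seg As in
#'   [fit_model3()].
#' @param qei Data frame with columns `qtl`, `parent`: the alleles whose
#'   QEI is regressed on the EC (typically `table[table$class == "QEI", ]`
#'   from [fit_model3()]).
#' @param ec_values Named list of per-environment EC values (one element
#'   per EC, names matching environments), e.g. the `ec_values` attribute
#'   of [select_top_ecs()].
#' @return Object of class `ec_sensitivity`: data frame with one row per
#'   (QTL, parent, EC): `alpha`, `sensitivity`, `se`, `wald`, `p_value`,
#'   `ec_center`; per-EC fits in the `fits` attribute.
#' @export
fit_model4 <- function(blues, dosage, markers, qei, ec_values,
                       trait = NULL, subpopulation = NULL, min_seg = 10) {
  stack <- .make_stack(blues, trait)
  J <- length(stack$envs)
  if (J < 3L) {
    warning("fewer than 3 environments: the EC response has no residual ",
            "degrees of freedom within parent", call. = FALSE)
  }
  Xb <- .base_design(stack)
  rows <- list(); fits <- list()
  for (ec in names(ec_values)) {
    ecv <- ec_values[[ec]]
    if (!all(stack$envs %in% names(ecv))) {
      stop("EC '", ec, "' lacks values for some observed environments")
    }
    ecv <- ecv[stack$envs]
    if (stats::sd(ecv) < 1e-12) {
      message("EC '", ec, "' is constant across environments; skipped")
      next
    }
    center <- mean(ecv)
    ecc <- ecv - center
    blocks <- list(); bds <- list(); excl <- integer(0)
    for (m in markers) {
      bd <- build_design_matrix(dosage, marker = m,
                                subpopulation = subpopulation,
                                min_seg = min_seg)
      if (!bd$scannable) next
      types <- lapply(stats::setNames(colnames(bd$X), colnames(bd$X)),
                      function(p) {
                        if (any(qei$qtl == m & qei$parent == p))
                          "main_ec" else "main_qei"
                      })
      Q <- .qtl_term(stack, bd, m, types, ecc = ecc)
      excl <- union(excl, attr(Q, "exclude"))
      blocks[[m]] <- Q
      bds[[m]] <- bd
    }
    keep <- setdiff(seq_along(stack$y), excl)
    s <- if (length(excl)) .subset_stack(stack, keep) else stack
    X <- do.call(cbind, c(list(Xb), unname(blocks)))[keep, , drop = FALSE]
    fit <- .reml_fit_stack(s, X)
    fits[[ec]] <- fit
    for (i in seq_len(nrow(qei))) {
      m <- qei$qtl[i]; p <- qei$parent[i]
      if (is.null(bds[[m]]) || !p %in% colnames(bds[[m]]$X)) next
      s_name <- sprintf("q:%s.%s.S", m, p)
      a_name <- sprintf("q:%s.%s.a", m, p)
      if (!s_name %in% names(fit$beta)) next
      w <- wald_test(fit, s_name)
      rows[[length(rows) + 1L]] <- data.frame(
        qtl = m, parent = p, ec = ec,
        alpha = if (a_name %in% names(fit$beta))
          fit$beta[[a_name]] else NA_real_,
        sensitivity = fit$beta[[s_name]],
        se = sqrt(fit$vcov_beta[s_name, s_name]),
        wald = w$statistic, p_value = w$p_value,
        ec_center = center, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(qtl = character(0), parent = character(0), ec = character(0),
               alpha = numeric(0), sensitivity = numeric(0),
               se = numeric(0), wald = numeric(0), p_value = numeric(0),
               ec_center = numeric(0))
  attr(out, "fits") <- fits
  class(out) <- c("ec_sensitivity", "data.frame")
  out
}

#' Summarize allelic-effect classes and EC interactions
#'
#' Proportions, over all (QTL, parent) cells of a model-3 table, of alleles
#' with a significant effect (main or QEI), with a significant QEI, and
#' with at least one significant EC interaction in the model-4 results.
#'
#' @param effects An `allelic_effects` object.
#' @param sens An `ec_sensitivity` table (may be empty).
#' @param alpha_level Significance level (default 0.05).
#' @return Named list: `n_alleles`, `prop_significant`, `prop_qei`,
#'   `prop_ec_interacting` (fractions in [0, 1]).
#' @export
classify_alleles <- function(effects, sens = NULL, alpha_level = 0.05) {
  tab <- effects$table
  if (is.null(tab) || nrow(tab) == 0L) {
    return(list(n_alleles = 0L, prop_significant = NA_real_,
                prop_qei = NA_real_, prop_ec_interacting = NA_real_))
  }
  signif <- (!is.na(tab$p_alpha) & tab$p_alpha < alpha_level) |
    (!is.na(tab$p_qei) & tab$p_qei < alpha_level)
  qei <- !is.na(tab$p_qei) & tab$p_qei < alpha_level
  ec_int <- rep(FALSE, nrow(tab))
  if (!is.null(sens) && nrow(sens) > 0L) {
    for (i in seq_len(nrow(tab))) {
      hit <- sens$qtl == tab$qtl[i] & sens$parent == tab$parent[i] &
        sens$p_value < alpha_level
      ec_int[i] <- any(hit, na.rm = TRUE)
    }
  }
  list(n_alleles = nrow(tab),
       prop_significant = mean(signif),
       prop_qei = mean(qei),
       prop_ec_interacting = mean(ec_int))
}

#' Group QTL detected in different subpopulations into unique positions
#'
#' Iterative agglomeration per trait and chromosome: repeatedly merge the
#' two closest clusters (smallest gap between their extreme positions;
#' ties resolved toward the leftmost pair) whenever the merged span does
#' not exceed `max_span` cM; stop when no merge is possible.
#'
#' @param qtl Data frame with columns `chr`, `pos` and optionally `trait`,
#'   `subpopulation`, `marker`.
#' @param max_span Maximum distance (cM) between the two most extreme
#'   member positions (default 10).
#' @return Data frame, one row per unique QTL group: `trait`, `chr`,
#'   `pos_min`, `pos_max`, `span`, `representative` (mean member
#'   position), `n_members`, `members`.
#' @export
group_unique_qtl <- function(qtl, max_span = 10) {
  if (nrow(qtl) == 0L) {
    return(data.frame(trait = character(0), chr = integer(0),
                      pos_min = numeric(0), pos_max = numeric(0),
                      span = numeric(0), representative = numeric(0),
                      n_members = integer(0), members = character(0)))
  }
  if (!"trait" %in% names(qtl)) qtl$trait <- "trait"
  lab <- if ("marker" %in% names(qtl)) as.character(qtl$marker)
  else if ("subpopulation" %in% names(qtl))
    paste0(qtl$subpopulation, "@", qtl$pos)
  else as.character(qtl$pos)
  out <- list()
  for (tr in unique(qtl$trait)) {
    for (ch in sort(unique(qtl$chr[qtl$trait == tr]))) {
      d <- qtl[qtl$trait == tr & qtl$chr == ch, , drop = FALSE]
      l <- lab[qtl$trait == tr & qtl$chr == ch]
      o <- order(d$pos)
      cl <- lapply(o, function(i) list(pos = d$pos[i], lab = l[i]))
      repeat {
        if (length(cl) < 2L) break
        lo <- vapply(cl, function(c) min(c$pos), numeric(1))
        hi <- vapply(cl, function(c) max(c$pos), numeric(1))
        gaps <- lo[-1] - hi[-length(hi)]
        spans <- hi[-1] - lo[-length(lo)]
        cand <- which(spans <= max_span)
        if (length(cand) == 0L) break
        i <- cand[order(gaps[cand], lo[cand])][1L]
        cl[[i]] <- list(pos = c(cl[[i]]$pos, cl[[i + 1L]]$pos),
                        lab = c(cl[[i]]$lab, cl[[i + 1L]]$lab))
        cl[[i + 1L]] <- NULL
      }
      for (c in cl) {
        out[[length(out) + 1L]] <- data.frame(
          trait = tr, chr = ch, pos_min = min(c$pos), pos_max = max(c$pos),
          span = max(c$pos) - min(c$pos),
          representative = mean(c$pos), n_members = length(c$pos),
          members = paste(c$lab, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Project allelic effects onto an environmental grid
#'
#' Evaluates `Qeff = alpha_hat + (EC - center) * S_hat` at every grid
#' point, for every (QTL, parent, EC) row of a sensitivity table. The Qeff
#' values are deviations with respect to the recurrent (reference) parent
#' background, affine in the EC.
#'
#' @param sens An `ec_sensitivity` table (usually filtered to significant
#'   sensitivities).
#' @param grid Data frame with a `point` id column, optional `lat`/`lon`,
#'   and one column per projected EC carrying its value at each point.
#' @return Long data frame `point`, `lat`, `lon`, `ec`, `qtl`, `parent`,
#'   `qeff`.
#' @export
project_effects <- function(sens, grid) {
  stopifnot(nrow(sens) > 0)
  if (!"point" %in% names(grid)) grid$point <- seq_len(nrow(grid))
  out <- list()
  for (i in seq_len(nrow(sens))) {
    ec <- sens$ec[i]
    if (!ec %in% names(grid)) {
      stop("grid lacks a column for EC '", ec, "'")
    }
    qeff <- sens$alpha[i] +
      (grid[[ec]] - sens$ec_center[i]) * sens$sensitivity[i]
    out[[i]] <- data.frame(
      point = grid$point,
      lat = if ("lat" %in% names(grid)) grid$lat else NA_real_,
      lon = if ("lon" %in% names(grid)) grid$lon else NA_real_,
      ec = ec, qtl = sens$qtl[i], parent = sens$parent[i], qeff = qeff,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
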