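# Genome scans: simple interval mapping (SIM), iterative cofactor/QTL
# selection, composite interval mapping (CIM), and R-squared summaries.
# Scan positions are the marker positions of the map.

# Environment + cross-within-environment null design on the stacked BLUEs.
.base_design <- function(stack) {
  env <- stack$env
  Xe <- stats::model.matrix(~ 0 + env)
  colnames(Xe) <- paste0("env:", levels(env))
  if (!is.null(stack$cross) && nlevels(stack$cross) > 1L) {
    cr <- stack$cross
    Xc <- stats::model.matrix(~ 0 + env:cr)
    colnames(Xc) <- sub("^env", "cx:", colnames(Xc))
    cbind(Xe, Xc)
  } else {
    Xe
  }
}

# Expand a per-genotype QTL incidence (genotypes x donors) to environment-
# specific observation columns (one column per donor x environment).
.expand_env <- function(stack, bd) {
  gi <- match(as.character(stack$geno), bd$genotype)
  Xg <- bd$X[gi, , drop = FALSE]
  Xg[is.na(gi), ] <- 0
  J <- length(stack$envs)
  ei <- as.integer(stack$env)
  cols <- vector("list", J)
  for (j in seq_len(J)) {
    cols[[j]] <- Xg * (ei == j)
    colnames(cols[[j]]) <- paste0(colnames(bd$X), "@", stack$envs[j])
  }
  out <- do.call(cbind, cols)
  attr(out, "exclude") <- which(!bd$keep[gi] & !is.na(gi))
  out
}

# One scan-position test; handles genotypes excluded for missing dosage by
# refitting the GLS context on the reduced observation set.
.scan_one <- function(stack, ctx, X_null, Sigma, Q, df_alleles) {
  excl <- attr(Q, "exclude")
  if (length(excl) == 0L) {
    return(gls_scan_stat(ctx, Q, df_alleles = df_alleles))
  }
  keep <- setdiff(seq_along(stack$y), excl)
  sub <- list(y = stack$y[keep], env = droplevels(stack$env[keep]),
              geno = droplevels(stack$geno[keep]),
              cross = if (is.null(stack$cross)) NULL else
                droplevels(stack$cross[keep]),
              envs = NULL, genos = NULL)
  sub$envs <- levels(sub$env); sub$genos <- levels(sub$geno)
  ctx2 <- .gls_context_stack(sub, X_null[keep, , drop = FALSE], Sigma)
  gls_scan_stat(ctx2, Q[keep, , drop = FALSE], df_alleles = df_alleles)
}

.scan_engine <- function(blues, dosage, trait, subpopulation, Sigma,
                         cofactors, window, min_seg) {
  stack <- .make_stack(blues, trait)
  map <- dosage$map
  Xb <- .base_design(stack)
  cof_blocks <- list()
  if (length(cofactors)) {
    for (m in cofactors) {
      bd <- build_design_matrix(dosage, marker = m,
                                subpopulation = subpopulation,
                                min_seg = min_seg)
      if (!bd$scannable) {
        warning("cofactor ", m, " is unscannable; skipped", call. = FALSE)
        next
      }
      Qc <- .expand_env(stack, bd)
      colnames(Qc) <- paste0("cof:", m, ":", colnames(Qc))
      cof_blocks[[m]] <- Qc
    }
  }
  X_all <- do.call(cbind, c(list(Xb), unname(cof_blocks)))
  if (is.null(Sigma)) {
    Sigma <- .reml_fit_stack(stack, X_all)$Sigma
  }
  cof_pos <- if (length(cof_blocks)) {
    map[match(names(cof_blocks), map$marker), c("marker", "chr", "pos")]
  } else NULL
  ctx_cache <- list()
  get_ctx <- function(active) {
    key <- paste0("k:", paste(active, collapse = "|"))
    if (is.null(ctx_cache[[key]])) {
      Xn <- do.call(cbind, c(list(Xb), unname(cof_blocks[active])))
      ctx_cache[[key]] <<- list(
        ctx = .gls_context_stack(stack, Xn, Sigma), X = Xn)
    }
    ctx_cache[[key]]
  }
  rows <- vector("list", nrow(map))
  for (i in seq_len(nrow(map))) {
    m <- map$marker[i]
    active <- character(0)
    if (!is.null(cof_pos)) {
      off_window <- cof_pos$chr != map$chr[i] |
        abs(cof_pos$pos - map$pos[i]) > window
      active <- cof_pos$marker[off_window]
    }
    bd <- build_design_matrix(dosage, marker = m,
                              subpopulation = subpopulation,
                              min_seg = min_seg)
    row <- data.frame(marker = m, chr = map$chr[i], pos = map$pos[i],
                      n_alleles = ncol(bd$X), wald = NA_real_,
                      df = NA_integer_, p = NA_real_,
                      neg_log10_p = NA_real_, df_alleles = NA_integer_,
                      p_alleles = NA_real_,
                      scannable = bd$scannable,
                      cofactors_active = paste(active, collapse = ";"),
                      stringsAsFactors = FALSE)
    if (bd$scannable) {
      cc <- get_ctx(active)
      Q <- .expand_env(stack, bd)
      res <- .scan_one(stack, cc$ctx, cc$X, Sigma, Q,
                       df_alleles = ncol(bd$X))
      if (!is.null(res)) {
        row$wald <- res$statistic
        row$df <- res$df
        row$p <- res$p_value
        row$neg_log10_p <- res$neg_log10_p
        row$df_alleles <- attr(res, "df_alleles")
        row$p_alleles <- attr(res, "p_alleles")
      } else {
        row$scannable <- FALSE
      }
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "Sigma") <- Sigma
  attr(out, "cofactors") <- if (is.null(cof_pos)) character(0) else
    cof_pos$marker
  class(out) <- c("scan_profile", "data.frame")
  out
}

#' Simple interval mapping scan
#'
#' Evaluates, at every marker position, the approximate GLS Wald statistic
#' for the environment-specific parental QTL effects added to the
#' environment + cross-within-environment null model, with the unstructured
#' environment covariance fixed at its null-model REML estimate. The
#' primary p-value uses the parameter-count degrees of freedom (retained
#' parental columns x environments); `p_alleles` reports the allele-count
#' convention alongside.
#'
#' @param blues A `blue_table`.
#' @param dosage A `parental_dosage`.
#' @param trait Optional trait filter.
#' @param subpopulation Optional cross ids to restrict to.
#' @param Sigma Optional fixed covariance; default: REML on the null model.
#' @param min_seg Minimum carriers per parental column.
#' @return A `scan_profile` data frame (one row per marker) with the fitted
#'   null `Sigma` attached as an attribute.
#' @export
sim_scan <- function(blues, dosage, trait = NULL, subpopulation = NULL,
                     Sigma = NULL, min_seg = 10) {
  .scan_engine(blues, dosage, trait, subpopulation, Sigma,
               cofactors = character(0), window = 20, min_seg = min_seg)
}

#' Composite interval mapping scan
#'
#' As [sim_scan()], with cofactor QTL incidence blocks in the fixed part of
#' the null model. A cofactor lying within `window` cM of the tested
#' position (same chromosome) is removed from the fixed part for that
#' position. Sigma is re-estimated once on the null model including all
#' cofactors, then held fixed for the whole pass.
#'
#' @inheritParams sim_scan
#' @param cofactors Character vector of cofactor marker ids (typically from
#'   [select_positions()] with `max_per_chr = 1`).
#' @param window Cofactor exclusion half-window in cM (default 20, applied
#'   on each side).
#' @return A `scan_profile`.
#' @export
cim_scan <- function(blues, dosage, cofactors, trait = NULL,
                     subpopulation = NULL, Sigma = NULL, window = 20,
                     min_seg = 10) {
  .scan_engine(blues, dosage, trait, subpopulation, Sigma,
               cofactors = cofactors, window = window, min_seg = min_seg)
}

#' Greedy selection of significant scan positions
#'
#' Per chromosome: repeatedly pick the most significant remaining position
#' below the threshold, then exclude all positions within `window` cM on
#' each side of it; stop when no free position is significant or the
#' per-chromosome cap is reached. Ties break toward the lower position.
#'
#' @param profile A `scan_profile`.
#' @param threshold P-value threshold (e.g. from
#'   [significance_threshold()]).
#' @param window Exclusion window in cM on each side (default 20).
#' @param max_per_chr Per-chromosome cap (1 for cofactor selection,
#'   `Inf` for final QTL selection).
#' @return Subset of `profile` rows (selected positions), ordered by
#'   chromosome and position.
#' @export
select_positions <- function(profile, threshold, window = 20,
                             max_per_chr = Inf) {
  sel <- list()
  prof <- profile[profile$scannable & !is.na(profile$p), , drop = FALSE]
  if (nrow(prof) == 0L) return(profile[0, ])
  for (ch in sort(unique(prof$chr))) {
    d <- prof[prof$chr == ch, , drop = FALSE]
    free <- rep(TRUE, nrow(d))
    n_sel <- 0L
    while (n_sel < max_per_chr) {
      cand <- which(free & d$p <= threshold)
      if (length(cand) == 0L) break
      best <- cand[order(d$p[cand], d$pos[cand])][1L]
      sel[[length(sel) + 1L]] <- d[best, , drop = FALSE]
      n_sel <- n_sel + 1L
      free <- free & abs(d$pos - d$pos[best]) > window
    }
  }
  if (length(sel) == 0L) return(profile[0, ])
  out <- do.call(rbind, sel)
  out <- out[order(out$chr, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Global and partial R-squared of a QTL set
#'
#' Ordinary linear model on the BLUEs with environment and cross-within-
#' environment intercepts plus the environment-specific incidence columns
#' of every QTL. The global R-squared is the proportion of the
#' residual-after-(environment + cross) variance explained by the full QTL
#' set; the partial R-squared of QTL q is the global value minus that of
#' the model without q. Values in percent.
#'
#' @param blues A `blue_table`.
#' @param dosage A `parental_dosage`.
#' @param markers Character vector of QTL marker ids.
#' @param trait,subpopulation,min_seg As in [sim_scan()].
#' @return List with `global_r2` and a data frame `partial` (marker,
#'   partial_r2).
#' @export
qtl_r2 <- function(blues, dosage, markers, trait = NULL,
                   subpopulation = NULL, min_seg = 10) {
  stack <- .make_stack(blues, trait)
  Xb <- .base_design(stack)
  if (length(markers) == 0L) {
    return(list(global_r2 = 0, partial = data.frame(
      marker = character(0), partial_r2 = numeric(0))))
  }
  blocks <- list(); excl <- integer(0)
  for (m in markers) {
    bd <- build_design_matrix(dosage, marker = m,
                              subpopulation = subpopulation,
                              min_seg = min_seg)
    Q <- .expand_env(stack, bd)
    excl <- union(excl, attr(Q, "exclude"))
    blocks[[m]] <- Q
  }
  keep <- setdiff(seq_along(stack$y), excl)
  y <- stack$y[keep]
  Xb <- Xb[keep, , drop = FALSE]
  blocks <- lapply(blocks, function(B) B[keep, , drop = FALSE])
  rss <- function(X) {
    X <- X[, .drop_aliased(X), drop = FALSE]
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  rss_base <- rss(Xb)
  rss_full <- rss(do.call(cbind, c(list(Xb), unname(blocks))))
  global <- 100 * (1 - rss_full / rss_base)
  partial <- vapply(seq_along(blocks), function(q) {
    others <- blocks[-q]
    r <- rss(do.call(cbind, c(list(Xb), unname(others))))
    global - 100 * (1 - r / rss_base)
  }, numeric(1))
  list(global_r2 = global,
       partial = data.frame(marker = markers, partial_r2 = partial,
                            stringsAsFactors = FALSE))
}

#' Full SIM -> cofactor -> CIM -> selection scan
#'
#' Convenience driver of the detection sequence: simple interval mapping,
#' cofactor selection (at most one per chromosome), composite interval
#' mapping with the cofactors, and final greedy QTL selection (uncapped),
#' all at the Li-Ji genome-wide threshold.
#'
#' @inheritParams sim_scan
#' @param alpha Family-wise error rate for the Li-Ji threshold.
#' @param window Exclusion window (cM, per side).
#' @return List with `sim`, `cim` (profiles), `cofactors`, `qtl` (selected
#'   rows with R-squared columns), `threshold`, `meff`.
#' @export
qtl_detect <- function(blues, dosage, trait = NULL, subpopulation = NULL,
                       alpha = 0.05, window = 20, min_seg = 10) {
  cr <- dosage$crosses
  gsub <- if (is.null(subpopulation)) cr$genotype else
    cr$genotype[cr$cross %in% subpopulation]
  meff <- meff_li_ji(dosage$dosage[gsub, , drop = FALSE], map = dosage$map)
  thr <- significance_threshold(alpha, meff)
  prof_sim <- sim_scan(blues, dosage, trait, subpopulation,
                       min_seg = min_seg)
  cof <- select_positions(prof_sim, thr$p_threshold, window = window,
                          max_per_chr = 1)
  if (nrow(cof) > 0L) {
    prof_cim <- cim_scan(blues, dosage, cofactors = cof$marker,
                         trait = trait, subpopulation = subpopulation,
                         window = window, min_seg = min_seg)
  } else {
    prof_cim <- prof_sim
  }
  qtl <- select_positions(prof_cim, thr$p_threshold, window = window)
  if (nrow(qtl) > 0L) {
    r2 <- qtl_r2(blues, dosage, qtl$marker, trait, subpopulation, min_seg)
    qtl$global_r2 <- r2$global_r2
    qtl$partial_r2 <- r2$partial$partial_r2[match(qtl$marker,
                                                  r2$partial$marker)]
  }
  list(sim = prof_sim, cim = prof_cim, cofactors = cof$marker, qtl = qtl,
       threshold = thr, meff = meff)
}
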