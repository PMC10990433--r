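#' Aggregate a daily EC over a time window
#'
#' @param ec_daily Data frame `environment`, `day`, `ec`, `value` with
#'   contiguous 1-based day indices per (environment, EC).
#' @param ec EC name.
#' @param start First day of the window (1-based from sowing).
#' @param size Window length in days.
#' @param stat `"mean"` (intensive ECs) or `"sum"` (cumulative ECs).
#' @return Named numeric, one value per environment.
#' @export
window_aggregate <- function(ec_daily, ec, start, size,
                             stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  sub <- ec_daily[ec_daily$ec == ec, ]
  if (nrow(sub) == 0L) stop("EC '", ec, "' not found in the daily series")
  end <- start + size - 1
  if (start < min(sub$day) || end > max(sub$day)) {
    stop("window [", start, ", ", end, "] exceeds the daily series")
  }
  sub <- sub[sub$day >= start & sub$day <= end, ]
  f <- if (stat == "mean") mean else sum
  v <- tapply(sub$value, sub$environment, f)
  v[sort(names(v))]
}

#' Scan EC windows for correlation with trait environment means
#'
#' For every (EC, window start, window size) cell, aggregates the daily EC
#' over the window in each environment and computes the Pearson correlation
#' with the per-environment trait means (the mean of genotype BLUEs per
#' environment). Cells where the windowed EC has zero variance across
#' environments are flagged and excluded from ranking.
#'
#' @param trait_env_means Named numeric: one trait value per environment
#'   (use [env_means()] on a `blue_table`).
#' @param ec_daily Daily EC series data frame.
#' @param sizes Window sizes in days (default 20, 40, 60, 80, 100).
#' @param start_by Step of the window start grid in days (starts at day 1).
#' @param stats Named character vector mapping EC name to `"mean"` or
#'   `"sum"`; unlisted ECs default to `"mean"` except known cumulative ones
#'   (rain, dd, hsun, photothermal), which default to `"sum"`.
#' @return Data frame `ec`, `start`, `size`, `stat`, `r`, `usable`; class
#'   `ec_corr_table`. Fewer than 3 environments is an error (the
#'   correlation is undefined).
#' @export
ec_trait_scan <- function(trait_env_means, ec_daily,
                          sizes = c(20, 40, 60, 80, 100),
                          start_by = 5, stats = NULL) {
  envs <- sort(names(trait_env_means))
  if (length(envs) < 3L) {
    stop("EC-trait correlation needs >= 3 environments")
  }
  if (length(envs) <= 4L) {
    warning("only ", length(envs), " environments: window correlations are ",
            "noisy; interpret the ranking with care", call. = FALSE)
  }
  y <- trait_env_means[envs]
  cumulative_default <- c("rain", "dd", "hsun", "photothermal")
  ecs <- sort(unique(ec_daily$ec))
  n_days <- max(ec_daily$day)
  rows <- list(); k <- 0L
  for (e in ecs) {
    st <- if (!is.null(stats) && e %in% names(stats)) stats[[e]] else
      if (tolower(e) %in% cumulative_default) "sum" else "mean"
    for (size in sizes) {
      starts <- seq(1, n_days - size + 1, by = start_by)
      for (s0 in starts) {
        v <- window_aggregate(ec_daily, e, s0, size, st)[envs]
        usable <- stats::sd(v) > 1e-12 && stats::sd(y) > 1e-12
        r <- if (usable) stats::cor(y, v) else NA_real_
        k <- k + 1L
        rows[[k]] <- data.frame(ec = e, start = s0, size = size, stat = st,
                                r = r, usable = usable,
                                stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ec_corr_table", "data.frame")
  out
}

#' Per-environment trait means from a BLUE table
#'
#' @param blues A `blue_table`.
#' @param trait Optional trait filter.
#' @return Named numeric of per-environment means of the genotype BLUEs.
#' @export
env_means <- function(blues, trait = NULL) {
  if (!is.null(trait)) blues <- blues[blues$trait == trait, ]
  v <- tapply(blues$value, blues$environment, mean, na.rm = TRUE)
  v[sort(names(v))]
}

#' Select the most influential ECs and their best windows
#'
#' ECs are ranked by the mean absolute correlation over all usable
#' (start, size) cells of the scan grid; ties break lexicographically on the
#' EC name. For each selected EC the single cell with the largest |r|
#' (ties: smaller start, then smaller size) defines the window whose
#' per-environment values are passed to the QTLxEC models.
#'
#' @param corr_table An `ec_corr_table` from [ec_trait_scan()].
#' @param ec_daily The daily series the table was computed from (needed to
#'   materialize the selected per-environment EC values).
#' @param k Number of ECs to select (default 5).
#' @return Object of class `ec_selection`: data frame `ec`, `start`, `size`,
#'   `stat`, `r`, `mean_abs_r` plus an `ec_values` attribute (named list of
#'   per-environment windowed values per selected EC).
#' @export
select_top_ecs <- function(corr_table, ec_daily, k = 5) {
  stopifnot(nrow(corr_table) > 0)
  us <- corr_table[corr_table$usable & !is.na(corr_table$r), ]
  if (nrow(us) == 0L) stop("no usable (EC, window) cell in the scan table")
  rank_tab <- aggregate(abs(r) ~ ec, data = us, FUN = mean)
  names(rank_tab)[2] <- "mean_abs_r"
  rank_tab <- rank_tab[order(-rank_tab$mean_abs_r, rank_tab$ec), ]
  if (nrow(rank_tab) < k) {
    warning("only ", nrow(rank_tab), " usable EC(s) available (k = ", k, ")",
            call. = FALSE)
  }
  sel <- utils::head(rank_tab, k)
  out <- list(); vals <- list()
  for (i in seq_len(nrow(sel))) {
    e <- sel$ec[i]
    cells <- us[us$ec == e, ]
    cells <- cells[order(-abs(cells$r), cells$start, cells$size), ]
    best <- cells[1, ]
    out[[i]] <- data.frame(ec = e, start = best$start, size = best$size,
                           stat = best$stat, r = best$r,
                           mean_abs_r = sel$mean_abs_r[i],
                           stringsAsFactors = FALSE)
    vals[[e]] <- window_aggregate(ec_daily, e, best$start, best$size,
                                  best$stat)
  }
  res <- do.call(rbind, out)
  attr(res, "ec_values") <- vals
  class(res) <- c("ec_selection", "data.frame")
  res
}
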