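#' @keywords internal
"_PACKAGE"

# Deterministic first-come column pruning: keep a column only if it increases
# the rank of the design built from the columns kept so far.
.drop_aliased <- function(X, tol = 1e-9) {
  if (ncol(X) == 0L) return(integer(0))
  qrx <- qr(X, tol = tol)
  if (qrx$rank == ncol(X)) return(seq_len(ncol(X)))
  keep <- integer(0)
  r <- 0L
  for (j in seq_len(ncol(X))) {
    cand <- c(keep, j)
    if (qr(X[, cand, drop = FALSE], tol = tol)$rank > r) {
      keep <- cand
      r <- r + 1L
    }
  }
  keep
}

# Quadratic-form Wald test from an estimate vector and its covariance.
# Falls back to a generalized inverse with rank-adjusted df when the
# covariance block is singular.
.wald_quad <- function(est, V, warn_singular = TRUE) {
  est <- as.numeric(est)
  df <- length(est)
  stat <- tryCatch({
    ch <- chol(V)
    z <- backsolve(ch, est, transpose = TRUE)
    sum(z^2)
  }, error = function(e) NA_real_)
  if (is.na(stat)) {
    ev <- eigen(V, symmetric = TRUE)
    tol <- max(ev$values) * length(est) * .Machine$double.eps
    pos <- ev$values > max(tol, 0)
    df <- sum(pos)
    if (warn_singular) {
      warning("singular coefficient covariance; using generalized inverse (df = ",
              df, ")", call. = FALSE)
    }
    if (df == 0L) {
      stat <- 0
      df <- 1L
    } else {
      z <- crossprod(ev$vectors[, pos, drop = FALSE], est)
      stat <- sum(z^2 / ev$values[pos])
    }
  }
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(
    list(statistic = stat, df = df, p_value = p,
         neg_log10_p = -log10(max(p, .Machine$double.xmin))),
    class = "wald_result")
}

#' @export
print.wald_result <- function(x, ...) {
  cat(sprintf("Wald chi-square = %.4g, df = %d, p = %.4g (-log10 p = %.3f)\n",
              x$statistic, x$df, x$p_value, x$neg_log10_p))
  invisible(x)
}

# Stable marker lookup: marker id, or chromosome + position.
.find_marker <- function(map, marker = NULL, chr = NULL, pos = NULL) {
  if (!is.null(marker)) {
    i <- match(marker, map$marker)
    if (is.na(i)) stop("marker '", marker, "' not found in map", call. = FALSE)
    return(i)
  }
  i <- which(map$chr == chr & abs(map$pos - pos) < 1e-8)
  if (length(i) == 0L) {
    stop("no marker at chr ", chr, ", ", pos, " cM", call. = FALSE)
  }
  i[1L]
}
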