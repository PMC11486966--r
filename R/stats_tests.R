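#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability method: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the probability of the observed table (within 1e-12).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return The p-value. A table with a zero margin returns 1 (flagged with
#'   attribute `"degenerate"`).
#' @examples
#' fisher_exact_two_tailed(matrix(c(9, 2, 0, 7), 2))  # 0.00226...
#' @export
fisher_exact_two_tailed <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table))) {
    abort("Need a 2x2 table of non-negative integer counts.",
          class = "clonetrace_validation_error")
  }
  r <- rowSums(table)
  cc <- colSums(table)
  n <- sum(table)
  if (any(r == 0) || any(cc == 0)) {
    return(structure(1, degenerate = TRUE))
  }
  a_range <- max(0, r[1] - cc[2]):min(r[1], cc[1])
  probs <- dhyper(a_range, cc[1], cc[2], r[1])
  p_obs <- dhyper(table[1, 1], cc[1], cc[2], r[1])
  sum(probs[probs <= p_obs + 1e-12])
}

#' Two-sided Mann-Whitney U test
#'
#' Computes the U statistic for `x` (number of (x, y) pairs with x > y,
#' ties counting one half) with a two-sided p-value: exact by full
#' enumeration of group assignments when the combined sample size is at
#' most `exact_below`, otherwise by normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact_below Combined-size threshold for the exact permutation
#'   null (default 20).
#' @return List with `u`, `p_value` and `method`.
#' @examples
#' mann_whitney_two_sided(c(1, 2), c(3, 4))$p_value  # 1/3
#' @export
mann_whitney_two_sided <- function(x, y, exact_below = 20) {
  if (!length(x) || !length(y)) {
    abort("Both samples must be non-empty.",
          class = "clonetrace_validation_error")
  }
  nx <- length(x); ny <- length(y)
  u_stat <- function(xv, yv) {
    sum(vapply(xv, function(v) sum(v > yv) + 0.5 * sum(v == yv), numeric(1)))
  }
  u <- u_stat(x, y)
  comb <- c(x, y)
  if (length(unique(comb)) == 1) {
    return(list(u = u, p_value = 1, method = "degenerate"))
  }
  mu <- nx * ny / 2
  if (nx + ny <= exact_below) {
    idx <- combn(nx + ny, nx)
    us <- apply(idx, 2, function(ii) u_stat(comb[ii], comb[-ii]))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    return(list(u = u, p_value = p, method = "exact"))
  }
  nn <- nx + ny
  ties <- table(comb)
  sigma2 <- nx * ny / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  list(u = u, p_value = min(1, 2 * pnorm(-max(z, 0))),
       method = "normal_approx")
}

#' Adjust p-values for multiple testing
#'
#' Thin wrapper over [stats::p.adjust()] offering the two corrections used
#' in this analysis context; no correction is applied by default anywhere
#' in the package.
#'
#' @param p Numeric p-values.
#' @param method `"none"`, `"bonferroni"` or `"BH"`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("none", "bonferroni", "BH")) {
  stats::p.adjust(p, method = match.arg(method))
}
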