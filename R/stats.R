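#' Two-sample t test
#'
#' Welch (unequal-variance) two-sided test by default, with a
#' pooled-variance option.
#'
#' @param a,b Numeric samples, each of length >= 2 with finite variance.
#' @param var_equal Use the pooled-variance test.
#' @return List with `t`, `df`, `p_value`.
#' @export
two_sample_t <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("samples must be finite")
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, df = length(a) + length(b) - 2, p_value = 1))
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

# all permutations of 1..n as an n! x n matrix (n <= 9)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank ties. For `n < 10` the two-sided p value
#' is computed by full permutation enumeration of one variable's ranks;
#' for larger n the asymptotic t approximation is used.
#'
#' @param x,y Equal-length numeric samples, `n >= 3`, neither constant.
#' @return List with `rho`, `p_value`, `method`.
#' @export
spearman_rank <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n < 10) {
    P <- all_perms(n)
    mx <- mean(rx); sx <- stats::sd(rx)
    my <- mean(ry); sy <- stats::sd(ry)
    rperm <- (matrix(rx[P], nrow(P)) %*% ry / (n - 1) - n / (n - 1) * mx * my) / (sx * sy)
    p <- mean(abs(rperm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    method <- "asymptotic t"
  }
  list(rho = rho, p_value = min(p, 1), method = method)
}

#' Group summary table
#'
#' Mean with SEM (`sd / sqrt(n)`, the reporting convention for group
#' comparisons), plus median, per group. A single-value group has `NA` SEM.
#'
#' @param values Numeric vector.
#' @param group Grouping factor/vector of the same length.
#' @return `data.frame` with `group`, `n`, `mean`, `sem`, `median`.
#' @export
summarize_groups <- function(values, group) {
  if (length(values) != length(group)) stop("values and group lengths differ")
  if (length(values) == 0) stop("empty input")
  g <- factor(group)
  if (any(tabulate(g) == 0)) stop("empty group")
  out <- do.call(rbind, lapply(levels(g), function(lv) {
    v <- values[g == lv]
    data.frame(group = lv, n = length(v), mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               median = stats::median(v))
  }))
  rownames(out) <- NULL
  out
}
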