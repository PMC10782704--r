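#' Paired sample container
#'
#' Matched (CT, pCT) value pairs across cases for one metric or feature.
#'
#' @param a,b Numeric vectors of equal length (>= 1), no NAs.
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  if (anyNA(a) || anyNA(b)) stop("paired_sample: NA values not allowed")
  structure(list(a = as.numeric(a), b = as.numeric(b), n = length(a)),
            class = "paired_sample")
}

# null distribution of the positive-rank sum W+ over all sign assignments,
# by generating-function convolution over the (doubled, so integer)
# mid-ranks; exact including ties
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1) # index = W2 + 1, W2 in 0..total
  f[1] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1):(total + 1)] <- g[(r + 1):(total + 1)] + f[1:(total + 1 - r)]
    f <- g
  }
  f / 2^length(ranks2)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped before ranking (the original zero rule;
#' `zero_rule = "pratt"` ranks them first and then drops their ranks). With
#' `n` nonzero differences at or below `exact_threshold` the two-sided
#' p-value is computed by exact enumeration of all `2^n` sign assignments
#' via convolution (exact also under ties); above it, a normal
#' approximation with tie-corrected variance and continuity correction is
#' used.
#'
#' @param s A [paired_sample()].
#' @param exact_threshold Largest `n` for exact enumeration (default 15).
#' @param zero_rule `"drop"` or `"pratt"`.
#' @return List: `p_value`, `statistic` (positive-rank sum V), `n_nonzero`,
#'   `method`, `degenerate` (TRUE when all differences are zero, p = 1).
#' @export
wilcoxon_signed_rank <- function(s, exact_threshold = 15,
                                 zero_rule = c("drop", "pratt")) {
  stopifnot(inherits(s, "paired_sample"))
  zero_rule <- match.arg(zero_rule)
  d <- s$a - s$b
  if (all(d == 0)) {
    return(list(p_value = 1, statistic = 0, n_nonzero = 0L,
                method = "degenerate", degenerate = TRUE))
  }
  if (zero_rule == "drop") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    keep <- d != 0
    r <- r_all[keep]
    d <- d[keep]
  }
  n <- length(d)
  v <- sum(r[d > 0])
  ranks2 <- as.integer(round(2 * r))
  if (n <= exact_threshold) {
    null <- signed_rank_null(ranks2)
    w2 <- as.integer(round(2 * v))
    p_le <- sum(null[seq_len(w2 + 1)])
    p_ge <- sum(null[(w2 + 1):length(null)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sig2 <- sum(r^2) / 4 # midranks make the tie correction implicit
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approximation"
  }
  list(p_value = p, statistic = v, n_nonzero = n, method = method,
       degenerate = FALSE)
}

#' Shapiro-Wilk normality pre-check
#'
#' Records whether a metric's paired differences look normal at level
#' `alpha`; used only to justify the nonparametric choice, never to switch
#' tests automatically.
#'
#' @param x Numeric sample.
#' @param alpha Significance level (default 0.05).
#' @return List: `normal` (TRUE/FALSE/NA), `p_value`, `inconclusive`.
#' @export
normality_check <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(unique(x)) == 1) {
    return(list(normal = NA, p_value = NA_real_, inconclusive = TRUE))
  }
  if (length(x) > 5000) x <- x[seq_len(5000)]
  p <- stats::shapiro.test(x)$p.value
  list(normal = p > alpha, p_value = p, inconclusive = FALSE)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties); the two-sided
#' p-value uses the t approximation on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors, `n >= 3` complete pairs.
#' @return List: `rho`, `p_value`, `n`, `degenerate` (TRUE when either
#'   variable has zero rank variance).
#' @export
spearman_corr <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("spearman_corr: need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, degenerate = FALSE)
}

#' Mean absolute deviation of a paired sample
#'
#' `mean(|a_i - b_i|)` over the pairs; symmetric in the two columns.
#'
#' @param s A [paired_sample()].
#' @return Scalar MAD.
#' @export
mad_paired <- function(s) {
  stopifnot(inherits(s, "paired_sample"))
  mean(abs(s$a - s$b))
}

#' Significance stars for p-values
#' @param p Numeric vector of p-values.
#' @return Character vector: `***` (<0.001), `**` (<0.01), `*` (<0.05),
#'   `x` otherwise (not significant), `NA` kept.
#' @export
p_stars <- function(p) {
  out <- ifelse(is.na(p), NA_character_,
                ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "x"))))
  out
}

#' Spearman correlation matrix with significance stars
#'
#' Full rho / p / star matrices over the columns of a case-level factor
#' table: lesion count, fraction number, PTV volume, gamma passing rates,
#' perturbation-profile code, DVH / HU metric deviations, PTV volume
#' deviation -- whatever columns the table carries. Constant columns are
#' flagged, not fatal.
#'
#' @param df Data.frame of numeric columns, >= 3 rows.
#' @return List of class `correlation_matrix`: `rho`, `p`, `stars`
#'   (matrices), `long` (tidy data.frame ready for heatmap rendering).
#' @export
correlation_report <- function(df) {
  stopifnot(is.data.frame(df), nrow(df) >= 3)
  num <- df[vapply(df, is.numeric, TRUE)]
  vars <- names(num)
  k <- length(vars)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    rho[i, i] <- 1
    p[i, i] <- 0
    for (j in seq_len(k)) {
      if (j <= i) next
      sc <- tryCatch(spearman_corr(num[[i]], num[[j]]),
                     error = function(e) list(rho = NA_real_,
                                              p_value = NA_real_))
      rho[i, j] <- rho[j, i] <- sc$rho
      p[i, j] <- p[j, i] <- sc$p_value
    }
  }
  stars <- matrix(p_stars(p), k, k, dimnames = dimnames(p))
  long <- data.frame(var1 = rep(vars, times = k), var2 = rep(vars, each = k),
                     rho = as.vector(rho), p = as.vector(p),
                     stars = as.vector(stars), stringsAsFactors = FALSE)
  structure(list(rho = rho, p = p, stars = stars, long = long,
                 n = nrow(num)), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix: %d variables, n = %d\n", ncol(x$rho), x$n))
  print(round(x$rho, 2))
  invisible(x)
}
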