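#' @include AllClasses.R
NULL

#' Mean and sample standard deviation
#'
#' The SD uses the n-1 divisor (sample SD) — the convention under which the
#' reference cohort's printed summaries reproduce exactly.
#'
#' @param values numeric vector, \code{n >= 2}.
#' @return named list \code{(n, mean, sd)}.
#' @export
describeValues <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("values contain NA")
  if (length(values) < 2L)
    stop("need at least 2 values for a sample SD")
  list(n = length(values), mean = mean(values), sd = stats::sd(values))
}

#' Per-group summary table
#'
#' @param labels group labels; output order follows the order of
#'   \code{levels} when given, otherwise first appearance (never sorted
#'   silently).
#' @param values numeric measurements, same length as \code{labels}.
#' @param levels optional explicit group order.
#' @return \code{data.frame} with columns \code{group, n, mean, sd}.
#' @export
groupSummary <- function(labels, values, levels = NULL) {
  if (length(labels) != length(values))
    stop("labels and values differ in length")
  if (is.null(levels)) levels <- unique(as.character(labels))
  labels <- factor(as.character(labels), levels = levels)
  if (anyNA(labels)) stop("labels contain values outside the given levels")
  do.call(rbind, lapply(levels, function(g) {
    d <- describeValues(values[labels == g])
    data.frame(group = g, n = d$n, mean = d$mean, sd = d$sd,
               stringsAsFactors = FALSE)
  }))
}

#' One-way ANOVA from per-group summary statistics
#'
#' Reconstructs the classical one-way ANOVA from group sizes, means and
#' sample SDs alone: grand mean \eqn{\bar x = \sum n_i m_i / N}, between
#' sum of squares \eqn{SS_b = \sum n_i (m_i - \bar x)^2}, within sum of
#' squares \eqn{SS_w = \sum (n_i - 1) s_i^2}, and
#' \eqn{F = (SS_b/df_b) / (SS_w/df_w)} with \eqn{df_b = k - 1},
#' \eqn{df_w = N - k}. This is exactly the F a raw-data ANOVA yields, so
#' published mean/SD tables can be re-analysed without the raw values.
#'
#' @param groups \code{data.frame} with columns \code{n}, \code{mean},
#'   \code{sd} (one row per group; a \code{group} label column is carried
#'   through if present). At least 2 groups, each \code{n >= 2}.
#' @param alpha significance level for the \code{significant} flag.
#' @return named list: \code{F}, \code{dfBetween}, \code{dfWithin},
#'   \code{p}, \code{significant}, \code{msWithin}, \code{degenerate}
#'   (TRUE when \code{SS_w = 0}, where F is infinite or undefined).
#' @examples
#' g <- data.frame(n = c(6, 10, 9),
#'                 mean = c(0.3701, 0.6070, 0.7143),
#'                 sd = c(0.0837, 0.0742, 0.0781))
#' anovaFromSummary(g)$F  # ~35.63
#' @export
anovaFromSummary <- function(groups, alpha = 0.05) {
  if (!all(c("n", "mean", "sd") %in% names(groups)))
    stop("groups must have columns n, mean, sd")
  n <- groups$n; m <- groups$mean; s <- groups$sd
  k <- length(n)
  if (k < 2L) stop("need at least 2 groups")
  if (any(n < 2L)) stop("every group needs n >= 2")
  if (any(s < 0)) stop("SDs must be non-negative")
  N <- sum(n)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  dfb <- k - 1L
  dfw <- N - k
  if (ssw == 0) {
    # all groups internally constant: F is +Inf if means differ, undefined
    # (0/0) if they coincide
    F <- if (ssb > 0) Inf else NaN
    p <- if (ssb > 0) 0 else NA_real_
    return(list(F = F, dfBetween = dfb, dfWithin = dfw, p = p,
                significant = isTRUE(p < alpha), msWithin = 0,
                degenerate = TRUE))
  }
  msw <- ssw / dfw
  F <- (ssb / dfb) / msw
  p <- stats::pf(F, dfb, dfw, lower.tail = FALSE)
  list(F = F, dfBetween = dfb, dfWithin = dfw, p = p,
       significant = p < alpha, msWithin = msw, degenerate = FALSE)
}

#' One-way ANOVA on raw measurements
#'
#' Classical fixed-effects one-way ANOVA, fitted with \code{stats::aov}.
#' Algebraically identical to \code{\link{anovaFromSummary}} applied to the
#' per-group summaries of the same data.
#'
#' @param values numeric measurements.
#' @param labels group labels, same length.
#' @param levels optional explicit group order.
#' @param alpha significance level for the \code{significant} flag.
#' @return as \code{\link{anovaFromSummary}}.
#' @export
anovaRaw <- function(values, labels, levels = NULL, alpha = 0.05) {
  if (length(values) != length(labels))
    stop("values and labels differ in length")
  g <- groupSummary(labels, values, levels)
  if (sum((g$n - 1) * g$sd^2) == 0)   # degenerate: no within-group variance
    return(anovaFromSummary(g, alpha))
  f <- factor(as.character(labels), levels = g$group)
  fit <- stats::aov(values ~ f)
  tab <- summary(fit)[[1]]
  F <- tab[["F value"]][1]
  dfb <- tab[["Df"]][1]
  dfw <- tab[["Df"]][2]
  p <- tab[["Pr(>F)"]][1]
  list(F = F, dfBetween = dfb, dfWithin = dfw, p = p,
       significant = p < alpha, msWithin = tab[["Mean Sq"]][2],
       degenerate = FALSE)
}

#' Fisher LSD post-hoc pairwise comparisons
#'
#' For each pair of groups computes
#' \deqn{t = (m_i - m_j) / \sqrt{MS_w (1/n_i + 1/n_j)}}
#' with the ANOVA within-group mean square, and a two-sided p from the t
#' distribution on the within degrees of freedom. By definition the LSD test
#' applies no multiplicity adjustment.
#'
#' @param groups \code{data.frame} with columns \code{group}, \code{n},
#'   \code{mean} (and \code{sd} if \code{msWithin} is to be derived).
#' @param msWithin within-group mean square; derived from the groups' SDs
#'   when \code{NULL}.
#' @param dfWithin within degrees of freedom; derived when \code{NULL}.
#' @param alpha significance level.
#' @return \code{data.frame}: \code{group1, group2, diff, t, p,
#'   significant}, one row per unordered pair in group order.
#' @export
lsdPosthoc <- function(groups, msWithin = NULL, dfWithin = NULL,
                       alpha = 0.05) {
  if (!all(c("n", "mean") %in% names(groups)))
    stop("groups must have columns n and mean")
  if (is.null(groups$group)) groups$group <- paste0("g", seq_len(nrow(groups)))
  if (is.null(msWithin) || is.null(dfWithin)) {
    if (is.null(groups$sd))
      stop("need an sd column to derive msWithin/dfWithin")
    a <- anovaFromSummary(groups)
    if (a$degenerate) stop("msWithin must be positive for an LSD test")
    msWithin <- a$msWithin
    dfWithin <- a$dfWithin
  }
  if (msWithin <= 0) stop("msWithin must be positive for an LSD test")
  k <- nrow(groups)
  out <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      diff <- groups$mean[i] - groups$mean[j]
      se <- sqrt(msWithin * (1 / groups$n[i] + 1 / groups$n[j]))
      t <- diff / se
      p <- 2 * stats::pt(-abs(t), dfWithin)
      out[[length(out) + 1L]] <- data.frame(
        group1 = groups$group[i], group2 = groups$group[j],
        diff = diff, t = t, p = p, significant = p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around \code{stats::cor.test} returning the coefficient,
#' the two-sided p (t transform on n-2 df) and the pair count.
#'
#' @param x,y numeric vectors of equal length, \code{n >= 3}, each with
#'   nonzero variance.
#' @param alpha significance level.
#' @return named list \code{(rho, p, n, significant)}.
#' @export
pearsonCorrelation <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       significant = ct$p.value < alpha)
}

#' Render a p value the way clinical tables print it
#'
#' @param p numeric p value(s).
#' @param alpha threshold.
#' @return character: \code{"<0.05"} or \code{">0.05"}.
#' @export
formatP <- function(p, alpha = 0.05) {
  ifelse(p < alpha, sprintf("<%g", alpha), sprintf(">%g", alpha))
}
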