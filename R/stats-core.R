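#' Pearson correlation with a two-tailed t-based p-value
#'
#' Product-moment correlation between two equal-length vectors, with the
#' p-value obtained from the exact null distribution of
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom.
#' Used throughout the package: sample-reproducibility checks, cross-species
#' ortholog profile comparison, and co-expression edge calling.
#'
#' @param x,y Numeric vectors of equal length (at least 3 values each).
#' @return A one-row tibble with columns `r`, `n` and `p`.
#' @examples
#' pearson_test(1:9, c(2, 1, 4, 3, 6, 5, 8, 7, 9))
#' @export
pearson_test <- function(x, y) {
  stop_if_not(length(x) == length(y), "`x` and `y` must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  stop_if_not(n >= 3L, "need at least 3 paired observations, got %d", n)
  stop_if_not(sd(x) > 0 && sd(y) > 0,
              "correlation undefined: at least one input has zero variance")
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(r = r, n = n, p = p)
}

#' Two-proportion z-test (pooled)
#'
#' Compares two proportions \eqn{k_1/n_1} and \eqn{k_2/n_2} with the pooled
#' z statistic and a two-tailed normal p-value. This is the test used to
#' compare percentages of upregulated genes between species.
#'
#' @param k1,n1 Successes and trials in the first group.
#' @param k2,n2 Successes and trials in the second group.
#' @return A one-row tibble with columns `z` and `p`.
#' @examples
#' two_proportion_z(30, 100, 50, 100)
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  n1 <- check_count(n1, "n1"); n2 <- check_count(n2, "n2")
  check_number(k1, "k1", 0, n1); check_number(k2, "k2", 0, n2)
  pool <- (k1 + k2) / (n1 + n2)
  stop_if_not(pool > 0 && pool < 1,
              "degenerate case: pooled proportion is %s", pool)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- (k1 / n1 - k2 / n2) / se
  tibble::tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control; a thin wrapper around
#' [stats::p.adjust()] kept so every stage uses one spelled-out entry point.
#'
#' @param p Numeric vector of p-values.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  stop_if_not(is.numeric(p), "`p` must be numeric")
  p.adjust(p, method = "BH")
}

#' Shapiro-Wilk normality test
#'
#' @param x Numeric vector (3 to 5000 values, non-constant).
#' @return A one-row tibble with columns `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  stop_if_not(length(x) >= 3L, "need at least 3 observations")
  stop_if_not(sd(x) > 0, "Shapiro-Wilk undefined for constant data")
  fit <- shapiro.test(x)
  tibble::tibble(W = unname(fit$statistic), p = fit$p.value)
}

#' Two-sample Student's t-test
#'
#' Classical pooled-variance two-sample t-test (the two-phase branch of the
#' cuticle-thickness decision tree).
#'
#' @param a,b Numeric vectors (at least 2 values each).
#' @return A one-row tibble with columns `t`, `df` and `p`.
#' @export
students_t <- function(a, b) {
  stop_if_not(length(a) >= 2L && length(b) >= 2L,
              "each sample needs at least 2 observations")
  if (sd(c(a, b)) == 0) return(tibble::tibble(t = 0, df = length(a) + length(b) - 2, p = 1))
  fit <- t.test(a, b, var.equal = TRUE)
  tibble::tibble(t = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p = fit$p.value)
}

# ---- pairwise_letters --------------------------------------------------------

new_pairwise_letters <- function(letters, p_pairwise, omnibus, alpha, method) {
  structure(
    list(letters = letters, p_pairwise = p_pairwise, omnibus = omnibus,
         alpha = alpha, method = method),
    class = "pairwise_letters")
}

#' @export
print.pairwise_letters <- function(x, ...) {
  cat(sprintf("<pairwise_letters> %s (alpha = %g)\n", x$method, x$alpha))
  cat(sprintf("omnibus: statistic = %.4g, p = %.4g\n",
              x$omnibus$statistic, x$omnibus$p))
  print(x$letters)
  invisible(x)
}

#' One-way ANOVA with Tukey's HSD and compact letters
#'
#' Fits a one-way ANOVA, runs all-pairs Tukey Honestly Significant Difference
#' comparisons on the studentized-range distribution, and encodes the outcome
#' as a compact-letter display: groups sharing a letter do not differ at
#' `alpha`.
#'
#' @param data Data frame with one observation per row.
#' @param value,group Column names (tidy-eval) holding the measurement and the
#'   grouping factor.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return A `pairwise_letters` object: `$letters` (tibble group/letter),
#'   `$p_pairwise` (symmetric matrix of Tukey-adjusted p-values), `$omnibus`
#'   (F statistic, df, p).
#' @examples
#' d <- data.frame(y = c(rnorm(5), rnorm(5, 5)), g = rep(c("a", "b"), each = 5))
#' anova_tukey(d, y, g)
#' @export
anova_tukey <- function(data, value, group, alpha = 0.05) {
  anova_tukey_vec(dplyr::pull(data, {{ value }}),
                  as.character(dplyr::pull(data, {{ group }})), alpha)
}

anova_tukey_vec <- function(v, g, alpha = 0.05) {
  check_groups(v, g, min_n = 2L)
  gf <- factor(g, levels = unique(g))
  fit <- aov(v ~ gf)
  an <- summary(fit)[[1]]
  omnibus <- tibble::tibble(statistic = an$`F value`[1],
                            df1 = an$Df[1], df2 = an$Df[2],
                            p = an$`Pr(>F)`[1], method = "one-way ANOVA")
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$gf
  pmat <- pair_matrix(rownames(tk), tk[, "p adj"], levels(gf))
  letters <- cld_letters(pmat, alpha = alpha)
  new_pairwise_letters(letters, pmat, omnibus, alpha, "ANOVA + Tukey HSD")
}

#' Kruskal-Wallis with Conover-Iman post hoc and compact letters
#'
#' Rank-based alternative used when residuals are non-normal: Kruskal-Wallis
#' H (with tie correction via midranks), followed by Conover-Iman pairwise
#' t statistics on rank means,
#' \deqn{t_{ij} = (\bar R_i - \bar R_j) / \sqrt{S^2 \frac{N-1-H}{N-k}
#'   (1/n_i + 1/n_j)}}
#' on \eqn{N-k} degrees of freedom, with Bonferroni correction across pairs.
#'
#' @inheritParams anova_tukey
#' @param p_adjust Multiplicity correction for the pairwise p-values
#'   (`"bonferroni"`, the convention followed here, or `"none"`).
#' @return A `pairwise_letters` object (see [anova_tukey()]).
#' @export
kruskal_conover <- function(data, value, group, alpha = 0.05,
                            p_adjust = c("bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  kruskal_conover_vec(dplyr::pull(data, {{ value }}),
                      as.character(dplyr::pull(data, {{ group }})),
                      alpha, p_adjust)
}

kruskal_conover_vec <- function(v, g, alpha = 0.05,
                                p_adjust = "bonferroni") {
  check_groups(v, g, min_n = 2L)
  stop_if_not(sd(v) > 0, "all values tied: rank tests undefined")
  gf <- factor(g, levels = unique(g))
  kw <- kruskal.test(v, gf)
  H <- unname(kw$statistic)
  N <- length(v); k <- nlevels(gf)
  rk <- rank(v)                      # midranks for ties
  rbar <- tapply(rk, gf, mean)
  ns <- tabulate(gf)
  S2 <- (sum(rk^2) - N * (N + 1)^2 / 4) / (N - 1)   # tie-aware rank variance
  pooled <- S2 * (N - 1 - H) / (N - k)
  pairs <- combn(levels(gf), 2)
  praw <- apply(pairs, 2, function(pr) {
    i <- match(pr[1], levels(gf)); j <- match(pr[2], levels(gf))
    tstat <- (rbar[[i]] - rbar[[j]]) /
      sqrt(pooled * (1 / ns[i] + 1 / ns[j]))
    2 * pt(-abs(tstat), df = N - k)
  })
  padj <- if (p_adjust == "bonferroni") pmin(1, praw * ncol(pairs)) else praw
  pmat <- pair_matrix(paste(pairs[2, ], pairs[1, ], sep = "-"), padj, levels(gf))
  letters <- cld_letters(pmat, alpha = alpha)
  omnibus <- tibble::tibble(statistic = H, df1 = k - 1, df2 = NA_real_,
                            p = kw$p.value, method = "Kruskal-Wallis")
  new_pairwise_letters(letters, pmat, omnibus, alpha,
                       sprintf("Kruskal-Wallis + Conover-Iman (%s)", p_adjust))
}

# Conover-Iman pairwise t statistic, exposed for verification against rank
# arithmetic done by hand.
#' Conover-Iman pairwise t statistic
#'
#' @param values Numeric vector of all observations.
#' @param groups Group label per observation.
#' @param i,j The two group labels to compare.
#' @return A one-row tibble with `t`, `df` and the unadjusted two-tailed `p`.
#' @export
conover_iman_t <- function(values, groups, i, j) {
  gf <- factor(as.character(groups), levels = unique(as.character(groups)))
  H <- unname(kruskal.test(values, gf)$statistic)
  N <- length(values); k <- nlevels(gf)
  rk <- rank(values)
  S2 <- (sum(rk^2) - N * (N + 1)^2 / 4) / (N - 1)
  pooled <- S2 * (N - 1 - H) / (N - k)
  rbar <- tapply(rk, gf, mean); ns <- tabulate(gf)
  ii <- match(i, levels(gf)); jj <- match(j, levels(gf))
  tstat <- (rbar[[ii]] - rbar[[jj]]) / sqrt(pooled * (1 / ns[ii] + 1 / ns[jj]))
  tibble::tibble(t = tstat, df = N - k, p = 2 * pt(-abs(tstat), df = N - k))
}

check_groups <- function(v, g, min_n = 2L) {
  stop_if_not(length(v) == length(g), "value and group lengths differ")
  stop_if_not(all(is.finite(v)), "non-finite measurements")
  ns <- table(g)
  stop_if_not(length(ns) >= 2L, "need at least 2 groups")
  stop_if_not(all(ns >= min_n), "every group needs at least %d observations", min_n)
}

pair_matrix <- function(labels, p, groups) {
  m <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  diag(m) <- 1
  parts <- strsplit(labels, "-", fixed = TRUE)
  for (idx in seq_along(parts)) {
    a <- parts[[idx]][1]; b <- parts[[idx]][2]
    m[a, b] <- m[b, a] <- p[idx]
  }
  m
}
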