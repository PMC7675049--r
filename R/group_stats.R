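#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Differences between group means of (approximately) normal data are
#' evaluated with a one-way analysis of variance followed by Tukey's honestly
#' significant difference test for every pair of groups.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return List of class `anova_tukey`: `F`, `p` (overall), `pairs` (data
#'   frame: `pair`, `diff`, `lwr`, `upr`, `p_adj`, `label`), `df`.
#' @examples
#' anova_tukey(list(a = rnorm(8), b = rnorm(8, 2), c = rnorm(8, 4)))$pairs
#' @export
anova_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("anova_tukey: need a list of >= 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  for (nm in names(groups))
    if (length(groups[[nm]]) < 2L)
      stop(sprintf("anova_tukey: group '%s' has fewer than 2 values", nm),
           call. = FALSE)
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  fit <- aov(value ~ group, data = dat)
  sm <- summary(fit)[[1L]]
  Fv <- sm[["F value"]][1L]
  pv <- sm[["Pr(>F)"]][1L]
  tk <- TukeyHSD(fit)$group
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  pairs$label <- vapply(pairs$p_adj, significance_label, character(1))
  structure(list(F = Fv, p = pv, pairs = pairs,
                 df = unname(sm[["Df"]])), class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1L], x$df[2L], x$F, x$p))
  cat("Tukey HSD pairwise comparisons:\n")
  for (i in seq_len(nrow(x$pairs)))
    cat(sprintf("  %-18s diff = %8.3g  p_adj = %.4g %s\n", x$pairs$pair[i],
                x$pairs$diff[i], x$pairs$p_adj[i], x$pairs$label[i]))
  invisible(x)
}

#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum comparison for non-normal data. For small samples
#' (`n_a + n_b <= 12`) the two-tailed p-value is computed by exact enumeration
#' of all group assignments of the pooled (average-rank) values, which remains
#' valid under ties; larger samples use the normal approximation with tie and
#' continuity corrections.
#'
#' @param a,b numeric vectors (each nonempty).
#' @param exact_max enumerate exactly when `length(a) + length(b)` is at most
#'   this (default 12).
#' @return List of class `mwu_test`: `U` (statistic of the first sample), `p`
#'   (two-tailed), `method` ("exact" or "normal"), `n` (c(n_a, n_b)).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p  # exact: 0.1
#' @export
mann_whitney_u <- function(a, b, exact_max = 12) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b))
    stop("mann_whitney_u: both groups must be nonempty", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("mann_whitney_u: values must be finite", call. = FALSE)
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (N <= exact_max) {
    combs <- combn(N, na)
    Us <- apply(combs, 2L, function(ix) sum(r[ix])) - na * (na + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    t <- table(pooled)
    s2 <- na * nb / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
    if (s2 <= 0) {
      p <- 1
      method <- "normal"
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(s2)
      p <- min(1, 2 * pnorm(-abs(z)))
      method <- "normal"
    }
  }
  structure(list(U = U, p = p, method = method, n = c(na, nb)),
            class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s): U = %g, n = (%d, %d), two-tailed p = %.4g\n",
              x$method, x$U, x$n[1L], x$n[2L], x$p))
  invisible(x)
}

#' Significance label for a p-value
#'
#' Star convention with strict thresholds: `p < 0.05` (*), `p < 0.01` (**),
#' `p < 0.005` (***), `p < 0.001` (****); otherwise `"ns"`. A p-value exactly
#' at a threshold takes the weaker label.
#'
#' @param p p-value in \[0, 1\].
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @examples
#' significance_label(0.04)
#' @export
significance_label <- function(p) {
  if (!is.finite(p) || p < 0 || p > 1)
    stop("significance_label: p must be in [0, 1]", call. = FALSE)
  if (p < 0.001) "****"
  else if (p < 0.005) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else "ns"
}
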