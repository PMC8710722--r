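#' One-way analysis of variance
#'
#' Classical fixed-effects between/within decomposition (equal-variance
#' F test) across independent groups.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 observations).
#' @return List: `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2 || any(vapply(groups, length, 1L) < 2)) {
    stop("invalid-input: need >= 2 groups with >= 2 observations each")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  fit <- oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic),
       df_between = unname(fit$parameter[1]),
       df_within = unname(fit$parameter[2]),
       p = if (is.nan(fit$p.value)) 1 else unname(fit$p.value))
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR procedure
#'
#' Adaptive linear step-up FDR control: stage 1 applies the linear step-up
#' procedure at `q' = q / (1 + q)` to estimate the number of true nulls
#' `m0 = m - r1`; stage 2 re-runs the step-up at `q' * m / m0`. If stage 1
#' rejects nothing, no hypotheses are rejected; if it rejects everything,
#' all are. Adjusted p values are consistent with the rejection set at the
#' declared `q` (`significant == (p_adjusted <= q)`).
#'
#' @param p_values numeric vector of p values in `[0, 1]`.
#' @param q FDR level in (0, 1), default 0.05.
#' @return List: `significant` (logical), `p_adjusted`, `m0`,
#'   `stage1_rejections`.
#' @export
fdr_bky <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  m <- length(p)
  if (m == 0 || any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("domain error: p values must lie in [0, 1]")
  }
  if (q <= 0 || q >= 1) stop("domain error: q must lie in (0, 1)")
  qp <- q / (1 + q)
  ord <- order(p)
  ps <- p[ord]
  # stage 1: linear step-up at q'
  r1 <- {
    pass <- which(ps <= seq_len(m) / m * qp)
    if (length(pass)) max(pass) else 0L
  }
  m0 <- m - r1
  if (m0 == 0) {
    padj <- rep(0, m)
  } else {
    # step-up at q'*m/m0  <=>  min_{j>=i} m0*p(j)/j <= q'
    t_sorted <- rev(cummin(rev(m0 * ps / seq_len(m))))
    padj_sorted <- pmin(t_sorted / pmax(1 - t_sorted, .Machine$double.eps), 1)
    padj <- numeric(m)
    padj[ord] <- padj_sorted
  }
  list(significant = padj <= q, p_adjusted = padj, m0 = m0,
       stage1_rejections = r1)
}

#' Tukey honestly-significant-difference post hoc test
#'
#' Pairwise comparisons after a one-way layout, using the studentized range
#' statistic with pooled within-group variance (Tukey-Kramer for unequal
#' group sizes); adjusted p values from the studentized range distribution.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 obs).
#' @return data.frame: `group_a`, `group_b`, `diff`, `q`, `df`,
#'   `p_adjusted`.
#' @export
tukey_hsd <- function(groups) {
  k <- length(groups)
  if (k < 2 || any(vapply(groups, length, 1L) < 2)) {
    stop("invalid-input: need >= 2 groups with >= 2 observations each")
  }
  ns <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1)
  N <- sum(ns)
  msw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 1)) / (N - k)
  df <- N - k
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(msw / 2 * (1 / ns[i] + 1 / ns[j]))
    qstat <- if (se == 0) 0 else abs(means[i] - means[j]) / se
    p <- if (se == 0 && means[i] == means[j]) 1 else
      ptukey(qstat, k, df, lower.tail = FALSE)
    c(i, j, means[j] - means[i], qstat, df, p)
  })
  out <- as.data.frame(t(res))
  names(out) <- c("group_a", "group_b", "diff", "q", "df", "p_adjusted")
  gn <- names(groups)
  if (!is.null(gn)) {
    out$group_a <- gn[out$group_a]
    out$group_b <- gn[out$group_b]
  }
  out
}

#' Normality screen (Kolmogorov-Smirnov and Shapiro-Wilk)
#'
#' One-sample KS test against a normal with sample-estimated mean and sd
#' (Lilliefors-style, so the KS p is approximate) plus the Shapiro-Wilk
#' test. `pass_flag` is TRUE when both p values exceed `alpha`. Constant
#' samples are flagged non-normal with `NA` p values.
#'
#' @param sample numeric vector, n >= 3.
#' @param alpha significance threshold (default 0.05).
#' @return List: `ks_p`, `shapiro_p`, `pass_flag`.
#' @export
normality_screen <- function(sample, alpha = 0.05) {
  x <- as.numeric(sample)
  if (length(x) < 3) stop("invalid-input: need at least 3 observations")
  if (sd(x) == 0) {
    return(list(ks_p = NA_real_, shapiro_p = NA_real_, pass_flag = FALSE))
  }
  ks_p <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
  xs <- if (length(x) > 5000) x[round(seq(1, length(x), length.out = 5000))]
        else x
  sh_p <- shapiro.test(xs)$p.value
  list(ks_p = ks_p, shapiro_p = sh_p,
       pass_flag = ks_p > alpha && sh_p > alpha)
}

#' Pairwise post hoc t tests with pooled within-group variance
#'
#' Fisher-LSD style uncorrected pairwise comparisons after a one-way
#' layout (t on the pooled error term, df = N - k), intended to be fed into
#' [fdr_bky()] per comparison family.
#'
#' @param groups named list of numeric vectors.
#' @return data.frame: `group_a`, `group_b`, `t`, `df`, `p_raw`.
#' @export
pairwise_posthoc <- function(groups) {
  k <- length(groups)
  if (k < 2 || any(vapply(groups, length, 1L) < 2)) {
    stop("invalid-input: need >= 2 groups with >= 2 observations each")
  }
  ns <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1)
  N <- sum(ns)
  msw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 1)) / (N - k)
  df <- N - k
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(msw * (1 / ns[i] + 1 / ns[j]))
    tstat <- if (se == 0) 0 else (means[j] - means[i]) / se
    p <- if (se == 0) 1 else 2 * pt(abs(tstat), df, lower.tail = FALSE)
    c(i, j, tstat, df, p)
  })
  out <- as.data.frame(t(res))
  names(out) <- c("group_a", "group_b", "t", "df", "p_raw")
  gn <- names(groups)
  if (!is.null(gn)) {
    out$group_a <- gn[out$group_a]
    out$group_b <- gn[out$group_b]
  }
  out
}
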