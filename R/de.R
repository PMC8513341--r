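#' Differential-expression test configuration
#'
#' @param alpha significance threshold on the raw P-value (default 0.05; no
#'   multiple-testing correction is applied to the significance flag, though
#'   a Benjamini-Hochberg column is emitted).
#' @param scale `"log2"` tests log2(count + 1) (variance-stabilized
#'   default); `"linear"` tests the normalized counts directly.
#' @param zero_variance how to report a zero pooled variance: equal means
#'   give P = 1; unequal means give P = 0 with a `zero_variance` flag.
#' @return a `de_config` list.
#' @export
de_config <- function(alpha = 0.05, scale = c("log2", "linear"),
                      zero_variance = "flag") {
  scale <- match.arg(scale)
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, scale = scale,
                 zero_variance = zero_variance), class = "de_config")
}

de_transform <- function(m, scale) {
  if (scale == "log2") log2(m + 1) else m
}

#' Per-miRNA two-sample Student's t-test
#'
#' Classical pooled-variance two-sided t-test per row between two library
#' groups, on the configured scale, with raw P-values (the study's
#' convention: significant at P < alpha with no correction). Fold changes
#' are log2 of (mean + 1) ratios of the normalized linear means.
#'
#' @param counts normalized miRNA x library matrix.
#' @param group_a,group_b column names (or indices) of the two groups; at
#'   least two libraries each.
#' @param config a [de_config()].
#' @param contrast label for the contrast (e.g. "HO40_vs_LO40").
#' @return data frame of class `mirna_de`: `id`, `contrast`, `mean_a`,
#'   `mean_b`, `log2fc` (a over b), `statistic`, `df`, `p_value`, `padj`
#'   (BH), `significant`, `zero_variance`.
#' @export
pairwise_ttest <- function(counts, group_a, group_b, config = de_config(),
                           contrast = "A_vs_B") {
  A <- counts[, group_a, drop = FALSE]
  B <- counts[, group_b, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  if (na < 2 || nb < 2) stop("need at least 2 replicates per group")
  xa <- de_transform(A, config$scale)
  xb <- de_transform(B, config$scale)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, stats::var); vb <- apply(xb, 1, stats::var)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- ifelse(se > 0, (ma - mb) / se, ifelse(ma == mb, 0, Inf * sign(ma - mb)))
  p <- ifelse(se > 0, 2 * stats::pt(-abs(tstat), df),
              ifelse(ma == mb, 1, 0))
  zero_var <- se == 0 & ma != mb
  mean_a <- rowMeans(A); mean_b <- rowMeans(B)
  out <- data.frame(id = rownames(counts), contrast = contrast,
                    mean_a = mean_a, mean_b = mean_b,
                    log2fc = log2((mean_a + 1) / (mean_b + 1)),
                    statistic = tstat, df = df, p_value = p,
                    padj = stats::p.adjust(p, "BH"),
                    significant = p < config$alpha,
                    zero_variance = zero_var,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("mirna_de", "data.frame")
  out
}

#' Per-miRNA one-way ANOVA across developmental stages
#'
#' One-way fixed-effects ANOVA per row over the supplied stage groups, on
#' the configured scale.
#'
#' @param counts normalized miRNA x library matrix.
#' @param groups list of character/integer vectors of columns, one per
#'   stage, or a factor of length ncol(counts).
#' @param config a [de_config()].
#' @param contrast label.
#' @return data frame of class `mirna_de` with `statistic` = F, `df1`,
#'   `df2`, `p_value`, `padj`, `significant`.
#' @export
stage_anova <- function(counts, groups, config = de_config(),
                        contrast = "stages") {
  if (is.factor(groups) || is.character(groups) && length(groups) == ncol(counts)) {
    groups <- split(seq_len(ncol(counts)), groups)
  }
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("need at least 2 replicates per group")
  x <- de_transform(counts, config$scale)
  n <- sum(sizes)
  gm <- vapply(groups, function(g) rowMeans(x[, g, drop = FALSE]),
               numeric(nrow(x)))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1)
  grand <- rowSums(sweep(gm, 2, sizes, "*")) / n
  ssb <- rowSums(sweep((gm - grand)^2, 2, sizes, "*"))
  ssw_parts <- vapply(seq_along(groups), function(i) {
    rowSums((x[, groups[[i]], drop = FALSE] - gm[, i])^2)
  }, numeric(nrow(x)))
  if (is.null(dim(ssw_parts))) ssw_parts <- matrix(ssw_parts, nrow = 1)
  ssw <- rowSums(ssw_parts)
  df1 <- k - 1; df2 <- n - k
  msb <- ssb / df1; msw <- ssw / df2
  f <- ifelse(msw > 0, msb / msw, ifelse(msb == 0, 0, Inf))
  p <- ifelse(msw > 0, stats::pf(f, df1, df2, lower.tail = FALSE),
              ifelse(msb == 0, 1, 0))
  out <- data.frame(id = rownames(counts), contrast = contrast,
                    statistic = f, df1 = df1, df2 = df2, p_value = p,
                    padj = stats::p.adjust(p, "BH"),
                    significant = p < config$alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("mirna_de", "data.frame")
  out
}

#' qRT-PCR relative expression by the 2^-dCT method
#'
#' @param ct_target cycle threshold of the target.
#' @param ct_reference cycle threshold of the internal reference.
#' @return 2^-(ct_target - ct_reference).
#' @export
delta_ct_expression <- function(ct_target, ct_reference) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_reference)))
  2^(-(ct_target - ct_reference))
}

#' PCA of library expression profiles
#'
#' Centered principal component analysis of the libraries on
#' log2(normalized + 1) expression, for replicate-consistency assessment.
#'
#' @param counts normalized miRNA x library matrix (>= 3 libraries).
#' @return list of class `sample_pca`: `scores` (libraries x components),
#'   `percent_variance` (per component, summing to 100 over the full
#'   decomposition), `prcomp` (the underlying fit).
#' @export
sample_pca <- function(counts) {
  if (ncol(counts) < 3) stop("need at least 3 samples")
  x <- t(log2(counts + 1))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  pv <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, percent_variance = pv, prcomp = pc),
            class = "sample_pca")
}

#' @export
print.sample_pca <- function(x, ...) {
  cat(sprintf("PCA of %d libraries: PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), x$percent_variance[1],
              if (length(x$percent_variance) > 1) x$percent_variance[2] else 0))
  invisible(x)
}

#' @method plot sample_pca
#' @export
plot.sample_pca <- function(x, ...) {
  graphics::plot(x$scores[, 1], x$scores[, 2],
                 xlab = sprintf("PC1 (%.1f%%)", x$percent_variance[1]),
                 ylab = sprintf("PC2 (%.1f%%)", x$percent_variance[2]),
                 pch = 19, ...)
  graphics::text(x$scores[, 1], x$scores[, 2], rownames(x$scores),
                 pos = 3, cex = 0.7)
  invisible(x)
}
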