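#' Quantile-normalize an expression matrix
#'
#' Forces every column onto the identical empirical distribution: the
#' sorted values of each column are replaced by the row means of the
#' column-sorted matrix. Row and column labels are preserved. The
#' operation is idempotent.
#'
#' @param matrix numeric matrix with at least two columns.
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("expected a numeric matrix", call. = FALSE)
  }
  if (ncol(matrix) < 2L) {
    stop("quantile normalization needs at least 2 columns", call. = FALSE)
  }
  if (any(!is.finite(matrix))) stop("matrix values must be finite",
                                    call. = FALSE)
  ranks <- apply(matrix, 2L, order)
  means <- rowMeans(apply(matrix, 2L, sort))
  out <- matrix
  for (j in seq_len(ncol(matrix))) out[ranks[, j], j] <- means
  out
}

#' Moderated two-sample differential expression
#'
#' For each feature, computes the log2 fold change between two conditions
#' and a moderated t statistic in which the per-feature sample variance is
#' shrunk towards a prior:
#' `s2_tilde = (prior_df * prior_var + df * s2) / (prior_df + df)`,
#' with `df = n1 + n2 - 2`. Two-sided p-values use a t distribution with
#' `df + prior_df` degrees of freedom; Benjamini-Hochberg adjustment is
#' applied across features. With `prior_df = 0` this is the ordinary
#' pooled-variance two-sample t test.
#'
#' @param matrix log2 expression matrix (features x samples), finite values.
#' @param samples sample sheet data frame (`sample_id`, `condition`,
#'   `replicate`) covering every column.
#' @param contrast character vector `c(treatment, control)`; the log2 fold
#'   change is treatment minus control.
#' @param prior_df prior degrees of freedom for the variance shrinkage
#'   (default 4; 0 disables moderation).
#' @param prior_var prior variance; default is the median per-feature
#'   pooled sample variance.
#' @return A `de_table` data frame with columns `feature_id`, `AveExpr`
#'   (mean over all samples), `logFC`, `t_mod`, `p`, `adjP`.
#' @export
differential <- function(matrix, samples, contrast, prior_df = 4,
                         prior_var = NULL) {
  if (!setequal(colnames(matrix), samples$sample_id)) {
    stop("sample sheet must cover exactly the matrix columns", call. = FALSE)
  }
  if (length(contrast) != 2L) {
    stop("contrast must be c(treatment, control)", call. = FALSE)
  }
  cond <- samples$condition[match(colnames(matrix), samples$sample_id)]
  unknown <- setdiff(contrast, cond)
  if (length(unknown)) {
    stop("contrast names unknown condition '", unknown[[1L]], "'",
         call. = FALSE)
  }
  i1 <- which(cond == contrast[[1L]])
  i2 <- which(cond == contrast[[2L]])
  if (length(i1) < 2L || length(i2) < 2L) {
    stop("each condition needs at least 2 replicates", call. = FALSE)
  }
  if (prior_df < 0) stop("prior_df must be >= 0", call. = FALSE)

  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(matrix[, i1, drop = FALSE])
  m2 <- rowMeans(matrix[, i2, drop = FALSE])
  logfc <- m1 - m2
  df <- n1 + n2 - 2L
  ss <- rowSums((matrix[, i1, drop = FALSE] - m1)^2) +
    rowSums((matrix[, i2, drop = FALSE] - m2)^2)
  s2 <- ss / df
  if (is.null(prior_var)) prior_var <- stats::median(s2)
  if (prior_var < 0) stop("prior_var must be >= 0", call. = FALSE)

  s2_tilde <- (prior_df * prior_var + df * s2) / (prior_df + df)
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, logfc / se, ifelse(logfc == 0, 0, Inf * sign(logfc)))
  if (any(se == 0 & logfc != 0)) {
    warning("zero-variance feature with nonzero logFC: t set to +/-Inf, p to 0")
  }
  p <- ifelse(is.infinite(t_mod), 0,
              2 * stats::pt(-abs(t_mod), df + prior_df))
  out <- data.frame(feature_id = rownames(matrix),
                    AveExpr = rowMeans(matrix),
                    logFC = logfc, t_mod = t_mod, p = p,
                    adjP = bh_adjust(p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns, in input order, `adj_i = min_{j >= i} min(1, m * p_(j) / j)`
#' over the sorted p-values.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values of the same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  o <- order(p_values)
  q <- m * p_values[o] / seq_len(m)
  adj_sorted <- pmin(1, rev(cummin(rev(q))))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

#' Category thresholds
#'
#' The three cutoffs used to call a transcript expressed and up- or
#' down-regulated. `preset = "standard"` is the permissive screen
#' (AveExpr >= 7.0, |logFC| > 0.7, adjP < 0.05); `preset = "stringent"` is
#' the high-confidence screen (AveExpr >= 7.0, |logFC| > 1.5, adjP < 0.01)
#' used for short candidate lists.
#'
#' @param min_aveexpr minimum log2 average intensity (inclusive).
#' @param min_abs_logfc minimum absolute log2 fold change (strict).
#' @param max_adjp maximum BH-adjusted p-value (strict), in `(0, 1]`.
#' @param preset optional name of a preset, overriding the other arguments.
#' @return A `de_thresholds` list.
#' @export
de_thresholds <- function(min_aveexpr = 7, min_abs_logfc = 0.7,
                          max_adjp = 0.05, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("standard", "stringent"))
    return(switch(preset,
                  standard = de_thresholds(7, 0.7, 0.05),
                  stringent = de_thresholds(7, 1.5, 0.01)))
  }
  if (max_adjp <= 0 || max_adjp > 1) stop("max_adjp must be in (0, 1]",
                                          call. = FALSE)
  if (min_abs_logfc < 0) stop("min_abs_logfc must be >= 0", call. = FALSE)
  structure(list(min_aveexpr = min_aveexpr, min_abs_logfc = min_abs_logfc,
                 max_adjp = max_adjp),
            class = "de_thresholds")
}

#' Categorize transcripts into up/down/background sets
#'
#' The background (expressed universe) is every feature with
#' `AveExpr >= min_aveexpr`. Within it, down-regulated features have
#' `logFC < -min_abs_logfc` and `adjP < max_adjp`, up-regulated features
#' symmetrically. Fold-change and significance comparisons are strict;
#' the expression floor is inclusive.
#'
#' @param detable a `de_table` from [differential()].
#' @param thresholds a [de_thresholds()] object.
#' @return A `category_sets` list with character vectors `up`, `down`,
#'   `background`.
#' @export
categorize <- function(detable, thresholds = de_thresholds()) {
  if (!nrow(detable)) stop("empty differential table", call. = FALSE)
  bg <- detable$AveExpr >= thresholds$min_aveexpr
  sig <- detable$adjP < thresholds$max_adjp
  up <- bg & sig & detable$logFC > thresholds$min_abs_logfc
  down <- bg & sig & detable$logFC < -thresholds$min_abs_logfc
  structure(list(up = detable$feature_id[up],
                 down = detable$feature_id[down],
                 background = detable$feature_id[bg]),
            class = "category_sets")
}

#' @export
print.category_sets <- function(x, ...) {
  cat("<category_sets> up:", length(x$up), " down:", length(x$down),
      " background:", length(x$background), "\n")
  invisible(x)
}

#' Relative expression by the comparative CT method
#'
#' qPCR relative quantification: `2^-(ct_target - ct_reference)`, the
#' standard 2^-deltaCT transform against an endogenous control.
#'
#' @param ct_target cycle threshold(s) of the target assay.
#' @param ct_reference cycle threshold(s) of the endogenous control.
#' @return Relative expression value(s).
#' @examples
#' relative_expression_ddct(25, 22)  # 0.125
#' @export
relative_expression_ddct <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop("CT values must be finite", call. = FALSE)
  }
  2^(-(ct_target - ct_reference))
}
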