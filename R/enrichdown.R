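#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` marked items in `n` draws without replacement
#' from `N` items of which `K` are marked. The upper tail includes the
#' observed `k`, the standard over-representation convention.
#'
#' @param N background size.
#' @param K marked items in the background.
#' @param n draws (category size).
#' @param k observed marked draws.
#' @return Upper-tail probability in `[0, 1]`.
#' @export
hypergeom_upper <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(!is.finite(vals)) || any(vals != round(vals)) || any(vals < 0)) {
    stop("N, K, n, k must be non-negative integers", call. = FALSE)
  }
  if (K > N || n > N) stop("K and n must not exceed N", call. = FALSE)
  if (k > min(K, n)) stop("k must not exceed min(K, n)", call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation of predicted targets in expression categories
#'
#' For each miRNA, each prediction source and each category (up, down),
#' tests whether the miRNA's predicted targets are over-represented in the
#' category relative to the expressed background, using the hypergeometric
#' upper tail on the quadruple `(N, K, n, k)`:
#' `N` = background size, `K` = predicted targets in the background,
#' `n` = category size, `k` = predicted targets in the category.
#' Benjamini-Hochberg adjustment is applied across miRNAs within each
#' (source, category) pair. A miRNA with no predicted target in the
#' background gets `p = 1` and an undefined (NA) fold enrichment, flagged
#' in `fold_undefined`.
#'
#' @param category_sets a `category_sets` list from [categorize()].
#' @param predictions_list list of [target_predictions()] objects (or a
#'   single one).
#' @return An `enrichment_table` data frame with columns `mirna_id`,
#'   `source`, `category`, `N`, `K`, `n`, `k`, `fold_enrichment`,
#'   `fold_undefined`, `p`, `adjP`, sorted by (source, category, adjP,
#'   fold descending).
#' @export
enrich <- function(category_sets, predictions_list) {
  if (inherits(predictions_list, "target_predictions")) {
    predictions_list <- list(predictions_list)
  }
  if (!length(predictions_list)) stop("no prediction sources", call. = FALSE)
  bg <- category_sets$background
  if (!length(bg)) stop("empty background", call. = FALSE)
  cats <- list(up = intersect(category_sets$up, bg),
               down = intersect(category_sets$down, bg))
  rows <- list()
  for (p in predictions_list) {
    for (m in names(p$targets)) {
      tg_bg <- intersect(p$targets[[m]], bg)
      for (cat in names(cats)) {
        N <- length(bg)
        K <- length(tg_bg)
        n <- length(cats[[cat]])
        k <- length(intersect(tg_bg, cats[[cat]]))
        undef <- K == 0L || n == 0L
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = m, source = p$source, category = cat,
          N = N, K = K, n = n, k = k,
          fold_enrichment = if (undef) NA_real_ else (k / n) / (K / N),
          fold_undefined = undef,
          p = if (undef) 1 else hypergeom_upper(N, K, n, k),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$adjP <- NA_real_
  for (src in unique(out$source)) {
    for (cat in c("up", "down")) {
      i <- out$source == src & out$category == cat
      out$adjP[i] <- bh_adjust(out$p[i])
    }
  }
  ord <- order(out$source, out$category, out$adjP,
               -ifelse(is.na(out$fold_enrichment), -Inf, out$fold_enrichment))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Plot-ready enrichment coordinates
#'
#' Maps each record to `(fold_enrichment, -log10(adjP))`, the usual
#' volcano-style enrichment display. Adjusted p-values of 0 are capped
#' before taking the log.
#'
#' @param records an `enrichment_table` from [enrich()].
#' @param cap floor applied to `adjP` before the log (default 1e-300).
#' @return Data frame with `mirna_id`, `source`, `category`,
#'   `fold_enrichment`, `neg_log10_adjp`.
#' @export
enrichment_plot_table <- function(records, cap = 1e-300) {
  if (!nrow(records)) stop("no enrichment records", call. = FALSE)
  data.frame(mirna_id = records$mirna_id,
             source = records$source,
             category = records$category,
             fold_enrichment = records$fold_enrichment,
             neg_log10_adjp = -log10(pmax(records$adjP, cap)),
             stringsAsFactors = FALSE)
}
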