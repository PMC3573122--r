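#' Build a ranked list from a differential table
#'
#' Features are ordered by the ranking metric, descending; ties are broken
#' lexicographically by feature id so the ordering is platform-independent.
#' The default metric is the moderated t statistic (a fold change scaled
#' by its standard deviation).
#'
#' @param detable a `de_table` from [differential()].
#' @param metric column of `detable` to rank by.
#' @return A `ranked_list` data frame with columns `id`, `metric`.
#' @export
ranked_list <- function(detable, metric = "t_mod") {
  if (!metric %in% colnames(detable)) {
    stop("no column '", metric, "' in the differential table", call. = FALSE)
  }
  v <- detable[[metric]]
  if (any(!is.finite(v))) stop("ranking metric must be finite", call. = FALSE)
  o <- order(-v, detable$feature_id)
  out <- data.frame(id = detable$feature_id[o], metric = v[o],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Derive an up/down signature from a differential table
#'
#' The signature is the pair of gene sets
#' `up = {p < alpha, logFC > 0}` and `down = {p < alpha, logFC < 0}`
#' (raw p-values, strict comparisons; a feature with `logFC = 0` joins
#' neither set). Set sizes are recorded in the descriptions.
#'
#' @param detable a `de_table` from [differential()].
#' @param alpha significance level in `(0, 1)`.
#' @return A `gene_sets` list with elements `up` and `down`.
#' @export
derive_signature <- function(detable, alpha = 0.05) {
  if (!nrow(detable)) stop("empty differential table", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  up <- detable$feature_id[detable$p < alpha & detable$logFC > 0]
  down <- detable$feature_id[detable$p < alpha & detable$logFC < 0]
  if (!length(up) && !length(down)) {
    stop("no feature passes p < ", alpha, "; use a larger alpha",
         call. = FALSE)
  }
  structure(list(up = up, down = down),
            descriptions = c(up = paste0("n=", length(up)),
                             down = paste0("n=", length(down))),
            class = "gene_sets")
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list from top to bottom, incrementing the running sum
#' at member genes by `|metric|^exponent / sum_members |metric|^exponent`
#' and decrementing at non-members by `1 / (M - M_hit)`. The enrichment
#' score is the running-sum value of maximal absolute deviation from zero
#' (signed). `exponent = 0` gives the classical unweighted
#' Kolmogorov-Smirnov statistic; `exponent = 1` is standard weighted GSEA.
#'
#' @param ranked a `ranked_list` from [ranked_list()].
#' @param gene_set character vector of member ids; must intersect the
#'   ranked ids and must not cover all of them.
#' @param exponent weighting exponent (>= 0).
#' @return An `es_profile` list with `es`, `running_sum` (per-rank),
#'   `peak_rank`, and `leading_edge` (member genes at or before the peak
#'   for a positive score, at or after it for a negative one).
#' @export
enrichment_score <- function(ranked, gene_set, exponent = 1) {
  hits <- ranked$id %in% gene_set
  M <- length(hits)
  m <- sum(hits)
  if (m == 0L) stop("gene set does not intersect the ranked list",
                    call. = FALSE)
  if (m == M) stop("gene set covers the whole ranked list", call. = FALSE)
  w <- abs(ranked$metric)^exponent
  wh <- sum(w[hits])
  if (wh == 0) {
    stop("all member metrics are zero under this exponent; ",
         "use exponent = 0", call. = FALSE)
  }
  step <- ifelse(hits, w / wh, -1 / (M - m))
  run <- cumsum(step)
  peak <- which.max(abs(run))
  es <- run[[peak]]
  leading <- if (es >= 0) ranked$id[seq_len(peak)][hits[seq_len(peak)]]
  else ranked$id[peak:M][hits[peak:M]]
  structure(list(es = es, running_sum = run, peak_rank = peak,
                 leading_edge = leading),
            class = "es_profile")
}

#' @export
print.es_profile <- function(x, ...) {
  cat("<es_profile> ES =", format(x$es, digits = 4),
      "at rank", x$peak_rank, "-", length(x$leading_edge),
      "leading-edge gene(s)\n")
  invisible(x)
}

# ES only, for permutation nulls; hits is a logical vector
es_stat <- function(w, hits, M, miss_dec) {
  step <- ifelse(hits, w / sum(w[hits]), miss_dec)
  run <- cumsum(step)
  run[[which.max(abs(run))]]
}

#' Permutation significance of an enrichment score
#'
#' The null distribution is built by gene-tag permutation: `n_perm`
#' size-matched gene sets are drawn uniformly from the ranked ids and
#' scored. The normalized enrichment score divides the observed score by
#' the mean absolute null score of the same sign; the nominal p-value is
#' the same-sign fraction of null scores at least as extreme, with an
#' add-one (pseudo-count) correction so it is never zero. Results are
#' deterministic given `(n_perm, seed)`.
#'
#' For a single gene set the sign-stratified FDR q-value coincides with
#' the nominal p-value; use repeated calls plus external adjustment for
#' collections.
#'
#' @param ranked a `ranked_list`.
#' @param gene_set character vector of member ids.
#' @param exponent weighting exponent.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer RNG seed.
#' @return A `significance_result` list: `es`, `nes`, `p_nominal`,
#'   `fdr_q`, `n_perm`, `seed`.
#' @export
significance <- function(ranked, gene_set, exponent = 1, n_perm = 1000L,
                         seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  obs <- enrichment_score(ranked, gene_set, exponent)
  M <- nrow(ranked)
  m <- sum(ranked$id %in% gene_set)
  w <- abs(ranked$metric)^exponent
  miss_dec <- -1 / (M - m)
  null_es <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      hits <- logical(M)
      hits[sample.int(M, m)] <- TRUE
      es_stat(w, hits, M, miss_dec)
    }, numeric(1))
  })
  same <- null_es[sign(null_es) == sign(obs$es)]
  nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
  structure(list(es = obs$es, nes = nes, p_nominal = p, fdr_q = p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat("<significance_result> ES =", format(x$es, digits = 4),
      " NES =", format(x$nes, digits = 4),
      " p =", format(x$p_nominal, digits = 4),
      " (", x$n_perm, "permutations )\n")
  invisible(x)
}
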