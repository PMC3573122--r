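#' Filter a differential table down to a candidate target list
#'
#' The candidate cascade keeps genes that (i) are consensus predicted
#' targets supported by at least `min_sources` prediction sources and
#' (ii) fall in the down-regulated category under the supplied thresholds.
#' Candidates are sorted by logFC ascending (largest inhibition first);
#' `AveExpr` and `logFC` are copied unchanged from the differential table.
#'
#' @param detable a `de_table` sharing an id space with the target sets.
#' @param consensus_targets the result of [intersect_sources()], or a
#'   plain character vector of consensus gene ids.
#' @param thresholds a [de_thresholds()] object; the stringent preset
#'   (`AveExpr >= 7`, `|logFC| > 1.5`, `adjP < 0.01`) reproduces a short
#'   high-confidence list.
#' @param min_sources minimum supporting sources; applied to the
#'   `support` counts when `consensus_targets` carries them.
#' @param annotations optional data frame with columns `symbol`,
#'   `accession`, `description` keyed by `symbol`.
#' @return A `candidate_table` data frame with columns `symbol`,
#'   `accession`, `description`, `AveExpr`, `logFC`, `n_sources`,
#'   `in_vivo_support`.
#' @export
candidate_filter <- function(detable, consensus_targets,
                             thresholds = de_thresholds(preset = "stringent"),
                             min_sources = NULL, annotations = NULL) {
  if (is.character(consensus_targets)) {
    support <- stats::setNames(rep(NA_integer_, length(consensus_targets)),
                               consensus_targets)
    consensus <- consensus_targets
  } else {
    support <- consensus_targets$support
    consensus <- consensus_targets$consensus
    if (!is.null(min_sources)) {
      consensus <- names(support)[support >= min_sources]
    }
  }
  if (!length(consensus)) {
    warning("empty consensus target set; no candidates")
  }
  down <- categorize(detable, thresholds)$down
  keep <- intersect(consensus, down)
  idx <- match(keep, detable$feature_id)
  out <- data.frame(symbol = keep,
                    accession = rep(NA_character_, length(keep)),
                    description = rep(NA_character_, length(keep)),
                    AveExpr = detable$AveExpr[idx],
                    logFC = detable$logFC[idx],
                    n_sources = unname(support[keep]),
                    in_vivo_support = rep(NA, length(keep)),
                    stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    j <- match(out$symbol, annotations$symbol)
    if ("accession" %in% colnames(annotations)) {
      out$accession <- annotations$accession[j]
    }
    if ("description" %in% colnames(annotations)) {
      out$description <- annotations$description[j]
    }
  }
  out <- out[order(out$logFC), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Flag candidates with in-vivo cross-species support
#'
#' A candidate is supported when its mapped ortholog is significantly
#' down-regulated (`adjP < alpha` and `logFC < 0`) in an independent
#' in-vivo differential table from the other species. Candidates without
#' an ortholog entry are flagged `FALSE` with a warning; symbol matching
#' goes through the map, never through case folding.
#'
#' @param candidates a `candidate_table` from [candidate_filter()].
#' @param in_vivo_detable differential table from the in-vivo experiment
#'   (needs `feature_id`, `logFC`, `adjP`).
#' @param map an [ortholog_map()] with candidate symbols in `symbol_a` and
#'   in-vivo feature ids in `symbol_b`.
#' @param alpha significance level for the in-vivo call.
#' @return The candidate table with `in_vivo_support` filled in.
#' @export
cross_species_support <- function(candidates, in_vivo_detable, map,
                                  alpha = 0.05) {
  need <- c("feature_id", "logFC", "adjP")
  if (!all(need %in% colnames(in_vivo_detable))) {
    stop("in-vivo table needs columns feature_id, logFC, adjP",
         call. = FALSE)
  }
  sig_down <- in_vivo_detable$feature_id[
    in_vivo_detable$adjP < alpha & in_vivo_detable$logFC < 0]
  unmapped <- character(0)
  candidates$in_vivo_support <- vapply(candidates$symbol, function(sym) {
    orth <- ortholog_lookup(map, sym, from = "a")
    if (!length(orth)) {
      unmapped <<- c(unmapped, sym)
      return(FALSE)
    }
    any(orth %in% sig_down)
  }, logical(1), USE.NAMES = FALSE)
  if (length(unmapped)) {
    warning("no ortholog mapping for: ", paste(unmapped, collapse = ", "))
  }
  candidates
}

# per-miRNA two-sample t over a model table (Welch by default)
model_table_stats <- function(table, var_equal = FALSE) {
  g <- table$groups
  lev <- levels(g)
  i1 <- which(g == lev[[1L]])  # treated
  i2 <- which(g == lev[[2L]])  # control
  v <- table$values
  res <- t(apply(v, 1L, function(x) {
    tt <- stats::t.test(x[i1], x[i2], var.equal = var_equal)
    c(p = tt$p.value, delta = mean(x[i1]) - mean(x[i2]))
  }))
  data.frame(mirna_id = rownames(v), p = res[, "p"],
             direction = sign(res[, "delta"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-model miRNA overlap
#'
#' Screens each model table for miRNAs differing between treated and
#' control groups (two-sample t test, Welch by default, raw p strictly
#' below `alpha`), then intersects the significant sets across models.
#' The common list is the full intersection restricted to miRNAs with
#' identical direction in every model; miRNAs significant everywhere but
#' with disagreeing signs are reported separately as discordant. Venn
#' region counts cover every membership region.
#'
#' @param model_tables list of [mirna_model_table()] objects (>= 2;
#'   typically 3).
#' @param alpha significance screen in `(0, 1)` (raw p, strict).
#' @param var_equal use the pooled-variance t instead of Welch.
#' @return An `overlap_result` list: `per_model` (data frame of
#'   significant miRNAs with direction per model), `common` (data frame
#'   `mirna_id`, `direction`), `discordant`, `venn` (named region counts)
#'   and `alpha`.
#' @export
model_overlap <- function(model_tables, alpha = 0.01, var_equal = FALSE) {
  if (length(model_tables) < 2L) {
    stop("need at least two model tables", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  names(model_tables) <- vapply(model_tables, `[[`, character(1), "model")
  stats_by_model <- lapply(model_tables, model_table_stats,
                           var_equal = var_equal)
  sig <- lapply(stats_by_model, function(s) {
    s[s$p < alpha, c("mirna_id", "direction"), drop = FALSE]
  })
  models <- names(model_tables)
  all_sig_ids <- Reduce(intersect, lapply(sig, `[[`, "mirna_id"))
  dir_mat <- vapply(sig, function(s) {
    s$direction[match(all_sig_ids, s$mirna_id)]
  }, numeric(length(all_sig_ids)))
  if (length(all_sig_ids) == 1L) dir_mat <- matrix(dir_mat, nrow = 1L)
  consistent <- if (length(all_sig_ids)) {
    apply(dir_mat, 1L, function(d) length(unique(d)) == 1L)
  } else logical(0)
  common <- data.frame(mirna_id = all_sig_ids[consistent],
                       direction = if (any(consistent))
                         dir_mat[consistent, 1L] else numeric(0),
                       stringsAsFactors = FALSE)
  common <- common[order(common$mirna_id), , drop = FALSE]
  rownames(common) <- NULL
  discordant <- sort(all_sig_ids[!consistent])

  universe <- sort(unique(unlist(lapply(sig, `[[`, "mirna_id"))))
  member <- vapply(sig, function(s) universe %in% s$mirna_id,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  region_names <- character(0)
  region_counts <- integer(0)
  for (size in seq_along(models)) {
    for (cmb in utils::combn(length(models), size, simplify = FALSE)) {
      in_region <- rowSums(member[, cmb, drop = FALSE]) == length(cmb) &
        rowSums(member) == length(cmb)
      region_names <- c(region_names, paste(models[cmb], collapse = "&"))
      region_counts <- c(region_counts, sum(in_region))
    }
  }
  structure(list(per_model = sig,
                 common = common,
                 discordant = discordant,
                 venn = stats::setNames(region_counts, region_names),
                 alpha = alpha),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("<overlap_result>", length(x$per_model), "models at p <", x$alpha, "\n")
  cat("  common (consistent sign):", nrow(x$common), "miRNA(s)\n")
  if (nrow(x$common)) {
    lab <- ifelse(x$common$direction > 0, "up", "down")
    cat("   ", paste0(x$common$mirna_id, " (", lab, ")", collapse = ", "),
        "\n")
  }
  if (length(x$discordant)) {
    cat("  discordant:", paste(x$discordant, collapse = ", "), "\n")
  }
  invisible(x)
}
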