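#' Generate 3'UTR sequences with planted seed sites
#'
#' Emulates a 3'UTR sequence space in which a known fraction of UTRs carry
#' at least one exact seed-complementary site for each miRNA, and the rest
#' carry none at all. After planting, any accidental occurrence of a
#' miRNA's seed complement in a UTR not planted for it is destroyed by a
#' single-base substitution (re-checked until clean), so the returned truth
#' is exact: a downstream exact-seed scan with `min_sites = 1` recovers it
#' with zero false positives or negatives.
#'
#' @param n_utrs number of UTRs to generate.
#' @param length_range integer vector of length 2; UTR lengths are drawn
#'   uniformly from this range (minimum 30 nt).
#' @param mirnas named character vector of mature miRNA sequences (RNA).
#' @param planted_fraction fraction of UTRs planted per miRNA; a single
#'   value or a named vector per miRNA id, each in `[0, 1]`.
#' @param seed integer RNG seed; generation is a pure function of the
#'   arguments including `seed`.
#' @param variant seed variant used for the planted motif, see
#'   [seed_sequence()].
#' @return A list with `sequences` (a [sequence_set()]) and `truth`, a named
#'   list per miRNA with elements `utrs` (planted UTR ids) and `sites`
#'   (data frame `utr_id`, `start`, `end`, 0-based half-open).
#' @export
gen_utrs <- function(n_utrs, length_range = c(60L, 120L), mirnas,
                     planted_fraction = 0.1, seed = 1L,
                     variant = c("seed2_7", "seed1_8")) {
  variant <- match.arg(variant)
  mirnas <- as_mature_mirnas(mirnas)
  if (min(length_range) < 30L) stop("UTR lengths must be >= 30", call. = FALSE)
  frac <- planted_fraction
  if (is.null(names(frac))) frac <- stats::setNames(rep_len(frac, length(mirnas)),
                                                    names(mirnas))
  frac <- frac[names(mirnas)]
  if (any(!is.finite(frac)) || any(frac < 0) || any(frac > 1)) {
    stop("planted_fraction must be in [0, 1]", call. = FALSE)
  }
  motifs <- vapply(mirnas, function(m) seed_sequence(m, variant)$target_motif,
                   character(1))
  if (anyDuplicated(motifs)) {
    stop("two miRNAs share the same seed-complement motif; planted truths ",
         "would be ambiguous", call. = FALSE)
  }
  if (max(nchar(motifs)) > min(length_range)) {
    stop("seed-complement motif longer than the shortest UTR", call. = FALSE)
  }
  withr::with_seed(seed, {
    ids <- sprintf("utr%0*d", nchar(as.character(n_utrs)), seq_len(n_utrs))
    lens <- sample(seq(length_range[[1L]], length_range[[2L]]), n_utrs,
                   replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- ids

    planted_ids <- lapply(names(mirnas), function(m) {
      k <- round(n_utrs * frac[[m]])
      if (k > 0L) sample(ids, k) else character(0)
    })
    names(planted_ids) <- names(mirnas)

    # plant sites: uniform over valid positions, non-overlapping per UTR
    site_rows <- list()
    protected <- stats::setNames(vector("list", n_utrs), ids)  # occupied intervals
    for (m in names(mirnas)) {
      motif <- motifs[[m]]
      w <- nchar(motif)
      for (id in planted_ids[[m]]) {
        L <- nchar(seqs[[id]])
        occ <- protected[[id]]
        valid <- setdiff(seq_len(L - w + 1L) - 1L, unlist(lapply(occ, function(iv) {
          seq(max(0L, iv[[1L]] - w + 1L), iv[[2L]] - 1L)
        })))
        if (!length(valid)) {
          stop("no room left to plant a site in ", id,
               "; increase UTR length or lower planted_fraction",
               call. = FALSE)
        }
        pos <- valid[sample.int(length(valid), 1L)]
        substr(seqs[[id]], pos + 1L, pos + w) <- motif
        protected[[id]] <- c(occ, list(c(pos, pos + w)))
        site_rows[[length(site_rows) + 1L]] <-
          data.frame(mirna_id = m, utr_id = id, start = pos, end = pos + w,
                     stringsAsFactors = FALSE)
      }
    }

    # destroy accidental occurrences in non-planted UTRs
    for (pass in seq_len(100L)) {
      dirty <- FALSE
      for (m in names(mirnas)) {
        motif <- motifs[[m]]
        w <- nchar(motif)
        others <- setdiff(ids, planted_ids[[m]])
        hits <- find_motif(seqs[others], motif)
        if (nrow(hits)) {
          dirty <- TRUE
          for (r in seq_len(nrow(hits))) {
            id <- hits$utr_id[[r]]
            cand <- seq(hits$start[[r]], hits$end[[r]] - 1L)
            prot <- unlist(lapply(protected[[id]], function(iv) {
              seq(iv[[1L]], iv[[2L]] - 1L)
            }))
            cand <- setdiff(cand, prot)
            if (!length(cand)) {
              stop("cannot remove an accidental seed site overlapping a ",
                   "planted one in ", id, call. = FALSE)
            }
            pos <- cand[sample.int(length(cand), 1L)]
            old <- substr(seqs[[id]], pos + 1L, pos + 1L)
            substr(seqs[[id]], pos + 1L, pos + 1L) <-
              sample(setdiff(c("A", "C", "G", "T"), old), 1L)
          }
        }
      }
      if (!dirty) break
      if (pass == 100L) {
        stop("failed to clear accidental seed sites after 100 passes",
             call. = FALSE)
      }
    }

    sites <- if (length(site_rows)) do.call(rbind, site_rows) else
      data.frame(mirna_id = character(0), utr_id = character(0),
                 start = integer(0), end = integer(0))
    truth <- lapply(names(mirnas), function(m) {
      s <- sites[sites$mirna_id == m, c("utr_id", "start", "end")]
      rownames(s) <- NULL
      list(utrs = sort(unique(s$utr_id)), sites = s)
    })
    names(truth) <- names(mirnas)
    list(sequences = sequence_set(seqs), truth = truth)
  })
}

# all exact (overlapping) occurrences of motif, 0-based half-open
find_motif <- function(seqs, motif) {
  w <- nchar(motif)
  out <- lapply(names(seqs), function(id) {
    m <- gregexpr(paste0("(?=", motif, ")"), seqs[[id]], perl = TRUE)[[1L]]
    st <- as.integer(m)
    st <- st[st > 0L] - 1L
    if (!length(st)) return(NULL)
    data.frame(utr_id = id, start = st, end = st + w,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(utr_id = character(0), start = integer(0),
                      end = integer(0)))
  }
  do.call(rbind, out)
}

#' Generate a two-condition log2 expression matrix with planted shifts
#'
#' Emulates a transfection-versus-control single-channel design: control
#' samples are per-feature baseline plus i.i.d. Gaussian noise on the log2
#' scale; treatment samples are additionally shifted by the planted log2
#' effect. Intensity-dependent variance and array artifacts are not
#' modeled.
#'
#' @param features character vector of feature ids, or an integer count.
#' @param truth_shifts named numeric vector of planted log2 shifts; features
#'   not named get shift 0.
#' @param n_per_group replicates per condition (>= 2).
#' @param noise_sd Gaussian noise standard deviation (log2 scale).
#' @param baseline_mean mean of the per-feature baseline intensity.
#' @param baseline_sd spread of per-feature baselines around
#'   `baseline_mean` (log2 scale); 0 gives a flat baseline.
#' @param seed integer RNG seed.
#' @param conditions labels for the two conditions,
#'   `c(treatment, control)`.
#' @return List with `matrix`, `samples` (sample sheet data frame) and
#'   `truth` (shifts, group size, noise sd, seed).
#' @export
gen_expression <- function(features, truth_shifts = numeric(0),
                           n_per_group = 3L, noise_sd = 0.3,
                           baseline_mean = 10, baseline_sd = 1,
                           seed = 1L,
                           conditions = c("treatment", "control")) {
  if (is.numeric(features) && length(features) == 1L) {
    features <- sprintf("g%0*d", nchar(as.character(features)),
                        seq_len(features))
  }
  if (n_per_group < 2L) stop("n_per_group must be >= 2", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(truth_shifts)) {
    if (is.null(names(truth_shifts))) {
      stop("truth_shifts must be named by feature id", call. = FALSE)
    }
    if (any(!is.finite(truth_shifts))) {
      stop("planted shifts must be finite", call. = FALSE)
    }
    unknown <- setdiff(names(truth_shifts), features)
    if (length(unknown)) {
      stop("shift for unknown feature ", unknown[[1L]], call. = FALSE)
    }
  }
  shifts <- stats::setNames(numeric(length(features)), features)
  shifts[names(truth_shifts)] <- truth_shifts

  withr::with_seed(seed, {
    p <- length(features)
    base <- baseline_mean + stats::rnorm(p, 0, baseline_sd)
    treat <- base + shifts +
      matrix(stats::rnorm(p * n_per_group, 0, noise_sd), p)
    ctrl <- base + matrix(stats::rnorm(p * n_per_group, 0, noise_sd), p)
    mat <- cbind(treat, ctrl)
    colnames(mat) <- c(paste0(conditions[[1L]], "_", seq_len(n_per_group)),
                       paste0(conditions[[2L]], "_", seq_len(n_per_group)))
    rownames(mat) <- features
    samples <- data.frame(
      sample_id = colnames(mat),
      condition = rep(conditions, each = n_per_group),
      replicate = rep(seq_len(n_per_group), 2L),
      stringsAsFactors = FALSE)
    list(matrix = mat, samples = samples,
         truth = list(shifts = shifts, n_per_group = n_per_group,
                      noise_sd = noise_sd, seed = seed))
  })
}

#' Generate per-model miRNA expression tables with a planted common subset
#'
#' Emulates miRNA profiling of several disease models (e.g. lung, liver and
#' kidney fibrosis) on a shared platform: each model table holds per-miRNA
#' log2 replicate values for a treated and a control group. A designated
#' common subset is shifted with consistent sign in every model
#' (`common_up` by `+effect`, `common_down` by `-effect`); per-model extras
#' are shifted in that model only, with random sign.
#'
#' @param mirnas character vector of miRNA ids (the platform universe).
#' @param common_up,common_down miRNA ids planted up/down in every model;
#'   must be disjoint.
#' @param per_model_extras named list (model -> miRNA ids) of
#'   model-specific planted miRNAs, or a single integer count per model
#'   sampled from the remaining universe.
#' @param n_per_group replicates per group (>= 2).
#' @param effect absolute planted log2 shift (> 0).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer RNG seed.
#' @param models model names (>= 2).
#' @return List with `tables` (named list of [mirna_model_table()]) and
#'   `truth` (per-model signed sets plus the common subsets).
#' @export
gen_model_tables <- function(mirnas, common_up = character(0),
                             common_down = character(0),
                             per_model_extras = 3L, n_per_group = 5L,
                             effect = 2, noise_sd = 0.4, seed = 1L,
                             models = c("lung", "liver", "kidney")) {
  if (length(intersect(common_up, common_down))) {
    stop("common_up and common_down must be disjoint", call. = FALSE)
  }
  if (!all(c(common_up, common_down) %in% mirnas)) {
    stop("common subsets must be drawn from `mirnas`", call. = FALSE)
  }
  if (effect <= 0) stop("effect must be > 0", call. = FALSE)
  if (n_per_group < 2L) stop("n_per_group must be >= 2", call. = FALSE)

  withr::with_seed(seed, {
    free <- setdiff(mirnas, c(common_up, common_down))
    if (is.numeric(per_model_extras) && length(per_model_extras) == 1L) {
      per_model_extras <- stats::setNames(
        lapply(models, function(m) sample(free, min(per_model_extras,
                                                    length(free)))),
        models)
    }
    per_model_extras <- per_model_extras[models]
    tables <- list()
    truth_models <- list()
    for (mod in models) {
      extras <- intersect(per_model_extras[[mod]], free)
      extra_sign <- sample(c(-1, 1), length(extras), replace = TRUE)
      shift <- stats::setNames(numeric(length(mirnas)), mirnas)
      shift[common_up] <- effect
      shift[common_down] <- -effect
      shift[extras] <- extra_sign * effect
      p <- length(mirnas)
      treat <- 8 + shift + matrix(stats::rnorm(p * n_per_group, 0, noise_sd), p)
      ctrl <- 8 + matrix(stats::rnorm(p * n_per_group, 0, noise_sd), p)
      values <- cbind(treat, ctrl)
      rownames(values) <- mirnas
      colnames(values) <- c(paste0("treated_", seq_len(n_per_group)),
                            paste0("control_", seq_len(n_per_group)))
      groups <- rep(c("treated", "control"), each = n_per_group)
      tables[[mod]] <- mirna_model_table(mod, values, groups)
      truth_models[[mod]] <- list(
        up = sort(c(common_up, extras[extra_sign > 0])),
        down = sort(c(common_down, extras[extra_sign < 0])))
    }
    list(tables = tables,
         truth = list(models = truth_models,
                      common_up = sort(common_up),
                      common_down = sort(common_down)))
  })
}

#' Per-model miRNA replicate table
#'
#' @param model model name.
#' @param values numeric matrix, miRNAs x samples.
#' @param groups character vector assigning each column to one of two
#'   groups; the first level in order of appearance is treated as the
#'   "treated" group for the direction sign.
#' @return A `mirna_model_table` object.
#' @export
mirna_model_table <- function(model, values, groups) {
  if (length(groups) != ncol(values)) {
    stop("groups must have one entry per column", call. = FALSE)
  }
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups required", call. = FALSE)
  if (min(table(groups)) < 2L) {
    stop("model ", model, " needs >= 2 replicates per group", call. = FALSE)
  }
  structure(list(model = model, values = values,
                 groups = factor(groups, levels = lev)),
            class = "mirna_model_table")
}

#' @export
print.mirna_model_table <- function(x, ...) {
  cat("<mirna_model_table>", x$model, "-", nrow(x$values), "miRNA(s),",
      ncol(x$values), "sample(s)\n")
  invisible(x)
}

#' Write / read a model table as TSV
#'
#' Columns are named `<group>_<replicate>` so the grouping survives a
#' round trip.
#'
#' @param table a [mirna_model_table()].
#' @param path file path.
#' @return `path` (write) or a [mirna_model_table()] (read).
#' @export
write_model_table <- function(table, path) {
  df <- data.frame(mirna_id = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_model_table
#' @param model model name to assign on reading.
#' @export
read_model_table <- function(path, model = basename(path)) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab[[1L]]
  groups <- sub("_[0-9]+$", "", colnames(values))
  mirna_model_table(model, values, groups)
}
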