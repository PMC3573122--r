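#' Seed sequence and target motif of a mature miRNA
#'
#' The seed is taken from the 5' end of the mature sequence: nucleotides
#' 2-7 (1-based, inclusive; a 6mer) or 1-8 (an 8mer). The target motif is
#' the reverse complement of the seed written as DNA, i.e. the exact
#' Watson-Crick complementary site searched for on a 3'UTR given 5'-to-3'.
#'
#' @param mirna mature miRNA sequence (RNA or DNA, any case), length >= 8.
#' @param variant `"seed2_7"` (nucleotides 2-7) or `"seed1_8"`
#'   (nucleotides 1-8).
#' @return List with `seed` (RNA) and `target_motif` (DNA).
#' @examples
#' seed_sequence("CCCAGUGUUCAGACUACCUGUUC", "seed2_7")
#' @export
seed_sequence <- function(mirna, variant = c("seed2_7", "seed1_8")) {
  variant <- match.arg(variant)
  rna <- chartr("T", "U", normalize_dna(mirna))
  if (nchar(rna) < 8L) {
    stop("mature sequence must be at least 8 nt to extract a seed",
         call. = FALSE)
  }
  if (grepl("[^ACGU]", rna)) {
    stop("mature sequence must use the ACGU/ACGT alphabet", call. = FALSE)
  }
  seed <- switch(variant,
                 seed2_7 = substr(rna, 2L, 7L),
                 seed1_8 = substr(rna, 1L, 8L))
  list(seed = seed, target_motif = revcomp_dna(chartr("U", "T", seed)))
}

#' Scan UTR sequences for exact seed-complementary sites
#'
#' Reports every exact occurrence of the seed target motif on the given
#' strand, overlapping occurrences included. Coordinates are 0-based
#' half-open on the UTR.
#'
#' @param sequence_set a [sequence_set()] of 3'UTRs (5'-to-3').
#' @param mirna mature miRNA sequence (single string).
#' @param variant seed variant, see [seed_sequence()].
#' @return A `seed_sites` data frame with columns `utr_id`, `start`,
#'   `end`, `variant`, `motif`, sorted by `(utr_id, start)`.
#' @export
scan_sites <- function(sequence_set, mirna,
                       variant = c("seed2_7", "seed1_8")) {
  variant <- match.arg(variant)
  stopifnot(inherits(sequence_set, "sequence_set"))
  motif <- seed_sequence(mirna, variant)$target_motif
  hits <- find_motif(unclass(sequence_set), motif)
  out <- data.frame(utr_id = hits$utr_id, start = hits$start,
                    end = hits$end,
                    variant = rep(variant, nrow(hits)),
                    motif = rep(motif, nrow(hits)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$utr_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("seed_sites", "data.frame")
  out
}

#' Predict targets of a set of miRNAs by exact seed scan
#'
#' A UTR is a predicted target of a miRNA when it carries at least
#' `min_sites` exact seed-complementary sites.
#'
#' @param sequence_set a [sequence_set()] of 3'UTRs.
#' @param mirnas named character vector of mature miRNA sequences.
#' @param variant seed variant, see [seed_sequence()].
#' @param min_sites minimum number of sites per UTR (>= 1).
#' @return A [target_predictions()] object with source
#'   `"seed-scan:<variant>"`.
#' @export
predict_targets <- function(sequence_set, mirnas,
                            variant = c("seed2_7", "seed1_8"),
                            min_sites = 1L) {
  variant <- match.arg(variant)
  if (min_sites < 1L) stop("min_sites must be >= 1", call. = FALSE)
  mirnas <- as_mature_mirnas(mirnas)
  targets <- lapply(names(mirnas), function(m) {
    sites <- scan_sites(sequence_set, mirnas[[m]], variant)
    counts <- table(sites$utr_id)
    sort(names(counts)[counts >= min_sites])
  })
  names(targets) <- names(mirnas)
  target_predictions(paste0("seed-scan:", variant), targets)
}

#' Intersect target predictions across sources
#'
#' Builds the consensus target set of one miRNA across prediction sources
#' (genes predicted by at least `min_sources` of them) together with Venn
#' region counts covering every membership region.
#'
#' @param predictions_list list of [target_predictions()] objects (>= 1),
#'   with distinct source labels.
#' @param mirna_id miRNA to intersect.
#' @param min_sources minimum number of supporting sources, between 1 and
#'   `length(predictions_list)`.
#' @return List with `consensus` (character vector), `support` (named
#'   integer, gene -> number of supporting sources), `venn` (named integer
#'   of exclusive region counts, names like `"A&B"`), and `sources`.
#' @export
intersect_sources <- function(predictions_list, mirna_id, min_sources) {
  if (inherits(predictions_list, "target_predictions")) {
    predictions_list <- list(predictions_list)
  }
  k <- length(predictions_list)
  if (k < 1L) stop("at least one prediction source required", call. = FALSE)
  if (min_sources < 1L || min_sources > k) {
    stop("min_sources must be between 1 and the number of sources",
         call. = FALSE)
  }
  sources <- vapply(predictions_list, `[[`, character(1), "source")
  if (anyDuplicated(sources)) stop("duplicate source labels", call. = FALSE)
  sets <- lapply(predictions_list, function(p) {
    unique(as.character(p$targets[[mirna_id]]))
  })
  names(sets) <- sources
  genes <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) genes %in% s,
                   logical(length(genes)))
  if (length(genes) == 1L) member <- matrix(member, nrow = 1L)
  if (!length(genes)) member <- matrix(logical(0), 0L, k)
  support <- stats::setNames(as.integer(rowSums(member)), genes)
  consensus <- genes[support >= min_sources]

  region_names <- character(0)
  region_counts <- integer(0)
  for (size in seq_len(k)) {
    combs <- utils::combn(k, size, simplify = FALSE)
    for (cmb in combs) {
      in_region <- rowSums(member[, cmb, drop = FALSE]) == length(cmb) &
        rowSums(member) == length(cmb)
      region_names <- c(region_names, paste(sources[cmb], collapse = "&"))
      region_counts <- c(region_counts, sum(in_region))
    }
  }
  list(consensus = consensus, support = support,
       venn = stats::setNames(region_counts, region_names),
       sources = sources)
}
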