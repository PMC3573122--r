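#' Sequence sets
#'
#' A `sequence_set` is an ordered, named character vector of uppercase DNA
#' sequences (alphabet `A C G T N`) with an optional per-record description
#' kept in the `"descriptions"` attribute. RNA input (`U`) and lowercase
#' letters are normalized on construction so DNA and RNA files are
#' interchangeable for seed scanning.
#'
#' @param sequences named character vector of nucleotide sequences.
#' @param descriptions optional character vector of free-text descriptions,
#'   recycled to `length(sequences)`.
#' @return A `sequence_set` object.
#' @examples
#' sequence_set(c(u1 = "acgu", u2 = "ACGT"))
#' @export
sequence_set <- function(sequences, descriptions = NULL) {
  if (length(sequences) == 0L) {
    stop("a sequence set must contain at least one record", call. = FALSE)
  }
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids)) {
    stop("every sequence must have a non-empty id", call. = FALSE)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate id ", dup[[1L]], call. = FALSE)
  }
  seqs <- normalize_dna(sequences)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id ", ids[!nzchar(seqs)][[1L]], call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    ch <- sub(".*?([^ACGTN]).*", "\\1", seqs[bad][[1L]])
    stop("non-IUPAC character '", ch, "' in sequence ", ids[bad][[1L]],
         call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- rep("", length(seqs))
  descriptions <- rep_len(as.character(descriptions), length(seqs))
  names(descriptions) <- ids
  structure(seqs, descriptions = descriptions, class = "sequence_set")
}

# uppercase + U->T; chartr drops names, so reattach them
normalize_dna <- function(x) {
  out <- chartr("U", "T", toupper(as.character(x)))
  names(out) <- names(x)
  out
}

# T->U keeping names
to_rna <- function(x) {
  out <- chartr("T", "U", x)
  names(out) <- names(x)
  out
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("<sequence_set> ", length(x), " record(s)\n", sep = "")
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    s <- unclass(x)[[i]]
    cat("  ", names(x)[[i]], ": ", nchar(s), " nt  ",
        substr(s, 1L, 40L), if (nchar(s) > 40L) "...", "\n", sep = "")
  }
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' @export
`[.sequence_set` <- function(x, i) {
  sequence_set(unclass(x)[i], attr(x, "descriptions")[i])
}

#' Read a FASTA file into a sequence set
#'
#' Headers are split on the first whitespace into id and description.
#' Sequences are normalized (uppercase, `U` to `T`); duplicate ids, empty
#' sequences and non-IUPAC characters are errors.
#'
#' @param path path to a FASTA file.
#' @return A [sequence_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(raw)
  names(seqs) <- ids
  sequence_set(seqs, desc)
}

#' Write a sequence set to FASTA
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f))` reproduces
#' `x` exactly.
#'
#' @param x a [sequence_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "sequence_set"))
  desc <- attr(x, "descriptions")
  headers <- ifelse(nzchar(desc), paste(names(x), desc), names(x))
  set <- Biostrings::BStringSet(unclass(x))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read mature miRNA sequences
#'
#' Mature miRNAs are stored 5'-to-3' as RNA. Any FASTA (DNA or RNA, either
#' case) is accepted; sequences are normalized to uppercase RNA. Mature
#' miRNAs shorter than 16 nt are rejected as implausible.
#'
#' @param path path to a FASTA file of mature miRNA sequences.
#' @return Named character vector of RNA sequences (class `mature_mirnas`).
#' @export
read_mirnas <- function(path) {
  set <- read_fasta(path)
  as_mature_mirnas(to_rna(unclass(set)))
}

#' Validate a set of mature miRNA sequences
#'
#' @param x named character vector of mature sequences (RNA or DNA).
#' @return Named character vector of uppercase RNA (class `mature_mirnas`).
#' @export
as_mature_mirnas <- function(x) {
  if (!length(x)) return(structure(character(0), class = "mature_mirnas"))
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every miRNA must have a non-empty id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate miRNA id ", ids[duplicated(ids)][[1L]], call. = FALSE)
  }
  seqs <- to_rna(normalize_dna(x))
  if (any(grepl("[^ACGU]", seqs))) {
    stop("miRNA sequences must use the ACGU alphabet", call. = FALSE)
  }
  short <- nchar(seqs) < 16L
  if (any(short)) {
    stop("mature miRNA ", ids[short][[1L]], " is shorter than 16 nt",
         call. = FALSE)
  }
  structure(seqs, class = "mature_mirnas")
}

# reverse complement of a DNA string
revcomp_dna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
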