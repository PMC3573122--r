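#' Read a log2 expression matrix with its sample sheet
#'
#' The matrix is a TSV with a header row of sample ids and a first column of
#' feature ids; the sample sheet is a TSV with columns `sample_id`,
#' `condition`, `replicate`. All cells must parse as finite numbers: the
#' arrays this pipeline models are complete, so missing values are rejected
#' rather than imputed.
#'
#' @param matrix_path path to the expression TSV.
#' @param samplesheet_path path to the sample sheet TSV.
#' @return A list with elements `matrix` (numeric matrix, features x
#'   samples) and `samples` (data frame `sample_id`, `condition`,
#'   `replicate`).
#' @export
read_expression <- function(matrix_path, samplesheet_path) {
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) stop("expression matrix needs at least one sample column",
                           call. = FALSE)
  feat <- raw[[1L]]
  if (anyDuplicated(feat)) {
    stop("duplicate feature id ", feat[duplicated(feat)][[1L]], call. = FALSE)
  }
  vals <- raw[, -1L, drop = FALSE]
  mat <- matrix(NA_real_, nrow(vals), ncol(vals),
                dimnames = list(feat, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop("non-numeric or missing value at feature '", feat[bad[[1L]]],
           "', sample '", colnames(vals)[[j]], "'", call. = FALSE)
    }
    mat[, j] <- v
  }
  samples <- read_samplesheet(samplesheet_path)
  missing <- setdiff(colnames(mat), samples$sample_id)
  if (length(missing)) {
    stop("unannotated sample ", missing[[1L]], call. = FALSE)
  }
  samples <- samples[match(colnames(mat), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  list(matrix = mat, samples = samples)
}

read_samplesheet <- function(path) {
  sheet <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "condition", "replicate")
  if (!all(need %in% colnames(sheet))) {
    stop("sample sheet must have columns sample_id, condition, replicate",
         call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  rep_num <- suppressWarnings(as.integer(sheet$replicate))
  if (any(!is.finite(rep_num)) || any(rep_num < 1L)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  data.frame(sample_id = as.character(sheet$sample_id),
             condition = as.character(sheet$condition),
             replicate = rep_num, stringsAsFactors = FALSE)
}

#' Write an expression matrix and sample sheet as TSV
#'
#' @param matrix numeric matrix (features x samples).
#' @param samples sample sheet data frame.
#' @param matrix_path,samplesheet_path output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(matrix, samples, matrix_path, samplesheet_path) {
  df <- data.frame(feature_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(samples, samplesheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' Read a GMT gene-set file
#'
#' Each line is `set_id<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate members within a set are collapsed.
#'
#' @param path path to the GMT file.
#' @return Named list of character vectors (class `gene_sets`) with set
#'   descriptions in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- vector("list", length(fields))
  desc <- character(length(fields))
  ids <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L || !nzchar(f[[1L]])) {
      stop("malformed GMT line ", i, ": need set_id, description and at ",
           "least one member", call. = FALSE)
    }
    ids[[i]] <- f[[1L]]
    desc[[i]] <- f[[2L]]
    sets[[i]] <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (!length(sets[[i]])) stop("malformed GMT line ", i, ": empty set",
                                 call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate set id ", ids[duplicated(ids)][[1L]], call. = FALSE)
  }
  names(sets) <- ids
  names(desc) <- ids
  structure(sets, descriptions = desc, class = "gene_sets")
}

#' Write gene sets to a GMT file
#'
#' @param sets a `gene_sets` object or named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Target predictions from one source
#'
#' A `target_predictions` object maps each miRNA id to the set of gene /
#' UTR ids that one prediction source (e.g. an external tool table or the
#' built-in seed scan) assigns to it.
#'
#' @param source non-empty source label.
#' @param targets named list of character vectors (miRNA id -> target ids).
#' @return A `target_predictions` object.
#' @export
target_predictions <- function(source, targets) {
  if (!is.character(source) || length(source) != 1L || !nzchar(source)) {
    stop("source label must be a non-empty string", call. = FALSE)
  }
  if (length(targets) && (is.null(names(targets)) || any(!nzchar(names(targets))))) {
    stop("targets must be a named list keyed by miRNA id", call. = FALSE)
  }
  targets <- lapply(targets, function(x) unique(as.character(x)))
  structure(list(source = source, targets = targets),
            class = "target_predictions")
}

#' @export
print.target_predictions <- function(x, ...) {
  cat("<target_predictions> source:", x$source, "-", length(x$targets),
      "miRNA(s)\n")
  invisible(x)
}

#' Read a flat target-prediction table
#'
#' TSV with columns `source`, `mirna_id`, `gene`; duplicate rows are
#' idempotent. External tool predictions (TargetScan-, PicTar-,
#' miRanda-style lists) enter the pipeline this way.
#'
#' @param path path to the TSV.
#' @return Named list of [target_predictions()] objects, one per source.
#' @export
read_target_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("source", "mirna_id", "gene")
  if (!all(need %in% colnames(tab))) {
    stop("target table must have columns source, mirna_id, gene",
         call. = FALSE)
  }
  if (!nrow(tab)) stop("empty target table: ", path, call. = FALSE)
  bad <- which(!nzchar(tab$source) | !nzchar(tab$mirna_id) | !nzchar(tab$gene))
  if (length(bad)) stop("malformed target table line ", bad[[1L]] + 1L,
                        ": empty field", call. = FALSE)
  out <- lapply(split(tab, tab$source), function(d) {
    target_predictions(d$source[[1L]],
                       lapply(split(d$gene, d$mirna_id), unique))
  })
  out[unique(tab$source)]
}

#' Write target predictions to a flat TSV
#'
#' @param predictions a [target_predictions()] object or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_target_table <- function(predictions, path) {
  if (inherits(predictions, "target_predictions")) {
    predictions <- list(predictions)
  }
  rows <- do.call(rbind, lapply(predictions, function(p) {
    if (!length(p$targets)) return(NULL)
    data.frame(source = p$source,
               mirna_id = rep(names(p$targets), lengths(p$targets)),
               gene = unlist(p$targets, use.names = FALSE),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ortholog map
#'
#' TSV with columns `symbol_a`, `symbol_b` (e.g. human and mouse gene
#' symbols). Many-to-one in either direction is allowed; exact duplicate
#' pairs are collapsed.
#'
#' @param path path to the TSV.
#' @return Data frame with columns `symbol_a`, `symbol_b`
#'   (class `ortholog_map`).
#' @export
read_ortholog_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("symbol_a", "symbol_b") %in% colnames(tab))) {
    stop("ortholog map must have columns symbol_a, symbol_b", call. = FALSE)
  }
  if (!nrow(tab)) stop("empty ortholog map: ", path, call. = FALSE)
  ortholog_map(tab$symbol_a, tab$symbol_b)
}

#' Construct an ortholog map from symbol pairs
#'
#' @param symbol_a,symbol_b character vectors of paired symbols.
#' @return Data frame of unique pairs (class `ortholog_map`).
#' @export
ortholog_map <- function(symbol_a, symbol_b) {
  if (any(!nzchar(symbol_a)) || any(!nzchar(symbol_b))) {
    stop("ortholog symbols must be non-empty", call. = FALSE)
  }
  out <- unique(data.frame(symbol_a = as.character(symbol_a),
                           symbol_b = as.character(symbol_b),
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("ortholog_map", "data.frame")
  out
}

#' Look up orthologs of a symbol
#'
#' @param map an [ortholog_map()].
#' @param symbol symbol to look up (exact match, no case folding).
#' @param from `"a"` to map symbol_a -> symbol_b, `"b"` for the reverse.
#' @return Character vector of mapped symbols (possibly empty).
#' @export
ortholog_lookup <- function(map, symbol, from = c("a", "b")) {
  from <- match.arg(from)
  if (from == "a") map$symbol_b[map$symbol_a == symbol]
  else map$symbol_a[map$symbol_b == symbol]
}

#' Read one of the annotation table kinds
#'
#' Dispatcher over [read_gmt()], [read_target_table()] and
#' [read_ortholog_map()].
#'
#' @param path input path.
#' @param kind one of `"gmt"`, `"targets"`, `"orthologs"`.
#' @return The corresponding parsed structure.
#' @export
read_annotation_tables <- function(path, kind = c("gmt", "targets", "orthologs")) {
  kind <- match.arg(kind)
  switch(kind,
         gmt = read_gmt(path),
         targets = read_target_table(path),
         orthologs = read_ortholog_map(path))
}
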