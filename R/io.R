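#' Read an expression matrix with its sample design
#'
#' The matrix file is TSV or CSV (delimiter sniffed from the header line):
#' first column gene ids, header row sample ids, numeric cells. The design
#' file has columns `sample_id`, `series_id`, `time` and optionally
#' `cyclic`. Samples present in one file but not the other, duplicate ids
#' and non-numeric cells are all hard errors naming the offenders.
#'
#' @param path expression matrix file.
#' @param design_path design table file.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, design_path) {
  tab <- read_delim_sniffed(path)
  if (ncol(tab) < 2L) stop("expression file needs a gene column plus samples")
  genes <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(tab[-1L], is.numeric, TRUE))
    stop("non-numeric expression column(s): ",
         paste(names(tab)[-1L][bad], collapse = ", "), " in ", path)
  }
  rownames(vals) <- genes
  design <- read_delim_sniffed(design_path)
  if (!is.null(design$cyclic)) design$cyclic <- parse_flag(design$cyclic)
  expression_matrix(vals, design)
}

read_delim_sniffed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "")
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Write an expression matrix and design to TSV
#'
#' @param expr an [expression_matrix()].
#' @param path,design_path output files.
#' @export
write_expression <- function(expr, path, design_path) {
  stopifnot(is_expression_matrix(expr))
  write_matrix_tsv(expr$values, path, id_col = "gene")
  utils::write.table(expr$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a RANGES/ExRANGES feature matrix to TSV
#'
#' Step columns are labelled `series_id:from_time`, parseable back to
#' (series, time) losslessly via [parse_step_labels()].
#'
#' @param x a `RangesMatrix` or `ExRangesMatrix` (or bare matrix).
#' @param path output file.
#' @export
write_feature_matrix <- function(x, path) {
  m <- if (is.list(x) && !is.null(x$values)) x$values else x
  write_matrix_tsv(m, path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV file, first column gene id.
#' @return numeric matrix with gene rownames.
#' @export
read_feature_matrix <- function(path) {
  tab <- read_delim_sniffed(path)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  if (!is.numeric(m)) stop("non-numeric cells in feature matrix ", path)
  m
}

#' Split `series:from_time` step labels back into metadata
#'
#' @param labels character vector of step labels.
#' @return data.frame with columns `series_id`, `from_time`.
#' @export
parse_step_labels <- function(labels) {
  parts <- regmatches(labels, regexpr(":", labels), invert = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed step label(s): ", paste(labels[bad], collapse = ", "))
  data.frame(series_id = vapply(parts, `[`, "", 1L),
             from_time = as.numeric(vapply(parts, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}

#' Read an edge list (gold standard or ranked predictions)
#'
#' Two columns (`regulator`, `target`) give an unscored edge set; a third
#' numeric column is parsed as a score. Duplicate edges are dropped with a
#' warning; self-loops are flagged; malformed lines are reported with their
#' line numbers.
#'
#' @param path TSV/CSV edge file, with or without a header line.
#' @return data.frame with columns `regulator`, `target` and optionally
#'   `score`.
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(regulator = character(), target = character(),
                      stringsAsFactors = FALSE))
  sep <- if (grepl("\t", lines[1L])) "\t" else ","
  cells <- strsplit(lines, sep, fixed = TRUE)
  has_header <- identical(tolower(trimws(cells[[1L]][1:2])),
                          c("regulator", "target"))
  body_at <- if (has_header) 2L else 1L
  body <- cells[seq.int(body_at, length.out = length(cells) - body_at + 1L)]
  nf <- lengths(body)
  if (length(body) == 0L)
    return(data.frame(regulator = character(), target = character(),
                      stringsAsFactors = FALSE))
  if (any(nf < 2L | nf > 3L))
    stop("malformed edge line(s) in ", path, " (need 2-3 fields): line ",
         paste(which(nf < 2L | nf > 3L) + body_at - 1L, collapse = ", "))
  df <- data.frame(regulator = trimws(vapply(body, `[`, "", 1L)),
                   target = trimws(vapply(body, `[`, "", 2L)),
                   stringsAsFactors = FALSE)
  if (max(nf) == 3L) {
    sc <- suppressWarnings(as.numeric(vapply(body, `[`, "", 3L)))
    if (anyNA(sc))
      stop("non-numeric score(s) in ", path, ": line ",
           paste(which(is.na(sc)) + body_at - 1L, collapse = ", "))
    df$score <- sc
  }
  dup <- duplicated(df[c("regulator", "target")])
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) dropped from ", path)
    df <- df[!dup, , drop = FALSE]
  }
  self <- df$regulator == df$target
  if (any(self))
    warning(sum(self), " self-loop(s) in ", path, ": ",
            paste(utils::head(df$regulator[self], 5L), collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Write an edge list to TSV
#'
#' Round-trips bit-identically through [read_edges()].
#'
#' @param edges data.frame with columns `regulator`, `target` and
#'   optionally `score`.
#' @param path output file.
#' @export
write_edges <- function(edges, path) {
  keep <- intersect(c("regulator", "target", "score"), names(edges))
  utils::write.table(edges[keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene -> category annotation map
#'
#' @param path two-column TSV/CSV (`gene`, `category`), header optional.
#' @return data.frame with columns `gene`, `category`.
#' @export
read_annotation <- function(path) {
  tab <- read_delim_sniffed(path)
  if (ncol(tab) < 2L) stop("annotation needs two columns (gene, category)")
  names(tab)[1:2] <- c("gene", "category")
  tab$gene <- as.character(tab$gene)
  tab$category <- as.character(tab$category)
  tab[1:2]
}

#' Read a one-id-per-line gene list
#'
#' @param path text file, one gene id per line; blanks ignored.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}
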