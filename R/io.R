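# All tabular I/O is tab-delimited UTF-8 with a single header row.

.schemas <- list(
  plate        = c("plate_id", "row", "col", "read", "role"),
  compound_map = c("compound_id", "plate_id", "row", "col", "concentration"),
  expression   = NULL,  # first column gene symbol, remaining columns samples
  drug_target  = c("drug", "gene"),
  dose_fa      = c("dose", "fa"),
  combo        = c("dose1", "dose2", "fa")
)

.numeric_cols <- list(
  plate = c("read"),
  compound_map = c("concentration"),
  dose_fa = c("dose", "fa"),
  combo = c("dose1", "dose2", "fa")
)

#' Read a typed pipeline table
#'
#' Validates one of the pipeline's tabular schemas: `plate`,
#' `compound_map`, `expression`, `drug_target`, `dose_fa`, `combo`.
#' Tab-delimited with a header row; expression files may carry a GCT-style
#' two-line preamble (`#1.2` + dimensions), which is skipped. Missing
#' required columns raise a schema error naming the column; non-numeric
#' values in numeric columns raise a row-level error with the line number.
#'
#' @param path file path.
#' @param schema one of the schema names above.
#' @param species species tag attached to expression matrices.
#' @return a data.frame, or an expression matrix for `schema =
#'   "expression"`.
#' @export
read_table <- function(path, schema, species = "unknown") {
  schema <- match.arg(schema, names(.schemas))
  if (!file.exists(path)) stop_input("no such file: ", path)

  skip <- 0L
  if (schema == "expression") {
    first <- readLines(path, n = 1L)
    if (startsWith(first, "#")) skip <- 2L  # GCT preamble: version + dims
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          skip = skip)
  if (schema == "expression") {
    if (ncol(df) < 2) stop_input("expression file needs gene + sample columns")
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(apply(df[, -1, drop = FALSE], 1,
                         function(r) anyNA(suppressWarnings(as.numeric(r)))))
      stop_input("non-numeric expression value at data line ",
                 if (length(bad)) bad[1] else "?")
    }
    rownames(m) <- genes
    return(expression_matrix(m, species = species))
  }

  need <- .schemas[[schema]]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop_input("schema '", schema, "': missing required column(s): ",
               paste(missing_cols, collapse = ", "))
  for (col in .numeric_cols[[schema]] %||% character(0)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0)
      stop_input("schema '", schema, "': non-numeric '", col,
                 "' at data line ", bad[1])
    df[[col]] <- v
  }
  message("read ", nrow(df), " row(s) from ", basename(path),
          " (schema ", schema, ")")
  df
}

#' Write a pipeline table (tab-delimited, single header row)
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an expression matrix (gene symbol first column)
#'
#' @param mat expression matrix.
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then gene symbols, tab-separated.
#'
#' @param path GMT file.
#' @return named list of uppercase gene-symbol vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop_input("malformed GMT line (need name, description, >=1 gene)")
    toupper(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write a network in SIF format plus a node-attribute table
#'
#' SIF rows are `node1 <relation> node2`; the companion attribute table
#' carries id, kind and, when a score table is supplied, the eccentricity
#' score.
#'
#' @param net igraph network.
#' @param sif_path SIF output path.
#' @param attr_path optional node-attribute table path.
#' @param scores optional score table from [eccentricity_scores()].
#' @export
write_sif <- function(net, sif_path, attr_path = NULL, scores = NULL) {
  el <- igraph::as_data_frame(net, what = "edges")
  rel <- el$relation %||% rep("pp", nrow(el))
  writeLines(paste(el$from, rel, el$to, sep = "\t"), sif_path)
  if (!is.null(attr_path)) {
    kind <- igraph::vertex_attr(net, "kind")
    at <- data.frame(id = igraph::V(net)$name,
                     kind = if (is.null(kind)) NA else kind,
                     stringsAsFactors = FALSE)
    if (!is.null(scores))
      at$score <- scores$score[match(at$id, scores$node)]
    write_table(at, attr_path)
  }
  invisible(sif_path)
}

#' The published top-50 hit table
#'
#' The 50 top-ranked screen hits as printed (compound name, curve class,
#' IC50 in uM, efficacy in %). The source prints curve classes and
#' efficacies with a leading minus sign - the screen's notation for the
#' inhibition direction of the response; the loader parses them by absolute
#' value and records the direction.
#'
#' @return data.frame: name, curve_class, ic50, efficacy, direction.
#' @export
pheo_top50_hits <- function() {
  path <- system.file("extdata", "published_top50_hits.tsv",
                      package = "pheoscreen", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$direction <- ifelse(grepl("^-", df$curve_class) | df$efficacy < 0,
                         "inhibition", "activation")
  df$curve_class <- sub("^-", "", df$curve_class)
  df$efficacy <- abs(df$efficacy)
  df
}

#' The published epirubicin + SAHA combination table
#'
#' Constant-ratio (1:200) combination rows as printed: IC50 fold, doses
#' (nM; the source's uM column header is inconsistent with doses equal to
#' stated IC50 multiples of 5 nM / 1 uM, so the fixture records nM),
#' fraction affected, combination index, call, and the two dose-reduction
#' indices.
#'
#' @return data.frame: fold, dose_epi, dose_saha, fa, ci, effect, dri_epi,
#'   dri_saha.
#' @export
pheo_combination_rows <- function() {
  path <- system.file("extdata", "published_combination_rows.tsv",
                      package = "pheoscreen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
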