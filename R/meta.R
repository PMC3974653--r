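#' Construct an expression matrix container
#'
#' A plain numeric matrix (genes x samples) tagged with its species and
#' normalization state. Genes with any missing value are dropped at
#' construction with a message (count logged), per the missing-value policy.
#'
#' @param mat numeric matrix with gene-symbol rownames and sample colnames.
#' @param species species tag (e.g. `"mouse"`, `"human"`).
#' @return the matrix with attributes `species` and `zscored`.
#' @export
expression_matrix <- function(mat, species = "unknown") {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(rownames(mat))) stop_input("gene-symbol rownames required")
  if (anyDuplicated(rownames(mat)))
    stop_input("duplicate gene symbols in expression matrix")
  drop <- apply(mat, 1, anyNA)
  if (any(drop)) {
    message("dropping ", sum(drop), " gene(s) with missing values")
    mat <- mat[!drop, , drop = FALSE]
  }
  attr(mat, "species") <- species
  attr(mat, "zscored") <- attr(mat, "zscored") %||% FALSE
  mat
}

#' Gene-wise Z-score normalization across samples
#'
#' Each gene row is centered and scaled to mean 0 and (population) standard
#' deviation 1 across samples. Zero-variance rows are set to all-zeros and
#' flagged. The pre-standardization row means and scales are retained as
#' attributes (`prescale_center`, `prescale_scale`) so downstream steps that
#' need gene-level location - the fold-change filter and the cross-data-set
#' gene-mean correlation - can use the original (log2-scale) means, which
#' row standardization otherwise removes.
#'
#' @param mat expression matrix (genes x samples).
#' @return z-scored matrix with attributes `zscored = TRUE`,
#'   `zero_variance` (flagged gene symbols), `prescale_center`,
#'   `prescale_scale`.
#' @export
zscore_genes <- function(mat) {
  if (ncol(mat) < 2) stop_input("z-score undefined for a single-sample matrix")
  ctr <- rowMeans(mat)
  dev <- mat - ctr
  sdp <- sqrt(rowMeans(dev^2))  # population sd
  flat <- sdp < 1e-12
  sdp[flat] <- 1
  z <- dev / sdp
  z[flat, ] <- 0
  out <- mat
  out[] <- z
  attr(out, "zscored") <- TRUE
  attr(out, "zero_variance") <- rownames(mat)[flat]
  attr(out, "prescale_center") <- stats::setNames(ctr, rownames(mat))
  attr(out, "prescale_scale") <- stats::setNames(ifelse(flat, 0, sdp),
                                                 rownames(mat))
  out
}

.upper_symbols <- function(x, ortholog_table = NULL) {
  if (!is.null(ortholog_table)) {
    stopifnot(ncol(ortholog_table) >= 2)
    hit <- match(x, ortholog_table[[1]])
    x[!is.na(hit)] <- ortholog_table[[2]][hit[!is.na(hit)]]
  }
  toupper(x)
}

#' Merge two expression data sets on their common genes
#'
#' Rows are matched on a shared uppercase gene-symbol namespace (murine
#' symbols are uppercased to their human counterparts; an optional
#' two-column ortholog table overrides the case mapping). The merged matrix
#' takes the row intersection (optionally restricted to a gene set) and the
#' column union; per-data-set pre-standardization gene means travel along
#' for scale-dependent downstream steps.
#'
#' @param a,b expression matrices, already z-scored with [zscore_genes()].
#' @param restrict_to optional gene set the intersection is restricted to.
#' @param ortholog_table optional data.frame (from-symbol, to-symbol).
#' @return list of class `merged_expression`: `z` (merged z-score matrix),
#'   `common_genes`, `samples_a`, `samples_b`, `means_a`, `means_b`
#'   (pre-standardization gene means over the common genes), `species`.
#' @export
merge_common_genes <- function(a, b, restrict_to = NULL,
                               ortholog_table = NULL) {
  if (!isTRUE(attr(a, "zscored")) || !isTRUE(attr(b, "zscored")))
    stop_input("both matrices must be z-scored before merging")
  ga <- .upper_symbols(rownames(a), ortholog_table)
  gb <- .upper_symbols(rownames(b), ortholog_table)
  common <- intersect(ga, gb)
  if (!is.null(restrict_to)) common <- intersect(common, toupper(restrict_to))
  if (length(common) == 0)
    stop_input("no genes in common (", length(ga), " vs ", length(gb),
               " genes", if (!is.null(restrict_to))
                 paste0(", ", length(restrict_to), " in restriction"), ")")
  ia <- match(common, ga); ib <- match(common, gb)
  za <- a[ia, , drop = FALSE]; zb <- b[ib, , drop = FALSE]
  z <- cbind(za, zb)
  rownames(z) <- common

  pick_means <- function(m, idx, genes) {
    ctr <- attr(m, "prescale_center")
    v <- if (!is.null(ctr)) unname(ctr[idx]) else rowMeans(m[idx, , drop = FALSE])
    stats::setNames(v, genes)
  }
  structure(list(
    z = z,
    common_genes = common,
    samples_a = colnames(a), samples_b = colnames(b),
    means_a = pick_means(a, ia, common),
    means_b = pick_means(b, ib, common),
    species = c(attr(a, "species") %||% "a", attr(b, "species") %||% "b")
  ), class = "merged_expression")
}

#' @export
print.merged_expression <- function(x, ...) {
  cat(sprintf("merged expression: %d common genes, %d + %d samples (%s vs %s)\n",
              length(x$common_genes), length(x$samples_a), length(x$samples_b),
              x$species[1], x$species[2]))
  invisible(x)
}

#' Filter genes by cross-data-set fold change
#'
#' Keeps genes whose per-data-set mean difference on the log2 scale is below
#' the stated fold change: `|mean_a - mean_b| < log2(threshold_fold)`.
#' Run on the pre-standardization gene means carried by the merged object.
#'
#' @param merged a `merged_expression` from [merge_common_genes()].
#' @param threshold_fold fold-change cutoff (> 1); default 2.
#' @return character vector of surviving gene symbols.
#' @export
fold_change_filter <- function(merged, threshold_fold = 2) {
  stopifnot(inherits(merged, "merged_expression"))
  if (threshold_fold <= 1) stop_input("threshold_fold must be > 1")
  keep <- abs(merged$means_a - merged$means_b) < log2(threshold_fold)
  merged$common_genes[keep]
}

#' Load/validate a drug-target map
#'
#' @param map data.frame with columns drug, gene (one pair per line).
#' @return validated map with uppercased gene symbols, duplicates removed.
#' @export
drug_target_map <- function(map) {
  stopifnot(is.data.frame(map), all(c("drug", "gene") %in% names(map)))
  map$gene <- toupper(map$gene)
  map <- map[!duplicated(paste(map$drug, map$gene, sep = "\r")), , drop = FALSE]
  if (any(!nzchar(map$gene)) || any(!nzchar(map$drug)))
    stop_input("empty drug or gene symbol in drug-target map")
  rownames(map) <- NULL
  map
}

#' Per-drug cross-data-set target-gene correlation
#'
#' For each drug, the Pearson correlation between the two data sets'
#' gene-mean expression profiles over that drug's mapped target genes
#' (restricted to genes present in the merged matrix, and optionally to a
#' filtered gene list). Drugs with fewer than `min_targets` mapped genes are
#' reported with `pearson_r = NA`. The overall value is the mean of defined
#' per-drug correlations.
#'
#' @param merged a `merged_expression` from [merge_common_genes()].
#' @param map drug-target map (data.frame drug, gene).
#' @param genes optional gene list restricting the correlation (e.g. the
#'   fold-change survivors).
#' @param min_targets minimum mapped targets for a defined correlation.
#' @param high_r threshold used to report each drug's number of highly
#'   correlated target genes (gene-level agreement of centered means).
#' @return list with `drugs` (drug, n_targets_mapped, pearson_r,
#'   n_high_cor) and `overall_r`.
#' @export
drug_target_correlation <- function(merged, map, genes = NULL,
                                    min_targets = 3, high_r = 0.5) {
  stopifnot(inherits(merged, "merged_expression"))
  map <- drug_target_map(map)
  universe <- if (is.null(genes)) merged$common_genes
              else intersect(merged$common_genes, toupper(genes))
  ma <- merged$means_a[universe]
  mb <- merged$means_b[universe]
  ca <- ma - mean(ma); cb <- mb - mean(mb)
  # per-gene contribution to agreement: product of standardized deviations
  agree <- (ca / stats::sd(ma)) * (cb / stats::sd(mb))

  per_drug <- lapply(split(map$gene, map$drug), function(tg) {
    tg <- intersect(unique(tg), universe)
    n <- length(tg)
    r <- if (n >= min_targets) stats::cor(ma[tg], mb[tg]) else NA_real_
    data.frame(n_targets_mapped = n, pearson_r = r,
               n_high_cor = sum(agree[tg] > high_r))
  })
  drugs <- do.call(rbind, per_drug)
  drugs <- data.frame(drug = names(per_drug), drugs,
                      stringsAsFactors = FALSE, row.names = NULL)
  drugs <- drugs[order(-ifelse(is.na(drugs$pearson_r), -Inf, drugs$pearson_r),
                       drugs$drug), , drop = FALSE]
  rownames(drugs) <- NULL
  list(drugs = drugs,
       overall_r = mean(drugs$pearson_r, na.rm = TRUE))
}

#' Overall cross-data-set gene-mean correlation
#'
#' Pearson correlation between the two data sets' gene-mean vectors over a
#' gene list (typically the fold-change survivors).
#'
#' @param merged a `merged_expression`.
#' @param genes gene list; default all common genes.
#' @export
overall_gene_correlation <- function(merged, genes = NULL) {
  stopifnot(inherits(merged, "merged_expression"))
  g <- if (is.null(genes)) merged$common_genes
       else intersect(merged$common_genes, toupper(genes))
  if (length(g) < 3) stop_input("need at least 3 genes")
  stats::cor(merged$means_a[g], merged$means_b[g])
}

#' Replicate-quality report: pairwise sample correlations
#'
#' Reported (not gated): pairwise Pearson correlations between samples of a
#' matrix; high-quality array replicates typically exceed 0.98.
#'
#' @param mat expression matrix (genes x samples).
#' @return data.frame sample1, sample2, pearson_r.
#' @export
replicate_qc <- function(mat) {
  cc <- stats::cor(mat)
  idx <- which(upper.tri(cc), arr.ind = TRUE)
  data.frame(sample1 = colnames(mat)[idx[, 1]],
             sample2 = colnames(mat)[idx[, 2]],
             pearson_r = cc[idx],
             stringsAsFactors = FALSE)
}
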