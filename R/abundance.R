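# TPM conversion and abundance roll-ups from genes to KOs, functional
# roles, vitamin pathways and taxa.
#
# Internal convention: abundance matrices are samples x features; the
# `unit` ("counts", "TPM", "relative") and `feature_level` ("gene", "KO",
# "role", "pathway", "phylum", "genus") travel as attributes.

#' Construct an abundance matrix
#'
#' @param values numeric samples x features matrix with dimnames.
#' @param unit one of `"counts"`, `"TPM"`, `"relative"`.
#' @param feature_level one of `"gene"`, `"KO"`, `"role"`, `"pathway"`,
#'   `"phylum"`, `"genus"`.
#' @return Matrix of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, unit = "counts", feature_level = "gene") {
  unit <- match.arg(unit, c("counts", "TPM", "relative"))
  feature_level <- match.arg(feature_level,
                             c("gene", "KO", "role", "pathway",
                               "phylum", "genus"))
  if (!is.matrix(values) || is.null(rownames(values)) ||
      (ncol(values) > 0L && is.null(colnames(values)))) {
    vp_stop("abundance values must be a matrix with sample and feature names")
  }
  if (any(values < 0)) vp_stop("abundance values must be non-negative")
  structure(values, unit = unit, feature_level = feature_level,
            class = c("abundance_matrix", "matrix", "array"))
}

abundance_unit <- function(x) attr(x, "unit")

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("Abundance matrix: %d samples x %d %s features (%s)\n",
              nrow(x), ncol(x), attr(x, "feature_level"), attr(x, "unit")))
  invisible(x)
}

#' Gene catalog table
#'
#' @param gene_id unique gene identifiers.
#' @param length_bp positive gene lengths in bp.
#' @param ko KO id per gene (`NA` for unannotated genes).
#' @param lineage data.frame of the seven taxonomy ranks, or character
#'   vector of `d__;p__;...` strings.
#' @return data.frame of class `gene_catalog`.
#' @export
gene_catalog <- function(gene_id, length_bp, ko = NA_character_,
                         lineage = NULL) {
  if (anyDuplicated(gene_id)) vp_stop("gene_id values must be unique")
  if (any(length_bp <= 0)) vp_stop("length_bp must be positive")
  n <- length(gene_id)
  if (is.character(lineage)) lineage <- parse_lineage(lineage)
  if (is.null(lineage)) {
    lineage <- as.data.frame(matrix("", n, 7,
                                    dimnames = list(NULL, TAXONOMY_RANKS)),
                             stringsAsFactors = FALSE)
  }
  out <- data.frame(gene_id = as.character(gene_id),
                    length_bp = as.integer(length_bp),
                    ko = as.character(ko), lineage,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_catalog", "data.frame")
  out
}

#' Read/write a gene catalog TSV
#'
#' Columns: `gene_id`, `length_bp`, `ko`, `lineage` (a
#' `d__;p__;c__;o__;f__;g__;s__` string).
#' @param path file path.
#' @return `gene_catalog` (read) or `path` invisibly (write).
#' @export
read_gene_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_catalog(tab$gene_id, tab$length_bp, tab$ko, tab$lineage)
}

#' @rdname read_gene_catalog
#' @param genes a `gene_catalog`.
#' @export
write_gene_catalog <- function(genes, path) {
  out <- data.frame(gene_id = genes$gene_id, length_bp = genes$length_bp,
                    ko = genes$ko, lineage = format_lineage(genes),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert read counts to TPM
#'
#' Per sample, each gene's count is divided by its length in kilobases to
#' give a rate, and rates are scaled to sum to one million.  All-zero
#' samples stay all-zero (with a warning).
#'
#' @param counts an [abundance_matrix()] of unit `"counts"` (samples x
#'   genes).
#' @param genes a [gene_catalog()] covering every counted gene.
#' @return An `abundance_matrix` of unit `"TPM"`.
#' @export
compute_tpm <- function(counts, genes) {
  if (any(counts < 0)) vp_stop("counts must be non-negative")
  lengths <- stats::setNames(genes$length_bp, genes$gene_id)
  missing <- setdiff(colnames(counts), names(lengths))
  if (length(missing) > 0L) {
    vp_stop("gene(s) missing from catalog: %s",
            paste(utils::head(missing, 5L), collapse = ", "))
  }
  kb <- lengths[colnames(counts)] / 1000
  rates <- sweep(unclass(counts), 2L, kb, `/`)
  totals <- rowSums(rates)
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("%d all-zero sample(s) left all-zero", sum(zero)))
    totals[zero] <- 1
  }
  tpm <- rates / totals * 1e6
  abundance_matrix(tpm, unit = "TPM", feature_level = "gene")
}

#' Aggregate features into groups
#'
#' Sums feature columns into group columns according to `key`; features
#' absent from `key` (or mapped to `NA`) are dropped, with the number
#' dropped reported via a message.
#'
#' @param mat an [abundance_matrix()].
#' @param key named character vector, feature id -> group id.
#' @param feature_level level label for the output.
#' @return An `abundance_matrix` at the group level, same unit.
#' @export
aggregate_abundance <- function(mat, key, feature_level = "KO") {
  if (length(key) == 0L) vp_stop("aggregation key is empty")
  key <- key[!is.na(key)]
  mapped <- intersect(colnames(mat), names(key))
  dropped <- ncol(mat) - length(mapped)
  if (dropped > 0L) message(sprintf("aggregate: dropped %d unmapped feature(s)",
                                    dropped))
  if (length(mapped) == 0L) vp_stop("no feature maps to any group")
  groups <- key[mapped]
  sub <- unclass(mat)[, mapped, drop = FALSE]
  out <- t(rowsum(t(sub), group = groups))
  abundance_matrix(out, unit = abundance_unit(mat),
                   feature_level = feature_level)
}

#' Per-vitamin pathway abundance
#'
#' Sums gene-level TPM over the genes whose KO belongs to each vitamin's
#' roles.  A KO shared between vitamins contributes fully to each of them.
#'
#' @param tpm gene-level [abundance_matrix()].
#' @param catalog a `vita_catalog`.
#' @param gene_ko named character vector, gene id -> KO id.
#' @return An `abundance_matrix` (samples x vitamins, unit preserved).
#' @export
pathway_abundance <- function(tpm, catalog, gene_ko) {
  vits <- names(catalog$pathways)
  out <- matrix(0, nrow(tpm), length(vits),
                dimnames = list(rownames(tpm), vits))
  gene_ko <- gene_ko[!is.na(gene_ko)]
  genes <- intersect(colnames(tpm), names(gene_ko))
  for (vit in vits) {
    kos <- unique(unlist(lapply(catalog$pathways[[vit]]$routes, function(rt) {
      unlist(lapply(rt$roles, function(r) catalog$roles[[r$role_id]]$kos))
    }), use.names = FALSE))
    sel <- genes[gene_ko[genes] %in% kos]
    if (length(sel) > 0L) {
      out[, vit] <- rowSums(unclass(tpm)[, sel, drop = FALSE])
    }
  }
  abundance_matrix(out, unit = abundance_unit(tpm), feature_level = "pathway")
}

#' Taxonomic profile of gene abundances
#'
#' Sums gene TPM per taxon at the requested rank (optionally restricted to
#' genes annotated with a given KO set, e.g. the catalog's KO universe),
#' then normalizes each sample to fractions.
#'
#' @param tpm gene-level [abundance_matrix()].
#' @param genes a [gene_catalog()].
#' @param rank `"phylum"` or `"genus"`.
#' @param restrict_to optional KO character vector; only genes with a KO in
#'   this set contribute.
#' @return An `abundance_matrix` of unit `"relative"` at the rank level.
#' @export
taxon_profile <- function(tpm, genes, rank = c("phylum", "genus"),
                          restrict_to = NULL) {
  rank <- match.arg(rank)
  idx <- match(colnames(tpm), genes$gene_id)
  if (anyNA(idx)) vp_stop("gene(s) absent from catalog")
  taxa <- genes[[rank]][idx]
  keep <- !is.na(taxa) & taxa != ""
  if (!is.null(restrict_to)) {
    if (length(restrict_to) == 0L) {
      warning("empty KO restriction: returning all-zero profile")
      keep <- keep & FALSE
    } else {
      keep <- keep & !is.na(genes$ko[idx]) & genes$ko[idx] %in% restrict_to
    }
  }
  if (!any(keep)) {
    out <- matrix(0, nrow(tpm), 0, dimnames = list(rownames(tpm), NULL))
    return(abundance_matrix(out, unit = "relative", feature_level = rank))
  }
  sub <- unclass(tpm)[, keep, drop = FALSE]
  agg <- t(rowsum(t(sub), group = taxa[keep]))
  totals <- rowSums(agg)
  totals[totals == 0] <- 1
  abundance_matrix(agg / totals, unit = "relative", feature_level = rank)
}

#' Read/write abundance matrices as TSV
#'
#' On disk, features are rows and samples are columns (the conventional
#' gene-by-sample layout); in memory the matrix is samples x features.
#' A YAML-style sidecar `<path>.meta.yml` records unit and feature level.
#'
#' @param path file path.
#' @param unit,feature_level metadata used when no sidecar is present.
#' @return `abundance_matrix` (read) or `path` invisibly (write).
#' @export
read_abundance <- function(path, unit = "counts", feature_level = "gene") {
  side <- paste0(path, ".meta.yml")
  if (file.exists(side)) {
    meta <- read_simple_yaml(side)
    unit <- meta$unit %||% unit
    feature_level <- meta$feature_level %||% feature_level
  }
  tab <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  abundance_matrix(t(as.matrix(tab)), unit = unit,
                   feature_level = feature_level)
}

#' @rdname read_abundance
#' @param mat an `abundance_matrix` to write.
#' @export
write_abundance <- function(mat, path) {
  out <- cbind(feature_id = colnames(mat),
               as.data.frame(t(unclass(mat)), check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("unit: %s", attr(mat, "unit")),
               sprintf("feature_level: %s", attr(mat, "feature_level"))),
             paste0(path, ".meta.yml"))
  invisible(path)
}

read_simple_yaml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl(":", lines, fixed = TRUE)]
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  stats::setNames(as.list(vals), keys)
}
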