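# Genome quality filtering and threshold-based ANI clustering.
#
# Inequality conventions (centralized here, used everywhere):
#   completeness  >= min_completeness
#   contamination <  max_contamination   (strict)
#   quality score >= min_score
#   ANI           >  threshold           (strict) for cluster membership

TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")

#' Genome quality score
#'
#' The standard MAG quality score, completeness minus five times
#' contamination (both in percent).
#'
#' @param completeness percent in \[0, 100\].
#' @param contamination percent, non-negative.
#' @return Numeric score (vectorized).
#' @export
quality_score <- function(completeness, contamination) {
  if (any(completeness < 0 | completeness > 100, na.rm = TRUE)) {
    vp_stop("completeness must lie in [0, 100]")
  }
  if (any(contamination < 0, na.rm = TRUE)) {
    vp_stop("contamination must be non-negative")
  }
  completeness - 5 * contamination
}

#' Construct a genome metadata table
#'
#' @param genome_id character vector of unique ids.
#' @param completeness,contamination percent values.
#' @param genome_size genome length in bp.
#' @param taxonomy data.frame with columns `domain` .. `species` (empty
#'   strings allowed), or a character vector of `d__;p__;...;s__` lineages.
#' @param source free-text label for the genome's origin.
#' @return A data.frame of class `genome_records`.
#' @export
genome_records <- function(genome_id, completeness, contamination,
                           genome_size = NA_real_, taxonomy = NULL,
                           source = "unknown") {
  if (anyDuplicated(genome_id)) vp_stop("genome_id values must be unique")
  n <- length(genome_id)
  quality_score(completeness, contamination)  # range checks
  if (is.character(taxonomy)) taxonomy <- parse_lineage(taxonomy)
  if (is.null(taxonomy)) {
    taxonomy <- as.data.frame(matrix("", n, 7,
                                     dimnames = list(NULL, TAXONOMY_RANKS)),
                              stringsAsFactors = FALSE)
  }
  stopifnot(identical(names(taxonomy), TAXONOMY_RANKS), nrow(taxonomy) == n)
  out <- data.frame(genome_id = as.character(genome_id),
                    completeness = as.numeric(completeness),
                    contamination = as.numeric(contamination),
                    genome_size = as.numeric(genome_size),
                    taxonomy, source = as.character(source),
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_records", "data.frame")
  out
}

#' Parse GTDB-style lineage strings
#'
#' @param x character vector like `"d__Bacteria;p__Bacillota;...;s__"`.
#' @return data.frame with the seven rank columns.
#' @export
parse_lineage <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)
  mat <- t(vapply(parts, function(p) {
    out <- rep("", 7L)
    for (i in seq_along(p)) {
      if (i > 7L) break
      out[i] <- sub("^[a-z]__", "", trimws(p[i]))
    }
    out
  }, character(7L)))
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- TAXONOMY_RANKS
  out
}

format_lineage <- function(taxonomy) {
  pre <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
  apply(taxonomy[TAXONOMY_RANKS], 1L,
        function(r) paste0(pre, r, collapse = ";"))
}

#' Quality-filter genomes
#'
#' Retains genomes with completeness at or above `min_completeness`,
#' contamination strictly below `max_contamination`, and quality score
#' (completeness - 5 x contamination) at or above `min_score`.  Defaults
#' reproduce the standard inclusion rule for draft genome collections.
#'
#' @param records a `genome_records` table.
#' @param min_completeness,max_contamination,min_score thresholds in percent.
#' @return List with `retained` (filtered `genome_records`) and `rejected`
#'   (data.frame of genome_id and comma-separated `failed_rules`).
#' @export
filter_genomes <- function(records, min_completeness = 50,
                           max_contamination = 5, min_score = 50) {
  score <- quality_score(records$completeness, records$contamination)
  fail_comp <- records$completeness < min_completeness
  fail_cont <- records$contamination >= max_contamination
  fail_score <- score < min_score
  keep <- !(fail_comp | fail_cont | fail_score)
  rej <- records$genome_id[!keep]
  rules <- mapply(function(a, b, c) {
    paste(c(if (a) "completeness", if (b) "contamination", if (c) "score"),
          collapse = ",")
  }, fail_comp[!keep], fail_cont[!keep], fail_score[!keep])
  list(retained = records[keep, , drop = FALSE],
       rejected = data.frame(genome_id = rej,
                             failed_rules = as.character(rules),
                             stringsAsFactors = FALSE))
}

#' High-quality genome filter
#'
#' Near-complete gate: completeness at or above 90 percent and contamination
#' strictly below 5 percent; no score rule.
#'
#' @inheritParams filter_genomes
#' @return Filtered `genome_records`.
#' @export
filter_high_quality <- function(records, min_completeness = 90,
                                max_contamination = 5) {
  keep <- records$completeness >= min_completeness &
    records$contamination < max_contamination
  records[keep, , drop = FALSE]
}

#' Construct an ANI matrix
#'
#' @param values square numeric matrix of pairwise ANI percentages with
#'   genome ids as dimnames; diagonal must be exactly 100 and the matrix
#'   symmetric (within 1e-9).
#' @return Matrix of class `ani_matrix`.
#' @export
ani_matrix <- function(values) {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    vp_stop("ANI values must form a square matrix")
  }
  if (is.null(rownames(values)) ||
      !identical(rownames(values), colnames(values))) {
    vp_stop("ANI matrix needs matching genome-id dimnames")
  }
  if (max(abs(values - t(values))) > 1e-9) vp_stop("ANI matrix not symmetric")
  if (any(diag(values) != 100)) vp_stop("ANI diagonal must be exactly 100")
  if (any(values < 0 | values > 100)) vp_stop("ANI values must lie in [0, 100]")
  structure(values, class = c("ani_matrix", "matrix", "array"))
}

#' Read/write ANI matrices as square TSV
#' @param path file path.
#' @return `ani_matrix` (for read) or `path` invisibly (for write).
#' @export
read_ani_matrix <- function(path) {
  tab <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  ani_matrix(as.matrix(tab))
}

#' @rdname read_ani_matrix
#' @param ani an `ani_matrix`.
#' @export
write_ani_matrix <- function(ani, path) {
  utils::write.table(cbind(genome_id = rownames(ani), as.data.frame(ani)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Greedy quality-ranked ANI clustering
#'
#' Deterministic centroid clustering of genomes over a precomputed ANI
#' matrix: genomes are ranked by quality score (ties broken by larger
#' genome size, then lexicographic id); the best unassigned genome becomes a
#' representative and absorbs every unassigned genome with ANI strictly
#' greater than `threshold` to it.  With `threshold = 99` this performs
#' strain-level dereplication; `threshold = 95` yields species-level genome
#' bins (SGBs).
#'
#' @param ani an [ani_matrix()] covering all genomes in `records`.
#' @param records `genome_records` for the genomes to cluster.
#' @param threshold ANI percent; membership requires ANI > threshold.
#' @return Object of class `ani_clusters`: list with `threshold`,
#'   `clusters` (named list representative -> member ids) and `membership`
#'   (named character vector genome -> representative).
#' @export
greedy_ani_cluster <- function(ani, records, threshold) {
  ids <- records$genome_id
  missing <- setdiff(ids, rownames(ani))
  if (length(missing) > 0L) {
    vp_stop("genome(s) missing from ANI matrix: %s",
            paste(missing, collapse = ", "))
  }
  score <- quality_score(records$completeness, records$contamination)
  size <- ifelse(is.na(records$genome_size), 0, records$genome_size)
  ord <- order(-score, -size, ids)
  ranked <- ids[ord]
  assigned <- character(0)
  clusters <- list()
  for (rep_id in ranked) {
    if (rep_id %in% assigned) next
    pool <- setdiff(ranked, assigned)
    members <- pool[ani[rep_id, pool] > threshold | pool == rep_id]
    clusters[[rep_id]] <- members
    assigned <- c(assigned, members)
  }
  membership <- character(0)
  for (rep_id in names(clusters)) {
    membership[clusters[[rep_id]]] <- rep_id
  }
  structure(list(threshold = threshold, clusters = clusters,
                 membership = membership[ids]),
            class = "ani_clusters")
}

#' @export
print.ani_clusters <- function(x, ...) {
  cat(sprintf("ANI clustering at >%s%%: %d genomes in %d clusters\n",
              format(x$threshold), length(x$membership), length(x$clusters)))
  invisible(x)
}

#' Cluster assignment as a two-column table
#' @param clusters an `ani_clusters` object.
#' @return data.frame with columns `representative`, `member`.
#' @export
cluster_table <- function(clusters) {
  data.frame(
    representative = rep(names(clusters$clusters),
                         lengths(clusters$clusters)),
    member = unlist(clusters$clusters, use.names = FALSE),
    stringsAsFactors = FALSE)
}

#' Read genome metadata TSV
#'
#' Expects header columns `genome_id`, `completeness`, `contamination`,
#' `genome_size`, the seven rank columns `domain` .. `species`, `source`.
#' @param path file path.
#' @return `genome_records`.
#' @export
read_genome_records <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  genome_records(tab$genome_id, tab$completeness, tab$contamination,
                 tab$genome_size, tab[TAXONOMY_RANKS], tab$source)
}

#' @rdname read_genome_records
#' @param records `genome_records` to write.
#' @export
write_genome_records <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
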