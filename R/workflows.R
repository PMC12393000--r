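# Canned end-to-end workflows: region contrast, infection contrast,
# cobalamin audit.  Each returns a report bundle carrying every table it
# computed plus a run manifest sufficient to reproduce it.

run_manifest <- function(command, parameters, seed) {
  list(command = command, parameters = parameters, seed = seed,
       package_version = as.character(utils::packageVersion("vitapath")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

require_metadata <- function(metadata, columns) {
  missing <- setdiff(columns, names(metadata))
  if (length(missing) > 0L) {
    vp_stop("sample metadata lacks column(s): %s",
            paste(missing, collapse = ", "))
  }
}

# Small- vs large-intestine grouping of the five gut regions.
SMALL_INTESTINE <- c("duodenum", "jejunum", "ileum")
LARGE_INTESTINE <- c("cecum", "colorectum")

#' Gut-region workflow
#'
#' TPM conversion, pathway and taxon profiles, alpha diversity, Bray-Curtis
#' beta diversity with PCoA, global and pairwise PERMANOVA (BH-FDR across
#' pairs), and small- vs large-intestine Wilcoxon contrasts per vitamin
#' pathway.
#'
#' @param counts samples x genes count [abundance_matrix()].
#' @param genes a [gene_catalog()].
#' @param metadata data.frame with `sample_id` and `group` columns; groups
#'   are gut regions.
#' @param catalog a `vita_catalog`.
#' @param seed integer seed for the permutation tests.
#' @param n_permutations PERMANOVA permutations.
#' @return List of class `region_report`: `tpm_pathway`, `taxon_phylum`,
#'   `taxon_genus`, `alpha`, `distance`, `pcoa`, `permanova_global`,
#'   `permanova_pairwise`, `small_vs_large`, `manifest`.
#' @export
run_region_workflow <- function(counts, genes, metadata,
                                catalog = default_catalog(), seed,
                                n_permutations = 1000) {
  if (missing(seed)) vp_stop("workflow requires a seed")
  require_metadata(metadata, c("sample_id", "group"))
  groups <- metadata$group[match(rownames(counts), metadata$sample_id)]
  if (anyNA(groups)) vp_stop("metadata lacks entries for some samples")

  tpm <- compute_tpm(counts, genes)
  gene_ko <- stats::setNames(genes$ko, genes$gene_id)
  pw <- pathway_abundance(tpm, catalog, gene_ko)
  vit_kos <- catalog$ko_universe
  phy <- taxon_profile(tpm, genes, "phylum", restrict_to = vit_kos)
  gen <- taxon_profile(tpm, genes, "genus", restrict_to = vit_kos)

  alpha <- alpha_diversity_table(unclass(pw))
  alpha$group <- groups

  d <- bray_curtis_matrix(unclass(pw))
  ord <- pcoa(d, n_axes = 2L)
  global <- permanova(d, groups, n_permutations, seed = seed)
  pairwise <- pairwise_permanova(d, groups, n_permutations, seed = seed)

  svl <- NULL
  if (all(groups %in% c(SMALL_INTESTINE, LARGE_INTESTINE))) {
    seg <- ifelse(groups %in% SMALL_INTESTINE, "small", "large")
    svl <- compare_groups(unclass(pw), seg)
  }

  structure(list(
    tpm_pathway = pw, taxon_phylum = phy, taxon_genus = gen,
    alpha = alpha, distance = d, pcoa = ord,
    permanova_global = global, permanova_pairwise = pairwise,
    small_vs_large = svl,
    manifest = run_manifest("region-workflow",
                            list(n_permutations = n_permutations), seed)),
    class = "region_report")
}

#' @export
print.region_report <- function(x, ...) {
  cat("Gut-region workflow report\n")
  print(x$permanova_global)
  cat(sprintf("PCoA axes 1-2 explain %.1f%% of the variation\n",
              100 * sum(x$pcoa$explained_fraction[1:2], na.rm = TRUE)))
  invisible(x)
}

#' Infection-contrast workflow
#'
#' For 2-group (e.g. NC/ST) or 3-group (e.g. JC/JS/JR) designs: pathway
#' TPM profiles, per-vitamin Wilcoxon contrasts across all group pairs
#' with BH-FDR, alpha diversity with Cohen's d per index and pair,
#' Bray-Curtis PCoA and PERMANOVA.
#'
#' @inheritParams run_region_workflow
#' @return List of class `infection_report`: `tpm_pathway`, `taxon_genus`,
#'   `alpha`, `alpha_tests` (per index and group pair: Wilcoxon p and
#'   Cohen's d), `pathway_tests`, `pcoa`, `permanova_global`, `manifest`.
#' @export
run_infection_workflow <- function(counts, genes, metadata,
                                   catalog = default_catalog(), seed,
                                   n_permutations = 1000) {
  if (missing(seed)) vp_stop("workflow requires a seed")
  require_metadata(metadata, c("sample_id", "group"))
  groups <- metadata$group[match(rownames(counts), metadata$sample_id)]
  if (anyNA(groups)) vp_stop("metadata lacks entries for some samples")

  tpm <- compute_tpm(counts, genes)
  gene_ko <- stats::setNames(genes$ko, genes$gene_id)
  pw <- pathway_abundance(tpm, catalog, gene_ko)
  gen <- taxon_profile(tpm, genes, "genus", restrict_to = catalog$ko_universe)

  alpha <- alpha_diversity_table(unclass(pw))
  alpha$group <- groups

  levs <- sort(unique(groups))
  pairs <- utils::combn(levs, 2L)
  alpha_tests <- list()
  for (idx in c("richness", "shannon", "simpson")) {
    for (i in seq_len(ncol(pairs))) {
      g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
      x <- alpha[[idx]][groups == g1]; y <- alpha[[idx]][groups == g2]
      tst <- wilcoxon_rank_sum(x, y)
      dval <- if (stats::var(x) > 0 || stats::var(y) > 0) cohens_d(x, y) else 0
      alpha_tests[[length(alpha_tests) + 1L]] <- data.frame(
        index = idx, group1 = g1, group2 = g2, p_value = tst$p_value,
        cohens_d = dval, stringsAsFactors = FALSE)
    }
  }
  alpha_tests <- do.call(rbind, alpha_tests)
  alpha_tests$p_adjusted <- bh_fdr(alpha_tests$p_value)

  pathway_tests <- compare_groups(unclass(pw), groups)

  d <- bray_curtis_matrix(unclass(pw))
  ord <- pcoa(d, n_axes = 2L)
  global <- permanova(d, groups, n_permutations, seed = seed)

  structure(list(
    tpm_pathway = pw, taxon_genus = gen, alpha = alpha,
    alpha_tests = alpha_tests, pathway_tests = pathway_tests,
    pcoa = ord, permanova_global = global,
    manifest = run_manifest("infection-workflow",
                            list(n_permutations = n_permutations), seed)),
    class = "infection_report")
}

#' @export
print.infection_report <- function(x, ...) {
  cat("Infection-contrast workflow report\n")
  print(x$permanova_global)
  sig <- x$pathway_tests[x$pathway_tests$p_adjusted < 0.05, , drop = FALSE]
  cat(sprintf("%d pathway contrast(s) at FDR < 0.05\n", nrow(sig)))
  invisible(x)
}

#' Cobalamin audit workflow
#'
#' Classifies every genome CCG/SCG/other, tabulates per-stage role counts,
#' and emits the per-genus gap table plus the per-genome role-count matrix.
#'
#' @param profiles list of [ko_profile()]s.
#' @param records matching [genome_records()].
#' @param catalog a `vita_catalog` with a stage-labelled Cob pathway.
#' @param scg_genera genera eligible for the SCG label.
#' @return List of class `cobalamin_report`: `profiles`
#'   (cobalamin_profile list), `label_counts`, `gap` (see
#'   [genus_gap_table()]), `stage_map`, `manifest`.
#' @export
run_cobalamin_audit <- function(profiles, records,
                                catalog = default_catalog(),
                                scg_genera = SCG_GENERA) {
  if (is.null(catalog$pathways$Cob)) vp_stop("catalog has no Cob pathway")
  cps <- cobalamin_profiles(profiles, catalog, records, scg_genera)
  labels <- vapply(cps, `[[`, "", "label")
  gap <- genus_gap_table(cps)
  structure(list(
    profiles = cps,
    label_counts = table(factor(labels, levels = c("CCG", "SCG", "other"))),
    gap = gap, stage_map = cobalamin_stage_map(catalog),
    manifest = run_manifest("cobalamin-audit",
                            list(scg_genera = scg_genera), NA_integer_)),
    class = "cobalamin_report")
}

#' @export
print.cobalamin_report <- function(x, ...) {
  cat("Cobalamin audit: ")
  cat(sprintf("%d CCG, %d SCG, %d other\n", x$label_counts[["CCG"]],
              x$label_counts[["SCG"]], x$label_counts[["other"]]))
  invisible(x)
}
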