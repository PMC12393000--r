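# Synthetic metagenome study generator.  Emits genome metadata, per-genome
# KO profiles, a gene catalog, sample x gene count matrices with group
# structure, and an ANI matrix -- together with the planted ground truth --
# so the whole analysis chain can be validated without external data.
#
# All generators are pure functions of (config); every random draw is
# governed by the config seed.

# Genus -> phylum map for the synthetic community (GTDB-style names).
SYNTH_PHYLUM <- c(
  Bacillus = "Bacillota", Faecalibacterium = "Bacillota",
  Blautia = "Bacillota", Ligilactobacillus = "Bacillota",
  Limosilactobacillus = "Bacillota", Mediterraneibacter = "Bacillota",
  Corynebacterium = "Actinomycetota", Campylobacter = "Campylobacterota",
  Phocaeicola = "Bacteroidota", Prevotella = "Bacteroidota",
  Alistipes = "Bacteroidota")

default_plant_spec <- function() {
  # genus, vitamin, route: the de novo capabilities planted per genus.
  # Mirrors the qualitative producer structure reported for gut
  # communities: a broad Bacillus producer, anaerobic-route cobalamin
  # producers within Bacillota, menaquinone via the classical Men route in
  # Campylobacter, folate in Bacteroidota, and single-vitamin genomes.
  rbind(
    data.frame(genus = "Bacillus",
               vitamin = c("Thi", "Rib", "Nia", "Pan", "Bio", "Fol", "Men"),
               route = c("thiI", "ribD1", "NaMNAT", "pan", "FabG", "fol", "Men")),
    data.frame(genus = "Faecalibacterium",
               vitamin = c("Cob", "Cob", "Rib", "Nia"),
               route = c("anaerobic", "aerobic", "ribD1", "NaMNAT")),
    data.frame(genus = "Blautia", vitamin = c("Cob", "Cob", "Nia"),
               route = c("anaerobic", "aerobic", "NaMNAT")),
    data.frame(genus = "Ligilactobacillus", vitamin = c("Cob", "Cob", "Rib"),
               route = c("anaerobic", "aerobic", "ribD1")),
    data.frame(genus = "Limosilactobacillus", vitamin = c("Cob", "Cob", "Pan"),
               route = c("anaerobic", "aerobic", "pan")),
    data.frame(genus = "Mediterraneibacter", vitamin = c("Cob", "Cob", "Pan"),
               route = c("anaerobic", "aerobic", "pan")),
    data.frame(genus = "Corynebacterium", vitamin = c("Nia", "Pan", "Bio"),
               route = c("NaMNAT", "pan", "FabG")),
    data.frame(genus = "Campylobacter", vitamin = c("Men", "Nia"),
               route = c("Men", "NaMNAT")),
    data.frame(genus = "Phocaeicola", vitamin = c("Fol", "Nia", "Pyr"),
               route = c("fol", "NaMNAT", "r5p")),
    data.frame(genus = "Prevotella", vitamin = c("Fol", "Rib", "Pan"),
               route = c("fol", "ribD1", "pan")),
    data.frame(genus = "Alistipes", vitamin = "Nia", route = "NaMNAT"))
}

default_deficiency_spec <- function() {
  # Planted role knockouts (fraction of the genus' genomes losing the
  # role's KOs).  The six focal genera carry partial cobalamin gene sets,
  # with Blautia-style 90% loss of five roles and complete loss of the
  # aerobic-only roles elsewhere.
  rbind(
    expand.grid(genus = "Blautia",
                role = c("CobF", "CobG", "CobK", "CobNST", "CbiJ"),
                fraction = 0.9, stringsAsFactors = FALSE),
    expand.grid(genus = "Mediterraneibacter",
                role = c("CobF", "CobG", "CobNST"),
                fraction = 1.0, stringsAsFactors = FALSE),
    expand.grid(genus = "Mediterraneibacter", role = "CbiD",
                fraction = 0.9, stringsAsFactors = FALSE),
    expand.grid(genus = "Faecalibacterium",
                role = c("CobF", "CobG", "CobNST"),
                fraction = 0.95, stringsAsFactors = FALSE),
    expand.grid(genus = "Faecalibacterium", role = "CbiK",
                fraction = 0.8, stringsAsFactors = FALSE),
    expand.grid(genus = "Ligilactobacillus",
                role = c("CobF", "CobG", "CobNST", "CbiD", "CbiET", "CobO"),
                fraction = 1.0, stringsAsFactors = FALSE),
    expand.grid(genus = "Limosilactobacillus",
                role = c("CobF", "CobG", "CobNST", "CbiK", "CbiD", "CobU"),
                fraction = 1.0, stringsAsFactors = FALSE))
}

default_effect_spec <- function(design) {
  switch(design,
    regions5 = data.frame(
      group = c("duodenum", "jejunum", "ileum", "duodenum", "jejunum",
                "ileum", "cecum", "colorectum"),
      vitamin = c("Rib", "Rib", "Rib", "Bio", "Bio", "Bio", "Cob", "Cob"),
      log2_fc = 1, stringsAsFactors = FALSE),
    infectionNC_ST = data.frame(group = "ST", vitamin = "Pan", log2_fc = 1,
                                stringsAsFactors = FALSE),
    infectionJC_JS_JR = data.frame(group = "JR", vitamin = "Rib",
                                   log2_fc = 1, stringsAsFactors = FALSE))
}

design_groups <- function(design, n_samples_per_group = NULL) {
  groups <- switch(design,
    regions5 = c("duodenum", "jejunum", "ileum", "cecum", "colorectum"),
    infectionNC_ST = c("NC", "ST"),
    infectionJC_JS_JR = c("JC", "JS", "JR"),
    vp_stop("unknown design '%s'", design))
  n <- n_samples_per_group %||%
    switch(design, regions5 = 27L, infectionNC_ST = 5L,
           infectionJC_JS_JR = 4L)
  list(groups = groups, n_per_group = as.integer(n))
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic study in one validated object.
#' Defaults encode the study conditions the package is exercised under:
#' five gut regions (duodenum, jejunum, ileum, cecum, colorectum) with 27
#' samples each, or infection contrasts with 5+5 (NC/ST) or 4+4+4
#' (JC/JS/JR) samples; negative-binomial counts with dispersion 0.3;
#' planted per-genus producer phenotypes and cobalamin role knockouts.
#'
#' @param seed integer seed governing every random draw.
#' @param design `"regions5"`, `"infectionNC_ST"` or `"infectionJC_JS_JR"`.
#' @param n_genomes number of genomes in the synthetic collection.
#' @param n_samples_per_group samples per group (design default if NULL).
#' @param plant_spec data.frame (genus, vitamin, route) of planted de novo
#'   capabilities.
#' @param deficiency_spec data.frame (genus, role, fraction) of planted
#'   role knockouts; applied deterministically to
#'   `round(fraction * n_genus)` genomes.
#' @param effect_spec data.frame (group, vitamin, log2_fc) of planted
#'   abundance effects (design default if NULL).
#' @param dispersion negative-binomial dispersion (0 gives Poisson counts).
#' @param library_size_range sample library-size range (reads).
#' @param n_background_kos background (non-pathway) KOs per genome.
#' @param completeness_range,contamination_range quality metric ranges.
#' @param gene_dup_prob probability that a (genome, KO) pair yields a
#'   second gene copy.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       design = c("regions5", "infectionNC_ST",
                                  "infectionJC_JS_JR"),
                       n_genomes = 120L,
                       n_samples_per_group = NULL,
                       plant_spec = default_plant_spec(),
                       deficiency_spec = default_deficiency_spec(),
                       effect_spec = NULL,
                       dispersion = 0.3,
                       library_size_range = c(5e5, 2e6),
                       n_background_kos = 20L,
                       completeness_range = c(75, 100),
                       contamination_range = c(0, 4),
                       gene_dup_prob = 0.2) {
  design <- match.arg(design)
  if (missing(seed)) vp_stop("sim_config requires a seed")
  if (any(deficiency_spec$fraction < 0 | deficiency_spec$fraction > 1)) {
    vp_stop("deficiency fractions must lie in [0, 1]")
  }
  if (dispersion < 0) vp_stop("dispersion must be non-negative")
  effect_spec <- effect_spec %||% default_effect_spec(design)
  gd <- design_groups(design, n_samples_per_group)
  structure(list(seed = as.integer(seed), design = design,
                 n_genomes = as.integer(n_genomes),
                 groups = gd$groups, n_per_group = gd$n_per_group,
                 plant_spec = plant_spec,
                 deficiency_spec = deficiency_spec,
                 effect_spec = effect_spec,
                 dispersion = dispersion,
                 library_size_range = library_size_range,
                 n_background_kos = as.integer(n_background_kos),
                 completeness_range = completeness_range,
                 contamination_range = contamination_range,
                 gene_dup_prob = gene_dup_prob),
            class = "sim_config")
}

route_kos <- function(catalog, vitamin, route_id, essential_only = FALSE) {
  routes <- catalog$pathways[[vitamin]]$routes
  ids <- vapply(routes, `[[`, "", "route_id")
  route <- routes[[match(route_id, ids)]]
  if (is.null(route)) vp_stop("unknown route '%s' for %s", route_id, vitamin)
  unique(unlist(lapply(route$roles, function(r) {
    role <- catalog$roles[[r$role_id]]
    if (!essential_only || role$essential) role$kos
  }), use.names = FALSE))
}

# Background KO pool: identifiers disjoint from the catalog universe.
background_ko_pool <- function(catalog, n = 300L) {
  pool <- sprintf("K%05d", 90000L + seq_len(n))
  setdiff(pool, catalog$ko_universe)
}

#' Simulate a genome collection with planted producer phenotypes
#'
#' Each genome is assigned a genus (round-robin over the plant spec's
#' genera), receives the union of its genus' planted route KOs, loses the
#' KOs of knocked-out roles (applied to exactly `round(fraction * n)`
#' genomes of the genus, deterministically), and gains random background
#' KOs.  Quality metrics are drawn uniformly in the configured ranges.
#' Ground truth records, per genome, the planted capabilities and the
#' vitamin calls implied by its final KO set (evaluated by direct set
#' logic over the catalog, independently of [classify_genome()]).
#'
#' @param config a [sim_config()].
#' @param catalog a `vita_catalog` (default: the shipped one).
#' @return List with `records` ([genome_records()]), `profiles` (list of
#'   [ko_profile()]), and `truth` (list: `calls` logical genome x vitamin
#'   matrix, `planted` data.frame, `knockouts` data.frame).
#' @export
simulate_genomes <- function(config, catalog = default_catalog()) {
  stopifnot(inherits(config, "sim_config"))
  unknown <- setdiff(config$deficiency_spec$role, names(catalog$roles))
  if (length(unknown) > 0L) {
    vp_stop("deficiency spec references unknown role(s): %s",
            paste(unknown, collapse = ", "))
  }
  set.seed(config$seed)
  genera <- unique(config$plant_spec$genus)
  n <- config$n_genomes
  genome_genus <- genera[((seq_len(n) - 1L) %% length(genera)) + 1L]
  ids <- sprintf("G%04d", seq_len(n))
  pool <- background_ko_pool(catalog)

  planted_kos <- lapply(genera, function(g) {
    rows <- config$plant_spec[config$plant_spec$genus == g, , drop = FALSE]
    unique(unlist(Map(function(v, r) route_kos(catalog, v, r),
                      rows$vitamin, rows$route), use.names = FALSE))
  })
  names(planted_kos) <- genera

  # Deterministic knockout assignment: the first round(fraction * n_genus)
  # genomes (in id order) of each genus lose the role's KOs.
  knockouts <- list()
  ko_removal <- stats::setNames(vector("list", n), ids)
  for (g in genera) {
    members <- ids[genome_genus == g]
    spec <- config$deficiency_spec[config$deficiency_spec$genus == g, ,
                                   drop = FALSE]
    for (i in seq_len(nrow(spec))) {
      k <- round(spec$fraction[i] * length(members))
      hit <- members[seq_len(k)]
      for (m in hit) {
        ko_removal[[m]] <- c(ko_removal[[m]],
                             catalog$roles[[spec$role[i]]]$kos)
      }
      if (k > 0L) {
        knockouts[[length(knockouts) + 1L]] <- data.frame(
          genus = g, role = spec$role[i], fraction = spec$fraction[i],
          n_affected = k, stringsAsFactors = FALSE)
      }
    }
  }

  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    kos <- setdiff(planted_kos[[genome_genus[i]]], ko_removal[[ids[i]]])
    bg <- sample(pool, config$n_background_kos)
    profiles[[i]] <- ko_profile(ids[i], c(kos, bg))
  }
  names(profiles) <- ids

  records <- genome_records(
    genome_id = ids,
    completeness = stats::runif(n, config$completeness_range[1L],
                                config$completeness_range[2L]),
    contamination = stats::runif(n, config$contamination_range[1L],
                                 config$contamination_range[2L]),
    genome_size = round(stats::runif(n, 2e6, 7e6)),
    taxonomy = data.frame(domain = "Bacteria",
                          phylum = unname(SYNTH_PHYLUM[genome_genus]),
                          class = "", order = "", family = "",
                          genus = genome_genus,
                          species = paste0(genome_genus, " sp."),
                          stringsAsFactors = FALSE),
    source = "synthetic")

  # Truth calls by direct set logic over the final KO sets.
  calls <- matrix(FALSE, n, length(VITAMIN_CODES),
                  dimnames = list(ids, VITAMIN_CODES))
  for (i in seq_len(n)) {
    kos <- profiles[[i]]$kos
    for (vit in names(catalog$pathways)) {
      for (route in catalog$pathways[[vit]]$routes) {
        ok <- TRUE
        for (r in route$roles) {
          role <- catalog$roles[[r$role_id]]
          if (role$essential && !any(role$kos %in% kos)) { ok <- FALSE; break }
        }
        if (ok) { calls[i, vit] <- TRUE; break }
      }
    }
  }

  planted <- data.frame(genome_id = ids, genus = genome_genus,
                        stringsAsFactors = FALSE)
  truth <- list(calls = calls, planted = planted,
                knockouts = if (length(knockouts)) do.call(rbind, knockouts)
                            else data.frame())
  list(records = records, profiles = profiles, truth = truth)
}

#' Simulate a gene catalog from KO profiles
#'
#' One gene per (genome, KO) pair, plus an occasional duplicate copy;
#' lengths uniform on \[300, 3000\] bp; lineage inherited from the genome.
#' A few unannotated genes per genome are added (KO `NA`).
#'
#' @param config a [sim_config()].
#' @param profiles list of [ko_profile()]s.
#' @param records matching [genome_records()].
#' @param n_unannotated unannotated genes added per genome.
#' @return A [gene_catalog()] with an extra `genome_id` column.
#' @export
simulate_gene_catalog <- function(config, profiles, records,
                                  n_unannotated = 3L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  tax <- as.data.frame(records)[match(vapply(profiles, `[[`, "", "genome_id"),
                                      records$genome_id), TAXONOMY_RANKS]
  rows_ko <- list()
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    copies <- 1L + stats::rbinom(length(p$kos), 1L, config$gene_dup_prob)
    kos <- c(rep(p$kos, copies), rep(NA_character_, n_unannotated))
    rows_ko[[i]] <- data.frame(genome_id = p$genome_id, ko = kos,
                               stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows_ko)
  gidx <- match(tab$genome_id, records$genome_id)
  lineage <- as.data.frame(records)[gidx, TAXONOMY_RANKS]
  rownames(lineage) <- NULL
  genes <- gene_catalog(
    gene_id = sprintf("gene%06d", seq_len(nrow(tab))),
    length_bp = round(stats::runif(nrow(tab), 300, 3000)),
    ko = tab$ko, lineage = lineage)
  genes$genome_id <- tab$genome_id
  genes
}

#' Simulate a sample x gene count matrix with planted group effects
#'
#' Baseline gene abundances are log-normal; each sample's expected gene
#' proportion is scaled by `2^log2_fc` for every planted effect whose
#' vitamin pathway contains the gene's KO; counts are negative binomial
#' around `proportion * library_size` (Poisson when dispersion is 0).
#'
#' @param config a [sim_config()].
#' @param genes a [gene_catalog()].
#' @param catalog a `vita_catalog`.
#' @return List with `counts` (an [abundance_matrix()], samples x genes),
#'   `metadata` (data.frame sample_id, group) and `expected` (samples x
#'   genes expected proportions).
#' @export
simulate_counts <- function(config, genes, catalog = default_catalog()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  groups <- rep(config$groups, each = config$n_per_group)
  sample_ids <- sprintf("S%03d", seq_along(groups))
  n_genes <- nrow(genes)

  ko_by_vit <- lapply(catalog$pathways, function(p) {
    unique(unlist(lapply(p$routes, function(rt) {
      unlist(lapply(rt$roles, function(r) catalog$roles[[r$role_id]]$kos))
    }), use.names = FALSE))
  })

  baseline <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
  lib_sizes <- round(stats::runif(length(sample_ids),
                                  config$library_size_range[1L],
                                  config$library_size_range[2L]))
  counts <- matrix(0, length(sample_ids), n_genes,
                   dimnames = list(sample_ids, genes$gene_id))
  expected <- counts
  for (s in seq_along(sample_ids)) {
    eff <- rep(1, n_genes)
    es <- config$effect_spec[config$effect_spec$group == groups[s], ,
                             drop = FALSE]
    for (i in seq_len(nrow(es))) {
      hit <- !is.na(genes$ko) & genes$ko %in% ko_by_vit[[es$vitamin[i]]]
      eff[hit] <- eff[hit] * 2^es$log2_fc[i]
    }
    mu <- baseline * eff
    prop <- mu / sum(mu)
    expected[s, ] <- prop
    lambda <- prop * lib_sizes[s]
    counts[s, ] <- if (config$dispersion > 0) {
      stats::rnbinom(n_genes, mu = lambda, size = 1 / config$dispersion)
    } else {
      stats::rpois(n_genes, lambda)
    }
  }
  list(counts = abundance_matrix(counts, unit = "counts",
                                 feature_level = "gene"),
       metadata = data.frame(sample_id = sample_ids, group = groups,
                             stringsAsFactors = FALSE),
       expected = expected)
}

#' Simulate a pairwise ANI matrix
#'
#' Within-genus pairs draw high identities (a configurable fraction of
#' strain-level pairs above 99), across-genus pairs draw 70-80, so that
#' dereplication at 99 and species binning at 95 both have work to do.
#'
#' @param config a [sim_config()].
#' @param records [genome_records()].
#' @return An [ani_matrix()].
#' @export
simulate_ani <- function(config, records) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  ids <- records$genome_id
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  genus <- records$genus
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      m[i, j] <- m[j, i] <- if (genus[i] == genus[j]) {
        stats::runif(1, 94, 100)
      } else {
        stats::runif(1, 70, 80)
      }
    }
  }
  diag(m) <- 100
  ani_matrix(m)
}

#' Multinomial down-sampling of a count matrix
#'
#' Draws `depth` reads per sample with probabilities proportional to the
#' sample's counts (with-replacement thinning); every row of the result
#' sums to `depth`.
#'
#' @param counts samples x genes count [abundance_matrix()].
#' @param depth target reads per sample (non-negative integer).
#' @param seed integer seed.
#' @return An `abundance_matrix` of counts.
#' @export
downsample_counts <- function(counts, depth, seed) {
  if (depth < 0) vp_stop("depth must be non-negative")
  if (missing(seed)) vp_stop("downsample_counts requires a seed")
  set.seed(seed)
  lib <- rowSums(counts)
  if (depth > min(lib)) {
    warning("depth exceeds the smallest library; sampling with replacement")
  }
  out <- unclass(counts)
  for (s in seq_len(nrow(out))) {
    out[s, ] <- if (depth == 0 || lib[s] == 0) 0 else {
      as.numeric(stats::rmultinom(1L, depth, prob = out[s, ]))
    }
  }
  abundance_matrix(out, unit = "counts", feature_level = "gene")
}

#' Simulate a full study
#'
#' Convenience wrapper chaining [simulate_genomes()],
#' [simulate_gene_catalog()], [simulate_counts()] and [simulate_ani()].
#'
#' @param config a [sim_config()].
#' @param catalog a `vita_catalog`.
#' @return List of class `sim_study` with elements `records`, `profiles`,
#'   `truth`, `genes`, `counts`, `metadata`, `expected`, `ani`, `config`.
#' @export
simulate_study <- function(config, catalog = default_catalog()) {
  g <- simulate_genomes(config, catalog)
  genes <- simulate_gene_catalog(config, g$profiles, g$records)
  cc <- simulate_counts(config, genes, catalog)
  ani <- simulate_ani(config, g$records)
  structure(c(g, list(genes = genes, counts = cc$counts,
                      metadata = cc$metadata, expected = cc$expected,
                      ani = ani, config = config)),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic study (%s, seed %d): %d genomes, %d genes, %d samples\n",
    x$config$design, x$config$seed, nrow(x$records), nrow(x$genes),
    nrow(x$counts)))
  invisible(x)
}
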