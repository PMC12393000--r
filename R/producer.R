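# Pathway-completeness classification of genomes as de novo vitamin
# producers, plus the stage-aware cobalamin gap analysis.
#
# Call logic: a role is satisfied when the genome carries any of its KOs
# (OR over KOs); a route is complete when all its essential roles are
# satisfied (AND over essential roles); a genome produces a vitamin when at
# least one route is complete (OR over routes).  Copy numbers never affect
# calls; they are retained only for role-count heatmaps.

# Focal genera for partial-cobalamin (SCG) accounting.
SCG_GENERA <- c("Ligilactobacillus", "Faecalibacterium", "Corynebacterium",
                "Mediterraneibacter", "Blautia", "Limosilactobacillus")

#' KO profile of a genome
#'
#' @param genome_id genome identifier.
#' @param kos character vector of KEGG KO ids (`K#####`).
#' @param ko_counts optional named integer vector of gene copy counts; names
#'   must be a subset of `kos`.
#' @return List of class `ko_profile`.
#' @export
ko_profile <- function(genome_id, kos, ko_counts = NULL) {
  kos <- unique(as.character(kos))
  if (length(kos) > 0L && !all(grepl(KO_PATTERN, kos))) {
    vp_stop("malformed KO id(s) in profile '%s'", genome_id)
  }
  if (!is.null(ko_counts)) {
    if (is.null(names(ko_counts)) || !all(names(ko_counts) %in% kos)) {
      vp_stop("ko_counts names must be a subset of kos ('%s')", genome_id)
    }
    if (any(ko_counts < 1)) vp_stop("ko_counts must be >= 1")
  }
  structure(list(genome_id = as.character(genome_id), kos = kos,
                 ko_counts = ko_counts),
            class = "ko_profile")
}

#' Read per-genome KO annotations
#'
#' TSV with header `genome_id, ko, count` (count optional).
#' @param path file path.
#' @return List of `ko_profile` objects, named by genome id.
#' @export
read_ko_profiles <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("genome_id", "ko") %in% names(tab))) {
    vp_stop("KO annotation TSV needs columns genome_id, ko")
  }
  out <- lapply(split(tab, tab$genome_id), function(g) {
    counts <- NULL
    if ("count" %in% names(g)) {
      counts <- tapply(g$count, g$ko, sum)
      counts <- stats::setNames(as.integer(counts), names(counts))
    }
    ko_profile(g$genome_id[1L], unique(g$ko), counts)
  })
  out[order(names(out))]
}

#' @rdname read_ko_profiles
#' @param profiles list of `ko_profile`s to write.
#' @export
write_ko_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    counts <- if (is.null(p$ko_counts)) {
      stats::setNames(rep(1L, length(p$kos)), p$kos)
    } else {
      cn <- stats::setNames(rep(1L, length(p$kos)), p$kos)
      cn[names(p$ko_counts)] <- p$ko_counts
      cn
    }
    data.frame(genome_id = p$genome_id, ko = names(counts),
               count = as.integer(counts), stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Is a functional role satisfied by a KO profile?
#'
#' @param profile a [ko_profile()].
#' @param role a role definition (list with `ko_ids`/`kos`).
#' @return TRUE iff the profile carries at least one of the role's KOs.
#' @export
role_present <- function(profile, role) {
  kos <- role$kos %||% role$ko_ids
  length(intersect(profile$kos, kos)) > 0L
}

#' Is a route complete in a genome?
#'
#' @param profile a [ko_profile()].
#' @param route a route entry of a catalog pathway.
#' @param catalog the `vita_catalog` resolving role definitions.
#' @return TRUE iff every essential role of the route is satisfied.
#' @export
route_complete <- function(profile, route, catalog) {
  for (r in route$roles) {
    role <- catalog$roles[[r$role_id]]
    if (is.null(role)) vp_stop("route '%s' references unknown role '%s'",
                               route$route_id, r$role_id)
    if (role$essential && !role_present(profile, role)) return(FALSE)
  }
  TRUE
}

#' Classify one genome's de novo vitamin biosynthesis capability
#'
#' @param profile a [ko_profile()].
#' @param catalog a `vita_catalog`.
#' @return List with `vitamins` (character vector of producible vitamin
#'   codes) and `routes` (named character: the first complete route in
#'   catalog order, per called vitamin).
#' @export
classify_genome <- function(profile, catalog) {
  vitamins <- character(0)
  routes <- character(0)
  for (vit in names(catalog$pathways)) {
    for (route in catalog$pathways[[vit]]$routes) {
      if (route_complete(profile, route, catalog)) {
        vitamins <- c(vitamins, vit)
        routes[[vit]] <- route$route_id
        break
      }
    }
  }
  list(vitamins = vitamins, routes = routes)
}

#' Producer matrix over a genome collection
#'
#' @param profiles list of [ko_profile()]s.
#' @param catalog a `vita_catalog`.
#' @return Object of class `producer_matrix`: list with `calls` (logical
#'   genomes x vitamins matrix over the nine vitamin codes) and `routes`
#'   (character matrix of satisfying route ids, `NA` where the call is
#'   false).
#' @export
producer_matrix <- function(profiles, catalog) {
  ids <- unname(vapply(profiles, `[[`, "", "genome_id"))
  if (anyDuplicated(ids)) vp_stop("duplicate genome ids among profiles")
  calls <- matrix(FALSE, length(ids), length(VITAMIN_CODES),
                  dimnames = list(ids, VITAMIN_CODES))
  routes <- matrix(NA_character_, length(ids), length(VITAMIN_CODES),
                   dimnames = list(ids, VITAMIN_CODES))
  for (i in seq_along(profiles)) {
    cl <- classify_genome(profiles[[i]], catalog)
    calls[i, cl$vitamins] <- TRUE
    routes[i, names(cl$routes)] <- cl$routes
  }
  structure(list(calls = calls, routes = routes), class = "producer_matrix")
}

#' @export
print.producer_matrix <- function(x, ...) {
  cat(sprintf("Producer matrix: %d genomes x %d vitamins; %d producer(s)\n",
              nrow(x$calls), ncol(x$calls), sum(rowSums(x$calls) > 0)))
  print(colSums(x$calls))
  invisible(x)
}

#' Producer matrix as a 0/1 table with route annotations
#' @param pm a `producer_matrix`.
#' @return data.frame suitable for TSV export.
#' @export
producer_table <- function(pm) {
  routes <- apply(pm$routes, 1L, function(r) {
    hit <- !is.na(r)
    paste(sprintf("%s:%s", names(r)[hit], r[hit]), collapse = ";")
  })
  data.frame(genome_id = rownames(pm$calls), pm$calls * 1L,
             routes = routes, stringsAsFactors = FALSE, row.names = NULL)
}

#' Producer breadth histogram
#'
#' Number of distinct vitamins each genome is called capable of producing.
#'
#' @param pm a `producer_matrix`.
#' @param producers_only if TRUE, fractions are over genomes with at least
#'   one call; otherwise over all genomes.
#' @return List with `histogram` (named integer vector over breadth 0..9),
#'   `fractions`, and the `denominator` used.
#' @export
producer_breadth <- function(pm, producers_only = TRUE) {
  breadth <- rowSums(pm$calls)
  hist <- table(factor(breadth, levels = 0:length(VITAMIN_CODES)))
  hist <- stats::setNames(as.integer(hist), names(hist))
  denom <- if (producers_only) sum(breadth > 0) else length(breadth)
  frac <- if (denom == 0) hist * NA_real_ else {
    f <- hist / denom
    if (producers_only) f["0"] <- NA_real_
    f
  }
  list(histogram = hist, fractions = frac, denominator = denom)
}

#' Stage-aware cobalamin profile of one genome
#'
#' Labels a genome `CCG` (complete cobalamin genome) when some full Cob
#' route is complete, `SCG` when incomplete but carrying at least one
#' cobalamin-associated KO and belonging to one of the focal genera, and
#' `other` otherwise.
#'
#' @param profile a [ko_profile()].
#' @param catalog a `vita_catalog` with a stage-labelled Cob pathway.
#' @param genus the genome's genus (string, may be empty).
#' @param scg_genera genera eligible for the SCG label.
#' @return List of class `cobalamin_profile` with `genome_id`, `genus`,
#'   `role_present` (named logical), `role_counts` (named integer, gene
#'   copies summed over the role's KOs), `stage_counts` (3 x 2 present/total
#'   matrix) and `label`.
#' @export
cobalamin_profile <- function(profile, catalog, genus = "",
                              scg_genera = SCG_GENERA) {
  stages <- cobalamin_stage_map(catalog)
  present <- logical(0)
  counts <- integer(0)
  for (rid in names(stages)) {
    role <- catalog$roles[[rid]]
    present[[rid]] <- role_present(profile, role)
    hit <- intersect(profile$kos, role$kos)
    counts[[rid]] <- if (is.null(profile$ko_counts)) length(hit) else {
      cn <- stats::setNames(rep(1L, length(profile$kos)), profile$kos)
      cn[names(profile$ko_counts)] <- profile$ko_counts
      sum(cn[hit])
    }
  }
  stage_counts <- t(vapply(COBALAMIN_STAGES, function(s) {
    in_stage <- names(stages)[stages == s]
    c(present = sum(present[in_stage]), total = length(in_stage))
  }, c(present = 0, total = 0)))
  is_ccg <- "Cob" %in% classify_genome(profile, catalog)$vitamins
  label <- if (is_ccg) "CCG"
  else if (any(present) && genus %in% scg_genera) "SCG"
  else "other"
  structure(list(genome_id = profile$genome_id, genus = genus,
                 role_present = present, role_counts = counts,
                 stage_counts = stage_counts, label = label),
            class = "cobalamin_profile")
}

#' Cobalamin profiles for a genome collection
#'
#' @param profiles list of [ko_profile()]s.
#' @param catalog a `vita_catalog`.
#' @param records `genome_records` supplying each genome's genus.
#' @param scg_genera genera eligible for the SCG label.
#' @return List of `cobalamin_profile`s, named by genome id.
#' @export
cobalamin_profiles <- function(profiles, catalog, records,
                               scg_genera = SCG_GENERA) {
  genus <- stats::setNames(records$genus, records$genome_id)
  lapply(profiles, function(p) {
    g <- unname(genus[p$genome_id])
    cobalamin_profile(p, catalog, if (is.na(g) || length(g) == 0L) "" else g,
                      scg_genera)
  })
}

#' Per-genus cobalamin role gap table
#'
#' For every genus represented in the input, the fraction of its genomes
#' lacking each cobalamin role, plus the per-genome role-count matrix used
#' for stage-annotated heatmaps.
#'
#' @param cob_profiles list of [cobalamin_profile()]s.
#' @return List with `fraction_missing` (genera x roles numeric matrix),
#'   `role_counts` (genomes x roles integer matrix) and `labels` (named
#'   character genome -> CCG/SCG/other).
#' @export
genus_gap_table <- function(cob_profiles) {
  if (length(cob_profiles) == 0L) vp_stop("no cobalamin profiles supplied")
  role_ids <- names(cob_profiles[[1L]]$role_present)
  genomes <- vapply(cob_profiles, `[[`, "", "genome_id")
  genera <- vapply(cob_profiles, `[[`, "", "genus")
  pres <- t(vapply(cob_profiles,
                   function(p) p$role_present[role_ids], logical(length(role_ids))))
  counts <- t(vapply(cob_profiles,
                     function(p) p$role_counts[role_ids], integer(length(role_ids))))
  rownames(pres) <- rownames(counts) <- genomes
  by_genus <- split(seq_along(genomes), genera)
  by_genus <- by_genus[names(by_genus) != ""]
  if (length(by_genus) == 0L) vp_stop("every profile lacks a genus")
  frac <- t(vapply(by_genus, function(idx) {
    colMeans(!pres[idx, , drop = FALSE])
  }, numeric(length(role_ids))))
  colnames(frac) <- role_ids
  labels <- stats::setNames(vapply(cob_profiles, `[[`, "", "label"), genomes)
  list(fraction_missing = frac, role_counts = counts, labels = labels)
}
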