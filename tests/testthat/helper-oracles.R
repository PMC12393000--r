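# Independent oracles and random-input generators shared across tests.
# These deliberately re-derive results through different code paths than
# the package implementation.

KO_POOL <- sprintf("K%05d", 1:50)

# Random small catalog: 1-3 vitamins, 1-2 routes each, 1-4 roles per route.
random_catalog <- function() {
  vits <- sample(c("Thi", "Rib", "Nia", "Pan", "Pyr", "Bio", "Fol", "Cob",
                   "Men"), sample(1:3, 1))
  role_counter <- 0L
  pathways <- lapply(vits, function(v) {
    routes <- lapply(seq_len(sample(1:2, 1)), function(r) {
      n_roles <- sample(1:4, 1)
      roles <- lapply(seq_len(n_roles), function(i) {
        role_counter <<- role_counter + 1L
        list(role_id = sprintf("%s_role%03d", v, role_counter),
             kos = sample(KO_POOL, sample(1:3, 1)),
             essential = stats::runif(1) < 0.7, stage = NULL)
      })
      # guarantee at least one essential role per route
      roles[[sample(n_roles, 1)]]$essential <- TRUE
      list(route_id = sprintf("%s_route%d", v, r), roles = roles)
    })
    list(routes = routes)
  })
  names(pathways) <- vits
  vita_catalog(pathways)
}

random_profile <- function(id = "G1", max_kos = 12L) {
  ko_profile(id, sample(KO_POOL, sample(0:max_kos, 1)))
}

# Brute-force producer oracle: explicit route enumeration with plain set
# operations (no shared code with classify_genome).
oracle_classify <- function(kos, catalog) {
  called <- character(0)
  for (vit in names(catalog$pathways)) {
    complete_any <- FALSE
    for (route in catalog$pathways[[vit]]$routes) {
      essential_ok <- vapply(route$roles, function(r) {
        role <- catalog$roles[[r$role_id]]
        if (!role$essential) return(TRUE)
        length(intersect(kos, role$kos)) > 0L
      }, logical(1))
      if (all(essential_ok)) complete_any <- TRUE
    }
    if (complete_any) called <- c(called, vit)
  }
  called
}

# Independent greedy-clustering oracle: re-derives the ranked order and the
# absorb step with explicit loops over an id set.
oracle_greedy_cluster <- function(ani, records, threshold) {
  ids <- records$genome_id
  score <- records$completeness - 5 * records$contamination
  size <- ifelse(is.na(records$genome_size), 0, records$genome_size)
  remaining <- ids
  clusters <- list()
  while (length(remaining) > 0L) {
    # pick the best remaining genome by (score, size, id) by enumeration
    best <- remaining[1L]
    for (cand in remaining[-1L]) {
      bi <- match(best, ids); ci <- match(cand, ids)
      better <- (score[ci] > score[bi]) ||
        (score[ci] == score[bi] && size[ci] > size[bi]) ||
        (score[ci] == score[bi] && size[ci] == size[bi] && cand < best)
      if (better) best <- cand
    }
    members <- best
    for (m in setdiff(remaining, best)) {
      if (ani[best, m] > threshold) members <- c(members, m)
    }
    clusters[[best]] <- sort(members)
    remaining <- setdiff(remaining, members)
  }
  clusters
}

random_ani_records <- function(n) {
  ids <- sprintf("g%02d", seq_len(n))
  m <- matrix(stats::runif(n * n, 70, 100), n, n,
              dimnames = list(ids, ids))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 100
  rec <- genome_records(ids,
                        completeness = round(stats::runif(n, 50, 100), 1),
                        contamination = round(stats::runif(n, 0, 4), 1),
                        genome_size = sample(2e6:7e6, n))
  list(ani = ani_matrix(m), records = rec)
}

# Strip abundance-matrix attributes for plain numeric comparison.
bare <- function(m) {
  m <- unclass(m)
  attr(m, "unit") <- NULL
  attr(m, "feature_level") <- NULL
  m
}

# Canonical form of a clustering for comparison.
cluster_canonical <- function(clusters) {
  out <- lapply(clusters, sort)
  out[order(names(out))]
}

# Tiny deterministic study for workflow tests.
small_study <- function(seed = 42L, n_genomes = 22L, n_per_group = 5L,
                        design = "regions5", ...) {
  simulate_study(sim_config(seed = seed, design = design,
                            n_genomes = n_genomes,
                            n_samples_per_group = n_per_group, ...))
}
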