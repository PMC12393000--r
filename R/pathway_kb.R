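# Nine vitamin codes handled by the catalog (thiamine .. menaquinone).
VITAMIN_CODES <- c("Thi", "Rib", "Nia", "Pan", "Pyr", "Bio", "Fol", "Cob", "Men")

COBALAMIN_STAGES <- c("aerobic", "anaerobic", "post_cobyrinate")

KO_PATTERN <- "^K[0-9]{5}$"

vp_stop <- function(fmt, ..., class = "vitapath_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

vp_validation_error <- function(fmt, ...) {
  vp_stop(fmt, ..., class = c("vitapath_validation_error", "vitapath_error"))
}

#' Vitamin-pathway knowledge base
#'
#' A pathway catalog maps each vitamin to one or more biosynthetic routes
#' (alternative branches such as the `thiI`/`thiO` thiazole branches of
#' thiamine, the `Men` and `Meq` (futalosine) menaquinone routes, or the
#' aerobic and anaerobic corrin-ring routes of cobalamin).  Each route is an
#' ordered list of functional roles; a role is a set of KEGG KO identifiers
#' that perform the same biosynthetic step, with an `essential` flag.  A
#' genome satisfies a role when it carries at least one of the role's KOs,
#' completes a route when every essential role is satisfied, and is called a
#' de novo producer of the vitamin when at least one route is complete.
#'
#' Cobalamin roles additionally carry a `stage` label (`"aerobic"`,
#' `"anaerobic"` or `"post_cobyrinate"`) used by the stage-aware gap
#' analysis.
#'
#' @param pathways named list (vitamin code -> list with a `routes` element);
#'   see [load_catalog()] for the on-disk schema.
#' @param version catalog version string.
#' @return An object of class `vita_catalog` with elements `version`,
#'   `pathways`, `roles` (named list of unique role definitions) and
#'   `ko_universe` (sorted character vector of all referenced KOs).
#' @seealso [load_catalog()], [default_catalog()], [catalog_stats()],
#'   [cobalamin_stage_map()]
#' @export
vita_catalog <- function(pathways, version = "custom") {
  cat <- structure(
    list(version = as.character(version), pathways = pathways),
    class = "vita_catalog"
  )
  validate_catalog(cat)
}

#' Validate a pathway catalog
#'
#' Checks the structural invariants: vitamin codes drawn from the nine
#' supported ones, non-empty routes, every role with a non-empty KO set
#' matching `K#####`, at least one essential role per route, consistent
#' definitions when a role id recurs across routes, and legal cobalamin
#' stage labels.  Derives `roles` and `ko_universe`.
#'
#' @param catalog a `vita_catalog` (possibly not yet validated).
#' @return The validated catalog, with derived fields filled in.
#' @export
validate_catalog <- function(catalog) {
  pw <- catalog$pathways
  if (is.null(names(pw)) && length(pw) > 0L) {
    vp_validation_error("pathways must be a named list of vitamin entries")
  }
  bad <- setdiff(names(pw), VITAMIN_CODES)
  if (length(bad) > 0L) {
    vp_validation_error("unknown vitamin code(s): %s", paste(bad, collapse = ", "))
  }
  roles <- list()
  for (vit in names(pw)) {
    routes <- pw[[vit]]$routes
    if (length(routes) == 0L) {
      vp_validation_error("vitamin '%s' has no routes", vit)
    }
    route_ids <- vapply(routes, function(r) as.character(r$route_id %||% ""), "")
    if (anyDuplicated(route_ids) || any(route_ids == "")) {
      vp_validation_error("vitamin '%s' has missing or duplicated route_id", vit)
    }
    for (route in routes) {
      if (length(route$roles) == 0L) {
        vp_validation_error("route '%s' (%s) has no roles", route$route_id, vit)
      }
      any_essential <- FALSE
      for (role in route$roles) {
        rid <- as.character(role$role_id %||% "")
        if (rid == "") {
          vp_validation_error("route '%s' (%s) contains a role without role_id",
                              route$route_id, vit)
        }
        kos <- unique(as.character(role$kos))
        if (length(kos) == 0L) {
          vp_validation_error("role '%s' in route '%s' has an empty KO set",
                              rid, route$route_id)
        }
        if (!all(grepl(KO_PATTERN, kos))) {
          vp_validation_error("role '%s' has malformed KO id(s): %s", rid,
                              paste(kos[!grepl(KO_PATTERN, kos)], collapse = ", "))
        }
        essential <- isTRUE(role$essential %||% TRUE)
        stage <- role$stage
        if (!is.null(stage) && !is.na(stage)) {
          stage <- as.character(stage)
          if (!stage %in% COBALAMIN_STAGES) {
            vp_validation_error("role '%s' has unknown stage '%s'", rid, stage)
          }
        } else {
          stage <- NULL
        }
        def <- list(role_id = rid, kos = sort(kos), essential = essential,
                    stage = stage)
        if (!is.null(roles[[rid]])) {
          prev <- roles[[rid]]
          if (!identical(prev$kos, def$kos) ||
              !identical(prev$essential, def$essential) ||
              !identical(prev$stage, def$stage)) {
            vp_validation_error(
              "role '%s' is defined inconsistently across routes", rid)
          }
        } else {
          roles[[rid]] <- def
        }
        if (essential) any_essential <- TRUE
      }
      if (!any_essential) {
        vp_validation_error("route '%s' (%s) has no essential role",
                            route$route_id, vit)
      }
    }
  }
  catalog$roles <- roles
  catalog$ko_universe <- sort(unique(unlist(lapply(roles, `[[`, "kos"),
                                            use.names = FALSE)))
  catalog
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a pathway catalog from JSON or TSV
#'
#' The JSON schema is
#' `{"version", "pathways": {vitamin: {"routes": [{"route_id",
#' "roles": [{"role_id", "kos": [...], "essential": bool, "stage": str|null}]}]}}}`.
#' A flat TSV with header `vitamin, route_id, role_id, ko, essential, stage`
#' (one row per role-KO pair) is accepted for files ending in `.tsv`/`.txt`.
#'
#' @param path path to a catalog file.
#' @return A validated [vita_catalog()].
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) vp_stop("catalog file not found: %s", path)
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    return(read_catalog_tsv(path))
  }
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) vp_validation_error("cannot parse catalog '%s': %s",
                                            path, conditionMessage(e))
  )
  if (is.null(raw$pathways)) {
    vp_validation_error("catalog '%s' lacks a 'pathways' entry", path)
  }
  vita_catalog(raw$pathways, version = raw$version %||% "unversioned")
}

#' Write a pathway catalog
#'
#' @param catalog a validated `vita_catalog`.
#' @param path output path; `.json` writes the nested schema, `.tsv` the flat
#'   role-KO table.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "vita_catalog"))
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    utils::write.table(catalog_to_table(catalog), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    out <- list(version = catalog$version, pathways = catalog$pathways)
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                         null = "null", digits = NA)
  }
  invisible(path)
}

catalog_to_table <- function(catalog) {
  rows <- list()
  for (vit in names(catalog$pathways)) {
    for (route in catalog$pathways[[vit]]$routes) {
      for (role in route$roles) {
        for (ko in role$kos) {
          rows[[length(rows) + 1L]] <- data.frame(
            vitamin = vit, route_id = route$route_id,
            role_id = role$role_id, ko = ko,
            essential = isTRUE(role$essential %||% TRUE),
            stage = if (is.null(role$stage)) NA_character_ else role$stage,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

read_catalog_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("vitamin", "route_id", "role_id", "ko", "essential", "stage")
  if (!all(need %in% names(tab))) {
    vp_validation_error("catalog TSV '%s' lacks column(s): %s", path,
                        paste(setdiff(need, names(tab)), collapse = ", "))
  }
  pathways <- list()
  for (vit in unique(tab$vitamin)) {
    vt <- tab[tab$vitamin == vit, , drop = FALSE]
    routes <- lapply(unique(vt$route_id), function(rid) {
      rt <- vt[vt$route_id == rid, , drop = FALSE]
      roles <- lapply(unique(rt$role_id), function(role_id) {
        rr <- rt[rt$role_id == role_id, , drop = FALSE]
        stage <- rr$stage[1L]
        list(role_id = role_id, kos = unique(rr$ko),
             essential = isTRUE(as.logical(rr$essential[1L])),
             stage = if (is.na(stage) || stage == "") NULL else stage)
      })
      list(route_id = rid, roles = roles)
    })
    pathways[[vit]] <- list(routes = routes)
  }
  vita_catalog(pathways, version = "tsv-import")
}

#' The shipped default catalog
#'
#' Loads the vitamin-pathway knowledge base distributed with the package:
#' nine vitamins (Thi, Rib, Nia, Pan, Pyr, Bio, Fol, Cob, Men), with the
#' alternative branches observed in gut microbiomes (thiI/thiO, ribD1/RIB7,
#' NMNAT/NaMNAT, the dxp branch with its pdxH bottleneck, four biotin clades
#' including FabG, Men/Meq, and the aerobic/anaerobic/post-cobyrinate
#' cobalamin stages).  The KO fills are curated from public KEGG pathway-map
#' definitions and are meant to be edited by users with their own curation.
#'
#' @return A validated `vita_catalog`.
#' @export
default_catalog <- function() {
  load_catalog(system.file("extdata", "vitamin_pathways.json",
                           package = "vitapath", mustWork = TRUE))
}

#' Summarize a catalog
#'
#' @param catalog a `vita_catalog`.
#' @return A list with `n_vitamins`, `n_routes`, `n_roles` (unique role ids)
#'   and `n_kos` (size of the KO universe).
#' @export
catalog_stats <- function(catalog) {
  stopifnot(inherits(catalog, "vita_catalog"))
  n_routes <- sum(vapply(catalog$pathways,
                         function(p) length(p$routes), integer(1L)))
  list(n_vitamins = length(catalog$pathways),
       n_routes = as.integer(n_routes),
       n_roles = length(catalog$roles),
       n_kos = length(catalog$ko_universe))
}

#' Cobalamin role-to-stage map
#'
#' @param catalog a `vita_catalog` containing a Cob pathway whose roles all
#'   carry stage labels.
#' @return Named character vector mapping each cobalamin role id to one of
#'   `"aerobic"`, `"anaerobic"`, `"post_cobyrinate"`.
#' @export
cobalamin_stage_map <- function(catalog) {
  stopifnot(inherits(catalog, "vita_catalog"))
  if (is.null(catalog$pathways$Cob)) {
    vp_stop("catalog has no Cob pathway")
  }
  out <- character(0)
  for (route in catalog$pathways$Cob$routes) {
    for (role in route$roles) {
      if (is.null(role$stage)) {
        vp_stop("cobalamin role '%s' lacks a stage label", role$role_id)
      }
      out[[role$role_id]] <- role$stage
    }
  }
  out[!duplicated(names(out))]
}

#' Roles of a route, resolved against the catalog role table
#' @keywords internal
route_roles <- function(catalog, route) {
  lapply(route$roles, function(r) catalog$roles[[r$role_id]])
}

#' @export
print.vita_catalog <- function(x, ...) {
  st <- catalog_stats(x)
  cat(sprintf("Vitamin pathway catalog (version %s)\n", x$version))
  cat(sprintf("  %d vitamins, %d routes, %d functional roles, %d KOs\n",
              st$n_vitamins, st$n_routes, st$n_roles, st$n_kos))
  for (vit in names(x$pathways)) {
    rids <- vapply(x$pathways[[vit]]$routes, `[[`, "", "route_id")
    cat(sprintf("  %s: %s\n", vit, paste(rids, collapse = ", ")))
  }
  invisible(x)
}
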