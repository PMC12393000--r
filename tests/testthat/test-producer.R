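make_toy_catalog <- function() {
  # 3-role route: two essential, one optional
  vita_catalog(list(Pan = list(routes = list(list(
    route_id = "toy",
    roles = list(
      list(role_id = "e1", kos = c("K00001", "K00002"), essential = TRUE),
      list(role_id = "e2", kos = "K00003", essential = TRUE),
      list(role_id = "opt", kos = "K00004", essential = FALSE)))))))
}

test_that("role presence is OR over the role's KOs", {
  role <- list(role_id = "r", kos = c("K00001", "K00002"))
  expect_true(role_present(ko_profile("g", "K00001"), role))
  expect_true(role_present(ko_profile("g", "K00002"), role))
  expect_false(role_present(ko_profile("g", "K00003"), role))
  expect_false(role_present(ko_profile("g", character(0)), role))
})

test_that("route completeness is AND over essential roles only", {
  cat0 <- make_toy_catalog()
  route <- cat0$pathways$Pan$routes[[1L]]
  # enumerate every subset of the toy KOs and compare with direct logic
  kos_all <- c("K00001", "K00002", "K00003", "K00004")
  for (mask in 0:15) {
    kos <- kos_all[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0]
    got <- route_complete(ko_profile("g", kos), route, cat0)
    want <- (any(c("K00001", "K00002") %in% kos)) && ("K00003" %in% kos)
    expect_identical(got, want)
  }
})

test_that("classification matches the brute-force oracle on random inputs", {
  set.seed(101)
  for (i in 1:200) {
    cat0 <- random_catalog()
    prof <- random_profile()
    got <- sort(classify_genome(prof, cat0)$vitamins)
    want <- sort(oracle_classify(prof$kos, cat0))
    expect_identical(got, want)
  }
})

test_that("classification is monotone under KO addition", {
  set.seed(102)
  for (i in 1:100) {
    cat0 <- random_catalog()
    kos <- sample(KO_POOL, 4)
    prev <- classify_genome(ko_profile("g", kos), cat0)$vitamins
    for (step in 1:4) {
      kos <- union(kos, sample(KO_POOL, 3))
      now <- classify_genome(ko_profile("g", kos), cat0)$vitamins
      expect_true(all(prev %in% now))
      prev <- now
    }
  }
})

test_that("the satisfying route is the first complete one in catalog order", {
  cat0 <- default_catalog()
  # full anaerobic cobalamin complement (anaerobic + post stages)
  an <- cat0$pathways$Cob$routes[[2L]]
  kos <- unlist(lapply(an$roles, function(r) cat0$roles[[r$role_id]]$kos))
  cl <- classify_genome(ko_profile("g", kos), cat0)
  expect_true("Cob" %in% cl$vitamins)
  expect_identical(unname(cl$routes[["Cob"]]), "anaerobic")
})

test_that("a genome lacking CobNST cannot complete the aerobic route", {
  cat0 <- default_catalog()
  aerobic_only <- vita_catalog(list(Cob = list(routes =
    list(cat0$pathways$Cob$routes[[1L]]))))
  ae <- aerobic_only$pathways$Cob$routes[[1L]]
  kos <- unlist(lapply(ae$roles, function(r) cat0$roles[[r$role_id]]$kos))
  kos_missing <- setdiff(kos, cat0$roles$CobNST$kos)
  expect_false("Cob" %in%
    classify_genome(ko_profile("g", kos_missing), aerobic_only)$vitamins)
  expect_true("Cob" %in%
    classify_genome(ko_profile("g", kos), aerobic_only)$vitamins)
})

test_that("producer breadth histogram and fractions are consistent", {
  cat0 <- make_toy_catalog()
  profs <- list(ko_profile("g1", c("K00001", "K00003")),  # producer
                ko_profile("g2", "K00001"),               # not
                ko_profile("g3", c("K00002", "K00003")))  # producer
  pm <- producer_matrix(profs, cat0)
  pb <- producer_breadth(pm, producers_only = TRUE)
  expect_identical(pb$histogram[["1"]], 2L)
  expect_identical(pb$histogram[["0"]], 1L)
  expect_identical(pb$denominator, 2L)
  expect_equal(pb$fractions[["1"]], 1)

  pb_all <- producer_breadth(pm, producers_only = FALSE)
  expect_equal(sum(pb_all$fractions), 1)

  empty <- producer_matrix(list(ko_profile("g", character(0))), cat0)
  expect_identical(producer_breadth(empty,
                                    producers_only = FALSE)$histogram[["0"]],
                   1L)
})

test_that("cobalamin labels follow the CCG/SCG/other rule", {
  cat0 <- default_catalog()
  an <- cat0$pathways$Cob$routes[[2L]]
  full <- unlist(lapply(an$roles, function(r) cat0$roles[[r$role_id]]$kos))

  expect_identical(cobalamin_profile(ko_profile("g", full), cat0,
                                     genus = "Bacillus")$label, "CCG")
  # a CCG lacking the aerobic-only genes is still a CCG
  no_aer <- setdiff(full, unlist(cat0$roles[c("CobF", "CobG",
                                              "CobNST")], use.names = FALSE))
  expect_identical(cobalamin_profile(ko_profile("g", no_aer), cat0,
                                     genus = "Blautia")$label, "CCG")
  # partial + focal genus -> SCG; partial + other genus -> other
  cbik_only <- cat0$roles$CbiK$kos[1L]
  expect_identical(cobalamin_profile(ko_profile("g", cbik_only), cat0,
                                     genus = "Blautia")$label, "SCG")
  expect_identical(cobalamin_profile(ko_profile("g", cbik_only), cat0,
                                     genus = "Escherichia")$label, "other")
  # no cobalamin KOs at all -> other even in a focal genus
  expect_identical(cobalamin_profile(ko_profile("g", "K00001"), cat0,
                                     genus = "Blautia")$label, "other")
})

test_that("stage counts track role presence", {
  cat0 <- default_catalog()
  sm <- cobalamin_stage_map(cat0)
  an <- cat0$pathways$Cob$routes[[2L]]
  full <- unlist(lapply(an$roles, function(r) cat0$roles[[r$role_id]]$kos))
  cp <- cobalamin_profile(ko_profile("g", full), cat0, genus = "Blautia")
  expect_equal(cp$stage_counts["anaerobic", "present"],
               cp$stage_counts["anaerobic", "total"])
  expect_equal(cp$stage_counts["post_cobyrinate", "present"],
               cp$stage_counts["post_cobyrinate", "total"])
  expect_identical(sum(cp$role_present),
                   sum(vapply(names(sm), function(r)
                     any(cat0$roles[[r]]$kos %in% full), logical(1))))
})

test_that("genus gap fractions are exact for planted deficiencies", {
  cat0 <- default_catalog()
  an <- cat0$pathways$Cob$routes[[2L]]
  full <- unlist(lapply(an$roles, function(r) cat0$roles[[r$role_id]]$kos))
  cobf <- cat0$roles$CobF$kos
  # 10 genomes, 9 lacking CobF (aerobic-only KO set is absent anyway);
  # plant CobF KOs in exactly one genome
  profs <- lapply(1:10, function(i) {
    kos <- if (i == 1L) c(full, cobf) else full
    cobalamin_profile(ko_profile(sprintf("g%02d", i), kos), cat0,
                      genus = "Blautia")
  })
  gap <- genus_gap_table(profs)
  expect_equal(gap$fraction_missing["Blautia", "CobF"], 0.9)
  expect_equal(gap$fraction_missing["Blautia", "CbiK"], 0)
  expect_true(all(rownames(gap$role_counts) == sprintf("g%02d", 1:10)))
  expect_error(genus_gap_table(list()), "profiles")
})
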