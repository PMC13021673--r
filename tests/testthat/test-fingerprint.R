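test_that("build_matrix transcribes directional observations into ternary entries", {
  m <- toy_t1()
  expect_identical(unname(m$entries),
                   matrix(c(-1L, -1L, 0L, -1L, 0L, 1L, 0L, 0L, -1L),
                          3, 3, byrow = TRUE))
  expect_identical(rownames(m$entries), c("r1", "r2", "r3"))
  expect_identical(colnames(m$entries), c("s1", "s2", "s3"))

  empty <- build_matrix(data.frame(), toy_regions(), toy_studies())
  expect_true(all(empty$entries == 0L))
  expect_identical(dim(empty), c(3L, 3L))
})

test_that("same-sign duplicates consolidate to a single entry", {
  obs <- data.frame(roi_id = c("r1", "r1"), study_id = c("s1", "s1"),
                    direction = c(-1L, -1L))
  m <- build_matrix(obs, toy_regions(), toy_studies())
  expect_identical(m$entries["r1", "s1"], -1L)
  expect_identical(sum(m$entries != 0L), 1L)
})

test_that("opposite-sign conflicts follow the conflict policy", {
  obs <- data.frame(roi_id = "r1", study_id = c("s1", "s1", "s1"),
                    direction = c(-1L, -1L, 1L))
  expect_error(build_matrix(obs, toy_regions(), toy_studies()),
               "opposite-sign.*\\(r1, s1\\)")
  m <- build_matrix(obs, toy_regions(), toy_studies(),
                    conflict_policy = "MAJORITY")
  expect_identical(m$entries["r1", "s1"], -1L)
  tie <- data.frame(roi_id = "r1", study_id = c("s1", "s1"),
                    direction = c(-1L, 1L))
  expect_error(build_matrix(tie, toy_regions(), toy_studies(),
                            conflict_policy = "MAJORITY"),
               "tie.*cannot be majority-resolved")
})

test_that("undeclared ids and zero directions are rejected by name", {
  expect_error(build_matrix(data.frame(roi_id = "rX", study_id = "s1",
                                       direction = -1L),
                            toy_regions(), toy_studies()),
               "undeclared roi_id: rX")
  expect_error(build_matrix(data.frame(roi_id = "r1", study_id = "sX",
                                       direction = -1L),
                            toy_regions(), toy_studies()),
               "undeclared study_id: sX")
  expect_error(build_matrix(data.frame(roi_id = "r1", study_id = "s1",
                                       direction = 0L),
                            toy_regions(), toy_studies()),
               "direction must be -1 or \\+1")
})

test_that("round-trip: non-zero cells reproduce the consolidated observations", {
  set.seed(11)
  for (rep in 1:5) {
    fp <- rand_fingerprint(12, 6)
    obs <- matrix_observations(fp$matrix)
    rebuilt <- build_matrix(obs, fp$matrix$regions, fp$matrix$studies)
    expect_identical(rebuilt$entries, fp$matrix$entries)
  }
})

test_that("observation order never changes the resulting matrix", {
  set.seed(7)
  obs <- matrix_observations(toy_t1())
  for (rep in 1:10) {
    perm <- obs[sample(nrow(obs)), , drop = FALSE]
    m <- build_matrix(perm, toy_regions(), toy_studies())
    expect_identical(m$entries, toy_t1()$entries)
  }
})

test_that("validate_matrix reports domain violations without raising", {
  expect_identical(nrow(validate_matrix(toy_t1())), 0L)

  m <- toy_t1()
  m$entries["r1", "s1"] <- 2L
  issues <- validate_matrix(m)
  expect_identical(issues$severity, "ERROR")
  expect_match(issues$location, "\\(r1, s1\\)")

  m2 <- toy_t1()
  m2$regions$networks[2] <- ""
  issues2 <- validate_matrix(m2)
  expect_true(any(issues2$severity == "ERROR" & issues2$location == "r2"))

  m3 <- toy_t1()
  m3$entries["r3", "s3"] <- 0L  # all-zero row: flagged, not an error
  issues3 <- validate_matrix(m3)
  expect_identical(issues3$severity, "WARNING")
  expect_identical(issues3$location, "r3")
})

test_that("subset_matrix restricts the region axis and preserves order", {
  m <- toy_t1(); sch <- toy_scheme()
  sub <- subset_matrix(m, sch, network = "k1")
  expect_identical(rownames(sub$entries), c("r1", "r2"))
  expect_identical(sub$entries, m$entries[c("r1", "r2"), ])
  expect_identical(colnames(sub$entries), colnames(m$entries))

  # empty network -> 0-row matrix, no error
  sch2 <- network_scheme(list(r1 = "k1", r2 = "k1", r3 = "k1"),
                         network_ids = c("k1", "k2"),
                         priority = c("k1", "k2"))
  m2 <- fingerprint_matrix(m$entries, m$regions, m$studies)
  expect_identical(nrow(subset_matrix(m2, sch2, network = "k2")$entries), 0L)

  expect_identical(subset_matrix(m)$entries, m$entries)  # identity
  expect_error(subset_matrix(m, sch, network = "nope"), "unknown network")

  wm <- subset_matrix(m, tissue = "WM")
  expect_identical(nrow(wm$entries), 0L)
})

test_that("subsetting to a network commutes with metric computation", {
  set.seed(21)
  fp <- rand_fingerprint(15, 8)
  for (k in fp$scheme$network_ids) {
    sub <- subset_matrix(fp$matrix, fp$scheme, network = k)
    expect_identical(total_abnormal_load(sub, fp$scheme, k),
                     total_abnormal_load(fp$matrix, fp$scheme, k))
    expect_identical(distinct_abnormal_regions(sub, fp$scheme, k),
                     distinct_abnormal_regions(fp$matrix, fp$scheme, k))
    expect_equal(mean_direction(sub, fp$scheme, k),
                 mean_direction(fp$matrix, fp$scheme, k))
  }
})

test_that("region and scheme constructors enforce their invariants", {
  expect_error(region_records(c("a", "a"), "x", "BILATERAL", "GM", "DMN"),
               "duplicate roi_id")
  expect_error(region_records("a", "x", "BILATERAL", "GM", "XXX"),
               "unknown network")
  expect_error(region_records("a", "x", "MIDDLE", "GM", "DMN"),
               "invalid hemisphere")
  expect_error(network_scheme(list(r1 = "DMN"), network_ids = "SAL"),
               "absent from network_ids")
  expect_error(network_scheme(list(r1 = "DMN"), network_ids = "DMN",
                              priority = c("DMN", "SAL")),
               "permutation")
  sch <- network_scheme(list(r1 = c("SAL", "DMN"), r2 = "SAL"))
  expect_identical(unname(dominant_network(sch, "r1")), "DMN")
})
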