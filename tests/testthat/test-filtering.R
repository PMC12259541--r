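# Analysis-set construction: low-confidence drop, then single-medium
# exclusion with the congeneric high-confidence rescue.

test_that("drop_low keeps exactly the medium and high records in order", {
  rs <- make_records(record_id = c("a", "b", "c"),
                     confidence = c("high", "medium", "low"))
  expect_equal(drop_low(rs)$record_id, c("a", "b"))
  allhigh <- make_records(record_id = c("a", "b"), confidence = "high")
  expect_identical(drop_low(allhigh), allhigh)
  rs$confidence[2] <- NA
  expect_error(drop_low(rs), "unrated")
})

test_that("an unrescued medium singleton is removed and logged", {
  rs <- dplyr::bind_rows(
    make_record(record_id = "s1", parasite_species = "Para alpha",
                confidence = "medium"),
    make_record(record_id = "k1", parasite_species = "Para beta",
                host_family = "Fam2", confidence = "high",
                reference_id = "ref2")
  )
  res <- single_medium_filter(rs)
  expect_equal(res$removed_record_ids, "s1")
  expect_equal(res$removed_parasite_species, "Para alpha")
  expect_equal(nrow(res$rescue_log), 0)
  expect_false("s1" %in% res$kept$record_id)
})

test_that("a congeneric high record from the same host family rescues", {
  rs <- dplyr::bind_rows(
    make_record(record_id = "s1", parasite_species = "Para alpha",
                parasite_genus = "Para", host_family = "Fam1",
                confidence = "medium"),
    make_record(record_id = "k1", parasite_species = "Para beta",
                parasite_genus = "Para", host_family = "Fam1",
                confidence = "high", reference_id = "ref2"),
    make_record(record_id = "k2", parasite_species = "Para beta",
                parasite_genus = "Para", host_family = "Fam2",
                confidence = "medium", reference_id = "ref3")
  )
  res <- single_medium_filter(rs)
  expect_length(res$removed_record_ids, 0)
  expect_equal(res$rescue_log$parasite_species, "Para alpha")
  expect_equal(res$rescue_log$rescuing_parasite_species, "Para beta")
  # the rescue must come from a different parasite species in the genus;
  # a high record of another genus does not rescue
  rs$parasite_genus[rs$record_id == "k1"] <- "Alia"
  rs$parasite_species[rs$record_id %in% c("k1", "k2")] <- "Alia beta"
  res2 <- single_medium_filter(rs)
  expect_equal(res2$removed_record_ids, "s1")
})

test_that("species with two medium records or one high record are kept", {
  two_medium <- make_records(record_id = c("a", "b"),
                             confidence = "medium",
                             reference_id = c("ref1", "ref2"))
  expect_length(single_medium_filter(two_medium)$removed_record_ids, 0)
  one_high <- make_record(record_id = "a", confidence = "high")
  expect_length(single_medium_filter(one_high)$removed_record_ids, 0)
})

test_that("build_analysis_set composes the two rules on a 6-record fixture", {
  # 1 low + an unrescued medium singleton leave 4 records
  rs <- dplyr::bind_rows(
    make_record(record_id = "lo", parasite_species = "Para gamma",
                confidence = "low"),
    make_record(record_id = "s1", parasite_species = "Para alpha",
                host_family = "Fam3", confidence = "medium"),
    make_records(record_id = c("k1", "k2"), parasite_species = "Para beta",
                 parasite_genus = "Beta", confidence = "medium",
                 reference_id = c("ref2", "ref3")),
    make_records(record_id = c("k3", "k4"), parasite_species = "Alia una",
                 parasite_genus = "Alia", confidence = c("high", "medium"),
                 reference_id = c("ref4", "ref5"))
  )
  res <- build_analysis_set(rs)
  expect_equal(nrow(res$kept), 4)
  expect_equal(res$n_low_dropped, 1)
  expect_equal(res$removed_record_ids, "s1")
  expect_equal(sort(setdiff(rs$record_id, res$kept$record_id)),
               c("lo", "s1"))
  g <- glance(res)
  expect_equal(g$n_kept, 4)
  expect_equal(g$n_input, 6)

  # idempotence: filtering an already-filtered set changes nothing
  res2 <- build_analysis_set(res$kept)
  expect_identical(res2$kept, res$kept)
  expect_length(res2$removed_record_ids, 0)

  empty <- rs[0, ]
  res0 <- build_analysis_set(empty)
  expect_equal(nrow(res0$kept), 0)
  expect_length(res0$removed_record_ids, 0)
})

test_that("adding a high record can only grow the kept set", {
  rs <- dplyr::bind_rows(
    make_record(record_id = "s1", parasite_species = "Para alpha",
                parasite_genus = "Para", host_family = "Fam1",
                confidence = "medium"),
    make_record(record_id = "k1", parasite_species = "Alia una",
                parasite_genus = "Alia", host_family = "Fam2",
                confidence = "medium", reference_id = "ref2"),
    make_record(record_id = "k2", parasite_species = "Alia una",
                parasite_genus = "Alia", host_family = "Fam2",
                confidence = "medium", reference_id = "ref3")
  )
  before <- build_analysis_set(rs)$kept
  extra <- make_record(record_id = "hi", parasite_species = "Para beta",
                       parasite_genus = "Para", host_family = "Fam1",
                       confidence = "high", reference_id = "refX")
  after <- build_analysis_set(dplyr::bind_rows(rs, extra))$kept
  expect_true(all(before$record_id %in% after$record_id))
  expect_true("s1" %in% after$record_id)  # rescued by the new high record
})

test_that("filter invariants hold across synthetic seeds", {
  for (seed in 1:10) {
    synth <- generate_host_data(small_synth_config(seed))
    rated <- suppressWarnings(apply_confidence(synth$records))
    res <- build_analysis_set(rated)
    # idempotence
    res2 <- build_analysis_set(res$kept)
    expect_identical(res2$kept, res$kept)
    # no surviving unrescued medium singleton
    per <- dplyr::count(res$kept, parasite_species)
    singles <- per$parasite_species[per$n == 1]
    lone <- res$kept[res$kept$parasite_species %in% singles &
                       res$kept$confidence == "medium", ]
    if (nrow(lone) > 0) {
      expect_true(all(lone$parasite_species %in%
                        res$rescue_log$parasite_species))
    }
    # every removal is logged with its parasite species
    removed <- rated[rated$record_id %in% res$removed_record_ids, ]
    expect_setequal(unique(removed$parasite_species),
                    res$removed_parasite_species)
    # partition: kept + removed = input after the low drop
    no_low <- drop_low(rated)
    expect_setequal(c(res$kept$record_id, res$removed_record_ids),
                    no_low$record_id)
  }
})
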