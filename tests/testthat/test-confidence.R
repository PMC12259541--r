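# The rule engine: H1-H4 high, M1-M4 medium, L1-L3 low, precedence
# P0 (dubious) > P1 (high, pre-1950 cap) > P2 (medium) > P3 (low fallbacks)
# > P4 (default medium).

classify_one <- function(rec, ctx = build_confidence_context(rec)) {
  classify_confidence(rec, ctx)
}

test_that("excavation with confirmed host contact rates high", {
  out <- classify_one(make_record(excavated_confirmed = TRUE))
  expect_equal(out$confidence, "high")
  expect_equal(out$rule_id, "H1")
})

test_that("expert reports and host material on the sheet rate high", {
  expect_equal(classify_one(make_record(expert_report = TRUE))$confidence,
               "high")
  out <- classify_one(make_record(host_material_on_sheet = TRUE,
                                  record_type = "herbarium"))
  expect_equal(out$confidence, "high")
  expect_equal(out$rule_id, "H3")
})

test_that("database observation without photo or congeneric high rates low", {
  rec <- make_record(database_observation = TRUE,
                     record_type = "database_obs")
  out <- classify_one(rec)
  expect_equal(out$confidence, "low")
  expect_equal(out$rule_id, "L3")
})

test_that("an author-flagged dubious report is low regardless of evidence", {
  out <- classify_one(make_record(author_flags_dubious = TRUE,
                                  excavated_confirmed = TRUE))
  expect_equal(out$confidence, "low")
  expect_equal(out$rule_id, "L1")
})

test_that("pre-1950 reports cap at medium unless excavation is explicit", {
  out <- classify_one(make_record(pre_1950 = TRUE, expert_report = TRUE))
  expect_equal(out$confidence, "medium")
  expect_equal(out$rule_id, "M2")
  # explicit excavation lifts the cap
  out2 <- classify_one(make_record(pre_1950 = TRUE,
                                   excavated_confirmed = TRUE,
                                   excavation_explicit = TRUE))
  expect_equal(out2$confidence, "high")
})

test_that("a congeneric high-rated host genus lifts photo-less database
           records to medium", {
  rs <- dplyr::bind_rows(
    make_record(record_id = "hi", host_species = "Hosta una",
                excavated_confirmed = TRUE),
    make_record(record_id = "db", host_species = "Hosta dua",
                database_observation = TRUE, record_type = "database_obs",
                reference_id = "ref2")
  )
  out <- classify_confidence(rs)
  expect_equal(out$confidence[out$record_id == "db"], "medium")
  expect_equal(out$rule_id[out$record_id == "db"], "M4")
})

test_that("a host family unrelated to all other recorded hosts rates low", {
  rs <- dplyr::bind_rows(
    make_record(record_id = "a", host_family = "Fam1", host_order = "Ord1",
                excavated_confirmed = TRUE),
    make_record(record_id = "b", host_species = "Alia mira",
                host_genus = "Alia", host_family = "Fam9",
                host_order = "Ord9", reference_id = "ref2")
  )
  out <- classify_confidence(rs)
  expect_equal(out$confidence[out$record_id == "b"], "low")
  expect_equal(out$rule_id[out$record_id == "b"], "L2")
  # same report with a related (same-order) second family is medium (M1)
  rs2 <- rs
  rs2$host_order[rs2$record_id == "b"] <- "Ord1"
  out2 <- classify_confidence(rs2)
  expect_equal(out2$confidence[out2$record_id == "b"], "medium")
  expect_equal(out2$rule_id[out2$record_id == "b"], "M1")
})

test_that("the high-genus context is built from context-free rules only", {
  # medium-only parasite contributes nothing to the high-genus map
  rs <- make_record(herbarium_host_named_no_material = TRUE)
  ctx <- build_confidence_context(rs)
  expect_length(ctx$high_genera, 0)
  ctx2 <- build_confidence_context(make_record(excavated_confirmed = TRUE))
  expect_equal(ctx2$high_genera[["Para alpha"]], "Hosta")
  expect_length(build_confidence_context(rs[0, ])$high_genera, 0)
})

test_that("records without evidence need a supplied confidence", {
  rec <- make_record()
  for (fl in evidence_flags()) rec[[fl]] <- NA
  expect_error(classify_confidence(rec), "no evidence")
  rec$confidence <- "medium"
  expect_warning(out <- apply_confidence(rec[, ]), NA)
  expect_equal(out$confidence, "medium")
})

test_that("every valid evidence combination in every context yields exactly
           one rating", {
  flags <- evidence_flags()
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(flags)))
  names(grid) <- flags
  valid <- grid[
    (!grid$photo_connection_visible | grid$has_photo) &
      (!grid$photo_host_visible | grid$has_photo) &
      (!grid$excavation_explicit | grid$excavated_confirmed), ]
  rs <- make_records(record_id = paste0("e", seq_len(nrow(valid))))
  for (fl in flags) rs[[fl]] <- valid[[fl]]

  ctx_cases <- list(
    plain = structure(list(high_genera = list(),
                           family_orders = tibble::tibble(
                             parasite_species = character(),
                             host_family = character(),
                             host_order = character())),
                      class = "host_confidence_ctx"),
    congeneric_high = structure(
      list(high_genera = list("Para alpha" = "Hosta"),
           family_orders = tibble::tibble(parasite_species = character(),
                                          host_family = character(),
                                          host_order = character())),
      class = "host_confidence_ctx"),
    unrelated = structure(
      list(high_genera = list(),
           family_orders = tibble::tibble(
             parasite_species = "Para alpha",
             host_family = c("Fam1", "Fam2"),
             host_order = c("Ord1", "Ord2"))),
      class = "host_confidence_ctx"),
    related = structure(
      list(high_genera = list(),
           family_orders = tibble::tibble(
             parasite_species = "Para alpha",
             host_family = c("Fam1", "Fam2"),
             host_order = c("Ord1", "Ord1"))),
      class = "host_confidence_ctx")
  )
  for (ctx in ctx_cases) {
    out <- suppressMessages(classify_confidence(rs, ctx))
    expect_equal(nrow(out), nrow(valid))
    expect_true(all(out$confidence %in% confidence_levels()))
    expect_false(any(is.na(out$confidence)))
    # determinism
    out2 <- suppressMessages(classify_confidence(rs, ctx))
    expect_identical(out, out2)
  }
})

test_that("adding a congeneric high record never lowers any rating", {
  set.seed(101)
  flags <- evidence_flags()
  for (i in seq_len(200)) {
    n <- sample(3:8, 1)
    rs <- make_records(
      record_id = paste0("r", seq_len(n)),
      parasite_species = sample(c("Para alpha", "Para beta"), n, TRUE),
      host_genus = sample(c("Hosta", "Alia"), n, TRUE),
      host_species = NA,
      host_family = sample(c("Fam1", "Fam2"), n, TRUE),
      host_order = sample(c("Ord1", "Ord2"), n, TRUE),
      reference_id = paste0("ref", seq_len(n))
    )
    draw <- matrix(runif(n * length(flags)) < 0.25, nrow = n)
    colnames(draw) <- flags
    draw[, "has_photo"] <- draw[, "has_photo"] |
      draw[, "photo_connection_visible"] | draw[, "photo_host_visible"]
    draw[, "excavated_confirmed"] <- draw[, "excavated_confirmed"] |
      draw[, "excavation_explicit"]
    draw[, "author_flags_dubious"] <- FALSE
    for (fl in flags) rs[[fl]] <- draw[, fl]
    before <- suppressMessages(classify_confidence(rs))
    extra <- make_record(record_id = "extra",
                         parasite_species = rs$parasite_species[1],
                         host_species = NA,
                         host_genus = rs$host_genus[1],
                         host_family = rs$host_family[1],
                         host_order = rs$host_order[1],
                         reference_id = "refX",
                         excavated_confirmed = TRUE)
    after <- suppressMessages(
      classify_confidence(dplyr::bind_rows(rs, extra))
    )
    after <- after[match(before$record_id, after$record_id), ]
    expect_true(all(conf_rank(after$confidence) >=
                      conf_rank(before$confidence)))
  }
})

test_that("apply_confidence is idempotent and respects pre-set ratings", {
  rs <- dplyr::bind_rows(
    make_record(record_id = "a", excavated_confirmed = TRUE),
    make_record(record_id = "b", confidence = "low", reference_id = "ref2"),
    make_record(record_id = "c", herbarium_host_named_no_material = TRUE,
                reference_id = "ref3")
  )
  once <- apply_confidence(rs)
  twice <- apply_confidence(once)
  expect_identical(once$confidence, twice$confidence)
  expect_equal(once$confidence, c("high", "low", "medium"))
  # pre-set confidence kept unless overwrite
  pre <- make_record(record_id = "d", excavated_confirmed = TRUE,
                     confidence = "low")
  expect_equal(apply_confidence(pre)$confidence, "low")
  expect_equal(apply_confidence(pre, overwrite = TRUE)$confidence, "high")
})

test_that("confidence tallies sum and error on unrated records", {
  rs <- make_records(record_id = c("a", "b", "c"),
                     confidence = c("high", "high", "low"))
  tl <- confidence_tally(rs)
  expect_equal(tl, tibble::tibble(low = 1L, medium = 0L, high = 2L,
                                  total = 3L))
  expect_equal(confidence_tally(rs[0, ])$total, 0)
  rs$confidence[1] <- NA
  expect_error(confidence_tally(rs), "unrated")
})
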