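# Flat-file schema, class cutoff, stratified split.

test_that("drug table round-trips through write and read", {
  drugs <- tiny_drug_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_drug_table(drugs, path)
  back <- read_drug_table(path)
  expect_equal(as.data.frame(back), as.data.frame(drugs))
})

test_that("both CYP dialects parse to the same normalized form", {
  drugs <- tiny_drug_table()
  # single-column dialect equivalent (no drug is substrate+perpetrator at
  # the same enzyme in this fixture except d2 at 3A4 -> use d1, d3, d4)
  sub <- drugs[c(1, 3, 4), ]
  single <- tibble::tibble(drug_id = sub$drug_id, smiles = sub$smiles)
  for (e in cyp_enzymes()) {
    role <- ifelse(sub[[paste0("sub_", e)]] == 1, "substrate",
                   sub[[paste0("perp_", e)]])
    single[[paste0("cyp_", e)]] <- role
  }
  p1 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(single, p1)
  parsed <- read_drug_table(p1)
  expect_equal(parsed$sub_1A2, sub$sub_1A2)
  expect_equal(parsed$perp_3A4, sub$perp_3A4)
})

test_that("tab-delimited input is auto-detected", {
  drugs <- tiny_drug_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_drug_table(drugs, path, delim = "\t")
  expect_equal(as.data.frame(read_drug_table(path)), as.data.frame(drugs))
})

test_that("schema violations are reported with offender names", {
  drugs <- tiny_drug_table()
  path <- withr::local_tempfile(fileext = ".csv")
  dup <- dplyr::bind_rows(drugs, drugs[1, ])
  write_drug_table(dup, path)
  err <- expect_error(read_drug_table(path), class = "ddihybrid_schema_error")
  expect_match(conditionMessage(err), "d1")

  bad <- drugs
  bad$perp_2B6[2] <- "blocker"
  write_drug_table(bad, path)
  err <- expect_error(read_drug_table(path), class = "ddihybrid_schema_error")
  expect_match(conditionMessage(err), "blocker")
  expect_match(conditionMessage(err), "row 2")

  readr::write_csv(tibble::tibble(drug_id = "x"), path)
  expect_error(read_drug_table(path), class = "ddihybrid_schema_error")
})

test_that("pair tables validate ids, labels and duplicates", {
  drugs <- tiny_drug_table()
  pairs <- tiny_pair_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_ddi_table(pairs, path)
  expect_equal(as.data.frame(read_ddi_table(path, drugs = drugs)),
               as.data.frame(pairs))

  write_ddi_table(dplyr::bind_rows(pairs, pairs[1, ]), path)
  expect_warning(read_ddi_table(path), "duplicate")

  write_ddi_table(dplyr::bind_rows(
    pairs, tibble::tibble(victim_id = "zz", perpetrator_id = "d1",
                          label = 1L)), path)
  expect_error(read_ddi_table(path, drugs = drugs),
               class = "ddihybrid_schema_error")

  write_ddi_table(dplyr::bind_rows(
    pairs, tibble::tibble(victim_id = "d4", perpetrator_id = "d1",
                          label = 99L)), path)
  expect_error(read_ddi_table(path), class = "ddihybrid_schema_error")
})

test_that("label catalog has 19 templated entries", {
  cat <- label_catalog()
  expect_equal(cat$label, 1:19)
  expect_true(all(grepl("DRUG_A", cat$description)))
  expect_true(all(grepl("DRUG_B", cat$description)))
})

test_that("low-count class filtering keeps original labels", {
  pairs <- tibble::tibble(
    victim_id = paste0("v", 1:16), perpetrator_id = paste0("p", 1:16),
    label = rep(c(1L, 2L, 3L), times = c(5, 2, 9))
  )
  suppressMessages({
    kept <- filter_low_count_classes(pairs, min_count = 3)
  })
  expect_equal(nrow(kept), 14)
  expect_setequal(unique(kept$label), c(1L, 3L))
  expect_equal(filter_low_count_classes(pairs, min_count = 1), pairs)
  suppressMessages(
    expect_equal(nrow(filter_low_count_classes(pairs, min_count = 100)), 0)
  )
})

test_that("stratified split preserves proportions and partitions", {
  pairs <- tibble::tibble(
    victim_id = paste0("v", 1:100), perpetrator_id = paste0("p", 1:100),
    label = rep(c(1L, 2L), times = c(80, 20))
  )
  sp <- stratified_split(pairs, 0.7, seed = 5)
  expect_equal(sum(sp$train$label == 1), 56)
  expect_equal(sum(sp$train$label == 2), 14)
  expect_equal(sum(sp$test$label == 1), 24)
  expect_equal(sum(sp$test$label == 2), 6)
  joined <- dplyr::bind_rows(sp$train, sp$test)
  expect_setequal(joined$victim_id, pairs$victim_id)
  expect_equal(nrow(dplyr::intersect(sp$train, sp$test)), 0)
  # determinism
  sp2 <- stratified_split(pairs, 0.7, seed = 5)
  expect_identical(sp, sp2)
  sp3 <- stratified_split(pairs, 0.7, seed = 6)
  expect_false(identical(sp$train$victim_id, sp3$train$victim_id))
})

test_that("singleton classes cannot be split", {
  pairs <- tibble::tibble(victim_id = c("a", "b", "c"),
                          perpetrator_id = c("b", "c", "a"),
                          label = c(1L, 1L, 2L))
  expect_error(stratified_split(pairs, 0.7, seed = 1),
               class = "ddihybrid_error")
})
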