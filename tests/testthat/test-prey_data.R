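# Observation I/O, filtering and aggregation rules.

test_that("observation files round-trip, preserve order, and handle empties", {
  cat0 <- make_default_catalog()
  obs <- simulate_study(cat0, study_design(seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_equal(back, obs, ignore_attr = TRUE)

  empty <- obs[0, , drop = FALSE]
  write_observations(empty, path)
  expect_equal(nrow(read_observations(path)), 0)
})

test_that("malformed observation files fail with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")

  # missing required column (no `mode`)
  writeLines(c("dive_id,site_kind,transect_id,replicate,family,species,length_cm,identified",
               "D1,verification,,1,Labridae,,10,true"), path)
  expect_error(read_observations(path), "mode")

  # non-numeric length, reported with its row
  writeLines(c("dive_id,site_kind,transect_id,replicate,mode,family,species,length_cm,identified",
               "D1,verification,,1,sponging,Labridae,,big,true"), path)
  expect_error(read_observations(path), "length_cm.*row", ignore.case = TRUE)

  # unidentified rows must carry the UNKNOWN sentinel
  writeLines(c("dive_id,site_kind,transect_id,replicate,mode,family,species,length_cm,identified",
               "D1,verification,,1,sponging,Labridae,,10,false"), path)
  expect_error(read_observations(path), "UNKNOWN")

  # transect rows need a transect id
  writeLines(c("dive_id,site_kind,transect_id,replicate,mode,family,species,length_cm,identified",
               "D1,transect,,1,sponging,Labridae,,10,true"), path)
  expect_error(read_observations(path), "transect_id")
})

test_that("a fully specified row reads back with its fields", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dive_id,site_kind,transect_id,replicate,mode,family,species,length_cm,identified",
               "D7,verification,,1,sponging,Pinguipedidae,Parapercis nebulosa,12.6,true"),
             path)
  obs <- read_observations(path)
  expect_equal(nrow(obs), 1)
  expect_equal(obs$family, "Pinguipedidae")
  expect_equal(obs$species, "Parapercis nebulosa")
  expect_equal(obs$length_cm, 12.6)
  expect_true(obs$identified)
})

test_that("family annotations merge duplicates and reject conflicts", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("family,has_swimbladder,evidence",
               "Pinguipedidae,N,dissected",
               "Labridae,Y,dissected"), path)
  u <- read_family_annotations(path)
  expect_s3_class(u, "family_universe")
  expect_equal(nrow(u), 2)
  expect_equal(sum(!u$has_swimbladder), 1)

  # two species sharing a family: one record
  writeLines(c("family,has_swimbladder,evidence",
               "Dasyatidae,N,literature",
               "Dasyatidae,N,literature"), path)
  expect_equal(nrow(read_family_annotations(path)), 1)

  writeLines(c("family,has_swimbladder,evidence",
               "Dasyatidae,N,literature",
               "Dasyatidae,Y,literature"), path)
  expect_error(read_family_annotations(path), "conflict")

  writeLines(c("family,has_swimbladder,evidence",
               "Dasyatidae,maybe,literature"), path)
  expect_error(read_family_annotations(path), "unparseable")
})

test_that("filters drop small and unidentified prey, strictly and idempotently", {
  obs <- obs_frame(
    obs_row(family = "Pinguipedidae", length_cm = 12.6),
    obs_row(family = "Labridae", length_cm = 7.0),      # boundary: retained
    obs_row(family = "Labridae", length_cm = 6.9),      # removed
    obs_row(family = "UNKNOWN", length_cm = 3.0, identified = FALSE),
    obs_row(family = "UNKNOWN", identified = FALSE),    # removed by flag alone
    obs_row(family = "Sepiidae"))                       # no length: retained
  out <- apply_filters(obs)
  expect_equal(out$family, c("Pinguipedidae", "Labridae", "Sepiidae"))
  expect_equal(out$length_cm[2], 7.0)
  expect_identical(apply_filters(out), out)  # idempotent
  expect_equal(nrow(apply_filters(obs[0, ])), 0)

  # the two rules commute
  only_len <- apply_filters(obs, filter_config(drop_unidentified = FALSE))
  only_id <- apply_filters(obs, filter_config(min_length_cm = 0))
  both1 <- apply_filters(only_len, filter_config(min_length_cm = 0))
  both2 <- apply_filters(only_id, filter_config(drop_unidentified = FALSE))
  expect_identical(both1, both2)
})

test_that("unidentified small prey leave N-19 retained", {
  keep <- do.call(rbind, lapply(1:115, function(i)
    obs_row(dive_id = paste0("D", i), length_cm = 10)))
  drop <- do.call(rbind, lapply(1:19, function(i)
    obs_row(dive_id = paste0("U", i), family = "UNKNOWN",
            length_cm = 4, identified = FALSE)))
  obs <- validate_observations(rbind(keep, drop))
  expect_equal(nrow(apply_filters(obs)), nrow(obs) - 19)
})

test_that("family rollup counts per cell and rejects UNKNOWN", {
  obs <- obs_frame(
    obs_row(mode = "non_sponging", family = "Labridae",
            species = "Choerodon cephalotes"),
    obs_row(mode = "non_sponging", family = "Labridae",
            species = "Choerodon schoenleinii"),
    obs_row(mode = "sponging", family = "Pinguipedidae"))
  tab <- rollup_to_family(obs)
  expect_equal(sum(tab$count), nrow(obs))
  lab <- tab[tab$family == "Labridae", ]
  expect_equal(nrow(lab), 1)
  expect_equal(lab$count, 2)

  expect_error(rollup_to_family(obs_frame(
    obs_row(family = "UNKNOWN", identified = FALSE))), "UNKNOWN")
  expect_equal(nrow(rollup_to_family(obs[0, ])), 0)
})

test_that("replicate averaging means across passes with zero fill", {
  tab <- abundance_frame(
    cell("Pinguipedidae", "sponging", "T1", 3, replicate = 1),
    cell("Pinguipedidae", "sponging", "T1", 1, replicate = 2))
  out <- average_replicates(tab)
  expect_equal(out$count, 2.0)
  expect_equal(unique(out$replicate), 1L)

  # family seen only in pass 1 of 2: its absence in pass 2 counts as zero
  tab2 <- abundance_frame(
    cell("Pinguipedidae", "sponging", "T1", 4, replicate = 1),
    cell("Labridae", "sponging", "T1", 2, replicate = 2))
  out2 <- average_replicates(tab2)
  expect_equal(out2$count[out2$family == "Pinguipedidae"], 2.0)
  expect_equal(out2$count[out2$family == "Labridae"], 1.0)

  # single replicate: identity
  tab3 <- abundance_frame(cell("Labridae", "sponging", "T1", 5))
  expect_equal(average_replicates(tab3)$count, 5)

  expect_error(average_replicates(abundance_frame(
    cell("Labridae", "sponging", NA, 1, site_kind = "verification"))),
    "verification")
})

test_that("pooling conserves totals and is order-invariant", {
  cat0 <- make_default_catalog()
  obs <- simulate_study(cat0, study_design(seed = 5))
  retained <- apply_filters(obs)
  tab <- rollup_to_family(retained)

  pooled <- pool_counts(tab, "all_dives")
  expect_equal(sum(pooled$count), nrow(retained))
  tr <- pool_counts(tab, "transects_only")
  expect_equal(sum(tr$count),
               sum(retained$site_kind == "transect"))

  # row-order invariance of rollup + pool
  set.seed(1)
  shuffled <- retained[sample.int(nrow(retained)), , drop = FALSE]
  expect_equal(pool_counts(rollup_to_family(shuffled), "all_dives"), pooled,
               ignore_attr = TRUE)

  expect_equal(nrow(pool_counts(tab[0, ], "all_dives")), 0)
  expect_error(pool_counts(average_replicates(
    tab[tab$site_kind == "transect", ]), "all_dives"), "integer")
})
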