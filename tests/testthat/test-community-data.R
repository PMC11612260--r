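test_that("read_occurrences validates, reports bad codes and aggregates duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  toy_occurrence_csv(path)
  rec <- read_occurrences(path)
  expect_equal(nrow(rec), 3)
  expect_named(rec, c("site_id", "taxon_id", "abundance", "year",
                      "ecoregion", "vegetation"))

  # unknown ecoregion is a hard error naming the offending code
  toy_occurrence_csv(path, "s3,baetis,2,2011,LHX,bulrush")
  expect_error(read_occurrences(path), "LHX")

  # duplicated (site, taxon, year) rows: abundances sum (2 + 40 = 42)
  toy_occurrence_csv(path, "s1,chironomus,40,2011,LHW,bulrush")
  rec <- read_occurrences(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$abundance[rec$site_id == "s1" & rec$taxon_id == "chironomus"],
               17 + 40)

  # missing required column
  writeLines(c("site_id,taxon_id,abundance", "s1,x,1"), path)
  expect_error(read_occurrences(path), "missing required column")

  # column mapping renames work
  writeLines(c("Station,Taxon,Count,Yr,Region,Zone",
               "s1,x,4,2012,LS,lily"), path)
  rec <- read_occurrences(path, mapping = list(
    site_id = "Station", taxon_id = "Taxon", abundance = "Count",
    year = "Yr", ecoregion = "Region", vegetation = "Zone"))
  expect_equal(rec$taxon_id, "x")
})

test_that("binarize maps positive abundance to presence and rejects negatives", {
  expect_equal(binarize(c(0, 1, 250)), c(0L, 1L, 1L))
  expect_equal(binarize(17), 1L)
  expect_equal(binarize(0), 0L)
  expect_error(binarize(c(1, -2)), "negative")
  df <- data.frame(abundance = c(0, 3))
  expect_equal(binarize(df)$abundance, c(0L, 1L))
})

test_that("partition_matrices builds one matrix per stratum and excludes unattributed taxa", {
  rec <- expand.grid(site_id = c("a", "b"), taxon_id = c("t1", "t2", "t3"),
                     year = c(2000L, 2001L), stringsAsFactors = FALSE)
  rec$abundance <- 1
  rec$ecoregion <- "LMN"
  rec$vegetation <- "bulrush"
  att <- data.frame(taxon_id = c("t1", "t2", "t3"),
                    ffg = c("collector", "predator", NA),
                    stringsAsFactors = FALSE)
  mats <- partition_matrices(rec, att, unit_type = "trophic")
  # 2 years x 1 ecoregion x 1 zone x 2 attributed FFGs
  expect_length(mats, 4)
  expect_equal(attr(mats, "excluded"), "t3")
  expect_true(all(vapply(mats, inherits, logical(1), "community_matrix")))

  # occurrences are conserved: total presences across matrices equals the
  # number of distinct presence records with the attribute defined
  total_cells <- sum(vapply(mats, sum, numeric(1)))
  expect_equal(total_cells, sum(rec$taxon_id %in% c("t1", "t2")))

  expect_error(partition_matrices(rec, data.frame(taxon_id = "t1")),
               "lacks the ffg column")
})

test_that("partition count matches the synthetic generator's declared strata", {
  study <- generate_study(study_plan(n_null = 4, n_segregated = 2,
                                     env_shift = 3), seed = 11)
  mats <- partition_matrices(study$occurrences, study$attributes, "trophic")
  expect_length(mats, nrow(study$plan))
  expect_setequal(names(mats), vapply(study$truth, `[[`, character(1), "key"))
})

test_that("clean_degenerate removes zero margins, flags empties, and is idempotent", {
  m <- community_matrix(rbind(a = c(1, 0, 1), b = c(0, 0, 0), c = c(1, 1, 0)))
  cl <- clean_degenerate(m)
  expect_equal(rownames(cl), c("a", "c"))
  expect_match(paste(attr(cl, "log"), collapse = " "), "b")
  expect_identical(clean_degenerate(cl), cl)  # idempotent / identity

  # zero column removed, label order preserved
  m2 <- community_matrix(rbind(a = c(1, 0, 1), b = c(1, 0, 0)))
  cl2 <- clean_degenerate(m2)
  expect_equal(dim(cl2), c(2L, 2L))
  expect_equal(rownames(cl2), c("a", "b"))

  # all-zero matrix becomes unusable
  z <- clean_degenerate(community_matrix(matrix(0, 2, 2)))
  expect_true(attr(z, "unusable"))

  # discard mode flags instead of repairing
  d <- clean_degenerate(m, action = "discard")
  expect_true(attr(d, "unusable"))
  expect_equal(dim(d), dim(m))
})

test_that("filter_size keeps matrices at or above 5 taxa x 4 sites", {
  expect_true(filter_size(community_matrix(matrix(1, 5, 4))))
  expect_false(filter_size(community_matrix(matrix(1, 4, 10))))
  expect_true(filter_size(community_matrix(matrix(1, 66, 24))))
  dropped <- filter_size(community_matrix(matrix(1, 3, 3)))
  expect_match(attr(dropped, "reason"), "below")
})

test_that("community matrices round-trip through TSV + sidecar exactly", {
  set.seed(5)
  m <- community_matrix(random_binary_matrix(6, 5),
                        taxa = paste0("tax", 1:6), sites = paste0("site", 1:5),
                        key = stratum_key(2011, "LHW", "bulrush", "trophic",
                                          "predator"))
  attr(m, "log") <- "note"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_community_matrix(m, path)
  back <- read_community_matrix(path)
  expect_identical(matrix(as.integer(back), nrow(back)),
                   matrix(as.integer(m), nrow(m)))
  expect_identical(dimnames(back), dimnames(m))
  expect_equal(format(attr(back, "key")), format(attr(m, "key")))
  expect_equal(attr(back, "log"), "note")
})

test_that("constructor rejects non-binary cells and duplicate labels", {
  expect_error(community_matrix(matrix(c(0, 2), 1, 2)), "0/1")
  expect_error(community_matrix(matrix(0:1, 2, 2,
                                       dimnames = list(c("a", "a"), NULL))),
               "duplicated taxon")
})
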