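test_that("Gale-Ryser feasibility and fixed-marginal sampling", {
  expect_true(gale_ryser_feasible(c(2, 1, 1), c(2, 1, 1)))
  bad <- gale_ryser_feasible(c(3, 2), c(2, 2, 2))
  expect_false(as.logical(bad))
  expect_match(attr(bad, "reason"), "row sum")
  expect_error(random_fixed_marginal_matrix(c(3, 2), c(2, 2, 2)),
               "infeasible")
  # equal sums but dominance violated: col total 3 forces 3 distinct rows
  dom <- gale_ryser_feasible(c(2, 2, 0), c(3, 1))
  expect_false(as.logical(dom))
  expect_match(attr(dom, "reason"), "dominance")

  set.seed(61)
  m <- random_fixed_marginal_matrix(c(2, 1, 1), c(2, 1, 1))
  expect_equal(unname(rowSums(m)), c(2, 1, 1))
  expect_equal(unname(colSums(m)), c(2, 1, 1))

  # heterogeneous larger case
  set.seed(62)
  base <- random_binary_matrix(8, 7, 0.4)
  m <- random_fixed_marginal_matrix(rowSums(base), colSums(base))
  expect_equal(unname(rowSums(m)), unname(rowSums(base)))
  expect_equal(unname(colSums(m)), unname(colSums(base)))
})

test_that("the swap sampler reaches every matrix in a small marginal class", {
  # oracle: enumerate all 3x3 binary matrices with the target marginals
  target_r <- c(2, 1, 1)
  target_c <- c(2, 1, 1)
  all_mats <- list()
  for (code in 0:511) {
    m <- matrix(as.integer(intToBits(code)[1:9]), 3, 3)
    if (all(rowSums(m) == target_r) && all(colSums(m) == target_c))
      all_mats[[length(all_mats) + 1]] <- m
  }
  keys <- vapply(all_mats, function(m) paste(m, collapse = ""), character(1))
  expect_gt(length(keys), 1)

  set.seed(63)
  draws <- replicate(3000, paste(
    random_fixed_marginal_matrix(target_r, target_c, n_shuffle = 50),
    collapse = ""))
  tab <- table(factor(draws, levels = keys))
  # every enumerable matrix appears, roughly uniformly (generous band for
  # the known sequential-swap bias)
  expect_true(all(tab > 0))
  expect_lt(max(tab) / min(tab), 2.5)
})

test_that("planted pairs are exactly disjoint and recorded in metadata", {
  set.seed(64)
  m <- plant_segregation(4, 4, 1, fill = 0.5)
  pairs <- attr(m, "planted_pairs")
  expect_equal(nrow(pairs), 1)
  a <- m[pairs$taxon_a[1], ]
  b <- m[pairs$taxon_b[1], ]
  expect_equal(sum(a * b), 0)          # shared-site count 0
  expect_equal(sum(a) * sum(b), 4)     # CU = 2 x 2 for a 4-site even split

  for (i in 1:10) {
    m <- plant_segregation(12, 10, sample(1:5, 1))
    pairs <- attr(m, "planted_pairs")
    for (k in seq_len(nrow(pairs)))
      expect_equal(sum(m[pairs$taxon_a[k], ] * m[pairs$taxon_b[k], ]), 0)
    expect_true(all(colSums(m) > 0))
    expect_true(all(rowSums(m) > 0))
  }
  expect_error(plant_segregation(4, 4, 3), "at most")

  # leakage softens exclusivity
  set.seed(65)
  m <- plant_segregation(2, 20, 1, leakage = 0.5)
  pairs <- attr(m, "planted_pairs")
  expect_gt(sum(m[pairs$taxon_a[1], ] * m[pairs$taxon_b[1], ]), 0)
})

test_that("generate_env shifts focal sites and warns on an empty focal set", {
  set.seed(66)
  sites <- paste0("s", 1:40)
  X <- generate_env(sites, n_vars = 4, focal_sites = c("s1", "s2"), shift = 5)
  expect_equal(dim(X), c(40, 4))
  expect_true(all(colnames(X) %in% coocnull:::ENV_VARIABLES))
  # focal rows are shifted by +5 standardized units in expectation
  expect_gt(mean(X[1:2, ]) - mean(X[-(1:2), ]), 3)
  expect_warning(generate_env(sites, shift = 2), "no focal sites")
})

test_that("generate_tolerances produces similar or separated score sets", {
  set.seed(67)
  sim <- generate_tolerances(paste0("t", 1:10), "similar")
  expect_true(all(sim$tolerance >= 4 & sim$tolerance <= 6))
  sep <- generate_tolerances(paste0("t", 1:10), "separated",
                             focal_taxa = "t1")
  gap <- abs(sep$tolerance[1] - sep$tolerance[-1])
  expect_true(all(gap >= 3))
})

test_that("generate_study is reproducible and its truth sidecar is verifiable", {
  plan <- study_plan(n_null = 2, n_segregated = 2, env_shift = 3)
  s1 <- generate_study(plan, seed = 68)
  s2 <- generate_study(plan, seed = 68)
  expect_identical(s1$occurrences, s2$occurrences)
  expect_identical(s1$environment, s2$environment)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(s1, d1)
  write_study(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }

  # truth matches the generated data: planted pairs never co-occur
  mats <- partition_matrices(s1$occurrences, s1$attributes, "trophic")
  for (tr in s1$truth) {
    m <- mats[[tr$key]]
    if (tr$n_segregated_pairs > 0) {
      for (k in seq_len(nrow(tr$planted_pairs))) {
        a <- tr$planted_pairs$taxon_a[k]
        b <- tr$planted_pairs$taxon_b[k]
        expect_equal(sum(m[a, ] * m[b, ]), 0)
      }
    }
    # the planted driver's focal sites are exactly its presence sites
    if (!is.na(tr$planted_driver))
      expect_setequal(tr$focal_sites, colnames(m)[m[tr$planted_driver, ] == 1])
  }
})
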