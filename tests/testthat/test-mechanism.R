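test_that("driver taxa are flagged by checkerboard-unit z-score", {
  fake_cb <- function(sums) {
    structure(list(per_taxon = data.frame(
      taxon = paste0("t", seq_along(sums)), cu_sum = sums,
      cu_mean = sums, stringsAsFactors = FALSE),
      pairs = data.frame(), c_score = mean(sums)),
      class = "checkerboard_units")
  }
  # equal contributions: no outlier exists
  expect_length(flag_driver_taxa(fake_cb(rep(4, 6))), 0)
  # all-zero CU table (full-overlap matrix)
  expect_length(flag_driver_taxa(fake_cb(rep(0, 5))), 0)
  expect_length(flag_driver_taxa(checkerboard_units(matrix(1, 4, 4))), 0)
  # one outlier among nine: z computed by hand must exceed 2
  sums <- c(rep(1, 8), 40)
  z_hand <- (40 - mean(sums)) / sd(sums)
  expect_gt(z_hand, 2)
  hits <- flag_driver_taxa(fake_cb(sums))
  expect_equal(as.character(hits), "t9")
  expect_null(attr(hits, "below_threshold"))
  # nobody above threshold but contributions unequal: max with a flag
  hits <- flag_driver_taxa(fake_cb(c(1, 2, 3, 4)))
  expect_equal(as.character(hits), "t4")
  expect_true(attr(hits, "below_threshold"))
})

test_that("tolerance separation applies the gap rule and propagates unknowns", {
  tol <- c(d = 8, p1 = 7, p2 = 8, p3 = 9)
  expect_equal(as.character(
    tolerance_separation("d", c("p1", "p2", "p3"), tol)), "similar")
  tol <- c(d = 1, p1 = 8, p2 = 9)
  call <- tolerance_separation("d", c("p1", "p2"), tol)
  expect_equal(as.character(call), "differential")
  expect_equal(sort(attr(call, "gaps")$gap), c(7, 8))
  # majority unscored -> unknown
  tol <- c(d = 1, p1 = NA, p2 = NA)
  expect_equal(as.character(tolerance_separation("d", c("p1", "p2"), tol)),
               "unknown")
  # data.frame input form; gap 2 is below the default threshold of 3
  df <- data.frame(taxon_id = c("d", "p1"), tolerance = c(4, 6))
  expect_equal(as.character(tolerance_separation("d", "p1", df)), "similar")
})

test_that("environmental PCA matches an eigendecomposition oracle", {
  set.seed(31)
  X <- matrix(rnorm(24), 6, 4,
              dimnames = list(paste0("s", 1:6), c("do", "temp", "pH", "cond")))
  pca <- pca_environment(X, n_components = 3)
  ev <- eigen(cor(X))
  expect_equal(pca$sdev, sqrt(ev$values[1:3]), tolerance = 1e-10)
  expect_equal(pca$proportion_variance, ev$values[1:3] / 4, tolerance = 1e-10)
  for (j in 1:3) {
    expect_equal(abs(unname(pca$loadings[, j])), abs(ev$vectors[, j]),
                 tolerance = 1e-8)  # equal up to sign
    # sign convention: dominant loading positive
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
  }
  # scores are centered and consistent with standardized data x loadings
  expect_equal(colMeans(pca$scores), rep(0, 3), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(unname(pca$scores), unname(scale(X) %*% pca$loadings),
               tolerance = 1e-10)
})

test_that("PCA handles rank deficiency and constant variables", {
  set.seed(32)
  v <- rnorm(6)
  X <- cbind(a = v, b = 2 * v, c = -v + 0, d = 3 * v)
  expect_warning(pca <- pca_environment(X), "non-degenerate")
  expect_equal(ncol(pca$loadings), 1)
  expect_equal(pca$proportion_variance, 1, tolerance = 1e-10)

  Y <- cbind(a = rnorm(6), b = rnorm(6), d = rnorm(6), e = rnorm(6),
             c = rep(2, 6))
  expect_warning(pca <- pca_environment(Y), "dropping variable")
  expect_false("c" %in% rownames(pca$loadings))
  expect_equal(pca$variables_dropped, "c")
})

test_that("PERMANOVA agrees with the exhaustive enumeration oracle", {
  x <- matrix(c(1.0, 1.5, 2.0, 5.0, 5.5, 6.0), ncol = 1)
  g <- rep(c("A", "B"), each = 3)
  # oracle: enumerate all C(6,3) = 20 assignments from first principles
  fs <- apply(combn(6, 3), 2, function(idx) {
    gg <- rep("B", 6); gg[idx] <- "A"
    oracle_pseudo_f(x, gg)
  })
  f_obs <- oracle_pseudo_f(x, g)
  p_oracle <- mean(fs >= f_obs - 1e-12)
  fit <- permanova(x, g, n_permutations = 999)
  expect_true(fit$exact)
  expect_equal(fit$n_permutations, 20)
  expect_equal(fit$pseudo_f, f_obs, tolerance = 1e-12)
  expect_equal(fit$p, p_oracle, tolerance = 1e-12)
  expect_equal(fit$p, 0.1)  # the two extreme assignments out of 20

  # invariant to which group is called "present" and to adding a constant
  fit2 <- permanova(x, rev(g), n_permutations = 999)
  expect_equal(fit2$pseudo_f, fit$pseudo_f)
  expect_equal(fit2$p, fit$p)
  fit3 <- permanova(x + 100, g, n_permutations = 999)
  expect_equal(fit3$pseudo_f, fit$pseudo_f)
  expect_equal(fit3$p, fit$p)

  # degenerate inputs
  expect_error(permanova(x, rep("A", 6)), "two levels")
  ident <- permanova(matrix(1, 6, 2), g)
  expect_true(ident$indeterminate)
  # singleton group allowed but flagged
  fit4 <- permanova(x, c("A", rep("B", 5)), n_permutations = 999)
  expect_true(fit4$low_power)
  expect_true(is.finite(fit4$pseudo_f))
})

test_that("PERMANOVA pseudo-F matches vegan::adonis2 on Euclidean distance", {
  skip_if_not_installed("vegan")
  set.seed(33)
  X <- matrix(rnorm(30), 10, 3)
  g <- rep(c("A", "B"), each = 5)
  fit <- permanova(X, g, n_permutations = 199)
  ad <- vegan::adonis2(dist(X) ~ g, permutations = 99)
  expect_equal(fit$pseudo_f, ad$F[1], tolerance = 1e-10)
})

test_that("the mechanism decision table is exhaustive and respects the tree", {
  expected <- function(cls, tol, hab) {
    if (cls == "random") return("neutral")
    if (cls == "negative") {
      if (tol == "differential") return("differential_tolerance")
      if (hab == "different") return("differential_habitat")
      if (tol == "similar" && hab == "homogeneous")
        return("competitive_exclusion")
      return("indeterminate")
    }
    # positive
    if (hab == "homogeneous") return("shared_habitat")
    if (tol == "similar") return("shared_tolerance")
    if (hab == "different") return("biological_homogenization")
    "indeterminate"
  }
  neg_set <- c("competitive_exclusion", "differential_tolerance",
               "differential_habitat", "indeterminate")
  pos_set <- c("shared_habitat", "shared_tolerance",
               "biological_homogenization", "indeterminate")
  for (cls in c("negative", "positive", "random")) {
    for (tol in c("similar", "differential", "unknown")) {
      for (hab in c("homogeneous", "different", "unknown")) {
        v <- decide_mechanism(cls, tol, hab)
        expect_equal(v$verdict, expected(cls, tol, hab),
                     label = paste(cls, tol, hab))
        # verdict vocabulary constrained by classification
        if (cls == "random") expect_equal(v$verdict, "neutral")
        if (cls == "negative") expect_true(v$verdict %in% neg_set)
        if (cls == "positive") expect_true(v$verdict %in% pos_set)
        # purity: repeated evaluation gives the same answer
        expect_identical(decide_mechanism(cls, tol, hab)$verdict, v$verdict)
      }
    }
  }
  expect_equal(decide_mechanism("unusable", "unknown", "unknown")$verdict,
               "neutral")
})

test_that("mechanism_test wires drivers, tolerance, and habitat together", {
  set.seed(41)
  # filler taxa make the planted taxa stand out as checkerboard drivers
  m <- plant_segregation(12, 10, 3)
  fit <- cscore_test(m, n_iter = 500, seed = 14)
  expect_equal(fit$classification, "negative")
  tol <- generate_tolerances(rownames(m), "similar")
  top <- fit$checkerboard$per_taxon$taxon[
    which.max(fit$checkerboard$per_taxon$cu_sum)]
  drv_sites <- colnames(m)[m[top, ] == 1]

  # homogeneous environment + similar tolerances -> competitive exclusion
  env0 <- generate_env(colnames(m), shift = 0)
  mech0 <- mechanism_test(fit, tol, env0, seed = 15)
  r0 <- Filter(function(r) r$driver == top, mech0$results)[[1]]
  expect_equal(r0$tolerance_call, "similar")

  # strong shift at the driver's sites -> differential habitat
  env1 <- generate_env(colnames(m), focal_sites = drv_sites, shift = 8)
  mech1 <- mechanism_test(fit, tol, env1, seed = 16)
  r1 <- Filter(function(r) r$driver == top, mech1$results)[[1]]
  expect_equal(r1$habitat_call, "different")
  expect_equal(r1$verdict$verdict, "differential_habitat")

  # no environment -> unknown habitat call
  mech2 <- mechanism_test(fit, tol, env = NULL)
  expect_true(all(vapply(mech2$results, function(r) r$habitat_call,
                         character(1)) == "unknown"))

  # random matrices are neutral without further computation
  set.seed(42)
  rfit <- cscore_test(random_binary_matrix(6, 6), n_iter = 300, seed = 17)
  if (rfit$classification == "random") {
    mech3 <- mechanism_test(rfit)
    expect_equal(mech3$results[[1]]$verdict$verdict, "neutral")
  }
})
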