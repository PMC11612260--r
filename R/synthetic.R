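#' Check feasibility of binary-matrix marginals
#'
#' The Gale-Ryser condition: with row totals sorted in decreasing order,
#' marginals are achievable by some 0/1 matrix iff the row and column sums
#' agree and for every k, \eqn{\sum_{i \le k} r_i \le \sum_j \min(c_j, k)}.
#'
#' @param row_totals,col_totals non-negative integer vectors.
#' @return `TRUE`, or `FALSE` with attribute `reason`.
#' @export
gale_ryser_feasible <- function(row_totals, col_totals) {
  r <- as.integer(row_totals)
  cc <- as.integer(col_totals)
  fail <- function(reason) structure(FALSE, reason = reason)
  if (any(r < 0) || any(cc < 0)) return(fail("negative totals"))
  if (any(r > length(cc)))
    return(fail("a row total exceeds the number of columns"))
  if (any(cc > length(r)))
    return(fail("a column total exceeds the number of rows"))
  if (sum(r) != sum(cc))
    return(fail(sprintf("row sum %d != column sum %d", sum(r), sum(cc))))
  rs <- sort(r, decreasing = TRUE)
  for (k in seq_along(rs)) {
    if (sum(rs[seq_len(k)]) > sum(pmin(cc, k)))
      return(fail(sprintf("dominance condition violated at k = %d", k)))
  }
  TRUE
}

#' Sample a random binary matrix with fixed marginals
#'
#' Builds a canonical feasible matrix for the requested row and column
#' totals (greedy Gale-Ryser construction) and randomizes it with a long
#' sequential-swap chain. The sequential swap has a small known sampling
#' bias over the fixed-marginal class; for the calibration and testing
#' purposes of this generator that bias is acceptable.
#'
#' @param row_totals,col_totals target marginals (must be feasible).
#' @param n_shuffle successful swaps to apply; default
#'   `max(1000, 10 * R * C)`.
#' @return a [community_matrix()] with exactly the requested totals.
#' @export
random_fixed_marginal_matrix <- function(row_totals, col_totals,
                                         n_shuffle = NULL) {
  ok <- gale_ryser_feasible(row_totals, col_totals)
  if (!ok) stop("infeasible marginals: ", attr(ok, "reason"))
  R <- length(row_totals)
  C <- length(col_totals)
  m <- matrix(0L, R, C)
  resid <- as.integer(col_totals)
  for (i in order(row_totals, decreasing = TRUE)) {
    k <- row_totals[i]
    if (k > 0) {
      cols <- order(resid, decreasing = TRUE)[seq_len(k)]
      m[i, cols] <- 1L
      resid[cols] <- resid[cols] - 1L
    }
  }
  stopifnot(all(resid == 0))
  if (is.null(n_shuffle)) n_shuffle <- max(1000L, 10L * R * C)
  if (cpp_has_swap(m) && n_shuffle > 0) m <- cpp_swap_shuffle(m, n_shuffle)
  community_matrix(m)
}

#' Generate a community matrix with planted segregated pairs
#'
#' One random bipartition of the sites is drawn per matrix and every
#' planted pair straddles it: the first member occupies one side, the
#' second the other, so each planted pair has shared-site count 0. A
#' common bipartition (rather than an independent split per pair) models a
#' two-assemblage checkerboard and carries the strongest segregation
#' signal: independent per-pair splits add random cross-pair structure
#' that largely cancels the planted signal under the fixed-fixed null.
#' Remaining taxa are filled independently at probability `fill`. A
#' `leakage` probability softens the pattern by letting the second member
#' of a pair co-occur at some of its partner's sites.
#'
#' @param n_taxa,n_sites matrix dimensions.
#' @param n_pairs number of planted mutually exclusive pairs
#'   (`<= n_taxa / 2`).
#' @param fill presence probability for unplanted taxa (default 0.5).
#' @param leakage per-site probability that a planted exclusion is violated
#'   (default 0, exact disjointness).
#' @return a [community_matrix()] with attribute `planted_pairs`
#'   (data.frame `taxon_a`, `taxon_b`).
#' @export
plant_segregation <- function(n_taxa, n_sites, n_pairs, fill = 0.5,
                              leakage = 0) {
  if (n_pairs > floor(n_taxa / 2))
    stop("n_pairs must be at most n_taxa / 2")
  taxa <- sprintf("taxon_%02d", seq_len(n_taxa))
  sites <- sprintf("site_%02d", seq_len(n_sites))
  m <- matrix(0L, n_taxa, n_sites, dimnames = list(taxa, sites))
  half <- floor(n_sites / 2)
  perm <- sample.int(n_sites)  # one bipartition shared by all pairs
  side_a <- perm[seq_len(half)]
  side_b <- perm[(half + 1):n_sites]
  pairs <- data.frame(taxon_a = character(0), taxon_b = character(0),
                      stringsAsFactors = FALSE)
  for (p in seq_len(n_pairs)) {
    ia <- 2L * p - 1L
    ib <- 2L * p
    m[ia, side_a] <- 1L
    m[ib, side_b] <- 1L
    if (leakage > 0) {
      leak <- side_a[runif(half) < leakage]
      m[ib, leak] <- 1L
    }
    pairs <- rbind(pairs, data.frame(taxon_a = taxa[ia], taxon_b = taxa[ib],
                                     stringsAsFactors = FALSE))
  }
  for (i in seq_len(n_taxa)) {
    if (i > 2L * n_pairs) {
      repeat {
        row <- as.integer(runif(n_sites) < fill)
        if (any(row == 1L)) break
      }
      m[i, ] <- row
    }
  }
  # with no planted pairs a site can end up empty; give it one occupant so
  # the matrix is non-degenerate by construction
  empty <- colSums(m) == 0
  if (any(empty))
    m[cbind(sample.int(n_taxa, sum(empty), replace = TRUE), which(empty))] <- 1L
  out <- community_matrix(m)
  attr(out, "planted_pairs") <- pairs
  out
}

#' Generate a synthetic site environmental table
#'
#' Variables are independent standard normals per site; designated focal
#' sites receive a mean shift of `shift` standardized units on every
#' variable. Variable names come from the package's environmental
#' vocabulary.
#'
#' @param sites character vector of site ids.
#' @param n_vars number of variables (at most
#'   `length(ENV_VARIABLES)`).
#' @param focal_sites sites receiving the shift.
#' @param shift mean shift in standardized units (>= 0).
#' @return a numeric matrix, sites x variables.
#' @export
generate_env <- function(sites, n_vars = 6, focal_sites = character(0),
                         shift = 0) {
  stopifnot(shift >= 0, n_vars <= length(ENV_VARIABLES))
  if (shift > 0 && !length(focal_sites))
    warning("shift requested but no focal sites designated")
  X <- matrix(stats::rnorm(length(sites) * n_vars), length(sites), n_vars,
              dimnames = list(sites, ENV_VARIABLES[seq_len(n_vars)]))
  X[sites %in% focal_sites, ] <- X[sites %in% focal_sites, ] + shift
  X
}

#' Generate a synthetic taxon tolerance table
#'
#' `"similar"` draws all scores from a narrow mid-scale band (4-6) so no
#' pair is separated; `"separated"` puts the focal taxa at the sensitive
#' end (0-1) and the rest at the tolerant end (8-10), guaranteeing gaps
#' above the default separation threshold.
#'
#' @param taxa character vector of taxon ids.
#' @param mode `"similar"` or `"separated"`.
#' @param focal_taxa taxa placed at the sensitive end under
#'   `"separated"`.
#' @return data.frame with `taxon_id` and `tolerance`.
#' @export
generate_tolerances <- function(taxa, mode = c("similar", "separated"),
                                focal_taxa = character(0)) {
  mode <- match.arg(mode)
  tol <- if (mode == "similar") {
    stats::runif(length(taxa), 4, 6)
  } else {
    ifelse(taxa %in% focal_taxa, stats::runif(length(taxa), 0, 1),
           stats::runif(length(taxa), 8, 10))
  }
  data.frame(taxon_id = taxa, tolerance = round(tol, 2),
             stringsAsFactors = FALSE)
}

#' Generate a multi-stratum synthetic study
#'
#' Builds long-format occurrence, taxon-attribute and environmental tables
#' for a plan of strata with known planted structure, so the whole pipeline
#' can be exercised end to end against a recorded ground truth. For each
#' planted-segregation stratum with a positive `env_shift`, the shift is
#' applied at the presence sites of the taxon with the highest
#' checkerboard-unit sum (recorded as the planted driver).
#'
#' @param plan a data.frame with one row per stratum and columns `year`,
#'   `ecoregion`, `vegetation`, `ffg`, `n_taxa`, `n_sites`,
#'   `n_segregated_pairs`, `env_shift`, `tolerance_mode`. See
#'   [study_plan()] for a convenient constructor.
#' @param seed integer seed; the whole study is reproducible from it.
#' @return an object of class `synthetic_study`: list with `occurrences`,
#'   `attributes`, `environment` (data.frames), `truth` (per-stratum list
#'   of planted structure and expected mechanism) and `plan`.
#' @export
generate_study <- function(plan, seed = 1) {
  required <- c("year", "ecoregion", "vegetation", "ffg", "n_taxa",
                "n_sites", "n_segregated_pairs", "env_shift",
                "tolerance_mode")
  stopifnot(all(required %in% names(plan)))
  set.seed(seed)
  occ <- list()
  att <- list()
  env <- list()
  truth <- list()
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    sid <- sprintf("S%02d", i)
    m <- plant_segregation(p$n_taxa, p$n_sites, p$n_segregated_pairs)
    rownames(m) <- sprintf("%s_%s", sid, rownames(m))
    colnames(m) <- sprintf("%s_%s", sid, colnames(m))
    pairs <- attr(m, "planted_pairs")
    if (nrow(pairs)) {
      pairs$taxon_a <- sprintf("%s_%s", sid, pairs$taxon_a)
      pairs$taxon_b <- sprintf("%s_%s", sid, pairs$taxon_b)
    }
    driver <- NA_character_
    focal <- character(0)
    if (p$n_segregated_pairs > 0 && p$env_shift > 0) {
      cb <- checkerboard_units(m)
      driver <- cb$per_taxon$taxon[which.max(cb$per_taxon$cu_sum)]
      focal <- colnames(m)[m[driver, ] == 1]
    }
    stratum_env <- generate_env(colnames(m), n_vars = 6,
                                focal_sites = focal, shift = p$env_shift)
    idx <- which(m == 1, arr.ind = TRUE)
    occ[[i]] <- data.frame(
      site_id = colnames(m)[idx[, 2]],
      taxon_id = rownames(m)[idx[, 1]],
      abundance = 1L + stats::rpois(nrow(idx), 5),
      year = p$year, ecoregion = p$ecoregion, vegetation = p$vegetation,
      stringsAsFactors = FALSE)
    tol <- generate_tolerances(rownames(m), mode = p$tolerance_mode,
                               focal_taxa = if (is.na(driver)) character(0) else driver)
    att[[i]] <- data.frame(
      taxon_id = rownames(m),
      family = sprintf("Family_%s", sid),
      ffg = p$ffg,
      tolerance = tol$tolerance,
      overwinters = stats::runif(nrow(m)) < 0.5,
      stringsAsFactors = FALSE)
    env[[i]] <- data.frame(site_id = rownames(stratum_env), year = p$year,
                           as.data.frame(stratum_env),
                           stringsAsFactors = FALSE, check.names = FALSE)
    truth[[i]] <- list(
      key = paste(p$year, p$ecoregion, p$vegetation, "trophic", p$ffg,
                  sep = "|"),
      n_segregated_pairs = p$n_segregated_pairs,
      planted_pairs = pairs,
      planted_driver = driver,
      focal_sites = focal,
      expected_mechanism = if (p$n_segregated_pairs == 0) "neutral"
        else if (p$env_shift > 0) "differential_habitat"
        else "competitive_exclusion")
  }
  out <- list(occurrences = do.call(rbind, occ),
              attributes = do.call(rbind, att),
              environment = do.call(rbind, env),
              truth = truth, plan = plan, seed = seed)
  rownames(out$occurrences) <- NULL
  rownames(out$attributes) <- NULL
  rownames(out$environment) <- NULL
  class(out) <- "synthetic_study"
  out
}

#' Convenience constructor for a study plan
#'
#' Lays out `n_null` unstructured strata followed by `n_segregated`
#' planted-segregation strata, cycling years, ecoregions, zones and FFGs.
#' The defaults leave unplanted filler taxa in segregated matrices so that
#' the planted taxa stand out as checkerboard drivers (a matrix whose taxa
#' all contribute equally has no identifiable driver).
#'
#' @param n_null number of unstructured strata.
#' @param n_segregated number of planted-segregation strata.
#' @param n_taxa,n_sites matrix dimensions per stratum.
#' @param n_pairs planted pairs per segregated stratum.
#' @param env_shift standardized environmental shift for segregated strata.
#' @param tolerance_mode passed to [generate_tolerances()].
#' @return a plan data.frame for [generate_study()].
#' @export
study_plan <- function(n_null = 10, n_segregated = 0, n_taxa = 12,
                       n_sites = 10, n_pairs = 4, env_shift = 0,
                       tolerance_mode = "similar") {
  n <- n_null + n_segregated
  stopifnot(n > 0)
  data.frame(
    year = 2000L + (seq_len(n) - 1L) %% 9L,
    ecoregion = ECOREGIONS[(seq_len(n) - 1L) %% length(ECOREGIONS) + 1L],
    vegetation = VEGETATION_ZONES[(seq_len(n) - 1L) %% 2L + 1L],
    ffg = FFG_LEVELS[(seq_len(n) - 1L) %% 4L + 1L],
    n_taxa = n_taxa, n_sites = n_sites,
    n_segregated_pairs = rep(c(0L, n_pairs), c(n_null, n_segregated)),
    env_shift = rep(c(0, env_shift), c(n_null, n_segregated)),
    tolerance_mode = tolerance_mode,
    stringsAsFactors = FALSE)
}

#' Write a synthetic study to disk
#'
#' Emits `occurrences.csv`, `attributes.csv`, `environment.csv` and a
#' `truth.json` sidecar in `dir` — the same formats the reading functions
#' consume. Output is byte-identical for a given study object.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$occurrences, file.path(dir, "occurrences.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(study$attributes, file.path(dir, "attributes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(study$environment, file.path(dir, "environment.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
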