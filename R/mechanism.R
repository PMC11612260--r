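#' Flag driver taxa by checkerboard-unit contribution
#'
#' In a segregated matrix, one taxon often carries far more checkerboard
#' units than the rest (typically present only at sites where most other
#' taxa are absent). Driver taxa are those whose per-taxon CU sum has a
#' z-score above `z_threshold` relative to the matrix's per-taxon
#' distribution. When no taxon exceeds the threshold the single maximum
#' contributor is returned with attribute `below_threshold = TRUE`, unless
#' all contributions are equal (no outlier exists), in which case the
#' result is empty.
#'
#' @param cb a [checkerboard_units()] object.
#' @param z_threshold z-score cutoff (default 2).
#' @return character vector of driver taxa (possibly empty), with
#'   attribute `z` holding all z-scores.
#' @export
flag_driver_taxa <- function(cb, z_threshold = 2.0) {
  stopifnot(inherits(cb, "checkerboard_units"))
  sums <- cb$per_taxon$cu_sum
  taxa <- cb$per_taxon$taxon
  if (all(sums == 0)) return(character(0))
  s <- stats::sd(sums)
  if (!is.finite(s) || s == 0) return(character(0))  # all equal: no outlier
  z <- (sums - mean(sums)) / s
  names(z) <- taxa
  hits <- taxa[z > z_threshold]
  if (!length(hits)) {
    hits <- taxa[which.max(sums)]
    attr(hits, "below_threshold") <- TRUE
  }
  attr(hits, "z") <- z
  hits
}

#' Compare pollution tolerances between a driver taxon and its partners
#'
#' Operationalizes the tolerance step of the decision tree on the 0-10
#' Hilsenhoff scale: the call is `"differential"` when the absolute
#' tolerance gap between the driver and a partner reaches `gap_threshold`
#' for the majority of scored driver-partner pairs, `"similar"` otherwise,
#' and `"unknown"` when more than half of the involved taxa lack scores (or
#' no pair is scored). The raw gaps are attached so users can re-judge.
#'
#' @param driver_taxa,partner_taxa character vectors of taxon ids.
#' @param tolerances a data.frame with `taxon_id` and `tolerance` columns,
#'   or a named numeric vector of scores.
#' @param gap_threshold gap (in score units) counted as separation
#'   (default 3).
#' @return `"similar"`, `"differential"` or `"unknown"`, with attribute
#'   `gaps` (data.frame of driver, partner, gap).
#' @export
tolerance_separation <- function(driver_taxa, partner_taxa, tolerances,
                                 gap_threshold = 3.0) {
  tol <- if (is.data.frame(tolerances)) {
    stats::setNames(tolerances$tolerance, tolerances$taxon_id)
  } else tolerances
  involved <- unique(c(driver_taxa, partner_taxa))
  scored <- !is.na(tol[involved])
  pairs <- expand.grid(driver = driver_taxa, partner = partner_taxa,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$driver != pairs$partner, , drop = FALSE]
  pairs$gap <- abs(tol[pairs$driver] - tol[pairs$partner])
  call <- if (mean(scored) < 0.5 || !any(!is.na(pairs$gap))) {
    "unknown"
  } else if (mean(pairs$gap >= gap_threshold, na.rm = TRUE) > 0.5) {
    "differential"
  } else "similar"
  attr(call, "gaps") <- pairs
  call
}

#' Reduce site environmental data to principal components
#'
#' Standardizes each variable to zero mean and unit variance and performs a
#' PCA (via [stats::prcomp()], i.e. the correlation structure). Variables
#' with any missing value are dropped (complete-case by variable, so the
#' variable set is data-driven per matrix), as are constant variables. At
#' most `n_components` components are kept, fewer when the data have lower
#' rank. Sign convention: the largest-magnitude loading of each component
#' is positive.
#'
#' @param env a numeric matrix or data.frame, sites in rows (rownames are
#'   site ids), environmental variables in columns.
#' @param n_components components to retain (default 3).
#' @return an object of class `pca_environment`: list with `loadings`
#'   (variables x k), `sdev`, `proportion_variance` (fractions of total
#'   standardized variance), `scores` (sites x k), `variables_used`,
#'   `variables_dropped`.
#' @export
pca_environment <- function(env, n_components = 3) {
  X <- as.matrix(env)
  if (is.null(rownames(X))) rownames(X) <- paste0("s", seq_len(nrow(X)))
  storage.mode(X) <- "double"
  has_na <- apply(X, 2, function(v) any(!is.finite(v)))
  constant <- apply(X, 2, function(v) isTRUE(stats::sd(v[is.finite(v)]) == 0))
  drop <- has_na | constant
  if (any(drop))
    warning("dropping variable(s): ",
            paste(colnames(X)[drop], collapse = ", "))
  X <- X[, !drop, drop = FALSE]
  if (ncol(X) < 2) stop("fewer than 2 usable environmental variables")
  if (nrow(X) < 3) stop("PCA needs at least 3 sites")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  positive <- pc$sdev > max(pc$sdev) * 1e-8
  k <- min(n_components, sum(positive))
  if (k < n_components)
    warning("only ", k, " non-degenerate component(s) available")
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(loadings = load, sdev = pc$sdev[seq_len(k)],
                 proportion_variance = pc$sdev[seq_len(k)]^2 / ncol(X),
                 scores = scores,
                 variables_used = colnames(X),
                 variables_dropped = colnames(as.matrix(env))[drop]),
            class = "pca_environment")
}

#' @export
print.pca_environment <- function(x, digits = 4, ...) {
  cat("PCA of", length(x$variables_used), "standardized environmental",
      "variables,", nrow(x$scores), "sites\n")
  tab <- rbind(`Standard deviation` = x$sdev,
               `Proportion of variance` = x$proportion_variance)
  colnames(tab) <- colnames(x$loadings)
  print(round(x$loadings, digits))
  print(round(tab, digits))
  invisible(x)
}

#' One-way PERMANOVA with Euclidean distance
#'
#' Tests whether multivariate site positions (typically principal-component
#' scores) differ between two groups, using the permutational pseudo-F
#' \deqn{F = \frac{SS_{between}/(g-1)}{SS_{within}/(N-g)}}
#' on Euclidean distances. Significance comes from relabelings that
#' preserve group sizes: when the complete enumeration of group assignments
#' is no larger than `n_permutations` it is used exhaustively (exact mode;
#' p = fraction of assignments, the observed one included, with F at least
#' the observed); otherwise `n_permutations` random relabelings with the
#' `(count + 1)/(n + 1)` correction.
#'
#' @param scores numeric matrix (sites x k) or vector.
#' @param grouping logical/factor of length `nrow(scores)` with exactly two
#'   levels; singleton groups are allowed but flagged low-power.
#' @param n_permutations number of random permutations (default 999).
#' @param seed optional integer seed, recorded in the result.
#' @return an object of class `permanova` with `pseudo_f`, `p`,
#'   `n_permutations` (permutations actually used), `exact`, `group_sizes`,
#'   `seed`, and flags `indeterminate` (all points identical) and
#'   `low_power` (singleton group).
#' @export
permanova <- function(scores, grouping, n_permutations = 999, seed = NULL) {
  X <- as.matrix(scores)
  storage.mode(X) <- "double"
  g <- as.factor(grouping)
  if (nlevels(g) != 2) stop("grouping must have exactly two levels")
  if (any(table(g) == 0)) stop("a group is empty")
  n <- nrow(X)
  if (n < 3) stop("PERMANOVA needs at least 3 sites")
  if (length(g) != n) stop("grouping length must match the number of sites")
  if (!is.null(seed)) set.seed(seed)
  sizes <- as.integer(table(g))
  pseudo_f <- function(idx1) {
    in1 <- logical(n)
    in1[idx1] <- TRUE
    ss_within <- 0
    ss_between <- 0
    grand <- colMeans(X)
    for (grp in list(which(in1), which(!in1))) {
      cen <- colMeans(X[grp, , drop = FALSE])
      ss_within <- ss_within +
        sum(sweep(X[grp, , drop = FALSE], 2, cen)^2)
      ss_between <- ss_between + length(grp) * sum((cen - grand)^2)
    }
    (ss_between / 1) / (ss_within / (n - 2))
  }
  total_ss <- sum(sweep(X, 2, colMeans(X))^2)
  if (total_ss <= .Machine$double.eps * n) {
    out <- list(pseudo_f = NA_real_, p = NA_real_,
                n_permutations = 0L, exact = FALSE,
                group_sizes = sizes, seed = seed,
                indeterminate = TRUE, low_power = any(sizes == 1))
    class(out) <- "permanova"
    return(out)
  }
  idx_obs <- which(g == levels(g)[1])
  f_obs <- pseudo_f(idx_obs)
  n1 <- length(idx_obs)
  n_complete <- choose(n, n1)
  if (n_complete <= n_permutations) {
    combos <- utils::combn(n, n1)
    fs <- apply(combos, 2, pseudo_f)
    p <- mean(fs >= f_obs - 1e-12)
    used <- ncol(combos)
    exact <- TRUE
  } else {
    fs <- replicate(n_permutations, pseudo_f(sample.int(n, n1)))
    p <- (sum(fs >= f_obs - 1e-12) + 1) / (n_permutations + 1)
    used <- n_permutations
    exact <- FALSE
  }
  out <- list(pseudo_f = f_obs, p = p, n_permutations = used, exact = exact,
              group_sizes = sizes, seed = seed, indeterminate = FALSE,
              low_power = any(sizes == 1))
  class(out) <- "permanova"
  out
}

#' @export
print.permanova <- function(x, digits = 4, ...) {
  cat("One-way PERMANOVA (Euclidean)\n")
  if (x$indeterminate) {
    cat("  indeterminate: all points identical\n")
    return(invisible(x))
  }
  cat(sprintf("  pseudo-F = %s, p = %.*f (%s, %d %s; groups %s)\n",
              format(x$pseudo_f, digits = digits), digits, x$p,
              if (x$exact) "exact" else "permutation",
              x$n_permutations,
              if (x$exact) "assignments" else "permutations",
              paste(x$group_sizes, collapse = "/")))
  if (x$low_power) cat("  note: singleton group, low power\n")
  invisible(x)
}

#' Decision-tree verdict for a community matrix
#'
#' Pure function implementing the mechanism decision matrix. A random
#' classification is neutral. For negative (segregated) matrices,
#' differential tolerance is checked first, then differential microhabitat,
#' and competitive exclusion is concluded only by elimination when both
#' calls are resolved and show neither. For positive (aggregated) matrices,
#' a homogeneous shared habitat implies shared habitat affinity, similar
#' tolerances imply shared tolerance, and a resolved habitat difference
#' with neither of those implies biological homogenization by elimination;
#' an unresolved habitat call leaves the verdict indeterminate, since
#' elimination needs a resolved call.
#'
#' @param classification `"negative"`, `"positive"`, `"random"` or
#'   `"unusable"` (from [cscore_test()]).
#' @param tolerance_call `"similar"`, `"differential"` or `"unknown"`.
#' @param habitat_call `"homogeneous"`, `"different"` or `"unknown"`.
#' @return an object of class `mechanism_verdict`: list with `verdict` and
#'   the three input calls.
#' @export
decide_mechanism <- function(classification, tolerance_call, habitat_call) {
  classification <- match.arg(classification,
                              c("negative", "positive", "random", "unusable"))
  tolerance_call <- match.arg(tolerance_call,
                              c("similar", "differential", "unknown"))
  habitat_call <- match.arg(habitat_call,
                            c("homogeneous", "different", "unknown"))
  verdict <- if (classification %in% c("random", "unusable")) {
    "neutral"
  } else if (classification == "negative") {
    if (tolerance_call == "differential") "differential_tolerance"
    else if (habitat_call == "different") "differential_habitat"
    else if (tolerance_call == "similar" && habitat_call == "homogeneous")
      "competitive_exclusion"
    else "indeterminate"
  } else {  # positive
    if (habitat_call == "homogeneous") "shared_habitat"
    else if (tolerance_call == "similar") "shared_tolerance"
    else if (habitat_call == "different") "biological_homogenization"
    else "indeterminate"
  }
  structure(list(verdict = verdict, classification = classification,
                 tolerance_call = tolerance_call,
                 habitat_call = habitat_call),
            class = "mechanism_verdict")
}

#' @export
print.mechanism_verdict <- function(x, ...) {
  cat(sprintf("Mechanism verdict: %s (co-occurrence %s, tolerance %s, habitat %s)\n",
              x$verdict, x$classification, x$tolerance_call, x$habitat_call))
  invisible(x)
}

#' Full mechanism inference for one fitted matrix
#'
#' For a non-random [cscore_test()] fit: flags driver taxa, compares
#' pollution tolerances between each driver and its checkerboard partners,
#' reduces the matrix's site environmental data to principal components,
#' tests the driver's presence/absence site grouping by PERMANOVA, and
#' issues a [decide_mechanism()] verdict per driver.
#'
#' @param fit a [cscore_test()] object.
#' @param tolerances taxon tolerance scores (data.frame `taxon_id`,
#'   `tolerance`, or named vector); `NULL` gives an unknown tolerance call.
#' @param env sites x variables environmental data for the matrix's sites
#'   (rownames must be site ids); `NULL` gives an unknown habitat call.
#' @param alpha significance level for the habitat test (default 0.05).
#' @param z_threshold driver-taxon z cutoff.
#' @param gap_threshold tolerance-gap cutoff.
#' @param n_permutations PERMANOVA permutations.
#' @param seed optional seed for the PERMANOVA.
#' @return an object of class `mechanism_test`: list of per-driver results
#'   (driver, partners, tolerance_call, habitat_call, permanova, verdict)
#'   plus `drivers` and `classification`.
#' @export
mechanism_test <- function(fit, tolerances = NULL, env = NULL, alpha = 0.05,
                           z_threshold = 2.0, gap_threshold = 3.0,
                           n_permutations = 999, seed = NULL) {
  stopifnot(inherits(fit, "cscore_test"))
  cls <- fit$classification
  if (cls %in% c("random", "unusable")) {
    out <- list(classification = cls, drivers = character(0),
                results = list(
                  list(driver = NA_character_, partners = character(0),
                       tolerance_call = "unknown", habitat_call = "unknown",
                       permanova = NULL,
                       verdict = decide_mechanism(cls, "unknown", "unknown"))))
    class(out) <- "mechanism_test"
    return(out)
  }
  cb <- fit$checkerboard
  drivers <- flag_driver_taxa(cb, z_threshold = z_threshold)
  m <- fit$matrix
  pca <- NULL
  if (!is.null(env)) {
    env <- as.matrix(env)
    env <- env[intersect(rownames(env), colnames(m)), , drop = FALSE]
    pca <- tryCatch(suppressWarnings(pca_environment(env)),
                    error = function(e) NULL)
  }
  if (!is.null(seed)) set.seed(seed)
  results <- lapply(as.character(drivers), function(d) {
    prs <- cb$pairs[(cb$pairs$taxon_i == d | cb$pairs$taxon_j == d) &
                      cb$pairs$cu > 0, , drop = FALSE]
    partners <- setdiff(unique(c(prs$taxon_i, prs$taxon_j)), d)
    tolerance_call <- if (is.null(tolerances) || !length(partners)) {
      "unknown"
    } else {
      as.character(tolerance_separation(d, partners, tolerances,
                                        gap_threshold = gap_threshold))
    }
    perm <- NULL
    habitat_call <- "unknown"
    if (!is.null(pca)) {
      present <- colnames(m)[m[d, ] == 1]
      grp <- rownames(pca$scores) %in% present
      if (any(grp) && any(!grp)) {
        perm <- tryCatch(permanova(pca$scores, grp,
                                   n_permutations = n_permutations),
                         error = function(e) NULL)
        if (!is.null(perm) && !perm$indeterminate)
          habitat_call <- if (perm$p <= alpha) "different" else "homogeneous"
      }
    }
    list(driver = d, partners = partners, tolerance_call = tolerance_call,
         habitat_call = habitat_call, permanova = perm,
         verdict = decide_mechanism(cls, tolerance_call, habitat_call))
  })
  out <- list(classification = cls, drivers = as.character(drivers),
              results = results, pca = pca)
  class(out) <- "mechanism_test"
  out
}

#' @export
print.mechanism_test <- function(x, ...) {
  cat("Mechanism inference (classification:", x$classification, ")\n")
  for (r in x$results) {
    cat(sprintf("  driver %s: tolerance %s, habitat %s -> %s\n",
                r$driver %||% "-", r$tolerance_call, r$habitat_call,
                r$verdict$verdict))
  }
  invisible(x)
}
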