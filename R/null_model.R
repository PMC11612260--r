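#' One sequential-swap attempt
#'
#' Draws two distinct rows and two distinct columns uniformly at random; if
#' the 2x2 submatrix is a checkerboard (`[[1,0],[0,1]]` or `[[0,1],[1,0]]`)
#' it is flipped to the other form, which conserves all row and column
#' totals. Otherwise the matrix is returned unchanged.
#'
#' @param x a binary matrix with at least 2 rows and 2 columns.
#' @return a list with elements `matrix` and `swapped` (logical).
#' @export
attempt_swap <- function(x) {
  m <- as_cells(community_matrix(x))
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("attempt_swap needs at least a 2x2 matrix")
  rows <- sample.int(nrow(m), 2)
  cols <- sample.int(ncol(m), 2)
  out <- swap_at(m, rows, cols)
  list(matrix = out$matrix, swapped = out$swapped,
       rows = rows, cols = cols)
}

# deterministic flip of the 2x2 submatrix at (rows, cols); applying it
# twice at the same location restores the original matrix
swap_at <- function(m, rows, cols) {
  sub <- m[rows, cols]
  if (sub[1, 1] == sub[2, 2] && sub[1, 2] == sub[2, 1] &&
      sub[1, 1] != sub[1, 2]) {
    m[rows, cols] <- 1L - sub
    list(matrix = m, swapped = TRUE)
  } else {
    list(matrix = m, swapped = FALSE)
  }
}

#' Does the matrix contain any swappable checkerboard submatrix?
#'
#' A matrix with no checkerboard 2x2 submatrix is alone in its fixed-
#' marginal class: the swap chain is frozen and no null distribution can be
#' generated.
#'
#' @inheritParams attempt_swap
#' @return logical.
#' @export
has_swappable <- function(x) {
  cpp_has_swap(as_cells(community_matrix(x)))
}

#' Sample the fixed-fixed null distribution of the C-score
#'
#' Runs the sequential-swap Markov chain from the observed matrix: after
#' `burn_in` successful swaps, one C-score is recorded every `thin`
#' attempted swaps, `n_iter` times. Row and column totals are conserved
#' exactly throughout (the fixed-fixed constraint).
#'
#' @param x a [community_matrix()] or 0/1 matrix.
#' @param n_iter number of null C-scores to sample (default 5000).
#' @param burn_in successful swaps to discard before sampling; default
#'   `max(1000, 10 * nrow * ncol)`.
#' @param thin attempted swaps between retained samples; default
#'   `nrow * ncol`.
#' @return a numeric vector of length `n_iter` with attributes
#'   `acceptance_rate` (accepted/attempted swaps) and `unusable` (`TRUE`
#'   when the chain is frozen, in which case the vector is empty).
#' @export
null_distribution <- function(x, n_iter = 5000, burn_in = NULL, thin = NULL) {
  m <- as_cells(community_matrix(x))
  if (is.null(burn_in)) burn_in <- max(1000L, 10L * nrow(m) * ncol(m))
  if (is.null(thin)) thin <- nrow(m) * ncol(m)
  if (!cpp_has_swap(m))
    return(structure(numeric(0), unusable = TRUE, acceptance_rate = NA_real_))
  res <- cpp_null_cscores(m, as.integer(n_iter), as.integer(burn_in),
                          as.integer(thin))
  structure(res$sims, unusable = FALSE,
            acceptance_rate = res$accepts / res$attempts)
}

#' Standardized effect size
#'
#' \eqn{SES = (obs - mean(sims)) / sd(sims)} with the sample (n-1) standard
#' deviation. Under the null, SES is approximately zero-mean with about 95%
#' of values in (-2, 2); SES > 2 indicates segregation, SES < -2
#' aggregation.
#'
#' @param observed observed index value.
#' @param sims numeric vector of null index values.
#' @return the SES, or `NA` with attribute `undefined = TRUE` when the null
#'   distribution has zero variance.
#' @export
ses <- function(observed, sims) {
  if (!length(sims)) stop("empty null distribution")
  s <- stats::sd(sims)
  if (!is.finite(s) || s == 0)
    return(structure(NA_real_, undefined = TRUE))
  (observed - mean(sims)) / s
}

#' Two-tailed randomization probabilities
#'
#' `p_ge` is the fraction of null values at or above the observed index,
#' `p_le` the fraction at or below; ties count in both tails, so
#' `p_le + p_ge >= 1`. With `correction = "plus_one"` the conservative
#' `(count + 1) / (n + 1)` form is used instead.
#'
#' @inheritParams ses
#' @param correction `"none"` (count/n, the default) or `"plus_one"`.
#' @return a list with `p_le` and `p_ge`.
#' @export
tail_probabilities <- function(observed, sims,
                               correction = c("none", "plus_one")) {
  correction <- match.arg(correction)
  if (!length(sims)) stop("empty null distribution")
  tol <- 1e-9 * max(1, abs(observed))
  n_ge <- sum(sims >= observed - tol)
  n_le <- sum(sims <= observed + tol)
  n <- length(sims)
  if (correction == "plus_one")
    list(p_le = (n_le + 1) / (n + 1), p_ge = (n_ge + 1) / (n + 1))
  else
    list(p_le = n_le / n, p_ge = n_ge / n)
}

#' Classify co-occurrence structure from tail probabilities
#'
#' A matrix is non-random when the observed C-score falls in either 2.5%
#' tail of its null distribution (at the default `alpha = 0.05`). A high
#' C-score (small `p_ge`) means *segregation*, i.e. NEGATIVE co-occurrence;
#' a low C-score (small `p_le`) means aggregation, i.e. POSITIVE
#' co-occurrence. Note the direction: the upper tail of the C-score
#' distribution corresponds to negative association.
#'
#' @param p_le,p_ge tail probabilities from [tail_probabilities()].
#' @param alpha two-tailed significance level (default 0.05).
#' @param unusable set `TRUE` when no null distribution exists.
#' @return one of `"negative"`, `"positive"`, `"random"`, `"unusable"`;
#'   when pathological ties make both tails significant the result is
#'   `"random"` with attribute `ambiguous = TRUE` and a warning.
#' @export
classify_cscore <- function(p_le, p_ge, alpha = 0.05, unusable = FALSE) {
  if (unusable) return("unusable")
  neg <- p_ge <= alpha / 2
  pos <- p_le <= alpha / 2
  if (neg && pos) {
    warning("both tails significant (pathological ties); reported as random")
    return(structure("random", ambiguous = TRUE))
  }
  if (neg) "negative" else if (pos) "positive" else "random"
}

#' Fit a fixed-fixed null model test of the C-score
#'
#' The central fitting function of the package: computes the observed
#' C-score of a binary community matrix, samples its null distribution
#' under fixed row and column totals by sequential swap, and returns the
#' standardized effect size, two-tailed randomization probabilities and a
#' segregation/aggregation classification.
#'
#' @inheritParams null_distribution
#' @param alpha two-tailed significance level (default 0.05).
#' @param seed integer seed recorded in the result; when `NULL` one is
#'   drawn from the current RNG state so the fit is always reproducible
#'   from its record.
#' @param p_correction passed to [tail_probabilities()].
#' @return an object of class `cscore_test` with components `observed_c`,
#'   `sims`, `sim_mean`, `sim_sd`, `ses`, `p_le`, `p_ge`, `classification`,
#'   `n_iterations`, `burn_in`, `thin`, `seed`, `alpha`,
#'   `acceptance_rate`, `checkerboard` (the [checkerboard_units()] table)
#'   and `matrix` (the fitted matrix).
#' @seealso [print.cscore_test()], [summary.cscore_test()],
#'   [plot.cscore_test()], [simulate.cscore_test()]
#' @examples
#' set.seed(1)
#' m <- plant_segregation(n_taxa = 10, n_sites = 10, n_pairs = 5)
#' fit <- cscore_test(m, n_iter = 500, seed = 42)
#' fit
#' @export
cscore_test <- function(x, n_iter = 5000, burn_in = NULL, thin = NULL,
                        alpha = 0.05, seed = NULL,
                        p_correction = c("none", "plus_one")) {
  p_correction <- match.arg(p_correction)
  x <- community_matrix(x)
  m <- as_cells(x)
  if (nrow(m) < 2) stop("cscore_test requires at least 2 taxa")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  if (is.null(burn_in)) burn_in <- max(1000L, 10L * nrow(m) * ncol(m))
  if (is.null(thin)) thin <- nrow(m) * ncol(m)
  obs <- cpp_cscore(m)
  cb <- checkerboard_units(x)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  sims <- null_distribution(x, n_iter = n_iter, burn_in = burn_in, thin = thin)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  unusable <- isTRUE(attr(sims, "unusable"))
  if (unusable) {
    out <- list(observed_c = obs, sims = numeric(0), sim_mean = NA_real_,
                sim_sd = NA_real_, ses = NA_real_, ses_undefined = TRUE,
                p_le = NA_real_, p_ge = NA_real_,
                classification = "unusable", n_iterations = n_iter,
                burn_in = burn_in, thin = thin, seed = seed, alpha = alpha,
                acceptance_rate = NA_real_, checkerboard = cb, matrix = x)
    class(out) <- "cscore_test"
    return(out)
  }
  z <- ses(obs, sims)
  p <- tail_probabilities(obs, sims, correction = p_correction)
  cls <- classify_cscore(p$p_le, p$p_ge, alpha = alpha)
  out <- list(observed_c = obs, sims = as.numeric(sims),
              sim_mean = mean(sims), sim_sd = stats::sd(sims),
              ses = as.numeric(z),
              ses_undefined = isTRUE(attr(z, "undefined")),
              p_le = p$p_le, p_ge = p$p_ge,
              classification = as.character(cls),
              ambiguous = isTRUE(attr(cls, "ambiguous")),
              n_iterations = n_iter, burn_in = burn_in, thin = thin,
              seed = seed, alpha = alpha,
              acceptance_rate = attr(sims, "acceptance_rate"),
              checkerboard = cb, matrix = x)
  class(out) <- "cscore_test"
  out
}

#' @export
print.cscore_test <- function(x, digits = 4, ...) {
  key <- attr(x$matrix, "key")
  cat("C-score null model test (fixed-fixed, sequential swap)\n")
  if (!is.null(key)) cat("  stratum: ", format(key), "\n", sep = "")
  cat(sprintf("  matrix: %d taxa x %d sites\n",
              nrow(x$matrix), ncol(x$matrix)))
  if (x$classification == "unusable") {
    cat("  no swappable submatrix: chain frozen, result unusable\n")
    return(invisible(x))
  }
  cat(sprintf("  observed C-score: %.*f\n", digits, x$observed_c))
  cat(sprintf("  null mean (sd):   %.*f (%.*f)  [%d iterations]\n",
              digits, x$sim_mean, digits, x$sim_sd, x$n_iterations))
  cat(sprintf("  SES: %s   p(obs<=exp) = %.*f   p(obs>=exp) = %.*f\n",
              if (x$ses_undefined) "undefined" else sprintf("%.*f", digits, x$ses),
              digits, x$p_le, digits, x$p_ge))
  cat(sprintf("  classification at alpha = %s: %s\n",
              format(x$alpha), x$classification))
  invisible(x)
}

#' @export
summary.cscore_test <- function(object, ...) {
  structure(list(fit = object,
                 per_taxon = object$checkerboard$per_taxon[
                   order(-object$checkerboard$per_taxon$cu_sum), ]),
            class = "summary.cscore_test")
}

#' @export
print.summary.cscore_test <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  swap acceptance rate: %s\n",
              format(x$fit$acceptance_rate, digits = 3)))
  cat("\nPer-taxon checkerboard-unit sums (descending):\n")
  print(x$per_taxon, row.names = FALSE)
  invisible(x)
}

#' Plot a C-score null distribution
#'
#' Histogram of the simulated null C-scores with the observed value marked.
#'
#' @param x a [cscore_test()] fit.
#' @param ... passed to [graphics::hist()].
#' @export
plot.cscore_test <- function(x, ...) {
  if (!length(x$sims)) stop("nothing to plot: unusable fit")
  h <- graphics::hist(x$sims, main = "C-score null distribution",
                      xlab = "simulated C-score",
                      xlim = range(c(x$sims, x$observed_c)), ...)
  graphics::abline(v = x$observed_c, lwd = 2)
  graphics::legend("topright", legend = sprintf("observed = %.4f (SES %.2f)",
                                                x$observed_c, x$ses),
                   bty = "n")
  invisible(h)
}

#' Simulate null community matrices from a fitted test
#'
#' Draws matrices from the same fixed-marginal swap chain the fit used:
#' each draw continues the chain by `thin` attempted swaps.
#'
#' @param object a [cscore_test()] fit.
#' @param nsim number of matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return a list of binary matrices with the observed margins.
#' @export
simulate.cscore_test <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- as_cells(object$matrix)
  if (!cpp_has_swap(m)) stop("chain frozen: no swappable submatrix")
  m <- cpp_swap_shuffle(m, object$burn_in)
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    m <- cpp_swap_attempts(m, object$thin)
    dimnames(m) <- dimnames(object$matrix)
    out[[i]] <- m
  }
  out
}
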