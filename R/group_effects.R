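#' Summarize an SES distribution against the null band
#'
#' Under random assembly the standardized effect sizes of a batch of
#' matrices have mean zero with about 95% of values between -2 and +2.
#' This reports the observed mean and the fraction outside that band.
#'
#' @param ses_values numeric vector of SES values (NAs from undefined SES
#'   are dropped with a message).
#' @return list with `mean`, `prop_outside` (fraction with |SES| > 2) and
#'   `n`.
#' @export
ses_band_summary <- function(ses_values) {
  drop <- !is.finite(ses_values)
  if (any(drop)) {
    message(sum(drop), " undefined SES value(s) excluded")
    ses_values <- ses_values[!drop]
  }
  if (!length(ses_values)) stop("no defined SES values")
  list(mean = mean(ses_values),
       prop_outside = mean(abs(ses_values) > 2),
       n = length(ses_values))
}

#' Kruskal-Wallis test of SES across groups
#'
#' Rank-based test (with the standard midrank tie correction, via
#' [stats::kruskal.test()]) of whether the SES distribution differs among
#' biological groupings; p comes from the chi-square approximation with
#' `groups - 1` degrees of freedom.
#'
#' @param values numeric vector.
#' @param groups grouping vector of the same length.
#' @return list with `H`, `df`, `p`, `group_sizes` and
#'   `tie_correction_applied`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2) stop("need at least 2 groups with data")
  if (length(unique(values)) == 1L) {
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1,
                group_sizes = as.integer(table(groups)),
                tie_correction_applied = TRUE))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, group_sizes = as.integer(table(groups)),
       tie_correction_applied = any(duplicated(values)))
}

#' Pairwise two-sided Wilcoxon rank-sum tests
#'
#' One two-sided rank-sum (Mann-Whitney U) p-value per pair of groups via
#' [stats::wilcox.test()]: exact enumeration when both samples have at
#' most 8 values and no ties are present, the normal approximation with
#' tie correction otherwise. Unadjusted by default; `adjust = "holm"`
#' applies a Holm correction across the pairs.
#'
#' @inheritParams kruskal_wallis
#' @param adjust `"none"` (default) or `"holm"`.
#' @return a data.frame with columns `group1`, `group2`, `n1`, `n2`, `p`.
#' @export
pairwise_wilcoxon <- function(values, groups, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  groups <- as.factor(groups)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  lev <- levels(groups)
  if (length(lev) < 2) stop("need at least 2 groups with data")
  combos <- utils::combn(lev, 2)
  res <- apply(combos, 2, function(pr) {
    a <- values[groups == pr[1]]
    b <- values[groups == pr[2]]
    exact <- length(a) <= 8 && length(b) <= 8 &&
      !any(duplicated(c(a, b)))
    p <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                         correct = !exact)$p.value)
    c(n1 = length(a), n2 = length(b), p = p)
  })
  out <- data.frame(group1 = combos[1, ], group2 = combos[2, ],
                    n1 = as.integer(res["n1", ]), n2 = as.integer(res["n2", ]),
                    p = res["p", ], stringsAsFactors = FALSE)
  if (adjust == "holm") out$p_adjusted <- stats::p.adjust(out$p, "holm")
  rownames(out) <- NULL
  out
}
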