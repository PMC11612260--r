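#' Stone-Roberts C-score of a binary community matrix
#'
#' The C-score is the mean number of checkerboard units (CU) over all
#' unordered taxon pairs. For taxa i and j with site counts \eqn{r_i},
#' \eqn{r_j} and \eqn{S_{ij}} shared sites,
#' \deqn{CU_{ij} = (r_i - S_{ij})(r_j - S_{ij}),}
#' the number of 2x2 mutually exclusive submatrices the pair forms. Higher
#' values indicate segregation.
#'
#' @param x a [community_matrix()] or 0/1 matrix with at least 2 rows.
#' @return a single non-negative number.
#' @export
c_score <- function(x) {
  m <- as_cells(community_matrix(x))
  if (nrow(m) < 2) stop("C-score requires at least 2 taxa")
  cpp_cscore(m)
}

#' Per-pair checkerboard units and per-taxon aggregates
#'
#' Computes \eqn{CU_{ij}} for every unordered taxon pair plus, for each
#' taxon, the sum and mean of CU over the pairs it participates in. The
#' mean of the pair table equals [c_score()]. The per-taxon sums drive
#' driver-taxon detection in mechanism inference.
#'
#' @inheritParams c_score
#' @return an object of class `checkerboard_units`: a list with `pairs`
#'   (data.frame `taxon_i`, `taxon_j`, `cu`), `per_taxon` (data.frame
#'   `taxon`, `cu_sum`, `cu_mean`) and `c_score`.
#' @export
checkerboard_units <- function(x) {
  m <- as_cells(community_matrix(x))
  if (nrow(m) < 2) stop("checkerboard units require at least 2 taxa")
  r <- rowSums(m)
  S <- tcrossprod(m)
  # (r - S)[i,j] = r_i - S_ij by column recycling; S is symmetric
  CU <- (r - S) * t(r - S)
  idx <- which(upper.tri(CU), arr.ind = TRUE)
  taxa <- rownames(m)
  pairs <- data.frame(taxon_i = taxa[idx[, 1]], taxon_j = taxa[idx[, 2]],
                      cu = CU[idx], stringsAsFactors = FALSE)
  diag(CU) <- 0
  per_taxon <- data.frame(taxon = taxa,
                          cu_sum = rowSums(CU),
                          cu_mean = rowSums(CU) / (nrow(m) - 1),
                          stringsAsFactors = FALSE)
  rownames(per_taxon) <- NULL
  structure(list(pairs = pairs, per_taxon = per_taxon,
                 c_score = mean(pairs$cu)),
            class = "checkerboard_units")
}

#' @export
print.checkerboard_units <- function(x, ...) {
  cat("Checkerboard units over", nrow(x$pairs), "taxon pairs; C-score =",
      format(x$c_score, digits = 6), "\n")
  cat("Top per-taxon CU sums:\n")
  pt <- x$per_taxon[order(-x$per_taxon$cu_sum), ]
  print(head(pt, 5), row.names = FALSE)
  invisible(x)
}
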