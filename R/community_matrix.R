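#' Stratum key for a community matrix
#'
#' Identifies the nested stratum a matrix belongs to: sampling year,
#' ecoregion, vegetation zone, and the biological unit (a functional feeding
#' group under `unit_type = "trophic"`, a taxonomic family under
#' `unit_type = "taxonomic"`).
#'
#' @param year integer sampling year.
#' @param ecoregion ecoregion code (one of `r paste(ECOREGIONS, collapse = ", ")`).
#' @param vegetation vegetation zone, `"bulrush"` or `"lily"`.
#' @param unit_type `"trophic"` or `"taxonomic"`.
#' @param unit_label the FFG or family name.
#' @return an object of class `stratum_key`.
#' @export
stratum_key <- function(year, ecoregion, vegetation, unit_type, unit_label) {
  stopifnot(length(year) == 1L, length(ecoregion) == 1L)
  if (!ecoregion %in% ECOREGIONS)
    stop("unknown ecoregion code: ", ecoregion)
  if (!vegetation %in% VEGETATION_ZONES)
    stop("unknown vegetation zone: ", vegetation)
  unit_type <- match.arg(unit_type, c("trophic", "taxonomic"))
  key <- list(year = as.integer(year), ecoregion = ecoregion,
              vegetation = vegetation, unit_type = unit_type,
              unit_label = as.character(unit_label))
  class(key) <- "stratum_key"
  key
}

#' @export
format.stratum_key <- function(x, ...) {
  paste(x$year, x$ecoregion, x$vegetation, x$unit_type, x$unit_label,
        sep = "|")
}

#' @export
print.stratum_key <- function(x, ...) {
  cat("<stratum>", format(x), "\n")
  invisible(x)
}

#' Construct a binary community matrix
#'
#' Rows are taxa, columns are sites; cells are 1 where the taxon was present
#' at the site. This orientation is assumed by all downstream functions.
#'
#' @param cells a matrix coercible to 0/1 integers.
#' @param taxa,sites optional row/column labels; taken from `dimnames(cells)`
#'   when omitted.
#' @param key optional [stratum_key()].
#' @return an object of class `community_matrix` (an integer matrix with a
#'   `key` attribute and a cleanup `log` attribute).
#' @export
community_matrix <- function(cells, taxa = NULL, sites = NULL, key = NULL) {
  if (inherits(cells, "community_matrix") && is.null(key))
    key <- attr(cells, "key")
  m <- as.matrix(cells)
  if (!all(m %in% c(0, 1)))
    stop("community matrix cells must be 0/1")
  storage.mode(m) <- "integer"
  if (is.null(taxa)) taxa <- rownames(m)
  if (is.null(sites)) sites <- colnames(m)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(m)))
  if (is.null(sites)) sites <- paste0("s", seq_len(ncol(m)))
  if (anyDuplicated(taxa)) stop("duplicated taxon labels")
  if (anyDuplicated(sites)) stop("duplicated site labels")
  dimnames(m) <- list(taxa, sites)
  structure(m, key = key, log = character(0), unusable = FALSE,
            class = c("community_matrix", "matrix", "array"))
}

as_cells <- function(x) {
  # strip class/attrs down to a plain integer matrix for the C++ engine
  m <- unclass(x)
  attr(m, "key") <- NULL
  attr(m, "log") <- NULL
  attr(m, "unusable") <- NULL
  storage.mode(m) <- "integer"
  m
}

#' @export
print.community_matrix <- function(x, ...) {
  key <- attr(x, "key")
  cat("Community matrix: ", nrow(x), " taxa x ", ncol(x), " sites",
      if (!is.null(key)) paste0(" [", format(key), "]"), "\n", sep = "")
  if (isTRUE(attr(x, "unusable"))) cat("  flagged unusable\n")
  print(matrix(as.integer(x), nrow(x), dimnames = dimnames(x)))
  invisible(x)
}

#' Remove all-zero rows and columns from a community matrix
#'
#' Fixed-fixed randomization cannot act on degenerate margins, so all-zero
#' taxon rows and site columns are removed (`action = "repair"`, the
#' default) or the whole matrix is flagged unusable (`action = "discard"`).
#' Removals are appended to the matrix's `log` attribute and label order is
#' preserved. Repair is idempotent: removing zero rows cannot create zero
#' columns and vice versa.
#'
#' @param x a [community_matrix()].
#' @param action `"repair"` or `"discard"`.
#' @return the cleaned matrix; if nothing remains (or `action = "discard"`
#'   fired) the `unusable` attribute is `TRUE`.
#' @export
clean_degenerate <- function(x, action = c("repair", "discard")) {
  action <- match.arg(action)
  rs <- rowSums(x)
  cs <- colSums(x)
  zero_r <- rs == 0
  zero_c <- cs == 0
  log <- attr(x, "log")
  if (!any(zero_r) && !any(zero_c)) return(x)
  if (action == "discard") {
    attr(x, "unusable") <- TRUE
    attr(x, "log") <- c(log, "discarded: degenerate margins present")
    return(x)
  }
  keep_r <- !zero_r
  keep_c <- !zero_c
  if (any(zero_r))
    log <- c(log, paste0("removed all-zero taxa: ",
                         paste(rownames(x)[zero_r], collapse = ", ")))
  if (any(zero_c))
    log <- c(log, paste0("removed all-zero sites: ",
                         paste(colnames(x)[zero_c], collapse = ", ")))
  key <- attr(x, "key")
  if (!any(keep_r) || !any(keep_c)) {
    out <- community_matrix(matrix(0L, 0, 0), taxa = character(0),
                            sites = character(0), key = key)
    attr(out, "unusable") <- TRUE
    attr(out, "log") <- c(log, "unusable: empty after degeneracy cleanup")
    return(out)
  }
  out <- community_matrix(unclass(x)[keep_r, keep_c, drop = FALSE], key = key)
  attr(out, "log") <- log
  out
}

#' Decide whether a matrix is large enough to analyze
#'
#' Small matrices are prone to degeneracy and have little power; matrices
#' below the threshold are dropped from analysis.
#'
#' @param x a [community_matrix()].
#' @param min_taxa minimum number of taxon rows (default 5).
#' @param min_sites minimum number of site columns (default 4).
#' @return `TRUE` (keep) or `FALSE` (drop), with a `reason` attribute when
#'   dropped.
#' @export
filter_size <- function(x, min_taxa = 5, min_sites = 4) {
  keep <- nrow(x) >= min_taxa && ncol(x) >= min_sites
  if (!keep)
    attr(keep, "reason") <- sprintf("%d taxa x %d sites below %d x %d minimum",
                                    nrow(x), ncol(x), min_taxa, min_sites)
  keep
}

#' Write / read a community matrix as TSV plus JSON sidecar
#'
#' The TSV has one taxon per row (first column `taxon_id`, then 0/1 site
#' columns); the sidecar `<path basename>.json` carries the stratum key and
#' the cleanup log, so a matrix round-trips exactly.
#'
#' @param x a [community_matrix()].
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_community_matrix <- function(x, path) {
  df <- data.frame(taxon_id = rownames(x),
                   matrix(as.integer(x), nrow(x), dimnames = dimnames(x)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  key <- attr(x, "key")
  sidecar <- list(
    key = if (is.null(key)) NULL else unclass(key),
    log = as.list(attr(x, "log")),
    unusable = isTRUE(attr(x, "unusable"))
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' @rdname write_community_matrix
#' @export
read_community_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  key <- NULL
  log <- character(0)
  unusable <- FALSE
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    sc <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (!is.null(sc$key))
      key <- stratum_key(sc$key$year, sc$key$ecoregion, sc$key$vegetation,
                         sc$key$unit_type, sc$key$unit_label)
    log <- as.character(unlist(sc$log))
    unusable <- isTRUE(sc$unusable)
  }
  out <- community_matrix(m, key = key)
  attr(out, "log") <- log
  attr(out, "unusable") <- unusable
  out
}
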