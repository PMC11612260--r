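#' Read a long-format occurrence table
#'
#' Reads a CSV/TSV with one row per (site, taxon, year) observation,
#' validates codes against the closed ecoregion/vegetation vocabularies and
#' aggregates duplicated (site, taxon, year) rows by summing abundance.
#'
#' @param path file path (CSV by default; TSV when the extension is
#'   `.tsv`/`.txt` or `sep` is given).
#' @param mapping optional named list/vector mapping the required names
#'   (`site_id`, `taxon_id`, `abundance`, `year`, `ecoregion`, `vegetation`)
#'   to the column names actually present in the file, e.g.
#'   `list(site_id = "SiteCode")`.
#' @param config optional path to a YAML file whose `columns` entry holds
#'   the same mapping.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return a data.frame of validated occurrence records with the canonical
#'   column names, one row per (site, taxon, year).
#' @export
read_occurrences <- function(path, mapping = NULL, config = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.null(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read a YAML column-mapping config")
    cfg <- yaml::read_yaml(config)
    mapping <- utils::modifyList(as.list(cfg$columns %||% list()),
                                 as.list(mapping %||% list()))
  }
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("site_id", "taxon_id", "abundance", "year", "ecoregion",
                "vegetation")
  cols <- stats::setNames(required, required)
  for (nm in names(mapping %||% list())) cols[[nm]] <- mapping[[nm]]
  missing <- setdiff(unname(cols), names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  rec <- data.frame(
    site_id = as.character(raw[[cols[["site_id"]]]]),
    taxon_id = as.character(raw[[cols[["taxon_id"]]]]),
    abundance = raw[[cols[["abundance"]]]],
    year = raw[[cols[["year"]]]],
    ecoregion = as.character(raw[[cols[["ecoregion"]]]]),
    vegetation = as.character(raw[[cols[["vegetation"]]]]),
    stringsAsFactors = FALSE
  )
  line_no <- seq_len(nrow(rec)) + 1L  # header is line 1
  bad <- !is.finite(suppressWarnings(as.numeric(rec$abundance))) |
    suppressWarnings(as.numeric(rec$abundance)) < 0
  if (any(bad))
    stop("malformed abundance on line(s): ",
         paste(line_no[bad], collapse = ", "))
  rec$abundance <- as.numeric(rec$abundance)
  bad_year <- is.na(suppressWarnings(as.integer(rec$year)))
  if (any(bad_year))
    stop("malformed year on line(s): ", paste(line_no[bad_year], collapse = ", "))
  rec$year <- as.integer(rec$year)
  unknown_eco <- setdiff(unique(rec$ecoregion), ECOREGIONS)
  if (length(unknown_eco))
    stop("unknown ecoregion code(s): ", paste(unknown_eco, collapse = ", "))
  unknown_veg <- setdiff(unique(rec$vegetation), VEGETATION_ZONES)
  if (length(unknown_veg))
    stop("unknown vegetation code(s): ", paste(unknown_veg, collapse = ", "))
  # aggregate duplicates: abundances sum within (site, taxon, year);
  # ecoregion/vegetation are site-by-year attributes and must be consistent
  keyv <- paste(rec$site_id, rec$taxon_id, rec$year, sep = "\r")
  if (anyDuplicated(keyv)) {
    agg <- rowsum(rec$abundance, keyv)
    first <- rec[!duplicated(keyv), , drop = FALSE]
    first$abundance <- agg[match(paste(first$site_id, first$taxon_id,
                                       first$year, sep = "\r"),
                                 rownames(agg)), 1]
    rec <- first
  }
  rownames(rec) <- NULL
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert abundances to presence/absence
#'
#' Presence is any positive abundance; there is no minimum-count filter.
#'
#' @param records an occurrence data.frame (from [read_occurrences()]) or a
#'   numeric vector of abundances.
#' @return the same structure with abundances replaced by 0/1 presence.
#' @export
binarize <- function(records) {
  if (is.numeric(records)) {
    if (any(records < 0)) stop("negative abundance")
    return(as.integer(records > 0))
  }
  if (any(records$abundance < 0)) stop("negative abundance")
  records$abundance <- as.integer(records$abundance > 0)
  records
}

#' Read a taxon-attribute table
#'
#' Columns: `taxon_id` (required), and optionally `family`, `ffg`
#' (collector/grazer/predator/shredder), `tolerance` (0-10 pollution
#' tolerance score, 0 = sensitive), `overwinters` (logical).
#'
#' @param path CSV path.
#' @return a data.frame keyed by `taxon_id`.
#' @export
read_taxon_attributes <- function(path) {
  at <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"taxon_id" %in% names(at)) stop("attribute table needs a taxon_id column")
  if ("ffg" %in% names(at)) {
    bad <- setdiff(setdiff(unique(at$ffg), NA), FFG_LEVELS)
    if (length(bad)) stop("unknown ffg value(s): ", paste(bad, collapse = ", "))
  }
  if ("tolerance" %in% names(at)) {
    tl <- at$tolerance
    if (any(!is.na(tl) & (tl < 0 | tl > 10)))
      stop("tolerance scores must lie in [0, 10]")
  }
  at
}

#' Read a site environmental table
#'
#' @param path CSV path with `site_id`, `year` and numeric environmental
#'   variable columns.
#' @return a data.frame.
#' @export
read_env_table <- function(path) {
  env <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("site_id", "year") %in% names(env)))
    stop("environmental table needs site_id and year columns")
  env
}

#' Partition occurrence records into stratified community matrices
#'
#' One binary taxa-by-sites matrix is built per (year, ecoregion,
#' vegetation, unit) stratum, where the unit is the functional feeding
#' group (`unit_type = "trophic"`) or the taxonomic family
#' (`unit_type = "taxonomic"`). Taxa lacking the grouping attribute are
#' excluded and reported in the `excluded` attribute of the result.
#'
#' @param records occurrence data.frame (abundances are binarized
#'   internally).
#' @param attributes taxon-attribute data.frame with `taxon_id` and the
#'   column required by `unit_type` (`ffg` or `family`).
#' @param unit_type `"trophic"` or `"taxonomic"`.
#' @return a named list of [community_matrix()] objects (names are the
#'   stratum key strings), with attribute `excluded` listing taxa dropped
#'   for missing attributes.
#' @export
partition_matrices <- function(records, attributes,
                               unit_type = c("trophic", "taxonomic")) {
  unit_type <- match.arg(unit_type)
  attr_col <- if (unit_type == "trophic") "ffg" else "family"
  if (!attr_col %in% names(attributes))
    stop("attribute table lacks the ", attr_col, " column required by unit_type")
  rec <- binarize(records)
  rec <- rec[rec$abundance > 0, , drop = FALSE]
  unit <- attributes[[attr_col]][match(rec$taxon_id, attributes$taxon_id)]
  excluded <- sort(unique(rec$taxon_id[is.na(unit)]))
  rec <- rec[!is.na(unit), , drop = FALSE]
  unit <- unit[!is.na(unit)]
  if (!nrow(rec)) {
    out <- list()
    attr(out, "excluded") <- excluded
    return(out)
  }
  strat <- paste(rec$year, rec$ecoregion, rec$vegetation, unit, sep = "\r")
  out <- lapply(split(seq_len(nrow(rec)), strat), function(idx) {
    sub <- rec[idx, , drop = FALSE]
    taxa <- sort(unique(sub$taxon_id))
    sites <- sort(unique(sub$site_id))
    m <- matrix(0L, length(taxa), length(sites),
                dimnames = list(taxa, sites))
    m[cbind(match(sub$taxon_id, taxa), match(sub$site_id, sites))] <- 1L
    community_matrix(m, key = stratum_key(sub$year[1], sub$ecoregion[1],
                                          sub$vegetation[1], unit_type,
                                          unit[idx][1]))
  })
  names(out) <- vapply(out, function(m) format(attr(m, "key")), character(1))
  out <- out[order(names(out))]
  attr(out, "excluded") <- excluded
  out
}
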