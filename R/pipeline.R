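# Batch drivers tying the stages together: null models over a set of
# stratified matrices, mechanism inference for the non-random ones, and
# SES distribution analysis, with TSV/JSON outputs.

# 31-bit polynomial rolling hash of a key string; used only to derive
# per-matrix seeds deterministically from the master seed, so adding
# strata never perturbs existing results
string_hash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Derive a per-matrix seed from a master seed and a stratum key
#'
#' @param master_seed integer master seed.
#' @param key stratum key string (or a [stratum_key()]).
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, key) {
  if (inherits(key, "stratum_key")) key <- format(key)
  as.integer((as.numeric(master_seed) + string_hash(key)) %% 2147483646 + 1)
}

#' Run null-model tests over a batch of community matrices
#'
#' Applies degeneracy cleanup, the size filter and [cscore_test()] to every
#' matrix; per-matrix seeds derive from `master_seed` and the stratum key.
#'
#' @param matrices a named list of [community_matrix()] objects (e.g. from
#'   [partition_matrices()]).
#' @param n_iter,alpha,burn_in,thin passed to [cscore_test()].
#' @param master_seed master seed for per-matrix seed derivation.
#' @param min_taxa,min_sites size filter thresholds.
#' @param degenerate_action passed to [clean_degenerate()].
#' @param out_dir when given, `null_results.tsv` and `manifest.json` are
#'   written there.
#' @return an object of class `cooc_batch`: list with `results` (one row
#'   per matrix: stratum fields, sizes, c_score, sim_mean, sim_sd, ses,
#'   p_le, p_ge, classification, seed, acceptance_rate, note) and `fits`
#'   (the [cscore_test()] objects for analyzed matrices).
#' @export
run_null_batch <- function(matrices, n_iter = 5000, alpha = 0.05,
                           master_seed = 1, min_taxa = 5, min_sites = 4,
                           burn_in = NULL, thin = NULL,
                           degenerate_action = "repair", out_dir = NULL) {
  if (is.null(names(matrices)))
    names(matrices) <- vapply(matrices, function(m) {
      k <- attr(m, "key")
      if (is.null(k)) stop("matrices must be named or carry stratum keys")
      format(k)
    }, character(1))
  rows <- list()
  fits <- list()
  for (nm in names(matrices)) {
    m <- clean_degenerate(matrices[[nm]], action = degenerate_action)
    key <- attr(m, "key")
    base <- list(
      year = if (is.null(key)) NA_integer_ else key$year,
      ecoregion = if (is.null(key)) NA_character_ else key$ecoregion,
      vegetation = if (is.null(key)) NA_character_ else key$vegetation,
      unit_type = if (is.null(key)) NA_character_ else key$unit_type,
      unit = if (is.null(key)) NA_character_ else key$unit_label,
      n_taxa = nrow(m), n_sites = ncol(m))
    empty_stats <- list(c_score = NA_real_, sim_mean = NA_real_,
                        sim_sd = NA_real_, ses = NA_real_, p_le = NA_real_,
                        p_ge = NA_real_, seed = NA_integer_,
                        acceptance_rate = NA_real_)
    if (isTRUE(attr(m, "unusable"))) {
      rows[[nm]] <- c(base, empty_stats,
                      list(classification = "unusable", note = "degenerate"))
      next
    }
    keep <- filter_size(m, min_taxa = min_taxa, min_sites = min_sites)
    if (!keep) {
      rows[[nm]] <- c(base, empty_stats,
                      list(classification = "dropped",
                           note = attr(keep, "reason")))
      next
    }
    fit <- cscore_test(m, n_iter = n_iter, burn_in = burn_in, thin = thin,
                       alpha = alpha, seed = derive_seed(master_seed, nm))
    fits[[nm]] <- fit
    rows[[nm]] <- c(base, list(
      c_score = fit$observed_c, sim_mean = fit$sim_mean,
      sim_sd = fit$sim_sd, ses = fit$ses, p_le = fit$p_le, p_ge = fit$p_ge,
      seed = fit$seed, acceptance_rate = fit$acceptance_rate,
      classification = fit$classification,
      note = if (fit$classification == "unusable") "chain frozen" else ""))
  }
  results <- do.call(rbind, lapply(names(rows), function(nm) {
    data.frame(stratum = nm, rows[[nm]], stringsAsFactors = FALSE)
  }))
  rownames(results) <- NULL
  out <- list(results = results, fits = fits, alpha = alpha,
              n_iter = n_iter, master_seed = master_seed)
  class(out) <- "cooc_batch"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(results, file.path(out_dir, "null_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(master_seed = master_seed, n_iterations = n_iter,
                     alpha = alpha,
                     burn_in_policy = "max(1000, 10 * taxa * sites) successful swaps",
                     thin_policy = "taxa * sites attempted swaps",
                     seeds = stats::setNames(as.list(results$seed),
                                             results$stratum))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.cooc_batch <- function(x, ...) {
  tab <- table(factor(x$results$classification,
                      c("negative", "positive", "random", "unusable",
                        "dropped")))
  cat(sprintf("Null-model batch: %d matrices (%d analyzed)\n",
              nrow(x$results), length(x$fits)))
  cat(sprintf("  negative %d | positive %d | random %d | unusable %d | dropped %d\n",
              tab["negative"], tab["positive"], tab["random"],
              tab["unusable"], tab["dropped"]))
  invisible(x)
}

#' Mechanism inference for the non-random matrices of a batch
#'
#' Runs [mechanism_test()] for every negative or positive matrix in a
#' [run_null_batch()] result, one row per driver taxon. When the attribute
#' table has an `overwinters` column, the involved taxa known to
#' overwinter are listed per row.
#'
#' @param batch a `cooc_batch`.
#' @param attributes taxon-attribute data.frame (`taxon_id`, optionally
#'   `tolerance`, `overwinters`); `NULL` gives unknown tolerance calls.
#' @param env_table site environmental data.frame (`site_id`, `year`,
#'   variables); `NULL` gives unknown habitat calls.
#' @param alpha,z_threshold,gap_threshold,n_permutations see
#'   [mechanism_test()].
#' @param out_dir when given, `mechanisms.tsv` is written there.
#' @return a data.frame with one row per (matrix, driver): stratum fields,
#'   driver, partners, tolerance_call, habitat_call, pseudo_f, p_habitat,
#'   verdict, overwinterers.
#' @export
run_mechanisms <- function(batch, attributes = NULL, env_table = NULL,
                           alpha = 0.05, z_threshold = 2.0,
                           gap_threshold = 3.0, n_permutations = 999,
                           out_dir = NULL) {
  stopifnot(inherits(batch, "cooc_batch"))
  res <- batch$results
  nonrandom <- res$stratum[res$classification %in% c("negative", "positive")]
  rows <- list()
  for (nm in nonrandom) {
    fit <- batch$fits[[nm]]
    m <- fit$matrix
    env <- NULL
    if (!is.null(env_table)) {
      key <- attr(m, "key")
      sel <- env_table$site_id %in% colnames(m)
      if (!is.null(key) && "year" %in% names(env_table))
        sel <- sel & env_table$year == key$year
      sub <- env_table[sel, , drop = FALSE]
      if (nrow(sub)) {
        env <- as.matrix(sub[, setdiff(names(sub), c("site_id", "year")),
                             drop = FALSE])
        rownames(env) <- sub$site_id
      }
    }
    mech <- mechanism_test(fit, tolerances = attributes, env = env,
                           alpha = alpha, z_threshold = z_threshold,
                           gap_threshold = gap_threshold,
                           n_permutations = n_permutations,
                           seed = derive_seed(batch$master_seed,
                                              paste0(nm, "|mech")))
    for (r in mech$results) {
      involved <- c(r$driver, r$partners)
      ow <- ""
      if (!is.null(attributes) && "overwinters" %in% names(attributes)) {
        flag <- attributes$taxon_id %in% involved &
          attributes$overwinters %in% TRUE
        ow <- paste(attributes$taxon_id[flag], collapse = ",")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = nm, classification = mech$classification,
        driver = r$driver, partners = paste(r$partners, collapse = ","),
        tolerance_call = r$tolerance_call, habitat_call = r$habitat_call,
        pseudo_f = if (is.null(r$permanova)) NA_real_ else r$permanova$pseudo_f,
        p_habitat = if (is.null(r$permanova)) NA_real_ else r$permanova$p,
        verdict = r$verdict$verdict, overwinterers = ow,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stratum = character(0), classification = character(0),
               driver = character(0), partners = character(0),
               tolerance_call = character(0), habitat_call = character(0),
               pseudo_f = numeric(0), p_habitat = numeric(0),
               verdict = character(0), overwinterers = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(out, file.path(out_dir, "mechanisms.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' SES distribution analysis over a batch
#'
#' For each unit type in the batch: the null-band summary of SES values
#' (mean and fraction outside +/-2), a Kruskal-Wallis test of SES across
#' the biological units, the pairwise Wilcoxon table, and binned histogram
#' counts with band markers.
#'
#' @param batch a `cooc_batch`.
#' @param adjust multiple-comparison adjustment for the pairwise table
#'   (`"none"`, matching unadjusted reporting, or `"holm"`).
#' @param out_dir when given, `group_effects_<unit_type>.tsv` and
#'   `ses_histogram_<unit_type>.tsv` files are written there.
#' @return a named list per unit type with `band`, `kruskal`, `pairwise`,
#'   `histogram`; unit types with fewer than 2 groups are skipped with a
#'   warning.
#' @export
run_group_effects <- function(batch, adjust = "none", out_dir = NULL) {
  stopifnot(inherits(batch, "cooc_batch"))
  res <- batch$results
  res <- res[is.finite(res$ses), , drop = FALSE]
  out <- list()
  for (ut in unique(res$unit_type)) {
    sub <- res[res$unit_type %in% ut, , drop = FALSE]
    band <- ses_band_summary(sub$ses)
    if (length(unique(sub$unit)) < 2) {
      warning("unit type ", ut, ": fewer than 2 groups, tests skipped")
      kw <- NULL
      pw <- NULL
    } else {
      kw <- kruskal_wallis(sub$ses, sub$unit)
      pw <- pairwise_wilcoxon(sub$ses, sub$unit, adjust = adjust)
    }
    h <- graphics::hist(sub$ses, breaks = "Sturges", plot = FALSE)
    histogram <- data.frame(bin_left = h$breaks[-length(h$breaks)],
                            bin_right = h$breaks[-1], count = h$counts)
    attr(histogram, "band") <- c(-2, 2)
    out[[as.character(ut)]] <- list(band = band, kruskal = kw,
                                    pairwise = pw, histogram = histogram)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      if (!is.null(kw)) {
        summary_df <- data.frame(
          unit_type = ut, n = band$n, mean_ses = band$mean,
          prop_outside_band = band$prop_outside, H = kw$H, df = kw$df,
          p = kw$p, stringsAsFactors = FALSE)
        write.table(summary_df,
                    file.path(out_dir, paste0("group_effects_", ut, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      write.table(histogram,
                  file.path(out_dir, paste0("ses_histogram_", ut, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}
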