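# End-to-end orchestration: configuration, descriptive summaries, and the
# pipeline that runs read -> filter -> rollup -> (descriptive | inferential)
# branches and assembles a reproducible study report.

#' Pipeline configuration
#'
#' All defaults match the study protocol: the 7 cm length exclusion, the +1
#' pseudocount, 8 families resampled 10,000 times from the annotated
#' universe, and 13.3 hours of sponging effort.  The descriptive branch pools
#' all dives; the inferential branch uses transects only.
#'
#' @param filter a [filter_config()].
#' @param ratio a [ratio_config()].
#' @param resampling list with `n_draw` (NULL = use the number of families
#'   observed during sponging), `reps`, `seed`, `two_tail`.
#' @param sponging_hours total human-sponging effort in hours (study: 13.3).
#' @param transect_ids optional explicit transect id set for the paired tests.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(filter = filter_config(),
                            ratio = ratio_config(),
                            resampling = list(),
                            sponging_hours = 13.3,
                            transect_ids = NULL) {
  res <- utils::modifyList(
    list(n_draw = NULL, reps = 10000L, seed = 1L, two_tail = "deviation"),
    resampling)
  stopifnot(inherits(filter, "filter_config"), inherits(ratio, "ratio_config"),
            sponging_hours > 0)
  structure(list(filter = filter, ratio = ratio, resampling = res,
                 sponging_hours = sponging_hours, transect_ids = transect_ids),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' The file mirrors [pipeline_config()]: top-level keys `filter`
#' (`min_length_cm`, `drop_unidentified`), `ratio` (`offset`), `resampling`
#' (`n_draw`, `reps`, `seed`, `two_tail`) and `sponging_hours`.  Missing keys
#' keep their study defaults.
#'
#' @param path path to the configuration file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    filter = do.call(filter_config, raw$filter %||% list()),
    ratio = do.call(ratio_config, raw$ratio %||% list()),
    resampling = raw$resampling %||% list(),
    sponging_hours = raw$sponging_hours %||% 13.3,
    transect_ids = raw$transect_ids)
}

#' Descriptive summaries of pooled prey counts
#'
#' Per mode: the percentage of prey belonging to swimbladderless families,
#' and each family's (and, when species-level counts are supplied, each
#' species') share of the mode total.  Raw percentages are kept to machine
#' precision; display values are rounded half-up to integers.  A mode with
#' zero total prey has no defined percentages and is reported as absent (NA).
#'
#' @param pooled family-level pooled counts, `family, mode, count`, from
#'   [pool_counts()] with `all_dives` scope (integer counts).
#' @param universe a [family_universe()] annotating every family in `pooled`.
#' @param pooled_species optional species-level pooled counts
#'   (`family, species, mode, count`).
#' @return list with `totals`, `pct_no_sb` (raw and display per mode),
#'   `family_pcts`, and `species_pcts` (NULL unless supplied).
#' @export
summarize_descriptives <- function(pooled, universe, pooled_species = NULL) {
  unknown <- setdiff(unique(pooled$family), universe$family)
  if (length(unknown) > 0) {
    stop_stage("descriptives", "family not annotated in universe: %s",
               paste(unknown, collapse = ", "))
  }
  no_sb <- universe$family[!universe$has_swimbladder]
  totals <- vapply(MODES, function(m)
    sum(pooled$count[pooled$mode == m]), numeric(1))
  pct_raw <- vapply(MODES, function(m) {
    if (totals[[m]] == 0) return(NA_real_)
    100 * sum(pooled$count[pooled$mode == m & pooled$family %in% no_sb]) /
      totals[[m]]
  }, numeric(1))
  share <- function(tab, key_cols) {
    tab$pct_raw <- ifelse(totals[tab$mode] == 0, NA_real_,
                          100 * tab$count / totals[tab$mode])
    tab$pct_display <- round_half_up(tab$pct_raw)
    tab[c(key_cols, "mode", "count", "pct_raw", "pct_display")]
  }
  list(totals = as.list(totals),
       pct_no_sb = list(raw = as.list(pct_raw),
                        display = as.list(round_half_up(pct_raw))),
       family_pcts = share(pooled, "family"),
       species_pcts = if (!is.null(pooled_species))
         share(pooled_species, c("family", "species")))
}

#' Mean extraction interval
#'
#' Minutes of sponging effort per extracted prey item; the report renders it
#' rounded half-up to the nearest minute.
#'
#' @param prey_count number of prey extracted (> 0).
#' @param effort_hours sponging effort in hours (> 0).
#' @return minutes per item (unrounded).
#' @export
extraction_interval <- function(prey_count, effort_hours) {
  if (prey_count <= 0) stop_stage("interval", "prey_count must be > 0")
  if (effort_hours <= 0) stop_stage("interval", "effort_hours must be > 0")
  effort_hours * 60 / prey_count
}

pool_species_counts <- function(obs) {
  obs <- obs[!is.na(obs$species), , drop = FALSE]
  if (nrow(obs) == 0) {
    return(data.frame(family = character(0), species = character(0),
                      mode = character(0), count = numeric(0),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(obs$family, obs$species, obs$mode, drop = TRUE, sep = "\r")
  counts <- table(key)
  parts <- do.call(rbind, strsplit(names(counts), "\r", fixed = TRUE))
  out <- data.frame(family = parts[, 1], species = parts[, 2],
                    mode = parts[, 3], count = as.numeric(counts),
                    stringsAsFactors = FALSE)
  out[order(out$family, out$species, out$mode), , drop = FALSE]
}

#' Run the full analysis pipeline
#'
#' Reads observations and family annotations, applies the exclusion filters,
#' rolls encounters up to family counts, and runs both branches: the
#' descriptive branch pools all dives (integer counts) for the abundance
#' table, swimbladder percentages, species shares and the extraction
#' interval; the inferential branch restricts to transects, averages
#' replicate passes, and runs the two exact paired Wilcoxon tests (ratio and
#' extracted-family abundance) plus the Monte Carlo family-resampling test
#' against the annotated universe.  Identical inputs, configuration and seed
#' give an identical report.
#'
#' @param observations_path path to the observations file.
#' @param annotations_path path to the family-annotation file (the full
#'   candidate universe, e.g. 29 families).
#' @param cfg a [pipeline_config()].
#' @return a `study_report` list.
#' @export
run_pipeline <- function(observations_path, annotations_path,
                         cfg = pipeline_config()) {
  obs <- read_observations(observations_path)
  universe <- read_family_annotations(annotations_path)
  log_stage("read", "%d observations, %d families in universe",
            nrow(obs), nrow(universe))

  retained <- apply_filters(obs, cfg$filter)
  log_stage("filter", "%d rows in, %d retained (min_length_cm=%g, drop_unidentified=%s)",
            nrow(obs), nrow(retained), cfg$filter$min_length_cm,
            cfg$filter$drop_unidentified)

  tab <- rollup_to_family(retained)
  log_stage("rollup", "%d abundance cells", nrow(tab))

  # descriptive branch: all dives, raw integer counts
  pooled_all <- pool_counts(tab, "all_dives")
  desc <- summarize_descriptives(pooled_all, universe,
                                 pool_species_counts(retained))
  sponging_total <- desc$totals$sponging
  target <- NULL
  interval <- NULL
  sp_pool <- pooled_all[pooled_all$mode == "sponging", , drop = FALSE]
  if (nrow(sp_pool) > 0 && max(sp_pool$count) > 0) {
    target <- sp_pool$family[which.max(sp_pool$count)]
    interval <- extraction_interval(max(sp_pool$count), cfg$sponging_hours)
  }
  log_stage("descriptives", "sponging total %g; non-sponging total %g",
            desc$totals$sponging, desc$totals$non_sponging)

  # inferential branch: transects only, replicate-averaged
  transect_tab <- tab[tab$site_kind == "transect", , drop = FALSE]
  averaged <- average_replicates(transect_tab)
  ratio_pairs <- transect_ratio_pairs(averaged, universe, cfg$ratio,
                                      cfg$transect_ids)
  ratio_test <- wilcoxon_signed_rank_exact(ratio_pairs)
  abundance_pairs <- extracted_family_abundance_pairs(averaged,
                                                      cfg$transect_ids)
  abundance_test <- wilcoxon_signed_rank_exact(abundance_pairs)
  log_stage("wilcoxon", "ratio: W=%g p=%.6g; abundance: W=%g p=%.6g",
            ratio_test$w_statistic, ratio_test$p_two_sided,
            abundance_test$w_statistic, abundance_test$p_two_sided)

  stat <- sponging_family_stat(pooled_all, universe)
  n_draw <- cfg$resampling$n_draw %||% stat$n_families
  resampling <- family_resampling_test(
    universe, n_draw = n_draw, observed_no_sb = stat$n_no_sb,
    reps = cfg$resampling$reps, seed = cfg$resampling$seed,
    two_tail = cfg$resampling$two_tail)
  log_stage("resampling", "%d of %d sponging families lack swimbladders; p_mc=%.4g p_exact=%.4g",
            stat$n_no_sb, stat$n_families, resampling$p_mc, resampling$p_exact)

  report <- structure(list(
    pooled_table = pooled_all,
    totals = desc$totals,
    pct_no_sb_sponging = desc$pct_no_sb$raw$sponging,
    pct_no_sb_nonsponging = desc$pct_no_sb$raw$non_sponging,
    pct_no_sb_display = desc$pct_no_sb$display,
    family_pcts = desc$family_pcts,
    species_pcts = desc$species_pcts,
    target_family = target,
    extraction_interval_min = interval,
    ratio_test = ratio_test,
    abundance_test = abundance_test,
    resampling_test = resampling,
    ratio_pairs = ratio_pairs,
    abundance_pairs = abundance_pairs,
    config = list(min_length_cm = cfg$filter$min_length_cm,
                  drop_unidentified = cfg$filter$drop_unidentified,
                  offset = cfg$ratio$offset,
                  n_draw = n_draw, reps = cfg$resampling$reps,
                  seed = cfg$resampling$seed,
                  two_tail = cfg$resampling$two_tail,
                  sponging_hours = cfg$sponging_hours)),
    class = "study_report")
  check_report_consistency(report, universe)
  report
}

# Internal consistency: the report's percentages must recompute exactly from
# its own pooled table.
check_report_consistency <- function(report, universe) {
  no_sb <- universe$family[!universe$has_swimbladder]
  tab <- report$pooled_table
  for (m in MODES) {
    tot <- sum(tab$count[tab$mode == m])
    field <- if (m == "sponging") "pct_no_sb_sponging" else "pct_no_sb_nonsponging"
    if (tot == 0) {
      stopifnot(is.na(report[[field]]))
    } else {
      pct <- 100 * sum(tab$count[tab$mode == m & tab$family %in% no_sb]) / tot
      stopifnot(isTRUE(all.equal(pct, report[[field]])))
    }
  }
  invisible(TRUE)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report\n")
  cat(sprintf("  prey pooled over all dives: sponging %g, non-sponging %g\n",
              x$totals$sponging, x$totals$non_sponging))
  cat(sprintf("  %% in swimbladderless families: sponging %s, non-sponging %s\n",
              x$pct_no_sb_display$sponging, x$pct_no_sb_display$non_sponging))
  if (!is.null(x$target_family)) {
    cat(sprintf("  top sponging prey %s: one every %s minutes (%.2f)\n",
                x$target_family, round_half_up(x$extraction_interval_min),
                x$extraction_interval_min))
  }
  print(x$ratio_test)
  print(x$abundance_test)
  print(x$resampling_test)
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' Numbers are written at machine precision; identical inputs + seed give a
#' byte-identical file.
#'
#' @param report a `study_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- unclass(report)
  out$ratio_test <- unclass(out$ratio_test)
  out$abundance_test <- unclass(out$abundance_test)
  out$resampling_test <- unclass(out$resampling_test)
  out$ratio_pairs <- unclass(out$ratio_pairs)
  out$abundance_pairs <- unclass(out$abundance_pairs)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", pretty = TRUE)
  invisible(path)
}

#' Render a study report as text tables
#'
#' @param report a `study_report` (or a list read back from its JSON form).
#' @param format `"md"` for Markdown pipe tables, `"tsv"` for tab-separated.
#' @return character vector of lines.
#' @export
render_report <- function(report, format = c("md", "tsv")) {
  format <- match.arg(format)
  tab <- as.data.frame(report$pooled_table)
  wide <- stats::reshape(tab, idvar = "family", timevar = "mode",
                         direction = "wide")
  names(wide) <- sub("^count\\.", "", names(wide))
  for (m in MODES) if (!m %in% names(wide)) wide[[m]] <- 0
  wide <- wide[order(-wide$sponging, -wide$non_sponging), , drop = FALSE]
  line <- function(...) paste(..., sep = if (format == "md") " | " else "\t")
  header <- line("family", "sponging", "non_sponging")
  body <- vapply(seq_len(nrow(wide)), function(i)
    line(wide$family[i], wide$sponging[i], wide$non_sponging[i]), character(1))
  rows <- if (format == "md") {
    c(header, line("---", "---", "---"), body)
  } else c(header, body)
  tests <- c(
    sprintf("ratio test: W = %g, P = %s (n = %d)",
            report$ratio_test$w_statistic,
            signif(report$ratio_test$p_two_sided, 3),
            report$ratio_test$n_effective),
    sprintf("extracted-family abundance test: W = %g, P = %s (n = %d)",
            report$abundance_test$w_statistic,
            signif(report$abundance_test$p_two_sided, 3),
            report$abundance_test$n_effective),
    sprintf("family-resampling test: P = %s (analytic %s, %d reps)",
            signif(report$resampling_test$p_mc, 3),
            signif(report$resampling_test$p_exact, 3),
            report$resampling_test$reps))
  c(rows, "", tests)
}
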