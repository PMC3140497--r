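# Observation schema, tabular I/O, and the filtering / aggregation rules that
# turn raw prey encounters into analysis-ready family-level abundance tables.

OBS_COLUMNS <- c("dive_id", "site_kind", "transect_id", "replicate",
                 "mode", "family", "species", "length_cm", "identified")
SITE_KINDS <- c("transect", "verification")
MODES <- c("sponging", "non_sponging")
UNKNOWN_FAMILY <- "UNKNOWN"

#' Validate a prey-observation data frame
#'
#' Checks the encounter-level schema used throughout the pipeline: one row per
#' prey encounter with its sampling context (`dive_id`, `site_kind`,
#' `transect_id`, `replicate`, `mode`), taxonomy (`family`, `species`), an
#' optional length estimate in cm, and an `identified` flag.  Enforced
#' invariants: transect rows carry a transect id, unidentified rows carry the
#' `UNKNOWN` family sentinel, and lengths (when present) are positive.
#'
#' @param obs data frame of prey observations.
#' @return the validated data frame, invisibly unchanged apart from column
#'   type coercion.
#' @export
validate_observations <- function(obs) {
  missing_cols <- setdiff(OBS_COLUMNS, names(obs))
  if (length(missing_cols) > 0) {
    stop_stage("read", "missing required column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  obs$site_kind <- as.character(obs$site_kind)
  obs$mode <- as.character(obs$mode)
  obs$family <- normalize_family(obs$family)
  obs$species <- as.character(obs$species)
  obs$species[!is.na(obs$species) & obs$species == ""] <- NA_character_
  obs$transect_id <- as.character(obs$transect_id)
  obs$transect_id[!is.na(obs$transect_id) & obs$transect_id == ""] <- NA_character_

  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      stop_stage("read", "%s (row%s %s)", what,
                 if (length(rows) > 1) "s" else "",
                 paste(utils::head(rows, 5), collapse = ", "))
    }
  }
  bad(!obs$site_kind %in% SITE_KINDS,
      sprintf("site_kind must be one of {%s}", paste(SITE_KINDS, collapse = ", ")))
  bad(!obs$mode %in% MODES,
      sprintf("mode must be one of {%s}", paste(MODES, collapse = ", ")))
  if (!is.numeric(obs$replicate)) {
    repl <- suppressWarnings(as.numeric(obs$replicate))
    bad(is.na(repl) & !is.na(obs$replicate), "non-numeric replicate")
    obs$replicate <- repl
  }
  bad(is.na(obs$replicate) | obs$replicate < 1 | obs$replicate %% 1 != 0,
      "replicate must be a positive integer")
  obs$replicate <- as.integer(obs$replicate)
  if (!is.numeric(obs$length_cm)) {
    len <- suppressWarnings(as.numeric(obs$length_cm))
    bad(is.na(len) & !is.na(obs$length_cm) & obs$length_cm != "",
        "non-numeric length_cm")
    obs$length_cm <- len
  }
  bad(!is.na(obs$length_cm) & obs$length_cm <= 0, "length_cm must be > 0")
  obs$identified <- parse_flag(obs$identified)
  bad(is.na(obs$identified), "identified must be a boolean")
  bad(obs$site_kind == "transect" & is.na(obs$transect_id),
      "transect observations require a transect_id")
  bad(!obs$identified & obs$family != UNKNOWN_FAMILY,
      "unidentified observations must have family=UNKNOWN")
  bad(is.na(obs$family) | obs$family == "", "family must be non-empty")
  obs[OBS_COLUMNS]
}

#' Read prey observations from a delimited text file
#'
#' The file must carry the header
#' `dive_id,site_kind,transect_id,replicate,mode,family,species,length_cm,identified`.
#' Empty strings encode missing optional fields (`transect_id`, `species`,
#' `length_cm`).  Row order is preserved and malformed rows are reported with
#' their (data-)row numbers.
#'
#' @param path path to the observations file.
#' @param sep field delimiter (default comma).
#' @return a validated observation data frame (see [validate_observations()]).
#' @export
read_observations <- function(path, sep = ",") {
  if (!file.exists(path)) {
    stop_stage("read", "observations file not found: %s", path)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", na.strings = NULL,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0) {
    raw <- as.data.frame(stats::setNames(
      replicate(length(OBS_COLUMNS), character(0), simplify = FALSE),
      names(raw)))
  }
  missing_cols <- setdiff(OBS_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop_stage("read", "missing required column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  raw$length_cm[raw$length_cm == ""] <- NA_character_
  validate_observations(raw)
}

#' Write prey observations to a delimited text file
#'
#' Inverse of [read_observations()]; missing optional fields are written as
#' empty strings so that a write/read cycle reproduces the input exactly.
#'
#' @param obs validated observation data frame.
#' @param path output file path.
#' @param sep field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path, sep = ",") {
  obs <- validate_observations(obs)
  out <- obs
  out$identified <- ifelse(out$identified, "true", "false")
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a family universe
#'
#' The universe is the catalog of candidate prey families, each with a
#' definite swimbladder status and an evidence tag (e.g. "dissected",
#' "literature").  It doubles as the null universe for the family-resampling
#' test, where its size and swimbladderless count define the sampling null.
#'
#' @param family character vector of family names (unique after
#'   whitespace/case normalization).
#' @param has_swimbladder logical vector, no missing values.
#' @param evidence optional character vector of evidence tags.
#' @return a `family_universe` data frame with one row per family.
#' @export
family_universe <- function(family, has_swimbladder, evidence = NA_character_) {
  family <- normalize_family(family)
  has_swimbladder <- as.logical(has_swimbladder)
  if (anyNA(has_swimbladder)) {
    stop_stage("universe", "has_swimbladder must be a definite boolean for every family")
  }
  if (anyDuplicated(family)) {
    dup <- unique(family[duplicated(family)])
    stop_stage("universe", "duplicate family name(s): %s", paste(dup, collapse = ", "))
  }
  out <- data.frame(family = family,
                    has_swimbladder = has_swimbladder,
                    evidence = rep_len(as.character(evidence), length(family)),
                    stringsAsFactors = FALSE)
  class(out) <- c("family_universe", "data.frame")
  out
}

#' Read a family annotation table
#'
#' Expects the header `family,has_swimbladder,evidence`; `has_swimbladder`
#' accepts Y/N, true/false, 1/0.  Duplicate rows for one family with the same
#' status are merged (several species can share a family); rows asserting
#' conflicting status for one family raise a data-conflict error.
#'
#' @param path path to the annotation file.
#' @param sep field delimiter (default comma).
#' @return a [family_universe()].
#' @export
read_family_annotations <- function(path, sep = ",") {
  if (!file.exists(path)) {
    stop_stage("read", "family annotation file not found: %s", path)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  needed <- c("family", "has_swimbladder")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop_stage("read", "missing required column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  if (!"evidence" %in% names(raw)) raw$evidence <- NA_character_
  raw$family <- normalize_family(raw$family)
  flag <- parse_flag(raw$has_swimbladder)
  if (anyNA(flag)) {
    rows <- which(is.na(flag))
    stop_stage("read", "unparseable has_swimbladder value(s) in row(s) %s",
               paste(utils::head(rows, 5), collapse = ", "))
  }
  raw$has_swimbladder <- flag
  status <- tapply(raw$has_swimbladder, raw$family,
                   function(v) length(unique(v)))
  conflicts <- names(status)[status > 1]
  if (length(conflicts) > 0) {
    stop_stage("read", "conflicting swimbladder status for family: %s",
               paste(conflicts, collapse = ", "))
  }
  first <- !duplicated(raw$family)
  family_universe(raw$family[first], raw$has_swimbladder[first],
                  raw$evidence[first])
}

#' Write a family annotation table
#'
#' @param universe a [family_universe()].
#' @param path output file path.
#' @param sep field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_family_annotations <- function(universe, path, sep = ",") {
  out <- as.data.frame(universe)
  out$has_swimbladder <- ifelse(out$has_swimbladder, "Y", "N")
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Filter configuration
#'
#' The study removed prey estimated at under 7 cm (too small to be a sponging
#' target) and prey that could not be identified to family.  The length rule
#' is strictly "less than": a 7.0 cm prey is retained.  Observations with no
#' length estimate are retained, since only prey known or estimated to be
#' small were removed.
#'
#' @param min_length_cm minimum retained length in cm (default 7).
#' @param drop_unidentified drop rows with `identified = FALSE` (default TRUE).
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_length_cm = 7, drop_unidentified = TRUE) {
  stopifnot(is.numeric(min_length_cm), min_length_cm >= 0,
            is.logical(drop_unidentified))
  structure(list(min_length_cm = min_length_cm,
                 drop_unidentified = drop_unidentified),
            class = "filter_config")
}

#' Apply the exclusion filters to raw observations
#'
#' Removes encounters with `length_cm < min_length_cm` (strict inequality) and,
#' when `drop_unidentified`, encounters not identified to family.  Filtering is
#' idempotent and order-independent, and never fails.
#'
#' @param obs validated observation data frame.
#' @param cfg a [filter_config()].
#' @return the retained subset of `obs`, row order preserved.
#' @export
apply_filters <- function(obs, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  keep <- rep(TRUE, nrow(obs))
  keep <- keep & !(!is.na(obs$length_cm) & obs$length_cm < cfg$min_length_cm)
  if (cfg$drop_unidentified) keep <- keep & obs$identified
  obs[keep, , drop = FALSE]
}

#' Roll observations up to family-level counts
#'
#' Aggregates filtered encounters into an abundance table with one cell per
#' (family, mode, site_kind, transect_id, replicate).  All downstream analysis
#' is at the family level.  Observations still carrying the `UNKNOWN` family
#' sentinel are a contract violation: filters must run first.
#'
#' @param obs filtered, validated observation data frame.
#' @return an `abundance_table` data frame with integer `count` cells and a
#'   `provenance` attribute describing this stage.
#' @export
rollup_to_family <- function(obs) {
  if (any(obs$family == UNKNOWN_FAMILY)) {
    stop_stage("rollup", "observations with family=UNKNOWN present; apply filters first")
  }
  if (nrow(obs) == 0) {
    tab <- data.frame(family = character(0), mode = character(0),
                      site_kind = character(0), transect_id = character(0),
                      replicate = integer(0), count = numeric(0),
                      stringsAsFactors = FALSE)
    return(new_abundance_table(tab, "rollup_to_family on 0 observations"))
  }
  key <- interaction(obs$family, obs$mode, obs$site_kind,
                     ifelse(is.na(obs$transect_id), "", obs$transect_id),
                     obs$replicate, drop = TRUE, sep = "\r")
  counts <- table(key)
  parts <- do.call(rbind, strsplit(names(counts), "\r", fixed = TRUE))
  tab <- data.frame(family = parts[, 1], mode = parts[, 2],
                    site_kind = parts[, 3],
                    transect_id = ifelse(parts[, 4] == "", NA_character_, parts[, 4]),
                    replicate = as.integer(parts[, 5]),
                    count = as.numeric(counts),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$family, tab$mode, tab$site_kind,
                   tab$transect_id, tab$replicate), , drop = FALSE]
  rownames(tab) <- NULL
  new_abundance_table(tab,
                      sprintf("rollup_to_family on %d observations", nrow(obs)))
}

new_abundance_table <- function(tab, provenance) {
  attr(tab, "provenance") <- provenance
  class(tab) <- c("abundance_table", "data.frame")
  tab
}

#' Average replicate passes into a single transect value
#'
#' For each (family, mode, transect), the count becomes the arithmetic mean
#' across replicate passes, with a family absent from a pass contributing 0 to
#' the mean.  The number of passes is taken as the number of distinct
#' replicate indices present anywhere in the table (the study design: every
#' transect swum twice in each mode), overridable via `n_replicates`.  Only
#' transect cells may be present; verification dives are never averaged so
#' that descriptive pooled counts stay integral.
#'
#' @param table an `abundance_table` restricted to `site_kind = "transect"`.
#' @param n_replicates optional explicit number of replicate passes.
#' @return an `abundance_table` with a single pseudo-replicate (index 1) and
#'   rational counts.
#' @export
average_replicates <- function(table, n_replicates = NULL) {
  if (any(table$site_kind != "transect")) {
    stop_stage("average", "verification-dive cells present; restrict to transects first")
  }
  if (nrow(table) == 0) return(table)
  n_rep <- n_replicates %||% length(unique(table$replicate))
  stopifnot(n_rep >= 1)
  key <- interaction(table$family, table$mode, table$transect_id,
                     drop = TRUE, sep = "\r")
  sums <- tapply(table$count, key, sum)
  parts <- do.call(rbind, strsplit(names(sums), "\r", fixed = TRUE))
  out <- data.frame(family = parts[, 1], mode = parts[, 2],
                    site_kind = "transect", transect_id = parts[, 3],
                    replicate = 1L,
                    count = as.numeric(sums) / n_rep,
                    stringsAsFactors = FALSE)
  out <- out[order(out$family, out$mode, out$transect_id), , drop = FALSE]
  rownames(out) <- NULL
  new_abundance_table(out, paste0(attr(table, "provenance") %||% "",
                                  sprintf("; replicates averaged (n=%d)", n_rep)))
}

#' Pool abundance counts over dives
#'
#' Collapses an abundance table to (family, mode) totals.  `all_dives` pools
#' transects and verification dives and is the descriptive scope (requires
#' raw, un-averaged integer counts so that totals equal numbers of prey);
#' `transects_only` restricts to the systematic transect data, the only scope
#' used for inference.
#'
#' @param table an `abundance_table`.
#' @param scope `"all_dives"` or `"transects_only"`.
#' @return a data frame `family, mode, count`, zero-filled over the two modes
#'   for every family present in scope.
#' @export
pool_counts <- function(table, scope = c("all_dives", "transects_only")) {
  scope <- match.arg(scope)
  if (scope == "transects_only") {
    table <- table[table$site_kind == "transect", , drop = FALSE]
  } else if (nrow(table) > 0 && any(table$count %% 1 != 0)) {
    stop_stage("pool", "all_dives pooling requires raw integer counts (do not average first)")
  }
  if (nrow(table) == 0) {
    return(data.frame(family = character(0), mode = character(0),
                      count = numeric(0), stringsAsFactors = FALSE))
  }
  grid <- expand.grid(family = sort(unique(table$family)), mode = MODES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sums <- tapply(table$count, list(table$family, table$mode), sum)
  grid$count <- vapply(seq_len(nrow(grid)), function(i) {
    v <- sums[grid$family[i], ]
    v <- v[grid$mode[i]]
    if (is.na(v)) 0 else as.numeric(v)
  }, numeric(1))
  grid[order(grid$family, grid$mode), , drop = FALSE]
}
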