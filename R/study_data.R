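# The published pooled prey-abundance table from the Shark Bay human-sponging
# field study, shipped as a reference dataset so the descriptive results can
# be recomputed without the original dive videos.

#' Published pooled prey counts
#'
#' The study's pooled abundance table (transects and verification dives
#' combined, after the under-7 cm / unidentified exclusions): per species row,
#' the prey counts extracted during sponging and observed during
#' non-sponging, with the family's swimbladder status.  Sponging column total
#' 134 prey over 13.3 hours of human sponging; non-sponging total 85.
#'
#' @return a data frame with columns `common_name`, `family`, `species`,
#'   `sponging`, `non_sponging`, `has_swimbladder`.
#' @export
study_pooled_counts <- function() {
  r <- function(common, fam, sp, s, ns, sb)
    data.frame(common_name = common, family = fam, species = sp,
               sponging = s, non_sponging = ns, has_swimbladder = sb,
               stringsAsFactors = FALSE)
  rbind(
    r("barred sandperch",     "Pinguipedidae",   "Parapercis nebulosa",      87, 15, FALSE),
    r("sand lizardfish",      "Synodontidae",    "Synodus dermatogenys",      9,  0, FALSE),
    r("cuttlefishes",         "Sepiidae",        NA,                          5,  0, FALSE),
    r("stingrays",            "Dasyatidae",      NA,                          1,  1, FALSE),
    r("lefteye flounders",    "Bothidae",        NA,                          1,  0, FALSE),
    r("painted maskray",      "Dasyatidae",      "Neotrygon leylandi",        1,  0, FALSE),
    r("tasselsnout flathead", "Platycephalidae", "Thysanophrys cirronasa",    1,  0, FALSE),
    r("purple tuskfish",      "Labridae",        "Choerodon cephalotes",     23, 23, TRUE),
    r("freckled goatfish",    "Mullidae",        "Upeneus tragula",           4,  0, TRUE),
    r("wrasses",              "Labridae",        NA,                          2,  0, TRUE),
    r("striped whiptail",     "Nemipteridae",    "Pentapodus vitta",          0, 29, TRUE),
    r("margined coralfish",   "Chaetodontidae",  "Chelmon marginalis",        0,  6, TRUE),
    r("blackspot tuskfish",   "Labridae",        "Choerodon schoenleinii",    0,  5, TRUE),
    r("bluntheaded wrasse",   "Labridae",        "Thalassoma amblycephalum",  0,  2, TRUE),
    r("humpback batfish",     "Ephippidae",      "Platax batavianus",         0,  2, TRUE),
    r("yellowtail clownfish", "Pomacentridae",   "Amphiprion clarkii",        0,  1, TRUE),
    r("puffers",              "Tetraodontidae",  NA,                          0,  1, TRUE))
}

#' Family universe of the published study counts
#'
#' The swimbladder annotations for the families appearing in
#' [study_pooled_counts()] (13 families; 6 lack swimbladders).  Note this is
#' the dive prey list only, not the full 29-family historical resampling
#' universe.
#'
#' @return a [family_universe()].
#' @export
study_family_universe <- function() {
  tab <- study_pooled_counts()
  first <- !duplicated(tab$family)
  family_universe(tab$family[first], tab$has_swimbladder[first],
                  evidence = "published")
}

#' Expand pooled species counts into encounter-level observations
#'
#' Turns a pooled species x mode count table into one observation row per
#' prey, so the descriptive branch of the pipeline can be exercised on the
#' published totals.  The per-dive split of the pooled counts was not
#' published, so all rows are attributed to a single pseudo-dive per mode
#' (`site_kind = "verification"`), with no length estimate (retained by the
#' filters) and `identified = TRUE`.
#'
#' @param pooled a table in the shape of [study_pooled_counts()].
#' @return a validated observation data frame.
#' @export
expand_pooled_to_observations <- function(pooled = study_pooled_counts()) {
  rows <- list()
  for (i in seq_len(nrow(pooled))) {
    for (mode in MODES) {
      n <- pooled[[if (mode == "sponging") "sponging" else "non_sponging"]][i]
      if (n > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          dive_id = paste0("pooled-", mode), site_kind = "verification",
          transect_id = NA_character_, replicate = 1L, mode = mode,
          family = pooled$family[i], species = pooled$species[i],
          length_cm = NA_real_, identified = TRUE,
          stringsAsFactors = FALSE)[rep(1, n), , drop = FALSE]
      }
    }
  }
  validate_observations(do.call(rbind, rows))
}
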