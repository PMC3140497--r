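# Shared builders and independent oracles for the test suite.

obs_row <- function(dive_id = "V1", site_kind = "verification",
                    transect_id = NA_character_, replicate = 1L,
                    mode = "sponging", family = "Pinguipedidae",
                    species = NA_character_, length_cm = NA_real_,
                    identified = TRUE) {
  data.frame(dive_id = dive_id, site_kind = site_kind,
             transect_id = transect_id, replicate = replicate, mode = mode,
             family = family, species = species, length_cm = length_cm,
             identified = identified, stringsAsFactors = FALSE)
}

obs_frame <- function(...) validate_observations(rbind(...))

# A cell of an abundance-table-like data frame (transect scope by default).
cell <- function(family, mode, transect_id, count, replicate = 1L,
                 site_kind = "transect") {
  data.frame(family = family, mode = mode, site_kind = site_kind,
             transect_id = transect_id, replicate = as.integer(replicate),
             count = count, stringsAsFactors = FALSE)
}

abundance_frame <- function(...) {
  tab <- rbind(...)
  class(tab) <- c("abundance_table", "data.frame")
  tab
}

# Wide published count table -> long (family, mode, count) pooled mapping.
pooled_long <- function(tab) {
  long <- rbind(
    data.frame(family = tab$family, mode = "sponging",
               count = tab$sponging, stringsAsFactors = FALSE),
    data.frame(family = tab$family, mode = "non_sponging",
               count = tab$non_sponging, stringsAsFactors = FALSE))
  stats::aggregate(count ~ family + mode, long, sum)
}

# Independent brute-force oracle for the exact signed-rank test: literal
# enumeration of every sign vector via expand.grid.
wilcoxon_brute <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  ranks <- rank(abs(d))
  w_obs <- sum(ranks[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% ranks)
  eps <- 1e-9
  p <- min(1, 2 * min(mean(ws <= w_obs + eps), mean(ws >= w_obs - eps)))
  list(w = w_obs, p = p, n = n)
}
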