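# Camp-level summary tables, the exact Wilcoxon signed-rank test used
# for small paired camp samples, and Cohen's d effect sizes.

#' Exact Wilcoxon signed-rank test
#'
#' Paired one-sample test on differences `a - b` (or on `a` alone when
#' `b` is missing). `V` is the sum of the ranks of the positive
#' differences, ranking `|d|` with average ranks for ties after zero
#' differences are dropped. The two-sided p value is exact, computed by
#' enumerating the null distribution over all `2^n` sign assignments
#' (by convolution), which is feasible for the camp-level sample sizes
#' (`n <= 25`) this is meant for.
#'
#' @param a,b paired numeric vectors.
#' @return list with `V`, `p_value`, `n` (non-zero pairs), and
#'   `n_zero` dropped pairs.
#' @export
wilcoxon_exact <- function(a, b = NULL) {
  d <- if (is.null(b)) a else a - b
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero; the test statistic is undefined")
  if (n > 25) stop("exact enumeration supported for n <= 25 non-zero pairs")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  # null distribution of V by convolution over sign assignments; ranks
  # doubled so tied average ranks (k + 0.5) stay on an integer lattice
  r2 <- round(2 * r)
  dist <- c(1, rep(0, sum(r2)))
  for (rk in r2) {
    shifted <- c(rep(0, rk), dist[seq_len(length(dist) - rk)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  v2 <- round(2 * V)
  p_lo <- sum(dist[seq_len(v2 + 1)])              # P(V' <= V)
  p_hi <- sum(dist[seq.int(v2 + 1, length(dist))]) # P(V' >= V)
  list(V = V, p_value = min(1, 2 * min(p_lo, p_hi)), n = n, n_zero = n_zero)
}

#' Cohen's d with a bootstrap confidence interval
#'
#' Standardised mean difference `(mean(x) - mean(y)) / s_pooled` with
#' the pooled standard deviation, plus a percentile bootstrap CI.
#'
#' @param x,y numeric samples (each of size >= 2).
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level.
#' @param seed optional seed for the bootstrap.
#' @return list with `d`, `ci_low`, `ci_high`.
#' @export
cohens_d <- function(x, y, n_boot = 1000, conf = 0.95, seed = NULL) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  d_of <- function(x, y) {
    sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    if (sp == 0) stop("zero pooled variance; Cohen's d is undefined")
    (mean(x) - mean(y)) / sp
  }
  d <- d_of(x, y)
  if (!is.null(seed)) set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(k)
    d_of(sample(x, replace = TRUE), sample(y, replace = TRUE)), numeric(1))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  list(d = d, ci_low = qs[1], ci_high = qs[2])
}

#' Cross-camp mean row for a camp-by-gender land summary
#'
#' Column-wise unweighted means over camps; the ratio column is the
#' mean of per-camp male:female ratios, while the overlap percentage is
#' recomputed as the ratio of mean areas (mean both-gender area over
#' mean total area), not the mean of percentages.
#'
#' @param df data frame with columns `total_km2`, `male_km2`,
#'   `female_km2`, `ratio`, `both_km2` (one row per camp).
#' @return one-row data frame of the same shape plus `overlap_pct`.
#' @export
summary_mean_row <- function(df) {
  need <- c("total_km2", "male_km2", "female_km2", "ratio", "both_km2")
  stopifnot(all(need %in% names(df)))
  data.frame(camp_id = "Mean", year = NA,
             total_km2 = mean(df$total_km2),
             male_km2 = mean(df$male_km2),
             female_km2 = mean(df$female_km2),
             ratio = mean(df$ratio),
             both_km2 = mean(df$both_km2),
             overlap_pct = 100 * mean(df$both_km2) / mean(df$total_km2),
             stringsAsFactors = FALSE)
}

#' Assemble the camp-by-gender summary table
#'
#' One row per camp (areas from [gender_segregation()], mean daily
#' distances by gender, MCP areas by gender) plus the cross-camp
#' unweighted mean row.
#'
#' @param segs list of `cpf_segregation` objects, one per camp.
#' @param distances optional data frame `camp_id`, `gender`,
#'   `daily_km` of per-person-day distances.
#' @param mcps optional data frame `camp_id`, `gender`, `area_km2`.
#' @return data frame with one row per camp and a final `Mean` row.
#' @export
camp_summary <- function(segs, distances = NULL, mcps = NULL) {
  rows <- do.call(rbind, lapply(segs, function(s) data.frame(
    camp_id = s$camp_id, year = s$year,
    total_km2 = s$total_km2, male_km2 = s$male_km2,
    female_km2 = s$female_km2, ratio = s$male_female_ratio,
    both_km2 = s$both_km2, overlap_pct = s$overlap_pct,
    stringsAsFactors = FALSE)))
  add_gender_col <- function(rows, df, value, prefix) {
    for (g in c("male", "female")) {
      col <- paste0(prefix, "_", g)
      rows[[col]] <- NA_real_
      for (r in seq_len(nrow(rows))) {
        sel <- df$camp_id == rows$camp_id[r] & df$gender == g
        if (any(sel)) rows[[col]][r] <- mean(df[[value]][sel])
      }
    }
    rows
  }
  if (!is.null(distances))
    rows <- add_gender_col(rows, distances, "daily_km", "mean_daily_km")
  if (!is.null(mcps))
    rows <- add_gender_col(rows, mcps, "area_km2", "mcp_km2")
  mean_row <- summary_mean_row(rows)
  for (col in setdiff(names(rows), names(mean_row)))
    mean_row[[col]] <- mean(rows[[col]], na.rm = TRUE)
  rbind(rows, mean_row[names(rows)])
}

#' Export tidy model-ready tables
#'
#' Writes the per-person-day metrics table, the sociality table and a
#' column dictionary as CSVs for external model fitting (for example
#' hierarchical additive models of distance, exploration, sinuosity or
#' proximity).
#'
#' @param per_day data frame of per-person-day metrics (must include
#'   `person_id`; typically `daily_km`, `daily_m2`, `cumulative_m2`,
#'   `outbound`, `inbound`).
#' @param sociality a [sociality_table()] data frame.
#' @param persons person metadata.
#' @param dir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
export_model_tables <- function(per_day, sociality, persons, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- match(per_day$person_id, persons$person_id)
  if (anyNA(m)) stop("per-day rows with no matching person metadata")
  per_day$gender <- persons$gender[m]
  per_day$age <- persons$age[m]
  per_day$camp_id <- persons$camp_id[m]
  per_day$has_dependent_infant <- persons$has_dependent_infant[m]
  f1 <- file.path(dir, "person_days.csv")
  f2 <- file.path(dir, "sociality.csv")
  f3 <- file.path(dir, "column_dictionary.csv")
  utils::write.csv(per_day, f1, row.names = FALSE)
  utils::write.csv(sociality, f2, row.names = FALSE)
  dict <- data.frame(
    column = c("person_id", "camp_id", "gender", "age", "date", "daily_km",
               "daily_m2", "cumulative_m2", "outbound", "inbound",
               "has_dependent_infant", "dist_from_camp_m", "nn_dist_m",
               "within_5m", "n_concurrent"),
    description = c("individual identifier", "camp identifier",
                    "male or female", "age in years", "observation date",
                    "total distance walked that day (km)",
                    "daily land visited (m2)",
                    "cumulative land explored through that day (m2)",
                    "outbound sinuosity of the principal bout",
                    "inbound sinuosity of the principal bout",
                    "cares for a co-resident child aged <= 2",
                    "distance from camp centroid at the sampled fix (m)",
                    "nearest-neighbour distance (m)",
                    "nearest neighbour within 5 m (inclusive)",
                    "individuals with a fix within +/-60 s"))
  utils::write.csv(dict, f3, row.names = FALSE)
  invisible(c(f1, f2, f3))
}
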