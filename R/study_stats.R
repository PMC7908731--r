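#' Per-participant medians over successful trials
#'
#' Aggregates a tidy trial-level task-result table to one row per
#' participant per condition: the median completion time over successful
#' trials only (cells with no successful trial are kept but flagged
#' missing) plus sums of any auxiliary count columns (drops, releases,
#' ...).
#'
#' @param table data.frame with columns `participant`, the condition
#'   columns named in `by`, `success` (0/1) and `completion_time_s`;
#'   any extra numeric columns are treated as per-trial counts and
#'   summed.
#' @param by character vector of condition column names (default
#'   `"condition"`).
#' @return data.frame with one row per (participant, condition) cell:
#'   `median_time`, `n_success`, `n_trials`, `missing`, and summed
#'   counts.
#' @export
participant_medians <- function(table, by = "condition") {
  if (!nrow(table %||% data.frame())) abort_data("empty result table")
  need <- c("participant", by, "success", "completion_time_s")
  if (!all(need %in% names(table)))
    abort_config("table needs columns: ", paste(need, collapse = ", "))
  if (!all(table$success %in% c(0, 1)))
    abort_data("success must be 0/1")
  bad <- table$success == 1 & !(table$completion_time_s > 0)
  if (any(bad)) abort_data("successful trials must have positive times")
  count_cols <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                        c("participant", "success", "completion_time_s",
                          "trial", by))
  key <- interaction(table[c("participant", by)], drop = TRUE, sep = "\r")
  out <- lapply(split(seq_len(nrow(table)), key), function(idx) {
    rows <- table[idx, , drop = FALSE]
    ok <- rows$success == 1
    cell <- rows[1, c("participant", by), drop = FALSE]
    cell$median_time <- if (any(ok))
      stats::median(rows$completion_time_s[ok]) else NA_real_
    cell$n_success <- sum(ok)
    cell$n_trials <- nrow(rows)
    cell$missing <- !any(ok)
    for (cc in count_cols) cell[[cc]] <- sum(rows[[cc]])
    cell
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Dunn-Sidak correction for multiple comparisons
#'
#' `p_adj = 1 - (1 - p)^m` for `m` comparisons; always >= the raw p.
#'
#' @param p numeric vector of p-values.
#' @param m number of comparisons (default `length(p)`).
#' @return Corrected p-values.
#' @export
dunn_sidak <- function(p, m = length(p)) pmin(1, 1 - (1 - p)^m)

#' Statistical comparison plan
#'
#' Declares which test to run over an aggregated medians table, how
#' groups and pairing units are identified, and whether pairwise
#' follow-ups are corrected. Pre-planned hypotheses run uncorrected;
#' post-hoc plans use the Dunn-Sidak correction.
#'
#' @param test one of `"wilcoxon_signed_rank"`, `"kruskal_wallis"`,
#'   `"anova_tukey"`.
#' @param group_col column defining the compared groups.
#' @param value_col column holding the aggregated values.
#' @param id_cols columns identifying the pairing unit (required for the
#'   signed-rank test; used to pair the follow-ups otherwise).
#' @param alpha significance level (default 0.05).
#' @param correction `"none"` or `"dunn_sidak"` for pairwise follow-ups.
#' @return An object of class `comparison_plan`.
#' @export
comparison_plan <- function(test = c("wilcoxon_signed_rank",
                                     "kruskal_wallis", "anova_tukey"),
                            group_col = "group", value_col = "value",
                            id_cols = NULL, alpha = 0.05,
                            correction = c("none", "dunn_sidak")) {
  test <- match.arg(test)
  correction <- match.arg(correction)
  if (alpha <= 0 || alpha >= 1) abort_config("alpha must be in (0, 1)")
  structure(list(test = test, group_col = group_col,
                 value_col = value_col, id_cols = id_cols,
                 alpha = alpha, correction = correction),
            class = "comparison_plan")
}

#' Run a planned comparison over aggregated medians
#'
#' Records a Shapiro-Wilk normality check per group, then delegates the
#' planned test to the standard implementation: paired Wilcoxon
#' signed-rank (two groups, paired by `id_cols`), Kruskal-Wallis with
#' pairwise signed-rank follow-ups when significant, or one-way ANOVA
#' with Tukey HSD. An all-ties signed-rank comparison returns a flagged
#' no-information result rather than an arbitrary p-value.
#'
#' @param data data.frame of aggregated values (e.g. from
#'   [participant_medians()], possibly stacked across conditions).
#' @param plan a [comparison_plan()].
#' @return A report list: test name, per-group `n`, `shapiro` gate,
#'   `p_value`, optional `pairwise` table, `all_ties` flag.
#' @export
run_comparison <- function(data, plan) {
  if (!inherits(plan, "comparison_plan")) abort_config("plan required")
  g <- factor(data[[plan$group_col]])
  v <- data[[plan$value_col]]
  if (is.null(v)) abort_config("missing value column '", plan$value_col, "'")
  keep <- !is.na(v)
  g <- g[keep]; v <- v[keep]; data <- data[keep, , drop = FALSE]
  shapiro <- vapply(split(v, g), function(x) {
    if (length(unique(x)) < 3) NA_real_ else stats::shapiro.test(x)$p.value
  }, numeric(1))
  report <- list(test = plan$test, alpha = plan$alpha,
                 n_per_group = as.vector(table(g)),
                 groups = levels(g), shapiro = shapiro,
                 correction = plan$correction, all_ties = FALSE)
  if (plan$test == "wilcoxon_signed_rank") {
    if (nlevels(g) != 2) abort_config("signed-rank test needs 2 groups")
    if (is.null(plan$id_cols)) abort_config("signed-rank test needs id_cols")
    pairs <- pair_values(data, plan, levels(g))
    d <- pairs[[1]] - pairs[[2]]
    if (all(d == 0)) {
      report$all_ties <- TRUE
      report$p_value <- NA_real_
    } else {
      report$p_value <- suppressWarnings(
        stats::wilcox.test(pairs[[1]], pairs[[2]], paired = TRUE))$p.value
    }
  } else if (plan$test == "kruskal_wallis") {
    report$p_value <- stats::kruskal.test(v, g)$p.value
    if (is.finite(report$p_value) && report$p_value < plan$alpha)
      report$pairwise <- pairwise_followup(data, plan, levels(g))
  } else {
    df <- data.frame(v = v, g = g)
    fit <- stats::aov(v ~ g, data = df)
    report$p_value <- summary(fit)[[1]][["Pr(>F)"]][1]
    if (is.finite(report$p_value) && report$p_value < plan$alpha) {
      tk <- stats::TukeyHSD(fit)$g
      report$pairwise <- data.frame(pair = rownames(tk),
                                    p_adj = tk[, "p adj"],
                                    row.names = NULL)
    }
  }
  report
}

# align the two groups' values on the pairing unit
pair_values <- function(data, plan, lv) {
  lv <- as.character(lv)
  g <- as.character(data[[plan$group_col]])
  a <- data[g == lv[1], , drop = FALSE]
  b <- data[g == lv[2], , drop = FALSE]
  ia <- interaction(a[plan$id_cols], drop = TRUE)
  ib <- interaction(b[plan$id_cols], drop = TRUE)
  common <- intersect(as.character(ia), as.character(ib))
  if (!length(common)) abort_config("no paired observations across groups")
  if (anyDuplicated(as.character(ia)) || anyDuplicated(as.character(ib)))
    abort_config("pairing ids are not unique within groups")
  list(a[[plan$value_col]][match(common, as.character(ia))],
       b[[plan$value_col]][match(common, as.character(ib))])
}

pairwise_followup <- function(data, plan, lv) {
  lv <- as.character(lv)
  combos <- utils::combn(lv, 2, simplify = FALSE)
  p <- vapply(combos, function(cp) {
    sub <- data[as.character(data[[plan$group_col]]) %in% cp, ,
                drop = FALSE]
    sub[[plan$group_col]] <- factor(as.character(sub[[plan$group_col]]),
                                    levels = cp)
    if (!is.null(plan$id_cols)) {
      pr <- pair_values(sub, list(group_col = plan$group_col,
                                  value_col = plan$value_col,
                                  id_cols = plan$id_cols), cp)
      if (all(pr[[1]] == pr[[2]])) return(NA_real_)
      suppressWarnings(stats::wilcox.test(pr[[1]], pr[[2]],
                                          paired = TRUE))$p.value
    } else {
      suppressWarnings(
        stats::wilcox.test(sub[[plan$value_col]] ~
                             sub[[plan$group_col]]))$p.value
    }
  }, numeric(1))
  p_adj <- if (plan$correction == "dunn_sidak") dunn_sidak(p) else p
  data.frame(pair = vapply(combos, paste, character(1), collapse = " vs "),
             p_raw = p, p_adj = p_adj)
}

#' Kruskal-Wallis analysis of aggregated preference ranks
#'
#' Users rank the algorithms after each task; rows must form a
#' permutation of 1..k per participant-task. Runs a Kruskal-Wallis test
#' across algorithms over the pooled ranks, with Dunn-Sidak-corrected
#' pairwise signed-rank follow-ups (paired on participant-task) when
#' significant, and reports median ranks.
#'
#' @param ranks long data.frame with columns `participant`, `task`,
#'   `algorithm`, `rank`.
#' @param alpha significance level (default 0.05).
#' @return Report list: `median_ranks`, `kruskal_p`, optional `pairwise`.
#' @export
preference_rank_analysis <- function(ranks, alpha = 0.05) {
  need <- c("participant", "task", "algorithm", "rank")
  if (!all(need %in% names(ranks)))
    abort_config("ranks needs columns: ", paste(need, collapse = ", "))
  k <- length(unique(ranks$algorithm))
  unit <- interaction(ranks$participant, ranks$task, drop = TRUE)
  for (u in levels(unit)) {
    r <- sort(ranks$rank[unit == u])
    if (!identical(as.integer(r), seq_len(k)))
      abort_data("ranks for unit '", u, "' are not a permutation of 1..", k)
  }
  if (nlevels(unit) < 2)
    abort_data("need at least 2 participant-task units")
  res <- stats::kruskal.test(ranks$rank, factor(ranks$algorithm))
  report <- list(
    test = "kruskal_wallis", alpha = alpha,
    median_ranks = vapply(split(ranks$rank, ranks$algorithm),
                          stats::median, numeric(1)),
    n_units = nlevels(unit),
    kruskal_p = res$p.value)
  if (is.finite(res$p.value) && res$p.value < alpha) {
    plan <- comparison_plan("kruskal_wallis", group_col = "algorithm",
                            value_col = "rank",
                            id_cols = c("participant", "task"),
                            alpha = alpha, correction = "dunn_sidak")
    report$pairwise <- pairwise_followup(ranks, plan,
                                         sort(unique(ranks$algorithm)))
  }
  report
}

#' Break-force to mass difficulty ratio of a fragile-object task
#'
#' The ratio of an object's breaking force to its mass summarizes how
#' delicate a grasp the task demands; lower is harder. The standard
#' mechanical test egg (20 N break force, 615 g) gives 0.03 N/g.
#'
#' @param break_force_n breaking force in newtons.
#' @param mass_g object mass in grams.
#' @return The ratio in N/g.
#' @export
egg_difficulty_ratio <- function(break_force_n = 20, mass_g = 615) {
  check_scalar_pos(break_force_n, "break_force_n")
  check_scalar_pos(mass_g, "mass_g")
  break_force_n / mass_g
}
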