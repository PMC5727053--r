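#' Logical combination of the two SVM decisions
#'
#' Maps the detector pair to the 3-class index: only the low detector firing
#' gives `"low"`, only the high detector `"high"`, neither `"moderate"`.
#' Both firing is a conflict; by default it resolves to the least-committal
#' `"moderate"`, or errors when `conflict = "error"` (for auditing).
#'
#' @param is_low,is_high logical vectors (recycled to common length).
#' @param conflict `"moderate"` or `"error"`.
#' @return character vector of classes.
#' @export
combine_index <- function(is_low, is_high, conflict = c("moderate", "error")) {
  conflict <- match.arg(conflict)
  n <- max(length(is_low), length(is_high))
  is_low <- rep_len(as.logical(is_low), n)
  is_high <- rep_len(as.logical(is_high), n)
  if (conflict == "error" && any(is_low & is_high))
    stop("conflicting detector outputs (both low and high fired)")
  ifelse(is_low & !is_high, "low",
         ifelse(is_high & !is_low, "high", "moderate"))
}

#' Compute the 5 s workload index series for one subject
#'
#' Runs the per-segment tail of the pipeline: band power, z-scoring against
#' the subject baseline, DFHM construction, classification by the frozen
#' model pair, and logical combination — one class per segment at the
#' segmentation cadence. Segments flagged as classifier-training material
#' (first-minute maps) are still indexed but marked so evaluation summaries
#' can exclude them.
#'
#' @param segments list of `eeg_segment` for one subject.
#' @param baseline the subject's `baseline_stats`.
#' @param models a frozen `model_pair`.
#' @param montage the [dfhm_montage()].
#' @param bands band definitions.
#' @param training_flags optional logical vector marking training segments.
#' @return object of class `workload_index_series`: a data frame with
#'   columns `time_s`, `task_id`, `class`, `training`.
#' @export
workload_index <- function(segments, baseline, models,
                           montage = default_montage(),
                           bands = band_definitions(),
                           training_flags = NULL) {
  if (is.null(baseline))
    stop("no baseline statistics for this subject; fit one with ",
         "fit_baseline() first")
  if (length(segments) == 0L)
    return(structure(data.frame(time_s = numeric(), task_id = character(),
                                class = character(), training = logical()),
                     class = c("workload_index_series", "data.frame")))
  maps <- lapply(segments, function(s)
    make_dfhm(zscore_power(band_power(s, bands), baseline), montage))
  X <- do.call(rbind, lapply(maps, dfhm_to_vector))
  dec <- classify_matrix(X, models)
  out <- data.frame(
    time_s = vapply(segments, `[[`, 0, "start_s"),
    task_id = vapply(segments, `[[`, "", "task_id"),
    class = combine_index(dec$is_low, dec$is_high),
    training = training_flags %||% rep(FALSE, length(segments)),
    stringsAsFactors = FALSE)
  structure(out, class = c("workload_index_series", "data.frame"))
}

#' Per-task portions of low/moderate/high-load segments
#'
#' The per-task summary statistic of the index: the percentage of segments
#' classified into each of the three classes (LLS / MLS / HLS).
#'
#' @param series a `workload_index_series` (or any data frame with a
#'   `class` column), typically restricted to one task.
#' @param drop_training exclude segments flagged as classifier training
#'   material.
#' @return data frame with `pct_low`, `pct_moderate`, `pct_high`,
#'   `n_segments` (percentages sum to 100).
#' @export
task_portions <- function(series, drop_training = TRUE) {
  if (drop_training && "training" %in% names(series))
    series <- series[!series$training, , drop = FALSE]
  n <- nrow(series)
  if (n == 0L) stop("empty index series: no segments to summarise")
  data.frame(pct_low = 100 * mean(series$class == "low"),
             pct_moderate = 100 * mean(series$class == "moderate"),
             pct_high = 100 * mean(series$class == "high"),
             n_segments = n)
}

#' Cohort table of per-subject, per-task portions
#'
#' Builds the wide subjects x tasks table of one portion measure, the input
#' for within-subject analysis. Tasks a subject is missing appear as `NA`
#' cells, never silently dropped.
#'
#' @param series_list named list: subject id -> `workload_index_series`
#'   covering that subject's whole session.
#' @param measure `"pct_high"`, `"pct_low"` or `"pct_moderate"`.
#' @param drop_training exclude classifier-training segments.
#' @return numeric matrix, subjects x tasks.
#' @export
cohort_table <- function(series_list,
                         measure = c("pct_high", "pct_low", "pct_moderate"),
                         drop_training = TRUE) {
  measure <- match.arg(measure)
  stopifnot(length(series_list) >= 1L)
  tasks <- unique(unlist(lapply(series_list, function(s) unique(s$task_id))))
  out <- matrix(NA_real_, nrow = length(series_list), ncol = length(tasks),
                dimnames = list(names(series_list), tasks))
  for (subj in names(series_list)) {
    s <- series_list[[subj]]
    for (tk in unique(s$task_id)) {
      sub <- s[s$task_id == tk, , drop = FALSE]
      if (drop_training && "training" %in% names(sub))
        sub <- sub[!sub$training, , drop = FALSE]
      if (nrow(sub))
        out[subj, tk] <- task_portions(sub, drop_training = FALSE)[[measure]]
    }
  }
  out
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject ANOVA over the task levels of a cohort table, with
#' Greenhouse-Geisser sphericity correction of the degrees of freedom, plus
#' all pairwise paired t comparisons with Bonferroni adjustment at family
#' alpha 0.05.
#'
#' @param table numeric matrix, subjects x levels, complete cases required.
#' @return list with `F`, `df1`, `df2` (GG-corrected), `p`, `epsilon`, the
#'   uncorrected degrees of freedom, and `pairwise` (data frame of paired
#'   comparisons with Bonferroni-adjusted p-values).
#' @export
rm_anova_gg <- function(table) {
  table <- as.matrix(table)
  n <- nrow(table); k <- ncol(table)
  if (n < 3L) stop("repeated-measures ANOVA needs at least 3 subjects")
  if (k < 2L) stop("need at least 2 levels")
  if (anyNA(table))
    stop("incomplete cases: repeated-measures ANOVA requires every subject ",
         "to have every level")
  grand <- mean(table)
  subj_means <- rowMeans(table)
  lvl_means <- colMeans(table)
  ss_lvl <- n * sum((lvl_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((table - grand)^2)
  ss_err <- ss_tot - ss_lvl - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  Fval <- (ss_lvl / df1) / (ss_err / df2)
  # Greenhouse-Geisser epsilon from the double-centered covariance matrix
  S <- stats::cov(table)
  Sc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  eps <- min(max(eps, 1 / (k - 1)), 1)
  p <- stats::pf(Fval, df1 * eps, df2 * eps, lower.tail = FALSE)
  pairs <- utils::combn(k, 2)
  pw <- data.frame(
    level_a = colnames(table)[pairs[1, ]] %||% pairs[1, ],
    level_b = colnames(table)[pairs[2, ]] %||% pairs[2, ],
    t = NA_real_, p_raw = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    tt <- stats::t.test(table[, pairs[1, j]], table[, pairs[2, j]],
                        paired = TRUE)
    pw$t[j] <- unname(tt$statistic)
    pw$p_raw[j] <- tt$p.value
  }
  pw$p_bonferroni <- pmin(pw$p_raw * nrow(pw), 1)
  pw$significant <- pw$p_bonferroni < 0.05
  list(F = Fval, df1 = df1 * eps, df2 = df2 * eps, p = p, epsilon = eps,
       df1_uncorrected = df1, df2_uncorrected = df2, pairwise = pw)
}
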