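#' Mann-Whitney U test for two independent samples
#'
#' Wrapper around the standard rank-sum machinery with an explicit,
#' recorded exact/approximate switch: the exact null distribution is used
#' when the combined sample size is at most `exact_max_n` and there are no
#' ties; otherwise the normal approximation with tie correction (and
#' continuity correction) is used — the branch the 15-20 cells per condition
#' of a typical timecourse lands in. The reported statistic is U for the
#' first sample (rank-sum of `x` minus its minimum).
#'
#' @param x,y numeric samples (non-empty)
#' @param alternative `"two_sided"`, `"less"`, or `"greater"`
#' @param exact_max_n combined-size bound for the exact branch (default 12)
#' @return data.frame row: `test`, `statistic`, `p_raw`, `alternative`,
#'   `n_x`, `n_y`, `method` (`"exact"` or `"normal_approx"`)
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two_sided", "less", "greater"),
                           exact_max_n = 12L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= exact_max_n) && !has_ties
  alt <- switch(alternative, two_sided = "two.sided", less = "less",
                greater = "greater")
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alt, exact = exact, correct = TRUE))
  r <- rank(c(x, y))  # midranks under ties
  u_x <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  data.frame(test = "mann_whitney_u",
             statistic = u_x,
             p_raw = wt$p.value,
             alternative = alternative,
             n_x = length(x), n_y = length(y),
             method = if (exact) "exact" else "normal_approx",
             stringsAsFactors = FALSE)
}

#' One-sample sign test
#'
#' Exact two-sided binomial test on the number of values above `null_value`,
#' with success probability 1/2. Values exactly equal to the null are
#' discarded (classic convention) and their count reported. If every value
#' ties with the null the result is flagged degenerate with `p_raw = NA`.
#'
#' @param values numeric sample (e.g. fold changes)
#' @param null_value reference value; default 1
#' @return data.frame row: `test`, `statistic` (count above null), `p_raw`,
#'   `n_used`, `n_ties`, `degenerate`
#' @export
sign_test <- function(values, null_value = 1) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("empty sample")
  ties <- sum(values == null_value)
  v <- values[values != null_value]
  if (length(v) == 0)
    return(data.frame(test = "sign_test", statistic = NA_real_,
                      p_raw = NA_real_, n_used = 0L, n_ties = ties,
                      degenerate = TRUE, stringsAsFactors = FALSE))
  n_above <- sum(v > null_value)
  bt <- binom.test(n_above, length(v), p = 0.5, alternative = "two.sided")
  data.frame(test = "sign_test", statistic = n_above, p_raw = bt$p.value,
             n_used = length(v), n_ties = ties, degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Bonferroni-Holm adjustment of a p-value family
#'
#' Step-down Holm procedure: with the family sorted ascending, the k-th
#' adjusted value is `max_{j<=k} min(1, (m-j+1) p_(j))`, returned in the
#' original order.
#'
#' @param pvals numeric vector of raw p-values in \[0, 1\] (`NA` passed
#'   through)
#' @return adjusted p-values, same length and order
#' @export
holm_adjust <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value family")
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "holm")
}

#' Densitometry fold changes relative to an unstimulated control
#'
#' Per lane, the band density is normalized by its loading-control density
#' (Ponceau S); the fold change is the normalized density divided by the
#' normalized density of the same replicate's control lane, so each
#' biological replicate is its own reference.
#'
#' @param table data.frame with columns `timepoint`, `replicate`,
#'   `band_density`, `loading_density` (densities > 0)
#' @param control_label the control timepoint's label
#' @return the table with added `normalized` and `fold_change` columns
#' @export
densitometry_foldchange <- function(table, control_label) {
  need <- c("timepoint", "replicate", "band_density", "loading_density")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (any(table$loading_density <= 0)) stop("loading densities must be > 0")
  if (!control_label %in% table$timepoint)
    stop("control label '", control_label, "' not present in table")
  table$normalized <- table$band_density / table$loading_density
  ctrl <- table[table$timepoint == control_label, c("replicate", "normalized")]
  for (rep_i in unique(table$replicate)) {
    if (!rep_i %in% ctrl$replicate)
      stop("replicate ", rep_i, " has no control ('", control_label,
           "') lane")
  }
  table$fold_change <- table$normalized /
    ctrl$normalized[match(table$replicate, ctrl$replicate)]
  attr(table, "control_label") <- control_label
  table
}

#' Sign tests of membrane-marker fold changes against the control
#'
#' For each non-control timepoint, an exact one-sample sign test of the
#' replicate fold changes against 1 (no change), followed by Bonferroni-Holm
#' adjustment across the timepoints.
#'
#' @param folds output of [densitometry_foldchange()]
#' @param control_label control timepoint; defaults to the label recorded by
#'   [densitometry_foldchange()]
#' @return data.frame, one row per non-control timepoint: `timepoint`,
#'   `statistic`, `n_used`, `n_ties`, `p_raw`, `p_adjusted`
#' @export
membrane_marker_test <- function(folds,
                                 control_label = attr(folds, "control_label")) {
  if (is.null(control_label)) stop("control_label is required")
  tps <- unique(folds$timepoint[folds$timepoint != control_label])
  if (length(tps) == 0) stop("no non-control timepoint to test")
  rows <- lapply(tps, function(tp) {
    st <- sign_test(folds$fold_change[folds$timepoint == tp], null_value = 1)
    data.frame(timepoint = tp, statistic = st$statistic, n_used = st$n_used,
               n_ties = st$n_ties, p_raw = st$p_raw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- holm_adjust(out$p_raw)
  out
}

#' Mann-Whitney timecourse comparisons against the control condition
#'
#' Each non-control condition's per-cell values are compared with the
#' control's by [mann_whitney_u()], with Holm adjustment across the family
#' and a significance star at `alpha`.
#'
#' @param values named list of numeric vectors (per-cell values per
#'   condition), control included
#' @param control_label name of the control condition
#' @param alpha significance mark level; default 0.05
#' @param ... passed to [mann_whitney_u()]
#' @return data.frame, one row per non-control condition: `condition`,
#'   `statistic`, `n`, `n_control`, `method`, `p_raw`, `p_adjusted`,
#'   `significant`
#' @export
timecourse_tests <- function(values, control_label, alpha = 0.05, ...) {
  if (!control_label %in% names(values))
    stop("control '", control_label, "' not among conditions")
  ctrl <- values[[control_label]]
  others <- setdiff(names(values), control_label)
  if (length(others) == 0) stop("no non-control condition to test")
  rows <- lapply(others, function(cond) {
    mw <- mann_whitney_u(values[[cond]], ctrl, ...)
    data.frame(condition = cond, statistic = mw$statistic, n = mw$n_x,
               n_control = mw$n_y, method = mw$method, p_raw = mw$p_raw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- holm_adjust(out$p_raw)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out
}
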