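# Per-neighborhood drug quantification: raw channel distributions per
# neighborhood, positive-voxel fractions per FOV, and rank-based
# comparison of conditions.

#' Channel distribution per neighborhood
#'
#' @param table Voxel table.
#' @param labels Neighborhood labels aligned with rows.
#' @param channel Channel to summarize (e.g. the drug channel).
#' @return A list with `values` (named list of per-neighborhood value
#'   vectors) and `summary` (data.frame: neighborhood, n, mean, median,
#'   q25, q75).
#' @export
channel_distribution_by_neighborhood <- function(table, labels, channel) {
  if (length(labels) != nrow(table)) stopf("labels do not align with table rows")
  if (!channel %in% names(table)) stopf("channel '%s' missing from table", channel)
  vals <- split(table[[channel]], labels)
  if (any(lengths(vals) == 0L)) stopf("empty neighborhood")
  summ <- do.call(rbind, lapply(names(vals), function(nb) {
    v <- vals[[nb]]
    data.frame(neighborhood = nb, n = length(v), mean = mean(v),
               median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  }))
  list(values = vals, summary = summ)
}

#' Fraction of positive voxels per FOV and neighborhood
#'
#' Positivity is evaluated on a (typically clip-normalized) channel; the
#' default rule is `value > 0`, i.e. a raw mean above the lower clip limit.
#'
#' @param table Voxel table with `fov_id`.
#' @param labels Neighborhood labels aligned with rows.
#' @param channel Channel to test.
#' @param positive_rule A predicate function on the channel values
#'   (default `function(x) x > 0`).
#' @return Data.frame `fov_id, neighborhood, n, n_positive, fraction`.
#' @export
positive_fraction <- function(table, labels, channel,
                              positive_rule = function(x) x > 0) {
  if (!is.function(positive_rule)) stopf("`positive_rule` must be a function")
  if (!channel %in% names(table)) stopf("channel '%s' missing from table", channel)
  pos <- positive_rule(table[[channel]])
  agg <- stats::aggregate(pos, by = list(fov_id = table$fov_id,
                                         neighborhood = labels),
                          FUN = function(v) c(n = length(v), pos = sum(v)))
  out <- data.frame(fov_id = agg$fov_id, neighborhood = agg$neighborhood,
                    n = agg$x[, "n"], n_positive = agg$x[, "pos"],
                    stringsAsFactors = FALSE)
  out$fraction <- out$n_positive / out$n
  out[order(out$neighborhood, out$fov_id), ]
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration with midranks.
# Two-sided p = min(1, 2 * min(P(W <= w), P(W >= w))) over all C(n, nA)
# equally likely rank assignments.
wilcoxon_exact_midrank <- function(a, b) {
  vals <- c(a, b)
  r <- rank(vals)                      # midranks
  nA <- length(a)
  w <- sum(r[seq_len(nA)])
  splits <- utils::combn(length(vals), nA)
  W <- colSums(matrix(r[splits], nrow = nA))
  eps <- 1e-9
  p_le <- mean(W <= w + eps)
  p_ge <- mean(W >= w - eps)
  min(1, 2 * min(p_le, p_ge))
}

#' Two-sided rank-sum comparison of per-FOV fractions between conditions
#'
#' Per neighborhood, a two-sided Wilcoxon rank-sum test of the per-FOV
#' positive fractions of `group_a` against `group_b`. For total n <= 12 the
#' p-value is computed by exact enumeration of all rank assignments with
#' midranks for ties; above that, the normal approximation with tie
#' correction ([stats::wilcox.test()]).
#'
#' @param fractions Data.frame from [positive_fraction()] with an added
#'   `condition` column, or any data.frame with columns `neighborhood`,
#'   `condition`, `fraction`.
#' @param group_a,group_b Condition labels to compare.
#' @param exact_max Largest total n for exact enumeration (default 12).
#' @return Data.frame `neighborhood, n_a, n_b, median_a, median_b, p`.
#' @export
compare_conditions <- function(fractions, group_a, group_b, exact_max = 12) {
  need <- c("neighborhood", "condition", "fraction")
  miss <- setdiff(need, names(fractions))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  nbs <- sort(unique(fractions$neighborhood))
  out <- lapply(nbs, function(nb) {
    fa <- fractions$fraction[fractions$neighborhood == nb &
                               fractions$condition == group_a]
    fb <- fractions$fraction[fractions$neighborhood == nb &
                               fractions$condition == group_b]
    if (length(fa) == 0L || length(fb) == 0L) stopf("empty group for neighborhood %s", nb)
    p <- if (length(fa) + length(fb) <= exact_max) {
      wilcoxon_exact_midrank(fa, fb)
    } else {
      suppressWarnings(stats::wilcox.test(fa, fb, exact = FALSE,
                                          correct = TRUE)$p.value)
    }
    data.frame(neighborhood = nb, n_a = length(fa), n_b = length(fb),
               median_a = stats::median(fa), median_b = stats::median(fb),
               p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Overall positive fraction per condition
#'
#' Pooled (voxel-weighted) positive fraction per condition, with the
#' per-FOV breakdown attached.
#'
#' @param tables_by_condition Named list of voxel tables, one per condition.
#' @param labels_by_condition Optional named list of label vectors; if
#'   omitted all voxels count as one group.
#' @inheritParams positive_fraction
#' @return List with `overall` (condition, n, n_positive, fraction) and
#'   `per_fov`.
#' @export
condition_positive_summary <- function(tables_by_condition, channel,
                                       positive_rule = function(x) x > 0,
                                       labels_by_condition = NULL) {
  per_fov <- do.call(rbind, lapply(names(tables_by_condition), function(cond) {
    tab <- tables_by_condition[[cond]]
    labs <- labels_by_condition[[cond]] %||% rep(1L, nrow(tab))
    pf <- positive_fraction(tab, labs, channel, positive_rule)
    pf$condition <- cond
    pf
  }))
  overall <- do.call(rbind, lapply(split(per_fov, per_fov$condition), function(d) {
    data.frame(condition = d$condition[1], n = sum(d$n),
               n_positive = sum(d$n_positive),
               fraction = sum(d$n_positive) / sum(d$n),
               stringsAsFactors = FALSE)
  }))
  rownames(overall) <- NULL
  list(overall = overall, per_fov = per_fov)
}
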