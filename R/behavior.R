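# Behavioural scoring: Y-maze spontaneous alternation, novel-object /
# novel-location recognition index with the low-exploration exclusion rule,
# and the routine group statistics (one-way ANOVA + LSD, Levene, Pearson
# marker-memory correlation) used to compare groups.

#' Spontaneous alternation percentage
#'
#' An alternation is a window of 3 consecutive arm entries visiting 3
#' distinct arms; overlapping windows count. The score is
#' 100 * alternations / (total entries - 2), the denominator being the
#' number of such windows. Sequences shorter than 3 entries are undefined
#' (NA with a warning).
#'
#' @param entries character vector of arm labels, e.g. `c("A","B","C")`.
#' @return percentage in \[0, 100\], or NA for sequences shorter than 3.
#' @export
spontaneous_alternation <- function(entries) {
  n <- length(entries)
  if (n < 3L) {
    warning("fewer than 3 arm entries: alternation undefined", call. = FALSE)
    return(NA_real_)
  }
  wins <- vapply(seq_len(n - 2L), function(i) {
    length(unique(entries[i:(i + 2L)])) == 3L
  }, logical(1))
  100 * sum(wins) / (n - 2L)
}

#' Recognition index with low-exploration exclusion
#'
#' index = time exploring the novel object (or location) / total
#' exploration time; 0.5 indicates no preference. Records whose total
#' exploration is below `min_total_s` seconds (default 5 s) are flagged
#' excluded; zero-time records are excluded with an NA index.
#'
#' @param time_novel,time_familiar exploration times in seconds
#'   (vectorized).
#' @param min_total_s exclusion threshold on total exploration time.
#' @return data.frame with columns `index` and `excluded`.
#' @export
recognition_index <- function(time_novel, time_familiar, min_total_s = 5) {
  stopifnot(length(time_novel) == length(time_familiar),
            all(is.finite(time_novel)), all(is.finite(time_familiar)),
            all(time_novel >= 0), all(time_familiar >= 0))
  total <- time_novel + time_familiar
  idx <- ifelse(total > 0, time_novel / total, NA_real_)
  data.frame(index = idx, excluded = total < min_total_s | total == 0)
}

#' Group comparison: one-way ANOVA, LSD pairwise tests, Levene's test
#'
#' Standard one-way ANOVA decomposition with Fisher's least-significant-
#' difference pairwise tests using the pooled within-group variance
#' (df = N - k), plus a variance-homogeneity test on absolute deviations
#' from the group medians (Brown-Forsythe form of Levene's test, via
#' \pkg{car}). A zero pooled within-group variance (all groups internally
#' constant) is flagged degenerate; the F statistic is then infinite and
#' its p-value the minimal representable value.
#'
#' @param values numeric vector of measurements.
#' @param groups group label per value (>= 2 groups, >= 2 values each).
#' @return list with `anova` (F, df1, df2, p), `lsd` (one row per pair:
#'   diff, se, t, df, p), `levene` (F, df1, df2, p or NA when degenerate),
#'   `degenerate` flag.
#' @export
group_compare <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2L)
  if (any(table(groups) < 2L))
    stop("each group needs >= 2 values", call. = FALSE)
  k <- nlevels(groups)
  n <- length(values)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  grand <- mean(values)
  ss_between <- sum(gn * (gm - grand)^2)
  ss_within <- sum((values - gm[groups])^2)
  df1 <- k - 1L
  df2 <- n - k
  degenerate <- ss_within == 0
  mse <- ss_within / df2
  if (!degenerate) {
    f <- (ss_between / df1) / mse
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  } else if (ss_between == 0) {
    f <- 0; p <- 1            # all values identical everywhere
  } else {
    f <- Inf; p <- .Machine$double.xmin
  }

  pairs <- utils::combn(levels(groups), 2L, simplify = FALSE)
  lsd <- do.call(rbind, lapply(pairs, function(pr) {
    d <- gm[[pr[1L]]] - gm[[pr[2L]]]
    se <- sqrt(mse * (1 / gn[[pr[1L]]] + 1 / gn[[pr[2L]]]))
    t <- if (se > 0) d / se else sign(d) * Inf
    pv <- if (se > 0) 2 * stats::pt(abs(t), df2, lower.tail = FALSE)
          else if (d == 0) 1 else .Machine$double.xmin
    data.frame(group_a = pr[1L], group_b = pr[2L], diff = d, se = se,
               t = t, df = df2, p = pv, stringsAsFactors = FALSE)
  }))
  rownames(lsd) <- NULL

  lev <- tryCatch({
    lv <- car::leveneTest(values ~ groups, center = stats::median)
    data.frame(F = lv[1L, "F value"], df1 = lv[1L, "Df"],
               df2 = lv[2L, "Df"], p = lv[1L, "Pr(>F)"])
  }, error = function(e) data.frame(F = NA_real_, df1 = NA_integer_,
                                    df2 = NA_integer_, p = NA_real_))

  list(anova = data.frame(F = f, df1 = df1, df2 = df2, p = p),
       lsd = lsd, levene = lev, degenerate = degenerate)
}

#' Pearson correlation between a marker and the recognition index
#'
#' @param marker numeric marker values (e.g. a plasticity-related protein
#'   level per animal).
#' @param index paired recognition indices.
#' @return list with `r`, `r2`, `p`, `n`; NA-flagged when either vector has
#'   zero variance or fewer than 3 pairs.
#' @export
marker_memory_correlation <- function(marker, index) {
  keep <- is.finite(marker) & is.finite(index)
  marker <- marker[keep]; index <- index[keep]
  n <- length(marker)
  if (n < 3L || stats::sd(marker) == 0 || stats::sd(index) == 0)
    return(list(r = NA_real_, r2 = NA_real_, p = NA_real_, n = n))
  ct <- stats::cor.test(marker, index, method = "pearson")
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value, n = n)
}

#' Score a full behavioural session set
#'
#' Per-animal spontaneous alternation and per-phase recognition indices
#' with exclusion flags, plus group-level statistics for each metric.
#'
#' @param behavior list as returned by [generate_behavior()] or
#'   [read_behavior()].
#' @param min_total_s exclusion threshold for recognition records.
#' @return list with `per_animal` (one row per animal: alternation, NOR and
#'   NLR indices, exclusion flags) and `group_stats` (named list of
#'   [group_compare()] results per metric).
#' @export
behavior_summary <- function(behavior, min_total_s = 5) {
  ae <- behavior$arm_entries
  alt <- vapply(ae$entries, spontaneous_alternation, numeric(1))
  per <- data.frame(animal_id = ae$animal_id, group = ae$group,
                    alternation_pct = alt, stringsAsFactors = FALSE)
  for (phase in unique(behavior$exploration$phase)) {
    ex <- behavior$exploration[behavior$exploration$phase == phase, ]
    ri <- recognition_index(ex$time_novel, ex$time_familiar, min_total_s)
    m <- match(per$animal_id, ex$animal_id)
    per[[paste0("ri_", tolower(phase))]] <- ri$index[m]
    per[[paste0("excluded_", tolower(phase))]] <- ri$excluded[m]
  }
  group_stats <- list(
    alternation = group_compare(per$alternation_pct, per$group))
  for (phase in unique(behavior$exploration$phase)) {
    col <- paste0("ri_", tolower(phase))
    exc <- per[[paste0("excluded_", tolower(phase))]]
    keep <- !exc & !is.na(per[[col]])
    if (length(unique(per$group[keep])) >= 2L &&
        all(table(per$group[keep]) >= 2L))
      group_stats[[col]] <- group_compare(per[[col]][keep], per$group[keep])
  }
  list(per_animal = per, group_stats = group_stats)
}
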