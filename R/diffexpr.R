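# Group-contrast log2 fold changes, the >= 1.5-fold differential filter,
# hierarchical clustering of expression patterns and Venn-style comparison
# of differential sets.

#' Compute a group-vs-control contrast
#'
#' Per-protein log2 fold change of a case group against the matrix's
#' control group. The group summary is the arithmetic mean of linear-scale
#' abundances over non-missing replicates (the convention for label-free
#' intensities); `summary = "log-mean"` instead averages log2 abundances,
#' i.e. a geometric-mean ratio. A protein is flagged invalid (logfc NA)
#' when either group has fewer than 2 non-missing replicates.
#'
#' @param mat an [abundance_matrix()].
#' @param case_group group to contrast against the control group.
#' @param summary `"linear-mean"` (default) or `"log-mean"`.
#' @return object of class `contrast_vector`: named `logfc` vector (NA =
#'   invalid), per-group replicate counts, group labels.
#' @export
compute_contrast <- function(mat, case_group,
                             summary = c("linear-mean", "log-mean")) {
  stopifnot(inherits(mat, "abundance_matrix"))
  summary <- match.arg(summary)
  groups <- unique(unname(mat$sample_groups))
  if (!case_group %in% groups)
    stop("unknown group '", case_group, "'", call. = FALSE)
  if (case_group == mat$control_group)
    stop("case group must differ from the control group", call. = FALSE)
  case <- mat$values[, mat$sample_groups == case_group, drop = FALSE]
  ctrl <- mat$values[, mat$sample_groups == mat$control_group, drop = FALSE]
  n_case <- rowSums(!is.na(case))
  n_ctrl <- rowSums(!is.na(ctrl))
  grp_mean <- function(x) {
    if (summary == "linear-mean") rowMeans(x, na.rm = TRUE)
    else 2 ^ rowMeans(log2(x), na.rm = TRUE)
  }
  logfc <- log2(grp_mean(case) / grp_mean(ctrl))
  logfc[n_case < 2L | n_ctrl < 2L] <- NA_real_
  structure(
    list(logfc = logfc, case_group = case_group,
         control_group = mat$control_group,
         n_case = n_case, n_control = n_ctrl, summary = summary),
    class = "contrast_vector"
  )
}

#' @export
print.contrast_vector <- function(x, ...) {
  cat(sprintf("contrast_vector: %s vs %s, %d proteins (%d valid)\n",
              x$case_group, x$control_group, length(x$logfc),
              sum(!is.na(x$logfc))))
  invisible(x)
}

#' Proteins with a valid log fold change
#' @param contrast a `contrast_vector` (or a list of them, in which case
#'   the intersection of valid proteins is returned).
#' @return character vector of protein ids.
#' @export
valid_proteins <- function(contrast) {
  if (inherits(contrast, "contrast_vector"))
    return(names(contrast$logfc)[!is.na(contrast$logfc)])
  Reduce(intersect, lapply(contrast, valid_proteins))
}

#' Fold-change differential filter
#'
#' Selects proteins whose expression differs from the control group by more
#' than `fold` times in either direction, i.e. |logfc| > log2(fold). The
#' inequality is strict: a ratio of exactly `fold` is not selected.
#' Proteins with an invalid (missing) contrast are excluded.
#'
#' @param contrast a `contrast_vector`.
#' @param fold fold threshold, > 1 (default 1.5).
#' @param label set label; defaults to the contrast's case group.
#' @return object of class `differential_set` with `members`, `label`,
#'   `fold`.
#' @export
fold_change_filter <- function(contrast, fold = 1.5, label = NULL) {
  stopifnot(inherits(contrast, "contrast_vector"))
  if (fold <= 1) stop("fold threshold must be > 1", call. = FALSE)
  if (is.null(label)) label <- contrast$case_group
  lfc <- contrast$logfc
  # strict inequality; the tolerance keeps ratios of exactly `fold` (e.g. a
  # down-regulation of 1/1.5, one ulp off on the log scale) unselected
  thr <- log2(fold) * (1 + 1e-9)
  sel <- !is.na(lfc) & abs(lfc) > thr
  differential_set(label, names(lfc)[sel], fold)
}

#' Construct a differential protein set
#' @param label contrast label.
#' @param members member protein ids.
#' @param fold fold threshold used (NA when selected by another rule).
#' @return object of class `differential_set`.
#' @export
differential_set <- function(label, members, fold = NA_real_) {
  structure(list(label = label, members = unique(as.character(members)),
                 fold = fold),
            class = "differential_set")
}

#' @export
print.differential_set <- function(x, ...) {
  cat(sprintf("differential_set '%s': %d proteins%s\n", x$label,
              length(x$members),
              if (is.na(x$fold)) "" else sprintf(" (fold > %g)", x$fold)))
  invisible(x)
}

#' Cluster proteins by expression pattern across contrasts
#'
#' Average-linkage hierarchical clustering of the protein x contrast log2
#' fold-change matrix with Euclidean distances. Proteins are ordered
#' lexicographically by id before clustering, so the result (including the
#' leaf order) does not depend on input order; identical rows merge at
#' distance zero.
#'
#' @param contrasts list of `contrast_vector`s (>= 2).
#' @param proteins proteins to cluster (>= 2); defaults to all proteins
#'   valid in every contrast.
#' @return object of class `expression_clustering`: leaf-ordered protein
#'   ids (`order`), the logfc matrix, and the underlying
#'   [stats::hclust] object (`merge`/`height` are the merge record).
#' @export
cluster_expression <- function(contrasts, proteins = NULL) {
  stopifnot(length(contrasts) >= 2L)
  if (is.null(proteins)) proteins <- valid_proteins(contrasts)
  proteins <- sort(unique(proteins))
  if (length(proteins) < 2L)
    stop("need >= 2 proteins with valid contrasts to cluster", call. = FALSE)
  m <- vapply(contrasts, function(ct) ct$logfc[proteins],
              numeric(length(proteins)))
  rownames(m) <- proteins
  colnames(m) <- vapply(contrasts, `[[`, "", "case_group")
  if (anyNA(m))
    stop("clustering input contains proteins without a valid contrast",
         call. = FALSE)
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "average")
  structure(
    list(order = rownames(m)[hc$order], logfc = m, hclust = hc),
    class = "expression_clustering"
  )
}

#' @export
print.expression_clustering <- function(x, ...) {
  cat(sprintf("expression_clustering: %d proteins x %d contrasts\n",
              nrow(x$logfc), ncol(x$logfc)))
  invisible(x)
}

#' Venn-partition counts of differential sets
#'
#' Exact counts of every non-empty region of the Venn partition over two or
#' more differential sets; the counts sum to the size of the union.
#'
#' @param sets list of `differential_set`s (or named list of character
#'   vectors), length >= 2.
#' @return data.frame with columns `region` (labels joined by `&`) and
#'   `count`, one row per region of the partition (zero-count regions
#'   included).
#' @export
compare_sets <- function(sets) {
  stopifnot(length(sets) >= 2L)
  members <- lapply(sets, function(s) {
    if (inherits(s, "differential_set")) s$members else as.character(s)
  })
  labels <- vapply(seq_along(sets), function(i) {
    if (inherits(sets[[i]], "differential_set")) sets[[i]]$label
    else if (!is.null(names(sets))) names(sets)[i]
    else paste0("set", i)
  }, "")
  universe <- unique(unlist(members))
  inset <- vapply(members, function(m) universe %in% m,
                  logical(length(universe)))
  if (length(universe) == 1L) inset <- matrix(inset, nrow = 1L)
  k <- length(sets)
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-(2^k), , drop = FALSE]
  region <- apply(patterns, 1L, function(p) paste(labels[unlist(p)],
                                                  collapse = "&"))
  count <- apply(patterns, 1L, function(p) {
    sum(apply(inset, 1L, function(row) all(row == unlist(p))))
  })
  data.frame(region = region, count = as.integer(count),
             stringsAsFactors = FALSE)
}
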