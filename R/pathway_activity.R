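# Signed pathway-activity scoring: the activity of a pathway under a
# contrast is the sum of its members' log2 fold changes vs the control
# group, with repressor members weighted -1; significance comes from
# random same-size protein sets drawn from the measured background.

#' Signed pathway activity score
#'
#' activity = sum over usable members of sign_i * logfc_i, where a member
#' is usable when it has a valid log2 fold change in the contrast. Members
#' absent from the contrast (or invalid) are skipped but counted in the
#' bookkeeping. A pathway with zero usable members is flagged undefined
#' (NA activity).
#'
#' @param pathway a [signed_pathway()].
#' @param contrast a `contrast_vector`.
#' @return list with `activity`, `n_members_used`, `n_members`.
#' @export
pathway_score <- function(pathway, contrast) {
  stopifnot(inherits(pathway, "signed_pathway"))
  lfc <- contrast$logfc[pathway$members]
  usable <- !is.na(lfc)
  activity <- if (any(usable)) sum(pathway$signs[usable] * lfc[usable])
              else NA_real_
  list(activity = activity, n_members_used = sum(usable),
       n_members = length(pathway$members))
}

#' Permutation significance of a pathway activity
#'
#' The null draws random protein sets of the pathway's usable size from the
#' measured background, without replacement, and scores each with the
#' pathway's own sign multiset assigned uniformly at random to the drawn
#' proteins (so the repressor fraction is preserved under the null);
#' `null_signs = "all-positive"` instead scores every draw with all +1
#' weights. The p-value is two-sided on the distance from the null mean,
#' with the add-one rule for sampled nulls. With `exhaustive = TRUE` every
#' subset and, for mixed signs, every distinct assignment of the sign
#' multiset is enumerated and exact counts are used.
#'
#' @param pathway a [signed_pathway()].
#' @param contrast a `contrast_vector`.
#' @param background proteins with valid logfc; defaults to all such
#'   proteins in the contrast.
#' @param n_perm number of random draws.
#' @param seed RNG seed.
#' @param exhaustive enumerate the null exactly.
#' @param null_signs `"carry"` (default) or `"all-positive"`.
#' @return a [permutation_result()] (statistic `"pathway_activity"`), with
#'   the observed signed activity; NA observed/p when no member is usable.
#' @export
pathway_significance <- function(pathway, contrast, background = NULL,
                                 n_perm = 1000, seed = 1,
                                 exhaustive = FALSE,
                                 null_signs = c("carry", "all-positive")) {
  null_signs <- match.arg(null_signs)
  if (is.null(background)) background <- valid_proteins(contrast)
  obs <- pathway_score(pathway, contrast)
  if (obs$n_members_used == 0L)
    return(permutation_result("pathway_activity", NA_real_, numeric(0),
                              NA_real_, 0L, seed, "two", exhaustive))
  lfc_bg <- contrast$logfc[background]
  if (anyNA(lfc_bg))
    stop("background contains proteins without a valid logfc", call. = FALSE)
  m <- obs$n_members_used
  nb <- length(lfc_bg)
  if (m > nb)
    stop("usable pathway size ", m, " exceeds background size ", nb,
         call. = FALSE)
  usable_signs <- pathway$signs[!is.na(contrast$logfc[pathway$members])]
  if (null_signs == "all-positive") usable_signs <- rep(1, m)
  n_neg <- sum(usable_signs < 0)

  if (exhaustive) {
    idx <- utils::combn(nb, m)
    if (n_neg == 0L || n_neg == m) {
      sgn <- if (n_neg == m) -1 else 1
      null <- sgn * colSums(matrix(lfc_bg[idx], nrow = m))
    } else {
      # every subset x every distinct placement of the -1 signs
      neg_pos <- utils::combn(m, n_neg)
      if (ncol(idx) * ncol(neg_pos) > 5e5)
        stop("exhaustive pathway null too large", call. = FALSE)
      null <- as.vector(apply(idx, 2L, function(ix) {
        v <- lfc_bg[ix]
        tot <- sum(v)
        apply(neg_pos, 2L, function(q) tot - 2 * sum(v[q]))
      }))
    }
    p <- empirical_p(obs$activity, null, "two", TRUE)
    return(permutation_result("pathway_activity", obs$activity, null, p,
                              length(null), NA_integer_, "two", TRUE))
  }

  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    v <- lfc_bg[sample.int(nb, m)]
    s <- if (n_neg == 0L) usable_signs else sample(usable_signs)
    sum(s * v)
  }, numeric(1))
  p <- empirical_p(obs$activity, null, "two", FALSE)
  permutation_result("pathway_activity", obs$activity, null, p,
                     n_perm, seed, "two", FALSE)
}

#' Score every pathway under every contrast
#'
#' One activity + permutation significance per pathway x contrast cell,
#' in stable (pathway, contrast) order.
#'
#' @param pathways list of [signed_pathway()]s.
#' @param contrasts named list of `contrast_vector`s.
#' @param n_perm permutations per cell.
#' @param seed run seed; a sub-seed is derived per cell.
#' @param null_signs passed to [pathway_significance()].
#' @return data.frame with columns pathway_id, contrast, activity,
#'   n_members_used, null_mean, null_sd, p, n_perm, perm_seed.
#' @export
score_all_pathways <- function(pathways, contrasts, n_perm = 1000,
                               seed = 1, null_signs = "carry") {
  if (inherits(contrasts, "contrast_vector")) contrasts <- list(contrasts)
  if (is.null(names(contrasts)) || any(!nzchar(names(contrasts))))
    names(contrasts) <- vapply(contrasts, `[[`, "", "case_group")
  rows <- list()
  for (pw in pathways) {
    for (lab in names(contrasts)) {
      ct <- contrasts[[lab]]
      sub_seed <- derive_seed(seed, paste0("pathway:", pw$pathway_id, ":", lab))
      res <- pathway_significance(pw, ct, n_perm = n_perm, seed = sub_seed,
                                  null_signs = null_signs)
      sc <- pathway_score(pw, ct)
      rows[[length(rows) + 1L]] <- data.frame(
        pathway_id = pw$pathway_id, contrast = lab,
        activity = sc$activity, n_members_used = sc$n_members_used,
        null_mean = if (length(res$null)) mean(res$null) else NA_real_,
        null_sd = if (length(res$null) > 1L) stats::sd(res$null) else NA_real_,
        p = res$empirical_p, n_perm = res$n_perm, perm_seed = sub_seed,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
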