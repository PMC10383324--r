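# Network-based selection of differentially expressed proteins: for each
# measured protein, the ego-module (the protein plus its direct interactors
# in the interaction network) is summarised by the mean and SD of member
# log2 fold changes and compared against random same-size protein sets
# drawn from the measured background; between-contrast module Pearson
# correlations are tested the same way.

#' Build an ego-module
#'
#' The module of a seed protein is the seed together with all proteins that
#' directly interact with it, restricted to the measured background (the
#' proteins with a valid contrast value).
#'
#' @param network igraph interaction network.
#' @param seed_protein seed protein id.
#' @param background character vector of measured protein ids.
#' @return object of class `ego_module` with `seed`, `members`, `size`.
#' @export
build_module <- function(network, seed_protein, background) {
  nodes <- igraph::V(network)$name
  if (!seed_protein %in% nodes)
    stop("seed protein '", seed_protein, "' is not in the network",
         call. = FALSE)
  if (!seed_protein %in% background)
    stop("seed protein '", seed_protein, "' is not in the measured background",
         call. = FALSE)
  nb <- igraph::neighbors(network, seed_protein)$name
  members <- c(seed_protein, intersect(nb, background))
  structure(list(seed = seed_protein, members = members,
                 size = length(members)),
            class = "ego_module")
}

#' @export
print.ego_module <- function(x, ...) {
  cat(sprintf("ego_module seed '%s': %d members\n", x$seed, x$size))
  invisible(x)
}

#' Module mean and standard deviation
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of the module members'
#' log2 fold changes; a size-1 module has SD 0 by convention.
#'
#' @param module an `ego_module` (or a character vector of member ids).
#' @param contrast a `contrast_vector`.
#' @return named numeric `c(mean, sd)`.
#' @export
module_stats <- function(module, contrast) {
  members <- if (inherits(module, "ego_module")) module$members else module
  lfc <- contrast$logfc[members]
  if (anyNA(lfc))
    stop("module member(s) without a valid logfc: ",
         paste(members[is.na(lfc)], collapse = ", "),
         " (restrict the background first)", call. = FALSE)
  c(mean = mean(lfc),
    sd = if (length(lfc) < 2L) 0 else stats::sd(lfc))
}

#' Random same-size module null
#'
#' Draws `n_perm` protein sets of the given size uniformly without
#' replacement from the measured background and records the mean and SD of
#' each set's log2 fold changes. With `exhaustive = TRUE` all
#' choose(|background|, size) subsets are enumerated instead.
#'
#' @param contrast a `contrast_vector`.
#' @param background character vector of protein ids with valid logfc.
#' @param size module size, <= |background|.
#' @param n_perm number of random draws (ignored when exhaustive).
#' @param seed RNG seed for the draws.
#' @param exhaustive enumerate all subsets exactly.
#' @return list with numeric vectors `mean` and `sd` (one entry per draw),
#'   plus `n_perm`, `exhaustive`, `seed`.
#' @export
random_module_null <- function(contrast, background, size, n_perm = 1000,
                               seed = 1, exhaustive = FALSE) {
  lfc <- contrast$logfc[background]
  if (anyNA(lfc))
    stop("background contains proteins without a valid logfc", call. = FALSE)
  nb <- length(lfc)
  if (size > nb)
    stop("module size ", size, " exceeds background size ", nb, call. = FALSE)
  stopifnot(size >= 1L, n_perm >= 1L)
  if (exhaustive) {
    n_comb <- choose(nb, size)
    if (n_comb > 5e5)
      stop("exhaustive null over ", n_comb, " subsets is too large",
           call. = FALSE)
    idx <- utils::combn(nb, size)
    draws <- matrix(lfc[idx], nrow = size)
    ms <- .col_mean_sd(draws)
    return(list(mean = ms$mean, sd = ms$sd, n_perm = ncol(idx),
                exhaustive = TRUE, seed = NA_integer_))
  }
  set.seed(seed)
  idx <- vapply(seq_len(n_perm), function(i) sample.int(nb, size),
                integer(size))
  draws <- matrix(lfc[idx], nrow = size)
  ms <- .col_mean_sd(draws)
  list(mean = ms$mean, sd = ms$sd, n_perm = n_perm,
       exhaustive = FALSE, seed = seed)
}

#' Permutation significance of module statistics
#'
#' Empirical p-values for the observed module mean and SD against the
#' random same-size module null: two-sided for the mean (distance from the
#' null mean), upper-tailed for the SD. Sampled nulls use the add-one rule;
#' exhaustive nulls use exact counts.
#'
#' @param observed named `c(mean, sd)` from [module_stats()].
#' @param null a null from [random_module_null()].
#' @return list of two [permutation_result()]s, `mean` and `sd`.
#' @export
module_significance <- function(observed, null) {
  stopifnot(all(c("mean", "sd") %in% names(observed)))
  p_mean <- empirical_p(observed[["mean"]], null$mean, "two", null$exhaustive)
  p_sd <- empirical_p(observed[["sd"]], null$sd, "upper", null$exhaustive)
  list(
    mean = permutation_result("module_mean", observed[["mean"]], null$mean,
                              p_mean, null$n_perm, null$seed, "two",
                              null$exhaustive),
    sd = permutation_result("module_sd", observed[["sd"]], null$sd,
                            p_sd, null$n_perm, null$seed, "upper",
                            null$exhaustive)
  )
}

#' Between-contrast module correlation with permutation significance
#'
#' Pearson correlation between the module members' log2 fold changes in two
#' contrasts, tested against random same-size protein sets drawn from the
#' common measured background, with a two-sided empirical p (add-one rule
#' when sampled). Modules smaller than 3 or with a zero-variance member
#' vector are flagged undefined (NA observed value, no p).
#'
#' @param module an `ego_module` (or character vector of member ids).
#' @param contrast_a,contrast_b `contrast_vector`s.
#' @param background proteins with valid logfc in both contrasts; defaults
#'   to the intersection of the two contrasts' valid proteins.
#' @param n_perm number of random draws.
#' @param seed RNG seed.
#' @param exhaustive enumerate all subsets exactly.
#' @return a [permutation_result()] (statistic `"module_correlation"`), or
#'   one with NA observed/p when undefined.
#' @export
module_correlation <- function(module, contrast_a, contrast_b,
                               background = NULL, n_perm = 1000, seed = 1,
                               exhaustive = FALSE) {
  members <- if (inherits(module, "ego_module")) module$members else module
  if (is.null(background))
    background <- valid_proteins(list(contrast_a, contrast_b))
  a <- contrast_a$logfc[members]
  b <- contrast_b$logfc[members]
  if (anyNA(a) || anyNA(b))
    stop("module member(s) lack a valid logfc in one of the contrasts",
         call. = FALSE)
  size <- length(members)
  undefined <- size < 3L || stats::sd(a) == 0 || stats::sd(b) == 0
  if (undefined) {
    return(permutation_result("module_correlation", NA_real_, numeric(0),
                              NA_real_, 0L, seed, "two", exhaustive))
  }
  r_obs <- stats::cor(a, b)
  av <- contrast_a$logfc[background]
  bv <- contrast_b$logfc[background]
  if (anyNA(av) || anyNA(bv))
    stop("background contains proteins without a valid logfc in both contrasts",
         call. = FALSE)
  nb <- length(background)
  if (size > nb) stop("module larger than the common background", call. = FALSE)
  draw_r <- function(idx) {
    x <- av[idx]; y <- bv[idx]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  if (exhaustive) {
    if (choose(nb, size) > 5e5)
      stop("exhaustive correlation null too large", call. = FALSE)
    idx <- utils::combn(nb, size)
    null <- apply(idx, 2L, draw_r)
  } else {
    set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i) {
      draw_r(sample.int(nb, size))
    }, numeric(1))
  }
  null <- null[!is.na(null)]
  p <- empirical_p(r_obs, null, "two", exhaustive)
  permutation_result("module_correlation", r_obs, null, p,
                     length(null), if (exhaustive) NA_integer_ else seed,
                     "two", exhaustive)
}

# null draws for the `ego` null mode: uniform over ego-modules of matching
# size; falls back to random sets when fewer than 50 candidates exist
.ego_null <- function(contrast, background, size, module_members, n_perm,
                      seed) {
  cand <- module_members[vapply(module_members, length, 1L) == size]
  if (length(cand) < 50L) return(NULL)
  set.seed(seed)
  picks <- sample.int(length(cand), n_perm, replace = TRUE)
  draws <- vapply(picks, function(i) contrast$logfc[cand[[i]]],
                  numeric(size))
  draws <- matrix(draws, nrow = size)
  ms <- .col_mean_sd(draws)
  list(mean = ms$mean, sd = ms$sd, n_perm = n_perm, exhaustive = FALSE,
       seed = seed)
}

#' Network-based selection of differentially expressed proteins
#'
#' Runs the full ego-module procedure: for every measured protein that is a
#' network node, builds its module, computes the module mean/SD of log2
#' fold changes, tests both against `n_perm` random same-size protein sets
#' from the measured background, and selects proteins whose module-mean
#' empirical p falls below `alpha`. For each pair of contrasts, module
#' Pearson correlations are tested the same way and seeds with correlation
#' p below `alpha` form the between-contrast set. Measured proteins absent
#' from the network are reported as untestable, not dropped silently.
#'
#' @param network igraph interaction network.
#' @param contrasts named list of `contrast_vector`s (names default to
#'   each contrast's case group).
#' @param alpha selection threshold on the module-mean empirical p.
#' @param n_perm permutations per module (1000 by convention).
#' @param seed run seed; a sub-seed is derived per contrast and seed
#'   protein.
#' @param null `"sets"` (random same-size protein sets, default) or
#'   `"ego"` (uniform over ego-modules of matching size when at least 50
#'   exist, else falling back to sets for that size).
#' @param pairs also compute between-contrast module correlations.
#' @return list with `per_seed` (one row per contrast x testable seed:
#'   module size, mean, sd, p_mean, p_sd, selected), `sets` (a
#'   `differential_set` per contrast), `pair_per_seed` and `pair_sets`
#'   (between-contrast correlation results), and `untestable` (measured
#'   proteins absent from the network).
#' @export
select_de_proteins <- function(network, contrasts, alpha = 0.05,
                               n_perm = 1000, seed = 1,
                               null = c("sets", "ego"), pairs = TRUE) {
  null <- match.arg(null)
  stopifnot(alpha >= 0, alpha < 1, n_perm >= 1)
  if (inherits(contrasts, "contrast_vector")) contrasts <- list(contrasts)
  if (is.null(names(contrasts)) || any(!nzchar(names(contrasts))))
    names(contrasts) <- vapply(contrasts, `[[`, "", "case_group")
  nodes <- igraph::V(network)$name

  per_seed <- list()
  sets <- list()
  module_cache <- list()
  for (lab in names(contrasts)) {
    ct <- contrasts[[lab]]
    background <- valid_proteins(ct)
    testable <- intersect(background, nodes)
    members_by_seed <- lapply(testable, function(s) {
      c(s, intersect(igraph::neighbors(network, s)$name, background))
    })
    names(members_by_seed) <- testable
    module_cache[[lab]] <- members_by_seed
    rows <- lapply(testable, function(s) {
      mem <- members_by_seed[[s]]
      obs <- module_stats(mem, ct)
      sub_seed <- derive_seed(seed, paste0("module:", lab, ":", s))
      nl <- NULL
      if (null == "ego")
        nl <- .ego_null(ct, background, length(mem), members_by_seed,
                        n_perm, sub_seed)
      if (is.null(nl))
        nl <- random_module_null(ct, background, length(mem), n_perm,
                                 sub_seed)
      sig <- module_significance(obs, nl)
      data.frame(contrast = lab, seed_protein = s, size = length(mem),
                 module_mean = obs[["mean"]], module_sd = obs[["sd"]],
                 null_mean = mean(nl$mean), null_sd = stats::sd(nl$mean),
                 p_mean = sig$mean$empirical_p, p_sd = sig$sd$empirical_p,
                 n_perm = nl$n_perm, perm_seed = sub_seed,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$selected <- tab$p_mean < alpha
    per_seed[[lab]] <- tab
    sets[[lab]] <- differential_set(lab, tab$seed_protein[tab$selected])
  }
  per_seed <- do.call(rbind, per_seed)
  rownames(per_seed) <- NULL

  pair_per_seed <- NULL
  pair_sets <- list()
  if (pairs && length(contrasts) >= 2L) {
    combos <- utils::combn(names(contrasts), 2L, simplify = FALSE)
    for (cmb in combos) {
      lab <- paste(cmb, collapse = "-")
      ca <- contrasts[[cmb[1L]]]; cb <- contrasts[[cmb[2L]]]
      bg <- valid_proteins(list(ca, cb))
      testable <- intersect(bg, nodes)
      rows <- lapply(testable, function(s) {
        mem <- c(s, intersect(igraph::neighbors(network, s)$name, bg))
        if (length(mem) < 3L) {
          return(data.frame(pair = lab, seed_protein = s,
                            size = length(mem), r = NA_real_,
                            p = NA_real_, stringsAsFactors = FALSE))
        }
        sub_seed <- derive_seed(seed, paste0("corr:", lab, ":", s))
        res <- module_correlation(mem, ca, cb, bg, n_perm, sub_seed)
        data.frame(pair = lab, seed_protein = s, size = length(mem),
                   r = res$observed, p = res$empirical_p,
                   stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      tab$selected <- !is.na(tab$p) & tab$p < alpha
      pair_per_seed <- rbind(pair_per_seed, tab)
      pair_sets[[lab]] <- differential_set(lab,
                                           tab$seed_protein[tab$selected])
    }
    rownames(pair_per_seed) <- NULL
  }

  untestable <- lapply(contrasts, function(ct) {
    setdiff(valid_proteins(ct), nodes)
  })
  list(per_seed = per_seed, sets = sets,
       pair_per_seed = pair_per_seed, pair_sets = pair_sets,
       untestable = untestable, alpha = alpha, n_perm = n_perm, seed = seed)
}

#' Rank seed proteins of one contrast by module-mean significance
#'
#' Orders the per-seed table by module-mean empirical p, breaking the ties
#' that discrete permutation p-values produce by the magnitude of the
#' standardized deviation of the observed module mean from its null.
#'
#' @param per_seed the `per_seed` table from [select_de_proteins()].
#' @param contrast contrast label to rank (default: the only one present).
#' @return the table rows for that contrast, ordered most to least
#'   significant.
#' @export
rank_module_seeds <- function(per_seed, contrast = NULL) {
  if (!is.null(contrast)) per_seed <- per_seed[per_seed$contrast == contrast, ]
  z <- abs(per_seed$module_mean - per_seed$null_mean) /
    ifelse(per_seed$null_sd > 0, per_seed$null_sd, Inf)
  per_seed[order(per_seed$p_mean, -z), ]
}
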