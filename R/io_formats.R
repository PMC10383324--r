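# Readers/writers for every external artifact the pipeline touches.
# All files are UTF-8 TSV (or signed GMT); readers validate strictly and
# reject malformed input rather than coercing it.

#' Construct an abundance matrix
#'
#' The pipeline's entry point: linear-scale protein abundances (proteins x
#' samples) with a group assignment per sample and a designated control
#' group. Missing measurements are `NA`, never zero.
#'
#' @param values numeric matrix, rows = proteins, columns = samples, with
#'   dimnames set; values > 0 or NA.
#' @param sample_groups named character vector mapping sample id -> group.
#' @param control_group the group label used as reference in all contrasts.
#' @return an object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, sample_groups, control_group) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have protein row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  missing_sheet <- setdiff(colnames(values), names(sample_groups))
  if (length(missing_sheet))
    stop("samples without a group assignment: ",
         paste(missing_sheet, collapse = ", "), call. = FALSE)
  sample_groups <- sample_groups[colnames(values)]
  if (!control_group %in% sample_groups)
    stop("control group '", control_group, "' has no samples", call. = FALSE)
  if (any(values <= 0, na.rm = TRUE))
    stop("abundances must be positive (missing values are NA, not 0)",
         call. = FALSE)
  structure(
    list(values = values, sample_groups = sample_groups,
         control_group = control_group),
    class = "abundance_matrix"
  )
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d proteins x %d samples, groups: %s (control: %s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$sample_groups), collapse = ", "),
              x$control_group))
  invisible(x)
}

#' Group labels of an abundance matrix
#' @param mat an `abundance_matrix`.
#' @return character vector of group labels, control first.
#' @export
abundance_groups <- function(mat) {
  g <- unique(unname(mat$sample_groups))
  c(mat$control_group, setdiff(g, mat$control_group))
}

#' Read a protein abundance table and its sample sheet
#'
#' @param table_path TSV with a header row of sample ids; first column
#'   protein ids. Empty cells or `NA` are missing.
#' @param sheet_path TSV with columns `sample_id` and `group`.
#' @param control_group control group label; defaults to the group of the
#'   first sample sheet row.
#' @return an `abundance_matrix`.
#' @export
read_abundance <- function(table_path, sheet_path, control_group = NULL) {
  tab <- utils::read.delim(table_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L)
    stop("abundance table needs a protein id column plus >= 1 sample",
         call. = FALSE)
  ids <- tab[[1L]]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  bad <- which(is.na(num) & !(is.na(vals) | vals == "" | vals == "NA"),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric abundance at protein '%s', sample '%s'",
                 ids[bad[1L, 1L]], colnames(num)[bad[1L, 2L]]),
         call. = FALSE)
  sheet <- utils::read.delim(sheet_path, header = TRUE, sep = "\t",
                             colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(sheet)))
    stop("sample sheet must have columns 'sample_id' and 'group'",
         call. = FALSE)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample ids in sample sheet", call. = FALSE)
  groups <- stats::setNames(sheet$group, sheet$sample_id)
  if (is.null(control_group)) control_group <- sheet$group[1L]
  abundance_matrix(num, groups, control_group)
}

#' Write an abundance matrix and sample sheet
#' @param mat an `abundance_matrix`.
#' @param table_path,sheet_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_abundance <- function(mat, table_path, sheet_path) {
  df <- data.frame(protein_id = rownames(mat$values),
                   mat$values, check.names = FALSE)
  utils::write.table(df, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sheet <- data.frame(sample_id = names(mat$sample_groups),
                      group = unname(mat$sample_groups))
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(table_path, sheet_path))
}

#' Read an undirected protein-interaction edge list
#'
#' Two or more tab-separated columns (columns beyond the first two are
#' ignored, so trimmed BioGRID TAB exports parse unchanged); lines starting
#' with `#` are comments. Duplicate edges are merged, self-loops dropped
#' with a warning.
#'
#' @param path edge-list file.
#' @return an [igraph::igraph] undirected simple graph.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx))
    return(igraph::make_empty_graph(0, directed = FALSE))
  parts <- strsplit(lines[idx], "[\t ]+")
  nfield <- lengths(parts)
  if (any(nfield < 2L))
    stop("malformed edge at line ", idx[which(nfield < 2L)[1L]],
         ": need >= 2 tab-separated columns", call. = FALSE)
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  loops <- a == b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped (e.g. '", a[loops][1L], "')",
            call. = FALSE)
    a <- a[!loops]; b <- b[!loops]
  }
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write an edge list
#' @param network an igraph graph.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_edge_list <- function(network, path) {
  el <- igraph::as_edgelist(network, names = TRUE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# protein_a\tprotein_b", con)
  if (nrow(el))
    writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), con)
  invisible(path)
}

#' Construct a signed pathway definition
#'
#' A named set of member proteins, each carrying a role sign: +1 for a
#' pathway component/activator, -1 for a repressor of the pathway's signal
#' transduction.
#'
#' @param pathway_id identifier.
#' @param name free-text description.
#' @param members character vector of member protein ids (unique).
#' @param signs numeric vector of +1/-1, one per member.
#' @return an object of class `signed_pathway`.
#' @export
signed_pathway <- function(pathway_id, name, members, signs = NULL) {
  if (is.null(signs)) signs <- rep(1, length(members))
  stopifnot(length(members) >= 1L, length(signs) == length(members))
  if (anyDuplicated(members))
    stop("duplicate member ids in pathway '", pathway_id, "'", call. = FALSE)
  if (!all(signs %in% c(-1, 1)))
    stop("member signs must be +1 or -1", call. = FALSE)
  structure(
    list(pathway_id = pathway_id, name = name,
         members = as.character(members), signs = as.numeric(signs)),
    class = "signed_pathway"
  )
}

#' @export
print.signed_pathway <- function(x, ...) {
  cat(sprintf("signed_pathway '%s': %d members (%d repressors)\n",
              x$pathway_id, length(x$members), sum(x$signs < 0)))
  invisible(x)
}

#' Read a signed GMT gene-set file
#'
#' GMT dialect: `pathway_id TAB description TAB member...`, where a member
#' token is either a plain id (sign +1) or `id|-1` marking a repressor.
#' Plain (unsigned) GMT files parse with all signs +1.
#'
#' @param path GMT file.
#' @return list of [signed_pathway] objects.
#' @export
read_signed_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, ": fewer than 3 tab-separated columns",
           call. = FALSE)
    toks <- f[-(1:2)]
    toks <- toks[nzchar(toks)]
    split_tok <- strsplit(toks, "|", fixed = TRUE)
    ids <- vapply(split_tok, `[[`, "", 1L)
    signs <- vapply(split_tok, function(p) {
      if (length(p) == 1L) return(1)
      if (length(p) == 2L && p[[2L]] %in% c("-1", "1", "+1"))
        return(as.numeric(sub("^\\+", "", p[[2L]])))
      stop("GMT line ", i, ": unknown member sign suffix in token '",
           paste(p, collapse = "|"), "'", call. = FALSE)
    }, numeric(1))
    signed_pathway(f[[1L]], f[[2L]], ids, signs)
  })
}

#' Write signed pathways as GMT
#' @param pathways list of `signed_pathway`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_signed_gmt <- function(pathways, path) {
  lines <- vapply(pathways, function(p) {
    toks <- ifelse(p$signs < 0, paste0(p$members, "|-1"), p$members)
    paste(c(p$pathway_id, p$name, toks), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a results table as TSV
#'
#' Fixed column order as given; numeric columns serialized at 6 significant
#' digits.
#'
#' @param records a data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- signif(out[[j]], 6)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
}

#' Write behavioural session records
#'
#' Arm-entry sequences are stored one animal per row with the entries
#' concatenated (e.g. `ABCAB`); exploration records one row per animal and
#' phase with novel/familiar times in seconds.
#'
#' @param behavior list with elements `arm_entries` and `exploration` as
#'   returned by [generate_behavior()].
#' @param entries_path,exploration_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_behavior <- function(behavior, entries_path, exploration_path) {
  ae <- data.frame(
    animal_id = behavior$arm_entries$animal_id,
    group = behavior$arm_entries$group,
    entries = vapply(behavior$arm_entries$entries, paste, "", collapse = "")
  )
  utils::write.table(ae, entries_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(behavior$exploration, exploration_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(entries_path, exploration_path))
}

#' Read behavioural session records
#' @param entries_path,exploration_path TSV paths written by
#'   [write_behavior()].
#' @return list with `arm_entries` (animal_id, group, entries as list of
#'   character vectors) and `exploration` data.frame.
#' @export
read_behavior <- function(entries_path, exploration_path) {
  ae <- utils::read.delim(entries_path, header = TRUE, sep = "\t",
                          colClasses = "character")
  expl <- utils::read.delim(exploration_path, header = TRUE, sep = "\t")
  bad <- !grepl("^[ABC]+$", ae$entries)
  if (any(bad))
    stop("arm entries must use labels A/B/C (animal '",
         ae$animal_id[bad][1L], "')", call. = FALSE)
  list(
    arm_entries = data.frame(
      animal_id = ae$animal_id, group = ae$group,
      entries = I(strsplit(ae$entries, "")), stringsAsFactors = FALSE),
    exploration = expl
  )
}
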