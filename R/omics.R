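#' Five-level copy-number scale, in increasing order
#'
#' Homozygous deletion, heterozygous (single-allele) deletion, normal copy
#' number, low-level gain, high-level gain. TSV files encode these as the
#' integer codes -2..2.
#' @export
cnv_categories <- c("hom_del", "het_del", "normal", "low_gain", "high_gain")

cnv_code_to_category <- function(code) {
  out <- rep(NA_character_, length(code))
  ok <- !is.na(code) & code %in% -2:2
  out[ok] <- cnv_categories[code[ok] + 3L]
  out
}

#' Construct an omics dataset
#'
#' A gene-by-sample matrix of one declared type. Ordinal copy-number values
#' are stored as their integer codes -2..2 ([cnv_categories]); binary
#' values are 0/1; `NA` marks missing.
#'
#' @param dataset_id Identifier.
#' @param dtype `"numerical"`, `"ordinal_cnv"` or `"binary"`.
#' @param values Numeric matrix with gene rownames and sample colnames.
#' @param color_tag Display color class for the dataset (used as caption
#'   background in the linear view).
#' @return An object of class `omics_dataset`.
#' @export
omics_dataset <- function(dataset_id, dtype, values, color_tag = "#BBBBBB") {
  dtype <- match.arg(dtype, c("numerical", "ordinal_cnv", "binary"))
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  v <- values[!is.na(values)]
  if (dtype == "binary" && !all(v %in% c(0, 1)))
    stop("binary dataset values must be 0/1 or missing")
  if (dtype == "ordinal_cnv" && !all(v %in% -2:2))
    stop("ordinal_cnv dataset values must be integer codes -2..2 or missing")
  if (dtype == "numerical" && !all(is.finite(v)))
    stop("numerical dataset values must be finite or missing")
  structure(list(dataset_id = dataset_id, dtype = dtype, values = values,
                 color_tag = color_tag),
            class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("omics_dataset '%s' [%s]: %d genes x %d samples (%d missing)\n",
              x$dataset_id, x$dtype, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' Read a gene-by-sample matrix from TSV
#'
#' Expects a header row of sample ids and gene ids in the first column;
#' empty cells are missing.
#'
#' @param file TSV path or connection.
#' @param dtype Declared type, see [omics_dataset()].
#' @param dataset_id Identifier; defaults to the file name without
#'   extension.
#' @param color_tag Display color class.
#' @return An [omics_dataset()].
#' @export
read_omics_matrix <- function(file, dtype, dataset_id = NULL,
                              color_tag = "#BBBBBB") {
  if (is.null(dataset_id))
    dataset_id <- sub("\\.[^.]*$", "", basename(if (is.character(file)) file else "dataset"))
  tab <- utils::read.delim(file, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", na.strings = "")
  if (ncol(tab) < 2) stop("matrix needs a gene-id column and at least one sample")
  genes <- tab[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  raw <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                 dimnames = list(genes, colnames(raw))))
  bad <- which(is.na(num) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                 genes[bad[1, 1]], colnames(raw)[bad[1, 2]]))
  omics_dataset(dataset_id, dtype, num, color_tag)
}

#' Construct a sample grouping
#'
#' Named, ordered groups of sample ids for one dataset. Groups may overlap;
#' every sample must be a column of the dataset.
#'
#' @param dataset_id Dataset the grouping refers to.
#' @param groups Named list of character vectors of sample ids.
#' @param dataset Optional [omics_dataset()] to validate sample membership
#'   against.
#' @return An object of class `sample_grouping`.
#' @export
sample_grouping <- function(dataset_id, groups, dataset = NULL) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named list")
  if (!is.null(dataset)) {
    unknown <- setdiff(unlist(groups), colnames(dataset$values))
    if (length(unknown))
      stop("samples not in dataset '", dataset_id, "': ",
           paste(unknown, collapse = ", "))
  }
  structure(list(dataset_id = dataset_id,
                 groups = lapply(groups, as.character)),
            class = "sample_grouping")
}

#' Read sample groupings from TSV
#'
#' Expects columns `dataset_id`, `group_label`, `sample_id` (one sample per
#' line, order-preserving).
#'
#' @param file TSV path or connection.
#' @param datasets Optional named list of [omics_dataset()] for validation.
#' @return Named list of [sample_grouping()] keyed by dataset id.
#' @export
read_sample_groups <- function(file, datasets = NULL) {
  tab <- utils::read.delim(file, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- c("dataset_id", "group_label", "sample_id")
  if (!all(need %in% names(tab)))
    stop("grouping file needs columns: ", paste(need, collapse = ", "))
  out <- list()
  for (ds in unique(tab$dataset_id)) {
    sub <- tab[tab$dataset_id == ds, , drop = FALSE]
    groups <- lapply(split(sub$sample_id, factor(sub$group_label,
                                                 levels = unique(sub$group_label))),
                     as.character)
    out[[ds]] <- sample_grouping(ds, groups,
                                 dataset = if (!is.null(datasets)) datasets[[ds]])
  }
  out
}

#' Read a member-to-row alias table
#'
#' Two-column TSV (`member_id`, `row_id`) translating pathway member
#' identifiers to dataset row identifiers. Pathway databases often use a
#' different alias for a gene than the measurement platform; the table
#' makes that translation explicit and offline. Without a table, row ids
#' must match member ids exactly.
#'
#' @param file TSV path or connection.
#' @return Named character vector (`member_id -> row_id`).
#' @export
read_alias_table <- function(file) {
  tab <- utils::read.delim(file, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2) stop("alias table needs two columns (member_id, row_id)")
  stats::setNames(tab[[2]], tab[[1]])
}

#' Resolve a pathway node to dataset rows
#'
#' Multi-mapping resolution: a gene node maps to every dataset row matching
#' one of its member identifiers (in member order, after optional alias
#' translation); a group (complex) node maps to the concatenation over its
#' children in child order, deduplicated; compounds and map links map to
#' nothing.
#'
#' @param node A [pathway_node()], or a node id with `graph` supplied.
#' @param dataset An [omics_dataset()].
#' @param alias_table Optional named vector from [read_alias_table()].
#' @param graph Required when `node` is given as an id, and for resolving
#'   group children.
#' @return Character vector of dataset row ids (possibly empty).
#' @export
resolve_mappings <- function(node, dataset, alias_table = NULL, graph = NULL) {
  if (is.character(node)) {
    if (is.null(graph)) stop("graph required when node is given by id")
    node <- graph$nodes[[node]]
    if (is.null(node)) stop("unknown node id")
  }
  rows <- rownames(dataset$values)
  if (node$kind %in% c("compound", "map_link")) return(character())
  if (node$kind == "group") {
    if (is.null(graph)) stop("graph required to resolve group children")
    hit <- unlist(lapply(node$children, function(ch)
      resolve_mappings(graph$nodes[[ch]], dataset, alias_table, graph)))
    return(unique(hit))
  }
  translated <- vapply(node$members, function(m) {
    if (!is.null(alias_table) && m %in% names(alias_table)) alias_table[[m]] else m
  }, character(1), USE.NAMES = FALSE)
  unique(translated[translated %in% rows])
}

#' Summarize the data mapped onto a node
#'
#' Pools all values over the node's resolved rows and the selected samples
#' (all columns, or one group), excluding missing cells. `mean`/`std` use
#' the population standard deviation; ordinal copy-number values enter the
#' mean via their integer codes and additionally yield per-category counts;
#' for binary data the mean is the mutated fraction. With zero non-missing
#' values the summary is flagged `defined = FALSE` rather than propagating
#' `NaN`.
#'
#' @param node A [pathway_node()] or node id.
#' @param dataset An [omics_dataset()].
#' @param grouping Optional [sample_grouping()]; required when `group` is
#'   given.
#' @param group Group label selecting a sample subset, or `NULL` for all
#'   samples.
#' @param alias_table Optional alias translation.
#' @param graph Graph context for id/group resolution.
#' @return An object of class `node_summary`: `mean`, `std`, `n_rows`,
#'   `n_samples`, `n_values`, `has_missing`, `defined`, plus
#'   `category_counts` (ordinal) or `mutated_fraction` (binary).
#' @export
node_summary <- function(node, dataset, grouping = NULL, group = NULL,
                         alias_table = NULL, graph = NULL) {
  rows <- resolve_mappings(node, dataset, alias_table, graph)
  samples <- colnames(dataset$values)
  if (!is.null(group)) {
    if (is.null(grouping)) stop("grouping required to select a group")
    if (!group %in% names(grouping$groups)) stop("unknown group: ", group)
    samples <- grouping$groups[[group]]
  }
  vals <- dataset$values[rows, samples, drop = FALSE]
  v <- as.vector(vals)
  n_total <- length(v)
  v_obs <- v[!is.na(v)]
  n <- length(v_obs)
  defined <- n > 0L
  out <- list(
    mean = if (defined) mean(v_obs) else NA_real_,
    std = if (defined) sqrt(mean((v_obs - mean(v_obs))^2)) else NA_real_,
    n_rows = length(rows), n_samples = length(samples), n_values = n,
    has_missing = !defined || n < n_total, defined = defined)
  if (dataset$dtype == "ordinal_cnv") {
    counts <- vapply(-2:2, function(code) sum(v_obs == code), integer(1))
    out$category_counts <- stats::setNames(counts, cnv_categories)
  }
  if (dataset$dtype == "binary")
    out$mutated_fraction <- if (defined) mean(v_obs) else NA_real_
  structure(out, class = "node_summary")
}

#' @export
print.node_summary <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("node_summary: no data (%d row(s) x %d sample(s))\n",
                x$n_rows, x$n_samples))
  } else {
    cat(sprintf("node_summary: mean %.4g, sd %.4g over %d value(s) (%d row(s) x %d sample(s))%s\n",
                x$mean, x$std, x$n_values, x$n_rows, x$n_samples,
                if (x$has_missing) ", missing present" else ""))
  }
  invisible(x)
}

#' Summarize one sample group on a node
#'
#' [node_summary()] restricted to a single group's samples: the basis of
#' the abstract group representations (mean bar with standard-deviation
#' error bars, copy-number histogram, mutation histogram).
#'
#' @inheritParams node_summary
#' @param group Group label (required).
#' @return A `node_summary`.
#' @export
group_summary <- function(node, dataset, grouping, group,
                          alias_table = NULL, graph = NULL) {
  node_summary(node, dataset, grouping, group, alias_table, graph)
}

#' Categorize a quantitative copy-number value
#'
#' Maps a log-ratio-like value to the five-level scale with symmetric
#' thresholds: values of magnitude below `t_low` are normal, between
#' `t_low` (inclusive) and `t_high` (exclusive) a low gain/single-allele
#' loss, and at or beyond `t_high` a high gain/two-allele loss (boundaries
#' closed away from zero). Non-finite values give `NA`.
#'
#' @param value Numeric vector.
#' @param t_low,t_high Positive thresholds, `t_high > t_low`.
#' @return Character vector over [cnv_categories] (with `NA` for missing).
#' @export
categorize_cnv <- function(value, t_low = 0.3, t_high = 1.0) {
  if (!(t_high > t_low && t_low > 0)) stop("need t_high > t_low > 0")
  out <- rep(NA_character_, length(value))
  ok <- is.finite(value)
  v <- value[ok]
  cat <- ifelse(v >= t_high, "high_gain",
         ifelse(v >= t_low, "low_gain",
         ifelse(v > -t_low, "normal",
         ifelse(v > -t_high, "het_del", "hom_del"))))
  out[ok] <- cat
  out
}

#' Per-group data preview for a branch head node
#'
#' The compact preview drawn on expanded branch nodes: per group one mean
#' value for numerical data, the five category counts for ordinal
#' copy-number data, and (mutated, non-mutated) counts for binary data.
#'
#' @param head_node A [pathway_node()] or node id.
#' @param datasets Named list of [omics_dataset()].
#' @param groupings Named list of [sample_grouping()] keyed by dataset id.
#' @param alias_table Optional alias translation.
#' @param graph Graph context.
#' @return Nested list `dataset -> group -> preview`, each preview carrying
#'   `kind` and either `mean`, `category_counts` or `counts`; datasets with
#'   no mapped rows yield `no_data = TRUE` (the missing-data marker).
#' @export
branch_preview <- function(head_node, datasets, groupings,
                           alias_table = NULL, graph = NULL) {
  out <- list()
  for (ds_id in names(datasets)) {
    ds <- datasets[[ds_id]]
    grp <- groupings[[ds_id]]
    if (is.null(grp)) next
    rows <- resolve_mappings(head_node, ds, alias_table, graph)
    per_group <- list()
    for (g in names(grp$groups)) {
      s <- group_summary(head_node, ds, grp, g, alias_table, graph)
      per_group[[g]] <- switch(ds$dtype,
        numerical = list(kind = "mean_bar", mean = s$mean,
                         no_data = !s$defined),
        ordinal_cnv = list(kind = "stacked_cnv",
                           category_counts = s$category_counts,
                           no_data = !s$defined),
        binary = list(kind = "stacked_binary",
                      counts = c(mutated = round(s$n_values *
                                   ifelse(s$defined, s$mutated_fraction, 0)),
                                 non_mutated = s$n_values - round(s$n_values *
                                   ifelse(s$defined, s$mutated_fraction, 0))),
                      no_data = !s$defined))
    }
    out[[ds_id]] <- list(no_data = length(rows) == 0L, groups = per_group)
  }
  out
}
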