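#' Configuration for the synthetic pathway/omics generators
#'
#' The generators emulate the structure of the case-study data: a
#' connected pathway map with a planted diamond motif (so at least two
#' alternative paths exist between the designated start and end nodes),
#' multi-mapping nodes including one complex node carrying 16 member
#' genes, a group (complex) node with children, and grouped omics matrices
#' in which a gene's copy-number state shifts its expression (amplified
#' samples express more, coupling coefficient `rho`).
#'
#' @param seed Integer seed; fully determines all outputs.
#' @param n_nodes Number of gene nodes.
#' @param n_edges Total number of edges (at least `n_nodes - 1`).
#' @param complex_members Member-gene count of the designated complex
#'   node (0 disables it).
#' @param members_dist Named probabilities over members-per-node for the
#'   remaining gene nodes.
#' @param include_group_node Add one group node with two children.
#' @param n_samples Samples per group.
#' @param group_labels Labels of the (disjoint) sample groups.
#' @param shift Per-group mean shift of the numerical (expression) data.
#' @param cnv_probs Per-group probability vectors over [cnv_categories]
#'   (ordered homozygous deletion to high gain).
#' @param mutation_rate Per-group Bernoulli rate of mutation.
#' @param rho Amplification coupling: expression gains `rho` per
#'   copy-number code unit.
#' @param noise_sd Residual standard deviation of the expression values.
#' @param missing_rate Fraction of cells set to missing in each matrix.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_nodes = 14L, n_edges = 20L,
                           complex_members = 16L,
                           members_dist = c("1" = 0.7, "2" = 0.2, "3" = 0.1),
                           include_group_node = TRUE,
                           n_samples = 12L,
                           group_labels = c("tumor", "normal"),
                           shift = c(tumor = 1, normal = 0),
                           cnv_probs = list(
                             tumor = c(0.05, 0.10, 0.50, 0.20, 0.15),
                             normal = c(0.02, 0.08, 0.80, 0.08, 0.02)),
                           mutation_rate = c(tumor = 0.2, normal = 0.05),
                           rho = 0.5, noise_sd = 1, missing_rate = 0.02) {
  stopifnot(n_edges >= n_nodes - 1, n_nodes >= 4,
            abs(sum(members_dist) - 1) < 1e-9,
            all(abs(vapply(cnv_probs, sum, numeric(1)) - 1) < 1e-9))
  structure(as.list(environment()), class = "fixture_config")
}

#' Generate a synthetic pathway graph
#'
#' Builds a connected directed pathway in the KGML dialect: gene nodes on
#' a jittered grid (no overlapping boxes), a planted diamond between the
#' start node `n01` and end node `n04` guaranteeing at least two
#' alternative simple paths, one complex node with
#' `config$complex_members` member genes, and optionally a group node with
#' two children. The planted start/end ids are attached as the `"planted"`
#' attribute.
#'
#' @param config A [fixture_config()].
#' @return A [pathway_graph()].
#' @export
make_pathway <- function(config = fixture_config()) {
  set.seed(config$seed)
  n <- config$n_nodes
  n_total <- n + as.integer(config$include_group_node)
  ncol_grid <- ceiling(sqrt(n_total))
  nrow_grid <- ceiling(n_total / ncol_grid)
  sx <- 110; sy <- 60; w <- 46; h <- 17
  image_size <- c(ncol_grid * sx + 60, nrow_grid * sy + 60)

  member_counter <- 0L
  next_members <- function(k) {
    ids <- paste0("entrez:", 10000L + member_counter + seq_len(k))
    member_counter <<- member_counter + k
    ids
  }
  place <- function(i) {
    col <- (i - 1L) %% ncol_grid
    row <- (i - 1L) %/% ncol_grid
    c(60 + col * sx + stats::runif(1, -10, 10),
      50 + row * sy + stats::runif(1, -8, 8), w, h)
  }

  complex_idx <- if (config$complex_members > 0) min(5L, n) else 0L
  nodes <- vector("list", n)
  for (i in seq_len(n)) {
    k <- if (i == complex_idx) config$complex_members else {
      ks <- as.integer(names(config$members_dist))
      sample(ks, 1, prob = config$members_dist)
    }
    nodes[[i]] <- pathway_node(sprintf("n%02d", i), "gene",
                               label = sprintf("G%d", i),
                               bbox = place(i),
                               members = next_members(k))
  }

  edge_set <- character()
  edges <- list()
  add_edge <- function(a, b, relation = NULL, directed = TRUE) {
    key <- paste(a, b)
    if (a == b || key %in% edge_set) return(FALSE)
    if (is.null(relation))
      relation <- sample(c("activation", "inhibition", "other", "binding"),
                         1, prob = c(0.5, 0.2, 0.2, 0.1))
    edge_set <<- c(edge_set, key)
    edges[[length(edges) + 1L]] <<- data.frame(
      source = a, target = b, relation = relation, directed = directed,
      stringsAsFactors = FALSE)
    TRUE
  }

  # planted diamond n01 -> {n02, n03} -> n04
  add_edge("n01", "n02", "activation")
  add_edge("n02", "n04", "activation")
  add_edge("n01", "n03", "activation")
  add_edge("n03", "n04", "activation")
  # connect the remainder (connected as an undirected graph)
  if (n >= 5) for (i in 5:n) {
    j <- sample(seq_len(i - 1L), 1)
    if (stats::runif(1) < 0.5) add_edge(sprintf("n%02d", j), sprintf("n%02d", i))
    else add_edge(sprintf("n%02d", i), sprintf("n%02d", j))
  }
  guard <- 0L
  while (length(edges) < config$n_edges && guard < 1000L) {
    guard <- guard + 1L
    ab <- sample(n, 2)
    add_edge(sprintf("n%02d", ab[1]), sprintf("n%02d", ab[2]),
             directed = stats::runif(1) > 0.1)
  }

  if (config$include_group_node) {
    kid_pool <- if (n >= 7) setdiff(5:n, complex_idx) else setdiff(2:n, complex_idx)
    kids <- sprintf("n%02d", sort(sample(kid_pool, 2)))
    nodes[[n + 1L]] <- pathway_node("grp1", "group", label = "complex1",
                                    bbox = place(n + 1L), children = kids)
    add_edge(sprintf("n%02d", sample(2:3, 1)), "grp1", "binding")
  }

  g <- pathway_graph(sprintf("synthetic%03d", config$seed),
                     "synthetic pathway", nodes, do.call(rbind, edges),
                     image_size, "kgml")
  attr(g, "planted") <- list(start = "n01", end = "n04")
  g
}

#' Generate synthetic omics matrices for a pathway
#'
#' One row per distinct member gene of the graph. Copy-number codes are
#' drawn per group from `config$cnv_probs`; expression is
#' `shift[group] + rho * code + Gaussian noise`, so amplified samples of a
#' gene express more; mutation status is Bernoulli per gene and group.
#' Missing values are injected at `config$missing_rate` into each matrix.
#'
#' @param graph A [pathway_graph()] from [make_pathway()].
#' @param config The same [fixture_config()].
#' @return List with `datasets` (named list of [omics_dataset()]: `mrna`,
#'   `cnv`, `mutation`), `groupings` (matching [sample_grouping()] per
#'   dataset) and `genes`.
#' @export
make_omics <- function(graph, config = fixture_config()) {
  set.seed(config$seed + 1L)
  genes <- unique(unlist(lapply(graph$nodes, function(n) n$members)))
  n_g <- length(genes)
  labels <- config$group_labels
  sample_ids <- sprintf("s%03d", seq_len(config$n_samples * length(labels)))
  groups <- split(sample_ids, rep(labels, each = config$n_samples))[labels]
  group_of <- rep(labels, each = config$n_samples)

  n_s <- length(sample_ids)
  cnv <- matrix(NA_real_, n_g, n_s, dimnames = list(genes, sample_ids))
  mrna <- matrix(NA_real_, n_g, n_s, dimnames = list(genes, sample_ids))
  mut <- matrix(NA_real_, n_g, n_s, dimnames = list(genes, sample_ids))
  for (j in seq_len(n_s)) {
    gl <- group_of[j]
    codes <- sample(-2:2, n_g, replace = TRUE, prob = config$cnv_probs[[gl]])
    cnv[, j] <- codes
    mrna[, j] <- config$shift[[gl]] + config$rho * codes +
      stats::rnorm(n_g, 0, config$noise_sd)
    mut[, j] <- stats::rbinom(n_g, 1, config$mutation_rate[[gl]])
  }
  inject_missing <- function(m) {
    if (config$missing_rate <= 0) return(m)
    drop <- stats::runif(length(m)) < config$missing_rate
    m[drop] <- NA_real_
    m
  }
  mrna <- inject_missing(mrna)
  cnv <- inject_missing(cnv)
  mut <- inject_missing(mut)

  datasets <- list(
    mrna = omics_dataset("mrna", "numerical", mrna, color_tag = "#3DB7B7"),
    cnv = omics_dataset("cnv", "ordinal_cnv", cnv, color_tag = "#4477AA"),
    mutation = omics_dataset("mutation", "binary", mut, color_tag = "#CC99CC"))
  groupings <- lapply(stats::setNames(names(datasets), names(datasets)),
                      function(ds) sample_grouping(ds, groups, datasets[[ds]]))
  list(datasets = datasets, groupings = groupings, genes = genes)
}

#' Write a complete fixture set to disk
#'
#' Produces `pathway.kgml`, `mrna.tsv`, `cnv.tsv`, `mutation.tsv`,
#' `groups.tsv` and `config.yaml` under `dir`. The same seed always
#' produces byte-identical files.
#'
#' @param dir Output directory (created if absent).
#' @param config A [fixture_config()].
#' @return Invisibly, the list of written paths.
#' @export
write_fixture_set <- function(dir, config = fixture_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- make_pathway(config)
  om <- make_omics(g, config)
  paths <- c(pathway = file.path(dir, "pathway.kgml"),
             mrna = file.path(dir, "mrna.tsv"),
             cnv = file.path(dir, "cnv.tsv"),
             mutation = file.path(dir, "mutation.tsv"),
             groups = file.path(dir, "groups.tsv"),
             config = file.path(dir, "config.yaml"))
  write_kgml(g, paths["pathway"])
  write_matrix_tsv(om$datasets$mrna, paths["mrna"])
  write_matrix_tsv(om$datasets$cnv, paths["cnv"])
  write_matrix_tsv(om$datasets$mutation, paths["mutation"])
  grp_rows <- do.call(rbind, lapply(names(om$groupings), function(ds) {
    grp <- om$groupings[[ds]]
    do.call(rbind, lapply(names(grp$groups), function(g)
      data.frame(dataset_id = ds, group_label = g,
                 sample_id = grp$groups[[g]], stringsAsFactors = FALSE)))
  }))
  utils::write.table(grp_rows, paths["groups"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- unclass(config)
  cfg$members_dist <- as.list(cfg$members_dist)
  cfg$shift <- as.list(cfg$shift)
  cfg$mutation_rate <- as.list(cfg$mutation_rate)
  yaml::write_yaml(cfg, paths["config"])
  invisible(paths)
}

write_matrix_tsv <- function(dataset, file) {
  m <- dataset$values
  chr <- matrix(vapply(m, function(v)
    if (is.na(v)) NA_character_ else format(v, digits = 10, trim = TRUE,
                                            scientific = FALSE),
    character(1)), nrow = nrow(m), dimnames = dimnames(m))
  tab <- data.frame(gene = rownames(m), chr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}
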