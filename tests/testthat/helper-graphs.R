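# Graph construction helpers for tests. Bounding boxes are laid out on a
# spaced grid so geometry tests have non-overlapping boxes.

mk_graph <- function(ids, edges = NULL, members = NULL, labels = NULL,
                     spacing = c(120, 70)) {
  ncols <- ceiling(sqrt(length(ids)))
  nodes <- lapply(seq_along(ids), function(i) {
    pathway_node(ids[i], "gene",
                 label = if (is.null(labels)) ids[i] else labels[i],
                 bbox = c(80 + ((i - 1) %% ncols) * spacing[1],
                          60 + ((i - 1) %/% ncols) * spacing[2], 46, 17),
                 members = if (is.null(members)) paste0("entrez:", i)
                           else members[[i]])
  })
  if (is.null(edges)) edges <- enroute:::empty_edges()
  if (is.character(edges)) {
    # "A>B" directed, "A-B" undirected
    rows <- lapply(edges, function(s) {
      if (grepl(">", s, fixed = TRUE)) {
        ab <- strsplit(s, ">", fixed = TRUE)[[1]]
        data.frame(source = ab[1], target = ab[2], relation = "activation",
                   directed = TRUE, stringsAsFactors = FALSE)
      } else {
        ab <- strsplit(s, "-", fixed = TRUE)[[1]]
        data.frame(source = ab[1], target = ab[2], relation = "binding",
                   directed = FALSE, stringsAsFactors = FALSE)
      }
    })
    edges <- do.call(rbind, rows)
  }
  pathway_graph("test", "test", nodes, edges)
}

diamond_graph <- function() mk_graph(c("A", "B", "C", "D"),
                                     c("A>B", "A>C", "B>D", "C>D"))

# growth-factor receptor branch fixture: the selected path runs
# EGFR -> A1 -> A2 -> MTOR; EGFR additionally feeds PLCG1 and SHC2;
# following SHC2 leads via GRB2 and SOS to HRAS, which has two leaving
# branches (RAF1, PIK3) and therefore terminates a branch walk
egfr_graph <- function() {
  mk_graph(c("EGFR", "A1", "A2", "MTOR", "PLCG1", "SHC2", "GRB2", "SOS",
             "HRAS", "RAF1", "PIK3"),
           c("EGFR>A1", "A1>A2", "A2>MTOR",
             "EGFR>PLCG1", "EGFR>SHC2",
             "SHC2>GRB2", "GRB2>SOS", "SOS>HRAS",
             "HRAS>RAF1", "HRAS>PIK3"))
}

random_test_graph <- function(seed, n_max = 12L, m_max = 20L) {
  set.seed(seed)
  n <- sample(4:n_max, 1)
  ids <- sprintf("v%02d", seq_len(n))
  m <- sample(seq_len(m_max), 1)
  pairs <- unique(t(replicate(m, sample(n, 2))))
  edges <- data.frame(source = ids[pairs[, 1]], target = ids[pairs[, 2]],
                      relation = "activation",
                      directed = stats::runif(nrow(pairs)) > 0.2,
                      stringsAsFactors = FALSE)
  mk_graph(ids, edges)
}

# independent oracle: exhaustive simple-path enumeration working directly
# on the edge table (no shared code with find_alternatives)
oracle_simple_paths <- function(graph, start, end, max_len = Inf) {
  e <- graph$edges
  step <- function(cur) {
    out <- c(e$target[e$source == cur & e$directed],
             e$target[e$source == cur & !e$directed],
             e$source[e$target == cur & !e$directed])
    unique(out)
  }
  acc <- list()
  recurse <- function(seq_nodes) {
    cur <- seq_nodes[length(seq_nodes)]
    if (cur == end) { acc[[length(acc) + 1L]] <<- seq_nodes; return() }
    if (length(seq_nodes) - 1 >= max_len) return()
    for (nb in step(cur)) if (!nb %in% seq_nodes) recurse(c(seq_nodes, nb))
  }
  recurse(start)
  acc
}

path_key_set <- function(paths) {
  sort(vapply(paths, paste, character(1), collapse = "|"))
}

# omics helpers -------------------------------------------------------------

mk_dataset <- function(values, dtype = "numerical", id = "ds1") {
  omics_dataset(id, dtype, values)
}

mk_matrix <- function(genes, samples, data) {
  matrix(data, nrow = length(genes), ncol = length(samples),
         dimnames = list(genes, samples), byrow = TRUE)
}
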