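test_that("TSV matrices read back typed, with empty cells as missing", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3",
               "g1\t0.5\t\t-1.25",
               "g2\t2\t0.125\t3"), tsv)
  ds <- read_omics_matrix(tsv, "numerical", "expr")
  expect_equal(ds$values["g1", "s1"], 0.5)
  expect_true(is.na(ds$values["g1", "s2"]))
  expect_equal(dim(ds$values), c(2, 3))

  writeLines(c("gene\ts1\ts2", "g1\t-2\t2"), tsv)
  cn <- read_omics_matrix(tsv, "ordinal_cnv")
  expect_equal(enroute:::cnv_code_to_category(cn$values["g1", "s1"]), "hom_del")
  expect_equal(enroute:::cnv_code_to_category(cn$values["g1", "s2"]), "high_gain")

  writeLines(c("gene\ts1", "g1\tabc"), tsv)
  expect_error(read_omics_matrix(tsv, "numerical"), "non-numeric cell")
  writeLines(c("gene\ts1", "g1\t1", "g1\t0"), tsv)
  expect_error(read_omics_matrix(tsv, "binary"), "duplicate gene")
  writeLines(c("gene\ts1", "g1\t3"), tsv)
  expect_error(read_omics_matrix(tsv, "ordinal_cnv"), "-2\\.\\.2")
})

test_that("node-to-row resolution honors members, aliases and groups", {
  ds <- mk_dataset(mk_matrix(c("g2", "g3", "g5"), c("s1", "s2"), 1:6))
  n <- pathway_node("n", "gene", members = c("g1", "g2"))
  expect_equal(resolve_mappings(n, ds), "g2")
  # alias translation
  al <- c(g1 = "g3")
  expect_equal(resolve_mappings(n, ds, alias_table = al), c("g3", "g2"))
  # compounds and map links never map
  expect_equal(resolve_mappings(pathway_node("c", "compound"), ds), character())
  # group nodes concatenate children child-major and deduplicate
  ga <- pathway_node("a", "gene", members = c("g5", "g2"))
  gb <- pathway_node("b", "gene", members = c("g2", "g3"))
  grp <- pathway_node("grp", "group", children = c("a", "b"))
  g <- pathway_graph("p", "p", list(ga, gb, grp))
  expect_equal(resolve_mappings(grp, ds, graph = g), c("g5", "g2", "g3"))
})

test_that("node_summary matches the direct pooled formulas", {
  ds <- mk_dataset(mk_matrix("g1", paste0("s", 1:4), c(1, 2, 3, 4)))
  n <- pathway_node("n", "gene", members = "g1")
  s <- node_summary(n, ds)
  expect_equal(s$mean, 2.5)
  expect_equal(s$std, sqrt(1.25))
  expect_false(s$has_missing)

  same <- mk_dataset(mk_matrix("g1", paste0("s", 1:3), c(2, 2, 2)))
  s2 <- node_summary(n, same)
  expect_equal(s2$mean, 2)
  expect_equal(s2$std, 0)

  # 2 rows x 3 samples with one missing: 5 values pooled
  m <- mk_matrix(c("g1", "g2"), paste0("s", 1:3), c(1, 2, NA, 4, 5, 6))
  s3 <- node_summary(pathway_node("n", "gene", members = c("g1", "g2")),
                     mk_dataset(m))
  vals <- c(1, 2, 4, 5, 6)
  expect_equal(s3$n_values, 5)
  expect_equal(s3$mean, mean(vals))
  expect_equal(s3$std, sqrt(mean((vals - mean(vals))^2)))
  expect_true(s3$has_missing)

  # zero mapped values: flagged, not NaN
  s4 <- node_summary(pathway_node("x", "gene", members = "nope"), ds)
  expect_false(s4$defined)
  expect_true(s4$has_missing)
  expect_true(is.na(s4$mean))
})

test_that("summaries match brute force on random datasets", {
  for (seed in 1:30) {
    set.seed(seed)
    genes <- paste0("g", 1:6)
    samples <- paste0("s", 1:8)
    m <- mk_matrix(genes, samples, stats::rnorm(48))
    m[stats::runif(48) < 0.15] <- NA
    ds <- mk_dataset(m)
    grp <- sample_grouping("ds1", list(a = samples[1:5], b = samples[4:8]), ds)
    members <- sample(c(genes, "absent1", "absent2"), sample(1:5, 1))
    n <- pathway_node("n", "gene", members = members)
    for (gl in c(NA, "a", "b")) {
      s <- if (is.na(gl)) node_summary(n, ds)
           else group_summary(n, ds, grp, gl)
      cols <- if (is.na(gl)) samples else grp$groups[[gl]]
      pool <- as.vector(m[intersect(members, genes), cols])
      pool <- pool[!is.na(pool)]
      if (length(pool)) {
        expect_equal(s$mean, mean(pool), tolerance = 1e-12)
        expect_equal(s$std, sqrt(mean((pool - mean(pool))^2)), tolerance = 1e-12)
        expect_equal(s$n_values, length(pool))
      } else {
        expect_false(s$defined)
      }
    }
  }
})

test_that("group summaries respect overlaps and binary fractions", {
  m <- mk_matrix("g1", paste0("s", 1:4), c(1, 0, 0, 1))
  ds <- omics_dataset("mut", "binary", m)
  grp <- sample_grouping("mut", list(all = paste0("s", 1:4),
                                     first = "s1"), ds)
  n <- pathway_node("n", "gene", members = "g1")
  expect_equal(group_summary(n, ds, grp, "all")$mutated_fraction, 0.5)
  one <- group_summary(n, ds, grp, "first")
  expect_equal(one$mean, 1)
  expect_equal(one$std, 0)
  # an overlapping sample contributes to both groups
  expect_equal(group_summary(n, ds, grp, "all")$n_values, 4)
  expect_equal(one$n_values, 1)
})

test_that("union-of-groups mean equals the size-weighted group combination", {
  set.seed(42)
  m <- mk_matrix(c("g1", "g2"), paste0("s", 1:10), stats::rnorm(20))
  ds <- mk_dataset(m)
  grp <- sample_grouping("ds1", list(a = paste0("s", 1:4),
                                     b = paste0("s", 5:10),
                                     all = paste0("s", 1:10)), ds)
  n <- pathway_node("n", "gene", members = c("g1", "g2"))
  sa <- group_summary(n, ds, grp, "a")
  sb <- group_summary(n, ds, grp, "b")
  sall <- group_summary(n, ds, grp, "all")
  expect_equal(sall$mean,
               (sa$n_values * sa$mean + sb$n_values * sb$mean) /
                 (sa$n_values + sb$n_values))
})

test_that("quantitative copy-number categorization is piecewise and monotone", {
  expect_equal(categorize_cnv(0), "normal")
  expect_equal(categorize_cnv(0.5, 0.3, 1.0), "low_gain")
  expect_equal(categorize_cnv(-1.2, 0.3, 1.0), "hom_del")
  # boundary closed away from zero
  expect_equal(categorize_cnv(1.0, 0.3, 1.0), "high_gain")
  expect_equal(categorize_cnv(-0.3, 0.3, 1.0), "het_del")
  expect_true(is.na(categorize_cnv(NaN)))
  expect_true(is.na(categorize_cnv(Inf)))
  expect_error(categorize_cnv(0, 1, 0.5), "t_high > t_low")
  v <- seq(-2, 2, by = 0.01)
  ranks <- match(categorize_cnv(v), cnv_categories)
  expect_true(all(diff(ranks) >= 0))
})

test_that("ordinal summaries count categories conservatively", {
  m <- mk_matrix(c("g1", "g2"), paste0("s", 1:3),
                 c(0, 1, 1, -2, NA, 2))
  ds <- omics_dataset("cnv", "ordinal_cnv", m)
  n <- pathway_node("n", "gene", members = c("g1", "g2"))
  s <- node_summary(n, ds)
  expect_equal(unname(s$category_counts),
               c(1, 0, 1, 2, 1))  # hom, het, normal, low, high
  expect_equal(sum(s$category_counts) + (s$n_rows * s$n_samples - s$n_values),
               s$n_rows * s$n_samples)
  expect_equal(s$mean, mean(c(0, 1, 1, -2, 2)))
})

test_that("branch previews summarize per dataset and group", {
  m_num <- mk_matrix("g1", paste0("s", 1:2), c(1, 3))
  m_cnv <- mk_matrix("g1", paste0("s", 1:3), c(0, 1, 1))
  m_bin <- mk_matrix("g1", paste0("s", 1:2), c(0, 1))
  datasets <- list(mrna = omics_dataset("mrna", "numerical", m_num),
                   cnv = omics_dataset("cnv", "ordinal_cnv", m_cnv),
                   mut = omics_dataset("mut", "binary", m_bin))
  groupings <- list(
    mrna = sample_grouping("mrna", list(g = c("s1", "s2"))),
    cnv = sample_grouping("cnv", list(g = c("s1", "s2", "s3"))),
    mut = sample_grouping("mut", list(g = c("s1", "s2"))))
  n <- pathway_node("n", "gene", members = "g1")
  pv <- branch_preview(n, datasets, groupings)
  expect_equal(pv$mrna$groups$g$mean, 2)
  expect_equal(unname(pv$cnv$groups$g$category_counts), c(0, 0, 1, 2, 0))
  expect_equal(unname(pv$mut$groups$g$counts), c(1, 1))
  # unmapped head: flagged, no crash
  pv2 <- branch_preview(pathway_node("x", "gene", members = "zzz"),
                        datasets, groupings)
  expect_true(pv2$mrna$no_data)
})

test_that("empirical category fractions converge to generation probabilities", {
  set.seed(7)
  probs <- c(0.05, 0.1, 0.55, 0.2, 0.1)
  n <- 1000
  codes <- sample(-2:2, n, replace = TRUE, prob = probs)
  ds <- omics_dataset("cnv", "ordinal_cnv",
                      mk_matrix("g1", paste0("s", 1:n), codes))
  s <- node_summary(pathway_node("n", "gene", members = "g1"), ds)
  frac <- s$category_counts / n
  se <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(frac - probs) <= 3 * se + 1e-9))
})
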