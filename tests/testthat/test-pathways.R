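kgml_text <- function(entries = "", relations = "",
                      pathway = 'name="path:dme00001"') {
  sprintf("<pathway %s>%s%s</pathway>", pathway, entries, relations)
}

test_that("KGML entries map to nodes per the format rules", {
  doc <- kgml_text(
    '<entry id="1" name="dme:Dmel_CG1234 dme:Dmel_CG5678" type="gene">
       <graphics name="SdhA"/></entry>
     <entry id="2" name="path:dme00020" type="map"/>',
    '<relation entry1="1" entry2="2" type="maplink">
       <subtype name="compound" value="x"/></relation>')
  g <- read_kgml(xml2::read_xml(doc))
  expect_identical(g$pathway_id, "path:dme00001")
  expect_identical(g$members[["1"]],
                   c("dme:Dmel_CG1234", "dme:Dmel_CG5678"))
  expect_length(g$members[["2"]], 0L)   # non-gene entry: empty membership
  expect_identical(g$nodes$label[1], "SdhA")
  expect_identical(g$edges$relation, "compound")

  empty <- read_kgml(xml2::read_xml(kgml_text()))
  expect_identical(nrow(empty$nodes), 0L)

  expect_error(read_kgml(xml2::read_xml(kgml_text(pathway = ""))),
               "name attribute")
})

test_that("KGML and node-map writers round-trip generated pathways", {
  pw <- gen_toy_pathway(5, c(2, 0, 3, 1, 4), seed = 31)
  xml_path <- withr::local_tempfile(fileext = ".xml")
  write_kgml(pw, xml_path)
  back <- read_kgml(xml_path)
  expect_identical(back$pathway_id, pw$pathway_id)
  expect_identical(back$nodes, pw$nodes)
  expect_identical(back$members, pw$members)
  expect_identical(back$edges$from, pw$edges$from)
  expect_identical(back$edges$to, pw$edges$to)
  expect_identical(back$edges$relation, pw$edges$relation)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node_id\twrong", "a\tb"), bad)
  expect_error(read_node_map(bad), "gene_ids")
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node_id\tgene_ids", "a\tg1", "a\tg2"), dup)
  expect_error(read_node_map(dup), "duplicate")
})

test_that("node aggregation implements weighted and sum methods", {
  sdh <- data.frame(logfc = c(-2.1, 5.2), cpm = c(100, 1))
  expect_equal(aggregate_node(sdh, "sum")$logfc_final, 3.1)
  expect_equal(round(aggregate_node(sdh, "weighted")$logfc_final, 4),
               -2.0277)

  single <- data.frame(logfc = 1.7, cpm = 55)
  expect_equal(aggregate_node(single, "weighted")$logfc_final, 1.7)
  expect_equal(aggregate_node(single, "sum")$logfc_final, 1.7)

  eqw <- data.frame(logfc = c(-1, 0, 2.5), cpm = rep(8, 3))
  expect_equal(aggregate_node(eqw, "weighted")$logfc_final,
               mean(eqw$logfc))

  none <- aggregate_node(data.frame(logfc = numeric(0),
                                    cpm = numeric(0)), "weighted")
  expect_false(none$scored)
  expect_true(is.na(none$logfc_final))
  zero_w <- aggregate_node(data.frame(logfc = c(1, 2), cpm = c(0, 0)),
                           "weighted")
  expect_false(zero_w$scored)

  expect_error(aggregate_node(data.frame(logfc = NaN, cpm = 1)), "finite")
})

test_that("weighted aggregation is scale-free, convex and limit-correct", {
  set.seed(7)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    m <- data.frame(logfc = rnorm(k, sd = 2), cpm = rlnorm(k))
    w <- aggregate_node(m, "weighted")$logfc_final
    m2 <- transform(m, cpm = cpm * runif(1, 0.01, 500))
    expect_equal(aggregate_node(m2, "weighted")$logfc_final, w,
                 tolerance = 1e-10)
    expect_gte(w, min(m$logfc))
    expect_lte(w, max(m$logfc))
  }
  dom <- data.frame(logfc = c(4.2, -1, 2), cpm = c(1e6, 1, 1))
  expect_equal(aggregate_node(dom, "weighted")$logfc_final, 4.2,
               tolerance = 1e-4)
})

test_that("pathway scoring joins, orders and reports missingness", {
  stats <- data.frame(gene_id = c("g1", "g2", "g3"),
                      logfc = c(-2.1, 5.2, 0.4),
                      cpm = c(100, 1, 7))
  g <- pathway_graph(
    "toy",
    nodes = data.frame(node_id = c("b_sdh", "a_single", "c_miss"),
                       label = c("Sdh", "single", "missing")),
    members = list(b_sdh = c("g1", "g2"), a_single = "g3",
                   c_miss = c("g3", "gX")))
  sw <- suppressMessages(score_pathway(g, stats, "weighted"))
  expect_identical(sw$node_id, c("a_single", "b_sdh", "c_miss"))
  expect_equal(sw$logfc_final[sw$node_id == "b_sdh"], -2.027723,
               tolerance = 1e-6)
  expect_equal(score_pathway(g, stats, "sum")$logfc_final[2], 3.1)
  expect_identical(sw$n_missing, c(0L, 0L, 1L))
  expect_equal(sw$logfc_final[1], 0.4)  # single-gene node = gene lookup

  # permuting the stats rows changes nothing
  sp <- suppressMessages(score_pathway(g, stats[c(3, 1, 2), ], "weighted"))
  expect_equal(sp, sw)

  # genes mapping to no node are counted in a message
  stats2 <- rbind(stats, data.frame(gene_id = "orphan", logfc = 1, cpm = 1))
  expect_message(score_pathway(g, stats2, "weighted"), "1 gene")
})

test_that("scoring matches a brute-force per-node recomputation", {
  set.seed(55)
  for (i in 1:10) {
    n_nodes <- sample(2:6, 1)
    pw <- gen_toy_pathway(n_nodes, sample(0:4, n_nodes, replace = TRUE),
                          seed = i)
    genes <- unique(unlist(pw$members))
    if (length(genes) == 0) next
    stats <- data.frame(gene_id = genes,
                        logfc = rnorm(length(genes)),
                        cpm = rlnorm(length(genes)))
    got <- suppressMessages(score_pathway(pw, stats, "weighted"))
    for (j in seq_len(nrow(got))) {
      mem <- pw$members[[got$node_id[j]]]
      rows <- stats[stats$gene_id %in% mem, ]
      if (nrow(rows) == 0) {
        expect_false(got$scored[j])
      } else {
        expect_equal(got$logfc_final[j],
                     sum(rows$logfc * rows$cpm) / sum(rows$cpm),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("score export writes TSV and DOT as specified", {
  stats <- data.frame(gene_id = c("g1", "g2"), logfc = c(-2.1, 5.2),
                      cpm = c(100, 1))
  g <- pathway_graph("toy",
                     nodes = data.frame(node_id = c("n1", "n2"),
                                        label = c("Sdh", "empty")),
                     members = list(n1 = c("g1", "g2"),
                                    n2 = character(0)))
  sc <- suppressMessages(score_pathway(g, stats, "weighted"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_scores(sc, tsv, "tsv")
  expect_match(readLines(tsv, n = 1), "^node_id\t")
  back <- read_scores(tsv)
  expect_equal(back$logfc_final, sc$logfc_final)
  expect_identical(back$node_id, sc$node_id)

  dot <- withr::local_tempfile(fileext = ".dot")
  export_scores(sc, dot, "dot", graph = g)
  txt <- readLines(dot)
  expect_true(any(grepl("#bdbdbd", txt)))  # unscored node rendered grey
  expect_true(any(grepl("digraph", txt)))
  expect_error(export_scores(sc, dot, "svg"))
})
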