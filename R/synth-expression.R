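#' Generate a synthetic gene-level differential-expression table
#'
#' Emulates the gene-level statistics a differential-expression fit
#' produces: a log2 fold-change per gene (an exact `fraction_null` share
#' of genes is exactly 0) and a strictly positive lognormal CPM weight.
#'
#' @param scenario An [expression_scenario()].
#' @param seed Integer seed.
#' @return A data.frame of gene statistics with columns `gene_id`,
#'   `logfc`, `cpm`.
#' @export
gen_gene_stats <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "expression_scenario"))
  n <- scenario$n_genes
  with_seed(seed, {
    n_null <- round(scenario$fraction_null * n)
    null_idx <- sample.int(n, n_null)
    logfc <- rnorm(n, mean = 0, sd = scenario$logfc_effect_sd)
    logfc[null_idx] <- 0
    cpm <- rlnorm(n, meanlog = scenario$cpm_log_mean,
                  sdlog = scenario$cpm_log_sd)
    data.frame(gene_id = sprintf("FBgn%07d", seq_len(n)),
               logfc = logfc, cpm = cpm)
  })
}

#' Generate a toy pathway graph
#'
#' Builds a small pathway with the given number of nodes and member-gene
#' counts (0 members allowed, producing an unmeasured node). Gene ids are
#' unique across the pathway; consecutive nodes are linked by edges so
#' the graph exports sensibly.
#'
#' @param n_nodes Number of nodes.
#' @param genes_per_node Integer vector (length `n_nodes`) of member-gene
#'   counts, each >= 0.
#' @param seed Integer seed (used to draw the gene-id numbering).
#' @param pathway_id Pathway label.
#' @param node_ids Optional explicit node ids (must be unique).
#' @return A [pathway_graph()].
#' @export
gen_toy_pathway <- function(n_nodes, genes_per_node, seed = 1L,
                            pathway_id = "toy00001", node_ids = NULL) {
  if (length(genes_per_node) != n_nodes) {
    stop_param("genes_per_node must have length n_nodes (%d vs %d)",
               length(genes_per_node), n_nodes)
  }
  if (n_nodes < 1) stop_param("n_nodes must be >= 1")
  if (any(genes_per_node < 0)) stop_param("genes_per_node must be >= 0")
  if (is.null(node_ids)) {
    node_ids <- sprintf("n%02d", seq_len(n_nodes))
  }
  if (anyDuplicated(node_ids)) {
    stop_param("duplicate node id requested: %s",
               node_ids[duplicated(node_ids)][1L])
  }
  total <- sum(genes_per_node)
  gene_nums <- with_seed(seed, sample.int(9999999, total))
  gene_ids <- sprintf("FBgn%07d", gene_nums)
  members <- vector("list", n_nodes)
  names(members) <- node_ids
  at <- 0L
  for (i in seq_len(n_nodes)) {
    k <- genes_per_node[i]
    members[[i]] <- if (k > 0) gene_ids[at + seq_len(k)] else character(0)
    at <- at + k
  }
  edges <- if (n_nodes >= 2) {
    data.frame(from = node_ids[-n_nodes], to = node_ids[-1L],
               relation = "ECrel")
  } else {
    data.frame(from = character(0), to = character(0),
               relation = character(0))
  }
  pathway_graph(pathway_id,
                nodes = data.frame(node_id = node_ids,
                                   label = paste0("gene ", node_ids)),
                members = members, edges = edges)
}
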