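#' Aggregate member-gene log fold-changes into one node score
#'
#' The core pathway computation: a multi-gene KEGG node's log2
#' fold-change is the expression-weighted mean of its members,
#' `sum(logfc_i * w_i) / sum(w_i)`, with absolute expression (CPM/FPKM) as
#' the weight `w`. This keeps a lowly expressed isoform from dominating
#' the node the way plain summation lets it (the `"sum"` method, kept for
#' comparison, adds the members' logFCs outright). Nodes with no measured
#' member, or zero total weight under the weighted method, are reported
#' as *unscored* — never as 0, which would mean "no change".
#'
#' @param members data.frame of measured member genes with columns
#'   `logfc` and `cpm` (the weight); zero rows allowed.
#' @param method `"weighted"` (default) or `"sum"`.
#' @return A list with `logfc_final` (NA when unscored), `total_weight`,
#'   `n_measured`, `method`, `scored`.
#' @examples
#' sdh <- data.frame(logfc = c(-2.1, 5.2), cpm = c(100, 1))
#' aggregate_node(sdh, "sum")$logfc_final       # +3.1
#' aggregate_node(sdh, "weighted")$logfc_final  # -2.0277
#' @export
aggregate_node <- function(members, method = c("weighted", "sum")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(members),
            all(c("logfc", "cpm") %in% names(members)))
  if (any(is.nan(members$logfc)) || any(!is.finite(members$logfc))) {
    stop_param("member logfc values must be finite")
  }
  if (any(members$cpm < 0)) stop_param("weights (cpm) must be >= 0")
  n <- nrow(members)
  tw <- sum(members$cpm)
  unscored <- function() {
    list(logfc_final = NA_real_, total_weight = tw, n_measured = n,
         method = method, scored = FALSE)
  }
  if (n == 0L) return(unscored())
  if (method == "weighted") {
    if (tw <= 0) return(unscored())
    lf <- sum(members$logfc * members$cpm) / tw
  } else {
    lf <- sum(members$logfc)
  }
  list(logfc_final = lf, total_weight = tw, n_measured = n,
       method = method, scored = TRUE)
}

#' Score every node of a pathway from a gene-statistics table
#'
#' Joins each node's membership against the gene table and aggregates
#' with [aggregate_node()]. Member genes absent from the table are
#' excluded and counted per node in `n_missing`; genes in the table that
#' map to no node are counted once in a message. A gene belonging to
#' several nodes contributes independently to each.
#'
#' @param graph A [pathway_graph()].
#' @param stats data.frame of gene statistics with columns `gene_id`,
#'   `logfc`, `cpm` (as from [gen_gene_stats()]); `gene_id` must be
#'   unique.
#' @param method `"weighted"` or `"sum"`.
#' @return data.frame ordered by `node_id` with columns `node_id`,
#'   `label`, `logfc_final`, `total_weight`, `n_measured`, `n_missing`,
#'   `method`, `scored`.
#' @export
score_pathway <- function(graph, stats, method = c("weighted", "sum")) {
  method <- match.arg(method)
  stopifnot(inherits(graph, "pathway_graph"), is.data.frame(stats),
            all(c("gene_id", "logfc", "cpm") %in% names(stats)))
  if (nrow(graph$nodes) == 0L || nrow(stats) == 0L) {
    stop_param("graph and stats must both be non-empty")
  }
  if (anyDuplicated(stats$gene_id)) {
    stop_param("duplicate gene_id in stats: %s",
               stats$gene_id[duplicated(stats$gene_id)][1L])
  }
  ord <- order(graph$nodes$node_id)
  node_ids <- graph$nodes$node_id[ord]
  labels <- graph$nodes$label[ord]
  rows <- lapply(seq_along(node_ids), function(i) {
    mem <- graph$members[[node_ids[i]]]
    idx <- match(mem, stats$gene_id)
    hit <- !is.na(idx)
    sc <- aggregate_node(stats[idx[hit], c("logfc", "cpm"), drop = FALSE],
                         method)
    data.frame(node_id = node_ids[i], label = labels[i],
               logfc_final = sc$logfc_final, total_weight = sc$total_weight,
               n_measured = sc$n_measured, n_missing = sum(!hit),
               method = sc$method, scored = sc$scored)
  })
  unmapped <- sum(!stats$gene_id %in% unlist(graph$members))
  if (unmapped > 0) {
    message(sprintf("score_pathway: %d gene(s) in stats map to no node of %s",
                    unmapped, graph$pathway_id))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Export node scores as TSV or a colorable DOT graph
#'
#' TSV export writes the score table as-is. DOT export colors each scored
#' node on a symmetric blue-white-red diverging scale clipped at
#' `|logFC| = clip`; unscored nodes are grey. Edges come from the graph,
#' when given.
#'
#' @param scores Score table from [score_pathway()].
#' @param path Output file path.
#' @param format `"tsv"` or `"dot"`.
#' @param graph Optional [pathway_graph()] supplying edges for DOT.
#' @param clip Absolute logFC at which the color scale saturates
#'   (default 2).
#' @return `path`, invisibly.
#' @export
export_scores <- function(scores, path, format = c("tsv", "dot"),
                          graph = NULL, clip = 2) {
  format <- match.arg(format)
  stopifnot(is.data.frame(scores))
  if (format == "tsv") {
    write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  ramp <- grDevices::colorRamp(c("#2166ac", "#ffffff", "#b2182b"))
  node_color <- function(lf, scored) {
    if (!scored || is.na(lf)) return("#bdbdbd")
    z <- max(-1, min(1, lf / clip))
    grDevices::rgb(ramp((z + 1) / 2), maxColorValue = 255)
  }
  lines <- c("digraph pathway {",
             "  node [style=filled, shape=box];")
  for (i in seq_len(nrow(scores))) {
    lab <- if (scores$scored[i]) {
      sprintf("%s\\n%.2f", scores$label[i], scores$logfc_final[i])
    } else {
      sprintf("%s\\n(unscored)", scores$label[i])
    }
    lines <- c(lines, sprintf('  "%s" [label="%s", fillcolor="%s"];',
                              scores$node_id[i], lab,
                              node_color(scores$logfc_final[i],
                                         scores$scored[i])))
  }
  if (!is.null(graph)) {
    for (i in seq_len(nrow(graph$edges))) {
      lines <- c(lines, sprintf('  "%s" -> "%s" [label="%s"];',
                                graph$edges$from[i], graph$edges$to[i],
                                graph$edges$relation[i]))
    }
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Read a node-score TSV written by [export_scores()]
#'
#' @param path Input TSV path.
#' @return The score data.frame.
#' @export
read_scores <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
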