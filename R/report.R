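#' Full screening analysis of a model file
#'
#' Reads a Boolean network model (format auto-detected: an XML prolog or
#' `<sbml` root means SBML-qual, anything else BoolNet text), scores every
#' node, classifies gatekeepers, and writes `report.json`, `scores.tsv`, and
#' `graph.dot` to `out_dir`. The recommended intervention targets, sorted by
#' mismatch, come first in the JSON report. Optionally, for small networks,
#' a set of perturbations is validated dynamically: for each requested
#' knockout/overexpression the exhaustive attractor engine computes the
#' landscape impact metrics and adds them to the report.
#'
#' @param model_path Path to a BoolNet text or SBML-qual model file.
#' @param threshold Selection threshold as a percent in `(0, 100]`
#'   (default 73).
#' @param hub_threshold Connectivity z-score defining hubs (default 2.5).
#' @param out_dir Output directory, created if missing; `NULL` writes no
#'   files.
#' @param format `"auto"`, `"boolnet"`, or `"sbmlqual"`.
#' @param sort_by Score-table sort column (default `"mismatch"`); rows tie-
#'   break on node name.
#' @param dynamics Optional named integer vector of perturbations, e.g.
#'   `c(A = 0, B = 1)` for a knockout of A and overexpression of B.
#' @param max_dyn_nodes Capacity cap forwarded to [find_attractors()].
#' @return An object of class `bn_report`: list with `network` (the parsed
#'   model), `graph`, `scores`, `classification`, `parameters`, `summary`,
#'   optional `dynamics`, and `timestamp`.
#' @examples
#' path <- system.file("extdata", "bottleneck12.bn", package = "bnscreen")
#' report <- run_analysis(path, out_dir = NULL)
#' report$classification$recommendations
#' @export
run_analysis <- function(model_path, threshold = 73, hub_threshold = 2.5,
                         out_dir = NULL, format = c("auto", "boolnet",
                                                    "sbmlqual"),
                         sort_by = "mismatch", dynamics = NULL,
                         max_dyn_nodes = 20L) {
  format <- match.arg(format)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0 || threshold > 100) {
    bn_stop("threshold must be a percent in (0, 100]", "bn_usage_error")
  }
  if (!file.exists(model_path)) {
    bn_stop(sprintf("model file not found: %s", model_path), "bn_io_error")
  }

  net <- read_network(model_path, format)
  graph <- build_interaction_graph(net)
  scores <- score_nodes(net, graph)
  classification <- classify(scores, T = threshold / 100,
                             hub_threshold = hub_threshold)

  dyn_results <- NULL
  if (!is.null(dynamics)) {
    if (is.null(names(dynamics)) || any(!nzchar(names(dynamics)))) {
      bn_stop("dynamics perturbations must be named by node", "bn_usage_error")
    }
    original <- find_attractors(net, max_nodes = max_dyn_nodes)
    dyn_results <- lapply(seq_along(dynamics), function(i) {
      node <- names(dynamics)[[i]]
      value <- as.integer(dynamics[[i]])
      perturbed <- find_attractors(apply_perturbation(net, node, value),
                                   max_nodes = max_dyn_nodes)
      impact <- impact_metrics(original, perturbed)
      list(node = node, value = value,
           fraction_lost = impact$fraction_lost,
           n_new = impact$n_new,
           min_hamming = impact$min_hamming)
    })
  }

  report <- structure(
    list(
      network = net,
      graph = graph,
      scores = scores,
      classification = classification,
      parameters = list(threshold_percent = threshold,
                        hub_threshold = hub_threshold),
      summary = list(n_nodes = length(net$nodes),
                     n_interactions = igraph::ecount(graph)),
      dynamics = dyn_results,
      sort_by = sort_by,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    class = "bn_report"
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
      bn_stop(sprintf("cannot create output directory: %s", out_dir),
              "bn_io_error")
    }
    write_report_json(report, file.path(out_dir, "report.json"))
    write_score_table(report, file.path(out_dir, "scores.tsv"),
                      sort_by = sort_by)
    writeLines(export_graph(graph, classification, format = "dot"),
               file.path(out_dir, "graph.dot"))
  }
  report
}

read_network <- function(path, format = "auto") {
  if (format == "auto") {
    head <- tryCatch(readLines(path, n = 5L, warn = FALSE),
                     error = function(e) character(0))
    format <- if (any(grepl("^\\s*<\\?xml|^\\s*<sbml", head))) {
      "sbmlqual"
    } else {
      "boolnet"
    }
  }
  switch(format,
         boolnet = parse_boolnet(path),
         sbmlqual = parse_sbml_qual(path))
}

#' @export
print.bn_report <- function(x, ...) {
  cat(sprintf("Boolean network screening report (%d nodes, %d interactions)\n",
              x$summary$n_nodes, x$summary$n_interactions))
  print(x$classification)
  invisible(x)
}

write_report_json <- function(report, file) {
  cls <- report$classification
  payload <- list(
    suggested_targets_sorted_by_mismatch = cls$recommendations,
    network = report$summary,
    parameters = report$parameters,
    classification = list(
      gatekeepers = cls$table$node[cls$table$class == "gatekeeper"],
      selected_non_gatekeepers =
        cls$table$node[cls$table$class == "selected_non_gatekeeper"],
      non_selected = cls$table$node[cls$table$class == "non_selected"],
      hubs = cls$table$node[cls$table$is_hub]
    ),
    scores = report$scores,
    dynamics = report$dynamics,
    timestamp = report$timestamp
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(file)
}

#' Write the per-node score table as TSV
#'
#' One row per node with VB, DP, degree, z-connectivity, the three ranks,
#' mismatch, class, and hub flag. Numeric columns carry 6 significant
#' digits; rows are ordered by the chosen column (descending for scores,
#' ascending for ranks and names) with node name as tie-break, so output is
#' stable and diff-friendly.
#'
#' @param report A `bn_report` from [run_analysis()], or a
#'   `bn_classification`.
#' @param file Path of the TSV to write, or `NULL` to return lines.
#' @param sort_by Column to order rows by (default `"node"`).
#' @return The TSV lines, invisibly when `file` is given.
#' @export
write_score_table <- function(report, file = NULL, sort_by = "node") {
  table <- if (inherits(report, "bn_report")) {
    report$classification$table
  } else if (inherits(report, "bn_classification")) {
    report$table
  } else {
    bn_stop("expected a bn_report or bn_classification", "bn_usage_error")
  }
  if (!sort_by %in% names(table)) {
    bn_stop(sprintf("unknown sort column '%s'", sort_by), "bn_usage_error")
  }
  key <- table[[sort_by]]
  ord <- if (is.numeric(key) && !sort_by %in% c("rank_VB", "rank_DP",
                                               "rank_C", "degree")) {
    order(-key, table$node)
  } else {
    order(key, table$node)
  }
  table <- table[ord, , drop = FALSE]

  fmt <- function(x) {
    if (is.numeric(x) && !is.integer(x)) {
      vapply(x, function(v) format(signif(v, 6), scientific = FALSE), "")
    } else {
      as.character(x)
    }
  }
  body <- vapply(seq_len(nrow(table)), function(i) {
    paste(vapply(names(table), function(col) fmt(table[[col]])[i], ""),
          collapse = "\t")
  }, "")
  lines <- c(paste(names(table), collapse = "\t"), body)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Export the annotated interaction graph
#'
#' Emits DOT or GraphML with the visual conventions of the screening report:
#' gatekeepers red, hubs blue, gatekeeper-hubs purple, everything else grey;
#' gatekeeper opacity decreases linearly with recommendation rank (the top
#' target is fully opaque); node size grows linearly with total degree; all
#' edges directed.
#'
#' @param graph Interaction graph from [build_interaction_graph()].
#' @param result A `bn_classification` over the same node set.
#' @param format `"dot"` or `"graphml"`.
#' @return Character vector of output lines.
#' @export
export_graph <- function(graph, result, format = c("dot", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "bn_classification"))
  nodes <- igraph::V(graph)$name
  if (!setequal(nodes, result$table$node)) {
    bn_stop("graph and classification cover different node sets",
            "bn_domain_error")
  }
  table <- result$table[match(nodes, result$table$node), , drop = FALSE]
  degree <- igraph::degree(graph, mode = "all", loops = TRUE)

  is_gk <- table$class == "gatekeeper"
  color <- ifelse(is_gk & table$is_hub, "purple",
                  ifelse(is_gk, "red",
                         ifelse(table$is_hub, "blue", "grey")))
  # top recommendation opaque, linear falloff over the ranked list
  opacity <- rep(1, length(nodes))
  n_rec <- length(result$recommendations)
  if (n_rec > 0L) {
    rec_rank <- match(nodes, result$recommendations)
    opacity[!is.na(rec_rank)] <-
      1 - 0.75 * (rec_rank[!is.na(rec_rank)] - 1) / max(n_rec - 1L, 1L)
  }
  max_deg <- max(degree, 1L)
  size <- 0.3 + 0.7 * degree / max_deg

  edges <- igraph::as_edgelist(graph)
  if (format == "dot") {
    node_lines <- sprintf(
      "  \"%s\" [color=%s, fillcolor=%s, style=filled, opacity=%.3f, width=%.3f];",
      nodes, color, color, opacity, size)
    edge_lines <- if (nrow(edges) > 0L) {
      sprintf("  \"%s\" -> \"%s\";", edges[, 1L], edges[, 2L])
    } else {
      character(0)
    }
    return(c("digraph interaction_graph {", node_lines, edge_lines, "}"))
  }

  node_xml <- unlist(lapply(seq_along(nodes), function(i) {
    c(sprintf("    <node id=\"%s\">", xml_escape(nodes[[i]])),
      sprintf("      <data key=\"color\">%s</data>", color[[i]]),
      sprintf("      <data key=\"opacity\">%.3f</data>", opacity[[i]]),
      sprintf("      <data key=\"size\">%.3f</data>", size[[i]]),
      "    </node>")
  }))
  edge_xml <- if (nrow(edges) > 0L) {
    sprintf("    <edge source=\"%s\" target=\"%s\"/>",
            xml_escape(edges[, 1L]), xml_escape(edges[, 2L]))
  } else {
    character(0)
  }
  c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"color\" for=\"node\" attr.name=\"color\" attr.type=\"string\"/>",
    "  <key id=\"opacity\" for=\"node\" attr.name=\"opacity\" attr.type=\"double\"/>",
    "  <key id=\"size\" for=\"node\" attr.name=\"size\" attr.type=\"double\"/>",
    "  <graph id=\"interaction_graph\" edgedefault=\"directed\">",
    node_xml, edge_xml,
    "  </graph>", "</graphml>")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
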