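#' Read a Boolean network from BoolNet plain text
#'
#' Parses the simple rule format used by the BoolNet R package: an optional
#' block of `#` comment lines, a `targets, factors` header, then one
#' `<target>, <expression>` line per node. Expressions use `!`, `&`, `|`,
#' parentheses, and the constants `0`/`1`; identifiers are case-sensitive.
#' Probabilistic rules (a third comma-separated field or a
#' `targets, factors, probabilities` header) and temporal/ensemble operators
#' are rejected rather than silently ignored.
#'
#' @param x A file path, a single string containing the whole document, or a
#'   character vector of lines.
#' @return A [boolean_network][new_boolean_network] with one rule per target
#'   line; each rule's inputs are the distinct variables of its expression in
#'   first-occurrence order, and truth tables are compiled eagerly.
#' @examples
#' net <- parse_boolnet("targets, factors\nA, B\nB, A")
#' net$rules$B$table
#' @seealso [write_boolnet()], [parse_sbml_qual()]
#' @export
parse_boolnet <- function(x) {
  lines <- read_text_lines(x)
  line_no <- seq_along(lines)
  keep <- !grepl("^\\s*(#.*)?$", lines)
  lines <- lines[keep]
  line_no <- line_no[keep]
  if (length(lines) == 0L) {
    bn_stop("format error: empty document, expected 'targets, factors' header",
            "bn_format_error")
  }

  header <- trimws(lines[[1L]])
  if (grepl("^targets\\s*,\\s*factors\\s*,\\s*probabilities$", header,
            ignore.case = TRUE)) {
    bn_stop("unsupported format: probabilistic Boolean networks ('targets, factors, probabilities') are not supported",
            "bn_format_error")
  }
  if (!grepl("^targets\\s*,\\s*factors$", header, ignore.case = TRUE)) {
    bn_stop(sprintf("format error on line %d: expected header 'targets, factors', found '%s'",
                    line_no[[1L]], header),
            "bn_format_error")
  }

  nodes <- character(0)
  exprs <- list()
  for (i in seq_along(lines)[-1L]) {
    line <- lines[[i]]
    comma <- regexpr(",", line, fixed = TRUE)
    if (comma < 0L) {
      bn_stop(sprintf("format error on line %d: expected '<target>, <expression>'",
                      line_no[[i]]),
              "bn_format_error")
    }
    target <- trimws(substr(line, 1L, comma - 1L))
    body <- trimws(substr(line, comma + 1L, nchar(line)))
    if (grepl(",", body, fixed = TRUE)) {
      bn_stop(sprintf("unsupported format on line %d: extra comma-separated field (probabilistic rules are not supported)",
                      line_no[[i]]),
              "bn_format_error")
    }
    if (!grepl("^[A-Za-z_][A-Za-z0-9_.]*$", target)) {
      bn_stop(sprintf("format error on line %d: invalid target name '%s'",
                      line_no[[i]], target),
              "bn_format_error")
    }
    if (target %in% nodes) {
      bn_stop(sprintf("format error on line %d: duplicate target '%s'",
                      line_no[[i]], target),
              "bn_format_error")
    }
    nodes <- c(nodes, target)
    exprs <- c(exprs, list(parse_bool_expr(body, line = line_no[[i]])))
  }
  if (length(nodes) == 0L) {
    bn_stop("format error: no rule lines after header", "bn_format_error")
  }
  network_from_expressions(nodes, exprs)
}

#' Write a Boolean network in BoolNet plain text
#'
#' Emits the `targets, factors` header followed by one rule line per node.
#' Re-parsing the output reproduces the network's node names, input sets, and
#' truth tables exactly.
#'
#' @param net A `boolean_network`.
#' @param file Optional path; if given the text is written there.
#' @return The document as a character vector of lines, invisibly when `file`
#'   is given.
#' @export
write_boolnet <- function(net, file = NULL) {
  validate_boolean_network(net)
  lines <- c(
    "targets, factors",
    vapply(net$nodes, function(name) {
      sprintf("%s, %s", name, deparse_expr(net$rules[[name]]$expr))
    }, character(1), USE.NAMES = FALSE)
  )
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

read_text_lines <- function(x) {
  if (!is.character(x) || length(x) == 0L) {
    bn_stop("input must be a file path or character text", "bn_format_error")
  }
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}
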