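#' Read a Boolean network from SBML Level 3 qual
#'
#' Imports qualitative models in the SBML Level 3 `qual` extension, restricted
#' to Boolean (two-level) species: every qualitative species must have
#' `maxLevel <= 1`. Each transition's function terms may use the MathML
#' logical constructs `and`, `or`, `not`, the comparisons
#' `eq`/`neq`/`geq`/`leq`/`gt`/`lt` between a species and the constants 0/1,
#' and the literals `true`/`false`. The transition is compiled to a truth
#' table by evaluating the function terms in document order (first matching
#' term wins, the `defaultTerm` covering the rest) and a Boolean expression
#' is synthesized from the table. Species without a transition become
#' constant nodes fixed at their `initialLevel` (0 when unset). The SBML
#' species `id` attribute is the canonical node name.
#'
#' @param x Path to an SBML file, or a single string holding the XML document.
#' @return A [boolean_network][new_boolean_network], one node per qualitative
#'   species in document order.
#' @seealso [parse_boolnet()]
#' @export
parse_sbml_qual <- function(x) {
  doc <- tryCatch(
    if (is.character(x) && length(x) == 1L && !grepl("<", x, fixed = TRUE) &&
        file.exists(x)) {
      xml2::read_xml(x)
    } else {
      xml2::read_xml(paste(x, collapse = "\n"))
    },
    error = function(e) {
      bn_stop(sprintf("parse error: malformed XML (%s)",
                      conditionMessage(e)),
              "bn_parse_error")
    }
  )

  species_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name() = 'qualitativeSpecies']")
  if (length(species_nodes) == 0L) {
    bn_stop("format error: no qualitativeSpecies found (is the qual extension present?)",
            "bn_format_error")
  }

  species <- lapply(species_nodes, function(node) {
    id <- qual_attr(node, "id")
    if (is.na(id)) {
      bn_stop("format error: qualitativeSpecies without an id",
              "bn_format_error")
    }
    max_level <- qual_attr(node, "maxLevel")
    if (!is.na(max_level) && as.integer(max_level) > 1L) {
      bn_stop(
        sprintf("unsupported model: species '%s' has maxLevel %s; only Boolean (two-level) species are supported",
                id, max_level),
        "bn_unsupported_error"
      )
    }
    initial <- qual_attr(node, "initialLevel")
    list(id = id,
         initial = if (is.na(initial)) 0L else as.integer(initial))
  })
  ids <- vapply(species, `[[`, "", "id")
  initial_levels <- vapply(species, `[[`, 0L, "initial")
  names(initial_levels) <- ids

  transitions <- xml2::xml_find_all(doc, ".//*[local-name() = 'transition']")
  rules <- list()
  for (tr in transitions) {
    parsed <- parse_qual_transition(tr, ids)
    for (out in parsed$outputs) {
      if (!is.null(rules[[out]])) {
        bn_stop(sprintf("format error: multiple transitions target species '%s'", out),
                "bn_format_error")
      }
      rules[[out]] <- parsed$rule
    }
  }

  exprs <- lapply(ids, function(id) {
    if (is.null(rules[[id]])) bn_const(initial_levels[[id]]) else NULL
  })
  names(exprs) <- ids

  # Assemble directly so transition-derived rules keep their declared input
  # order; expressions are synthesized from the compiled tables.
  out_rules <- vector("list", length(ids))
  names(out_rules) <- ids
  for (id in ids) {
    if (is.null(rules[[id]])) {
      tab <- compile_truth_table(exprs[[id]], character(0))
      out_rules[[id]] <- list(inputs = character(0), expr = exprs[[id]],
                              table = tab)
    } else {
      rule <- rules[[id]]
      out_rules[[id]] <- list(
        inputs = rule$inputs,
        expr = expr_from_table(rule$table, rule$inputs),
        table = rule$table
      )
    }
  }
  new_boolean_network(ids, out_rules)
}

# One transition: inputs, outputs, and the compiled truth table.
parse_qual_transition <- function(tr, ids) {
  input_nodes <- xml2::xml_find_all(tr, ".//*[local-name() = 'input']")
  inputs <- unique(vapply(input_nodes, qual_attr, "", "qualitativeSpecies"))
  output_nodes <- xml2::xml_find_all(tr, ".//*[local-name() = 'output']")
  outputs <- vapply(output_nodes, qual_attr, "", "qualitativeSpecies")
  unknown <- setdiff(c(inputs, outputs), ids)
  if (length(unknown) > 0L) {
    bn_stop(sprintf("format error: transition references unknown species '%s'",
                    unknown[[1L]]),
            "bn_symbol_error")
  }

  default_nodes <- xml2::xml_find_all(tr, ".//*[local-name() = 'defaultTerm']")
  term_nodes <- xml2::xml_find_all(tr, ".//*[local-name() = 'functionTerm']")
  if (length(default_nodes) == 0L && length(term_nodes) == 0L) {
    bn_stop("format error: transition without function terms", "bn_format_error")
  }
  result_level <- function(node) {
    lv <- qual_attr(node, "resultLevel")
    lv <- if (is.na(lv)) 0L else as.integer(lv)
    if (lv > 1L) {
      bn_stop("unsupported model: resultLevel > 1 in a transition",
              "bn_unsupported_error")
    }
    lv
  }
  default_level <- if (length(default_nodes) > 0L) {
    result_level(default_nodes[[1L]])
  } else {
    0L
  }
  terms <- lapply(term_nodes, function(node) {
    math <- xml2::xml_find_first(node, ".//*[local-name() = 'math']")
    if (inherits(math, "xml_missing")) {
      bn_stop("format error: functionTerm without MathML", "bn_format_error")
    }
    children <- xml2::xml_children(math)
    if (length(children) != 1L) {
      bn_stop("format error: functionTerm math must hold one expression",
              "bn_format_error")
    }
    list(level = result_level(node),
         predicate = parse_mathml_predicate(children[[1L]]))
  })

  k <- length(inputs)
  table <- vapply(0:(2^k - 1), function(b) {
    values <- as.list(as.integer(bitwAnd(bitwShiftR(b, seq_len(k) - 1L), 1L)))
    names(values) <- inputs
    for (term in terms) {
      if (term$predicate(values)) return(term$level)
    }
    default_level
  }, integer(1))

  list(inputs = inputs, outputs = outputs,
       rule = list(inputs = inputs, table = table))
}

# MathML -> predicate closure over a named list of 0/1 species values.
parse_mathml_predicate <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "true") return(function(values) TRUE)
  if (name == "false") return(function(values) FALSE)
  if (name == "ci") {
    id <- trimws(xml2::xml_text(node))
    return(function(values) mathml_value(id, values) == 1L)
  }
  if (name != "apply") {
    bn_stop(sprintf("unsupported construct: MathML element '%s'", name),
            "bn_unsupported_error")
  }
  children <- xml2::xml_children(node)
  op <- xml2::xml_name(children[[1L]])
  args <- children[-1L]
  if (op %in% c("and", "or", "not", "xor")) {
    preds <- lapply(args, parse_mathml_predicate)
    return(switch(op,
      and = function(values) all(vapply(preds, function(p) p(values), TRUE)),
      or = function(values) any(vapply(preds, function(p) p(values), TRUE)),
      xor = function(values) {
        sum(vapply(preds, function(p) p(values), TRUE)) %% 2L == 1L
      },
      not = {
        if (length(preds) != 1L) {
          bn_stop("parse error: MathML 'not' takes one argument",
                  "bn_parse_error")
        }
        function(values) !preds[[1L]](values)
      }
    ))
  }
  if (op %in% c("eq", "neq", "geq", "leq", "gt", "lt")) {
    if (length(args) != 2L) {
      bn_stop(sprintf("parse error: MathML '%s' takes two arguments", op),
              "bn_parse_error")
    }
    operands <- lapply(args, parse_mathml_operand)
    cmp <- switch(op,
      eq = `==`, neq = `!=`, geq = `>=`, leq = `<=`, gt = `>`, lt = `<`)
    return(function(values) {
      cmp(operands[[1L]](values), operands[[2L]](values))
    })
  }
  bn_stop(
    sprintf("unsupported construct: arithmetic or unknown MathML operator '%s'", op),
    "bn_unsupported_error"
  )
}

parse_mathml_operand <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "ci") {
    id <- trimws(xml2::xml_text(node))
    return(function(values) mathml_value(id, values))
  }
  if (name == "cn") {
    value <- suppressWarnings(as.numeric(trimws(xml2::xml_text(node))))
    if (is.na(value) || !value %in% c(0, 1)) {
      bn_stop("unsupported construct: numeric constants other than 0/1",
              "bn_unsupported_error")
    }
    return(function(values) as.integer(value))
  }
  bn_stop(
    sprintf("unsupported construct: comparison operand '%s'", name),
    "bn_unsupported_error"
  )
}

mathml_value <- function(id, values) {
  v <- values[[id]]
  if (is.null(v)) {
    bn_stop(sprintf("unresolved symbol '%s' in transition math (not a declared input)", id),
            "bn_symbol_error")
  }
  v
}

# Attribute lookup tolerant of the qual namespace prefix.
qual_attr <- function(node, name) {
  attrs <- xml2::xml_attrs(node)
  hits <- which(names(attrs) == name | endsWith(names(attrs), paste0(":", name)))
  if (length(hits) == 0L) NA_character_ else unname(attrs[[hits[[1L]]]])
}
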