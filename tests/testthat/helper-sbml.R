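# Build minimal SBML Level 3 qual documents in code (synthetic fixtures).
# `species` is a data.frame-like list of lists with id, maxLevel,
# initialLevel (NA to omit); `transitions` a list of lists with inputs,
# output, default_level, and terms (list of list(level, math)) where math is
# a MathML fragment string.
make_sbml_qual <- function(species, transitions = list()) {
  sp_xml <- vapply(species, function(s) {
    attrs <- sprintf('qual:id="%s" qual:constant="false"', s$id)
    if (!is.null(s$maxLevel) && !is.na(s$maxLevel)) {
      attrs <- paste(attrs, sprintf('qual:maxLevel="%d"', s$maxLevel))
    }
    if (!is.null(s$initialLevel) && !is.na(s$initialLevel)) {
      attrs <- paste(attrs, sprintf('qual:initialLevel="%d"', s$initialLevel))
    }
    sprintf("      <qual:qualitativeSpecies %s/>", attrs)
  }, "")

  tr_xml <- unlist(lapply(seq_along(transitions), function(i) {
    tr <- transitions[[i]]
    inputs <- vapply(tr$inputs, function(id) {
      sprintf('        <qual:input qual:qualitativeSpecies="%s" qual:transitionEffect="none"/>', id)
    }, "")
    terms <- unlist(lapply(tr$terms, function(term) {
      c(sprintf('          <qual:functionTerm qual:resultLevel="%d">', term$level),
        '            <math xmlns="http://www.w3.org/1998/Math/MathML">',
        paste0("              ", term$math),
        "            </math>",
        "          </qual:functionTerm>")
    }))
    c(sprintf('      <qual:transition qual:id="tr_%d">', i),
      "        <qual:listOfInputs>", inputs, "        </qual:listOfInputs>",
      "        <qual:listOfOutputs>",
      sprintf('        <qual:output qual:qualitativeSpecies="%s" qual:transitionEffect="assignmentLevel"/>', tr$output),
      "        </qual:listOfOutputs>",
      "        <qual:listOfFunctionTerms>",
      sprintf('          <qual:defaultTerm qual:resultLevel="%d"/>',
              if (is.null(tr$default_level)) 0L else tr$default_level),
      terms,
      "        </qual:listOfFunctionTerms>",
      "      </qual:transition>")
  }))

  paste(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    '      xmlns:qual="http://www.sbml.org/sbml/level3/version1/qual/version1"',
    '      level="3" version="1" qual:required="true">',
    '  <model id="test_model">',
    "    <qual:listOfQualitativeSpecies>",
    sp_xml,
    "    </qual:listOfQualitativeSpecies>",
    "    <qual:listOfTransitions>",
    tr_xml,
    "    </qual:listOfTransitions>",
    "  </model>",
    "</sbml>"
  ), collapse = "\n")
}

qs <- function(id, maxLevel = 1L, initialLevel = NA) {
  list(id = id, maxLevel = maxLevel, initialLevel = initialLevel)
}
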