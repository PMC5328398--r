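# SBML Level 3 (subset) export / import of kinetic models.
#
# The subset covers everything this package's models use: compartments,
# species with boundary conditions, global parameters, reactions with
# stoichiometry, modifiers and MathML kinetic laws built from the
# arithmetic operators and the natural logarithm.  Constructs outside the
# subset (rules, events, function definitions, ...) are rejected with a
# named error, never silently ignored.  Parameter ids are the package's
# "REACTION.name" names with the dot encoded as a double underscore
# (SBML ids cannot contain dots).

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

sbml_par_id <- function(nm) gsub(".", "__", nm, fixed = TRUE)
sbml_par_name <- function(id) sub("__", ".", id, fixed = TRUE)

# ---- MathML ------------------------------------------------------------------

mathml_from_expr <- function(node, e) {
  if (is.numeric(e)) {
    xml2::xml_add_child(node, "cn", format(e, digits = 17))
  } else if (is.symbol(e)) {
    xml2::xml_add_child(node, "ci", sbml_par_id(as.character(e)))
  } else if (is.call(e)) {
    fn <- as.character(e[[1]])
    if (fn == "(") return(mathml_from_expr(node, e[[2]]))
    ap <- xml2::xml_add_child(node, "apply")
    if (fn == "-" && length(e) == 2L) {
      xml2::xml_add_child(ap, "minus")
      mathml_from_expr(ap, e[[2]])
    } else if (fn == "log" && length(e) == 2L) {
      xml2::xml_add_child(ap, "ln")
      mathml_from_expr(ap, e[[2]])
    } else if (fn %in% c("+", "-", "*", "/", "^") && length(e) == 3L) {
      op <- c("+" = "plus", "-" = "minus", "*" = "times", "/" = "divide",
              "^" = "power")[[fn]]
      xml2::xml_add_child(ap, op)
      mathml_from_expr(ap, e[[2]])
      mathml_from_expr(ap, e[[3]])
    } else {
      stop("cannot export function '", fn, "' to MathML", call. = FALSE)
    }
  } else {
    stop("cannot export expression component of class ", class(e)[1],
         call. = FALSE)
  }
  invisible(node)
}

expr_from_mathml <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "cn") return(as.numeric(xml2::xml_text(node)))
  if (nm == "ci") return(as.symbol(sbml_par_name(trimws(xml2::xml_text(node)))))
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], expr_from_mathml)
    f <- switch(op, plus = "+", minus = "-", times = "*", divide = "/",
                power = "^", ln = "log",
                stop("unsupported MathML operator: ", op, call. = FALSE))
    if (op == "ln") return(as.call(c(as.symbol("log"), args)))
    if (length(args) == 1L && op == "minus") {
      return(as.call(list(as.symbol("-"), args[[1]])))
    }
    # fold n-ary plus/times left-associatively
    out <- args[[1]]
    for (k in seq_along(args)[-1]) {
      out <- as.call(list(as.symbol(f), out, args[[k]]))
    }
    return(out)
  }
  if (nm == "math") return(expr_from_mathml(xml2::xml_child(node)))
  stop("unsupported MathML node: ", nm, call. = FALSE)
}

# ---- writer ------------------------------------------------------------------

#' Write a kinetic model as SBML Level 3
#'
#' @param model a `kinetic_model`
#' @param path output file
#' @return invisibly, the path
#' @export
write_sbml_model <- function(model, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, level = "3", version = "1")
  md <- xml2::xml_add_child(doc, "model", id = model$id)

  lc <- xml2::xml_add_child(md, "listOfCompartments")
  for (i in seq_len(nrow(model$compartments))) {
    xml2::xml_add_child(lc, "compartment",
                        id = model$compartments$id[i],
                        size = format(model$compartments$volume[i], digits = 17),
                        spatialDimensions = "3", constant = "true")
  }
  ls <- xml2::xml_add_child(md, "listOfSpecies")
  for (i in seq_len(nrow(model$species))) {
    xml2::xml_add_child(ls, "species",
                        id = model$species$id[i],
                        compartment = model$species$compartment[i],
                        initialConcentration = format(model$species$conc[i], digits = 17),
                        boundaryCondition = tolower(model$species$boundary[i]),
                        hasOnlySubstanceUnits = "false", constant = "false")
  }
  lp <- xml2::xml_add_child(md, "listOfParameters")
  for (nm in names(model$params)) {
    xml2::xml_add_child(lp, "parameter", id = sbml_par_id(nm),
                        value = format(model$params[[nm]], digits = 17),
                        constant = "true")
  }
  lr <- xml2::xml_add_child(md, "listOfReactions")
  rev_forms <- c("mass_action_reversible", "reversible_michaelis_menten",
                 "ndhi", "ndh2", "sqr", "cytbo", "atp_syn")
  for (r in model$reactions) {
    rx <- xml2::xml_add_child(lr, "reaction", id = r$id,
                              reversible = tolower(r$form %in% rev_forms),
                              fast = "false")
    nt <- xml2::xml_add_child(rx, "notes")
    bd <- xml2::xml_add_child(nt, "body", xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(bd, "p", paste0("form: ", r$form))
    subs <- r$stoich[r$stoich < 0]
    prods <- r$stoich[r$stoich > 0]
    if (length(subs)) {
      lrt <- xml2::xml_add_child(rx, "listOfReactants")
      for (sname in names(subs)) {
        xml2::xml_add_child(lrt, "speciesReference", species = sname,
                            stoichiometry = format(abs(subs[[sname]]), digits = 17),
                            constant = "true")
      }
    }
    if (length(prods)) {
      lpd <- xml2::xml_add_child(rx, "listOfProducts")
      for (sname in names(prods)) {
        xml2::xml_add_child(lpd, "speciesReference", species = sname,
                            stoichiometry = format(prods[[sname]], digits = 17),
                            constant = "true")
      }
    }
    if (length(r$modifiers)) {
      lm <- xml2::xml_add_child(rx, "listOfModifiers")
      for (sname in r$modifiers) {
        xml2::xml_add_child(lm, "modifierSpeciesReference", species = sname)
      }
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    mt <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
    mathml_from_expr(mt, r$expr)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# ---- reader ------------------------------------------------------------------

#' Read a kinetic model from SBML Level 3 (subset)
#'
#' Maps compartments, species (with boundary conditions), global parameters
#' and reactions with MathML kinetic laws onto the package's model
#' container.  A reaction without a kinetic law, or any construct outside
#' the supported subset (function definitions, rules, events, local
#' parameters, ...), raises an error naming the offending element.
#'
#' @param path SBML file
#' @return a `kinetic_model`
#' @export
read_sbml_model <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  unsupported <- c("listOfFunctionDefinitions", "listOfRules", "listOfEvents",
                   "listOfConstraints", "listOfInitialAssignments",
                   "listOfUnitDefinitions")
  for (u in unsupported) {
    if (length(xml2::xml_find_all(doc, paste0("//", u)))) {
      stop("unsupported SBML construct: ", u, call. = FALSE)
    }
  }
  md <- xml2::xml_find_first(doc, "//model")
  if (inherits(md, "xml_missing")) stop("no <model> element", call. = FALSE)
  mid <- xml2::xml_attr(md, "id")

  cmp <- xml2::xml_find_all(doc, "//listOfCompartments/compartment")
  compartments <- data.frame(
    id = xml2::xml_attr(cmp, "id"),
    volume = as.numeric(xml2::xml_attr(cmp, "size")),
    kind = xml2::xml_attr(cmp, "id"))
  sp <- xml2::xml_find_all(doc, "//listOfSpecies/species")
  species <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    compartment = xml2::xml_attr(sp, "compartment"),
    conc = as.numeric(xml2::xml_attr(sp, "initialConcentration")),
    boundary = xml2::xml_attr(sp, "boundaryCondition") == "true")
  pr <- xml2::xml_find_all(doc, "//listOfParameters/parameter")
  params <- setNames(as.numeric(xml2::xml_attr(pr, "value")),
                     sbml_par_name(xml2::xml_attr(pr, "id")))

  reactions <- list()
  for (rx in xml2::xml_find_all(doc, "//listOfReactions/reaction")) {
    rid <- xml2::xml_attr(rx, "id")
    if (length(xml2::xml_find_all(rx, ".//localParameter"))) {
      stop("unsupported SBML construct in reaction ", rid, ": localParameter",
           call. = FALSE)
    }
    get_refs <- function(xp, sign) {
      refs <- xml2::xml_find_all(rx, xp)
      if (!length(refs)) return(numeric(0))
      setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
               xml2::xml_attr(refs, "species"))
    }
    stoich_sub <- get_refs("./listOfReactants/speciesReference", -1)
    stoich_prod <- get_refs("./listOfProducts/speciesReference", 1)
    stoich <- c(stoich_sub, stoich_prod)
    mods <- xml2::xml_attr(
      xml2::xml_find_all(rx, "./listOfModifiers/modifierSpeciesReference"),
      "species")
    math <- xml2::xml_find_first(rx, "./kineticLaw/math")
    if (inherits(math, "xml_missing")) {
      stop("reaction ", rid, " has no kinetic law", call. = FALSE)
    }
    expr <- expr_from_mathml(math)
    note <- xml2::xml_text(xml2::xml_find_first(rx, "./notes//p"))
    form <- if (!is.na(note) && startsWith(note, "form: "))
      sub("^form: ", "", note) else "legacy"
    par_syms <- setdiff(all.vars(expr), species$id)
    bad <- par_syms[!startsWith(par_syms, paste0(rid, "."))]
    if (length(bad)) {
      stop("reaction ", rid, " kinetic law uses symbols that are neither ",
           "species nor own parameters: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    law <- list(form = form, params = sub("^[^.]+\\.", "", par_syms),
                expr = expr)
    reactions[[length(reactions) + 1L]] <- new_reaction(rid, stoich, law, mods)
  }
  compile_model(kinetic_model(mid, compartments, species, reactions, params))
}
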