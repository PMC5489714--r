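# Minimal SBML Level 3 reader (core + fbc package: flux bounds and gene
# product associations), sufficient for BiGG-style genome-scale models. No
# SBML package exists in the R dependency stack, so the relevant subset is
# parsed directly with xml2; namespace prefixes are bypassed with
# local-name() XPath.

#' @keywords internal
.xp <- function(node, path) xml2::xml_find_all(node, path)

# attribute lookup tolerant of namespace prefixes ("fbc:chemicalFormula")
#' @keywords internal
.attr_any <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | endsWith(names(at), paste0(":", name)))
  if (length(hit)) at[[hit[1]]] else NA_character_
}

#' Read a metabolic model from SBML
#'
#' Supports SBML Level 3 with the fbc package: species (with boundary flag
#' and chemical formula), reactions with stoichiometry, flux bounds given as
#' parameter references, and gene product associations (reconstructed as
#' and/or text over gene labels). Boundary species are dropped from the
#' stoichiometric matrix. Reactions with missing bounds default to
#' (-Inf, Inf) when reversible and (0, Inf) otherwise, with a warning.
#'
#' @param path SBML file
#' @return a `metabolic_network`
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error in '", path,
                                           "': ", conditionMessage(e)))
  model <- .xp(doc, ".//*[local-name()='model']")
  if (length(model) == 0L) stop("SBML parse error: no <model> element")
  model <- model[[1]]

  params <- .xp(model, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  gps <- .xp(model, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  glabel <- stats::setNames(
    vapply(gps, function(g) {
      lb <- .attr_any(g, "label")
      if (is.na(lb)) .attr_any(g, "id") else lb
    }, ""),
    vapply(gps, function(g) .attr_any(g, "id"), ""))

  sp <- .xp(model, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  sp_id <- xml2::xml_attr(sp, "id")
  if (anyNA(sp_id)) stop("SBML parse error: <species> without id")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  mets <- data.frame(
    id = sp_id,
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = vapply(sp, .attr_any, "", "chemicalFormula"),
    stringsAsFactors = FALSE)
  internal <- mets[!boundary, , drop = FALSE]
  rownames(internal) <- NULL

  gpr_text <- function(node) {
    name <- xml2::xml_name(node)
    if (name == "geneProductRef") {
      ref <- .attr_any(node, "geneProduct")
      lab <- glabel[ref]
      return(if (is.na(lab)) ref else unname(lab))
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpr_text, "")
    op <- if (name == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rx <- .xp(model, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  n <- length(rx)
  if (n == 0L)
    return(metabolic_network(internal,
                             data.frame(id = character(), lb = numeric(),
                                        ub = numeric(), reversible = logical(),
                                        repressible = logical(),
                                        gpr = character(),
                                        is_exchange = logical(),
                                        stringsAsFactors = FALSE),
                             matrix(0, nrow(internal), 0)))
  ids <- xml2::xml_attr(rx, "id")
  if (anyNA(ids)) stop("SBML parse error: <reaction> without id")
  reversible <- xml2::xml_attr(rx, "reversible") %in% "true"
  lb <- ub <- rep(NA_real_, n)
  gpr <- rep(NA_character_, n)
  ii <- integer(); jj <- integer(); xx <- numeric()
  met_pos <- stats::setNames(seq_len(nrow(internal)), internal$id)
  is_boundary <- stats::setNames(boundary, sp_id)
  touches_boundary <- rep(FALSE, n)
  missing_bounds <- character()

  for (k in seq_len(n)) {
    node <- rx[[k]]
    lref <- .attr_any(node, "lowerFluxBound")
    uref <- .attr_any(node, "upperFluxBound")
    lb[k] <- if (!is.na(lref) && lref %in% names(pval)) pval[[lref]] else NA
    ub[k] <- if (!is.na(uref) && uref %in% names(pval)) pval[[uref]] else NA
    if (is.na(lb[k]) || is.na(ub[k])) {
      missing_bounds <- c(missing_bounds, ids[k])
      if (is.na(lb[k])) lb[k] <- if (reversible[k]) -Inf else 0
      if (is.na(ub[k])) ub[k] <- Inf
    }
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- .xp(node, paste0("./*[local-name()='", tag,
                               "']/*[local-name()='speciesReference']"))
      for (r in refs) {
        s <- xml2::xml_attr(r, "species")
        if (is.na(s) || !(s %in% sp_id))
          stop("SBML parse error: reaction ", ids[k],
               " references unknown species '", s, "'")
        st <- xml2::xml_attr(r, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        if (isTRUE(is_boundary[[s]])) {
          touches_boundary[k] <- TRUE
          next
        }
        ii <- c(ii, met_pos[[s]]); jj <- c(jj, k); xx <- c(xx, side * st)
      }
    }
    ga <- .xp(node, ".//*[local-name()='geneProductAssociation']")
    if (length(ga)) {
      kids <- xml2::xml_children(ga[[1]])
      if (length(kids)) {
        txt <- gpr_text(kids[[1]])
        gpr[k] <- sub("^\\((.*)\\)$", "\\1", txt)
      }
    }
  }
  if (length(missing_bounds))
    warning("missing flux bounds for reaction(s) ",
            paste(missing_bounds, collapse = ", "),
            "; defaulted to (-Inf, Inf) / (0, Inf)")

  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(internal), n))
  # exchange: touches a boundary species, or a single internal participant
  n_internal <- tabulate(jj, nbins = n)
  rxns <- data.frame(id = ids, lb = lb, ub = ub,
                     reversible = reversible | lb < 0,
                     repressible = TRUE,
                     gpr = gpr,
                     is_exchange = touches_boundary | n_internal == 1L |
                       grepl("^(R_)?EX_", ids),
                     stringsAsFactors = FALSE)
  metabolic_network(internal, rxns, S)
}
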