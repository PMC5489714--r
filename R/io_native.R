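# Native text formats: a JSON dialect for networks (round-trip identity on
# all fields, infinities encoded as the strings "inf"/"-inf") and YAML/JSON
# configuration files.

#' Write a network in the native JSON dialect
#'
#' One JSON document with `metabolites` (id, name, compartment, formula) and
#' `reactions` (id, stoich map, lb, ub, reversible, repressible, gpr,
#' is_exchange). Infinite bounds are written as `"inf"` / `"-inf"`.
#'
#' @param net a `metabolic_network`
#' @param path output file
#' @return invisibly `path`
#' @export
write_native <- function(net, path) {
  enc_bound <- function(v) {
    if (v == Inf) "inf" else if (v == -Inf) "-inf" else v
  }
  rxns <- lapply(seq_len(n_rxns(net)), function(j) {
    nz <- which(net$S[, j] != 0)
    list(id = net$rxns$id[j],
         stoich = as.list(stats::setNames(as.numeric(net$S[nz, j]),
                                          net$mets$id[nz])),
         lb = enc_bound(net$rxns$lb[j]),
         ub = enc_bound(net$rxns$ub[j]),
         reversible = net$rxns$reversible[j],
         repressible = net$rxns$repressible[j],
         gpr = if (is.na(net$rxns$gpr[j])) NULL else net$rxns$gpr[j],
         is_exchange = net$rxns$is_exchange[j])
  })
  mets <- lapply(seq_len(n_mets(net)), function(i) {
    m <- net$mets[i, ]
    list(id = m$id,
         name = if (is.na(m$name)) NULL else m$name,
         compartment = if (is.na(m$compartment)) NULL else m$compartment,
         formula = if (is.na(m$formula)) NULL else m$formula)
  })
  jsonlite::write_json(list(metabolites = mets, reactions = rxns), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a network from the native JSON dialect
#'
#' @param path input file written by [write_native()] (or by hand)
#' @return a `metabolic_network`
#' @export
read_native <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  dec_bound <- function(v, default) {
    if (is.null(v)) return(default)
    if (identical(v, "inf")) Inf else if (identical(v, "-inf")) -Inf
    else as.numeric(v)
  }
  field <- function(x, name, default = NA_character_)
    if (is.null(x[[name]])) default else x[[name]]
  met_ids <- vapply(doc$metabolites, `[[`, "", "id")
  if (anyDuplicated(met_ids))
    stop("duplicate metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  mets <- data.frame(
    id = met_ids,
    name = vapply(doc$metabolites, field, "", "name"),
    compartment = vapply(doc$metabolites, field, "", "compartment"),
    formula = vapply(doc$metabolites, field, "", "formula"),
    stringsAsFactors = FALSE)
  rxn_ids <- vapply(doc$reactions, `[[`, "", "id")
  if (anyDuplicated(rxn_ids))
    stop("duplicate reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  reversible <- vapply(doc$reactions, function(r)
    isTRUE(r$reversible), TRUE)
  rxns <- data.frame(
    id = rxn_ids,
    lb = vapply(seq_along(doc$reactions), function(k)
      dec_bound(doc$reactions[[k]]$lb, if (reversible[k]) -Inf else 0), 0),
    ub = vapply(doc$reactions, function(r) dec_bound(r$ub, Inf), 0),
    reversible = reversible,
    repressible = vapply(doc$reactions, function(r)
      isTRUE(r$repressible), TRUE),
    gpr = vapply(doc$reactions, field, "", "gpr"),
    is_exchange = vapply(doc$reactions, function(r)
      isTRUE(r$is_exchange), TRUE),
    stringsAsFactors = FALSE)
  i <- integer(); j <- integer(); x <- numeric()
  for (k in seq_along(doc$reactions)) {
    st <- doc$reactions[[k]]$stoich
    if (!length(st)) next
    idx <- match(names(st), met_ids)
    if (anyNA(idx))
      stop("reaction ", rxn_ids[k], " references unknown metabolite(s): ",
           paste(names(st)[is.na(idx)], collapse = ", "))
    i <- c(i, idx); j <- c(j, rep(k, length(st)))
    x <- c(x, as.numeric(unlist(st)))
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(met_ids), length(rxn_ids)))
  metabolic_network(mets, rxns, S)
}

#' Read a model configuration from YAML or JSON
#'
#' The file holds the [model_config()] fields by name; infinities may be
#' written as `"inf"`. YAML needs the `yaml` package.
#'
#' @param path `.yaml`/`.yml` or `.json` file
#' @return a `model_config`
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configuration requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  num_fields <- c("substrate_uptake_limit", "maintenance_lb",
                  "min_biomass_yield", "flux_cap", "milp_time_limit_s",
                  "milp_gap")
  for (f in num_fields)
    if (!is.null(raw[[f]]) && is.character(raw[[f]]))
      raw[[f]] <- .dec_num(raw[[f]])
  known <- names(formals(model_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  do.call(model_config, raw)
}
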