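# Core container: a metabolic network at steady state, N r = 0 with bounds.
# Metabolites and reactions are plain data frames; stoichiometry is a sparse
# m x n Matrix whose rows are internal metabolites only (boundary species are
# dropped on input and never enter mass balance).

#' Construct a metabolic network
#'
#' The canonical internal representation used by all other functions:
#' `m` internal metabolites, `n` reactions, sparse stoichiometric matrix `S`
#' (rows named by metabolite id, columns by reaction id), and per-reaction
#' bounds, reversibility, repressibility and gene-association text.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `formula` (chemical formula string or `NA`).
#' @param reactions data.frame with columns `id`, `lb`, `ub`, `reversible`,
#'   `repressible`, `gpr` (gene association text or `NA`), `is_exchange`.
#' @param stoich sparse or dense m x n matrix; rows must match
#'   `metabolites$id`, columns `reactions$id`.
#' @return object of class `metabolic_network`
#' @export
metabolic_network <- function(metabolites, reactions, stoich) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  for (col in c("name", "compartment", "formula"))
    if (is.null(metabolites[[col]])) metabolites[[col]] <- NA_character_
  if (is.null(reactions$gpr)) reactions$gpr <- NA_character_
  if (is.null(reactions$repressible)) reactions$repressible <- FALSE
  if (is.null(reactions$is_exchange)) reactions$is_exchange <- FALSE
  S <- methods::as(methods::as(Matrix::Matrix(stoich, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  dimnames(S) <- list(metabolites$id, reactions$id)
  net <- structure(list(mets = metabolites, rxns = reactions, S = S),
                   class = "metabolic_network")
  validate_network(net)
  net
}

#' @keywords internal
validate_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  if (anyDuplicated(net$mets$id))
    stop("duplicate metabolite ids: ",
         paste(unique(net$mets$id[duplicated(net$mets$id)]), collapse = ", "))
  if (anyDuplicated(net$rxns$id))
    stop("duplicate reaction ids: ",
         paste(unique(net$rxns$id[duplicated(net$rxns$id)]), collapse = ", "))
  if (nrow(net$mets) != nrow(net$S) || nrow(net$rxns) != ncol(net$S))
    stop("stoichiometric matrix dimensions do not match metabolite/reaction tables")
  bad <- which(net$rxns$lb > net$rxns$ub)
  if (length(bad))
    stop("lb > ub for reactions: ", paste(net$rxns$id[bad], collapse = ", "))
  bad <- which(!net$rxns$reversible & net$rxns$lb < 0)
  if (length(bad))
    stop("irreversible reactions with negative lower bound: ",
         paste(net$rxns$id[bad], collapse = ", "))
  invisible(net)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("metabolic_network:", nrow(x$mets), "internal metabolites,",
      nrow(x$rxns), "reactions",
      sprintf("(%d reversible, %d repressible, %d exchanges)\n",
              sum(x$rxns$reversible), sum(x$rxns$repressible),
              sum(x$rxns$is_exchange)))
  invisible(x)
}

#' Number of internal metabolites / reactions
#' @param net a `metabolic_network`
#' @return integer count
#' @export
n_mets <- function(net) nrow(net$mets)

#' @rdname n_mets
#' @export
n_rxns <- function(net) nrow(net$rxns)

#' @keywords internal
rxn_index <- function(net, ids) {
  idx <- match(ids, net$rxns$id)
  if (anyNA(idx))
    stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  idx
}

#' @keywords internal
met_index <- function(net, ids) {
  idx <- match(ids, net$mets$id)
  if (anyNA(idx))
    stop("unknown metabolite id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  idx
}

#' Set flux bounds of one reaction
#' @param net a `metabolic_network`
#' @param id reaction id
#' @param lb,ub new bounds (either may be `NULL` to keep the current value)
#' @return modified network
#' @export
set_bounds <- function(net, id, lb = NULL, ub = NULL) {
  i <- rxn_index(net, id)
  if (!is.null(lb)) net$rxns$lb[i] <- lb
  if (!is.null(ub)) net$rxns$ub[i] <- ub
  if (net$rxns$lb[i] > net$rxns$ub[i])
    stop("lb > ub for reaction ", id)
  net
}

#' Add a reaction to a network
#' @param net a `metabolic_network`
#' @param id new reaction id
#' @param stoich named numeric vector, names are metabolite ids
#' @param lb,ub flux bounds
#' @param reversible logical; defaults to `lb < 0`
#' @param repressible may the reaction be knocked out
#' @param gpr gene association text or `NA`
#' @param is_exchange logical
#' @return modified network
#' @export
add_reaction <- function(net, id, stoich, lb = 0, ub = Inf,
                         reversible = lb < 0, repressible = FALSE,
                         gpr = NA_character_, is_exchange = FALSE) {
  if (id %in% net$rxns$id) stop("reaction id already present: ", id)
  col <- Matrix::sparseMatrix(i = met_index(net, names(stoich)),
                              j = rep(1L, length(stoich)),
                              x = as.numeric(stoich),
                              dims = c(n_mets(net), 1L))
  net$S <- methods::cbind2(net$S, col)
  net$rxns <- rbind(net$rxns,
                    data.frame(id = id, lb = lb, ub = ub,
                               reversible = reversible,
                               repressible = repressible, gpr = gpr,
                               is_exchange = is_exchange,
                               stringsAsFactors = FALSE))
  colnames(net$S) <- net$rxns$id
  validate_network(net)
  net
}

#' Remove reactions from a network
#' @param net a `metabolic_network`
#' @param ids reaction ids to drop
#' @return modified network
#' @export
drop_reactions <- function(net, ids) {
  idx <- rxn_index(net, ids)
  net$S <- net$S[, -idx, drop = FALSE]
  net$rxns <- net$rxns[-idx, , drop = FALSE]
  rownames(net$rxns) <- NULL
  net
}

# Compartment-stripped compound key ("glc__D_c" -> "glc__D"), used to decide
# whether two metabolites in different compartments are the same compound.
#' @keywords internal
compound_key <- function(net) {
  ids <- net$mets$id
  comp <- net$mets$compartment
  out <- ids
  has <- !is.na(comp) & nzchar(comp) &
    endsWith(ids, paste0("_", ifelse(is.na(comp), "", comp)))
  out[has] <- substr(ids[has], 1L, nchar(ids[has]) - nchar(comp[has]) - 1L)
  out
}

# Carbon count parsed from a chemical formula string; NA when no formula.
#' @keywords internal
carbon_count <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_real_)
    m <- regmatches(f, regexpr("C(?![a-z])[0-9]*", f, perl = TRUE))
    if (!length(m)) return(0)
    num <- sub("^C", "", m)
    if (!nzchar(num)) 1 else as.numeric(num)
  }, numeric(1), USE.NAMES = FALSE)
}

# The metabolite an exchange reaction exchanges: the single internal species
# in its column (sign gives direction).
#' @keywords internal
exchange_metabolite <- function(net, rxn_id) {
  j <- rxn_index(net, rxn_id)
  col <- net$S[, j]
  nz <- which(col != 0)
  if (length(nz) != 1L) return(NA_character_)
  net$mets$id[nz]
}
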