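# Linear-programming primitives over a constrained steady-state flux region
# {r : N r = 0, lb <= r <= ub, extra rows hold, r_i = 0 for knockouts}.

ZERO_TOL <- 1e-6

#' A set of extra linear constraints on fluxes
#'
#' Each row is a sparse linear form over reaction ids with a sense and a
#' finite right-hand side. Used for the undesired region (T r <= t), the
#' desired region (D r <= d) and ad-hoc restrictions such as minimum biomass
#' yield during flux variability analysis.
#'
#' @param rows list of rows, each `list(coef = c(rxn_id = value, ...),
#'   sense = "<="|"="|">=", rhs = number)`
#' @return object of class `constraint_set`
#' @export
constraint_set <- function(rows = list()) {
  for (r in rows) {
    stopifnot(is.numeric(r$coef), !is.null(names(r$coef)),
              r$sense %in% c("<=", "=", ">="), is.finite(r$rhs))
  }
  structure(list(rows = rows), class = "constraint_set")
}

#' @keywords internal
n_constraints <- function(cs) if (is.null(cs)) 0L else length(cs$rows)

#' A flux region: network plus extra constraints plus knockouts
#'
#' @param net a `metabolic_network`
#' @param extra a `constraint_set` or `NULL`
#' @param knockouts character vector of reaction ids forced to zero flux
#' @return object of class `flux_region`
#' @export
flux_region <- function(net, extra = NULL, knockouts = character()) {
  rxn_index(net, knockouts)  # id check
  structure(list(net = net, extra = extra, knockouts = knockouts),
            class = "flux_region")
}

# Assemble the LP blocks (1-based triplets) of a region. Equalities: N r = 0
# plus "=" extra rows; inequalities: "<="/" >=" extra rows as <=.
#' @keywords internal
region_lp_parts <- function(region) {
  net <- region$net
  n <- n_rxns(net)
  Ts <- Matrix::mat2triplet(net$S)
  eq <- list(i = Ts$i, j = Ts$j, x = Ts$x, nrow = n_mets(net),
             rhs = rep(0, n_mets(net)))
  le <- list(i = integer(), j = integer(), x = numeric(), nrow = 0L,
             rhs = numeric())
  if (!is.null(region$extra)) {
    for (row in region$extra$rows) {
      j <- rxn_index(net, names(row$coef))
      if (row$sense == "=") {
        eq$i <- c(eq$i, rep(eq$nrow + 1L, length(j)))
        eq$j <- c(eq$j, j)
        eq$x <- c(eq$x, row$coef)
        eq$nrow <- eq$nrow + 1L
        eq$rhs <- c(eq$rhs, row$rhs)
      } else {
        sgn <- if (row$sense == "<=") 1 else -1
        le$i <- c(le$i, rep(le$nrow + 1L, length(j)))
        le$j <- c(le$j, j)
        le$x <- c(le$x, sgn * row$coef)
        le$nrow <- le$nrow + 1L
        le$rhs <- c(le$rhs, sgn * row$rhs)
      }
    }
  }
  lb <- net$rxns$lb
  ub <- net$rxns$ub
  if (length(region$knockouts)) {
    k <- rxn_index(net, region$knockouts)
    lb[k] <- 0
    ub[k] <- 0
  }
  list(n = n, lb = lb, ub = ub, eq = eq,
       le = if (le$nrow) le else NULL)
}

#' Feasibility of a flux region
#'
#' Solves one LP: is the region non-empty? When feasible, a witness flux
#' vector satisfying all constraints (to solver tolerance) is returned.
#'
#' @param region a `flux_region`
#' @return list with `feasible` (logical) and `witness` (named flux vector or
#'   `NULL`)
#' @export
check_region_feasible <- function(region) {
  p <- region_lp_parts(region)
  res <- solver_lp(p$n, obj = NULL, lb = p$lb, ub = p$ub, eq = p$eq,
                   le = p$le, want_x = TRUE)
  if (identical(res$status, "infeasible"))
    return(list(feasible = FALSE, witness = NULL))
  w <- as.numeric(res$x)
  names(w) <- region$net$rxns$id
  list(feasible = TRUE, witness = w)
}

#' Maximize a linear flux objective over a region
#'
#' @param region a `flux_region`
#' @param objective named numeric vector of objective coefficients over
#'   reaction ids (maximized)
#' @return list with `status` (`"optimal"`, `"unbounded"` or `"infeasible"`),
#'   `value` and `solution` (named flux vector, `"optimal"` only)
#' @export
maximize <- function(region, objective) {
  p <- region_lp_parts(region)
  obj <- rep(0, p$n)
  obj[rxn_index(region$net, names(objective))] <- -as.numeric(objective)
  res <- solver_lp(p$n, obj = obj, lb = p$lb, ub = p$ub, eq = p$eq,
                   le = p$le, want_x = TRUE)
  if (identical(res$status, "infeasible"))
    return(list(status = "infeasible", value = NA_real_, solution = NULL))
  if (identical(res$status, "unbounded"))
    return(list(status = "unbounded", value = Inf, solution = NULL))
  if (!identical(res$status, "optimal"))
    stop("LP solver returned status ", res$status)
  sol <- as.numeric(res$x)
  names(sol) <- region$net$rxns$id
  list(status = "optimal", value = -res$obj, solution = sol)
}

#' Maximum product yield
#'
#' Maximizes the flux through a product exchange reaction under the
#' configured substrate uptake limit and maintenance demand, and divides it
#' by the substrate uptake realized at the optimum. Classifies the outcome:
#' a metabolite with zero maximal flux cannot be produced at all; an
#' unbounded one is not limited by the substrate (and is not a coupling
#' candidate).
#'
#' @param net configured `metabolic_network` (see [apply_config()])
#' @param product_exchange id of the product export reaction
#' @param config the `model_config` (for the uptake orientation)
#' @return list with `status` (`"ok"`, `"zero"` or `"unbounded"`) and `yield`
#' @export
max_product_yield <- function(net, product_exchange, config) {
  obj <- stats::setNames(1, product_exchange)
  res <- maximize(flux_region(net), obj)
  if (identical(res$status, "infeasible"))
    stop("configured network is infeasible; check medium and maintenance")
  if (identical(res$status, "unbounded"))
    return(list(status = "unbounded", yield = Inf))
  if (res$value <= ZERO_TOL)
    return(list(status = "zero", yield = 0))
  uptake <- substrate_orientation(config) *
    res$solution[[config$substrate_exchange_id]]
  if (uptake <= ZERO_TOL)
    return(list(status = "unbounded", yield = Inf))
  list(status = "ok", yield = res$value / uptake)
}

#' Flux variability analysis
#'
#' Per reaction, the minimum and maximum flux over the region. Infinite
#' results are replaced by -/+ `flux_cap`. When the region itself is
#' infeasible a distinguished sentinel is returned (this happens when the
#' minimum-biomass-yield row is added to a network that cannot grow, in
#' which case growth-coupled production is impossible).
#'
#' @param region a `flux_region`
#' @param flux_cap replacement magnitude for unbounded directions
#' @return list with `status` (`"ok"` or `"infeasible"`) and `table`
#'   (data.frame `reaction_id`, `min`, `max`)
#' @export
fva <- function(region, flux_cap = 2000) {
  p <- region_lp_parts(region)
  res <- solver_fva_call(p$n, lb = p$lb, ub = p$ub, eq = p$eq, le = p$le,
                         cols = seq_len(p$n))
  if (identical(res$status, "infeasible"))
    return(list(status = "infeasible", table = NULL))
  mn <- pmax(.dec_num(res$min), -flux_cap)
  mx <- pmin(.dec_num(res$max), flux_cap)
  list(status = "ok",
       table = data.frame(reaction_id = region$net$rxns$id, min = mn, max = mx,
                          stringsAsFactors = FALSE))
}

#' Operative reactions
#'
#' Reactions that can carry a nonzero flux under the configured constraints,
#' detected by flux variability analysis.
#'
#' @param net configured `metabolic_network`
#' @param config a `model_config`
#' @return character vector of operative reaction ids
#' @export
operative_reactions <- function(net, config) {
  v <- fva(flux_region(net), flux_cap = config$flux_cap)
  if (identical(v$status, "infeasible"))
    return(character())
  tab <- v$table
  tab$reaction_id[pmax(abs(tab$min), abs(tab$max)) > ZERO_TOL]
}

#' Export an FVA table as TSV
#' @param table data.frame from [fva()]
#' @param path output file
#' @return invisibly `path`
#' @export
write_fva_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
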