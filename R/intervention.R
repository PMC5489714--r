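# Construction of the undesired and desired flux regions for a product and
# yield level -- the mathematical heart of strong coupling.
#
# Undesired (to be disabled by knockouts): product yield at or below the
# threshold,    r_P - Y_P * r_S <= 0          (one row, T r <= t)
# Desired (to be preserved): yield and growth above their thresholds,
#               -r_P + Y_P  * r_S <= 0
#               -mu  + Y_BM * r_S <= 0        (two rows, D r <= d)
# r_S is the substrate uptake rate, expressed through the stored orientation
# of the substrate exchange flux; mu is the biomass reaction flux.

#' Build a coupling problem
#'
#' Computes the maximum product yield, sets the minimum demanded product
#' yield to `yield_fraction` times it, and writes the undesired and desired
#' constraint rows. The zero flux vector must lie outside the undesired
#' region, otherwise no knockout set can ever disable it; a maintenance
#' reaction with positive lower bound achieves this, and when the model has
#' none a minimum substrate uptake of `0.001 * uptake limit` is imposed on
#' the undesired region instead.
#'
#' @param net configured `metabolic_network` (see [apply_config()])
#' @param config a `model_config`
#' @param product_exchange id of the product export reaction
#' @param yield_fraction demanded fraction of the maximum product yield,
#'   in (0, 1]
#' @return object of class `coupling_problem`
#' @export
build_coupling_problem <- function(net, config, product_exchange,
                                   yield_fraction) {
  stopifnot(yield_fraction > 0, yield_fraction <= 1)
  my <- max_product_yield(net, product_exchange, config)
  if (!identical(my$status, "ok"))
    stop("not a coupling candidate: maximum yield of ", product_exchange,
         " is ", my$status)
  Y_P <- yield_fraction * my$yield
  orient <- substrate_orientation(config)
  sub <- config$substrate_exchange_id
  bio <- config$biomass_reaction_id

  undesired_rows <- list(list(
    coef = stats::setNames(c(1, -Y_P * orient), c(product_exchange, sub)),
    sense = "<=", rhs = 0))
  zero_exclusion <- "maintenance"
  has_maint <- !is.null(config$maintenance_reaction_id) &&
    config$maintenance_lb > 0
  if (!has_maint) {
    eps <- 0.001 * config$substrate_uptake_limit
    undesired_rows <- c(undesired_rows, list(list(
      coef = stats::setNames(-orient, sub), sense = "<=", rhs = -eps)))
    zero_exclusion <- sprintf("min-uptake eps=%g", eps)
  }

  desired_rows <- list(
    list(coef = stats::setNames(c(-1, Y_P * orient), c(product_exchange, sub)),
         sense = "<=", rhs = 0),
    list(coef = stats::setNames(c(-1, config$min_biomass_yield * orient),
                                c(bio, sub)),
         sense = "<=", rhs = 0))

  structure(list(
    net = net,
    config = config,
    product_exchange = product_exchange,
    substrate_exchange = sub,
    orient = orient,
    biomass_reaction = bio,
    yield_fraction = yield_fraction,
    max_yield = my$yield,
    Y_P = Y_P,
    Y_BM = config$min_biomass_yield,
    undesired = constraint_set(undesired_rows),
    desired = constraint_set(desired_rows),
    repressible = net$rxns$id[net$rxns$repressible],
    zero_exclusion = zero_exclusion
  ), class = "coupling_problem")
}

#' @export
print.coupling_problem <- function(x, ...) {
  cat(sprintf(
    "coupling_problem: product %s, Y_min_P = %.4g (%.0f%% of max yield %.4g), Y_min_BM = %.4g\n",
    x$product_exchange, x$Y_P, 100 * x$yield_fraction, x$max_yield, x$Y_BM))
  cat(" repressible reactions:", length(x$repressible),
      "| zero exclusion:", x$zero_exclusion, "\n")
  invisible(x)
}

#' @keywords internal
undesired_region <- function(problem, knockouts = character()) {
  flux_region(problem$net, extra = problem$undesired, knockouts = knockouts)
}

#' @keywords internal
desired_region <- function(problem, knockouts = character()) {
  flux_region(problem$net, extra = problem$desired, knockouts = knockouts)
}

#' Wild-type sanity check
#'
#' Feasibility of the undesired and desired regions on the unmodified
#' network. A wild type whose desired region is already infeasible can never
#' be coupled (knockouts only shrink flux spaces); a wild type whose
#' undesired region is already infeasible is coupled with zero knockouts.
#'
#' @param problem a `coupling_problem`
#' @return list with logicals `undesired_feasible`, `desired_feasible`
#' @export
wildtype_sanity <- function(problem) {
  list(undesired_feasible = check_region_feasible(undesired_region(problem))$feasible,
       desired_feasible = check_region_feasible(desired_region(problem))$feasible)
}
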