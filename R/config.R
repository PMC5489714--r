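# Model configuration: medium, substrate uptake limit, maintenance demand,
# open organic outflows, oxygen condition and repressibility rules, plus the
# solver budgets used by the cut-set search.

#' Create a model configuration
#'
#' Captures everything the screening pipeline needs to know about the growth
#' condition: which exchange supplies the substrate and with what limit, the
#' non-growth-associated ATP maintenance demand, which organic outflows stay
#' open, the oxygen regime, and which reactions may never be knocked out.
#'
#' @param substrate_exchange_id id of the substrate exchange reaction.
#' @param substrate_uptake_limit maximal uptake rate (mmol/gDW/h), positive.
#' @param uptake_sign `"negative-exchange"` when uptake is a negative flux of
#'   an export-positive exchange (SBML/BiGG convention) or
#'   `"positive-uptake"` when the substrate reaction runs forward on uptake.
#' @param biomass_reaction_id id of the biomass (growth) reaction.
#' @param maintenance_reaction_id id of the ATP maintenance pseudo-reaction,
#'   or `NULL` when the model has none.
#' @param maintenance_lb lower flux bound imposed on the maintenance reaction.
#' @param open_outflow_ids exchange ids of organic outflows left open; all
#'   other organic exchanges are closed in the outflow direction.
#' @param oxygen_mode `"aerobic"`, `"anaerobic-remove-exchange"` (close the
#'   oxygen exchange) or `"anaerobic-remove-reaction:<id>"` (disable a named
#'   respiratory reaction such as cytochrome c oxidase).
#' @param irrepressible_ids reaction ids that are always irrepressible, in
#'   addition to the rule flags.
#' @param irrepressible_rules named logical flags `exchanges`, `transporters`,
#'   `pseudo_reactions`, `spontaneous`, `no_gene`; a `TRUE` flag marks the
#'   whole class irrepressible.
#' @param inorganic_carbon_ids compound keys that contain carbon but do not
#'   count as organic (CO2, CO, carbonate, bicarbonate by default).
#' @param spontaneous_keywords regexes identifying spontaneous reactions by
#'   their id, name or gene text.
#' @param yield_levels fractions of the maximum product yield demanded as
#'   minimum yields, each in (0, 1].
#' @param min_biomass_yield minimum demanded biomass yield (gDW per mmol
#'   substrate) defining the desired region.
#' @param oxygen_exchange_id id of the oxygen exchange (needed only for
#'   `"anaerobic-remove-exchange"`).
#' @param flux_cap replacement for unbounded flux-variability results
#'   (mmol/gDW/h).
#' @param milp_time_limit_s per-attempt MILP time limit in seconds.
#' @param milp_retries maximal number of MILP attempts with different seeds.
#' @param milp_gap relative gap at which the MILP accepts an incumbent.
#' @param rng_seed base seed for solver randomisation.
#' @return object of class `model_config`
#' @export
model_config <- function(substrate_exchange_id,
                         substrate_uptake_limit,
                         biomass_reaction_id,
                         uptake_sign = c("positive-uptake", "negative-exchange"),
                         maintenance_reaction_id = NULL,
                         maintenance_lb = 0,
                         open_outflow_ids = character(),
                         oxygen_mode = "aerobic",
                         irrepressible_ids = character(),
                         irrepressible_rules = list(),
                         inorganic_carbon_ids = c("co2", "co", "co3", "hco3"),
                         spontaneous_keywords = c("spontaneous", "_s0001"),
                         yield_levels = c(0.1, 0.3, 0.5),
                         min_biomass_yield = 0.01,
                         oxygen_exchange_id = NULL,
                         flux_cap = 2000,
                         milp_time_limit_s = 60,
                         milp_retries = 10,
                         milp_gap = 0.98,
                         rng_seed = 1L) {
  uptake_sign <- match.arg(uptake_sign)
  rules <- list(exchanges = TRUE, transporters = TRUE, pseudo_reactions = TRUE,
                spontaneous = TRUE, no_gene = FALSE)
  rules[names(irrepressible_rules)] <- irrepressible_rules
  stopifnot(substrate_uptake_limit > 0, flux_cap > 0, milp_retries >= 1,
            all(yield_levels > 0), all(yield_levels <= 1))
  structure(list(
    substrate_exchange_id = substrate_exchange_id,
    substrate_uptake_limit = substrate_uptake_limit,
    uptake_sign = uptake_sign,
    biomass_reaction_id = biomass_reaction_id,
    maintenance_reaction_id = maintenance_reaction_id,
    maintenance_lb = maintenance_lb,
    open_outflow_ids = open_outflow_ids,
    oxygen_mode = oxygen_mode,
    oxygen_exchange_id = oxygen_exchange_id,
    irrepressible_ids = irrepressible_ids,
    irrepressible_rules = rules,
    inorganic_carbon_ids = inorganic_carbon_ids,
    spontaneous_keywords = spontaneous_keywords,
    yield_levels = sort(yield_levels),
    min_biomass_yield = min_biomass_yield,
    flux_cap = flux_cap,
    milp_time_limit_s = milp_time_limit_s,
    milp_retries = milp_retries,
    milp_gap = milp_gap,
    rng_seed = as.integer(rng_seed)
  ), class = "model_config")
}

# Orientation of the substrate uptake rate: r_S = orient * flux(exchange).
#' @keywords internal
substrate_orientation <- function(config) {
  if (config$uptake_sign == "negative-exchange") -1 else 1
}

# Transport reaction: participants span >= 2 compartments, or the same
# compound appears on both sides in different compartments.
#' @keywords internal
is_transport <- function(net) {
  keys <- compound_key(net)
  comp <- net$mets$compartment
  vapply(seq_len(n_rxns(net)), function(j) {
    nz <- which(net$S[, j] != 0)
    if (length(nz) < 2L) return(FALSE)
    cs <- unique(comp[nz])
    length(cs[!is.na(cs)]) >= 2L
  }, logical(1))
}

#' @keywords internal
is_spontaneous <- function(net, keywords) {
  if (!length(keywords)) return(rep(FALSE, n_rxns(net)))
  pat <- paste(keywords, collapse = "|")
  hit_id <- grepl(pat, net$rxns$id, ignore.case = TRUE)
  hit_gpr <- !is.na(net$rxns$gpr) & grepl(pat, net$rxns$gpr, ignore.case = TRUE)
  hit_id | hit_gpr
}

# Organic = formula contains carbon and the compound is not on the inorganic
# carbon list (bicarbonate etc. contain C but do not count).
#' @keywords internal
is_organic <- function(net, config) {
  cc <- carbon_count(net$mets$formula)
  keys <- tolower(compound_key(net))
  !is.na(cc) & cc >= 1 & !(keys %in% tolower(config$inorganic_carbon_ids))
}

#' Apply a model configuration to a network
#'
#' Bounds the substrate uptake, imposes the maintenance demand, closes all
#' organic-metabolite outflows except the configured open ones, applies the
#' oxygen regime, and sets every reaction's repressibility flag from the
#' explicit list plus the rule flags (exchanges, transporters, pseudo and
#' spontaneous reactions, and optionally reactions without gene association
#' are irrepressible). The biomass and maintenance reactions are always
#' irrepressible.
#'
#' @param net a `metabolic_network`
#' @param config a `model_config`
#' @return the configured network, with attribute `"config"` set
#' @export
apply_config <- function(net, config) {
  stopifnot(inherits(net, "metabolic_network"), inherits(config, "model_config"))
  sub_j <- rxn_index(net, config$substrate_exchange_id)
  if (config$uptake_sign == "negative-exchange") {
    net$rxns$lb[sub_j] <- -config$substrate_uptake_limit
  } else {
    net$rxns$ub[sub_j] <- config$substrate_uptake_limit
  }

  if (!is.null(config$maintenance_reaction_id)) {
    mj <- rxn_index(net, config$maintenance_reaction_id)
    net$rxns$lb[mj] <- config$maintenance_lb
  }

  # close organic outflows except the configured ones
  organic <- is_organic(net, config)
  for (j in which(net$rxns$is_exchange)) {
    id <- net$rxns$id[j]
    if (id == config$substrate_exchange_id) next
    met <- exchange_metabolite(net, id)
    if (is.na(met) || !organic[met_index(net, met)]) next
    if (id %in% config$open_outflow_ids) next
    # outflow direction = the direction that removes the metabolite
    coef <- net$S[met_index(net, met), j]
    if (coef < 0) net$rxns$ub[j] <- min(net$rxns$ub[j], 0)
    else net$rxns$lb[j] <- max(net$rxns$lb[j], 0)
  }

  if (identical(config$oxygen_mode, "anaerobic-remove-exchange")) {
    if (is.null(config$oxygen_exchange_id))
      stop("oxygen_mode 'anaerobic-remove-exchange' requires oxygen_exchange_id")
    oj <- rxn_index(net, config$oxygen_exchange_id)
    net$rxns$lb[oj] <- 0
    net$rxns$ub[oj] <- 0
  } else if (startsWith(config$oxygen_mode, "anaerobic-remove-reaction:")) {
    rid <- sub("^anaerobic-remove-reaction:", "", config$oxygen_mode)
    rj <- rxn_index(net, rid)
    net$rxns$lb[rj] <- 0
    net$rxns$ub[rj] <- 0
  } else if (!identical(config$oxygen_mode, "aerobic")) {
    stop("unknown oxygen_mode: ", config$oxygen_mode)
  }

  # repressibility: start from the network's own flags, then apply rules
  irre <- rep(FALSE, n_rxns(net))
  rules <- config$irrepressible_rules
  if (isTRUE(rules$exchanges)) irre <- irre | net$rxns$is_exchange
  if (isTRUE(rules$transporters)) irre <- irre | is_transport(net)
  if (isTRUE(rules$pseudo_reactions))
    irre <- irre | grepl("^(DM_|SK_|ATPM|BIOMASS)", net$rxns$id, ignore.case = TRUE)
  if (isTRUE(rules$spontaneous))
    irre <- irre | is_spontaneous(net, config$spontaneous_keywords)
  if (isTRUE(rules$no_gene) && any(!is.na(net$rxns$gpr)))
    irre <- irre | is.na(net$rxns$gpr) | !nzchar(net$rxns$gpr)
  irre <- irre | net$rxns$id %in% config$irrepressible_ids
  # biomass and maintenance are pseudo reactions, never knockout targets
  irre[rxn_index(net, config$biomass_reaction_id)] <- TRUE
  if (!is.null(config$maintenance_reaction_id))
    irre[rxn_index(net, config$maintenance_reaction_id)] <- TRUE
  net$rxns$repressible <- net$rxns$repressible & !irre

  validate_network(net)
  attr(net, "config") <- config
  net
}
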