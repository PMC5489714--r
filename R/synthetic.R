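# Small fixture networks with known coupling structure, a seeded random
# network generator, and an exhaustive brute-force oracle. The oracle works
# on the original network with its true bounds (no FVA tightening, no big-M)
# and is the soundness reference for the MILP path.

#' Built-in toy fixtures
#'
#' * `TOY1` ("uncoupled branches"): substrate A feeds independent branches to
#'   biomass precursor B, product P and waste W; maintenance drains A
#'   directly. No knockout set can force production: coupling is infeasible
#'   for every yield level.
#' * `TOY3` ("coupled catabolism"): two catabolic routes `CAT1: A -> ATP + P`
#'   and `CAT2: A -> ATP + W` supply ATP for maintenance and anabolism
#'   (`ANA: A + ATP -> B`). Cutting `CAT2` makes ATP supply, and hence
#'   maintenance, force product synthesis: the unique minimal cut set for P
#'   is `{CAT2}` at all levels up to 50%.
#' * `TOY3-G`: `TOY3` with one dedicated gene per repressible reaction
#'   (`CAT1 <- gA`, `CAT2 <- gB`, `ANA <- gC`), so gene-level results are
#'   isomorphic to reaction-level ones.
#' * `TOY3-GI`: `TOY3-G` with an isozyme pair on `CAT2` (`gB or gD`); both
#'   isozymes must be removed, so the minimal gene cut set has size 2.
#'
#' @param name fixture name
#' @return list with elements `net` (configured network), `config`,
#'   `products` (candidate product exchange ids) and `ground_truth` notes
#' @export
make_toy <- function(name = c("TOY1", "TOY3", "TOY3-G", "TOY3-GI")) {
  name <- match.arg(name)
  cfg <- model_config(
    substrate_exchange_id = "EX_S", substrate_uptake_limit = 10,
    uptake_sign = "positive-uptake", biomass_reaction_id = "BIO",
    maintenance_reaction_id = "MAINT", maintenance_lb = 1,
    open_outflow_ids = c("EX_P", "EX_W"),
    min_biomass_yield = 0.01, milp_time_limit_s = 10, rng_seed = 1L)

  if (name == "TOY1") {
    mets <- data.frame(
      id = c("A", "B", "P", "W"),
      name = c("substrate", "biomass precursor", "product", "waste"),
      compartment = "c",
      formula = c("C6H12O6", NA, "C3H6O3", "C2H4O2"),
      stringsAsFactors = FALSE)
    rxns <- data.frame(
      id = c("EX_S", "MAINT", "R_B", "R_P", "R_W", "BIO", "EX_P", "EX_W"),
      lb = c(0, 1, 0, 0, 0, 0, 0, 0),
      ub = c(10, 2000, Inf, Inf, Inf, Inf, Inf, Inf),
      reversible = FALSE,
      repressible = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
      gpr = NA_character_,
      is_exchange = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
      stringsAsFactors = FALSE)
    S <- matrix(0, 4, 8, dimnames = list(mets$id, rxns$id))
    S["A", "EX_S"] <- 1
    S["A", "MAINT"] <- -1
    S["A", "R_B"] <- -1; S["B", "R_B"] <- 1
    S["A", "R_P"] <- -1; S["P", "R_P"] <- 1
    S["A", "R_W"] <- -1; S["W", "R_W"] <- 1
    S["B", "BIO"] <- -1
    S["P", "EX_P"] <- -1
    S["W", "EX_W"] <- -1
    gt <- list(P = "INFEASIBLE at every yield level (maintenance bypasses all branches)")
  } else {
    mets <- data.frame(
      id = c("A", "ATP", "B", "P", "W"),
      name = c("substrate", "energy currency", "biomass precursor",
               "product", "waste"),
      compartment = "c",
      formula = c("C6H12O6", NA, NA, "C3H6O3", "C2H4O2"),
      stringsAsFactors = FALSE)
    gpr_cat2 <- switch(name, "TOY3-G" = "gB", "TOY3-GI" = "gB or gD",
                       NA_character_)
    gpr <- if (name == "TOY3") rep(NA_character_, 8) else
      c(NA, "gA", gpr_cat2, "gC", NA, NA, NA, NA)
    rxns <- data.frame(
      id = c("EX_S", "CAT1", "CAT2", "ANA", "MAINT", "BIO", "EX_P", "EX_W"),
      lb = c(0, 0, 0, 0, 1, 0, 0, 0),
      ub = c(10, Inf, Inf, Inf, 2000, Inf, Inf, Inf),
      reversible = FALSE,
      repressible = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
      gpr = gpr,
      is_exchange = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
      stringsAsFactors = FALSE)
    S <- matrix(0, 5, 8, dimnames = list(mets$id, rxns$id))
    S["A", "EX_S"] <- 1
    S["A", "CAT1"] <- -1; S["ATP", "CAT1"] <- 1; S["P", "CAT1"] <- 1
    S["A", "CAT2"] <- -1; S["ATP", "CAT2"] <- 1; S["W", "CAT2"] <- 1
    S["A", "ANA"] <- -1; S["ATP", "ANA"] <- -1; S["B", "ANA"] <- 1
    S["ATP", "MAINT"] <- -1
    S["B", "BIO"] <- -1
    S["P", "EX_P"] <- -1
    S["W", "EX_W"] <- -1
    gt <- list(P = "FEASIBLE, unique cMCS {CAT2} at 10/30/50% (r_P - 0.5 r_S = 0.5 MAINT >= 0.5)",
               W = "FEASIBLE, unique cMCS {CAT1} by symmetry")
  }
  net <- apply_config(metabolic_network(mets, rxns, S), cfg)
  list(name = name, net = net, config = cfg,
       products = c("EX_P", "EX_W"), ground_truth = gt)
}

#' Seeded random fixture generator
#'
#' Emulates the structure of the genome models at miniature scale: a limited
#' substrate uptake, a maintenance reaction with positive lower bound (so the
#' zero flux vector is never feasible), a biomass sink, one candidate product
#' and one or two waste branches. Two archetypes are drawn: an energy-coupled
#' one in which all catabolic routes co-produce an organic compound (coupling
#' typically enforceable) and an uncoupled one in which maintenance drains
#' the substrate directly (coupling typically impossible). Decorations --
#' stoichiometric coefficients in {1, 2}, an optional ADP/ATP conserved
#' moiety, an optional fully coupled two-step product chain, an optional
#' redundant duplicate branch, and per-branch repressibility -- vary with the
#' seed. At most 12 reactions and 6 repressible reactions, so the exhaustive
#' oracle stays tractable.
#'
#' @param seed integer seed; the same seed always yields the same fixture
#' @return list with `net` (configured), `config`, `products`
#' @export
random_network <- function(seed) {
  rng <- local({
    set.seed(as.integer(seed))
    list(flip = function(p = 0.5) stats::runif(1) < p,
         pick = function(v) v[sample.int(length(v), 1)])
  })
  coupled <- rng$flip(0.5)
  n_waste <- if (rng$flip(0.5)) 1L else 2L
  use_adp <- coupled && rng$flip(0.5)
  chain <- rng$flip(0.4)        # product made via a fully coupled 2-step chain
  dup_branch <- rng$flip(0.3)   # redundant duplicate waste branch
  # with an explicit ADP pool the phosphate transfer must be 1:1, which
  # plants the intended ATP/ADP conservation relation (dependent rows)
  atp_per_cat <- if (use_adp) 1L else rng$pick(1:2)
  ana_atp <- if (!coupled) 0 else if (use_adp) 1L else rng$pick(1:2)

  met_ids <- c("A", "B", "P", paste0("W", seq_len(n_waste)))
  formulas <- c("C6H12O6", NA, "C3H6O3", rep("C2H4O2", n_waste))
  if (coupled) { met_ids <- c(met_ids, "ATP"); formulas <- c(formulas, NA) }
  if (use_adp) { met_ids <- c(met_ids, "ADP"); formulas <- c(formulas, NA) }
  if (chain) { met_ids <- c(met_ids, "M1"); formulas <- c(formulas, "C3H6O3") }
  mets <- data.frame(id = met_ids, name = met_ids, compartment = "c",
                     formula = formulas, stringsAsFactors = FALSE)

  rxn <- list()
  add <- function(id, stoich, lb = 0, ub = Inf, repressible = FALSE,
                  is_exchange = FALSE) {
    rxn[[length(rxn) + 1L]] <<- list(id = id, stoich = stoich, lb = lb,
                                     ub = ub, repressible = repressible,
                                     is_exchange = is_exchange)
  }
  adp_in <- function(s) if (use_adp) c(s, ADP = -1) else s
  adp_out <- function(s) if (use_adp) c(s, ADP = 1) else s

  add("EX_S", c(A = 1), lb = 0, ub = 10, is_exchange = TRUE)
  if (coupled) {
    if (chain) {
      add("CATP1", adp_in(c(A = -1, M1 = 1, ATP = atp_per_cat)),
          repressible = TRUE)
      add("CATP2", c(M1 = -1, P = 1), repressible = rng$flip(0.7))
    } else {
      add("CATP", adp_in(c(A = -1, P = 1, ATP = atp_per_cat)),
          repressible = TRUE)
    }
    for (k in seq_len(n_waste))
      add(paste0("CATW", k),
          adp_in(stats::setNames(c(-1, 1, atp_per_cat),
                                 c("A", paste0("W", k), "ATP"))),
          repressible = TRUE)
    if (dup_branch)
      add("CATW1b", adp_in(c(A = -1, W1 = 1, ATP = atp_per_cat)),
          repressible = TRUE)
    add("ANA", adp_out(c(A = -1, B = 1, ATP = -ana_atp)),
        repressible = rng$flip(0.5))
    add("MAINT", adp_out(c(ATP = -1)), lb = 1, ub = 2000)
  } else {
    if (chain) {
      add("R_P1", c(A = -1, M1 = 1), repressible = TRUE)
      add("R_P2", c(M1 = -1, P = 1), repressible = rng$flip(0.7))
    } else {
      add("R_P", c(A = -1, P = 1), repressible = TRUE)
    }
    for (k in seq_len(n_waste))
      add(paste0("R_W", k),
          stats::setNames(c(-1, 1), c("A", paste0("W", k))),
          repressible = TRUE)
    if (dup_branch) add("R_W1b", c(A = -1, W1 = 1), repressible = TRUE)
    add("R_B", c(A = -1, B = 1), repressible = rng$flip(0.5))
    add("MAINT", c(A = -1), lb = 1, ub = 2000)
  }
  add("BIO", c(B = -1))
  add("EX_P", c(P = -1), is_exchange = TRUE)
  for (k in seq_len(n_waste))
    add(paste0("EX_W", k),
        stats::setNames(-1, paste0("W", k)), is_exchange = TRUE)

  rxns <- data.frame(
    id = vapply(rxn, `[[`, "", "id"),
    lb = vapply(rxn, `[[`, 0, "lb"),
    ub = vapply(rxn, `[[`, 0, "ub"),
    reversible = FALSE,
    repressible = vapply(rxn, `[[`, FALSE, "repressible"),
    gpr = NA_character_,
    is_exchange = vapply(rxn, `[[`, FALSE, "is_exchange"),
    stringsAsFactors = FALSE)
  S <- matrix(0, nrow(mets), nrow(rxns), dimnames = list(mets$id, rxns$id))
  for (k in seq_along(rxn))
    S[names(rxn[[k]]$stoich), k] <- rxn[[k]]$stoich

  cfg <- model_config(
    substrate_exchange_id = "EX_S", substrate_uptake_limit = 10,
    uptake_sign = "positive-uptake", biomass_reaction_id = "BIO",
    maintenance_reaction_id = "MAINT", maintenance_lb = 1,
    open_outflow_ids = grep("^EX_", rxns$id, value = TRUE),
    min_biomass_yield = 0.01, milp_time_limit_s = 10,
    rng_seed = as.integer(seed))
  net <- apply_config(metabolic_network(mets, rxns, S), cfg)
  stopifnot(n_rxns(net) <= 12, sum(net$rxns$repressible) <= 6)
  list(name = paste0("RANDOM", seed), net = net, config = cfg,
       products = "EX_P")
}

# All subsets of a set, ascending size, as a list of integer vectors.
#' @keywords internal
all_subsets <- function(n, max_size = n) {
  out <- list(integer())
  for (k in seq_len(min(n, max_size)))
    out <- c(out, utils::combn(n, k, simplify = FALSE))
  out
}

#' Exhaustive ground-truth verdict
#'
#' Enumerates every subset of the repressible reactions (ascending size, up
#' to `max_size`) and tests with two LPs per subset, on the original network
#' with its true bounds, whether the knockouts disable the undesired region
#' while keeping the desired region feasible. This is the definition of a
#' constrained minimal cut set made executable, and serves as the soundness
#' oracle for the MILP path.
#'
#' @param problem a `coupling_problem`
#' @param max_size largest subset size enumerated (default: all repressible)
#' @return object of class `oracle_verdict`: `status` (`"FEASIBLE"`,
#'   `"INFEASIBLE"`, or `"UNDECIDED"` when `max_size` truncated the
#'   enumeration without finding a valid set), `minimal_cutsets` (list of
#'   character vectors), `n_subsets` tested
#' @export
brute_force_verdict <- function(problem, max_size = Inf) {
  rep_ids <- problem$repressible
  nr <- length(rep_ids)
  max_size <- min(max_size, nr)
  subsets <- all_subsets(nr, max_size)
  rep_idx <- rxn_index(problem$net, rep_ids)

  scen <- lapply(subsets, function(s) {
    idx <- rep_idx[s]
    list(lb_idx = idx, lb_val = rep(0, length(idx)),
         ub_idx = idx, ub_val = rep(0, length(idx)))
  })
  pu <- region_lp_parts(undesired_region(problem))
  pd <- region_lp_parts(desired_region(problem))
  res_u <- solver_lp_batch(pu$n, pu$lb, pu$ub, pu$eq, pu$le, scen)
  res_d <- solver_lp_batch(pd$n, pd$lb, pd$ub, pd$eq, pd$le, scen)
  u_inf <- vapply(res_u, function(r) identical(r$status, "infeasible"), TRUE)
  d_fea <- vapply(res_d, function(r) identical(r$status, "optimal"), TRUE)
  valid <- u_inf & d_fea

  valid_sets <- subsets[valid]
  minimal <- valid_sets[vapply(valid_sets, function(s) {
    !any(vapply(valid_sets, function(t)
      length(t) < length(s) && all(t %in% s), TRUE))
  }, TRUE)]

  status <- if (any(valid)) "FEASIBLE"
    else if (max_size >= nr) "INFEASIBLE" else "UNDECIDED"
  structure(list(
    status = status,
    minimal_cutsets = lapply(minimal, function(s) rep_ids[s]),
    valid_cutsets = lapply(valid_sets, function(s) rep_ids[s]),
    n_subsets = length(subsets)
  ), class = "oracle_verdict")
}

#' Is a cut set valid according to an oracle verdict?
#' @param oracle an `oracle_verdict`
#' @param cutset character vector of reaction ids
#' @return logical
#' @export
oracle_validates <- function(oracle, cutset) {
  any(vapply(oracle$valid_cutsets, function(s) setequal(s, cutset), TRUE))
}
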