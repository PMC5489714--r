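# LP primitives: feasibility with witness, FBA-style maximization, maximum
# product yield, flux variability and operative-reaction detection.

test_that("region feasibility returns consistent witnesses", {
  fx <- make_toy("TOY3")
  res <- check_region_feasible(flux_region(fx$net))
  expect_true(res$feasible)
  expect_lt(max(abs(flux_residuals(fx$net, res$witness))), 1e-6)
  expect_true(all(res$witness >= fx$net$rxns$lb - 1e-6))
  expect_true(all(res$witness <= fx$net$rxns$ub + 1e-6))

  # ATP loses all producers: the maintenance demand cannot be served
  res2 <- check_region_feasible(flux_region(fx$net,
                                            knockouts = c("CAT1", "CAT2")))
  expect_false(res2$feasible)

  # all bounds containing zero and no positive lower bound: zero flux works
  net0 <- fx$net
  net0$rxns$lb[net0$rxns$id == "MAINT"] <- 0
  expect_true(check_region_feasible(flux_region(net0))$feasible)
})

test_that("maximization matches hand-computed optima and detects unboundedness", {
  toy3 <- make_toy("TOY3")
  toy1 <- make_toy("TOY1")
  expect_equal(maximize(flux_region(toy3$net), c(EX_P = 1))$value, 10)
  expect_equal(maximize(flux_region(toy1$net), c(EX_P = 1))$value, 9)

  # a two-reaction uncapped loop producing the objective is unbounded
  mets <- data.frame(id = c("X", "Y"), name = NA, compartment = "c",
                     formula = NA, stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("F", "G"), lb = 0, ub = Inf, reversible = FALSE,
                     repressible = FALSE, gpr = NA_character_,
                     is_exchange = FALSE, stringsAsFactors = FALSE)
  S <- matrix(c(1, -1, -1, 1), 2, 2, dimnames = list(mets$id, rxns$id))
  loop <- metabolic_network(mets, rxns, S)
  expect_equal(maximize(flux_region(loop), c(F = 1))$status, "unbounded")
})

test_that("maximum product yield classifies zero, bounded and unbounded cases", {
  toy3 <- make_toy("TOY3")
  toy1 <- make_toy("TOY1")
  expect_equal(max_product_yield(toy3$net, "EX_P", toy3$config)$yield, 1.0)
  expect_equal(max_product_yield(toy1$net, "EX_P", toy1$config)$yield, 0.9)

  # a metabolite without producer has zero maximal flux
  net0 <- toy3$net
  net0$rxns$ub[net0$rxns$id == "CAT2"] <- 0  # W loses its only producer
  expect_equal(max_product_yield(net0, "EX_W", toy3$config)$status, "zero")
})

test_that("product yield is invariant to uniform rescaling of all bounds", {
  fx <- make_toy("TOY3")
  y1 <- max_product_yield(fx$net, "EX_P", fx$config)$yield
  scaled <- fx$net
  fin <- is.finite(scaled$rxns$lb)
  scaled$rxns$lb[fin] <- scaled$rxns$lb[fin] * 3
  fin <- is.finite(scaled$rxns$ub)
  scaled$rxns$ub[fin] <- scaled$rxns$ub[fin] * 3
  cfg <- fx$config
  cfg$substrate_uptake_limit <- cfg$substrate_uptake_limit * 3
  y3 <- max_product_yield(scaled, "EX_P", cfg)$yield
  expect_equal(y1, y3, tolerance = 1e-9)
})

test_that("FVA respects the biomass-yield row, caps and infeasibility sentinel", {
  fx <- make_toy("TOY3")
  p <- build_coupling_problem(fx$net, fx$config, "EX_P", 0.5)
  # with the minimum-biomass-yield row, maintenance forces positive uptake
  v <- fva(flux_region(fx$net, extra = constraint_set(p$desired$rows[2])),
           flux_cap = 2000)
  expect_equal(v$status, "ok")
  ex <- v$table[v$table$reaction_id == "EX_S", ]
  expect_gt(ex$min, 0.5)
  expect_lte(ex$max, 10 + 1e-9)
  expect_true(all(v$table$min <= v$table$max + 1e-9))

  # unbounded internal fluxes are clipped to +-flux_cap
  mets <- data.frame(id = c("X"), name = NA, compartment = "c",
                     formula = NA, stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("F", "G"), lb = 0, ub = Inf, reversible = FALSE,
                     repressible = FALSE, gpr = NA_character_,
                     is_exchange = FALSE, stringsAsFactors = FALSE)
  S <- matrix(c(1, -1), 1, 2, dimnames = list("X", rxns$id))
  loop <- metabolic_network(mets, rxns, S)
  vl <- fva(flux_region(loop), flux_cap = 2000)
  expect_equal(vl$table$max, c(2000, 2000))

  # contradictory extra rows yield the infeasible sentinel
  bad <- constraint_set(list(
    list(coef = c(EX_S = 1), sense = ">=", rhs = 5),
    list(coef = c(EX_S = 1), sense = "<=", rhs = 1)))
  expect_equal(fva(flux_region(fx$net, extra = bad))$status, "infeasible")
})

test_that("shrinking a region never widens FVA intervals", {
  fx <- make_toy("TOY3")
  v0 <- fva(flux_region(fx$net))$table
  row <- constraint_set(list(list(coef = c(EX_S = 1), sense = ">=", rhs = 4)))
  v1 <- fva(flux_region(fx$net, extra = row))$table
  expect_true(all(v1$min >= v0$min - 1e-7))
  expect_true(all(v1$max <= v0$max + 1e-7))
})

test_that("operative reactions are those able to carry flux", {
  fx <- make_toy("TOY3")
  expect_setequal(operative_reactions(fx$net, fx$config), fx$net$rxns$id)

  closed <- set_bounds(fx$net, "EX_W", ub = 0)
  op <- operative_reactions(closed, fx$config)
  expect_false("CAT2" %in% op)   # W has no sink
  expect_false("EX_W" %in% op)
  expect_true("CAT1" %in% op)

  # a dead-end metabolite forces its sole reaction to zero
  net <- fx$net
  net$mets <- rbind(net$mets, data.frame(id = "D", name = NA,
                                         compartment = "c", formula = NA,
                                         stringsAsFactors = FALSE))
  net$S <- methods::rbind2(net$S, Matrix::sparseMatrix(
    i = integer(), j = integer(), x = numeric(), dims = c(1L, n_rxns(net))))
  rownames(net$S) <- net$mets$id
  net <- add_reaction(net, "R_DEAD", c(A = -1, D = 1))
  expect_false("R_DEAD" %in% operative_reactions(net, fx$config))
})
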