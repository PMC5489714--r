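# Network container, configuration application, native JSON round trip and
# the SBML reader.

test_that("network invariants are enforced at construction", {
  fx <- make_toy("TOY3")
  expect_equal(n_mets(fx$net), 5L)
  expect_equal(n_rxns(fx$net), 8L)
  bad <- fx$net$rxns
  bad$lb[2] <- 5
  bad$ub[2] <- 1
  expect_error(metabolic_network(fx$net$mets, bad, fx$net$S), "lb > ub")
  dup <- fx$net$mets
  dup$id[2] <- "A"
  expect_error(metabolic_network(dup, fx$net$rxns, fx$net$S), "duplicate")
})

test_that("apply_config sets uptake, maintenance, outflows and repressibility", {
  fx <- make_toy("TOY3")
  net <- fx$net
  expect_equal(net$rxns$ub[net$rxns$id == "EX_S"], 10)
  expect_equal(net$rxns$lb[net$rxns$id == "MAINT"], 1)
  # partition: every reaction is exactly one of repressible/irrepressible
  expect_false(any(is.na(net$rxns$repressible)))
  expect_setequal(net$rxns$id[net$rxns$repressible], c("CAT1", "CAT2", "ANA"))
  # exchanges, biomass and maintenance always irrepressible
  expect_false(any(net$rxns$repressible[net$rxns$is_exchange]))
  expect_false(net$rxns$repressible[net$rxns$id == "BIO"])
  expect_false(net$rxns$repressible[net$rxns$id == "MAINT"])
})

test_that("organic outflows are closed except the configured open ones", {
  fx <- make_toy("TOY3")
  cfg <- fx$config
  cfg$open_outflow_ids <- "EX_P"  # close the waste outflow
  raw <- make_toy("TOY3")$net     # already configured; reconfigure from flags
  raw$rxns$repressible <- c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  net <- apply_config(raw, cfg)
  expect_equal(net$rxns$ub[net$rxns$id == "EX_W"], 0)
  expect_gt(net$rxns$ub[net$rxns$id == "EX_P"], 0)
})

test_that("anaerobic modes zero out the configured reaction", {
  fx <- make_toy("TOY3")
  net <- fx$net
  net <- add_reaction(net, "EX_O2", c(A = 0.0001), lb = 0, ub = Inf,
                      is_exchange = TRUE)  # stand-in oxygen exchange
  cfg <- fx$config
  cfg$oxygen_mode <- "anaerobic-remove-exchange"
  cfg$oxygen_exchange_id <- "EX_O2"
  out <- apply_config(net, cfg)
  expect_equal(out$rxns$lb[out$rxns$id == "EX_O2"], 0)
  expect_equal(out$rxns$ub[out$rxns$id == "EX_O2"], 0)
  cfg$oxygen_mode <- "anaerobic-remove-reaction:CAT2"
  out2 <- apply_config(net, cfg)
  expect_equal(out2$rxns$ub[out2$rxns$id == "CAT2"], 0)
  cfg$oxygen_mode <- "aerobic-typo"
  expect_error(apply_config(net, cfg), "oxygen_mode")
})

test_that("unknown ids in the configuration raise errors", {
  fx <- make_toy("TOY3")
  cfg <- fx$config
  cfg$substrate_exchange_id <- "EX_NOPE"
  expect_error(apply_config(fx$net, cfg), "EX_NOPE")
})

test_that("native JSON write-then-read is the identity", {
  for (name in c("TOY1", "TOY3", "TOY3-G")) {
    fx <- make_toy(name)
    path <- withr::local_tempfile(fileext = ".json")
    write_native(fx$net, path)
    back <- read_native(path)
    expect_equal(back$mets, fx$net$mets)
    expect_equal(back$rxns, fx$net$rxns)
    expect_equal(as.matrix(back$S), as.matrix(fx$net$S))
  }
})

test_that("native round trip preserves infinite bounds on generated networks", {
  for (seed in 1:8) {
    fx <- random_network(seed)
    path <- withr::local_tempfile(fileext = ".json")
    write_native(fx$net, path)
    back <- read_native(path)
    expect_equal(back$rxns$lb, fx$net$rxns$lb)
    expect_equal(back$rxns$ub, fx$net$rxns$ub)
    expect_equal(as.matrix(back$S), as.matrix(fx$net$S))
  }
})

test_that("native reader rejects duplicate ids and bound violations", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"metabolites":[{"id":"A"},{"id":"A"}],"reactions":[]}', path)
  expect_error(read_native(path), "duplicate metabolite ids")
  writeLines(paste0('{"metabolites":[{"id":"A"}],"reactions":[',
                    '{"id":"R1","stoich":{"A":1},"lb":2,"ub":1,',
                    '"reversible":false}]}'), path)
  expect_error(read_native(path), "lb > ub")
})

test_that("SBML reader mirrors the file and drops boundary species", {
  net <- read_sbml(system.file("extdata", "toy3.xml", package = "cmcs"))
  expect_equal(n_mets(net), 5L)          # boundary species A_b dropped
  expect_equal(n_rxns(net), 8L)
  expect_false("A_b" %in% net$mets$id)
  expect_equal(net$rxns$ub[net$rxns$id == "EX_S"], 10)
  expect_equal(net$rxns$lb[net$rxns$id == "MAINT"], 1)
  expect_equal(net$rxns$gpr[net$rxns$id == "CAT2"], "gB or gD")
  expect_equal(net$mets$formula[net$mets$id == "A"], "C6H12O6")
  expect_true(net$rxns$is_exchange[net$rxns$id == "EX_S"])
  # the file's stoichiometry matches the built-in fixture exactly
  fx <- make_toy("TOY3")
  expect_equal(as.matrix(net$S)[fx$net$mets$id, fx$net$rxns$id],
               as.matrix(fx$net$S))
})

test_that("SBML reader handles empty models, missing bounds and malformed files", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c('<?xml version="1.0"?>',
               '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
               '<model id="empty"><listOfSpecies>',
               '<species id="m1" compartment="c" boundaryCondition="false"/>',
               '</listOfSpecies></model></sbml>'), path)
  net <- read_sbml(path)
  expect_equal(n_rxns(net), 0L)
  expect_equal(n_mets(net), 1L)

  writeLines(c('<?xml version="1.0"?>',
               '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
               '<model id="nb"><listOfSpecies>',
               '<species id="m1" compartment="c" boundaryCondition="false"/>',
               '</listOfSpecies><listOfReactions>',
               '<reaction id="R1" reversible="true">',
               '<listOfProducts><speciesReference species="m1"/></listOfProducts>',
               '</reaction></listOfReactions></model></sbml>'), path)
  expect_warning(net2 <- read_sbml(path), "missing flux bounds")
  expect_equal(net2$rxns$lb, -Inf)
  expect_equal(net2$rxns$ub, Inf)

  writeLines("this is not xml <", path)
  expect_error(read_sbml(path), "parse error")
})

test_that("configuration files round through YAML and JSON", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("substrate_exchange_id: EX_S",
               "substrate_uptake_limit: 10",
               "uptake_sign: positive-uptake",
               "biomass_reaction_id: BIO",
               "maintenance_reaction_id: MAINT",
               "maintenance_lb: 1",
               "open_outflow_ids: [EX_P, EX_W]",
               "yield_levels: [0.1, 0.3, 0.5]"), path)
  cfg <- read_config(path)
  expect_s3_class(cfg, "model_config")
  expect_equal(cfg$substrate_uptake_limit, 10)
  expect_equal(cfg$yield_levels, c(0.1, 0.3, 0.5))
  jpath <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    substrate_exchange_id = "EX_S", substrate_uptake_limit = 10,
    biomass_reaction_id = "BIO", flux_cap = "inf"), auto_unbox = TRUE), jpath)
  expect_error(read_config(jpath), NA)
  writeLines('{"substrate_exchange_id":"EX_S","substrate_uptake_limit":1,"biomass_reaction_id":"BIO","bogus_field":1}', jpath)
  expect_error(read_config(jpath), "bogus_field")
})
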