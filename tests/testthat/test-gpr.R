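# Gene association parsing, DNF conversion, the structural gene extension
# and gene-level cut sets.

test_that("the gene association grammar parses with correct precedence", {
  e <- parse_gpr("g1 and g2")
  expect_equal(e$type, "and")
  expect_equal(vapply(e$args, `[[`, "", "id"), c("g1", "g2"))

  e2 <- parse_gpr("g1 or (g2 and g3)")
  expect_equal(e2$type, "or")
  expect_equal(e2$args[[2]]$type, "and")

  # and binds tighter than or even without parentheses
  e3 <- parse_gpr("g1 or g2 and g3")
  expect_equal(e3$type, "or")

  # idempotent re-serialization
  for (txt in c("g1 and g2", "g1 or (g2 and g3)", "(g1 or g2) and g3")) {
    expect_equal(parse_gpr(deparse_gpr(parse_gpr(txt))), parse_gpr(txt))
  }

  expect_error(parse_gpr("g1 and"), "parse error")
  expect_error(parse_gpr("(g1 or g2"), "parse error")
  expect_error(parse_gpr("g1 g2"), "parse error")
})

test_that("DNF conversion distributes and over or, with absorption and cap", {
  dnf <- gpr_to_dnf(parse_gpr("(g1 or g2) and g3"))
  expect_setequal(lapply(dnf, sort), list(c("g1", "g3"), c("g2", "g3")))
  expect_equal(gpr_to_dnf(parse_gpr("g1 or (g1 and g2)")), list("g1"))
  big <- paste(sprintf("(g%da or g%db)", 1:8, 1:8), collapse = " and ")
  expect_error(gpr_to_dnf(parse_gpr(big), term_cap = 64L), "cap")
})

test_that("the gene extension reproduces isozyme and complex logic in flux space", {
  fx <- make_toy("TOY3")
  net <- fx$net
  net$rxns$gpr[net$rxns$id == "CAT1"] <- "g1 or g2"     # isozymes
  net$rxns$gpr[net$rxns$id == "CAT2"] <- "g3 and g4"    # complex
  ext <- extend_with_genes(net)
  e <- ext$net
  expect_equal(sum(startsWith(e$rxns$id, "ENZ__CAT1")), 2L)
  expect_equal(sum(startsWith(e$rxns$id, "ENZ__CAT2")), 1L)
  # only translation reactions are repressible in the extended network
  expect_true(all(startsWith(e$rxns$id[e$rxns$repressible], "TL__")))

  max_flux <- function(net, ko, rxn) {
    maximize(flux_region(net, knockouts = ko), stats::setNames(1, rxn))$value
  }
  # cutting one isozyme leaves CAT1 usable; cutting both disables it
  expect_gt(max_flux(e, "TL__g1", "CAT1"), 1)
  expect_lt(max_flux(e, c("TL__g1", "TL__g2"), "CAT1"), 1e-6)
  # cutting either complex subunit disables CAT2
  expect_lt(max_flux(e, "TL__g3", "CAT2"), 1e-6)
  expect_lt(max_flux(e, "TL__g4", "CAT2"), 1e-6)
})

test_that("gene knockouts project onto exactly the GPR-disabled reactions", {
  fx <- make_toy("TOY3-G")
  ext <- extend_with_genes(fx$net)
  for (genes in list("gA", "gB", c("gA", "gC"))) {
    tl <- ext$extension$translation[genes]
    disabled <- ext$extension$extended_rxns[!vapply(
      ext$extension$trees[ext$extension$extended_rxns], eval_gpr, TRUE,
      off_genes = genes)]
    # extended network with the translations cut == original with the
    # disabled reactions cut, projected on original reaction fluxes
    for (obj in c("EX_P", "EX_W", "BIO")) {
      a <- maximize(flux_region(ext$net, knockouts = unname(tl)),
                    stats::setNames(1, obj))$value
      b <- maximize(flux_region(fx$net, knockouts = disabled),
                    stats::setNames(1, obj))$value
      expect_equal(a, b, tolerance = 1e-6,
                   label = paste(paste(genes, collapse = "+"), obj))
    }
  }
})

test_that("reversible reactions are split so both directions need the enzyme", {
  fx <- make_toy("TOY3")
  net <- fx$net
  j <- which(net$rxns$id == "CAT1")
  net$rxns$lb[j] <- -5
  net$rxns$reversible[j] <- TRUE
  net$rxns$gpr[j] <- "g1"
  ext <- extend_with_genes(net)
  expect_true("CAT1__rev" %in% ext$net$rxns$id)
  expect_equal(ext$net$rxns$lb[ext$net$rxns$id == "CAT1"], 0)
  expect_equal(ext$net$rxns$ub[ext$net$rxns$id == "CAT1__rev"], 5)
  # backward flux is also disabled by the gene knockout
  v <- maximize(flux_region(ext$net, knockouts = "TL__g1"),
                stats::setNames(1, "CAT1__rev"))
  expect_lt(v$value, 1e-6)
})

test_that("gene-level verdicts match reaction-level ones with dedicated genes", {
  fxg <- make_toy("TOY3-G")
  for (lev in c(0.1, 0.5)) {
    vg <- gene_cutsets(fxg$net, fxg$config, "EX_P", lev)
    expect_equal(vg$status, "FEASIBLE")
    expect_equal(vg$cutset, "gB")       # isomorphic to reaction cut {CAT2}
    expect_equal(vg$disabled_reactions, "CAT2")
    expect_true(vg$reaction_level_valid)
  }
  # isozyme pair on CAT2: both genes must go
  fxi <- make_toy("TOY3-GI")
  vi <- gene_cutsets(fxi$net, fxi$config, "EX_P", 0.5)
  expect_equal(vi$status, "FEASIBLE")
  expect_setequal(vi$cutset, c("gB", "gD"))
})

test_that("genes shared with irrepressible reactions are protected", {
  fx <- make_toy("TOY3-G")
  net <- fx$net
  # gB also drives the (irrepressible) maintenance reaction
  net$rxns$gpr[net$rxns$id == "MAINT"] <- "gB"
  ext <- extend_with_genes(net)
  expect_false("TL__gB" %in% ext$net$rxns$id[ext$net$rxns$repressible])
  v <- gene_cutsets(net, fx$config, "EX_P", 0.5)
  expect_equal(v$status, "INFEASIBLE")  # without gB no coupling cut exists
})

test_that("a network without associations has nothing repressible at gene level", {
  fx <- make_toy("TOY3")
  ext <- extend_with_genes(fx$net)
  expect_equal(n_rxns(ext$net), n_rxns(fx$net))
  expect_false(any(ext$net$rxns$repressible))
  v <- gene_cutsets(fx$net, fx$config, "EX_P", 0.5)
  expect_equal(v$status, "INFEASIBLE")
})
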