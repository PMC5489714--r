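# Candidate enumeration and the per-metabolite / whole-model drivers.

test_that("candidate enumeration applies the organic and producibility rules", {
  fx <- make_toy("TOY3")
  cand <- enumerate_candidates(fx$net, fx$config)
  expect_setequal(cand$met_id, c("P", "W"))   # A is the substrate; ATP and
                                              # B carry no carbon formula
  expect_equal(cand$exchange[cand$met_id == "P"], "EX_P")
  expect_false(any(cand$temporary))

  # engineered free-carbon loop: unbounded yield excludes the metabolite
  net <- fx$net
  net$mets <- rbind(net$mets, data.frame(id = "FREE", name = NA,
                                         compartment = "c",
                                         formula = "C2H2",
                                         stringsAsFactors = FALSE))
  net$S <- methods::rbind2(net$S, Matrix::sparseMatrix(
    i = integer(), j = integer(), x = numeric(), dims = c(1L, n_rxns(net))))
  rownames(net$S) <- net$mets$id
  net <- add_reaction(net, "SPRING", c(FREE = 1), lb = 0, ub = Inf)
  cand2 <- enumerate_candidates(net, fx$config)
  expect_false("FREE" %in% cand2$met_id)
})

test_that("compounds with an open outflow are screened only extracellularly", {
  fx <- make_toy("TOY3")
  net <- fx$net
  # cytosolic P has an extracellular twin connected to the open outflow
  net$mets <- rbind(net$mets, data.frame(id = "P_e", name = "product (ext)",
                                         compartment = "e",
                                         formula = "C3H6O3",
                                         stringsAsFactors = FALSE))
  net$S <- methods::rbind2(net$S, Matrix::sparseMatrix(
    i = integer(), j = integer(), x = numeric(), dims = c(1L, n_rxns(net))))
  rownames(net$S) <- net$mets$id
  net <- drop_reactions(net, "EX_P")
  net <- add_reaction(net, "P_TRANS", c(P = -1, P_e = 1))
  net <- add_reaction(net, "EX_P", c(P_e = -1), lb = 0, ub = Inf,
                      is_exchange = TRUE)
  cand <- enumerate_candidates(net, fx$config)
  expect_true("P_e" %in% cand$met_id)
  expect_false("P" %in% cand$met_id)   # same compound, intracellular copy
})

test_that("a temporary export-only exchange is added when none exists", {
  fx <- make_toy("TOY3")
  net <- drop_reactions(fx$net, "EX_W")
  ex <- cmcs:::ensure_product_exchange(net, "W")
  expect_true(ex$temporary)
  expect_equal(ex$net$rxns$lb[ex$net$rxns$id == ex$exchange], 0)  # no uptake
  verdicts <- screen_metabolite(net, fx$config, "W")
  expect_equal(unname(vapply(verdicts, `[[`, "", "status")),
               rep("FEASIBLE", 3))
})

test_that("screening a metabolite reuses lower-level cut sets without new MILPs", {
  fx <- make_toy("TOY3")
  verdicts <- screen_metabolite(fx$net, fx$config, "P",
                                levels = c(0.1, 0.3, 0.5))
  expect_equal(unname(vapply(verdicts, `[[`, "", "status")),
               rep("FEASIBLE", 3))
  expect_equal(unname(vapply(verdicts, function(v)
    paste(v$cutset, collapse = "+"), "")), rep("CAT2", 3))
  expect_false(verdicts[["0.1"]]$reused)
  expect_true(verdicts[["0.3"]]$reused)
  expect_true(verdicts[["0.5"]]$reused)
  expect_equal(verdicts[["0.5"]]$attempts$status, "reused-from-lower-level")

  w <- screen_metabolite(fx$net, fx$config, "W", levels = 0.5)
  expect_equal(w[["0.5"]]$cutset, "CAT1")
})

test_that("whole-model screening summarises verdicts per level", {
  fx <- make_toy("TOY3")
  res <- screen_model(fx$net, fx$config)
  expect_s3_class(res, "screening_result")
  expect_equal(nrow(res$results), 6L)    # 2 candidates x 3 levels
  expect_true(all(res$summary$pct_feasible == 100))
  expect_true(all(abs(res$summary$pct_feasible + res$summary$pct_infeasible +
                        res$summary$pct_undecided - 100) < 1e-9))
  expect_true(all(res$summary$mean_cutset_size == 1))
  expect_true(all(is.na(res$results$cutset_size) |
                    res$results$status == "FEASIBLE"))

  fx1 <- make_toy("TOY1")
  res1 <- screen_model(fx1$net, fx1$config)
  expect_true(all(res1$results$status == "INFEASIBLE"))
  expect_true(all(res1$summary$pct_infeasible == 100))
})

test_that("screening summary fractions equal oracle fractions on a fixture batch", {
  statuses_pipeline <- character()
  statuses_oracle <- character()
  for (seed in 61:70) {
    fx <- random_network(seed)
    p <- build_coupling_problem(fx$net, fx$config, "EX_P", 0.3)
    statuses_oracle <- c(statuses_oracle, brute_force_verdict(p)$status)
    res <- screen_model(fx$net, fx$config, levels = 0.3)
    row <- res$results[res$results$met_id == "P", ]
    statuses_pipeline <- c(statuses_pipeline, row$status)
  }
  expect_equal(statuses_pipeline, statuses_oracle)
})

test_that("reruns with the same seed give identical verdict statuses", {
  fx <- random_network(17)
  r1 <- screen_model(fx$net, fx$config)
  r2 <- screen_model(fx$net, fx$config)
  expect_equal(r1$results$status, r2$results$status)
  expect_equal(r1$results$cutset, r2$results$cutset)
})

test_that("screening an empty candidate list yields an empty result", {
  fx <- make_toy("TOY3")
  net <- fx$net
  net$mets$formula <- NA_character_   # nothing organic any more
  res <- screen_model(net, fx$config)
  expect_equal(nrow(res$results), 0L)
  expect_true(all(res$summary$n_candidates == 0))
  expect_true(all(res$summary$pct_feasible == 0))
})

test_that("results export as TSV with fixed columns", {
  fx <- make_toy("TOY3")
  res <- screen_model(fx$net, fx$config, levels = 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_screening_tsv(res, path)
  tab <- utils::read.delim(path)
  expect_equal(names(tab), c("met_id", "level", "status", "cutset_size",
                             "cutset", "attempts", "reused", "wall_s"))
  expect_equal(nrow(tab), 2L)
})
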