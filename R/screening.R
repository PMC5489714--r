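# Whole-model screening: enumerate the organic, substrate-producible
# candidate metabolites and decide coupling feasibility for each of them at
# each demanded yield level.

# Find an export route for a metabolite, or add a temporary export-only
# exchange. Returns the (possibly modified) network and the exchange id.
#' @keywords internal
ensure_product_exchange <- function(net, met_id) {
  i <- met_index(net, met_id)
  for (j in which(net$rxns$is_exchange)) {
    coef <- net$S[i, j]
    if (coef < 0 && net$rxns$ub[j] > 0)
      return(list(net = net, exchange = net$rxns$id[j], temporary = FALSE))
  }
  ex_id <- paste0("EX__tmp_", met_id)
  net <- add_reaction(net, ex_id, stats::setNames(-1, met_id),
                      lb = 0, ub = Inf, repressible = FALSE,
                      is_exchange = TRUE)
  list(net = net, exchange = ex_id, temporary = TRUE)
}

#' Enumerate candidate metabolites for coupling
#'
#' A metabolite is a candidate when it is organic (carbon-containing
#' formula, not on the inorganic-carbon list) and producible from the
#' substrate (maximum product yield finite and positive), with two
#' exceptions: every compartmental instance of the substrate compound is
#' excluded, and for compounds connected to an open standard outflow only
#' the excreted (extracellular) instance is a candidate.
#'
#' @param net configured `metabolic_network`
#' @param config a `model_config`
#' @return data.frame `met_id`, `exchange`, `temporary`, `max_yield`
#' @export
enumerate_candidates <- function(net, config) {
  organic <- is_organic(net, config)
  keys <- compound_key(net)
  sub_met <- exchange_metabolite(net, config$substrate_exchange_id)
  sub_key <- if (!is.na(sub_met)) keys[met_index(net, sub_met)] else NA
  cand <- which(organic & keys != sub_key)

  # compounds with an open outflow: keep only the excreted instance(s)
  open_ex <- intersect(config$open_outflow_ids, net$rxns$id)
  excreted <- vapply(open_ex, function(ex) exchange_metabolite(net, ex), "")
  excreted <- excreted[!is.na(excreted)]
  excreted_keys <- keys[met_index(net, excreted)]
  drop <- keys[cand] %in% excreted_keys & !(net$mets$id[cand] %in% excreted)
  cand <- cand[!drop]

  rows <- lapply(cand, function(i) {
    ex <- ensure_product_exchange(net, net$mets$id[i])
    my <- max_product_yield(ex$net, ex$exchange, config)
    if (!identical(my$status, "ok")) return(NULL)
    data.frame(met_id = net$mets$id[i], exchange = ex$exchange,
               temporary = ex$temporary, max_yield = my$yield,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(met_id = character(), exchange = character(),
                      temporary = logical(), max_yield = numeric(),
                      stringsAsFactors = FALSE)
  out
}

#' Decide coupling feasibility of one metabolite at several yield levels
#'
#' Levels are processed in ascending order. A cut set found at a lower level
#' is re-verified at the next level and, when still valid, reused without a
#' new MILP search. After all levels, a smaller cut set found at a higher
#' level replaces larger lower-level records (affects reported sizes only;
#' validity at the lower level is implied by threshold monotonicity).
#'
#' @param net configured `metabolic_network`
#' @param config a `model_config`
#' @param met_id candidate metabolite id
#' @param levels yield fractions (defaults to `config$yield_levels`)
#' @return list of `cmcs_verdict` objects named by level, each with extra
#'   fields `level`, `reused`, `wall_s`
#' @export
screen_metabolite <- function(net, config, met_id,
                              levels = config$yield_levels) {
  ex <- ensure_product_exchange(net, met_id)
  levels <- sort(levels)
  out <- list()
  prev_cut <- NULL
  for (lev in levels) {
    t0 <- Sys.time()
    problem <- build_coupling_problem(ex$net, config, ex$exchange, lev)
    reused <- FALSE
    if (!is.null(prev_cut) && applicable_at(problem, prev_cut)) {
      v <- structure(list(status = "FEASIBLE", cutset = prev_cut,
                          alternatives = list(), proven_minimal = FALSE,
                          attempts = data.frame(
                            attempt = 0L, seed = config$rng_seed,
                            status = "reused-from-lower-level", time_s = 0)),
                     class = "cmcs_verdict")
      v$cutset <- reduce_to_cmcs(problem, prev_cut)
      v$proven_minimal <- TRUE
      reused <- TRUE
    } else {
      v <- find_cmcs(problem)
    }
    if (identical(v$status, "FEASIBLE")) prev_cut <- v$cutset
    v$level <- lev
    v$reused <- reused
    v$wall_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out[[as.character(lev)]] <- v
  }
  # cross-level replacement: smaller higher-level cut sets stand in for
  # larger lower-level ones (valid there by threshold monotonicity)
  for (i in seq_along(out)) {
    for (j in seq_along(out)) {
      if (j <= i) next
      vi <- out[[i]]; vj <- out[[j]]
      if (identical(vi$status, "FEASIBLE") && identical(vj$status, "FEASIBLE") &&
          length(vj$cutset) < length(vi$cutset)) {
        out[[i]]$cutset <- vj$cutset
        out[[i]]$replaced_from <- vj$level
      }
    }
  }
  out
}

#' Screen a whole model
#'
#' Runs [screen_metabolite()] for every candidate of
#' [enumerate_candidates()] and summarises, per yield level, the percentage
#' of candidates for which strong coupling is feasible, provably infeasible,
#' or undecided, together with cut-set size statistics. Failures for single
#' metabolites are isolated and reported as UNDECIDED rows.
#'
#' @param net configured `metabolic_network`
#' @param config a `model_config`
#' @param levels yield fractions (defaults to `config$yield_levels`)
#' @return object of class `screening_result`: `results` (one row per
#'   metabolite and level), `summary` (one row per level), `candidates`
#' @export
screen_model <- function(net, config, levels = config$yield_levels) {
  candidates <- enumerate_candidates(net, config)
  rows <- list()
  for (k in seq_len(nrow(candidates))) {
    met <- candidates$met_id[k]
    verdicts <- tryCatch(
      screen_metabolite(net, config, met, levels),
      error = function(e) {
        warning("screening of ", met, " failed: ", conditionMessage(e))
        NULL
      })
    for (lev in as.character(sort(levels))) {
      v <- verdicts[[lev]]
      rows[[length(rows) + 1L]] <- data.frame(
        met_id = met,
        level = as.numeric(lev),
        status = if (is.null(v)) "UNDECIDED" else v$status,
        cutset_size = if (!is.null(v) && identical(v$status, "FEASIBLE"))
          length(v$cutset) else NA_integer_,
        cutset = if (!is.null(v) && identical(v$status, "FEASIBLE"))
          paste(v$cutset, collapse = ";") else NA_character_,
        attempts = if (is.null(v)) 0L else nrow(v$attempts),
        reused = if (is.null(v)) FALSE else isTRUE(v$reused),
        wall_s = if (is.null(v)) NA_real_ else v$wall_s,
        stringsAsFactors = FALSE)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(met_id = character(), level = numeric(), status = character(),
               cutset_size = integer(), cutset = character(),
               attempts = integer(), reused = logical(), wall_s = numeric(),
               stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(sort(levels), function(lev) {
    r <- results[results$level == lev, , drop = FALSE]
    n <- nrow(r)
    sizes <- r$cutset_size[!is.na(r$cutset_size)]
    data.frame(
      level = lev,
      n_candidates = n,
      pct_feasible = if (n) 100 * mean(r$status == "FEASIBLE") else 0,
      pct_infeasible = if (n) 100 * mean(r$status == "INFEASIBLE") else 0,
      pct_undecided = if (n) 100 * mean(r$status == "UNDECIDED") else 0,
      mean_cutset_size = if (length(sizes)) mean(sizes) else NA_real_,
      max_cutset_size = if (length(sizes)) max(sizes) else NA_integer_,
      stringsAsFactors = FALSE)
  }))
  structure(list(results = results, summary = summary,
                 candidates = candidates),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("screening_result:", nrow(x$candidates),
      "candidate metabolites x", length(unique(x$results$level)),
      "yield levels\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write screening results as TSV
#' @param x a `screening_result`
#' @param path output file
#' @return invisibly `path`
#' @export
write_screening_tsv <- function(x, path) {
  utils::write.table(x$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
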