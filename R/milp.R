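# The cut-set MILP. A knockout set K makes the undesired region
#   { r : N r = 0, alpha <= r <= beta, T r <= t, r_i = 0 for i in K }
# empty exactly when a Farkas certificate for its infeasibility exists. The
# MILP searches over knockout indicators z for a certificate of the
# knocked-out undesired region while a primal flux vector survives in the
# knocked-out desired region:
#
#   dual (certificate) part, one stationarity row per reaction i:
#     N_i' u + lam_ub_i - lam_lb_i + T_i' w + vp_i - vn_i = 0
#     beta' lam_ub - alpha' lam_lb + t' w <= -1
#   with u free, lam/w/vp/vn >= 0; vp_i (and vn_i for reversible i) exist
#   only for repressible reactions and are the duals of the knockout
#   constraint r_i <= 0 (resp. r_i >= 0), allowed to be nonzero only when
#   the corresponding binary zp_i (zn_i) is one:  vp_i <= M zp_i.
#
#   primal (desired) part:
#     N r_des = 0,  D r_des <= d,
#     alpha_i (1 - zp_i - zn_i) <= r_des_i <= beta_i (1 - zp_i - zn_i)
#   with the original (flux-cap-truncated) bounds, so a cut reaction carries
#   no desired flux.
#
#   objective: minimize sum(zp) + sum(zn),  zp_i + zn_i <= 1.
#
# The dual side uses the (possibly tightened) flux-variability bounds, which
# must all be finite. Because those bounds were computed with the
# minimum-biomass-yield restriction, candidate solutions can be unsound for
# the true undesired region; every candidate is therefore re-verified with
# plain LPs on the original network before any verdict is FEASIBLE.
# Infeasibility verdicts remain sound: tightening the undesired region only
# strengthens the claim that no certificate-admitting knockout set exists.

#' Assemble the cut-set MILP
#'
#' @param problem a `coupling_problem`
#' @param finite_bounds data.frame `reaction_id`, `min`, `max` from [fva()];
#'   every bound must be finite
#' @return object of class `cmcs_milp` (sparse blocks plus variable maps)
#' @export
assemble_cmcs_milp <- function(problem, finite_bounds) {
  net <- problem$net
  n <- n_rxns(net)
  m <- n_mets(net)
  fb <- finite_bounds[match(net$rxns$id, finite_bounds$reaction_id), ]
  if (any(!is.finite(fb$min)) || any(!is.finite(fb$max)))
    stop("non-finite bounds; run fva() with a flux cap first")
  alpha <- pmin(fb$min, fb$max)
  beta <- pmax(fb$min, fb$max)

  cap <- problem$config$flux_cap
  alpha_d <- pmax(net$rxns$lb, -cap)   # desired side keeps original bounds
  beta_d <- pmin(net$rxns$ub, cap)

  rep_idx <- rxn_index(net, problem$repressible)
  nrep <- length(rep_idx)
  rev_rep <- rep_idx[net$rxns$reversible[rep_idx]]
  nrev <- length(rev_rep)

  Trows <- problem$undesired$rows
  nT <- length(Trows)
  M <- 10 * max(1, max(abs(alpha)), max(abs(beta)),
                max(abs(alpha_d)), max(abs(beta_d)))

  # variable layout
  off <- 0L
  u <- off + seq_len(m); off <- off + m
  lam_lb <- off + seq_len(n); off <- off + n
  lam_ub <- off + seq_len(n); off <- off + n
  w <- off + seq_len(nT); off <- off + nT
  vp <- off + seq_len(nrep); off <- off + nrep
  vn <- if (nrev) off + seq_len(nrev) else integer(); off <- off + nrev
  zp <- off + seq_len(nrep); off <- off + nrep
  zn <- if (nrev) off + seq_len(nrev) else integer(); off <- off + nrev
  r_des <- off + seq_len(n); off <- off + n
  nvar <- off

  lb <- rep(0, nvar); ub <- rep(Inf, nvar)
  lb[u] <- -Inf
  ub[vp] <- M
  if (nrev) ub[vn] <- M
  ub[zp] <- 1
  if (nrev) ub[zn] <- 1
  lb[r_des] <- alpha_d
  ub[r_des] <- beta_d
  integrality <- rep(0L, nvar)
  integrality[c(zp, zn)] <- 1L

  eq <- list(i = integer(), j = integer(), x = numeric(), nrow = 0L,
             rhs = numeric())
  le <- list(i = integer(), j = integer(), x = numeric(), nrow = 0L,
             rhs = numeric())
  add_row <- function(block, j, x, rhs) {
    block$i <- c(block$i, rep(block$nrow + 1L, length(j)))
    block$j <- c(block$j, j)
    block$x <- c(block$x, x)
    block$nrow <- block$nrow + 1L
    block$rhs <- c(block$rhs, rhs)
    block
  }

  Tt <- lapply(Trows, function(row)
    list(j = rxn_index(net, names(row$coef)), x = as.numeric(row$coef),
         rhs = row$rhs))

  # (a) stationarity, one equality per reaction column
  Sm <- net$S
  for (i in seq_len(n)) {
    met_nz <- which(Sm[, i] != 0)
    j <- c(u[met_nz], lam_ub[i], lam_lb[i])
    x <- c(as.numeric(Sm[met_nz, i]), 1, -1)
    for (k in seq_len(nT)) {
      pos <- match(i, Tt[[k]]$j)
      if (!is.na(pos)) { j <- c(j, w[k]); x <- c(x, Tt[[k]]$x[pos]) }
    }
    p <- match(i, rep_idx)
    if (!is.na(p)) { j <- c(j, vp[p]); x <- c(x, 1) }
    q <- match(i, rev_rep)
    if (!is.na(q)) { j <- c(j, vn[q]); x <- c(x, -1) }
    eq <- add_row(eq, j, x, 0)
  }

  # (b) certificate row: beta' lam_ub - alpha' lam_lb + t' w <= -1
  le <- add_row(le,
                c(lam_ub, lam_lb, w),
                c(beta, -alpha, vapply(Tt, `[[`, 0, "rhs")),
                -1)

  # (c) indicator linking and mutual exclusion
  for (p in seq_len(nrep))
    le <- add_row(le, c(vp[p], zp[p]), c(1, -M), 0)
  for (q in seq_len(nrev)) {
    le <- add_row(le, c(vn[q], zn[q]), c(1, -M), 0)
    p <- match(rev_rep[q], rep_idx)
    le <- add_row(le, c(zp[p], zn[q]), c(1, 1), 1)
  }

  # (d) desired-side primal feasibility with knockout linking
  for (r in seq_len(m)) {
    rx_nz <- which(Sm[r, ] != 0)
    eq <- add_row(eq, r_des[rx_nz], as.numeric(Sm[r, rx_nz]), 0)
  }
  for (row in problem$desired$rows) {
    j <- rxn_index(net, names(row$coef))
    sgn <- switch(row$sense, "<=" = 1, ">=" = -1,
                  stop("equality rows unsupported in desired set"))
    le <- add_row(le, r_des[j], sgn * as.numeric(row$coef), sgn * row$rhs)
  }
  for (p in seq_len(nrep)) {
    i <- rep_idx[p]
    q <- match(i, rev_rep)
    zj <- c(zp[p], if (!is.na(q)) zn[q])
    # r_des_i <= beta_d_i (1 - zp - zn)
    le <- add_row(le, c(r_des[i], zj), c(1, rep(beta_d[i], length(zj))),
                  beta_d[i])
    # alpha_d_i (1 - zp - zn) <= r_des_i
    le <- add_row(le, c(r_des[i], zj), c(-1, rep(-alpha_d[i], length(zj))),
                  -alpha_d[i])
  }

  obj <- rep(0, nvar)
  obj[c(zp, zn)] <- 1

  structure(list(
    nvar = nvar, obj = obj, lb = lb, ub = ub, eq = eq, le = le,
    integrality = integrality, M = M,
    rep_ids = net$rxns$id[rep_idx], zp = zp, zn = zn, rev_rep = rev_rep,
    rep_idx = rep_idx,
    counts = list(u = m, lam = 2L * n, w = nT, vp = nrep, vn = nrev,
                  binaries = nrep + nrev, r_des = n)
  ), class = "cmcs_milp")
}

#' @export
print.cmcs_milp <- function(x, ...) {
  cat("cmcs_milp:", x$nvar, "variables,",
    x$counts$binaries, "binaries,", x$eq$nrow, "equalities,",
    x$le$nrow, "inequalities, M =", x$M, "\n")
  invisible(x)
}

#' Run the cut-set MILP once
#'
#' A single solver attempt. The seed permutes the variable order, which
#' changes the solver's exploration of the search tree; the relative gap at
#' which an incumbent is accepted is deliberately large (0.98 by default)
#' because any cut set, optimal or not, proves feasibility of coupling and is
#' minimized afterwards.
#'
#' @param milp a `cmcs_milp`
#' @param time_limit_s wall-clock limit for this attempt, seconds
#' @param seed integer; permutes the variable order
#' @param gap relative MILP gap at which an incumbent is accepted
#' @return list with `status` (`"cutset"`, `"infeasible"` or `"timeout"`)
#'   and, for `"cutset"`, the reaction ids in the z-support (possibly
#'   non-minimal, possibly unsound: must be verified)
#' @export
solve_cmcs_once <- function(milp, time_limit_s = 60, seed = 1L, gap = 0.98) {
  nvar <- milp$nvar
  perm <- withr::with_seed(as.integer(seed) %% .Machine$integer.max,
                           sample.int(nvar))
  inv <- order(perm)
  remap <- function(block) {
    if (is.null(block)) return(NULL)
    block$j <- inv[block$j]
    block
  }
  res <- tryCatch(
    solver_milp(nvar, obj = milp$obj[perm], lb = milp$lb[perm],
                ub = milp$ub[perm], eq = remap(milp$eq), le = remap(milp$le),
                integrality = milp$integrality[perm],
                time_limit = time_limit_s, mip_gap = gap),
    error = function(e) list(status = "error", message = conditionMessage(e)))
  if (identical(res$status, "infeasible"))
    return(list(status = "infeasible"))
  if (res$status %in% c("optimal", "feasible")) {
    x <- as.numeric(unlist(res$x))[inv]
    zval <- x[milp$zp]
    if (length(milp$zn)) {
      p <- match(milp$rev_rep, milp$rep_idx)
      zval[p] <- zval[p] + x[milp$zn]
    }
    cut <- milp$rep_ids[zval > 0.5]
    return(list(status = "cutset", cutset = cut,
                objective = sum(round(zval)),
                proven_optimal = identical(res$status, "optimal")))
  }
  # solver crash or timeout counts as a failed attempt
  list(status = "timeout")
}

#' Find a constrained minimal cut set
#'
#' The full per-product decision procedure: wild-type sanity checks, optional
#' network compression, flux variability analysis with the minimum
#' biomass-yield restriction (infeasible FVA already refutes coupling), the
#' cut-set MILP with up to `milp_retries` seeded attempts, LP verification of
#' every candidate on the original uncompressed network, and iterative
#' reduction to an inclusion-minimal cut set.
#'
#' @param problem a `coupling_problem`
#' @param compress_network merge fully coupled sets before the MILP
#'   (candidates are expanded and verified on the original network)
#' @return object of class `cmcs_verdict`: `status` (`"FEASIBLE"`,
#'   `"INFEASIBLE"` or `"UNDECIDED"`), `cutset` (FEASIBLE only),
#'   `alternatives` (interchangeable members of merged sets),
#'   `proven_minimal`, and `attempts` (data.frame log)
#' @export
find_cmcs <- function(problem, compress_network = TRUE) {
  config <- problem$config
  attempts <- data.frame(attempt = integer(), seed = integer(),
                         status = character(), time_s = numeric(),
                         stringsAsFactors = FALSE)
  log_attempt <- function(a, seed, status, t0) {
    attempts[nrow(attempts) + 1L, ] <<-
      list(a, as.integer(seed), status,
           as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  verdict <- function(status, cutset = NULL, alternatives = list(),
                      proven_minimal = FALSE) {
    structure(list(status = status, cutset = cutset,
                   alternatives = alternatives,
                   proven_minimal = proven_minimal, attempts = attempts),
              class = "cmcs_verdict")
  }

  sane <- wildtype_sanity(problem)
  if (!sane$desired_feasible) {
    log_attempt(0L, config$rng_seed, "wildtype-desired-infeasible", Sys.time())
    return(verdict("INFEASIBLE"))
  }
  if (!sane$undesired_feasible) {
    log_attempt(0L, config$rng_seed, "wildtype-already-coupled", Sys.time())
    return(verdict("FEASIBLE", cutset = character(), proven_minimal = TRUE))
  }

  if (compress_network) {
    comp <- compress(problem$net)
    cprob <- translate_problem(problem, comp$net, comp$map)
  } else {
    comp <- NULL
    cprob <- problem
  }

  # FVA bounds with the minimum biomass yield restriction (desired row 2)
  bio_row <- constraint_set(cprob$desired$rows[2])
  fv <- fva(flux_region(cprob$net, extra = bio_row), config$flux_cap)
  if (identical(fv$status, "infeasible")) {
    log_attempt(0L, config$rng_seed, "fva-infeasible", Sys.time())
    return(verdict("INFEASIBLE"))
  }

  milp <- assemble_cmcs_milp(cprob, fv$table)
  for (a in seq_len(config$milp_retries)) {
    seed <- config$rng_seed + a - 1L
    t0 <- Sys.time()
    res <- solve_cmcs_once(milp, time_limit_s = config$milp_time_limit_s,
                           seed = seed, gap = config$milp_gap)
    if (identical(res$status, "infeasible")) {
      log_attempt(a, seed, "proven-infeasible", t0)
      return(verdict("INFEASIBLE"))
    }
    if (identical(res$status, "cutset")) {
      if (!is.null(comp)) {
        ex <- expand_cutset(comp$map, res$cutset)
        cand <- ex$cutset
        alts <- ex$alternatives
      } else {
        cand <- res$cutset
        alts <- stats::setNames(as.list(cand), cand)
      }
      v <- verify_cutset(problem, cand)
      if (v$valid) {
        log_attempt(a, seed, "cutset-verified", t0)
        red <- reduce_to_cmcs(problem, cand)
        return(verdict("FEASIBLE", cutset = red,
                       alternatives = alts[names(alts) %in% red],
                       proven_minimal = TRUE))
      }
      log_attempt(a, seed, "cutset-failed-verification", t0)
    } else {
      log_attempt(a, seed, res$status, t0)
    }
  }
  verdict("UNDECIDED")
}

#' @export
print.cmcs_verdict <- function(x, ...) {
  cat("cmcs_verdict:", x$status)
  if (identical(x$status, "FEASIBLE"))
    cat(" | cMCS {", paste(x$cutset, collapse = ", "), "}",
        if (x$proven_minimal) "(inclusion-minimal)")
  cat("\n attempts:", nrow(x$attempts),
      paste0("[", paste(x$attempts$status, collapse = ", "), "]"), "\n")
  invisible(x)
}
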