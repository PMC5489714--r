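# Plain-LP verification of candidate cut sets and reduction to true
# constrained minimal cut sets. Verification always runs on the original
# network with its original (possibly infinite) bounds and no big-M, so it
# is immune to any unsoundness of the MILP relaxation.

#' Verify a candidate cut set
#'
#' Two LP feasibility checks on the original network under the knockouts:
#' coupling is achieved iff the undesired region becomes infeasible while
#' the desired region stays feasible.
#'
#' @param problem a `coupling_problem`
#' @param cutset character vector of reaction ids, all repressible
#' @return list with `valid`, `undesired_feasible`, `desired_feasible`
#' @export
verify_cutset <- function(problem, cutset) {
  bad <- setdiff(cutset, problem$repressible)
  if (length(bad))
    stop("cut set contains irrepressible reaction(s): ",
         paste(bad, collapse = ", "))
  u <- check_region_feasible(undesired_region(problem, cutset))$feasible
  d <- check_region_feasible(desired_region(problem, cutset))$feasible
  list(valid = !u && d, undesired_feasible = u, desired_feasible = d)
}

#' Reduce a valid cut set to a constrained minimal cut set
#'
#' Iteratively tests the necessity of each knockout: a knockout is dropped
#' when the undesired region stays infeasible without it. Desired-region
#' feasibility is monotone under removing knockouts, so only the
#' undesired-infeasibility LP is needed per candidate removal; a final full
#' verification guards the result. Knockouts are visited in descending
#' network order; other orders may yield different, equally valid minimal
#' sets.
#'
#' @param problem a `coupling_problem`
#' @param cutset a valid cut set (see [verify_cutset()])
#' @return inclusion-minimal valid cut set (character vector)
#' @export
reduce_to_cmcs <- function(problem, cutset) {
  v <- verify_cutset(problem, cutset)
  if (!v$valid)
    stop("reduce_to_cmcs requires a valid cut set (undesired feasible: ",
         v$undesired_feasible, ", desired feasible: ", v$desired_feasible, ")")
  keep <- cutset[order(rxn_index(problem$net, cutset), decreasing = TRUE)]
  for (j in seq_along(keep)) {
    cand <- keep[!is.na(keep) & keep != keep[j]]
    if (is.na(keep[j])) next
    u <- check_region_feasible(undesired_region(problem, cand))$feasible
    if (!u) keep[j] <- NA
  }
  out <- keep[!is.na(keep)]
  stopifnot(verify_cutset(problem, out)$valid)
  out[order(rxn_index(problem$net, out))]
}

#' Shrink a cut set towards the smallest cMCS
#'
#' Restarts the MILP with the incumbent fixed to the given cut set and
#' continues minimizing the number of knockouts for up to `budget_s`
#' seconds. With a zero budget the input is returned unchanged. The
#' incumbent warm start is emulated by restricting the binary support to
#' improve on `|cutset|` (an upper-bound constraint on the objective).
#'
#' @param problem a `coupling_problem`
#' @param cutset a valid cut set
#' @param budget_s time budget in seconds
#' @return list with `cutset` (smaller or equal valid cMCS) and
#'   `proven_optimal` (solver closed the gap)
#' @export
shrink_cmcs <- function(problem, cutset, budget_s = 60) {
  stopifnot(verify_cutset(problem, cutset)$valid)
  if (budget_s <= 0)
    return(list(cutset = cutset, proven_optimal = FALSE))
  best <- reduce_to_cmcs(problem, cutset)
  config <- problem$config
  bio_row <- constraint_set(problem$desired$rows[2])
  fv <- fva(flux_region(problem$net, extra = bio_row), config$flux_cap)
  if (identical(fv$status, "infeasible"))
    return(list(cutset = best, proven_optimal = FALSE))
  milp <- assemble_cmcs_milp(problem, fv$table)
  # demand strictly fewer cuts than the incumbent, solve to optimality
  milp$le <- local({
    le <- milp$le
    zj <- c(milp$zp, milp$zn)
    le$i <- c(le$i, rep(le$nrow + 1L, length(zj)))
    le$j <- c(le$j, zj)
    le$x <- c(le$x, rep(1, length(zj)))
    le$nrow <- le$nrow + 1L
    le$rhs <- c(le$rhs, length(best) - 1)
    le
  })
  proven_optimal <- FALSE
  deadline <- Sys.time() + budget_s
  repeat {
    left <- as.numeric(difftime(deadline, Sys.time(), units = "secs"))
    if (left <= 0) break
    res <- solve_cmcs_once(milp, time_limit_s = left, seed = config$rng_seed,
                           gap = 1e-4)
    if (identical(res$status, "infeasible")) {
      # nothing smaller admits a certificate: incumbent size is optimal
      proven_optimal <- TRUE
      break
    }
    if (!identical(res$status, "cutset")) break
    v <- verify_cutset(problem, res$cutset)
    if (v$valid && length(res$cutset) < length(best)) {
      best <- reduce_to_cmcs(problem, res$cutset)
      milp$le$rhs[milp$le$nrow] <- length(best) - 1
      if (res$proven_optimal) { proven_optimal <- TRUE; break }
    } else {
      break  # unsound or non-improving candidate; stop shrinking
    }
  }
  list(cutset = best, proven_optimal = proven_optimal)
}

#' Is a cut set found at one yield level applicable at another?
#'
#' Cut sets found for a lower minimum product yield are re-verified before
#' being reused at a higher level; when valid, the expensive MILP search is
#' skipped for that level.
#'
#' @param problem a `coupling_problem` (the new level)
#' @param cutset a cut set found at another level
#' @return logical
#' @export
applicable_at <- function(problem, cutset) {
  verify_cutset(problem, cutset)$valid
}
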