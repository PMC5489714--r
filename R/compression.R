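# Lossless network reduction before the MILP: drop linearly dependent mass
# balance rows (conservation relations), prune blocked reactions, and merge
# sets of fully coupled reactions, with an exact mapping back to the
# original network so that cut sets can be expanded and re-verified there.

KERNEL_TOL <- 1e-9

#' Remove conservation relations
#'
#' Drops metabolite rows of the stoichiometric matrix that are linear
#' combinations of the others. The steady-state flux solution set is
#' unchanged because dependent equality rows are redundant.
#'
#' @param net a `metabolic_network`
#' @return list with `net` (row-reduced network) and `dropped` (metabolite
#'   ids of the removed rows)
#' @export
remove_conservation_relations <- function(net) {
  A <- t(as.matrix(net$S))              # n x m, columns = metabolite rows
  d <- qr(A)
  if (d$rank == n_mets(net))
    return(list(net = net, dropped = character()))
  keep <- sort(d$pivot[seq_len(d$rank)])
  dropped <- net$mets$id[-keep]
  net$S <- net$S[keep, , drop = FALSE]
  net$mets <- net$mets[keep, , drop = FALSE]
  rownames(net$mets) <- NULL
  list(net = net, dropped = dropped)
}

# Kernel basis of the stoichiometric matrix (columns span {v : S v = 0}).
#' @keywords internal
kernel_basis <- function(S) {
  A <- as.matrix(S)
  n <- ncol(A)
  sv <- svd(rbind(A, matrix(0, max(0, n - nrow(A)), n)), nu = 0)
  rank <- sum(sv$d > max(dim(A)) * max(sv$d, 1e-12) * 1e-12)
  if (rank == n) return(matrix(0, n, 0))
  sv$v[, seq.int(rank + 1L, n), drop = FALSE]
}

#' Partition reactions into fully coupled sets
#'
#' Reactions i and j are fully coupled when every steady-state flux vector
#' satisfies `r_i = c * r_j` for a fixed nonzero `c` -- i.e. their rows of a
#' kernel basis of the stoichiometric matrix are proportional. Bounds are
#' deliberately ignored (bound-aware coupling is condition-dependent;
#' kernel coupling is the safe lossless criterion). Blocked reactions (zero
#' kernel row: no steady-state flux ever) each form their own group.
#'
#' @param net a `metabolic_network`
#' @return data.frame with columns `member_id`, `group` (integer label),
#'   `scale` (flux of member per unit flux of the group representative) and
#'   `blocked`
#' @export
fully_coupled_sets <- function(net) {
  K <- kernel_basis(net$S)
  n <- n_rxns(net)
  scale_ref <- apply(abs(K), 1, max)
  blocked <- scale_ref <= KERNEL_TOL
  group <- integer(n)
  scale <- rep(1, n)
  g <- 0L
  for (i in seq_len(n)) {
    if (group[i]) next
    g <- g + 1L
    group[i] <- g
    if (blocked[i]) next
    for (j in seq_len(n)) {
      if (group[j] || blocked[j]) next
      # proportional rows: all 2x2 minors of rbind(K_i, K_j) vanish
      cross <- outer(K[i, ], K[j, ]) - outer(K[j, ], K[i, ])
      if (max(abs(cross)) <= KERNEL_TOL * max(scale_ref[i] * scale_ref[j], 1)) {
        p <- which.max(abs(K[i, ]))
        group[j] <- g
        scale[j] <- K[j, p] / K[i, p]
      }
    }
  }
  data.frame(member_id = net$rxns$id, group = group, scale = scale,
             blocked = blocked, stringsAsFactors = FALSE)
}

#' Compress a network
#'
#' Prunes blocked reactions, removes conservation relations and merges each
#' fully coupled reaction set into a single compressed reaction whose column
#' is the scale-weighted sum of the member columns. Member bounds are
#' intersected after scaling. A compressed reaction is repressible when at
#' least one member is repressible; cutting any single member of a fully
#' coupled set already forces the whole set to zero flux, so expansion picks
#' one repressible member.
#'
#' @param net a `metabolic_network`
#' @return list with `net` (compressed network) and `map` (a
#'   `compression_map`: data.frame `group_id`, `member_id`, `scale`,
#'   `repressible`, `blocked`, plus attribute `dropped_metabolites`)
#' @export
compress <- function(net) {
  original <- net
  cons <- remove_conservation_relations(net)
  net <- cons$net
  fc <- fully_coupled_sets(net)

  groups <- split(seq_len(n_rxns(net)), fc$group)
  keep_groups <- Filter(function(idx) !fc$blocked[idx[1]], groups)
  cols <- vector("list", length(keep_groups))
  rx <- data.frame(id = character(), lb = numeric(), ub = numeric(),
                   reversible = logical(), repressible = logical(),
                   gpr = character(), is_exchange = logical(),
                   stringsAsFactors = FALSE)
  for (k in seq_along(keep_groups)) {
    idx <- keep_groups[[k]]
    sc <- fc$scale[idx]
    col <- as.matrix(net$S[, idx, drop = FALSE]) %*% sc
    lb <- -Inf; ub <- Inf
    for (q in seq_along(idx)) {
      b <- c(net$rxns$lb[idx[q]], net$rxns$ub[idx[q]]) / sc[q]
      if (sc[q] < 0) b <- rev(b)
      lb <- max(lb, b[1]); ub <- min(ub, b[2])
    }
    if (lb > ub + 1e-9)
      stop("contradictory member bounds while merging coupled set {",
           paste(net$rxns$id[idx], collapse = ", "), "}")
    cols[[k]] <- col
    rx <- rbind(rx, data.frame(
      id = net$rxns$id[idx[1]], lb = lb, ub = ub,
      reversible = lb < 0,
      repressible = any(net$rxns$repressible[idx]),
      gpr = NA_character_,
      is_exchange = any(net$rxns$is_exchange[idx]),
      stringsAsFactors = FALSE))
  }
  Sc <- do.call(cbind, cols)
  # metabolites internal to merged chains now have all-zero rows; drop them
  rowmax <- apply(abs(Sc), 1, max)
  keep_m <- rowmax > KERNEL_TOL
  mets <- net$mets[keep_m, , drop = FALSE]
  rownames(mets) <- NULL
  cnet <- metabolic_network(mets, rx, Sc[keep_m, , drop = FALSE])

  map <- data.frame(
    group_id = net$rxns$id[vapply(fc$group, function(g) groups[[g]][1], 1L)],
    member_id = fc$member_id,
    scale = fc$scale,
    repressible = net$rxns$repressible,
    blocked = fc$blocked[vapply(fc$group, function(g) groups[[g]][1], 1L)],
    stringsAsFactors = FALSE)
  attr(map, "dropped_metabolites") <-
    c(cons$dropped, net$mets$id[!keep_m])
  class(map) <- c("compression_map", "data.frame")
  list(net = cnet, map = map)
}

#' Expand a compressed cut set to the original network
#'
#' Each compressed cut is replaced by one repressible member of its fully
#' coupled set (the first in network order); the remaining repressible
#' members are reported as interchangeable alternatives.
#'
#' @param map a `compression_map` from [compress()]
#' @param cut character vector of compressed reaction ids
#' @return list with `cutset` (original reaction ids) and `alternatives`
#'   (named list: per cut, all interchangeable members)
#' @export
expand_cutset <- function(map, cut) {
  cutset <- character()
  alternatives <- list()
  for (g in cut) {
    members <- map$member_id[map$group_id == g & map$repressible]
    if (!length(members))
      stop("compressed cut ", g, " has no repressible member")
    cutset <- c(cutset, members[1])
    alternatives[[members[1]]] <- members
  }
  list(cutset = cutset, alternatives = alternatives)
}

# Translate a coupling problem onto a compressed network: constraint-row
# coefficients move to the member's group, weighted by the member's scale.
#' @keywords internal
translate_problem <- function(problem, cnet, map) {
  move_rows <- function(cs) {
    rows <- lapply(cs$rows, function(row) {
      coef <- stats::setNames(numeric(0), character(0))
      for (rid in names(row$coef)) {
        hit <- match(rid, map$member_id)
        if (map$blocked[hit]) next  # blocked member: zero flux, drop term
        g <- map$group_id[hit]
        coef[g] <- (if (g %in% names(coef)) coef[[g]] else 0) +
          row$coef[[rid]] * map$scale[hit]
      }
      list(coef = coef, sense = row$sense, rhs = row$rhs)
    })
    constraint_set(rows)
  }
  out <- problem
  out$net <- cnet
  out$undesired <- move_rows(problem$undesired)
  out$desired <- move_rows(problem$desired)
  out$repressible <- cnet$rxns$id[cnet$rxns$repressible]
  out
}

#' Export a compression map as TSV
#' @param map a `compression_map`
#' @param path output file
#' @return invisibly `path`
#' @export
write_compression_tsv <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
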