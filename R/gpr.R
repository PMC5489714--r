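# Gene-protein-reaction logic. Gene associations are Boolean and/or
# expressions over gene ids. For gene-level cut sets the association is
# compiled into network structure: each catalysed reaction consumes an
# auxiliary "catalysis" metabolite produced by one enzyme pseudo-reaction
# per DNF term; enzymes consume gene-product metabolites made by translation
# pseudo-reactions (which consume nothing). Only translation reactions may
# then be knocked out.

#' Parse a gene association expression
#'
#' Standard and/or grammar with parentheses; `and` binds tighter than `or`.
#'
#' @param text gene association text, e.g. `"g1 or (g2 and g3)"`
#' @return parse tree: nested lists with `type` `"gene"`, `"and"` or `"or"`
#' @export
parse_gpr <- function(text) {
  tokens <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  fail <- function(msg) stop("gene association parse error at token ", pos,
                             " ('", peek(), "'): ", msg)
  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1]] else list(type = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1L) args[[1]] else list(type = "and", args = args)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) fail("unexpected end of expression")
    if (t == "(") {
      take()
      e <- parse_or()
      if (!identical(peek(), ")")) fail("expected ')'")
      take()
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) fail("expected gene id")
    take()
    list(type = "gene", id = t)
  }
  out <- parse_or()
  if (!is.na(peek())) fail("trailing input")
  out
}

#' Serialize a gene association parse tree
#' @param expr a tree from [parse_gpr()]
#' @return character, reparsing which gives the same tree
#' @export
deparse_gpr <- function(expr) {
  if (expr$type == "gene") return(expr$id)
  parts <- vapply(expr$args, function(a) {
    s <- deparse_gpr(a)
    if (a$type != "gene" && a$type != expr$type && expr$type == "and")
      s <- paste0("(", s, ")")
    else if (a$type == "or" && expr$type == "and") s <- paste0("(", s, ")")
    s
  }, "")
  paste(parts, collapse = paste0(" ", expr$type, " "))
}

#' Genes occurring in a gene association
#' @param expr a tree from [parse_gpr()]
#' @return character vector of gene ids
#' @export
gpr_genes <- function(expr) {
  if (expr$type == "gene") return(expr$id)
  unique(unlist(lapply(expr$args, gpr_genes)))
}

#' Convert a gene association to disjunctive normal form
#'
#' Distributes `and` over `or`; each resulting term is one enzyme (a gene
#' set whose joint presence suffices to catalyse the reaction). Absorbed
#' (superset) terms are removed.
#'
#' @param expr a tree from [parse_gpr()]
#' @param term_cap abort when the expansion exceeds this many terms
#' @return list of character vectors (gene sets)
#' @export
gpr_to_dnf <- function(expr, term_cap = 64L) {
  rec <- function(e) {
    if (e$type == "gene") return(list(e$id))
    if (e$type == "or") {
      out <- unlist(lapply(e$args, rec), recursive = FALSE)
      if (length(out) > term_cap) stop("DNF term cap exceeded")
      return(out)
    }
    terms <- list(character())
    for (a in e$args) {
      sub <- rec(a)
      terms <- unlist(lapply(terms, function(t)
        lapply(sub, function(s) unique(c(t, s)))), recursive = FALSE)
      if (length(terms) > term_cap) stop("DNF term cap exceeded")
    }
    terms
  }
  terms <- unique(lapply(rec(expr), sort))
  # absorption: drop terms that contain another term
  keep <- vapply(seq_along(terms), function(i) {
    !any(vapply(seq_along(terms), function(j)
      j != i && length(terms[[j]]) < length(terms[[i]]) &&
        all(terms[[j]] %in% terms[[i]]), TRUE))
  }, TRUE)
  terms[keep]
}

#' Evaluate a gene association under gene knockouts
#' @param expr a tree from [parse_gpr()]
#' @param off_genes gene ids knocked out (FALSE); all others TRUE
#' @return logical: can the reaction still be catalysed
#' @export
eval_gpr <- function(expr, off_genes) {
  if (expr$type == "gene") return(!(expr$id %in% off_genes))
  vals <- vapply(expr$args, eval_gpr, TRUE, off_genes = off_genes)
  if (expr$type == "and") all(vals) else any(vals)
}

#' Extend a network with gene-protein-reaction structure
#'
#' Every reaction with a parseable gene association gains an auxiliary
#' catalysis metabolite `X__<rxn>` consumed at unit stoichiometry per unit
#' flux; reversible associated reactions are first split into forward and
#' backward irreversible halves sharing the auxiliary metabolite (otherwise
#' backward flux would produce it). One enzyme pseudo-reaction per DNF term
#' produces the auxiliary metabolite and consumes the gene-product
#' metabolites `G__<gene>`, each made by a translation pseudo-reaction
#' `TL__<gene>` from nothing. In the extended network only translation
#' reactions are repressible, and only for genes whose associations touch
#' exclusively repressible reactions: a gene occurring in the association of
#' any irrepressible (or unextended) reaction must not be knocked out.
#'
#' @param net configured `metabolic_network`
#' @param term_cap maximal DNF terms per reaction; beyond it the reaction is
#'   left unextended (irrepressible at gene level) with a warning
#' @return list with `net` (extended network) and `extension` (gene map:
#'   `genes`, `translation` named by gene, `extended_rxns`, `dnf`, `split`)
#' @export
extend_with_genes <- function(net, term_cap = 64L) {
  has_gpr <- !is.na(net$rxns$gpr) & nzchar(net$rxns$gpr)
  trees <- list()
  dnfs <- list()
  capped <- character()
  for (id in net$rxns$id[has_gpr]) {
    tree <- parse_gpr(net$rxns$gpr[net$rxns$id == id])
    dnf <- tryCatch(gpr_to_dnf(tree, term_cap), error = function(e) NULL)
    if (is.null(dnf)) {
      warning("gene association of ", id, " exceeds ", term_cap,
              " DNF terms; reaction left unextended (gene-irrepressible)")
      capped <- c(capped, id)
      next
    }
    trees[[id]] <- tree
    dnfs[[id]] <- dnf
  }
  extended <- names(dnfs)

  # genes that touch an irrepressible or unextended reaction are protected
  all_genes <- unique(unlist(lapply(trees, gpr_genes)))
  protected <- character()
  for (id in net$rxns$id[has_gpr]) {
    rep_ok <- net$rxns$repressible[net$rxns$id == id] && !(id %in% capped)
    if (!rep_ok)
      protected <- union(protected, gpr_genes(parse_gpr(
        net$rxns$gpr[net$rxns$id == id])))
  }

  ext <- net
  ext$rxns$repressible <- FALSE
  split_map <- list()
  for (id in extended) {
    j <- rxn_index(ext, id)
    aux <- paste0("X__", id)
    ext$mets <- rbind(ext$mets, data.frame(
      id = aux, name = paste("catalysis of", id), compartment = NA_character_,
      formula = NA_character_, stringsAsFactors = FALSE))
    ext$S <- methods::rbind2(ext$S, Matrix::sparseMatrix(
      i = integer(), j = integer(), x = numeric(), dims = c(1L, n_rxns(ext))))
    rownames(ext$S) <- ext$mets$id
    if (ext$rxns$reversible[j] && ext$rxns$lb[j] < 0) {
      rev_id <- paste0(id, "__rev")
      nz <- which(ext$S[, j] != 0)
      stoich <- stats::setNames(-as.numeric(ext$S[nz, j]), ext$mets$id[nz])
      stoich[aux] <- -1  # both halves consume the catalysis metabolite
      ext <- add_reaction(ext, rev_id, stoich, lb = 0,
                          ub = -ext$rxns$lb[j], repressible = FALSE)
      split_map[[id]] <- rev_id
      ext$rxns$lb[j] <- 0
      ext$rxns$reversible[j] <- FALSE
    }
    ext$S[aux, j] <- -1
    for (t in seq_along(dnfs[[id]])) {
      term <- dnfs[[id]][[t]]
      stoich <- stats::setNames(c(1, rep(-1, length(term))),
                                c(aux, paste0("G__", term)))
      for (g in term) {
        gm <- paste0("G__", g)
        if (!(gm %in% ext$mets$id)) {
          ext$mets <- rbind(ext$mets, data.frame(
            id = gm, name = paste("gene product", g),
            compartment = NA_character_, formula = NA_character_,
            stringsAsFactors = FALSE))
          ext$S <- methods::rbind2(ext$S, Matrix::sparseMatrix(
            i = integer(), j = integer(), x = numeric(),
            dims = c(1L, n_rxns(ext))))
          rownames(ext$S) <- ext$mets$id
        }
      }
      ext <- add_reaction(ext, paste0("ENZ__", id, "__", t), stoich,
                          lb = 0, ub = Inf, repressible = FALSE)
    }
  }
  translation <- stats::setNames(paste0("TL__", all_genes), all_genes)
  for (g in all_genes) {
    gm <- paste0("G__", g)
    if (!(gm %in% ext$mets$id)) next  # gene only in capped reactions
    ext <- add_reaction(ext, translation[[g]], stats::setNames(1, gm),
                        lb = 0, ub = Inf,
                        repressible = !(g %in% protected))
  }
  translation <- translation[paste0("G__", names(translation)) %in% ext$mets$id]

  list(net = ext,
       extension = list(genes = names(translation),
                        translation = translation,
                        protected = protected,
                        extended_rxns = extended,
                        capped = capped,
                        dnf = dnfs, trees = trees, split = split_map))
}

#' Gene-level cut sets for growth coupling
#'
#' Builds the coupling problem on the gene-extended network, where only
#' translation pseudo-reactions are repressible, runs the full cut-set
#' search, and maps the verdict back to gene ids. The implied
#' reaction-disablement pattern (reactions whose association evaluates to
#' FALSE under the gene knockouts) is cross-verified on the reaction-level
#' problem.
#'
#' @param net configured `metabolic_network` with gene associations
#' @param config a `model_config`
#' @param product_exchange id of the product export reaction
#' @param yield_fraction demanded fraction of the maximum product yield
#' @param term_cap see [extend_with_genes()]
#' @return a `cmcs_verdict` whose `cutset` contains gene ids, with extra
#'   fields `disabled_reactions` and `reaction_level_valid`
#' @export
gene_cutsets <- function(net, config, product_exchange, yield_fraction,
                         term_cap = 64L) {
  ext <- extend_with_genes(net, term_cap)
  problem <- build_coupling_problem(ext$net, config, product_exchange,
                                    yield_fraction)
  v <- find_cmcs(problem)
  if (!identical(v$status, "FEASIBLE")) return(v)
  genes <- names(ext$extension$translation)[
    match(v$cutset, ext$extension$translation)]
  v$cutset <- genes
  v$alternatives <- NULL
  disabled <- ext$extension$extended_rxns[!vapply(
    ext$extension$trees[ext$extension$extended_rxns],
    eval_gpr, TRUE, off_genes = genes)]
  v$disabled_reactions <- disabled
  rxn_problem <- build_coupling_problem(net, config, product_exchange,
                                        yield_fraction)
  v$reaction_level_valid <- verify_cutset(rxn_problem, disabled)$valid
  v
}
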