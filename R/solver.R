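# Bridge to the persistent Python/SciPy HiGHS worker. All LPs and MILPs in
# the package go through solver_lp(), solver_lp_batch(), solver_fva() and
# solver_milp(). The worker lives for the whole R session; one JSON request
# per line in, one JSON response per line out.

.cmcs_state <- new.env(parent = emptyenv())

.worker_script <- function() {
  path <- system.file("python", "lp_worker.py", package = "cmcs")
  if (!nzchar(path)) stop("lp_worker.py not found; is the package installed?")
  path
}

.python_bin <- function() {
  bin <- getOption("cmcs.python", Sys.getenv("CMCS_PYTHON", "python"))
  full <- Sys.which(bin)
  if (!nzchar(full)) stop("python interpreter '", bin, "' not found on PATH")
  full
}

.worker_start <- function() {
  p <- processx::process$new(.python_bin(), c("-u", .worker_script()),
                             stdin = "|", stdout = "|", stderr = "|")
  if (!p$is_alive()) stop("failed to start LP worker process")
  .cmcs_state$worker <- p
  p
}

.worker <- function() {
  p <- .cmcs_state$worker
  if (is.null(p) || !p$is_alive()) p <- .worker_start()
  p
}

#' Shut down the background solver process
#'
#' The worker is started lazily on first use and normally lives until the R
#' session ends; calling this is only needed to force a restart.
#' @return invisibly `TRUE`
#' @export
solver_shutdown <- function() {
  p <- .cmcs_state$worker
  if (!is.null(p) && p$is_alive()) {
    try(p$write_input('{"op":"quit"}\n'), silent = TRUE)
    p$wait(500)
    if (p$is_alive()) p$kill()
  }
  .cmcs_state$worker <- NULL
  invisible(TRUE)
}

# Encode +-Inf as strings: JSON has no infinity literal.
.enc_num <- function(v) {
  out <- as.list(v)
  out[v == Inf] <- "inf"
  out[v == -Inf] <- "-inf"
  out
}

.dec_num <- function(v) {
  if (is.numeric(v)) return(v)
  vapply(v, function(x) {
    if (identical(x, "inf")) Inf else if (identical(x, "-inf")) -Inf else as.numeric(x)
  }, numeric(1))
}

# Sparse constraint block in 0-based triplet form.
.enc_block <- function(block) {
  if (is.null(block) || block$nrow == 0L) return(NULL)
  list(i = as.integer(block$i - 1L), j = as.integer(block$j - 1L),
       x = block$x, nrow = block$nrow, rhs = .enc_num(block$rhs))
}

.solver_rpc <- function(req, timeout_ms = 600000) {
  p <- .worker()
  line <- jsonlite::toJSON(req, auto_unbox = TRUE, digits = NA, null = "null")
  p$write_input(paste0(line, "\n"))
  t0 <- Sys.time()
  repeat {
    ln <- p$read_output_lines(n = 1)
    if (length(ln) == 1L && nzchar(ln)) break
    if (!p$is_alive()) {
      err <- paste(p$read_error_lines(), collapse = "\n")
      .cmcs_state$worker <- NULL
      stop("LP worker died: ", err)
    }
    if (as.numeric(difftime(Sys.time(), t0, units = "secs")) * 1000 > timeout_ms)
      stop("LP worker timed out")
    p$poll_io(200)
  }
  res <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
  if (identical(res$status, "error"))
    stop("solver failure: ", res$message)
  res
}

#' @keywords internal
solver_lp <- function(n, obj = NULL, lb, ub, eq = NULL, le = NULL, want_x = FALSE) {
  req <- list(op = "lp", n = n, obj = obj, lb = .enc_num(lb), ub = .enc_num(ub),
              eq = .enc_block(eq), le = .enc_block(le), want_x = want_x)
  .solver_rpc(req)
}

#' @keywords internal
solver_lp_batch <- function(n, lb, ub, eq = NULL, le = NULL, scenarios,
                            want_x = FALSE) {
  sc <- lapply(scenarios, function(s) {
    out <- list()
    if (length(s$lb_idx)) {
      out$lb_idx <- as.integer(s$lb_idx - 1L)
      out$lb_val <- .enc_num(s$lb_val)
    }
    if (length(s$ub_idx)) {
      out$ub_idx <- as.integer(s$ub_idx - 1L)
      out$ub_val <- .enc_num(s$ub_val)
    }
    if (!is.null(s$obj)) out$obj <- s$obj
    out
  })
  req <- list(op = "lp_batch", n = n, lb = .enc_num(lb), ub = .enc_num(ub),
              eq = .enc_block(eq), le = .enc_block(le), scenarios = sc,
              want_x = want_x)
  res <- .solver_rpc(req)
  res$results
}

#' @keywords internal
solver_fva_call <- function(n, lb, ub, eq = NULL, le = NULL, cols) {
  req <- list(op = "fva", n = n, lb = .enc_num(lb), ub = .enc_num(ub),
              eq = .enc_block(eq), le = .enc_block(le),
              cols = as.integer(cols - 1L))
  .solver_rpc(req)
}

#' @keywords internal
solver_milp <- function(n, obj, lb, ub, eq = NULL, le = NULL, integrality,
                        time_limit = NULL, mip_gap = NULL) {
  req <- list(op = "milp", n = n, obj = obj, lb = .enc_num(lb),
              ub = .enc_num(ub), eq = .enc_block(eq), le = .enc_block(le),
              integrality = as.integer(integrality),
              time_limit = time_limit, mip_gap = mip_gap)
  .solver_rpc(req, timeout_ms = if (is.null(time_limit)) 600000
              else (time_limit * 1000 + 120000))
}

.onUnload <- function(libpath) {
  solver_shutdown()
}
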