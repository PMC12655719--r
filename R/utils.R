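#' @keywords internal
#' @importFrom stats predict coef lm median sd dist runif rnorm setNames
#' @importFrom utils read.csv write.csv
"_PACKAGE"

#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded helpers never perturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_dooit <- function(msg, class = "dooit_error", call. = FALSE) {
  cond <- structure(
    class = c(class, "dooit_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

#' @noRd
dooit_verbosity <- function() {
  lvl <- getOption("dooit.verbose", "warn")
  match.arg(lvl, c("quiet", "warn", "info", "debug"))
}

dooit_log <- function(level = c("info", "debug", "warn"), ...) {
  level <- match.arg(level)
  cur <- dooit_verbosity()
  rank <- c(quiet = 0L, warn = 1L, info = 2L, debug = 3L)
  if (rank[[cur]] >= rank[[switch(level, warn = "warn", info = "info", debug = "debug")]]) {
    message(sprintf("[%s] %s", toupper(level), paste0(..., collapse = "")))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_scalar_number <- function(x, name) {
  if (!is_scalar_number(x)) {
    stop_dooit(sprintf("'%s' must be a single finite number", name), "dooit_validation_error")
  }
  invisible(x)
}
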