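`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded estimators never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# two-sided normal p-value from an estimate and its SE
norm_pval <- function(estimate, se) {
  p <- 2 * stats::pnorm(-abs(estimate / se))
  pmax(p, 1e-300)
}

z975 <- function() stats::qnorm(0.975)

stop_mr <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "mrkit_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# rbind data frames whose column sets differ, filling absent columns with NA
rbind_fill <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(data.frame())
  cols <- unique(unlist(lapply(rows, names)))
  filled <- lapply(rows, function(df) {
    for (c in setdiff(cols, names(df))) df[[c]] <- NA
    df[cols]
  })
  out <- do.call(rbind, filled)
  rownames(out) <- NULL
  out
}

mr_log <- function(level = "INFO", msg, ...) {
  message(sprintf("[%s] %s", level, sprintf(msg, ...)))
}
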