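# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' disturb the global random stream.
#'
#' @param seed integer seed, or NULL to leave the RNG alone.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == round(x)

#' Significance star labels used on the invasion figures
#'
#' Bands follow the figure captions: `****` for p <= 1e-4, `***` for
#' p <= 1e-3, `**` for p <= 5e-3, otherwise `ns`.
#'
#' @param p numeric vector of p-values.
#' @return character vector of labels.
#' @export
p_stars <- function(p) {
  out <- rep("ns", length(p))
  out[p <= 5e-3]  <- "**"
  out[p <= 1e-3]  <- "***"
  out[p <= 1e-4]  <- "****"
  out[is.na(p)]   <- NA_character_
  out
}
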