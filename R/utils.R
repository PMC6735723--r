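#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a reproducible child seed from a parent seed and a stream label.
## Kept below 2^31 - 1 so it is always a valid R integer seed.
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  raw <- utils::head(utf8ToInt(key), 50)
  as.integer((sum(raw * seq_along(raw) * 2654435.0) + as.numeric(seed)) %%
               2147483647)
}

#' Significance codes for P values
#'
#' Annotation convention used in the report tables: `***` P < 0.001,
#' `**` P < 0.01, `*` P < 0.05, `.` 0.05 <= P < 0.10, empty otherwise.
#'
#' @param p numeric vector of P values.
#' @return character vector of codes.
#' @export
#' @examples
#' signif_code(c(0.0001, 0.02, 0.07, 0.5))
signif_code <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.10]  <- "."
  out[!is.na(p) & p < 0.05]  <- "*"
  out[!is.na(p) & p < 0.01]  <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop(sprintf("'%s' must be a single non-negative number", name),
         call. = FALSE)
}
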