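`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a comma-separated junction string
#'
#' Junction sets travel through TSV files as comma-separated lists of class
#' letters.  `"."` (or the empty string) encodes the empty set — PCR was done
#' and no junction amplified — whereas `NA` means the derivative was never
#' assayed.
#'
#' @param x A length-one character value such as `"A,B,C"`, `"."`, or `NA`.
#' @return A sorted character vector of junction classes (possibly empty), or
#'   `NA` if `x` is `NA`.
#' @export
parse_junctions <- function(x) {
  stopifnot(length(x) == 1L)
  if (is.na(x)) return(NA_character_)
  x <- trimws(as.character(x))
  if (x %in% c(".", "")) return(character(0))
  sort(unique(trimws(strsplit(x, ",", fixed = TRUE)[[1]])))
}

#' Format a junction set for TSV output
#'
#' Inverse of [parse_junctions()]: the empty set becomes `"."`.
#'
#' @param x Character vector of junction classes, or `NA`.
#' @return A length-one character value.
#' @export
format_junctions <- function(x) {
  if (length(x) == 1L && is.na(x)) return(NA_character_)
  if (!length(x)) return(".")
  paste(sort(unique(x)), collapse = ",")
}

## normalize either a single object of class `cls` or a list of them
as_object_list <- function(x, cls) {
  if (inherits(x, cls)) return(list(x))
  if (is.list(x) && all(vapply(x, inherits, TRUE, cls))) return(x)
  stop("expected a '", cls, "' object or a list of them")
}

as_rearrangement_list <- function(x) {
  rl <- as_object_list(x, "rearrangement")
  names(rl) <- vapply(rl, `[[`, "", "id")
  rl
}

as_nucleus_list <- function(x) as_object_list(x, "nucleus_state")

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("'", name, "' must be a single probability in [0, 1]")
  x
}

## sample() without the length-one surprise
sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)
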