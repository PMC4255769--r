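#' Chromosome-arm identifiers
#'
#' Hexaploid wheat has 21 chromosomes (homoeologous groups 1-7 crossed with
#' subgenomes A, B and D), each with a short (S) and long (L) arm. Arms are
#' written in the field's canonical form `"<group><subgenome><arm>"`, e.g.
#' `"1AL"`. `parse_arm()` decomposes a vector of arm strings into a tibble;
#' `arm_string()` is its inverse; `opposite_arm()` swaps S and L.
#'
#' @param x Character vector of arm identifiers such as `"1AL"`.
#' @param group Integer vector of homoeologous groups (1-7).
#' @param subgenome Character vector, one of `"A"`, `"B"`, `"D"`.
#' @param side Character vector, `"S"` or `"L"`.
#'
#' @return `parse_arm()` returns a tibble with columns `arm`, `group`,
#'   `subgenome`, `side` and `chromosome`; `arm_string()` and
#'   `opposite_arm()` return character vectors.
#'
#' @examples
#' parse_arm(c("1AL", "7DS"))
#' opposite_arm("4AS")
#' @export
parse_arm <- function(x) {
  ok <- is_arm(x)
  if (any(!ok)) {
    abort(paste0(
      "Invalid chromosome-arm identifier(s): ",
      paste(unique(x[!ok]), collapse = ", ")
    ))
  }
  tibble(
    arm        = x,
    group      = as.integer(substr(x, 1L, 1L)),
    subgenome  = substr(x, 2L, 2L),
    side       = substr(x, 3L, 3L),
    chromosome = substr(x, 1L, 2L)
  )
}

#' @rdname parse_arm
#' @export
arm_string <- function(group, subgenome, side) {
  stopifnot(all(group %in% 1:7), all(subgenome %in% c("A", "B", "D")),
            all(side %in% c("S", "L")))
  paste0(group, subgenome, side)
}

#' @rdname parse_arm
#' @export
is_arm <- function(x) {
  grepl("^[1-7][ABD][SL]$", x)
}

#' @rdname parse_arm
#' @export
opposite_arm <- function(x) {
  p <- parse_arm(x)
  arm_string(p$group, p$subgenome, ifelse(p$side == "S", "L", "S"))
}

#' @rdname parse_arm
#' @export
wheat_chromosomes <- function() {
  as.vector(outer(1:7, c("A", "B", "D"), paste0))
}

#' @rdname parse_arm
#' @export
wheat_arms <- function() {
  as.vector(outer(wheat_chromosomes(), c("S", "L"), paste0))
}
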