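#' Expected homoeologous arm relationships
#'
#' For homoeologous groups 1, 2, 3, 5, 6 and 7 the mutually homoeologous arm
#' sets are simply the three short arms and the three long arms. Group 4 is
#' the exception: the ancient 4A/5A/7B cyclic translocation (plus pericentric
#' inversion) reversed the homoeology of chromosome 4A's arms, so the
#' expected arm sets are 4AL/4BS/4DS (the "short set") and 4AS/4BL/4DL (the
#' "long set").
#'
#' @return A tibble with one row per group and set (`"short_set"` /
#'   `"long_set"`) and columns `A`, `B`, `D` giving the member arm of each
#'   subgenome.
#'
#' @examples
#' expected_homoeology()
#' expected_triplets(4)
#' @export
expected_homoeology <- function() {
  cached <- get0("expected_homoeology", envir = .pericentr_cache)
  if (!is.null(cached)) return(cached)
  tbl <- tidyr::crossing(group = 1:7, set = c("short_set", "long_set")) |>
    mutate(
      side = ifelse(.data$set == "short_set", "S", "L"),
      A = arm_string(.data$group, "A", .data$side),
      B = arm_string(.data$group, "B", .data$side),
      D = arm_string(.data$group, "D", .data$side)
    )
  # group-4 swap: the modern 4A arms pair with the opposite B/D arms
  tbl$A[tbl$group == 4] <- ifelse(tbl$set[tbl$group == 4] == "short_set",
                                  "4AL", "4AS")
  out <- tbl |>
    select("group", "set", "A", "B", "D") |>
    arrange(.data$group, desc(.data$set))
  assign("expected_homoeology", out, envir = .pericentr_cache)
  out
}

#' @rdname expected_homoeology
#' @param group A single homoeologous group, 1-7.
#' @export
expected_triplets <- function(group) {
  if (length(group) != 1L || !group %in% 1:7) {
    abort("`group` must be a single homoeologous group between 1 and 7.")
  }
  tbl <- expected_homoeology()
  short <- tbl[tbl$group == group & tbl$set == "short_set", ]
  long <- tbl[tbl$group == group & tbl$set == "long_set", ]
  list(
    short_set = c(A = short$A, B = short$B, D = short$D),
    long_set  = c(A = long$A, B = long$B, D = long$D)
  )
}

# Arm on which a gene of a given (group, subgenome) sits when it belongs to
# the short or long homoeologous set. Vectorized lookup used throughout.
expected_arm <- function(group, subgenome, set) {
  side <- ifelse(set %in% c("short_set", "S"), "S", "L")
  out <- arm_string(group, subgenome, side)
  swap <- group == 4 & subgenome == "A"
  out[swap] <- opposite_arm(out[swap])
  out
}

#' Assign a chromosome-3B gene to an arm from its physical position
#'
#' Chromosome 3B was flow-sorted in its entirety rather than as separate
#' arms, so arm locations of 3B genes are obtained by placing them on the 3B
#' pseudomolecule: positions below the centromeric interval belong to 3BS,
#' positions above it to 3BL, and positions inside it are ambiguous and are
#' excluded from triplet formation downstream. The default centromeric
#' interval is 265-387 Mb. Positions equal to an interval bound are treated
#' as ambiguous (the conservative choice).
#'
#' @param position_bp Numeric vector of 1-based physical positions (bp).
#' @param centromere Length-2 numeric, the centromeric interval in bp.
#'
#' @return Character vector with elements `"3BS"`, `"3BL"` or `"ambiguous"`.
#'
#' @examples
#' assign_3b_arm(c(100e6, 500e6, 300e6))
#' @export
assign_3b_arm <- function(position_bp, centromere = c(265e6, 387e6)) {
  if (length(centromere) != 2L || !all(is.finite(centromere)) ||
      centromere[1] <= 0 || centromere[1] >= centromere[2]) {
    abort("`centromere` must be an interval 0 < start < end (bp).")
  }
  if (any(!is.finite(position_bp)) || any(position_bp <= 0)) {
    abort("`position_bp` must be positive physical coordinates.")
  }
  dplyr::case_when(
    position_bp < centromere[1] ~ "3BS",
    position_bp > centromere[2] ~ "3BL",
    TRUE ~ "ambiguous"
  )
}

#' The ten-segment model of modern chromosome 4A
#'
#' The modern chromosome 4A of bread wheat is a mosaic of ten ordered
#' segments drawn from four ancestral chromosome arms (original 4AS,
#' original 4AL, 5AL and 7BS), the product of the 4A/5A/7B cyclic
#' translocation and subsequent inversions. Segment extents in base pairs
#' are not part of the model; segments are ordinal (order along the modern
#' chromosome, origin and matching homoeologous arms only). The terminal
#' segment of the modern short arm derives from the original 4AS and is
#' homoeologous to the terminal regions of 4BS and 4DS.
#'
#' @return A tibble with ten rows and columns `segment` (1-10, ordered from
#'   the modern 4AS telomere to the modern 4AL telomere), `modern_arm`,
#'   `origin` and `matching_arms`.
#'
#' @examples
#' build_4a_model()
#' @export
build_4a_model <- function() {
  origin <- c("original_4AS", "original_4AL", "original_4AS", "original_4AL",
              "original_4AS", "original_4AL", "original_4AS",
              "5AL", "7BS", "5AL")
  matching <- c(
    original_4AS = "4BS/4DS",
    original_4AL = "4BL/4DL",
    `5AL` = "5BL/5DL",
    `7BS` = "7AS/7DS"
  )
  tibble(
    segment = 1:10,
    modern_arm = rep(c("modern_4AS", "modern_4AL"), c(4L, 6L)),
    origin = origin,
    matching_arms = unname(matching[origin])
  )
}

#' Read or write a homoeology configuration file
#'
#' The expected-homoeology table and the ten-segment 4A model can be
#' serialized to a YAML file so alternative polyploid karyotypes can be
#' described without changing code.
#'
#' @param path File path of the YAML configuration.
#' @param homoeology Tibble as returned by [expected_homoeology()].
#' @param model_4a Tibble as returned by [build_4a_model()].
#'
#' @return `read_homoeology_config()` returns a list with elements
#'   `homoeology` and `model_4a`; `write_homoeology_config()` returns `path`
#'   invisibly.
#' @export
write_homoeology_config <- function(path,
                                    homoeology = expected_homoeology(),
                                    model_4a = build_4a_model()) {
  yaml::write_yaml(
    list(
      homoeology = purrr::transpose(as.list(homoeology)),
      model_4a = purrr::transpose(as.list(model_4a))
    ),
    path
  )
  invisible(path)
}

#' @rdname write_homoeology_config
#' @export
read_homoeology_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!all(c("homoeology", "model_4a") %in% names(raw))) {
    abort("Homoeology config must contain `homoeology` and `model_4a`.")
  }
  list(
    homoeology = purrr::map_dfr(raw$homoeology, as_tibble),
    model_4a = purrr::map_dfr(raw$model_4a, as_tibble)
  )
}
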