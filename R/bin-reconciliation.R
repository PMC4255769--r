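#' Parse deletion-bin locus labels
#'
#' Deletion-bin labels locate an EST on a chromosome arm as a
#' fraction-length interval, e.g. `"1AL1-0.17-0.61"` (bin 1 of arm 1AL,
#' spanning fraction 0.17 to 0.61 of the arm). Labels beginning `"C-"` are
#' centromere-anchored: `"C-1AS1-0.47"` spans from the centromere (fraction
#' 0) out to 0.47 of 1AS. Hyphen and en-dash are both accepted as interval
#' separators, and an optional hyphen before the bin number is tolerated
#' (`"C-4AL-12-0.43"` and `"C-4AL12-0.43"` are the same bin), as published
#' labels mix these forms.
#'
#' @param label Character vector of bin labels.
#' @return A tibble with columns `label`, `chromosome`, `arm` (`"S"`/`"L"`),
#'   `centromere_anchored`, `lo`, `hi` (fraction interval).
#'
#' @examples
#' parse_bin_label(c("C-1AS1-0.47", "1AL1-0.17-0.61"))
#' @export
parse_bin_label <- function(label) {
  if (any(!nzchar(label)) || any(is.na(label))) {
    abort("Bin labels must be non-empty strings.")
  }
  rx <- paste0(
    "^(C-)?",                       # centromere anchoring
    "([1-7][ABD])([SL])",           # chromosome + arm
    "-?([0-9]+)",                   # bin number (optional leading hyphen)
    "-([0-9]*\\.?[0-9]+)",          # first fraction
    "(?:[-–]([0-9]*\\.?[0-9]+))?$" # optional second fraction
  )
  m <- regmatches(label, regexec(rx, label, perl = TRUE))
  bad <- lengths(m) == 0L
  if (any(bad)) {
    abort(paste0("Unparseable deletion-bin label(s): ",
                 paste(unique(label[bad]), collapse = ", ")))
  }
  parts <- do.call(rbind, m)
  anchored <- parts[, 2] == "C-"
  f1 <- as.numeric(parts[, 6])
  f2 <- suppressWarnings(as.numeric(parts[, 7]))
  lo <- ifelse(anchored & is.na(f2), 0, ifelse(is.na(f2), NA, f1))
  hi <- ifelse(is.na(f2), f1, f2)
  if (any(is.na(lo))) {
    abort(paste0(
      "Non-anchored bin label(s) need a fraction interval a-b: ",
      paste(unique(label[is.na(lo)]), collapse = ", ")
    ))
  }
  if (any(lo >= hi)) {
    abort(paste0("Bin interval must satisfy lo < hi: ",
                 paste(unique(label[lo >= hi]), collapse = ", ")))
  }
  tibble(
    label = as.character(label),
    chromosome = parts[, 3],
    arm = parts[, 4],
    centromere_anchored = anchored,
    lo = lo,
    hi = hi
  )
}

#' Reconcile a shotgun arm call with a deletion-bin location
#'
#' A deletion-bin location and a shotgun-derived arm call for the same
#' chromosome agree when they name the same arm. When they disagree, the
#' verdict depends on the bin: a pericentromeric location in deletion-bin
#' mapping is concluded when a hybridizing fragment is present in all
#' deletion lines, so a centromere-anchored bin cannot by itself
#' distinguish a pericentromeric short-arm from a long-arm location --
#' without ditelosomic-line arm evidence such a disagreement is
#' `uninformative_pericentromeric` rather than a contradiction.
#'
#' @param arm_call Character vector of shotgun arm calls (e.g. `"4AL"`).
#' @param bin Tibble of parsed bins ([parse_bin_label()]), or a character
#'   vector of labels.
#' @param ditelosomic_evidence Logical: is chromosome-arm information from
#'   ditelosomic lines available for the bin assignment?
#'
#' @return Character vector of verdicts: `"concordant"`, `"contradicts"` or
#'   `"uninformative_pericentromeric"`.
#'
#' @examples
#' reconcile("4AL", "C-4AL12-0.43")
#' reconcile("1AS", "1AL1-0.17-0.61", ditelosomic_evidence = TRUE)
#' reconcile("1AS", "C-1AL1-0.47", ditelosomic_evidence = FALSE)
#' @export
reconcile <- function(arm_call, bin, ditelosomic_evidence = TRUE) {
  if (is.character(bin)) bin <- parse_bin_label(bin)
  call <- parse_arm(arm_call)
  n <- max(nrow(call), nrow(bin))
  if (any(call$chromosome != bin$chromosome)) {
    abort(paste0(
      "Arm call and deletion bin refer to different chromosomes: ",
      paste(unique(paste(call$arm, "vs", bin$label)
                   [call$chromosome != bin$chromosome]), collapse = ", ")
    ))
  }
  case_when(
    call$side == bin$arm ~ "concordant",
    bin$centromere_anchored & !ditelosomic_evidence ~
      "uninformative_pericentromeric",
    TRUE ~ "contradicts"
  )
}

#' Reconcile a table of arm calls against deletion-bin locations
#'
#' Joins shotgun arm calls and deletion-bin records on gene/EST id and
#' chromosome and applies [reconcile()] to every pair.
#'
#' @param arm_calls Tibble with columns `gene` and `arm` (shotgun arm call).
#' @param bins Tibble with columns `gene`, `bin_label` and optionally
#'   `ditelosomic_evidence` (default `TRUE` where absent: arm evidence is
#'   assumed available unless stated otherwise).
#'
#' @return A tibble with one row per joined (call, bin) pair: `gene`,
#'   `arm`, `bin_label`, `ditelosomic_evidence`, `verdict`; summary counts
#'   by verdict are attached as attribute `summary`.
#' @export
reconcile_all <- function(arm_calls, bins) {
  if (!all(c("gene", "arm") %in% names(arm_calls))) {
    abort("`arm_calls` needs columns `gene` and `arm`.")
  }
  if (!all(c("gene", "bin_label") %in% names(bins))) {
    abort("`bins` needs columns `gene` and `bin_label`.")
  }
  if (!"ditelosomic_evidence" %in% names(bins)) {
    bins$ditelosomic_evidence <- TRUE
  }
  parsed <- parse_bin_label(bins$bin_label)
  bins2 <- bins |>
    mutate(bin_chromosome = parsed$chromosome,
           bin_arm = parsed$arm,
           centromere_anchored = parsed$centromere_anchored)
  joined <- arm_calls |>
    mutate(chromosome = substr(.data$arm, 1, 2)) |>
    inner_join(bins2, by = c("gene", chromosome = "bin_chromosome"))
  out <- joined |>
    mutate(
      verdict = case_when(
        substr(.data$arm, 3, 3) == .data$bin_arm ~ "concordant",
        .data$centromere_anchored & !.data$ditelosomic_evidence ~
          "uninformative_pericentromeric",
        TRUE ~ "contradicts"
      )
    ) |>
    select("gene", "arm", "bin_label", "ditelosomic_evidence", "verdict")
  summary <- out |>
    count(.data$verdict, name = "n") |>
    tidyr::complete(
      verdict = c("concordant", "contradicts",
                  "uninformative_pericentromeric"),
      fill = list(n = 0L)
    )
  attr(out, "summary") <- setNames(summary$n, summary$verdict)
  out
}
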