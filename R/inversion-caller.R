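#' Per-chromosome transfer direction counts
#'
#' Each accepted nonstandard gene names one inferred transfer (e.g.
#' `"1AL->1AS"`): its minority arm disagrees with the expected homoeologous
#' triplet, so the gene is counted once, on the minority chromosome, in the
#' direction of the transfer.
#'
#' @param patterns An `arm_patterns` tibble (see [classify_arm_patterns()]);
#'   only accepted/flagged nonstandard rows contribute.
#' @param strict Drop genes flagged by the secondary-hit check instead of
#'   counting them.
#'
#' @return A tibble with columns `chromosome`, `n_short_to_long`,
#'   `n_long_to_short` and `n_flagged`, one row per chromosome with at least
#'   one nonstandard gene.
#' @export
direction_counts <- function(patterns, strict = FALSE) {
  keep <- c("accepted", if (!strict) "flagged_ambiguous_secondary")
  patterns |>
    filter(.data$status %in% keep, .data$classification == "nonstandard") |>
    group_by(.data$chromosome) |>
    summarise(
      n_short_to_long = sum(.data$direction == "short_to_long"),
      n_long_to_short = sum(.data$direction == "long_to_short"),
      n_flagged = sum(.data$status == "flagged_ambiguous_secondary"),
      .groups = "drop"
    )
}

#' Do short- and long-arm transfer loci co-map?
#'
#' A pericentric inversion encompasses the centromere, so genes transferred
#' from the short arm and genes transferred from the long arm must derive
#' from one contiguous pericentromeric segment: at least one locus now on
#' each arm should co-locate, or be tightly linked, on the genetic map.
#' Recombination suppression around wheat centromeres means such loci
#' typically collapse onto (nearly) a single map position.
#'
#' @param positions Tibble with columns `cM` (genetic map position) and
#'   `side` (`"S"`/`"L"`, the arm the nonstandard locus is on) for the
#'   nonstandard genes of one chromosome.
#' @param epsilon Co-mapping tolerance in centimorgans.
#'
#' @return `TRUE` iff some short-arm locus and some long-arm locus lie
#'   within `epsilon` cM of each other; `FALSE` when either direction has
#'   no mapped gene.
#' @export
comap_test <- function(positions, epsilon = 2) {
  s <- positions$cM[positions$side == "S"]
  l <- positions$cM[positions$side == "L"]
  s <- s[is.finite(s)]; l <- l[is.finite(l)]
  if (length(s) == 0L || length(l) == 0L) return(FALSE)
  min(abs(outer(s, l, "-"))) <= epsilon
}

classify_call <- function(n_short_to_long, n_long_to_short, comap,
                          strong_total = 6L, strong_min_per_arm = 3L,
                          putative_total = 11L) {
  if (any(n_short_to_long < 0) || any(n_long_to_short < 0)) {
    abort("Direction counts must be non-negative.")
  }
  total <- n_short_to_long + n_long_to_short
  minority <- pmin(n_short_to_long, n_long_to_short)
  case_when(
    total >= strong_total & minority >= strong_min_per_arm & comap ~ "strong",
    total >= putative_total & minority < strong_min_per_arm ~ "putative",
    TRUE ~ "none"
  )
}

#' Call pericentric inversions per chromosome
#'
#' Aggregates nonstandard arm patterns by chromosome and applies the
#' evidence criteria for a pericentric inversion. A chromosome has *strong*
#' evidence when (1) at least `strong_total` genes were transferred to the
#' opposite arm, (2) both arms are involved with at least
#' `strong_min_per_arm` genes each, and (3) the rearrangement demonstrably
#' encompasses the centromere: short- and long-arm transfer loci co-map
#' within `epsilon` cM ([comap_test()]). A chromosome with
#' `putative_total` or more transferred genes but essentially one-sided
#' evidence (minority direction below `strong_min_per_arm`) is a *putative*
#' inversion; everything else is *none*.
#'
#' Chromosome 3B is called like any other but carries a data-quality
#' warning: its arm assignments rest on pseudomolecule scaffold placement
#' rather than on flow-sorted arm libraries, and misplaced scaffolds mimic
#' nonstandard arm locations.
#'
#' @inheritParams direction_counts
#' @param map Tibble with columns `gene`, `chromosome`, `cM`: genetic map
#'   positions. Genes without a position on the transfer chromosome simply
#'   do not contribute to the co-mapping test.
#' @param epsilon Co-mapping tolerance in centimorgans.
#' @param strong_total,strong_min_per_arm,putative_total Evidence
#'   thresholds (see above).
#'
#' @return A tibble of class `inversion_calls` with one row per chromosome
#'   (all 21): `chromosome`, `n_short_to_long`, `n_long_to_short`,
#'   `n_total`, `n_flagged`, `comap_satisfied`, `class`, `warning` and a
#'   list-column `supporting_genes`.
#' @export
call_inversions <- function(patterns, map = NULL, epsilon = 2,
                            strict = FALSE, strong_total = 6L,
                            strong_min_per_arm = 3L, putative_total = 11L) {
  counts <- direction_counts(patterns, strict = strict)
  keep <- c("accepted", if (!strict) "flagged_ambiguous_secondary")
  nonstd <- patterns |>
    filter(.data$status %in% keep, .data$classification == "nonstandard") |>
    mutate(obs_side = ifelse(.data$direction == "short_to_long", "L", "S"))

  calls <- tibble(chromosome = wheat_chromosomes()) |>
    left_join(counts, by = "chromosome") |>
    mutate(across(c("n_short_to_long", "n_long_to_short", "n_flagged"),
                  ~ tidyr::replace_na(.x, 0L)),
           n_total = .data$n_short_to_long + .data$n_long_to_short)

  comap <- vapply(calls$chromosome, function(chr) {
    g <- nonstd |> filter(.data$chromosome == chr)
    if (nrow(g) == 0L || is.null(map)) return(FALSE)
    pos <- g |>
      inner_join(map |> filter(.data$chromosome == chr) |>
                   select("gene", "cM"),
                 by = "gene") |>
      transmute(cM = .data$cM, side = .data$obs_side)
    comap_test(pos, epsilon = epsilon)
  }, logical(1))

  genes_by_chr <- lapply(calls$chromosome, function(chr) {
    sort(nonstd$gene[nonstd$chromosome == chr])
  })

  calls <- calls |>
    mutate(
      comap_satisfied = comap,
      class = classify_call(.data$n_short_to_long, .data$n_long_to_short,
                            comap, strong_total, strong_min_per_arm,
                            putative_total),
      warning = ifelse(
        .data$chromosome == "3B" & .data$n_total > 0L,
        "3B arm assignments derive from pseudomolecule placement, not arm libraries; scaffold misplacement can mimic nonstandard locations",
        NA_character_
      ),
      supporting_genes = genes_by_chr
    ) |>
    select("chromosome", "n_short_to_long", "n_long_to_short", "n_total",
           "n_flagged", "comap_satisfied", "class", "warning",
           "supporting_genes")
  if (any(calls$chromosome == "3B" & calls$n_total > 0L)) {
    warn(paste("Chromosome 3B has nonstandard genes; its arm assignments",
               "rest on pseudomolecule placement and should be treated",
               "with caution."))
  }
  structure(calls, class = c("inversion_calls", class(calls)))
}

#' Call inversions from bare direction counts
#'
#' Convenience path for count-only data (no per-gene patterns or map), such
#' as published per-chromosome tallies. The co-mapping criterion cannot be
#' evaluated from counts, so its assumed value must be supplied explicitly.
#'
#' @param counts Tibble with columns `chromosome`, `n_short_to_long`,
#'   `n_long_to_short`.
#' @param comap Logical (scalar or per-row): assumed outcome of the
#'   co-mapping criterion.
#' @inheritParams call_inversions
#' @return An `inversion_calls` tibble (without supporting genes).
#' @export
call_inversions_from_counts <- function(counts, comap = TRUE,
                                        strong_total = 6L,
                                        strong_min_per_arm = 3L,
                                        putative_total = 11L) {
  calls <- counts |>
    mutate(
      n_total = .data$n_short_to_long + .data$n_long_to_short,
      n_flagged = 0L,
      comap_satisfied = comap,
      class = classify_call(.data$n_short_to_long, .data$n_long_to_short,
                            comap, strong_total, strong_min_per_arm,
                            putative_total),
      warning = NA_character_,
      supporting_genes = list(character(0))
    ) |>
    select("chromosome", "n_short_to_long", "n_long_to_short", "n_total",
           "n_flagged", "comap_satisfied", "class", "warning",
           "supporting_genes")
  structure(calls, class = c("inversion_calls", class(calls)))
}

#' Per-chromosome rearrangement report
#'
#' A report table mirroring the two direction columns and
#' per-chromosome layout of the study design: 21 chromosome rows plus a
#' grand-total row. The grand total equals the number of accepted
#' nonstandard genes.
#'
#' @param calls An `inversion_calls` tibble.
#' @return A tibble with frozen column order `chromosome`,
#'   `n_short_to_long`, `n_long_to_short`, `n_total`, `class`.
#' @export
report_table <- function(calls) {
  stopifnot(inherits(calls, "inversion_calls"))
  body <- calls |>
    as_tibble() |>
    select("chromosome", "n_short_to_long", "n_long_to_short", "n_total",
           "class")
  bind_rows(
    body,
    tibble(
      chromosome = "Total",
      n_short_to_long = sum(body$n_short_to_long),
      n_long_to_short = sum(body$n_long_to_short),
      n_total = sum(body$n_total),
      class = NA_character_
    )
  )
}

#' @rdname call_inversions
#' @param x An `inversion_calls` object.
#' @param ... Unused.
#' @export
tidy.inversion_calls <- function(x, ...) {
  x |>
    as_tibble() |>
    select("chromosome", "n_short_to_long", "n_long_to_short", "n_total",
           "n_flagged", "comap_satisfied", "class")
}

#' @rdname call_inversions
#' @export
glance.inversion_calls <- function(x, ...) {
  tibble(
    n_chromosomes = nrow(x),
    n_strong = sum(x$class == "strong"),
    n_putative = sum(x$class == "putative"),
    n_none = sum(x$class == "none"),
    n_nonstandard_genes = sum(x$n_total)
  )
}

#' @export
print.inversion_calls <- function(x, ...) {
  cat("<inversion_calls> per-chromosome pericentric inversion evidence\n")
  print(tidy.inversion_calls(x), n = nrow(x))
  g <- glance.inversion_calls(x)
  cat(sprintf("strong: %d  putative: %d  nonstandard genes: %d\n",
              g$n_strong, g$n_putative, g$n_nonstandard_genes))
  invisible(x)
}
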