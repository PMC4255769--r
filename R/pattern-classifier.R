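#' Read a BLAST tabular hit file
#'
#' Reads the standard 12-column BLAST tabular format (`-outfmt 6`:
#' qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore). Subject ids must be chromosome-arm library names
#' (`"1AL"` ... `"7DS"`) or `"3B"` for the whole-chromosome 3B library.
#'
#' @param path Path to a tab-separated hit file without header.
#' @return A tibble with the 12 standard columns.
#' @export
read_blast_tab <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore"),
    col_types = "ccdiiiiiiidd",
    progress = FALSE
  )
}

validate_hits <- function(hits) {
  needed <- c("qseqid", "sseqid", "pident", "evalue", "bitscore",
              "sstart", "send")
  missing <- setdiff(needed, names(hits))
  if (length(missing) > 0L) {
    abort(paste0("Hit table lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  known <- c(wheat_arms(), "3B")
  bad <- setdiff(unique(hits$sseqid), known)
  if (length(bad) > 0L) {
    abort(paste0("Unknown subject library id(s): ",
                 paste(bad, collapse = ", ")))
  }
  invisible(hits)
}

#' Rank the hits of one gene and keep the best k
#'
#' One hit per arm library (the best HSP per library) is ranked by
#' descending bitscore, with ties broken by ascending e-value, then
#' descending percent identity, then lexicographic library id, so that the
#' ranking is a total order and results are reproducible byte for byte.
#'
#' @param hits Tibble of BLAST hit rows for a single gene (already e-value
#'   filtered).
#' @param k Number of top hits to keep.
#' @return The first `k` rows in rank order (fewer if fewer are available).
#' @export
top_hits <- function(hits, k = 3) {
  hits |>
    group_by(.data$sseqid) |>
    arrange(desc(.data$bitscore), .data$evalue, desc(.data$pident),
            .by_group = FALSE) |>
    slice_head(n = 1L) |>
    ungroup() |>
    arrange(desc(.data$bitscore), .data$evalue, desc(.data$pident),
            .data$sseqid) |>
    slice_head(n = k)
}

#' Classify genes into homoeologous arm-location patterns
#'
#' Implements the arm-pattern pipeline for BLAST tabular hits of orthologous
#' query genes against flow-sorted chromosome-arm sequence libraries:
#'
#' 1. hits are filtered at an e-value threshold (default `1e-5`);
#' 2. hits on the whole-chromosome 3B library are converted to 3BS/3BL via
#'    [assign_3b_arm()] on the hit midpoint; hits falling inside the
#'    centromeric interval are dropped;
#' 3. hits are reduced to the best HSP per arm library and ranked
#'    ([top_hits()]);
#' 4. genes whose location-determining (top three) hits include both arms
#'    of one chromosome are excluded (`excluded_both_arms`) -- a minute
#'    centromeric region can be present in both telosomic arm libraries,
#'    making the arm of origin undecidable; opposite-arm hits further down
#'    the ranking are the business of the secondary check (step 7);
#' 5. the three best hits must fall on the three chromosomes of one
#'    homoeologous group, one per subgenome, to form a triplet; genes with
#'    fewer than three hits are `excluded_incomplete`, genes whose top three
#'    span groups or repeat a subgenome are `excluded_top3_not_homoeologous`;
#' 6. a triplet equal to one of the group's expected homoeologous triplets
#'    is `standard`; otherwise it is `nonstandard` and the minority arm
#'    (the one disagreeing with the expected triplet matched by the other
#'    two) names the inferred transfer, e.g. `"1DL->1DS"`;
#' 7. for nonstandard genes, hits ranked 4-10 are inspected: a hit on the
#'    opposite arm of a triplet chromosome with bitscore within `delta`
#'    (a fraction of the rank-3 bitscore) marks the gene
#'    `flagged_ambiguous_secondary`. Flagged genes keep their triplet; they
#'    are surfaced, never auto-excluded.
#'
#' @param hits Tibble of BLAST tabular hits (see [read_blast_tab()]).
#' @param evalue_max E-value threshold applied before any ranking.
#' @param delta Secondary-hit bitscore window, as a fraction of the rank-3
#'   bitscore.
#' @param centromere_3b Centromeric interval of the 3B pseudomolecule (bp).
#'
#' @return A tibble of class `arm_patterns` with one row per input gene:
#'   `gene`, `status`, `group`, `triplet`, `classification`, `transfer`,
#'   `chromosome` (of the inferred transfer), `direction`
#'   (`"short_to_long"` / `"long_to_short"`). A run summary (status counts)
#'   is attached as attribute `summary` and available via [glance()].
#' @export
classify_arm_patterns <- function(hits, evalue_max = 1e-5, delta = 0.10,
                                  centromere_3b = c(265e6, 387e6)) {
  validate_hits(hits)
  all_genes <- unique(hits$qseqid)

  h <- hits |> filter(.data$evalue <= evalue_max)

  # 3B whole-chromosome hits: locate by midpoint, drop centromeric ones
  is3b <- h$sseqid == "3B"
  if (any(is3b)) {
    mid <- (h$sstart[is3b] + h$send[is3b]) / 2
    arm3b <- assign_3b_arm(mid, centromere_3b)
    h$sseqid[is3b] <- ifelse(arm3b == "ambiguous", NA_character_, arm3b)
    h <- h |> filter(!is.na(.data$sseqid))
  }

  # best HSP per (gene, library), then rank within gene
  h <- h |>
    group_by(.data$qseqid, .data$sseqid) |>
    arrange(desc(.data$bitscore), .data$evalue, desc(.data$pident),
      .by_group = FALSE
    ) |>
    slice_head(n = 1L) |>
    ungroup() |>
    arrange(
      .data$qseqid, desc(.data$bitscore), .data$evalue,
      desc(.data$pident), .data$sseqid
    ) |>
    group_by(.data$qseqid) |>
    mutate(rank = row_number()) |>
    ungroup()

  ap <- parse_arm(h$sseqid)
  h$group <- ap$group
  h$subgenome <- ap$subgenome
  h$side <- ap$side
  h$chromosome <- ap$chromosome

  # both-arm exclusion applies to the location-determining (top-3) hits;
  # deeper-ranked opposite-arm hits are the secondary check's business
  both_arm_genes <- h |>
    filter(.data$rank <= 3L) |>
    distinct(.data$qseqid, .data$chromosome, .data$side) |>
    count(.data$qseqid, .data$chromosome) |>
    filter(.data$n == 2L) |>
    pull(.data$qseqid) |>
    unique()

  top3 <- h |>
    filter(.data$rank <= 3L, !.data$qseqid %in% both_arm_genes)

  trip <- top3 |>
    group_by(.data$qseqid) |>
    summarise(
      n_hits = n(),
      n_groups = n_distinct(.data$group),
      n_subg = n_distinct(.data$subgenome),
      group1 = .data$group[1],
      arm_A = .data$sseqid[match("A", .data$subgenome)],
      arm_B = .data$sseqid[match("B", .data$subgenome)],
      arm_D = .data$sseqid[match("D", .data$subgenome)],
      bitscore3 = min(.data$bitscore),
      .groups = "drop"
    ) |>
    mutate(
      status = case_when(
        .data$n_hits < 3L ~ "excluded_incomplete",
        .data$n_groups == 1L & .data$n_subg == 3L ~ "accepted",
        TRUE ~ "excluded_top3_not_homoeologous"
      )
    )

  acc <- trip |> filter(.data$status == "accepted")
  if (nrow(acc) > 0L) {
    side_A <- substr(acc$arm_A, 3, 3)
    side_B <- substr(acc$arm_B, 3, 3)
    side_D <- substr(acc$arm_D, 3, 3)
    exp_S <- cbind(
      expected_arm(acc$group1, "A", "S"),
      expected_arm(acc$group1, "B", "S"),
      expected_arm(acc$group1, "D", "S")
    )
    obs <- cbind(acc$arm_A, acc$arm_B, acc$arm_D)
    n_short <- rowSums(obs == exp_S)
    acc <- acc |>
      mutate(
        triplet = paste(.data$arm_A, .data$arm_B, .data$arm_D, sep = "/"),
        classification = ifelse(n_short %in% c(0L, 3L),
                                "standard", "nonstandard")
      )
    # minority subgenome: the one disagreeing with the majority expected set
    majority_set <- ifelse(n_short >= 2L, "S", "L")
    min_idx <- integer(nrow(acc))
    for (j in 1:3) {
      disagree <- (obs[, j] == exp_S[, j]) != (majority_set == "S")
      min_idx[disagree] <- j
    }
    subg <- c("A", "B", "D")
    nonstd <- acc$classification == "nonstandard"
    exp_min <- ifelse(nonstd,
      expected_arm(acc$group1, subg[pmax(min_idx, 1L)], majority_set),
      NA_character_
    )
    obs_min <- ifelse(nonstd, obs[cbind(seq_len(nrow(acc)),
                                        pmax(min_idx, 1L))], NA_character_)
    acc <- acc |>
      mutate(
        transfer = ifelse(nonstd, paste0(exp_min, "->", obs_min),
                          NA_character_),
        chromosome = ifelse(nonstd, substr(exp_min, 1, 2), NA_character_),
        direction = case_when(
          !nonstd ~ NA_character_,
          substr(exp_min, 3, 3) == "S" ~ "short_to_long",
          TRUE ~ "long_to_short"
        )
      )
  } else {
    acc <- acc |>
      mutate(triplet = character(0), classification = character(0),
             transfer = character(0), chromosome = character(0),
             direction = character(0))
  }

  # secondary-hit consistency check on ranks 4-10 for nonstandard genes
  flagged <- character(0)
  nonstd_acc <- acc |> filter(.data$classification == "nonstandard")
  if (nrow(nonstd_acc) > 0L) {
    sec <- h |>
      filter(.data$rank >= 4L, .data$rank <= 10L,
             .data$qseqid %in% nonstd_acc$qseqid) |>
      inner_join(
        nonstd_acc |>
          select("qseqid", "arm_A", "arm_B", "arm_D", "bitscore3"),
        by = "qseqid"
      ) |>
      mutate(
        triplet_arm = case_when(
          .data$subgenome == "A" ~ .data$arm_A,
          .data$subgenome == "B" ~ .data$arm_B,
          TRUE ~ .data$arm_D
        ),
        opposite = .data$group == as.integer(substr(.data$triplet_arm, 1, 1)) &
          .data$sseqid != .data$triplet_arm &
          .data$chromosome == substr(.data$triplet_arm, 1, 2),
        close = .data$bitscore >= .data$bitscore3 * (1 - delta)
      ) |>
      filter(.data$opposite, .data$close)
    flagged <- unique(sec$qseqid)
  }

  patterns <- tibble(gene = all_genes) |>
    left_join(
      acc |>
        select("qseqid", "status", group = "group1", "triplet",
               "classification", "transfer", "chromosome", "direction"),
      by = c(gene = "qseqid")
    )
  other <- trip |> filter(.data$status != "accepted")
  patterns <- patterns |>
    mutate(
      status = case_when(
        !is.na(.data$status) ~ .data$status,
        .data$gene %in% both_arm_genes ~ "excluded_both_arms",
        .data$gene %in% other$qseqid ~
          other$status[match(.data$gene, other$qseqid)],
        TRUE ~ "excluded_incomplete"
      ),
      status = ifelse(.data$gene %in% flagged,
                      "flagged_ambiguous_secondary", .data$status)
    ) |>
    arrange(.data$gene)

  summary <- patterns |>
    count(.data$status, name = "n") |>
    tidyr::complete(
      status = c("accepted", "flagged_ambiguous_secondary",
                 "excluded_both_arms", "excluded_top3_not_homoeologous",
                 "excluded_incomplete"),
      fill = list(n = 0L)
    )
  summary <- c(
    as.list(setNames(summary$n, summary$status)),
    n_genes = nrow(patterns),
    n_nonstandard = sum(patterns$classification == "nonstandard",
                        na.rm = TRUE)
  )

  structure(patterns,
            summary = summary,
            class = c("arm_patterns", class(patterns)))
}

#' @rdname classify_arm_patterns
#' @param x An `arm_patterns` object.
#' @param ... Unused.
#' @export
glance.arm_patterns <- function(x, ...) {
  as_tibble(attr(x, "summary"))
}

#' Assemble a nonredundant ortholog set from reciprocal best hits
#'
#' Orthologous query genes are pooled from several source gene sets in a
#' fixed priority order (Brachypodium > T. urartu > Ae. tauschii > wheat
#' ESTs). Cross-source reciprocal-best-hit pairs connect genes into
#' clusters; one representative per cluster is retained, chosen by source
#' priority (ties broken lexicographically by gene id). Genes with no
#' reciprocal partner are retained as their own record. A reciprocal pair
#' within one source is ill-formed input and raises an error.
#'
#' @param genes Tibble with columns `gene` and `source` (one of
#'   `"Brachypodium"`, `"T_urartu"`, `"Ae_tauschii"`, `"wheat_EST"`).
#' @param rbh Tibble with columns `gene1`, `gene2`: reciprocal best-hit
#'   pairs between sources. May be empty.
#'
#' @return A tibble with one row per cluster: `gene` (the representative),
#'   `source`, `n_members` and a list-column `members`.
#' @export
build_ortholog_set <- function(genes, rbh = tibble(gene1 = character(0),
                                                   gene2 = character(0))) {
  sources <- c("Brachypodium", "T_urartu", "Ae_tauschii", "wheat_EST")
  if (!all(c("gene", "source") %in% names(genes))) {
    abort("`genes` needs columns `gene` and `source`.")
  }
  if (anyDuplicated(genes$gene)) {
    abort("Gene ids must be unique across sources.")
  }
  if (!all(genes$source %in% sources)) {
    abort(paste0("Unknown source(s): ",
                 paste(setdiff(genes$source, sources), collapse = ", ")))
  }
  unknown <- setdiff(c(rbh$gene1, rbh$gene2), genes$gene)
  if (length(unknown) > 0L) {
    abort(paste0("Reciprocal-best-hit table names unknown gene(s): ",
                 paste(unknown, collapse = ", ")))
  }
  src <- setNames(genes$source, genes$gene)
  same <- src[rbh$gene1] == src[rbh$gene2]
  if (any(same)) {
    abort(paste0(
      "Within-source reciprocal best-hit pair(s) are ill-formed input: ",
      paste(rbh$gene1[same], rbh$gene2[same], sep = " <-> ",
            collapse = ", ")
    ))
  }

  # union-find over the RBH graph
  parent <- setNames(genes$gene, genes$gene)
  find <- function(g) {
    while (parent[[g]] != g) {
      parent[[g]] <<- parent[[parent[[g]]]]
      g <- parent[[g]]
    }
    g
  }
  for (i in seq_len(nrow(rbh))) {
    a <- find(rbh$gene1[i]); b <- find(rbh$gene2[i])
    if (a != b) parent[[a]] <- b
  }
  genes$cluster <- vapply(genes$gene, find, character(1))
  genes |>
    mutate(priority = match(.data$source, sources)) |>
    group_by(.data$cluster) |>
    arrange(.data$priority, .data$gene, .by_group = TRUE) |>
    summarise(
      gene = .data$gene[1],
      source = .data$source[1],
      n_members = n(),
      members = list(sort(.data$gene)),
      .groups = "drop"
    ) |>
    select(-"cluster") |>
    arrange(.data$gene)
}
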