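#' Simulation settings for a synthetic allohexaploid genome
#'
#' Describes the genome to simulate: homoeologous gene triplets across the
#' seven groups and three subgenomes, euploid pericentric inversions,
#' per-arm-library aneuploid artifacts (extra inversions in the aneuploid
#' source line of a flow-sorted arm library), gene loss and duplication,
#' hit-score noise, pericentromeric recombination suppression, and the 3B
#' whole-chromosome special case.
#'
#' Depth coordinates are fractions of an arm (0 = centromere, 1 = telomere).
#' Inversions and artifacts are named lists keyed by chromosome
#' (e.g. `"6A"`) or arm library (e.g. `"6DS"`), each value a vector
#' `c(s = , l = )` of breakpoint depths. An artifact applies to the
#' aneuploid line from which that one arm library was sorted; listing the
#' same artifact for both arm libraries of a chromosome models a
#' double-ditelosomic source line whose restructuring is seen consistently
#' by both libraries.
#'
#' @param genes_per_group Homoeologous gene triplets per group.
#' @param centromere_frac Centromere position as a fraction of chromosome
#'   length (short arm proportion).
#' @param pericentromere_frac Fraction of each arm (from the centromere)
#'   under recombination suppression.
#' @param recomb_suppression Relative recombination density inside the
#'   suppressed region (1 = no suppression).
#' @param map_length_cm Genetic map length per chromosome.
#' @param chrom_length_bp Physical chromosome length (arbitrary, Mb scale).
#' @param inversions Named list of euploid pericentric inversions.
#' @param artifacts Named list of per-arm-library aneuploid inversions.
#' @param loss_rate Per-copy probability that a subgenome copy is missing
#'   from the sequence libraries.
#' @param dup_rate Per-gene probability of an extra off-group duplicate
#'   locus.
#' @param decoy_rate Per-gene probability of a spurious off-group hit that
#'   can displace a true homoeologue from the top three.
#' @param identity_mean,identity_sd Percent-identity model for true
#'   homoeologous hits.
#' @param dup_identity_mean,decoy_identity_mean,decoy_identity_sd Identity
#'   model for duplicate and decoy hits.
#' @param aln_length Alignment length used for emitted hits (bp).
#'
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(genes_per_group = 200,
                              centromere_frac = 0.5,
                              pericentromere_frac = 0.3,
                              recomb_suppression = 0.02,
                              map_length_cm = 150,
                              chrom_length_bp = 800e6,
                              inversions = list(),
                              artifacts = list(),
                              loss_rate = 0.05,
                              dup_rate = 0.10,
                              decoy_rate = 0.05,
                              identity_mean = 97,
                              identity_sd = 1.5,
                              dup_identity_mean = 90,
                              decoy_identity_mean = 93,
                              decoy_identity_sd = 3,
                              aln_length = 400) {
  cfg <- as.list(environment())
  rates <- c(loss_rate = loss_rate, dup_rate = dup_rate,
             decoy_rate = decoy_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("loss_rate, dup_rate and decoy_rate must lie in [0, 1].")
  }
  if (centromere_frac <= 0 || centromere_frac >= 1) {
    abort("`centromere_frac` must lie in (0, 1).")
  }
  if (recomb_suppression <= 0) {
    abort("`recomb_suppression` must be positive (cM must stay monotone).")
  }
  check_inv_list <- function(lst, keys, what) {
    bad <- setdiff(names(lst), keys)
    if (length(bad) > 0L) {
      abort(paste0("Unknown ", what, ": ", paste(bad, collapse = ", ")))
    }
    for (nm in names(lst)) {
      v <- lst[[nm]]
      if (!all(c("s", "l") %in% names(v)) || any(v[c("s", "l")] <= 0) ||
          any(v[c("s", "l")] > 1)) {
        abort(paste0(what, " '", nm,
                     "' needs breakpoint depths c(s = , l = ) in (0, 1]."))
      }
    }
  }
  check_inv_list(inversions, wheat_chromosomes(), "inversion chromosome")
  check_inv_list(artifacts, setdiff(wheat_arms(), c("3BS", "3BL")),
                 "artifact arm library")
  structure(cfg, class = "sim_config")
}

# piecewise-linear genetic position: recombination density is
# `suppression` within `p` of the centromere (in arm fraction) and 1
# outside; cM is the scaled cumulative density from the short-arm telomere.
cm_position <- function(side, depth, fc, p, r, map_length) {
  x <- ifelse(side == "S", fc * (1 - depth), fc + depth * (1 - fc))
  lo <- fc * (1 - p)          # start of suppressed region
  hi <- fc + p * (1 - fc)     # end of suppressed region
  cum <- ifelse(
    x <= lo, x,
    ifelse(x <= hi, lo + r * (x - lo),
           lo + r * (hi - lo) + (x - hi))
  )
  total <- lo + r * (hi - lo) + (1 - hi)
  map_length * cum / total
}

# physical coordinate; 3B uses the pseudomolecule with its centromeric
# interval so emitted positions exercise the coordinate->arm rule.
bp_position <- function(chromosome, side, depth, fc, len, aln) {
  cen3b <- c(265e6, 387e6); len3b <- 774e6
  ifelse(
    chromosome == "3B",
    ifelse(side == "S",
           (cen3b[1] - aln) * (1 - depth),
           cen3b[2] + depth * (len3b - cen3b[2] - aln)),
    ifelse(side == "S",
           round(fc * len * depth),
           round((1 - fc) * len * depth))
  )
}

#' Simulate an allohexaploid genome with planted rearrangements
#'
#' Places `genes_per_group` homoeologous gene triplets on each of the seven
#' groups (each gene has one copy per subgenome, on the arm its ancestral
#' homoeologous set predicts -- including the group-4 swap on chromosome
#' 4A), applies the configured euploid pericentric inversions (copies with
#' depth shallower than the breakpoint move to the opposite arm), then
#' determines each copy's membership in the flow-sorted arm libraries under
#' the per-library aneuploid artifacts, and finally applies gene loss and
#' duplication. Everything is deterministic given `seed`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; all randomness flows from it.
#'
#' @return A list of class `wheat_sim` with elements:
#'   * `model`: per-copy placements (gene, group, subgenome, chromosome,
#'     ancestral side, expected arm, euploid arm, depth, bp, cM, flags);
#'   * `truth`: per-copy library memberships and rearrangement labels;
#'   * `truth_patterns`: per-gene observable triplet and nonstandard flag
#'     (where well-defined, i.e. exactly one library per subgenome);
#'   * `map`: genetic map positions (gene, chromosome, cM);
#'   * `config`, `seed`.
#' @export
simulate_genome <- function(config = simulation_config(), seed) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed)) abort("A `seed` is mandatory for simulation.")
  set.seed(seed)

  genes <- tidyr::crossing(group = 1:7,
                           idx = seq_len(config$genes_per_group)) |>
    mutate(
      gene = sprintf("g%d_%04d", .data$group, .data$idx),
      side_ancestral = sample(c("S", "L"), n(), replace = TRUE),
      depth = runif(n(), 0.005, 0.995),
      duplicated = runif(n()) < config$dup_rate
    ) |>
    select(-"idx")

  model <- genes |>
    tidyr::crossing(subgenome = c("A", "B", "D")) |>
    mutate(
      chromosome = paste0(.data$group, .data$subgenome),
      arm_expected = expected_arm(.data$group, .data$subgenome,
                                  .data$side_ancestral),
      side_expected = substr(.data$arm_expected, 3, 3),
      side = .data$side_expected,
      depth_now = .data$depth,
      moved_by_euploid = FALSE
    )

  # euploid pericentric inversions
  for (chr in names(config$inversions)) {
    bp <- config$inversions[[chr]]
    i <- model$chromosome == chr &
      model$depth_now < ifelse(model$side == "S", bp[["s"]], bp[["l"]])
    from_s <- i & model$side == "S"
    from_l <- i & model$side == "L"
    model$depth_now[from_s] <- model$depth_now[from_s] * bp[["l"]] / bp[["s"]]
    model$depth_now[from_l] <- model$depth_now[from_l] * bp[["s"]] / bp[["l"]]
    model$side[i] <- ifelse(model$side[i] == "S", "L", "S")
    model$moved_by_euploid[i] <- TRUE
  }
  model <- model |>
    mutate(
      arm = paste0(.data$chromosome, .data$side),
      lost = runif(n()) < config$loss_rate,
      bp = bp_position(.data$chromosome, .data$side, .data$depth_now,
                       config$centromere_frac, config$chrom_length_bp,
                       config$aln_length),
      cM = cm_position(.data$side, .data$depth_now, config$centromere_frac,
                       config$pericentromere_frac,
                       config$recomb_suppression, config$map_length_cm)
    )

  # arm-library membership: each arm library was sorted from its own
  # aneuploid line, which may carry an artifact inversion; a copy appears
  # in library X iff in X's source line it sits on X's arm. 3B was sorted
  # whole, so its single library always contains the copy.
  art_s <- art_l <- setNames(rep(NA_real_, length(wheat_arms())),
                             wheat_arms())
  for (lib in names(config$artifacts)) {
    art_s[lib] <- config$artifacts[[lib]][["s"]]
    art_l[lib] <- config$artifacts[[lib]][["l"]]
  }
  side_in_line <- function(lib) {
    s <- art_s[lib]; l <- art_l[lib]
    flip <- !is.na(s) &
      model$depth_now < ifelse(model$side == "S", s, l)
    ifelse(flip, ifelse(model$side == "S", "L", "S"), model$side)
  }
  lib_s <- paste0(model$chromosome, "S")
  lib_l <- paste0(model$chromosome, "L")
  truth <- model |>
    mutate(
      in_short_lib = ifelse(.data$chromosome == "3B", .data$side == "S",
                            side_in_line(lib_s) == "S"),
      in_long_lib = ifelse(.data$chromosome == "3B", .data$side == "L",
                           side_in_line(lib_l) == "L"),
      in_short_lib = .data$in_short_lib & !.data$lost,
      in_long_lib = .data$in_long_lib & !.data$lost,
      moved_by_aneuploid = !.data$lost &
        ((.data$in_short_lib != (.data$side == "S")) |
           (.data$in_long_lib != (.data$side == "L"))),
      arm_observed = case_when(
        .data$in_short_lib & !.data$in_long_lib ~
          paste0(.data$chromosome, "S"),
        .data$in_long_lib & !.data$in_short_lib ~
          paste0(.data$chromosome, "L"),
        TRUE ~ NA_character_
      )
    )

  truth_patterns <- truth |>
    group_by(.data$gene, .data$group) |>
    summarise(
      well_defined = all(!is.na(.data$arm_observed)) && n() == 3L,
      triplet = if (well_defined) {
        paste(.data$arm_observed[order(.data$subgenome)], collapse = "/")
      } else {
        NA_character_
      },
      .groups = "drop"
    )
  exp_std <- expected_homoeology() |>
    mutate(triplet = paste(.data$A, .data$B, .data$D, sep = "/"))
  truth_patterns <- truth_patterns |>
    mutate(nonstandard = .data$well_defined &
             !.data$triplet %in% exp_std$triplet)

  keep_model <- model |>
    select("gene", "group", "subgenome", "chromosome", "side_ancestral",
           "arm_expected", "arm", "side", "depth", "depth_now", "bp", "cM",
           "moved_by_euploid", "lost", "duplicated")
  keep_truth <- truth |>
    select("gene", "group", "subgenome", "chromosome", "arm_expected",
           "arm", "arm_observed", "in_short_lib", "in_long_lib",
           "moved_by_euploid", "moved_by_aneuploid", "lost", "duplicated")

  structure(
    list(
      model = keep_model,
      truth = keep_truth,
      truth_patterns = truth_patterns,
      map = keep_model |>
        filter(!.data$lost) |>
        select("gene", "chromosome", "cM"),
      config = config,
      seed = seed
    ),
    class = "wheat_sim"
  )
}

#' Genetic map positions under a recombination profile
#'
#' Recomputes centimorgan positions for the placements of a simulated
#' genome under a two-level recombination profile: density
#' `suppression` (relative to the distal rate of 1) within
#' `pericentromere_frac` of the centromere on each arm, 1 outside. With
#' `suppression = 1` the map is proportional to physical position; with a
#' strongly suppressed pericentromere all pericentromeric genes compress
#' onto nearly a single map locus, which is what makes the co-mapping
#' criterion for pericentric inversions testable.
#'
#' @param model Placement tibble (`sim$model`) with columns `gene`,
#'   `chromosome`, `side` and `depth_now`.
#' @param centromere_frac,pericentromere_frac,suppression,map_length_cm
#'   Profile parameters; see [simulation_config()].
#' @return A tibble `gene`, `chromosome`, `cM`, with `cM` monotone along
#'   each chromosome from the short-arm telomere.
#' @export
genetic_map <- function(model, centromere_frac = 0.5,
                        pericentromere_frac = 0.3, suppression = 0.02,
                        map_length_cm = 150) {
  if (suppression <= 0) {
    abort("`suppression` must be positive: the map must stay monotone.")
  }
  model |>
    mutate(cM = cm_position(.data$side, .data$depth_now, centromere_frac,
                            pericentromere_frac, suppression,
                            map_length_cm)) |>
    select("gene", "chromosome", "cM")
}

#' @export
print.wheat_sim <- function(x, ...) {
  cat(sprintf(
    "<wheat_sim> seed %d: %d gene triplets, %d placements (%d moved euploid, %d moved aneuploid, %d lost)\n",
    x$seed, nrow(x$truth_patterns), nrow(x$truth),
    sum(x$truth$moved_by_euploid), sum(x$truth$moved_by_aneuploid),
    sum(x$truth$lost)
  ))
  invisible(x)
}

#' Emit a BLAST-like tabular hit file for a simulated genome
#'
#' One hit per surviving library membership, with percent identity drawn
#' from the homoeologue divergence model and bitscore increasing in
#' identity; duplicated genes contribute an extra off-group hit at lower
#' identity, and decoy hits (off-group, occasionally high-scoring) can
#' displace a true homoeologue from the top three. Hits on chromosome 3B
#' carry pseudomolecule coordinates under the subject id `"3B"`.
#' Deterministic given `seed`.
#'
#' @param sim A `wheat_sim` from [simulate_genome()].
#' @param seed Integer seed for the emission noise.
#' @return A 12-column BLAST tabular tibble (see [read_blast_tab()]).
#' @export
emit_hits <- function(sim, seed = sim$seed + 1L) {
  stopifnot(inherits(sim, "wheat_sim"))
  set.seed(seed)
  cfg <- sim$config

  rows <- sim$truth |>
    filter(!.data$lost, .data$in_short_lib | .data$in_long_lib) |>
    tidyr::pivot_longer(c("in_short_lib", "in_long_lib"),
                        names_to = "which_lib", values_to = "present") |>
    filter(.data$present) |>
    mutate(
      lib_side = ifelse(.data$which_lib == "in_short_lib", "S", "L"),
      sseqid = ifelse(.data$chromosome == "3B", "3B",
                      paste0(.data$chromosome, .data$lib_side))
    ) |>
    left_join(sim$model |> select("gene", "subgenome", "depth_now"),
              by = c("gene", "subgenome")) |>
    mutate(pident = pmin(99.9, pmax(80, rnorm(n(), cfg$identity_mean,
                                              cfg$identity_sd))))

  mk_hits <- function(df) {
    side_for_bp <- if ("lib_side" %in% names(df)) df$lib_side else df$side
    bp <- bp_position(df$chromosome, side_for_bp, df$depth_now,
                      cfg$centromere_frac, cfg$chrom_length_bp,
                      cfg$aln_length)
    sstart <- pmax(1, round(bp))
    bits <- round(2 * cfg$aln_length * df$pident / 100 +
                    runif(nrow(df), 0, 0.5), 1)
    tibble(
      qseqid = df$gene,
      sseqid = df$sseqid,
      pident = round(df$pident, 2),
      length = cfg$aln_length,
      mismatch = as.integer(round(cfg$aln_length *
                                    (100 - df$pident) / 100)),
      gapopen = 0L,
      qstart = 1L,
      qend = cfg$aln_length,
      sstart = as.integer(sstart),
      send = as.integer(sstart + cfg$aln_length - 1L),
      evalue = pmax(1e-180, 10^(-bits / 10)),
      bitscore = bits
    )
  }
  hits <- mk_hits(rows)

  # extra-group duplicate loci
  dup_genes <- sim$truth |>
    filter(.data$duplicated, .data$subgenome == "A") |>
    distinct(.data$gene, .data$group)
  if (nrow(dup_genes) > 0L) {
    dup_rows <- dup_genes |>
      mutate(
        sseqid = vapply(.data$group, function(g) {
          sample(wheat_arms()[!grepl(paste0("^", g), wheat_arms()) &
                                !grepl("^3B", wheat_arms())], 1L)
        }, character(1)),
        chromosome = substr(.data$sseqid, 1, 2),
        lib_side = substr(.data$sseqid, 3, 3),
        depth_now = runif(n(), 0.005, 0.995),
        pident = pmin(99.9, pmax(80, rnorm(n(), cfg$dup_identity_mean,
                                           cfg$identity_sd)))
      )
    hits <- bind_rows(hits, mk_hits(dup_rows))
  }

  # decoy hits: off-group, occasionally outscoring a true homoeologue
  all_genes <- unique(sim$truth$gene)
  is_decoy <- runif(length(all_genes)) < cfg$decoy_rate
  if (any(is_decoy)) {
    dg <- tibble(gene = all_genes[is_decoy]) |>
      mutate(group = as.integer(sub("^g(\\d)_.*$", "\\1", .data$gene)))
    decoy_rows <- dg |>
      mutate(
        sseqid = vapply(.data$group, function(g) {
          sample(wheat_arms()[!grepl(paste0("^", g), wheat_arms()) &
                                !grepl("^3B", wheat_arms())], 1L)
        }, character(1)),
        chromosome = substr(.data$sseqid, 1, 2),
        lib_side = substr(.data$sseqid, 3, 3),
        depth_now = runif(n(), 0.005, 0.995),
        pident = pmin(99.9, pmax(80, rnorm(n(), cfg$decoy_identity_mean,
                                           cfg$decoy_identity_sd)))
      )
    hits <- bind_rows(hits, mk_hits(decoy_rows))
  }

  hits |>
    arrange(.data$qseqid, desc(.data$bitscore), .data$sseqid)
}

#' Simulate deletion-bin records for a simulated genome
#'
#' Samples genes with a well-defined observed arm and writes deletion-bin
#' labels consistent with that arm (bin fraction interval around the
#' gene's depth), planting a configurable number of discordant records
#' whose label names the opposite arm. Genes within the pericentromeric
#' fraction receive centromere-anchored (`C-`) labels.
#'
#' @param sim A `wheat_sim`.
#' @param n Number of bin records to draw.
#' @param n_discordant How many of them are planted discordances.
#' @param seed Integer seed.
#' @return A tibble `gene`, `bin_label`, `ditelosomic_evidence`, plus the
#'   truth columns `arm_true` and `planted_discordant`.
#' @export
simulate_bin_data <- function(sim, n = 50, n_discordant = 0,
                              seed = sim$seed + 2L) {
  stopifnot(inherits(sim, "wheat_sim"), n_discordant <= n)
  set.seed(seed)
  pool <- sim$truth |>
    filter(!is.na(.data$arm_observed), .data$chromosome != "3B") |>
    left_join(sim$model |> select("gene", "subgenome", "depth_now"),
              by = c("gene", "subgenome"))
  pool <- pool[sample(nrow(pool), min(n, nrow(pool))), ]
  p <- sim$config$pericentromere_frac
  out <- pool |>
    mutate(
      planted_discordant = seq_len(n()) <= n_discordant,
      label_arm = ifelse(.data$planted_discordant,
                         opposite_arm(.data$arm_observed),
                         .data$arm_observed),
      anchored = .data$depth_now < p,
      bin_label = ifelse(
        .data$anchored,
        sprintf("C-%s1-%.2f", .data$label_arm,
                pmin(0.99, .data$depth_now + 0.1)),
        sprintf("%s1-%.2f-%.2f", .data$label_arm,
                pmax(0, .data$depth_now - 0.1),
                pmin(1, .data$depth_now + 0.1))
      ),
      ditelosomic_evidence = TRUE
    ) |>
    transmute(
      gene = .data$gene,
      bin_label = .data$bin_label,
      ditelosomic_evidence = .data$ditelosomic_evidence,
      arm_true = .data$arm_observed,
      planted_discordant = .data$planted_discordant
    )
  out
}
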