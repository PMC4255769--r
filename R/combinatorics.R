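#' Pericentric inversion configurations
#'
#' A pericentric inversion spans the centromere, so it has one breakpoint on
#' each arm. A configuration records, for each of the three homoeologues of
#' one group, whether an inversion is present and how deep its breakpoints
#' reach into the short and long arms (distance from the centromere, in
#' arbitrary units -- only the relative order of breakpoint depths matters
#' for which arm-location patterns can arise).
#'
#' @param s,l Named numeric vectors (`A`, `B`, `D`) of short- and long-arm
#'   breakpoint depths. A subgenome is inverted iff both its depths are
#'   positive; an absent inversion must have both depths zero.
#'
#' @return An object of class `inversion_config`: a list with elements `s`,
#'   `l` and logical `present`.
#'
#' @examples
#' # nested triple inversion, deepest on D, shallowest on A
#' inversion_config(s = c(A = 1, B = 2, D = 3), l = c(A = 1, B = 2, D = 3))
#' @export
inversion_config <- function(s = c(A = 0, B = 0, D = 0),
                             l = c(A = 0, B = 0, D = 0)) {
  subg <- c("A", "B", "D")
  s <- s[subg]; l <- l[subg]
  if (any(is.na(s)) || any(is.na(l))) {
    abort("`s` and `l` must be named numeric vectors with names A, B, D.")
  }
  if (any(s < 0) || any(l < 0)) abort("Breakpoint depths must be >= 0.")
  if (any(xor(s > 0, l > 0))) {
    abort(paste(
      "A pericentric inversion spans the centromere, so each inverted",
      "subgenome needs a positive breakpoint depth on both arms",
      "(and an absent one zero on both)."
    ))
  }
  structure(
    list(s = s, l = l, present = unname(s > 0 & l > 0)),
    names_present = subg,
    class = "inversion_config"
  )
}

#' @export
print.inversion_config <- function(x, ...) {
  subg <- c("A", "B", "D")
  cat("<inversion_config>\n")
  for (i in seq_along(subg)) {
    if (x$present[i]) {
      cat(sprintf("  %s: inverted  (short-arm depth %g, long-arm depth %g)\n",
                  subg[i], x$s[i], x$l[i]))
    } else {
      cat(sprintf("  %s: not inverted\n", subg[i]))
    }
  }
  invisible(x)
}

# Format a triplet of homoeologous-set memberships ("S"/"L" roles per
# subgenome) as the observable arm triplet of a group, honouring the
# group-4 homoeology swap. roles: character matrix/data frame cols A,B,D.
format_triplet <- function(group, role_A, role_B, role_D) {
  paste(
    expected_arm(group, "A", role_A),
    expected_arm(group, "B", role_B),
    expected_arm(group, "D", role_D),
    sep = "/"
  )
}

#' Arm-location pattern of a probe gene under an inversion configuration
#'
#' A probe gene sits at some depth from the centromere on one ancestral
#' homoeologous arm set (`"S"` or `"L"`) in all three subgenomes. On each
#' subgenome carrying a pericentric inversion whose breakpoint on that arm
#' is deeper than the probe, the probe's copy is relocated to the opposite
#' arm. The resulting observable triplet is returned in canonical arm
#' notation for the requested group (so the group-4 arm swap is applied
#' automatically).
#'
#' @param config An [inversion_config()].
#' @param origin `"S"` or `"L"`: the ancestral homoeologous arm set of the
#'   probe.
#' @param depth Positive probe depth, in the same units as the breakpoint
#'   depths. Must differ from every breakpoint depth (general position).
#' @param group Homoeologous group used for arm labels (default 6, as in the
#'   classic worked example).
#'
#' @return A single triplet string such as `"6AS/6BS/6DL"`.
#'
#' @examples
#' cfg <- inversion_config(s = c(A = 0, B = 0, D = 2), l = c(A = 0, B = 0, D = 2))
#' derive_pattern(cfg, "S", 1)  # moved only on D
#' @export
derive_pattern <- function(config, origin, depth, group = 6) {
  stopifnot(inherits(config, "inversion_config"))
  if (!origin %in% c("S", "L") || length(origin) != 1L) {
    abort('`origin` must be "S" or "L".')
  }
  if (length(depth) != 1L || !is.finite(depth) || depth <= 0) {
    abort("`depth` must be a single positive number.")
  }
  bp <- if (origin == "S") config$s else config$l
  if (any(config$present & abs(bp - depth) < .Machine$double.eps^0.5)) {
    abort("Probe depth coincides with a breakpoint depth (degenerate input).")
  }
  moved <- config$present & depth < bp
  role <- ifelse(moved, setdiff(c("S", "L"), origin), origin)
  format_triplet(group, role[1], role[2], role[3])
}

#' Enumerate the nonstandard patterns achievable under a configuration
#'
#' Probes are placed in every depth interval delimited by the breakpoint
#' depths on each ancestral arm set, the observable triplet of each probe is
#' derived, and the distinct nonstandard triplets (those differing from both
#' of the group's expected homoeologous triplets) are collected. Probes
#' relocated on all three subgenomes produce a standard-appearing triplet
#' and therefore do not contribute.
#'
#' @inheritParams derive_pattern
#' @return Sorted character vector of distinct nonstandard triplet strings.
#'
#' @examples
#' nested <- inversion_config(s = c(A = 1, B = 2, D = 3),
#'                            l = c(A = 1, B = 2, D = 3))
#' enumerate_patterns(nested)
#' @export
enumerate_patterns <- function(config, group = 6) {
  stopifnot(inherits(config, "inversion_config"))
  exp_trip <- expected_triplets(group)
  short_arms <- exp_trip$short_set
  long_arms <- exp_trip$long_set
  standard <- c(paste(short_arms, collapse = "/"),
                paste(long_arms, collapse = "/"))
  pats <- character(0)
  for (origin in c("S", "L")) {
    bp <- if (origin == "S") config$s else config$l
    crit <- sort(unique(bp[config$present & bp > 0]))
    edges <- c(0, crit)
    probes <- c((edges[-1] + edges[-length(edges)]) / 2,
                max(edges) + 1)
    for (d in probes) {
      moved <- config$present & d < bp
      role <- if (origin == "S") ifelse(moved, "L", "S") else
        ifelse(moved, "S", "L")
      arms <- ifelse(role == "S", short_arms, long_arms)
      pats <- c(pats, paste(arms, collapse = "/"))
    }
  }
  sort(setdiff(unique(pats), standard))
}

# All canonical configurations with inversions on a given subset of
# subgenomes, breakpoint depths discretized to ranks 1..k (ties included).
canonical_configs <- function(n_inverted = 0:3) {
  subg <- c("A", "B", "D")
  configs <- list()
  for (k in intersect(n_inverted, 0:3)) {
    subsets <- utils::combn(subg, k, simplify = FALSE)
    if (k == 0L) subsets <- list(character(0))
    for (inv in subsets) {
      if (k == 0L) {
        configs[[length(configs) + 1L]] <- inversion_config()
        next
      }
      ranks <- expand.grid(rep(list(seq_len(k)), 2L * k))
      for (r in seq_len(nrow(ranks))) {
        sv <- lv <- c(A = 0, B = 0, D = 0)
        sv[inv] <- as.numeric(ranks[r, seq_len(k)])
        lv[inv] <- as.numeric(ranks[r, k + seq_len(k)])
        configs[[length(configs) + 1L]] <- inversion_config(sv, lv)
      }
    }
  }
  configs
}

#' Maximum number of nonstandard patterns from a single genotype
#'
#' Exhaustive search over all pericentric-inversion configurations of the
#' three homoeologues of one group: every subset of inverted subgenomes
#' crossed with every ordering-with-ties of short-arm and of long-arm
#' breakpoint depths (depths discretized to ranks; only comparisons matter).
#' Returns the maximum number of distinct nonstandard arm-location triplets
#' any single configuration -- i.e. any single genotype -- can produce.
#'
#' `closed_form_max()` is the analytic companion: with `k` inverted
#' homoeologues each arm side contributes at most `min(k, 2)` nonstandard
#' nested breakpoint subsets (the subset containing all three is
#' standard-appearing), giving 0, 2, 4, 4 for k = 0..3.
#'
#' @param n_inverted Integer vector restricting the search to configurations
#'   with these numbers of inverted homoeologues (default all, 0-3).
#' @param group Homoeologous group used for arm labels.
#'
#' @return A single integer.
#'
#' @examples
#' max_nonstandard_patterns()      # 4
#' closed_form_max(2)              # 4
#' @export
max_nonstandard_patterns <- function(n_inverted = 0:3, group = 6) {
  max(vapply(canonical_configs(n_inverted),
             function(cfg) length(enumerate_patterns(cfg, group = group)),
             integer(1)), 0L)
}

#' @rdname max_nonstandard_patterns
#' @param k Number of inverted homoeologues, 0-3.
#' @export
closed_form_max <- function(k) {
  if (length(k) != 1L || !k %in% 0:3) {
    abort("`k` must be a single integer between 0 and 3.")
  }
  2L * min(k, 2L)
}

#' Can a set of nonstandard patterns arise in a single genotype?
#'
#' Searches the canonical configuration space for a pericentric-inversion
#' configuration whose achievable nonstandard patterns form a superset of
#' the observed set. Since no single configuration can produce more than
#' four nonstandard patterns, any five-pattern set is infeasible --
#' observing one is evidence that some of the rearrangements arose in
#' different (aneuploid) genotypes rather than in the euploid line.
#'
#' @param observed Character vector of triplet strings (e.g.
#'   `"6AS/6BS/6DL"`), all from one homoeologous group. Standard triplets
#'   are ignored.
#' @param group Homoeologous group; inferred from `observed` if missing.
#'
#' @return A list with elements `feasible` (logical) and `witness` (an
#'   [inversion_config()] reproducing the observed patterns, or `NULL`).
#'
#' @examples
#' feasibility_check(c("6AS/6BS/6DL", "6AS/6BL/6DL",
#'                     "6AL/6BS/6DS", "6AL/6BL/6DS"))$feasible
#' @export
feasibility_check <- function(observed, group = NULL) {
  observed <- unique(observed)
  if (length(observed) == 0L) {
    return(list(feasible = TRUE, witness = inversion_config()))
  }
  arms <- strsplit(observed, "/", fixed = TRUE)
  if (any(lengths(arms) != 3L)) {
    abort("Each observed pattern must be a triplet like \"6AS/6BL/6DL\".")
  }
  parsed <- parse_arm(unlist(arms))
  if (length(unique(parsed$group)) != 1L) {
    abort("All observed patterns must belong to one homoeologous group.")
  }
  if (is.null(group)) group <- parsed$group[1]
  if (group != parsed$group[1]) {
    abort("`group` does not match the group of the observed patterns.")
  }
  bad <- vapply(arms, function(a) {
    length(unique(substr(a, 2, 2))) != 3L
  }, logical(1))
  if (any(bad)) {
    abort("Each triplet must contain one arm per subgenome (A, B, D).")
  }
  exp_trip <- expected_triplets(group)
  standard <- c(paste(exp_trip$short_set, collapse = "/"),
                paste(exp_trip$long_set, collapse = "/"))
  observed <- setdiff(observed, standard)
  if (length(observed) == 0L) {
    return(list(feasible = TRUE, witness = inversion_config()))
  }
  for (cfg in canonical_configs()) {
    if (all(observed %in% enumerate_patterns(cfg, group = group))) {
      return(list(feasible = TRUE, witness = cfg))
    }
  }
  list(feasible = FALSE, witness = NULL)
}
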