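test_that("direction counts attribute each transfer to the minority chromosome", {
  patterns <- dplyr::bind_rows(
    make_patterns("1A", n_sl = 8, n_ls = 20),
    make_patterns("2D", n_sl = 0, n_ls = 1)
  )
  counts <- direction_counts(patterns)
  expect_equal(counts$n_short_to_long[counts$chromosome == "1A"], 8L)
  expect_equal(counts$n_long_to_short[counts$chromosome == "1A"], 20L)
  expect_equal(counts$n_long_to_short[counts$chromosome == "2D"], 1L)
  expect_equal(nrow(direction_counts(make_patterns("1A", 0, 0))), 0L)
})

test_that("co-mapping requires loci from both arms within tolerance", {
  # pericentromeric compression: everything at one locus
  pos <- tibble::tibble(cM = rep(78.56, 25),
                        side = rep(c("S", "L"), c(17, 8)))
  expect_true(comap_test(pos))
  # distal loci on each arm: not linked
  pos2 <- tibble::tibble(cM = c(10, 90), side = c("S", "L"))
  expect_false(comap_test(pos2, epsilon = 2))
  expect_true(comap_test(pos2, epsilon = 100))
  # no mapped gene in one direction
  pos3 <- tibble::tibble(cM = c(10, 12), side = c("S", "S"))
  expect_false(comap_test(pos3))
  expect_false(comap_test(pos3[0, ]))
})

test_that("evidence classes follow the count and co-mapping criteria", {
  calls <- call_inversions_from_counts(
    tibble::tibble(
      chromosome = c("1A", "4D", "1B", "2A"),
      n_short_to_long = c(8L, 20L, 3L, 2L),
      n_long_to_short = c(20L, 0L, 3L, 1L)
    ),
    comap = c(TRUE, FALSE, FALSE, TRUE)
  )
  cls <- setNames(calls$class, calls$chromosome)
  expect_equal(unname(cls["1A"]), "strong")
  # one-sided evidence with 11+ genes: putative regardless of co-mapping
  expect_equal(unname(cls["4D"]), "putative")
  # meets both count criteria but loci do not co-map: no call
  expect_equal(unname(cls["1B"]), "none")
  expect_equal(unname(cls["2A"]), "none")
  expect_error(
    call_inversions_from_counts(
      tibble::tibble(chromosome = "1A", n_short_to_long = -1L,
                     n_long_to_short = 0L)
    ),
    "non-negative"
  )
})

test_that("emitted calls always satisfy the class invariants", {
  set.seed(20)
  for (i in 1:50) {
    n_sl <- sample(0:25, 1)
    n_ls <- sample(0:25, 1)
    comap <- sample(c(TRUE, FALSE), 1)
    calls <- call_inversions_from_counts(
      tibble::tibble(chromosome = "5B", n_short_to_long = n_sl,
                     n_long_to_short = n_ls),
      comap = comap
    )
    total <- n_sl + n_ls
    minority <- min(n_sl, n_ls)
    if (calls$class == "strong") {
      expect_true(total >= 6 && minority >= 3 && comap)
    } else if (calls$class == "putative") {
      expect_true(total >= 11 && minority < 3)
    }
  }
})

test_that("adding a nonstandard gene never demotes a chromosome", {
  rank_class <- function(x) match(x, c("none", "putative", "strong"))
  set.seed(21)
  for (i in 1:60) {
    n_sl <- sample(0:15, 1); n_ls <- sample(0:15, 1)
    comap <- sample(c(TRUE, FALSE), 1)
    base <- call_inversions_from_counts(
      tibble::tibble(chromosome = "6A", n_short_to_long = n_sl,
                     n_long_to_short = n_ls), comap = comap)$class
    for (d in list(c(1, 0), c(0, 1))) {
      more <- call_inversions_from_counts(
        tibble::tibble(chromosome = "6A", n_short_to_long = n_sl + d[1],
                       n_long_to_short = n_ls + d[2]), comap = comap)$class
      if (base == "strong") expect_equal(more, "strong")
    }
  }
})

test_that("full calling path: planted inversion strong, 1B-like case none", {
  sim <- simulate_genome(quiet_config("2B", genes_per_group = 80), seed = 9)
  pat <- classify_arm_patterns(emit_hits(sim))
  calls <- call_inversions(pat, map = sim$map)
  expect_s3_class(calls, "inversion_calls")
  expect_equal(nrow(calls), 21L)
  expect_equal(calls$class[calls$chromosome == "2B"], "strong")
  expect_true(all(calls$class[calls$chromosome != "2B"] == "none"))
  expect_true(calls$comap_satisfied[calls$chromosome == "2B"])

  # a 1B-like chromosome: 3 + 3 transfers whose loci do not co-map
  patterns <- make_patterns("1B", n_sl = 3, n_ls = 3)
  map <- tibble::tibble(
    gene = patterns$gene, chromosome = "1B",
    cM = c(5, 6, 7, 80, 81, 82)  # short-arm loci far from long-arm loci
  )
  calls2 <- call_inversions(patterns, map = map, epsilon = 2)
  expect_equal(calls2$class[calls2$chromosome == "1B"], "none")
  expect_false(calls2$comap_satisfied[calls2$chromosome == "1B"])
  # the identical counts with co-mapping loci are strong
  map$cM <- rep(50, 6)
  calls3 <- call_inversions(patterns, map = map, epsilon = 2)
  expect_equal(calls3$class[calls3$chromosome == "1B"], "strong")
})

test_that("strict mode excludes flagged genes but tallies them", {
  patterns <- dplyr::bind_rows(
    make_patterns("6A", n_sl = 4, n_ls = 4),
    make_patterns("6A", n_sl = 3, n_ls = 0,
                  status = "flagged_ambiguous_secondary",
                  gene_prefix = "6Af")
  )
  lax <- direction_counts(patterns)
  expect_equal(lax$n_short_to_long, 7L)
  expect_equal(lax$n_flagged, 3L)
  strict <- direction_counts(patterns, strict = TRUE)
  expect_equal(strict$n_short_to_long, 4L)
})

test_that("3B calls carry a data-quality warning", {
  patterns <- make_patterns("3B", n_sl = 6, n_ls = 6)
  map <- tibble::tibble(gene = patterns$gene, chromosome = "3B", cM = 50)
  expect_warning(calls <- call_inversions(patterns, map = map), "3B")
  expect_match(calls$warning[calls$chromosome == "3B"], "pseudomolecule")
})

test_that("the report table mirrors counts and sums to the accepted total", {
  patterns <- dplyr::bind_rows(
    make_patterns("1A", 8, 20),
    make_patterns("4D", 20, 0)
  )
  calls <- call_inversions(patterns,
                           map = tibble::tibble(gene = character(0),
                                                chromosome = character(0),
                                                cM = numeric(0)))
  rt <- report_table(calls)
  expect_equal(nrow(rt), 22L)
  expect_equal(rt$n_total[rt$chromosome == "Total"], 48L)
  expect_equal(
    rt$n_total[rt$chromosome == "Total"],
    sum(patterns$classification == "nonstandard")
  )
  # empty pattern list: all-zero table
  rt0 <- report_table(call_inversions(make_patterns("1A", 0, 0), map = NULL))
  expect_true(all(rt0$n_total == 0L))

  # tidy/glance accessors
  expect_equal(nrow(tidy(calls)), 21L)
  g <- glance(calls)
  expect_equal(g$n_nonstandard_genes, 48L)
  expect_equal(g$n_putative, 1L)
})
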