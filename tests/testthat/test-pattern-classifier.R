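test_that("top_hits ranks by bitscore with a total tie-break chain", {
  h <- make_gene_hits("g", c("1AS", "1BS", "1DS", "2AS", "2BS"),
                      bitscores = c(500, 700, 600, 400, 300))
  expect_equal(top_hits(h, 3)$sseqid, c("1BS", "1DS", "1AS"))
  # bitscore and e-value tied: identity then library id decide,
  # deterministically
  h2 <- dplyr::bind_rows(
    make_hit("g", "2BS", 500, pident = 95),
    make_hit("g", "1AS", 500, pident = 97),
    make_hit("g", "1DL", 500, pident = 95)
  )
  expect_equal(top_hits(h2, 3)$sseqid, c("1AS", "1DL", "2BS"))
  # k larger than the number of hits truncates gracefully
  expect_equal(nrow(top_hits(h, 10)), 5L)
  expect_equal(nrow(top_hits(h[0, ], 3)), 0L)
  # multiple HSPs on one library: only the best one is ranked
  h3 <- dplyr::bind_rows(make_hit("g", "1AS", 700), make_hit("g", "1AS", 650),
                         make_hit("g", "1BS", 660))
  expect_equal(top_hits(h3, 2)$bitscore, c(700, 660))
})

test_that("triplets on one group classify as standard or named transfers", {
  hits <- dplyr::bind_rows(
    make_gene_hits("transfer_1d", c("1AL", "1BL", "1DS")),
    make_gene_hits("standard_2", c("2AS", "2BS", "2DS")),
    make_gene_hits("group4_alt", c("4AL", "4BL", "4DL")),
    make_gene_hits("group4_std", c("4AL", "4BS", "4DS"))
  )
  pat <- classify_arm_patterns(hits)
  row <- function(g) pat[pat$gene == g, ]
  expect_equal(row("transfer_1d")$classification, "nonstandard")
  expect_equal(row("transfer_1d")$transfer, "1DL->1DS")
  expect_equal(row("transfer_1d")$direction, "long_to_short")
  expect_equal(row("standard_2")$classification, "standard")
  # 4AL/4BL/4DL is nonstandard for group 4 (expected sets are swapped on 4A)
  expect_equal(row("group4_alt")$classification, "nonstandard")
  expect_equal(row("group4_alt")$transfer, "4AS->4AL")
  expect_equal(row("group4_std")$classification, "standard")
})

test_that("exclusion rules fire: both arms, non-homoeologous top-3, incomplete", {
  hits <- dplyr::bind_rows(
    # both arms of 1A detected: arm of origin is undecidable
    make_gene_hits("both_arms", c("1AS", "1AL", "1BL", "1DL")),
    # third-best hit off group displaces a homoeologue
    make_gene_hits("off_group", c("1AL", "1BL", "2DS", "1DS")),
    # hits on different chromosomes but not both arms of one
    make_gene_hits("two_chroms", c("1AS", "2AL", "1BS")),
    # only two homoeologous hits
    make_gene_hits("two_hits", c("1AS", "1BS")),
    # e-value above threshold removes the third hit
    dplyr::bind_rows(
      make_gene_hits("high_evalue", c("3AS", "3DS")),
      make_hit("high_evalue", "3BS", 600, evalue = 1e-3)
    )
  )
  pat <- classify_arm_patterns(hits)
  status <- setNames(pat$status, pat$gene)
  expect_equal(unname(status["both_arms"]), "excluded_both_arms")
  expect_equal(unname(status["off_group"]), "excluded_top3_not_homoeologous")
  expect_equal(unname(status["two_chroms"]), "excluded_top3_not_homoeologous")
  expect_equal(unname(status["two_hits"]), "excluded_incomplete")
  expect_equal(unname(status["high_evalue"]), "excluded_incomplete")
})

test_that("whole-chromosome 3B hits are located by midpoint coordinate", {
  hits <- dplyr::bind_rows(
    make_gene_hits("on_3bs", c("3AS", "3DS")),
    make_hit("on_3bs", "3B", 600, sstart = 100e6),
    make_gene_hits("centromeric", c("3AS", "3DS")),
    make_hit("centromeric", "3B", 600, sstart = 300e6),
    make_gene_hits("moved_3b", c("3AS", "3DS")),
    make_hit("moved_3b", "3B", 600, sstart = 500e6)
  )
  pat <- classify_arm_patterns(hits)
  row <- function(g) pat[pat$gene == g, ]
  expect_equal(row("on_3bs")$classification, "standard")
  expect_equal(row("on_3bs")$triplet, "3AS/3BS/3DS")
  # centromeric-interval hits are dropped before triplet formation
  expect_equal(row("centromeric")$status, "excluded_incomplete")
  expect_equal(row("moved_3b")$classification, "nonstandard")
  expect_equal(row("moved_3b")$transfer, "3BS->3BL")
})

test_that("secondary hits on an opposite triplet arm flag ambiguity", {
  base <- make_gene_hits("flagme", c("1AL", "1BL", "1DS"),
                         bitscores = c(800, 790, 780))
  close_opposite <- make_hit("flagme", "1DL", 760)   # within 10% of 780
  far_opposite <- make_hit("far", "1DL", 500)        # well outside
  base_far <- make_gene_hits("far", c("1AL", "1BL", "1DS"),
                             bitscores = c(800, 790, 780))
  unrelated <- make_hit("unrel", "5AS", 770)
  base_unrel <- make_gene_hits("unrel", c("1AL", "1BL", "1DS"),
                               bitscores = c(800, 790, 780))
  pat <- classify_arm_patterns(dplyr::bind_rows(
    base, close_opposite, base_far, far_opposite, base_unrel, unrelated
  ))
  status <- setNames(pat$status, pat$gene)
  expect_equal(unname(status["flagme"]), "flagged_ambiguous_secondary")
  expect_equal(unname(status["far"]), "accepted")
  expect_equal(unname(status["unrel"]), "accepted")
  # flagged genes keep their triplet
  expect_equal(pat$triplet[pat$gene == "flagme"], "1AL/1BL/1DS")
})

test_that("unknown subject libraries are rejected by name", {
  hits <- make_gene_hits("g", c("1AS", "9XY"))
  expect_error(classify_arm_patterns(hits), "9XY")
})

test_that("classification is total, conserved and deterministic", {
  sim <- simulate_genome(
    simulation_config(genes_per_group = 40,
                      inversions = list("2B" = c(s = 0.25, l = 0.25))),
    seed = 5
  )
  hits <- emit_hits(sim)
  pat <- classify_arm_patterns(hits)
  expect_equal(nrow(pat), length(unique(hits$qseqid)))
  expect_equal(anyDuplicated(pat$gene), 0L)
  s <- attr(pat, "summary")
  expect_equal(
    s$accepted + s$flagged_ambiguous_secondary + s$excluded_both_arms +
      s$excluded_top3_not_homoeologous + s$excluded_incomplete,
    s$n_genes
  )
  # byte-identical on identical input
  pat2 <- classify_arm_patterns(hits)
  expect_identical(as.data.frame(pat), as.data.frame(pat2))
  # shuffling input rows does not change the result
  pat3 <- classify_arm_patterns(hits[sample(nrow(hits)), ])
  expect_identical(as.data.frame(pat), as.data.frame(pat3))
  # no accepted triplet mixes homoeologous groups
  acc <- pat[pat$status %in% c("accepted", "flagged_ambiguous_secondary"), ]
  arm_groups <- lapply(strsplit(acc$triplet, "/"),
                       function(a) unique(substr(a, 1, 1)))
  expect_true(all(lengths(arm_groups) == 1L))
})

test_that("ortholog sets are assembled by source priority over RBH clusters", {
  genes <- tibble::tibble(
    gene = c("b1", "u1", "u2", "a1", "e1"),
    source = c("Brachypodium", "T_urartu", "T_urartu", "Ae_tauschii",
               "wheat_EST")
  )
  rbh <- tibble::tibble(gene1 = c("b1", "u1"), gene2 = c("u1", "a1"))
  out <- build_ortholog_set(genes, rbh)
  expect_equal(nrow(out), 3L)
  # cluster {b1, u1, a1} represented by the Brachypodium member
  expect_true("b1" %in% out$gene)
  expect_equal(out$n_members[out$gene == "b1"], 3L)
  # the unpaired T. urartu gene is retained as its own record
  expect_true("u2" %in% out$gene)
  expect_true("e1" %in% out$gene)
  # a within-source reciprocal pair is ill-formed input
  expect_error(
    build_ortholog_set(genes,
                       tibble::tibble(gene1 = "u1", gene2 = "u2")),
    "Within-source"
  )
  expect_error(
    build_ortholog_set(genes, tibble::tibble(gene1 = "b1", gene2 = "zz")),
    "unknown gene"
  )
})
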