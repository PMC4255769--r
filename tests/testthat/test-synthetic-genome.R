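test_that("simulation is deterministic given the seed and conserves genes", {
  cfg <- simulation_config(genes_per_group = 30,
                           inversions = list("1A" = c(s = 0.2, l = 0.2)))
  s1 <- simulate_genome(cfg, seed = 17)
  s2 <- simulate_genome(cfg, seed = 17)
  expect_identical(s1$model, s2$model)
  expect_identical(s1$truth, s2$truth)
  expect_identical(emit_hits(s1), emit_hits(s2))
  s3 <- simulate_genome(cfg, seed = 18)
  expect_false(identical(s1$model, s3$model))
  # placements: one copy per subgenome for every configured gene
  expect_equal(nrow(s1$model), 30L * 7L * 3L)
  expect_equal(dplyr::count(s1$truth, gene)$n, rep(3L, 30L * 7L))
  expect_error(simulate_genome(cfg), "seed")
  expect_error(
    simulation_config(inversions = list("9Z" = c(s = 0.2, l = 0.2))),
    "9Z"
  )
  expect_error(simulation_config(loss_rate = 1.2), "0, 1")
})

test_that("no rearrangements are planted unless configured", {
  sim <- simulate_genome(quiet_config(), seed = 4)
  expect_equal(sum(sim$truth$moved_by_euploid), 0L)
  expect_equal(sum(sim$truth$moved_by_aneuploid), 0L)
  expect_equal(sum(sim$truth_patterns$nonstandard), 0L)
})

test_that("a nested triple inversion emits exactly the four classic patterns", {
  cfg <- simulation_config(
    genes_per_group = 300, loss_rate = 0, dup_rate = 0, decoy_rate = 0,
    inversions = list("6A" = c(s = 0.1, l = 0.1),
                      "6B" = c(s = 0.2, l = 0.2),
                      "6D" = c(s = 0.3, l = 0.3))
  )
  sim <- simulate_genome(cfg, seed = 8)
  got <- sort(unique(
    sim$truth_patterns$triplet[sim$truth_patterns$nonstandard &
                                 sim$truth_patterns$group == 6]
  ))
  expect_setequal(got, fig3a_patterns)
})

test_that("euploid-only simulations never exceed four patterns per group", {
  set.seed(41)
  for (rep in 1:5) {
    chrs <- paste0(6, sample(c("A", "B", "D"), sample(1:3, 1)))
    inv <- lapply(chrs, function(x) {
      c(s = runif(1, 0.05, 0.45), l = runif(1, 0.05, 0.45))
    })
    names(inv) <- chrs
    cfg <- simulation_config(genes_per_group = 150, loss_rate = 0,
                             dup_rate = 0, decoy_rate = 0,
                             inversions = inv)
    sim <- simulate_genome(cfg, seed = 100 + rep)
    n_pat <- sim$truth_patterns |>
      dplyr::filter(nonstandard, group == 6) |>
      dplyr::distinct(triplet) |>
      nrow()
    expect_lte(n_pat, max_nonstandard_patterns())
  }
})

test_that("matched aneuploid artifacts escape the single-genotype bound", {
  sim <- simulate_genome(aneuploid_escape_config(), seed = 7)
  pats <- sort(unique(
    sim$truth_patterns$triplet[sim$truth_patterns$nonstandard &
                                 sim$truth_patterns$group == 6]
  ))
  expect_gte(length(pats), 5L)
  expect_false(feasibility_check(pats)$feasible)
})

test_that("unmatched artifacts create both-arm and missing-gene exclusions", {
  cfg <- simulation_config(
    genes_per_group = 80, loss_rate = 0, dup_rate = 0, decoy_rate = 0,
    artifacts = list("6DL" = c(s = 0.3, l = 0.3))
  )
  sim <- simulate_genome(cfg, seed = 12)
  t6d <- dplyr::filter(sim$truth, chromosome == "6D")
  # short-arm genes shallower than the artifact appear in both libraries
  expect_gt(sum(t6d$in_short_lib & t6d$in_long_lib), 0L)
  # long-arm genes shallower than the artifact appear in neither
  expect_gt(sum(!t6d$in_short_lib & !t6d$in_long_lib), 0L)
  pat <- classify_arm_patterns(emit_hits(sim))
  expect_gt(attr(pat, "summary")$excluded_both_arms, 0L)
  expect_gt(attr(pat, "summary")$excluded_incomplete, 0L)
})

test_that("loss and duplication rates shape the emitted hit table", {
  cfg <- simulation_config(genes_per_group = 20, loss_rate = 0,
                           dup_rate = 1, decoy_rate = 0)
  hits <- emit_hits(simulate_genome(cfg, seed = 2))
  expect_true(all(dplyr::count(hits, qseqid)$n >= 4L))

  cfg2 <- simulation_config(genes_per_group = 20, loss_rate = 1,
                            dup_rate = 0, decoy_rate = 0)
  sim2 <- simulate_genome(cfg2, seed = 2)
  expect_equal(nrow(emit_hits(sim2)), 0L)
  expect_true(all(sim2$truth$lost))
})

test_that("map positions are monotone and compress in the pericentromere", {
  sim <- simulate_genome(quiet_config(genes_per_group = 120), seed = 6)
  # uniform profile: cM proportional to position along the chromosome
  uni <- genetic_map(sim$model, suppression = 1, map_length_cm = 150)
  m <- dplyr::inner_join(sim$model, uni, by = c("gene", "chromosome"))
  x <- ifelse(m$side == "S", 0.5 * (1 - m$depth_now),
              0.5 + 0.5 * m$depth_now)
  expect_equal(m$cM.y, 150 * x, tolerance = 1e-10)

  # suppressed profile: all pericentromeric genes of a chromosome co-map
  sup <- genetic_map(sim$model, suppression = 0.02)
  peri <- sim$model |>
    dplyr::filter(chromosome == "5D", depth_now < 0.3) |>
    dplyr::inner_join(sup, by = c("gene", "chromosome"))
  expect_gt(nrow(peri), 5L)
  expect_lt(diff(range(peri$cM.y)), 2)

  expect_error(genetic_map(sim$model, suppression = 0), "monotone")
})

test_that("moved pericentromeric genes satisfy the co-mapping test", {
  sim <- simulate_genome(quiet_config("7A", genes_per_group = 80), seed = 15)
  moved <- sim$truth |>
    dplyr::filter(moved_by_euploid, chromosome == "7A") |>
    dplyr::inner_join(sim$map, by = c("gene", "chromosome")) |>
    dplyr::transmute(cM = cM, side = substr(arm, 3, 3))
  expect_true(comap_test(moved, epsilon = 2))
})
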