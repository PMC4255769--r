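# Shared fixture builders: everything is generated in code at test time.

# One BLAST tabular row per call; defaults make a comfortable true hit.
make_hit <- function(gene, lib, bitscore, pident = 95, evalue = 1e-50,
                     sstart = 1000L, len = 400L) {
  tibble::tibble(
    qseqid = gene, sseqid = lib, pident = pident, length = len,
    mismatch = as.integer(round(len * (100 - pident) / 100)), gapopen = 0L,
    qstart = 1L, qend = len, sstart = as.integer(sstart),
    send = as.integer(sstart + len - 1L), evalue = evalue,
    bitscore = bitscore
  )
}

# Hits for one gene across several libraries, bitscores descending by
# default so ranks follow the order given.
make_gene_hits <- function(gene, libs, bitscores = NULL, ...) {
  if (is.null(bitscores)) bitscores <- seq(800, by = -10,
                                           length.out = length(libs))
  purrr::map2_dfr(libs, bitscores,
                  function(lib, bs) make_hit(gene, lib, bs, ...))
}

# Minimal arm_patterns-shaped tibble for caller tests: n_sl genes moved
# short-to-long and n_ls long-to-short on one chromosome.
make_patterns <- function(chromosome, n_sl, n_ls,
                          status = "accepted", gene_prefix = chromosome) {
  side <- substr(chromosome, 3, 3)
  n <- n_sl + n_ls
  if (n == 0) {
    return(tibble::tibble(
      gene = character(0), status = character(0), group = integer(0),
      triplet = character(0), classification = character(0),
      transfer = character(0), chromosome = character(0),
      direction = character(0)
    ))
  }
  tibble::tibble(
    gene = sprintf("%s_mv%03d", gene_prefix, seq_len(n)),
    status = status,
    group = as.integer(substr(chromosome, 1, 1)),
    triplet = NA_character_,
    classification = "nonstandard",
    transfer = NA_character_,
    chromosome = chromosome,
    direction = rep(c("short_to_long", "long_to_short"), c(n_sl, n_ls))
  )
}

# The classic nested triple-inversion configuration (deepest on D).
nested_config <- function() {
  inversion_config(s = c(A = 1, B = 2, D = 3), l = c(A = 1, B = 2, D = 3))
}

fig3a_patterns <- c("6AS/6BS/6DL", "6AS/6BL/6DL",
                    "6AL/6BS/6DS", "6AL/6BL/6DS")

# Noise-free simulation settings with inversions planted on `chromosomes`.
quiet_config <- function(chromosomes = character(0), depth = 0.25,
                         genes_per_group = 60, ...) {
  inv <- lapply(chromosomes, function(x) c(s = depth, l = depth))
  names(inv) <- chromosomes
  simulation_config(genes_per_group = genes_per_group, loss_rate = 0,
                    dup_rate = 0, decoy_rate = 0, inversions = inv, ...)
}

# The documented aneuploid-artifact configuration whose observable pattern
# set escapes the single-genotype bound: euploid inversions on 6B and 6D
# plus a shallower artifact inversion shared by both 6D arm libraries
# (a restructured double-ditelosomic source line), which turns the 6D
# moved set into an annulus.
aneuploid_escape_config <- function(genes_per_group = 200) {
  simulation_config(
    genes_per_group = genes_per_group,
    loss_rate = 0, dup_rate = 0, decoy_rate = 0,
    inversions = list("6B" = c(s = 0.3, l = 0.3),
                      "6D" = c(s = 0.4, l = 0.4)),
    artifacts = list("6DS" = c(s = 0.2, l = 0.2),
                     "6DL" = c(s = 0.2, l = 0.2))
  )
}

classified_nonstandard <- function(patterns) {
  sort(patterns$gene[!is.na(patterns$classification) &
                       patterns$classification == "nonstandard"])
}

truth_nonstandard <- function(sim) {
  sort(sim$truth_patterns$gene[sim$truth_patterns$nonstandard])
}
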