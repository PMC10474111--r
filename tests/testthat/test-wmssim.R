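test_that("genome generation is deterministic and respects GC content", {
  g1 <- generate_genomes(2, 1000, seed = 7)
  g2 <- generate_genomes(2, 1000, seed = 7)
  expect_identical(g1[[1]]$sequences, g2[[1]]$sequences)
  expect_false(identical(g1[[1]]$sequences, generate_genomes(2, 1000, seed = 8)[[1]]$sequences))

  g <- generate_genomes(1, 1e5, gc = 0.5, seed = 9)[[1]]$sequences[[1]]
  gc_obs <- sum(strsplit(g, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 5e4), 4 * sqrt(1e5 * 0.25))  # binomial 4 sigma

  g30 <- generate_genomes(1, 1e5, gc = 0.3, seed = 9)[[1]]$sequences[[1]]
  gc30 <- sum(strsplit(g30, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc30 - 3e4), 4 * sqrt(1e5 * 0.3 * 0.7))
})

test_that("independently generated genomes share essentially no tags", {
  e <- synthetic_enzyme()
  g <- generate_genomes(2, 5e4, seed = 17)
  t1 <- unique(oracle_tags(g[[1]]$sequences[[1]], e))
  t2 <- unique(oracle_tags(g[[2]]$sequences[[1]], e))
  expect_lte(length(intersect(t1, t2)), 1)  # 4^-20 collision scale
})

test_that("composition draws carry a consistent dual ground truth", {
  u <- tiny_universe()
  truth <- sample_composition(u$genomes, 1, seed = 5)
  expect_equal(truth$T_true, 1)
  expect_equal(truth$S_true, 1)

  truth <- sample_composition(u$genomes, 8, seed = 6)
  expect_equal(sum(truth$T_true), 1, tolerance = 1e-9)
  expect_equal(sum(truth$S_true), 1, tolerance = 1e-9)
  # S* prop. to T* x L, and converting back recovers T*
  expect_equal(truth$S_true, truth$T_true * truth$L / sum(truth$T_true * truth$L),
               tolerance = 1e-12)
  t_back <- (truth$S_true / truth$L) / sum(truth$S_true / truth$L)
  expect_equal(t_back, truth$T_true, tolerance = 1e-9)
  expect_error(sample_composition(u$genomes, 999, seed = 1), "exceeds")
})

test_that("equal taxonomic abundance with unequal genome lengths weights S by length", {
  gs <- list(genome_record("g1", "spA", oracle_random_dna(1000, 1)),
             genome_record("g2", "spB", oracle_random_dna(2000, 2)))
  # richness 2 = whole pool; abundances random but S must follow T*L
  truth <- sample_composition(gs, 2, seed = 3)
  expect_equal(truth$S_true / sum(truth$S_true),
               truth$T_true * truth$L / sum(truth$T_true * truth$L))
  # the documented 50/50 over 1Mb/2Mb case
  manual <- c(0.5, 0.5) * c(1e6, 2e6)
  expect_equal(manual / sum(manual), c(1/3, 2/3))
})

test_that("normalized log-normal draws have the stated meanlog/sdlog", {
  u <- tiny_universe()
  set.seed(1234)
  draws <- replicate(2000, {
    tr <- sample_composition(u$genomes, 10, seed = sample.int(1e6, 1))
    tr$T_true
  })
  expect_true(all(abs(colSums(draws) - 1) < 1e-9))
  # recover unnormalized scale: log of ratios is a difference of normals;
  # var(log T_i - log T_j) = 2 sdlog^2
  lr <- log(draws[1, ] / draws[2, ])
  expect_lt(abs(mean(lr)), 3 * sqrt(2) / sqrt(ncol(draws)) * 1.2)
  expect_lt(abs(sd(lr) - sqrt(2)), 3 * sd(lr) / sqrt(2 * ncol(draws)) + 0.05)
})

test_that("genome mutation is a per-base substitution process", {
  s <- oracle_random_dna(1000, 77)
  expect_identical(mutate_genome(s, 0, seed = 1), s)
  full <- mutate_genome(s, 1, seed = 1)
  expect_true(all(strsplit(full, "")[[1]] != strsplit(s, "")[[1]]))
  expect_equal(nchar(full), nchar(s))

  big <- oracle_random_dna(1e5, 78)
  mut <- mutate_genome(big, 0.03, seed = 2)
  ndiff <- sum(strsplit(mut, "")[[1]] != strsplit(big, "")[[1]])
  expect_lt(abs(ndiff - 3000), 4 * sqrt(1e5 * 0.03 * 0.97))
  # genome_record interface preserves structure
  rec <- mutate_genome(genome_record("g", "sp", big), 0.01, seed = 3)
  expect_s3_class(rec, "genome_record")
  expect_equal(rec$length, 1e5)
})

test_that("error-free reads are exact (possibly reverse-complemented) substrings", {
  u <- tiny_universe()
  truth <- sample_composition(u$genomes, 1, seed = 11)
  g <- Filter(function(x) x$species_id == truth$species_id, u$genomes)[[1]]
  sim <- simulate_reads(truth, u$genomes, sim_config(depth = 200, error_rate = 0, seed = 11))
  expect_length(sim$reads, 200)
  genome <- g$sequences[[1]]
  both <- c(genome, oracle_revcomp(genome))
  expect_true(all(vapply(sim$reads, function(r)
    any(grepl(r, both, fixed = TRUE)), logical(1))))
})

test_that("reads are allocated to species by sequence abundance", {
  u <- tiny_universe()
  gs <- u$genomes[1:2]
  truth <- sample_composition(gs, 2, seed = 21)
  # force equal sequence abundance via equal lengths and equal T
  truth$T_true <- c(0.5, 0.5)
  truth$S_true <- truth$T_true * truth$L / sum(truth$T_true * truth$L)
  sim <- simulate_reads(truth, gs, sim_config(depth = 100000, seed = 21))
  n1 <- sum(sim$read_species == truth$species_id[1])
  expect_lt(abs(n1 - 50000), 4 * sqrt(100000 * 0.25))
})

test_that("simulation output is deterministic per seed, including files", {
  u <- tiny_universe()
  truth <- sample_composition(u$genomes, 4, seed = 31)
  cfg <- sim_config(depth = 5000, seed = 31)
  d1 <- withr::local_tempdir()
  s1 <- simulate_reads(truth, u$genomes, cfg, out = file.path(d1, "a"))
  s2 <- simulate_reads(truth, u$genomes, cfg, out = file.path(d1, "b"))
  expect_identical(s1$reads, s2$reads)
  expect_equal(unname(tools::md5sum(file.path(d1, "a.fastq"))),
               unname(tools::md5sum(file.path(d1, "b.fastq"))))
  # truth TSV round trip (seed recorded in header comment)
  expect_true(startsWith(readLines(file.path(d1, "a.truth.tsv"), n = 1), "# seed="))
  back <- read_truth(file.path(d1, "a.truth.tsv"))
  expect_equal(back$species_id, truth$species_id)
  expect_equal(back$T_true, truth$T_true, tolerance = 1e-12)
})

test_that("degenerate depth zero yields a valid empty simulation", {
  u <- tiny_universe()
  truth <- sample_composition(u$genomes, 2, seed = 41)
  sim <- simulate_reads(truth, u$genomes, sim_config(depth = 0, seed = 41))
  expect_length(sim$reads, 0)
})

test_that("paired mode emits opposite-strand mates at the fixed insert size", {
  u <- tiny_universe()
  truth <- sample_composition(u$genomes, 1, seed = 51)
  g <- Filter(function(x) x$species_id == truth$species_id, u$genomes)[[1]]
  sim <- simulate_reads(truth, u$genomes,
                        sim_config(depth = 100, error_rate = 0, paired = TRUE,
                                   insert_size = 250, seed = 51))
  expect_length(sim$reads, 100)
  genome <- g$sequences[[1]]
  m1 <- sim$reads[seq(1, 99, 2)]
  m2 <- sim$reads[seq(2, 100, 2)]
  pos_fwd <- function(r) {
    p <- regexpr(r, genome, fixed = TRUE)
    if (p < 0) p <- regexpr(oracle_revcomp(r), genome, fixed = TRUE)
    as.integer(p)
  }
  for (k in 1:10) {
    p1 <- pos_fwd(m1[k])
    p2 <- pos_fwd(m2[k])
    expect_gt(p1, 0)
    expect_gt(p2, 0)
    # mates sit at the two ends of a fixed-size fragment
    expect_equal(abs(p2 - p1), 250 - 100)
  }
})

test_that("mosaic novel genomes share segments with their donors only", {
  u <- tiny_universe()
  novel <- u$novel_genomes[[1]]
  e <- u$enzyme
  novel_tags <- unique(oracle_tags(novel$sequences[[1]], e))
  hits <- u$db$index[novel_tags, on = "tag", nomatch = NULL]
  donors <- unique(hits$species_id)
  expect_gt(nrow(hits), 0)          # shares some database tags
  expect_lte(length(donors), 3)     # at most segment_donors species
  # shared fraction is small relative to a genuine community member
  expect_lt(nrow(hits) / mean(u$db$species$E), 0.2)
})
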