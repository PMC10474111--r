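# Build a minimal tag_db directly from a genome list for formula tests.
formula_db <- function() {
  memo("formula_db", function() {
    gs <- lapply(1:4, function(i)
      genome_record(paste0("fg", i), sprintf("fsp%d", i),
                    oracle_random_dna(6000, 600 + i)))
    build_tag_db(gs, synthetic_enzyme())
  })
}

test_that("first-round features follow the documented formulas", {
  # synthetic counts: Q=100, U=50, E=100, R=1000
  db <- formula_db()
  sp <- db$species$species_id[1]
  E <- db$species$E[db$species$species_id == sp]
  tags <- db$index[species_id == sp]$tag
  # craft counts: U distinct tags, one of them seen Q-U+1 times
  U <- 50L
  Q <- 100L
  counts <- data.table::data.table(tag = tags[seq_len(U)],
                                   count = c(rep(1L, U - 1L), Q - U + 1L))
  f <- first_round(counts, db, total_reads = 1000)
  f <- f[species_id == sp]
  expect_equal(f$Q, Q)
  expect_equal(f$U, U)
  expect_equal(f$C, U / E)
  expect_equal(f$Q_tilde, Q / (U / E))
  expect_equal(f$N, Q / U)
  expect_equal(f$R_seq, Q * E / (U * 1000))
  expect_equal(f$G, sqrt(Q * U))
  expect_equal(f$logC, log(f$C))
  # the two printed forms of the taxonomic/sequence count agree
  expect_equal(f$N, f$Q_tilde / f$E, tolerance = 1e-12)
  expect_equal(f$R_seq, f$Q_tilde / 1000, tolerance = 1e-12)
})

test_that("worked feature example: Q=100 U=50 E=100 R=1000", {
  # direct arithmetic on the published formulas, independent of any DB
  Q <- 100; U <- 50; E <- 100; R <- 1000
  C <- U / E
  expect_equal(C, 0.5)
  expect_equal(Q / C, 200)
  expect_equal(Q / U, 2.0)
  expect_equal(Q * E / (U * R), 0.2)
  expect_equal(sqrt(Q * U), 70.71068, tolerance = 1e-6)
  # G of Q=16, U=4
  expect_equal(sqrt(16 * 4), 8)
})

test_that("full coverage at single copy gives C = 1 and N = 1", {
  db <- formula_db()
  sp <- db$species$species_id[2]
  tags <- db$index[species_id == sp]$tag
  counts <- data.table::data.table(tag = tags, count = 1L)
  f <- first_round(counts, db, total_reads = 500)[species_id == sp]
  expect_equal(f$C, 1)
  expect_equal(f$N, 1)
  expect_equal(f$U, f$E)
})

test_that("feature identities and scale behavior hold on random count tables", {
  db <- formula_db()
  set.seed(99)
  for (rep in 1:5) {
    counts <- db$index[sample(nrow(db$index), 400)][, .(tag)]
    counts[, count := sample(1:5, .N, replace = TRUE)]
    R <- 2000
    f1 <- first_round(counts, db, total_reads = R)
    expect_true(all(f1$U >= 1 & f1$U <= pmin(f1$Q, f1$E)))
    expect_true(all(f1$C > 0 & f1$C <= 1))
    expect_true(all(f1$N >= 1))
    expect_true(all(f1$G >= 1))
    expect_true(all(f1$Q_tilde >= f1$Q))
    expect_equal(f1$N, f1$Q_tilde / f1$E, tolerance = 1e-12)
    expect_equal(f1$N, f1$Q / f1$U, tolerance = 1e-12)
    expect_equal(f1$R_seq, f1$Q_tilde / R, tolerance = 1e-12)
    # doubling every tag count doubles Q, Q~ and N; C unchanged
    doubled <- data.table::copy(counts)[, count := count * 2L]
    f2 <- first_round(doubled, db, total_reads = R)
    expect_equal(f2$Q, 2 * f1$Q)
    expect_equal(f2$Q_tilde, 2 * f1$Q_tilde)
    expect_equal(f2$N, 2 * f1$N)
    expect_equal(f2$C, f1$C)
  }
})

test_that("adding reads from a species never decreases U, C or G", {
  u <- tiny_universe()
  truth <- sample_composition(u$genomes, 3, seed = 61)
  sim1 <- simulate_reads(truth, u$genomes, sim_config(depth = 5000, seed = 61))
  sim2 <- simulate_reads(truth, u$genomes, sim_config(depth = 20000, seed = 61))
  f1 <- first_round(digest_reads(sim1$reads, u$enzyme), u$db)
  f2 <- first_round(digest_reads(c(sim1$reads, sim2$reads), u$enzyme), u$db,
                    total_reads = 25000)
  j <- merge(f1, f2, by = "species_id")
  expect_true(all(j$U.y >= j$U.x))
  expect_true(all(j$C.y >= j$C.x))
  expect_true(all(j$G.y >= j$G.x))
})

test_that("enzyme provenance mismatches are rejected", {
  u <- tiny_universe()
  counts <- digest_reads("ACGTACGTACGT", toy_enzyme())
  expect_error(first_round(counts, u$db), "enzyme")
})

test_that("second-round abundance is the H-normalized share", {
  # two species with Q2/H = 10/100 and 30/100 -> T = 0.25, 0.75
  gs <- shared_segment_genomes()
  db <- build_tag_db(gs, synthetic_enzyme())
  sub <- build_sample_specific_db(db, c("spA", "spB"))
  stats <- data.table::copy(db$species)
  stats[, H := 100L]
  cA <- sub$index[species_id == "spA"]$tag[1:10]
  cB <- sub$index[species_id == "spB"]$tag[1:10]
  counts <- data.table::data.table(tag = c(cA, cB), count = c(rep(1L, 10), rep(3L, 10)))
  prof <- second_round(counts, sub, stats)
  expect_equal(prof[species_id == "spA"]$T, 0.25)
  expect_equal(prof[species_id == "spB"]$T, 0.75)
  expect_equal(sum(prof$T), 1, tolerance = 1e-9)
  expect_equal(prof[species_id == "spA"]$O, 10 / prof[species_id == "spA"]$E2)
  # sorted by decreasing abundance
  expect_equal(prof$species_id, c("spB", "spA"))
  # single identified species always gets T = 1
  solo <- build_sample_specific_db(db, "spA")
  p1 <- second_round(counts[tag %in% solo$index$tag], solo, stats)
  expect_equal(p1$T, 1)
})

test_that("second round catches database desynchronization", {
  gs <- shared_segment_genomes()
  db <- build_tag_db(gs, synthetic_enzyme())
  sub <- build_sample_specific_db(db, c("spA", "spB"))
  broken <- db$species[species_id != "spA"]
  counts <- data.table::data.table(tag = sub$index$tag[1], count = 1L)
  expect_error(second_round(counts, sub, broken), "desync")
})

test_that("deep two-species profiling recovers the taxonomic abundance", {
  u <- tiny_universe()
  gs <- u$genomes[1:2]
  truth <- sample_composition(gs, 2, seed = 71)
  truth$T_true <- c(0.3, 0.7)
  truth$S_true <- truth$T_true * truth$L / sum(truth$T_true * truth$L)
  sim <- simulate_reads(truth, gs, sim_config(depth = 150000, error_rate = 0, seed = 71))
  counts <- digest_reads(sim$reads, u$enzyme)
  feats <- first_round(counts, u$db)
  sub <- build_sample_specific_db(u$db, feats$species_id)
  prof <- second_round(counts, sub, u$db$species)
  expect_equal(sum(prof$T), 1, tolerance = 1e-9)
  got <- setNames(prof$T, prof$species_id)[truth$species_id]
  expect_equal(unname(got), truth$T_true, tolerance = 0.02)
})

test_that("end-to-end profiling is deterministic and audit-complete", {
  u <- tiny_universe()
  m <- tiny_model()$model
  truth <- sample_composition(u$genomes, 5, seed = 81)
  sim <- simulate_reads(truth, u$genomes, sim_config(depth = 30000, seed = 81))
  r1 <- profile_sample(sim$reads, u$db, m)
  r2 <- profile_sample(sim$reads, u$db, m)
  expect_identical(r1$profile, r2$profile)
  expect_identical(r1$features, r2$features)
  expect_equal(sum(r1$profile$T), 1, tolerance = 1e-9)
  expect_true(all(c("Q", "U", "E", "C", "N", "R_seq", "G", "prob", "kept")
                  %in% names(r1$features)))
  # reads without any recognition site produce an empty profile with warning
  expect_warning(r0 <- profile_sample(strrep("T", 100), u$db, m), "no species")
  expect_equal(nrow(r0$profile), 0)
})
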