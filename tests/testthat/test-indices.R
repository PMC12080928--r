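test_that("reciprocal best hits require reciprocity and follow tie-break rules", {
  filters <- hit_filters()
  # symmetric one-protein toy
  rbh <- reciprocal_best_hits(toy_hits("p", "q", 90), toy_hits("q", "p", 90), filters)
  expect_equal(rbh$protein_a, "p")
  expect_equal(rbh$pident, 90)
  # p's best is q but q's best is r -> no pair
  ab <- toy_hits("p", "q", 90, bitscore = 100)
  ba <- rbind(toy_hits("q", "r", 95, bitscore = 120),
              toy_hits("q", "p", 90, bitscore = 100))
  expect_equal(nrow(reciprocal_best_hits(ab, ba, filters)), 0L)
  # bitscore ties broken by evalue then lexicographic subject id
  ab2 <- rbind(toy_hits("p", "z", 90, bitscore = 100, evalue = 1e-30),
               toy_hits("p", "q", 90, bitscore = 100, evalue = 1e-40))
  ba2 <- toy_hits("q", "p", 90)
  expect_equal(reciprocal_best_hits(ab2, ba2, filters)$protein_b, "q")
  ab3 <- rbind(toy_hits("p", "z", 90, bitscore = 100),
               toy_hits("p", "q", 90, bitscore = 100))
  ba3 <- rbind(toy_hits("q", "p", 90), toy_hits("z", "p", 90))
  expect_equal(reciprocal_best_hits(ab3, ba3, filters)$protein_b, "q")
})

test_that("reciprocal best hits agree with a definitional oracle on random toys", {
  filters <- hit_filters(min_pident = 30, max_evalue = 1e-3)
  prots_a <- paste0("a", 1:3); prots_b <- paste0("b", 1:3)
  for (seed in 1:25) {
    set.seed(seed)
    grid <- expand.grid(q = prots_a, s = prots_b, stringsAsFactors = FALSE)
    keep <- runif(nrow(grid)) < 0.7
    mk <- function(g) {
      if (!nrow(g)) return(toy_hits("x", "y")[0, ])
      do.call(rbind, lapply(seq_len(nrow(g)), function(i)
        toy_hits(g$q[i], g$s[i], pident = round(runif(1, 20, 100), 1),
                 bitscore = sample(50:150, 1), evalue = 10^-sample(1:50, 1))))
    }
    hits_ab <- mk(grid[keep, ])
    hits_ba <- mk(stats::setNames(grid[runif(nrow(grid)) < 0.7, 2:1], c("q", "s")))
    got <- reciprocal_best_hits(hits_ab, hits_ba, filters)
    expect_identical(sort(paste(got$protein_a, got$protein_b)),
                     oracle_rbh(hits_ab, hits_ba, filters))
  }
})

test_that("AAI is the unweighted mean of ortholog identities", {
  rbh <- data.frame(protein_a = c("a1", "a2", "a3"),
                    protein_b = c("b1", "b2", "b3"),
                    pident = c(70, 80, 90), aln_length = 100,
                    qcov_a = 1, qcov_b = 1)
  res <- compute_aai(rbh)
  expect_equal(res$value, 80)
  expect_equal(res$support$n, 3L)
  expect_equal(res$sd, sd(c(70, 80, 90)))
  single <- compute_aai(rbh[2, ])
  expect_equal(single$value, 80)
  expect_true(is.na(single$sd))
  none <- compute_aai(rbh[0, ])
  expect_true(is.na(none$value))
  expect_equal(none$flag, "no_orthologs")
})

test_that("identical proteomes give AAI and POCP of 100", {
  sim <- simulate_proteome_pair(target_aai = 100, n_proteins = 10,
                                length = 80, seed = 4)
  rbh <- reciprocal_best_hits(sim$hits_ab, sim$hits_ba, hit_filters())
  expect_equal(compute_aai(rbh)$value, 100)
  pocp <- compute_pocp(sim$hits_ab, sim$hits_ba, t1 = 10, t2 = 10)
  expect_equal(pocp$value, 100)
})

test_that("POCP equals the closed formula and is monotone in the E-value cut", {
  # C1 = 2 of 4, C2 = 3 of 6 -> 100*(2+3)/(4+6) = 50
  hits_ab <- rbind(toy_hits("a1", "b1", 60), toy_hits("a2", "b2", 55),
                   toy_hits("a3", "b3", 40))           # a3 fails identity
  hits_ba <- rbind(toy_hits("b1", "a1", 60), toy_hits("b2", "a2", 70),
                   toy_hits("b3", "a3", 52),
                   toy_hits("b4", "a1", 80, evalue = 1e-3))  # fails E-value
  res <- compute_pocp(hits_ab, hits_ba, t1 = 4, t2 = 6)
  expect_equal(res$support[c("C1", "C2")], list(C1 = 2L, C2 = 3L))
  expect_equal(res$value, 50)
  # relaxing the E-value cut can only add conserved proteins
  loose <- compute_pocp(hits_ab, hits_ba, t1 = 4, t2 = 6,
                        filters = hit_filters(min_pident = 50, min_cov = 0.5,
                                              max_evalue = 1))
  expect_gte(loose$value, res$value)
  expect_equal(compute_pocp(hits_ab[0, ], hits_ba[0, ], 4, 6)$value, 0)
  expect_error(compute_pocp(hits_ab, hits_ba, 0, 0), "T1 \\+ T2")
})

test_that("fragmenting discards trailing remainders and names fragments", {
  fr <- fragment_genome(c(chr = strrep("A", 2500)), fragment_length = 1000)
  expect_equal(length(fr), 2L)
  expect_equal(names(fr), c("chr|1", "chr|2"))
  expect_equal(unname(nchar(fr)), c(1000L, 1000L))
  expect_equal(length(fragment_genome(c(s = "ACGT"), 1020)), 0L)
})

test_that("orthoani is 100 for self-comparison and matches the fragment toy", {
  set.seed(1)
  g <- c(chr = paste(sample(c("A", "C", "G", "T"), 1100, TRUE), collapse = ""))
  self <- orthoani(g, g)
  expect_equal(self$value, 100)
  # fragment 1 identical, fragment 2 with 102/1020 substitutions -> mean(100, 90)
  set.seed(2)
  a <- sample(c("A", "C", "G", "T"), 2040, TRUE)
  b <- a
  pos <- seq(1021, by = 10, length.out = 102)
  b[pos] <- chartr("ACGT", "CATG", a[pos])
  res <- orthoani(c(chr = paste(a, collapse = "")),
                  c(chr = paste(b, collapse = "")))
  expect_equal(res$value, 95)
  expect_equal(res$support$n_pairs, 2L)
})

test_that("orthoani recovers the substitution rate on simulated genome pairs", {
  for (s in c(0.02, 0.1)) {
    sim <- simulate_genome_pair(n_fragments = 2, sub_rate = s, seed = 7)
    res <- orthoani(sim$genome_a, sim$genome_b)
    expect_equal(res$value, 100 * (1 - s), tolerance = 1 / 100)
  }
  empty <- orthoani(c(x = "ACGT"), c(y = "ACGT"))
  expect_equal(empty$flag, "below_detection")
})

test_that("species calls follow the ANI 95-96 band and the dDDH 70 rule", {
  expect_equal(species_call(100, 80)$verdict, "same_species")
  expect_equal(species_call(71.31)$verdict, "different_species")
  expect_equal(species_call(95.5)$verdict, "ambiguous")
  expect_equal(species_call(96)$verdict, "same_species")
  # conflicting indices -> ambiguous
  expect_equal(species_call(97, 60)$verdict, "ambiguous")
  expect_equal(species_call(90, 75)$verdict, "ambiguous")
  expect_equal(species_call(90, 60)$verdict, "different_species")
})

test_that("indices are symmetric in genome order", {
  sim <- simulate_proteome_pair(target_aai = 85, n_proteins = 20,
                                length = 120, seed = 9)
  f <- hit_filters()
  aai_ab <- compute_aai(reciprocal_best_hits(sim$hits_ab, sim$hits_ba, f))
  aai_ba <- compute_aai(reciprocal_best_hits(sim$hits_ba, sim$hits_ab, f))
  expect_equal(aai_ab$value, aai_ba$value)
  p1 <- compute_pocp(sim$hits_ab, sim$hits_ba, 20, 20)
  p2 <- compute_pocp(sim$hits_ba, sim$hits_ab, 20, 20)
  expect_equal(p1$value, p2$value)
  gp <- simulate_genome_pair(n_fragments = 1, sub_rate = 0.03, seed = 3)
  expect_equal(orthoani(gp$genome_a, gp$genome_b)$value,
               orthoani(gp$genome_b, gp$genome_a)$value)
})
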