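spec_toy <- function() {
  m <- matrix(61, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- m["b", "a"] <- 95
  m["c", "d"] <- m["d", "c"] <- 96
  as_similarity_matrix(m)
}

test_that("threshold clustering is single-linkage connected components", {
  S <- spec_toy()
  expect_equal(partition_key(cluster_at_threshold(S, 80)), "a,b;c,d")
  expect_equal(partition_key(cluster_at_threshold(S, 96)), "a;b;c,d")
  expect_equal(partition_key(cluster_at_threshold(S, 50)), "a,b,c,d")
  # all off-diagonal 100 -> single block at any t
  m <- matrix(100, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(length(cluster_at_threshold(as_similarity_matrix(m), 100)), 1L)
})

test_that("threshold clustering agrees with the reachability-closure oracle", {
  for (seed in 1:40) {
    n <- sample(3:8, 1)
    S <- random_similarity(n, seed)
    for (t in sort(unique(S[upper.tri(S)]))) {
      expect_equal(partition_key(cluster_at_threshold(S, t)),
                   partition_key(oracle_partition(S, t)),
                   info = sprintf("seed %d t %.1f", seed, t))
    }
  }
})

test_that("cluster counts are monotone in the threshold", {
  S <- random_similarity(7, seed = 99)
  vals <- sort(unique(S[upper.tri(S)]))
  sizes <- vapply(vals, function(t) length(cluster_at_threshold(S, t)), 1L)
  expect_true(all(diff(sizes) >= 0))
  expect_equal(length(cluster_at_threshold(S, min(vals))), 1L)
  expect_equal(length(cluster_at_threshold(S, max(vals) + 0.1)), nrow(S))
})

test_that("stable intervals match the spec toy and tile the value range", {
  iv <- enumerate_stable_intervals(spec_toy())
  expect_equal(iv$lower, c(61, 95, 96))
  expect_equal(iv$upper, c(61, 95, 96))
  expect_equal(iv$n_clusters, c(1L, 2L, 3L))
  expect_equal(iv$t_open, c(-Inf, 61, 95))

  S <- random_similarity(8, seed = 5)
  iv <- enumerate_stable_intervals(S)
  vals <- sort(unique(round(S[upper.tri(S)], 2)))
  expect_equal(iv$lower[1], min(vals))
  expect_equal(iv$upper[nrow(iv)], max(vals))
  # t_open chains: each run opens where the previous one ends
  expect_equal(iv$t_open[-1], iv$upper[-nrow(iv)])
  # partitions strictly refine along the list
  parts <- attr(iv, "partition")
  for (k in seq_len(length(parts) - 1)) {
    expect_true(is_refinement(parts[[k + 1]], parts[[k]]))
    expect_false(identical(partition_key(parts[[k + 1]]),
                           partition_key(parts[[k]])))
  }
})

test_that("a planted similarity gap carries the planted partition", {
  sim <- simulate_similarity_matrix(c(3, 4, 2), intra_range = c(85, 95),
                                    inter_range = c(60, 70), seed = 3)
  iv <- enumerate_stable_intervals(sim$S)
  gap <- sim$truth$gap_interval
  hit <- which(iv$t_open < gap[2] & iv$upper >= gap[2])
  expect_length(hit, 1L)
  expect_equal(partition_key(attr(iv, "partition")[[hit]]),
               partition_key(sim$truth$partition))
  # the planted gap lies inside the run's effective threshold range
  expect_lte(iv$t_open[hit], gap[1])
  expect_gte(iv$upper[hit], gap[2])
})

test_that("adjusted Rand index matches the contingency formula and mclust", {
  p <- list(c("a", "b"), c("c", "d"))
  q <- list(c("a", "c"), c("b", "d"))
  expect_equal(adjusted_rand_index(p, p), 1)
  expect_equal(adjusted_rand_index(p, q), -0.5)
  singl <- list("a", "b", "c", "d")
  one <- list(c("a", "b", "c", "d"))
  expect_equal(adjusted_rand_index(singl, one), 0)
  expect_error(adjusted_rand_index(p, list(c("x", "y"), c("z", "w"))),
               "different genome sets")
  skip_if_not_installed("mclust")
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:12, 1)
    la <- sample(1:4, n, TRUE); lb <- sample(1:3, n, TRUE)
    ids <- paste0("g", 1:n)
    expect_equal(
      adjusted_rand_index(split(ids, la), split(ids, lb)),
      mclust::adjustedRandIndex(la, lb))
  }
})

test_that("candidate evaluation ranks by ARI then constraints then singletons", {
  sim <- simulate_similarity_matrix(c(2, 2, 2), seed = 2)
  iv <- enumerate_stable_intervals(sim$S)
  ev <- evaluate_candidates(iv, sim$truth$partition)
  expect_equal(ev$rank, seq_len(nrow(ev)))
  expect_true(ev$exact_match[1])
  expect_equal(ev$ari[1], 1)
  expect_true(all(diff(ev$ari) <= 0))
  # forbidden merges break ties at equal ARI
  m <- matrix(60, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- m["b", "a"] <- 90
  m["c", "d"] <- m["d", "c"] <- 80
  iv2 <- enumerate_stable_intervals(as_similarity_matrix(m))
  ref_singl <- as.list(letters[1:4])  # ARI 0 for every non-trivial partition
  forb <- rbind(c("a", "b"), c("c", "d"))
  ev2 <- evaluate_candidates(iv2, ref_singl, forbidden_merge_pairs = forb)
  expect_equal(ev2$forbidden_merges[ev2$n_clusters == 1], 2L)
  expect_equal(ev2$forbidden_merges[ev2$n_clusters == 3], 1L)
  expect_lt(ev2$rank[ev2$n_clusters == 3],
            min(ev2$rank[ev2$n_clusters < 3]))
})

test_that("reference restricted to common genomes still evaluates", {
  sim <- simulate_similarity_matrix(c(2, 2), seed = 8)
  ref <- sim$truth$partition
  ref_sub <- lapply(ref, function(b) b[1])  # one genome per genus
  iv <- enumerate_stable_intervals(sim$S)
  ev <- evaluate_candidates(iv, ref_sub)
  expect_true(any(ev$ari == 1))
  expect_error(evaluate_candidates(iv, list(c("zz1", "zz2"))), "no genomes")
})

test_that("delineate_genera returns a ranked fit with methods", {
  sim <- simulate_similarity_matrix(c(2, 3, 2), seed = 6)
  fit <- delineate_genera(sim$S, sim$truth$partition)
  expect_s3_class(fit, "genus_delineation")
  expect_equal(fit$optimal$ari, 1)
  expect_equal(partition_key(fit$partition), partition_key(sim$truth$partition))
  expect_output(print(fit), "optimal interval")
  expect_output(summary(fit), "ranking")
})

test_that("dendrogram export is ultrametric and cut-consistent", {
  m <- matrix(c(100, 80, 80, 100), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(export_dendrogram(as_similarity_matrix(m)), "(a:10,b:10);")
  sim <- simulate_similarity_matrix(c(3, 3, 2), seed = 4)
  nwk <- export_dendrogram(sim$S)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, rownames(sim$S))
  # cutting the merge tree inside the planted gap recovers the partition
  hc <- taxoforce:::delineation_hclust(sim$S)
  t_star <- mean(sim$truth$gap_interval)
  cut <- stats::cutree(hc, h = 100 - t_star)
  expect_equal(partition_key(split(names(cut), cut)),
               partition_key(sim$truth$partition))
  # cut consistency at every observed threshold
  for (t in sort(unique(sim$S[upper.tri(sim$S)]))) {
    expect_equal(partition_key(split(names(cutree(hc, h = 100 - t)),
                                     cutree(hc, h = 100 - t))),
                 partition_key(cluster_at_threshold(sim$S, t)))
  }
})
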