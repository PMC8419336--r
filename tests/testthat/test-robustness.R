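two_clone_ds <- function() {
  # clone c1 = {m1} at 0.4, clone c2 = {m1, m2} at 0.6
  g <- matrix(c(1L, 1L, 0L, 1L), 2, 2,
              dimnames = list(c("c1", "c2"), c("m1", "m2")))
  single_cell_dataset(g, frequencies = c(0.4, 0.6), timepoint = "diagnosis")
}

test_that("bulk VAFs are the clone-frequency-weighted allele sums", {
  b <- bulk_vaf_from_sc(two_clone_ds(), normalize = FALSE)
  expect_equal(unname(b$vaf), c(100, 60)) # raw (1.0, 0.6) in percent
  expect_equal(unname(bulk_vaf_from_sc(two_clone_ds())$vaf), c(100, 60))
  # single clone: all its alleles at 100
  g1 <- matrix(c(1L, 1L), 1, 2, dimnames = list("c1", c("m1", "m2")))
  ds1 <- single_cell_dataset(g1, frequencies = 1)
  expect_equal(unname(bulk_vaf_from_sc(ds1)$vaf), c(100, 100))
})

test_that("bulk VAFs are invariant under consistent clone permutation", {
  tr <- random_tree(5, seed = 9)
  f <- random_frequencies(5, seed = 9)
  ds <- sc_dataset_from_tree(tr, frequencies = f)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  ds_p <- single_cell_dataset(ds$genotypes[perm, ],
                              frequencies = unname(ds$f[perm]))
  expect_equal(bulk_vaf_from_sc(ds)$vaf,
               bulk_vaf_from_sc(ds_p)$vaf[names(bulk_vaf_from_sc(ds)$vaf)])
})

test_that("multinomial resampling preserves totals and recovers means", {
  tr <- random_tree(4, seed = 5)
  f <- random_frequencies(4, seed = 5)
  ds <- sc_dataset_from_tree(tr, counts = stats::setNames(
    as.integer(stats::rmultinom(1, 400, f)), depth_order(tr)))
  reps <- multinomial_resample(ds, 1000, seed = 5)
  counts <- vapply(reps, function(r) sum(r$counts), numeric(1))
  expect_true(all(counts == ds$n_cells))
  fmat <- vapply(reps, function(r) unname(r$f), numeric(4))
  se <- sqrt(ds$f * (1 - ds$f) / ds$n_cells) / sqrt(1000)
  expect_true(all(abs(rowMeans(fmat) - unname(ds$f)) <= 3 * se + 1e-12))
  # degenerate single clone: replicates identical to the input
  g1 <- matrix(1L, 1, 1, dimnames = list("c1", "m1"))
  ds1 <- single_cell_dataset(g1, counts = 50)
  expect_true(all(vapply(multinomial_resample(ds1, 20, seed = 1),
                         function(r) r$counts == 50, logical(1))))
})

test_that("resampling is reproducible under a fixed seed", {
  g <- matrix(c(1L, 1L, 0L, 1L), 2, 2,
              dimnames = list(c("c1", "c2"), c("m1", "m2")))
  ds <- single_cell_dataset(g, counts = c(40, 60))
  a <- multinomial_resample(ds, 5, seed = 99)
  b <- multinomial_resample(ds, 5, seed = 99)
  expect_identical(lapply(a, `[[`, "counts"), lapply(b, `[[`, "counts"))
})

test_that("perturbed VAFs stay in [0,100], are unbiased, and honour sd = 0", {
  s <- vaf_sample(c("m1", "m2", "m3"), c(100, 50, 3))
  reps0 <- perturb_vafs(s, sd = 0, n_reps = 5, seed = 1)
  for (r in reps0) expect_equal(r$vaf, s$vaf)
  reps <- perturb_vafs(s, sd = 5, n_reps = 1000, seed = 1)
  vals <- vapply(reps, function(r) unname(r$vaf), numeric(3))
  expect_true(all(vals >= 0 & vals <= 100))
  # far from the bounds the noise is unbiased: mean within 3 standard errors
  expect_lt(abs(mean(vals[2L, ]) - 50), 3 * 5 / sqrt(1000))
  # same seed, same draws; replicate-rejection policy also respects bounds
  reps_b <- perturb_vafs(s, sd = 5, n_reps = 1000, seed = 1)
  expect_equal(vals, vapply(reps_b, function(r) unname(r$vaf), numeric(3)))
  reps_r <- perturb_vafs(s, sd = 5, n_reps = 200, seed = 2,
                         policy = "redraw_replicate")
  vals_r <- vapply(reps_r, function(r) unname(r$vaf), numeric(3))
  expect_true(all(vals_r >= 0 & vals_r <= 100))
})

test_that("zero noise keeps the truth optimal and exact in every replicate", {
  p <- simulate_patient(4, n_cells = NULL, seed = 11)
  out <- robustness_experiment(p$truth, p$sc_by_timepoint,
                               noise = "perturb", sd = 0, n_reps = 20,
                               seed = 11)
  expect_equal(out$frac_true_optimal, 1)
  expect_equal(out$frac_true_exact, 1)
  expect_equal(sum(out$histogram_n_compatible), 20)
  expect_equal(sum(out$rank_distribution), 20)
})

test_that("resampling error keeps reconstructed mean frequencies near truth", {
  p <- simulate_patient(4, timepoints = "diagnosis", n_cells = 500,
                        seed = 21, min_clone_freq = 0.05)
  ds <- p$sc_by_timepoint$diagnosis
  A <- tree_to_genotype_matrix(p$truth)
  reps <- multinomial_resample(ds, 1000, seed = 21)
  xs <- vapply(reps, function(r)
    unname(back_substitute(A, bulk_vaf_from_sc(r))), numeric(4))
  x_true <- unname(back_substitute(A, bulk_vaf_from_sc(ds)))
  expect_true(all(abs(rowMeans(xs) - x_true) < 1))
})

test_that("large perturbations destabilise a small founder clone", {
  # founder clone at ~2%: noise with sd 8% frequently reorders the top VAFs
  tr <- chain_tree(c("m1", "m2", "m3"))
  f <- c(m1 = 0.02, m2 = 0.49, m3 = 0.49)
  ds <- sc_dataset_from_tree(tr, frequencies = f)
  out <- robustness_experiment(tr, list(ds), noise = "perturb", sd = 8,
                               n_reps = 100, seed = 31)
  expect_lt(out$frac_true_optimal, 1)
})

test_that("two clones always reconstruct uniquely from exact data", {
  u <- uniqueness_experiment(2, n_datasets = 200, timepoints = 1, seed = 3)
  expect_true(all(u$counts == 1L))
})

test_that("the generating topology always fits its own data", {
  u <- uniqueness_experiment(4, n_datasets = 300, timepoints = 2, seed = 4)
  expect_true(all(u$counts >= 1L))
  expect_equal(dim(u$counts), c(16L, 300L))
})

test_that("a 3-clone chain is uniquely identified in about half of the draws", {
  # the star also fits iff x_root >= x_deepest, probability 1/2 under the
  # flat Dirichlet; analytic value verified by direct simulation
  set.seed(12)
  sims <- replicate(20000, {
    g <- stats::rexp(3); x <- g / sum(g); x[1] >= x[3]
  })
  expect_equal(mean(sims), 0.5, tolerance = 0.02)
  u <- uniqueness_experiment(3, n_datasets = 4000, timepoints = 1, seed = 12)
  chain_idx <- which(vapply(u$topologies, function(tr)
    identical(unname(tr$parent[c("m2", "m3")]), c("m1", "m2")), logical(1)))
  frac_unique_chain <- mean(u$counts[chain_idx, ] == 1L)
  expect_equal(frac_unique_chain, 0.5, tolerance = 0.05)
})

test_that("a second timepoint never hurts uniqueness", {
  u1 <- uniqueness_experiment(4, n_datasets = 2000, timepoints = 1, seed = 8)
  u2 <- uniqueness_experiment(4, n_datasets = 2000, timepoints = 2, seed = 8)
  f1 <- rowMeans(u1$counts == 1L)
  f2 <- rowMeans(u2$counts == 1L)
  mc <- 3 * sqrt(0.25 / 2000) # Monte-Carlo slack
  expect_true(all(f2 >= f1 - mc))
})
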