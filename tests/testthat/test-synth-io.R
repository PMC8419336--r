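test_that("random trees are reproducible and cover edge cases", {
  expect_identical(random_tree(1)$n_nodes, 1L)
  expect_identical(random_tree(2, seed = 1)$parent[["m2"]], "m1")
  a <- random_tree(6, seed = 42)
  b <- random_tree(6, seed = 42)
  expect_identical(a$parent, b$parent)
  wt <- random_tree(4, seed = 1, mode = "wildtype")
  expect_identical(wt$root, "WT")
  expect_setequal(wt$labels, c("WT", "m1", "m2", "m3"))
})

test_that("random trees are uniform over the fixed-root topologies", {
  # 16,000 draws over the 16 topologies on 4 nodes; chi-square GOF
  keys <- vapply(1:16000, function(k)
    clonehier:::canonical_tree_key(random_tree(4, seed = k)), character(1))
  all_keys <- vapply(enumerate_trees(4, fixed_root = "m1"),
                     clonehier:::canonical_tree_key, character(1))
  counts <- table(factor(keys, levels = all_keys))
  expect_length(counts, 16L)
  chi <- stats::chisq.test(counts)
  expect_gt(chi$p.value, 1e-4)
  expect_true(all(abs(counts - 1000) < 3 * sqrt(16000 * (1 / 16) * (15 / 16))
                  + 30))
})

test_that("random frequencies live on the simplex and respect bounds", {
  expect_equal(random_frequencies(1), 1)
  f <- random_frequencies(5, seed = 2)
  expect_equal(sum(f), 1)
  expect_true(all(f >= 0))
  fmin <- random_frequencies(4, seed = 3, min_clone_freq = 0.1)
  expect_true(all(fmin >= 0.1))
  expect_error(random_frequencies(4, min_clone_freq = 0.3), "infeasible")
  # exchangeability: P(f1 < f3) ~ 1/2
  set.seed(4)
  cmp <- replicate(10000, { f <- random_frequencies(3); f[1] < f[3] })
  expect_equal(mean(cmp), 0.5, tolerance = 0.02)
})

test_that("simulated patients are pure functions of their seed", {
  a <- simulate_patient(5, seed = 77)
  b <- simulate_patient(5, seed = 77)
  expect_identical(a$truth$parent, b$truth$parent)
  expect_identical(a$frequencies_by_timepoint, b$frequencies_by_timepoint)
  expect_identical(lapply(a$bulk_by_timepoint, `[[`, "vaf"),
                   lapply(b$bulk_by_timepoint, `[[`, "vaf"))
})

test_that("noiseless patients are self-consistent end to end", {
  for (seed in c(1, 2, 3)) {
    p <- simulate_patient(4, seed = seed, vaf_noise_sd = 0)
    # bulk equals the bulk recomputed from the single-cell table
    for (tp in names(p$bulk_by_timepoint))
      expect_equal(p$bulk_by_timepoint[[tp]]$vaf,
                   bulk_vaf_from_sc(p$sc_by_timepoint[[tp]])$vaf)
    r <- reconstruct(p$bulk_by_timepoint)
    expect_true(rank_summary(r, p$truth)$is_exact)
  }
})

test_that("large single-cell samples recover the drawn frequencies", {
  p <- simulate_patient(4, timepoints = "diagnosis", n_cells = 1e6,
                        seed = 13)
  f_hat <- p$sc_by_timepoint$diagnosis$f
  f_true <- p$frequencies_by_timepoint$diagnosis
  expect_true(all(abs(f_hat - f_true[names(f_hat)]) < 0.002))
})

test_that("VAF tables round-trip losslessly and validate their schema", {
  p <- simulate_patient(3, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_vaf_table(p$bulk_by_timepoint, path)
  back <- read_vaf_table(path)
  expect_setequal(names(back), names(p$bulk_by_timepoint))
  for (tp in names(back))
    expect_equal(back[[tp]]$vaf, p$bulk_by_timepoint[[tp]]$vaf)

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines("mutation_id,timepoint,vaf_percent\nm1,d,120", csv)
  expect_error(read_vaf_table(csv), "\\[0, 100\\]")
  writeLines("mutation_id,vaf_percent\nm1,50", csv)
  expect_error(read_vaf_table(csv), "timepoint")
})

test_that("confidence intervals become least-squares weights", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mutation_id,timepoint,vaf_percent,ci_low,ci_high",
               "m1,d,100,98,102", "m2,d,40,35,45"), path)
  s <- read_vaf_table(path)[["d"]]
  expect_equal(unname(s$weights), c(1 / 2, 1 / 5))
})

test_that("single-cell tables round-trip and validate binariness", {
  p <- simulate_patient(4, seed = 6, n_cells = 300)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sc_table(p$sc_by_timepoint, path)
  back <- read_sc_table(path)
  for (tp in names(back)) {
    orig <- p$sc_by_timepoint[[tp]]
    expect_equal(back[[tp]]$counts, orig$counts)
    expect_equal(back[[tp]]$genotypes[rownames(orig$genotypes),
                                      colnames(orig$genotypes)],
                 orig$genotypes)
  }
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("timepoint\tcount\tm1\nd\t10\t2", bad)
  expect_error(read_sc_table(bad), "binary")
})

test_that("reconstruction reports serialise to versioned JSON plus Newick", {
  r <- reconstruct(vaf_sample(c("m1", "m2", "m3"), c(100, 60, 30)))
  path <- withr::local_tempfile(fileext = ".json")
  nwk_dir <- withr::local_tempdir()
  write_report(r, path, newick_dir = nwk_dir)
  obj <- jsonlite::read_json(path)
  expect_identical(obj$schema_version, 1L)
  expect_identical(obj$mode, "founder")
  expect_identical(obj$n_exact, 2L)
  expect_length(obj$trees, 3L)
  expect_identical(obj$trees[[1L]]$rank, 1L)
  expect_identical(obj$trees[[2L]]$rank, 1L) # exact ties share rank 1
  expect_identical(obj$trees[[3L]]$rank, 3L)
  nwk <- list.files(nwk_dir, pattern = "\\.nwk$")
  expect_length(nwk, 3L)
  expect_length(grep("_exact", nwk), 2L)
})

test_that("the command-line wrapper reconstructs from a VAF table", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "clonehier", package = "clonehier")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  vaf <- file.path(dir, "vaf.tsv")
  write_vaf_table(simulate_patient(3, seed = 14)$bulk_by_timepoint, vaf)
  out <- file.path(dir, "report.json")
  status <- system2("Rscript", c(cli, "reconstruct", "--vaf", vaf,
                                 "--out", out),
                    env = paste0("R_LIBS=",
                                 paste(.libPaths(), collapse = ":")),
                    stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  obj <- jsonlite::read_json(out)
  expect_identical(obj$n_trees_enumerated, 3L)
})

test_that("robustness summaries serialise with per-replicate tables", {
  p <- simulate_patient(3, seed = 9, n_cells = 200)
  out <- robustness_experiment(p$truth, p$sc_by_timepoint,
                               noise = "resample", n_reps = 25, seed = 9)
  json <- withr::local_tempfile(fileext = ".json")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_summary(out, json, replicates_path = tsv)
  obj <- jsonlite::read_json(json)
  expect_identical(obj$n_reps, 25L)
  expect_equal(obj$frac_true_exact, out$frac_true_exact)
  reps <- utils::read.delim(tsv)
  expect_identical(nrow(reps), 25L)
  expect_setequal(names(reps), c("replicate", "n_compatible", "true_rank",
                                 "true_optimal", "true_exact",
                                 "optimum_unique"))
})
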