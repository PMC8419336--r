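# Independent oracles, deliberately naive: brute force over parent vectors
# and dense grid search, never the package's own Pruefer/QP machinery.

chain_tree <- function(labels) {
  parent <- c(NA_character_, labels[-length(labels)])
  clonal_tree(stats::setNames(parent, labels))
}

star_tree <- function(root, leaves) {
  clonal_tree(stats::setNames(c(NA_character_, rep(root, length(leaves))),
                              c(root, leaves)))
}

# All rooted labeled trees on nodes 1..n by exhausting parent vectors:
# every non-root node picks any other node as parent; keep the acyclic,
# connected assignments. Returns canonical strings "root|p2,p3,..." for
# de-duplicated comparison with the Pruefer-based enumeration.
brute_force_rooted_trees <- function(n, roots = seq_len(n)) {
  out <- character(0)
  for (root in roots) {
    others <- setdiff(seq_len(n), root)
    if (!length(others)) {
      out <- c(out, paste0(root, "|"))
      next
    }
    grid <- expand.grid(rep(list(seq_len(n)), length(others)))
    for (k in seq_len(nrow(grid))) {
      parent <- rep(NA_integer_, n)
      parent[others] <- as.integer(grid[k, ])
      if (any(parent[others] == others)) next
      ok <- TRUE
      for (v in others) { # walk up; must hit the root within n steps
        u <- v; steps <- 0L
        while (!is.na(parent[u]) && steps <= n) {
          u <- parent[u]; steps <- steps + 1L
        }
        if (u != root || steps > n) { ok <- FALSE; break }
      }
      if (ok) out <- c(out, paste0(root, "|", paste(parent[others],
                                                    collapse = ",")))
    }
  }
  unique(out)
}

same_tree_fixture <- function(a, b) {
  identical(a$root, b$root) && setequal(a$labels, b$labels) &&
    identical(unname(a$parent[sort(a$labels)]),
              unname(b$parent[sort(b$labels)]))
}

tree_key_numeric <- function(tree) {
  # same canonical string as brute_force_rooted_trees for labels "1".."n"
  labs <- as.character(sort(as.integer(tree$labels)))
  others <- setdiff(labs, tree$root)
  paste0(tree$root, "|", paste(tree$parent[others], collapse = ","))
}

# Dense simplex grid search oracle for the constrained least-squares fit
# (3 clones, step 1 percent by default).
grid_search_fit <- function(A, b, step = 1, total = 100) {
  best <- Inf
  for (x1 in seq(0, total, by = step)) {
    for (x2 in seq(0, total - x1, by = step)) {
      x <- c(x1, x2, total - x1 - x2)
      r <- sqrt(sum((unclass(A) %*% x - b)^2))
      if (r < best) best <- r
    }
  }
  best
}

random_patient_exact <- function(n, seed, timepoints = c("diagnosis",
                                                         "relapse")) {
  simulate_patient(n, timepoints = timepoints, n_cells = NULL, seed = seed)
}
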