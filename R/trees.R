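#' Construct a clonal tree
#'
#' A clonal hierarchy is a rooted labeled tree: each node is a clone, labelled
#' by the mutation (allele) that distinguishes it from its direct ancestor.
#' For wild-type-root reconstructions the root carries the reserved reference
#' allele identifier (conventionally `"WT"`).
#'
#' @param parent named character vector over all node labels; `parent[v]` is
#'   the label of the parent of node `v`, and the root maps to `NA`.
#' @param validate check tree invariants (connected, acyclic, unique root).
#' @return an object of class `clonal_tree` with elements `labels`, `parent`,
#'   `root` and `n_nodes`.
#' @examples
#' clonal_tree(c(m1 = NA, m2 = "m1", m3 = "m2"))
#' @export
clonal_tree <- function(parent, validate = TRUE) {
  parent <- vapply(parent, as.character, character(1))
  labels <- names(parent)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels))
    stop("'parent' must be a named vector with unique, non-empty node labels")
  root <- labels[is.na(parent)]
  tree <- structure(
    list(labels = labels, parent = parent, root = root,
         n_nodes = length(labels)),
    class = "clonal_tree"
  )
  if (validate) validate_clonal_tree(tree)
  tree
}

#' Validate clonal tree invariants
#'
#' Checks that the parent map defines a connected acyclic graph with exactly
#' one root, that every non-root node has a parent inside the tree, and that
#' labels are unique.
#'
#' @param tree a [clonal_tree()].
#' @return `tree`, invisibly; errors on violation.
#' @export
validate_clonal_tree <- function(tree) {
  stopifnot(inherits(tree, "clonal_tree"))
  if (length(tree$root) != 1L)
    stop("tree must have exactly one root, found ", length(tree$root))
  non_root <- setdiff(tree$labels, tree$root)
  bad <- non_root[!(tree$parent[non_root] %in% tree$labels)]
  if (length(bad))
    stop("parent of node(s) ", paste(bad, collapse = ", "), " not in tree")
  # every node must reach the root without revisiting a node
  for (v in tree$labels) {
    seen <- character(0)
    while (!is.na(tree$parent[[v]])) {
      if (v %in% seen) stop("cycle detected at node ", v)
      seen <- c(seen, v)
      v <- tree$parent[[v]]
    }
    if (v != tree$root) stop("node does not reach the root")
  }
  invisible(tree)
}

#' @export
print.clonal_tree <- function(x, ...) {
  cat("Clonal tree with", x$n_nodes, "clone(s), root:", x$root, "\n")
  if (x$n_nodes > 1L) {
    edges <- paste0(x$parent[!is.na(x$parent)], " -> ",
                    x$labels[x$labels != x$root])
    cat("  edges:", paste(edges, collapse = ", "), "\n")
  }
  invisible(x)
}

children_of <- function(tree) {
  non_root <- tree$labels[!is.na(tree$parent)]
  split(non_root, factor(tree$parent[non_root], levels = tree$labels))
}

node_depths <- function(tree) {
  depth <- stats::setNames(integer(tree$n_nodes), tree$labels)
  for (v in tree$labels) {
    d <- 0L
    u <- v
    while (!is.na(tree$parent[[u]])) {
      d <- d + 1L
      u <- tree$parent[[u]]
    }
    depth[[v]] <- d
  }
  depth
}

#' Decode a Pruefer sequence into an unrooted labeled tree
#'
#' Standard Pruefer decoding: sequences of length n-2 over {1,...,n} are in
#' bijection with unrooted labeled trees on n nodes, which is the basis of
#' exhaustive tree enumeration.
#'
#' @param sequence integer vector of length n-2 with elements in 1..n
#'   (zero-length for n = 2).
#' @param n number of nodes (at least 2).
#' @return integer matrix with n-1 rows and two columns, one edge per row.
#' @examples
#' prufer_to_tree(c(1L, 1L), 4) # star with center 1
#' @export
prufer_to_tree <- function(sequence, n) {
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be at least 2")
  sequence <- as.integer(sequence)
  if (length(sequence) != n - 2L)
    stop("sequence must have length n-2 = ", n - 2L)
  if (length(sequence) && (any(sequence < 1L) || any(sequence > n)))
    stop("sequence elements must lie in 1..", n)
  degree <- tabulate(sequence, nbins = n) + 1L
  edges <- matrix(0L, nrow = n - 1L, ncol = 2L)
  for (i in seq_along(sequence)) {
    leaf <- which(degree == 1L)[1L] # smallest remaining leaf
    edges[i, ] <- c(leaf, sequence[i])
    degree[leaf] <- 0L
    degree[sequence[i]] <- degree[sequence[i]] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  edges
}

#' Encode an unrooted labeled tree as a Pruefer sequence
#'
#' Inverse of [prufer_to_tree()]: repeatedly removes the smallest-labelled
#' leaf and records its neighbour.
#'
#' @param edges integer matrix with two columns, one edge per row, on nodes
#'   1..n where n = nrow(edges) + 1.
#' @return integer vector of length n-2.
#' @export
tree_to_prufer <- function(edges) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  n <- nrow(edges) + 1L
  if (any(edges < 1L) || any(edges > n))
    stop("edge endpoints must lie in 1..", n)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1L]; b <- edges[k, 2L]
    if (a == b) stop("self-loop at node ", a)
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  degree <- lengths(adj)
  if (any(degree == 0L)) stop("input tree is disconnected")
  seqout <- integer(max(0L, n - 2L))
  alive <- rep(TRUE, n)
  for (i in seq_len(n - 2L)) {
    leaf <- which(alive & degree == 1L)[1L]
    if (is.na(leaf)) stop("input is not a tree (cycle present)")
    nb <- adj[[leaf]][alive[adj[[leaf]]]][1L]
    seqout[i] <- nb
    alive[leaf] <- FALSE
    degree[leaf] <- 0L
    degree[nb] <- degree[nb] - 1L
  }
  if (sum(alive) != 2L || any(degree[alive] != 1L))
    stop("input is not a tree (cycle present)")
  seqout
}

root_edges <- function(edges, root, labels) {
  # orient an unrooted edge list away from `root` (node index), label-centric
  n <- length(labels)
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (n > 1L) {
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1L]; b <- edges[k, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  parent_idx <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  queue <- root
  visited[root] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!visited[w]) {
        visited[w] <- TRUE
        parent_idx[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  if (!all(visited)) stop("edge list is disconnected")
  parent <- stats::setNames(ifelse(is.na(parent_idx), NA_character_,
                                   labels[parent_idx]), labels)
  clonal_tree(parent, validate = FALSE)
}

cayley_count <- function(n, fixed_root) {
  if (n == 1L) return(1)
  if (fixed_root) n^(n - 2) else n^(n - 1)
}

#' Walk all labeled rooted trees, streaming
#'
#' Visits every rooted labeled tree on `n` nodes exactly once, invoking `fun`
#' on each [clonal_tree()] as it is decoded from its Pruefer sequence; memory
#' stays O(n) per tree. With `fixed_root` set, only trees rooted at that label
#' are visited (n^(n-2) trees); otherwise every node serves as root in turn
#' (n^(n-1) trees).
#'
#' @param n number of nodes.
#' @param fun function applied to each tree; its return value is discarded.
#' @param fixed_root optional label from `labels` at which to root all trees.
#' @param labels node labels, default `m1..mn`.
#' @param limit refuse enumeration beyond this many nodes; exhaustive
#'   enumeration is combinatorial (n^(n-2) trees) and only feasible for small
#'   clone numbers.
#' @return number of trees visited, invisibly.
#' @export
walk_trees <- function(n, fun, fixed_root = NULL,
                       labels = paste0("m", seq_len(n)), limit = 8L) {
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be at least 1")
  if (length(labels) != n || anyDuplicated(labels))
    stop("'labels' must be ", n, " unique labels")
  if (n > limit) {
    count <- cayley_count(n, !is.null(fixed_root))
    stop("refusing to enumerate ", format(count, big.mark = ","),
         " labeled trees on ", n, " nodes (limit ", limit,
         "); raise 'limit' explicitly to proceed")
  }
  roots <- if (is.null(fixed_root)) seq_len(n) else {
    r <- match(fixed_root, labels)
    if (is.na(r)) stop("fixed_root '", fixed_root, "' is not among the labels")
    r
  }
  count <- 0L
  if (n == 1L) {
    for (r in roots) {
      fun(clonal_tree(stats::setNames(NA_character_, labels), validate = FALSE))
      count <- count + 1L
    }
    return(invisible(count))
  }
  seq_count <- n^(n - 2L) # number of Pruefer sequences
  for (k in seq_len(seq_count) - 1L) {
    # k written in base n gives one Pruefer sequence of length n-2
    s <- integer(max(0L, n - 2L))
    kk <- k
    for (pos in seq_along(s)) {
      s[pos] <- kk %% n + 1L
      kk <- kk %/% n
    }
    edges <- prufer_to_tree(s, n)
    for (r in roots) {
      fun(root_edges(edges, r, labels))
      count <- count + 1L
    }
  }
  invisible(count)
}

#' Enumerate all labeled rooted trees
#'
#' Materialises the trees visited by [walk_trees()] into a list. With
#' `fixed_root` there are n^(n-2) trees, without it n^(n-1) (each node
#' designated root in turn).
#'
#' @inheritParams walk_trees
#' @return list of [clonal_tree()] objects, no duplicates.
#' @examples
#' length(enumerate_trees(4, fixed_root = "m1")) # 16
#' @export
enumerate_trees <- function(n, fixed_root = NULL,
                            labels = paste0("m", seq_len(n)), limit = 8L) {
  out <- vector("list", cayley_count(as.integer(n), !is.null(fixed_root)))
  i <- 0L
  walk_trees(n, function(tree) {
    i <<- i + 1L
    out[[i]] <<- tree
  }, fixed_root = fixed_root, labels = labels, limit = limit)
  out[seq_len(i)]
}

#' Depth ordering of clones
#'
#' Orders the clones root-first with nondecreasing depth, parents always
#' before children; ties within a depth level are broken by ascending node
#' label so the ordering (and hence every genotype-matrix layout) is
#' deterministic.
#'
#' @param tree a [clonal_tree()].
#' @return character vector of node labels in depth order.
#' @export
depth_order <- function(tree) {
  stopifnot(inherits(tree, "clonal_tree"))
  depth <- node_depths(tree)
  tree$labels[order(depth, tree$labels)]
}

#' Map a clonal tree to its genotype matrix
#'
#' Builds the binary clone-membership matrix A with `a[i, j] = 1` iff the
#' clone of column j carries the mutation defining the clone of row i, i.e.
#' iff clone i is an ancestor of clone j or j itself. In depth order A is
#' unit upper triangular and has determinant 1, so Ax = b always has a unique
#' solution.
#'
#' @param tree a [clonal_tree()].
#' @return an integer matrix of class `genotype_matrix`; rows are alleles and
#'   columns clones, both in depth order (identical labels since clone j is
#'   defined by mutation j).
#' @examples
#' tree_to_genotype_matrix(clonal_tree(c(m1 = NA, m2 = "m1", m3 = "m2")))
#' @export
tree_to_genotype_matrix <- function(tree) {
  stopifnot(inherits(tree, "clonal_tree"))
  ord <- depth_order(tree)
  n <- tree$n_nodes
  A <- matrix(0L, n, n, dimnames = list(allele = ord, clone = ord))
  for (j in seq_len(n)) {
    v <- ord[j]
    while (!is.na(v)) { # ancestors-or-self of clone j
      A[v, j] <- 1L
      v <- tree$parent[[v]]
    }
  }
  structure(A, class = c("genotype_matrix", class(A)))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix (", nrow(x), " clones, unit upper triangular)\n",
      sep = "")
  print(unclass(x), ...)
  invisible(x)
}

canonical_tree_key <- function(tree) {
  # deterministic identity string: root label plus the Pruefer encoding of
  # the unrooted tree under the sorted-label indexing; used for tie-breaking
  labels <- sort(tree$labels)
  if (tree$n_nodes == 1L) return(tree$root)
  idx <- stats::setNames(seq_along(labels), labels)
  child <- tree$labels[!is.na(tree$parent)]
  edges <- cbind(idx[child], idx[tree$parent[child]])
  paste(c(tree$root, tree_to_prufer(edges)), collapse = "|")
}

same_tree <- function(a, b) {
  a$n_nodes == b$n_nodes && a$root == b$root &&
    setequal(a$labels, b$labels) &&
    identical(unname(a$parent[sort(a$labels)]), unname(b$parent[sort(b$labels)]))
}

#' Write a clonal tree in Newick format
#'
#' Emits a rooted Newick string with node labels equal to the allele
#' identifiers. Clone frequencies, when supplied, are embedded as
#' square-bracket comments after each label so that standard Newick readers
#' ignore them.
#'
#' @param tree a [clonal_tree()].
#' @param frequencies optional named list, one numeric vector of per-clone
#'   frequencies (named by clone label) per timepoint.
#' @param file optional path; when given the string is also written there.
#' @return the Newick string, invisibly when `file` is given.
#' @examples
#' write_newick(clonal_tree(c(m1 = NA, m2 = "m1"))) # "(m2)m1;"
#' @export
write_newick <- function(tree, frequencies = NULL, file = NULL) {
  stopifnot(inherits(tree, "clonal_tree"))
  kids <- children_of(tree)
  annot <- function(v) {
    if (is.null(frequencies)) return("")
    vals <- vapply(names(frequencies),
                   function(tp) frequencies[[tp]][[v]], numeric(1))
    paste0("[&", paste0(names(frequencies), "=",
                        sprintf("%g", vals), collapse = ","), "]")
  }
  emit <- function(v) {
    ch <- sort(kids[[v]])
    inner <- if (length(ch))
      paste0("(", paste(vapply(ch, emit, character(1)), collapse = ","), ")")
    else ""
    paste0(inner, v, annot(v))
  }
  out <- paste0(emit(tree$root), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
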