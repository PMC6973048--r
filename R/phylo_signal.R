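# Phylogenetic signal in phenological traits: newick input, Felsenstein's
# independent contrasts by pruning, Blomberg's K, and a tip-shuffling
# permutation test on the contrast variance.

#' Read and validate a phylogeny from a newick file
#'
#' Parses a rooted newick tree with branch lengths. Polytomies are resolved
#' to binary splits with zero-length branches, and zero-length branches are
#' then perturbed by `1e-8` times the tree depth so that contrast
#' standardization never divides by zero.
#'
#' @param path newick file path (or a newick string containing `"("`).
#' @return an `ape` `phylo` object, binary, with positive branch lengths.
#' @export
read_phylogeny <- function(path) {
  tree <- tryCatch(
    if (grepl("(", path, fixed = TRUE)) ape::read.tree(text = path)
    else ape::read.tree(path),
    error = function(e) stopf("newick parse error: %s", conditionMessage(e)))
  if (is.null(tree)) stopf("newick parse error: no tree could be read")
  prepare_phylogeny(tree)
}

# validation + polytomy resolution shared by read_phylogeny and the
# trait functions when handed a phylo directly
prepare_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("not a phylogeny")
  if (anyDuplicated(tree$tip.label)) {
    stopf("duplicate tip labels: %s",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stopf("negative branch lengths")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  if (any(tree$edge.length == 0)) {
    depth <- max(ape::node.depth.edgelength(tree))
    eps <- if (depth > 0) 1e-8 * depth else 1e-8
    tree$edge.length[tree$edge.length == 0] <- eps
  }
  tree
}

# match a named trait vector against the tips; errors on gaps
align_traits <- function(tree, x) {
  if (is.null(names(x))) {
    if (length(x) != length(tree$tip.label)) {
      stopf("unnamed trait vector must have one value per tip")
    }
    names(x) <- tree$tip.label
  }
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss)) stopf("trait values missing for tips: %s",
                          paste(miss, collapse = ", "))
  x <- x[tree$tip.label]
  if (any(!is.finite(x))) stopf("non-finite trait values")
  x
}

# Felsenstein pruning on a matrix of trait vectors (tips x m), vectorized
# across columns so permutation tests stay cheap. Returns list(contrasts =
# (n-1) x m matrix in internal-node order, root_value, sum_sq identity parts).
pic_engine <- function(tree, X) {
  tree <- prepare_phylogeny(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stopf("need >= 2 tips")
  tr <- stats::reorder(tree, "pruningwise")  # sibling edges adjacent, pairs
  nnode <- tr$Nnode
  m <- ncol(X)
  val <- matrix(NA_real_, ntip + nnode, m)
  val[seq_len(ntip), ] <- X
  bl <- numeric(ntip + nnode)
  bl[tr$edge[, 2L]] <- tr$edge.length
  contrasts <- matrix(NA_real_, nnode, m)
  parents <- tr$edge[, 1L]
  children <- tr$edge[, 2L]
  # postorder edges come in sibling pairs for a binary tree
  for (e in seq(1L, length(parents), by = 2L)) {
    nd <- parents[e]
    c1 <- children[e]; c2 <- children[e + 1L]
    b1 <- bl[c1]; b2 <- bl[c2]
    vsum <- b1 + b2
    if (vsum <= 0) stopf("zero combined branch length at node %d", nd)
    contrasts[nd - ntip, ] <- (val[c1, ] - val[c2, ]) / sqrt(vsum)
    val[nd, ] <- (b2 * val[c1, ] + b1 * val[c2, ]) / vsum
    bl[nd] <- bl[nd] + b1 * b2 / vsum
  }
  list(contrasts = contrasts, root_value = val[ntip + 1L, ],
       tree = tr, ntip = ntip)
}

#' Phylogenetic independent contrasts
#'
#' Felsenstein's (1985) contrasts by the standard pruning pass: at each
#' internal node the contrast between the two daughter values standardized
#' by the square root of their combined (extended) branch lengths, the
#' ancestral value as the branch-length-weighted mean, and the parent branch
#' extended by \eqn{b_1 b_2 / (b_1 + b_2)}.
#'
#' @param tree a `phylo` tree (binary after polytomy resolution).
#' @param x named numeric trait vector covering every tip.
#' @return numeric vector of `n - 1` contrasts named by internal node
#'   number (same convention as `ape`).
#' @export
pic_contrasts <- function(tree, x) {
  x <- align_traits(prepare_phylogeny(tree), x)
  eng <- pic_engine(prepare_phylogeny(tree), matrix(unname(x), ncol = 1L))
  out <- drop(eng$contrasts)
  names(out) <- as.character(eng$ntip + seq_along(out))
  out
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' The ratio-of-ratios statistic of Blomberg, Garland & Ives (2003):
#' \deqn{K = \frac{(MSE_0 / MSE)_{obs}}{(MSE_0 / MSE)_{exp}}}
#' where \eqn{MSE_0} is the mean squared deviation of tip values from the
#' phylogenetically (GLS) corrected mean, \eqn{MSE} the GLS mean squared
#' error under the Brownian-motion covariance \eqn{V}, and the expected
#' ratio is \eqn{[\mathrm{tr}(V) - n / (\mathbf{1}' V^{-1} \mathbf{1})] /
#' (n - 1)}. K = 1 is the Brownian expectation on the given tree; K near 0
#' means trait variation is independent of phylogeny; K > 1 means closer
#' relatives are even more similar than Brownian motion predicts. K is
#' invariant to affine trait transforms and to rescaling all branch lengths.
#'
#' @param tree a `phylo` tree with >= 4 tips.
#' @param x named numeric trait vector covering every tip.
#' @return K (non-negative scalar).
#' @export
blomberg_k <- function(tree, x) {
  tree <- prepare_phylogeny(tree)
  x <- align_traits(tree, x)
  n <- length(x)
  if (n < 4L) stopf("Blomberg's K needs >= 4 tips")
  V <- ape::vcv(tree)
  Vi <- tryCatch(solve(V), error = function(e) {
    stopf("singular phylogenetic covariance matrix")
  })
  one <- rep(1, n)
  denom1 <- drop(one %*% Vi %*% one)
  a <- drop(one %*% Vi %*% x) / denom1      # GLS (phylogenetic) mean
  r <- x - a
  MSE0 <- sum(r^2) / (n - 1)
  MSE <- drop(r %*% Vi %*% r) / (n - 1)
  observed <- MSE0 / MSE
  expected <- (sum(diag(V)) - n / denom1) / (n - 1)
  observed / expected
}

#' Permutation test of phylogenetic signal
#'
#' Shuffles trait values across the tips and compares the observed mean
#' squared independent contrast with its permutation distribution: low
#' contrast variance relative to shuffles indicates that close relatives
#' have similar trait values. The p value uses the add-one estimator
#' \eqn{p = (1 + \#\{s_{perm} \le s_{obs}\}) / (n_{perm} + 1)}, so it is
#' never exactly zero. With `statistic = "K"` the test is run on Blomberg's
#' K instead (rejecting for large observed K).
#'
#' @param tree a `phylo` tree.
#' @param x named numeric trait vector covering every tip.
#' @param n_perm number of permutations, >= 99 (default 999).
#' @param seed integer seed or `NULL`.
#' @param statistic `"pic_variance"` (default) or `"K"`.
#' @return object of class `phylo_signal`: list with `K`, `observed` (the
#'   permuted statistic), `p_permutation`, `n_perm`, `statistic`, `seed`.
#' @export
signal_test <- function(tree, x, n_perm = 999L, seed = NULL,
                        statistic = c("pic_variance", "K")) {
  statistic <- match.arg(statistic)
  if (n_perm < 99L) stopf("use at least 99 permutations")
  tree <- prepare_phylogeny(tree)
  x <- align_traits(tree, x)
  n <- length(x)
  K <- if (n >= 4L) blomberg_k(tree, x) else NA_real_
  if (stats::var(x) == 0) {
    warnf("constant trait: no signal to test")
    return(structure(list(K = K, observed = NA_real_, p_permutation = 1,
                          n_perm = n_perm, statistic = statistic, seed = seed),
                     class = "phylo_signal"))
  }
  if (statistic == "pic_variance") {
    X <- matrix(unname(x), ncol = 1L)
    obs <- mean(pic_engine(tree, X)$contrasts^2)
    perm_stats <- with_seed(seed, {
      P <- vapply(seq_len(n_perm), function(i) sample(unname(x)), numeric(n))
      colMeans(pic_engine(tree, P)$contrasts^2)
    })
    p <- (1 + sum(perm_stats <= obs)) / (n_perm + 1)
  } else {
    obs <- K
    perm_stats <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        xp <- unname(sample(unname(x)))
        names(xp) <- names(x)
        blomberg_k(tree, xp)
      }, 0)
    })
    p <- (1 + sum(perm_stats >= obs)) / (n_perm + 1)
  }
  structure(list(K = K, observed = obs, p_permutation = p,
                 n_perm = n_perm, statistic = statistic, seed = seed),
            class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat(sprintf("Phylogenetic signal: K = %.4g, permutation p = %.4g (%s, %d permutations)\n",
              x$K, x$p_permutation, x$statistic, x$n_perm))
  invisible(x)
}
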