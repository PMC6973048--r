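# Independent oracles and fixture builders used across the suite. These are
# deliberately naive re-derivations (enumeration, closed forms, matrix
# algebra) kept separate from the package's own computation paths.

# Fligner-Policello U by direct placement counting
fp_oracle <- function(x, y) {
  P <- vapply(x, function(xi) sum(y < xi) + 0.5 * sum(y == xi), 0)
  Q <- vapply(y, function(yj) sum(x < yj) + 0.5 * sum(x == yj), 0)
  V1 <- sum((P - mean(P))^2)
  V2 <- sum((Q - mean(Q))^2)
  (sum(P) - sum(Q)) / (2 * sqrt(V1 + V2 + mean(P) * mean(Q)))
}

# Holm step-down by the definition: sort, multiply, cummax, cap, unsort
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(cummax(p[o] * (m - seq_len(m) + 1L)), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Morisita's index straight from its definition
morisita_oracle <- function(counts) {
  N <- sum(counts)
  length(counts) * sum(counts * (counts - 1)) / (N * (N - 1))
}

# GLS pieces for contrast checks: sum of squared contrasts must equal the
# quadratic form (x - mu)' V^-1 (x - mu) with mu the GLS mean
gls_contrast_ss <- function(tree, x) {
  V <- ape::vcv(tree)
  x <- x[rownames(V)]
  Vi <- solve(V)
  one <- rep(1, length(x))
  mu <- drop(one %*% Vi %*% x) / drop(one %*% Vi %*% one)
  drop((x - mu) %*% Vi %*% (x - mu))
}

# Matrix-based GLS oracle for independent contrasts: for each internal node,
# the contrast between its two child-subtree GLS mean estimates, standardized
# by child branch lengths extended with the GLS estimator variance
# 1 / (1' V^-1 1) of each subtree (V measured from the subtree root).
gls_pic_oracle <- function(tree, x) {
  ntip <- length(tree$tip.label)
  x <- x[tree$tip.label]
  sub_stats <- function(node, b) {
    if (node <= ntip) return(c(mean = unname(x[node]), var = b))
    cl <- ape::extract.clade(tree, node)
    V <- ape::vcv(cl)
    xi <- x[rownames(V)]
    Vi <- solve(V)
    w <- rowSums(Vi) / sum(Vi)
    c(mean = sum(w * xi), var = b + 1 / sum(Vi))
  }
  internal <- (ntip + 1):(ntip + tree$Nnode)
  out <- vapply(internal, function(nd) {
    rows <- which(tree$edge[, 1] == nd)
    kids <- tree$edge[rows, 2]
    bl <- tree$edge.length[rows]
    s1 <- sub_stats(kids[1], bl[1])
    s2 <- sub_stats(kids[2], bl[2])
    unname((s1["mean"] - s2["mean"]) / sqrt(s1["var"] + s2["var"]))
  }, 0)
  names(out) <- as.character(internal)
  out
}

# small two-year census fixture: weekly, 1 March - 31 July
toy_calendars <- function(years = c(2016L, 2017L)) {
  lapply(years, weekly_calendar)
}

# hand-built dataset: 3 species x 2 life forms, census-aligned dates
toy_dataset <- function() {
  cal <- weekly_calendar(2016)
  d <- cal$dates
  rec <- function(sp, genus, lf, ids, onsets, ends) {
    data.frame(species = sp, genus = genus, family = paste0("fam_", genus),
               life_form = lf, year = 2016L,
               individual_id = paste0(sp, "_", ids),
               onset = d[onsets], end = d[ends], stringsAsFactors = FALSE)
  }
  records <- rbind(
    rec("Alnus_demo", "Alnus", "tree", 1:5, c(5, 5, 6, 5, 6), c(7, 8, 8, 7, 8)),
    rec("Bellis_demo", "Bellis", "perennial", 1:5, c(2, 4, 6, 8, 10), c(6, 9, 12, 14, 16)),
    rec("Carex_demo", "Carex", "annual", 1:4, c(1, 3, 9, 12), c(4, 8, 14, 18))
  )
  pheno_dataset(records, cal)
}

# write a dataset to temp CSVs, returning the three paths
write_toy_csvs <- function(ds = toy_dataset()) {
  paths <- list(records = tempfile(fileext = ".csv"),
                calendar = tempfile(fileext = ".csv"),
                meta = tempfile(fileext = ".csv"))
  write_pheno_dataset(ds, paths$records, paths$calendar, paths$meta)
  paths
}
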