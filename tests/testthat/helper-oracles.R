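# Independent oracles used to check pipeline operations by brute force or
# closed form. These deliberately avoid the code paths they verify.

# --- tree oracles: direct recursion over the edge matrix ---------------------

# tip labels under each node (tips included), by plain recursion
oracle_node_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  res <- vector("list", nnode)
  desc <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  for (v in seq_len(nnode)) res[[v]] <- desc(v)
  res
}

# smallest clade (node tip set) containing all of `refs`
oracle_min_superset <- function(tree, refs) {
  tipsets <- oracle_node_tips(tree)
  ok <- vapply(tipsets, function(s) all(refs %in% s), TRUE)
  sizes <- lengths(tipsets)
  sizes[!ok] <- Inf
  tipsets[[which.min(sizes)]]
}

# expected sporulation-clade members by enumeration
oracle_clade_members <- function(tree, meta, spore_refs, sigb_refs) {
  clade <- oracle_min_superset(tree, spore_refs)
  excl <- oracle_min_superset(tree, sigb_refs)
  phage <- meta$tip[meta$source == "phage"]
  list(clade = sort(clade), excl = sort(excl),
       members = sort(setdiff(intersect(clade, phage), excl)))
}

# maximal phage-only clades by enumeration over all node tip sets
oracle_phage_only <- function(tree, meta) {
  ntip <- length(tree$tip.label)
  tipsets <- oracle_node_tips(tree)
  phage <- meta$tip[meta$source == "phage"]
  all_phage <- vapply(tipsets, function(s) all(s %in% phage), TRUE)
  parent <- integer(length(tipsets))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  keep <- which(all_phage & (seq_along(tipsets) == root | !all_phage[pmax(parent, 1L)]))
  lapply(keep, function(v) sort(tipsets[[v]]))
}

# random annotated tree for property tests: binary rooted topology with at
# least `min_bact` bacterial tips to draw references from
oracle_random_annotated_tree <- function(n_tips, min_bact = 4L) {
  tree <- ape::rtree(n_tips, rooted = TRUE)
  src <- sample(c("phage", "bacterial"), n_tips, replace = TRUE)
  src[sample(n_tips, min_bact)] <- "bacterial"
  meta <- data.frame(tip = tree$tip.label, source = src,
                     family = NA_character_, stringsAsFactors = FALSE)
  list(tree = tree, meta = meta)
}

# --- closed-form statistics oracles ------------------------------------------

oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

oracle_one_sample <- function(d) {
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

# Holm step-down written from its definition
oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, (n - seq_len(n) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(n); out[o] <- adj
  out
}

# Benjamini-Hochberg step-up written from its definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, n / seq_len(n) * p[o])
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n); out[o] <- adj
  out
}

# upper-tail hypergeometric probability by exhaustive enumeration of draws
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  annotated <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% annotated))
  mean(hits >= k)
}

# all permutations of 1:n, written independently (Heap-style recursion)
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- oracle_perms(n - 1L)
  out <- list()
  for (p in smaller) for (pos in 0:(n - 1)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos)
  }
  out
}

# exact two-sided permutation p for Spearman rho
oracle_spearman_perm_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(stats::cor(rx, ry))
  rhos <- vapply(oracle_perms(length(y)),
                 function(p) abs(stats::cor(rx, ry[p])), 0)
  mean(rhos >= obs - 1e-12)
}

# --- misc --------------------------------------------------------------------

# fine-grid trapezoid quadrature of a function on [0, t_end]
oracle_quadrature <- function(f, t_end, dt = 0.01) {
  tt <- seq(0, t_end, by = dt)
  y <- f(tt)
  sum((y[-1] + y[-length(y)]) / 2 * diff(tt))
}

logistic_od <- function(t, r = 0.8, K = 1, od0 = 0.05) {
  K * od0 * exp(r * t) / (K + od0 * (exp(r * t) - 1))
}

# long-format curve set where every infected well is c x control
constant_suppression_curves <- function(c_frac, mois = 10^seq(-5, 0),
                                        t_max = 10, dt = 0.25) {
  tt <- seq(0, t_max, by = dt)
  ctrl <- logistic_od(tt)
  rows <- list(data.frame(moi = 0, replicate = 1L, time_h = tt, od600 = ctrl))
  for (m in mois)
    rows[[length(rows) + 1L]] <-
      data.frame(moi = m, replicate = 1L, time_h = tt, od600 = c_frac * ctrl)
  do.call(rbind, rows)
}
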