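# Allele-sharing dissimilarities and a classical neighbor-joining tree,
# with group extraction by cutting the longest internal branches.

#' Pairwise allele-sharing dissimilarity
#'
#' For each sample pair, over the sites where both are called,
#' `d = 1 - mean(s)` with `s = 1` for identical genotypes, `s = 0.5` for a
#' homozygote vs a heterozygote sharing one allele, and `s = 0` otherwise
#' (the default dissimilarity for codominant SNP data). Pairs sharing fewer
#' than `min_shared` called sites get `NA`.
#'
#' @param gm a `genotype_matrix` with at least 3 samples
#' @param min_shared minimum shared non-missing sites per pair (default 30)
#' @return object of class `snp_dist`: list with `d` (symmetric matrix,
#'   zero diagonal) and `shared` (pairwise shared-site counts)
#' @export
snp_dissimilarity <- function(gm, min_shared = 30L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- nrow(gm$calls)
  if (n < 3L) stop("need at least 3 samples")
  al <- split_alleles(gm$calls)
  a1 <- al$a1; a2 <- al$a2
  hom <- !is.na(gm$calls) & a1 == a2
  d <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  shared <- matrix(0L, n, n, dimnames = list(gm$samples, gm$samples))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(gm$calls[i, ]) & !is.na(gm$calls[j, ])
      L <- sum(ok)
      shared[i, j] <- shared[j, i] <- L
      if (L < min_shared) { d[i, j] <- d[j, i] <- NA_real_; next }
      gi <- gm$calls[i, ok]; gj <- gm$calls[j, ok]
      ident <- gi == gj
      x1 <- a1[i, ok]; x2 <- a2[i, ok]; y1 <- a1[j, ok]; y2 <- a2[j, ok]
      hi <- hom[i, ok]; hj <- hom[j, ok]
      half <- !ident & ((hi & !hj & (x1 == y1 | x1 == y2)) |
                        (hj & !hi & (y1 == x1 | y1 == x2)))
      s <- sum(ident) + 0.5 * sum(half)
      d[i, j] <- d[j, i] <- 1 - s / L
    }
  }
  structure(list(d = d, shared = shared, samples = gm$samples),
            class = "snp_dist")
}

#' @export
print.snp_dist <- function(x, ...) {
  cat("snp_dist:", length(x$samples), "samples;",
      sum(is.na(x$d[upper.tri(x$d)])), "pair(s) below min_shared\n")
  invisible(x)
}

#' Neighbor-joining tree
#'
#' Classical agglomerative neighbor joining (Saitou-Nei, Studier-Keppler
#' update): at each step the pair minimizing
#' `Q(i,j) = (N-2) d(i,j) - r(i) - r(j)` is joined, with branch lengths
#' `l(i) = d(i,j)/2 + (r(i) - r(j)) / (2(N-2))`; ties in Q are broken toward
#' the smallest index pair. Negative branch lengths are clamped to zero (the
#' raw lengths are kept in the `raw_edge_length` attribute).
#'
#' @param d a `snp_dist`, `dist`, or complete symmetric numeric matrix
#' @return an unrooted binary [ape::phylo] tree
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "snp_dist")) d <- d$d
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (anyNA(d)) stop("distance matrix contains NA (pairs below min_shared?)")
  labels <- rownames(d)
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(n))
  # node ids: tips 1..n, internal n+1, n+2, ... as created
  active <- seq_len(n)          # node ids of current clusters
  D <- d
  next_node <- n + 1L
  edges <- matrix(0L, 0L, 2L); lens <- numeric(0)
  while (length(active) > 3L) {
    N <- length(active)
    r <- rowSums(D)
    Q <- (N - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # smallest-index tie-break: scan column-major upper triangle
    Qu <- Q; Qu[lower.tri(Qu, diag = TRUE)] <- Inf
    k <- which(Qu == min(Qu), arr.ind = TRUE)
    k <- k[order(k[, 1], k[, 2]), , drop = FALSE][1, ]
    i <- k[1]; j <- k[2]
    dij <- D[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (N - 2))
    lj <- dij - li
    edges <- rbind(edges, c(next_node, active[i]), c(next_node, active[j]))
    lens <- c(lens, li, lj)
    dnew <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    active <- c(active[keep], next_node)
    next_node <- next_node + 1L
  }
  # join the last three clusters at a central node (three-point formulas)
  a <- D[1, 2]; b <- D[1, 3]; cc <- D[2, 3]
  v <- next_node
  edges <- rbind(edges, c(v, active[1]), c(v, active[2]), c(v, active[3]))
  lens <- c(lens, (a + b - cc) / 2, (a + cc - b) / 2, (b + cc - a) / 2)
  # renumber internal nodes into ape convention (root = n+1, preorder)
  n_internal <- next_node - n
  new_id <- integer(next_node)
  new_id[seq_len(n)] <- seq_len(n)
  # preorder walk from the final center node
  children <- split(seq_len(nrow(edges)), edges[, 1])
  counter <- n
  assign_ids <- function(node) {
    stack <- node
    while (length(stack)) {
      nd <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (nd > n) {
        counter <<- counter + 1L
        new_id[nd] <<- counter
        kids <- edges[children[[as.character(nd)]], 2]
        stack <- c(stack, rev(kids[kids > n]))
      }
    }
  }
  assign_ids(v)
  edge <- cbind(new_id[edges[, 1]], new_id[edges[, 2]])
  # ape expects edges ordered so that parents appear before children (cladewise
  # works after reorder); build tree then reorder
  raw <- lens
  clamped <- pmax(lens, 0)
  tree <- structure(list(edge = edge, edge.length = clamped,
                         tip.label = labels, Nnode = n_internal),
                    class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  o <- attr(tree, "order")
  # reorder raw lengths to match the reordered edges
  m <- match(paste(tree$edge[, 1], tree$edge[, 2]),
             paste(edge[, 1], edge[, 2]))
  attr(tree, "raw_edge_length") <- raw[m]
  attr(tree, "negative_clamped") <- any(raw < 0)
  tree
}

#' Extract groups by cutting the longest internal branches
#'
#' Removes the `k - 1` longest internal branches of the tree (ties broken by
#' edge index); the connected components of what remains define the groups.
#' `k = 1` returns a single group; `k >=` the number of tips returns
#' singletons.
#'
#' @param tree an [ape::phylo] tree
#' @param k number of groups
#' @return named integer vector: group id (1..k) per tip label
#' @export
extract_groups <- function(tree, k) {
  n <- length(tree$tip.label)
  stopifnot(k >= 1, k <= n)
  if (k == 1L)
    return(stats::setNames(rep(1L, n), tree$tip.label))
  if (k == n)
    return(stats::setNames(seq_len(n), tree$tip.label))
  internal <- which(tree$edge[, 2] > n)
  if (k - 1L > length(internal))
    stop("tree has only ", length(internal), " internal branches; cannot ",
         "form ", k, " groups by internal cuts")
  ord <- internal[order(-tree$edge.length[internal], internal)]
  cut <- ord[seq_len(k - 1L)]
  keep_edges <- tree$edge[-cut, , drop = FALSE]
  # union-find over nodes
  n_nodes <- n + tree$Nnode
  parent <- seq_len(n_nodes)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in seq_len(nrow(keep_edges))) {
    a <- find(keep_edges[e, 1]); b <- find(keep_edges[e, 2])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  grp <- as.integer(factor(roots, levels = unique(roots)))
  stats::setNames(grp, tree$tip.label)
}

#' Purity of recovered groups against known lineages
#'
#' Counts the groups whose members all share one lineage label (pure
#' single-lineage clusters). With `require_complete = TRUE` a group must
#' additionally contain every sample of its lineage (a one-to-one match
#' between groups and lineages).
#'
#' @param groups named group assignment from [extract_groups()]
#' @param lineages named character vector of true lineage labels (same names)
#' @param require_complete also require the group to hold its whole lineage?
#' @return integer: number of qualifying groups
#' @export
group_lineage_purity <- function(groups, lineages, require_complete = FALSE) {
  lineages <- lineages[names(groups)]
  pure <- 0L
  for (g in unique(groups)) {
    members <- names(groups)[groups == g]
    labs <- unique(lineages[members])
    if (length(labs) != 1L) next
    if (require_complete &&
        !all(names(lineages)[lineages == labs] %in% members)) next
    pure <- pure + 1L
  }
  pure
}
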