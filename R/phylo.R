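# ---------------------------------------------------------------------------
# Distance-based phylogenetics for segment-family verification:
# Poisson-corrected amino-acid distances, p/JC69/K80 nucleotide distances,
# Saitou-Nei neighbor joining and column-resampling bootstrap support.
# ---------------------------------------------------------------------------

.DIST_CAP <- 10  # saturated distances are capped, keeping NJ runnable

.as_aln_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    m <- toupper(alignment)
  } else {
    if (is.null(names(alignment))) names(alignment) <- paste0("seq", seq_along(alignment))
    if (length(unique(nchar(alignment))) != 1L) {
      stop("alignment rows must have equal length")
    }
    m <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
    rownames(m) <- names(alignment)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  m
}

.pair_p <- function(m, valid) {
  # proportion of differing sites per pair under pairwise deletion of
  # ambiguous columns, via one-hot cross products (fast enough to sit in
  # the bootstrap inner loop); returns list(p, n) of matrices
  letters <- unique(as.vector(m[valid]))
  n <- nrow(m)
  Ncmp <- tcrossprod(valid * 1)
  Mt <- matrix(0, n, n)
  for (a in letters) {
    B <- (m == a) & valid
    Mt <- Mt + tcrossprod(B * 1)
  }
  P <- 1 - Mt / Ncmp
  P[Ncmp == 0] <- NA_real_
  dimnames(P) <- list(rownames(m), rownames(m))
  dimnames(Ncmp) <- dimnames(P)
  list(p = P, n = Ncmp)
}

.saturate <- function(d, where) {
  if (any(where)) {
    warning("saturated distance(s) capped at ", .DIST_CAP)
    d[where] <- .DIST_CAP
  }
  d
}

#' Poisson-corrected amino-acid distances
#'
#' For each sequence pair, ambiguous positions (gaps, `X`, `*`, `?`) are
#' removed pairwise, `p` is the proportion of differing sites and the
#' corrected distance is `d = -ln(1 - p)` (substitutions per site).
#' Saturated pairs (`p >= 1`) are capped with a warning.
#'
#' @param alignment character vector of equal-length aligned amino-acid
#'   sequences (named), or a character matrix.
#' @return object of class `trb_dist`: list with `labels`, `d` (distance
#'   matrix), `p` and `n_sites`.
#' @export
aa_distance_poisson <- function(alignment) {
  m <- .as_aln_matrix(alignment)
  valid <- !(m %in% c("-", ".", "X", "*", "?"))
  dim(valid) <- dim(m)
  pp <- .pair_p(m, valid)
  d <- -log(1 - pp$p)
  d <- .saturate(d, !is.finite(d) | pp$p >= 1)
  diag(d) <- 0
  structure(list(labels = rownames(m), d = d, p = pp$p, n_sites = pp$n),
            class = "trb_dist")
}

#' Nucleotide distances (p, JC69, K80)
#'
#' Pairwise-deletion distances on an aligned nucleotide matrix: raw
#' p-distance, Jukes-Cantor `d = -(3/4) ln(1 - 4p/3)`, or Kimura
#' two-parameter from transition (`P`) and transversion (`Q`) proportions,
#' `d = -(1/2) ln((1-2P-Q) sqrt(1-2Q))`. Saturated pairs are capped.
#'
#' @param alignment named character vector or matrix of aligned sequences.
#' @param model `"p"`, `"JC69"` or `"K80"`.
#' @return a `trb_dist` object.
#' @export
nt_distance <- function(alignment, model = c("p", "JC69", "K80")) {
  model <- match.arg(model)
  m <- .as_aln_matrix(alignment)
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  pp <- .pair_p(m, valid)
  if (model == "p") {
    d <- pp$p
  } else if (model == "JC69") {
    d <- -0.75 * log(1 - 4 * pp$p / 3)
    d <- .saturate(d, !is.finite(d) | pp$p >= 0.75)
  } else {
    Ncmp <- pp$n
    ind <- function(a) (m == a) & valid
    A <- ind("A") * 1; G <- ind("G") * 1; C <- ind("C") * 1; Tt <- ind("T") * 1
    TS <- tcrossprod(A, G) + tcrossprod(G, A) + tcrossprod(C, Tt) + tcrossprod(Tt, C)
    P <- TS / Ncmp
    Q <- pp$p - P
    P[Ncmp == 0] <- NA_real_
    d <- -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
    d <- .saturate(d, !is.finite(d))
    dimnames(d) <- dimnames(pp$p)
  }
  diag(d) <- 0
  structure(list(labels = rownames(m), d = d, p = pp$p, n_sites = pp$n),
            class = "trb_dist")
}

#' @export
print.trb_dist <- function(x, ...) {
  cat("distance matrix over", length(x$labels), "sequences\n")
  print(round(x$d, 4))
  invisible(x)
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Standard Q-criterion agglomeration. Ties in the Q minimization join the
#' lowest-index pair; negative branch lengths are clamped to zero with the
#' deficit transferred to the sibling edge. On an additive matrix the
#' tree's path lengths reproduce the input exactly.
#'
#' @param dm a `trb_dist` object, `dist`, or a square symmetric matrix with
#'   dimnames.
#' @return an [ape] `phylo` tree (unrooted).
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "trb_dist")) {
    D <- dm$d
  } else if (inherits(dm, "dist")) {
    D <- as.matrix(dm)
  } else {
    D <- as.matrix(dm)
  }
  n <- nrow(D)
  if (n < 3L) stop("nj_tree needs at least 3 labels")
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  # each active cluster carries a newick fragment
  frag <- labs
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  active <- seq_len(n)
  while (length(active) > 3L) {
    k <- length(active)
    Da <- D[active, active, drop = FALSE]
    r <- rowSums(Da)
    Q <- (k - 2) * Da - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest-index pair on ties (column-major scan respects (i,j) order)
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[order(pmin(best[, 1], best[, 2]), pmax(best[, 1], best[, 2])), , drop = FALSE]
    i <- min(best[1, ]); j <- max(best[1, ])
    vi <- Da[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    vj <- Da[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    vi <- max(vi, 0); vj <- max(vj, 0)
    ai <- active[i]; aj <- active[j]
    new_frag <- paste0("(", frag[ai], ":", fmt(vi), ",", frag[aj], ":", fmt(vj), ")")
    # distances from the new node
    rest <- active[-c(i, j)]
    newd <- (D[ai, rest] + D[aj, rest] - D[ai, aj]) / 2
    D <- rbind(cbind(D, 0), 0)
    idx <- nrow(D)
    D[idx, rest] <- newd; D[rest, idx] <- newd
    frag <- c(frag, new_frag)
    active <- c(rest, idx)
  }
  a <- active[1]; b <- active[2]; cc <- active[3]
  va <- (D[a, b] + D[a, cc] - D[b, cc]) / 2
  vb <- (D[a, b] + D[b, cc] - D[a, cc]) / 2
  vc <- (D[a, cc] + D[b, cc] - D[a, b]) / 2
  nwk <- paste0("(", frag[a], ":", fmt(va), ",", frag[b], ":", fmt(vb),
                ",", frag[cc], ":", fmt(vc), ");")
  ape::read.tree(text = nwk)
}

# Canonical bipartition keys of a phylo tree's internal edges: each key is
# the sorted tip set on the side not containing the first label.
.bipartitions <- function(tree) {
  nt <- length(tree$tip.label)
  keys <- character(0)
  nodes <- integer(0)
  all_tips <- sort(tree$tip.label)
  ref_tip <- all_tips[1]  # fixed reference: canonical across trees
  desc <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    out <- character(0)
    for (kd in kids) {
      out <- c(out, if (kd <= nt) tree$tip.label[kd] else desc(kd))
    }
    out
  }
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(nt))
  for (node in internal) {
    side <- sort(desc(node))
    if (length(side) <= 1L || length(side) >= nt - 1L) next
    if (ref_tip %in% side) side <- setdiff(all_tips, side)
    keys <- c(keys, paste(side, collapse = "|"))
    nodes <- c(nodes, node)
  }
  list(keys = keys, nodes = nodes)
}

.tree_from_alignment <- function(alignment, model) {
  dmf <- switch(model,
                poisson = aa_distance_poisson,
                function(a) nt_distance(a, model = model))
  nj_tree(dmf(alignment))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal bipartition of the full-data
#' tree the percentage of replicates containing it. Seeded runs are
#' reproducible.
#'
#' @param alignment named character vector / matrix of aligned sequences.
#' @param model `"poisson"` (amino acid), `"p"`, `"JC69"` or `"K80"`.
#' @param replicates number of bootstrap replicates.
#' @param seed RNG seed.
#' @return the full-data `phylo` tree with `node.label` carrying support
#'   percentages (root label empty) and attribute `support` (named vector
#'   keyed by bipartition).
#' @export
bootstrap_support <- function(alignment, model = c("poisson", "p", "JC69", "K80"),
                              replicates = 1000L, seed = 1L) {
  model <- match.arg(model)
  if (replicates < 1L) stop("replicates must be >= 1")
  m <- .as_aln_matrix(alignment)
  if (ncol(m) < 2L) warning("degenerate alignment: a single column")
  full <- .tree_from_alignment(m, model)
  bp <- .bipartitions(full)
  counts <- setNames(rep(0L, length(bp$keys)), bp$keys)
  set.seed(seed)
  for (b in seq_len(replicates)) {
    cols <- sample(ncol(m), ncol(m), replace = TRUE)
    rep_tree <- tryCatch(
      suppressWarnings(.tree_from_alignment(m[, cols, drop = FALSE], model)),
      error = function(e) NULL)
    if (is.null(rep_tree)) next
    rk <- .bipartitions(rep_tree)$keys
    hit <- bp$keys %in% rk
    counts[hit] <- counts[hit] + 1L
  }
  support <- 100 * counts / replicates
  nt <- length(full$tip.label)
  node_lab <- rep("", full$Nnode)
  for (i in seq_along(bp$nodes)) {
    node_lab[bp$nodes[i] - nt] <- sprintf("%g", support[i])
  }
  full$node.label <- node_lab
  attr(full, "support") <- support
  full
}

#' Export a distance matrix in PHYLIP format
#' @param dm a `trb_dist` object or matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(dm, path) {
  D <- if (inherits(dm, "trb_dist")) dm$d else as.matrix(dm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste(sprintf("%-10s", rownames(D)[i]),
                     paste(sprintf("%.6f", D[i, ]), collapse = " ")), con)
  }
  invisible(path)
}
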