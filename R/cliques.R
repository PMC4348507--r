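#' Per-marker IBD graph
#'
#' Weighted undirected graph whose nodes are all haplotypes and whose edges
#' connect haplotype pairs with an IBD segment covering the marker; the
#' edge weight is the covering segment's mean HMM posterior (the maximum
#' when several segments cover).
#'
#' @param store an [segment_store()].
#' @param marker global marker index into the store's map.
#' @return An object of class `IBDGraph`: `marker`, `n_hap`, and an edge
#'   `data.frame` `edges` with columns `u`, `v`, `w`.
#' @export
build_graph <- function(store, marker) {
  s <- store$segments
  cov <- s$start <= marker & marker < s$end &
    s$chrom == store$map$chrom[marker]
  e <- s[cov, c("hap_a", "hap_b", "mean_posterior")]
  names(e) <- c("u", "v", "w")
  if (nrow(e)) {
    key <- paste(e$u, e$v)
    w <- tapply(e$w, key, max)
    uv <- do.call(rbind, strsplit(names(w), " ", fixed = TRUE))
    e <- data.frame(u = as.integer(uv[, 1]), v = as.integer(uv[, 2]),
                    w = as.numeric(w))
    e <- e[order(e$u, e$v), , drop = FALSE]
    rownames(e) <- NULL
  }
  structure(list(marker = marker, n_hap = store$n_hap, edges = e),
            class = "IBDGraph")
}

# sparse symmetric weight matrix with unit diagonal (closed neighborhoods)
graph_closed_adjacency <- function(G) {
  e <- G$edges
  Matrix::sparseMatrix(i = c(e$u, e$v, seq_len(G$n_hap)),
                       j = c(e$v, e$u, seq_len(G$n_hap)),
                       x = c(e$w, e$w, rep(1, G$n_hap)),
                       dims = c(G$n_hap, G$n_hap))
}

#' Neighborhood affinity of two nodes
#'
#' Cosine similarity of the closed-neighborhood weight vectors of `u` and
#' `v` (the vectors over all nodes with entries `w_ux`, and 1 at the node
#' itself). Affinity is large when the nodes share many strongly weighted
#' common neighbors; it is the pruning score used before clique partition.
#'
#' @param G an [build_graph()] object.
#' @param u,v distinct node (haplotype) indices.
#' @return Value in \[0, 1\].
#' @export
affinity <- function(G, u, v) {
  stopifnot(u != v)
  A <- graph_closed_adjacency(G)
  xu <- A[, u]; xv <- A[, v]
  den <- sqrt(sum(xu^2) * sum(xv^2))
  if (den == 0) return(0)
  sum(xu * xv) / den
}

# affinities of every edge in one pass (crossprod of the closed adjacency)
edge_affinities <- function(G) {
  if (nrow(G$edges) == 0) return(numeric(0))
  A <- graph_closed_adjacency(G)
  C <- Matrix::crossprod(A)
  d <- Matrix::diag(C)
  num <- C[cbind(G$edges$u, G$edges$v)]
  num / sqrt(d[G$edges$u] * d[G$edges$v])
}

#' Partition an IBD graph into cliques
#'
#' Edges with weight below `w_min` or neighborhood affinity below `a_min`
#' are removed (affinities are computed on the full graph, then both
#' filters apply simultaneously); the connected components of the pruned
#' graph are returned as blocks and treated as cliques. Isolated nodes are
#' singleton blocks. Runtime is linear in the number of edges.
#'
#' @param G an [build_graph()] object.
#' @param w_min weight threshold; edges with `w < w_min` are removed
#'   (default 0.85).
#' @param a_min affinity threshold; edges with affinity `< a_min` are
#'   removed (default 0.9).
#' @return Integer membership vector over all haplotypes (clique ids), with
#'   the blocks as a `blocks` attribute.
#' @export
partition_cliques <- function(G, w_min = 0.85, a_min = 0.9) {
  keep <- G$edges$w >= w_min
  if (any(keep)) {
    aff <- edge_affinities(G)
    keep <- keep & aff >= a_min
  }
  e <- G$edges[keep, , drop = FALSE]
  membership <- seq_len(G$n_hap)
  if (nrow(e)) {
    g <- igraph::graph_from_edgelist(cbind(e$u, e$v), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, G$n_hap - igraph::vcount(g)))
    membership <- as.integer(igraph::components(g)$membership)
  }
  # canonical ids: number blocks by their smallest member
  membership <- match(membership, membership[!duplicated(membership)])
  first <- tapply(seq_len(G$n_hap), membership, min)
  membership <- match(first[membership], sort(first))
  structure(membership, blocks = split(seq_len(G$n_hap), membership))
}

#' Per-marker IBD clique dictionary
#'
#' Builds the clique partition at each requested marker, chromosome by
#' chromosome, yielding O(1) same-clique queries. Cliques at a marker
#' partition all haplotypes; haplotypes in no segment are singletons.
#'
#' @param store an [segment_store()].
#' @param markers global marker indices at which to build partitions.
#' @param w_min,a_min pruning thresholds (see [partition_cliques()]).
#' @return An object of class `CliqueDictionary`.
#' @export
build_dictionary <- function(store, markers, w_min = 0.85, a_min = 0.9) {
  markers <- sort(unique(as.integer(markers)))
  n_hap <- store$n_hap
  membership <- matrix(NA_integer_, n_hap, length(markers))
  s <- store$segments
  for (ch in unique(store$map$chrom[markers])) {
    mk <- markers[store$map$chrom[markers] == ch]
    sub <- s[s$chrom == ch, , drop = FALSE]
    if (nrow(sub)) {
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(mk, mk),
        IRanges::IRanges(sub$start, sub$end - 1L))
      by_marker <- split(S4Vectors::subjectHits(ov),
                         S4Vectors::queryHits(ov))
    } else by_marker <- list()
    for (k in seq_along(mk)) {
      rows <- by_marker[[as.character(k)]]
      col <- match(mk[k], markers)
      if (is.null(rows)) {
        membership[, col] <- seq_len(n_hap)
        next
      }
      e <- sub[rows, , drop = FALSE]
      key <- paste(e$hap_a, e$hap_b)
      top <- !duplicated(key)
      w <- tapply(e$mean_posterior, key, max)
      G <- structure(list(marker = mk[k], n_hap = n_hap,
                          edges = data.frame(u = e$hap_a[top], v = e$hap_b[top],
                                             w = as.numeric(w[key[top]]))),
                     class = "IBDGraph")
      membership[, col] <- as.integer(partition_cliques(G, w_min, a_min))
    }
  }
  structure(list(markers = markers, membership = membership,
                 samples = store$samples, map = store$map),
            class = "CliqueDictionary")
}

#' @export
print.CliqueDictionary <- function(x, ...) {
  cat(sprintf("CliqueDictionary: %d markers x %d haplotypes\n",
              length(x$markers), nrow(x$membership)))
  invisible(x)
}

#' Clique membership queries
#'
#' `clique_of()` returns the clique id of a haplotype at a marker;
#' `same_clique()` answers whether two haplotypes are IBD at a marker in
#' O(1). A haplotype in no recorded clique is its own singleton.
#'
#' @param D a [build_dictionary()] object.
#' @param hap,hap_a,hap_b haplotype row indices.
#' @param marker a marker index present in `D$markers`.
#' @return `clique_of()`: integer id; `same_clique()`: logical.
#' @export
clique_of <- function(D, hap, marker) {
  col <- match(marker, D$markers)
  if (is.na(col)) stop("marker not indexed in dictionary")
  D$membership[hap, col]
}

#' @rdname clique_of
#' @export
same_clique <- function(D, hap_a, hap_b, marker) {
  col <- match(marker, D$markers)
  if (is.na(col)) stop("marker not indexed in dictionary")
  D$membership[hap_a, col] == D$membership[hap_b, col]
}

#' Maximum imputation call rate at a marker
#'
#' The ratio of the number of haplotypes in cliques containing at least one
#' haplotype of a sequenced individual to the total number of haplotypes —
#' the ceiling on the allele call rate pedigree-based imputation can reach
#' at that marker.
#'
#' @param D a [build_dictionary()] object.
#' @param sequenced character vector of sequenced sample ids.
#' @param marker marker index present in `D$markers`.
#' @return Fraction in \[0, 1\].
#' @export
max_call_rate <- function(D, sequenced, marker) {
  col <- match(marker, D$markers)
  if (is.na(col)) stop("marker not indexed in dictionary")
  mem <- D$membership[, col]
  idx <- match(sequenced, D$samples)
  if (anyNA(idx)) stop("sequenced samples absent from dictionary")
  if (length(idx) == 0) return(0)
  seq_haps <- c(hap_index(idx, 0L), hap_index(idx, 1L))
  mean(mem %in% unique(mem[seq_haps]))
}

#' Export a clique dictionary as text
#'
#' One row per (marker, haplotype): marker index, sample, slot, clique id.
#'
#' @param D a [build_dictionary()] object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_dictionary <- function(D, path) {
  n_hap <- nrow(D$membership)
  out <- data.frame(
    marker = rep(D$markers, each = n_hap),
    sample = rep(D$samples[hap_sample(seq_len(n_hap))], length(D$markers)),
    slot = rep(hap_slot(seq_len(n_hap)), length(D$markers)),
    clique = as.vector(D$membership))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
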