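AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
GAP_CHARS <- c("-", ".", "?", "X")

#' Read / write amino-acid alignments
#'
#' Alignments are plain character matrices, taxa in rows (rownames are the
#' taxon names), alignment columns in matrix columns; `-` is the gap symbol.
#'
#' @param path FASTA file.
#' @return character matrix (taxa x sites).
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(unique(Biostrings::width(seqs))) != 1L)
    stop_nd("alignment sequences differ in length (not aligned?)")
  m <- do.call(rbind, strsplit(as.character(seqs), ""))
  rownames(m) <- sub("\\s.*$", "", names(seqs))
  toupper(m)
}

#' @rdname read_alignment
#' @param alignment character matrix (taxa x sites).
#' @export
write_alignment <- function(alignment, path) {
  seqs <- Biostrings::AAStringSet(apply(alignment, 1L, paste0, collapse = ""))
  names(seqs) <- rownames(alignment)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Pairwise p-distance
#'
#' Proportion of differing sites between two aligned sequences, counted
#' over sites where neither sequence has a gap (pairwise deletion).
#'
#' @param alignment character matrix (taxa x sites) with rownames.
#' @param i,j taxon names or row indices.
#' @return a number in \[0, 1\].
#' @export
p_distance <- function(alignment, i, j) {
  a <- alignment[i, ]; b <- alignment[j, ]
  ok <- !(a %in% GAP_CHARS) & !(b %in% GAP_CHARS)
  if (!any(ok)) stop_nd("no comparable (gap-free) sites between ", i, " and ", j)
  mean(a[ok] != b[ok])
}

#' p-distance matrix
#'
#' @param alignment character matrix (taxa x sites).
#' @return symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
p_distance_matrix <- function(alignment) {
  taxa <- rownames(alignment) %||% as.character(seq_len(nrow(alignment)))
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- p_distance(alignment, i, j)
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining: repeatedly join the pair minimizing the
#' Q-criterion, assign branch lengths by the standard divergence formulas,
#' and reduce the distance matrix, ending in an unrooted tree (trifurcating
#' root for n >= 3). Ties in Q are broken by the lexicographically smallest
#' pair of cluster labels (a cluster is labelled by its alphabetically first
#' member), making the output deterministic. Negative branch length
#' estimates are clamped to zero with the deficit moved onto the sister
#' branch so that the joined pair's path length is preserved.
#'
#' @param d symmetric distance matrix with taxon dimnames.
#' @return an \pkg{ape} `phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(d) {
  check_symmetric(d, "d")
  taxa <- rownames(d) %||% as.character(seq_len(nrow(d)))
  n0 <- length(taxa)
  if (n0 < 2L) stop_nd("neighbor joining needs at least 2 taxa")
  if (n0 == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
               edge.length = c(d[1, 2] / 2, d[1, 2] / 2),
               tip.label = taxa, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  # active clusters: node id in the growing edge table + representative label
  next_node <- n0 + 1L  # internal ids assigned on the fly, renumbered below
  active_id <- seq_len(n0)
  active_lab <- taxa
  edges <- NULL; elen <- NULL
  D <- unname(d)
  clamp_pair <- function(b) {
    # Kuhner-Felsenstein: negative estimate -> 0, deficit to the sister
    if (b[1] < 0) { b[2] <- b[2] + b[1]; b[1] <- 0 }
    if (b[2] < 0) { b[1] <- max(0, b[1] + b[2]); b[2] <- 0 }
    b
  }
  while (length(active_id) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(p) {
      lab <- sort(active_lab[p]); paste(lab[1], lab[2], sep = "\r")
    })
    sel <- cand[order(key)[1L], ]
    i <- sel[1]; j <- sel[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    b <- clamp_pair(c(bi, bj))
    new_id <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges, c(new_id, active_id[i]), c(new_id, active_id[j]))
    elen <- c(elen, b)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    D <- D2
    active_id <- c(active_id[keep], new_id)
    active_lab <- c(active_lab[keep], min(active_lab[c(i, j)]))
  }
  root_id <- next_node
  if (length(active_id) == 3L) {
    b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    b <- pmax(c(b1, b2, b3), 0)
    edges <- rbind(edges, c(root_id, active_id[1]), c(root_id, active_id[2]),
                   c(root_id, active_id[3]))
    elen <- c(elen, b)
  } else {  # exactly 2 left (n0 == 3 never reaches here; defensive)
    edges <- rbind(edges, c(root_id, active_id[1]), c(root_id, active_id[2]))
    elen <- c(elen, rep(D[1, 2] / 2, 2L))
  }
  # renumber internals so the root is n0+1 and ids are contiguous (ape order)
  internal <- unique(edges[, 1])
  remap <- integer(max(edges))
  remap[seq_len(n0)] <- seq_len(n0)
  remap[rev(internal)] <- n0 + seq_along(internal)
  tr <- list(edge = matrix(remap[edges], ncol = 2L),
             edge.length = as.numeric(elen),
             tip.label = taxa, Nnode = length(internal))
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Sum of branch lengths of a tree (total evolutionary time)
#'
#' @param tree an ape `phylo` tree with branch lengths.
#' @return total branch length (expected substitutions/site at unit rate).
#' @export
tree_length <- function(tree) {
  if (is.null(tree$edge.length)) stop_nd("tree has no branch lengths")
  sum(tree$edge.length)
}

# char matrix column -> bitmask integer vector over a site, given alphabet
state_masks <- function(chars, alphabet) {
  idx <- match(chars, alphabet)
  full <- sum(bitwShiftL(1L, seq_along(alphabet) - 1L))
  m <- ifelse(is.na(idx), full, bitwShiftL(1L, idx - 1L))
  as.integer(m)
}

#' Per-site Fitch parsimony change counts
#'
#' Minimum number of substitutions per alignment column on the subtree
#' spanned by `cluster_taxa` (Fitch's set method, run on an arbitrarily
#' resolved binary version of the subtree; the minimum is invariant under
#' resolution of polytomies). Gaps and unknown characters contribute the
#' full alphabet (missing data).
#'
#' @param alignment character matrix (taxa x sites) with rownames.
#' @param tree an ape `phylo` tree whose tips include `cluster_taxa`.
#' @param cluster_taxa taxa to restrict to (default: all tree tips).
#' @param alphabet state alphabet (default the 20 amino acids).
#' @return integer vector of per-site minimum change counts.
#' @export
fitch_site_changes <- function(alignment, tree, cluster_taxa = tree$tip.label,
                               alphabet = AA_ALPHABET) {
  if (length(alphabet) > 30L) stop_nd("alphabet too large for bitmask Fitch")
  if (!all(cluster_taxa %in% tree$tip.label))
    stop_nd("cluster taxa missing from tree: ",
            paste(setdiff(cluster_taxa, tree$tip.label), collapse = ", "))
  if (length(cluster_taxa) < 2L)
    stop_nd("need at least 2 taxa in the cluster to count changes")
  if (!all(cluster_taxa %in% rownames(alignment)))
    stop_nd("cluster taxa missing from alignment")
  sub <- if (length(cluster_taxa) < length(tree$tip.label))
    ape::keep.tip(tree, cluster_taxa) else tree
  if (length(cluster_taxa) == 2L) {
    a <- alignment[cluster_taxa[1], ]; b <- alignment[cluster_taxa[2], ]
    known <- !(a %in% GAP_CHARS) & !(b %in% GAP_CHARS)
    return(as.integer(known & a != b))
  }
  sub <- ape::multi2di(sub)
  sub <- ape::reorder.phylo(sub, "postorder")
  n_tip <- length(sub$tip.label)
  n_sites <- ncol(alignment)
  masks <- matrix(0L, n_tip + sub$Nnode, n_sites)
  for (t in seq_len(n_tip))
    masks[t, ] <- state_masks(alignment[sub$tip.label[t], ], alphabet)
  changes <- integer(n_sites)
  seen <- logical(n_tip + sub$Nnode)
  for (e in seq_len(nrow(sub$edge))) {
    parent <- sub$edge[e, 1]; child <- sub$edge[e, 2]
    if (!seen[parent]) {
      masks[parent, ] <- masks[child, ]
      seen[parent] <- TRUE
    } else {
      inter <- bitwAnd(masks[parent, ], masks[child, ])
      empty <- inter == 0L
      changes <- changes + empty
      masks[parent, ] <- ifelse(empty,
                                bitwOr(masks[parent, ], masks[child, ]),
                                inter)
    }
  }
  changes
}
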