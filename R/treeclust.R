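# From a sequence-similarity tree to island-domain clusters: cophenetic
# distances, the d < cutoff similarity network, Louvain communities, and
# cluster composition by family/subgroup.

#' Parse a newick tree
#'
#' Wraps \code{ape::read.tree} with the validation the downstream pipeline
#' relies on: unique leaf labels, non-negative branch lengths (missing
#' lengths default to 0 with a warning), and tolerated-but-ignored internal
#' support labels.
#'
#' @param text Newick string, or \code{NULL} when \code{file} is given.
#' @param file Path to a newick file.
#' @return An \code{ape} \code{phylo} object.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  tree <- if (!is.null(text)) {
    tr <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tr)) stop("malformed newick string")
    tr
  } else {
    stopifnot(!is.null(file))
    ape::read.tree(file)
  }
  if (is.null(tree)) stop("malformed newick input")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L)
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  tree
}

#' Cophenetic (patristic) distance matrix of a tree
#'
#' d(i, j) is the sum of branch lengths on the path between leaves i and j
#' (via \code{ape::cophenetic.phylo}).
#'
#' @param tree A \code{phylo} object.
#' @return Symmetric leaf-by-leaf distance matrix with zero diagonal.
#' @export
cophenetic_matrix <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Build the thresholded similarity network
#'
#' Leaf pairs with cophenetic distance strictly below \code{cutoff} become
#' weighted undirected edges; the default weight is 1 - d/cutoff (positive,
#' bounded by 1, cutoff-relative), \code{"linear"} gives 1 - d.  All leaves
#' are vertices, so leaves without any close neighbour stay as isolated
#' nodes.
#'
#' @param D Distance matrix.
#' @param cutoff Strict distance cutoff (> 0), default 0.2
#'   substitutions/site.
#' @param similarity \code{"relative"} or \code{"linear"}.
#' @return An \pkg{igraph} graph with a \code{cutoff} attribute.
#' @export
threshold_network <- function(D, cutoff = 0.2,
                              similarity = c("relative", "linear")) {
  similarity <- match.arg(similarity)
  stopifnot(cutoff > 0)
  D <- as.matrix(D)
  labs <- rownames(D) %||% as.character(seq_len(nrow(D)))
  ut <- which(upper.tri(D) & D < cutoff, arr.ind = TRUE)
  w <- if (similarity == "relative") 1 - D[ut] / cutoff else 1 - D[ut]
  g <- igraph::make_empty_graph(n = nrow(D), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = labs)
  if (nrow(ut) > 0L) {
    g <- igraph::add_edges(g, rbind(ut[, 1], ut[, 2]), weight = w)
  }
  g <- igraph::set_graph_attr(g, "cutoff", cutoff)
  g
}

#' Louvain communities of the similarity network
#'
#' Weighted modularity maximization (resolution 1) on a seeded shuffle of
#' the vertex order, making the greedy Louvain pass deterministic for a
#' given seed.  Isolated vertices become singleton clusters.
#'
#' @param network \pkg{igraph} graph from [threshold_network()].
#' @param seed Integer seed.
#' @return List of class \code{"community_set"}: \code{membership}
#'   (data.frame leaf/cluster), \code{n_clusters}, \code{seed}.
#' @export
louvain_communities <- function(network, seed = 1L) {
  n <- igraph::vcount(network)
  set.seed(seed)
  perm <- sample.int(n)
  shuffled <- igraph::permute(network, perm)
  comm <- igraph::cluster_louvain(shuffled,
                                  weights = igraph::E(shuffled)$weight)
  memb <- igraph::membership(comm)
  df <- data.frame(leaf = names(memb), cluster = as.integer(memb),
                   stringsAsFactors = FALSE)
  df <- df[match(igraph::V(network)$name, df$leaf), ]
  rownames(df) <- NULL
  structure(list(membership = df,
                 n_clusters = length(unique(df$cluster)),
                 seed = as.integer(seed)),
            class = "community_set")
}

#' Summarize cluster composition by leaf label
#'
#' Counts, per cluster, the distinct family/subgroup labels of its leaves,
#' and totals the single-label and two-label clusters plus the counts per
#' unordered label pair among two-label clusters.
#'
#' @param communities A \code{community_set}.
#' @param metadata Data.frame with columns \code{leaf} and \code{label}
#'   (family or subgroup of each leaf).
#' @return List with \code{per_cluster} (cluster, size, n_labels, labels),
#'   \code{n_single_label}, \code{n_two_label}, \code{n_multi_label}, and
#'   \code{pair_counts} (data.frame pair/count for two-label clusters).
#' @export
composition_summary <- function(communities, metadata) {
  memb <- communities$membership
  lab <- metadata$label[match(memb$leaf, metadata$leaf)]
  if (anyNA(lab)) {
    missing <- memb$leaf[is.na(lab)]
    stop("unlabeled leaf/leaves: ", paste(missing, collapse = ", "))
  }
  split_lab <- split(lab, memb$cluster)
  per <- do.call(rbind, lapply(names(split_lab), function(cl) {
    u <- sort(unique(split_lab[[cl]]))
    data.frame(cluster = as.integer(cl), size = length(split_lab[[cl]]),
               n_labels = length(u), labels = paste(u, collapse = "+"),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  two <- per[per$n_labels == 2L, , drop = FALSE]
  pair_counts <- if (nrow(two) > 0L) {
    tab <- table(two$labels)
    data.frame(pair = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(pair = character(0), count = integer(0))
  }
  list(per_cluster = per,
       n_single_label = sum(per$n_labels == 1L),
       n_two_label = sum(per$n_labels == 2L),
       n_multi_label = sum(per$n_labels > 2L),
       pair_counts = pair_counts)
}

#' Run the full island-domain clustering pipeline
#'
#' Tree to cophenetic distances to thresholded network to Louvain
#' communities, with an optional composition summary.
#'
#' @param tree A \code{phylo} object or newick string.
#' @param metadata Optional leaf metadata (columns \code{leaf},
#'   \code{label}).
#' @param config Analysis configuration (cutoff, similarity, seed).
#' @return List with \code{distances}, \code{network}, \code{communities},
#'   and \code{composition} (when metadata given).
#' @export
cluster_tree <- function(tree, metadata = NULL,
                         config = analysis_config()) {
  if (is.character(tree)) tree <- parse_newick(text = tree)
  D <- cophenetic_matrix(tree)
  net <- threshold_network(D, config$cophenetic_cutoff, config$similarity)
  comm <- louvain_communities(net, seed = config$seed)
  out <- list(distances = D, network = net, communities = comm)
  if (!is.null(metadata))
    out$composition <- composition_summary(comm, metadata)
  out
}
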