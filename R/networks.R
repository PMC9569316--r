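# Co-fractionation correlation networks: Pearson correlation between
# deconvolved peaks, thresholded edges, Louvain communities, Ward grouping
# of dipeptides from a chemical distance matrix, and the dipeptide-pathway
# interaction-rate matrix.

#' Pearson correlations between deconvolved peaks
#'
#' For every pair of peaks (one from each collection) the Pearson
#' correlation is computed between the two subprofiles over the union of
#' the peaks' fraction ranges; pairs where either subprofile is constant on
#' that range are skipped.
#'
#' @param peaksA,peaksB named lists of [deconvolve_peaks()] results (names
#'   are molecule ids).  Pass the same list twice for within-set
#'   correlations (self-pairs are excluded).
#' @return data.frame with molecule_a, peak_a, molecule_b, peak_b, pcc; the
#'   number of skipped degenerate pairs is in attribute `n_skipped`.
#' @export
peak_correlations <- function(peaksA, peaksB = peaksA) {
  flat <- function(ps) {
    out <- list()
    for (mol in names(ps)) {
      pk <- ps[[mol]]
      stopifnot(inherits(pk, "peak_set"))
      for (j in seq_len(nrow(pk$peaks)))
        out[[length(out) + 1L]] <- list(
          molecule = mol, peak = j,
          left = pk$peaks$left_bound[j], right = pk$peaks$right_bound[j],
          sub = pk$subprofiles[[j]])
    }
    out
  }
  fa <- flat(peaksA); fb <- flat(peaksB)
  same <- identical(peaksA, peaksB)
  rows <- list(); skipped <- 0L
  for (i in seq_along(fa)) {
    jj <- if (same) seq_along(fb)[seq_along(fb) > i] else seq_along(fb)
    for (j in jj) {
      a <- fa[[i]]; b <- fb[[j]]
      if (same && a$molecule == b$molecule) next
      rng <- min(a$left, b$left):max(a$right, b$right)
      va <- a$sub[rng]; vb <- b$sub[rng]
      if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
        skipped <- skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        molecule_a = a$molecule, peak_a = a$peak,
        molecule_b = b$molecule, peak_b = b$peak,
        pcc = stats::cor(va, vb), stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(molecule_a = character(), peak_a = integer(),
               molecule_b = character(), peak_b = integer(),
               pcc = numeric())
  structure(res, n_skipped = skipped)
}

peak_node_id <- function(molecule, peak) {
  if (!length(molecule)) return(character(0))  # paste0 would recycle "#"
  paste0(molecule, "#", peak)
}

#' Build a co-fractionation network from peak correlations
#'
#' Retains edges with `pcc >= threshold`; all peaks remain as nodes, with
#' isolated nodes flagged.
#'
#' @param correlations a [peak_correlations()] data.frame.
#' @param threshold correlation cut-off in (-1, 1] (default 0.7).
#' @param node_classes optional named vector mapping molecule ids to a
#'   class label (e.g. protein/metabolite), attached to the nodes.
#' @return list of class `cofrac_network` with `nodes` (data.frame node,
#'   molecule, peak, class, isolated) and `edges` (node_a, node_b, pcc).
#' @export
build_network <- function(correlations, threshold = 0.7,
                          node_classes = NULL) {
  assert_scalar_number(threshold, "threshold", lower = -1, upper = 1)
  nodes_all <- unique(rbind(
    data.frame(molecule = correlations$molecule_a,
               peak = correlations$peak_a, stringsAsFactors = FALSE),
    data.frame(molecule = correlations$molecule_b,
               peak = correlations$peak_b, stringsAsFactors = FALSE)))
  nodes_all <- nodes_all[order(nodes_all$molecule, nodes_all$peak), ]
  nodes_all$node <- peak_node_id(nodes_all$molecule, nodes_all$peak)
  nodes_all$class <- if (is.null(node_classes)) NA_character_ else
    unname(node_classes[nodes_all$molecule])
  keep <- correlations$pcc >= threshold
  edges <- data.frame(
    node_a = peak_node_id(correlations$molecule_a[keep],
                          correlations$peak_a[keep]),
    node_b = peak_node_id(correlations$molecule_b[keep],
                          correlations$peak_b[keep]),
    pcc = correlations$pcc[keep], stringsAsFactors = FALSE)
  nodes_all$isolated <- !(nodes_all$node %in% c(edges$node_a, edges$node_b))
  rownames(nodes_all) <- NULL
  structure(list(nodes = nodes_all[, c("node", "molecule", "peak",
                                       "class", "isolated")],
                 edges = edges, threshold = threshold),
            class = "cofrac_network")
}

#' @export
print.cofrac_network <- function(x, ...) {
  cat("cofrac_network:", nrow(x$nodes), "peak nodes,", nrow(x$edges),
      "edges at PCC >=", x$threshold, "\n")
  invisible(x)
}

as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("node_a", "node_b")], directed = FALSE,
    vertices = data.frame(name = sort(network$nodes$node)))
  igraph::E(g)$weight <- network$edges$pcc
  g
}

#' Louvain community detection on a co-fractionation network
#'
#' Modularity-maximizing Louvain partition of the network (edge weights =
#' PCC).  Node order is canonicalized (sorted ids) and the RNG seeded, so
#' the partition is reproducible.  Isolated nodes become singleton
#' communities.
#'
#' @param network a [build_network()] result.
#' @param seed RNG seed (default 1).
#' @param resolution Louvain resolution parameter (default 1).
#' @return named integer vector of community ids (attribute `modularity`
#'   carries the achieved modularity of the non-singleton subgraph).
#' @export
detect_communities <- function(network, seed = 1L, resolution = 1.0) {
  stopifnot(inherits(network, "cofrac_network"))
  if (nrow(network$nodes) == 0L)
    return(structure(integer(0), modularity = NA_real_))
  g <- as_igraph(network)
  w <- igraph::E(g)$weight
  if (length(w) && any(w < 0)) w <- NULL  # Louvain needs nonneg weights
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = w, resolution = resolution)
  membership <- igraph::membership(cl)
  out <- stats::setNames(as.integer(membership), names(membership))
  structure(out[order(names(out))],
            modularity = igraph::modularity(g, membership, weights = w))
}

#' Interaction rate between two molecule groups
#'
#' Percentage of observed co-fractionating peak pairs among all possible
#' pairs: `100 * n_interactions / (n_dipeptide_peaks * n_protein_peaks)`.
#'
#' @param n_interactions observed co-fractionating pairs (PCC above the
#'   network threshold).
#' @param n_dipeptide_peaks,n_protein_peaks peak counts of the two groups.
#' @return rate in `[0, 100]`.
#' @export
interaction_rate <- function(n_interactions, n_dipeptide_peaks,
                             n_protein_peaks) {
  n_dipeptide_peaks <- assert_count(n_dipeptide_peaks, "n_dipeptide_peaks", 1L)
  n_protein_peaks <- assert_count(n_protein_peaks, "n_protein_peaks", 1L)
  if (!is.numeric(n_interactions) || n_interactions < 0 ||
      n_interactions > n_dipeptide_peaks * n_protein_peaks)
    stop_secshift("n_interactions must lie in [0, n_dipeptide_peaks * n_protein_peaks]",
                  "secshift_parameter_error")
  100 * n_interactions / (n_dipeptide_peaks * n_protein_peaks)
}

#' Dipeptide-group x pathway interaction-rate matrix
#'
#' For each (dipeptide group, protein pathway) pair, counts the network
#' edges connecting a peak of a group member to a peak of a pathway member
#' and divides by all possible such peak pairs.  Proteins belonging to
#' several pathways contribute their peaks to each pathway independently.
#'
#' @param network a [build_network()] result for one phase.
#' @param dipeptide_groups named character vector: metabolite id -> group
#'   label (each dipeptide in exactly one group).
#' @param pathway_groups named list: pathway label -> character vector of
#'   protein ids.
#' @return data.frame with group, pathway, n_interactions,
#'   n_dipeptide_peaks, n_protein_peaks, rate (NA with a warning entry when
#'   a group has no peaks in the network).
#' @export
rate_matrix <- function(network, dipeptide_groups, pathway_groups) {
  stopifnot(inherits(network, "cofrac_network"))
  if (anyDuplicated(names(dipeptide_groups)))
    stop_secshift("each dipeptide must map to exactly one group",
                  "secshift_parameter_error")
  nodes <- network$nodes
  edges <- network$edges
  edge_mol <- data.frame(
    mol_a = nodes$molecule[match(edges$node_a, nodes$node)],
    mol_b = nodes$molecule[match(edges$node_b, nodes$node)],
    stringsAsFactors = FALSE)
  out <- list()
  for (grp in sort(unique(dipeptide_groups))) {
    dips <- names(dipeptide_groups)[dipeptide_groups == grp]
    n_dip_peaks <- sum(nodes$molecule %in% dips)
    for (pw in names(pathway_groups)) {
      prots <- pathway_groups[[pw]]
      n_prot_peaks <- sum(nodes$molecule %in% prots)
      if (n_dip_peaks == 0L || n_prot_peaks == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          group = grp, pathway = pw, n_interactions = NA_integer_,
          n_dipeptide_peaks = n_dip_peaks, n_protein_peaks = n_prot_peaks,
          rate = NA_real_, stringsAsFactors = FALSE)
        next
      }
      n_int <- sum((edge_mol$mol_a %in% dips & edge_mol$mol_b %in% prots) |
                     (edge_mol$mol_b %in% dips & edge_mol$mol_a %in% prots))
      out[[length(out) + 1L]] <- data.frame(
        group = grp, pathway = pw, n_interactions = n_int,
        n_dipeptide_peaks = n_dip_peaks, n_protein_peaks = n_prot_peaks,
        rate = interaction_rate(n_int, n_dip_peaks, n_prot_peaks),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ward clustering of items from a distance matrix
#'
#' Ward's minimum-variance agglomeration (`hclust` method `ward.D2`) on a
#' user-supplied symmetric distance matrix, cut at a fixed height to give
#' flat groups (e.g. dipeptide groups from chemical-structure distances).
#'
#' @param distance_matrix symmetric numeric matrix with zero diagonal and
#'   nonnegative entries.
#' @param cut_height dendrogram cut height (default 1.6).
#' @return named integer vector of group labels; the `hclust` object is in
#'   attribute `hclust`.
#' @export
ward_group <- function(distance_matrix, cut_height = 1.6) {
  if (!is.matrix(distance_matrix) || !is.numeric(distance_matrix) ||
      nrow(distance_matrix) != ncol(distance_matrix))
    stop_secshift("need a square numeric distance matrix",
                  "secshift_validation_error")
  if (any(distance_matrix < 0) ||
      any(abs(diag(distance_matrix)) > 1e-12) ||
      any(abs(distance_matrix - t(distance_matrix)) > 1e-8))
    stop_secshift("distance matrix must be symmetric, nonnegative, zero-diagonal",
                  "secshift_validation_error")
  assert_scalar_number(cut_height, "cut_height", lower = 0)
  hc <- stats::hclust(stats::as.dist(distance_matrix), method = "ward.D2")
  groups <- stats::cutree(hc, h = cut_height)
  structure(groups, hclust = hc)
}

#' Export a network as edge-list TSV and GraphML
#'
#' @param network a `cofrac_network`.
#' @param edge_path TSV path for the edge list (NULL to skip).
#' @param graphml_path GraphML path (NULL to skip).
#' @export
write_network <- function(network, edge_path = NULL, graphml_path = NULL) {
  stopifnot(inherits(network, "cofrac_network"))
  if (!is.null(edge_path))
    utils::write.table(network$edges, edge_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(as_igraph(network), graphml_path,
                        format = "graphml")
  invisible(network)
}
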