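DESCRIPTOR_COLS <- c("distance", "angle", "dihedral", "energy")

#' Build a per-frame interaction multigraph
#'
#' Groups one frame's interaction records into a residue-level multigraph:
#' one edge per (residue pair, interaction type), with the within-frame
#' multiplicity (e.g. the number of distinct hydrogen bonds between the
#' pair) kept as a \code{count} attribute and descriptors averaged over the
#' grouped records. Isolated residues are retained as nodes.
#'
#' @param records Interaction records from one frame (see
#'   \code{\link{detect_all}}).
#' @param system The \code{molecular_system} the records came from (supplies
#'   the node set).
#' @param frame Frame index the records belong to.
#' @return An object of class \code{frame_graph} with \code{nodes} and
#'   \code{edges} data.frames.
#' @export
build_frame_graph <- function(records, system, frame = 1) {
  if (nrow(records) > 0 && any(records$frame != frame)) {
    stop("build_frame_graph(): records from a different frame supplied")
  }
  nodes <- rin_nodes(system)
  if (nrow(records) == 0) {
    edges <- data.frame(
      res_i = integer(0), res_j = integer(0), type = character(0),
      count = integer(0), distance = numeric(0), angle = numeric(0),
      dihedral = numeric(0), energy = numeric(0), stringsAsFactors = FALSE
    )
  } else {
    # hydrogen-bond direction is an attribute, not an identity: group on the
    # unordered pair
    lo <- pmin(records$res_i, records$res_j)
    hi <- pmax(records$res_i, records$res_j)
    key <- paste(records$type, lo, hi, sep = "\r")
    grp <- split(seq_len(nrow(records)), key)
    edges <- do.call(rbind, lapply(grp, function(ix) {
      data.frame(
        res_i = lo[ix[1]], res_j = hi[ix[1]], type = records$type[ix[1]],
        count = length(ix),
        distance = mean_or_na(records$distance[ix]),
        angle = mean_or_na(records$angle[ix]),
        dihedral = mean_or_na(records$dihedral[ix]),
        energy = mean_or_na(records$energy[ix]),
        stringsAsFactors = FALSE
      )
    }))
    edges <- edges[order(match(edges$type, interaction_types()),
                         edges$res_i, edges$res_j), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(
    list(nodes = nodes, edges = edges, frame = frame),
    class = "frame_graph"
  )
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else mean(x)
}

rin_nodes <- function(system) {
  res <- system$residues
  data.frame(
    label = residue_labels(system),
    chain = res$chain,
    resname = res$resname,
    resno = res$resno,
    insert = res$insert,
    stringsAsFactors = FALSE
  )
}

#' Build a consensus residue interaction network
#'
#' An edge of a given type between a residue pair is retained when it is
#' present in at least \code{persistence_min} of the frames; its persistence
#' is stored as the exact fraction of frames in which it appears, and each
#' descriptor is summarized (mean/min/max) over those frames.
#'
#' @param frame_graphs List of \code{frame_graph} objects over an identical
#'   node set.
#' @param persistence_min Minimum fraction of frames (in (0, 1]; 0 keeps the
#'   union of all frame edges).
#' @return An object of class \code{consensus_rin}.
#' @export
build_consensus <- function(frame_graphs, persistence_min = 0.75) {
  stopifnot(length(frame_graphs) >= 1)
  nodes <- frame_graphs[[1]]$nodes
  for (fg in frame_graphs[-1]) {
    if (!identical(fg$nodes$label, nodes$label)) {
      stop("build_consensus(): frame graphs have inconsistent node sets")
    }
  }
  nf <- length(frame_graphs)
  all_edges <- do.call(rbind, lapply(frame_graphs, function(fg) fg$edges))
  if (is.null(all_edges) || nrow(all_edges) == 0) {
    edges <- empty_consensus_edges()
  } else {
    key <- paste(all_edges$type, all_edges$res_i, all_edges$res_j, sep = "\r")
    grp <- split(seq_len(nrow(all_edges)), key)
    rows <- lapply(grp, function(ix) {
      e <- all_edges[ix, , drop = FALSE]
      stat <- lapply(DESCRIPTOR_COLS, function(cl) {
        v <- e[[cl]][!is.na(e[[cl]])]
        if (length(v) == 0) c(NA_real_, NA_real_, NA_real_)
        else c(mean(v), min(v), max(v))
      })
      names(stat) <- DESCRIPTOR_COLS
      data.frame(
        res_i = e$res_i[1], res_j = e$res_j[1], type = e$type[1],
        persistence = length(ix) / nf, frame_count = length(ix),
        count_mean = mean(e$count),
        distance_mean = stat$distance[1], distance_min = stat$distance[2],
        distance_max = stat$distance[3],
        angle_mean = stat$angle[1], angle_min = stat$angle[2],
        angle_max = stat$angle[3],
        dihedral_mean = stat$dihedral[1], dihedral_min = stat$dihedral[2],
        dihedral_max = stat$dihedral[3],
        energy_mean = stat$energy[1], energy_min = stat$energy[2],
        energy_max = stat$energy[3],
        stringsAsFactors = FALSE
      )
    })
    edges <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    edges <- edges[edges$persistence >= persistence_min, , drop = FALSE]
    edges <- edges[order(match(edges$type, interaction_types()),
                         edges$res_i, edges$res_j), , drop = FALSE]
    rownames(edges) <- NULL
  }
  edges$label_i <- nodes$label[edges$res_i]
  edges$label_j <- nodes$label[edges$res_j]
  structure(
    list(nodes = nodes, edges = edges, n_frames = nf,
         persistence_min = persistence_min),
    class = "consensus_rin"
  )
}

empty_consensus_edges <- function() {
  out <- data.frame(
    res_i = integer(0), res_j = integer(0), type = character(0),
    persistence = numeric(0), frame_count = integer(0),
    count_mean = numeric(0), stringsAsFactors = FALSE
  )
  for (cl in DESCRIPTOR_COLS) {
    for (s in c("mean", "min", "max")) out[[paste(cl, s, sep = "_")]] <- numeric(0)
  }
  out
}

#' @export
print.consensus_rin <- function(x, ...) {
  cat(sprintf(
    "consensus_rin: %d nodes, %d edges over %d frame(s) (persistence >= %g)\n",
    nrow(x$nodes), nrow(x$edges), x$n_frames, x$persistence_min
  ))
  if (nrow(x$edges) > 0) {
    tab <- table(x$edges$type)
    cat("  edges by type:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify consensus edges by chain topology
#'
#' Each edge is INTRA_CHAIN when both residues share a chain, otherwise
#' INTER_CHAIN when the chains map to the same assembly label, otherwise
#' INTER_ASSEMBLY. With no assembly map every cross-chain edge is
#' INTER_CHAIN.
#'
#' @param rin A \code{consensus_rin}.
#' @param assembly_map Optional named vector/list mapping chain id to an
#'   assembly label (e.g. the two halves of a docked channel).
#' @return \code{rin} with an \code{edge_class} column added and a
#'   \code{class_counts} table (rows = interaction types, columns =
#'   classes) attached.
#' @export
classify_edges <- function(rin, assembly_map = NULL) {
  chains_i <- rin$nodes$chain[rin$edges$res_i]
  chains_j <- rin$nodes$chain[rin$edges$res_j]
  if (!is.null(assembly_map)) {
    used <- unique(c(chains_i, chains_j))
    missing <- setdiff(used, names(assembly_map))
    if (length(missing) > 0) {
      stop("classify_edges(): chain(s) missing from assembly_map: ",
           paste(missing, collapse = ", "))
    }
  }
  cls <- ifelse(chains_i == chains_j, "INTRA_CHAIN", "INTER_CHAIN")
  if (!is.null(assembly_map) && length(cls) > 0) {
    am <- unlist(assembly_map)
    cross <- cls == "INTER_CHAIN"
    cls[cross & am[chains_i] != am[chains_j]] <- "INTER_ASSEMBLY"
  }
  rin$edges$edge_class <- cls
  classes <- c("INTRA_CHAIN", "INTER_CHAIN", "INTER_ASSEMBLY")
  tab <- table(
    factor(rin$edges$type, levels = interaction_types()),
    factor(cls, levels = classes)
  )
  rin$class_counts <- as.matrix(tab)
  rin
}

#' Simple-graph projection of a consensus RIN
#'
#' Parallel typed edges between a residue pair are collapsed into one edge
#' whose weight is the number of distinct interaction types connecting the
#' pair.
#'
#' @param rin A \code{consensus_rin}.
#' @return An \code{igraph} graph with vertex attributes from the node
#'   table and an edge \code{weight} attribute.
#' @export
rin_igraph <- function(rin) {
  g <- igraph::make_empty_graph(n = nrow(rin$nodes), directed = FALSE)
  igraph::V(g)$name <- rin$nodes$label
  igraph::V(g)$chain <- rin$nodes$chain
  igraph::V(g)$resname <- rin$nodes$resname
  igraph::V(g)$resno <- rin$nodes$resno
  if (nrow(rin$edges) > 0) {
    key <- paste(rin$edges$res_i, rin$edges$res_j, sep = "\r")
    w <- tapply(rin$edges$type, key, function(x) length(unique(x)))
    ij <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    g <- igraph::add_edges(
      g, rbind(as.integer(ij[, 1]), as.integer(ij[, 2])),
      weight = as.numeric(w)
    )
  }
  g
}

#' Node centralities of a consensus RIN
#'
#' Computed on the simple-graph projection (see \code{\link{rin_igraph}}):
#' degree; weighted degree (sum of distinct-type multiplicities); shortest
#' path based betweenness and closeness on the unweighted projection
#' (multiplicity is an affinity, not a cost, so it is not used as an edge
#' length), both normalized, closeness within each connected component;
#' eigenvector centrality using the multiplicity weights.
#'
#' @param rin A \code{consensus_rin}.
#' @return data.frame with one row per node: \code{label}, \code{degree},
#'   \code{weighted_degree}, \code{betweenness}, \code{closeness},
#'   \code{eigenvector}.
#' @export
centralities <- function(rin) {
  g <- rin_igraph(rin)
  n <- igraph::vcount(g)
  if (n == 0) stop("centralities(): empty network")
  btw <- igraph::betweenness(g, weights = NA,
                             normalized = n > 2)
  comp <- igraph::components(g)$membership
  cls <- rep(NA_real_, n)
  for (cm in unique(comp)) {
    vs <- which(comp == cm)
    if (length(vs) < 2) { cls[vs] <- NA_real_; next }
    sub <- igraph::induced_subgraph(g, vs)
    cls[vs] <- igraph::closeness(sub, weights = NA, normalized = TRUE)
  }
  # principal eigenvector of the weighted adjacency matrix, computed with a
  # dense symmetric eigendecomposition: deterministic (no iterative solver
  # start-vector dependence) and well-defined on disconnected graphs, where
  # mass concentrates on the component with the largest eigenvalue
  eig <- if (igraph::ecount(g) > 0) {
    adj <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                                 sparse = FALSE))
    v <- eigen(adj, symmetric = TRUE)$vectors[, 1]
    v <- abs(v)
    v / max(v)
  } else {
    rep(0, n)
  }
  data.frame(
    label = igraph::V(g)$name,
    degree = as.numeric(igraph::degree(g)),
    weighted_degree = as.numeric(igraph::strength(g)),
    betweenness = as.numeric(btw),
    closeness = cls,
    eigenvector = as.numeric(eig),
    stringsAsFactors = FALSE
  )
}

# full-fidelity igraph multigraph used for GraphML round trips
rin_multigraph <- function(rin, types = NULL) {
  e <- rin$edges
  if (!is.null(types)) e <- e[e$type %in% types, , drop = FALSE]
  g <- igraph::make_empty_graph(n = nrow(rin$nodes), directed = FALSE)
  igraph::V(g)$name <- rin$nodes$label
  igraph::V(g)$chain <- rin$nodes$chain
  igraph::V(g)$resname <- rin$nodes$resname
  igraph::V(g)$resno <- rin$nodes$resno
  igraph::V(g)$insert <- rin$nodes$insert
  if (!is.null(rin$nodes$sasa)) igraph::V(g)$sasa <- rin$nodes$sasa
  if (nrow(e) > 0) {
    attrs <- as.list(e[, !(names(e) %in% c("res_i", "res_j", "label_i",
                                           "label_j")), drop = FALSE])
    g <- do.call(igraph::add_edges,
                 c(list(g, rbind(e$res_i, e$res_j)), attrs))
  }
  igraph::graph_attr(g, "n_frames") <- rin$n_frames
  igraph::graph_attr(g, "persistence_min") <- rin$persistence_min
  g
}

#' Write network files for a consensus RIN
#'
#' Writes a global GraphML file containing all interactions, one GraphML
#' file per interaction type, and Cytoscape-importable TSV node/edge
#' attribute tables. GraphML files carry full attribute fidelity and can be
#' read back with \code{\link{read_network}}.
#'
#' @param rin A \code{consensus_rin}.
#' @param dir Output directory (created if needed).
#' @param name File-name stem (default "rin").
#' @param types Interaction types to emit per-type files for; defaults to
#'   the nine standard types.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(rin, dir, name = "rin",
                          types = interaction_types()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  gml <- file.path(dir, paste0(name, "_global.graphml"))
  igraph::write_graph(rin_multigraph(rin), gml, format = "graphml")
  paths <- c(paths, gml)
  for (ty in types) {
    p <- file.path(dir, paste0(name, "_", ty, ".graphml"))
    igraph::write_graph(rin_multigraph(rin, ty), p, format = "graphml")
    paths <- c(paths, p)
  }
  ntsv <- file.path(dir, paste0(name, "_nodes.tsv"))
  utils::write.table(rin$nodes, ntsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  etsv <- file.path(dir, paste0(name, "_edges.tsv"))
  ecols <- rin$edges
  ecols <- ecols[, c("label_i", "label_j",
                     setdiff(names(ecols), c("label_i", "label_j", "res_i",
                                             "res_j"))), drop = FALSE]
  utils::write.table(format_tsv_numbers(ecols), etsv, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  paths <- c(paths, ntsv, etsv)
  invisible(paths)
}

format_tsv_numbers <- function(df) {
  for (cl in names(df)) {
    if (is.numeric(df[[cl]]) && !is.integer(df[[cl]])) {
      df[[cl]] <- ifelse(is.na(df[[cl]]), NA,
                         sprintf("%.6f", df[[cl]]))
    }
  }
  df
}

#' Read a GraphML network file back into a consensus RIN
#'
#' @param path A GraphML file written by \code{\link{write_network}}.
#' @return A \code{consensus_rin}.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("read_network(): file not found: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(
    label = igraph::V(g)$name,
    chain = igraph::V(g)$chain,
    resname = igraph::V(g)$resname,
    resno = igraph::V(g)$resno,
    insert = if (is.null(igraph::V(g)$insert)) "" else
      ifelse(is.na(igraph::V(g)$insert), "", igraph::V(g)$insert),
    stringsAsFactors = FALSE
  )
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- empty_consensus_edges()
  if (nrow(el) > 0) {
    edges <- data.frame(
      res_i = pmin(el[, 1], el[, 2]),
      res_j = pmax(el[, 1], el[, 2]),
      stringsAsFactors = FALSE
    )
    for (attr in igraph::edge_attr_names(g)) {
      edges[[attr]] <- igraph::edge_attr(g, attr)
    }
    edges <- edges[order(match(edges$type, interaction_types()),
                         edges$res_i, edges$res_j), , drop = FALSE]
    rownames(edges) <- NULL
  }
  edges$label_i <- nodes$label[edges$res_i]
  edges$label_j <- nodes$label[edges$res_j]
  structure(
    list(
      nodes = nodes, edges = edges,
      n_frames = igraph::graph_attr(g, "n_frames") %||% 1L,
      persistence_min = igraph::graph_attr(g, "persistence_min") %||% 0
    ),
    class = "consensus_rin"
  )
}
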