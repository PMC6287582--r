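#' Per-residue interaction-count time series
#'
#' Each residue is represented by a vector whose f-th element is the number
#' of interactions of the given type it participates in during frame f; the
#' Pearson correlation between two such vectors measures coordinated
#' formation and rupture of interactions.
#'
#' @param frame_records List of per-frame interaction record data.frames,
#'   in frame order.
#' @param type Interaction type name (see \code{\link{interaction_types}}).
#' @param n_residues Number of residues (rows of the count matrix).
#' @param labels Optional residue labels used as row names.
#' @return An object of class \code{count_series}: integer matrix
#'   (n_residues x n_frames) with a \code{type} attribute. Each interaction
#'   increments both of its residues, so every frame column sums to twice
#'   the number of that type's records.
#' @export
count_series <- function(frame_records, type, n_residues, labels = NULL) {
  counts <- matrix(0L, n_residues, length(frame_records))
  for (f in seq_along(frame_records)) {
    rec <- frame_records[[f]]
    rec <- rec[rec$type == type, , drop = FALSE]
    if (nrow(rec) == 0) next
    tal <- tabulate(c(rec$res_i, rec$res_j), nbins = n_residues)
    counts[, f] <- as.integer(tal)
  }
  if (!is.null(labels)) rownames(counts) <- labels
  structure(counts, type = type, class = c("count_series", "matrix", "array"))
}

#' Pearson correlation matrix of interaction-count vectors
#'
#' Standard Pearson r between the per-residue count vectors over a closed
#' frame window. A residue whose series is constant within the window has
#' undefined correlations: those entries are NA (never silently zero) and
#' are excluded from correlated-pair counts.
#'
#' @param series A \code{count_series} matrix (residues x frames).
#' @param window Closed 1-based frame-index interval \code{c(first, last)};
#'   default spans all frames.
#' @return An object of class \code{correlation_matrix}: symmetric n x n
#'   matrix of Pearson coefficients with \code{window} and \code{type}
#'   attributes; diagonal 1 for non-constant series, NA otherwise.
#' @export
pearson_matrix <- function(series, window = NULL) {
  nf <- ncol(series)
  if (is.null(window)) window <- c(1L, nf)
  if (window[1] < 1 || window[2] > nf || window[2] - window[1] + 1 < 2) {
    stop("pearson_matrix(): window must cover at least 2 frames within ",
         "the series")
  }
  x <- t(series[, window[1]:window[2], drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  structure(
    r,
    window = as.integer(window),
    type = attr(series, "type"),
    class = c("correlation_matrix", "matrix", "array")
  )
}

#' Count strongly correlated residue pairs
#'
#' For each |r| cutoff, counts the unordered residue pairs (diagonal
#' excluded, NA entries skipped) whose absolute Pearson correlation meets
#' the cutoff, and optionally the rate relative to a reference matrix (the
#' convention used to normalize per-window counts by the first window). A
#' rate with a zero reference count is undefined (NA), never infinite.
#'
#' @param matrix_ A \code{correlation_matrix}.
#' @param thresholds Numeric vector of |r| cutoffs (default
#'   \code{c(0.5, 0.6, 0.7, 0.8, 0.9)}).
#' @param reference Optional reference \code{correlation_matrix}.
#' @return data.frame with \code{threshold}, \code{count} and (when a
#'   reference is supplied) \code{reference_count} and \code{rate}.
#' @export
correlated_pair_counts <- function(matrix_,
                                   thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9),
                                   reference = NULL) {
  count_at <- function(m, thr) {
    v <- abs(m[upper.tri(m)])
    sum(v >= thr, na.rm = TRUE)
  }
  out <- data.frame(
    threshold = thresholds,
    count = vapply(thresholds, function(t) count_at(matrix_, t), numeric(1))
  )
  if (!is.null(reference)) {
    out$reference_count <- vapply(thresholds,
                                  function(t) count_at(reference, t),
                                  numeric(1))
    out$rate <- ifelse(out$reference_count == 0, NA_real_,
                       out$count / out$reference_count)
  }
  out
}

#' Collective variable: mean strand-to-center distance
#'
#' Per frame, the mean over residue groups of the Euclidean distance
#' between each group's center of mass and the center of mass of the whole
#' selection (all groups pooled). Used to track cavity opening/closure:
#' with the beta strands as groups, it shrinks as the strands collapse
#' toward the molecular center.
#'
#' @param system A \code{molecular_system} with charges/masses resolvable
#'   from elements.
#' @param group_definitions List of integer vectors of residue row indices
#'   (the strands).
#' @param frames Frame indices to evaluate (default all).
#' @return An object of class \code{collective_variable}: numeric vector of
#'   per-frame values (Angstrom) with \code{n_groups} attribute.
#' @export
collective_variable_d0 <- function(system, group_definitions,
                                   frames = seq_along(system$frames)) {
  if (length(group_definitions) == 0 ||
      any(lengths(group_definitions) == 0)) {
    stop("collective_variable_d0(): every group must be non-empty")
  }
  res <- system$residues
  masses <- atom_masses(system)
  group_atoms <- lapply(group_definitions, function(g) {
    unlist(lapply(g, function(r) res$first[r]:res$last[r]))
  })
  all_atoms <- sort(unique(unlist(group_atoms)))
  com <- function(xyz, idx) {
    w <- masses[idx]
    colSums(xyz[idx, , drop = FALSE] * w) / sum(w)
  }
  d0 <- vapply(frames, function(f) {
    xyz <- system$frames[[f]]
    global <- com(xyz, all_atoms)
    mean(vapply(group_atoms, function(idx) {
      sqrt(sum((com(xyz, idx) - global)^2))
    }, numeric(1)))
  }, numeric(1))
  structure(d0, n_groups = length(group_definitions),
            class = "collective_variable")
}

#' Write / read a correlation matrix as TSV
#'
#' Residue labels form the header row and first column; undefined entries
#' are written as NA and survive a round trip.
#'
#' @param matrix_ A \code{correlation_matrix}.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_correlation <- function(matrix_, path) {
  m <- unclass(matrix_)
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("R", seq_len(nrow(m)))
  chr <- matrix(sprintf("%.6f", m), nrow(m))
  chr[is.na(m)] <- "NA"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("residue", labs), collapse = "\t"), con)
  utils::write.table(cbind(labs, chr), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_correlation
#' @param path Path of a TSV written by \code{write_correlation}.
#' @export
read_correlation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$residue
  colnames(m) <- df$residue
  structure(m, class = c("correlation_matrix", "matrix", "array"))
}

#' Plot a correlation matrix heatmap
#'
#' Cosmetic rendering of a \code{correlation_matrix}; undefined entries are
#' left blank.
#'
#' @param x A \code{correlation_matrix}.
#' @param ... Passed to \code{image}.
#' @export
plot.correlation_matrix <- function(x, ...) {
  m <- unclass(x)
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  zlim = c(-1, 1),
                  col = grDevices::hcl.colors(65, "Blue-Red 2"),
                  xlab = "residue", ylab = "residue", ...)
  invisible(x)
}
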