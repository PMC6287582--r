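#' Read a flat key = value run-configuration file
#'
#' One option per line, \code{key = value}, \code{#} comments; mirrors the
#' command-line flags of the \code{rinmd} script. Values are kept as
#' strings and interpreted by \code{\link{run_pipeline}}.
#'
#' @param path Configuration file path.
#' @return Named list of strings.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$",
                                  lines))
  bad <- lengths(kv) != 3
  if (any(bad)) {
    stop("read_run_config(): malformed line: ", lines[bad][1])
  }
  stats::setNames(
    lapply(kv, function(m) gsub("^\"|\"$", "", trimws(m[3]))),
    vapply(kv, `[[`, "", 2)
  )
}

parse_windows <- function(spec) {
  if (is.null(spec) || !nzchar(spec)) return(NULL)
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    ab <- suppressWarnings(
      as.integer(strsplit(trimws(p), ":", fixed = TRUE)[[1]])
    )
    if (length(ab) != 2 || anyNA(ab)) {
      stop("parse_windows(): window must look like first:last, got ", p)
    }
    ab
  })
}

parse_assembly_map <- function(spec) {
  if (is.null(spec) || !nzchar(spec)) return(NULL)
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  kv <- strsplit(trimws(parts), "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[[`, "", 2), vapply(kv, `[[`, "", 1))
}

#' Apply a detector to many frames, optionally in parallel
#'
#' Frames are partitioned across forked workers; results are reassembled in
#' frame order, so the output is identical for any worker count (per-frame
#' detection is pure and the reduction order is fixed).
#'
#' @param system A \code{molecular_system}.
#' @param frames Frame indices (default all).
#' @param fun Function of (system, frame) returning that frame's records.
#' @param workers Worker count (default 1; forking is unavailable on
#'   Windows, where 1 is used).
#' @return List of per-frame results, in frame order.
#' @export
parallel_map_frames <- function(system, frames = seq_along(system$frames),
                                fun, workers = 1) {
  stopifnot(workers >= 1)
  if (length(frames) == 0) return(list())
  run_one <- function(f) {
    tryCatch(fun(system, f),
             error = function(e) {
               structure(list(frame = f, message = conditionMessage(e)),
                         class = "rinmd_frame_error")
             })
  }
  if (workers == 1 || .Platform$OS.type == "windows") {
    out <- lapply(frames, run_one)
  } else {
    out <- parallel::mclapply(frames, run_one, mc.cores = workers,
                              mc.preschedule = TRUE)
  }
  for (r in out) {
    if (inherits(r, "rinmd_frame_error")) {
      stop("parallel_map_frames(): frame ", r$frame, " failed: ", r$message)
    }
  }
  out
}

default_run_config <- function() {
  list(
    pdb = NULL, psf = NULL, dcd = NULL, params = NULL,
    first = 0L, last = NULL, stride = 1L,
    types = interaction_types(),
    persistence = 0.75,
    corr_types = c("HBOND", "VDW"),
    windows = NULL,
    assembly_map = NULL,
    out = "rinmd_out",
    workers = 1L,
    criteria = interaction_criteria(),
    compute_sasa = FALSE
  )
}

normalize_config <- function(config) {
  cfg <- default_run_config()
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  if (is.character(cfg$types) && length(cfg$types) == 1 &&
      grepl(",", cfg$types)) {
    cfg$types <- trimws(strsplit(cfg$types, ",")[[1]])
  }
  if (is.character(cfg$corr_types) && length(cfg$corr_types) == 1 &&
      grepl(",", cfg$corr_types)) {
    cfg$corr_types <- trimws(strsplit(cfg$corr_types, ",")[[1]])
  }
  if (is.character(cfg$windows)) cfg$windows <- parse_windows(cfg$windows)
  if (is.character(cfg$assembly_map) && length(cfg$assembly_map) == 1) {
    cfg$assembly_map <- parse_assembly_map(cfg$assembly_map)
  }
  for (nm in c("first", "stride", "workers")) {
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  if (!is.null(cfg$last)) cfg$last <- as.integer(cfg$last)
  cfg$persistence <- as.numeric(cfg$persistence)
  has_pdb <- !is.null(cfg$pdb)
  has_trj <- !is.null(cfg$psf) && !is.null(cfg$dcd)
  if (has_pdb == has_trj) {
    stop("run_pipeline(): exactly one of {pdb} or {psf + dcd} must be given")
  }
  if (cfg$persistence <= 0 || cfg$persistence > 1) {
    stop("run_pipeline(): persistence must be in (0, 1]")
  }
  if (cfg$workers < 1) stop("run_pipeline(): workers must be >= 1")
  cfg
}

log_line <- function(con, ...) {
  msg <- paste0(...)
  writeLines(msg, con)
  msg
}

#' Run the full RIN pipeline
#'
#' Input reading and pre-processing (protein-only filtering, charge and
#' Lennard-Jones assignment), per-frame interaction detection, consensus
#' network construction with persistence filtering, edge classification,
#' node centralities, per-type Pearson correlation matrices, and all output
#' files (GraphML networks, TSV tables, correlation matrices, class-count
#' table, run log).
#'
#' @param config Named list (or the result of
#'   \code{\link{read_run_config}}): exactly one of \code{pdb} or
#'   \code{psf} + \code{dcd}; optional \code{params} (CHARMM parameter
#'   file; the bundled set is the default), \code{first}/\code{last}/
#'   \code{stride} frame selection, \code{types} (interaction types to
#'   detect), \code{persistence} (consensus cutoff, default 0.75),
#'   \code{corr_types}, \code{windows} (list of c(first, last) frame
#'   windows for correlation), \code{assembly_map}, \code{out} directory,
#'   \code{workers}, \code{criteria} (an
#'   \code{\link{interaction_criteria}}), \code{compute_sasa}.
#' @return Invisibly, a list with the \code{consensus_rin}, centralities,
#'   correlation matrices, per-frame record list and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- normalize_config(config)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out, "run.log")
  con <- file(logf, "w")
  on.exit(close(con))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name) {
    log_line(con, sprintf("[%8.2fs] %s", proc.time()[["elapsed"]] - t0, name))
  }

  stage("input")
  if (!is.null(cfg$pdb)) {
    sys <- read_pdb(cfg$pdb)
  } else {
    sys <- read_psf(cfg$psf)
    sys <- read_dcd(cfg$dcd, sys, stride = cfg$stride, first = cfg$first,
                    last = cfg$last)
  }
  log_line(con, sprintf("  %d atoms, %d residues, %d frame(s)",
                        nrow(sys$atoms), nrow(sys$residues), n_frames(sys)))

  stage("pre-processing")
  sys <- withCallingHandlers(
    strip_non_protein(sys),
    warning = function(w) {
      log_line(con, paste("  warning:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )
  needs_params <- any(c("COULOMB", "VDW") %in% cfg$types)
  if (needs_params) {
    sys <- withCallingHandlers(
      assign_nonbonded_params(sys, cfg$params %||num% default_param_file()),
      warning = function(w) {
        log_line(con, paste("  warning:", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  }
  if (!is.null(cfg$pdb) && cfg$stride > 1) {
    sel <- seq(1, n_frames(sys), by = cfg$stride)
    sys$frames <- sys$frames[sel]
  }
  log_line(con, sprintf("  %d protein residues retained", nrow(sys$residues)))

  stage("interaction detection")
  crit <- cfg$criteria
  frame_records <- parallel_map_frames(
    sys, seq_along(sys$frames),
    function(s, f) suppressWarnings(detect_all(s, f, crit, cfg$types)),
    workers = cfg$workers
  )
  for (ty in cfg$types) {
    tot <- sum(vapply(frame_records, function(r) sum(r$type == ty),
                      numeric(1)))
    log_line(con, sprintf("  %s: %d record(s) over all frames", ty, tot))
  }

  stage("consensus network")
  fgs <- lapply(seq_along(frame_records), function(f) {
    build_frame_graph(frame_records[[f]], sys, f)
  })
  rin <- build_consensus(fgs, persistence_min = cfg$persistence)
  if (isTRUE(cfg$compute_sasa)) {
    rin$nodes$sasa <- round(shrake_rupley_sasa(sys, 1), 3)
  }
  rin <- classify_edges(rin, cfg$assembly_map)
  cent <- centralities(rin)
  log_line(con, sprintf("  %d consensus edge(s) at persistence >= %g",
                        nrow(rin$edges), cfg$persistence))

  stage("output")
  paths <- write_network(rin, cfg$out, "rin", types = cfg$types)
  utils::write.table(
    data.frame(type = rownames(rin$class_counts), rin$class_counts,
               check.names = FALSE),
    file.path(cfg$out, "class_counts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    format_tsv_numbers(cent), file.path(cfg$out, "centralities.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
  )
  corr <- list()
  if (n_frames(sys) >= 2) {
    windows <- cfg$windows
    if (is.null(windows)) windows <- list(c(1L, n_frames(sys)))
    for (ty in intersect(cfg$corr_types, cfg$types)) {
      series <- count_series(frame_records, ty, nrow(sys$residues),
                             labels = residue_labels(sys))
      for (w in seq_along(windows)) {
        cm <- pearson_matrix(series, windows[[w]])
        nm <- sprintf("corr_%s_w%d", ty, w)
        write_correlation(cm, file.path(cfg$out, paste0(nm, ".tsv")))
        corr[[nm]] <- cm
      }
    }
  }
  stage("done")
  invisible(list(
    system = sys, frame_records = frame_records, rin = rin,
    centralities = cent, correlations = corr,
    out = cfg$out, log = logf, paths = paths
  ))
}
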