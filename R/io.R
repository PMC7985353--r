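# File formats: a network "bundle" is a directory with nodes.csv
# (name,x_um,y_um,z_um,polarity,class), edges.csv (source,target) and an
# optional delays.csv (source,target,steps). All node references are by
# name; indices in exports are assigned by sorted name order so files are
# stable across platforms.

#' Write a network bundle
#'
#' Serializes a network (and optionally its delay assignment) to the
#' standard CSV bundle consumed by [load_network_bundle()] and the
#' pipeline. Round-trips bit-exactly: names, edges, positions, polarity
#' and class labels are preserved.
#'
#' @param net a `geom_network`.
#' @param dir output directory (created if needed).
#' @param delays optional `delay_assignment` written as `delays.csv`.
#' @return `dir`, invisibly.
#' @export
write_network_bundle <- function(net, dir, delays = NULL) {
  stopifnot(inherits(net, "geom_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nodes <- net$nodes
  utils::write.csv(nodes, file.path(dir, "nodes.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  utils::write.csv(net$edges, file.path(dir, "edges.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(delays)) {
    stopifnot(inherits(delays, "delay_assignment"))
    utils::write.csv(as.data.frame(delays), file.path(dir, "delays.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Load a network bundle
#'
#' Reads and validates the CSV bundle written by [write_network_bundle()].
#' If a `delays.csv` is present its delays are used verbatim (positions
#' are then not needed for delay purposes); otherwise delays are derived
#' downstream with [euclidean_delay_steps()]. Schema violations are
#' reported with the offending row.
#'
#' @param dir bundle directory.
#' @return List with `network` (a `geom_network`) and `delays` (a
#'   `delay_assignment` or `NULL`).
#' @export
load_network_bundle <- function(dir) {
  nodes_path <- file.path(dir, "nodes.csv")
  edges_path <- file.path(dir, "edges.csv")
  for (p in c(nodes_path, edges_path))
    if (!file.exists(p)) stop("missing bundle file: ", p)
  nodes <- utils::read.csv(nodes_path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  edges <- utils::read.csv(edges_path, stringsAsFactors = FALSE)
  bad <- which(!(edges$source %in% nodes$name) |
               !(edges$target %in% nodes$name))
  if (length(bad))
    stop(sprintf("edges.csv row %d references an unknown node (%s -> %s)",
                 bad[1L], edges$source[bad[1L]], edges$target[bad[1L]]))
  net <- build_network(edges, nodes)
  delays <- NULL
  delays_path <- file.path(dir, "delays.csv")
  if (file.exists(delays_path)) {
    dd <- utils::read.csv(delays_path, stringsAsFactors = FALSE)
    if (!all(c("source", "target", "steps") %in% names(dd)))
      stop("delays.csv must have columns source,target,steps")
    ix <- match(edge_key(net$edges$source, net$edges$target),
                edge_key(dd$source, dd$target))
    if (anyNA(ix))
      stop("delays.csv does not cover the edge set")
    delays <- delay_assignment(net, dd$steps[ix])
  }
  list(network = net, delays = delays)
}

#' Export an event log to CSV
#'
#' Writes one row per firing event with columns `event_id,node,step,
#' emitted,parent_ids`, parent event ids semicolon-joined.
#'
#' @param log an `event_log`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  df <- data.frame(event_id = log$event_id, node = log$node,
                   step = log$step, emitted = log$emitted,
                   parent_ids = vapply(log$parents, paste, character(1),
                                       collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a state matrix as a coordinate list
#'
#' Writes the nonzero entries of a binary state matrix as
#' `node,step` rows (steps 0-based), a compact sparse representation of
#' the raster.
#'
#' @param sm state matrix from [firing_raster()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_state_matrix <- function(sm, path) {
  idx <- which(sm != 0L, arr.ind = TRUE)
  df <- data.frame(node = rownames(sm)[idx[, 1L]],
                   step = idx[, 2L] - 1L, stringsAsFactors = FALSE)
  df <- df[order(df$step, df$node), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export Temporal Sequences as JSON lines
#'
#' One JSON object per sequence: `{"nodes": [...], "steps": [...],
#' "terminus": "..."}`. The inverse of [read_tseqs()].
#'
#' @param X a `tseq_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_tseqs <- function(X, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (x in X) {
    writeLines(jsonlite::toJSON(list(nodes = x$nodes, steps = x$steps,
                                     terminus = x$nodes[length(x$nodes)]),
                                auto_unbox = FALSE), con)
  }
  invisible(path)
}

#' @rdname export_tseqs
#' @param start_node,end_nodes metadata attached to the read set.
#' @export
read_tseqs <- function(path, start_node = NA_character_,
                       end_nodes = character()) {
  lines <- readLines(path)
  seqs <- lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln)
    tseq(obj$nodes, obj$steps)
  })
  tseq_set(seqs, start_node = start_node, end_nodes = end_nodes)
}

#' Temporal Sequence plot data
#'
#' Flattens a sequence set into per-sequence polylines of
#' `(step, node_index)` points, with node indices assigned by sorted node
#' name, plus the end-node index legend (the horizontal guide lines of a
#' sequence plot). Rendering is left to the caller; this is the data
#' layer.
#'
#' @param X a `tseq_set`.
#' @param net the `geom_network` the sequences live on.
#' @return List with `polylines` (data.frame `seq_id,step,node,
#'   node_index`) and `end_node_index` (data.frame `node,node_index`).
#' @export
tseq_plot_data <- function(X, net) {
  stopifnot(inherits(net, "geom_network"))
  nm <- sort(net$nodes$name)
  poly <- do.call(rbind, lapply(seq_along(X), function(i) {
    x <- X[[i]]
    data.frame(seq_id = i, step = x$steps, node = x$nodes,
               node_index = match(x$nodes, nm), stringsAsFactors = FALSE)
  }))
  ends <- intersect(attr(X, "end_nodes"), nm)
  list(polylines = poly,
       end_node_index = data.frame(node = ends,
                                   node_index = match(ends, nm),
                                   stringsAsFactors = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates one end-to-end run: load (or generate) a network, derive
#' delays, simulate, and write the event log, raster, unique-state curve,
#' class histograms, Temporal Sequences, self-similarity table (or a
#' comparison against a supplied reference set), basis decomposition and
#' class-interaction counts, together with a manifest carrying the config
#' hash so a run is reproducible from its persisted config alone.
#' Deterministic given the config: rerunning into a fresh directory
#' produces byte-identical artifacts.
#'
#' @param cfg a run configuration: a named list (or path to a YAML file)
#'   with fields `network_dir` (a bundle directory) or `fixture`
#'   (`list(kind = ..., ...)` for [make_fixture()]); optional `params`
#'   (arguments to [signaling_params()]); `stimuli` (list of `"node@step"`
#'   strings, defaults to the fixture's); `start_node`; `end_nodes` or
#'   `end_classes`; optional `alphas`, `bin_steps`, `max_paths`,
#'   `dedupe_labels`, `compare_tseqs` (JSONL path used as the comparison
#'   set of the similarity table), `interaction_classes`, `out_dir`.
#' @return The output directory, invisibly; a `manifest.json` inside
#'   lists every artifact written.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L)
    cfg <- yaml::read_yaml(cfg)
  stopifnot(is.list(cfg))
  out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("config must name an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  artifacts <- character(0)
  manifest_path <- file.path(out_dir, "manifest.json")
  stage <- "config"
  write_manifest <- function(status) {
    jsonlite::write_json(
      list(status = status, stage = stage, artifacts = artifacts,
           config_hash = unname(tools::md5sum(file.path(out_dir,
                                                        "config.json"))),
           package_version = as.character(utils::packageVersion("tseqnet"))),
      manifest_path, auto_unbox = TRUE, pretty = TRUE)
  }
  emit <- function(name) artifacts <<- c(artifacts, name)

  tryCatch({
    cfg_norm <- cfg[order(names(cfg))]
    jsonlite::write_json(cfg_norm, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    emit("config.json")

    stage <- "network"
    if (!is.null(cfg$fixture)) {
      fx <- do.call(make_fixture, cfg$fixture)
      net <- fx$network; delays <- fx$delays
      params <- fx$params; stimuli <- fx$stimuli
    } else if (!is.null(cfg$network_dir)) {
      bundle <- load_network_bundle(cfg$network_dir)
      net <- bundle$network; delays <- bundle$delays
      params <- NULL; stimuli <- NULL
    } else stop("config must name a network_dir or a fixture")
    if (!is.null(cfg$params))
      params <- do.call(signaling_params, cfg$params)
    if (is.null(params)) params <- signaling_params()
    if (is.null(delays)) delays <- euclidean_delay_steps(net, params)
    if (!is.null(cfg$stimuli))
      stimuli <- lapply(cfg$stimuli, function(s) {
        parts <- strsplit(s, "@", fixed = TRUE)[[1L]]
        stimulus(parts[1L], as.integer(parts[2L]))
      })
    if (is.null(stimuli)) stop("config must specify stimuli")
    write_network_bundle(net, file.path(out_dir, "network"), delays)
    emit("network/")

    stage <- "simulate"
    log <- run_simulation(net, delays, params, stimuli)
    export_event_log(log, file.path(out_dir, "event_log.csv"))
    emit("event_log.csv")
    sm <- firing_raster(log)
    export_state_matrix(sm, file.path(out_dir, "raster.csv"))
    emit("raster.csv")
    cu <- cumulative_unique_states(sm)
    utils::write.csv(data.frame(step = seq_along(cu) - 1L,
                                cumulative_unique_states = cu),
                     file.path(out_dir, "unique_states.csv"),
                     row.names = FALSE, quote = FALSE)
    emit("unique_states.csv")

    stage <- "histogram"
    if (any(!is.na(net$nodes$class))) {
      bin <- if (is.null(cfg$bin_steps)) 250L else as.integer(cfg$bin_steps)
      h <- class_activity_histogram(log, bin_steps = bin)
      utils::write.csv(data.frame(class = rownames(h), h,
                                  check.names = FALSE),
                       file.path(out_dir, "class_histogram.csv"),
                       row.names = FALSE, quote = FALSE)
      emit("class_histogram.csv")
    }

    stage <- "tseq"
    start_node <- if (!is.null(cfg$start_node)) cfg$start_node
                  else stimuli[[1L]]$node
    end_nodes <- cfg$end_nodes
    if (is.null(end_nodes) && !is.null(cfg$end_classes))
      end_nodes <- net$nodes$name[net$nodes$class %in% cfg$end_classes]
    if (is.null(end_nodes))
      stop("config must specify end_nodes or end_classes")
    X <- extract_tseqs(
      log, start_node, end_nodes,
      max_paths = if (is.null(cfg$max_paths)) 1e6 else cfg$max_paths,
      dedupe_labels = isTRUE(cfg$dedupe_labels))
    export_tseqs(X, file.path(out_dir, "tseqs.jsonl"))
    emit("tseqs.jsonl")

    stage <- "similarity"
    alphas <- if (is.null(cfg$alphas)) c(0, 0.25, 0.5, 0.75, 1)
              else as.numeric(cfg$alphas)
    Y <- if (!is.null(cfg$compare_tseqs)) read_tseqs(cfg$compare_tseqs)
         else X
    st <- similarity_table(X, Y, alphas)
    utils::write.csv(as.data.frame(st),
                     file.path(out_dir, "similarity.csv"),
                     row.names = FALSE, quote = FALSE)
    emit("similarity.csv")

    stage <- "basis"
    basis <- decompose_basis(X)
    jsonlite::write_json(
      list(n_sequences = basis$n_sequences,
           n_one_time = basis$n_one_time,
           n_repeating = basis$n_repeating,
           repeating_canonicals = lapply(basis$repeating_groups,
                                         function(g) g$canonical),
           group_sizes = vapply(basis$repeating_groups,
                                function(g) length(g$members), integer(1))),
      file.path(out_dir, "basis.json"), auto_unbox = TRUE, pretty = TRUE)
    emit("basis.json")

    stage <- "interactions"
    int_classes <- cfg$interaction_classes
    if (is.null(int_classes)) {
      cls <- net$nodes$class
      int_classes <- sort(unique(cls[!is.na(cls)]))
    }
    if (length(int_classes) >= 1L && length(X) >= 1L) {
      rows <- do.call(rbind, lapply(seq_len(min(4L, length(int_classes))),
        function(k) {
          df <- class_interaction_counts(X, net, int_classes, k)
          df$k <- k
          df
        }))
      utils::write.csv(rows, file.path(out_dir, "class_interactions.csv"),
                       row.names = FALSE, quote = FALSE)
      emit("class_interactions.csv")
    }

    stage <- "plot-data"
    pd <- tseq_plot_data(X, net)
    utils::write.csv(pd$polylines, file.path(out_dir, "tseq_plot.csv"),
                     row.names = FALSE, quote = FALSE)
    emit("tseq_plot.csv")

    stage <- "done"
    write_manifest("ok")
  }, error = function(e) {
    write_manifest("failed")
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(out_dir)
}
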