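# Deterministic toy-network generators with ground truth computed by
# construction, plus brute-force oracles. These exist so the simulator,
# sequence extraction and null models are testable end-to-end without any
# external connectome data.

fixture_kinds <- c("chain", "diamond", "cycle_with_tap",
                   "random_geometric", "two_population")

#' Generate a synthetic network fixture
#'
#' Builds a small geometric network together with its delay assignment,
#' signaling parameters and (for the deterministic kinds) machine-checkable
#' ground truth derived in closed form:
#'
#' * `chain`: a feed-forward path `N1 -> N2 -> ...` with explicit delays;
#'   each node fires exactly once, at the cumulative delay.
#' * `diamond`: two equal-total-delay branches `A -> B -> D` and
#'   `A -> C -> D`, so D's single activation has two causal parents and
#'   two Temporal Sequences reach it.
#' * `cycle_with_tap`: a two-node oscillator `A <-> B` with a tap edge
#'   `B -> E`; the signal circulates with period equal to the delay sum,
#'   producing one additional, longer sequence to the tap per lap.
#' * `random_geometric`: `n` nodes placed uniformly in a worm-like box
#'   (default 50 x 1000 x 50 um) with independent directed edges of
#'   probability `p`; delays derive from the embedding, so they are
#'   heterogeneous as in a real connectome.
#' * `two_population`: a start node driving a two-node oscillator whose
#'   half-cycles feed two labeled node groups ("VB", "DB") through
#'   staggered taps, yielding alternating class activity histograms at
#'   toy scale.
#'
#' @param kind one of `"chain"`, `"diamond"`, `"cycle_with_tap"`,
#'   `"random_geometric"`, `"two_population"`.
#' @param ... kind-specific parameters, see Details in each generator:
#'   `chain(delays, n_steps)`; `cycle_with_tap(delay, tap_delay,
#'   refractory, n_steps)`; `random_geometric(n, p, seed, box_um,
#'   frac_inhibitory, ensure_connected, n_steps)`;
#'   `two_population(n_per_class, half_period, n_steps)`.
#' @return A list with `network`, `delays`, `params`, `stimuli` and
#'   `truth` (ground-truth list, `NULL` for `random_geometric`).
#' @export
make_fixture <- function(kind = fixture_kinds, ...) {
  kind <- match.arg(kind)
  switch(kind,
         chain = fixture_chain(...),
         diamond = fixture_diamond(...),
         cycle_with_tap = fixture_cycle_with_tap(...),
         random_geometric = fixture_random_geometric(...),
         two_population = fixture_two_population(...))
}

unit_params <- function(refractory_steps, n_steps) {
  signaling_params(velocity_mm_s = 1, refractory_s = refractory_steps,
                   dt_s = 1, n_steps = n_steps)
}

fixture_chain <- function(delays = c(2L, 3L), n_steps = 20L) {
  delays <- as.integer(delays)
  n <- length(delays) + 1L
  nm <- paste0("N", seq_len(n))
  nodes <- data.frame(name = nm,
                      x_um = c(0, cumsum(delays)) * 2, y_um = 0, z_um = 0,
                      polarity = "E", stringsAsFactors = FALSE)
  edges <- data.frame(source = nm[-n], target = nm[-1L],
                      stringsAsFactors = FALSE)
  net <- build_network(edges, nodes)
  steps <- c(0L, cumsum(delays))
  list(network = net,
       delays = delay_assignment(net, delays),
       params = unit_params(refractory_steps = 2L, n_steps = n_steps),
       stimuli = list(stimulus(nm[1L], 0L)),
       truth = list(expected_events = data.frame(node = nm, step = steps,
                                                 stringsAsFactors = FALSE),
                    expected_tseqs = list(tseq(nm, steps)),
                    expected_unique_states = n + 1L))
}

fixture_diamond <- function(n_steps = 20L) {
  nodes <- data.frame(name = c("A", "B", "C", "D"),
                      x_um = c(0, 2, 4, 10), y_um = 0, z_um = 0,
                      polarity = "E", stringsAsFactors = FALSE)
  edges <- data.frame(source = c("A", "B", "A", "C"),
                      target = c("B", "D", "C", "D"),
                      stringsAsFactors = FALSE)
  net <- build_network(edges, nodes)
  # both branch totals are 5 steps, so D activates once with two parents
  delays <- delay_assignment(net, c(2L, 3L, 1L, 4L))
  ev <- data.frame(node = c("A", "C", "B", "D"),
                   step = c(0L, 1L, 2L, 5L), stringsAsFactors = FALSE)
  list(network = net, delays = delays,
       params = unit_params(2L, n_steps),
       stimuli = list(stimulus("A", 0L)),
       truth = list(expected_events = ev,
                    expected_tseqs = list(
                      tseq(c("A", "B", "D"), c(0L, 2L, 5L)),
                      tseq(c("A", "C", "D"), c(0L, 1L, 5L)))))
}

fixture_cycle_with_tap <- function(delay = 3L, tap_delay = 1L,
                                   refractory = 2L, n_steps = 20L) {
  nodes <- data.frame(name = c("A", "B", "E"),
                      x_um = c(0, delay * 2, delay * 4), y_um = 0, z_um = 0,
                      polarity = "E", stringsAsFactors = FALSE)
  edges <- data.frame(source = c("A", "B", "B"),
                      target = c("B", "A", "E"),
                      stringsAsFactors = FALSE)
  net <- build_network(edges, nodes)
  delays <- delay_assignment(net, c(delay, delay, tap_delay))
  period <- 2L * delay
  a_steps <- seq.int(0L, n_steps - 1L, by = period)
  b_steps <- seq.int(delay, n_steps - 1L, by = period)
  b_steps <- b_steps[b_steps < n_steps]
  e_steps <- b_steps + tap_delay
  e_steps <- e_steps[e_steps < n_steps]
  ev <- data.frame(
    node = c(rep("A", length(a_steps)), rep("B", length(b_steps)),
             rep("E", length(e_steps))),
    step = c(a_steps, b_steps, e_steps), stringsAsFactors = FALSE)
  ev <- ev[order(ev$step, ev$node), , drop = FALSE]
  rownames(ev) <- NULL
  # the k-th sequence to the tap makes k laps of the A-B cycle first
  expected_tseqs <- lapply(seq_along(e_steps), function(k) {
    lap_nodes <- c(rep(c("A", "B"), k), "E")
    lap_steps <- c(rbind(a_steps[seq_len(k)], b_steps[seq_len(k)]),
                   e_steps[k])
    tseq(lap_nodes, lap_steps)
  })
  list(network = net, delays = delays,
       params = unit_params(refractory, n_steps),
       stimuli = list(stimulus("A", 0L)),
       truth = list(expected_events = ev,
                    expected_tseqs = expected_tseqs,
                    period = period))
}

fixture_random_geometric <- function(n = 30L, p = 0.1, seed = 1L,
                                     box_um = c(50, 1000, 50),
                                     frac_inhibitory = 0.1,
                                     ensure_connected = FALSE,
                                     n_steps = 6000L) {
  stopifnot(n >= 2, p >= 0, p <= 1, length(box_um) == 3L)
  nm <- sprintf("R%02d", seq_len(n))
  gen <- with_local_seed(seed, {
    pos <- cbind(stats::runif(n, 0, box_um[1L]),
                 stats::runif(n, 0, box_um[2L]),
                 stats::runif(n, 0, box_um[3L]))
    adj <- matrix(stats::runif(n * n) <= p, n, n)
    diag(adj) <- FALSE
    pol <- ifelse(stats::runif(n) < frac_inhibitory, "I", "E")
    list(pos = pos, adj = adj, pol = pol)
  })
  idx <- which(gen$adj, arr.ind = TRUE)
  edges <- data.frame(source = nm[idx[, 1L]], target = nm[idx[, 2L]],
                      stringsAsFactors = FALSE)
  if (ensure_connected) {
    ring <- data.frame(source = nm, target = nm[c(2:n, 1L)],
                       stringsAsFactors = FALSE)
    edges <- rbind(edges, ring)
    edges <- edges[!duplicated(edge_key(edges$source, edges$target)), ,
                   drop = FALSE]
  }
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  nodes <- data.frame(name = nm, x_um = gen$pos[, 1L],
                      y_um = gen$pos[, 2L], z_um = gen$pos[, 3L],
                      polarity = gen$pol, stringsAsFactors = FALSE)
  net <- build_network(edges, nodes)
  params <- signaling_params(n_steps = n_steps)
  list(network = net,
       delays = euclidean_delay_steps(net, params),
       params = params,
       stimuli = list(stimulus(nm[1L], 0L)),
       truth = NULL)
}

fixture_two_population <- function(n_per_class = 3L, half_period = 250L,
                                   n_steps = 3000L) {
  stopifnot(n_per_class >= 1, half_period >= 10)
  vb <- sprintf("VB%d", seq_len(n_per_class))
  db <- sprintf("DB%d", seq_len(n_per_class))
  nm <- c("S", "O1", "O2", vb, db)
  nodes <- data.frame(name = nm, x_um = seq_along(nm), y_um = 0, z_um = 0,
                      polarity = "E",
                      class = c(NA, NA, NA, rep("VB", n_per_class),
                                rep("DB", n_per_class)),
                      stringsAsFactors = FALSE)
  tap_delays <- 5L + 2L * (seq_len(n_per_class) - 1L)
  edges <- data.frame(
    source = c("S", "O1", "O2", rep("O1", n_per_class),
               rep("O2", n_per_class)),
    target = c("O1", "O2", "O1", vb, db),
    stringsAsFactors = FALSE)
  net <- build_network(edges, nodes)
  delays <- delay_assignment(
    net, c(1L, half_period, half_period, tap_delays, tap_delays))
  params <- unit_params(refractory_steps = min(100L, half_period - 1L),
                        n_steps = n_steps)
  period <- 2L * half_period
  o1_steps <- seq.int(1L, n_steps - 1L, by = period)
  o2_steps <- seq.int(1L + half_period, n_steps - 1L, by = period)
  per_node_steps <- c(
    stats::setNames(list(0L, o1_steps, o2_steps), c("S", "O1", "O2")),
    stats::setNames(lapply(tap_delays, function(d) {
      s <- o1_steps + d; s[s < n_steps]
    }), vb),
    stats::setNames(lapply(tap_delays, function(d) {
      s <- o2_steps + d; s[s < n_steps]
    }), db))
  ev <- data.frame(
    node = rep(names(per_node_steps), lengths(per_node_steps)),
    step = unlist(per_node_steps, use.names = FALSE),
    stringsAsFactors = FALSE)
  ev <- ev[order(ev$step, ev$node), , drop = FALSE]
  rownames(ev) <- NULL
  list(network = net, delays = delays, params = params,
       stimuli = list(stimulus("S", 0L)),
       truth = list(expected_events = ev,
                    classes = c("VB", "DB"),
                    period = period))
}

#' Brute-force oracle: enumerate causal paths backwards
#'
#' Independent check of Temporal Sequence extraction: starting from every
#' activation of an end node, recursively walks the parent links back to
#' a root (stimulus-driven) event of the start node, emitting one
#' sequence per complete ancestor chain. Exhaustive and unoptimized by
#' design; only suitable for small logs.
#'
#' @param log an `event_log`.
#' @param start start node name.
#' @param ends character vector of end node names.
#' @param max_paths overflow guard on the search.
#' @return A `tseq_set`.
#' @export
oracle_enumerate_paths <- function(log, start, ends, max_paths = 1e6) {
  stopifnot(inherits(log, "event_log"))
  paths <- list()
  back <- function(e, suffix) {
    ps <- log$parents[[e]]
    if (!length(ps)) {
      if (log$node[e] == start) {
        if (length(paths) >= max_paths) stop("oracle search-space overflow")
        paths[[length(paths) + 1L]] <<- c(e, suffix)
      }
    } else {
      for (p in ps) back(p, c(e, suffix))
    }
  }
  for (ee in which(log$node %in% ends)) back(ee, integer(0))
  tseq_set(lapply(paths, function(p) tseq(log$node[p], log$step[p])),
           start_node = start, end_nodes = ends)
}

#' Brute-force oracle: distinct network states
#'
#' Counts the distinct column vectors of a binary state matrix by naive
#' set insertion, as an independent check of the cumulative unique-state
#' curve's final value.
#'
#' @param sm binary state matrix (nodes x steps).
#' @return Integer count of distinct states.
#' @export
oracle_unique_states <- function(sm) {
  stopifnot(is.matrix(sm))
  if (ncol(sm) == 0L) return(0L)
  length(unique(apply(sm, 2L, paste, collapse = "")))
}
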