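#' Stimulus specification
#'
#' A single-pulse stimulus delivered to one node at one simulation step.
#' Stimuli are excitatory: the stimulated node fires (if not refractory)
#' and its root firing event has no causal parents.
#'
#' @param node node name.
#' @param step integer step at which the pulse is delivered (0-based).
#' @return A `stimulus` object.
#' @export
stimulus <- function(node, step = 0L) {
  stopifnot(is.character(node), length(node) == 1L, step >= 0)
  structure(list(node = node, step = as.integer(step)), class = "stimulus")
}

#' Run the discrete signaling simulation
#'
#' Time-stepped execution of the threshold-1 excitatory/inhibitory
#' refractory signaling model. A signal emitted by a node travels along
#' every outgoing edge and arrives after that edge's delay. Arrivals are
#' grouped per (node, step); a node is eligible to activate if its last
#' activation is at least `refractory_steps` in the past, and an eligible
#' node with at least one arrival activates at that step (the activation
#' threshold is a single incoming signal). An activation triggered by any
#' inhibitory arrival is non-emitting: the node activates and becomes
#' refractory but generates no outgoing signals. Otherwise the node emits
#' one signal per outgoing edge, with the polarity of the emitting node
#' itself. Arrivals at refractory nodes are discarded, and signals still
#' in flight when the simulation window closes are dropped.
#'
#' Every firing event records all same-step arriving source events as
#' causal parents, which is what makes Temporal Sequence extraction
#' possible downstream.
#'
#' @param net a `geom_network`.
#' @param delays a `delay_assignment` covering exactly `net`'s edges.
#' @param params a `signaling_params`.
#' @param stimuli a list of [stimulus()] objects (or a single one).
#' @return An `event_log`: a data.frame with columns `event_id`, `node`,
#'   `step`, `emitted` and a list-column `parents` (integer event ids),
#'   carrying the network, delays, parameters and stimuli as attributes.
#' @examples
#' nodes <- data.frame(name = c("A", "B", "C"), polarity = "E")
#' net <- build_network(data.frame(source = c("A", "B"),
#'                                 target = c("B", "C")), nodes)
#' del <- delay_assignment(net, c(2L, 3L))
#' par <- signaling_params(refractory_s = 2, dt_s = 1, n_steps = 20)
#' log <- run_simulation(net, del, par, stimulus("A", 0))
#' log$step  # 0, 2, 5
#' @export
run_simulation <- function(net, delays, params, stimuli) {
  stopifnot(inherits(net, "geom_network"),
            inherits(delays, "delay_assignment"),
            inherits(params, "signaling_params"))
  if (inherits(stimuli, "stimulus")) stimuli <- list(stimuli)
  if (length(stimuli) == 0L) stop("at least one stimulus is required")
  nm <- net$nodes$name
  n <- length(nm)
  T_ <- params$n_steps
  r_steps <- params$refractory_steps

  for (s in stimuli) {
    if (!inherits(s, "stimulus")) stop("stimuli must be stimulus objects")
    if (!s$node %in% nm) stop("stimulus to unknown node: ", s$node)
    if (s$step >= T_) stop("stimulus step out of range: ", s$step)
  }

  # delay lookup aligned to the edge set
  ix <- match(edge_key(net$edges$source, net$edges$target),
              edge_key(delays$source, delays$target))
  if (anyNA(ix) || nrow(delays) != n_edges(net))
    stop("delay assignment must cover exactly the network's edges")
  e_src <- match(net$edges$source, nm)
  e_tgt <- match(net$edges$target, nm)
  e_del <- as.integer(delays$steps[ix])
  out_t <- split(e_tgt, factor(e_src, levels = seq_len(n)))
  out_d <- split(e_del, factor(e_src, levels = seq_len(n)))
  inhibitory <- net$nodes$polarity == "I"

  # per-step arrival buffers: each is a list of c(target, source_event, inhib)
  arrivals <- vector("list", T_)
  stim_at <- vector("list", T_)
  for (s in stimuli)
    stim_at[[s$step + 1L]] <- c(stim_at[[s$step + 1L]], match(s$node, nm))

  last_fire <- rep.int(-.Machine$integer.max %/% 2L, n)
  ev_node <- integer(0); ev_step <- integer(0); ev_emit <- logical(0)
  ev_parents <- list()
  n_ev <- 0L

  for (t in 0:(T_ - 1L)) {
    buf <- arrivals[[t + 1L]]
    stim_nodes <- stim_at[[t + 1L]]
    if (is.null(buf) && is.null(stim_nodes)) next
    if (!is.null(buf)) {
      amat <- matrix(unlist(buf, use.names = FALSE), ncol = 3L, byrow = TRUE)
      a_tgt <- amat[, 1L]; a_src <- amat[, 2L]; a_inh <- amat[, 3L] == 1L
    } else {
      a_tgt <- integer(0); a_src <- integer(0); a_inh <- logical(0)
    }
    for (v in sort(unique(c(a_tgt, stim_nodes)))) {
      if (t - last_fire[v] < r_steps) next   # refractory: arrivals discarded
      sel <- a_tgt == v
      parents <- a_src[sel]
      emitted <- !any(a_inh[sel])            # inhibition dominates the step
      n_ev <- n_ev + 1L
      ev_node[n_ev] <- v
      ev_step[n_ev] <- t
      ev_emit[n_ev] <- emitted
      ev_parents[[n_ev]] <- as.integer(parents)
      last_fire[v] <- t
      if (emitted) {
        tgts <- out_t[[v]]; dels <- out_d[[v]]
        if (length(tgts)) {
          at <- t + dels
          ok <- at < T_                      # in-flight past the window: drop
          if (any(ok)) {
            inh <- as.integer(inhibitory[v])
            for (k in which(ok)) {
              st <- at[k] + 1L
              arrivals[[st]] <- c(arrivals[[st]],
                                  list(c(tgts[k], n_ev, inh)))
            }
          }
        }
      }
    }
  }

  log <- data.frame(event_id = seq_len(n_ev),
                    node = nm[ev_node],
                    step = ev_step,
                    emitted = ev_emit,
                    stringsAsFactors = FALSE)
  log$parents <- ev_parents
  structure(log,
            network = net, delays = delays, params = params,
            stimuli = stimuli,
            class = c("event_log", "data.frame"))
}

#' Binary firing raster
#'
#' Converts an event log into the N x T binary state matrix `y`, where
#' `y[i, t] = 1` iff node `i` fires (an emitting event) at step `t`.
#' Non-emitting (inhibited) activations are excluded from the raster; the
#' flag is retained in the log so the alternative convention remains
#' recomputable.
#'
#' @param log an `event_log`.
#' @return An integer matrix with node names as row names and one column
#'   per simulation step (columns are steps `0 .. n_steps - 1`).
#' @export
firing_raster <- function(log) {
  stopifnot(inherits(log, "event_log"))
  net <- attr(log, "network")
  T_ <- attr(log, "params")$n_steps
  nm <- net$nodes$name
  y <- matrix(0L, length(nm), T_, dimnames = list(nm, NULL))
  emit <- log$emitted
  if (any(emit))
    y[cbind(match(log$node[emit], nm), log$step[emit] + 1L)] <- 1L
  y
}

#' Cumulative count of unique network states
#'
#' The network state at step `t` is the binary vector of nodal firings
#' `y(t)`. This returns, for each step, the number of distinct state
#' vectors observed up to and including that step; the all-zero
#' (quiescent) vector counts as a state. A spatially embedded network
#' typically exhibits many more unique states than its uniform-delay
#' lattice counterpart.
#'
#' @param sm a binary state matrix (nodes x steps), as from
#'   [firing_raster()].
#' @return Integer vector `c` with `c[t]` the cumulative unique-state
#'   count through step `t - 1` (1-indexed over columns).
#' @export
cumulative_unique_states <- function(sm) {
  stopifnot(is.matrix(sm))
  T_ <- ncol(sm)
  if (T_ == 0L) return(integer(0))
  keys <- vapply(seq_len(T_),
                 function(t) paste(which(sm[, t] != 0L), collapse = ","),
                 character(1))
  cummax(cumsum(!duplicated(keys)))
}

#' Class-wise activity histogram
#'
#' Bins the emitting firing events of each node class (e.g., VB, DB
#' motorneuron classes) into fixed-width windows of simulation steps,
#' producing the class activity histograms used to visualize alternating
#' ventral/dorsal motorneuron firing.
#'
#' @param log an `event_log`.
#' @param classes optional character vector restricting (and ordering) the
#'   classes reported; defaults to all classes present in the network.
#' @param bin_steps histogram bin width in steps (default 250).
#' @return An integer matrix classes x bins; bin `k` counts emitting
#'   events with step in `[(k-1) * bin_steps, k * bin_steps)`.
#' @export
class_activity_histogram <- function(log, classes = NULL, bin_steps = 250L) {
  stopifnot(inherits(log, "event_log"), bin_steps >= 1)
  net <- attr(log, "network")
  T_ <- attr(log, "params")$n_steps
  cls_map <- stats::setNames(net$nodes$class, net$nodes$name)
  if (is.null(classes)) {
    classes <- sort(unique(cls_map[!is.na(cls_map)]))
  } else {
    unknown <- setdiff(classes, cls_map[!is.na(cls_map)])
    if (length(unknown))
      stop("unknown class(es): ", paste(unknown, collapse = ", "))
  }
  n_bins <- ceiling(T_ / bin_steps)
  h <- matrix(0L, length(classes), n_bins,
              dimnames = list(classes,
                              as.character(seq_len(n_bins) - 1L)))
  emit <- log[log$emitted, , drop = FALSE]
  ev_cls <- cls_map[emit$node]
  keep <- !is.na(ev_cls) & ev_cls %in% classes
  if (any(keep)) {
    bins <- emit$step[keep] %/% bin_steps + 1L
    tb <- table(factor(ev_cls[keep], levels = classes),
                factor(bins, levels = seq_len(n_bins)))
    h[] <- as.integer(tb)
  }
  h
}
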