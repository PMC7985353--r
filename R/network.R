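# internal: round half away from zero (base round() is round-half-even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# internal: canonical edge key
edge_key <- function(source, target) paste(source, target, sep = "\r")

#' Directed geometric network
#'
#' Constructs and validates a directed geometric network: a directed graph
#' whose nodes carry optional 3-D soma positions (micrometres), a signaling
#' polarity (excitatory or inhibitory), and an optional class label such as
#' a motorneuron class ("VB", "DB", ...). Edges represent chemical
#' (axonal) connections and are unweighted; multiple reported synapses
#' between the same pair collapse to a single edge.
#'
#' Nodes whose position is missing (any of x/y/z is `NA`) are dropped
#' together with their incident edges, mirroring the usual reduction of a
#' connectome to the neurons with known soma positions; the dropped names
#' are recorded in the `dropped_nodes` attribute. If the node table has no
#' position columns at all, the network is built without positions and can
#' only be simulated with an explicit delay assignment.
#'
#' @param edge_list data.frame with character columns `source`, `target`.
#' @param node_table data.frame with columns `name`, `polarity` (one of
#'   `"E"`/`"I"`, or `"excitatory"`/`"inhibitory"`), optional `x_um`,
#'   `y_um`, `z_um` positions and an optional `class` label column.
#' @return An object of class `geom_network`: a list with elements
#'   `nodes` (data.frame `name`, `x_um`, `y_um`, `z_um`, `polarity`,
#'   `class`) and `edges` (data.frame `source`, `target`), plus attribute
#'   `dropped_nodes`.
#' @examples
#' nodes <- data.frame(name = c("A", "B", "C"),
#'                     x_um = c(0, 1000, 2000), y_um = 0, z_um = 0,
#'                     polarity = "E")
#' edges <- data.frame(source = c("A", "B"), target = c("B", "C"))
#' net <- build_network(edges, nodes)
#' n_nodes(net); n_edges(net)
#' @export
build_network <- function(edge_list, node_table) {
  stopifnot(is.data.frame(edge_list), is.data.frame(node_table))
  if (!all(c("name", "polarity") %in% names(node_table)))
    stop("node_table must have columns 'name' and 'polarity'")
  if (nrow(edge_list) > 0 && !all(c("source", "target") %in% names(edge_list)))
    stop("edge_list must have columns 'source' and 'target'")

  name <- as.character(node_table$name)
  if (anyDuplicated(name))
    stop("duplicate node names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))

  pol <- as.character(node_table$polarity)
  pol[pol == "excitatory"] <- "E"
  pol[pol == "inhibitory"] <- "I"
  if (any(is.na(pol)) || !all(pol %in% c("E", "I")))
    stop("polarity must be 'E' or 'I' for every node")

  cls <- if ("class" %in% names(node_table)) {
    cl <- as.character(node_table$class)
    cl[!is.na(cl) & cl == ""] <- NA_character_
    cl
  } else rep(NA_character_, length(name))

  pos_cols <- c("x_um", "y_um", "z_um")
  has_pos <- all(pos_cols %in% names(node_table))
  if (has_pos) {
    pos <- as.matrix(node_table[pos_cols])
    storage.mode(pos) <- "double"
    if (any(is.nan(pos)) || any(is.infinite(pos)))
      stop("non-finite node coordinate")
    missing_pos <- apply(is.na(pos), 1L, any)
  } else {
    pos <- matrix(NA_real_, length(name), 3L,
                  dimnames = list(NULL, pos_cols))
    missing_pos <- rep(FALSE, length(name))
  }

  dropped <- name[missing_pos]
  keep <- !missing_pos
  nodes <- data.frame(name = name[keep],
                      x_um = pos[keep, 1L], y_um = pos[keep, 2L],
                      z_um = pos[keep, 3L],
                      polarity = pol[keep], class = cls[keep],
                      stringsAsFactors = FALSE)

  src <- as.character(edge_list$source)
  tgt <- as.character(edge_list$target)
  unknown <- setdiff(c(src, tgt), name)
  if (length(unknown))
    stop("edge references unknown node(s): ",
         paste(unknown, collapse = ", "))
  if (any(src == tgt))
    stop("self-loops are not allowed (the signaling model gives them no meaning)")
  # drop edges incident to dropped nodes, collapse duplicates
  keep_e <- !(src %in% dropped) & !(tgt %in% dropped)
  src <- src[keep_e]; tgt <- tgt[keep_e]
  dup <- duplicated(edge_key(src, tgt))
  edges <- data.frame(source = src[!dup], target = tgt[!dup],
                      stringsAsFactors = FALSE)

  structure(list(nodes = nodes, edges = edges),
            dropped_nodes = dropped,
            has_positions = has_pos,
            class = "geom_network")
}

#' @export
print.geom_network <- function(x, ...) {
  cat(sprintf("geom_network: %d nodes, %d edges%s\n",
              nrow(x$nodes), nrow(x$edges),
              if (isTRUE(attr(x, "has_positions"))) " (positioned)" else ""))
  ni <- sum(x$nodes$polarity == "I")
  cat(sprintf("  polarities: %d excitatory, %d inhibitory\n",
              nrow(x$nodes) - ni, ni))
  cls <- unique(x$nodes$class[!is.na(x$nodes$class)])
  if (length(cls))
    cat("  classes:", paste(sort(cls), collapse = ", "), "\n")
  dn <- attr(x, "dropped_nodes")
  if (length(dn))
    cat(sprintf("  %d node(s) dropped for missing positions\n", length(dn)))
  invisible(x)
}

#' @rdname build_network
#' @param net a `geom_network`.
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname build_network
#' @export
n_edges <- function(net) nrow(net$edges)

#' Signaling parameters
#'
#' Bundles the physical parameters of the discrete signaling model: the
#' axonal conduction velocity, the node refractory period, the simulation
#' time step and the number of steps. Defaults reproduce the standard
#' connectome-scale run: 80 mm/s conduction velocity, a 4 ms refractory
#' period, and 0.15 s of activity split into 6000 steps (dt = 25 us).
#'
#' @param velocity_mm_s conduction velocity in mm/s.
#' @param refractory_s refractory period in seconds.
#' @param dt_s simulation step in seconds.
#' @param n_steps number of simulation steps.
#' @return Object of class `signaling_params` with the derived integer
#'   `refractory_steps` (at least 1).
#' @export
signaling_params <- function(velocity_mm_s = 80,
                             refractory_s = 0.004,
                             dt_s = 0.15 / 6000,
                             n_steps = 6000L) {
  stopifnot(velocity_mm_s > 0, refractory_s > 0, dt_s > 0, n_steps >= 1)
  rs <- as.integer(max(1, round_half_up(refractory_s / dt_s)))
  structure(list(velocity_mm_s = velocity_mm_s,
                 refractory_s = refractory_s,
                 dt_s = dt_s,
                 n_steps = as.integer(n_steps),
                 refractory_steps = rs),
            class = "signaling_params")
}

#' @export
print.signaling_params <- function(x, ...) {
  cat(sprintf(paste0("signaling_params: v = %g mm/s, refractory = %g s",
                     " (%d steps), dt = %g s, %d steps\n"),
              x$velocity_mm_s, x$refractory_s, x$refractory_steps,
              x$dt_s, x$n_steps))
  invisible(x)
}

#' Explicit edge delay assignment
#'
#' Builds a delay assignment directly from per-edge step counts, in the
#' network's edge order. Used for fixtures and for the lattice variant
#' where delays are not derived from geometry.
#'
#' @param net a `geom_network`.
#' @param steps integer vector of per-edge delays (recycled if length 1);
#'   every delay must be at least 1 step.
#' @return Object of class `delay_assignment`: a data.frame with columns
#'   `source`, `target`, `steps` covering exactly the network's edges.
#' @export
delay_assignment <- function(net, steps) {
  stopifnot(inherits(net, "geom_network"))
  steps <- as.integer(steps)
  if (length(steps) == 1L) steps <- rep(steps, n_edges(net))
  if (length(steps) != n_edges(net))
    stop("need one delay per edge")
  if (n_edges(net) > 0 && any(is.na(steps) | steps < 1L))
    stop("every delay must be an integer >= 1 step")
  structure(data.frame(source = net$edges$source,
                       target = net$edges$target,
                       steps = steps, stringsAsFactors = FALSE),
            class = c("delay_assignment", "data.frame"))
}

#' Euclidean edge delays in simulation steps
#'
#' Derives each edge's signal delay from the straight-line distance between
#' the somata of its endpoints and the conduction velocity:
#' `delay = max(1, round(||p_i - p_j|| / v / dt))`, with rounding half away
#' from zero. The clamp to one step prevents zero-delay (instantaneous)
#' signaling between distinct nodes.
#'
#' @param net a `geom_network` with positions for every node.
#' @param params a `signaling_params` object.
#' @return A `delay_assignment` covering exactly the network's edges.
#' @examples
#' nodes <- data.frame(name = c("A", "B"), x_um = c(0, 2000),
#'                     y_um = 0, z_um = 0, polarity = "E")
#' net <- build_network(data.frame(source = "A", target = "B"), nodes)
#' euclidean_delay_steps(net, signaling_params())$steps  # 1000
#' @export
euclidean_delay_steps <- function(net, params) {
  stopifnot(inherits(net, "geom_network"), inherits(params, "signaling_params"))
  if (!isTRUE(attr(net, "has_positions")) || anyNA(net$nodes[c("x_um", "y_um", "z_um")]))
    stop("all nodes must have positions to derive Euclidean delays")
  pos <- as.matrix(net$nodes[c("x_um", "y_um", "z_um")])
  rownames(pos) <- net$nodes$name
  d_um <- sqrt(rowSums((pos[net$edges$source, , drop = FALSE] -
                        pos[net$edges$target, , drop = FALSE])^2))
  # um -> mm, divide by velocity (mm/s) then by dt (s)
  steps <- pmax(1, round_half_up(d_um * 1e-3 / params$velocity_mm_s / params$dt_s))
  delay_assignment(net, steps)
}

#' Induced subnetwork
#'
#' Extracts the subgraph induced by a set of member nodes: the members with
#' their positions, polarities and class labels, and exactly the edges with
#' both endpoints among the members. Physical signaling parameters are
#' unchanged by subsetting and should be reused as-is.
#'
#' @param net a `geom_network`.
#' @param member_names character vector of node names, all present in `net`.
#' @return A `geom_network` on `member_names`.
#' @export
extract_subnetwork <- function(net, member_names) {
  stopifnot(inherits(net, "geom_network"))
  member_names <- as.character(member_names)
  unknown <- setdiff(member_names, net$nodes$name)
  if (length(unknown))
    stop("unknown member name(s): ", paste(unknown, collapse = ", "))
  nodes <- net$nodes[net$nodes$name %in% member_names, , drop = FALSE]
  keep <- net$edges$source %in% member_names & net$edges$target %in% member_names
  edges <- net$edges[keep, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges),
            dropped_nodes = character(),
            has_positions = attr(net, "has_positions"),
            class = "geom_network")
}

#' Spatially-unaware lattice variant
#'
#' Produces the lattice counterpart of a geometric network: identical
#' adjacency and polarities, but every edge delay set to one arbitrary time
#' unit and the refractory period to 0.9 time units, removing all effects
#' of the spatial embedding. One time unit is realized as
#' `steps_per_tu` simulation steps (default 10) so the 0.9 refraction
#' ratio is exact in integers (delay 10 steps, refractory 9 steps).
#'
#' @param net a `geom_network`.
#' @param steps_per_tu integer steps per time unit; must make
#'   `0.9 * steps_per_tu` a whole number.
#' @param n_steps length of the intended simulation, stored in the
#'   returned parameters.
#' @return A list with elements `network` (identical adjacency),
#'   `delays` (all equal to `steps_per_tu`) and `params` (a
#'   `signaling_params` whose `refractory_steps` is `0.9 * steps_per_tu`).
#' @export
lattice_variant <- function(net, steps_per_tu = 10L, n_steps = 6000L) {
  stopifnot(inherits(net, "geom_network"), steps_per_tu >= 1)
  r_steps <- 0.9 * steps_per_tu
  if (r_steps != round(r_steps))
    stop("steps_per_tu must make 0.9 * steps_per_tu an integer")
  # dt is one step; velocity is irrelevant because delays are explicit
  params <- signaling_params(velocity_mm_s = 1,
                             refractory_s = r_steps,
                             dt_s = 1, n_steps = n_steps)
  list(network = net,
       delays = delay_assignment(net, as.integer(steps_per_tu)),
       params = params)
}

#' Convert to igraph
#'
#' Builds an igraph representation of the network, carrying polarity and
#' class as vertex attributes and, when a delay assignment is supplied,
#' `delay_steps` as an edge attribute.
#'
#' @param net a `geom_network`.
#' @param delays optional `delay_assignment`.
#' @return An `igraph` directed graph.
#' @export
as_igraph <- function(net, delays = NULL) {
  stopifnot(inherits(net, "geom_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = net$nodes)
  if (!is.null(delays)) {
    stopifnot(inherits(delays, "delay_assignment"))
    ix <- match(edge_key(net$edges$source, net$edges$target),
                edge_key(delays$source, delays$target))
    if (anyNA(ix)) stop("delay assignment does not cover the edge set")
    g <- igraph::set_edge_attr(g, "delay_steps", value = delays$steps[ix])
  }
  g
}
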