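# internal: run code under a seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

new_randomization_report <- function(method, seed, before, after,
                                     n_successful_swaps = NA_integer_,
                                     connectedness_preserved = NA,
                                     p = NA_real_) {
  structure(list(method = method, seed = seed,
                 n_edges_before = as.integer(before),
                 n_edges_after = as.integer(after),
                 n_successful_swaps = n_successful_swaps,
                 connectedness_preserved = connectedness_preserved,
                 p = p),
            class = "randomization_report")
}

#' @export
print.randomization_report <- function(x, ...) {
  cat(sprintf("randomization_report: %s (seed %d), edges %d -> %d\n",
              x$method, x$seed, x$n_edges_before, x$n_edges_after))
  if (!is.na(x$n_successful_swaps))
    cat(sprintf("  successful swaps: %d\n", x$n_successful_swaps))
  if (!is.na(x$p)) cat(sprintf("  edge probability p = %.6g\n", x$p))
  invisible(x)
}

#' Gilbert edge-density randomization
#'
#' Replaces the edge set by a Gilbert (Erdos-Renyi G(n, p)) directed random
#' graph that matches the original edge density in expectation: every
#' ordered pair (i, j) with i != j becomes an edge independently with
#' probability `p = e / (N (N - 1))`, where `e` is the original edge count
#' and `N` the node count. Node positions, polarities and class labels are
#' preserved; self-loops are excluded (hence the N(N-1) denominator).
#' Delays must be recomputed from positions afterwards with
#' [euclidean_delay_steps()].
#'
#' @param net a `geom_network` with at least 2 nodes.
#' @param seed integer seed; the draw is bit-reproducible given the seed
#'   and the caller's RNG state is left untouched.
#' @return A list with `network` (the randomized `geom_network`) and
#'   `report` (a `randomization_report` recording `p` and edge counts).
#' @export
gilbert_randomize <- function(net, seed) {
  stopifnot(inherits(net, "geom_network"))
  N <- n_nodes(net)
  if (N < 2) stop("need at least 2 nodes")
  e <- n_edges(net)
  p <- e / (N * (N - 1))
  adj <- with_local_seed(seed, {
    u <- matrix(stats::runif(N * N), N, N)
    keep <- u <= p
    diag(keep) <- FALSE
    keep
  })
  idx <- which(adj, arr.ind = TRUE)
  nm <- net$nodes$name
  edges <- data.frame(source = nm[idx[, 1L]], target = nm[idx[, 2L]],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  out <- structure(list(nodes = net$nodes, edges = edges),
                   dropped_nodes = character(),
                   has_positions = attr(net, "has_positions"),
                   class = "geom_network")
  list(network = out,
       report = new_randomization_report("gilbert", seed, e, nrow(edges),
                                         p = p))
}

# internal: weak connectedness of an edge list over a fixed node set
is_weakly_connected <- function(node_names, src, tgt) {
  g <- igraph::graph_from_data_frame(
    data.frame(source = src, target = tgt, stringsAsFactors = FALSE),
    directed = TRUE, vertices = data.frame(name = node_names))
  igraph::is_connected(g, mode = "weak")
}

#' Degree-preserving edge-swap randomization
#'
#' Randomizes connectivity by repeatedly swapping the target nodes of two
#' randomly chosen edges (a Rubinov-Sporns / Maslov-Sneppen rewiring): for
#' edges (a -> b) and (c -> d) with distinct sources and distinct targets,
#' the swap produces (a -> d) and (c -> b), and is applied only when
#' neither new edge already exists and no self-loop would be created. Any
#' swap that breaks weak connectedness is reverted. Each iteration attempts
#' as many swaps as there are edges. Edge count and both degree sequences
#' are preserved exactly.
#'
#' @param net a weakly connected `geom_network`.
#' @param n_iterations number of sweeps; each attempts `|E|` swaps
#'   (default 10).
#' @param seed integer seed (caller's RNG state is left untouched).
#' @param check_connectedness if `TRUE` (default), a disconnected input is
#'   an error and any swap that would break weak connectedness is
#'   reverted; set `FALSE` to rewire fragments or to study the bare swap
#'   rule in isolation.
#' @return A list with `network` and `report` (including
#'   `n_successful_swaps` and `connectedness_preserved`).
#' @export
edge_swap_randomize <- function(net, n_iterations = 10L, seed = 1L,
                                check_connectedness = TRUE) {
  stopifnot(inherits(net, "geom_network"), n_iterations >= 1)
  m <- n_edges(net)
  if (m < 2) stop("need at least 2 edges to swap")
  nm <- net$nodes$name
  if (check_connectedness &&
      !is_weakly_connected(nm, net$edges$source, net$edges$target))
    stop("input network must be weakly connected")
  src <- match(net$edges$source, nm)
  tgt <- match(net$edges$target, nm)
  N <- length(nm)
  exists_m <- matrix(FALSE, N, N)
  exists_m[cbind(src, tgt)] <- TRUE

  n_success <- 0L
  with_local_seed(seed, {
    for (iter in seq_len(n_iterations)) {
      for (attempt in seq_len(m)) {
        pick <- sample.int(m, 2L)
        a <- src[pick[1L]]; b <- tgt[pick[1L]]
        c_ <- src[pick[2L]]; d <- tgt[pick[2L]]
        if (a == c_ || b == d || a == d || c_ == b) next
        if (exists_m[a, d] || exists_m[c_, b]) next
        # apply swap
        exists_m[a, b] <- FALSE; exists_m[c_, d] <- FALSE
        exists_m[a, d] <- TRUE;  exists_m[c_, b] <- TRUE
        tgt[pick[1L]] <- d; tgt[pick[2L]] <- b
        if (check_connectedness &&
            !is_weakly_connected(nm, nm[src], nm[tgt])) {
          # revert
          exists_m[a, d] <- FALSE; exists_m[c_, b] <- FALSE
          exists_m[a, b] <- TRUE;  exists_m[c_, d] <- TRUE
          tgt[pick[1L]] <- b; tgt[pick[2L]] <- d
        } else {
          n_success <- n_success + 1L
        }
      }
    }
  })
  edges <- data.frame(source = nm[src], target = nm[tgt],
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  out <- structure(list(nodes = net$nodes, edges = edges),
                   dropped_nodes = character(),
                   has_positions = attr(net, "has_positions"),
                   class = "geom_network")
  list(network = out,
       report = new_randomization_report(
         "edge_swap", seed, m, nrow(edges),
         n_successful_swaps = n_success,
         connectedness_preserved = if (check_connectedness) TRUE else NA))
}

#' Embed a randomized subnetwork into the full network
#'
#' Substitutes the member-by-member block of the full network's adjacency
#' with a randomized subnetwork's edges: edges with both endpoints among
#' the members are replaced by the subnetwork's edges, while every edge
#' with at least one endpoint outside the member set is preserved, so the
#' full network's connectivity outside the subnetwork is untouched. Node
#' positions, polarities and class labels come from the full network.
#'
#' @param full a `geom_network`.
#' @param randomized_sub a `geom_network` whose node set equals
#'   `member_names`.
#' @param member_names character vector, a subset of `full`'s node names.
#' @return A `geom_network` on `full`'s node set.
#' @export
embed_randomized_subnetwork <- function(full, randomized_sub, member_names) {
  stopifnot(inherits(full, "geom_network"),
            inherits(randomized_sub, "geom_network"))
  member_names <- as.character(member_names)
  if (!all(member_names %in% full$nodes$name))
    stop("member_names must be a subset of the full network's nodes")
  if (!setequal(randomized_sub$nodes$name, member_names))
    stop("randomized_sub's node set must equal member_names")
  inside <- full$edges$source %in% member_names &
            full$edges$target %in% member_names
  edges <- rbind(full$edges[!inside, , drop = FALSE],
                 randomized_sub$edges)
  dup <- duplicated(edge_key(edges$source, edges$target))
  edges <- edges[!dup, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = full$nodes, edges = edges),
            dropped_nodes = character(),
            has_positions = attr(full, "has_positions"),
            class = "geom_network")
}
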