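#' Temporal Sequence
#'
#' A Temporal Sequence (TSeq) is a timed causal walk on the network: the
#' ordered list of (node, step) pairs traced by one quantum of signal from
#' a stimulated start node to an end node. Consecutive entries are joined
#' by network edges and their step differences equal the edge delays.
#'
#' @param nodes character vector of node labels, in activation order.
#' @param steps integer vector of activation steps, strictly increasing,
#'   same length as `nodes`.
#' @return A `tseq` object.
#' @export
tseq <- function(nodes, steps) {
  nodes <- as.character(nodes)
  steps <- as.integer(steps)
  stopifnot(length(nodes) >= 1L, length(nodes) == length(steps))
  if (length(steps) > 1L && any(diff(steps) <= 0L))
    stop("steps must be strictly increasing")
  structure(list(nodes = nodes, steps = steps), class = "tseq")
}

#' @export
print.tseq <- function(x, ...) {
  cat(sprintf("tseq (%d activations): %s\n", length(x$nodes),
              paste0(x$nodes, "@", x$steps, collapse = " -> ")))
  invisible(x)
}

#' @export
format.tseq <- function(x, ...) paste(x$nodes, collapse = ",")

tseq_identity <- function(x, by_labels = FALSE) {
  if (by_labels) paste(x$nodes, collapse = "\r")
  else paste(paste(x$nodes, x$steps, sep = "@"), collapse = "\r")
}

#' Set of Temporal Sequences
#'
#' Collects [tseq()] objects extracted from one simulation, recording the
#' start node and end-node set. Duplicates (identical in both labels and
#' steps, or in labels only when `dedupe_labels` was requested upstream)
#' are removed.
#'
#' @param sequences list of `tseq` objects.
#' @param start_node name of the stimulated start node.
#' @param end_nodes character vector of end-node names.
#' @param dedupe_labels if `TRUE`, sequences are considered identical when
#'   their node-label sequences match, regardless of timing.
#' @return A `tseq_set` (a list of `tseq` with metadata attributes).
#' @export
tseq_set <- function(sequences, start_node = NA_character_,
                     end_nodes = character(), dedupe_labels = FALSE) {
  stopifnot(is.list(sequences))
  ids <- vapply(sequences, tseq_identity, character(1),
                by_labels = dedupe_labels)
  sequences <- sequences[!duplicated(ids)]
  structure(sequences, start_node = start_node, end_nodes = end_nodes,
            dedupe_labels = dedupe_labels, class = "tseq_set")
}

#' @export
print.tseq_set <- function(x, ...) {
  cat(sprintf("tseq_set: %d sequences from %s to {%s}\n", length(x),
              attr(x, "start_node"),
              paste(attr(x, "end_nodes"), collapse = ", ")))
  invisible(x)
}

#' @export
`[.tseq_set` <- function(x, i) {
  tseq_set(unclass(x)[i], attr(x, "start_node"), attr(x, "end_nodes"),
           attr(x, "dedupe_labels"))
}

#' Extract Temporal Sequences from an event log
#'
#' Enumerates, by depth-first traversal of the causal event graph, every
#' causal path from the start node's root (stimulus-driven) events to
#' every activation of a node in the end set. A path that continues past
#' an end node contributes additional, longer sequences ending at later
#' end-node activations. Inhibited (non-emitting) activations can
#' terminate a walk but never continue one, since no signal is emitted
#' past them.
#'
#' @param log an `event_log` from [run_simulation()].
#' @param start_node name of the stimulated start node; it must have a
#'   root event (one with no causal parents) in the log.
#' @param end_nodes character vector of end-node names.
#' @param max_paths hard cap on the number of enumerated sequences; if the
#'   cap is exceeded the function fails loudly rather than truncate
#'   silently (causal path counts can grow combinatorially on cyclic
#'   networks).
#' @param dedupe_labels if `TRUE`, sequences tracing the same node labels
#'   at different times are collapsed; by default identity is the pair
#'   (label sequence, step sequence).
#' @return A `tseq_set`.
#' @export
extract_tseqs <- function(log, start_node, end_nodes, max_paths = 1e6,
                          dedupe_labels = FALSE) {
  stopifnot(inherits(log, "event_log"))
  end_nodes <- as.character(end_nodes)
  n_ev <- nrow(log)
  roots <- which(log$node == start_node &
                 lengths(log$parents) == 0L)
  if (!length(roots))
    stop("start node '", start_node, "' has no root event in the log")

  # children adjacency of the causal event DAG
  kids <- vector("list", n_ev)
  for (e in seq_len(n_ev)) {
    for (p in log$parents[[e]]) kids[[p]] <- c(kids[[p]], e)
  }
  is_end <- log$node %in% end_nodes

  results <- vector("list", 256L)
  n_res <- 0L
  record <- function(path) {
    n_res <<- n_res + 1L
    if (n_res > max_paths)
      stop("path explosion: more than ", max_paths,
           " temporal sequences; raise max_paths to proceed")
    if (n_res > length(results))
      length(results) <<- 2L * length(results)
    results[[n_res]] <<- path
  }

  for (root in roots) {
    path <- root
    stack_children <- list(kids[[root]])
    stack_idx <- 0L
    if (is_end[root]) record(path)
    depth <- 1L
    while (depth > 0L) {
      i <- stack_idx[depth] + 1L
      ch <- stack_children[[depth]]
      if (i > length(ch)) {
        depth <- depth - 1L
        path <- path[-length(path)]
        next
      }
      stack_idx[depth] <- i
      e <- ch[i]
      path <- c(path, e)
      if (is_end[e]) record(path)
      depth <- depth + 1L
      stack_children[depth] <- list(kids[[e]])   # list() guards NULL
      stack_idx[depth] <- 0L
    }
  }

  seqs <- lapply(results[seq_len(n_res)], function(p)
    tseq(log$node[p], log$step[p]))
  tseq_set(seqs, start_node = start_node, end_nodes = end_nodes,
           dedupe_labels = dedupe_labels)
}

as_label_vector <- function(x) {
  if (inherits(x, "tseq")) x$nodes else as.character(x)
}

#' Greedy in-order match fraction between two sequences
#'
#' The pairwise core of the Temporal Sequence similarity measure: the node
#' labels of the reference sequence `x` are matched greedily, in order,
#' against the comparison sequence `y`. A cursor scans `y` left to right;
#' each successive label of `x` advances the cursor to its first later
#' occurrence in `y` (if any), counting a match and moving past it. The
#' returned fraction is `matches / length(x)`; the measure is asymmetric
#' in its arguments by construction.
#'
#' @param x,y `tseq` objects or character label vectors; non-empty.
#' @return A fraction in `[0, 1]`; `1` means every label of `x` was found
#'   in order in `y` (e.g., 4 of 5 labels found in order gives 0.8).
#' @export
pairwise_match_fraction <- function(x, y) {
  xl <- as_label_vector(x); yl <- as_label_vector(y)
  if (!length(xl) || !length(yl)) stop("sequences must be non-empty")
  ny <- length(yl)
  cursor <- 1L
  count <- 0L
  for (u in xl) {
    if (cursor > ny) break
    hit <- which(yl[cursor:ny] == u)
    if (length(hit)) {
      count <- count + 1L
      cursor <- cursor + hit[1L]   # move past the matched position
    }
  }
  count / length(xl)
}

#' Count reference sequences meeting a similarity threshold
#'
#' For each reference sequence `x` in `X`, evaluates the greedy match
#' fraction against every `y` in `Y` and counts `x` when the best match
#' meets the threshold `alpha`. Iteration over `Y` exits early once the
#' threshold is met (the count is unchanged by the shortcut).
#'
#' @param X reference `tseq_set` (non-empty).
#' @param Y comparison `tseq_set`.
#' @param alpha threshold in `[0, 1]`.
#' @return The count `c_alpha` of reference sequences meeting the
#'   threshold; `c_0 = |X|` whenever `Y` is non-empty.
#' @export
similarity_count <- function(X, Y, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (!length(X)) stop("reference set X must be non-empty")
  count <- 0L
  for (x in X) {
    best <- 0
    for (y in Y) {
      f <- pairwise_match_fraction(x, y)
      if (f > best) best <- f
      if (best >= alpha) break
    }
    if (best >= alpha) count <- count + 1L
  }
  count
}

#' Similarity table over a threshold grid
#'
#' Tabulates [similarity_count()] over a grid of thresholds, producing the
#' percent-match table used to compare Temporal Sequence sets across
#' networks. Counts are non-increasing in the threshold and the zero
#' threshold row always equals the reference set size.
#'
#' @param X reference `tseq_set`.
#' @param Y comparison `tseq_set`.
#' @param alphas ascending thresholds (default `c(0, .25, .5, .75, 1)`).
#' @return A `similarity_table`: data.frame with columns `alpha`, `count`,
#'   `ref_size`, `cmp_size`.
#' @export
similarity_table <- function(X, Y, alphas = c(0, 0.25, 0.5, 0.75, 1)) {
  stopifnot(!is.unsorted(alphas))
  counts <- vapply(alphas, function(a) similarity_count(X, Y, a), integer(1))
  structure(data.frame(alpha = alphas, count = counts,
                       ref_size = length(X), cmp_size = length(Y)),
            class = c("similarity_table", "data.frame"))
}

# internal: one left-to-right tandem-collapse pass over a label vector.
# Returns a list of units: list(block = <labels>, count = <int>).
# Smallest block period wins at each position; scanning is leftmost-first.
compress_once <- function(s) {
  units <- list()
  lit <- character(0)
  flush_lit <- function() {
    if (length(lit)) {
      units[[length(units) + 1L]] <<- list(block = lit, count = 1L)
      lit <<- character(0)
    }
  }
  i <- 1L
  n <- length(s)
  while (i <= n) {
    found <- NULL
    maxL <- (n - i + 1L) %/% 2L
    for (L in seq_len(maxL)) {
      block <- s[i:(i + L - 1L)]
      k <- 1L
      while (i + (k + 1L) * L - 1L <= n &&
             identical(s[(i + k * L):(i + (k + 1L) * L - 1L)], block))
        k <- k + 1L
      if (k >= 2L) { found <- list(block = block, k = k, L = L); break }
    }
    if (is.null(found)) {
      lit <- c(lit, s[i])
      i <- i + 1L
    } else {
      flush_lit()
      units[[length(units) + 1L]] <-
        list(block = found$block, count = found$k)
      i <- i + found$k * found$L
    }
  }
  flush_lit()
  units
}

expand_units <- function(units, counts = NULL) {
  rep_units <- which(vapply(units, function(u) u$count, integer(1)) >= 2L)
  if (!is.null(counts)) {
    if (length(counts) != length(rep_units))
      stop("need exactly one repetition count per repeated unit")
    if (any(counts < 1L)) stop("repetition counts must be positive")
  }
  out <- character(0)
  j <- 0L
  for (u in units) {
    k <- u$count
    if (u$count >= 2L && !is.null(counts)) {
      j <- j + 1L
      k <- counts[j]
    }
    out <- c(out, rep(u$block, k))
  }
  out
}

#' Compress a sequence by collapsing tandem repeats
#'
#' Scans the label sequence left to right and collapses every maximal
#' tandem repeat (two or more contiguous copies of a block) into a
#' (primitive block, repetition count) unit, preferring the smallest block
#' period and the leftmost occurrence so the result is unique. Expanding
#' the units with their stored counts reproduces the original labels
#' exactly. The canonical form is obtained by setting every repetition
#' count to one and re-collapsing until a fixed point, so sequences that
#' differ only in how many times a signal circulated a cycle share one
#' canonical form.
#'
#' @param x a `tseq` or character label vector.
#' @return A `compressed_tseq`: list with `units` (each
#'   `list(block, count)`), `canonical` (the fully collapsed label
#'   vector) and `labels` (the original labels).
#' @examples
#' canonicalize(c("A", "B", "A", "B", "C"))$canonical  # "A" "B" "C"
#' @export
canonicalize <- function(x) {
  s <- as_label_vector(x)
  if (!length(s)) stop("sequence must be non-empty")
  units <- compress_once(s)
  # iterate count-1 expansion + collapse to a fixed point for the
  # canonical (grouping) form; the first-pass units keep the exact
  # expansion invariant for recompose()
  canon <- expand_units(lapply(units, function(u)
    list(block = u$block, count = 1L)))
  repeat {
    nxt <- expand_units(lapply(compress_once(canon), function(u)
      list(block = u$block, count = 1L)))
    if (identical(nxt, canon)) break
    canon <- nxt
  }
  structure(list(units = units, canonical = canon, labels = s),
            class = "compressed_tseq")
}

#' @export
print.compressed_tseq <- function(x, ...) {
  parts <- vapply(x$units, function(u) {
    b <- paste(u$block, collapse = ",")
    if (u$count >= 2L) sprintf("(%s)^%d", b, u$count) else b
  }, character(1))
  cat("compressed_tseq:", paste(parts, collapse = " "), "\n")
  cat("  canonical:", paste(x$canonical, collapse = ","), "\n")
  invisible(x)
}

#' Re-expand a compressed sequence
#'
#' Expands a [canonicalize()] result back into a label sequence, using
#' either the stored repetition counts (the exact inverse of compression)
#' or caller-supplied counts, one per repeated unit.
#'
#' @param compressed a `compressed_tseq`.
#' @param repetitions optional positive integer vector, one entry per
#'   repeated unit (units with stored count >= 2); defaults to the stored
#'   counts.
#' @return Character label vector.
#' @export
recompose <- function(compressed, repetitions = NULL) {
  stopifnot(inherits(compressed, "compressed_tseq"))
  expand_units(compressed$units,
               if (is.null(repetitions)) NULL else as.integer(repetitions))
}

#' Decompose a Temporal Sequence set into basis sequences
#'
#' Splits a set of Temporal Sequences into One-Time sequences and
#' Repeating groups. Members are grouped by the canonical (repeat-
#' collapsed) form of their node labels: a group of two or more sequences
#' that differ only in repetition counts of primitive sub-sequences (a
#' signal circulating a graph cycle a different number of times) is a
#' Repeating group, represented in the basis by its shortest member's
#' compressed form. Sequences whose canonical form matches no other
#' sequence are One-Time. Timing is ignored for membership: repetition is
#' defined over node sub-sequences.
#'
#' @param X a non-empty `tseq_set`.
#' @return A `basis_decomposition`: list with `one_time` (list of `tseq`),
#'   `repeating_groups` (list of `list(canonical, members, compressed,
#'   representative)`), and counts `n_one_time`, `n_repeating` (number of
#'   groups), `n_sequences`. One-Time and Repeating members partition `X`.
#' @export
decompose_basis <- function(X) {
  if (!length(X)) stop("X must be non-empty")
  comp <- lapply(X, canonicalize)
  keys <- vapply(comp, function(cc) paste(cc$canonical, collapse = "\r"),
                 character(1))
  groups <- split(seq_along(X), keys)
  sizes <- lengths(groups)
  one_time_idx <- sort(unlist(groups[sizes == 1L], use.names = FALSE))
  rep_groups <- groups[sizes >= 2L]
  repeating <- lapply(rep_groups, function(ix) {
    lens <- vapply(ix, function(i) length(X[[i]]$nodes), integer(1))
    rep_i <- ix[which.min(lens)]
    list(canonical = comp[[rep_i]]$canonical,
         members = unclass(X)[ix],
         compressed = comp[ix],
         representative = comp[[rep_i]])
  })
  names(repeating) <- vapply(repeating, function(g)
    paste(g$canonical, collapse = ","), character(1))
  structure(list(one_time = unclass(X)[one_time_idx],
                 repeating_groups = repeating,
                 n_one_time = length(one_time_idx),
                 n_repeating = length(repeating),
                 n_sequences = length(X)),
            class = "basis_decomposition")
}

#' @export
print.basis_decomposition <- function(x, ...) {
  cat(sprintf(paste0("basis_decomposition: %d sequences -> %d one-time, ",
                     "%d repeating group(s)\n"),
              x$n_sequences, x$n_one_time, x$n_repeating))
  invisible(x)
}

#' Count class interactions within Temporal Sequences
#'
#' For every k-subset of the given node classes, counts the Temporal
#' Sequences that contain at least one node of every class in the subset
#' (unordered containment; a sequence may count toward many subsets).
#' Used to quantify which motorneuron classes co-occur along signaling
#' paths.
#'
#' @param X a `tseq_set`.
#' @param class_map named character vector mapping node name to class, or
#'   a `geom_network` whose class labels are used.
#' @param classes character vector of classes under consideration.
#' @param k subset size, `1 <= k <= length(classes)`.
#' @return data.frame with columns `subset` (classes joined by `+`) and
#'   `count`, one row per k-subset.
#' @export
class_interaction_counts <- function(X, class_map, classes, k) {
  if (inherits(class_map, "geom_network"))
    class_map <- stats::setNames(class_map$nodes$class,
                                 class_map$nodes$name)
  classes <- as.character(classes)
  stopifnot(k >= 1, k <= length(classes))
  unknown <- setdiff(classes, class_map)
  if (length(unknown))
    stop("unknown class(es): ", paste(unknown, collapse = ", "))
  seq_classes <- lapply(X, function(x) {
    cl <- unique(class_map[x$nodes])
    cl[!is.na(cl)]
  })
  subsets <- utils::combn(sort(classes), k, simplify = FALSE)
  counts <- vapply(subsets, function(S)
    sum(vapply(seq_classes, function(cl) all(S %in% cl), logical(1))),
    integer(1))
  data.frame(subset = vapply(subsets, paste, character(1), collapse = "+"),
             count = counts, stringsAsFactors = FALSE)
}
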