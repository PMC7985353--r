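# Shared builders for small test networks and randomized toy event logs.

simple_nodes <- function(names, polarity = "E", x = NULL, class = NULL) {
  df <- data.frame(name = names,
                   polarity = rep(polarity, length.out = length(names)),
                   stringsAsFactors = FALSE)
  if (!is.null(x)) {
    df$x_um <- x; df$y_um <- 0; df$z_um <- 0
  }
  if (!is.null(class)) df$class <- class
  df
}

simple_net <- function(src, tgt, names = NULL, polarity = "E", x = NULL,
                       class = NULL) {
  if (is.null(names)) names <- sort(unique(c(src, tgt)))
  build_network(data.frame(source = src, target = tgt,
                           stringsAsFactors = FALSE),
                simple_nodes(names, polarity, x, class))
}

# A random small directed network with explicit small integer delays and a
# short horizon: enough structure (branching, cycles, inhibition) to
# exercise the simulator and sequence extraction while keeping exhaustive
# path enumeration cheap.
random_toy_log <- function(seed, n = 8L, p = 0.22, n_steps = 40L,
                           frac_inhibitory = 0.15) {
  set.seed(seed)
  nm <- paste0("n", seq_len(n))
  adj <- matrix(runif(n * n) <= p, n, n)
  diag(adj) <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  pol <- ifelse(runif(n) < frac_inhibitory, "I", "E")
  net <- build_network(
    data.frame(source = nm[idx[, 1L]], target = nm[idx[, 2L]],
               stringsAsFactors = FALSE),
    data.frame(name = nm, polarity = pol, stringsAsFactors = FALSE))
  delays <- delay_assignment(net, sample(1:5, n_edges(net), replace = TRUE))
  params <- signaling_params(velocity_mm_s = 1,
                             refractory_s = sample(2:4, 1L),
                             dt_s = 1, n_steps = n_steps)
  start <- nm[1L]
  log <- run_simulation(net, delays, params, stimulus(start, 0L))
  list(net = net, delays = delays, params = params, log = log,
       start = start, nodes = nm)
}

expect_same_tseq_set <- function(X, Y) {
  idx <- function(S) sort(vapply(S, function(x)
    paste(paste(x$nodes, x$steps, sep = "@"), collapse = ">"), character(1)))
  expect_identical(idx(X), idx(Y))
}
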