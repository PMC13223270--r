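#' Network topologies
#'
#' A `network_topology` stores a directed graph as an edge list together with
#' per-neuron excitatory/inhibitory labels and optional spatial positions.
#' The directionality convention is `pre -> post`: an edge (j, i) means j is
#' presynaptic to i (adjacency entry M_ij = 1). Self-connections are
#' forbidden.
#'
#' @param n number of neurons
#' @param pre,post integer edge endpoints (1-based neuron ids)
#' @param is_excitatory logical label per neuron
#' @param positions optional numeric matrix (n rows) of coordinates (um)
#' @param p connection probability used to build the graph (metadata)
#' @param seed RNG seed used to build the graph (metadata)
#' @return an object of class `network_topology`
#' @export
network_topology <- function(n, pre, post, is_excitatory, positions = NULL,
                             p = NA_real_, seed = NA_integer_) {
  n <- as.integer(n)
  pre <- as.integer(pre)
  post <- as.integer(post)
  if (n < 1L) stop_param("`n` must be at least 1")
  if (length(pre) != length(post))
    stop_param("`pre` and `post` must have equal length")
  if (length(is_excitatory) != n)
    stop_param("`is_excitatory` must have exactly n entries")
  if (length(pre) && (min(pre, post) < 1L || max(pre, post) > n))
    stop_param("edge indices out of range [1, n]")
  if (any(pre == post))
    stop_param("self-connections are not allowed")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != n)
      stop_param("`positions` must have one row per neuron")
  }
  out <- list(n = n, pre = pre, post = post,
              is_excitatory = as.logical(is_excitatory),
              positions = positions, p = p, seed = seed)
  class(out) <- "network_topology"
  out
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf("network_topology: %d neurons (%d excitatory, %d inhibitory), %d edges\n",
              x$n, sum(x$is_excitatory), sum(!x$is_excitatory), length(x$pre)))
  if (!is.null(x$positions))
    cat(sprintf("  positions: %d-D coordinates\n", ncol(x$positions)))
  invisible(x)
}

# edge draws with the RNG already seeded by the caller
er_edges <- function(n, p) {
  if (p <= 0 || n < 2L) return(list(pre = integer(0), post = integer(0)))
  npairs <- as.double(n) * (n - 1)
  m <- rbinom(1L, npairs, p)
  idx <- sort(sample(npairs, m)) - 1
  j <- floor(idx / (n - 1))
  r <- idx - j * (n - 1)
  i <- r + (r >= j)
  list(pre = as.integer(j + 1), post = as.integer(i + 1))
}

ei_labels <- function(n, frac_excitatory) {
  lab <- rep(FALSE, n)
  k <- round(n * frac_excitatory)
  if (k > 0) lab[sample.int(n, k)] <- TRUE
  lab
}

#' Build an Erdős–Rényi network with excitatory/inhibitory labels
#'
#' Each ordered pair (j, i), j != i, is connected independently with
#' probability `p`; exactly `round(n * frac_excitatory)` neurons are labelled
#' excitatory. Reproducible for a fixed seed.
#'
#' @param n number of neurons
#' @param p connection probability
#' @param frac_excitatory fraction of excitatory neurons
#' @param seed RNG seed
#' @return a [network_topology()]
#' @export
build_er_topology <- function(n, p, frac_excitatory = 0.8, seed = 1) {
  check_fraction(p, "p")
  check_fraction(frac_excitatory, "frac_excitatory")
  if (n < 1) stop_param("`n` must be at least 1")
  with_seed(seed, {
    e <- er_edges(n, p)
    lab <- ei_labels(n, frac_excitatory)
    network_topology(n, e$pre, e$post, lab, p = p, seed = as.integer(seed))
  })
}

#' Toy spatial connectome: random graph with uniform random positions
#'
#' An Erdős–Rényi graph whose neurons additionally receive independent
#' uniform positions inside a rectangular box, supporting radius-based
#' stimulation-target selection as used for spatially embedded networks.
#'
#' @inheritParams build_er_topology
#' @param box box edge lengths (um); a scalar is recycled to 3 dimensions
#' @return a [network_topology()] with a `positions` matrix
#' @export
toy_spatial_connectome <- function(n, box = 200, p = 0.1,
                                   frac_excitatory = 0.8, seed = 1) {
  check_fraction(p, "p")
  check_fraction(frac_excitatory, "frac_excitatory")
  if (length(box) == 1L) box <- rep(box, 3L)
  if (any(box <= 0)) stop_param("`box` lengths must be positive")
  with_seed(seed, {
    e <- er_edges(n, p)
    lab <- ei_labels(n, frac_excitatory)
    pos <- vapply(box, function(b) runif(n, 0, b), numeric(n))
    if (n == 1L) pos <- matrix(pos, nrow = 1L)
    colnames(pos) <- c("x", "y", "z")[seq_along(box)]
    network_topology(n, e$pre, e$post, lab, positions = pos,
                     p = p, seed = as.integer(seed))
  })
}

#' Save / load a topology as a plain-text table
#'
#' The file is a TSV with one `node` line per neuron
#' (`node <id> <ei> [<x> <y> <z>]`, `ei` 1 for excitatory) followed by one
#' `edge` line per connection (`edge <pre> <post>`, presynaptic first).
#' Indices in the file are 0-based; positions are written in full precision so
#' a save/load/save cycle is byte-identical.
#'
#' @param topology a [network_topology()]
#' @param path file path
#' @return `load_topology` returns a [network_topology()];
#'   `save_topology` returns `path` invisibly.
#' @export
save_topology <- function(topology, path) {
  stopifnot(inherits(topology, "network_topology"))
  hdr <- "# silencenet topology v1"
  pos <- topology$positions
  nodes <- vapply(seq_len(topology$n), function(i) {
    base <- sprintf("node\t%d\t%d", i - 1L, as.integer(topology$is_excitatory[i]))
    if (is.null(pos)) base
    else paste(base, paste(fmt_num(pos[i, ]), collapse = "\t"), sep = "\t")
  }, character(1))
  edges <- sprintf("edge\t%d\t%d", topology$pre - 1L, topology$post - 1L)
  writeLines(c(hdr, nodes, edges), path)
  invisible(path)
}

#' @rdname save_topology
#' @export
load_topology <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kind <- vapply(parts, `[[`, character(1), 1L)
  nodep <- parts[kind == "node"]
  edgep <- parts[kind == "edge"]
  if (!length(nodep)) stop_param("topology file has no node lines")
  ids <- vapply(nodep, function(x) as.integer(x[2]), integer(1))
  n <- length(ids)
  if (!setequal(ids, 0:(n - 1)))
    stop_param("node ids must be 0..n-1")
  ord <- order(ids)
  lab <- vapply(nodep, function(x) as.integer(x[3]) == 1L, logical(1))[ord]
  npos <- length(nodep[[1]]) - 3L
  pos <- NULL
  if (npos > 0) {
    pos <- t(vapply(nodep, function(x) as.numeric(x[-(1:3)]), numeric(npos)))
    pos <- pos[ord, , drop = FALSE]
    colnames(pos) <- c("x", "y", "z")[seq_len(npos)]
  }
  pre <- post <- integer(0)
  if (length(edgep)) {
    pre <- vapply(edgep, function(x) as.integer(x[2]), integer(1)) + 1L
    post <- vapply(edgep, function(x) as.integer(x[3]), integer(1)) + 1L
    if (anyNA(pre) || anyNA(post)) stop_param("non-numeric edge entry")
    if (min(pre, post) < 1L || max(pre, post) > n)
      stop_param("edge index out of range in file")
    if (any(pre == post)) stop_param("self-connection found in file")
  }
  network_topology(n, pre, post, lab, positions = pos)
}
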