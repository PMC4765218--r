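#' Build a participant communication network
#'
#' Aggregates a communication log (one row per interaction, with the
#' initiating and receiving participant) into a directed weighted network:
#' nodes are participants, a tie's weight is the number of interactions in
#' that direction. Self-loops are dropped unless requested.
#'
#' @param records Tibble with columns `source` and `target` (and
#'   optionally `timestamp`, `subprocess`, ...).
#' @param subprocess If given and `records` has a `subprocess` column,
#'   restrict to that sub-process (e.g. separate contract and budget
#'   networks).
#' @param allow_self_loops Keep source == target records?
#' @return A `comm_network`: `ties` tibble (source, target, weight),
#'   `nodes`, and the underlying directed weighted `igraph` graph.
#' @examples
#' net <- build_network(tibble::tibble(source = c("PI", "PI", "PI"),
#'                                     target = "OCR"))
#' net$ties
#' @export
build_network <- function(records, subprocess = NULL,
                          allow_self_loops = FALSE) {
  records <- as_tibble(records)
  if (!all(c("source", "target") %in% names(records)))
    abort("`records` needs columns source and target.",
          class = "trialflow_error_bad_log")
  if (!is.null(subprocess) && "subprocess" %in% names(records))
    records <- dplyr::filter(records, .data$subprocess == !!subprocess)
  if (nrow(records) > 0 &&
      (any(!nzchar(records$source)) || any(!nzchar(records$target)) ||
       anyNA(records$source) || anyNA(records$target)))
    abort("Participants must be non-empty strings.",
          class = "trialflow_error_bad_log")
  if (!allow_self_loops)
    records <- dplyr::filter(records, .data$source != .data$target)
  ties <- records |>
    dplyr::count(.data$source, .data$target, name = "weight") |>
    dplyr::arrange(.data$source, .data$target)
  nodes <- sort(unique(c(ties$source, ties$target)))
  g <- if (nrow(ties) > 0)
    igraph::graph_from_data_frame(ties, directed = TRUE,
                                  vertices = data.frame(name = nodes))
  else igraph::make_empty_graph(directed = TRUE)
  structure(list(ties = ties, nodes = nodes, graph = g),
            class = "comm_network")
}

#' @export
print.comm_network <- function(x, ...) {
  cat("<comm_network> ", length(x$nodes), " participants, ",
      nrow(x$ties), " directed ties, total weight ",
      sum(x$ties$weight), "\n", sep = "")
  invisible(x)
}

#' Degree centrality
#'
#' In- and out-degree count distinct alters (binary ties); the weighted
#' variant sums interaction counts instead.
#'
#' @param net A [build_network()] result.
#' @param weighted Sum tie weights instead of counting alters?
#' @return Tibble: `participant`, `in_degree`, `out_degree`.
#' @export
degree_centrality <- function(net, weighted = FALSE) {
  stopifnot(inherits(net, "comm_network"))
  if (length(net$nodes) == 0)
    return(tibble(participant = character(), in_degree = numeric(),
                  out_degree = numeric()))
  g <- net$graph
  if (weighted) {
    ind <- igraph::strength(g, mode = "in")
    outd <- igraph::strength(g, mode = "out")
  } else {
    ind <- igraph::degree(g, mode = "in")
    outd <- igraph::degree(g, mode = "out")
  }
  tibble(participant = igraph::V(g)$name,
         in_degree = as.numeric(ind), out_degree = as.numeric(outd))
}

#' Closeness centrality
#'
#' Geodesic distances are taken on the binarised digraph (weights are
#' interaction counts, not lengths, so they are ignored for paths).
#' Because communication networks need not be strongly connected the
#' default is harmonic closeness -- the sum of reciprocal distances, with
#' unreachable pairs contributing zero. `method = "freeman"` gives the
#' classic reciprocal-of-total-distance closeness, computed by igraph over
#' reachable vertices only.
#'
#' @param net A [build_network()] result.
#' @param method `"harmonic"` (default) or `"freeman"`.
#' @return Tibble: `participant`, `in_closeness`, `out_closeness`.
#' @export
closeness_centrality <- function(net, method = c("harmonic", "freeman")) {
  stopifnot(inherits(net, "comm_network"))
  method <- match.arg(method)
  if (length(net$nodes) == 0)
    return(tibble(participant = character(), in_closeness = numeric(),
                  out_closeness = numeric()))
  g <- net$graph
  if (method == "harmonic") {
    ic <- igraph::harmonic_centrality(g, mode = "in", weights = NA)
    oc <- igraph::harmonic_centrality(g, mode = "out", weights = NA)
  } else {
    ic <- suppressWarnings(igraph::closeness(g, mode = "in", weights = NA))
    oc <- suppressWarnings(igraph::closeness(g, mode = "out", weights = NA))
  }
  tibble(participant = igraph::V(g)$name,
         in_closeness = as.numeric(ic), out_closeness = as.numeric(oc))
}

#' Betweenness centrality
#'
#' Directed geodesic betweenness on the binarised digraph:
#' \eqn{\sum_{s \ne t \ne v} \sigma_{st}(v)/\sigma_{st}}.
#'
#' @param net A [build_network()] result.
#' @return Tibble: `participant`, `betweenness`.
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "comm_network"))
  if (length(net$nodes) == 0)
    return(tibble(participant = character(), betweenness = numeric()))
  b <- igraph::betweenness(net$graph, directed = TRUE, weights = NA)
  tibble(participant = igraph::V(net$graph)$name,
         betweenness = as.numeric(b))
}

symmetrized_adjacency <- function(net) {
  g <- igraph::as_undirected(net$graph, mode = "collapse")
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  A[A > 0] <- 1
  A
}

#' Bonacich power centrality
#'
#' \eqn{c(\beta) = \alpha (I - \beta A)^{-1} A \mathbf{1}} on the
#' symmetrised binary adjacency, with \eqn{\alpha} scaled so that
#' \eqn{\sum c^2 = n}. A negative \eqn{\beta} (the default,
#' \eqn{-0.75/\lambda_{max}}) rewards being connected to participants who
#' are themselves poorly connected -- the "power" reading. Requires
#' \eqn{|\beta| < 1/\lambda_{max}} for the series to converge. At
#' \eqn{\beta = 0} the index reduces to degree up to scaling.
#'
#' @param net A [build_network()] result.
#' @param beta Attenuation parameter; default `-0.75 / lambda_max`.
#' @return Tibble: `participant`, `bonacich_power`, with the `beta` used
#'   as an attribute.
#' @export
bonacich_power <- function(net, beta = NULL) {
  stopifnot(inherits(net, "comm_network"))
  if (length(net$nodes) == 0)
    return(tibble(participant = character(), bonacich_power = numeric()))
  A <- symmetrized_adjacency(net)
  lmax <- max(abs(eigen(A, only.values = TRUE)$values))
  if (is.null(beta)) beta <- if (lmax > 0) -0.75 / lmax else 0
  if (lmax > 0 && abs(beta) >= 1 / lmax)
    abort("`beta` must satisfy |beta| < 1/lambda_max for convergence.",
          class = "trialflow_error_nonconvergent_beta")
  g <- igraph::as_undirected(net$graph, mode = "collapse")
  p <- igraph::power_centrality(g, exponent = beta)
  out <- tibble(participant = igraph::V(g)$name,
                bonacich_power = as.numeric(p))
  attr(out, "beta") <- beta
  out
}

#' Full centrality report
#'
#' Joins the four centrality families into one table per participant.
#'
#' @param net A [build_network()] result.
#' @param beta Passed to [bonacich_power()].
#' @param closeness_method Passed to [closeness_centrality()].
#' @return Tibble with in/out degree, betweenness, in/out closeness and
#'   Bonacich power per participant.
#' @export
centrality_report <- function(net, beta = NULL,
                              closeness_method = "harmonic") {
  degree_centrality(net) |>
    dplyr::left_join(betweenness_centrality(net), by = "participant") |>
    dplyr::left_join(closeness_centrality(net, closeness_method),
                     by = "participant") |>
    dplyr::left_join(bonacich_power(net, beta), by = "participant")
}

#' Export a communication network
#'
#' `write_edge_list()` writes the weighted edge list as CSV;
#' `write_graphml()` writes GraphML via igraph.
#'
#' @param net A [build_network()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "comm_network"))
  readr::write_csv(net$ties, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "comm_network"))
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' Read a communication log CSV
#'
#' @param path CSV with at least `source` and `target` columns.
#' @return A tibble.
#' @export
read_communication_log <- function(path) {
  if (!file.exists(path))
    abort(paste0("No such file: ", path), class = "trialflow_error_io")
  readr::read_csv(path, show_col_types = FALSE)
}

#' @export
autoplot.comm_network <- function(object, ...) {
  g <- object$graph
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble(participant = igraph::V(g)$name,
                  x = lay[, 1], y = lay[, 2])
  edges <- object$ties |>
    dplyr::left_join(nodes, by = c(source = "participant")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(nodes, by = c(target = "participant"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x, yend = .data$y,
                                       linewidth = .data$weight),
                          colour = "grey60",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y,
                                    label = .data$participant),
                       vjust = -1) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::theme_void() +
    ggplot2::labs(linewidth = "interactions")
}
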