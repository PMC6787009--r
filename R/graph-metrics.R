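#' Node degree and betweenness centrality across subjects
#'
#' For each subject's binarised network: degree (row sums of the
#' adjacency) and betweenness centrality of the unweighted graph (fraction
#' of all shortest paths passing through each node, endpoints excluded,
#' all shortest paths counted with multiplicity, disconnected pairs
#' contributing nothing), normalised by (n-1)(n-2)/2 so values lie in
#' [0, 1]; the raw path counts are reported alongside.  The group result
#' is the per-node median across subjects, with range / median /
#' interquartile summaries of the group node distributions.
#'
#' @param adjacencies list of square symmetric binary matrices with zero
#'   diagonal ([Connectome-class] objects are binarised via [adjacency()]).
#' @return list with `perSubject` (data.frames of node, degree,
#'   betweenness, betweennessRaw), `groupMedian` (per-node medians) and
#'   `summary` (max, min, median, q25, q75 of the group-median degree and
#'   betweenness distributions).
#' @export
graphMetrics <- function(adjacencies) {
  mats <- lapply(adjacencies, function(a) {
    if (is(a, "Connectome")) a <- adjacency(a)
    a <- unname(as.matrix(a)) + 0
    if (nrow(a) != ncol(a) || max(abs(a - t(a))) > 0 || any(diag(a) != 0))
      stop("adjacency must be square, symmetric, with zero diagonal",
           call. = FALSE)
    a
  })
  n <- nrow(mats[[1]])
  nodeNames <- if (is(adjacencies[[1]], "Connectome"))
    adjacencies[[1]]@roiNames
  else rownames(as.matrix(adjacencies[[1]])) %||%
    sprintf("node%02d", seq_len(n))
  norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  perSubject <- lapply(mats, function(a) {
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    raw <- igraph::betweenness(g, directed = FALSE, weights = NA)
    data.frame(node = nodeNames, degree = rowSums(a),
               betweenness = raw / norm, betweennessRaw = raw)
  })
  deg <- vapply(perSubject, function(x) x$degree, numeric(n))
  btw <- vapply(perSubject, function(x) x$betweenness, numeric(n))
  groupMedian <- data.frame(node = nodeNames,
                            degree = rowMedians_(deg),
                            betweenness = rowMedians_(btw))
  summ <- function(x) c(max = max(x), min = min(x),
                        median = stats::median(x),
                        q25 = pctl(x, 0.25), q75 = pctl(x, 0.75))
  list(perSubject = perSubject, groupMedian = groupMedian,
       summary = rbind(degree = summ(groupMedian$degree),
                       betweenness = summ(groupMedian$betweenness)))
}
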