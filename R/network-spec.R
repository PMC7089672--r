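#' Candidate-network specification
#'
#' Describes a regulatory network hypothesis: the node set, signed edges
#' (activations and inhibitions), and optionally pairs of regulators that act
#' multiplicatively on a target through complex formation (e.g. a protein
#' heterodimer binding a promoter).
#'
#' @param nodes character vector of node identifiers.
#' @param edges data frame with columns `regulator`, `target`, `sign`
#'   (`"activator"` or `"inhibitor"`). May have zero rows.
#' @param complexes optional data frame with columns `regulator_a`,
#'   `regulator_b`, `target`, `sign_a`, `sign_b` declaring multiplicative
#'   regulator pairs.
#' @return An object of class `sm_network`.
#' @export
network_spec <- function(nodes, edges = NULL, complexes = NULL) {
  nodes <- as.character(nodes)
  if (is.null(edges))
    edges <- data.frame(regulator = character(), target = character(),
                        sign = character(), stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("regulator", "target", "sign") %in% names(edges)))
  if (anyDuplicated(edges[c("regulator", "target")]))
    stop("duplicate (regulator, target) pair in edge list")
  if (!all(edges$regulator %in% nodes) || !all(edges$target %in% nodes))
    stop("edge references a node not in `nodes`")
  if (nrow(edges) && !all(edges$sign %in% c("activator", "inhibitor")))
    stop("edge sign must be 'activator' or 'inhibitor'")
  if (!is.null(complexes)) {
    complexes <- as.data.frame(complexes, stringsAsFactors = FALSE)
    need <- c("regulator_a", "regulator_b", "target", "sign_a", "sign_b")
    stopifnot(all(need %in% names(complexes)))
    refs <- unlist(complexes[c("regulator_a", "regulator_b", "target")])
    if (!all(refs %in% nodes))
      stop("complex pair references a node not in `nodes`")
  }
  structure(list(nodes = nodes, edges = edges, complexes = complexes),
            class = "sm_network")
}

#' @export
print.sm_network <- function(x, ...) {
  cat("<sm_network> ", length(x$nodes), " nodes, ", nrow(x$edges), " edges",
      if (!is.null(x$complexes)) paste0(", ", nrow(x$complexes), " complex pair(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Read / write a network specification (YAML)
#'
#' The on-disk format is a small YAML document with keys `nodes`, `edges`
#' (list of `[regulator, target, sign]` triples) and optional `complexes`
#' (list of `[regulator_a, regulator_b, target, sign_a, sign_b]`).
#'
#' @param path file path.
#' @return [read_network_spec()] returns an `sm_network`;
#'   [write_network_spec()] returns the path invisibly.
#' @export
read_network_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- yaml::read_yaml(path)
  edges <- NULL
  if (length(doc$edges)) {
    edges <- do.call(rbind, lapply(doc$edges, function(e)
      data.frame(regulator = e[[1]], target = e[[2]], sign = e[[3]],
                 stringsAsFactors = FALSE)))
  }
  complexes <- NULL
  if (length(doc$complexes)) {
    complexes <- do.call(rbind, lapply(doc$complexes, function(e)
      data.frame(regulator_a = e[[1]], regulator_b = e[[2]], target = e[[3]],
                 sign_a = e[[4]], sign_b = e[[5]], stringsAsFactors = FALSE)))
  }
  network_spec(doc$nodes, edges, complexes)
}

#' @rdname read_network_spec
#' @param net an `sm_network` object.
#' @export
write_network_spec <- function(net, path) {
  doc <- list(nodes = as.list(net$nodes),
              edges = unname(apply(net$edges, 1, as.list)))
  if (!is.null(net$complexes))
    doc$complexes <- unname(apply(net$complexes, 1, as.list))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' True-adjacency lookup used by the scoring functions
#' @noRd
network_adjacency <- function(net) {
  adj <- matrix(0L, length(net$nodes), length(net$nodes),
                dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges))
    adj[cbind(net$edges$regulator, net$edges$target)] <- 1L
  adj
}
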