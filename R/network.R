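# Ego-network assembly and structural metrics.
#
# The roster has no pairwise acquaintance survey: alter-alter ties are
# inferred from shared interaction contexts (two alters are tied iff the
# sets of settings in which each interacts with the child intersect).  The
# ego is never part of the tie graph; components are connected components of
# the alter-alter graph, so a network of family members sharing the "family"
# context forms a single component even with the child removed.

#' Infer alter-alter ties from shared contexts
#'
#' Pair `(a, b)` is a tie iff `contexts(a)` and `contexts(b)` intersect.
#' Group nodes (e.g. a preschool class) participate through their contexts,
#' which connects them to the individually-named members of that setting.
#'
#' @param alters alter data.frame for a single ego (see [read_alter_table()]).
#' @return data.frame with character columns `from`, `to` (unordered pairs,
#'   each pair once, `from` < `to` in roster order).
#' @export
infer_ties <- function(alters) {
  n <- nrow(alters)
  ids <- alters$alter_id
  from <- character(0); to <- character(0)
  if (n >= 2L) {
    cx <- alters$contexts
    for (i in seq_len(n - 1L)) {
      ci <- cx[[i]]
      for (j in seq.int(i + 1L, n)) {
        if (any(ci %in% cx[[j]])) {
          from <- c(from, ids[i]); to <- c(to, ids[j])
        }
      }
    }
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' Assemble an ego network from one ego row and its alter roster
#'
#' Builds the derived structure for one child: the inferred alter-alter tie
#' set and the partition of alters into connected components.
#'
#' @param ego single-row ego data.frame (see [read_ego_table()]).
#' @param alters alter data.frame; every row must carry the same `ego_id`
#'   as `ego`.  An empty roster is invalid input.
#' @return An object of class `ego_network`: a list with elements `ego`,
#'   `alters`, `ties` (data.frame `from`/`to`), `membership` (named integer
#'   vector: component index per alter) and `n_components`.
#' @export
assemble_network <- function(ego, alters) {
  stopifnot(is.data.frame(ego), nrow(ego) == 1L)
  if (nrow(alters) == 0L)
    stop(sprintf("ego %s: empty alter roster; a network needs at least one alter",
                 ego$ego_id), call. = FALSE)
  if (!all(alters$ego_id == ego$ego_id))
    stop(sprintf("ego %s: alter rows with foreign ego_id", ego$ego_id),
         call. = FALSE)
  if (anyDuplicated(alters$alter_id))
    stop(sprintf("ego %s: duplicate alter_id", ego$ego_id), call. = FALSE)
  ties <- infer_ties(alters)
  membership <- component_membership(alters$alter_id, ties)
  structure(list(ego = ego, alters = alters, ties = ties,
                 membership = membership,
                 n_components = max(membership)),
            class = "ego_network")
}

# connected components of the alter-alter graph via igraph
component_membership <- function(ids, ties) {
  g <- igraph::graph_from_data_frame(
    ties, directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  out <- as.integer(comp[ids])
  names(out) <- ids
  out
}

#' Network size
#'
#' Total number of unique individuals and groups in the roster.
#'
#' @param net an `ego_network`.
#' @return integer count.
#' @export
network_size <- function(net) nrow(net$alters)

#' Density of the alter-alter graph
#'
#' `2 * T / (N * (N - 1))` where `T` is the number of ties and `N` the
#' network size; 1 means every pair of alters shares a setting.  Undefined
#' (NA) for `N < 2`.
#'
#' @param n_ties number of alter-alter ties.
#' @param n_alters network size.
#' @return numeric in `[0, 1]`, or `NA` when `N < 2`.
#' @export
network_density <- function(n_ties, n_alters) {
  if (n_alters < 2L) return(NA_real_)
  2 * n_ties / (n_alters * (n_alters - 1))
}

#' Connected components of an ego network
#'
#' @param net an `ego_network`.
#' @return list with `membership` (named integer vector) and `n_components`.
#' @export
find_components <- function(net) {
  list(membership = net$membership, n_components = net$n_components)
}

#' Component ratio
#'
#' `(C - 1) / (N - 1)`: a size-normalized fragmentation measure; 0 for a
#' single component, 1 when every alter is isolated.  Undefined for `N = 1`.
#'
#' @param n_components number of components `C`.
#' @param n_alters network size `N` (requires `1 <= C <= N`).
#' @return numeric in `[0, 1]`, or `NA` when `N < 2`.
#' @export
component_ratio <- function(n_components, n_alters) {
  stopifnot(n_components >= 1L, n_components <= n_alters)
  if (n_alters < 2L) return(NA_real_)
  (n_components - 1) / (n_alters - 1)
}

#' Convert an ego network to an igraph object
#'
#' The graph has a node for the ego plus one per alter; the ego is connected
#' to every alter (spokes) and alter-alter edges are the inferred ties.
#'
#' @param net an `ego_network`.
#' @param include_ego include the ego node and its spokes (default `TRUE`).
#' @return an `igraph` graph.
#' @export
as_igraph <- function(net, include_ego = TRUE) {
  ids <- net$alters$alter_id
  vdf <- data.frame(name = ids,
                    role = "alter",
                    is_group = net$alters$is_group,
                    stringsAsFactors = FALSE)
  edf <- net$ties
  if (include_ego) {
    ego_id <- net$ego$ego_id
    vdf <- rbind(data.frame(name = ego_id, role = "ego", is_group = FALSE,
                            stringsAsFactors = FALSE), vdf)
    edf <- rbind(data.frame(from = rep(ego_id, length(ids)), to = ids,
                            stringsAsFactors = FALSE), edf)
  }
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' Export an ego network graph
#'
#' Writes the star-plus-ties graph (ego spokes plus inferred alter ties)
#' as a plain edge list or GraphML.
#'
#' @param net an `ego_network`.
#' @param path output path.
#' @param format `"edgelist"` (two-column delimited text with header) or
#'   `"graphml"`.
#' @param include_ego include the ego node and spokes.
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("edgelist", "graphml"),
                         include_ego = TRUE) {
  format <- match.arg(format)
  g <- as_igraph(net, include_ego = include_ego)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    utils::write.table(data.frame(from = el[, 1], to = el[, 2]),
                       path, sep = ",", row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' @export
print.ego_network <- function(x, ...) {
  cat(sprintf("Ego network for '%s' (age %.1f months)\n",
              x$ego$ego_id, x$ego$age_months))
  cat(sprintf("  alters: %d (%d group node%s)\n", nrow(x$alters),
              sum(x$alters$is_group), if (sum(x$alters$is_group) == 1) "" else "s"))
  cat(sprintf("  ties: %d   components: %d   density: %s\n",
              nrow(x$ties), x$n_components,
              format(round(network_density(nrow(x$ties), nrow(x$alters)), 3))))
  invisible(x)
}

#' @export
plot.ego_network <- function(x, include_ego = TRUE, ...) {
  g <- as_igraph(x, include_ego = include_ego)
  cols <- ifelse(igraph::V(g)$role == "ego", "steelblue",
                 ifelse(igraph::V(g)$is_group, "orange", "grey70"))
  igraph::plot.igraph(g, vertex.color = cols, vertex.label.cex = 0.7, ...)
  invisible(x)
}
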