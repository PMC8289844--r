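net_weights <- function(net) {
  if (inherits(net, "item_network")) net$weights else as.matrix(net)
}

#' Global strength of a network
#'
#' Sum of absolute edge weights over unique node pairs.
#'
#' @param net an `item_network` (or weight matrix).
#' @return Non-negative scalar.
#' @export
global_strength <- function(net) {
  W <- net_weights(net)
  sum(abs(W[upper.tri(W)]))
}

#' Node strength centrality
#'
#' Per node, the sum of absolute weights of its incident edges.
#'
#' @inheritParams global_strength
#' @return Named numeric vector over nodes.
#' @export
node_strength <- function(net) {
  W <- net_weights(net)
  colSums(abs(W))
}

#' Bridge strength centrality
#'
#' Per node, the sum of absolute incident edge weights whose other endpoint
#' lies in a *different* community. With the default two-community
#' assignment this measures each item's direct connectivity to the other
#' questionnaire domain.
#'
#' @inheritParams global_strength
#' @param communities named character vector of community labels per node;
#'   defaults to the network's own labels.
#' @return Named numeric vector over nodes.
#' @export
bridge_strength <- function(net, communities = NULL) {
  W <- net_weights(net)
  labels <- colnames(W)
  if (is.null(communities) && inherits(net, "item_network"))
    communities <- net$communities
  if (is.null(communities)) stop("community labels are required")
  communities <- communities[labels]
  if (anyNA(communities))
    stop("unlabeled node(s): ",
         paste(labels[is.na(communities)], collapse = ", "))
  cross <- outer(communities, communities, FUN = "!=")
  colSums(abs(W) * cross)
}

#' Centrality table
#'
#' Strength and bridge strength for every node in one data frame.
#'
#' @inheritParams bridge_strength
#' @return Data frame with columns `node`, `strength`, `bridge_strength`.
#' @export
centrality_table <- function(net, communities = NULL) {
  s <- node_strength(net)
  b <- bridge_strength(net, communities)
  data.frame(node = names(s), strength = unname(s),
             bridge_strength = unname(b), row.names = NULL)
}

#' Within/between-questionnaire average absolute edge values
#'
#' For each pair of scales (including a scale with itself) the mean of
#' `|omega_ij|` over *all* node pairs in the block -- zero edges count in the
#' denominator, which is what makes sparse between-questionnaire blocks
#' average close to zero. Within-scale blocks average over unique pairs; a
#' scale with fewer than two nodes has an undefined within-block entry
#' (`NA`).
#'
#' @inheritParams global_strength
#' @param scales named character vector of scale membership per node, or an
#'   [item_catalog()].
#' @return A symmetric scales x scales matrix of class `block_summary`.
#' @export
block_summary <- function(net, scales) {
  W <- net_weights(net)
  labels <- colnames(W)
  if (inherits(scales, "item_catalog"))
    scales <- stats::setNames(scales$scale, scales$item_id)
  scales <- scales[labels]
  if (anyNA(scales))
    stop("node(s) without a scale assignment: ",
         paste(labels[is.na(scales)], collapse = ", "))
  lev <- unique(scales)
  out <- matrix(NA_real_, length(lev), length(lev),
                dimnames = list(lev, lev))
  A <- abs(W)
  for (a in seq_along(lev)) {
    for (b in a:length(lev)) {
      ia <- which(scales == lev[a])
      ib <- which(scales == lev[b])
      if (a == b) {
        if (length(ia) < 2) next
        blk <- A[ia, ia, drop = FALSE]
        val <- sum(blk[upper.tri(blk)]) / choose(length(ia), 2)
      } else {
        val <- mean(A[ia, ib, drop = FALSE])
      }
      out[a, b] <- out[b, a] <- val
    }
  }
  structure(out, class = c("block_summary", "matrix"),
            denominator = "all pairs (zero edges included)")
}

#' Strongest edges of a network
#'
#' Edges ranked by absolute weight, descending; ties break lexicographically
#' on the node-label pair. Only nonzero edges are listed.
#'
#' @inheritParams global_strength
#' @param k number of edges to return (capped at the edge count).
#' @return Data frame with columns `node_i`, `node_j`, `weight`.
#' @export
top_edges <- function(net, k = 10) {
  stopifnot(k >= 1)
  W <- net_weights(net)
  labels <- colnames(W)
  ut <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  if (nrow(ut) == 0)
    return(data.frame(node_i = character(), node_j = character(),
                      weight = numeric()))
  df <- data.frame(node_i = labels[ut[, 1]], node_j = labels[ut[, 2]],
                   weight = W[ut], stringsAsFactors = FALSE)
  ord <- order(-abs(df$weight), df$node_i, df$node_j)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, min(k, nrow(df)))
}
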