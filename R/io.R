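#' Read a paired panel from long-format delimited text
#'
#' Expected columns: `subject_id`, `wave` (1 or 2), `item_id`, `response`
#' (empty = missing). Validation rejects duplicate `(subject, wave, item)`
#' rows, items absent from the catalog, responses outside an item's category
#' range, and subjects present in only one wave (listed by name).
#'
#' @param path CSV file path.
#' @param catalog an [item_catalog()] defining items and category counts.
#' @return A `paired_panel`.
#' @export
read_panel <- function(path, catalog) {
  catalog <- validate_item_catalog(catalog)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(subject_id = "character",
                                item_id = "character"))
  needed <- c("subject_id", "wave", "item_id", "response")
  if (!all(needed %in% names(df)))
    stop("panel file must have columns: ", paste(needed, collapse = ", "))
  if (!all(df$wave %in% c(1L, 2L)))
    stop("wave must be 1 or 2")
  unknown <- setdiff(unique(df$item_id), catalog$item_id)
  if (length(unknown))
    stop("unknown item(s) in panel: ", paste(unknown, collapse = ", "))
  key <- paste(df$subject_id, df$wave, df$item_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject, wave, item) rows, e.g. ",
         gsub("\r", "/", key[duplicated(key)][1]))

  ncat <- stats::setNames(catalog$n_categories, catalog$item_id)
  obs <- !is.na(df$response)
  bad <- obs & (df$response < 0 | df$response > ncat[df$item_id] - 1L |
                  df$response != floor(df$response))
  if (any(bad)) {
    i <- which(bad)[1]
    stop("response ", df$response[i], " out of range for item ",
         df$item_id[i], " (subject ", df$subject_id[i], ")")
  }

  subj1 <- unique(df$subject_id[df$wave == 1L])
  subj2 <- unique(df$subject_id[df$wave == 2L])
  lonely <- c(setdiff(subj1, subj2), setdiff(subj2, subj1))
  if (length(lonely))
    stop("subject(s) present in only one wave: ",
         paste(sort(lonely), collapse = ", "))

  subjects <- sort(unique(df$subject_id))
  items <- catalog$item_id
  build <- function(w) {
    m <- matrix(NA_integer_, length(subjects), length(items),
                dimnames = list(subjects, items))
    sub <- df[df$wave == w & obs, , drop = FALSE]
    m[cbind(match(sub$subject_id, subjects), match(sub$item_id, items))] <-
      as.integer(sub$response)
    m
  }
  new_paired_panel(subjects, build(1L), build(2L), catalog)
}

#' Write a paired panel as delimited text
#'
#' `format = "long"` writes one row per `(subject, wave, item)` cell with an
#' empty `response` for missing values; `format = "wide"` writes one row per
#' subject-wave with one column per item.
#'
#' @param panel a `paired_panel`.
#' @param path output CSV path.
#' @param format `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, format = c("long", "wide")) {
  format <- match.arg(format)
  items <- colnames(panel$wave1)
  if (format == "long") {
    long_one <- function(m, w) {
      data.frame(
        subject_id = rep(panel$subject_ids, times = length(items)),
        wave = w,
        item_id = rep(items, each = length(panel$subject_ids)),
        response = as.vector(m),
        stringsAsFactors = FALSE
      )
    }
    out <- rbind(long_one(panel$wave1, 1L), long_one(panel$wave2, 2L))
    out <- out[order(out$subject_id, out$wave, out$item_id), ]
    write.csv(out, path, row.names = FALSE, na = "")
  } else {
    wide_one <- function(m, w)
      data.frame(subject_id = panel$subject_ids, wave = w, m,
                 check.names = FALSE, stringsAsFactors = FALSE)
    write.csv(rbind(wide_one(panel$wave1, 1L), wide_one(panel$wave2, 2L)),
              path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Write or read an estimated network as JSON
#'
#' Dense weight matrix with node labels, plus selection metadata (chosen
#' penalty, gamma, the full (lambda, EBIC, edge-count) path, the EBIC sample
#' size, and community labels).
#'
#' @param net an `item_network`.
#' @param path JSON file path.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns an `item_network`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "item_network"))
  payload <- list(
    node_labels = net$node_labels,
    communities = as.list(net$communities),
    weights = net$weights,
    selected_lambda = net$selected_lambda,
    gamma = net$gamma,
    n_used = net$n_used,
    ebic_path = net$ebic_path,
    settings = net$settings
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- as.matrix(x$weights)
  dimnames(W) <- list(x$node_labels, x$node_labels)
  communities <- if (length(x$communities))
    unlist(x$communities) else NULL
  structure(list(
    weights = W, precision = NULL,
    selected_lambda = if (is.null(x$selected_lambda)) NA_real_
                      else x$selected_lambda,
    gamma = x$gamma,
    ebic_path = as.data.frame(x$ebic_path),
    n_used = x$n_used, node_labels = x$node_labels,
    communities = communities, correlation = NULL, repaired = NA,
    settings = x$settings
  ), class = "item_network")
}

#' Write a network as a weighted edge list
#'
#' One row per nonzero edge: `node_i`, `node_j`, `weight` -- the plain-text
#' format common to graph tooling.
#'
#' @inheritParams write_network
#' @export
write_edge_list <- function(net, path) {
  W <- net_weights(net)
  labels <- colnames(W)
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  df <- data.frame(node_i = labels[idx[, 1]], node_j = labels[idx[, 2]],
                   weight = W[idx])
  write.csv(df[order(df$node_i, df$node_j), ], path, row.names = FALSE)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' Dense true partials and precisions per wave, thresholds, coupling, and
#' the planted wave-2 changes.
#'
#' @param truth a [build_true_network()] result.
#' @param path JSON file path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  payload <- list(
    items = truth$catalog$item_id,
    partials_w1 = truth$partials_w1, partials_w2 = truth$partials_w2,
    precisions_w1 = truth$precisions_w1, precisions_w2 = truth$precisions_w2,
    thresholds_w1 = truth$thresholds_w1, thresholds_w2 = truth$thresholds_w2,
    cross_wave_rho = as.list(truth$cross_wave_rho),
    planted_changes = truth$planted_changes,
    ridge_delta = as.list(truth$ridge_delta)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
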