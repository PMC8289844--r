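#' Item catalog
#'
#' An item catalog describes every questionnaire item entering the analysis:
#' which scale it belongs to, the community label used for bridge statistics,
#' how many response categories it has, whether a higher raw response means a
#' worse outcome (`keyed_direction = +1`) or a better one (`-1`), an optional
#' clinical cutoff for its scale total, and a scoring offset added per item
#' when totals are formed (five-point items stored as 0--4 but scored 1--5
#' carry `score_offset = 1`).
#'
#' @param item_id character vector of unique item labels.
#' @param scale scale membership per item (e.g. `"DEP"`, `"ANX"`, `"ISO"`).
#' @param community community label per item used by bridge strength.
#' @param n_categories integer number of response categories (>= 2) per item.
#' @param keyed_direction `+1` or `-1` per item.
#' @param cutoff optional numeric clinical cutoff per item's scale (the lower
#'   bound of the "cutoff a/b" convention; totals strictly above it count as
#'   exceeding the cutoff). `NA` when the scale has none.
#' @param score_offset numeric offset added to each raw response when scoring.
#'
#' @return A data frame of class `item_catalog`.
#' @seealso [default_item_catalog()]
#' @export
item_catalog <- function(item_id, scale, community, n_categories,
                         keyed_direction, cutoff = NA_real_,
                         score_offset = 0) {
  cat <- data.frame(
    item_id = as.character(item_id),
    scale = as.character(scale),
    community = as.character(community),
    n_categories = as.integer(n_categories),
    keyed_direction = as.integer(keyed_direction),
    cutoff = as.numeric(cutoff),
    score_offset = as.numeric(score_offset),
    stringsAsFactors = FALSE
  )
  validate_item_catalog(cat)
}

validate_item_catalog <- function(cat) {
  stopifnot(is.data.frame(cat))
  needed <- c("item_id", "scale", "community", "n_categories",
              "keyed_direction", "cutoff", "score_offset")
  missing_cols <- setdiff(needed, names(cat))
  if (length(missing_cols))
    stop("item catalog is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(cat$item_id))
    stop("item_ids must be unique; duplicated: ",
         paste(unique(cat$item_id[duplicated(cat$item_id)]), collapse = ", "))
  if (any(cat$n_categories < 2L))
    stop("every item needs at least 2 response categories")
  if (!all(cat$keyed_direction %in% c(-1L, 1L)))
    stop("keyed_direction must be +1 or -1")
  class(cat) <- c("item_catalog", "data.frame")
  cat
}

#' Default 41-item catalog
#'
#' The default panel mirrors a geriatric mental-health battery: 15 binary
#' depression items (DEP, scored 0/1, scale cutoff 4/5), 20 binary anxiety
#' items (ANX, cutoff 10/11), and 6 five-point social-isolation items (ISO,
#' stored 0--4 and scored 1--5, higher = better, hence keyed `-1`). DEP and
#' ANX items share the `affective` community; ISO items form the `isolation`
#' community used by bridge-strength statistics.
#'
#' @return An [item_catalog()] with 41 rows.
#' @export
default_item_catalog <- function() {
  item_catalog(
    item_id = c(sprintf("dep%02d", 1:15),
                sprintf("anx%02d", 1:20),
                sprintf("iso%02d", 1:6)),
    scale = rep(c("DEP", "ANX", "ISO"), c(15, 20, 6)),
    community = rep(c("affective", "isolation"), c(35, 6)),
    n_categories = rep(c(2L, 2L, 5L), c(15, 20, 6)),
    keyed_direction = rep(c(1L, 1L, -1L), c(15, 20, 6)),
    cutoff = rep(c(4, 10, NA), c(15, 20, 6)),
    score_offset = rep(c(0, 0, 1), c(15, 20, 6))
  )
}

#' Read or write an item catalog as YAML
#'
#' The YAML layout is a list of per-item records with the same fields as
#' [item_catalog()].
#'
#' @param path file path.
#' @return `read_item_catalog()` returns an [item_catalog()];
#'   `write_item_catalog()` returns `path` invisibly.
#' @export
read_item_catalog <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- lapply(raw$items, function(x) {
    data.frame(
      item_id = x$item_id, scale = x$scale, community = x$community,
      n_categories = as.integer(x$n_categories),
      keyed_direction = as.integer(x$keyed_direction),
      cutoff = if (is.null(x$cutoff)) NA_real_ else as.numeric(x$cutoff),
      score_offset = if (is.null(x$score_offset)) 0 else
        as.numeric(x$score_offset),
      stringsAsFactors = FALSE
    )
  })
  validate_item_catalog(do.call(rbind, rows))
}

#' @rdname read_item_catalog
#' @param catalog an [item_catalog()].
#' @export
write_item_catalog <- function(catalog, path) {
  catalog <- validate_item_catalog(catalog)
  items <- lapply(seq_len(nrow(catalog)), function(i) {
    rec <- list(
      item_id = catalog$item_id[i],
      scale = catalog$scale[i],
      community = catalog$community[i],
      n_categories = catalog$n_categories[i],
      keyed_direction = catalog$keyed_direction[i],
      score_offset = catalog$score_offset[i]
    )
    if (!is.na(catalog$cutoff[i])) rec$cutoff <- catalog$cutoff[i]
    rec
  })
  yaml::write_yaml(list(items = items), path)
  invisible(path)
}
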